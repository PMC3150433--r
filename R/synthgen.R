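#' Specification for a synthetic codon alignment
#'
#' Describes an in-frame codon alignment simulated on a known tree, with a
#' tunable synonymous:nonsynonymous rate ratio, taxon-group-specific
#' third-position base composition, per-fragment missing taxa and a plan of
#' clean (and optionally staggered) shared deletions. The generator exists so
#' that every operation in the package can be validated against planted
#' structure: known tree, known synonymous load, known bias groups, known
#' indels.
#'
#' @param tree newick text or `phylo` with branch lengths in nonsynonymous
#'   substitutions per site.
#' @param n_fragments number of gene fragments.
#' @param n_codons codons per fragment (scalar or vector of length
#'   `n_fragments`).
#' @param syn_rate_multiplier ratio of synonymous to nonsynonymous rate
#'   (0 = no synonymous change; arthropod-style data are strongly
#'   synonymously saturated, e.g. 10).
#' @param nt3_bias named list of bias groups, each
#'   `list(taxa = <labels>, freq = c(A=,C=,G=,T=))` with `freq` summing
#'   to 1; taxa outside every group draw synonymous states uniformly.
#' @param missing_taxa named list: fragment name -> taxa whose rows are
#'   rendered entirely `?` for that fragment.
#' @param indel_plan list of entries
#'   `list(fragment =, codon_start =, codon_end =, taxa =, staggered =)`;
#'   see [inject_indels()].
#' @param seed integer; all randomness flows from it.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(tree, n_fragments = 4L, n_codons = 100L,
                     syn_rate_multiplier = 10, nt3_bias = list(),
                     missing_taxa = list(), indel_plan = list(),
                     seed = 1L) {
  phy <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
  if (is.null(phy$edge.length))
    stop("tree must have branch lengths", call. = FALSE)
  n_codons <- rep_len(as.integer(n_codons), n_fragments)
  if (syn_rate_multiplier < 0) stop("rates must be >= 0", call. = FALSE)
  for (g in nt3_bias) {
    if (abs(sum(g$freq) - 1) > 1e-6)
      stop("bias frequencies must sum to 1", call. = FALSE)
    if (!all(g$taxa %in% phy$tip.label))
      stop("bias group names a taxon not in the tree", call. = FALSE)
  }
  frag_names <- sprintf("frag%02d", seq_len(n_fragments))
  if (length(missing_taxa) && !all(names(missing_taxa) %in% frag_names))
    stop("missing_taxa names must be fragment names (frag01, ...)",
         call. = FALSE)
  structure(list(tree = phy, n_fragments = as.integer(n_fragments),
                 n_codons = n_codons, frag_names = frag_names,
                 syn_rate_multiplier = syn_rate_multiplier,
                 nt3_bias = nt3_bias, missing_taxa = missing_taxa,
                 indel_plan = indel_plan, seed = as.integer(seed)),
            class = "sim_spec")
}

# stationary codon weights for one amino-acid family under a group's nt3 bias
family_codon_weights <- function(codons, freq) {
  nt3 <- substr(codons, 3L, 3L)
  w <- freq[nt3]
  if (sum(w) == 0) w <- rep(1, length(w))
  w / sum(w)
}

#' Simulate a codon alignment on a known tree
#'
#' Codon sequences are evolved along the tree with an amino-acid replacement
#' process layered over a within-family synonymous process. On each edge of
#' length `b`, a site's amino acid changes with probability `1 - exp(-b)`
#' (to a uniformly chosen different amino acid); independently its
#' synonymous state is redrawn with probability
#' `1 - exp(-syn_rate_multiplier * b)`. Whenever a codon is (re)drawn, it is
#' sampled from the amino acid's codon family with weights proportional to
#' the receiving lineage's target third-position frequencies (`nt3_bias` of
#' the taxon group below the edge, uniform otherwise) -- this is what creates
#' fast, compositionally biased synonymous change on top of conservative
#' nonsynonymous change. With `syn_rate_multiplier = 0` a codon passes to the
#' descendant unchanged unless the amino acid itself changed.
#'
#' Stop codons never arise (amino acids are drawn from the 20 sense
#' families; serine uses its Ser1/Ser2 components as separate families, so
#' synonymous redraw never crosses the TCN/AGY boundary).
#'
#' @param spec a [sim_spec()].
#' @return a [nuc_matrix()] with one charset per fragment (all flagged as
#'   fragments), the spec recorded as attribute `"sim_spec"`.
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, simulate_alignment_impl(spec))
}

simulate_alignment_impl <- function(spec) {
  phy <- ape::reorder.phylo(spec$tree, "postorder")
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  edges <- phy$edge[rev(seq_len(nrow(phy$edge))), , drop = FALSE]  # preorder
  elen <- phy$edge.length[rev(seq_len(nrow(phy$edge)))]

  fams <- cached_families(standard_code())
  n_fam <- length(fams)   # 21 families incl. Ser1/Ser2 as separate states

  # group lookup: every node gets the bias of the group all its tips share
  node_group <- rep(NA_integer_, ntip + phy$Nnode)
  tip_group <- rep(NA_integer_, ntip)
  for (gi in seq_along(spec$nt3_bias))
    tip_group[match(spec$nt3_bias[[gi]]$taxa, phy$tip.label)] <- gi
  node_tips <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) node_tips[[i]] <- i
  for (r in seq_len(nrow(phy$edge))) {  # postorder accumulation
    p <- phy$edge[r, 1]; ch <- phy$edge[r, 2]
    node_tips[[p]] <- c(node_tips[[p]], node_tips[[ch]])
  }
  for (v in seq_along(node_tips)) {
    g <- unique(tip_group[node_tips[[v]]])
    if (length(g) == 1L && !is.na(g)) node_group[v] <- g
  }
  draw_codon <- function(fam_idx, node) {
    fam <- fams[[fam_idx]]
    g <- node_group[node]
    if (is.na(g)) {
      sample(fam$codons, 1L)
    } else {
      sample(fam$codons, 1L,
             prob = family_codon_weights(fam$codons,
                                         spec$nt3_bias[[g]]$freq))
    }
  }

  frag_seqs <- vector("list", spec$n_fragments)
  for (f in seq_len(spec$n_fragments)) {
    ns <- spec$n_codons[f]
    fam_state <- matrix(NA_integer_, nrow = ntip + phy$Nnode, ncol = ns)
    codon_state <- matrix(NA_character_, nrow = ntip + phy$Nnode, ncol = ns)
    fam_state[root, ] <- sample.int(n_fam, ns, replace = TRUE)
    codon_state[root, ] <- vapply(fam_state[root, ], draw_codon,
                                  character(1), node = root)
    for (r in seq_len(nrow(edges))) {
      p <- edges[r, 1]; ch <- edges[r, 2]; b <- elen[r]
      p_ns <- 1 - exp(-b)
      p_syn <- 1 - exp(-spec$syn_rate_multiplier * b)
      fam_ch <- fam_state[p, ]
      cod_ch <- codon_state[p, ]
      ns_hit <- stats::runif(ns) < p_ns
      if (any(ns_hit)) {
        fam_ch[ns_hit] <- vapply(fam_ch[ns_hit], function(old) {
          sample(setdiff(seq_len(n_fam), old), 1L)
        }, integer(1))
      }
      syn_hit <- stats::runif(ns) < p_syn
      redraw <- ns_hit | syn_hit
      if (any(redraw)) {
        cod_ch[redraw] <- vapply(fam_ch[redraw], draw_codon, character(1),
                                 node = ch)
      }
      fam_state[ch, ] <- fam_ch
      codon_state[ch, ] <- cod_ch
    }
    tip_rows <- apply(codon_state[seq_len(ntip), , drop = FALSE], 1L,
                      paste0, collapse = "")
    miss <- spec$missing_taxa[[spec$frag_names[f]]]
    if (!is.null(miss)) {
      i <- match(miss, phy$tip.label)
      tip_rows[i] <- strrep("?", 3L * ns)
    }
    frag_seqs[[f]] <- tip_rows
  }
  seqs <- do.call(paste0, frag_seqs)
  offsets <- cumsum(c(0L, 3L * spec$n_codons))
  charsets <- stats::setNames(lapply(seq_len(spec$n_fragments), function(f)
    (offsets[f] + 1L):offsets[f + 1L]), spec$frag_names)
  out <- nuc_matrix(phy$tip.label, seqs, charsets = charsets,
                    fragments = spec$frag_names)
  attr(out, "sim_spec") <- spec
  out
}

#' Plant shared deletions into a simulated alignment
#'
#' Each `indel_plan` entry deletes a codon interval of one fragment (columns
#' set to `-`) in every taxon of the given set, with identical bounds -- a
#' clean, high-quality shared deletion. With `staggered = TRUE` the last
#' taxon of the set instead has its run extended by one codon, planting a
#' staggered decoy that the quality filter must reject.
#'
#' @param m a [nuc_matrix()] from [simulate_alignment()].
#' @param spec the [sim_spec()] carrying `indel_plan`.
#' @return the matrix with gaps planted.
#' @export
inject_indels <- function(m, spec) {
  mat <- as_char_matrix(m)
  for (ev in spec$indel_plan) {
    cols <- m$charsets[[ev$fragment]]
    if (is.null(cols)) stop("unknown fragment: ", ev$fragment, call. = FALSE)
    n_cod <- length(cols) %/% 3L
    if (ev$codon_start < 1L || ev$codon_end > n_cod ||
        ev$codon_end < ev$codon_start)
      stop("indel interval outside fragment", call. = FALSE)
    span <- cols[(3L * (ev$codon_start - 1L) + 1L):(3L * ev$codon_end)]
    idx <- match(ev$taxa, m$taxa)
    if (anyNA(idx)) stop("indel plan names unknown taxon", call. = FALSE)
    if (any(mat[idx, span] == "-"))
      stop("indel overlaps an existing gap", call. = FALSE)
    mat[idx, span] <- "-"
    if (isTRUE(ev$staggered)) {
      if (ev$codon_end >= n_cod)
        stop("staggered decoy needs a codon after the interval",
             call. = FALSE)
      extra <- cols[(3L * ev$codon_end + 1L):(3L * (ev$codon_end + 1L))]
      mat[idx[length(idx)], extra] <- "-"
    }
  }
  m$seqs <- chars_to_seqs(mat)
  m
}

#' Write a sim_spec as JSON next to a generated fixture
#'
#' @param spec a [sim_spec()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_sim_spec <- function(spec, path) {
  x <- spec
  x$tree <- ape::write.tree(spec$tree)
  x$frag_names <- NULL
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
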