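#' Trees with bootstrap support, decomposed into bipartitions
#'
#' A `supported_tree` is a leaf-labelled topology with per-clade bootstrap
#' percentages, held as a set of informative bipartitions (unrooted
#' semantics; both sides >= 2 leaves). Node matching and conflict accounting
#' all operate on bipartitions.
#'
#' @param newick newick text, a file path containing newick, or an
#'   `ape::phylo` object. Bootstrap percentages are read from internal node
#'   labels; trees without labels get absent (`NA`) supports, not zero.
#' @return an object of class `supported_tree` with elements `leaves`
#'   (character vector) and `bipartitions` (list of `side_a`, `side_b`,
#'   `support`).
#' @examples
#' tr <- parse_tree("((A,B)95,(C,D)87);")
#' length(tr$bipartitions)  # 1: AB|CD (its mirror is the same split)
#' @export
parse_tree <- function(newick) {
  phy <- if (inherits(newick, "phylo")) {
    newick
  } else if (length(newick) == 1L && !grepl("(", newick, fixed = TRUE) &&
             file.exists(newick)) {
    ape::read.tree(newick)
  } else {
    tryCatch(ape::read.tree(text = newick),
             error = function(e) stop("malformed newick: ",
                                      conditionMessage(e), call. = FALSE))
  }
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("malformed newick input", call. = FALSE)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf label in tree", call. = FALSE)
  leaves <- phy$tip.label
  bips <- list()
  if (phy$Nnode >= 1L && length(leaves) >= 4L) {
    pp <- ape::prop.part(phy)
    labs <- attr(pp, "labels")
    supports <- phy$node.label
    for (i in seq_along(pp)) {
      side_a <- labs[pp[[i]]]
      side_b <- setdiff(leaves, side_a)
      if (length(side_a) < 2L || length(side_b) < 2L) next
      sup <- NA_real_
      if (!is.null(supports) && i <= length(supports)) {
        v <- suppressWarnings(as.numeric(supports[i]))
        if (!is.na(v)) sup <- v
      }
      bips <- add_bipartition(bips, side_a, side_b, sup, leaves)
    }
  }
  structure(list(leaves = leaves, bipartitions = bips, phylo = phy),
            class = "supported_tree")
}

# canonical key: the sorted side NOT containing the alphabetically first leaf
bip_key <- function(side_a, side_b) {
  anchor <- min(c(side_a, side_b))
  side <- if (anchor %in% side_a) side_b else side_a
  paste(sort(side), collapse = "|")
}

add_bipartition <- function(bips, side_a, side_b, support, leaves) {
  key <- bip_key(side_a, side_b)
  for (i in seq_along(bips)) {
    if (bips[[i]]$key == key) {
      # same split seen twice (e.g. both root children): keep max support
      if (!is.na(support) &&
          (is.na(bips[[i]]$support) || support > bips[[i]]$support))
        bips[[i]]$support <- support
      return(bips)
    }
  }
  bips[[length(bips) + 1L]] <- list(side_a = sort(side_a),
                                    side_b = sort(side_b),
                                    support = support, key = key)
  bips
}

#' @export
print.supported_tree <- function(x, ...) {
  cat("<supported_tree> ", length(x$leaves), " leaves, ",
      length(x$bipartitions), " informative bipartitions\n", sep = "")
  invisible(x)
}

# Restrict bipartitions to a leaf subset; drop ones that become trivial;
# merge duplicates keeping the maximum support.
restrict_bipartitions <- function(bips, shared) {
  out <- list()
  for (b in bips) {
    a <- intersect(b$side_a, shared)
    d <- intersect(b$side_b, shared)
    if (length(a) < 2L || length(d) < 2L) next
    out <- add_bipartition(out, a, d, b$support, shared)
  }
  out
}

#' Classify candidate clades against a reference topology
#'
#' Implements bipartition-level support/conflict accounting. The reference's
#' "nodes" are its bipartitions with support at or above `strong` (all of its
#' bipartitions when the reference carries no support values, e.g. a plain
#' maximum-likelihood topology). After restricting both trees to their shared
#' leaves:
#' * **strongly supporting**: candidate bipartitions with support >= `strong`
#'   that match a reference node exactly;
#' * **conflicting**: candidate bipartitions with support >= `report` that
#'   match no reference node;
#' * **strongly conflicting**: the subset of conflicting ones with support
#'   >= `strong`.
#' Matching is bipartition identity after restriction, not mere
#' compatibility: on a fixed taxon set, a non-matching informative
#' bipartition of a binary candidate necessarily conflicts with some
#' reference clade.
#'
#' @param reference,candidate `supported_tree` objects; the candidate's
#'   leaves should be a subset of the reference's.
#' @param strong "strong" bootstrap threshold in percent (default 80).
#' @param report reporting threshold in percent (default 50).
#' @return object of class `support_comparison`: counts `n_strong_match`,
#'   `n_conflict`, `n_strong_conflict`, plus the classified bipartition
#'   lists.
#' @export
classify_support <- function(reference, candidate, strong = 80,
                             report = 50) {
  shared <- intersect(reference$leaves, candidate$leaves)
  if (!length(shared)) stop("disjoint leaf sets", call. = FALSE)
  ref <- restrict_bipartitions(reference$bipartitions, shared)
  cand <- restrict_bipartitions(candidate$bipartitions, shared)
  ref_has_support <- any(vapply(ref, function(b) !is.na(b$support),
                                logical(1)))
  ref_nodes <- if (ref_has_support) {
    Filter(function(b) !is.na(b$support) && b$support >= strong, ref)
  } else {
    ref
  }
  ref_keys <- vapply(ref_nodes, `[[`, character(1), "key")
  sup <- vapply(cand, function(b)
    if (is.na(b$support)) -Inf else b$support, numeric(1))
  matched <- vapply(cand, function(b) b$key %in% ref_keys, logical(1))
  strong_match <- cand[matched & sup >= strong]
  conflict <- cand[!matched & sup >= report]
  strong_conflict <- cand[!matched & sup >= strong]
  structure(list(
    n_strong_match = length(strong_match),
    n_conflict = length(conflict),
    n_strong_conflict = length(strong_conflict),
    thresholds = c(strong = strong, report = report),
    n_reference_nodes = length(ref_nodes),
    strong_match = strong_match, conflict = conflict,
    strong_conflict = strong_conflict),
    class = "support_comparison")
}

#' @export
print.support_comparison <- function(x, ...) {
  cat("<support_comparison> vs ", x$n_reference_nodes,
      " reference nodes (strong >= ", x$thresholds["strong"],
      "%, report >= ", x$thresholds["report"], "%)\n",
      "  strongly supporting: ", x$n_strong_match, "\n",
      "  conflicting:         ", x$n_conflict, "\n",
      "  strongly conflicting:", x$n_strong_conflict, "\n", sep = "")
  invisible(x)
}

#' Count genes supporting each reference node
#'
#' For every informative reference bipartition, counts how many single-gene
#' trees recover it with bootstrap support at or above `threshold`, after
#' restricting the reference to each gene's taxon sample. A reference node
#' that becomes trivial under a gene's taxa cannot be supported by that gene.
#'
#' @param reference a `supported_tree`.
#' @param single_gene_trees list of `supported_tree` objects.
#' @param threshold single-gene bootstrap threshold in percent (default 75).
#' @return data.frame with one row per reference bipartition: `key`,
#'   `support` (reference's own), `n_genes`.
#' @export
genes_supporting_nodes <- function(reference, single_gene_trees,
                                   threshold = 75) {
  ref <- reference$bipartitions
  counts <- integer(length(ref))
  for (g in single_gene_trees) {
    shared <- intersect(reference$leaves, g$leaves)
    gb <- restrict_bipartitions(g$bipartitions, shared)
    g_keys <- vapply(gb, function(b) {
      if (!is.na(b$support) && b$support >= threshold) b$key else NA_character_
    }, character(1))
    g_keys <- g_keys[!is.na(g_keys)]
    for (i in seq_along(ref)) {
      a <- intersect(ref[[i]]$side_a, shared)
      d <- intersect(ref[[i]]$side_b, shared)
      if (length(a) < 2L || length(d) < 2L) next
      if (bip_key(a, d) %in% g_keys) counts[i] <- counts[i] + 1L
    }
  }
  data.frame(
    key = vapply(ref, `[[`, character(1), "key"),
    support = vapply(ref, function(b) b$support, numeric(1)),
    n_genes = counts, stringsAsFactors = FALSE)
}

#' Per-gene phylogenetic utility
#'
#' The utility of a gene fragment is the number of reference nodes it
#' recovers with strong single-gene bootstrap support, per kilobase of
#' sequence, corrected for taxa missing from that fragment:
#' \deqn{U = \frac{G}{L \times 10^{-3}} \times \frac{T}{T - m}}
#' where `G` is the number of nodes recovered with BP >= 75, `L` the
#' fragment length in nucleotides, `m` the number of missing taxa and `T`
#' the total taxon count (80 in the study design this reproduces).
#'
#' @param G count of nodes recovered (BP >= threshold).
#' @param L fragment length in nucleotides (> 0).
#' @param m number of taxa entirely missing for the fragment.
#' @param total_taxa total taxa in the study (default 80).
#' @return the dimensionless utility score.
#' @examples
#' utility(10, 1000, 0)   # 10
#' utility(10, 1000, 16)  # 12.5 = 10 * 80 / 64
#' @export
utility <- function(G, L, m, total_taxa = 80) {
  if (any(L <= 0)) stop("L must be positive", call. = FALSE)
  if (any(m >= total_taxa)) stop("m must be < total_taxa", call. = FALSE)
  if (any(m < 0) || any(G < 0)) stop("G and m must be non-negative",
                                     call. = FALSE)
  (G / (L * 1e-3)) * (total_taxa / (total_taxa - m))
}

#' Build per-gene utility records from trees and a supermatrix
#'
#' Ties the support and matrix machinery together: for each fragment, `G` is
#' the number of reference bipartitions recovered by that gene's tree at
#' `threshold`, `L` the fragment charset size, and `m` the number of taxa
#' whose fragment row consists entirely of missing symbols (`?`, `-`, `N`).
#'
#' @param reference a `supported_tree`.
#' @param gene_trees named list of `supported_tree`, names matching fragment
#'   charsets of `m`.
#' @param m a [nuc_matrix()] with fragment charsets.
#' @param threshold single-gene bootstrap threshold (default 75).
#' @param total_taxa total taxa (default `n_taxa(m)`).
#' @return data.frame: `gene_id`, `G`, `L`, `m`, `utility`.
#' @export
gene_utility <- function(reference, gene_trees, m, threshold = 75,
                         total_taxa = n_taxa(m)) {
  stopifnot(all(names(gene_trees) %in% names(m$charsets)))
  mat <- as_char_matrix(m)
  rows <- lapply(names(gene_trees), function(nm) {
    cols <- m$charsets[[nm]]
    sub <- mat[, cols, drop = FALSE]
    missing_taxa <- sum(apply(sub, 1L, function(r)
      all(r %in% c("?", "-", "N"))))
    tr <- gene_trees[[nm]]
    shared <- intersect(reference$leaves, tr$leaves)
    gb <- restrict_bipartitions(tr$bipartitions, shared)
    g_keys <- vapply(Filter(function(b) !is.na(b$support) &&
                              b$support >= threshold, gb),
                     `[[`, character(1), "key")
    G <- 0L
    for (b in reference$bipartitions) {
      a <- intersect(b$side_a, shared)
      d <- intersect(b$side_b, shared)
      if (length(a) >= 2L && length(d) >= 2L && bip_key(a, d) %in% g_keys)
        G <- G + 1L
    }
    data.frame(gene_id = nm, G = G, L = length(cols), m = missing_taxa,
               utility = utility(G, length(cols), missing_taxa, total_taxa),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Linear trend of utility on nonsynonymous rate
#'
#' Ordinary least-squares fit of per-gene utility against the fragment's
#' average nonsynonymous rate, with standard errors of both coefficients.
#'
#' @param records data.frame from [gene_utility()] (columns `gene_id`,
#'   `utility`).
#' @param rates a [rate_table()] with matching `fragment` names.
#' @return list: `slope`, `intercept`, `slope_sd`, `intercept_sd`, and the
#'   underlying `lm` fit.
#' @export
fit_utility_trend <- function(records, rates) {
  df <- merge(records, rates, by.x = "gene_id", by.y = "fragment")
  if (nrow(df) < 3L) stop("need at least 3 records", call. = FALSE)
  if (stats::var(df$rate) == 0)
    stop("zero rate variance", call. = FALSE)
  fit <- stats::lm(utility ~ rate, data = df)
  cf <- summary(fit)$coefficients
  list(slope = cf["rate", "Estimate"],
       intercept = cf["(Intercept)", "Estimate"],
       slope_sd = cf["rate", "Std. Error"],
       intercept_sd = cf["(Intercept)", "Std. Error"],
       fit = fit)
}
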