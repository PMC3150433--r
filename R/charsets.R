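#' Codon-position character sets
#'
#' Returns the column indices at a given codon position (nt1, nt2 or nt3),
#' using the per-column positions stored in the matrix. The three sets are
#' disjoint and their union is all columns.
#'
#' @param m a [nuc_matrix()].
#' @param pos codon position, 1, 2 or 3.
#' @return sorted integer vector of column indices.
#' @export
codon_position_columns <- function(m, pos) {
  if (!pos %in% 1:3) stop("`pos` must be 1, 2 or 3", call. = FALSE)
  which(m$codon_pos == as.integer(pos))
}

#' Leucine/arginine classification of first-position columns
#'
#' A first-position column belongs to `LRall1` if and only if at least one
#' taxon's codon at that column has at least one IUPAC resolution translating
#' to leucine or arginine — the only amino acids that can undergo synonymous
#' change at the first codon position. Codons containing `-`, `?` or `N` do
#' not trigger membership (they are unknowns, not evidence of an L/R
#' residue). First-position columns of incomplete codons fall into
#' `noLRall1`.
#'
#' @param m an in-frame [nuc_matrix()].
#' @param code a genetic code.
#' @return list with sorted integer vectors `LRall1` and `noLRall1`,
#'   a partition of the nt1 columns.
#' @export
lr_classify_columns <- function(m, code = standard_code()) {
  cod <- codon_blocks(m)
  mat <- as_char_matrix(m)
  lr_codons <- names(code)[code %in% c("L", "R")]
  memo <- new.env(parent = emptyenv())
  is_lr <- function(cd) {
    hit <- memo[[cd]]
    if (!is.null(hit)) return(hit)
    sym <- strsplit(cd, "")[[1]]
    out <- if (any(!sym %in% names(IUPAC)) || any(sym == "N")) {
      FALSE
    } else {
      res <- expand.grid(IUPAC[[sym[1]]], IUPAC[[sym[2]]], IUPAC[[sym[3]]],
                         stringsAsFactors = FALSE)
      any(paste0(res[[1]], res[[2]], res[[3]]) %in% lr_codons)
    }
    memo[[cd]] <- out
    out
  }
  lr_first <- integer(0)
  for (block in cod$complete) {
    codons <- unique(paste0(mat[, block[1]], mat[, block[2]],
                            mat[, block[3]]))
    if (any(vapply(codons, is_lr, logical(1))))
      lr_first <- c(lr_first, block[1])
  }
  nt1 <- codon_position_columns(m, 1L)
  list(LRall1 = sort(lr_first), noLRall1 = sort(setdiff(nt1, lr_first)))
}

#' Build one of the named character-set matrices
#'
#' Constructs the standard character sets used to separate synonymous from
#' nonsynonymous signal in an in-frame supermatrix. `noLRall1nt2` (nt2 plus
#' the non-L/R first positions) and `LRall1nt3` (nt3 plus the L/R first
#' positions) are complementary: together they reconstitute `nt123` exactly.
#' The `*_degen1` sets degenerate first, then slice (the result is identical
#' either way because degeneration is codon-local). `nt3_4foldsynon` is the
#' fourfold-synonymous third-position matrix of [fourfold_synon_matrix()].
#'
#' Apply the exclusion mask ([apply_exclusion()]) before building named sets.
#'
#' @param m an in-frame, masked [nuc_matrix()].
#' @param name one of `"nt123"`, `"nt1"`, `"nt2"`, `"nt3"`, `"LRall1"`,
#'   `"noLRall1"`, `"LRall1nt3"`, `"noLRall1nt2"`, `"nt123_degen1"`,
#'   `"nt3_degen1"`, `"LRall1nt3_degen1"`, `"nt3_4foldsynon"`.
#' @param code a genetic code.
#' @return a `nuc_matrix`.
#' @export
build_named_set <- function(m, name, code = standard_code()) {
  nt <- function(p) codon_position_columns(m, p)
  lr <- function() lr_classify_columns(m, code)
  slice <- function(x, cols) extract_submatrix(x, cols, name = name)
  switch(
    name,
    nt123 = slice(m, seq_len(m$n_cols)),
    nt1 = slice(m, nt(1)),
    nt2 = slice(m, nt(2)),
    nt3 = slice(m, nt(3)),
    LRall1 = slice(m, lr()$LRall1),
    noLRall1 = slice(m, lr()$noLRall1),
    LRall1nt3 = slice(m, sort(c(lr()$LRall1, nt(3)))),
    noLRall1nt2 = slice(m, sort(c(lr()$noLRall1, nt(2)))),
    nt123_degen1 = degen1_matrix(m, degen_map(code)),
    nt3_degen1 = slice(degen1_matrix(m, degen_map(code)), nt(3)),
    LRall1nt3_degen1 = slice(degen1_matrix(m, degen_map(code)),
                             sort(c(lr()$LRall1, nt(3)))),
    nt3_4foldsynon = fourfold_synon_matrix(m, code),
    stop("unknown character-set name: ", name, call. = FALSE)
  )
}

#' Per-fragment nonsynonymous rate table
#'
#' Holds the rate ranking used to bin gene fragments. `fragment` names must
#' match fragment charsets of the matrix the table is used with; `rate` is
#' nonsynonymous substitutions per site. Ranks (1 = fastest) follow
#' decreasing rate, ties broken by table order.
#'
#' @param fragment character vector of fragment names.
#' @param rate numeric vector of non-negative rates.
#' @return a `data.frame` with columns `fragment`, `rate`, `rank`.
#' @export
rate_table <- function(fragment, rate) {
  rate <- as.numeric(rate)
  if (any(rate < 0)) stop("rates must be non-negative", call. = FALSE)
  if (anyDuplicated(fragment)) stop("duplicate fragment id", call. = FALSE)
  ord <- order(-rate)
  rt <- data.frame(fragment = as.character(fragment), rate = rate,
                   stringsAsFactors = FALSE)
  rt$rank <- integer(nrow(rt))
  rt$rank[ord] <- seq_len(nrow(rt))
  rt
}

#' @rdname rate_table
#' @param path tab-separated file with columns fragment id and rate
#'   (header optional).
#' @export
read_rate_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\S+\t[0-9.eE+-]+\\s*$", first) ||
    is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][2])))
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  rate_table(df[[1]], df[[2]])
}

#' Bin rate-ranked fragments into contiguous, size-balanced groups
#'
#' Fragments are kept in rank order (fastest first) and split at `k - 1`
#' contiguous points chosen to minimise the maximum deviation of the bins'
#' character counts from `total / k`; ties are broken toward the earlier
#' split points. Character counts are the post-mask fragment charset sizes.
#' An explicit `breaks` vector (the last fragment rank of each bin except
#' the final one) overrides the balancing.
#'
#' @param m a masked [nuc_matrix()] with fragment charsets.
#' @param rt a [rate_table()] covering every fragment of `m`.
#' @param k number of bins (2 or 3, though any `k <=` fragment count works).
#' @param breaks optional integer vector of length `k - 1`: explicit split
#'   ranks.
#' @return list of `k` sorted column-index vectors, fastest bin first, with
#'   fragment ranks as the `"ranks"` attribute of each.
#' @export
rate_bins <- function(m, rt, k, breaks = NULL) {
  frags <- m$fragments
  if (!length(frags)) stop("matrix has no fragment charsets", call. = FALSE)
  missing_rate <- setdiff(frags, rt$fragment)
  if (length(missing_rate))
    stop("no rate for fragment(s): ", paste(missing_rate, collapse = ", "),
         call. = FALSE)
  if (k > length(frags))
    stop("k exceeds the number of fragments", call. = FALSE)
  rt <- rt[rt$fragment %in% frags, ]
  ord <- rt$fragment[order(rt$rank)]
  sizes <- vapply(ord, function(nm) length(m$charsets[[nm]]), integer(1))
  n <- length(sizes)
  if (is.null(breaks)) {
    target <- sum(sizes) / k
    combs <- utils::combn(n - 1L, k - 1L)
    best <- NULL
    best_dev <- Inf
    for (j in seq_len(ncol(combs))) {
      cut <- combs[, j]
      bounds <- c(0L, cut, n)
      bin_sizes <- vapply(seq_len(k), function(i)
        sum(sizes[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
      dev <- max(abs(bin_sizes - target))
      if (dev < best_dev) {   # strict: ties keep the earlier (first) split
        best_dev <- dev
        best <- cut
      }
    }
    breaks <- best
  }
  bounds <- c(0L, as.integer(breaks), n)
  lapply(seq_len(k), function(i) {
    nms <- ord[(bounds[i] + 1L):bounds[i + 1L]]
    cols <- sort(unlist(m$charsets[nms], use.names = FALSE))
    attr(cols, "ranks") <- (bounds[i] + 1L):bounds[i + 1L]
    attr(cols, "fragments") <- nms
    cols
  })
}
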