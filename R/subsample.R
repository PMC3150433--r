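# Seeded column shuffling and complementary fractional splits.
#
# A single Fisher-Yates pass from a seeded generator yields a uniform
# permutation, so one pass with a recorded seed is distribution-identical to
# repeated reshuffling; the seed makes every subsample reproducible.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Shuffle the columns of a matrix
#'
#' Permutes the column order by a uniform random permutation drawn from a
#' seeded generator. The column multiset is unchanged and every charset is
#' remapped through the permutation. The same seed always yields the same
#' permutation.
#'
#' @param m a [nuc_matrix()].
#' @param seed integer seed.
#' @return the shuffled `nuc_matrix`; the permutation (new order of original
#'   column indices) is attached as attribute `"permutation"`.
#' @export
shuffle_columns <- function(m, seed) {
  perm <- with_seed(seed, sample.int(m$n_cols))
  mat <- as_char_matrix(m)[, perm, drop = FALSE]
  remap <- integer(m$n_cols)
  remap[perm] <- seq_len(m$n_cols)
  charsets <- lapply(m$charsets, function(idx) sort(remap[idx]))
  out <- nuc_matrix(m$taxa, chars_to_seqs(mat), charsets = charsets,
                    exclusion = sort(remap[m$exclusion]),
                    fragments = character(0),   # shuffling breaks codon frame
                    codon_pos = m$codon_pos[perm])
  attr(out, "permutation") <- perm
  attr(out, "seed") <- seed
  out
}

#' Split a matrix into complementary fractional blocks
#'
#' Cuts a (typically pre-shuffled) matrix into consecutive column blocks of
#' sizes `floor(f_i * n)`, with remainder columns going to the last block.
#' The blocks are disjoint and jointly exhaust the columns, so each pair or
#' triple of outputs is a complementary split: e.g. `c(0.5, 0.5)` gives the
#' two halves of a 50% subsampling design, `c(0.85, 0.15)` an 85%/15% pair,
#' and `1` the full-size shuffled control.
#'
#' @param m a [nuc_matrix()], usually the output of [shuffle_columns()].
#' @param fractions numeric vector of proportions in (0, 1] summing to 1
#'   (within the rounding of one column).
#' @return list of `nuc_matrix` blocks; each carries a `"provenance"`
#'   attribute with its column indices in `m`.
#' @export
complementary_split <- function(m, fractions) {
  if (!length(fractions)) stop("fraction list empty", call. = FALSE)
  if (any(fractions <= 0 | fractions > 1))
    stop("each fraction must be in (0, 1]", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1 / max(m$n_cols, 1))
    stop("fractions must sum to 1", call. = FALSE)
  n <- m$n_cols
  sizes <- floor(fractions * n)
  sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
  bounds <- cumsum(c(0L, sizes))
  lapply(seq_along(sizes), function(i) {
    cols <- if (sizes[i] > 0) (bounds[i] + 1L):bounds[i + 1L] else integer(0)
    extract_submatrix(m, cols, name = sprintf("block%d_f%.3g", i,
                                              fractions[i]))
  })
}

#' One-call shuffled subsampling with a manifest
#'
#' Convenience wrapper: shuffles with the given seed, splits by `fractions`,
#' and returns blocks plus a manifest recording seed, fractions and the
#' original column indices of every block (the provenance needed to audit a
#' subsampling experiment).
#'
#' @inheritParams shuffle_columns
#' @inheritParams complementary_split
#' @param replicate_id integer tag recorded in the manifest; the effective
#'   seed is `seed + replicate_id` so replicates are independent but fully
#'   determined by `(seed, fractions, replicate_id)`.
#' @return list with `blocks` (list of `nuc_matrix`) and `manifest` (list).
#' @export
subsample_matrix <- function(m, fractions, seed, replicate_id = 0L) {
  eff <- as.integer(seed) + as.integer(replicate_id)
  sh <- shuffle_columns(m, eff)
  blocks <- complementary_split(sh, fractions)
  perm <- attr(sh, "permutation")
  manifest <- list(
    seed = as.integer(seed), replicate_id = as.integer(replicate_id),
    effective_seed = eff, fractions = fractions,
    n_cols = m$n_cols,
    block_columns = lapply(blocks, function(b)
      perm[attr(b, "provenance")$original_columns]))
  list(blocks = blocks, manifest = manifest)
}
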