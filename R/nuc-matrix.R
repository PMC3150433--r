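#' Aligned nucleotide matrix with character-set metadata
#'
#' `nuc_matrix()` builds the central container of the package: a taxa-labelled
#' aligned nucleotide matrix together with named character sets (typically one
#' per gene fragment), an exclusion set of column indices, and per-column codon
#' positions. All column indices are 1-based and inclusive, the R convention;
#' NEXUS I/O converts from/to the 1-based inclusive ranges of that format.
#'
#' The reading frame is global: column `c` has codon position
#' `(c - 1) %% 3 + 1` at construction. Operations that drop columns (masking,
#' slicing) carry the per-column codon positions along, so frame-aware
#' operations (degeneration, position subsets) always know which position each
#' surviving column occupies even when its codon is no longer complete.
#'
#' @param taxa character vector of unique taxon labels.
#' @param seqs character vector of aligned sequences, one per taxon, all the
#'   same length, over `{A,C,G,T, IUPAC ambiguity codes, '-', '?'}`.
#' @param charsets named list of strictly increasing integer vectors of column
#'   indices.
#' @param exclusion integer vector of column indices to be masked by
#'   [apply_exclusion()].
#' @param fragments character vector naming which charsets are gene fragments.
#'   Fragment charsets must be disjoint and consist of whole codons aligned to
#'   the global frame.
#' @param codon_pos optional integer vector (values 1/2/3) of per-column codon
#'   positions; defaults to the global frame.
#' @return an object of class `nuc_matrix`.
#' @examples
#' m <- nuc_matrix(c("t1", "t2"), c("ATGAAA", "ATGAAG"),
#'                 charsets = list(g1 = 1:6), fragments = "g1")
#' n_cols(m)
#' @export
nuc_matrix <- function(taxa, seqs, charsets = list(), exclusion = integer(0),
                       fragments = character(0), codon_pos = NULL) {
  taxa <- unname(as.character(taxa))
  seqs <- unname(as.character(seqs))
  if (length(taxa) != length(seqs))
    stop("`taxa` and `seqs` must have the same length", call. = FALSE)
  if (anyDuplicated(taxa))
    stop("duplicate taxon label: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "), call. = FALSE)
  nc <- if (length(seqs)) nchar(seqs[1]) else 0L
  if (length(seqs) && any(nchar(seqs) != nc))
    stop("alignment error: ragged rows (unequal sequence lengths)",
         call. = FALSE)
  if (is.null(codon_pos)) {
    codon_pos <- if (nc > 0) rep_len(1:3, nc) else integer(0)
  }
  if (length(codon_pos) != nc)
    stop("`codon_pos` must have one entry per column", call. = FALSE)
  charsets <- lapply(charsets, function(idx) sort(unique(as.integer(idx))))
  m <- structure(
    list(taxa = taxa, seqs = seqs, n_cols = as.integer(nc),
         charsets = charsets, exclusion = sort(unique(as.integer(exclusion))),
         fragments = as.character(fragments),
         codon_pos = as.integer(codon_pos)),
    class = "nuc_matrix")
  validate_nuc_matrix(m)
  m
}

validate_nuc_matrix <- function(m) {
  nc <- m$n_cols
  for (nm in names(m$charsets)) {
    idx <- m$charsets[[nm]]
    if (length(idx) && (min(idx) < 1L || max(idx) > nc))
      stop("metadata error: charset '", nm, "' has out-of-bounds columns",
           call. = FALSE)
  }
  if (length(m$exclusion) && (min(m$exclusion) < 1L || max(m$exclusion) > nc))
    stop("metadata error: exclusion set out of bounds", call. = FALSE)
  bad <- setdiff(m$fragments, names(m$charsets))
  if (length(bad))
    stop("unknown fragment charset: ", paste(bad, collapse = ", "),
         call. = FALSE)
  seen <- integer(0)
  for (nm in m$fragments) {
    idx <- m$charsets[[nm]]
    if (length(intersect(idx, seen)))
      stop("fragment charsets must be disjoint ('", nm, "' overlaps)",
           call. = FALSE)
    seen <- c(seen, idx)
    if (length(idx) %% 3L != 0L)
      stop("fragment '", nm, "' length not divisible by 3", call. = FALSE)
    pos <- m$codon_pos[idx]
    if (length(idx) && any(pos != rep_len(1:3, length(idx))))
      stop("fragment '", nm, "' is not in frame ",
           "(columns must form whole codons)", call. = FALSE)
  }
  invisible(m)
}

#' @export
print.nuc_matrix <- function(x, ...) {
  cat("<nuc_matrix> ", length(x$taxa), " taxa x ", x$n_cols, " columns\n",
      sep = "")
  if (length(x$charsets))
    cat("  charsets: ", paste(names(x$charsets), collapse = ", "), "\n",
        sep = "")
  if (length(x$fragments))
    cat("  fragments: ", length(x$fragments), "\n", sep = "")
  if (length(x$exclusion))
    cat("  exclusion: ", length(x$exclusion), " columns\n", sep = "")
  invisible(x)
}

#' @rdname nuc_matrix
#' @param m a `nuc_matrix`.
#' @export
n_cols <- function(m) m$n_cols

#' @rdname nuc_matrix
#' @export
n_taxa <- function(m) length(m$taxa)

#' Matrix view of the aligned sequences
#'
#' One character per cell, taxa in rows (rownames are the taxon labels).
#' @param m a `nuc_matrix`.
#' @return a character matrix.
#' @export
as_char_matrix <- function(m) {
  if (m$n_cols == 0L || n_taxa(m) == 0L) {
    out <- matrix(character(0), nrow = n_taxa(m), ncol = m$n_cols)
    rownames(out) <- m$taxa
    return(out)
  }
  out <- matrix(unlist(strsplit(m$seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = n_taxa(m), byrow = TRUE)
  rownames(out) <- m$taxa
  out
}

chars_to_seqs <- function(mat) {
  if (ncol(mat) == 0L) return(rep("", nrow(mat)))
  unname(apply(mat, 1L, paste0, collapse = ""))
}

#' Extract a column-sliced submatrix
#'
#' Slices the given columns (in increasing order), preserving taxon order and
#' re-indexing every charset to the new coordinates. The original column
#' indices are retained as the `"provenance"` attribute.
#'
#' @param m a `nuc_matrix`.
#' @param cols integer vector of column indices to keep (1-based).
#' @param name optional name recorded with the provenance.
#' @return a `nuc_matrix` over the selected columns.
#' @export
extract_submatrix <- function(m, cols, name = NULL) {
  cols <- sort(unique(as.integer(cols)))
  if (length(cols) && (min(cols) < 1L || max(cols) > m$n_cols))
    stop("column index out of range", call. = FALSE)
  remap <- integer(m$n_cols)
  remap[cols] <- seq_along(cols)
  mat <- as_char_matrix(m)[, cols, drop = FALSE]
  charsets <- lapply(m$charsets, function(idx) remap[intersect(idx, cols)])
  # fragments that lose columns are no longer guaranteed whole-codon
  frag_ok <- vapply(m$fragments, function(nm) {
    length(charsets[[nm]]) == length(m$charsets[[nm]])
  }, logical(1))
  out <- nuc_matrix(m$taxa, chars_to_seqs(mat), charsets = charsets,
                    exclusion = remap[intersect(m$exclusion, cols)],
                    fragments = m$fragments[frag_ok],
                    codon_pos = m$codon_pos[cols])
  attr(out, "provenance") <- list(name = name, original_columns = cols)
  out
}

#' Apply the character-exclusion mask
#'
#' Removes every column in the exclusion set and re-indexes all charsets.
#' Exactly `length(m$exclusion)` columns are removed. If the mask takes out
#' part of a codon, the surviving columns of that codon are set to `N` in
#' every taxon rather than silently re-framed: their codon identity is gone,
#' so degeneracy-aware operations must not interpret them.
#'
#' @param m a `nuc_matrix` with (possibly empty) exclusion set.
#' @return the masked `nuc_matrix`, with an empty exclusion set.
#' @export
apply_exclusion <- function(m) {
  if (!length(m$exclusion)) return(m)
  excl <- m$exclusion
  codon_id <- cumsum(m$codon_pos == 1L)   # consecutive-triplet grouping
  broken <- unique(codon_id[excl])
  keep <- setdiff(seq_len(m$n_cols), excl)
  mat <- as_char_matrix(m)
  partial <- setdiff(which(codon_id %in% broken), excl)
  if (length(partial)) mat[, partial] <- "N"
  out <- extract_submatrix(
    nuc_matrix(m$taxa, chars_to_seqs(mat), charsets = m$charsets,
               exclusion = integer(0), fragments = character(0),
               codon_pos = m$codon_pos),
    keep, name = "masked")
  # fragments survive if still whole-codon after masking
  frag_ok <- vapply(m$fragments, function(nm) {
    idx <- out$charsets[[nm]]
    length(idx) %% 3L == 0L &&
      (!length(idx) || all(out$codon_pos[idx] == rep_len(1:3, length(idx))))
  }, logical(1))
  out$fragments <- m$fragments[frag_ok]
  validate_nuc_matrix(out)
  out
}
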