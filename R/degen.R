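#' degen1 codon degeneration
#'
#' degen1 replaces every codon by the maximally degenerate IUPAC codon of its
#' synonymous family, so that within-family (synonymous) differences become
#' invisible while nonsynonymous differences remain: `CAT -> CAY`,
#' `TTA -> YTN`, `AGA -> MGN`, `ATG -> ATG`. Over-degeneration is deliberate
#' and matches the published coding: `YTN` also covers Phe (TTY) and `MGN`
#' also covers Ser2 (AGY); the Ser1/Ser2 split itself is preserved
#' (`TCN` vs `AGY`).
#'
#' @section Totality and idempotence:
#' The mapping is total over codons drawn from `{A,C,G,T, IUPAC, '-', '?'}`
#' and idempotent. Codons containing `-` or `?` map to `NNN`. An ambiguous
#' codon is resolved by enumerating its IUPAC resolutions: if every
#' resolution yields the same degenerate codon, that codon is emitted;
#' a codon that is already a degen1 output (e.g. `YTN`, `CAY`) is a fixed
#' point; anything else (ambiguity spanning families) maps to `NNN`,
#' which never invents nonsynonymous signal. Stop codons map to `NNN`
#' (in-frame nuclear coding data should be stop-free; a warning is issued at
#' the matrix level).
#'
#' @name degen1
NULL

#' Build a degen1 map for a genetic code
#'
#' @param code a genetic code, see [standard_code()].
#' @return an environment memoising codon -> degenerate codon; use
#'   [degen1_codon()] to query it.
#' @export
degen_map <- function(code = standard_code()) {
  fams <- cached_families(code)
  base <- character(0)
  for (fam in fams) {
    cs <- do.call(rbind, strsplit(fam$codons, ""))
    deg <- paste0(iupac_symbol(cs[, 1]), iupac_symbol(cs[, 2]),
                  iupac_symbol(cs[, 3]))
    base[fam$codons] <- deg
  }
  base[names(code)[code == "*"]] <- "NNN"
  env <- new.env(parent = emptyenv())
  env$code <- code
  env$base <- base                      # the 64 unambiguous codons
  env$image <- unique(c(base, "NNN"))   # fixed points
  env$memo <- as.list(base)
  env
}

default_dm <- local({
  dm <- NULL
  function() {
    if (is.null(dm)) dm <<- degen_map(standard_code())
    dm
  }
})

#' Degenerate a single codon
#'
#' @param codon a 3-symbol codon, possibly containing IUPAC ambiguity codes,
#'   `-` or `?`.
#' @param dm a degen1 map from [degen_map()].
#' @return the 3-symbol degenerate codon.
#' @examples
#' degen1_codon("CAT")  # "CAY"
#' degen1_codon("TTA")  # "YTN"
#' @export
degen1_codon <- function(codon, dm = default_dm()) {
  codon <- toupper(codon)
  hit <- dm$memo[[codon]]
  if (!is.null(hit)) return(hit)
  out <- degen1_resolve(codon, dm)
  dm$memo[[codon]] <- out
  out
}

degen1_resolve <- function(codon, dm) {
  sym <- strsplit(codon, "")[[1]]
  if (length(sym) != 3L || any(!sym %in% names(IUPAC))) return("NNN")
  if (codon %in% dm$image) return(codon)      # already degenerate: fixed point
  res <- expand.grid(IUPAC[[sym[1]]], IUPAC[[sym[2]]], IUPAC[[sym[3]]],
                     stringsAsFactors = FALSE)
  outs <- unique(dm$base[paste0(res[[1]], res[[2]], res[[3]])])
  if (length(outs) == 1L) outs else "NNN"
}

#' Degenerate every codon of a matrix
#'
#' Applies [degen1_codon()] codon-by-codon to every row. Dimensions,
#' charsets and the exclusion set are unchanged. Columns whose codon is
#' incomplete (the frame was broken by masking or slicing) are set to `N`.
#'
#' @param m an in-frame [nuc_matrix()].
#' @param dm a degen1 map.
#' @return the degenerated `nuc_matrix`.
#' @export
degen1_matrix <- function(m, dm = default_dm()) {
  cod <- codon_blocks(m)
  mat <- as_char_matrix(m)
  out <- mat
  n_stop <- 0L
  stops <- names(dm$code)[dm$code == "*"]
  for (block in cod$complete) {
    codons <- paste0(mat[, block[1]], mat[, block[2]], mat[, block[3]])
    n_stop <- n_stop + sum(codons %in% stops)
    degen <- vapply(codons, degen1_codon, character(1), dm = dm,
                    USE.NAMES = FALSE)
    dchars <- matrix(unlist(strsplit(degen, ""), use.names = FALSE),
                     ncol = 3L, byrow = TRUE)
    out[, block] <- dchars
  }
  if (length(cod$orphans)) out[, cod$orphans] <- "N"
  if (n_stop > 0L)
    warning(n_stop, " in-frame stop codon cells degenerated to NNN",
            call. = FALSE)
  m$seqs <- chars_to_seqs(out)
  m
}

# Group columns into complete consecutive (1,2,3) codon runs; columns that
# cannot be completed (broken frame) are orphans.
codon_blocks <- function(m) {
  pos <- m$codon_pos
  complete <- list()
  orphans <- integer(0)
  i <- 1L
  while (i <= length(pos)) {
    if (pos[i] == 1L && i + 2L <= length(pos) &&
        pos[i + 1L] == 2L && pos[i + 2L] == 3L) {
      complete[[length(complete) + 1L]] <- i:(i + 2L)
      i <- i + 3L
    } else {
      orphans <- c(orphans, i)
      i <- i + 1L
    }
  }
  list(complete = complete, orphans = orphans)
}

#' Fourfold-synonymous masking of a codon's third position
#'
#' Returns the third-position nucleotide unchanged if and only if every
#' resolution of the codon belongs to a strictly fourfold family (Ala, Gly,
#' Pro, Thr, Val under the standard code) and the third position itself is a
#' determinate base; everything else (twofold, threefold and sixfold
#' families, Met, Trp, stops, gaps, unresolvable ambiguity) is returned as
#' `N`, making it uninformative.
#'
#' @param codon 3-symbol codon.
#' @param code a genetic code.
#' @return a single symbol in `{A,C,G,T,N}`.
#' @examples
#' fourfold_synon_cell("GGA")  # "A": Gly is strictly fourfold
#' fourfold_synon_cell("CAT")  # "N": His is twofold
#' @export
fourfold_synon_cell <- function(codon, code = standard_code()) {
  codon <- toupper(codon)
  sym <- strsplit(codon, "")[[1]]
  if (length(sym) != 3L || any(!sym %in% names(IUPAC))) return("N")
  if (!sym[3] %in% BASES) return("N")
  ff <- strictly_fourfold_aas(code)
  res <- expand.grid(IUPAC[[sym[1]]], IUPAC[[sym[2]]], c(sym[3]),
                     stringsAsFactors = FALSE)
  aas <- code[paste0(res[[1]], res[[2]], res[[3]])]
  if (all(aas %in% ff)) sym[3] else "N"
}

#' Fourfold-synonymous third-position matrix
#'
#' Reduces an in-frame matrix to one column per codon: the third position,
#' retained only where the codon is strictly fourfold-degenerate
#' (see [fourfold_synon_cell()]). Change in the result is purely synonymous.
#' Fragment charsets are re-indexed to codon coordinates.
#'
#' @param m an in-frame [nuc_matrix()].
#' @param code a genetic code.
#' @return a `nuc_matrix` with one (nt3) column per complete codon.
#' @export
fourfold_synon_matrix <- function(m, code = standard_code()) {
  cod <- codon_blocks(m)
  if (!length(cod$complete))
    stop("frame violation: no complete codons in matrix", call. = FALSE)
  mat <- as_char_matrix(m)
  out <- matrix("N", nrow = n_taxa(m), ncol = length(cod$complete))
  ff <- strictly_fourfold_aas(code)
  memo <- new.env(parent = emptyenv())
  for (k in seq_along(cod$complete)) {
    block <- cod$complete[[k]]
    codons <- paste0(mat[, block[1]], mat[, block[2]], mat[, block[3]])
    out[, k] <- vapply(codons, function(cd) {
      hit <- memo[[cd]]
      if (is.null(hit)) {
        hit <- fourfold_synon_cell(cd, code)
        memo[[cd]] <- hit
      }
      hit
    }, character(1), USE.NAMES = FALSE)
  }
  # map charsets: a codon belongs to a charset if its whole triplet does
  first_cols <- vapply(cod$complete, `[`, integer(1), 1L)
  charsets <- lapply(m$charsets, function(idx) {
    which(vapply(cod$complete, function(b) all(b %in% idx), logical(1)))
  })
  # whole-codon fragment semantics do not apply to an nt3-only matrix:
  # fragment membership survives as plain charsets in codon coordinates
  res <- nuc_matrix(m$taxa, chars_to_seqs(out), charsets = charsets,
                    fragments = character(0),
                    codon_pos = rep(3L, ncol(out)))
  attr(res, "provenance") <- list(name = "nt3_4foldsynon",
                                  original_columns = first_cols + 2L)
  res
}
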