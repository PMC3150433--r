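#' Genetic codes and codon degeneracy families
#'
#' The standard nuclear genetic code ships as the default. A code is a named
#' character vector mapping the 64 codons to one-letter amino acids (`*` for
#' stop). Degeneracy families are the connected components of each amino
#' acid's codon set under single-nucleotide interchange: this is what splits
#' serine into Ser1 (TCN) and Ser2 (AGY) while leucine (TTR + CTN) and
#' arginine (CGN + AGR) each remain a single six-codon family, because their
#' subsets are bridged by single first-position changes.
#'
#' @name genetic-code
NULL

BASES <- c("A", "C", "G", "T")

IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# base set -> IUPAC symbol
iupac_symbol <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  sets <- vapply(IUPAC[setdiff(names(IUPAC), "U")],
                 function(b) paste(sort(b), collapse = ""), character(1))
  names(sets)[match(key, sets)]
}

#' Standard nuclear genetic code
#'
#' @return named character vector: 64 codons to one-letter amino acids
#'   (`*` = stop).
#' @export
standard_code <- function() {
  aas <- paste0("KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLL",
                "EDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF")
  b1 <- rep(c("A", "C", "G", "T"), each = 16)
  b2 <- rep(rep(c("A", "C", "G", "T"), each = 4), 4)
  b3 <- rep(c("A", "C", "G", "T"), 16)
  codons <- paste0(b1, b2, b3)
  stats::setNames(strsplit(aas, "")[[1]], codons)
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "stop")

#' Degeneracy families of a genetic code
#'
#' Partitions the sense codons into synonymous families: connected components
#' of each amino acid's codons under single-nucleotide difference.
#'
#' @param code a genetic code as returned by [standard_code()].
#' @return a list of families, each with `aa` (one-letter), `label`
#'   (e.g. `"Ser1"`, `"Leu"`), and `codons`.
#' @export
degeneracy_families <- function(code = standard_code()) {
  fams <- list()
  for (aa in setdiff(unique(code), "*")) {
    codons <- names(code)[code == aa]
    comps <- connected_components(codons)
    # Convention: a family whose codons share both first positions is named
    # after the amino acid; split families get a numeric suffix with the
    # TCN-style (fourfold) component first (Ser1 = TCN, Ser2 = AGY).
    if (length(comps) == 1L) {
      fams[[length(fams) + 1L]] <-
        list(aa = aa, label = AA3[[aa]], codons = comps[[1]])
    } else {
      comps <- comps[order(-lengths(comps))]
      for (i in seq_along(comps))
        fams[[length(fams) + 1L]] <-
          list(aa = aa, label = paste0(AA3[[aa]], i), codons = comps[[i]])
    }
  }
  fams
}

connected_components <- function(codons) {
  n <- length(codons)
  if (n == 1L) return(list(codons))
  adj <- outer(codons, codons, function(a, b) {
    mapply(function(x, y) {
      sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]) == 1L
    }, a, b)
  })
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(codons, comp), sort))
}

#' Classify a sense codon by its degeneracy family
#'
#' Returns the family label in the form `degeneracy(Family)`, e.g.
#' `"fourfold(Ala)"`, `"twofold(His)"`, `"threefold(Ile)"`,
#' `"sixfold(Leu)"`, `"nondegenerate(Trp)"`, or `"stop"`. Serine is split:
#' `AGY` codons are `"twofold(Ser2)"` and `TCN` codons `"sixfold(Ser1)"`
#' (the amino acid is sixfold-degenerate; only its AGY component behaves as a
#' twofold family).
#'
#' @param codon a 3-letter unambiguous sense codon.
#' @param code a genetic code.
#' @return a classification string.
#' @export
classify_codon <- function(codon, code = standard_code()) {
  codon <- toupper(codon)
  if (!codon %in% names(code))
    stop("not an unambiguous codon: ", codon, call. = FALSE)
  aa <- code[[codon]]
  if (aa == "*") return("stop")
  fam <- codon_family(codon, code)
  deg <- switch(as.character(length(fam$codons)),
                "1" = "nondegenerate", "2" = "twofold", "3" = "threefold",
                "4" = "fourfold", "6" = "sixfold")
  if (aa == "S") deg <- if (fam$label == "Ser2") "twofold" else "sixfold"
  paste0(deg, "(", fam$label, ")")
}

codon_family <- function(codon, code = standard_code()) {
  fams <- cached_families(code)
  for (fam in fams) if (codon %in% fam$codons) return(fam)
  NULL
}

fam_cache <- new.env(parent = emptyenv())

cached_families <- function(code) {
  key <- paste(code, collapse = "")
  if (is.null(fam_cache[[key]])) fam_cache[[key]] <- degeneracy_families(code)
  fam_cache[[key]]
}

#' Amino acids with strictly fourfold-degenerate codon families
#'
#' Ala, Gly, Pro, Thr, Val under the standard code: the amino acids whose
#' entire codon set is one fourfold family. Serine's TCN component is
#' excluded because the amino acid is sixfold-degenerate.
#'
#' @param code a genetic code.
#' @return character vector of one-letter amino acids.
#' @export
strictly_fourfold_aas <- function(code = standard_code()) {
  fams <- cached_families(code)
  aa_nfam <- table(vapply(fams, `[[`, character(1), "aa"))
  out <- character(0)
  for (fam in fams) {
    if (length(fam$codons) == 4L && aa_nfam[[fam$aa]] == 1L)
      out <- c(out, fam$aa)
  }
  sort(out)
}
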