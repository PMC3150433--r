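# Compositional-heterogeneity analysis: per-taxon base frequencies,
# Euclidean distances on the percent scale, and a composition-only
# clustering diagram. Heterogeneous composition at (mostly synonymous)
# third positions is a classic source of nonphylogenetic signal: taxa with
# shared bias cluster together regardless of their true relationships.

#' Per-taxon nucleotide composition
#'
#' Counts A, C, G and T per taxon and expresses them as percentages of the
#' counted sites. Gaps, `?`, `N` and all other ambiguity symbols are excluded
#' from numerator and denominator alike. A taxon with zero countable sites is
#' flagged undefined.
#'
#' @param m a [nuc_matrix()].
#' @return data.frame with columns `taxon`, `A`, `C`, `G`, `T` (percent),
#'   `n_counted`, `defined`.
#' @export
base_composition <- function(m) {
  mat <- as_char_matrix(m)
  counts <- vapply(BASES, function(b) rowSums(mat == b), numeric(n_taxa(m)))
  if (n_taxa(m) == 1L) counts <- matrix(counts, nrow = 1L,
                                        dimnames = list(NULL, BASES))
  n_counted <- rowSums(counts)
  freq <- 100 * counts / ifelse(n_counted > 0, n_counted, NA_real_)
  out <- data.frame(taxon = m$taxa, freq, n_counted = n_counted,
                    defined = n_counted > 0, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out)[2:5] <- BASES
  out
}

#' Euclidean distance matrix on composition vectors
#'
#' Treats the four nucleotide percentages as independent characters:
#' `d(i, j) = sqrt(sum_b (freq_i(b) - freq_j(b))^2)`, in percent units.
#' Two taxa of pure, different composition are `sqrt(2) * 100 = 141.42`
#' apart. Undefined vectors are excluded with a warning.
#'
#' @param vectors data.frame from [base_composition()].
#' @return symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
euclidean_matrix <- function(vectors) {
  undef <- !vectors$defined
  if (any(undef)) {
    warning("excluding taxa with undefined composition: ",
            paste(vectors$taxon[undef], collapse = ", "), call. = FALSE)
    vectors <- vectors[!undef, , drop = FALSE]
  }
  if (nrow(vectors) < 2L)
    stop("need at least 2 defined composition vectors", call. = FALSE)
  f <- as.matrix(vectors[, BASES])
  rownames(f) <- vectors$taxon
  as.matrix(stats::dist(f, method = "euclidean"))
}

#' Composition-only clustering diagram
#'
#' Clusters taxa from a composition distance matrix: UPGMA
#' (average-linkage hierarchical clustering, the conventional choice for
#' composition dendrograms) by default, neighbor joining as an option. Output
#' is deterministic given the input order; ties are resolved by the first
#' (lowest-index) pair.
#'
#' @param d symmetric distance matrix from [euclidean_matrix()].
#' @param method `"upgma"` or `"nj"`.
#' @return a `supported_tree` over the taxa (supports absent).
#' @export
composition_tree <- function(d, method = c("upgma", "nj")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 taxa to cluster", call. = FALSE)
  phy <- if (method == "upgma") {
    ape::as.phylo(stats::hclust(stats::as.dist(d), method = "average"))
  } else {
    ape::nj(stats::as.dist(d))
  }
  parse_tree(phy)
}
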