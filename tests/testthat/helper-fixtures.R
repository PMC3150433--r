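# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# A tiny in-frame two-fragment matrix with known codon content.
tiny_matrix <- function() {
  # frag g1: codons (ATG, CAT|CAC, TTA|CTG) -- Met, His, Leu
  # frag g2: codons (GGA|GGT, AGT|AGC)      -- Gly, Ser2
  nuc_matrix(
    c("t1", "t2"),
    c("ATGCATTTAGGAAGT",
      "ATGCACCTGGGTAGC"),
    charsets = list(g1 = 1:9, g2 = 10:15),
    fragments = c("g1", "g2"))
}

nexus_fixture <- function(path, exset = TRUE) {
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    "  DIMENSIONS NTAX=2 NCHAR=15;",
    "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
    "  MATRIX",
    "  t1  ATGCATTTAGGAAGT",
    "  t2  ATGCACCTGGGTAGC",
    "  ;",
    "END;",
    "BEGIN SETS;",
    "  CHARSET g1 = 1-9;",
    "  CHARSET g2 = 10-15;",
    "  CHARSET nt3 = 3-15\\3;",
    if (exset) "  EXSET mask = 4-6;",
    "END;"), path)
  path
}

# A 6-taxon pectinate reference with supports, used across support tests.
ref_tree6 <- function() {
  parse_tree("(((A:1,B:1)100:1,(C:1,D:1)90:1)85:1,(E:1,F:1)95:1);")
}

balanced_sim <- function(seed = 11, syn = 20, n_codons = 150) {
  tr <- paste0("(((a1:.05,a2:.05):.05,(a3:.05,a4:.05):.05):.1,",
               "((b1:.05,b2:.05):.05,(b3:.05,b4:.05):.05):.1);")
  sim_spec(tr, n_fragments = 4, n_codons = n_codons,
           syn_rate_multiplier = syn,
           nt3_bias = list(
             gc = list(taxa = c("a1", "a2", "b1", "b3"),
                       freq = c(A = .02, C = .48, G = .48, T = .02)),
             at = list(taxa = c("a3", "a4", "b2", "b4"),
                       freq = c(A = .48, C = .02, G = .02, T = .48))),
           seed = seed)
}

# --- independent bipartition oracle -----------------------------------------
# Recursive traversal written separately from the package's prop.part route.
oracle_bipartitions <- function(phy) {
  ntip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  clade_tips <- function(v) {
    if (v <= ntip) return(phy$tip.label[v])
    unlist(lapply(kids[[as.character(v)]], clade_tips))
  }
  out <- list()
  for (v in (ntip + 1L):(ntip + phy$Nnode)) {
    side <- sort(clade_tips(v))
    other <- sort(setdiff(phy$tip.label, side))
    if (length(side) < 2L || length(other) < 2L) next
    key <- if (min(c(side, other)) %in% side) {
      paste(other, collapse = "|")
    } else {
      paste(side, collapse = "|")
    }
    sup <- if (!is.null(phy$node.label)) {
      suppressWarnings(as.numeric(phy$node.label[v - ntip]))
    } else NA_real_
    prev <- out[[key]]
    out[[key]] <- if (is.null(prev) || is.na(prev)) {
      sup
    } else if (is.na(sup)) {
      prev
    } else {
      max(prev, sup)
    }
  }
  out
}

# naive hamming p-distance over determinate bases
p_distance <- function(m) {
  cm <- as_char_matrix(m)
  n <- nrow(cm)
  d <- matrix(0, n, n, dimnames = list(rownames(cm), rownames(cm)))
  ok <- function(x) x %in% c("A", "C", "G", "T")
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    u <- cm[i, ]; v <- cm[j, ]
    w <- ok(u) & ok(v)
    d[i, j] <- d[j, i] <- if (any(w)) mean(u[w] != v[w]) else NA_real_
  }
  d
}
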