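test_that("the shipped genetic code and family split match an independent source", {
  skip_if_not_installed("Biostrings")
  bc <- Biostrings::GENETIC_CODE
  sc <- standard_code()
  expect_identical(as.character(sc[names(bc)]), as.character(bc))
})

test_that("codons classify into their degeneracy families", {
  expect_equal(classify_codon("GCA"), "fourfold(Ala)")
  expect_equal(classify_codon("TGG"), "nondegenerate(Trp)")
  expect_equal(classify_codon("ATG"), "nondegenerate(Met)")
  expect_equal(classify_codon("AGT"), "twofold(Ser2)")
  expect_equal(classify_codon("TCA"), "sixfold(Ser1)")
  expect_equal(classify_codon("CTG"), "sixfold(Leu)")
  expect_equal(classify_codon("AGA"), "sixfold(Arg)")
  expect_equal(classify_codon("ATA"), "threefold(Ile)")
  expect_equal(classify_codon("CAT"), "twofold(His)")
  expect_equal(classify_codon("TAA"), "stop")
  expect_error(classify_codon("CAY"), "unambiguous")
})

test_that("degen1 maps every family to its published degenerate codon", {
  # hand-derived family rules over the standard code
  frozen <- c(CAT = "CAY", CAC = "CAY",             # His twofold
              TTA = "YTN", CTG = "YTN", CTT = "YTN",# Leu sixfold
              AGA = "MGN", CGT = "MGN",             # Arg sixfold
              TCA = "TCN", AGT = "AGY",             # Ser1 / Ser2 split
              ATT = "ATH", ATA = "ATH",             # Ile threefold
              GCA = "GCN", GGT = "GGN", CCC = "CCN",# strict fourfold
              ACG = "ACN", GTT = "GTN",
              ATG = "ATG", TGG = "TGG",             # nondegenerate
              AAA = "AAR", GAT = "GAY", TGT = "TGY",
              TAA = "NNN", TGA = "NNN")             # stops
  for (cd in names(frozen))
    expect_equal(degen1_codon(cd), unname(frozen[cd]), label = cd)
  # totality over gaps, missing and unresolvable ambiguity
  expect_equal(degen1_codon("T-A"), "NNN")
  expect_equal(degen1_codon("?AT"), "NNN")
  expect_equal(degen1_codon("CAW"), "NNN")  # His-or-Gln: spans families
  # resolvable ambiguity degenerates like its family
  expect_equal(degen1_codon("YTR"), "YTN")  # every resolution is Leu
  expect_equal(degen1_codon("CAY"), "CAY")  # already degenerate: fixed point
})

test_that("degen1 is idempotent and total over the codon alphabet", {
  dm <- degen_map()
  syms <- c("A", "C", "G", "T", "R", "Y", "N", "-", "?")
  grid <- expand.grid(syms, syms, syms, stringsAsFactors = FALSE)
  codons <- paste0(grid[[1]], grid[[2]], grid[[3]])
  once <- vapply(codons, degen1_codon, character(1), dm = dm)
  twice <- vapply(once, degen1_codon, character(1), dm = dm)
  expect_identical(unname(twice), unname(once))
  # same-family codons always map identically
  for (fam in degeneracy_families()) {
    outs <- unique(vapply(fam$codons, degen1_codon, character(1), dm = dm))
    expect_length(outs, 1L)
  }
})

test_that("degen1 collapses synonymous rows and leaves Ser1/Ser2 visible", {
  # two sequences differing only within degeneracy families
  m <- nuc_matrix(c("x", "y"), c("CATTTAAGAGCT", "CACCTGCGGGCG"),
                  charsets = list(g = 1:12), fragments = "g")
  d <- degen1_matrix(m)
  expect_identical(d$seqs[1], d$seqs[2])
  expect_identical(d$seqs[1], "CAYYTNMGNGCN")
  # Ser1 vs Ser2 is a nonsynonymous-style difference that must survive
  s <- degen1_matrix(nuc_matrix(c("x", "y"), c("TCT", "AGT")))
  expect_false(s$seqs[1] == s$seqs[2])
  expect_identical(s$seqs, c("TCN", "AGY"))
})

test_that("after degen1 the only determinate third-position base is G", {
  dm <- degen_map()
  acgt <- c("A", "C", "G", "T")
  nt3 <- substr(unname(dm$base), 3L, 3L)
  expect_true(all(nt3[nt3 %in% acgt] == "G"))
  m <- simulate_alignment(sim_spec("((A:.2,B:.2):.1,(C:.2,D:.2):.1);",
                                   n_fragments = 2, n_codons = 60,
                                   syn_rate_multiplier = 5, seed = 3))
  d <- degen1_matrix(m)
  nt3_cells <- as.vector(as_char_matrix(d)[, codon_position_columns(d, 3)])
  expect_true(all(nt3_cells[nt3_cells %in% acgt] == "G"))
})

test_that("stop codons degenerate to NNN with a warning", {
  m <- nuc_matrix("x", "TAAATG")
  expect_warning(d <- degen1_matrix(m), "stop")
  expect_identical(d$seqs, "NNNATG")
})

test_that("fourfold-synonymous masking keeps only strict fourfold third positions", {
  expect_equal(fourfold_synon_cell("GGA"), "A")
  expect_equal(fourfold_synon_cell("GCT"), "T")
  expect_equal(fourfold_synon_cell("CAT"), "N")  # His: twofold
  expect_equal(fourfold_synon_cell("CTA"), "N")  # Leu: sixfold
  expect_equal(fourfold_synon_cell("TCA"), "N")  # Ser1: sixfold aa
  expect_equal(fourfold_synon_cell("TGG"), "N")
  expect_equal(fourfold_synon_cell("RCA"), "A")  # Thr-or-Ala: both fourfold
  expect_equal(fourfold_synon_cell("GC-"), "N")
  # all-Trp fixture -> all N; all-Gly fixture -> equal to raw nt3
  trp <- fourfold_synon_matrix(nuc_matrix(c("a", "b"),
                                          c("TGGTGG", "TGGTGG")))
  expect_true(all(as_char_matrix(trp) == "N"))
  gly <- nuc_matrix(c("a", "b"), c("GGAGGT", "GGCGGG"))
  ff <- fourfold_synon_matrix(gly)
  expect_identical(as.vector(as_char_matrix(ff)),
                   as.vector(as_char_matrix(gly)[, c(3, 6)]))
})

test_that("fourfold matrix agrees with the per-cell rule on mixed data", {
  m <- simulate_alignment(sim_spec("((A:.2,B:.2):.1,(C:.2,D:.2):.1);",
                                   n_fragments = 1, n_codons = 50,
                                   syn_rate_multiplier = 8, seed = 5))
  ff <- fourfold_synon_matrix(m)
  cm <- as_char_matrix(m)
  for (k in seq_len(n_cols(ff))) {
    block <- (3 * (k - 1) + 1):(3 * k)
    codons <- paste0(cm[, block[1]], cm[, block[2]], cm[, block[3]])
    expect_identical(as_char_matrix(ff)[, k],
                     setNames(vapply(codons, fourfold_synon_cell,
                                     character(1), USE.NAMES = FALSE),
                              rownames(cm)))
  }
  expect_true(all(as.vector(as_char_matrix(ff)) %in%
                    c("A", "C", "G", "T", "N")))
})
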