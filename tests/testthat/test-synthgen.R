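quartet <- "((A:.2,B:.2):.1,(C:.2,D:.2):.1);"

test_that("simulation is seed-deterministic and structurally valid", {
  sp <- sim_spec(quartet, n_fragments = 3, n_codons = 25,
                 syn_rate_multiplier = 5, seed = 21)
  m1 <- simulate_alignment(sp)
  m2 <- simulate_alignment(sp)
  expect_identical(m1$seqs, m2$seqs)
  m3 <- simulate_alignment(sim_spec(quartet, n_fragments = 3, n_codons = 25,
                                    syn_rate_multiplier = 5, seed = 22))
  expect_false(identical(m1$seqs, m3$seqs))
  expect_equal(n_cols(m1), 3 * 25 * 3)
  expect_setequal(m1$fragments, c("frag01", "frag02", "frag03"))
  # no stop codons are ever emitted
  cm <- as_char_matrix(m1)
  codons <- as.vector(apply(cm, 1, function(r)
    paste0(r[c(TRUE, FALSE, FALSE)], r[c(FALSE, TRUE, FALSE)],
           r[c(FALSE, FALSE, TRUE)])))
  expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
})

test_that("missing taxa render as all-? fragment rows", {
  sp <- sim_spec(quartet, n_fragments = 2, n_codons = 10,
                 missing_taxa = list(frag02 = c("B", "D")), seed = 2)
  m <- simulate_alignment(sp)
  cm <- as_char_matrix(m)
  expect_true(all(cm["B", m$charsets$frag02] == "?"))
  expect_true(all(cm["D", m$charsets$frag02] == "?"))
  expect_false(any(cm["A", ] == "?"))
})

test_that("zero synonymous rate leaves fourfold third positions invariant", {
  sp <- sim_spec(quartet, n_fragments = 2, n_codons = 60,
                 syn_rate_multiplier = 0, seed = 13)
  m <- simulate_alignment(sp)
  cm <- as_char_matrix(m)
  # wherever all taxa share one degeneracy family, the codon is identical:
  # without synonymous change the only differences are family replacements
  for (k in seq_len(n_cols(m) / 3)) {
    block <- (3 * (k - 1) + 1):(3 * k)
    codons <- paste0(cm[, block[1]], cm[, block[2]], cm[, block[3]])
    fams <- vapply(codons, classify_codon, character(1))
    if (length(unique(fams)) == 1L)
      expect_length(unique(codons), 1L)
  }
})

test_that("planted clean indels are recovered exactly; decoys are rejected", {
  plan <- list(
    list(fragment = "frag01", codon_start = 3, codon_end = 5,
         taxa = c("A", "B")),
    list(fragment = "frag02", codon_start = 1, codon_end = 2,
         taxa = c("C", "D")),
    list(fragment = "frag02", codon_start = 6, codon_end = 7,
         taxa = c("A", "B", "C")),
    # staggered decoy: D's run extends one codon past C's
    list(fragment = "frag01", codon_start = 8, codon_end = 9,
         taxa = c("C", "D"), staggered = TRUE))
  sp <- sim_spec(quartet, n_fragments = 2, n_codons = 12,
                 syn_rate_multiplier = 2, indel_plan = plan, seed = 17)
  m <- inject_indels(simulate_alignment(sp), sp)
  hq <- quality_filter(gap_events(m))
  expect_equal(nrow(hq), 3L)
  expect_setequal(
    paste(hq$fragment, hq$start, hq$end),
    c("frag01 7 15", "frag02 37 42", "frag02 52 57"))
  expect_true(setequal(hq$taxa[[which(hq$fragment == "frag01")]],
                       c("A", "B")))
  # no false positives on gap-free simulations
  clean <- simulate_alignment(sim_spec(quartet, n_fragments = 2,
                                       n_codons = 12, seed = 17))
  expect_equal(nrow(gap_events(clean)), 0L)
  # overlap with an existing gap is refused
  sp_bad <- sp
  sp_bad$indel_plan <- plan[1]
  expect_error(inject_indels(m, sp_bad), "overlaps")
})

test_that("strong nt3 bias misleads composition while degen1 tracks the tree", {
  sp <- balanced_sim(seed = 11, syn = 20, n_codons = 120)
  m <- simulate_alignment(sp)
  ff <- fourfold_synon_matrix(m)
  ct <- composition_tree(euclidean_matrix(base_composition(ff)))
  gc_group <- sp$nt3_bias$gc$taxa
  # the composition dendrogram groups the GC-biased taxa together,
  # cutting across the generating tree
  expect_true(ape::is.monophyletic(ape::unroot(ct$phylo), gc_group))
  # degen1 distances rank-correlate with true tree path lengths better
  # than raw nt3 distances, which are dominated by the bias
  td <- ape::cophenetic.phylo(sp$tree)
  taxa <- m$taxa
  d_deg <- p_distance(degen1_matrix(m))[taxa, taxa]
  d_nt3 <- p_distance(extract_submatrix(
    m, codon_position_columns(m, 3)))[taxa, taxa]
  ut <- upper.tri(td[taxa, taxa])
  cor_deg <- cor(d_deg[ut], td[taxa, taxa][ut], method = "spearman")
  cor_nt3 <- cor(d_nt3[ut], td[taxa, taxa][ut], method = "spearman")
  expect_gt(cor_deg, cor_nt3)
})

test_that("sim specs serialise to JSON manifests", {
  sp <- sim_spec(quartet, n_fragments = 1, n_codons = 5, seed = 1)
  f <- tempfile(fileext = ".json")
  write_sim_spec(sp, f)
  js <- jsonlite::read_json(f)
  expect_equal(js$seed, 1L)
  expect_match(js$tree, "^\\(")
})
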