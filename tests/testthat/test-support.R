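test_that("newick parsing yields informative bipartitions with supports", {
  tr <- parse_tree("((A,B)95,(C,D)87);")
  expect_length(tr$bipartitions, 1L)
  # AB|CD seen from both root children: the one split keeps the max label
  expect_equal(tr$bipartitions[[1]]$support, 95)
  # 5-leaf caterpillar: two informative bipartitions
  cat5 <- parse_tree("(((A,B),C),(D,E));")
  expect_length(cat5$bipartitions, 2L)
  # supports are absent, not zero, when labels are missing
  expect_true(all(is.na(vapply(cat5$bipartitions, `[[`, numeric(1),
                               "support"))))
  expect_error(parse_tree("((A,B),(A,C));"), "duplicate")
  expect_error(suppressWarnings(parse_tree("not a tree ((")), "malformed")
})

test_that("identical trees give all strong matches and no conflicts", {
  ref <- ref_tree6()
  cand <- parse_tree("(((A:1,B:1)100:1,(C:1,D:1)100:1)100:1,(E:1,F:1)100:1);")
  cmp <- classify_support(ref, cand)
  expect_equal(cmp$n_strong_match, 3L)
  expect_equal(cmp$n_conflict, 0L)
  expect_equal(cmp$n_strong_conflict, 0L)
})

test_that("a strongly supported clade absent from the reference conflicts", {
  ref <- ref_tree6()
  # candidate groups C with E at 82%: no such reference node
  cand <- parse_tree("(((A:1,B:1)99:1,(C:1,E:1)82:1)60:1,(D:1,F:1)30:1);")
  cmp <- classify_support(ref, cand)
  expect_equal(cmp$n_strong_match, 1L)       # AB at 99
  expect_equal(cmp$n_conflict, 2L)           # CE at 82, ABCE|DF at 60
  expect_equal(cmp$n_strong_conflict, 1L)    # CE only
  expect_true(cmp$n_strong_conflict <= cmp$n_conflict)
})

test_that("restriction to shared taxa never fabricates conflict", {
  ref <- ref_tree6()
  # same topology with E and F missing: on four shared taxa the AB and CD
  # clades collapse into the single split AB|CD, which matches
  cand <- parse_tree("((A:1,B:1)92:1,(C:1,D:1)85:1);")
  cmp <- classify_support(ref, cand)
  expect_equal(cmp$n_conflict, 0L)
  expect_equal(cmp$n_strong_match, 1L)
  expect_error(classify_support(ref, parse_tree("((x,y),(z,w));")),
               "disjoint")
})

test_that("support classification agrees with an exhaustive oracle", {
  skip_if_not_installed("ape")
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(4:7, 1)
    r <- ape::rtree(n, tip.label = LETTERS[1:n])
    c_ <- ape::rtree(n, tip.label = LETTERS[1:n])
    r$node.label <- as.character(sample(50:100, r$Nnode, replace = TRUE))
    c_$node.label <- as.character(sample(50:100, c_$Nnode, replace = TRUE))
    ref <- parse_tree(r)
    cand <- parse_tree(c_)
    ob_r <- oracle_bipartitions(r)
    ob_c <- oracle_bipartitions(c_)
    ref_keys <- names(ob_r)[vapply(ob_r, function(s) !is.na(s) && s >= 80,
                                   logical(1))]
    cand_sup <- unlist(ob_c)
    n_match <- sum(names(ob_c) %in% ref_keys & cand_sup >= 80)
    n_confl <- sum(!(names(ob_c) %in% ref_keys) & cand_sup >= 50)
    n_sconf <- sum(!(names(ob_c) %in% ref_keys) & cand_sup >= 80)
    cmp <- classify_support(ref, cand)
    expect_equal(cmp$n_strong_match, n_match)
    expect_equal(cmp$n_conflict, n_confl)
    expect_equal(cmp$n_strong_conflict, n_sconf)
  }
})

test_that("gene counts per node tally trees supporting each bipartition", {
  ref <- ref_tree6()
  g_yes <- parse_tree("(((A:1,B:1)90:1,(C:1,D:1)40:1)10:1,(E:1,F:1)88:1);")
  g_no <- parse_tree("(((A:1,C:1)90:1,(B:1,D:1)90:1)10:1,(E:1,F:1)70:1);")
  out0 <- genes_supporting_nodes(ref, list())
  expect_true(all(out0$n_genes == 0L))
  out <- genes_supporting_nodes(ref, list(g_yes, g_yes, g_yes, g_no, g_no))
  ab <- out$n_genes[out$key == paste(sort(c("C", "D", "E", "F")),
                                     collapse = "|")]
  expect_equal(ab, 3L)  # AB recovered at >=75 by three of five trees
  ef <- out$n_genes[out$key == "E|F"]
  expect_equal(ef, 3L)  # EF at 88 in the three g_yes trees only
})

test_that("utility follows the missing-taxon-corrected per-kb formula", {
  expect_equal(utility(10, 1000, 0), 10)
  expect_equal(utility(10, 1000, 16), 12.5)
  expect_equal(utility(0, 500, 10), 0)
  # homogeneity: double G doubles U; double L halves U
  expect_equal(utility(20, 1000, 16), 2 * utility(10, 1000, 16))
  expect_equal(utility(10, 2000, 16), utility(10, 1000, 16) / 2)
  expect_error(utility(1, 0, 0), "positive")
  expect_error(utility(1, 100, 80), "total_taxa")
})

test_that("gene utility records count missing taxa from all-missing rows", {
  m <- nuc_matrix(c("A", "B", "C", "D"),
                  c("ATGCATTTA", "ATGCACCTG", "?????????", "ATGCATCTG"),
                  charsets = list(g1 = 1:9), fragments = "g1")
  ref <- parse_tree("((A:1,B:1)90:1,(C:1,D:1)90:1);")
  gt <- list(g1 = parse_tree("((A:1,B:1)80:1,(C:1,D:1)80:1);"))
  rec <- gene_utility(ref, gt, m, total_taxa = 4)
  expect_equal(rec$m, 1L)
  expect_equal(rec$L, 9L)
  expect_equal(rec$G, 1L)  # the single informative split, at 80 >= 75
  expect_equal(rec$utility, (1 / (9e-3)) * (4 / 3))
})

test_that("the utility trend fit is exact on collinear points", {
  rec <- data.frame(gene_id = sprintf("g%d", 1:5),
                    utility = 2 * (1:5) + 1)
  rt <- rate_table(sprintf("g%d", 1:5), 1:5)
  fit <- suppressWarnings(fit_utility_trend(rec, rt))  # perfect-fit note
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_lt(fit$slope_sd, 1e-8)
  # symmetric perturbation keeps the slope within its standard error
  rec2 <- rec
  rec2$utility <- rec2$utility + c(0.5, -0.5, 0, 0.5, -0.5)
  fit2 <- fit_utility_trend(rec2, rt)
  expect_lt(abs(fit2$slope - 2), 2 * fit2$slope_sd + 0.5)
  # permutation invariance
  fit3 <- fit_utility_trend(rec2[c(3, 1, 5, 2, 4), ], rt)
  expect_equal(fit3$slope, fit2$slope)
  expect_error(fit_utility_trend(rec[1:2, ], rt), "at least 3")
  rt0 <- rate_table(sprintf("g%d", 1:5), rep(1, 5))
  expect_error(fit_utility_trend(rec, rt0), "variance")
})
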