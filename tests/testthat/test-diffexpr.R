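test_that("size factors obey symmetry, scaling, and the worked example", {
  m <- matrix(c(5, 50, 2, 5, 50, 2), nrow = 3,
              dimnames = list(letters[1:3], NULL))
  cm <- toy_count_matrix(m, lines = "MWT", stages = 1, reps = 2)
  expect_equal(unname(size_factors(cm)), c(1, 1))

  m2 <- matrix(c(10, 100, 4, 20, 200, 8), nrow = 3,
               dimnames = list(letters[1:3], NULL))
  cm2 <- toy_count_matrix(m2, lines = "MWT", stages = 1, reps = 2)
  s <- size_factors(cm2)
  expect_equal(unname(s[2] / s[1]), 2)
  # Hand evaluation: every gene ratio is 1/sqrt(2) and sqrt(2).
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)))

  # Gene-order invariance.
  cm3 <- toy_count_matrix(m2[c(3, 1, 2), ], lines = "MWT", stages = 1,
                          reps = 2)
  expect_equal(size_factors(cm3), s)
})

test_that("size factors fall back gracefully without an all-positive gene", {
  m <- matrix(c(0, 8, 4, 0), nrow = 2,
              dimnames = list(c("a", "b"), NULL))
  cm <- toy_count_matrix(m, lines = "MWT", stages = 1, reps = 2)
  expect_error(size_factors(cm, fallback = FALSE), "degenerate")
  expect_message(s <- size_factors(cm, fallback = TRUE), "positive-entry")
  expect_true(all(s > 0))
})

test_that("the variance-stabilizing transform matches its closed form", {
  sf <- c(S1 = 1)
  m <- matrix(0, 1, 1, dimnames = list("g", "S1"))
  expect_equal(vst_transform(m, sf, 0.25)[1, 1], 0)

  m[1, 1] <- 100
  expect_lt(abs(vst_transform(m, sf, 1e-10)[1, 1] - 20) / 20, 1e-5)

  m[1, 1] <- 48
  expect_equal(vst_transform(m, sf, 0.25)[1, 1],
               (2 / 0.5) * asinh(sqrt(12)))

  expect_error(vst_transform(m, sf, 0), "positive")
  # Strictly increasing in q.
  v <- vst_transform(matrix(0:50, 1, 51,
                            dimnames = list("g", sprintf("S%02d", 0:50))),
                     rep(1, 51), 0.1)
  expect_true(all(diff(v[1, ]) > 0))
})

test_that("dispersion estimates recover the simulated regime", {
  set.seed(42)
  # Poisson counts: dispersion collapses towards the floor.
  m <- matrix(rpois(200 * 500, 100), nrow = 200)
  disp <- estimate_dispersion(one_cell_count_matrix(m), rep(1, 500))
  expect_lt(disp$common, 0.01)

  # NB with alpha = 0.2: per-gene estimates bracket the truth.
  m2 <- matrix(rnbinom(200 * 200, mu = 100, size = 5), nrow = 200)
  disp2 <- estimate_dispersion(one_cell_count_matrix(m2), rep(1, 200))
  expect_gt(disp2$common, 0.1)
  expect_lt(disp2$common, 0.3)

  # Constant counts within the cell: everything floors.
  m3 <- matrix(7, 10, 4)
  disp3 <- estimate_dispersion(one_cell_count_matrix(m3), rep(1, 4))
  expect_true(all(disp3$per_gene == disp3$alpha_min))
})

test_that("the Wald test matches its closed forms", {
  # Identical groups: null identity.
  m <- matrix(rep(c(20, 60), each = 6), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  cm <- toy_count_matrix(m, lines = c("mlpa", "MWT"), stages = 1, reps = 3)
  disp <- list(per_gene = c(a = 0.01, b = 0.01), common = 0.01,
               alpha_min = 1e-8)
  res <- nb_wald_test(cm, rep(1, 6), disp, "mlpa", "MWT", 1)
  expect_equal(res$lfc, c(0, 0))
  expect_equal(res$p, c(1, 1))

  # mu_A = 30 vs mu_B = 10, n = 3, alpha = 0.01: independent evaluation.
  m2 <- matrix(c(rep(30, 3), rep(10, 3)), nrow = 1,
               dimnames = list("g", NULL))
  cm2 <- toy_count_matrix(m2, lines = c("mlpa", "MWT"), stages = 1,
                          reps = 3)
  disp2 <- list(per_gene = c(g = 0.01), common = 0.01, alpha_min = 1e-8)
  res2 <- nb_wald_test(cm2, rep(1, 6), disp2, "mlpa", "MWT", 1)
  lfc <- log2(31 / 11)
  se <- sqrt((1 / 3) * (1 / 31 + 0.01) + (1 / 3) * (1 / 11 + 0.01)) / log(2)
  expect_equal(res2$lfc, lfc)
  expect_equal(res2$se, se)
  expect_equal(res2$p, 2 * pnorm(-abs(lfc / se)))
  expect_equal(res2$baseMean, 20)

  expect_error(nb_wald_test(cm2, rep(1, 6), disp2, "mlpa", "MWT", 9),
               "stage")
})

test_that("the MRP rule intersects three comparisons, Mips uses one", {
  rec <- function(gene, comparison, deg) {
    data.frame(gene = gene, comparison = comparison, stage = 1L,
               is_deg = deg, stringsAsFactors = FALSE)
  }
  records <- rbind(
    rec("gX", "2mlpa_vs_2MWT", TRUE), rec("gX", "2mlpa_vs_2MWT-L", TRUE),
    rec("gX", "2mlpa_vs_2MWT-N", FALSE),
    rec("gY", "2mlpa_vs_2MWT", TRUE), rec("gY", "2mlpa_vs_2MWT-L", TRUE),
    rec("gY", "2mlpa_vs_2MWT-N", TRUE))
  degs <- call_degs_subset(records, "MRP")
  expect_identical(degs$stage1, "gY")

  mips <- rbind(rec(sprintf("g%d", 1:5), "1mlpa_vs_1MWT", TRUE))
  expect_length(call_degs_subset(mips, "Mips")$stage1, 5)

  expect_error(call_degs_subset(records, "Mips"), "expects 1")
})

test_that("the Venn partition is exact and sums to the union", {
  regions <- venn_partition(list(c("a", "b"), c("b", "c"), "c"))
  expect_equal(unname(regions[c("only1", "only2", "only3")]), c(1, 0, 0))
  expect_equal(unname(regions[c("s12", "s23", "s13", "all")]),
               c(1, 1, 0, 0))
  expect_equal(sum(regions), 3)

  same <- venn_partition(list(letters[1:4], letters[1:4], letters[1:4]))
  expect_equal(unname(same["all"]), 4)
  expect_equal(sum(same), 4)

  expect_true(all(venn_partition(list(character(0), character(0),
                                      character(0))) == 0))

  # Property: regions always sum to the union, random sets.
  set.seed(3)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j) sample(letters, sample(0:20, 1)))
    expect_equal(sum(venn_partition(sets)),
                 length(unique(unlist(sets))))
  }
})

test_that("type-I error stays controlled on null class contrasts", {
  d <- generate_design("standard")
  tr <- plant_truth(d, n_genes = 2000, n_tfs = 2, n_modules = 8,
                    n_edges = 0, n_de_per_stage = 0, seed = 77)
  sim <- simulate_counts(d, tr, seed = 78)
  cm <- sim$counts
  sf <- size_factors(cm)
  disp <- estimate_dispersion(cm, sf)
  rec <- de_analysis(cm, "MRP", sf, disp)
  # TF genes carry a genuine class effect by construction; exclude them.
  rec <- rec[!rec$gene %in% tr$tf_set, ]
  expect_lte(mean(rec$p < 0.05), 0.07)
})
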