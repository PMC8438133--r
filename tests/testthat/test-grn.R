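test_that("Gaussian-copula MI obeys its closed form and the cap", {
  set.seed(1)
  x <- rnorm(200)
  # Identical vectors hit the correlation cap.
  expect_equal(gaussian_mi(x, x), -0.5 * log(1 - 0.9999^2))
  # Independent vectors have near-zero MI.
  expect_lt(gaussian_mi(x, sample(x)), 0.05)
  # rho = 0.8 recovers MI = -0.5 ln(0.36) ~ 0.5108 at large n.
  set.seed(2)
  n <- 2e5
  a <- rnorm(n); b <- 0.8 * a + sqrt(1 - 0.64) * rnorm(n)
  expect_lt(abs(gaussian_mi(a, b) - (-0.5 * log(0.36))), 0.02)
  expect_error(gaussian_mi(rep(1, 10), rnorm(10)), "variance")
})

test_that("DPI prunes the indirect edge of a Markov chain", {
  set.seed(3)
  m <- gaussian_chain(500, 0.9, 0.9)
  sc <- aracne_scores(m, "X", c("Y", "Z"), epsilon = 0)
  expect_gt(sc$score[sc$module == "Y"], 0)
  expect_equal(sc$score[sc$module == "Z"], 0)
  # Tolerance only loosens pruning: still pruned at epsilon = 0.3.
  sc2 <- aracne_scores(m, "X", c("Y", "Z"), epsilon = 0.3)
  expect_equal(sc2$score[sc2$module == "Z"], 0)
})

test_that("exact MI ties survive DPI (strict inequality)", {
  v <- c(3, 1, 4, 1.5, 5, 9, 2.6, 6)
  m <- cbind(A = v, B = v, C = v)  # all pairwise MI equal (at the cap)
  sc <- aracne_scores(m, "A", c("B", "C"), epsilon = 0)
  expect_true(all(sc$score > 0))
})

test_that("CLR highlights the pair that beats its background", {
  v <- seq(-2, 2, length.out = 24)
  set.seed(4)
  mat <- cbind(tf1 = v + rnorm(24, 0, 0.05),
               tf2 = rnorm(24), tf3 = rnorm(24),
               m1 = v, m2 = rnorm(24), m3 = rnorm(24))
  sc <- clr_scores(mat, c("tf1", "tf2", "tf3"), c("m1", "m2", "m3"))
  top <- sc[which.max(sc$score), ]
  expect_identical(c(top$tf, top$module), c("tf1", "m1"))

  # All-equal MI: scores collapse to zero.
  w <- c(2, 7, 1, 8, 2.8, 9)
  flat <- cbind(a = w, b = w, c = w, d = w)
  sc2 <- clr_scores(flat, c("a", "b"), c("c", "d"))
  expect_true(all(sc2$score == 0))
})

test_that("LARS scores reward early path entry", {
  set.seed(5)
  X <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(NULL, paste0("tf", 1:6)))
  mat <- cbind(X, m1 = X[, "tf3"])
  sc <- lars_scores(mat, paste0("tf", 1:6), "m1", max_steps = 4)
  expect_equal(sc$score[sc$tf == "tf3"], 1)
  expect_true(all(sc$score[sc$tf != "tf3"] < 1))

  # Orthogonal target: no variable ever enters.
  y0 <- rnorm(20)
  y_orth <- stats::residuals(stats::lm(y0 ~ X))
  mat2 <- cbind(X, m1 = y_orth)
  sc2 <- lars_scores(mat2, paste0("tf", 1:6), "m1", max_steps = 4)
  expect_true(all(sc2$score == 0))

  expect_error(lars_scores(mat, paste0("tf", 1:6), "m1", max_steps = 50),
               "max_steps")
})

test_that("the LARS first entry is the most-correlated predictor", {
  set.seed(6)
  for (i in 1:10) {
    X <- matrix(rnorm(15 * 8), 15, 8,
                dimnames = list(NULL, paste0("tf", 1:8)))
    y <- rnorm(15)
    mat <- cbind(X, m1 = y)
    sc <- lars_scores(mat, paste0("tf", 1:8), "m1", max_steps = 3)
    cors <- abs(cor(X, y))
    expect_identical(sc$tf[which.max(sc$score)],
                     paste0("tf", which.max(cors)))
  }
})

test_that("partial correlation matches the 2x2 closed form and limits", {
  set.seed(7)
  x <- rnorm(40); y <- 0.6 * x + 0.8 * rnorm(40)
  mat <- cbind(tf1 = x, m1 = y)
  # Fixed lambda: the score is the shrunk correlation itself.
  for (lam in c(0.05, 0.3, 0.9)) {
    sc <- pcor_scores(mat, "tf1", "m1", shrinkage = lam)
    expect_equal(sc$score, abs((1 - lam) * cor(x, y)), tolerance = 1e-10)
  }
  # lambda = 1: identity precision, all scores vanish.
  sc1 <- pcor_scores(mat, "tf1", "m1", shrinkage = 1)
  expect_equal(sc1$score, 0)
})

test_that("partial correlation suppresses the indirect chain edge", {
  set.seed(8)
  m <- gaussian_chain(500, 0.8, 0.8)
  sc <- pcor_scores(m, "X", c("Y", "Z"), shrinkage = 0.05)
  # With Y observed, X tells little extra about Z.
  expect_lt(sc$score[sc$module == "Z"], sc$score[sc$module == "Y"])
  full <- pcor_scores(m[, c(1, 2, 3)], c("X", "Y"), "Z", shrinkage = 0.05)
  expect_lt(full$score[full$tf == "X"], full$score[full$tf == "Y"])
})

test_that("forest importance concentrates on the driving TF", {
  set.seed(9)
  X <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(NULL, paste0("tf", 1:10)))
  mat <- cbind(X, m1 = X[, "tf4"])
  sc <- rf_scores(mat, paste0("tf", 1:10), "m1", trees = 500, seed = 1)
  # With sqrt(p) feature subsampling, forced off-target splits dilute the
  # driver's impurity share; it still dominates the ranking decisively.
  expect_identical(sc$tf[which.max(sc$score)], "tf4")
  expect_gt(sc$score[sc$tf == "tf4"], 0.4)
  expect_gt(sc$score[sc$tf == "tf4"],
            3 * max(sc$score[sc$tf != "tf4"]))
  expect_equal(sum(sc$score), 1, tolerance = 1e-9)

  # Pure-noise target: no dominant regulator across seeds.
  maxima <- vapply(1:10, function(s) {
    set.seed(100 + s)
    mat2 <- cbind(X, m1 = rnorm(30))
    max(rf_scores(mat2, paste0("tf", 1:10), "m1", trees = 300,
                  seed = s)$score)
  }, numeric(1))
  expect_true(all(maxima < 0.5))

  # Determinism under a fixed seed.
  s1 <- rf_scores(mat, paste0("tf", 1:10), "m1", trees = 200, seed = 3)
  s2 <- rf_scores(mat, paste0("tf", 1:10), "m1", trees = 200, seed = 3)
  expect_identical(s1, s2)
})

test_that("binarization keeps the budget, breaks ties, drops zeros", {
  sc <- data.frame(tf = c("b", "a", "c"), module = c("m", "m", "m"),
                   method = "clr", score = c(5, 5, 1))
  kept <- binarize_scores(sc, 2)
  expect_identical(kept$tf, c("a", "b"))  # tie at 5: lexicographic

  sc$score <- 0
  expect_equal(nrow(binarize_scores(sc, 10)), 0)
})

test_that("consensus voting applies the at-least-four-of-five rule", {
  edge <- data.frame(tf = "tfA", module = "m1")
  none <- edge[0, ]
  sets <- list(aracne = edge, clr = edge, lars = edge, pcor = none,
               rf = edge)
  cons <- consensus_edges(sets, kmin = 4)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$support, 4L)
  expect_identical(cons$methods, "aracne,clr,lars,rf")

  sets3 <- list(aracne = edge, clr = edge, lars = edge, pcor = none,
                rf = none)
  expect_equal(nrow(consensus_edges(sets3, kmin = 4)), 0)

  # kmin = 1 returns the union; raising kmin never adds an edge.
  other <- data.frame(tf = "tfB", module = "m2")
  sets_u <- list(aracne = edge, clr = other, lars = none, pcor = none,
                 rf = none)
  expect_equal(nrow(consensus_edges(sets_u, kmin = 1)), 2)
  for (k in 2:5) {
    lo <- consensus_edges(sets, kmin = k - 1)
    hi <- consensus_edges(sets, kmin = k)
    expect_true(all(paste(hi$tf, hi$module) %in% paste(lo$tf, lo$module)))
  }

  expect_error(consensus_edges(sets[1:4], kmin = 4), "five")
})

test_that("deterministic scorers are invariant to condition permutation", {
  set.seed(10)
  mat <- matrix(rnorm(12 * 8), 12, 8,
                dimnames = list(NULL, c(paste0("tf", 1:5),
                                        paste0("m", 1:3))))
  tfs <- paste0("tf", 1:5); mods <- paste0("m", 1:3)
  perm <- sample(12)
  for (fn in list(
    function(m) aracne_scores(m, tfs, mods, 0.1),
    function(m) clr_scores(m, tfs, mods),
    function(m) lars_scores(m, tfs, mods, 4),
    function(m) pcor_scores(m, tfs, mods, 0.2))) {
    expect_equal(fn(mat), fn(mat[perm, ]), tolerance = 1e-12)
  }
  # The forest scorer is stochastic in row resampling; on a strong signal
  # its top regulator is stable under permutation.
  mat[, "m1"] <- mat[, "tf2"]
  r1 <- rf_scores(mat, tfs, mods, trees = 300, seed = 5)
  r2 <- rf_scores(mat[perm, ], tfs, mods, trees = 300, seed = 5)
  pick <- function(r) r$tf[r$module == "m1"][which.max(
    r$score[r$module == "m1"])]
  expect_identical(pick(r1), pick(r2))
})

test_that("the regulator matrix has deterministic shape and ordering", {
  d <- generate_design("standard")
  tr <- plant_truth(d, seed = 71)
  sim <- simulate_counts(d, tr, seed = 72)
  cm <- sim$counts
  sf <- size_factors(cm)
  vst <- vst_transform(cm, sf, estimate_dispersion(cm, sf))
  mg <- names(tr$module_of)[!is.na(tr$module_of)]
  prof <- build_profiles(vst, cm$meta, mg, "MRP")
  mm <- module_means(prof, tr$module_of)
  reg <- build_regulator_matrix(vst, cm$meta, tr$tf_set, mm, "MRP")
  expect_equal(dim(reg$mat), c(12, 38))  # 12 conditions, 30 TFs + 8 modules
  expect_identical(reg$tf_cols, sort(tr$tf_set))
  reg2 <- build_regulator_matrix(vst, cm$meta, rev(tr$tf_set), mm, "MRP")
  expect_identical(reg$mat, reg2$mat)
})
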