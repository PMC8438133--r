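test_that("design presets match the study layout", {
  full <- generate_design("paper_full")
  meta <- design_meta(full)
  expect_equal(nrow(meta), 72)  # 8 lines x 3 stages x 3 replicates
  expect_setequal(unique(meta$subset), c("Mips", "MRP", "MipsMRP"))

  # 2mlpa carries both MRP mutations but an intact MIPS1 allele.
  l <- full$lines[full$lines$line == "2mlpa", ]
  expect_false(l$mips1); expect_true(l$mrp_l); expect_true(l$mrp_n)
  expect_identical(l$phytic_class, "lpa")
  # Single-mrp lines are normal phytic acid.
  expect_identical(full$lines$phytic_class[full$lines$line == "2MWT-L"],
                   "normal")

  expect_equal(nrow(design_meta(generate_design("mini"))), 12)
  std <- design_meta(generate_design("standard"))
  expect_equal(nrow(std), 36)
  expect_identical(unique(std$subset), "MRP")

  expect_error(generate_design("bogus"), "unknown")
})

test_that("planted truth is deterministic and structurally sound", {
  d <- generate_design("standard")
  t1 <- plant_truth(d, seed = 11)
  t2 <- plant_truth(d, seed = 11)
  expect_identical(t1, t2)
  t3 <- plant_truth(d, seed = 12)
  expect_false(identical(t1$true_edges, t3$true_edges))

  # Every module regulated when n_edges >= n_modules.
  expect_setequal(unique(t1$true_edges$module), 1:8)
  # Planted DE genes live outside modules and outside the TF set.
  expect_true(all(is.na(t1$module_of[t1$de_genes$gene])))
  expect_length(intersect(t1$de_genes$gene, t1$tf_set), 0)
  expect_true(all(abs(t1$de_genes$delta) >= t1$lfc_scale))
  expect_true(all(abs(t1$true_edges$beta) >= t1$effect_scale / 2 &
                    abs(t1$true_edges$beta) <= t1$effect_scale))

  expect_error(plant_truth(d, n_tfs = 10, n_modules = 2, n_edges = 21),
               "infeasible")
})

test_that("module sizes stay at or above three across many seeds", {
  d <- generate_design("mini")
  min_sizes <- vapply(1:50, function(s) {
    tr <- plant_truth(d, n_genes = 200, n_tfs = 10, n_modules = 8,
                      n_edges = 8, seed = s)
    min(table(tr$module_of))
  }, numeric(1))
  expect_true(all(min_sizes >= 3))
})

test_that("identical seeds give bit-identical counts", {
  d <- generate_design("mini")
  tr <- plant_truth(d, n_genes = 60, n_tfs = 5, n_modules = 3, n_edges = 3,
                    n_de_per_stage = 2, seed = 4)
  s1 <- simulate_counts(d, tr, seed = 9)
  s2 <- simulate_counts(d, tr, seed = 9)
  expect_identical(s1$counts$counts, s2$counts$counts)
  s3 <- simulate_counts(d, tr, seed = 10)
  expect_false(identical(s1$counts$counts, s3$counts$counts))
})

test_that("the paper design yields 72 sample columns", {
  d <- generate_design("paper_full")
  tr <- plant_truth(d, n_genes = 50, n_tfs = 4, n_modules = 3, n_edges = 3,
                    n_de_per_stage = 1, seed = 1)
  sim <- simulate_counts(d, tr, seed = 1)
  expect_equal(ncol(sim$counts$counts), 72)
})

test_that("counts approach the Poisson limit as dispersion vanishes", {
  d <- generate_design("mini")
  d$replicates <- 200L
  tr <- plant_truth(d, n_genes = 40, n_tfs = 2, n_modules = 3, n_edges = 0,
                    alpha = 1e-8, sigma = 0, n_de_per_stage = 0, seed = 2)
  # High-baseline genes so the mean is >= 100.
  tr$baseline_log2[] <- 8
  sim <- simulate_counts(d, tr, seed = 3)
  sf <- attr(sim$counts, "size_factors")
  meta <- sim$counts$meta
  idx <- which(meta$line == "MWT" & meta$stage == 1)
  background <- setdiff(tr$genes[-(1:2)],
                        names(tr$module_of)[!is.na(tr$module_of)])
  ratios <- vapply(background, function(g) {
    x <- sim$counts$counts[g, idx] / sf[idx]   # each has mean mu, var mu/sf
    mu_hat <- mean(x)
    v <- mean(sf[idx] * (x - mu_hat)^2)        # pooled Poisson-scale variance
    v / mu_hat
  }, numeric(1))
  expect_lt(abs(stats::median(ratios) - 1), 0.2)
})

test_that("a planted +2 log2 effect quadruples the lpa mean", {
  d <- generate_design("mini")
  d$replicates <- 100L
  tr <- plant_truth(d, n_genes = 50, n_tfs = 2, n_modules = 3, n_edges = 0,
                    alpha = 0.01, sigma = 0, n_de_per_stage = 0, seed = 5)
  g <- setdiff(tr$genes, c(tr$tf_set,
                           names(tr$module_of)[!is.na(tr$module_of)]))[1]
  tr$de_genes <- data.frame(gene = g, subset = "Mips", stage = 1L,
                            delta = 2, stringsAsFactors = FALSE)
  sim <- simulate_counts(d, tr, seed = 6)
  sf <- attr(sim$counts, "size_factors")
  meta <- sim$counts$meta
  q <- sim$counts$counts[g, ] / sf
  ratio <- mean(q[meta$phytic_class == "lpa" & meta$stage == 1]) /
    mean(q[meta$phytic_class == "normal" & meta$stage == 1])
  expect_lt(abs(ratio - 4) / 4, 0.1)
  # The effect is stage-specific: other stages stay near parity.
  r2 <- mean(q[meta$phytic_class == "lpa" & meta$stage == 2]) /
    mean(q[meta$phytic_class == "normal" & meta$stage == 2])
  expect_lt(abs(r2 - 1), 0.2)
})

test_that("same-module genes are more correlated than cross-module pairs", {
  d <- generate_design("standard")
  tr <- plant_truth(d, seed = 21)
  sim <- simulate_counts(d, tr, seed = 22)
  cm <- sim$counts
  sf <- size_factors(cm)
  vst <- vst_transform(cm, sf, estimate_dispersion(cm, sf))
  genes <- names(tr$module_of)[!is.na(tr$module_of)][1:120]
  prof <- build_profiles(vst, cm$meta, genes, "MRP")
  cc <- stats::cor(t(prof))
  same <- outer(tr$module_of[genes], tr$module_of[genes], "==")
  diag(same) <- NA
  expect_gt(stats::median(cc[same & upper.tri(cc)], na.rm = TRUE),
            stats::median(cc[!same & upper.tri(cc)], na.rm = TRUE))
})

test_that("synthetic annotations are consistent with the planted truth", {
  d <- generate_design("standard")
  tr <- plant_truth(d, seed = 31)
  ann <- generate_annotations(tr, seed = 32)
  expect_setequal(names(ann), c("go_map", "tf_map", "homologs", "dap_edges",
                                "motif_matches"))
  expect_setequal(ann$tf_map$gene, tr$tf_set)
  # Module terms annotate only module members.
  mod_terms <- grepl("^GO:MOD", ann$go_map$term)
  expect_true(all(!is.na(tr$module_of[ann$go_map$gene[mod_terms]])))
  # Motif matches are a subset of the true edges.
  truth_keys <- paste(tr$true_edges$module, tr$true_edges$tf)
  expect_true(all(paste(ann$motif_matches$module,
                        ann$motif_matches$tf_gene) %in% truth_keys))
})
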