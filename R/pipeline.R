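# Orchestration: run every stage for one genotypic subset with a single
# config and deterministic derived seeds, writing all intermediate
# artifacts plus a manifest; and the end-to-end synthetic benchmark.

#' Pipeline configuration
#'
#' Collects the inputs and every stage parameter. Inputs may be file paths
#' (read with the io functions) or in-memory objects of the matching type.
#'
#' @param counts A [count_matrix()], or a counts TSV path (then `meta` must
#'   be the metadata TSV path).
#' @param meta Metadata TSV path when `counts` is a path.
#' @param go_map,tf_map,dap_edges,motif_matches Data frames or TSV paths.
#' @param homologs Data frame or 12-column alignment file path.
#' @param padj_max,lfc_min,basemean_min DEG filters.
#' @param enrich_fdr GO enrichment FDR threshold.
#' @param K_range,families,restarts Module-clustering sweep.
#' @param inference An [inference_config()].
#' @param evalue_max Homology e-value cutoff.
#' @param seed Global seed; per-stage seeds are derived via [stage_seed()].
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, meta = NULL, go_map = NULL,
                            tf_map = NULL, homologs = NULL,
                            dap_edges = NULL, motif_matches = NULL,
                            padj_max = 0.01, lfc_min = 1,
                            basemean_min = 10, enrich_fdr = 0.05,
                            K_range = 2:15, families = GMM_FAMILIES,
                            restarts = 5,
                            inference = inference_config(),
                            evalue_max = 1e-5, seed = 1,
                            out_dir = "germnet_out") {
  structure(list(counts = counts, meta = meta, go_map = go_map,
                 tf_map = tf_map, homologs = homologs,
                 dap_edges = dap_edges, motif_matches = motif_matches,
                 padj_max = padj_max, lfc_min = lfc_min,
                 basemean_min = basemean_min, enrich_fdr = enrich_fdr,
                 K_range = K_range, families = families,
                 restarts = restarts, inference = inference,
                 evalue_max = evalue_max, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

resolve_input <- function(x, reader, what) {
  if (is.null(x)) stop("missing pipeline input: ", what)
  if (is.character(x) && length(x) == 1) reader(x) else x
}

config_for_manifest <- function(config) {
  keep <- config[c("padj_max", "lfc_min", "basemean_min", "enrich_fdr",
                   "restarts", "evalue_max", "seed")]
  keep$K_range <- range(config$K_range)
  keep$families <- config$families
  keep$inference <- unclass(config$inference)
  keep
}

#' Run every stage of the pipeline for one genotypic subset
#'
#' Executes differential expression, module clustering, GO enrichment,
#' ensemble network inference, consensus voting, TF-gene expansion and
#' homology/DAP-seq/motif validation, writing each intermediate artifact as
#' TSV (or JSON) under `config$out_dir/<subset>/` plus a `manifest.json`
#' recording parameters, derived seeds and per-stage row counts. Reruns
#' with the same config and seed produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param subset Genotypic subset to analyse.
#' @return The manifest, invisibly (a list).
#' @export
run_subset <- function(config, subset) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- file.path(config$out_dir, subset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(subset = subset, package_version =
                     as.character(utils::packageVersion("germnet")),
                   parameters = config_for_manifest(config),
                   stages = list())
  state <- new.env(parent = emptyenv())

  finish_stage <- function(name, counts) {
    manifest$stages[[name]] <<- list(status = "ok", counts = counts)
    germnet_log("stage ", name, " done (", subset, ")")
  }
  fail <- function(name, err) {
    manifest$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(err))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stop("stage '", name, "' failed for subset ", subset, ": ",
         conditionMessage(err), call. = FALSE)
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) fail(name, e))
    finish_stage(name, res)
  }

  run_stage("de", function() {
    cm <- if (is.character(config$counts)) {
      read_counts(config$counts, config$meta)
    } else config$counts
    state$cm <- cm
    state$sf <- size_factors(cm)
    state$disp <- estimate_dispersion(cm, state$sf)
    records <- de_analysis(cm, subset, state$sf, state$disp,
                           padj_max = config$padj_max,
                           lfc_min = config$lfc_min,
                           basemean_min = config$basemean_min)
    state$degs <- call_degs_subset(records, subset)
    state$venn <- venn_partition(state$degs)
    write_tsv_table(records, file.path(out_dir, "de_records.tsv"))
    deg_df <- do.call(rbind, lapply(names(state$degs), function(st) {
      if (!length(state$degs[[st]])) return(NULL)
      data.frame(stage = st, gene = state$degs[[st]],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(deg_df)) {
      deg_df <- data.frame(stage = character(0), gene = character(0))
    }
    write_tsv_table(deg_df, file.path(out_dir, "deg_sets.tsv"))
    jsonlite::write_json(as.list(state$venn),
                         file.path(out_dir, "venn.json"),
                         auto_unbox = TRUE, digits = NA)
    list(records = nrow(records),
         degs = length(unique(unlist(state$degs))))
  })

  run_stage("cluster", function() {
    deg_union <- sort(unique(unlist(state$degs)))
    if (length(deg_union) < 10) {
      stop("too few DEGs to cluster (", length(deg_union), ")")
    }
    vst <- vst_transform(state$cm, state$sf, state$disp)
    state$vst <- vst
    state$profiles <- build_profiles(vst, state$cm$meta, deg_union, subset)
    k_range <- config$K_range[config$K_range < length(deg_union)]
    assignment <- select_model(state$profiles, k_range, config$families,
                               config$restarts,
                               seed = stage_seed(config$seed, "cluster",
                                                 subset))
    state$assignment <- assignment
    write_tsv_table(data.frame(gene = names(assignment$module_of),
                               module = unname(assignment$module_of)),
                    file.path(out_dir, "modules.tsv"))
    write_tsv_table(assignment$sweep, file.path(out_dir, "bic_sweep.tsv"))
    list(genes = length(deg_union), K = assignment$fit$K,
         family = assignment$fit$family)
  })

  run_stage("enrich", function() {
    go <- resolve_input(config$go_map, read_go_map, "go_map")
    res <- enrich_modules(state$assignment$module_of, go,
                          fdr = config$enrich_fdr)
    write_tsv_table(res, file.path(out_dir, "enrichment.tsv"))
    list(tested = nrow(res), enriched = sum(res$enriched))
  })

  run_stage("infer", function() {
    tf_map <- resolve_input(config$tf_map, read_tf_map, "tf_map")
    deg_union <- names(state$assignment$module_of)
    tfs <- intersect(deg_union, tf_map$gene)
    if (length(tfs) < 2) stop("fewer than 2 differentially expressed TFs")
    state$mod_means <- module_means(state$profiles,
                                    state$assignment$module_of)
    cfg <- config$inference
    cfg$rf_seed <- stage_seed(config$seed, "rf", subset)
    reg <- build_regulator_matrix(state$vst, state$cm$meta, tfs,
                                  state$mod_means, subset)
    state$grn <- infer_grn(reg, cfg)
    for (m in names(state$grn$scores)) {
      write_tsv_table(state$grn$scores[[m]],
                      file.path(out_dir, paste0("scores_", m, ".tsv")))
    }
    list(tfs = length(tfs), modules = length(reg$module_cols))
  })

  run_stage("consensus", function() {
    cons <- state$grn$consensus
    write_edge_list(data.frame(regulator = cons$tf, target = cons$module,
                               support = cons$support,
                               methods = cons$methods,
                               stringsAsFactors = FALSE),
                    file.path(out_dir, "network.tsv"))
    list(edges = nrow(cons))
  })

  run_stage("expand", function() {
    state$tf_gene <- expand_edges(state$grn$consensus,
                                  state$assignment$module_of)
    write_tsv_table(state$tf_gene, file.path(out_dir, "tf_gene_edges.tsv"))
    list(tf_gene_edges = nrow(state$tf_gene))
  })

  run_stage("validate", function() {
    hits <- resolve_input(config$homologs, read_tabular_hits, "homologs")
    dap <- resolve_input(config$dap_edges, read_dap_edges, "dap_edges")
    motifs <- resolve_input(config$motif_matches, read_motif_matches,
                            "motif_matches")
    hmap <- best_hits(hits, config$evalue_max)
    val <- dap_overlap(state$tf_gene, hmap, dap)
    cons_val <- motif_overlap(state$grn$consensus, motifs)
    write_tsv_table(val$edges, file.path(out_dir, "validated_edges.tsv"))
    write_tsv_table(cons_val,
                    file.path(out_dir, "consensus_validated.tsv"))
    jsonlite::write_json(val$summary,
                         file.path(out_dir, "validation_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    val$summary
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# ---- Synthetic benchmark ---------------------------------------------------

precision_recall <- function(predicted, truth_keys) {
  if (!length(predicted)) {
    return(c(precision = if (length(truth_keys)) 0 else 1, recall = 0))
  }
  tp <- sum(predicted %in% truth_keys)
  c(precision = tp / length(predicted),
    recall = if (length(truth_keys)) tp / length(truth_keys) else 1)
}

#' Ensemble edge recovery on one simulated data set
#'
#' Simulates counts under a design and planted truth, builds planted-module
#' mean profiles and TF profiles, runs the five-method ensemble and
#' compares the consensus TF-module edges (and each method's binarized
#' set) with the planted edges.
#'
#' @param design A [generate_design()] object (one genotypic subset).
#' @param truth A [plant_truth()] object.
#' @param seed Simulation seed.
#' @param config An [inference_config()].
#' @return List with `consensus` (precision/recall), `per_method` (matrix),
#'   `n_edges` (consensus size), and the consensus frame.
#' @export
ensemble_recovery <- function(design, truth, seed,
                              config = inference_config()) {
  subset <- unique(design$lines$subset)
  if (length(subset) != 1) {
    stop("ensemble_recovery expects a single-subset design")
  }
  sim <- simulate_counts(design, truth, seed)
  cm <- sim$counts
  sf <- size_factors(cm)
  disp <- estimate_dispersion(cm, sf)
  vst <- vst_transform(cm, sf, disp)
  module_genes <- names(truth$module_of)[!is.na(truth$module_of)]
  profiles <- build_profiles(vst, cm$meta, module_genes, subset)
  mm <- module_means(profiles, truth$module_of)
  cfg <- config
  cfg$rf_seed <- stage_seed(seed, "bench-rf")
  reg <- build_regulator_matrix(vst, cm$meta, truth$tf_set, mm, subset)
  grn <- infer_grn(reg, cfg)
  truth_keys <- paste(truth$true_edges$tf, truth$true_edges$module)
  cons_keys <- paste(grn$consensus$tf,
                     sub("^module_", "", grn$consensus$module))
  per_method <- t(vapply(grn$sets, function(s) {
    precision_recall(paste(s$tf, sub("^module_", "", s$module)),
                     truth_keys)
  }, c(precision = 0, recall = 0)))
  list(consensus = precision_recall(cons_keys, truth_keys),
       per_method = per_method, n_edges = nrow(grn$consensus),
       consensus_frame = grn$consensus)
}

#' Differential-expression recovery on one simulated data set
#'
#' Runs the subset's DE stage and scores it against the generative truth:
#' sensitivity over planted-Delta genes (|Delta| >= `delta_min`) whose
#' observed base mean reaches `basemean_min_eval`, and empirical FDR among
#' called DEGs counting as false positives only genes with exactly zero
#' model-implied class effect at the called stage.
#'
#' @param design,truth,seed As in [ensemble_recovery()].
#' @param delta_min Planted-effect floor for the sensitivity set.
#' @param basemean_min_eval Observed base-mean floor for the sensitivity
#'   set.
#' @param ... DEG thresholds passed to [de_analysis()].
#' @return List with `sensitivity`, `fdr`, `n_called`, `n_eligible`.
#' @export
de_recovery <- function(design, truth, seed, delta_min = 2,
                        basemean_min_eval = 50, ...) {
  subset <- unique(design$lines$subset)
  if (length(subset) != 1) stop("de_recovery expects a single-subset design")
  sim <- simulate_counts(design, truth, seed)
  cm <- sim$counts
  sf <- size_factors(cm)
  disp <- estimate_dispersion(cm, sf)
  records <- de_analysis(cm, subset, sf, disp, ...)
  degs <- call_degs_subset(records, subset)
  q <- sweep(cm$counts, 2, sf, "/")

  # Genes with a nonzero model-implied lpa-vs-normal effect: TF genes carry
  # their driver's class offset; module genes inherit their module's
  # beta-weighted offset sum. Only genes outside this set can be false
  # positives.
  has_class_effect <- !is.na(truth$module_of) &
    abs(truth$module_class_lfc[truth$module_of]) > 0
  names(has_class_effect) <- names(truth$module_of)
  has_class_effect[truth$tf_set] <- abs(truth$driver_c[truth$tf_set]) > 0

  n_tp <- 0; n_eligible <- 0; n_called <- 0; n_fp <- 0
  for (st in sort(unique(cm$meta$stage))) {
    called <- degs[[paste0("stage", st)]]
    n_called <- n_called + length(called)
    planted <- truth$de_genes[truth$de_genes$subset == subset &
                                truth$de_genes$stage == st, ]
    planted <- planted[abs(planted$delta) >= delta_min, ]
    idx <- cm$meta$subset == subset & cm$meta$stage == st
    bm <- rowMeans(q[planted$gene, idx, drop = FALSE])
    eligible <- planted$gene[bm >= basemean_min_eval]
    n_eligible <- n_eligible + length(eligible)
    n_tp <- n_tp + sum(eligible %in% called)
    planted_any <- truth$de_genes$gene[truth$de_genes$subset == subset &
                                         truth$de_genes$stage == st]
    null_gene <- !(called %in% planted_any) & !(has_class_effect[called])
    n_fp <- n_fp + sum(null_gene, na.rm = TRUE)
  }
  list(sensitivity = if (n_eligible) n_tp / n_eligible else NA_real_,
       fdr = if (n_called) n_fp / n_called else 0,
       n_called = n_called, n_eligible = n_eligible)
}

#' Clustering recovery on one simulated data set
#'
#' Clusters the subset's DEGs with the BIC-swept mixture model and returns
#' the adjusted Rand index against the planted modules, restricted to DEGs
#' that belong to a planted module.
#'
#' @param design,truth,seed As in [ensemble_recovery()].
#' @param K_range,families,restarts Sweep configuration (a focused default
#'   keeps the benchmark fast; the full six-family sweep is available).
#' @return List with `ari`, `K`, `n_clustered`.
#' @export
clustering_recovery <- function(design, truth, seed, K_range = 2:12,
                                families = "diagonal_varying",
                                restarts = 2) {
  subset <- unique(design$lines$subset)
  sim <- simulate_counts(design, truth, seed)
  cm <- sim$counts
  sf <- size_factors(cm)
  disp <- estimate_dispersion(cm, sf)
  records <- de_analysis(cm, subset, sf, disp)
  degs <- sort(unique(unlist(call_degs_subset(records, subset))))
  vst <- vst_transform(cm, sf, disp)
  profiles <- build_profiles(vst, cm$meta, degs, subset)
  assignment <- select_model(profiles, K_range[K_range < length(degs)],
                             families, restarts,
                             seed = stage_seed(seed, "bench-cluster"))
  in_mod <- degs[!is.na(truth$module_of[degs])]
  ari <- adjusted_rand_index(assignment$module_of[in_mod],
                             truth$module_of[in_mod])
  list(ari = ari, K = assignment$fit$K, n_clustered = length(in_mod))
}

#' End-to-end synthetic benchmark over seeds
#'
#' For each seed: generate a standard-preset data set and measure ensemble
#' edge recovery, DE recovery, and (for the first `cluster_seeds` seeds)
#' clustering recovery. Returns per-seed metrics and their medians.
#'
#' @param n_seeds Number of simulation seeds.
#' @param seed Base seed.
#' @param design Study design (default the standard 12-condition preset).
#' @param truth_args Named list of overrides for [plant_truth()].
#' @param config An [inference_config()].
#' @param cluster_seeds How many seeds also run the (slower) clustering
#'   recovery; 0 disables it.
#' @return List with `per_seed` (data frame) and `summary` (named medians).
#' @export
run_benchmark <- function(n_seeds = 10, seed = 1,
                          design = generate_design("standard"),
                          truth_args = list(),
                          config = inference_config(),
                          cluster_seeds = 0) {
  rows <- list()
  for (i in seq_len(n_seeds)) {
    s <- stage_seed(seed, "benchmark", i)
    truth <- do.call(plant_truth, c(list(design = design, seed = s),
                                    truth_args))
    ens <- ensemble_recovery(design, truth, stage_seed(s, "counts"), config)
    de <- de_recovery(design, truth, stage_seed(s, "counts"))
    ari <- NA_real_
    if (i <= cluster_seeds) {
      cl <- clustering_recovery(design, truth, stage_seed(s, "counts"))
      ari <- cl$ari
    }
    rows[[i]] <- data.frame(
      seed = s,
      precision = ens$consensus["precision"],
      recall = ens$consensus["recall"],
      n_consensus = ens$n_edges,
      de_sensitivity = de$sensitivity,
      de_fdr = de$fdr,
      ari = ari,
      stringsAsFactors = FALSE)
  }
  per_seed <- do.call(rbind, rows)
  rownames(per_seed) <- NULL
  summary <- c(
    precision = stats::median(per_seed$precision),
    recall = stats::median(per_seed$recall),
    de_sensitivity = stats::median(per_seed$de_sensitivity),
    de_fdr = stats::median(per_seed$de_fdr),
    ari = stats::median(per_seed$ari, na.rm = TRUE))
  list(per_seed = per_seed, summary = summary)
}
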