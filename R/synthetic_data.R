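# Synthetic count data with the germination study's design and a known
# ground truth (differential genes, co-expression modules, TF -> module
# regulation), so every downstream stage can be benchmarked without the
# deposited sequencing data.

PAPER_LINES <- data.frame(
  line = c("1mlpa", "1MWT", "2mlpa", "2MWT", "2MWT-L", "2MWT-N",
           "3mlpa", "3MWT"),
  subset = c("Mips", "Mips", "MRP", "MRP", "MRP", "MRP",
             "MipsMRP", "MipsMRP"),
  mips1 = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
  mrp_l = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
  mrp_n = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
  stringsAsFactors = FALSE
)
PAPER_LINES$phytic_class <-
  ifelse(PAPER_LINES$mips1 | (PAPER_LINES$mrp_l & PAPER_LINES$mrp_n),
         "lpa", "normal")

#' Build a germination study design
#'
#' `paper_full` is the complete design: eight lines in three genotypic
#' subsets (Mips: 1mlpa/1MWT; MRP: 2mlpa plus three normal near-isogenic
#' lines; Mips-MRP: 3mlpa/3MWT), three germination stages (dry seed, imbibed
#' seed, radicle emergence) and three biological replicates, i.e. 72
#' samples. `standard` is the MRP slice of that design (four lines, twelve
#' line-by-stage conditions), the default benchmarking regime. `mini` is a
#' two-line, two-replicate design for fast tests.
#'
#' @param preset One of `"paper_full"`, `"standard"`, `"mini"`.
#' @return An object of class `study_design`: a list with `lines` (data
#'   frame of line, subset, genotype flags, phytic_class), `stages`, and
#'   `replicates`.
#' @export
generate_design <- function(preset = c("paper_full", "standard", "mini")) {
  if (!is.character(preset) || !preset[1] %in%
      c("paper_full", "standard", "mini")) {
    stop("unknown design preset: ", preset[1])
  }
  preset <- preset[1]
  if (preset == "paper_full") {
    lines <- PAPER_LINES
    reps <- 3L
  } else if (preset == "standard") {
    lines <- PAPER_LINES[PAPER_LINES$subset == "MRP", ]
    reps <- 3L
  } else {
    lines <- data.frame(
      line = c("mlpa", "MWT"), subset = "Mips",
      mips1 = c(TRUE, FALSE), mrp_l = FALSE, mrp_n = FALSE,
      phytic_class = c("lpa", "normal"), stringsAsFactors = FALSE)
    reps <- 2L
  }
  rownames(lines) <- NULL
  structure(list(lines = lines, stages = 1:3, replicates = reps),
            class = "study_design")
}

#' Expand a study design into per-sample metadata
#'
#' @param design A [generate_design()] object.
#' @return Data frame with one row per sample (line x stage x replicate).
#' @export
design_meta <- function(design) {
  stopifnot(inherits(design, "study_design"))
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      stage = design$stages,
                      line = design$lines$line,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("line", "stage", "replicate")]
  idx <- match(grid$line, design$lines$line)
  meta <- data.frame(
    sample_id = sprintf("%s_s%d_r%d", grid$line, grid$stage, grid$replicate),
    line = grid$line,
    subset = design$lines$subset[idx],
    mips1 = design$lines$mips1[idx],
    mrp_l = design$lines$mrp_l[idx],
    mrp_n = design$lines$mrp_n[idx],
    phytic_class = design$lines$phytic_class[idx],
    stage = as.integer(grid$stage),
    replicate = as.integer(grid$replicate),
    stringsAsFactors = FALSE
  )
  rownames(meta) <- NULL
  meta
}

#' Plant a synthetic ground truth on top of a study design
#'
#' Draws, deterministically for a given seed: disjoint TF, module-member and
#' background gene sets; module memberships (every module gets at least
#' three genes); TF -> module regulatory edges with signed effects `beta`,
#' |beta| uniform in `[effect_scale/2, effect_scale]`, every module
#' receiving at least one regulator whenever `n_edges >= n_modules`;
#' per-TF driver profiles (a stage profile plus a low- vs normal-phytic-acid
#' offset, so regulation is identifiable from a handful of averaged
#' conditions); and planted stage-specific differential genes with
#' |Delta| in `[lfc_scale, lfc_scale + 1]` (log2) among background genes of
#' each genotypic subset.
#'
#' @param design A [generate_design()] object.
#' @param n_genes,n_tfs,n_modules,n_edges Problem dimensions; `n_tfs <
#'   n_genes`, `n_edges <= n_tfs * n_modules`.
#' @param effect_scale Upper bound of |beta| (log2 units per driver SD).
#' @param lfc_scale Lower bound of planted |Delta| (log2 units).
#' @param alpha Negative binomial dispersion (Var = mu + alpha mu^2).
#' @param sigma Log2-scale replicate noise SD.
#' @param seed Integer seed; identical seeds give field-wise identical truth.
#' @param module_frac Fraction of non-TF genes assigned to modules.
#' @param n_de_per_stage Planted differential genes per (subset, stage).
#' @param module_amp SD of the modules' intrinsic stage profiles.
#' @return An object of class `planted_truth`.
#' @export
plant_truth <- function(design, n_genes = 500, n_tfs = 30, n_modules = 8,
                        n_edges = 12, effect_scale = 2, lfc_scale = 2,
                        alpha = 0.05, sigma = 0.1, seed = 1,
                        module_frac = 0.65, n_de_per_stage = 20,
                        module_amp = 0.25) {
  stopifnot(inherits(design, "study_design"))
  if (n_tfs >= n_genes) stop("n_tfs must be < n_genes")
  if (n_edges > n_tfs * n_modules) {
    stop("infeasible edge count: n_edges > n_tfs * n_modules")
  }
  if (alpha <= 0) stop("alpha must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  n_stages <- length(design$stages)
  set.seed(seed)

  genes <- sprintf("g%05d", seq_len(n_genes))
  tf_set <- genes[seq_len(n_tfs)]
  non_tf <- genes[-seq_len(n_tfs)]
  n_module_genes <- max(3L * n_modules,
                        floor(module_frac * length(non_tf)))
  if (n_module_genes > length(non_tf)) {
    stop("not enough genes to fill modules of size >= 3")
  }
  module_genes <- non_tf[seq_len(n_module_genes)]
  background <- setdiff(non_tf, module_genes)

  # Module sizes: 3 guaranteed members each, remainder spread uniformly.
  sizes <- rep(3L, n_modules)
  extra <- n_module_genes - 3L * n_modules
  if (extra > 0) {
    add <- tabulate(sample.int(n_modules, extra, replace = TRUE), n_modules)
    sizes <- sizes + add
  }
  module_of <- rep(NA_integer_, n_genes)
  names(module_of) <- genes
  module_of[module_genes] <- rep(seq_len(n_modules), times = sizes)

  # Edges: one distinct regulator per module first, then extra random pairs.
  first_tfs <- sample(tf_set, min(n_modules, n_edges),
                      replace = n_tfs < n_modules)
  edges <- data.frame(tf = first_tfs,
                      module = seq_len(min(n_modules, n_edges)),
                      stringsAsFactors = FALSE)
  n_extra <- n_edges - nrow(edges)
  if (n_extra > 0) {
    all_pairs <- expand.grid(tf = tf_set, module = seq_len(n_modules),
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    key <- paste(all_pairs$tf, all_pairs$module)
    avail <- all_pairs[!key %in% paste(edges$tf, edges$module), ]
    pick <- avail[sample.int(nrow(avail), n_extra), ]
    edges <- rbind(edges, pick)
  }
  edges$beta <- sample(c(-1, 1), nrow(edges), replace = TRUE) *
    stats::runif(nrow(edges), effect_scale / 2, effect_scale)
  rownames(edges) <- NULL

  driver_a <- matrix(stats::rnorm(n_tfs * n_stages), n_tfs, n_stages,
                     dimnames = list(tf_set, paste0("stage", design$stages)))
  driver_c <- stats::rnorm(n_tfs)
  names(driver_c) <- tf_set

  module_profile <- matrix(stats::rnorm(n_modules * n_stages, 0, module_amp),
                           n_modules, n_stages)

  baseline_log2 <- stats::runif(n_genes, 3, 10)
  names(baseline_log2) <- genes

  # Planted DE: subsets that actually contain both classes, background genes
  # only, each gene planted for at most one (subset, stage).
  subs <- unique(design$lines$subset)
  subs <- subs[vapply(subs, function(s) {
    cls <- design$lines$phytic_class[design$lines$subset == s]
    all(c("lpa", "normal") %in% cls)
  }, logical(1))]
  de <- data.frame(gene = character(0), subset = character(0),
                   stage = integer(0), delta = numeric(0),
                   stringsAsFactors = FALSE)
  pool <- sample(background)
  for (s in if (n_de_per_stage > 0) subs else character(0)) {
    for (st in design$stages) {
      n_take <- min(n_de_per_stage, length(pool))
      if (n_take < n_de_per_stage) {
        warning("background gene pool exhausted while planting DE genes")
      }
      if (n_take == 0) break
      g <- pool[seq_len(n_take)]
      pool <- pool[-seq_len(n_take)]
      de <- rbind(de, data.frame(
        gene = g, subset = s, stage = st,
        delta = sample(c(-1, 1), n_take, replace = TRUE) *
          stats::runif(n_take, lfc_scale, lfc_scale + 1),
        stringsAsFactors = FALSE))
    }
  }

  # Model-implied lpa-vs-normal log2 effect carried by each module (the
  # class offsets of its regulators weighted by beta); stage-constant.
  module_class_lfc <- vapply(seq_len(n_modules), function(m) {
    e <- edges[edges$module == m, , drop = FALSE]
    if (!nrow(e)) return(0)
    sum(e$beta * driver_c[e$tf])
  }, numeric(1))

  structure(list(
    genes = genes, tf_set = tf_set, module_of = module_of,
    true_edges = edges, de_genes = de,
    baseline_log2 = baseline_log2,
    driver_a = driver_a, driver_c = driver_c,
    module_profile = module_profile,
    module_class_lfc = module_class_lfc,
    effect_scale = effect_scale, lfc_scale = lfc_scale,
    alpha = alpha, sigma = sigma, module_amp = module_amp,
    seed = seed
  ), class = "planted_truth")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("planted_truth:", length(x$genes), "genes,", length(x$tf_set), "TFs,",
      max(x$module_of, na.rm = TRUE), "modules,", nrow(x$true_edges),
      "TF->module edges,", nrow(x$de_genes), "planted DE records\n")
  invisible(x)
}

#' Simulate a count matrix from a design and a planted truth
#'
#' For gene g and sample j the log2 mean is baseline(g) + the driver profile
#' (TF genes), or the module's intrinsic stage profile plus the
#' beta-weighted sum of its regulators' drivers (module genes), plus the
#' planted Delta when (g, subset(j), stage(j)) is a planted differential
#' record and sample j is a low-phytic-acid line, plus N(0, sigma) replicate
#' noise. Counts are negative binomial with Var = mu + alpha mu^2, scaled by
#' per-sample library-size factors drawn log-uniform in [0.5, 2].
#'
#' @param design A [generate_design()] object.
#' @param truth A [plant_truth()] object.
#' @param seed Integer seed; identical inputs give bit-identical counts.
#' @return List with `counts` (a [count_matrix()], size factors in
#'   `attr(, "size_factors")`) and `truth`.
#' @export
simulate_counts <- function(design, truth, seed = 1) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "planted_truth"))
  meta <- design_meta(design)
  n_samples <- nrow(meta)
  n_genes <- length(truth$genes)
  n_tfs <- length(truth$tf_set)
  set.seed(seed)

  sf <- exp(stats::runif(n_samples, log(0.5), log(2)))
  names(sf) <- meta$sample_id

  stage_idx <- match(meta$stage, design$stages)
  is_lpa <- meta$phytic_class == "lpa"

  # TF driver values per sample: stage profile + class offset.
  drivers <- truth$driver_a[, stage_idx, drop = FALSE] +
    truth$driver_c %o% as.numeric(is_lpa)

  n_modules <- nrow(truth$module_profile)
  beta_mat <- matrix(0, n_modules, n_tfs,
                     dimnames = list(NULL, truth$tf_set))
  for (i in seq_len(nrow(truth$true_edges))) {
    e <- truth$true_edges[i, ]
    beta_mat[e$module, e$tf] <- beta_mat[e$module, e$tf] + e$beta
  }
  module_signal <- truth$module_profile[, stage_idx, drop = FALSE] +
    beta_mat %*% drivers

  log2mu <- matrix(truth$baseline_log2, n_genes, n_samples,
                   dimnames = list(truth$genes, meta$sample_id))
  log2mu[truth$tf_set, ] <- log2mu[truth$tf_set, , drop = FALSE] + drivers
  in_module <- !is.na(truth$module_of)
  log2mu[in_module, ] <- log2mu[in_module, , drop = FALSE] +
    module_signal[truth$module_of[in_module], , drop = FALSE]

  if (nrow(truth$de_genes)) {
    for (i in seq_len(nrow(truth$de_genes))) {
      r <- truth$de_genes[i, ]
      hit <- is_lpa & meta$subset == r$subset & meta$stage == r$stage
      if (any(hit)) log2mu[r$gene, hit] <- log2mu[r$gene, hit] + r$delta
    }
  }

  if (truth$sigma > 0) {
    log2mu <- log2mu + matrix(stats::rnorm(n_genes * n_samples, 0,
                                           truth$sigma),
                              n_genes, n_samples)
  }

  mu <- 2^log2mu * rep(sf, each = n_genes)
  counts <- if (truth$alpha < 1e-12) {
    matrix(stats::rpois(length(mu), mu), n_genes, n_samples)
  } else {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / truth$alpha),
           n_genes, n_samples)
  }
  dimnames(counts) <- dimnames(mu)
  cm <- count_matrix(counts, meta)
  attr(cm, "size_factors") <- sf
  list(counts = cm, truth = truth)
}

#' Generate synthetic annotation tables consistent with a planted truth
#'
#' Produces the side tables the validation and enrichment stages consume:
#' a GO map in which each module has a dedicated enriched term covering
#' most of its members (plus uniform background terms), a TF family map for
#' the planted regulators, 12-column homology hits mapping most genes to
#' synthetic Arabidopsis-style ids, a DAP-seq edge list containing a known
#' fraction of the true TF-target pairs (plus decoys), and motif matches
#' for a known fraction of the true TF-module edges. All outputs are
#' synthetic stand-ins for external resources, generated from the truth.
#'
#' @param truth A [plant_truth()] object.
#' @param seed Integer seed.
#' @param go_cover Fraction of each module's genes given its module term.
#' @param hom_cover Fraction of genes with a homology hit under the e-value
#'   threshold.
#' @param dap_cover Fraction of true TF-gene pairs present in the DAP table.
#' @param motif_cover Fraction of true TF-module edges with a motif match.
#' @return List of data frames: `go_map`, `tf_map`, `homologs`,
#'   `dap_edges`, `motif_matches`.
#' @export
generate_annotations <- function(truth, seed = 1, go_cover = 0.7,
                                 hom_cover = 0.85, dap_cover = 0.6,
                                 motif_cover = 0.7) {
  stopifnot(inherits(truth, "planted_truth"))
  set.seed(seed)
  genes <- truth$genes
  n_modules <- nrow(truth$module_profile)

  generic_terms <- sprintf("GO:%07d", 1:25)
  n_generic <- sample(1:3, length(genes), replace = TRUE)
  go <- data.frame(
    gene = rep(genes, n_generic),
    term = unlist(lapply(n_generic, function(k) sample(generic_terms, k))),
    stringsAsFactors = FALSE)
  for (m in seq_len(n_modules)) {
    members <- genes[!is.na(truth$module_of) & truth$module_of == m]
    pick <- members[stats::runif(length(members)) < go_cover]
    if (length(pick)) {
      go <- rbind(go, data.frame(gene = pick,
                                 term = sprintf("GO:MOD%04d", m),
                                 stringsAsFactors = FALSE))
    }
  }
  go <- go[!duplicated(paste(go$gene, go$term)), ]
  go$namespace <- "biological_process"
  go$description <- paste("synthetic process", go$term)
  rownames(go) <- NULL

  fams <- c("ERF", "NAC", "MYB", "bZIP", "C2H2", "Trihelix", "WRKY")
  tf_map <- data.frame(gene = truth$tf_set,
                       family = sample(fams, length(truth$tf_set),
                                       replace = TRUE),
                       stringsAsFactors = FALSE)

  at_ids <- sprintf("AT%dG%05d", sample(1:5, length(genes), replace = TRUE),
                    sample.int(99999, length(genes)))
  has_hit <- stats::runif(length(genes)) < hom_cover
  hom <- data.frame(
    query = genes[has_hit], subject = at_ids[has_hit],
    pct_id = round(stats::runif(sum(has_hit), 60, 99), 1),
    aln_len = sample(100:500, sum(has_hit), replace = TRUE),
    mismatches = sample(0:40, sum(has_hit), replace = TRUE),
    gaps = sample(0:5, sum(has_hit), replace = TRUE),
    qstart = 1, qend = 300, sstart = 1, send = 300,
    evalue = 10^stats::runif(sum(has_hit), -60, -10),
    bitscore = round(stats::runif(sum(has_hit), 120, 400), 1),
    stringsAsFactors = FALSE)
  # A few genes get only a weak hit, above the 1e-5 cutoff downstream.
  weak <- genes[!has_hit][stats::runif(sum(!has_hit)) < 0.2]
  if (length(weak)) {
    hom <- rbind(hom, data.frame(
      query = weak, subject = sprintf("AT1G%05d", sample.int(99999,
                                                             length(weak))),
      pct_id = 40, aln_len = 80, mismatches = 40, gaps = 5,
      qstart = 1, qend = 80, sstart = 1, send = 80,
      evalue = 10^stats::runif(length(weak), -4, -1), bitscore = 40,
      stringsAsFactors = FALSE))
  }
  rownames(hom) <- NULL
  at_of <- stats::setNames(hom$subject, hom$query)

  true_pairs <- do.call(rbind, lapply(seq_len(nrow(truth$true_edges)),
                                      function(i) {
    e <- truth$true_edges[i, ]
    members <- genes[!is.na(truth$module_of) & truth$module_of == e$module]
    members <- setdiff(members, e$tf)
    data.frame(tf = e$tf, target = members, stringsAsFactors = FALSE)
  }))
  mapped <- true_pairs[true_pairs$tf %in% names(at_of) &
                         true_pairs$target %in% names(at_of), ]
  keep <- stats::runif(nrow(mapped)) < dap_cover
  dap <- data.frame(regulator = at_of[mapped$tf[keep]],
                    target = at_of[mapped$target[keep]],
                    stringsAsFactors = FALSE)
  n_decoy <- max(10, nrow(dap) %/% 4)
  decoy <- data.frame(
    regulator = sprintf("AT%dG%05d", sample(1:5, n_decoy, TRUE),
                        sample.int(99999, n_decoy)),
    target = sprintf("AT%dG%05d", sample(1:5, n_decoy, TRUE),
                     sample.int(99999, n_decoy)),
    stringsAsFactors = FALSE)
  dap <- rbind(dap, decoy)
  dap <- dap[!duplicated(paste(dap$regulator, dap$target)), ]
  rownames(dap) <- NULL

  keep_motif <- stats::runif(nrow(truth$true_edges)) < motif_cover
  motifs <- data.frame(module = truth$true_edges$module[keep_motif],
                       tf_gene = truth$true_edges$tf[keep_motif],
                       stringsAsFactors = FALSE)

  list(go_map = go, tf_map = tf_map, homologs = hom, dap_edges = dap,
       motif_matches = motifs)
}
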