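# Differential expression: median-of-ratios size factors, method-of-moments
# NB dispersion, variance-stabilizing transform, and a simplified NB Wald
# test of lpa-vs-normal contrasts per stage, followed by the study's DEG
# filters (padj < 0.01, |log2 FC| > 1, base mean > 10), the MRP
# triple-intersection rule, and the stage-wise Venn partition.

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over genes g (with
#' all-positive counts) of counts[g, j] divided by the geometric mean of
#' gene g across samples. When no gene is positive in every sample and
#' `fallback` is TRUE, geometric means are taken over the positive entries
#' of each gene instead (logged); with `fallback = FALSE` that situation is
#' an error.
#'
#' @param cm A [count_matrix()] or a plain counts matrix.
#' @param fallback Use positive-entry geometric means when no gene is
#'   all-positive.
#' @return Named positive numeric vector of per-sample factors.
#' @export
size_factors <- function(cm, fallback = TRUE) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    sub <- counts[all_pos, , drop = FALSE]
    log_gm <- rowMeans(log(sub))
    ratios <- log(sub) - log_gm
  } else if (fallback) {
    germnet_log("no all-positive gene; using positive-entry geometric means")
    pos <- counts > 0
    if (!any(pos)) stop("degenerate input: all counts are zero")
    log_gm <- rowSums(ifelse(pos, log(pmax(counts, 1e-300)), 0)) /
      pmax(rowSums(pos), 1)
    keep <- rowSums(pos) > 0
    logc <- counts[keep, , drop = FALSE]
    logc <- ifelse(logc > 0, log(logc), NA)
    ratios <- logc - log_gm[keep]
  } else {
    stop("degenerate input: no gene has all-positive counts")
  }
  s <- exp(apply(ratios, 2, stats::median, na.rm = TRUE))
  if (any(!is.finite(s) | s <= 0)) {
    stop("degenerate input: could not compute positive size factors")
  }
  names(s) <- colnames(counts)
  s
}

#' Method-of-moments negative binomial dispersion
#'
#' On normalized counts, each gene's dispersion is the
#' degrees-of-freedom-weighted pool over replicate cells (line x stage with
#' at least two replicates) of (variance - mean) / mean^2, floored at
#' `alpha_min`. The common dispersion is the median of the per-gene values.
#'
#' @param cm A [count_matrix()].
#' @param sf Size factors from [size_factors()].
#' @param alpha_min Dispersion floor.
#' @return List with `per_gene` (named numeric), `common`, `alpha_min`.
#' @export
estimate_dispersion <- function(cm, sf, alpha_min = 1e-8) {
  stopifnot(inherits(cm, "count_matrix"))
  q <- sweep(cm$counts, 2, sf, "/")
  cell <- paste(cm$meta$line, cm$meta$stage, sep = "::")
  cells <- split(seq_len(ncol(q)), cell)
  cells <- cells[lengths(cells) >= 2]
  if (!length(cells)) {
    stop("degenerate input: no (line, stage) cell has >= 2 replicates")
  }
  num <- rep(0, nrow(q))
  den <- rep(0, nrow(q))
  for (idx in cells) {
    m <- rowMeans(q[, idx, drop = FALSE])
    v <- apply(q[, idx, drop = FALSE], 1, stats::var)
    w <- length(idx) - 1
    ok <- m > 1e-8
    num[ok] <- num[ok] + w * (v[ok] - m[ok]) / m[ok]^2
    den[ok] <- den[ok] + w
  }
  per_gene <- ifelse(den > 0, num / pmax(den, 1), alpha_min)
  per_gene <- pmax(per_gene, alpha_min)
  names(per_gene) <- rownames(q)
  list(per_gene = per_gene, common = stats::median(per_gene),
       alpha_min = alpha_min)
}

#' Variance-stabilizing transform of normalized counts
#'
#' Applies the closed-form NB variance stabilizer
#' `v(q) = (2 / sqrt(alpha)) * asinh(sqrt(alpha * q))` to normalized counts
#' `q = count / size factor`, with `alpha` the common dispersion. `v` is
#' strictly increasing with `v(0) = 0` and tends to `2 sqrt(q)` as
#' `alpha -> 0`.
#'
#' @param cm A [count_matrix()] or plain counts matrix.
#' @param sf Size factors.
#' @param disp Dispersion list from [estimate_dispersion()], or a single
#'   positive number.
#' @return Numeric matrix of transformed values.
#' @export
vst_transform <- function(cm, sf, disp) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  alpha <- if (is.list(disp)) disp$common else disp
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    stop("common dispersion must be a single positive number")
  }
  q <- sweep(counts, 2, sf, "/")
  (2 / sqrt(alpha)) * asinh(sqrt(alpha * q))
}

#' Simplified NB Wald test for one lpa-vs-normal comparison at one stage
#'
#' On normalized counts, with group means `muA` (lpa) and `muB` (normal) and
#' pseudocount 1: `lfc = log2((muA + 1) / (muB + 1))`, delta-method standard
#' error `se = sqrt((1/nA)(1/(muA+1) + alpha_g) + (1/nB)(1/(muB+1) +
#' alpha_g)) / ln 2`, Wald `z = lfc / se`, two-sided normal p-value, and BH
#' adjustment across all genes of the comparison. The DEG flag applies the
#' study's joint filters: `padj < 0.01`, `|lfc| > 1`, `baseMean > 10`
#' (strict inequalities), with baseMean the mean normalized count over both
#' groups' samples.
#'
#' @param cm A [count_matrix()].
#' @param sf Size factors.
#' @param disp Dispersion list from [estimate_dispersion()].
#' @param lpa_line,normal_line Line names forming the comparison.
#' @param stage Germination stage (1, 2, or 3).
#' @param padj_max,lfc_min,basemean_min DEG filter thresholds.
#' @return Data frame with one row per gene: `gene`, `comparison`, `stage`,
#'   `baseMean`, `lfc`, `se`, `p`, `padj`, `is_deg`.
#' @export
nb_wald_test <- function(cm, sf, disp, lpa_line, normal_line, stage,
                         padj_max = 0.01, lfc_min = 1, basemean_min = 10) {
  stopifnot(inherits(cm, "count_matrix"))
  meta <- cm$meta
  if (!stage %in% meta$stage) stop("stage ", stage, " absent from metadata")
  ia <- which(meta$line == lpa_line & meta$stage == stage)
  ib <- which(meta$line == normal_line & meta$stage == stage)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("both lines need >= 2 replicates at stage ", stage)
  }
  q <- sweep(cm$counts, 2, sf, "/")
  mu_a <- rowMeans(q[, ia, drop = FALSE])
  mu_b <- rowMeans(q[, ib, drop = FALSE])
  alpha_g <- disp$per_gene[rownames(q)]
  lfc <- log2((mu_a + 1) / (mu_b + 1))
  se <- sqrt((1 / length(ia)) * (1 / (mu_a + 1) + alpha_g) +
               (1 / length(ib)) * (1 / (mu_b + 1) + alpha_g)) / log(2)
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  padj <- stats::p.adjust(p, method = "BH")
  base_mean <- rowMeans(q[, c(ia, ib), drop = FALSE])
  data.frame(
    gene = rownames(q),
    comparison = paste0(lpa_line, "_vs_", normal_line),
    stage = as.integer(stage),
    baseMean = base_mean, lfc = lfc, se = se, p = p, padj = padj,
    is_deg = padj < padj_max & abs(lfc) > lfc_min & base_mean > basemean_min,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Comparisons defined by a genotypic subset
#'
#' Each low-phytic-acid line of the subset is compared against every normal
#' line of the subset (Mips and Mips-MRP: one comparison; MRP: three).
#'
#' @param meta Sample metadata.
#' @param subset Subset name.
#' @return Data frame with `lpa_line` and `normal_line`.
#' @export
subset_comparisons <- function(meta, subset) {
  sub <- unique(meta[meta$subset == subset, c("line", "phytic_class")])
  lpa <- sub$line[sub$phytic_class == "lpa"]
  normal <- sub$line[sub$phytic_class == "normal"]
  if (!length(lpa) || !length(normal)) {
    stop("subset ", subset, " lacks an lpa or a normal line")
  }
  expand.grid(lpa_line = lpa, normal_line = normal,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Run all comparisons x stages of one subset
#'
#' @param cm A [count_matrix()].
#' @param subset Subset name.
#' @param sf,disp Optional precomputed size factors / dispersion (computed
#'   from `cm` when NULL).
#' @param ... Filter thresholds passed to [nb_wald_test()].
#' @return Data frame of stacked [nb_wald_test()] records.
#' @export
de_analysis <- function(cm, subset, sf = NULL, disp = NULL, ...) {
  if (is.null(sf)) sf <- size_factors(cm)
  if (is.null(disp)) disp <- estimate_dispersion(cm, sf)
  comps <- subset_comparisons(cm$meta, subset)
  stages <- sort(unique(cm$meta$stage))
  out <- list()
  for (i in seq_len(nrow(comps))) {
    for (st in stages) {
      out[[length(out) + 1]] <- nb_wald_test(
        cm, sf, disp, comps$lpa_line[i], comps$normal_line[i], st, ...)
    }
  }
  do.call(rbind, out)
}

#' Stage-wise DEG sets under the subset's intersection rule
#'
#' Mips and Mips-MRP supply a single comparison, so a gene is a DEG at a
#' stage iff flagged in that comparison. The MRP subset supplies three
#' comparisons (2mlpa against each normal near-isogenic line) and a gene is
#' a DEG only if flagged in all three at that stage.
#'
#' @param records Stacked DE records from [de_analysis()].
#' @param subset Subset name (determines the expected comparison count).
#' @return Named list, one character vector of DEG ids per stage.
#' @export
call_degs_subset <- function(records, subset) {
  n_comp <- length(unique(records$comparison))
  expected <- if (subset == "MRP") 3L else 1L
  if (n_comp != expected) {
    stop("subset ", subset, " expects ", expected, " comparison(s), got ",
         n_comp)
  }
  stages <- sort(unique(records$stage))
  out <- lapply(stages, function(st) {
    r <- records[records$stage == st, ]
    hits <- tapply(r$is_deg, r$gene, sum)
    names(hits)[!is.na(hits) & hits == n_comp]
  })
  names(out) <- paste0("stage", stages)
  out
}

#' Seven-region Venn partition of three stage-wise DEG sets
#'
#' @param deg_by_stage List of three sets (stages 1..3; empty sets allowed).
#' @return Named integer vector: `only1`, `only2`, `only3`, `s12`, `s23`,
#'   `s13`, `all`; the regions are disjoint and sum to the union size.
#' @export
venn_partition <- function(deg_by_stage) {
  if (length(deg_by_stage) != 3) stop("need exactly three stage sets")
  s1 <- unique(deg_by_stage[[1]])
  s2 <- unique(deg_by_stage[[2]])
  s3 <- unique(deg_by_stage[[3]])
  u <- unique(c(s1, s2, s3))
  in1 <- u %in% s1; in2 <- u %in% s2; in3 <- u %in% s3
  c(only1 = sum(in1 & !in2 & !in3),
    only2 = sum(!in1 & in2 & !in3),
    only3 = sum(!in1 & !in2 & in3),
    s12 = sum(in1 & in2 & !in3),
    s23 = sum(!in1 & in2 & in3),
    s13 = sum(in1 & !in2 & in3),
    all = sum(in1 & in2 & in3))
}
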