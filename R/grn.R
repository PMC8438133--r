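# Module-network GRN inference core: TF and module-mean condition profiles
# are scored for TF -> module regulation by five algorithms (ARACNE, CLR,
# LARS, shrinkage partial correlation, random-forest importance); each
# method's ranking is binarized to a fixed edge budget and a consensus keeps
# edges detected by at least `consensus_threshold` of the five.

#' Inference configuration
#'
#' @param dpi_tolerance ARACNE data-processing-inequality tolerance
#'   (epsilon in \[0, 1); 0 = strict pruning).
#' @param edges_per_module Per-method kept-edge budget is
#'   `edges_per_module * n_modules`.
#' @param consensus_threshold Minimum number of supporting methods (1..5).
#' @param lars_max_steps LARS path steps scored per module.
#' @param rf_trees,rf_seed Random-forest size and seed.
#' @param shrinkage Partial-correlation shrinkage: `"analytic"` or a fixed
#'   lambda in (0, 1\].
#' @return List of class `inference_config`.
#' @export
inference_config <- function(dpi_tolerance = 0.1, edges_per_module = 10,
                             consensus_threshold = 4, lars_max_steps = 5,
                             rf_trees = 1000, rf_seed = 1,
                             shrinkage = "analytic") {
  stopifnot(dpi_tolerance >= 0, dpi_tolerance < 1,
            consensus_threshold >= 1, consensus_threshold <= 5,
            edges_per_module >= 1)
  structure(list(dpi_tolerance = dpi_tolerance,
                 edges_per_module = edges_per_module,
                 consensus_threshold = consensus_threshold,
                 lars_max_steps = lars_max_steps,
                 rf_trees = rf_trees, rf_seed = rf_seed,
                 shrinkage = shrinkage),
            class = "inference_config")
}

#' Condition x (TF + module) regulator matrix
#'
#' Stacks the z-scored replicate-averaged VST profiles of the candidate
#' regulator TFs with the module-mean profiles, conditions in rows. Columns
#' with zero variance are dropped with a log message. Column order is
#' deterministic: TFs sorted, then modules sorted.
#'
#' @param vst VST matrix (genes x samples).
#' @param meta Sample metadata.
#' @param tf_list Candidate regulator genes.
#' @param mod_means Module x condition matrix from [module_means()].
#' @param subset Genotypic subset.
#' @return List with `mat` (conditions x columns), `tf_cols`, `module_cols`.
#' @export
build_regulator_matrix <- function(vst, meta, tf_list, mod_means, subset) {
  tf_prof <- build_profiles(vst, meta, sort(unique(tf_list)), subset,
                            zscore = TRUE)
  if (!identical(colnames(tf_prof), colnames(mod_means))) {
    stop("TF profile conditions do not match module-mean conditions")
  }
  if (ncol(tf_prof) < 3) stop("degenerate input: fewer than 3 conditions")
  mat <- t(rbind(tf_prof, mod_means[order(rownames(mod_means)), ,
                                    drop = FALSE]))
  keep <- apply(mat, 2, stats::sd) > 0
  if (any(!keep)) {
    germnet_log("dropping zero-variance column(s): ",
                paste(colnames(mat)[!keep], collapse = ", "))
    mat <- mat[, keep, drop = FALSE]
  }
  list(mat = mat,
       tf_cols = intersect(colnames(mat), rownames(tf_prof)),
       module_cols = intersect(colnames(mat), rownames(mod_means)))
}

#' Gaussian-copula mutual information of two vectors
#'
#' Ranks are mapped to a Pearson correlation via the Gaussian-copula
#' relation `rho = 2 sin(pi rho_s / 6)` (rho_s the Spearman correlation),
#' |rho| is capped at 0.9999, and `MI = -0.5 ln(1 - rho^2)` nats. A robust
#' estimator for the handful of averaged conditions this pipeline works
#' with, where histogram or nearest-neighbour estimators are unusable.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Mutual information in nats (>= 0).
#' @export
gaussian_mi <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("vectors must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input to gaussian_mi")
  }
  rho_s <- stats::cor(rank(x), rank(y))
  rho <- 2 * sin(pi * rho_s / 6)
  rho <- max(min(rho, 0.9999), -0.9999)
  -0.5 * log(1 - rho^2)
}

# Pairwise Gaussian-copula MI over the columns of a matrix.
mi_matrix <- function(mat) {
  r <- 2 * sin(pi * stats::cor(mat, method = "spearman") / 6)
  r <- pmax(pmin(r, 0.9999), -0.9999)
  mi <- -0.5 * log(1 - r^2)
  diag(mi) <- 0
  mi
}

edge_score_frame <- function(tf_cols, module_cols, score_mat, method) {
  df <- expand.grid(tf = tf_cols, module = module_cols,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$method <- method
  df$score <- score_mat[cbind(df$tf, df$module)]
  df[order(df$tf, df$module), c("tf", "module", "method", "score")]
}

#' ARACNE scores: mutual information with DPI pruning
#'
#' Computes all pairwise MI among the TF and module nodes and applies the
#' data-processing inequality: for every triplet, the edge (i, j) is removed
#' when `MI(i,j) < min(MI(i,k), MI(j,k)) * (1 - epsilon)` for some third
#' node k (strict inequality, so exact ties survive). Pruning decisions are
#' taken simultaneously on the original MI matrix. Only TF-module pairs are
#' reported; pruned pairs score 0.
#'
#' @param mat Regulator matrix (conditions x columns).
#' @param tf_cols,module_cols Column names of TFs and modules.
#' @param epsilon DPI tolerance in \[0, 1).
#' @return Data frame `tf`, `module`, `method`, `score` (MI in nats).
#' @export
aracne_scores <- function(mat, tf_cols, module_cols, epsilon = 0.1) {
  nodes <- c(tf_cols, module_cols)
  mi <- mi_matrix(mat[, nodes, drop = FALSE])
  p <- length(nodes)
  pruned <- matrix(FALSE, p, p, dimnames = dimnames(mi))
  for (i in seq_len(p - 1)) {
    for (j in seq((i + 1), p)) {
      others <- setdiff(seq_len(p), c(i, j))
      bound <- max(pmin(mi[i, others], mi[j, others]))
      if (mi[i, j] < bound * (1 - epsilon)) {
        pruned[i, j] <- pruned[j, i] <- TRUE
      }
    }
  }
  score <- mi
  score[pruned] <- 0
  edge_score_frame(tf_cols, module_cols,
                   score[tf_cols, module_cols, drop = FALSE], "aracne")
}

#' CLR scores: background-corrected mutual information
#'
#' From the bipartite TF x module MI matrix, each entry is converted to a
#' row z-score (over the TF's modules) and a column z-score (over the
#' module's TFs), negatives clamped to zero, and combined as
#' `sqrt(z_tf^2 + z_module^2)`. Zero-SD rows or columns contribute z = 0.
#'
#' @inheritParams aracne_scores
#' @return Data frame `tf`, `module`, `method`, `score`.
#' @export
clr_scores <- function(mat, tf_cols, module_cols) {
  if (length(tf_cols) < 2 || length(module_cols) < 2) {
    stop("CLR needs >= 2 TFs and >= 2 modules")
  }
  mi <- mi_matrix(mat[, c(tf_cols, module_cols), drop = FALSE])
  b <- mi[tf_cols, module_cols, drop = FALSE]
  zrow <- (b - rowMeans(b)) / apply(b, 1, stats::sd)
  zrow[!is.finite(zrow)] <- 0
  cm <- colMeans(b); csd <- apply(b, 2, stats::sd)
  zcol <- sweep(sweep(b, 2, cm), 2, csd, "/")
  zcol[!is.finite(zcol)] <- 0
  score <- sqrt(pmax(zrow, 0)^2 + pmax(zcol, 0)^2)
  edge_score_frame(tf_cols, module_cols, score, "clr")
}

# Least-angle regression entry order of the columns of X for target y.
# Returns an integer vector: the step at which each column entered (NA if
# it never entered). Pure LAR (no lasso drops); ties broken by column order.
lars_entry_order <- function(X, y, max_steps) {
  n <- nrow(X); p <- ncol(X)
  Xs <- scale(X)
  sds <- attr(Xs, "scaled:scale")
  ok <- is.finite(sds) & sds > 0
  Xs[, !ok] <- 0
  Xs <- Xs / sqrt(pmax(n - 1, 1))  # unit-norm columns
  y <- y - mean(y)
  entered <- rep(NA_integer_, p)
  active <- integer(0)
  mu <- rep(0, n)
  max_steps <- min(max_steps, n - 1, sum(ok))
  for (step in seq_len(max_steps)) {
    c_vec <- drop(crossprod(Xs, y - mu))
    c_vec[!ok] <- 0
    inactive <- setdiff(which(ok), active)
    if (!length(inactive)) break
    C <- max(abs(c_vec[inactive]))
    if (C < 1e-12) break
    if (step == 1) {
      new <- inactive[which.max(abs(c_vec[inactive]))]
      active <- c(active, new)
      entered[new] <- step
    }
    s <- sign(c_vec[active])
    s[s == 0] <- 1
    Xa <- Xs[, active, drop = FALSE] * rep(s, each = n)
    G <- crossprod(Xa)
    ginv1 <- tryCatch(solve(G, rep(1, length(active))),
                      error = function(e) NULL)
    if (is.null(ginv1)) break
    Aa <- 1 / sqrt(sum(ginv1))
    u <- drop(Xa %*% (Aa * ginv1))
    a <- drop(crossprod(Xs, u))
    inactive <- setdiff(which(ok), active)
    if (!length(inactive)) break
    Cc <- max(abs(c_vec[active]))
    g1 <- (Cc - c_vec[inactive]) / (Aa - a[inactive])
    g2 <- (Cc + c_vec[inactive]) / (Aa + a[inactive])
    cand <- c(g1, g2)
    cand[!is.finite(cand) | cand <= 1e-12] <- Inf
    if (all(is.infinite(cand))) break
    gamma <- min(cand)
    idx <- which(cand == gamma)[1]
    new <- inactive[((idx - 1) %% length(inactive)) + 1]
    mu <- mu + gamma * u
    if (step < max_steps) {
      active <- c(active, new)
      entered[new] <- step + 1
    }
  }
  entered
}

#' LARS scores: least-angle-regression entry ranks
#'
#' For each module, a LARS path of the module profile on the standardized
#' TF columns is run for up to `max_steps` steps; a TF entering at step t
#' scores `(T - t + 1) / T`, TFs that never enter score 0.
#'
#' @inheritParams aracne_scores
#' @param max_steps Path length T (must be `<= n_conditions - 1`).
#' @return Data frame `tf`, `module`, `method`, `score`.
#' @export
lars_scores <- function(mat, tf_cols, module_cols, max_steps = 5) {
  n <- nrow(mat)
  if (max_steps > n - 1) stop("max_steps must be <= n_conditions - 1")
  X <- mat[, tf_cols, drop = FALSE]
  score <- matrix(0, length(tf_cols), length(module_cols),
                  dimnames = list(tf_cols, module_cols))
  for (m in module_cols) {
    entered <- lars_entry_order(X, mat[, m], max_steps)
    hit <- !is.na(entered) & entered <= max_steps
    score[hit, m] <- (max_steps - entered[hit] + 1) / max_steps
  }
  edge_score_frame(tf_cols, module_cols, score, "lars")
}

# Analytic (variance-of-entries) shrinkage intensity for a correlation
# matrix, after Schaefer & Strimmer: lambda = sum Var(r_ij) / sum r_ij^2
# over off-diagonal entries, clipped to [0.01, 1].
shrinkage_lambda <- function(mat) {
  n <- nrow(mat)
  xs <- scale(mat)
  xs[!is.finite(xs)] <- 0
  p <- ncol(xs)
  num <- 0; den <- 0
  for (i in seq_len(p - 1)) {
    w <- xs[, i] * xs[, (i + 1):p, drop = FALSE]
    wbar <- colMeans(w)
    vr <- n / ((n - 1)^3) * colSums(sweep(w, 2, wbar)^2)
    r <- (n / (n - 1)) * wbar
    num <- num + sum(vr)
    den <- den + sum(r^2)
  }
  if (den <= 0) return(1)
  min(max(num / den, 0.01), 1)
}

#' Shrinkage partial-correlation scores
#'
#' The correlation matrix R of all TF and module columns is shrunk towards
#' the identity, `R* = (1 - lambda) R + lambda I`, with lambda either the
#' analytic variance-of-entries estimate (clipped to \[0.01, 1\]) or a fixed
#' value; the score of a TF-module pair is the absolute partial correlation
#' `|-P_tm / sqrt(P_tt P_mm)|` from the precision matrix `P = (R*)^-1`.
#' Shrinkage keeps P well-defined with far more variables than conditions.
#'
#' @inheritParams aracne_scores
#' @param shrinkage `"analytic"` or a fixed lambda in (0, 1].
#' @return Data frame `tf`, `module`, `method`, `score`.
#' @export
pcor_scores <- function(mat, tf_cols, module_cols, shrinkage = "analytic") {
  cols <- c(tf_cols, module_cols)
  R <- stats::cor(mat[, cols, drop = FALSE])
  lambda <- if (identical(shrinkage, "analytic")) {
    shrinkage_lambda(mat[, cols, drop = FALSE])
  } else {
    lam <- as.numeric(shrinkage)
    if (!is.finite(lam) || lam <= 0 || lam > 1) {
      stop("fixed shrinkage lambda must be in (0, 1]")
    }
    lam
  }
  Rs <- (1 - lambda) * R
  diag(Rs) <- 1
  P <- solve(Rs)
  d <- sqrt(diag(P))
  pc <- -P / (d %o% d)
  score <- abs(pc[tf_cols, module_cols, drop = FALSE])
  out <- edge_score_frame(tf_cols, module_cols, score, "pcor")
  attr(out, "lambda") <- lambda
  out
}

#' Random-forest importance scores
#'
#' For each module, a regression forest of the module profile on all TF
#' columns (bootstrap rows, sqrt(p) candidate features per split) is grown
#' and each TF scores its share of the total impurity reduction, normalized
#' to sum to one per module whenever the forest made any split.
#'
#' @inheritParams aracne_scores
#' @param trees Number of trees.
#' @param seed Seed (one derived seed per module, so results are
#'   deterministic and independent of module evaluation order).
#' @return Data frame `tf`, `module`, `method`, `score`.
#' @export
rf_scores <- function(mat, tf_cols, module_cols, trees = 1000, seed = 1) {
  if (nrow(mat) < 3) stop("degenerate input: fewer than 3 conditions")
  X <- as.data.frame(mat[, tf_cols, drop = FALSE])
  score <- matrix(0, length(tf_cols), length(module_cols),
                  dimnames = list(tf_cols, module_cols))
  for (m in module_cols) {
    set.seed(stage_seed(seed, "rf", m))
    fit <- randomForest::randomForest(
      x = X, y = mat[, m], ntree = trees,
      mtry = max(1, floor(sqrt(length(tf_cols)))),
      nodesize = 2)
    imp <- fit$importance[, "IncNodePurity"]
    tot <- sum(imp)
    if (tot > 0) score[names(imp), m] <- imp / tot
  }
  edge_score_frame(tf_cols, module_cols, score, "rf")
}

#' Binarize one method's scores to a fixed edge budget
#'
#' Keeps the top-`budget` edges by descending score, breaking ties by
#' (tf, module) lexicographic order; zero-score edges are never kept.
#'
#' @param scores Data frame from one of the `*_scores()` functions.
#' @param budget Maximum edges kept (E = edges_per_module x n_modules).
#' @return Data frame `tf`, `module` of kept edges.
#' @export
binarize_scores <- function(scores, budget) {
  if (budget < 1) stop("budget must be >= 1")
  keep <- scores[scores$score > 0, , drop = FALSE]
  keep <- keep[order(-keep$score, keep$tf, keep$module), , drop = FALSE]
  utils::head(keep[, c("tf", "module")], budget)
}

#' Consensus vote over the five methods' edge sets
#'
#' @param method_sets Named list of exactly five data frames (names
#'   `aracne`, `clr`, `lars`, `pcor`, `rf`), each with `tf` and `module`
#'   columns as returned by [binarize_scores()].
#' @param kmin Minimum support (number of methods containing the edge).
#' @return Data frame sorted by (-support, tf, module): `tf`, `module`,
#'   `support`, `methods` (comma-joined canonical order).
#' @export
consensus_edges <- function(method_sets, kmin = 4) {
  if (length(method_sets) != 5 ||
      !setequal(names(method_sets), GRN_METHODS)) {
    stop("method_sets must be a named list of the five methods: ",
         paste(GRN_METHODS, collapse = ", "))
  }
  keys <- lapply(GRN_METHODS, function(m) {
    s <- method_sets[[m]]
    if (nrow(s)) paste(s$tf, s$module, sep = "\r") else character(0)
  })
  names(keys) <- GRN_METHODS
  all_keys <- unique(unlist(keys))
  if (!length(all_keys)) {
    return(data.frame(tf = character(0), module = character(0),
                      support = integer(0), methods = character(0),
                      stringsAsFactors = FALSE))
  }
  member <- vapply(GRN_METHODS, function(m) all_keys %in% keys[[m]],
                   logical(length(all_keys)))
  member <- matrix(member, nrow = length(all_keys),
                   dimnames = list(all_keys, GRN_METHODS))
  support <- rowSums(member)
  sel <- support >= kmin
  parts <- strsplit(all_keys[sel], "\r", fixed = TRUE)
  out <- data.frame(
    tf = vapply(parts, `[`, character(1), 1),
    module = vapply(parts, `[`, character(1), 2),
    support = as.integer(support[sel]),
    methods = apply(member[sel, , drop = FALSE], 1, function(z) {
      paste(GRN_METHODS[z], collapse = ",")
    }),
    stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$tf, out$module), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full five-method ensemble on a regulator matrix
#'
#' @param reg List from [build_regulator_matrix()].
#' @param config An [inference_config()].
#' @return List with `scores` (named list of the five score frames),
#'   `sets` (binarized edge sets), and `consensus` (from
#'   [consensus_edges()]).
#' @export
infer_grn <- function(reg, config = inference_config()) {
  stopifnot(inherits(config, "inference_config"))
  budget <- config$edges_per_module * length(reg$module_cols)
  scores <- list(
    aracne = aracne_scores(reg$mat, reg$tf_cols, reg$module_cols,
                           config$dpi_tolerance),
    clr = clr_scores(reg$mat, reg$tf_cols, reg$module_cols),
    lars = lars_scores(reg$mat, reg$tf_cols, reg$module_cols,
                       min(config$lars_max_steps, nrow(reg$mat) - 1)),
    pcor = pcor_scores(reg$mat, reg$tf_cols, reg$module_cols,
                       config$shrinkage),
    rf = rf_scores(reg$mat, reg$tf_cols, reg$module_cols,
                   config$rf_trees, config$rf_seed))
  sets <- lapply(scores, binarize_scores, budget = budget)
  list(scores = scores, sets = sets,
       consensus = consensus_edges(sets, config$consensus_threshold))
}
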