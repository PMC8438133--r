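# Co-expression module discovery: replicate-averaged condition profiles of
# the DEGs, clustered by Gaussian finite-mixture EM over six covariance
# families, with the component count and family selected by BIC.

GMM_FAMILIES <- c("spherical_equal", "spherical_varying", "diagonal_equal",
                  "diagonal_varying", "full_shared", "full_varying")

#' Replicate-averaged condition profiles for a gene set
#'
#' Averages a VST expression matrix over the replicates of each line x
#' stage cell of one genotypic subset, optionally z-scoring each gene's row
#' (SD floored at 1e-12, so constant genes become all-zero rows).
#'
#' @param vst VST matrix (genes x samples) from [vst_transform()].
#' @param meta Sample metadata matching the matrix columns.
#' @param genes Genes to keep (e.g. the subset's DEGs); all must be present.
#' @param subset Genotypic subset whose samples are used.
#' @param zscore Standardize each gene row.
#' @return Matrix genes x conditions; condition columns are named
#'   `line@stage` and ordered by line then stage.
#' @export
build_profiles <- function(vst, meta, genes, subset, zscore = TRUE) {
  missing <- setdiff(genes, rownames(vst))
  if (length(missing)) {
    stop("gene(s) absent from expression matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  keep <- meta$subset == subset
  if (!any(keep)) stop("no samples in subset ", subset)
  meta_s <- meta[keep, ]
  m <- vst[genes, keep, drop = FALSE]
  cell <- paste(meta_s$line, meta_s$stage, sep = "@")
  ord <- order(meta_s$line, meta_s$stage)
  cell_levels <- unique(cell[ord])
  prof <- sapply(cell_levels, function(cl) {
    rowMeans(m[, cell == cl, drop = FALSE])
  })
  prof <- matrix(prof, nrow = length(genes),
                 dimnames = list(genes, cell_levels))
  if (zscore) {
    mu <- rowMeans(prof)
    sd <- apply(prof, 1, stats::sd)
    prof <- (prof - mu) / pmax(sd, 1e-12)
  }
  prof
}

gmm_n_params <- function(K, d, family) {
  mean_w <- K * d + (K - 1)
  cov <- switch(family,
    spherical_equal = 1,
    spherical_varying = K,
    diagonal_equal = d,
    diagonal_varying = K * d,
    full_shared = d * (d + 1) / 2,
    full_varying = K * d * (d + 1) / 2,
    stop("unknown family: ", family))
  mean_w + cov
}

# Log density of each row of x under each component; covs is a list of
# d x d matrices (already ridged).
gmm_logdens <- function(x, means, covs) {
  n <- nrow(x); K <- nrow(means); d <- ncol(x)
  out <- matrix(0, n, K)
  for (k in seq_len(K)) {
    ch <- chol(covs[[k]])
    centered <- sweep(x, 2, means[k, ])
    z <- backsolve(ch, t(centered), transpose = TRUE)
    quad <- colSums(z^2)
    logdet <- 2 * sum(log(diag(ch)))
    out[, k] <- -0.5 * (d * log(2 * pi) + logdet + quad)
  }
  out
}

gmm_covariances <- function(x, means, resp, family, ridge) {
  n <- nrow(x); d <- ncol(x); K <- ncol(resp)
  nk <- pmax(colSums(resp), 1e-10)
  per_comp_ss <- function(k) {
    centered <- sweep(x, 2, means[k, ])
    crossprod(centered * sqrt(resp[, k]))  # d x d weighted scatter
  }
  covs <- vector("list", K)
  if (family == "spherical_equal") {
    tot <- sum(vapply(seq_len(K), function(k) sum(diag(per_comp_ss(k))),
                      numeric(1)))
    s2 <- tot / (n * d)
    for (k in seq_len(K)) covs[[k]] <- diag(s2 + ridge, d)
  } else if (family == "spherical_varying") {
    for (k in seq_len(K)) {
      s2 <- sum(diag(per_comp_ss(k))) / (nk[k] * d)
      covs[[k]] <- diag(s2 + ridge, d)
    }
  } else if (family == "diagonal_equal") {
    tot <- Reduce(`+`, lapply(seq_len(K),
                              function(k) diag(per_comp_ss(k))))
    v <- tot / n
    for (k in seq_len(K)) covs[[k]] <- diag(v + ridge, d)
  } else if (family == "diagonal_varying") {
    for (k in seq_len(K)) {
      v <- diag(per_comp_ss(k)) / nk[k]
      covs[[k]] <- diag(v + ridge, d)
    }
  } else if (family == "full_shared") {
    tot <- Reduce(`+`, lapply(seq_len(K), per_comp_ss))
    sig <- tot / n + diag(ridge, d)
    for (k in seq_len(K)) covs[[k]] <- sig
  } else if (family == "full_varying") {
    for (k in seq_len(K)) {
      covs[[k]] <- per_comp_ss(k) / nk[k] + diag(ridge, d)
    }
  } else stop("unknown family: ", family)
  covs
}

#' Fit a Gaussian finite mixture by EM
#'
#' EM from a k-means-style hard initialization, for one of six covariance
#' families (spherical/diagonal/full, shared or per-component). Iterations
#' stop when the relative log-likelihood change falls below `tol` or after
#' `max_iter` iterations; a ridge is added to every covariance diagonal for
#' numerical stability; the log-likelihood trace is recorded and is
#' non-decreasing up to round-off.
#'
#' @param x Numeric matrix, observations (genes) in rows.
#' @param K Number of components (`1 <= K < nrow(x)`).
#' @param family One of `spherical_equal`, `spherical_varying`,
#'   `diagonal_equal`, `diagonal_varying`, `full_shared`, `full_varying`.
#' @param seed Seed for the k-means initialization.
#' @param max_iter,tol EM stopping rule.
#' @param ridge Covariance diagonal ridge.
#' @return An object of class `gmm_fit`: weights, means, covariances,
#'   responsibilities, `loglik`, `loglik_trace`, `n_params`, `bic`
#'   (`2 loglik - n_params log n`, larger is better).
#' @export
fit_gmm <- function(x, K, family = "diagonal_varying", seed = 1,
                    max_iter = 500, tol = 1e-6, ridge = 1e-6) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (K < 1) stop("K must be >= 1")
  if (K >= n) stop("K must be smaller than the number of observations")
  family <- match.arg(family, GMM_FAMILIES)

  set.seed(seed)
  labels <- if (K == 1) rep(1L, n) else {
    km <- suppressWarnings(stats::kmeans(x, centers = K, nstart = 1,
                                         iter.max = 50))
    km$cluster
  }
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), labels)] <- 1

  loglik_trace <- numeric(0)
  loglik <- -Inf
  for (iter in seq_len(max_iter)) {
    nk <- pmax(colSums(resp), 1e-10)
    weights <- nk / sum(nk)
    means <- crossprod(resp, x) / nk
    covs <- gmm_covariances(x, means, resp, family, ridge)

    ld <- gmm_logdens(x, means, covs)
    ld <- sweep(ld, 2, log(pmax(weights, 1e-300)), "+")
    row_ll <- log_sum_exp_rows(ld)
    new_loglik <- sum(row_ll)
    loglik_trace <- c(loglik_trace, new_loglik)
    resp <- exp(ld - row_ll)

    if (is.finite(loglik) &&
        abs(new_loglik - loglik) <
        tol * (abs(loglik) + .Machine$double.eps)) {
      loglik <- new_loglik
      break
    }
    loglik <- new_loglik
  }
  nu <- gmm_n_params(K, d, family)
  structure(list(
    K = K, family = family, weights = weights, means = means,
    covariances = covs, responsibilities = resp,
    loglik = loglik, loglik_trace = loglik_trace,
    n_params = nu, bic = 2 * loglik - nu * log(n),
    n = n, d = d, iterations = length(loglik_trace), seed = seed
  ), class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("gmm_fit: K =", x$K, "family =", x$family,
      "loglik =", format(x$loglik), "BIC =", format(x$bic), "\n")
  invisible(x)
}

#' Select a mixture model by BIC and assign genes to modules
#'
#' Fits every (K, family) combination, keeping the best of `restarts`
#' seeded initializations per combination, and selects the fit with the
#' largest BIC (ties: smaller K, then family order). Genes are then hard-
#' assigned to their maximum-responsibility component (ties: lower index).
#'
#' @param profiles Condition-profile matrix from [build_profiles()].
#' @param K_range Integer vector of component counts to sweep.
#' @param families Covariance families to sweep.
#' @param restarts Seeded initializations per combination.
#' @param seed Base seed; restart seeds are derived deterministically.
#' @return An object of class `module_assignment`: `module_of` (named
#'   integer vector), `fit` (the selected [fit_gmm()]), and `sweep` (data
#'   frame of K, family, loglik, n_params, bic, converged).
#' @export
select_model <- function(profiles, K_range = 2:15,
                         families = GMM_FAMILIES, restarts = 5, seed = 1) {
  profiles <- as.matrix(profiles)
  if (!length(K_range)) stop("K_range must be nonempty")
  K_range <- sort(unique(as.integer(K_range)))
  K_range <- K_range[K_range < nrow(profiles)]
  if (!length(K_range)) stop("all K in K_range are >= the number of genes")
  sweep_rows <- list()
  best <- NULL
  failures <- character(0)
  for (fam_i in seq_along(families)) {
    fam <- families[fam_i]
    for (K in K_range) {
      fit <- NULL
      for (r in seq_len(restarts)) {
        s <- stage_seed(seed, "gmm", fam, K, r)
        cand <- tryCatch(fit_gmm(profiles, K, fam, seed = s),
                         error = function(e) NULL)
        if (!is.null(cand) &&
            (is.null(fit) || cand$loglik > fit$loglik)) fit <- cand
      }
      if (is.null(fit)) {
        failures <- c(failures, paste0(fam, "/K=", K))
        next
      }
      sweep_rows[[length(sweep_rows) + 1]] <- data.frame(
        K = K, family = fam, loglik = fit$loglik, n_params = fit$n_params,
        bic = fit$bic, iterations = fit$iterations,
        stringsAsFactors = FALSE)
      if (is.null(best) || fit$bic > best$bic ||
          (fit$bic == best$bic &&
           (K < best$K || (K == best$K && fam_i < match(best$family,
                                                        families))))) {
        best <- fit
      }
    }
  }
  if (is.null(best)) {
    stop("no mixture fit converged; failures: ",
         paste(failures, collapse = ", "))
  }
  resp <- best$responsibilities
  module_of <- max.col(resp, ties.method = "first")
  names(module_of) <- rownames(profiles)
  structure(list(module_of = module_of, fit = best,
                 sweep = do.call(rbind, sweep_rows),
                 failures = failures),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat("module_assignment:", length(x$module_of), "genes in", x$fit$K,
      "modules (", x$fit$family, ", BIC =", format(x$fit$bic), ")\n")
  print(table(x$module_of))
  invisible(x)
}

#' Module-mean condition profiles
#'
#' Row m is the unweighted mean of the profile rows of module m's member
#' genes; empty modules are dropped with a warning.
#'
#' @param profiles Condition-profile matrix.
#' @param module_of Named integer vector (gene -> module id) covering the
#'   profile genes, e.g. from [select_model()] or a planted truth.
#' @return Matrix modules x conditions with rownames `module_<id>`.
#' @export
module_means <- function(profiles, module_of) {
  genes <- rownames(profiles)
  if (!all(genes %in% names(module_of))) {
    stop("assignment does not cover all profile genes")
  }
  mod <- module_of[genes]
  ids <- sort(unique(mod[!is.na(mod)]))
  rows <- lapply(ids, function(m) {
    colMeans(profiles[!is.na(mod) & mod == m, , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- paste0("module_", ids)
  empty <- setdiff(seq_len(max(ids)), ids)
  if (length(empty)) {
    warning("empty module(s) excluded: ", paste(empty, collapse = ", "))
  }
  out
}
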