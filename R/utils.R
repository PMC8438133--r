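#' @keywords internal
"_PACKAGE"

# Canonical names of the five inference methods, fixed alphabetically so
# serialized edge lists are deterministic.
GRN_METHODS <- c("aracne", "clr", "lars", "pcor", "rf")

SUBSET_LEVELS <- c("Mips", "MRP", "MipsMRP")

#' Derive a per-stage random seed from a global seed
#'
#' One pipeline-level seed fans out to independent per-stage seeds via a
#' small polynomial rolling hash of the stage label, so stages can be rerun
#' in isolation without seed bookkeeping. The result is always a positive
#' integer below 2^31 - 1.
#'
#' @param seed Integer global seed.
#' @param ... Character labels (stage name, subset, replicate index, ...)
#'   mixed into the hash.
#' @return A single integer seed.
#' @export
stage_seed <- function(seed, ...) {
  label <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  m <- 2147483647
  h <- as.double(seed %% m)
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(max(1, h))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same objects.
#' Used to compare recovered co-expression modules with planted ones.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return Numeric scalar in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2) return(1)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

log_sum_exp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# Consistent run-time messages; everything informational goes through here so
# pipeline logs are greppable.
germnet_log <- function(...) {
  message("[germnet] ", ...)
}
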