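# Shared fixtures: everything is built in code at test time.

# A count_matrix from a plain matrix; lines/stages/replicates derived from
# a simple layout: `reps` replicates per (line, stage) cell, stages 1..3.
toy_count_matrix <- function(m, lines = c("mlpa", "MWT"), stages = 1:3,
                             reps = NULL, subset = "Mips") {
  n <- ncol(m)
  if (is.null(reps)) reps <- n / (length(lines) * length(stages))
  grid <- expand.grid(replicate = seq_len(reps), stage = stages,
                      line = lines, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  stopifnot(nrow(grid) == n)
  meta <- data.frame(
    sample_id = sprintf("%s_s%d_r%d", grid$line, grid$stage,
                        grid$replicate),
    line = grid$line, subset = subset,
    phytic_class = ifelse(grid$line == lines[1], "lpa", "normal"),
    stage = grid$stage, replicate = grid$replicate,
    stringsAsFactors = FALSE)
  if (is.null(rownames(m))) {
    rownames(m) <- sprintf("g%04d", seq_len(nrow(m)))
  }
  colnames(m) <- meta$sample_id
  count_matrix(m, meta)
}

# A count_matrix with a single (line, stage) cell of `reps` replicates.
one_cell_count_matrix <- function(m) {
  meta <- data.frame(
    sample_id = sprintf("S%03d", seq_len(ncol(m))),
    line = "L1", subset = "Mips", phytic_class = "normal",
    stage = 1L, replicate = seq_len(ncol(m)), stringsAsFactors = FALSE)
  if (is.null(rownames(m))) {
    rownames(m) <- sprintf("g%04d", seq_len(nrow(m)))
  }
  colnames(m) <- meta$sample_id
  count_matrix(m, meta)
}

write_tmp_tsv <- function(df, header = TRUE) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  path
}

# Exhaustive hypergeometric upper-tail oracle from the pmf definition.
brute_hyper_tail <- function(k, K, N, n) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Literal step-up BH reference.
brute_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  padj <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, n / i * p[ord[i]])
    padj[ord[i]] <- min(1, running)
  }
  padj
}

# Gaussian Markov chain X -> Y -> Z with the given link correlations.
gaussian_chain <- function(n, rho_xy, rho_yz) {
  x <- stats::rnorm(n)
  y <- rho_xy * x + sqrt(1 - rho_xy^2) * stats::rnorm(n)
  z <- rho_yz * y + sqrt(1 - rho_yz^2) * stats::rnorm(n)
  cbind(X = x, Y = y, Z = z)
}
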