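# Per-module GO term over-representation: one-sided hypergeometric
# (Fisher's exact) test with Benjamini-Hochberg FDR control.

# Upper-tail P(X >= k) for X hypergeometric: k successes drawn in a sample
# of n from a background of N with K successes. The single code path every
# enrichment p-value goes through.
hyper_upper_tail <- function(k, K, N, n) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' GO term enrichment of one module by the hypergeometric upper tail
#'
#' The background is restricted to genes with at least one annotation; for
#' every term annotated on at least one module gene, the p-value is the
#' hypergeometric upper tail P(X >= k) with k annotated genes in the module,
#' module size n (annotated members), K annotated background genes, and
#' background size N. BH adjustment is applied across the module's tested
#' terms; a term is enriched when `padj < fdr`.
#'
#' @param module_genes Character vector of the module's genes.
#' @param go_map Data frame with columns `gene` and `term` (e.g. from
#'   [read_go_map()]).
#' @param background_genes Candidate background gene universe (intersected
#'   with the annotated genes); defaults to all annotated genes.
#' @param fdr Enrichment threshold on the adjusted p-value.
#' @return Data frame sorted by `padj` then `term`: `term`, `k`, `n`, `K`,
#'   `N`, `p`, `padj`, `enriched`.
#' @export
fisher_enrich <- function(module_genes, go_map,
                          background_genes = NULL, fdr = 0.05) {
  annotated <- unique(go_map$gene)
  bg <- if (is.null(background_genes)) annotated else
    intersect(unique(background_genes), annotated)
  if (!length(bg)) stop("empty annotated background")
  extra <- setdiff(module_genes, bg)
  if (!is.null(background_genes) && length(setdiff(module_genes,
                                                   background_genes))) {
    stop("module genes must be a subset of the background")
  }
  mod <- intersect(unique(module_genes), bg)
  N <- length(bg)
  n <- length(mod)
  map <- go_map[go_map$gene %in% bg, c("gene", "term")]
  terms_in_module <- unique(map$term[map$gene %in% mod])
  if (!length(terms_in_module) || n == 0) {
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      padj = numeric(0), enriched = logical(0),
                      stringsAsFactors = FALSE))
  }
  term_genes <- split(map$gene, map$term)
  k <- vapply(terms_in_module,
              function(tm) length(intersect(term_genes[[tm]], mod)),
              integer(1))
  K <- vapply(terms_in_module,
              function(tm) length(unique(term_genes[[tm]])), integer(1))
  p <- hyper_upper_tail(k, K, N, n)
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term = terms_in_module, k = k, n = n, K = K, N = N,
                    p = p, padj = padj, enriched = padj < fdr,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$padj, out$term), , drop = FALSE]
}

#' GO enrichment for every module of an assignment
#'
#' @param module_of Named integer vector, gene -> module id.
#' @param go_map Data frame with `gene` and `term`.
#' @param fdr Enrichment threshold.
#' @return Data frame of stacked [fisher_enrich()] results with a leading
#'   `module` column.
#' @export
enrich_modules <- function(module_of, go_map, fdr = 0.05) {
  ids <- sort(unique(module_of[!is.na(module_of)]))
  out <- lapply(ids, function(m) {
    res <- fisher_enrich(names(module_of)[!is.na(module_of) &
                                            module_of == m],
                         go_map, fdr = fdr)
    if (nrow(res)) cbind(module = m, res) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(module = integer(0), term = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0), padj = numeric(0),
                      enriched = logical(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
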