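# Validation of inferred TF -> module interactions: expansion to TF -> gene
# edges, homology mapping of both endpoints to Arabidopsis via top BLAST
# hits (e-value <= 1e-5), overlap with published DAP-seq interactions, and
# overlap with precomputed motif matches.

#' Expand TF-module consensus edges to TF-gene edges
#'
#' Each consensus edge is matched to every gene assigned to its module;
#' self-edges (TF regulating itself through its own module) are excluded
#' and the result is deduplicated.
#'
#' @param consensus Data frame from [consensus_edges()] (`tf`, `module`,
#'   `support`, `methods`); `module` may be `"module_<id>"` or a bare id.
#' @param module_of Named integer vector, gene -> module id.
#' @return Data frame `tf_gene`, `target_gene`, `module`, `support`.
#' @export
expand_edges <- function(consensus, module_of) {
  ids <- sub("^module_", "", consensus$module)
  known <- unique(as.character(module_of[!is.na(module_of)]))
  unknown <- setdiff(unique(ids), known)
  if (length(unknown)) {
    stop("unknown module(s) in consensus: ",
         paste(unknown, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(consensus)), function(i) {
    m <- ids[i]
    members <- names(module_of)[!is.na(module_of) &
                                  as.character(module_of) == m]
    members <- setdiff(members, consensus$tf[i])
    if (!length(members)) return(NULL)
    data.frame(tf_gene = consensus$tf[i], target_gene = members,
               module = as.integer(m),
               support = consensus$support[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tf_gene = character(0), target_gene = character(0),
                      module = integer(0), support = integer(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[!duplicated(paste(out$tf_gene, out$target_gene, out$module)), ]
  rownames(out) <- NULL
  out
}

#' Best homology hit per query under an e-value threshold
#'
#' Per query: maximum bit score, ties broken by minimum e-value, then by
#' lexicographically smallest subject id; queries whose best hit exceeds
#' `evalue_max` are dropped from the map. Output is independent of input
#' row order.
#'
#' @param hits Data frame from [read_tabular_hits()].
#' @param evalue_max E-value cutoff (default 1e-5).
#' @return Data frame `query`, `subject`, `evalue`, `bitscore`, at most one
#'   row per query.
#' @export
best_hits <- function(hits, evalue_max = 1e-5) {
  stopifnot(evalue_max > 0)
  if (!nrow(hits)) {
    return(data.frame(query = character(0), subject = character(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ord <- order(hits$query, -hits$bitscore, hits$evalue, hits$subject)
  h <- hits[ord, c("query", "subject", "evalue", "bitscore")]
  h <- h[!duplicated(h$query), , drop = FALSE]
  h <- h[h$evalue <= evalue_max, , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Annotate TF-gene edges with DAP-seq support
#'
#' An edge is DAP-supported iff both endpoints map to homologs and the
#' mapped (regulator, target) pair occurs in the DAP edge set. Edges with
#' an unmapped endpoint are kept and counted separately so the support rate
#' stays interpretable.
#'
#' @param edges Data frame from [expand_edges()].
#' @param hmap Homology map from [best_hits()].
#' @param dap Data frame with `regulator`, `target` (homolog ids).
#' @return List with `edges` (input plus `mapped` and `dap_supported`
#'   columns) and `summary` (`n_edges`, `mapped`, `unmapped`, `supported`,
#'   `support_rate` among mapped edges).
#' @export
dap_overlap <- function(edges, hmap, dap) {
  map <- stats::setNames(hmap$subject, hmap$query)
  tf_h <- unname(map[edges$tf_gene])
  tg_h <- unname(map[edges$target_gene])
  mapped <- !is.na(tf_h) & !is.na(tg_h)
  dap_keys <- paste(dap$regulator, dap$target, sep = "\r")
  supported <- mapped & paste(tf_h, tg_h, sep = "\r") %in% dap_keys
  edges$mapped <- mapped
  edges$dap_supported <- supported
  list(edges = edges,
       summary = list(
         n_edges = nrow(edges),
         mapped = sum(mapped),
         unmapped = sum(!mapped),
         supported = sum(supported),
         support_rate = if (any(mapped)) sum(supported) / sum(mapped) else 0))
}

#' Annotate consensus TF-module edges with motif support
#'
#' A consensus edge (tf, module) is motif-supported iff the precomputed
#' motif table (from external 5'-flank motif discovery matched against
#' known TF binding motifs) contains that (module, tf) pair.
#'
#' @param consensus Data frame from [consensus_edges()].
#' @param motif_matches Data frame with `module`, `tf_gene`.
#' @return The consensus frame with a logical `motif_supported` column.
#' @export
motif_overlap <- function(consensus, motif_matches) {
  ids <- sub("^module_", "", consensus$module)
  keys <- paste(motif_matches$module, motif_matches$tf_gene, sep = "\r")
  consensus$motif_supported <- paste(ids, consensus$tf, sep = "\r") %in% keys
  consensus
}
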