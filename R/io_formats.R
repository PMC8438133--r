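# Tabular readers/writers for every artifact the pipeline touches.
# All tables are TSV, UTF-8, '#'-prefixed comment lines ignored, strict
# parsing: malformed numbers raise instead of silently coercing to NA.

read_tsv_lines <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^#", raw) & nzchar(raw)
  list(lines = raw[keep], lineno = which(keep))
}

split_fields <- function(lines) {
  # strsplit drops a trailing empty field; a sentinel preserves it so rows
  # ending in an empty column keep their full width.
  parts <- strsplit(paste0(lines, "\x01"), "\t", fixed = TRUE)
  lapply(parts, function(x) {
    x[length(x)] <- sub("\x01$", "", x[length(x)])
    x
  })
}

parse_num_strict <- function(x, what, where) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop("non-numeric value ", sQuote(x[bad][1]), " in ", what,
         " (", where[bad][1], ")", call. = FALSE)
  }
  out
}

#' Read a tab-separated table with a header row
#'
#' Shared low-level reader: skips `#` comment lines, requires every row to
#' have exactly as many fields as the header, returns all columns as
#' character (callers convert and validate).
#'
#' @param path Path to a TSV file.
#' @return A data.frame of character columns.
#' @export
read_tsv_table <- function(path) {
  parsed <- read_tsv_lines(path)
  if (length(parsed$lines) == 0) {
    stop("empty table: ", path, call. = FALSE)
  }
  fields <- split_fields(parsed$lines)
  header <- fields[[1]]
  body <- fields[-1]
  nf <- lengths(body)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1]
    stop("format error: line ", parsed$lineno[-1][bad], " of ", path,
         " has ", nf[bad], " fields, expected ", length(header),
         call. = FALSE)
  }
  out <- as.data.frame(
    do.call(rbind, c(body, list(deparse.level = 0))),
    stringsAsFactors = FALSE
  )
  if (length(body) == 0) {
    out <- as.data.frame(matrix(character(0), ncol = length(header)),
                         stringsAsFactors = FALSE)
  }
  names(out) <- header
  out
}

write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
}

# ---- CountMatrix -----------------------------------------------------------

#' Construct a validated gene x sample count matrix
#'
#' Couples an integer count matrix with its per-sample metadata. Metadata
#' must carry `sample_id`, `line`, `subset`, `phytic_class`, `stage`,
#' `replicate`; genotype flag columns (`mips1`, `mrp_l`, `mrp_n`) are
#' optional but, when present, must be consistent with `phytic_class`
#' (low phytic acid iff mips1 mutated or both mrp loci mutated).
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @param meta Data frame of per-sample metadata, one row per column of
#'   `counts`, in column order.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene-id rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in counts")
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("negative count for gene ", rownames(counts)[idx[1]],
         ", sample ", colnames(counts)[idx[2]])
  }
  if (any(counts != round(counts))) {
    idx <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop("non-integer count for gene ", rownames(counts)[idx[1]],
         ", sample ", colnames(counts)[idx[2]])
  }
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("sample_id", "line", "subset", "phytic_class", "stage",
                "replicate")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  }
  if (ncol(counts) != nrow(meta)) {
    stop("counts has ", ncol(counts), " samples but metadata has ",
         nrow(meta), " rows")
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  key <- paste(meta$line, meta$stage, meta$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (line, stage, replicate) combination: ",
         key[duplicated(key)][1])
  }
  if (!all(meta$subset %in% SUBSET_LEVELS)) {
    stop("subset must be one of ", paste(SUBSET_LEVELS, collapse = ", "))
  }
  meta$stage <- as.integer(meta$stage)
  if (!all(meta$stage %in% 1:3)) stop("stage must be in {1,2,3}")
  meta$replicate <- as.integer(meta$replicate)
  if (any(meta$replicate < 1)) stop("replicate must be >= 1")
  if (!all(meta$phytic_class %in% c("lpa", "normal"))) {
    stop("phytic_class must be 'lpa' or 'normal'")
  }
  if (all(c("mips1", "mrp_l", "mrp_n") %in% names(meta))) {
    for (fl in c("mips1", "mrp_l", "mrp_n")) {
      meta[[fl]] <- as.logical(meta[[fl]])
    }
    implied <- ifelse(meta$mips1 | (meta$mrp_l & meta$mrp_n), "lpa", "normal")
    if (!all(implied == meta$phytic_class)) {
      bad <- which(implied != meta$phytic_class)[1]
      stop("phytic_class of sample ", meta$sample_id[bad],
           " inconsistent with its genotype flags")
    }
  }
  if (!is.null(colnames(counts)) &&
      !identical(colnames(counts), meta$sample_id)) {
    stop("counts column names do not match metadata sample order")
  }
  colnames(counts) <- meta$sample_id
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("  lines:", paste(unique(x$meta$line), collapse = ", "), "\n")
  cat("  subsets:", paste(unique(x$meta$subset), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix and its sample metadata from TSV files
#'
#' The counts file has a header of sample ids and a first column of gene
#' ids; the metadata file has one row per sample. Matrix columns are
#' reordered to the metadata row order. Any sample present in one file but
#' not the other is an error, as is any negative or non-integer count.
#'
#' @param path Counts TSV.
#' @param meta_path Metadata TSV.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, meta_path) {
  tab <- read_tsv_table(path)
  meta <- read_tsv_table(meta_path)
  gene_ids <- tab[[1]]
  sample_ids <- names(tab)[-1]
  extra <- setdiff(sample_ids, meta$sample_id)
  missing <- setdiff(meta$sample_id, sample_ids)
  if (length(extra) || length(missing)) {
    stop("sample sets disagree between counts and metadata",
         if (length(extra)) paste0("; only in counts: ",
                                   paste(extra, collapse = ", ")),
         if (length(missing)) paste0("; only in metadata: ",
                                     paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  m <- matrix(0, nrow = nrow(tab), ncol = length(sample_ids),
              dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- tab[[j + 1]]
    ok <- grepl("^[0-9]+$", col)
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop("format error: count ", sQuote(col[bad]), " for gene ",
           gene_ids[bad], ", sample ", sample_ids[j], call. = FALSE)
    }
    m[, j] <- as.numeric(col)
  }
  m <- m[, meta$sample_id, drop = FALSE]
  for (col in intersect(c("mips1", "mrp_l", "mrp_n"), names(meta))) {
    meta[[col]] <- as.logical(meta[[col]])
  }
  count_matrix(m, meta)
}

#' Write a count matrix (and its metadata) to TSV files
#'
#' @param cm A [count_matrix()].
#' @param path Counts TSV output path.
#' @param meta_path Metadata TSV output path.
#' @return Invisibly, `cm`.
#' @export
write_counts <- function(cm, path, meta_path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(df, path)
  write_tsv_table(cm$meta, meta_path)
  invisible(cm)
}

# ---- 12-column tabular alignment hits --------------------------------------

HIT_FIELDS <- c("query", "subject", "pct_id", "aln_len", "mismatches",
                "gaps", "qstart", "qend", "sstart", "send", "evalue",
                "bitscore")

#' Read 12-column tabular alignment output
#'
#' Parses the conventional 12-field tab-separated alignment format (query,
#' subject, percent identity, alignment length, mismatches, gap opens,
#' query/subject coordinates, e-value, bit score). No filtering is applied;
#' rows keep file order.
#'
#' @param path Path to the alignment table (no header).
#' @return A data.frame with one row per hit and typed columns.
#' @export
read_tabular_hits <- function(path) {
  parsed <- read_tsv_lines(path)
  empty <- data.frame(matrix(nrow = 0, ncol = 12), stringsAsFactors = FALSE)
  names(empty) <- HIT_FIELDS
  for (nm in HIT_FIELDS[-(1:2)]) empty[[nm]] <- numeric(0)
  for (nm in HIT_FIELDS[1:2]) empty[[nm]] <- character(0)
  if (length(parsed$lines) == 0) return(empty)
  fields <- split_fields(parsed$lines)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    bad <- which(nf != 12)[1]
    stop("format error: line ", parsed$lineno[bad], " has ", nf[bad],
         " fields, expected 12", call. = FALSE)
  }
  m <- do.call(rbind, fields)
  out <- data.frame(query = m[, 1], subject = m[, 2],
                    stringsAsFactors = FALSE)
  for (j in 3:12) {
    out[[HIT_FIELDS[j]]] <- parse_num_strict(
      m[, j], HIT_FIELDS[j], paste("line", parsed$lineno))
  }
  if (any(out$evalue < 0)) stop("negative e-value in ", path, call. = FALSE)
  if (any(!is.finite(out$bitscore))) stop("non-finite bit score", call. = FALSE)
  out
}

# ---- Edge lists ------------------------------------------------------------

#' Write a consensus edge list to TSV
#'
#' Serializes regulator/target edges with their method-support count and the
#' supporting methods comma-joined in the fixed canonical order
#' `aracne,clr,lars,pcor,rf`.
#'
#' @param edges Data frame with columns `regulator`, `target`, `support`
#'   (0..5) and `methods` (either a comma-joined string or a list column of
#'   character vectors).
#' @param path Output path.
#' @return Invisibly, the serialized data.frame.
#' @export
write_edge_list <- function(edges, path) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  serialize_methods <- function(ms) {
    if (length(ms) == 1 && grepl(",", ms, fixed = TRUE)) {
      ms <- strsplit(ms, ",", fixed = TRUE)[[1]]
    }
    ms <- ms[nzchar(ms)]
    unknown <- setdiff(ms, GRN_METHODS)
    if (length(unknown)) {
      stop("unknown method name: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    paste(GRN_METHODS[GRN_METHODS %in% ms], collapse = ",")
  }
  if (nrow(edges)) {
    if (any(edges$support < 0 | edges$support > 5)) {
      stop("support must be in 0..5", call. = FALSE)
    }
    methods_col <- if (is.list(edges$methods)) edges$methods else
      as.list(edges$methods)
    edges$methods <- vapply(methods_col, serialize_methods, character(1))
  } else {
    edges <- data.frame(regulator = character(0), target = character(0),
                        support = integer(0), methods = character(0),
                        stringsAsFactors = FALSE)
  }
  write_tsv_table(edges[, c("regulator", "target", "support", "methods")],
                  path)
  invisible(edges)
}

#' Read an edge list written by [write_edge_list()]
#'
#' @param path Path to the edge-list TSV.
#' @return Data frame with `regulator`, `target`, integer `support`, and
#'   `methods` (comma-joined canonical order).
#' @export
read_edge_list <- function(path) {
  tab <- read_tsv_table(path)
  need <- c("regulator", "target", "support", "methods")
  if (!all(need %in% names(tab))) {
    stop("edge list must have columns ", paste(need, collapse = ", "))
  }
  tab$support <- as.integer(parse_num_strict(tab$support, "support", path))
  tab
}

# ---- Annotation tables -----------------------------------------------------

#' Read a gene-to-GO-term annotation table
#'
#' Expects columns `gene`, `term`, `namespace`, `description`.
#'
#' @param path Annotation TSV.
#' @return Data frame of the four columns.
#' @export
read_go_map <- function(path) {
  tab <- read_tsv_table(path)
  need <- c("gene", "term", "namespace", "description")
  if (!all(need %in% names(tab))) {
    stop("GO map must have columns ", paste(need, collapse = ", "))
  }
  tab[, need]
}

#' Read a gene-to-TF-family annotation table
#'
#' Expects columns `gene`, `family`.
#'
#' @param path TF map TSV.
#' @return Data frame with `gene` and `family`.
#' @export
read_tf_map <- function(path) {
  tab <- read_tsv_table(path)
  if (!all(c("gene", "family") %in% names(tab))) {
    stop("TF map must have columns gene, family")
  }
  tab[, c("gene", "family")]
}

#' Read a DAP-seq regulator-to-target edge table
#'
#' Expects columns `regulator`, `target`; duplicate pairs are an error.
#'
#' @param path DAP edge TSV.
#' @return Data frame with `regulator` and `target`.
#' @export
read_dap_edges <- function(path) {
  tab <- read_tsv_table(path)
  if (!all(c("regulator", "target") %in% names(tab))) {
    stop("DAP edges must have columns regulator, target")
  }
  if (anyDuplicated(paste(tab$regulator, tab$target))) {
    stop("duplicate DAP edge pairs")
  }
  tab[, c("regulator", "target")]
}

#' Read a module-to-matched-TF motif table
#'
#' Output of external motif discovery/comparison (e.g. 1,000 bp 5' flank
#' motif scans matched to known TF binding motifs), consumed as a
#' precomputed table with columns `module`, `tf_gene`.
#'
#' @param path Motif match TSV.
#' @return Data frame with `module` and `tf_gene`.
#' @export
read_motif_matches <- function(path) {
  tab <- read_tsv_table(path)
  if (!all(c("module", "tf_gene") %in% names(tab))) {
    stop("motif matches must have columns module, tf_gene")
  }
  tab$module <- as.integer(parse_num_strict(tab$module, "module", path))
  tab[, c("module", "tf_gene")]
}
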