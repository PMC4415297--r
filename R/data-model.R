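#' Expression matrix container
#'
#' Lightweight container for a genes-by-samples expression matrix holding
#' either continuous log2-scale values (microarray intensities or log2-CPM)
#' or binary expression-barcode calls. Genes with missing values are dropped
#' with a message rather than imputed.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   row and column names.
#' @param value_kind `"continuous"` or `"barcode"`; barcode matrices must
#'   contain only 0/1 entries.
#' @param probe_to_gene optional named character vector mapping probe ids
#'   (names) to gene symbols, used by [collapse_probesets()].
#' @param allow_duplicate_genes permit duplicated row ids (multiple probe
#'   sets per gene prior to collapsing).
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `value_kind` and optionally `probe_to_gene`.
#' @export
expression_matrix <- function(values, value_kind = c("continuous", "barcode"),
                              probe_to_gene = NULL,
                              allow_duplicate_genes = FALSE) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_input("'values' must have gene row names and sample column names")
  if (anyDuplicated(colnames(values)))
    stop_input("duplicate sample id(s): ",
               paste(unique(colnames(values)[duplicated(colnames(values))]),
                     collapse = ", "))
  if (!allow_duplicate_genes && anyDuplicated(rownames(values)))
    stop_input("duplicate gene id(s): ",
               paste(unique(rownames(values)[duplicated(rownames(values))]),
                     collapse = ", "))
  bad <- !complete.cases(values)
  if (any(bad)) {
    message(sum(bad), " gene(s) with missing values dropped")
    values <- values[!bad, , drop = FALSE]
  }
  if (value_kind == "barcode" && !all(values %in% c(0, 1)))
    stop_input("barcode matrix contains values other than 0/1")
  structure(list(values = values, value_kind = value_kind,
                 probe_to_gene = probe_to_gene),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples (", x$value_kind, ")\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

# subset an expression matrix by genes and/or samples, preserving metadata
subset_expr <- function(x, genes = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  structure(list(values = v, value_kind = x$value_kind,
                 probe_to_gene = x$probe_to_gene),
            class = "expression_matrix")
}

#' Per-sample survival table
#'
#' Clinical table with one row per sample: follow-up time, event indicator
#' (1 = death), histology subtype (AC or SCC) and optional clinical
#' covariates. Time is treated as unit-agnostic but must be positive.
#'
#' @param sample_id character vector of unique sample ids.
#' @param time positive follow-up times.
#' @param event 0/1 event indicators (1 = death observed).
#' @param subtype labels mapped case-insensitively to `AC`/`SCC`.
#' @param clinical optional data.frame of additional covariates.
#' @return A `survival_table`: a data.frame with attribute `clinical`
#'   naming the covariate columns.
#' @export
survival_table <- function(sample_id, time, event, subtype, clinical = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop_input("duplicate sample id(s): ",
               paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  time <- as.numeric(time)
  if (any(!is.finite(time)) || any(time <= 0))
    stop_input("survival time must be positive and finite")
  if (!all(event %in% c(0, 1)))
    stop_input("event indicator must be 0 or 1")
  st <- toupper(trimws(as.character(subtype)))
  bad <- !(st %in% c("AC", "SCC"))
  if (any(bad))
    stop_input("unknown subtype label(s): ",
               paste(unique(subtype[bad]), collapse = ", "))
  out <- data.frame(sample_id = sample_id, time = time,
                    event = as.integer(event),
                    subtype = factor(st, levels = c("AC", "SCC")),
                    stringsAsFactors = FALSE)
  cl <- character(0)
  if (!is.null(clinical) && ncol(clinical) > 0) {
    cl <- names(clinical)
    out <- cbind(out, clinical)
  }
  attr(out, "clinical") <- cl
  class(out) <- c("survival_table", "data.frame")
  out
}

#' Read a genes-by-samples expression matrix from delimited text
#'
#' The first column holds gene/probe ids, the header row sample ids. The
#' delimiter is auto-detected between tab and comma. Duplicate gene ids are
#' permitted at this stage (multiple probe sets per gene, collapsed later);
#' duplicate sample ids are an error.
#'
#' @param path file path.
#' @param value_kind `"continuous"` or `"barcode"`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, value_kind = c("continuous", "barcode")) {
  value_kind <- match.arg(value_kind)
  sep <- detect_sep(path)
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  hdr <- names(df)[-1]
  if (anyDuplicated(hdr))
    stop_input("duplicate sample id(s) in header: ",
               paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  genes <- as.character(df[[1]])
  for (jj in seq_along(hdr)) {
    col <- df[[jj + 1]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      stop_input("non-numeric value in column '", hdr[jj], "', row ",
                 if (is.na(bad)) "?" else bad, " (gene ",
                 if (is.na(bad)) "?" else genes[bad], ")")
    }
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(genes, hdr)
  expression_matrix(m, value_kind = value_kind, allow_duplicate_genes = TRUE)
}

#' Write an expression matrix as TSV
#'
#' Tab-separated, 6 significant digits, first column header `gene_id`.
#'
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @export
write_expression_matrix <- function(expr, path) {
  v <- expr$values
  out <- data.frame(gene_id = rownames(v),
                    signif(v, 6), check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample survival table from delimited text
#'
#' Requires columns `sample_id`, `time`, `event`, `subtype`; any additional
#' columns are captured as clinical covariates in their declared order.
#'
#' @param path file path.
#' @return A [survival_table()].
#' @export
read_survival_table <- function(path) {
  sep <- detect_sep(path)
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event", "subtype")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_input("missing required column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(df), need)
  survival_table(df$sample_id, df$time, df$event, df$subtype,
                 clinical = if (length(extra)) df[, extra, drop = FALSE])
}

#' Write a survival table as TSV
#' @param surv a [survival_table()].
#' @param path output path.
#' @export
write_survival_table <- function(surv, path) {
  df <- as.data.frame(surv)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

detect_sep <- function(path) {
  l1 <- readLines(path, n = 1)
  if (lengths(regmatches(l1, gregexpr("\t", l1))) >=
      lengths(regmatches(l1, gregexpr(",", l1)))) "\t" else ","
}

#' Align an expression matrix and a survival table on shared samples
#'
#' Both objects are restricted to the intersection of their sample ids, in
#' the expression matrix's order; dropped counts are reported via `message`.
#'
#' @param expr an [expression_matrix()].
#' @param surv a [survival_table()].
#' @return A list with elements `expr` and `surv`.
#' @export
align_samples <- function(expr, surv) {
  common <- intersect(sample_ids(expr), surv$sample_id)
  if (length(common) == 0)
    stop_input("no samples shared between expression matrix and survival table")
  de <- length(sample_ids(expr)) - length(common)
  ds <- nrow(surv) - length(common)
  if (de > 0) message(de, " expression sample(s) dropped during alignment")
  if (ds > 0) message(ds, " survival sample(s) dropped during alignment")
  expr2 <- subset_expr(expr, samples = common)
  surv2 <- surv[match(common, surv$sample_id), , drop = FALSE]
  rownames(surv2) <- NULL
  attr(surv2, "clinical") <- attr(surv, "clinical")
  class(surv2) <- class(surv)
  list(expr = expr2, surv = surv2)
}

#' Log2 counts-per-million transform
#'
#' `log2((count + 0.5) / (library_size + 1) * 1e6)` per entry, with the
#' library size taken as the column sum. The small offsets keep zero counts
#' finite; the filter only needs a monotone log-scale value, so no precision
#' weights are computed.
#'
#' @param counts an [expression_matrix()] of non-negative integer counts.
#' @return A continuous [expression_matrix()].
#' @export
log2_cpm_transform <- function(counts) {
  v <- counts$values
  if (any(v < 0) || any(abs(v - round(v)) > 1e-8))
    stop_input("counts must be non-negative integers")
  libsize <- colSums(v)
  if (any(libsize == 0))
    stop_input("library size zero for sample(s): ",
               paste(colnames(v)[libsize == 0], collapse = ", "))
  out <- log2(sweep(v + 0.5, 2, libsize + 1, "/") * 1e6)
  expression_matrix(out, value_kind = "continuous",
                    probe_to_gene = counts$probe_to_gene,
                    allow_duplicate_genes = TRUE)
}

#' Tumor-minus-normal paired log-expression differences
#'
#' For matched tumor/normal designs: per gene, the tumor sample's value
#' minus its matched normal sample's value. Sample ids of the result are the
#' tumor ids.
#'
#' @param tumor,normal [expression_matrix()] objects sharing gene ids.
#' @param pairs named character vector: `names(pairs)` are tumor sample ids,
#'   values the matched normal sample ids.
#' @return An [expression_matrix()] of per-pair differences.
#' @export
paired_log_difference <- function(tumor, normal, pairs) {
  if (!identical(gene_ids(tumor), gene_ids(normal)))
    stop_input("tumor and normal matrices must share identical gene ids")
  tum_ids <- names(pairs)
  missing_t <- setdiff(tum_ids, sample_ids(tumor))
  missing_n <- setdiff(unname(pairs), sample_ids(normal))
  if (length(missing_t))
    stop_input("tumor sample(s) not found: ", paste(missing_t, collapse = ", "))
  if (length(missing_n))
    stop_input("normal sample(s) not found: ", paste(missing_n, collapse = ", "))
  d <- tumor$values[, tum_ids, drop = FALSE] -
    normal$values[, unname(pairs), drop = FALSE]
  colnames(d) <- tum_ids
  expression_matrix(d, value_kind = "continuous",
                    probe_to_gene = tumor$probe_to_gene,
                    allow_duplicate_genes = TRUE)
}
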