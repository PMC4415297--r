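#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with validated
#' defaults. A configuration can also be loaded from a YAML file with
#' [load_pipeline_config()]; explicit arguments take precedence over file
#' values, which take precedence over defaults.
#'
#' @param expr_path,surv_path input TSV/CSV paths (see
#'   [read_expression_matrix()] and [read_survival_table()]).
#' @param probe_map_path optional two-column TSV (probe, gene) enabling
#'   probe-set collapse.
#' @param value_kind `"continuous"` or `"barcode"` analysis values for the
#'   Cox filter; `"barcode"` enables the barcode stage.
#' @param sd_threshold SD pre-filter cutoff.
#' @param deg_fdr moderated-t DEG selection FDR.
#' @param cox_fdr per-gene Cox filter FDR.
#' @param barcode_C barcode call threshold.
#' @param freq_high,freq_low barcode-frequency cutoffs (named AC/SCC).
#' @param risk_method `"pca"` or `"full"`.
#' @param var_threshold cumulative-variance threshold for the PCA risk
#'   model.
#' @param signature_family genes fed to the risk model: `"union"`, `"AC"`
#'   or `"SCC"` selections.
#' @param seed seed recorded in the run log (the pipeline itself is
#'   deterministic).
#' @param out_dir output directory (created if needed); `NULL` for
#'   in-memory runs.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(expr_path = NULL, surv_path = NULL,
                            probe_map_path = NULL,
                            value_kind = c("continuous", "barcode"),
                            sd_threshold = 0.1, deg_fdr = 0.05,
                            cox_fdr = 0.05, barcode_C = 0.01,
                            freq_high = c(AC = 0.95, SCC = 0.90),
                            freq_low = c(AC = 0.05, SCC = 0.10),
                            risk_method = c("pca", "full"),
                            var_threshold = 0.95,
                            signature_family = c("union", "AC", "SCC"),
                            seed = 1, out_dir = NULL) {
  value_kind <- match.arg(value_kind)
  risk_method <- match.arg(risk_method)
  signature_family <- match.arg(signature_family)
  for (nm in c("deg_fdr", "cox_fdr", "barcode_C", "var_threshold")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0 || v > 1)
      stop_input("'", nm, "' must lie in (0, 1]")
  }
  if (sd_threshold <= 0) stop_input("'sd_threshold' must be positive")
  structure(list(expr_path = expr_path, surv_path = surv_path,
                 probe_map_path = probe_map_path, value_kind = value_kind,
                 sd_threshold = sd_threshold, deg_fdr = deg_fdr,
                 cox_fdr = cox_fdr, barcode_C = barcode_C,
                 freq_high = freq_high, freq_low = freq_low,
                 risk_method = risk_method, var_threshold = var_threshold,
                 signature_family = signature_family, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @param ... overrides taking precedence over file values.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  for (nm in c("freq_high", "freq_low"))
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  vals <- modifyList(vals, list(...))
  do.call(pipeline_config, vals)
}

#' Run the full subtype-prognosis pipeline
#'
#' Stages: sample alignment, SD filter, moderated-t DEG filter, optional
#' probe-set collapse, optional barcode fit/calls/frequency filter (when
#' `value_kind = "barcode"`), per-gene interaction Cox filter, scenario
#' classification and signature selection, risk-score model on the
#' signature genes (continuous values), mean-cutoff stratification and
#' evaluation. Intermediate tables and a stage-by-stage run log are written
#' to `config$out_dir` when set.
#'
#' @param config a [pipeline_config()].
#' @param expr,surv optional pre-loaded inputs (otherwise read from the
#'   configured paths).
#' @return Invisibly, a `pipeline_result` list with every intermediate
#'   object (`expr`, `deg`, `records`, `signature`, `risk_model`, `scores`,
#'   `strata`, `evaluation`, `log`).
#' @export
run_full_pipeline <- function(config, expr = NULL, surv = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, fun) {
    tryCatch(fun, error = function(e) {
      stop_input("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  say("subtypeCox pipeline, seed = ", config$seed)
  if (is.null(expr))
    expr <- stage("read_expression",
                  read_expression_matrix(config$expr_path, "continuous"))
  if (is.null(surv))
    surv <- stage("read_survival", read_survival_table(config$surv_path))
  al <- stage("align", suppressMessages(align_samples(expr, surv)))
  expr <- al$expr; surv <- al$surv
  say("aligned: ", nrow(expr$values), " genes x ", ncol(expr$values),
      " samples (", sum(surv$subtype == "AC"), " AC / ",
      sum(surv$subtype == "SCC"), " SCC)")
  expr <- stage("sd_filter",
                suppressMessages(sd_filter(expr, config$sd_threshold)))
  say("after SD filter (>= ", config$sd_threshold, "): ",
      nrow(expr$values), " genes")
  deg <- stage("moderated_t_deg",
               moderated_t_deg(expr, surv$subtype,
                               fdr_cutoff = config$deg_fdr))
  expr <- subset_expr(expr, genes = which(deg$selected))
  say("after DEG filter (FDR ", config$deg_fdr, "): ",
      nrow(expr$values), " genes")
  if (!is.null(config$probe_map_path)) {
    pm <- read.delim(config$probe_map_path, sep = detect_sep(config$probe_map_path),
                     stringsAsFactors = FALSE)
    map <- setNames(as.character(pm[[2]]), as.character(pm[[1]]))
    expr <- stage("collapse_probesets", collapse_probesets(expr, deg, map))
    say("after probe collapse: ", nrow(expr$values), " genes")
  }
  continuous_expr <- expr
  barcode_model <- NULL; calls <- NULL
  if (config$value_kind == "barcode") {
    barcode_model <- stage("fit_barcode_model", fit_barcode_model(expr))
    calls <- stage("barcode_calls",
                   barcode_calls(expr, barcode_model, C = config$barcode_C))
    keep <- stage("barcode_frequency_filter",
                  suppressMessages(
                    barcode_frequency_filter(calls, surv$subtype,
                                             high = config$freq_high,
                                             low = config$freq_low)))
    calls <- subset_expr(calls, genes = keep)
    continuous_expr <- subset_expr(continuous_expr, genes = keep)
    say("after barcode frequency filter: ", length(keep), " genes")
    filter_input <- calls
  } else {
    say("barcode stage skipped (continuous values)")
    filter_input <- expr
  }
  records <- stage("fit_gene_models",
                   suppressMessages(fit_gene_models(filter_input, surv)))
  records <- classify_scenarios(records, alpha = config$cox_fdr)
  signature <- stage("select_signature",
                     suppressWarnings(suppressMessages(
                       select_signature(records))))
  say("Cox filter (FDR ", config$cox_fdr, "): ",
      length(signature$ac_all), " AC, ", length(signature$scc_all),
      " SCC, ", length(signature$shared), " shared")
  genes <- switch(config$signature_family,
                  union = union(signature$ac_all, signature$scc_all),
                  AC = signature$ac_all, SCC = signature$scc_all)
  risk <- NULL; scores <- NULL; strata <- NULL; evaluation <- NULL
  if (length(genes) >= 1) {
    risk <- stage("build_risk_model",
                  build_risk_model(continuous_expr, surv, genes,
                                   method = config$risk_method,
                                   var_threshold = config$var_threshold))
    scores <- compute_risk_scores(risk, continuous_expr)
    strata <- stratify_by_mean(scores, cutoff = risk$cutoff)
    evaluation <- evaluate_stratification(scores, strata, surv)
    say("risk model (", config$risk_method, "): accuracy ",
        sprintf("%.1f", evaluation$accuracy[["all"]]), "%, log-rank p ",
        format(evaluation$logrank$p, digits = 3))
  } else {
    say("empty signature: risk-model stage skipped")
  }
  result <- structure(list(config = config, expr = continuous_expr,
                           deg = deg, barcode_model = barcode_model,
                           calls = calls, records = records,
                           signature = signature, risk_model = risk,
                           scores = scores, strata = strata,
                           evaluation = evaluation, log = log_lines),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result)
  invisible(result)
}

# serialize every intermediate table of a pipeline run as TSV
write_pipeline_outputs <- function(result) {
  dir.create(result$config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(result$config$out_dir, f)
  wt <- function(df, f) write.table(df, out(f), sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  write_expression_matrix(result$expr, out("expression_filtered.tsv"))
  wt(num_signif(as.data.frame(result$deg)), "deg_table.tsv")
  if (!is.null(result$barcode_model)) {
    hy <- attr(result$barcode_model, "hyper")
    con <- file(out("barcode_model.tsv"), "w")
    writeLines(paste0("# ", names(hy), " = ", signif(hy, 6)), con)
    write.table(num_signif(as.data.frame(result$barcode_model)), con,
                sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    write_expression_matrix(result$calls, out("barcode_calls.tsv"))
  }
  wt(num_signif(as.data.frame(result$records)), "gene_filter_records.tsv")
  sig <- result$signature
  wt(data.frame(gene_id = c(sig$ac_specific, sig$scc_specific, sig$shared),
                list = rep(c("AC_specific", "SCC_specific", "shared"),
                           c(length(sig$ac_specific),
                             length(sig$scc_specific),
                             length(sig$shared)))),
     "signature.tsv")
  if (!is.null(result$scores)) {
    wt(data.frame(sample_id = names(result$scores),
                  score = signif(result$scores, 6),
                  stratum = result$strata), "risk_scores.tsv")
    ev <- result$evaluation
    wt(data.frame(metric = c(paste0("accuracy_", names(ev$accuracy)),
                             paste0("auc_", names(ev$auc)),
                             "logrank_chisq", "logrank_p"),
                  value = signif(c(ev$accuracy, ev$auc,
                                   ev$logrank$statistic, ev$logrank$p), 6)),
       "evaluation.tsv")
    km <- do.call(rbind, lapply(names(ev$km), function(s)
      cbind(stratum = s, num_signif(as.data.frame(ev$km[[s]])))))
    wt(km, "km_curves.tsv")
  }
  writeLines(result$log, file.path(result$config$out_dir, "run_log.txt"))
  invisible(result)
}

num_signif <- function(df, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}

#' FDR sensitivity sweep
#'
#' Reruns the pipeline downstream of the varied stage for each cutoff in
#' the grid and tabulates the resulting signature sizes and predictive
#' statistics, mirroring the cutoff-sensitivity analysis of the method.
#'
#' @param config a [pipeline_config()].
#' @param fdr_grid numeric vector of cutoffs in (0,1).
#' @param stage `"cox"` (vary the Cox-filter FDR) or `"deg"` (vary the DEG
#'   FDR).
#' @param expr,surv optional pre-loaded inputs.
#' @return Data.frame with one row per cutoff: `cutoff`, `n_selected`,
#'   `n_ac`, `n_scc`, `accuracy`, `auc_ac`, `auc_scc`, `logrank_p`.
#' @export
sensitivity_sweep <- function(config, fdr_grid, stage = c("cox", "deg"),
                              expr = NULL, surv = NULL) {
  stage <- match.arg(stage)
  if (length(fdr_grid) == 0) stop_input("empty FDR grid")
  if (any(fdr_grid <= 0 | fdr_grid >= 1))
    stop_input("grid values must lie strictly inside (0, 1)")
  rows <- lapply(fdr_grid, function(f) {
    cfg <- config
    if (stage == "cox") cfg$cox_fdr <- f else cfg$deg_fdr <- f
    cfg$out_dir <- NULL
    res <- suppressMessages(run_full_pipeline(cfg, expr = expr, surv = surv))
    sig <- res$signature
    ev <- res$evaluation
    data.frame(cutoff = f,
               n_selected = length(union(sig$ac_all, sig$scc_all)),
               n_ac = length(sig$ac_all), n_scc = length(sig$scc_all),
               accuracy = if (is.null(ev)) NA_real_ else ev$accuracy[["all"]],
               auc_ac = if (is.null(ev)) NA_real_ else ev$auc[["AC"]],
               auc_scc = if (is.null(ev)) NA_real_ else ev$auc[["SCC"]],
               logrank_p = if (is.null(ev)) NA_real_ else ev$logrank$p)
  })
  do.call(rbind, rows)
}
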