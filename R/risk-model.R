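#' Build a prognostic risk-score model from a gene signature
#'
#' Two variants: `method = "full"` fits one multivariable Cox model with all
#' signature genes as covariates; `method = "pca"` centers the genes, runs a
#' principal component analysis on the samples-by-genes matrix, retains the
#' smallest number of components whose cumulative explained variance reaches
#' `var_threshold`, and fits the Cox model on the component scores (useful
#' when the signature is large relative to the sample count). Genes are
#' centered but not scaled - the values already share the log2 scale.
#' Risk scores on the training data are computed and their mean stored as
#' the stratification cutoff.
#'
#' @param expr continuous [expression_matrix()] aligned with `surv`.
#' @param surv a [survival_table()].
#' @param signature non-empty character vector of gene ids present in
#'   `expr`.
#' @param method `"full"` or `"pca"`.
#' @param var_threshold cumulative-variance threshold for `"pca"`
#'   (default 0.95, applied as `>=`).
#' @param ties tie handling for the Cox fit.
#' @return A `risk_model` list: `genes`, `method`, `coef`, `cutoff`
#'   (training mean risk score), `fit`; for `"pca"` also `centers`,
#'   `rotation`, `n_pc`, `cum_var`.
#' @export
build_risk_model <- function(expr, surv, signature,
                             method = c("pca", "full"), var_threshold = 0.95,
                             ties = "efron") {
  method <- match.arg(method)
  if (length(signature) == 0) stop_input("empty signature")
  miss <- setdiff(signature, gene_ids(expr))
  if (length(miss))
    stop_input("signature gene(s) absent from expression matrix: ",
               paste(head(miss, 5), collapse = ", "))
  if (!identical(sample_ids(expr), surv$sample_id))
    stop_input("expression matrix and survival table are not aligned")
  X <- t(expr$values[signature, , drop = FALSE])
  model <- list(genes = signature, method = method)
  if (method == "full") {
    if (length(signature) >= nrow(X))
      stop_input("full method needs fewer genes than samples; use method ",
                 "= 'pca'")
    fit <- cox_fit(X, surv, ties = ties)
    if (!fit$converged || fit$monotone)
      stop_numeric("multivariable Cox fit did not converge")
    model$coef <- fit$coef
  } else {
    if (!is.numeric(var_threshold) || var_threshold <= 0 || var_threshold > 1)
      stop_input("'var_threshold' must lie in (0, 1]")
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    evar <- pc$sdev^2
    cum <- cumsum(evar) / sum(evar)
    k <- which(cum >= var_threshold - 1e-12)[1]
    fit <- cox_fit(pc$x[, seq_len(k), drop = FALSE], surv, ties = ties)
    if (!fit$converged || fit$monotone)
      stop_numeric("Cox fit on principal components did not converge")
    model$coef <- fit$coef
    model$centers <- pc$center
    model$rotation <- pc$rotation[, seq_len(k), drop = FALSE]
    model$n_pc <- k
    model$cum_var <- cum[k]
    model$explained_var <- evar / sum(evar)
  }
  model$fit <- fit
  class(model) <- "risk_model"
  model$cutoff <- mean(compute_risk_scores(model, expr))
  model
}

#' Per-sample risk scores under a fitted risk model
#'
#' The linear predictor of the stored Cox model. Continuous expression
#' values are used even when the signature was discovered on barcode calls.
#'
#' @param model a [build_risk_model()] result.
#' @param expr continuous [expression_matrix()] containing all model genes.
#' @return Named numeric vector of risk scores (one per sample).
#' @export
compute_risk_scores <- function(model, expr) {
  miss <- setdiff(model$genes, gene_ids(expr))
  if (length(miss))
    stop_input("gene(s) missing from expression matrix: ",
               paste(head(miss, 5), collapse = ", "))
  X <- t(expr$values[model$genes, , drop = FALSE])
  if (model$method == "full") {
    drop(X %*% model$coef)
  } else {
    scores <- sweep(X, 2, model$centers) %*% model$rotation
    drop(scores %*% model$coef)
  }
}

#' Stratify samples into low/high risk at a mean cutoff
#'
#' High risk iff score strictly exceeds the cutoff (training-set mean risk
#' score when a model is supplied; otherwise the mean of `scores`); ties at
#' the cutoff are low risk.
#'
#' @param scores numeric risk scores.
#' @param cutoff the stratification cutoff; defaults to `mean(scores)`.
#' @return Factor with levels `low`, `high`.
#' @export
stratify_by_mean <- function(scores, cutoff = mean(scores)) {
  if (length(scores) < 2) stop_input("at least 2 samples required")
  factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Evaluate a risk stratification
#'
#' Accuracy is the fraction of samples whose stratum matches vital status
#' (high-risk with event = 1, low-risk with event = 0), overall and per
#' subtype, in percent - censored patients count as non-events, a known
#' optimistic bias documented in the vignette. AUC is the Mann-Whitney
#' probability that a random event sample scores above a random non-event
#' sample, per subtype, in percent (undefined and reported `NA` when a
#' subtype has all-identical event status). Strata are compared by log-rank
#' and summarized by per-stratum Kaplan-Meier curves.
#'
#' @param scores numeric risk scores.
#' @param labels low/high strata from [stratify_by_mean()].
#' @param surv aligned [survival_table()].
#' @return An `evaluation_report` list: `accuracy` (named overall/AC/SCC,
#'   %), `auc` (named AC/SCC and overall, %), `logrank`
#'   (statistic, p), `group_sizes`, `km` (per-stratum curves).
#' @export
evaluate_stratification <- function(scores, labels, surv) {
  if (length(scores) != nrow(surv) || length(labels) != nrow(surv))
    stop_input("scores, labels and survival table must be aligned")
  event <- surv$event
  st <- as.character(surv$subtype)
  hit <- (labels == "high") == (event == 1)
  acc <- c(all = mean(hit),
           AC = mean(hit[st == "AC"]),
           SCC = mean(hit[st == "SCC"])) * 100
  auc1 <- function(sc, ev) {
    n1 <- sum(ev == 1); n0 <- sum(ev == 0)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(sc)
    (sum(r[ev == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0) * 100
  }
  auc <- c(all = auc1(scores, event),
           AC = auc1(scores[st == "AC"], event[st == "AC"]),
           SCC = auc1(scores[st == "SCC"], event[st == "SCC"]))
  lr <- if (length(unique(labels)) == 2) logrank_test(surv, labels)
  else list(statistic = NA_real_, p = NA_real_)
  km <- lapply(split(seq_along(labels), labels), function(ii) {
    if (length(ii)) km_estimate(surv[ii, , drop = FALSE])
  })
  structure(list(accuracy = acc, auc = auc, logrank = lr,
                 group_sizes = table(labels), km = km),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("accuracy (%):", paste(names(x$accuracy),
                             sprintf("%.1f", x$accuracy), collapse = "  "),
      "\nAUC (%):     ", paste(names(x$auc), sprintf("%.1f", x$auc),
                               collapse = "  "),
      "\nlog-rank:     chisq =", sprintf("%.3f", x$logrank$statistic),
      ", p =", format(x$logrank$p, digits = 3), "\n")
  invisible(x)
}

#' Likelihood-ratio test for clinical-covariate adjustment
#'
#' Within each subtype, compares Cox(risk score + clinical covariates)
#' against Cox(risk score); a small p-value means the clinical covariates
#' add prognostic information beyond the signature score.
#'
#' @param scores numeric risk scores.
#' @param surv aligned [survival_table()].
#' @param clinical data.frame of clinical covariates (factors are expanded
#'   to dummy columns).
#' @return Data.frame with one row per subtype: `subtype`, `df`,
#'   `statistic`, `p`.
#' @export
clinical_adjustment_test <- function(scores, surv, clinical) {
  Z <- model.matrix(~., data = as.data.frame(clinical))[, -1, drop = FALSE]
  out <- lapply(c("AC", "SCC"), function(s) {
    ii <- which(surv$subtype == s)
    Xf <- cbind(score = scores[ii], Z[ii, , drop = FALSE])
    # a covariate is collinear if appending it does not raise the rank
    base_mat <- cbind(1, Xf[, 1, drop = FALSE])
    bad <- character(0)
    for (j in seq(2, ncol(Xf))) {
      cand <- cbind(base_mat, Xf[, j])
      if (qr(cand)$rank == qr(base_mat)$rank) bad <- c(bad, colnames(Xf)[j])
      else base_mat <- cand
    }
    if (length(bad))
      stop_input("collinear covariate(s) in subtype ", s, ": ",
                 paste(bad, collapse = ", "))
    sub <- surv[ii, , drop = FALSE]
    full <- cox_fit(Xf, sub)
    null <- cox_fit(Xf[, "score", drop = FALSE], sub)
    lrt <- likelihood_ratio_test(full, null, df = ncol(Z))
    data.frame(subtype = s, df = lrt$df, statistic = lrt$statistic,
               p = lrt$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
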