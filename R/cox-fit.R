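#' Cox proportional-hazards fit by Newton-Raphson
#'
#' Maximizes the Cox partial log-likelihood with Efron (default) or Breslow
#' handling of tied event times, with step-halving whenever a Newton step
#' fails to improve the objective. A monotone-likelihood (separation) guard
#' aborts and flags the fit when any coefficient exceeds 15 in absolute
#' value during iteration; constant covariates are excluded from the
#' optimization and reported with coefficient 0 and infinite variance.
#'
#' @param covariates numeric vector or samples-by-k matrix.
#' @param surv a [survival_table()] (or any data.frame with `time` and
#'   `event` columns) aligned with the covariate rows.
#' @param ties `"efron"` or `"breslow"`.
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance on the partial log-likelihood.
#' @return A `cox_fit` list: `coef`, `var` (inverse observed information),
#'   `score`, `loglik0`/`loglik` (at zero and at the optimum), `iter`,
#'   `converged`, `monotone`, `inf_variance` (per-coefficient flag),
#'   `ties`, `n`, `nevent`.
#' @export
cox_fit <- function(covariates, surv, ties = c("efron", "breslow"),
                    max_iter = 50, tol = 1e-9) {
  ties <- match.arg(ties)
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  time <- as.numeric(surv$time)
  event <- as.integer(surv$event)
  if (nrow(X) != length(time))
    stop_input("covariate rows must match survival samples")
  if (sum(event) == 0) stop_input("no events in the data")
  const <- apply(X, 2, function(z) max(z) == min(z))
  fit <- cox_fit_core(time, event, X[, !const, drop = FALSE],
                      ties = ties, max_iter = max_iter, tol = tol)
  k <- ncol(X)
  coef <- numeric(k); score <- numeric(k)
  V <- matrix(0, k, k)
  coef[!const] <- fit$coef
  score[!const] <- fit$score
  V[!const, !const] <- fit$var
  diag(V)[const] <- Inf
  names(coef) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(coef = coef, var = V, score = score,
                 loglik0 = fit$loglik0, loglik = fit$loglik,
                 iter = fit$iter, converged = fit$converged,
                 monotone = fit$monotone, inf_variance = const,
                 ties = ties, n = length(time), nevent = sum(event)),
            class = "cox_fit")
}

# lean core used by the per-gene filter loop: no validation, covariates
# assumed non-constant, data unsorted.
cox_fit_core <- function(time, event, X, ties = "efron", max_iter = 50,
                         tol = 1e-9) {
  if (ncol(X) == 0) {
    # null model: partial likelihood at beta = 0
    r <- .cox_fit_cpp(sort(time), event[order(time)],
                      matrix(0, length(time), 1), ties == "efron", 1, tol, 15)
    return(list(coef = numeric(0), var = matrix(0, 0, 0), score = numeric(0),
                loglik0 = r$loglik0, loglik = r$loglik0, iter = 0L,
                converged = TRUE, monotone = FALSE))
  }
  o <- order(time)
  r <- .cox_fit_cpp(time[o], event[o], X[o, , drop = FALSE],
                    as.integer(ties == "efron"), as.integer(max_iter), tol, 15)
  V <- tryCatch(solve(r$imat), error = function(e) NULL)
  if (is.null(V) || r$singular) {
    V <- matrix(Inf, ncol(X), ncol(X))
    r$monotone <- TRUE
  }
  list(coef = as.numeric(r$coef), var = V, score = as.numeric(r$score),
       loglik0 = r$loglik0, loglik = r$loglik, iter = r$iter,
       converged = r$converged, monotone = r$monotone)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox model fit (", x$ties, " ties), n = ", x$n, ", events = ",
      x$nevent, "\n", sep = "")
  se <- sqrt(diag(x$var))
  print(data.frame(coef = x$coef, se = se, z = x$coef / se,
                   p = 2 * pnorm(-abs(x$coef / se))))
  cat("partial loglik:", x$loglik, "(null", x$loglik0, ")",
      if (x$monotone) " [monotone-likelihood flag]" else "", "\n")
  invisible(x)
}

#' Wald test of a linear contrast of Cox coefficients
#'
#' @param fit a converged [cox_fit()].
#' @param contrast numeric vector `c` of the same length as the
#'   coefficients; tests \eqn{c^T\beta = 0}.
#' @return A list: `estimate`, `se`, `z`, `p` (two-sided normal).
#' @export
wald_contrast <- function(fit, contrast) {
  contrast <- as.numeric(contrast)
  if (length(contrast) != length(fit$coef))
    stop_input("contrast length must match the number of coefficients")
  est <- sum(contrast * fit$coef)
  v <- drop(t(contrast) %*% fit$var %*% contrast)
  if (!is.finite(v) || v <= 0)
    stop_numeric("contrast variance is not positive")
  se <- sqrt(v)
  z <- est / se
  list(estimate = est, se = se, z = z, p = 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment (delegating to [stats::p.adjust()]), with input
#' validation; adjusted values lie in \[0,1\] and preserve the input order.
#'
#' @param pvalues numeric vector of p-values in \[0,1\].
#' @return The BH-adjusted q-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop_input("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Likelihood-ratio test between nested Cox fits
#'
#' @param full,null [cox_fit()] objects on the same data, `null` nested in
#'   `full`.
#' @param df degrees of freedom; must equal the difference in coefficient
#'   counts.
#' @return A list: `statistic` (floored at 0), `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, null, df) {
  if (df != length(full$coef) - length(null$coef))
    stop_input("'df' must equal the coefficient-count difference")
  if (full$loglik < null$loglik - 1e-6)
    stop_numeric("full-model log-likelihood below null: models not nested ",
                 "or fit not converged")
  stat <- max(2 * (full$loglik - null$loglik), 0)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}
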