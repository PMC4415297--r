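#' Kaplan-Meier product-limit estimate
#'
#' @param surv a [survival_table()] (or data.frame with `time`, `event`).
#' @return A `km_curve` data.frame: `time` (distinct event/censoring times),
#'   `n_risk`, `n_event`, `surv` (non-increasing, starting at 1).
#' @export
km_estimate <- function(surv) {
  time <- as.numeric(surv$time)
  event <- as.integer(surv$event)
  if (length(time) == 0) stop_input("empty survival data")
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  s <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event, surv = s)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic with hypergeometric variance at each
#' distinct event time, referred to chi-square on 1 df.
#'
#' @param surv a [survival_table()] (or data.frame with `time`, `event`).
#' @param groups binary labels (two levels) aligned with the rows.
#' @return A list: `statistic`, `p`, `observed`/`expected` per group.
#' @export
logrank_test <- function(surv, groups) {
  time <- as.numeric(surv$time)
  event <- as.integer(surv$event)
  g <- as.integer(factor(groups)) - 1L
  if (length(unique(g)) != 2) stop_input("exactly two non-empty groups required")
  et <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) {
    warning("log-rank variance is zero; statistic set to 0")
    return(list(statistic = 0, p = 1, observed = c(NA, O), expected = c(NA, E)))
  }
  stat <- (O - E)^2 / V
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE),
       observed = c(sum(event) - O, O),
       expected = c(sum(event) - E, E))
}

#' Schoenfeld residuals of a Cox fit
#'
#' One row per event (time-ascending): the dying subject's covariates minus
#' the risk-set weighted mean, with Efron tie adjustment matching the fit,
#' so the residuals sum to the score vector (zero at the MLE).
#'
#' @param fit a [cox_fit()].
#' @param covariates the covariate matrix used in the fit.
#' @param surv the survival data used in the fit.
#' @return A list: `residuals` (events-by-k matrix), `time` (event times).
#' @export
schoenfeld_residuals <- function(fit, covariates, surv) {
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  time <- as.numeric(surv$time)
  event <- as.integer(surv$event)
  o <- order(time)
  r <- .schoenfeld_cpp(time[o], event[o], X[o, , drop = FALSE],
                       as.numeric(fit$coef),
                       as.integer(fit$ties == "efron"))
  colnames(r$residuals) <- names(fit$coef)
  r
}

#' Schoenfeld test of the proportional-hazards assumption
#'
#' Score test for a zero slope of the Schoenfeld residuals against event
#' time (identity time transform), per covariate and globally. The test
#' variance uses the exact per-event risk-set covariance with the
#' correction for estimating the coefficients:
#' \eqn{D = \sum \tilde g_k^2 V_k - (\sum \tilde g_k V_k) I^{-1}
#' (\sum \tilde g_k V_k)} with \eqn{u = \sum \tilde g_k s_k}, global
#' statistic \eqn{u^T D^{-1} u} on k df.
#'
#' @param fit a converged [cox_fit()].
#' @param covariates covariate matrix used in the fit.
#' @param surv survival data used in the fit.
#' @return A list: `table` (per-covariate chi-square, df, p) and `global`
#'   (chi-square, df, p).
#' @export
schoenfeld_ph_test <- function(fit, covariates, surv) {
  if (!fit$converged) stop_input("fit did not converge")
  if (sum(surv$event) < 3) stop_input("at least 3 events required")
  sr <- schoenfeld_residuals(fit, covariates, surv)
  st <- ph_score_test(sr)
  k <- ncol(sr$residuals)
  tab <- data.frame(covariate = names(fit$coef),
                    chisq = st$per, df = 1,
                    p = pchisq(st$per, 1, lower.tail = FALSE),
                    row.names = NULL)
  list(table = tab,
       global = list(chisq = st$global, df = k,
                     p = pchisq(st$global, k, lower.tail = FALSE)))
}

# core of the PH score test, shared with the per-gene filter loop
ph_score_test <- function(sr) {
  res <- sr$residuals
  k <- ncol(res)
  gt <- sr$time - mean(sr$time)
  u <- drop(t(res) %*% gt)
  vm <- sr$vmat
  d <- length(gt)
  A <- matrix(0, k, k); B <- matrix(0, k, k); I <- matrix(0, k, k)
  for (jj in seq_len(d)) {
    Vk <- vm[, , jj]
    A <- A + gt[jj]^2 * Vk
    B <- B + gt[jj] * Vk
    I <- I + Vk
  }
  D <- A - B %*% solve(I, B)
  global <- drop(t(u) %*% solve(D, u))
  per <- u^2 / diag(D)
  list(global = global, per = as.numeric(per), u = u, D = D)
}

#' Breslow baseline cumulative hazard
#'
#' @param fit a [cox_fit()].
#' @param covariates covariate matrix used in the fit.
#' @param surv survival data used in the fit.
#' @return Data.frame `time`, `hazard` (increment), `cumhaz`.
#' @export
breslow_baseline <- function(fit, covariates, surv) {
  X <- as.matrix(covariates)
  time <- as.numeric(surv$time)
  event <- as.integer(surv$event)
  risk <- exp(drop(X %*% fit$coef))
  et <- sort(unique(time[event == 1]))
  h <- vapply(et, function(t) {
    sum(event == 1 & time == t) / sum(risk[time >= t])
  }, numeric(1))
  data.frame(time = et, hazard = h, cumhaz = cumsum(h))
}
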