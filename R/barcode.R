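#' Fit the expression-barcode mixture model
#'
#' Per gene g, log2 values are modelled as a two-component mixture
#' \deqn{y_{ig} \sim (1-p_g)\,N(\mu_g, \tau_g^2) + p_g\,U(\mu_g, S_g),}
#' the normal component describing the silenced state and the uniform
#' component the expressed state. The saturation value \eqn{S_g} is fixed to
#' the per-gene maximum observed value plus 0.1. Estimation is by EM with
#' empirical-Bayes shrinkage: hyperparameters \eqn{\xi, \lambda^2} (normal
#' prior on \eqn{\mu_g}) and \eqn{\alpha, \beta} (inverse-gamma prior on
#' \eqn{\tau_g^2}) are moment-matched across genes after an unshrunk first
#' pass, then used as MAP penalties in a second pass. Iteration stops when
#' the complete-data log-posterior improves by less than `tol`.
#'
#' Initialization is fixed for reproducibility: \eqn{\mu_g} at the 25th
#' percentile, \eqn{\tau_g} at half the interquartile distance below the
#' median, \eqn{p_g} at the fraction of values above the range midpoint.
#'
#' @param expr continuous [expression_matrix()] with at least 8 samples.
#' @param max_iter maximum EM iterations per gene (default 100).
#' @param tol convergence tolerance on the log-posterior (default 1e-6);
#'   `Inf` returns after a single EM step.
#' @return A `barcode_model`: data.frame with `gene_id`, `mu`, `tau2`, `p`,
#'   `S`, `converged`, `flagged`, plus attribute `hyper`
#'   (\eqn{\xi, \lambda^2, \alpha, \beta}).
#' @export
fit_barcode_model <- function(expr, max_iter = 100, tol = 1e-6) {
  if (expr$value_kind != "continuous")
    stop_input("fit_barcode_model requires continuous values")
  v <- expr$values
  if (ncol(v) < 8) stop_input("at least 8 samples required")
  # first pass: no shrinkage
  first <- t(apply(v, 1, fit_barcode_gene, max_iter = max_iter, tol = tol,
                   xi = NA, lambda2 = Inf, alpha = 0, beta = 0))
  ok <- first[, "flagged"] == 0
  if (sum(ok) >= 3) {
    mu <- first[ok, "mu"]; tau2 <- first[ok, "tau2"]
    xi <- mean(mu); lambda2 <- max(var(mu), 1e-6)
    mt <- mean(tau2); vt <- var(tau2)
    if (is.finite(vt) && vt > 0) {
      alpha <- 2 + mt^2 / vt
      beta <- (alpha - 1) * mt
    } else {
      alpha <- 2; beta <- mt
    }
    est <- t(apply(v, 1, fit_barcode_gene, max_iter = max_iter, tol = tol,
                   xi = xi, lambda2 = lambda2, alpha = alpha, beta = beta))
  } else {
    xi <- NA_real_; lambda2 <- Inf; alpha <- 0; beta <- 0
    est <- first
  }
  out <- data.frame(gene_id = rownames(v), mu = est[, "mu"],
                    tau2 = est[, "tau2"], p = est[, "p"], S = est[, "S"],
                    converged = est[, "converged"] == 1,
                    flagged = est[, "flagged"] == 1,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "hyper") <- c(xi = xi, lambda2 = lambda2, alpha = alpha,
                          beta = beta)
  class(out) <- c("barcode_model", "data.frame")
  out
}

# EM for a single gene; returns named numeric vector.
fit_barcode_gene <- function(y, max_iter, tol, xi, lambda2, alpha, beta) {
  n <- length(y)
  S <- max(y) + 0.1
  if (sd(y) == 0) {
    return(c(mu = unname(y[1]), tau2 = 1e-6, p = 0, S = S, converged = 1,
             flagged = 1))
  }
  q <- quantile(y, c(0.25, 0.5))
  mu <- unname(q[1])
  tau <- max((unname(q[2]) - unname(q[1])) / 2, 0.05)
  p <- mean(y > (min(y) + max(y)) / 2)
  tau2 <- tau^2
  logpost <- function(mu, tau2, p) {
    du <- ifelse(y > mu & y < S, 1 / (S - mu), 0)
    dens <- (1 - p) * dnorm(y, mu, sqrt(tau2)) + p * du
    lp <- sum(log(pmax(dens, 1e-300)))
    if (is.finite(lambda2)) lp <- lp + dnorm(mu, xi, sqrt(lambda2), log = TRUE)
    if (alpha > 0) lp <- lp - (alpha + 1) * log(tau2) - beta / tau2
    lp
  }
  last <- logpost(mu, tau2, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    du <- ifelse(y > mu & y < S, 1 / (S - mu), 0)
    fn <- (1 - p) * dnorm(y, mu, sqrt(tau2))
    fu <- p * du
    gam <- fu / pmax(fn + fu, 1e-300) # P(expressed | y)
    w <- 1 - gam
    sw <- sum(w)
    # MAP M-step
    if (is.finite(lambda2)) {
      mu_new <- (sum(w * y) / tau2 + xi / lambda2) / (sw / tau2 + 1 / lambda2)
    } else {
      mu_new <- if (sw > 0) sum(w * y) / sw else mu
    }
    rss <- sum(w * (y - mu_new)^2)
    tau2_new <- if (alpha > 0) (2 * beta + rss) / (2 * (alpha + 1) + sw)
    else if (sw > 0) rss / sw else tau2
    tau2_new <- max(tau2_new, 1e-8)
    p_new <- mean(gam)
    mu <- mu_new; tau2 <- tau2_new; p <- p_new
    cur <- logpost(mu, tau2, p)
    if (!is.finite(cur)) break
    if (abs(cur - last) < tol || is.infinite(tol)) {
      converged <- TRUE
      last <- cur
      break
    }
    last <- cur
  }
  c(mu = mu, tau2 = tau2, p = min(max(p, 0), 1), S = S,
    converged = as.numeric(converged), flagged = as.numeric(!converged))
}

#' Expression barcode calls
#'
#' A sample is called expressed (1) when the upper-tail probability of its
#' standardized value under the silenced normal component falls below the
#' threshold: \eqn{b_{ig} = 1} iff
#' \eqn{\Phi(-(y_{ig}-\mu_g)/\tau_g) < C}.
#'
#' @param expr continuous [expression_matrix()].
#' @param model a `barcode_model` from [fit_barcode_model()] covering all
#'   genes of `expr`.
#' @param C call threshold in (0,1); default 0.01.
#' @return A barcode [expression_matrix()] of 0/1 calls.
#' @export
barcode_calls <- function(expr, model, C = 0.01) {
  if (!is.numeric(C) || length(C) != 1 || C <= 0 || C >= 1)
    stop_input("'C' must lie strictly inside (0, 1)")
  genes <- gene_ids(expr)
  idx <- match(genes, model$gene_id)
  if (anyNA(idx))
    stop_input("model does not cover gene(s): ",
               paste(head(genes[is.na(idx)], 5), collapse = ", "))
  mu <- model$mu[idx]
  tau <- sqrt(model$tau2[idx])
  z <- -(expr$values - mu) / tau
  b <- (pnorm(z) < C) * 1
  dimnames(b) <- dimnames(expr$values)
  expression_matrix(b, value_kind = "barcode",
                    allow_duplicate_genes = TRUE)
}
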