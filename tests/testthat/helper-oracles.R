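# Independent oracles and small data builders used across the suite.

# Hand-coded Cox partial log-likelihood (single covariate), with Efron or
# Breslow handling of ties; written independently of the package's C++
# engine and used as a brute-force reference.
oracle_partial_loglik <- function(beta, time, status, x, ties = "efron") {
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    dead <- which(time == t & status == 1)
    risk <- which(time >= t)
    d <- length(dead)
    ll <- ll + sum(beta * x[dead])
    rs <- sum(exp(beta * x[risk]))
    rd <- sum(exp(beta * x[dead]))
    for (l in seq_len(d) - 1) {
      f <- if (ties == "efron") l / d else 0
      ll <- ll - log(rs - f * rd)
    }
  }
  ll
}

# golden-section maximizer of the hand-coded partial likelihood
oracle_cox_mle <- function(time, status, x, ties = "efron") {
  optimize(oracle_partial_loglik, c(-8, 8), maximum = TRUE, tol = 1e-9,
           time = time, status = status, x = x, ties = ties)$maximum
}

# small expression matrix with default ids
make_expr <- function(values, kind = "continuous", genes = NULL,
                      samples = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, value_kind = kind)
}

# survival table with default ids
make_surv <- function(time, event, subtype = NULL, ...) {
  n <- length(time)
  if (is.null(subtype)) subtype <- rep(c("AC", "SCC"), length.out = n)
  survival_table(paste0("s", seq_len(n)), time, event, subtype, ...)
}

# one simulated single-covariate survival dataset (exponential baseline)
sim_cox_data <- function(n, beta, cens_rate = 0, x = rnorm(n)) {
  T <- rexp(n, rate = exp(beta * x))
  if (cens_rate > 0) {
    C <- rexp(n, cens_rate)
    data.frame(time = pmin(T, C), event = as.integer(T <= C), x = x)
  } else {
    data.frame(time = T, event = rep(1L, n), x = x)
  }
}
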