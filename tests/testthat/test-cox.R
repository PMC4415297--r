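test_that("cox_fit matches a brute-force partial-likelihood maximizer", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    x <- if (rep %% 2) rnorm(n) else rbinom(n, 1, 0.5)
    if (max(x) == min(x)) x[1] <- x[1] + 1
    time <- if (rep %% 3) round(rexp(n), 3) + 0.001 else sample(1:4, n, TRUE)
    status <- rbinom(n, 1, 0.8)
    if (sum(status) == 0) status[1] <- 1
    for (ties in c("efron", "breslow")) {
      fit <- cox_fit(cbind(x = x), data.frame(time = time, event = status),
                     ties = ties)
      if (fit$monotone) next # separation: oracle optimum sits at the boundary
      bhat <- oracle_cox_mle(time, status, x, ties = ties)
      if (abs(bhat) > 7.5) next # boundary of the oracle's search interval
      expect_equal(unname(fit$coef), bhat, tolerance = 1e-4)
    }
  }
})

test_that("cox_fit agrees with survival::coxph on larger data", {
  skip_if_not_installed("survival")
  set.seed(32)
  n <- 150
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4), c = rnorm(n))
  d <- sim_cox_data(n, 0.7, cens_rate = 0.3, x = X[, 1])
  # inject ties to exercise the Efron correction
  d$time <- round(d$time, 1) + 0.01
  for (ties in c("efron", "breslow")) {
    fit <- cox_fit(X, d, ties = ties)
    ref <- survival::coxph(survival::Surv(d$time, d$event) ~ X,
                           ties = ties)
    expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$var), unname(vcov(ref)), tolerance = 1e-6)
    expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
    expect_equal(fit$loglik0, ref$loglik[1], tolerance = 1e-8)
  }
})

test_that("efron and breslow coincide when event times are distinct", {
  set.seed(33)
  d <- sim_cox_data(40, 0.5)
  f1 <- cox_fit(cbind(x = d$x), d, ties = "efron")
  f2 <- cox_fit(cbind(x = d$x), d, ties = "breslow")
  expect_equal(f1$coef, f2$coef, tolerance = 1e-12)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-12)
})

test_that("degenerate covariates are handled per contract", {
  d <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 1, 1, 1, 0))
  # all-zero covariate: coefficient 0, loglik equals null loglik
  f <- cox_fit(cbind(z = rep(0, 6)), d)
  expect_equal(unname(f$coef), 0)
  expect_equal(f$loglik, f$loglik0)
  expect_true(f$inf_variance[1])
  expect_true(is.infinite(f$var[1, 1]))
  # no events
  expect_error(cox_fit(cbind(x = rnorm(6)),
                       data.frame(time = 1:6, event = rep(0, 6))),
               "no events")
})

test_that("perfect separation raises the monotone-likelihood flag", {
  # covariate-1 subjects all die first: likelihood increases in beta forever
  d <- data.frame(time = c(1, 2, 3, 4, 5, 6, 7, 8),
                  event = rep(1, 8))
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  ll <- vapply(c(0, 2, 4, 6), oracle_partial_loglik, numeric(1),
               time = d$time, status = d$event, x = x)
  expect_true(all(diff(ll) > 0)) # oracle confirms monotone likelihood
  f <- cox_fit(cbind(x = x), d)
  expect_true(f$monotone)
})

test_that("negating a covariate negates its coefficient exactly", {
  set.seed(34)
  d <- sim_cox_data(60, 0.8, x = rbinom(60, 1, 0.5))
  f1 <- cox_fit(cbind(x = d$x), d)
  f2 <- cox_fit(cbind(x = -d$x), d)
  expect_equal(unname(f1$coef), -unname(f2$coef), tolerance = 1e-10)
})

test_that("score at a converged optimum is numerically zero", {
  set.seed(35)
  d <- sim_cox_data(100, 0.5, cens_rate = 0.2)
  f <- cox_fit(cbind(x = d$x), d, tol = 1e-9)
  expect_true(f$converged)
  expect_lt(max(abs(f$score)), 1e-8)
})

test_that("wald contrasts match single coefficients and reparameterization", {
  set.seed(36)
  n <- 200
  z <- rbinom(n, 1, 0.3)
  x <- rnorm(n)
  T <- rexp(n, exp(0.3 * z + 0.5 * x + 0.6 * z * x))
  d <- data.frame(time = T, event = 1L)
  X <- cbind(z = z, x = x, zx = z * x)
  fit <- cox_fit(X, d)
  # single-coordinate contrast is beta2/se2
  w <- wald_contrast(fit, c(0, 1, 0))
  expect_equal(w$estimate, unname(fit$coef[2]))
  expect_equal(w$se, sqrt(fit$var[2, 2]))
  # reparameterized fit makes beta2+beta3 a single coefficient:
  # covariates [z, x*(1-z), x*z] carry coefficients [b1, b2, b2+b3]
  X2 <- cbind(z = z, x_ac = x * (1 - z), x_scc = x * z)
  fit2 <- cox_fit(X2, d)
  w2 <- wald_contrast(fit, c(0, 1, 1))
  expect_equal(w2$estimate, unname(fit2$coef[3]), tolerance = 1e-6)
  expect_equal(w2$se, sqrt(fit2$var[3, 3]), tolerance = 1e-6)
  # variance composition identity
  expect_equal(w2$se^2,
               fit$var[2, 2] + fit$var[3, 3] + 2 * fit$var[2, 3],
               tolerance = 1e-12)
})

test_that("wald_contrast arithmetic on a synthetic fit", {
  fake <- structure(list(coef = c(0, 1, 1), var = diag(3),
                         converged = TRUE), class = "cox_fit")
  w <- wald_contrast(fake, c(0, 1, 1))
  expect_equal(w$z, 2 / sqrt(2))
  expect_error(wald_contrast(fake, c(0, 0, 0)), "positive")
})

test_that("BH adjustment matches hand computation and is equivariant", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  # hand computation: q_i = min_{j>=i} p_(j) * m / j
  p <- c(0.001, 0.3, 0.02, 0.9, 0.04)
  expect_equal(bh_adjust(p), c(0.005, 0.375, 0.05, 0.9, 0.0666666666666667),
               tolerance = 1e-12)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("likelihood-ratio test honors nesting and df contracts", {
  set.seed(37)
  d <- sim_cox_data(80, 0.6, cens_rate = 0.2)
  z <- rnorm(80)
  full <- cox_fit(cbind(x = d$x, z = z), d)
  null <- cox_fit(cbind(x = d$x), d)
  lrt <- likelihood_ratio_test(full, null, df = 1)
  expect_gte(lrt$statistic, 0)
  expect_true(lrt$p >= 0 && lrt$p <= 1)
  expect_error(likelihood_ratio_test(full, null, df = 2), "df")
  # full == null gives statistic 0, p = 1
  same <- likelihood_ratio_test(null, null, df = 0)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # reversed nesting errors
  expect_error(likelihood_ratio_test(null, full, df = -1), "nested")
})

test_that("null LRT p-values are uniform", {
  set.seed(38)
  ps <- replicate(300, {
    d <- sim_cox_data(60, 0.5, cens_rate = 0.2)
    z <- rnorm(60)
    full <- cox_fit(cbind(x = d$x, z = z), d)
    null <- cox_fit(cbind(x = d$x), d)
    likelihood_ratio_test(full, null, df = 1)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
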