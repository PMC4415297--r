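test_that("presets encode the two extreme-case designs", {
  s1 <- preset_extreme_cases("case1")
  expect_equal(s1$coef_scc[1:2], c(1.42, -0.75))
  expect_equal(s1$coef_ac[3:4], c(0.225, 0.177))
  expect_true(all(s1$coef_scc[3:100] == 0))
  expect_true(all(s1$coef_ac[c(1:2, 5:100)] == 0))
  s2 <- preset_extreme_cases("case2")
  expect_equal(s2$coef_ac, s2$coef_scc)
  expect_equal(s2$coef_ac[1:4], c(1.42, -0.75, 0.75, -0.59))
  for (s in list(s1, s2)) {
    expect_equal(s$n_genes, 100)
    expect_equal(s$n_ac, 127)
    expect_equal(s$n_scc, 42)
    expect_equal(s$censoring, 0.3)
    expect_equal(s$replicates, 500)
    expect_equal(s$alpha, 0.05)
  }
})

test_that("covariate draws are deterministic with sound moments", {
  spec <- preset_extreme_cases("case2")
  a <- make_covariates(spec, seed = 99)
  b <- make_covariates(spec, seed = 99)
  expect_identical(a$values, b$values)
  expect_equal(dim(a$values), c(100, 169))
  mu_ok <- mean(abs(rowMeans(a$values)) <= 0.25)
  sd_ok <- mean(abs(apply(a$values, 1, sd) - 1) <= 0.25)
  expect_gte(mu_ok, 0.95)
  expect_gte(sd_ok, 0.95)
})

test_that("resampling preserves the joint covariate distribution", {
  set.seed(81)
  z <- rnorm(500)
  src <- rbind(g1 = z, g2 = 0.9 * z + sqrt(1 - 0.81) * rnorm(500))
  colnames(src) <- paste0("c", 1:500)
  spec <- simulation_spec(n_ac = 700, n_scc = 300, n_genes = 2,
                          covariate_mode = "resample_from_matrix",
                          resample_matrix = src, censoring = 0)
  m <- make_covariates(spec, seed = 5)
  expect_lt(abs(cor(m$values[1, ], m$values[2, ]) - 0.9), 0.1)
  expect_error(simulation_spec(n_ac = 10, n_scc = 5, n_genes = 2,
                               covariate_mode = "resample_from_matrix"),
               "resample_matrix")
})

test_that("survival times follow the Cox-exponential construction", {
  spec <- simulation_spec(n_ac = 6e4, n_scc = 4e4, n_genes = 2,
                          censoring = 0)
  cov <- make_covariates(spec, seed = 7)
  surv <- simulate_survival(spec, cov, seed = 8)
  # null hazards, no censoring: times are Exp(1)
  expect_true(all(surv$event == 1))
  expect_lt(abs(mean(surv$time) - 1), 0.02)
  # eta fixed per sample: T * exp(eta) ~ Exp(1)
  spec2 <- simulation_spec(n_ac = 6000, n_scc = 4000, n_genes = 2,
                           coef_ac = c(X1 = 0.8), coef_scc = c(X1 = 0.8),
                           censoring = 0)
  cov2 <- make_covariates(spec2, seed = 9)
  surv2 <- simulate_survival(spec2, cov2, seed = 10)
  eta <- 0.8 * cov2$values[1, ]
  expect_gt(ks.test(surv2$time * exp(eta), "pexp")$p.value, 0.01)
  # stronger hazard coefficient: high expressers die sooner
  spec3 <- simulation_spec(n_ac = 6000, n_scc = 4000, n_genes = 2,
                           coef_ac = c(X1 = 1.6), coef_scc = c(X1 = 1.6),
                           censoring = 0)
  surv3 <- simulate_survival(spec3, cov2, seed = 10)
  r2 <- cor(cov2$values[1, ], surv2$time, method = "spearman")
  r3 <- cor(cov2$values[1, ], surv3$time, method = "spearman")
  expect_lt(r3, r2) # more negative under the doubled coefficient
})

test_that("censoring calibration hits its target", {
  # target 0: no censoring machinery at all
  spec0 <- simulation_spec(n_ac = 50, n_scc = 25, n_genes = 3, censoring = 0)
  expect_equal(calibrate_censoring(spec0), 0)
  # null hazards at target 0.5: two competing Exp(1)/Exp(theta) -> theta = 1
  spec5 <- simulation_spec(n_ac = 50, n_scc = 25, n_genes = 3,
                           censoring = 0.5)
  expect_lt(abs(calibrate_censoring(spec5) - 1), 0.02)
  # self-consistency on fresh draws under a non-null design
  spec <- preset_extreme_cases("case1")
  theta <- calibrate_censoring(spec)
  big <- simulation_spec(n_ac = round(1e5 * 127 / 169),
                         n_scc = round(1e5 * 42 / 169), n_genes = 100,
                         coef_ac = spec$coef_ac, coef_scc = spec$coef_scc,
                         censoring = 0.3)
  cov <- make_covariates(big, seed = 20)
  surv <- simulate_survival(big, cov, seed = 21, theta = theta)
  expect_lt(abs(mean(surv$event == 0) - 0.3), 0.01)
  expect_error(simulation_spec(n_ac = 10, n_scc = 5, n_genes = 2,
                               censoring = 1), "censoring")
})

test_that("quota censoring censors exactly the configured fraction", {
  spec <- simulation_spec(n_ac = 127, n_scc = 42, n_genes = 5,
                          censoring = 0.3, censoring_mode = "quota")
  cov <- make_covariates(spec, seed = 30)
  surv <- simulate_survival(spec, cov, seed = 31)
  expect_equal(sum(surv$event == 0), round(0.3 * 169))
})

test_that("a null study selects almost nothing and is reproducible", {
  spec <- simulation_spec(n_ac = 80, n_scc = 40, n_genes = 50,
                          censoring = 0.3, replicates = 50, seed = 1234)
  ft <- suppressWarnings(run_simulation_study(spec))
  expect_lte(attr(ft, "avg_selected_ac"), 1)
  expect_lte(attr(ft, "avg_selected_scc"), 1)
  expect_true(all(ft$freq_ac >= 0 & ft$freq_ac <= 100))
  ft2 <- suppressWarnings(run_simulation_study(spec))
  expect_identical(ft, ft2)
})

test_that("selection frequency increases with the causal coefficient", {
  base <- function(b) simulation_spec(n_ac = 127, n_scc = 42, n_genes = 10,
                                      coef_ac = c(X1 = b),
                                      coef_scc = c(X1 = b),
                                      censoring = 0.3, replicates = 60,
                                      seed = 77)
  freqs <- vapply(c(0.3, 0.8, 1.6), function(b) {
    ft <- suppressWarnings(run_simulation_study(base(b)))
    ft$freq_ac[1]
  }, numeric(1))
  expect_true(all(diff(freqs) >= 0))
  expect_gt(freqs[3], freqs[1])
})

test_that("the barcode-valued study variant runs end to end", {
  set.seed(91)
  spec <- simulation_spec(n_ac = 60, n_scc = 30, n_genes = 15,
                          coef_ac = c(X1 = 1.2), coef_scc = c(X1 = 1.2),
                          censoring = 0.3, replicates = 3, seed = 91,
                          value_kind = "barcode")
  ft <- suppressWarnings(run_simulation_study(spec))
  expect_s3_class(ft, "frequency_table")
  expect_equal(nrow(ft), 15)
  expect_true(all(ft$freq_ac >= 0 & ft$freq_ac <= 100))
})
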