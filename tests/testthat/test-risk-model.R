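sim_risk_data <- function(n, n_genes, beta = numeric(0), cens_rate = 0.3,
                          rank2 = FALSE) {
  if (rank2) {
    f <- matrix(rnorm(2 * n), 2, n)
    L <- matrix(rnorm(2 * n_genes), n_genes, 2)
    v <- L %*% f
  } else {
    v <- matrix(rnorm(n_genes * n), n_genes, n)
  }
  dimnames(v) <- list(paste0("g", seq_len(n_genes)),
                      paste0("s", seq_len(n)))
  eta <- if (length(beta)) drop(crossprod(v[seq_along(beta), , drop = FALSE],
                                          beta)) else numeric(n)
  T <- -log(runif(n)) / exp(eta)
  C <- if (cens_rate > 0) rexp(n, cens_rate) else rep(Inf, n)
  list(expr = expression_matrix(v),
       surv = survival_table(colnames(v), pmin(T, C),
                             as.integer(T <= C),
                             rep(c("AC", "SCC"), length.out = n)))
}

test_that("PCA risk model retains the expected number of components", {
  set.seed(71)
  d <- sim_risk_data(100, 10, beta = c(0.5), rank2 = TRUE)
  m <- build_risk_model(d$expr, d$surv, paste0("g", 1:10), method = "pca",
                        var_threshold = 0.95)
  expect_equal(m$n_pc, 2) # rank-2 data: two PCs explain everything
  expect_gte(m$cum_var, 0.95)
  # explained-variance fractions are non-increasing and sum to 1
  expect_true(all(diff(m$explained_var) <= 1e-12))
  expect_equal(sum(m$explained_var), 1, tolerance = 1e-10)
  # var_threshold 1 retains min(genes, samples - 1) components
  d2 <- sim_risk_data(8, 5, beta = c(0.8), cens_rate = 0)
  m2 <- build_risk_model(d2$expr, d2$surv, paste0("g", 1:5), method = "pca",
                         var_threshold = 1)
  expect_equal(m2$n_pc, min(5, 8 - 1))
})

test_that("single-gene signatures rank samples identically in both methods", {
  set.seed(72)
  d <- sim_risk_data(60, 3, beta = c(1.0))
  mf <- build_risk_model(d$expr, d$surv, "g1", method = "full")
  mp <- build_risk_model(d$expr, d$surv, "g1", method = "pca",
                         var_threshold = 0.5)
  sf <- compute_risk_scores(mf, d$expr)
  sp <- compute_risk_scores(mp, d$expr)
  expect_equal(order(sf), order(sp))
})

test_that("risk scores are linear and reproduce the stored cutoff", {
  set.seed(73)
  d <- sim_risk_data(50, 4, beta = c(0.7, -0.4))
  m <- build_risk_model(d$expr, d$surv, paste0("g", 1:4), method = "full")
  s <- compute_risk_scores(m, d$expr)
  expect_equal(mean(s), m$cutoff, tolerance = 1e-10)
  # adding a constant to every gene of every sample shifts scores equally
  e2 <- expression_matrix(d$expr$values + 2)
  s2 <- compute_risk_scores(m, e2)
  expect_equal(diff(range(s2 - s)), 0, tolerance = 1e-10)
  expect_equal(order(s2), order(s))
  # full-method ranking is invariant to per-gene centering
  e3 <- expression_matrix(d$expr$values - rowMeans(d$expr$values))
  expect_equal(order(compute_risk_scores(m, e3)), order(s))
  expect_error(compute_risk_scores(m, subset_expr(d$expr, genes = 1:2)),
               "missing")
  # full method requires fewer genes than samples
  d3 <- sim_risk_data(6, 10)
  expect_error(build_risk_model(d3$expr, d3$surv, paste0("g", 1:10),
                                method = "full"), "pca")
})

test_that("mean-cutoff stratification follows the tie rule", {
  expect_equal(as.character(stratify_by_mean(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(stratify_by_mean(rep(2, 5))), rep("low", 5))
  s <- c(0.3, 1.8, -0.5, 2.2)
  expect_equal(stratify_by_mean(s + 10, cutoff = mean(s) + 10),
               stratify_by_mean(s))
  expect_error(stratify_by_mean(1), "2 samples")
})

test_that("evaluation reports perfect and symmetric classification", {
  surv <- make_surv(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 0, 1, 0),
                    c("AC", "AC", "SCC", "SCC", "AC", "SCC"))
  scores <- surv$event * 2 - 1
  labels <- stratify_by_mean(scores)
  ev <- evaluate_stratification(scores, labels, surv)
  expect_equal(unname(ev$accuracy[["all"]]), 100)
  expect_equal(unname(ev$auc[["AC"]]), 100)
  expect_equal(unname(ev$auc[["SCC"]]), 100)
  # flipping score signs maps AUC to 100 - AUC
  ev2 <- evaluate_stratification(-scores, labels, surv)
  expect_equal(unname(ev2$auc[["AC"]]), 0)
  # a subtype with all-identical event status has undefined AUC
  surv3 <- make_surv(c(1, 2, 3, 4), c(1, 0, 1, 0),
                     c("AC", "SCC", "AC", "SCC"))
  ev3 <- evaluate_stratification(c(1, 0, 1, 0),
                                 factor(c("high", "low", "high", "low"),
                                        levels = c("low", "high")), surv3)
  expect_true(is.na(ev3$auc[["AC"]]))
})

test_that("null scores give ~50% AUC and strong genes stratify survival", {
  set.seed(74)
  aucs <- replicate(200, {
    surv <- make_surv(rexp(100), rbinom(100, 1, 0.6))
    sc <- rnorm(100)
    evaluate_stratification(sc, stratify_by_mean(sc), surv)$auc[["all"]]
  })
  expect_lt(abs(mean(aucs) - 50), 3)
  # single strong prognostic gene: high-risk stratum has worse survival
  hits <- 0
  R <- 100
  for (r in seq_len(R)) {
    d <- sim_risk_data(400, 5, beta = c(1.5))
    m <- build_risk_model(d$expr, d$surv, "g1", method = "full")
    sc <- compute_risk_scores(m, d$expr)
    lab <- stratify_by_mean(sc, cutoff = m$cutoff)
    ev <- evaluate_stratification(sc, lab, d$surv)
    km_high <- ev$km$high; km_low <- ev$km$low
    worse <- min(km_high$surv) <= min(km_low$surv)
    hits <- hits + (ev$logrank$p < 0.01 && worse)
  }
  expect_gte(hits / R, 0.95)
})

test_that("clinical adjustment LRT is calibrated and guards collinearity", {
  set.seed(75)
  ps <- replicate(200, {
    d <- sim_risk_data(120, 3, beta = c(0.8))
    m <- build_risk_model(d$expr, d$surv, "g1", method = "full")
    sc <- compute_risk_scores(m, d$expr)
    clin <- data.frame(age = rnorm(120), smoker = rnorm(120))
    out <- clinical_adjustment_test(sc, d$surv, clin)
    out$p
  })
  expect_gt(ks.test(as.numeric(ps), "punif")$p.value, 0.01)
  # df equals the number of covariate columns after categorical expansion
  d <- sim_risk_data(90, 3, beta = c(0.8))
  m <- build_risk_model(d$expr, d$surv, "g1", method = "full")
  sc <- compute_risk_scores(m, d$expr)
  clin <- data.frame(age = rnorm(90),
                     stage = factor(sample(c("I", "II", "III"), 90, TRUE)))
  out <- clinical_adjustment_test(sc, d$surv, clin)
  expect_equal(out$df, c(3, 3)) # age + two stage dummies
  # duplicating the score as a clinical covariate is collinear
  expect_error(clinical_adjustment_test(sc, d$surv,
                                        data.frame(dup = sc)),
               "collinear")
})
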