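#' Specification of a Cox-exponential simulation study
#'
#' Describes one selection-frequency experiment: sample counts per subtype,
#' total gene count, per-subtype log-hazard coefficient vectors, covariate
#' model, censoring target, replicate count and base seed. Replicate r uses
#' seeds derived from `seed + r`, so studies are reproducible and
#' parallelizable.
#'
#' @param n_ac,n_scc samples per subtype.
#' @param n_genes total number of genes (causal plus noise).
#' @param coef_ac,coef_scc log-hazard coefficient vectors of length
#'   `n_genes` (or named/indexed shorter vectors assigned to the leading
#'   genes), for the AC and SCC linear predictors.
#' @param covariate_mode `"independent_normal"` (i.i.d. standard normal
#'   entries) or `"resample_from_matrix"` (columns drawn with replacement
#'   from `resample_matrix`, preserving within-sample gene correlation).
#' @param resample_matrix genes-by-samples matrix for the resampling mode.
#' @param censoring target expected censored fraction in \[0, 1).
#' @param censoring_mode `"expected"` (independent exponential censoring
#'   calibrated to the target) or `"quota"` (censor exactly
#'   `round(target * n)` randomly chosen subjects at a uniform fraction of
#'   their event time).
#' @param replicates number of simulated datasets.
#' @param seed base random seed.
#' @param alpha BH-FDR level used by the per-gene filter.
#' @param value_kind `"continuous"`, or `"barcode"` to dichotomize the
#'   covariates with the barcode model before filtering.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_ac, n_scc, n_genes, coef_ac = numeric(0),
                            coef_scc = numeric(0),
                            covariate_mode = c("independent_normal",
                                               "resample_from_matrix"),
                            resample_matrix = NULL, censoring = 0.3,
                            censoring_mode = c("expected", "quota"),
                            replicates = 500, seed = 1, alpha = 0.05,
                            value_kind = c("continuous", "barcode")) {
  covariate_mode <- match.arg(covariate_mode)
  censoring_mode <- match.arg(censoring_mode)
  value_kind <- match.arg(value_kind)
  if (censoring < 0 || censoring >= 1)
    stop_input("'censoring' target must lie in [0, 1)")
  if (covariate_mode == "resample_from_matrix" && is.null(resample_matrix))
    stop_input("resample mode requires 'resample_matrix'")
  expand <- function(cf) {
    full <- numeric(n_genes)
    if (length(cf)) {
      idx <- if (!is.null(names(cf))) as.integer(sub("^X", "", names(cf)))
      else seq_along(cf)
      if (any(idx > n_genes)) stop_input("causal gene index exceeds n_genes")
      full[idx] <- cf
    }
    full
  }
  structure(list(n_ac = n_ac, n_scc = n_scc, n_genes = n_genes,
                 coef_ac = expand(coef_ac), coef_scc = expand(coef_scc),
                 covariate_mode = covariate_mode,
                 resample_matrix = resample_matrix, censoring = censoring,
                 censoring_mode = censoring_mode, replicates = replicates,
                 seed = seed, alpha = alpha, value_kind = value_kind),
            class = "simulation_spec")
}

#' Preset simulation designs for the two extreme cases
#'
#' Case 1 gives the subtypes mutually exclusive markers - SCC hazard
#' \eqn{\lambda_0\exp(1.42 X_1 - 0.75 X_2)}, AC hazard
#' \eqn{\lambda_0\exp(0.225 X_3 + 0.177 X_4)}. Case 2 gives both subtypes
#' the identical predictor \eqn{\lambda_0\exp(1.42 X_1 - 0.75 X_2 +
#' 0.75 X_3 - 0.59 X_4)}. Both use 96 additional noise genes (100 features
#' total), 127 AC and 42 SCC samples, a 30% censoring target and 500
#' replicates, with unit exponential baseline hazard.
#'
#' @param case `"case1"` or `"case2"`.
#' @param seed base seed stored in the spec.
#' @return A [simulation_spec()].
#' @export
preset_extreme_cases <- function(case = c("case1", "case2"), seed = 1) {
  case <- match.arg(case)
  if (case == "case1") {
    simulation_spec(n_ac = 127, n_scc = 42, n_genes = 100,
                    coef_ac = c(X3 = 0.225, X4 = 0.177),
                    coef_scc = c(X1 = 1.42, X2 = -0.75),
                    censoring = 0.3, replicates = 500, seed = seed,
                    alpha = 0.05)
  } else {
    both <- c(X1 = 1.42, X2 = -0.75, X3 = 0.75, X4 = -0.59)
    simulation_spec(n_ac = 127, n_scc = 42, n_genes = 100,
                    coef_ac = both, coef_scc = both,
                    censoring = 0.3, replicates = 500, seed = seed,
                    alpha = 0.05)
  }
}

#' Draw a covariate (expression) matrix under a simulation spec
#'
#' @param spec a [simulation_spec()].
#' @param seed random seed for this draw.
#' @return An [expression_matrix()] of `n_genes` by `n_ac + n_scc` values
#'   (AC samples first).
#' @export
make_covariates <- function(spec, seed) {
  set.seed(seed)
  n <- spec$n_ac + spec$n_scc
  p <- spec$n_genes
  if (spec$covariate_mode == "independent_normal") {
    m <- matrix(rnorm(p * n), nrow = p)
  } else {
    src <- spec$resample_matrix
    if (nrow(src) < p)
      stop_input("resample matrix has fewer genes than n_genes")
    m <- src[seq_len(p), sample.int(ncol(src), n, replace = TRUE),
             drop = FALSE]
  }
  dimnames(m) <- list(paste0("gene_", seq_len(p)),
                      paste0("sample_", seq_len(n)))
  expression_matrix(m, value_kind = "continuous")
}

# subtype labels in the spec's fixed sample order (AC block then SCC block)
spec_subtypes <- function(spec) {
  rep(c("AC", "SCC"), c(spec$n_ac, spec$n_scc))
}

# per-sample linear predictor under the subtype-appropriate coefficients
spec_linear_predictor <- function(spec, values) {
  st <- spec_subtypes(spec)
  eta <- numeric(ncol(values))
  eta[st == "AC"] <- drop(crossprod(values[, st == "AC", drop = FALSE],
                                    spec$coef_ac))
  eta[st == "SCC"] <- drop(crossprod(values[, st == "SCC", drop = FALSE],
                                     spec$coef_scc))
  eta
}

#' Calibrate the exponential censoring rate to the target fraction
#'
#' Independent censoring times are Exponential(\eqn{\theta}); \eqn{\theta}
#' is solved by bisection so that the Monte-Carlo expected censored
#' fraction, over a pilot sample of linear predictors drawn under the
#' spec's covariate and hazard model, matches the target. Event times are
#' Exponential(\eqn{e^\eta}) given \eqn{\eta}, so
#' \eqn{P(censored\,|\,\eta) = \theta/(\theta + e^\eta)} in closed form and
#' the bisection only needs the pilot \eqn{\eta} draws.
#'
#' @param spec a [simulation_spec()].
#' @param n_pilot pilot draws (default 1e5).
#' @param seed seed for the pilot; defaults to the spec's base seed.
#' @return The censoring rate \eqn{\theta} (0 when the target is 0).
#' @export
calibrate_censoring <- function(spec, n_pilot = 1e5, seed = spec$seed) {
  target <- spec$censoring
  if (target < 0 || target >= 1) stop_input("censoring target must be in [0, 1)")
  if (target == 0) return(0)
  set.seed(seed)
  causal <- which(spec$coef_ac != 0 | spec$coef_scc != 0)
  n <- spec$n_ac + spec$n_scc
  pr_scc <- spec$n_scc / n
  st <- sample(c("AC", "SCC"), n_pilot, replace = TRUE,
               prob = c(1 - pr_scc, pr_scc))
  if (length(causal)) {
    if (spec$covariate_mode == "independent_normal") {
      Xc <- matrix(rnorm(n_pilot * length(causal)), ncol = length(causal))
    } else {
      Xc <- t(spec$resample_matrix[causal,
                                   sample.int(ncol(spec$resample_matrix),
                                              n_pilot, replace = TRUE),
                                   drop = FALSE])
    }
    eta <- ifelse(st == "AC", drop(Xc %*% spec$coef_ac[causal]),
                  drop(Xc %*% spec$coef_scc[causal]))
  } else {
    eta <- numeric(n_pilot)
  }
  risk <- exp(eta)
  f <- function(th) mean(th / (th + risk)) - target
  lo <- 0; hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-12 * max(hi, 1)) break
  }
  (lo + hi) / 2
}

#' Simulate right-censored survival data under a spec
#'
#' Event times follow the Cox-exponential construction
#' \eqn{T = -\log(U)/(\lambda_0 e^\eta)} with \eqn{U\sim}Uniform(0,1) and
#' unit baseline \eqn{\lambda_0 = 1}. In `"expected"` censoring mode an
#' independent Exponential(\eqn{\theta}) censoring time is drawn with
#' \eqn{\theta} from [calibrate_censoring()]; in `"quota"` mode exactly
#' `round(target * n)` randomly chosen subjects are censored at a uniform
#' fraction of their event time.
#'
#' @param spec a [simulation_spec()].
#' @param covariates an [expression_matrix()] from [make_covariates()].
#' @param seed random seed for this draw.
#' @param theta optional pre-calibrated censoring rate (recomputed when
#'   missing and the target is positive).
#' @return A [survival_table()] aligned with the covariate columns.
#' @export
simulate_survival <- function(spec, covariates, seed, theta = NULL) {
  eta <- spec_linear_predictor(spec, covariates$values)
  n <- length(eta)
  if (is.null(theta) && spec$censoring > 0 &&
      spec$censoring_mode == "expected")
    theta <- calibrate_censoring(spec)
  set.seed(seed)
  T <- -log(runif(n)) / exp(eta)
  if (spec$censoring == 0) {
    time <- T; event <- rep(1L, n)
  } else if (spec$censoring_mode == "expected") {
    C <- rexp(n, rate = theta)
    time <- pmin(T, C)
    event <- as.integer(T <= C)
  } else {
    n_cens <- round(spec$censoring * n)
    idx <- sample.int(n, n_cens)
    time <- T
    time[idx] <- T[idx] * runif(n_cens)
    event <- rep(1L, n)
    event[idx] <- 0L
  }
  survival_table(sample_ids(covariates), time, event, spec_subtypes(spec))
}

#' Run a selection-frequency simulation study
#'
#' For each replicate: draw covariates, simulate survival, optionally
#' dichotomize the covariates with the barcode model, run the per-gene
#' interaction Cox filter, and record which genes reach `q <= alpha` in the
#' AC and SCC families. Frequencies are aggregated across replicates.
#'
#' @param spec a [simulation_spec()].
#' @param compute_ph compute per-gene Schoenfeld p-values inside each
#'   replicate (off by default; the diagnostics do not affect selection).
#' @param progress print a progress message every 100 replicates.
#' @param detail also keep the full genes-by-replicates selection indicator
#'   matrices (attributes `selected_ac`, `selected_scc`).
#' @return A `frequency_table` data.frame: `gene_id`, `freq_ac`,
#'   `freq_scc` (%); attributes `avg_selected_ac`, `avg_selected_scc`,
#'   `mean_censored`, `replicates`, `theta`.
#' @export
run_simulation_study <- function(spec, compute_ph = FALSE, progress = FALSE,
                                 detail = FALSE) {
  theta <- if (spec$censoring > 0 && spec$censoring_mode == "expected")
    calibrate_censoring(spec) else 0
  p <- spec$n_genes
  sel_ac <- sel_scc <- numeric(p)
  if (detail)
    det_ac <- det_scc <- matrix(FALSE, p, spec$replicates)
  n_sel_ac <- n_sel_scc <- numeric(spec$replicates)
  censored <- numeric(spec$replicates)
  for (r in seq_len(spec$replicates)) {
    covariates <- make_covariates(spec, seed = spec$seed + 2 * r)
    surv <- simulate_survival(spec, covariates, seed = spec$seed + 2 * r + 1,
                              theta = theta)
    censored[r] <- mean(surv$event == 0)
    X <- covariates
    if (spec$value_kind == "barcode") {
      model <- fit_barcode_model(covariates)
      X <- barcode_calls(covariates, model)
    }
    rec <- tryCatch(
      suppressMessages(fit_gene_models(X, surv, compute_ph = compute_ph)),
      error = function(e) NULL)
    if (is.null(rec)) {
      warning("replicate ", r, " failed; recorded as zero selections")
      next
    }
    a <- rec$q_ac <= spec$alpha & !rec$flagged
    s <- rec$q_scc <= spec$alpha & !rec$flagged
    sel_ac <- sel_ac + a
    sel_scc <- sel_scc + s
    if (detail) {
      det_ac[, r] <- a
      det_scc[, r] <- s
    }
    n_sel_ac[r] <- sum(a)
    n_sel_scc[r] <- sum(s)
    if (progress && r %% 100 == 0) message("replicate ", r)
  }
  out <- data.frame(gene_id = paste0("gene_", seq_len(p)),
                    freq_ac = 100 * sel_ac / spec$replicates,
                    freq_scc = 100 * sel_scc / spec$replicates,
                    stringsAsFactors = FALSE)
  attr(out, "avg_selected_ac") <- mean(n_sel_ac)
  attr(out, "avg_selected_scc") <- mean(n_sel_scc)
  attr(out, "mean_censored") <- mean(censored)
  attr(out, "replicates") <- spec$replicates
  attr(out, "theta") <- theta
  if (detail) {
    attr(out, "selected_ac") <- det_ac
    attr(out, "selected_scc") <- det_scc
  }
  class(out) <- c("frequency_table", "data.frame")
  out
}
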