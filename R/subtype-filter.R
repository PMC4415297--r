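#' Per-gene subtype-interaction Cox models
#'
#' For each gene g the 3-covariate Cox model
#' \deqn{\lambda(t) = \lambda_0(t)\exp(\beta_1 I(SCC) + \beta_2 x_g +
#'   \beta_3 I(SCC)\, x_g)}
#' is fitted. The Wald contrast (0,1,0) tests the gene's effect in AC
#' (\eqn{\beta_2}), the contrast (0,1,1) its effect in SCC
#' (\eqn{\beta_2+\beta_3}); the two p-value families are BH-adjusted
#' separately across genes (the per-subtype significance counts imply
#' per-family correction; a joint family is available via
#' `bh_family = "joint"`). Fits flagged for separation or non-convergence
#' carry q = 1 and are never selected. Schoenfeld proportional-hazards
#' p-values are recorded per gene when `compute_ph = TRUE`.
#'
#' @param expr [expression_matrix()] (continuous or barcode), samples
#'   aligned with `surv`.
#' @param surv a [survival_table()]; both subtypes must be present with at
#'   least one event each.
#' @param ties tie handling passed to the Cox fits.
#' @param compute_ph compute the Schoenfeld PH p-value per gene.
#' @param bh_family `"separate"` (default) or `"joint"` BH correction.
#' @return A `gene_filter_records` data.frame, one row per gene: `gene_id`,
#'   `beta1`..`beta3`, `se1`..`se3`, `beta_ac` (= beta2), `se_ac`,
#'   `beta_scc` (= beta2+beta3), `se_scc`, `p_ac`, `p_scc`, `q_ac`,
#'   `q_scc`, `ph_p`, `flagged`, `scenario` (NA until
#'   [classify_scenarios()]).
#' @export
fit_gene_models <- function(expr, surv, ties = c("efron", "breslow"),
                            compute_ph = TRUE,
                            bh_family = c("separate", "joint")) {
  ties <- match.arg(ties)
  bh_family <- match.arg(bh_family)
  if (!identical(sample_ids(expr), surv$sample_id))
    stop_input("expression matrix and survival table are not aligned; ",
               "run align_samples() first")
  st <- as.integer(surv$subtype == "SCC")
  if (length(unique(st)) != 2)
    stop_input("both subtypes must be present")
  if (any(tapply(surv$event, st, sum) < 1))
    stop_input("each subtype needs at least one event")
  time <- as.numeric(surv$time)
  event <- as.integer(surv$event)
  o <- order(time)
  time_o <- time[o]; event_o <- event[o]; st_o <- st[o]
  efron <- as.integer(ties == "efron")
  v <- expr$values
  p <- nrow(v)
  out <- data.frame(gene_id = rownames(v), beta1 = NA_real_,
                    beta2 = NA_real_, beta3 = NA_real_, se1 = NA_real_,
                    se2 = NA_real_, se3 = NA_real_, beta_ac = NA_real_,
                    se_ac = NA_real_, beta_scc = NA_real_, se_scc = NA_real_,
                    p_ac = NA_real_, p_scc = NA_real_, q_ac = 1, q_scc = 1,
                    ph_p = NA_real_, flagged = FALSE, scenario = NA_character_,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (g in seq_len(p)) {
    x <- v[g, o]
    X <- cbind(st_o, x, st_o * x)
    if (max(x) == min(x) || max(x[st_o == 1]) == min(x[st_o == 1]) ||
        max(x[st_o == 0]) == min(x[st_o == 0])) {
      out$flagged[g] <- TRUE
      next
    }
    r <- .cox_fit_cpp(time_o, event_o, X, efron, 50L, 1e-9, 15)
    V <- tryCatch(solve(r$imat), error = function(e) NULL)
    if (r$monotone || r$singular || !r$converged || is.null(V) ||
        any(diag(V) <= 0)) {
      out$flagged[g] <- TRUE
      out$beta1[g] <- r$coef[1]; out$beta2[g] <- r$coef[2]
      out$beta3[g] <- r$coef[3]
      next
    }
    b <- r$coef
    out$beta1[g] <- b[1]; out$beta2[g] <- b[2]; out$beta3[g] <- b[3]
    se <- sqrt(diag(V))
    out$se1[g] <- se[1]; out$se2[g] <- se[2]; out$se3[g] <- se[3]
    out$beta_ac[g] <- b[2]
    out$se_ac[g] <- se[2]
    out$beta_scc[g] <- b[2] + b[3]
    out$se_scc[g] <- sqrt(V[2, 2] + V[3, 3] + 2 * V[2, 3])
    out$p_ac[g] <- 2 * pnorm(-abs(out$beta_ac[g] / out$se_ac[g]))
    out$p_scc[g] <- 2 * pnorm(-abs(out$beta_scc[g] / out$se_scc[g]))
    if (compute_ph) {
      sr <- .schoenfeld_cpp(time_o, event_o, X, b, efron)
      glob <- tryCatch(ph_score_test(sr)$global, error = function(e) NA)
      out$ph_p[g] <- pchisq(glob, 3, lower.tail = FALSE)
    }
  }
  ok <- !out$flagged & !is.na(out$p_ac)
  if (any(ok)) {
    if (bh_family == "separate") {
      out$q_ac[ok] <- bh_adjust(out$p_ac[ok])
      out$q_scc[ok] <- bh_adjust(out$p_scc[ok])
    } else {
      qq <- bh_adjust(c(out$p_ac[ok], out$p_scc[ok]))
      out$q_ac[ok] <- qq[seq_len(sum(ok))]
      out$q_scc[ok] <- qq[sum(ok) + seq_len(sum(ok))]
    }
  }
  if (any(out$flagged))
    message(sum(out$flagged), " gene(s) flagged (separation/non-convergence)",
            " and excluded from selection")
  class(out) <- c("gene_filter_records", "data.frame")
  out
}

#' Classify genes into subtype-specificity scenarios
#'
#' Labels each gene by its pattern of subtype-specific significance:
#' `AC_specific` (significant in AC only), `SCC_specific` (SCC only),
#' `shared_concordant` / `shared_discordant` (significant in both, with
#' same/opposite effect signs), or `none`.
#'
#' @param records a `gene_filter_records` data.frame.
#' @param alpha FDR level in (0,1).
#' @return The records with the `scenario` column filled in.
#' @export
classify_scenarios <- function(records, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_input("'alpha' must lie strictly inside (0, 1)")
  sig_ac <- records$q_ac <= alpha & !records$flagged
  sig_scc <- records$q_scc <= alpha & !records$flagged
  lab <- rep("none", nrow(records))
  lab[sig_ac & !sig_scc] <- "AC_specific"
  lab[!sig_ac & sig_scc] <- "SCC_specific"
  both <- sig_ac & sig_scc
  same <- sign(records$beta_ac) == sign(records$beta_scc)
  lab[both & same] <- "shared_concordant"
  lab[both & !same] <- "shared_discordant"
  records$scenario <- lab
  attr(records, "alpha") <- alpha
  records
}

#' Extract the subtype-specific prognostic signature
#'
#' @param records classified `gene_filter_records`.
#' @param alpha FDR level; defaults to the level used for classification.
#' @return A `signature_set` list: `ac_specific`, `scc_specific`, `shared`
#'   gene-id vectors (pairwise disjoint), `ac_all`/`scc_all` (the full
#'   per-family selections), and `alpha`.
#' @export
select_signature <- function(records, alpha = attr(records, "alpha")) {
  if (is.null(alpha)) alpha <- 0.05
  sel_ac <- records$gene_id[records$q_ac <= alpha & !records$flagged]
  sel_scc <- records$gene_id[records$q_scc <= alpha & !records$flagged]
  shared <- intersect(sel_ac, sel_scc)
  out <- structure(list(ac_specific = setdiff(sel_ac, shared),
                        scc_specific = setdiff(sel_scc, shared),
                        shared = shared, ac_all = sel_ac,
                        scc_all = sel_scc, alpha = alpha),
                   class = "signature_set")
  if (length(sel_ac) + length(sel_scc) == 0)
    warning("no genes selected at alpha = ", alpha)
  message("signature: ", length(out$ac_specific), " AC-specific, ",
          length(out$scc_specific), " SCC-specific, ",
          length(shared), " shared")
  out
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set (alpha =", x$alpha, "):",
      length(x$ac_specific), "AC-specific,",
      length(x$scc_specific), "SCC-specific,",
      length(x$shared), "shared\n")
  invisible(x)
}
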