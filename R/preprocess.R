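#' Standard-deviation pre-filter
#'
#' Removes genes whose sample standard deviation (denominator n-1) falls
#' strictly below the threshold; such genes are regarded as non-informative.
#'
#' @param expr continuous [expression_matrix()].
#' @param threshold positive SD cutoff (default 0.1 on the log2 scale).
#' @return The filtered [expression_matrix()], order preserved.
#' @export
sd_filter <- function(expr, threshold = 0.1) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop_input("'threshold' must be a positive number")
  if (expr$value_kind != "continuous")
    stop_input("sd_filter requires continuous values")
  sds <- apply(expr$values, 1, sd)
  keep <- sds >= threshold
  message("sd_filter: ", sum(!keep), " of ", length(keep), " genes removed")
  subset_expr(expr, genes = which(keep))
}

#' Moderated-t differential expression between subtypes
#'
#' Empirical-Bayes moderated two-sample t-test per gene (SCC minus AC).
#' The pooled residual variance \eqn{s_g^2} on \eqn{d_g = n_1+n_2-2} df is
#' shrunk towards a prior \eqn{(d_0, s_0^2)} estimated by matching the first
#' two moments of \eqn{\log s_g^2} across genes (using the digamma/trigamma
#' moments of log chi-square); the posterior variance is
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0+d_g)} and the moderated
#' statistic is referred to a t distribution on \eqn{d_0+d_g} df.
#'
#' @param expr continuous [expression_matrix()].
#' @param subtype per-sample labels (coercible to AC/SCC factor), aligned
#'   with the matrix columns.
#' @param fdr_cutoff Benjamini-Hochberg selection cutoff (default 0.05).
#' @param prior_df optional override of the estimated prior df \eqn{d_0};
#'   `0` disables shrinkage and reproduces the ordinary pooled-variance t.
#' @return A `deg_table` data.frame: `gene_id`, `log2fc` (SCC - AC), `t`,
#'   `p`, `q`, `direction`, `selected`; attribute `prior` holds
#'   \eqn{(d_0, s_0^2)}.
#' @export
moderated_t_deg <- function(expr, subtype, fdr_cutoff = 0.05,
                            prior_df = NULL) {
  st <- toupper(as.character(subtype))
  if (!all(st %in% c("AC", "SCC")))
    stop_input("subtype labels must be AC/SCC")
  v <- expr$values
  if (length(st) != ncol(v))
    stop_input("subtype labels must match the number of samples")
  g1 <- st == "AC"; g2 <- st == "SCC"
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2)
    stop_input("each subtype needs at least 2 samples")
  m1 <- rowMeans(v[, g1, drop = FALSE])
  m2 <- rowMeans(v[, g2, drop = FALSE])
  s2 <- (rowSums((v[, g1, drop = FALSE] - m1)^2) +
           rowSums((v[, g2, drop = FALSE] - m2)^2)) / (n1 + n2 - 2)
  dg <- n1 + n2 - 2
  if (is.null(prior_df)) {
    pri <- estimate_variance_prior(s2, dg)
  } else {
    if (prior_df < 0) stop_input("'prior_df' must be >= 0")
    pri <- list(d0 = prior_df,
                s02 = if (prior_df > 0) mean(s2) else NA_real_)
  }
  d0 <- pri$d0
  s2tilde <- if (d0 == 0) s2
  else if (is.infinite(d0)) rep(pri$s02, length(s2))
  else (d0 * pri$s02 + dg * s2) / (d0 + dg)
  diff <- m2 - m1
  tstat <- diff / sqrt(s2tilde * (1 / n1 + 1 / n2))
  df <- d0 + dg
  p <- 2 * pt(-abs(tstat), df = df)
  p[s2tilde == 0 & diff == 0] <- 1 # constant genes carry no evidence
  q <- bh_adjust(p)
  out <- data.frame(gene_id = rownames(v), log2fc = diff, t = tstat,
                    p = p, q = q,
                    direction = ifelse(diff >= 0, "up", "down"),
                    selected = q <= fdr_cutoff,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "prior") <- c(d0 = d0, s02 = pri$s02)
  class(out) <- c("deg_table", "data.frame")
  out
}

# moment matching for the scaled-inverse-chi-square variance prior:
# e_g = log s_g^2 - digamma(dg/2) + log(dg/2) has mean log s0^2 (shifted by
# digamma(d0/2) - log(d0/2)) and excess variance trigamma(d0/2).
estimate_variance_prior <- function(s2, dg) {
  ok <- s2 > 0
  if (sum(ok) < 2) return(list(d0 = 0, s02 = NA_real_))
  z <- log(s2[ok])
  e <- z - digamma(dg / 2) + log(dg / 2)
  ev <- var(e) - trigamma(dg / 2)
  if (!is.finite(ev) || ev <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(ev)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

# Newton inversion of the trigamma function (monotone decreasing)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Collapse probe sets to gene symbols by largest fold change
#'
#' When several probe sets map to the same gene symbol, the one with the
#' largest absolute log2 fold change in `deg` is kept; exact ties are broken
#' by the lexicographically smallest probe id. The result is indexed by gene
#' symbol.
#'
#' @param expr [expression_matrix()] whose rows are probe ids.
#' @param deg a `deg_table` from [moderated_t_deg()] covering all probes.
#' @param probe_to_gene named character vector probe id -> gene symbol;
#'   defaults to the map stored in `expr`.
#' @return An [expression_matrix()] with one row per gene symbol.
#' @export
collapse_probesets <- function(expr, deg, probe_to_gene = expr$probe_to_gene) {
  probes <- gene_ids(expr)
  if (is.null(probe_to_gene))
    stop_input("no probe_to_gene map available")
  miss <- setdiff(probes, names(probe_to_gene))
  if (length(miss))
    stop_input("probe(s) missing from probe_to_gene map: ",
               paste(head(miss, 5), collapse = ", "))
  miss2 <- setdiff(probes, deg$gene_id)
  if (length(miss2))
    stop_input("probe(s) missing from DEG table: ",
               paste(head(miss2, 5), collapse = ", "))
  fc <- abs(deg$log2fc[match(probes, deg$gene_id)])
  symbol <- unname(probe_to_gene[probes])
  ord <- order(symbol, -fc, probes, method = "radix")
  keep_idx <- ord[!duplicated(symbol[ord])]
  keep_idx <- sort(keep_idx) # preserve input probe order
  v <- expr$values[keep_idx, , drop = FALSE]
  rownames(v) <- symbol[keep_idx]
  expression_matrix(v, value_kind = expr$value_kind)
}

#' Barcode-frequency filter
#'
#' Removes genes whose expressed fraction is extreme in *both* subtypes:
#' above the high cutoff in both AC and SCC, or below the low cutoff in
#' both (strict inequalities). This guards the downstream Cox fits against
#' complete separation. Laxer per-subtype cutoffs are used for SCC because
#' its sample count is about a third of AC's. Set `mode = "either"` to
#' remove genes extreme in either subtype instead (the rule's wording
#' admits both readings).
#'
#' @param calls barcode [expression_matrix()] (0/1 values).
#' @param subtype per-sample AC/SCC labels aligned with the columns.
#' @param high,low named numeric vectors with entries `AC` and `SCC` in
#'   (0,1); defaults 0.95/0.90 high and 0.05/0.10 low.
#' @param mode `"both"` (default) or `"either"`.
#' @return Character vector of retained gene ids.
#' @export
barcode_frequency_filter <- function(calls, subtype,
                                     high = c(AC = 0.95, SCC = 0.90),
                                     low = c(AC = 0.05, SCC = 0.10),
                                     mode = c("both", "either")) {
  mode <- match.arg(mode)
  if (calls$value_kind != "barcode")
    stop_input("barcode_frequency_filter requires barcode calls")
  if (any(c(high, low) <= 0) || any(c(high, low) >= 1))
    stop_input("frequency cutoffs must lie strictly inside (0, 1)")
  st <- toupper(as.character(subtype))
  if (!all(c("AC", "SCC") %in% st))
    stop_input("both subtypes must be present")
  f_ac <- rowMeans(calls$values[, st == "AC", drop = FALSE])
  f_scc <- rowMeans(calls$values[, st == "SCC", drop = FALSE])
  hi_ac <- f_ac > high[["AC"]]; hi_scc <- f_scc > high[["SCC"]]
  lo_ac <- f_ac < low[["AC"]]; lo_scc <- f_scc < low[["SCC"]]
  removed <- if (mode == "both") (hi_ac & hi_scc) | (lo_ac & lo_scc)
  else (hi_ac | hi_scc) | (lo_ac | lo_scc)
  message("barcode_frequency_filter: ", sum(removed), " of ", length(removed),
          " genes removed")
  gene_ids(calls)[!removed]
}
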