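#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW causal effect (model `"auto"`) with each instrument
#' removed in turn. An instrument is flagged as *driving* when its removal
#' flips the sign of the pooled estimate or moves its p-value across 0.05 —
#' an explicit formalization of the visual forest-plot inspection usually
#' used to spot such SNPs. With k = 2 each leave-one-out estimate is a
#' single-SNP Wald ratio (method `wald`).
#'
#' @param h Harmonized instrument table; needs at least 2 instruments.
#' @param alpha Significance level for the p-crossing rule. Default 0.05.
#' @return data.frame, one row per left-out SNP in input order: `left_out`,
#'   `method`, `k`, `beta`, `se`, `or`, `ci_low`, `ci_high`, `p`, `driving`.
#'   Attribute `full` holds the all-SNP estimate.
#' @export
leave_one_out <- function(h, alpha = 0.05) {
  .check_harmonized(h, k_min = 2)
  full <- mr_ivw(h, model = "auto")$estimate
  rows <- lapply(seq_len(nrow(h)), function(j) {
    est <- mr_ivw(h[-j, , drop = FALSE], model = "auto")$estimate
    cbind(data.frame(left_out = h$snp[j], stringsAsFactors = FALSE), est)
  })
  out <- do.call(rbind, rows)
  out$driving <- sign(out$beta) != sign(full$beta) |
    (out$p < alpha) != (full$p < alpha)
  out$model <- NULL
  rownames(out) <- NULL
  attr(out, "full") <- full
  out
}

#' Bonferroni adjustment across outcomes
#'
#' Divides the family-wise alpha by the number of outcomes tested and calls
#' each outcome significant when its p-value falls below the adjusted
#' threshold. The threshold is additionally reported rounded to 3 decimals
#' (0.05/3 prints as 0.017) while comparisons use the unrounded value.
#'
#' @param p_values Named numeric vector of per-outcome p-values.
#' @param family_alpha Family-wise error rate. Default 0.05.
#' @param m Number of tests; defaults to `length(p_values)`.
#' @return data.frame: `outcome`, `p`, `alpha_adjusted`, `alpha_reported`,
#'   `significant`.
#' @export
bonferroni <- function(p_values, family_alpha = 0.05, m = length(p_values)) {
  stopifnot(family_alpha > 0, family_alpha < 1)
  if (m < 1) stop("m must be a positive integer")
  alpha_adj <- family_alpha / m
  data.frame(outcome = if (is.null(names(p_values)))
               paste0("outcome", seq_along(p_values)) else names(p_values),
             p = unname(p_values),
             alpha_adjusted = alpha_adj,
             alpha_reported = round(alpha_adj, 3),
             significant = unname(p_values) < alpha_adj,
             stringsAsFactors = FALSE)
}

#' MR-Egger intercept test for horizontal pleiotropy
#'
#' Declares directional pleiotropy when the Egger intercept differs
#' significantly from zero.
#'
#' @param egger An `mr_egger` result (see [mr_egger()]).
#' @param alpha Significance level. Default 0.05.
#' @return `TRUE` when pleiotropy is detected (`intercept_p < alpha`).
#' @export
egger_intercept_test <- function(egger, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  egger$intercept_p < alpha
}
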