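#' @keywords internal
.mr_estimate <- function(method, model, k, beta, se, p = NULL) {
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(beta / se))
  data.frame(method = method, model = model, k = as.integer(k),
             beta = beta, se = se, or = exp(beta),
             ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
             p = p, stringsAsFactors = FALSE)
}

.check_harmonized <- function(h, k_min = 1) {
  need <- c("snp", "beta_exp", "se_exp", "beta_out", "se_out")
  if (!all(need %in% names(h))) {
    stop("harmonized table must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(h) < k_min) stop("need at least ", k_min, " instrument(s)")
  if (any(h$se_exp <= 0) || any(h$se_out <= 0)) stop("SEs must be positive")
  invisible(h)
}

#' Per-SNP Wald ratio
#'
#' The single-instrument causal estimate `theta = beta_out / beta_exp`, with
#' first-order (delta-method) standard error `se_out / |beta_exp|`, which
#' ignores the uncertainty in the SNP-exposure estimate as is standard in
#' two-sample MR with strong instruments.
#'
#' @param h Harmonized instrument table (see [harmonize()]); all rows used.
#' @return data.frame with columns `snp`, `theta`, `se`.
#' @export
wald_ratio <- function(h) {
  .check_harmonized(h)
  if (any(h$beta_exp == 0)) {
    stop("beta_exp is zero for SNP(s): ",
         paste(h$snp[h$beta_exp == 0], collapse = ", "))
  }
  data.frame(snp = h$snp, theta = h$beta_out / h$beta_exp,
             se = h$se_out / abs(h$beta_exp), stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines the per-SNP Wald ratios with weights `1/se^2`. The fixed-effect
#' standard error is `1/sqrt(sum w)`; under the multiplicative
#' random-effects (MRE) model the SE is inflated by
#' `max(1, sqrt(Q/(k-1)))`, where Q is Cochran's heterogeneity statistic
#' (floored at 1, so the MRE SE never undercuts the fixed-effect SE). With
#' `model = "auto"` the MRE model is adopted when the heterogeneity test
#' rejects (`p_Q < q_alpha`), otherwise fixed effects are used. With a
#' single instrument the estimate degenerates to the Wald ratio and Q is not
#' applicable.
#'
#' @param h Harmonized instrument table.
#' @param model `"auto"` (default), `"fixed"`, or `"mre"`.
#' @param q_alpha Significance level of the heterogeneity test used by
#'   `model = "auto"`. Default 0.05.
#' @return List of class `mr_ivw`: `estimate` (one-row data.frame as in
#'   [wald_ratio()]-style MR estimates: method, model, k, beta, se, or,
#'   ci_low, ci_high, p) and `heterogeneity` (list `q`, `df`, `p`; all `NA`
#'   when k = 1).
#' @export
mr_ivw <- function(h, model = c("auto", "fixed", "mre"), q_alpha = 0.05) {
  model <- match.arg(model)
  .check_harmonized(h)
  wr <- wald_ratio(h)
  k <- nrow(wr)
  if (k == 1) {
    est <- .mr_estimate("wald", "na", 1, wr$theta, wr$se)
    out <- list(estimate = est,
                heterogeneity = list(q = NA_real_, df = NA_integer_,
                                     p = NA_real_))
    class(out) <- "mr_ivw"
    return(out)
  }
  w <- 1 / wr$se^2
  beta <- sum(w * wr$theta) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum(w * (wr$theta - beta)^2)
  q_df <- k - 1L
  q_p <- stats::pchisq(q, df = q_df, lower.tail = FALSE)
  use_mre <- switch(model, fixed = FALSE, mre = TRUE, auto = q_p < q_alpha)
  se <- if (use_mre) se_fixed * max(1, sqrt(q / q_df)) else se_fixed
  est <- .mr_estimate("ivw", if (use_mre) "mre" else "fixed", k, beta, se)
  out <- list(estimate = est,
              heterogeneity = list(q = q, df = q_df, p = q_p))
  class(out) <- "mr_ivw"
  out
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of the SNP-outcome effects on the
#' SNP-exposure effects with an unconstrained intercept, weights
#' `1/se_out^2`, after re-orienting every instrument so its exposure effect
#' is positive. The slope is the pleiotropy-robust causal estimate; an
#' intercept different from zero indicates directional (horizontal)
#' pleiotropy. Coefficient standard errors use the model-based
#' `(X'WX)^{-1}` form with the residual scale floored at 1
#' (`max(1, sqrt(RSS_w/(k-2)))`), and p-values come from the t distribution
#' with k-2 degrees of freedom.
#'
#' @param h Harmonized instrument table; needs at least 3 instruments.
#' @return List of class `mr_egger`: `slope` (MR-estimate data.frame, model
#'   `"na"`), `intercept`, `intercept_se`, `intercept_p`, `sigma` (residual
#'   scale before flooring).
#' @export
mr_egger <- function(h) {
  .check_harmonized(h, k_min = 3)
  k <- nrow(h)
  flip <- sign(h$beta_exp) < 0
  bx <- abs(h$beta_exp)
  by <- ifelse(flip, -h$beta_out, h$beta_out)
  w <- 1 / h$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- stats::coef(fit)
  rss_w <- sum(w * stats::residuals(fit)^2)
  sigma <- sqrt(rss_w / (k - 2))
  xwx_inv <- chol2inv(chol(crossprod(cbind(1, bx) * sqrt(w))))
  se_unit <- sqrt(diag(xwx_inv))
  se <- se_unit * max(1, sigma)
  pvals <- 2 * stats::pt(-abs(cf / se), df = k - 2)
  slope <- .mr_estimate("egger_slope", "na", k, cf[[2]], se[[2]],
                        p = pvals[[2]])
  out <- list(slope = slope, intercept = cf[[1]], intercept_se = se[[1]],
              intercept_p = pvals[[1]], sigma = sigma)
  class(out) <- "mr_egger"
  out
}

#' @keywords internal
.weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(theta[1])
  n <- length(theta)
  if (0.5 >= s[n]) return(theta[n])
  stats::approx(s, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted median causal estimate
#'
#' The inverse-variance-weighted median of the per-SNP Wald ratios:
#' ratios are ordered, weights normalized, and the estimate interpolates the
#' ratio at the point where the cumulative weight (evaluated at interval
#' midpoints) crosses 50%. Consistent as long as instruments carrying at
#' least half of the total weight are valid. The standard error comes from a
#' parametric bootstrap: SNP-exposure and SNP-outcome effects are resampled
#' from normal distributions centred at their observed values with their
#' reported SEs, the weighted median is recomputed, and the SD across
#' replicates is taken.
#'
#' @param h Harmonized instrument table; needs at least 3 instruments.
#' @param n_boot Bootstrap replicates for the SE. Default 1000.
#' @param seed Integer seed for the bootstrap (required for
#'   reproducibility).
#' @return One-row MR-estimate data.frame (method `weighted_median`).
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed) {
  .check_harmonized(h, k_min = 3)
  if (missing(seed)) stop("seed is required for the bootstrap SE")
  wr <- wald_ratio(h)
  w <- 1 / wr$se^2
  beta <- .weighted_median_point(wr$theta, w)
  k <- nrow(h)
  boots <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(k, h$beta_exp, h$se_exp)
      by <- stats::rnorm(k, h$beta_out, h$se_out)
      ok <- bx != 0
      th <- by[ok] / bx[ok]
      sw <- (bx[ok] / h$se_out[ok])^2
      .weighted_median_point(th, sw)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  .mr_estimate("weighted_median", "na", k, beta, se)
}

#' Run local computations under a temporary RNG seed
#'
#' Evaluates `expr` with the RNG seeded at `seed`, restoring the caller's
#' RNG state afterwards so package internals never perturb user-level
#' random streams.
#' @keywords internal
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
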