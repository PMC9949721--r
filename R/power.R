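#' Statistical power of an MR analysis with a binary outcome
#'
#' Non-centrality-based power approximation for a two-sample MR design with
#' a case-control outcome. With case fraction `K`, hypothesized odds ratio
#' `OR`, outcome sample size `N` and exposure variance explained by the
#' instruments `R^2`:
#' \deqn{b = K (\frac{OR}{1 + K(OR - 1)} - 1), \quad
#'       v = \frac{K(1-K) - b^2}{N R^2},}
#' and power at two-sided level `alpha` is
#' `pnorm(sqrt(b^2/v) - qnorm(1 - alpha/2))`. At `OR = 1` this reduces to
#' the one-tail rejection probability `alpha/2`.
#'
#' @param n Outcome sample size (cases + controls).
#' @param k_case Case fraction in the outcome sample, in (0, 1).
#' @param or_hypothesized Hypothesized causal odds ratio per unit of
#'   exposure.
#' @param r2 Variance of the exposure explained by the instruments, in
#'   (0, 1).
#' @param alpha Two-sided significance level. Default 0.05.
#' @return Power as a probability in (0, 1). Vectorized over
#'   `or_hypothesized`, `n` and `r2`.
#' @export
mr_power_binary <- function(n, k_case, or_hypothesized, r2, alpha = 0.05) {
  stopifnot(all(n > 0), all(k_case > 0), all(k_case < 1),
            all(or_hypothesized > 0), all(r2 > 0), all(r2 < 1),
            alpha > 0, alpha < 1)
  b <- k_case * (or_hypothesized / (1 + k_case * (or_hypothesized - 1)) - 1)
  v <- (k_case * (1 - k_case) - b^2) / (n * r2)
  if (any(v <= 0)) {
    stop("variance term is nonpositive; parameter combination outside the ",
         "approximation's range")
  }
  stats::pnorm(sqrt(b^2 / v) - stats::qnorm(1 - alpha / 2))
}
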