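# Independent brute-force oracles used to cross-check the estimators.

# closed-form inverse-variance weighted mean and Cochran's Q
oracle_ivw <- function(theta, se) {
  w <- 1 / se^2
  beta <- sum(w * theta) / sum(w)
  list(beta = beta, se = sqrt(1 / sum(w)), q = sum(w * (theta - beta)^2))
}

# weighted least squares by explicit normal equations
oracle_wls <- function(bx, by, w) {
  X <- cbind(1, bx)
  unname(drop(solve(t(X) %*% (w * X), t(X) %*% (w * by))))
}

# weighted median by explicit midpoint accumulation and hand interpolation
oracle_weighted_median <- function(theta, w) {
  ord <- order(theta)
  th <- theta[ord]
  ww <- w[ord] / sum(w)
  s <- numeric(length(th))
  acc <- 0
  for (i in seq_along(th)) {
    s[i] <- acc + ww[i] / 2
    acc <- acc + ww[i]
  }
  n <- length(th)
  if (0.5 <= s[1]) return(th[1])
  if (0.5 >= s[n]) return(th[n])
  i <- max(which(s <= 0.5))
  th[i] + (th[i + 1] - th[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
}

# minimal harmonized instrument table
make_h <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.01,
                   snp = sprintf("rs%03d", seq_along(beta_exp))) {
  data.frame(snp = snp, beta_exp = beta_exp,
             se_exp = rep_len(se_exp, length(beta_exp)),
             beta_out = beta_out,
             se_out = rep_len(se_out, length(beta_exp)),
             eaf_exp = NA_real_, eaf_out = NA_real_,
             action = "unchanged", stringsAsFactors = FALSE)
}

# summary-association table builder for harmonization tests
make_assoc <- function(snp, a1, a2, beta, se = 0.01, eaf = NA_real_,
                       p = 1e-10) {
  data.frame(snp = snp, effect_allele = a1, other_allele = a2,
             eaf = rep_len(eaf, length(snp)), beta = beta,
             se = rep_len(se, length(snp)), p = rep_len(p, length(snp)),
             info = NA_real_, n = NA_real_, stringsAsFactors = FALSE)
}
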