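# MR-PRESSO: simulation-based residual-sum pleiotropy framework.
# Observed statistic: each SNP's outcome beta is compared with the value
# predicted by the IVW slope fitted on all *other* SNPs (leave-one-out), so
# an outlier cannot mask itself. The null distribution is built by
# parametric simulation from the observed effect sizes and SEs.

#' @keywords internal
.ivw_beta_fixed <- function(be, bo, seo) {
  sum(be * bo / seo^2) / sum(be^2 / seo^2)
}

# leave-one-out fixed-effect IVW slopes, vectorized over a matrix of
# replicates (rows = replicates, cols = SNPs)
#' @keywords internal
.loo_slopes <- function(BE, BO, seo) {
  W <- sweep(BE^2, 2, seo^2, "/")
  A <- sweep(BE * BO, 2, seo^2, "/")
  (rowSums(A) - A) / (rowSums(W) - W)
}

#' @keywords internal
.presso_sim <- function(h, n_sim, seed) {
  k <- nrow(h)
  th_loo <- drop(.loo_slopes(matrix(h$beta_exp, 1), matrix(h$beta_out, 1),
                             h$se_out))
  resid_obs <- h$beta_out - th_loo * h$beta_exp
  sims <- .with_seed(seed, {
    BE <- matrix(stats::rnorm(n_sim * k, rep(h$beta_exp, each = n_sim),
                              rep(h$se_exp, each = n_sim)), n_sim, k)
    BO <- matrix(stats::rnorm(n_sim * k,
                              rep(th_loo * h$beta_exp, each = n_sim),
                              rep(h$se_out, each = n_sim)), n_sim, k)
    TH <- .loo_slopes(BE, BO, h$se_out)
    RES <- BO - TH * BE
    list(rss = rowSums(RES^2), res2 = RES^2)
  })
  list(rss_obs = sum(resid_obs^2), res2_obs = resid_obs^2,
       rss_sim = sims$rss, res2_sim = sims$res2)
}

#' MR-PRESSO global pleiotropy test
#'
#' Tests whether the observed residual sum of squares — outcome effects
#' minus their leave-one-out IVW predictions — exceeds what sampling noise
#' alone produces. The null distribution is simulated by redrawing every
#' SNP's exposure and outcome effects from normal distributions centred at
#' the observed exposure effect and at its leave-one-out prediction, and
#' recomputing the statistic. The p-value uses the add-one empirical
#' estimator, so it is bounded below by `1/(n_sim + 1)`.
#'
#' @param h Harmonized instrument table; needs at least 3 instruments.
#' @param n_sim Number of simulated replicates (>= 100). Default 1000.
#' @param seed Integer seed (required).
#' @return List: `rss_observed`, `global_p`, `n_sim`, `seed`.
#' @export
presso_global <- function(h, n_sim = 1000, seed) {
  .check_harmonized(h, k_min = 3)
  stopifnot(n_sim >= 100)
  if (missing(seed)) stop("seed is required")
  s <- .presso_sim(h, n_sim, seed)
  list(rss_observed = s$rss_obs,
       global_p = (1 + sum(s$rss_sim >= s$rss_obs)) / (n_sim + 1),
       n_sim = n_sim, seed = seed)
}

#' MR-PRESSO per-SNP outlier test
#'
#' Compares each SNP's observed squared residual (from its leave-one-out IVW
#' prediction) with its own simulated null distribution. Raw add-one
#' empirical p-values are Bonferroni-adjusted by the number of instruments
#' and capped at 1; SNPs with adjusted p below `outlier_alpha` are declared
#' outliers.
#'
#' @inheritParams presso_global
#' @param outlier_alpha Significance level on the adjusted p-values.
#'   Default 0.05.
#' @return List: `per_snp_p` (named, Bonferroni-adjusted), `raw_p` (named),
#'   `outliers` (character vector), `n_sim`, `seed`.
#' @export
presso_outlier <- function(h, n_sim = 1000, seed, outlier_alpha = 0.05) {
  .check_harmonized(h, k_min = 3)
  stopifnot(n_sim >= 100)
  if (missing(seed)) stop("seed is required")
  s <- .presso_sim(h, n_sim, seed)
  k <- nrow(h)
  raw <- (1 + colSums(sweep(s$res2_sim, 2, s$res2_obs, ">="))) / (n_sim + 1)
  adj <- pmin(1, k * raw)
  names(raw) <- names(adj) <- h$snp
  list(per_snp_p = adj, raw_p = raw,
       outliers = h$snp[adj < outlier_alpha], n_sim = n_sim, seed = seed)
}

#' Outlier-corrected IVW estimate
#'
#' Re-runs the IVW estimator (model `"auto"`) on the instruments that were
#' not flagged as outliers. With an empty outlier set this equals the
#' uncorrected IVW; with fewer than 2 instruments remaining no corrected
#' estimate is produced.
#'
#' @param h Harmonized instrument table.
#' @param outliers Character vector of outlier rsIDs (order irrelevant).
#' @return `mr_ivw` result on the retained subset, or `NULL` (with a
#'   warning) when fewer than 2 instruments remain.
#' @export
presso_corrected <- function(h, outliers) {
  keep <- !h$snp %in% outliers
  if (sum(keep) < 2) {
    warning("fewer than 2 instruments remain after outlier removal; ",
            "no corrected estimate")
    return(NULL)
  }
  mr_ivw(h[keep, , drop = FALSE], model = "auto")
}

#' MR-PRESSO distortion test
#'
#' Asks whether removing the flagged outliers changes the causal estimate
#' more than removing a random subset of the same size would. The observed
#' change (outlier-corrected IVW minus all-SNP IVW) is compared two-sidedly
#' with the distribution of changes when random subsets of non-outlier
#' instruments are removed instead (falling back to all instruments when
#' too few non-outliers remain).
#'
#' @inheritParams presso_global
#' @param outliers Nonempty character vector of outlier rsIDs.
#' @return List: `distortion_p`, `delta_observed`, `n_sim`, `seed`.
#' @export
presso_distortion <- function(h, outliers, n_sim = 1000, seed) {
  .check_harmonized(h, k_min = 3)
  if (length(outliers) == 0) stop("outlier set is empty; not applicable")
  if (missing(seed)) stop("seed is required")
  full <- mr_ivw(h, model = "auto")$estimate$beta
  corrected <- presso_corrected(h, outliers)
  if (is.null(corrected)) return(list(distortion_p = NA_real_,
                                      delta_observed = NA_real_,
                                      n_sim = n_sim, seed = seed))
  delta_obs <- corrected$estimate$beta - full
  m <- sum(h$snp %in% outliers)
  pool <- which(!h$snp %in% outliers)
  if (length(pool) < m + 2) pool <- seq_len(nrow(h))
  deltas <- .with_seed(seed, {
    vapply(seq_len(n_sim), function(b) {
      drop_idx <- pool[sample.int(length(pool), m)]
      sub <- h[-drop_idx, , drop = FALSE]
      if (nrow(sub) < 2) return(NA_real_)
      mr_ivw(sub, model = "auto")$estimate$beta - full
    }, numeric(1))
  })
  deltas <- deltas[!is.na(deltas)]
  p <- (1 + sum(abs(deltas) >= abs(delta_obs))) / (length(deltas) + 1)
  list(distortion_p = p, delta_observed = delta_obs, n_sim = n_sim,
       seed = seed)
}

#' Full MR-PRESSO report
#'
#' Runs the global test, the per-SNP outlier test (sharing one simulation
#' set, so results are reproducible from a single seed), the
#' outlier-corrected estimate and, when outliers are found, the distortion
#' test.
#'
#' @inheritParams presso_outlier
#' @return List of class `mr_presso`: `rss_observed`, `global_p`,
#'   `per_snp_p`, `outliers`, `corrected` (an `mr_ivw` result or `NULL`),
#'   `distortion_p` (`NA` when no outliers), `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, seed, outlier_alpha = 0.05) {
  .check_harmonized(h, k_min = 3)
  stopifnot(n_sim >= 100)
  if (missing(seed)) stop("seed is required")
  s <- .presso_sim(h, n_sim, seed)
  k <- nrow(h)
  global_p <- (1 + sum(s$rss_sim >= s$rss_obs)) / (n_sim + 1)
  raw <- (1 + colSums(sweep(s$res2_sim, 2, s$res2_obs, ">="))) / (n_sim + 1)
  adj <- pmin(1, k * raw)
  names(adj) <- h$snp
  outliers <- h$snp[adj < outlier_alpha]
  corrected <- NULL
  distortion_p <- NA_real_
  if (length(outliers) > 0) {
    if (sum(!h$snp %in% outliers) >= 2) {
      corrected <- presso_corrected(h, outliers)
      distortion_p <- presso_distortion(h, outliers, n_sim = n_sim,
                                        seed = seed)$distortion_p
    } else {
      warning("fewer than 2 instruments remain after outlier removal")
    }
  }
  out <- list(rss_observed = s$rss_obs, global_p = global_p,
              per_snp_p = adj, outliers = outliers, corrected = corrected,
              distortion_p = distortion_p, n_sim = n_sim, seed = seed)
  class(out) <- "mr_presso"
  out
}
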