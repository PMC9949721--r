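#' Filter candidate instruments
#'
#' Applies the standard instrument filters for a two-sample MR analysis, in
#' this order: confounder exclusion list, minor allele frequency (MAF),
#' genome-wide significance, and imputation quality. Each removed candidate
#' carries the first failing filter as its reason. MAF is `min(eaf, 1-eaf)`;
#' candidates with missing EAF pass the MAF filter (frequency unknown), and
#' candidates with missing INFO pass the INFO filter.
#'
#' @param candidates Summary table (data.frame as from
#'   [read_summary_table()]).
#' @param p_max Significance threshold; retain when `p < p_max`.
#'   Default `5e-8` (genome-wide significance).
#' @param maf_min Minimum MAF; retain when `MAF >= maf_min`. Default 0.01.
#' @param info_min Imputation-quality floor; retain when `info > info_min`
#'   or INFO is missing. Default 0.9.
#' @param exclude Character vector of rsIDs excluded a priori (e.g. known
#'   confounder-associated variants).
#' @return List with `retained` (character vector of rsIDs, input order) and
#'   `removed` (data.frame `snp`, `reason` with reason in
#'   `excluded`/`MAF`/`p`/`INFO`). An empty retained set carries attribute
#'   `fatal = TRUE`: no MR estimate is possible downstream.
#' @export
select_instruments <- function(candidates, p_max = 5e-8, maf_min = 0.01,
                               info_min = 0.9, exclude = character(0)) {
  maf <- pmin(candidates$eaf, 1 - candidates$eaf)
  reason <- rep(NA_character_, nrow(candidates))
  flag <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  reason <- flag(candidates$snp %in% exclude, "excluded")
  reason <- flag(!is.na(maf) & maf < maf_min, "MAF")
  reason <- flag(candidates$p >= p_max, "p")
  reason <- flag(!is.na(candidates$info) & candidates$info <= info_min,
                 "INFO")
  retained <- candidates$snp[is.na(reason)]
  removed <- data.frame(snp = candidates$snp[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  out <- list(retained = retained, removed = removed)
  if (length(retained) == 0) attr(out, "fatal") <- TRUE
  out
}

#' Per-instrument F-statistic
#'
#' Instrument strength for a single SNP, `F = (beta/se)^2`. Values above 10
#' are the conventional threshold against weak-instrument bias. Published
#' instrument tables typically print this rounded to the nearest integer;
#' full precision is returned here.
#'
#' @param beta SNP-exposure effect estimate (vectorized).
#' @param se Its standard error; must be positive.
#' @return Nonnegative numeric, same length as `beta`.
#' @export
f_per_snp <- function(beta, se) {
  if (any(!is.finite(se) | se <= 0)) stop("se must be positive")
  (beta / se)^2
}

#' Overall F-statistic of an instrument set
#'
#' `F = ((N - k - 1) / k) * R^2 / (1 - R^2)`, where `N` is the exposure GWAS
#' sample size, `k` the number of instruments and `R^2` the fraction of
#' exposure variance they explain (see [r2_from_summary()]).
#'
#' @param n_exposure Exposure sample size; must exceed `k + 1`.
#' @param k Number of instruments.
#' @param r2_total Variance explained, in `[0, 1)`.
#' @return Nonnegative numeric.
#' @export
f_overall <- function(n_exposure, k, r2_total) {
  if (r2_total < 0 || r2_total >= 1) stop("r2_total must lie in [0,1)")
  if (n_exposure <= k + 1) stop("n_exposure must exceed k + 1")
  ((n_exposure - k - 1) / k) * r2_total / (1 - r2_total)
}

#' Variance explained by an instrument set
#'
#' Approximates the exposure variance explained by independent instruments as
#' `sum_j 2 * eaf_j * (1 - eaf_j) * beta_j^2`, treating the (liability or
#' log-odds scale) phenotype as unit-variance. This is the standard
#' summary-statistic approximation; it is isolated here so an alternative
#' definition can be substituted.
#'
#' @param records Summary table rows for the instruments; EAF must be present
#'   for every record.
#' @return Total R^2 (numeric scalar).
#' @export
r2_from_summary <- function(records) {
  if (any(is.na(records$eaf))) {
    stop("EAF missing for SNP(s): ",
         paste(records$snp[is.na(records$eaf)], collapse = ", "))
  }
  sum(2 * records$eaf * (1 - records$eaf) * records$beta^2)
}

#' Instrument-strength report
#'
#' Combines the per-SNP and overall F-statistics and total variance explained
#' for a retained instrument set.
#'
#' @param records Summary table rows for the retained instruments.
#' @param n_exposure Exposure GWAS sample size.
#' @return List: `per_snp_f` (named numeric), `r2_total`, `f_overall`,
#'   `n_exposure`, `k`.
#' @export
instrument_strength <- function(records, n_exposure) {
  f <- f_per_snp(records$beta, records$se)
  names(f) <- records$snp
  r2 <- r2_from_summary(records)
  list(per_snp_f = f, r2_total = r2,
       f_overall = f_overall(n_exposure, nrow(records), r2),
       n_exposure = n_exposure, k = nrow(records))
}
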