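# Synthetic two-sample GWAS summary statistics with known ground truth.
#
# Generative model, per SNP j (binary exposure and outcome, log-odds scale):
#   maf_j ~ Uniform(maf_range)
#   gamma_j ~ Normal(0, gamma_scale^2)          true SNP-exposure effect
#   se_exp_j = 1 / sqrt(2 maf (1-maf) N_exp K_e (1-K_e))
#   beta_exp_j ~ Normal(gamma_j, se_exp_j^2)    observed
#   alpha_j ~ Normal(pleiotropy_mean, pleiotropy_sd^2) for a seeded
#             fraction prop_invalid of SNPs, 0 otherwise (direct effect)
#   se_out_j analogous with N_out, K_o
#   beta_out_j ~ Normal(theta * gamma_j + alpha_j, se_out_j^2)
# The large-sample SE form matches a logistic case-control GWAS with case
# fraction K. Tables are reported on the exposure-increasing allele
# (effects oriented so gamma_j >= 0), the convention of published
# instrument tables; pleiotropic effects are assigned on that oriented
# scale, so pleiotropy_mean > 0 means directional pleiotropy.

#' Generate a synthetic two-sample GWAS summary dataset
#'
#' Draws independent SNPs under the model described above and returns
#' exposure and outcome summary tables in the standard dialect together
#' with the generating truth, for calibration and parameter-recovery
#' studies. Identical seeds give bit-identical output.
#'
#' Defaults mirror the scale of a large biobank exposure GWAS
#' (217,955 samples, 7.7% cases) and a consortium disease outcome
#' (659,316 samples, 9.5% cases), with exposure effect sizes on the order
#' of published sleep-apnea instruments (SD 0.1 on the log-odds scale) and
#' common variants (MAF 0.1-0.5).
#'
#' @param n_snps Number of independent SNPs. Default 50.
#' @param n_exp,n_out Exposure / outcome GWAS sample sizes.
#' @param case_fraction_exp,case_fraction_out Case fractions in (0, 1).
#' @param maf_range Length-2 interval within (0, 0.5] for the minor allele
#'   frequency. Default `c(0.1, 0.5)`.
#' @param gamma_scale SD of the true SNP-exposure effects. Default 0.1.
#' @param theta True causal effect (log-odds outcome per log-odds
#'   exposure). Default 0.
#' @param prop_invalid Fraction of SNPs given a direct (pleiotropic)
#'   outcome effect. Default 0.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the pleiotropic
#'   effects on the oriented (exposure-increasing allele) scale.
#' @param seed Integer seed (required).
#' @param gamma Optional numeric vector of true exposure effects
#'   (length `n_snps`), overriding the random draw; useful to hold the
#'   genetic architecture fixed across replicate datasets.
#' @param maf Optional numeric vector of minor allele frequencies
#'   (length `n_snps`, values in (0, 0.5]), overriding the uniform draw
#'   for the same purpose.
#' @param n_palindromic Number of leading SNPs given palindromic (A/T)
#'   alleles, to exercise harmonization. Default 0 (all non-palindromic).
#' @return List with `exposure` and `outcome` (data.frames in the
#'   [read_summary_table()] layout) and `truth` (list `theta`, `gamma`,
#'   `alpha`, `invalid_ids`, `seed`).
#' @export
simulate_mr_summary <- function(n_snps = 50,
                                n_exp = 217955,
                                case_fraction_exp = 16761 / 217955,
                                n_out = 659316,
                                case_fraction_out = 62892 / 659316,
                                maf_range = c(0.1, 0.5),
                                gamma_scale = 0.1,
                                theta = 0,
                                prop_invalid = 0,
                                pleiotropy_mean = 0,
                                pleiotropy_sd = 0,
                                seed,
                                gamma = NULL,
                                maf = NULL,
                                n_palindromic = 0) {
  stopifnot(n_snps >= 1, n_exp > 1, n_out > 1,
            case_fraction_exp > 0, case_fraction_exp < 1,
            case_fraction_out > 0, case_fraction_out < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], gamma_scale > 0,
            prop_invalid >= 0, prop_invalid <= 1, pleiotropy_sd >= 0,
            n_palindromic >= 0, n_palindromic <= n_snps)
  if (missing(seed)) stop("seed is required")
  if (!is.null(gamma) && length(gamma) != n_snps) {
    stop("gamma override must have length n_snps")
  }
  if (!is.null(maf) &&
      (length(maf) != n_snps || any(maf <= 0) || any(maf > 0.5))) {
    stop("maf override must have length n_snps with values in (0, 0.5]")
  }
  ke <- case_fraction_exp
  ko <- case_fraction_out
  maf_fixed <- maf
  dat <- .with_seed(seed, {
    maf <- if (is.null(maf_fixed)) {
      stats::runif(n_snps, maf_range[1], maf_range[2])
    } else maf_fixed
    g <- if (is.null(gamma)) stats::rnorm(n_snps, 0, gamma_scale) else gamma
    # report on the exposure-increasing allele
    ori <- ifelse(g < 0, -1, 1)
    g <- g * ori
    eaf <- ifelse(ori < 0, 1 - maf, maf)
    se_exp <- 1 / sqrt(2 * maf * (1 - maf) * n_exp * ke * (1 - ke))
    beta_exp <- stats::rnorm(n_snps, g, se_exp)
    n_invalid <- round(prop_invalid * n_snps)
    invalid <- sort(sample.int(n_snps, n_invalid))
    alpha <- numeric(n_snps)
    if (n_invalid > 0) {
      alpha[invalid] <- stats::rnorm(n_invalid, pleiotropy_mean,
                                     pleiotropy_sd)
    }
    se_out <- 1 / sqrt(2 * maf * (1 - maf) * n_out * ko * (1 - ko))
    beta_out <- stats::rnorm(n_snps, theta * g + alpha, se_out)
    list(maf = maf, g = g, eaf = eaf, se_exp = se_exp, beta_exp = beta_exp,
         alpha = alpha, invalid = invalid, se_out = se_out,
         beta_out = beta_out)
  })
  snp <- sprintf("rs%07d", seq_len(n_snps))
  pairs <- matrix(c("G", "A", "C", "T", "A", "G", "T", "C"), ncol = 2,
                  byrow = TRUE)
  pick <- ((seq_len(n_snps) - 1) %% 4) + 1
  a1 <- pairs[pick, 1]
  a2 <- pairs[pick, 2]
  if (n_palindromic > 0) {
    a1[seq_len(n_palindromic)] <- "A"
    a2[seq_len(n_palindromic)] <- "T"
  }
  mk <- function(beta, se) {
    data.frame(snp = snp, effect_allele = a1, other_allele = a2,
               eaf = dat$eaf, beta = beta, se = se,
               p = pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin),
               info = NA_real_, n = NA_real_, stringsAsFactors = FALSE)
  }
  exposure <- mk(dat$beta_exp, dat$se_exp)
  exposure$n <- n_exp
  outcome <- mk(dat$beta_out, dat$se_out)
  outcome$n <- n_out
  list(exposure = exposure, outcome = outcome,
       truth = list(theta = theta, gamma = dat$g, alpha = dat$alpha,
                    invalid_ids = snp[dat$invalid], seed = seed))
}

#' Candidate instruments for obstructive sleep apnea
#'
#' The five OSA-associated variants used as candidate instruments:
#' four with published effect-allele frequency, log-odds effect, SE and
#' p-value from the source exposure GWAS, plus rs185932673, a rare variant
#' (MAF 0.005) whose effect estimate was not published — its beta, SE and
#' p here are synthetic placeholders (flagged in the `note` column) present
#' only so the MAF filter has a rare candidate to act on.
#'
#' @return data.frame in the [read_summary_table()] layout plus a `note`
#'   column; exposure sample size 217,955 (16,761 cases, 201,194 controls).
#' @export
osa_instruments <- function() {
  data.frame(
    snp = c("rs9937053", "rs10507084", "rs4837016", "rs10928560",
            "rs185932673"),
    effect_allele = c("G", "C", "G", "C", "C"),
    other_allele = c("A", "T", "A", "T", "T"),
    eaf = c(0.43, 0.18, 0.47, 0.18, 0.005),
    beta = c(0.104, 0.104, -0.073, -0.083, 0.30),
    se = c(0.012, 0.016, 0.011, 0.014, 0.052),
    p = c(4.30e-16, 2.80e-11, 1.50e-08, 2.80e-08, 8.0e-09),
    info = NA_real_,
    n = 217955,
    note = c("", "", "", "",
             "synthetic placeholder beta/se/p (not published)"),
    stringsAsFactors = FALSE
  )
}
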