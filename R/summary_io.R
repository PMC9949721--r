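#' Default column mapping for GWAS summary tables
#'
#' Maps the internal field names to the column headers expected in an input
#' summary-association table. Override individual entries to read tables with
#' non-standard headers.
#'
#' @return Named character vector: internal name -> column header.
#' @export
default_column_map <- function() {
  c(snp = "SNP", effect_allele = "A1", other_allele = "A2", eaf = "EAF",
    beta = "BETA", se = "SE", p = "P", info = "INFO", n = "N")
}

.valid_alleles <- c("A", "C", "G", "T")

.complement <- function(a) {
  unname(c(A = "T", T = "A", C = "G", G = "C")[a])
}

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Read a GWAS summary-association table
#'
#' Reads a tab- or comma-separated table of per-SNP association records
#' (the delimiter is auto-detected from the header line) and validates each
#' row against the summary-association contract: distinct alleles drawn from
#' A/C/G/T, positive standard error, p in (0, 1], and effect-allele frequency
#' (EAF) and imputation INFO in [0, 1] when present. Rows violating the
#' contract are dropped, not fatal; the returned data frame carries a
#' `rejections` attribute with one reason per dropped row.
#'
#' @param path Path to the table. Must have a header row.
#' @param column_map Named character vector mapping internal names
#'   (`snp`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`,
#'   `info`, `n`) to column headers; see [default_column_map()]. The columns
#'   mapped by `eaf`, `info` and `n` are optional in the file.
#' @return A data.frame with columns `snp`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `p`, `info`, `n` (missing optional columns filled
#'   with `NA`), one row per accepted input row, input order preserved.
#'   Attribute `rejections` is a data.frame (`row`, `snp`, `reason`).
#' @export
read_summary_table <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) stop("summary table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "", strip.white = TRUE)
  map <- default_column_map()
  map[names(column_map)] <- column_map
  mandatory <- c("snp", "effect_allele", "other_allele", "beta", "se", "p")
  for (field in mandatory) {
    if (!map[[field]] %in% names(raw)) {
      stop("mandatory column '", map[[field]], "' (", field,
           ") missing from ", path)
    }
  }
  pull <- function(field, as_num = TRUE) {
    col <- map[[field]]
    if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    v <- raw[[col]]
    if (as_num) suppressWarnings(as.numeric(v)) else v
  }
  out <- data.frame(
    snp = pull("snp", as_num = FALSE),
    effect_allele = toupper(pull("effect_allele", as_num = FALSE)),
    other_allele = toupper(pull("other_allele", as_num = FALSE)),
    eaf = pull("eaf"), beta = pull("beta"), se = pull("se"), p = pull("p"),
    info = pull("info"), n = pull("n"),
    stringsAsFactors = FALSE
  )
  reason <- rep(NA_character_, nrow(out))
  flag <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  reason <- flag(!out$effect_allele %in% .valid_alleles |
                 !out$other_allele %in% .valid_alleles, "invalid allele")
  reason <- flag(out$effect_allele == out$other_allele, "identical alleles")
  reason <- flag(is.na(out$beta), "non-numeric beta")
  reason <- flag(is.na(out$se), "non-numeric SE")
  reason <- flag(out$se <= 0, "nonpositive SE")
  reason <- flag(is.na(out$p) | out$p <= 0 | out$p > 1, "p outside (0,1]")
  reason <- flag(!is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1),
                 "EAF outside [0,1]")
  reason <- flag(!is.na(out$info) & (out$info < 0 | out$info > 1),
                 "INFO outside [0,1]")
  keep <- is.na(reason)
  rejections <- data.frame(row = which(!keep), snp = out$snp[!keep],
                           reason = reason[!keep], stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  out
}

#' Read an LD lookup table
#'
#' Three columns: `snp_a`, `snp_b`, `r2` with r2 in [0, 1]. Lookup is
#' symmetric in the two SNP columns.
#'
#' @param path Path to a tab- or comma-separated file with a header.
#' @return data.frame with columns `snp_a`, `snp_b`, `r2`.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop("LD table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  ld <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("snp_a", "snp_b", "r2")
  if (!all(need %in% names(ld))) {
    stop("LD table must have columns snp_a, snp_b, r2")
  }
  ld$r2 <- as.numeric(ld$r2)
  if (any(is.na(ld$r2) | ld$r2 < 0 | ld$r2 > 1)) {
    stop("LD r2 values must lie in [0,1]")
  }
  ld[, need]
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns each outcome record to the exposure record's effect allele so both
#' betas refer to the same allele. Alleles already matching are copied
#' unchanged; swapped alleles negate the outcome beta and reflect its EAF;
#' strand-complemented alleles (A<->T, C<->G) are complemented first and then
#' aligned. Palindromic SNPs (A/T or C/G) carry no strand information in
#' their allele labels, so they are oriented by allele frequency: both EAFs
#' must be present and lie outside `0.5 +/- palindromic_eaf_window`,
#' otherwise the SNP is dropped (`dropped_palindromic`). Exposure SNPs absent
#' from the outcome are omitted (see [substitute_proxies()]); irreconcilable
#' allele pairs are dropped and logged.
#'
#' @param exposure,outcome Summary tables as returned by
#'   [read_summary_table()] (or any data.frame with those columns), keyed by
#'   `snp`.
#' @param palindromic_eaf_window Half-width of the ambiguity window around
#'   EAF 0.5 inside which palindromic SNPs are dropped. Default 0.08, i.e.
#'   drop when either EAF falls in [0.42, 0.58].
#' @return data.frame with columns `snp`, `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out`, `eaf_exp`, `eaf_out`, `action` (one of `unchanged`,
#'   `allele_flip`, `strand_flip`, `dropped_palindromic`); dropped SNPs are
#'   excluded from the rows and listed in the `log` attribute
#'   (data.frame `snp`, `reason`).
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  stopifnot(palindromic_eaf_window >= 0, palindromic_eaf_window < 0.5)
  idx <- match(exposure$snp, outcome$snp)
  log_snp <- character(0)
  log_reason <- character(0)
  rows <- vector("list", nrow(exposure))
  for (i in seq_len(nrow(exposure))) {
    j <- idx[i]
    if (is.na(j)) next  # absent from outcome; proxy handling is separate
    e1 <- exposure$effect_allele[i]; e2 <- exposure$other_allele[i]
    o1 <- outcome$effect_allele[j]; o2 <- outcome$other_allele[j]
    bo <- outcome$beta[j]; fo <- outcome$eaf[j]
    pal <- .is_palindromic(e1, e2)
    action <- NA_character_
    if (pal) {
      fe <- exposure$eaf[i]
      lo <- 0.5 - palindromic_eaf_window
      hi <- 0.5 + palindromic_eaf_window
      same_pair <- (o1 == e1 && o2 == e2) || (o1 == e2 && o2 == e1) ||
        (.complement(o1) == e1 && .complement(o2) == e2) ||
        (.complement(o1) == e2 && .complement(o2) == e1)
      if (!same_pair) {
        log_snp <- c(log_snp, exposure$snp[i])
        log_reason <- c(log_reason, "irreconcilable alleles")
        next
      }
      if (is.na(fe) || is.na(fo) || (fe >= lo && fe <= hi) ||
          (fo >= lo && fo <= hi)) {
        log_snp <- c(log_snp, exposure$snp[i])
        log_reason <- c(log_reason, "palindromic, ambiguous EAF")
        rows[[i]] <- data.frame(
          snp = exposure$snp[i], beta_exp = NA_real_, se_exp = NA_real_,
          beta_out = NA_real_, se_out = NA_real_, eaf_exp = fe,
          eaf_out = fo, action = "dropped_palindromic",
          stringsAsFactors = FALSE)
        next
      }
      # orient by frequency: same side of 0.5 means same allele
      if ((fe - 0.5) * (fo - 0.5) > 0) {
        action <- "unchanged"
      } else {
        bo <- -bo; fo <- 1 - fo
        action <- "allele_flip"
      }
    } else {
      if (o1 == e1 && o2 == e2) {
        action <- "unchanged"
      } else if (o1 == e2 && o2 == e1) {
        bo <- -bo; if (!is.na(fo)) fo <- 1 - fo
        action <- "allele_flip"
      } else {
        c1 <- .complement(o1); c2 <- .complement(o2)
        if (identical(c1, e1) && identical(c2, e2)) {
          action <- "strand_flip"
        } else if (identical(c1, e2) && identical(c2, e1)) {
          bo <- -bo; if (!is.na(fo)) fo <- 1 - fo
          action <- "strand_flip"
        } else {
          log_snp <- c(log_snp, exposure$snp[i])
          log_reason <- c(log_reason, "irreconcilable alleles")
          next
        }
      }
    }
    rows[[i]] <- data.frame(
      snp = exposure$snp[i], beta_exp = exposure$beta[i],
      se_exp = exposure$se[i], beta_out = bo, se_out = outcome$se[j],
      eaf_exp = exposure$eaf[i], eaf_out = fo, action = action,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(snp = character(0), beta_exp = numeric(0),
                      se_exp = numeric(0), beta_out = numeric(0),
                      se_out = numeric(0), eaf_exp = numeric(0),
                      eaf_out = numeric(0), action = character(0),
                      stringsAsFactors = FALSE)
  }
  dropped <- out$action == "dropped_palindromic"
  res <- out[!dropped, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped_palindromic") <- out$snp[dropped]
  attr(res, "log") <- data.frame(snp = log_snp, reason = log_reason,
                                 stringsAsFactors = FALSE)
  res
}

#' Substitute LD proxies for instruments missing from the outcome
#'
#' For each requested instrument absent from the outcome table, selects the
#' outcome-present SNP in highest linkage disequilibrium with it, subject to
#' r2 strictly above `r2_min` (the conventional proxy threshold r2 > 0.8).
#' Ties on r2 are broken by the lexicographically smallest rsID, so the
#' mapping is deterministic. Instruments present in the outcome map to
#' themselves; instruments with no qualifying proxy are reported as
#' unresolved.
#'
#' @param instruments Character vector of requested instrument rsIDs.
#' @param outcome Outcome summary table (needs a `snp` column).
#' @param ld LD lookup data.frame (`snp_a`, `snp_b`, `r2`); symmetric.
#' @param r2_min Minimum (exclusive) r2 for a proxy. Default 0.8.
#' @return data.frame with columns `requested`, `used` (rsID or
#'   `"unresolved"`), `r2` (`NA` for self/unresolved), `status`
#'   (`self`, `proxy`, `unresolved`).
#' @export
substitute_proxies <- function(instruments, outcome, ld, r2_min = 0.8) {
  stopifnot(r2_min > 0, r2_min <= 1)
  present <- outcome$snp
  res <- lapply(instruments, function(snp) {
    if (snp %in% present) {
      return(data.frame(requested = snp, used = snp, r2 = NA_real_,
                        status = "self", stringsAsFactors = FALSE))
    }
    cand <- rbind(
      data.frame(partner = ld$snp_b[ld$snp_a == snp],
                 r2 = ld$r2[ld$snp_a == snp], stringsAsFactors = FALSE),
      data.frame(partner = ld$snp_a[ld$snp_b == snp],
                 r2 = ld$r2[ld$snp_b == snp], stringsAsFactors = FALSE))
    cand <- cand[cand$partner %in% present & cand$r2 > r2_min, , drop = FALSE]
    if (nrow(cand) == 0) {
      return(data.frame(requested = snp, used = "unresolved", r2 = NA_real_,
                        status = "unresolved", stringsAsFactors = FALSE))
    }
    cand <- cand[order(-cand$r2, cand$partner), , drop = FALSE]
    data.frame(requested = snp, used = cand$partner[1], r2 = cand$r2[1],
               status = "proxy", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
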