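#' Percentage difference of an STP estimate versus the MTP reference
#'
#' @param stp A `"tia_estimate"` from [stp_prior()] or [stp_hanscheid()].
#' @param ref The `"tia_estimate"` with `method = "MTP_ref"` for the same
#'   VOI and cycle. Must be strictly positive.
#' @return `100 * (stp - ref) / ref`, a signed percentage.
#' @export
percent_difference <- function(stp, ref) {
  stopifnot(inherits(stp, "tia_estimate"), inherits(ref, "tia_estimate"))
  if (ref$method != "MTP_ref")
    stop("reference estimate must have method 'MTP_ref'", call. = FALSE)
  if (!is.finite(ref$value_MBq_h) || ref$value_MBq_h <= 0)
    stop("reference TIA must be strictly positive", call. = FALSE)
  same <- function(a, b) (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) && a == b)
  if (!(same(stp$patient_id, ref$patient_id) && same(stp$cycle, ref$cycle) &&
        same(stp$voi_id, ref$voi_id)))
    stop("STP and reference estimates refer to different VOIs", call. = FALSE)
  100 * (stp$value_MBq_h - ref$value_MBq_h) / ref$value_MBq_h
}

#' Fit every curve of a cohort
#'
#' @param curves List of [tac()] objects.
#' @return List of `"monoexp_fit"` objects, one per curve, in input order.
#' @export
fit_cohort <- function(curves) {
  stopifnot(is.list(curves))
  lapply(curves, fit_monoexponential)
}

#' Tabulate cohort fits
#'
#' @param fits List of `"monoexp_fit"` objects.
#' @return A data frame with one row per fit: identifiers, `A0_MBq`,
#'   `half_life_eff_h`, `decay_constant_per_h`, `n_points`,
#'   `rms_log_residual`, `decaying`.
#' @export
fit_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(patient_id = f$patient_id, cycle = f$cycle,
               voi_id = f$voi_id, voi_type = f$voi_type,
               A0_MBq = f$A0_MBq, half_life_eff_h = f$half_life_eff_h,
               decay_constant_per_h = f$decay_constant_per_h,
               n_points = f$n_points, rms_log_residual = f$rms_log_residual,
               decaying = f$decaying, stringsAsFactors = FALSE)))
}

fit_key <- function(f) paste(f$patient_id, f$voi_id, sep = "\r")

#' Compare STP estimators against the MTP reference across a cohort
#'
#' For every cycle-2 VOI, fits the multiple-time-point reference, then for
#' each requested nominal scan time evaluates both single-time-point
#' estimators from the *measured* (not model-predicted) activity at the
#' sample nearest the nominal time. The prior-information estimator uses the
#' effective half-life fitted to the same VOI in cycle 1; VOIs without a
#' usable cycle-1 counterpart contribute only Hanscheid records (with a
#' warning), mirroring the restriction to lesions visible in both cycles.
#'
#' @param curves List of [tac()] objects covering cycles 1 and 2.
#' @param times Nominal scan times in hours post injection
#'   (default `c(24, 48, 72)`).
#' @param window [stp_window()] used for the `in_window` flag, evaluated
#'   against the cycle-2 MTP half-life at the actual sample time used.
#' @param time_tol_h A nominal time with no sample within this tolerance is
#'   skipped with a warning (default 6 h, accommodating scheduling jitter).
#' @return A data frame of comparison records: one row per VOI x nominal
#'   time x method, with columns `patient_id`, `voi_id`, `voi_type`,
#'   `method` (`"STP_prior"` / `"STP_H"`), `nominal_time_h`, `time_used_h`,
#'   `tia_ref_MBq_h`, `tia_stp_MBq_h`, `pd_percent`, `within_10`,
#'   `within_20`, `in_window`.
#' @export
compare_cohort <- function(curves, times = c(24, 48, 72),
                           window = stp_window(), time_tol_h = 6) {
  stopifnot(is.list(curves), all(vapply(curves, inherits, TRUE, "tac")))
  cyc <- vapply(curves, `[[`, 1L, "cycle")
  c1 <- curves[cyc == 1L]; c2 <- curves[cyc == 2L]
  priors <- list()
  for (cv in c1) {
    f <- fit_monoexponential(cv)
    if (f$decaying) priors[[fit_key(f)]] <- f
  }
  rows <- list()
  for (cv in c2) {
    f2 <- fit_monoexponential(cv)
    if (!f2$decaying) {
      warning("skipping non-decaying cycle-2 VOI ", cv$voi_id,
              " of patient ", cv$patient_id, call. = FALSE)
      next
    }
    ref <- tia_reference(f2)
    prior <- priors[[fit_key(f2)]]
    if (is.null(prior))
      warning("no cycle-1 fit for VOI ", cv$voi_id, " of patient ",
              cv$patient_id, "; STP_prior skipped", call. = FALSE)
    src <- list(patient_id = cv$patient_id, cycle = cv$cycle,
                voi_id = cv$voi_id)
    for (tn in times) {
      i <- which.min(abs(cv$time_h - tn))
      if (abs(cv$time_h[i] - tn) > time_tol_h) {
        warning("no sample within ", time_tol_h, " h of t = ", tn,
                " h for VOI ", cv$voi_id, " of patient ", cv$patient_id,
                call. = FALSE)
        next
      }
      t_used <- cv$time_h[i]; a_used <- cv$activity_MBq[i]
      ests <- list(stp_hanscheid(a_used, t_used, source = src))
      if (!is.null(prior))
        ests <- c(ests, list(stp_prior(a_used, t_used,
                                       prior$half_life_eff_h, source = src)))
      for (est in ests) {
        pd <- percent_difference(est, ref)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = cv$patient_id, voi_id = cv$voi_id,
          voi_type = cv$voi_type, method = est$method,
          nominal_time_h = tn, time_used_h = t_used,
          tia_ref_MBq_h = ref$value_MBq_h, tia_stp_MBq_h = est$value_MBq_h,
          pd_percent = pd,
          within_10 = abs(pd) <= 10, within_20 = abs(pd) <= 20,
          in_window = in_hanscheid_window(t_used, f2$half_life_eff_h, window),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(patient_id = character(), voi_id = character(),
                      voi_type = character(), method = character(),
                      nominal_time_h = numeric(), time_used_h = numeric(),
                      tia_ref_MBq_h = numeric(), tia_stp_MBq_h = numeric(),
                      pd_percent = numeric(), within_10 = logical(),
                      within_20 = logical(), in_window = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bland-Altman summary of percentage differences
#'
#' Summarizes the per-pair relative differences of one stratum (one VOI type,
#' method and time point). The difference axis is the percentage difference
#' with the MTP reference as denominator, keeping one difference definition
#' across the PD analysis and the Bland-Altman analysis; set
#' `denominator = "pair_mean"` to use the conventional mean-of-pair
#' denominator instead (then supply the raw TIAs via `stp` and `ref`).
#'
#' @param pd_percent Numeric vector of percentage differences (used when
#'   `denominator = "reference"`).
#' @param stp,ref Raw TIA vectors, only needed for the pair-mean variant.
#' @param denominator `"reference"` (default) or `"pair_mean"`.
#' @param loa_mult Limits-of-agreement multiplier (default 1.96).
#' @return A `"bland_altman"` list: `n`, `mean_diff_percent`,
#'   `sd_diff_percent` (sample SD, n-1 denominator), `loa_low_percent`,
#'   `loa_high_percent`.
#' @export
bland_altman_summary <- function(pd_percent = NULL, stp = NULL, ref = NULL,
                                 denominator = c("reference", "pair_mean"),
                                 loa_mult = 1.96) {
  denominator <- match.arg(denominator)
  d <- if (denominator == "reference") {
    pd_percent
  } else {
    stopifnot(!is.null(stp), !is.null(ref), length(stp) == length(ref))
    100 * (stp - ref) / ((stp + ref) / 2)
  }
  if (length(d) < 2)
    stop("Bland-Altman summary requires at least 2 pairs", call. = FALSE)
  m <- mean(d); s <- stats::sd(d)
  structure(list(n = length(d), mean_diff_percent = m, sd_diff_percent = s,
                 loa_low_percent = m - loa_mult * s,
                 loa_high_percent = m + loa_mult * s),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean %.2f%%, SD %.2f%%, LoA [%.2f%%, %.2f%%]\n",
              x$n, x$mean_diff_percent, x$sd_diff_percent,
              x$loa_low_percent, x$loa_high_percent))
  invisible(x)
}

#' Coverage of STP estimates within +/-10% and +/-20% of the reference
#'
#' @param records Comparison records from [compare_cohort()].
#' @return A data frame with one row per `voi_type` x `method` x
#'   `nominal_time_h` stratum: `n`, `frac_within_10`, `frac_within_20`
#'   (inclusive bounds; empty strata are simply absent). Within-10 coverage
#'   never exceeds within-20 coverage.
#' @export
coverage_table <- function(records) {
  if (nrow(records) == 0)
    return(data.frame(voi_type = character(), method = character(),
                      nominal_time_h = numeric(), n = integer(),
                      frac_within_10 = numeric(), frac_within_20 = numeric(),
                      stringsAsFactors = FALSE))
  key <- interaction(records$voi_type, records$method,
                     records$nominal_time_h, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g)
    data.frame(voi_type = g$voi_type[1], method = g$method[1],
               nominal_time_h = g$nominal_time_h[1], n = nrow(g),
               frac_within_10 = mean(abs(g$pd_percent) <= 10),
               frac_within_20 = mean(abs(g$pd_percent) <= 20),
               stringsAsFactors = FALSE)))
  out <- out[order(out$voi_type, out$method, out$nominal_time_h), ]
  rownames(out) <- NULL
  out
}

#' Validity-window coverage per VOI type, cycle and time point
#'
#' Counts, per stratum, how many VOIs have the given nominal scan time inside
#' the Hanscheid validity window of their own fitted effective half-life.
#'
#' @param fits List of `"monoexp_fit"` objects (both cycles). Non-decaying
#'   fits are excluded.
#' @param times Nominal scan times (default `c(24, 48, 72)`).
#' @param window An [stp_window()].
#' @return Data frame with `voi_type`, `cycle`, `time_h`, `n`, `n_in_window`,
#'   `pct_in_window` (rounded to whole percent).
#' @export
window_coverage_table <- function(fits, times = c(24, 48, 72),
                                  window = stp_window()) {
  ft <- fit_table(fits)
  ft <- ft[ft$decaying, , drop = FALSE]
  rows <- list()
  for (g in split(ft, interaction(ft$voi_type, ft$cycle, drop = TRUE))) {
    for (tn in times) {
      inw <- in_hanscheid_window(tn, g$half_life_eff_h, window)
      rows[[length(rows) + 1L]] <- data.frame(
        voi_type = g$voi_type[1], cycle = g$cycle[1], time_h = tn,
        n = nrow(g), n_in_window = sum(inw),
        pct_in_window = round(100 * mean(inw)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$voi_type, out$cycle, out$time_h), ]
  rownames(out) <- NULL
  out
}

#' Inter-cycle change of effective half-lives
#'
#' Matches VOIs by patient and VOI label between the two cycles and reports
#' the per-VOI percentage change of the effective half-life, plus the count
#' of VOIs whose change exceeds +/-20% in magnitude (strictly more than 20,
#' so a change of exactly -20% is not counted).
#'
#' @param fits_c1,fits_c2 Lists of `"monoexp_fit"` objects for cycles 1 and
#'   2. Unmatched VOIs are skipped with a warning.
#' @return A list with `changes` (data frame: `patient_id`, `voi_id`,
#'   `voi_type`, `t_half_c1`, `t_half_c2`, `change_percent`), `n_exceed_20`
#'   and `frac_exceed_20`.
#' @export
half_life_change_stats <- function(fits_c1, fits_c2) {
  k1 <- vapply(fits_c1, fit_key, ""); k2 <- vapply(fits_c2, fit_key, "")
  unmatched <- sum(!(k2 %in% k1)) + sum(!(k1 %in% k2))
  if (unmatched > 0)
    warning(unmatched, " VOI(s) present in only one cycle were skipped",
            call. = FALSE)
  common <- intersect(k1, k2)
  rows <- lapply(common, function(k) {
    f1 <- fits_c1[[match(k, k1)]]; f2 <- fits_c2[[match(k, k2)]]
    data.frame(patient_id = f1$patient_id, voi_id = f1$voi_id,
               voi_type = f1$voi_type, t_half_c1 = f1$half_life_eff_h,
               t_half_c2 = f2$half_life_eff_h,
               change_percent = 100 * (f2$half_life_eff_h - f1$half_life_eff_h) /
                 f1$half_life_eff_h,
               stringsAsFactors = FALSE)
  })
  changes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), voi_id = character(),
               voi_type = character(), t_half_c1 = numeric(),
               t_half_c2 = numeric(), change_percent = numeric(),
               stringsAsFactors = FALSE)
  n_exceed <- sum(abs(changes$change_percent) > 20)
  list(changes = changes, n_exceed_20 = n_exceed,
       frac_exceed_20 = if (nrow(changes)) n_exceed / nrow(changes) else NaN)
}
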