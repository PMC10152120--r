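#' Time-activity curve for one VOI in one therapy cycle
#'
#' Container for the ordered activity samples of a single volume of interest
#' (VOI) measured at several times post injection. Units are fixed: hours for
#' time, MBq for activity. Unit conversions belong at the I/O boundary, not
#' here.
#'
#' @param patient_id Patient label (coerced to character).
#' @param cycle Therapy cycle, integer (typically 1 or 2).
#' @param voi_id VOI label, unique within a patient.
#' @param voi_type One of `"kidney_left"`, `"kidney_right"`, `"lesion"`,
#'   `"tb_fov"` (whole field-of-view tumor burden).
#' @param time_h Numeric vector of measurement times in hours post injection,
#'   strictly positive, strictly increasing, no duplicates.
#' @param activity_MBq Numeric vector of VOI activities in MBq, non-negative,
#'   same length as `time_h`.
#'
#' @return An object of class `"tac"`.
#' @export
tac <- function(patient_id, cycle, voi_id, voi_type, time_h, activity_MBq) {
  voi_type <- match.arg(voi_type, voi_types())
  stopifnot(length(time_h) == length(activity_MBq), length(time_h) >= 1)
  if (!all(is.finite(time_h)) || any(time_h <= 0))
    stop("time_h must be finite and strictly positive", call. = FALSE)
  if (!all(is.finite(activity_MBq)) || any(activity_MBq < 0))
    stop("activity_MBq must be finite and non-negative", call. = FALSE)
  ord <- order(time_h)
  time_h <- time_h[ord]; activity_MBq <- activity_MBq[ord]
  if (anyDuplicated(time_h))
    stop("duplicate measurement times in VOI '", voi_id, "'", call. = FALSE)
  structure(
    list(patient_id = as.character(patient_id), cycle = as.integer(cycle),
         voi_id = as.character(voi_id), voi_type = voi_type,
         time_h = as.numeric(time_h), activity_MBq = as.numeric(activity_MBq)),
    class = "tac")
}

voi_types <- function() c("kidney_left", "kidney_right", "lesion", "tb_fov")

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> patient %s cycle %d VOI %s (%s), %d samples\n",
              x$patient_id, x$cycle, x$voi_id, x$voi_type, length(x$time_h)))
  print(data.frame(time_h = x$time_h, activity_MBq = x$activity_MBq),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(patient_id = x$patient_id, cycle = x$cycle, voi_id = x$voi_id,
             voi_type = x$voi_type, time_h = x$time_h,
             activity_MBq = x$activity_MBq, stringsAsFactors = FALSE)
}

#' Fit a monoexponential washout model to a time-activity curve
#'
#' Fits \eqn{A(t) = A_0 \, 2^{-t/T_{1/2,\mathrm{eff}}}} by unweighted ordinary
#' least squares on the log scale, i.e. the linear model
#' \eqn{\ln A(t) = \ln A_0 - \lambda_{\mathrm{eff}} t}. This is exactly
#' solvable (no starting values), equivalent to assuming multiplicative
#' measurement error, and with exactly two points reduces to the exact
#' interpolant.
#'
#' A fitted decay constant \eqn{\lambda_{\mathrm{eff}} \le 0} (a net-increasing
#' or flat curve) is not an error: the fit is returned with a negative (or
#' infinite) effective half-life and `decaying = FALSE`, and downstream TIA
#' operations refuse it. Such curves are flagged, never silently truncated.
#'
#' @param curve A [tac()] object with at least 2 samples, all activities
#'   strictly positive (the log transform is undefined at zero).
#' @return An object of class `"monoexp_fit"`: a list with `A0_MBq`,
#'   `half_life_eff_h`, `decay_constant_per_h` (\eqn{\lambda_{\mathrm{eff}} =
#'   \ln 2 / T_{1/2,\mathrm{eff}}}), `n_points`, `rms_log_residual` (RMS
#'   residual of the fit in log-activity space), `decaying`, and the source
#'   VOI identifiers.
#' @export
#' @examples
#' cv <- tac("p1", 2, "kidney_left", "kidney_left",
#'           c(24, 48), c(50, 25))
#' f <- fit_monoexponential(cv)
#' f$half_life_eff_h  # 24 h: activity halves over one 24 h interval
fit_monoexponential <- function(curve) {
  stopifnot(inherits(curve, "tac"))
  t <- curve$time_h; a <- curve$activity_MBq
  if (length(t) < 2)
    stop("monoexponential fit requires at least 2 samples", call. = FALSE)
  if (any(a <= 0))
    stop("all activities must be strictly positive for a log-scale fit",
         call. = FALSE)
  y <- log(a)
  tm <- mean(t); ym <- mean(y)
  slope <- sum((t - tm) * (y - ym)) / sum((t - tm)^2)
  lambda <- -slope
  A0 <- exp(ym + lambda * tm)
  resid <- y - (log(A0) - lambda * t)
  half_life <- if (lambda == 0) Inf else log(2) / lambda
  structure(
    list(A0_MBq = A0,
         half_life_eff_h = half_life,
         decay_constant_per_h = lambda,
         n_points = length(t),
         rms_log_residual = sqrt(mean(resid^2)),
         decaying = is.finite(half_life) && half_life > 0,
         patient_id = curve$patient_id, cycle = curve$cycle,
         voi_id = curve$voi_id, voi_type = curve$voi_type),
    class = "monoexp_fit")
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf(
    "<monoexp_fit> %s cycle %d %s: A0 = %.4g MBq, T1/2eff = %.4g h%s (n = %d, RMS log resid = %.3g)\n",
    x$patient_id, x$cycle, x$voi_id, x$A0_MBq, x$half_life_eff_h,
    if (x$decaying) "" else " [non-decaying]", x$n_points, x$rms_log_residual))
  invisible(x)
}

#' Evaluate a fitted monoexponential model
#'
#' @param fit A `"monoexp_fit"` object.
#' @param time_h Time(s) in hours post injection, non-negative.
#' @return Predicted activity in MBq,
#'   \eqn{A_0 \, 2^{-t/T_{1/2,\mathrm{eff}}}}.
#' @export
predict_activity <- function(fit, time_h) {
  stopifnot(inherits(fit, "monoexp_fit"))
  if (any(!is.finite(time_h)) || any(time_h < 0))
    stop("time_h must be finite and non-negative", call. = FALSE)
  fit$A0_MBq * 2^(-time_h / fit$half_life_eff_h)
}

#' Multiple-time-point reference TIA
#'
#' The reference time-integrated activity of a fitted monoexponential curve:
#' the analytic integral of \eqn{A_0 \, 2^{-t/T_{1/2,\mathrm{eff}}}} from 0 to
#' infinity,
#' \deqn{\mathrm{TIA}_{\mathrm{ref}} = A_0 \, T_{1/2,\mathrm{eff}} / \ln 2 .}
#'
#' @param fit A `"monoexp_fit"` object with a positive effective half-life.
#' @return A `"tia_estimate"` object: list with `value_MBq_h`, `method`
#'   (`"MTP_ref"`), `time_used_h` (`NA` — all time points contribute),
#'   and the source VOI identifiers.
#' @export
tia_reference <- function(fit) {
  stopifnot(inherits(fit, "monoexp_fit"))
  if (!is.finite(fit$half_life_eff_h) || fit$half_life_eff_h <= 0)
    stop("reference TIA is undefined for a non-decaying VOI (half-life <= 0)",
         call. = FALSE)
  new_tia(fit$A0_MBq * fit$half_life_eff_h / log(2), "MTP_ref", NA_real_,
          fit$patient_id, fit$cycle, fit$voi_id)
}

new_tia <- function(value, method, time_used_h, patient_id = NA_character_,
                    cycle = NA_integer_, voi_id = NA_character_) {
  structure(
    list(value_MBq_h = value, method = method, time_used_h = time_used_h,
         patient_id = patient_id, cycle = cycle, voi_id = voi_id),
    class = "tia_estimate")
}

#' @export
print.tia_estimate <- function(x, ...) {
  tu <- if (is.na(x$time_used_h)) "all time points" else
    sprintf("t = %g h", x$time_used_h)
  cat(sprintf("<tia_estimate> %s: %.5g MBq.h (%s)\n", x$method,
              x$value_MBq_h, tu))
  invisible(x)
}
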