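#' Read per-VOI time-activity tables from CSV
#'
#' Expects columns `patient_id`, `cycle`, `voi_id`, `voi_type`, `time_h`,
#' `activity_MBq` (one row per measurement). Rows are validated
#' individually and offending lines are reported by file line number
#' (header = line 1).
#'
#' @param path CSV file path.
#' @return List of [tac()] objects, one per patient x cycle x VOI.
#' @export
read_tac_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "cycle", "voi_id", "voi_type", "time_h",
              "activity_MBq")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  line <- seq_len(nrow(df)) + 1L
  bad <- !is.finite(suppressWarnings(as.numeric(df$time_h))) |
    suppressWarnings(as.numeric(df$time_h)) <= 0 |
    !is.finite(suppressWarnings(as.numeric(df$activity_MBq))) |
    suppressWarnings(as.numeric(df$activity_MBq)) < 0 |
    !df$voi_type %in% voi_types() |
    is.na(suppressWarnings(as.integer(df$cycle)))
  if (any(bad))
    stop("invalid row(s) at line(s) ", paste(line[bad], collapse = ", "),
         ": time_h must be > 0, activity_MBq >= 0, voi_type one of ",
         paste(voi_types(), collapse = "/"), call. = FALSE)
  df$time_h <- as.numeric(df$time_h)
  df$activity_MBq <- as.numeric(df$activity_MBq)
  df$cycle <- as.integer(df$cycle)
  key <- paste(df$patient_id, df$cycle, df$voi_id, sep = "\r")
  dup <- duplicated(data.frame(key, df$time_h))
  if (any(dup))
    stop("duplicated (VOI, time) row(s) at line(s) ",
         paste(line[dup], collapse = ", "), call. = FALSE)
  unname(lapply(split(df, factor(key, levels = unique(key))), function(g)
    tac(g$patient_id[1], g$cycle[1], g$voi_id[1], g$voi_type[1],
        g$time_h, g$activity_MBq)))
}

#' Write time-activity curves to CSV
#'
#' Inverse of [read_tac_csv()]; the round trip is lossless to full double
#' precision (values are written with 17 significant digits).
#'
#' @param curves List of [tac()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tac_csv <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, as.data.frame))
  df$time_h <- sprintf("%.17g", df$time_h)
  df$activity_MBq <- sprintf("%.17g", df$activity_MBq)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param input Path to a time-activity CSV, or `NULL` to simulate a cohort
#'   with `params`.
#' @param params A [cohort_params()] used when `input` is `NULL`.
#' @param output_dir Directory for the report bundle (created if needed).
#' @param times Nominal single-time-point scan times, hours.
#' @param window An [stp_window()].
#' @param ba_denominator Bland-Altman difference denominator:
#'   `"reference"` (default) or `"pair_mean"`.
#' @param time_tol_h Nominal-time matching tolerance, hours.
#' @param seed Overrides `params$seed` when simulating; ignored for CSV
#'   input.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(input = NULL, params = cohort_params(),
                       output_dir, times = c(24, 48, 72),
                       window = stp_window(),
                       ba_denominator = c("reference", "pair_mean"),
                       time_tol_h = 6, seed = NULL) {
  stopifnot(all(times > 0), !anyDuplicated(times))
  structure(list(input = input, params = params, output_dir = output_dir,
                 times = times, window = window,
                 ba_denominator = match.arg(ba_denominator),
                 time_tol_h = time_tol_h, seed = seed),
            class = "run_config")
}

#' Run the full STP-versus-MTP comparison pipeline
#'
#' Loads (or simulates) the cohort, fits every curve, computes all three TIA
#' estimators, and writes the report bundle: `fits.csv`,
#' `pd_records.csv` (per-VOI comparison records), `bland_altman.csv`,
#' `coverage.csv`, `window_coverage.csv`, `wilcoxon.csv`,
#' `half_life_changes.csv` and `manifest.json`. All tables are
#' deterministic functions of the configuration and seed; wall-clock
#' timestamps appear only in the manifest. On any stage failure the
#' partially written bundle files are removed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`curves`, `fits`,
#'   `records`, and the summary tables) and `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- c("fits.csv", "pd_records.csv", "bland_altman.csv",
              "coverage.csv", "window_coverage.csv", "wilcoxon.csv",
              "half_life_changes.csv", "manifest.json")
  paths <- file.path(config$output_dir, bundle)
  stage <- "setup"
  tryCatch({
    stage <- "input"
    curves <- if (is.null(config$input)) {
      p <- config$params
      if (!is.null(config$seed)) p$seed <- as.integer(config$seed)
      generate_cohort(p)
    } else {
      read_tac_csv(config$input)
    }
    stage <- "fit"
    fits <- fit_cohort(curves)
    ftab <- fit_table(fits)
    stage <- "compare"
    records <- compare_cohort(curves, times = config$times,
                              window = config$window,
                              time_tol_h = config$time_tol_h)
    stage <- "summarize"
    ba <- ba_table(records, config$ba_denominator)
    cov <- coverage_table(records)
    wct <- window_coverage_table(fits, times = config$times,
                                 window = config$window)
    wil <- wilcoxon_table(records)
    cyc <- vapply(fits, `[[`, 1L, "cycle")
    dec <- vapply(fits, `[[`, TRUE, "decaying")
    hlc <- suppressWarnings(
      half_life_change_stats(fits[cyc == 1L & dec], fits[cyc == 2L & dec]))
    stage <- "write"
    wcsv <- function(df, f) utils::write.csv(
      df, file.path(config$output_dir, f), row.names = FALSE)
    wcsv(ftab, "fits.csv"); wcsv(records, "pd_records.csv")
    wcsv(ba, "bland_altman.csv"); wcsv(cov, "coverage.csv")
    wcsv(wct, "window_coverage.csv"); wcsv(wil, "wilcoxon.csv")
    wcsv(hlc$changes, "half_life_changes.csv")
    manifest <- list(
      package = "stpdosim",
      version = as.character(utils::packageVersion("stpdosim")),
      created = format(Sys.time(), tz = "UTC"),
      input = config$input %||% "simulated",
      seed = config$seed %||% config$params$seed,
      times = config$times,
      window = unclass(config$window),
      ba_denominator = config$ba_denominator,
      time_tol_h = config$time_tol_h,
      n_curves = length(curves),
      half_life_changes_exceeding_20pct = hlc$n_exceed_20)
    jsonlite::write_json(manifest, file.path(config$output_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(curves = curves, fits = fits, records = records,
                   bland_altman = ba, coverage = cov,
                   window_coverage = wct, wilcoxon = wil,
                   half_life_changes = hlc,
                   output_dir = config$output_dir))
  }, error = function(e) {
    unlink(paths[file.exists(paths)])
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

ba_table <- function(records, denominator = "reference") {
  if (nrow(records) == 0)
    return(data.frame(voi_type = character(), method = character(),
                      nominal_time_h = numeric(), n = integer(),
                      mean_diff_percent = numeric(),
                      sd_diff_percent = numeric(),
                      loa_low_percent = numeric(),
                      loa_high_percent = numeric(),
                      stringsAsFactors = FALSE))
  key <- interaction(records$voi_type, records$method,
                     records$nominal_time_h, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    if (nrow(g) < 2) return(NULL)
    s <- bland_altman_summary(pd_percent = g$pd_percent,
                              stp = g$tia_stp_MBq_h, ref = g$tia_ref_MBq_h,
                              denominator = denominator)
    data.frame(voi_type = g$voi_type[1], method = g$method[1],
               nominal_time_h = g$nominal_time_h[1], n = s$n,
               mean_diff_percent = s$mean_diff_percent,
               sd_diff_percent = s$sd_diff_percent,
               loa_low_percent = s$loa_low_percent,
               loa_high_percent = s$loa_high_percent,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$voi_type, out$method, out$nominal_time_h), ]
  rownames(out) <- NULL
  out
}

wilcoxon_table <- function(records) {
  if (nrow(records) == 0)
    return(data.frame(voi_type = character(), method = character(),
                      nominal_time_h = numeric(), n_used = integer(),
                      statistic_W = numeric(), p_value = numeric(),
                      p_method = character(), stringsAsFactors = FALSE))
  key <- interaction(records$voi_type, records$method,
                     records$nominal_time_h, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    w <- wilcoxon_signed_rank(g$tia_stp_MBq_h, g$tia_ref_MBq_h)
    data.frame(voi_type = g$voi_type[1], method = g$method[1],
               nominal_time_h = g$nominal_time_h[1], n_used = w$n_used,
               statistic_W = w$statistic_W, p_value = w$p_value,
               p_method = w$method, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$voi_type, out$method, out$nominal_time_h), ]
  rownames(out) <- NULL
  out
}
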