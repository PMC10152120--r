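test_that("percent_difference is guarded arithmetic", {
  src <- list(patient_id = "p", cycle = 2L, voi_id = "v")
  mk <- function(v, method = "MTP_ref", t = NA_real_)
    stpdosim:::new_tia(v, method, t, "p", 2L, "v")
  expect_equal(percent_difference(mk(110, "STP_H", 48), mk(100)), 10)
  expect_equal(percent_difference(mk(100, "STP_H", 48), mk(100)), 0)
  expect_equal(percent_difference(mk(6924.9, "STP_H", 48), mk(4688.8)),
               47.69, tolerance = 0.05 / 47.69)
  expect_error(percent_difference(mk(1, "STP_H", 48), mk(1, "STP_H", 48)),
               "MTP_ref")
  expect_error(percent_difference(mk(1, "STP_H", 48), mk(0)), "positive")
  other <- stpdosim:::new_tia(100, "MTP_ref", NA_real_, "q", 2L, "v")
  expect_error(percent_difference(mk(1, "STP_H", 48), other), "different")
})

test_that("compare_cohort composes the estimators as expected", {
  curves <- list(exact_tac(100, 32.5, c(24, 48, 72), cycle = 1L),
                 exact_tac(100, 32.5, c(24, 48, 72), cycle = 2L))
  rec <- compare_cohort(curves)
  expect_equal(nrow(rec), 6)
  prior <- rec[rec$method == "STP_prior", ]
  expect_true(all(abs(prior$pd_percent) < 1e-9))
  h <- rec[rec$method == "STP_H", ]
  expect_equal(h$pd_percent,
               100 * stp_h_relative_error(c(24, 48, 72) / 32.5),
               tolerance = 1e-9)
  expect_true(all(rec$within_10 <= rec$within_20))
  expect_equal(compare_cohort(list()) |> nrow(), 0)
})

test_that("compare_cohort counts records and handles missing priors", {
  curves <- list()
  for (p in c("A", "B")) for (k in c("kidney_left", "kidney_right"))
    for (cc in 1:2)
      curves[[length(curves) + 1]] <-
        exact_tac(100, 30, c(24, 48, 72), patient = p, cycle = cc,
                  voi = k, type = k)
  rec <- compare_cohort(curves)
  expect_equal(nrow(rec), 24)  # 2 patients x 2 kidneys x 3 times x 2 methods
  # drop one patient's cycle 1: that patient keeps only Hanscheid records
  keep <- !(vapply(curves, function(x) x$patient_id, "") == "B" &
              vapply(curves, function(x) x$cycle, 1L) == 1L)
  ws <- capture_warnings(rec2 <- compare_cohort(curves[keep]))
  expect_true(all(grepl("STP_prior skipped", ws)))
  expect_length(ws, 2)  # one per missing kidney prior
  expect_equal(sum(rec2$method == "STP_prior" & rec2$patient_id == "B"), 0)
  expect_equal(sum(rec2$method == "STP_H" & rec2$patient_id == "B"), 6)
})

test_that("samples outside the nominal-time tolerance are skipped", {
  curves <- list(exact_tac(100, 30, c(24, 48), cycle = 1L),
                 exact_tac(100, 30, c(24, 48), cycle = 2L))
  expect_warning(rec <- compare_cohort(curves, times = c(24, 48, 72)),
                 "no sample within")
  expect_equal(sort(unique(rec$nominal_time_h)), c(24, 48))
})

test_that("Bland-Altman summary matches hand-computed values", {
  s <- bland_altman_summary(c(10, -10, 0))
  expect_equal(s$n, 3)
  expect_equal(s$mean_diff_percent, 0)
  expect_equal(s$sd_diff_percent, 10)  # sqrt((100+100+0)/2)
  expect_equal(s$loa_low_percent, -19.6)
  expect_equal(s$loa_high_percent, 19.6)
  s2 <- bland_altman_summary(c(5, 5, 5))
  expect_equal(c(s2$mean_diff_percent, s2$sd_diff_percent,
                 s2$loa_low_percent, s2$loa_high_percent), c(5, 0, 5, 5))
  s3 <- bland_altman_summary(c(0, 0))
  expect_equal(s3$loa_low_percent, 0)
  expect_error(bland_altman_summary(5), "at least 2")
  # LoA symmetry about the mean, and mean is the plain average of the PDs
  set.seed(3)
  pd <- rnorm(40, 2, 8)
  s4 <- bland_altman_summary(pd)
  expect_equal(s4$mean_diff_percent, mean(pd))
  expect_equal(s4$loa_high_percent - s4$mean_diff_percent,
               s4$mean_diff_percent - s4$loa_low_percent)
  # pair-mean denominator variant
  s5 <- bland_altman_summary(stp = c(110, 90), ref = c(100, 100),
                             denominator = "pair_mean")
  expect_equal(s5$mean_diff_percent,
               mean(100 * c(10 / 105, -10 / 95)))
})

test_that("Wilcoxon signed-rank reproduces enumeration examples", {
  w <- wilcoxon_signed_rank(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$statistic_W, 0)
  expect_equal(w$p_value, 0.25)
  expect_identical(w$method, "exact")
  w2 <- wilcoxon_signed_rank(c(10, 20, 30, 40, 50, 60), c(1, 2, 3, 4, 5, 6))
  expect_equal(w2$statistic_W, 21)
  expect_equal(w2$p_value, 2 / 64)
  wd <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(wd$degenerate)
  expect_equal(wd$p_value, 1)
  expect_equal(wd$n_used, 0L)
})

test_that("Wilcoxon agrees with the brute-force sign-enumeration oracle", {
  set.seed(5)
  for (n in 2:8) {
    for (rep in 1:6) {
      d <- round(rnorm(n, 0, 3), if (rep %% 2) 0 else 2)  # ties when rounded
      d <- d[d != 0]
      if (length(d) < 1) next
      w <- wilcoxon_signed_rank(d, rep(0, length(d)))
      o <- wilcoxon_enum_oracle(d)
      expect_equal(w$statistic_W, o$W)
      expect_equal(w$p_value, o$p, tolerance = 1e-12)
    }
  }
  # distinct magnitudes also agree with the standard exact implementation
  set.seed(6)
  x <- rnorm(10); y <- rnorm(10)
  w <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("normal approximation takes over for large n", {
  set.seed(8)
  x <- rnorm(40, 0.3); y <- rnorm(40)
  w <- wilcoxon_signed_rank(x, y)
  expect_identical(w$method, "normal-approximation")
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("coverage table counts inclusively and is permutation invariant", {
  mk_rec <- function(pd) data.frame(
    patient_id = "p", voi_id = paste0("v", seq_along(pd)),
    voi_type = "lesion", method = "STP_H", nominal_time_h = 48,
    time_used_h = 48, tia_ref_MBq_h = 1, tia_stp_MBq_h = 1,
    pd_percent = pd, within_10 = abs(pd) <= 10, within_20 = abs(pd) <= 20,
    in_window = TRUE, stringsAsFactors = FALSE)
  ct <- coverage_table(mk_rec(c(5, -15, 25)))
  expect_equal(ct$frac_within_10, 1 / 3)
  expect_equal(ct$frac_within_20, 2 / 3)
  ct0 <- coverage_table(mk_rec(c(0, 0, 0)))
  expect_equal(c(ct0$frac_within_10, ct0$frac_within_20), c(1, 1))
  ctb <- coverage_table(mk_rec(c(10, -10, 20, -20)))
  expect_equal(c(ctb$frac_within_10, ctb$frac_within_20), c(0.5, 1))
  r <- mk_rec(c(3, 12, -25, 8, 19))
  expect_equal(coverage_table(r[sample(5), ]), coverage_table(r))
  expect_true(all(coverage_table(r)$frac_within_10 <=
                    coverage_table(r)$frac_within_20))
})

test_that("window coverage table applies the interval rule per stratum", {
  fits <- lapply(c(10, 30, 100), function(T)
    fit_monoexponential(exact_tac(100, T, c(24, 48, 72), cycle = 1L,
                                  voi = paste0("v", T))))
  wt <- window_coverage_table(fits, times = 24)
  expect_equal(wt$n, 3)
  expect_equal(wt$n_in_window, 2)  # T = 10 and 30 in, T = 100 out
  expect_equal(wt$pct_in_window, 67)
})

test_that("half-life change counting is strict at 20 percent", {
  mkfit <- function(T, cc, v) fit_monoexponential(
    exact_tac(100, T, c(24, 48, 72), cycle = cc, voi = v))
  f1 <- list(mkfit(50, 1L, "a"), mkfit(50, 1L, "b"), mkfit(50, 1L, "c"))
  f2 <- list(mkfit(40, 2L, "a"), mkfit(39, 2L, "b"), mkfit(50, 2L, "c"))
  s <- half_life_change_stats(f1, f2)
  expect_equal(sort(s$changes$change_percent), c(-22, -20, 0),
               tolerance = 1e-6)
  expect_equal(s$n_exceed_20, 1)  # only -22% is strictly beyond the bound
  # unmatched VOIs are dropped with a warning
  expect_warning(s2 <- half_life_change_stats(f1[1:2], f2), "skipped")
  expect_equal(nrow(s2$changes), 2)
})
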