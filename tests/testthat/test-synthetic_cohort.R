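test_that("cohort generation is a pure function of its seed", {
  p <- cohort_params(n_patients = 6, seed = 123)
  expect_identical(generate_cohort(p), generate_cohort(p))
  other <- generate_cohort(cohort_params(n_patients = 6, seed = 124))
  a1 <- unlist(lapply(generate_cohort(p), `[[`, "activity_MBq"))
  a2 <- unlist(lapply(other, `[[`, "activity_MBq"))
  expect_false(isTRUE(all.equal(mean(a1), mean(a2), tolerance = 1e-12)))
})

test_that("simulated measurements follow the noise model", {
  # noiseless samples sit exactly on the curve
  sm <- simulate_measurements(100, 32.5, c(24, 48, 72), noise_cv = 0)
  expect_equal(sm$activity_MBq, c(59.94, 35.92, 21.53), tolerance = 1e-3)
  # empirical CV of the multiplicative noise matches the requested CV and
  # the noise is mean-unbiased on the linear scale
  set.seed(21)
  reps <- replicate(1e4,
    simulate_measurements(100, 32.5, 48, noise_cv = 0.05)$activity_MBq)
  expect_gt(sd(reps) / mean(reps), 0.045)
  expect_lt(sd(reps) / mean(reps), 0.055)
  expect_equal(mean(reps), 100 * 2^(-48 / 32.5), tolerance = 0.005)
  expect_error(simulate_measurements(100, 32.5, 48, noise_cv = -1))
})

test_that("sampled half-lives respect their truncation ranges", {
  p <- cohort_params(n_patients = 40, seed = 9)
  truth <- attr(generate_cohort(p), "truth")
  for (cc in 1:2) {
    kd <- truth[truth$voi_type %in% c("kidney_left", "kidney_right") &
                  truth$cycle == cc, "half_life_h"]
    rng <- p$kidney_half_life_h[[paste0("c", cc)]]
    expect_true(all(kd >= rng["lo"] & kd <= rng["hi"]))
    ls <- truth[truth$voi_type == "lesion" & truth$cycle == cc,
                "half_life_h"]
    rng <- p$lesion_half_life_h[[paste0("c", cc)]]
    expect_true(all(ls >= rng["lo"] & ls <= rng["hi"]))
  }
  expect_error(cohort_params(kidney_half_life_h = list(
    c1 = c(mean = 10, sd = 1, lo = 20, hi = 30),
    c2 = c(mean = 25, sd = 1, lo = 20, hi = 30))), "contain the mean")
})

test_that("population mean of kidney half-lives matches the target", {
  truth <- attr(generate_cohort(cohort_params(n_patients = 200, seed = 4)),
                "truth")
  kd <- truth[truth$voi_type %in% c("kidney_left", "kidney_right") &
                truth$cycle == 1, "half_life_h"]
  # truncation pulls the realized mean slightly toward the center; stay
  # within 3 standard errors of the nominal 32.5 h population mean
  expect_lt(abs(mean(kd) - 32.5), 3 * 7.0 / sqrt(length(kd)))
})

test_that("TB_FOV curve is the sample-wise sum of the lesion curves", {
  co <- generate_cohort(cohort_params(n_patients = 10, seed = 2))
  pid <- vapply(co, `[[`, "", "patient_id")
  typ <- vapply(co, `[[`, "", "voi_type")
  cyc <- vapply(co, `[[`, 1L, "cycle")
  checked <- 0
  for (p in unique(pid)) for (cc in 1:2) {
    tb <- co[pid == p & cyc == cc & typ == "tb_fov"]
    les <- co[pid == p & cyc == cc & typ == "lesion"]
    if (length(tb) == 0) { expect_equal(length(les), 0); next }
    sum_les <- Reduce(`+`, lapply(les, `[[`, "activity_MBq"))
    expect_equal(tb[[1]]$activity_MBq, sum_les, tolerance = 1e-12)
    expect_equal(tb[[1]]$time_h, les[[1]]$time_h)
    checked <- checked + 1
  }
  expect_gt(checked, 5)
})

test_that("cohort structure mirrors the study design", {
  co <- generate_cohort(cohort_params(n_patients = 50, seed = 31))
  df <- do.call(rbind, lapply(co, as.data.frame))
  per <- unique(df[, c("patient_id", "cycle", "voi_id", "voi_type")])
  nles <- table(factor(per$patient_id[per$voi_type == "lesion" &
                                        per$cycle == 1],
                       levels = unique(per$patient_id)))
  expect_true(all(nles <= 6))
  nkid <- tapply(per$voi_type[per$cycle == 1] %in%
                   c("kidney_left", "kidney_right"),
                 per$patient_id[per$cycle == 1], sum)
  expect_true(all(nkid %in% c(1, 2)))
  expect_true(any(nkid == 1))  # some patients have a single active kidney
  # shared scan session: all VOIs of a patient-cycle share the same times
  t1 <- df[df$patient_id == df$patient_id[1] & df$cycle == 1, ]
  expect_equal(length(unique(tapply(t1$time_h, t1$voi_id,
                                    paste, collapse = ","))), 1)
})

test_that("noiseless identical-kinetics cohorts make STP_prior exact", {
  p <- cohort_params(
    n_patients = 8, noise_cv = 0, intercycle_correlation = 1,
    kidney_half_life_h = list(c1 = c(mean = 32.5, sd = 7, lo = 17.8, hi = 51.9),
                              c2 = c(mean = 32.5, sd = 7, lo = 17.8, hi = 51.9)),
    lesion_half_life_h = list(c1 = c(mean = 69, sd = 40, lo = 20.1, hi = 249.7),
                              c2 = c(mean = 69, sd = 40, lo = 20.1, hi = 249.7)),
    jitter_h = 0, seed = 17)
  rec <- compare_cohort(generate_cohort(p))
  prior <- rec[rec$method == "STP_prior" & rec$voi_type != "tb_fov", ]
  expect_gt(nrow(prior), 0)
  expect_true(all(abs(prior$pd_percent) < 1e-9))
})
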