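test_that("CSV round trip preserves a simulated cohort", {
  sim <- small_cohort(n = 8, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_bp_series(sim$series, path)
  back <- read_bp_series(path)
  expect_equal(back$patient_id, sim$series$patient_id)
  expect_equal(back$time, sim$series$time)
  expect_equal(back$sbp, sim$series$sbp, tolerance = 1e-12)
  expect_equal(back$artifact_truth, sim$series$artifact_truth)
})

test_that("reader enforces mandatory columns and re-sorts shuffled rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(patient_id = "a", sbp_mmhg = 120), path)
  expect_error(read_bp_series(path), "timestamp")

  s <- toy_series(c(30, 0, 15), c(120, 121, 122))[c(1, 2, 3), ]
  write_bp_series(s, path)
  expect_warning(out <- read_bp_series(path), "re-sorted")
  expect_false(is.unsorted(out$time))
  expect_equal(nrow(out), 3)
})

test_that("single-patient three-row file reads as one series of length 3", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_bp_series(toy_series(c(0, 15, 30), c(120, 125, 118)), path)
  out <- read_bp_series(path)
  expect_equal(nrow(out), 3)
  expect_equal(unique(out$patient_id), "P0001")
})

test_that("bound violations and pressure inversions are flagged", {
  s <- toy_series(seq(0, 60, by = 15), c(120, 300, 118, 50, 121),
                  dbp = c(70, 72, 130, 40, 71))
  out <- flag_artifacts(s)
  expect_equal(out$flag, c("valid", "artifact", "artifact", "artifact", "valid"))
})

test_that("a constant physiologic series gets zero flags", {
  s <- toy_series(seq(0, 600, by = 15), rep(125, 41), dbp = rep(75, 41))
  expect_true(all(flag_artifacts(s)$flag == "valid"))
})

test_that("spike rule needs both neighbours close in time and value-distant", {
  # 1-min spacing: middle reading jumps 80 mmHg against both neighbours
  s <- toy_series(0:4, c(120, 121, 201, 122, 120), dbp = rep(70, 5),
                  source = "invasive")
  out <- flag_artifacts(s)
  expect_equal(out$flag[3], "artifact")
  # same values 15 min apart: neighbours too far for the spike rule
  s2 <- toy_series(seq(0, 60, 15), c(120, 121, 201, 122, 120), dbp = rep(70, 5))
  expect_true(all(flag_artifacts(s2)$flag == "valid"))
})

test_that("flagging is idempotent", {
  sim <- small_cohort(n = 10, seed = 8)
  once <- flag_artifacts(sim$series)
  twice <- flag_artifacts(once)
  expect_identical(once, twice)
})

test_that("flagging recovers injected artifacts with sensitivity >= 0.95", {
  sim <- small_cohort(n = 40, seed = 13, artifact_rate = 0.03)
  out <- flag_artifacts(sim$series)
  truth <- out$artifact_truth == 1L
  expect_gt(sum(truth), 50)
  sens <- mean(out$flag[truth] == "artifact")
  expect_gte(sens, 0.95)
})

test_that("density is 1 for a complete schedule and 0.5 when half is missing", {
  offs <- schedule_offsets("cuff", 72)
  full <- toy_series(offs, rep(120, length(offs)), dbp = rep(70, length(offs)),
                     admission = t0_utc("2024-03-04 00:00:00"))
  d <- measurement_density(full)
  expect_equal(d$density, 1)
  half <- full[seq_len(nrow(full)) %% 2 == 1, ]
  d2 <- measurement_density(half, admissions = tibble::tibble(
    patient_id = "P0001", admission_time = t0_utc("2024-03-04 00:00:00")))
  expect_equal(d2$density, 0.5, tolerance = 0.01)
})

test_that("density is monotone non-increasing as readings are removed", {
  sim <- small_cohort(n = 8, seed = 4)
  s <- flag_artifacts(sim$series)
  adm <- tibble::tibble(
    patient_id = unique(s$patient_id),
    admission_time = tapply(s$time, s$patient_id, min) |>
      (\(x) as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC"))()
  )
  d_full <- measurement_density(s, admissions = adm)
  withr::with_seed(1, {
    drop <- sample(nrow(s), nrow(s) %/% 4)
  })
  d_less <- measurement_density(s[-drop, ], admissions = adm)
  j <- dplyr::inner_join(d_full, d_less, by = "patient_id")
  expect_true(all(j$density.y <= j$density.x + 1e-12))
})

test_that("a complete 72-h series is eligible", {
  offs <- schedule_offsets("cuff", 72)
  s <- toy_series(offs, 120 + 5 * sin(offs / 200), dbp = rep(70, length(offs)),
                  admission = t0_utc("2024-03-04 00:00:00"))
  qc <- check_eligibility(s)
  expect_true(qc$eligible)
  expect_equal(qc$exclusion_reasons, "")
})

test_that("inadequate night coverage and missingness trigger the stated reasons", {
  offs <- schedule_offsets("cuff", 72)
  base <- toy_series(offs, rep(120, length(offs)), dbp = rep(70, length(offs)),
                     admission = t0_utc("2024-03-04 00:00:00"))
  adm <- tibble::tibble(patient_id = "P0001",
                        admission_time = t0_utc("2024-03-04 00:00:00"))
  # remove 14 h of the second cycle -> only 10 h of coverage that night
  el <- as.numeric(difftime(base$time, adm$admission_time, units = "hours"))
  gap <- base[!(el >= 24 & el < 38), ]
  qc <- check_eligibility(gap, admissions = adm)
  expect_false(qc$eligible)
  expect_match(qc$exclusion_reasons, "night_coverage")

  # scatter 25% missingness without killing any hour bin
  withr::with_seed(2, {
    drop <- sample(nrow(base), round(0.25 * nrow(base)))
  })
  sparse <- base[-drop, ]
  qc2 <- check_eligibility(sparse, admissions = adm)
  expect_match(qc2$exclusion_reasons, "missingness")

  # span below 48 h
  short <- base[el < 40, ]
  qc3 <- check_eligibility(short, admissions = adm)
  expect_match(qc3$exclusion_reasons, "span")
})

test_that("eligibility depends on coverage only, not on BP values", {
  sim <- small_cohort(n = 8, seed = 6)
  s <- flag_artifacts(sim$series)
  q1 <- check_eligibility(s)
  s2 <- s
  s2$sbp <- s2$sbp + 30
  s2$dbp <- s2$dbp + 10
  q2 <- check_eligibility(s2)
  expect_equal(q1$eligible, q2$eligible)
  expect_equal(q1$exclusion_reasons, q2$exclusion_reasons)
})

test_that("no injected gap interval exceeds the configured maximum", {
  cc <- cohort_config(n_patients = 15, seed = 11, artifact_rate = 0,
                      gap_process = list(rate_per_hour = 0.005, rate_shape = 50,
                                         mean_minutes = 300, max_minutes = 120))
  sim <- generate_cohort(cc)
  # with a sparse gap process, observed missing runs are single injected gaps
  runs <- sim$series |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(longest = max(diff(as.numeric(time)) / 60), .groups = "drop")
  # a cuff slot is 30 min; a truncated 120-min gap spans at most 120 + 30 min
  expect_true(all(runs$longest <= 120 + 30 + 1e-9))
})
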