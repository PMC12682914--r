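#' Read blood-pressure series from CSV
#'
#' Expects the long dialect written by [write_bp_series()]: columns
#' `patient_id`, `timestamp` (ISO-8601, local clock), `sbp_mmhg`, `dbp_mmhg`,
#' `source` and optionally `flag` and `artifact_truth`. Rows whose timestamp
#' cannot be parsed are dropped with a message; rows out of time order are
#' re-sorted with a warning.
#'
#' @param path CSV file path.
#' @param tz timezone the clock times are interpreted in.
#' @return a tibble with columns `patient_id`, `time`, `sbp`, `dbp`,
#'   `source`, `flag` (and `artifact_truth` when present).
#' @export
read_bp_series <- function(path, tz = "UTC") {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("patient_id", "timestamp", "sbp_mmhg", "dbp_mmhg", "source")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("missing mandatory column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  time <- as.POSIXct(raw$timestamp, tz = tz,
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  bad <- is.na(time) & !is.na(raw$timestamp)
  if (any(bad)) {
    message(sprintf("dropped %d row(s) with unparseable timestamps", sum(bad)))
  }
  out <- tibble::tibble(
    patient_id = as.character(raw$patient_id)[!bad],
    time = time[!bad],
    sbp = as.numeric(raw$sbp_mmhg)[!bad],
    dbp = as.numeric(raw$dbp_mmhg)[!bad],
    source = as.character(raw$source)[!bad],
    flag = if ("flag" %in% names(raw)) as.character(raw$flag)[!bad] else "valid"
  )
  if ("artifact_truth" %in% names(raw)) {
    out$artifact_truth <- as.integer(raw$artifact_truth)[!bad]
  }
  unsorted <- out |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$time), .groups = "drop")
  if (any(!unsorted$ok)) {
    warning("readings out of time order; series re-sorted", call. = FALSE)
  }
  dplyr::arrange(out, .data$patient_id, .data$time)
}

#' Write blood-pressure series to CSV
#'
#' @param series a series tibble (internal column names).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bp_series <- function(series, path) {
  out <- tibble::tibble(
    patient_id = series$patient_id,
    timestamp = format(series$time, "%Y-%m-%dT%H:%M:%S"),
    sbp_mmhg = series$sbp,
    dbp_mmhg = series$dbp,
    source = series$source,
    flag = if ("flag" %in% names(series)) series$flag else "valid"
  )
  if ("artifact_truth" %in% names(series)) {
    out$artifact_truth <- series$artifact_truth
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Flag artefactual readings
#'
#' Recomputes artifact flags from scratch (so the operation is idempotent):
#' a reading is an artifact if systolic or diastolic BP falls outside the
#' physiologic bounds, if `dbp >= sbp`, or if its systolic value jumps by more
#' than `max_step` against *both* temporal neighbours when those neighbours
#' are within `step_window_min` minutes (a spike rule that effectively applies
#' to high-frequency invasive data). Imputed rows are never flagged.
#'
#' @param series a series tibble.
#' @param sbp_bounds,dbp_bounds physiologic bounds, mmHg.
#' @param max_step maximal plausible systolic step against both neighbours,
#'   mmHg.
#' @param step_window_min neighbour proximity required for the spike rule,
#'   minutes.
#' @return the series with an updated `flag` column
#'   (`valid` / `artifact` / `imputed`).
#' @export
flag_artifacts <- function(series, sbp_bounds = c(60, 260),
                           dbp_bounds = c(30, 150),
                           max_step = 60, step_window_min = 5) {
  if (nrow(series) == 0) stop("`series` is empty", call. = FALSE)
  series <- dplyr::arrange(series, .data$patient_id, .data$time)
  imputed <- series$flag == "imputed"
  bound_bad <- series$sbp < sbp_bounds[1] | series$sbp > sbp_bounds[2] |
    series$dbp < dbp_bounds[1] | series$dbp > dbp_bounds[2] |
    series$dbp >= series$sbp
  bound_bad[imputed] <- FALSE

  spike <- series |>
    dplyr::mutate(.bad = bound_bad, .imp = imputed) |>
    dplyr::filter(!.data$.bad, !.data$.imp) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(
      .dt_prev = as.numeric(difftime(.data$time, dplyr::lag(.data$time), units = "mins")),
      .dt_next = as.numeric(difftime(dplyr::lead(.data$time), .data$time, units = "mins")),
      .d_prev = abs(.data$sbp - dplyr::lag(.data$sbp)),
      .d_next = abs(dplyr::lead(.data$sbp) - .data$sbp),
      .spike = !is.na(.data$.d_prev) & !is.na(.data$.d_next) &
        .data$.dt_prev <= step_window_min & .data$.dt_next <= step_window_min &
        .data$.d_prev > max_step & .data$.d_next > max_step
    ) |>
    dplyr::ungroup()

  flag <- rep("valid", nrow(series))
  flag[imputed] <- "imputed"
  flag[bound_bad] <- "artifact"
  spike_rows <- which(!bound_bad & !imputed)[spike$.spike]
  flag[spike_rows] <- "artifact"
  series$flag <- flag
  series
}

#' Measurement density
#'
#' Fraction of the readings expected under the source's nominal schedule that
#' are present and valid within a window of the monitoring span.
#'
#' @param series a series tibble (artifact flags applied).
#' @param window numeric `c(start, end)` in hours since admission; default the
#'   full 72-h span.
#' @param admissions optional tibble `patient_id` / `admission_time`; by
#'   default the first reading per patient.
#' @param schedule nominal schedule parameters (see [schedule_offsets()]).
#' @param count_imputed whether imputed readings count as present (used for
#'   the post-imputation missingness rule).
#' @return a tibble `patient_id`, `n_expected`, `n_present`, `density`.
#' @export
measurement_density <- function(series, window = c(0, 72), admissions = NULL,
                                schedule = list(invasive_min = 1,
                                                cuff_first24_min = 15,
                                                cuff_later_min = 30),
                                count_imputed = FALSE) {
  adm <- resolve_admissions(series, admissions)
  ok_flags <- if (count_imputed) c("valid", "imputed") else "valid"
  series |>
    dplyr::left_join(adm, by = "patient_id") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      source = .data$source[1],
      n_present = {
        el <- elapsed_hours(.data$time, .data$admission_time[1])
        sum(.data$flag %in% ok_flags & el >= window[1] & el < window[2])
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_expected = vapply(.data$source, function(src) {
        offs <- schedule_offsets(src, max(window[2], 72), schedule) / 60
        sum(offs >= window[1] & offs < window[2])
      }, numeric(1), USE.NAMES = FALSE),
      density = ifelse(.data$n_expected == 0, NA_real_,
                       pmin(1, .data$n_present / .data$n_expected))
    ) |>
    dplyr::select("patient_id", "n_expected", "n_present", "density") |>
    (\(x) {
      if (any(x$n_expected == 0)) {
        stop("window contains no expected readings", call. = FALSE)
      }
      x
    })()
}

#' Eligibility check
#'
#' Applies the monitoring-adequacy rules after flagging and imputation: a
#' patient is ineligible if the monitored span is below `min_span_hours`, if
#' any complete 24-h monitoring cycle has fewer than `min_hours_per_night`
#' hour bins containing a usable reading, or if post-imputation missingness
#' (1 - density counting imputed readings) exceeds `max_missing`. The
#' decision depends only on reading presence, never on BP values.
#'
#' @param series a series tibble with flags (and imputed rows, if any).
#' @param admissions optional admission-time table.
#' @param min_span_hours minimal monitored span, hours.
#' @param min_hours_per_night minimal covered hours per 24-h cycle.
#' @param max_missing maximal post-imputation missing fraction.
#' @param n_cycles number of 24-h cycles checked for coverage.
#' @param schedule nominal schedule parameters.
#' @return a QC tibble: per patient the overall density (with and without
#'   imputed readings), hours covered per cycle, `eligible` and a
#'   comma-separated `exclusion_reasons` string (empty when eligible).
#' @export
check_eligibility <- function(series, admissions = NULL,
                              min_span_hours = 48,
                              min_hours_per_night = 12,
                              max_missing = 0.20,
                              n_cycles = 3,
                              schedule = list(invasive_min = 1,
                                              cuff_first24_min = 15,
                                              cuff_later_min = 30)) {
  adm <- resolve_admissions(series, admissions)
  dens_post <- measurement_density(series, admissions = adm,
                                   schedule = schedule, count_imputed = TRUE)
  dens_pre <- measurement_density(series, admissions = adm,
                                  schedule = schedule, count_imputed = FALSE)

  cov <- series |>
    dplyr::left_join(adm, by = "patient_id") |>
    dplyr::filter(.data$flag %in% c("valid", "imputed")) |>
    dplyr::mutate(el = elapsed_hours(.data$time, .data$admission_time)) |>
    dplyr::filter(.data$el >= 0, .data$el < 24 * n_cycles) |>
    dplyr::mutate(cycle = pmin(n_cycles, 1L + floor(.data$el / 24)),
                  hour_bin = floor(.data$el)) |>
    dplyr::group_by(.data$patient_id, .data$cycle) |>
    dplyr::summarise(hours = dplyr::n_distinct(.data$hour_bin),
                     .groups = "drop") |>
    tidyr::complete(patient_id = adm$patient_id,
                    cycle = seq_len(n_cycles),
                    fill = list(hours = 0L))

  span <- series |>
    dplyr::filter(.data$flag %in% c("valid", "imputed")) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(span_hours = as.numeric(difftime(max(.data$time),
                                                      min(.data$time),
                                                      units = "hours")),
                     .groups = "drop")

  min_cov <- cov |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(min_hours_night = min(.data$hours), .groups = "drop")

  out <- dens_post |>
    dplyr::rename(density_post = "density") |>
    dplyr::select("patient_id", "density_post") |>
    dplyr::left_join(dplyr::select(dens_pre, "patient_id", density_pre = "density"),
                     by = "patient_id") |>
    dplyr::left_join(span, by = "patient_id") |>
    dplyr::left_join(min_cov, by = "patient_id") |>
    dplyr::mutate(
      missing_post = 1 - .data$density_post,
      reason_span = .data$span_hours < min_span_hours,
      reason_night = .data$min_hours_night < min_hours_per_night,
      reason_missing = .data$missing_post > max_missing
    )
  reasons <- mapply(function(a, b, c) {
    paste(c(if (a) "span", if (b) "night_coverage", if (c) "missingness"),
          collapse = ",")
  }, out$reason_span, out$reason_night, out$reason_missing)
  out |>
    dplyr::mutate(exclusion_reasons = unname(reasons),
                  eligible = .data$exclusion_reasons == "") |>
    dplyr::select("patient_id", "density_pre", "density_post",
                  "span_hours", "min_hours_night", "missing_post",
                  "eligible", "exclusion_reasons")
}
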