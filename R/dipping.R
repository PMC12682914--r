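# mean of cos(w (t - phi)) over a clock window [w1, w2) (w2 may exceed 24
# for windows crossing midnight); closed-form integral of the cosine
window_cos_frac <- function(acrophase, window) {
  w1 <- window[1]
  w2 <- window[2]
  if (w2 <= w1) w2 <- w2 + 24
  (sin(OMEGA24 * (w2 - acrophase)) - sin(OMEGA24 * (w1 - acrophase))) /
    (OMEGA24 * (w2 - w1))
}

#' Mean of a fitted cosinor curve over a clock window
#'
#' Closed-form time average of `M + A cos(w (t - phi))` over `[w1, w2)`.
#'
#' @param mesor,amplitude,acrophase cosinor parameters.
#' @param window clock window `c(start, end)`; an end at or before the start
#'   is taken to wrap past midnight.
#' @return the window mean, mmHg.
#' @export
cosinor_window_mean <- function(mesor, amplitude, acrophase, window) {
  if (amplitude == 0 || is.na(acrophase)) return(mesor)
  mesor + amplitude * window_cos_frac(acrophase, window)
}

#' Day and night mean systolic BP
#'
#' Either the analytic means of the fitted cosinor curve over the two clock
#' windows (`basis = "cosinor"`, the default, which smooths over short-term
#' variability) or arithmetic means of the valid/imputed readings falling in
#' each window (`basis = "raw"`).
#'
#' @param fit a `cosinor_fit` (or a list with `mesor`, `amplitude`,
#'   `acrophase`) for the cosinor basis.
#' @param series,cycle_window for the raw basis: the patient's series tibble
#'   and the elapsed-hour window `c(start, end)` of the cycle.
#' @param day_window,night_window non-overlapping clock windows; defaults
#'   09:00-21:00 and 21:00-09:00.
#' @param basis `"cosinor"` or `"raw"`.
#' @param admissions admission-time table (raw basis).
#' @return named numeric `c(day, night)`, mmHg.
#' @export
day_night_means <- function(fit = NULL, series = NULL, cycle_window = NULL,
                            day_window = c(9, 21), night_window = c(21, 9),
                            basis = c("cosinor", "raw"), admissions = NULL) {
  basis <- match.arg(basis)
  if (basis == "cosinor") {
    stopifnot(!is.null(fit))
    day <- cosinor_window_mean(fit$mesor, fit$amplitude, fit$acrophase, day_window)
    night <- cosinor_window_mean(fit$mesor, fit$amplitude, fit$acrophase, night_window)
  } else {
    stopifnot(!is.null(series))
    adm <- resolve_admissions(series, admissions)
    d <- series |>
      dplyr::filter(.data$flag %in% c("valid", "imputed")) |>
      dplyr::left_join(adm, by = "patient_id") |>
      dplyr::mutate(el = elapsed_hours(.data$time, .data$admission_time),
                    ch = clock_hours(.data$time))
    if (!is.null(cycle_window)) {
      d <- dplyr::filter(d, .data$el >= cycle_window[1], .data$el < cycle_window[2])
    }
    in_win <- function(ch, w) {
      if (w[2] <= w[1]) ch >= w[1] | ch < w[2] %% 24 else ch >= w[1] & ch < w[2]
    }
    night_r <- d$sbp[in_win(d$ch, night_window)]
    day_r <- d$sbp[in_win(d$ch, day_window)]
    if (length(night_r) == 0) stop("no readings in the night window", call. = FALSE)
    day <- mean(day_r)
    night <- mean(night_r)
  }
  c(day = unname(day), night = unname(night))
}

#' Nocturnal systolic decline
#'
#' `100 * (day - night) / day` percent; negative when night pressure exceeds
#' day pressure (nocturnal rise).
#'
#' @param day_mean,night_mean window mean systolic BP, mmHg.
#' @return decline in percent.
#' @export
nocturnal_decline <- function(day_mean, night_mean) {
  if (any(is.na(day_mean)) || any(day_mean <= 0)) {
    stop("`day_mean` must be positive", call. = FALSE)
  }
  100 * (day_mean - night_mean) / day_mean
}

#' Classify dipper status
#'
#' Step function on the nocturnal decline: `< 0` reverse-dipper, `[0, 10)`
#' non-dipper, `[10, 20)` dipper, `>= 20` extreme-dipper. With
#' `collapse_extreme = TRUE` extreme dippers are reported as dippers,
#' matching the conventional three-way tables.
#'
#' @param decline_pct nocturnal decline, percent.
#' @param collapse_extreme collapse the extreme-dipper band into `dipper`.
#' @return factor with levels `reverse-dipper`, `non-dipper`, `dipper` (and
#'   `extreme-dipper` unless collapsed).
#' @export
classify_dipping <- function(decline_pct, collapse_extreme = FALSE) {
  if (any(is.na(decline_pct)) || any(!is.finite(decline_pct))) {
    stop("`decline_pct` must be finite", call. = FALSE)
  }
  lv <- c("dipper", "non-dipper", "reverse-dipper",
          if (!collapse_extreme) "extreme-dipper")
  out <- ifelse(decline_pct < 0, "reverse-dipper",
                ifelse(decline_pct < 10, "non-dipper",
                       ifelse(decline_pct < 20 | collapse_extreme,
                              "dipper", "extreme-dipper")))
  factor(out, levels = lv)
}

#' Per-patient, per-night dipping results
#'
#' Applies [day_night_means()], [nocturnal_decline()] and
#' [classify_dipping()] to each successful cosinor cycle fit; night `n` is the
#' night of cycle `n`.
#'
#' @param fits output of [cosinor_fits()].
#' @param day_window,night_window clock windows.
#' @param collapse_extreme see [classify_dipping()].
#' @return tibble with `patient_id`, `night_index`, `daytime_mean_sbp`,
#'   `nighttime_mean_sbp`, `decline_pct`, `category`, `basis`.
#' @export
dipping_results <- function(fits, day_window = c(9, 21),
                            night_window = c(21, 9),
                            collapse_extreme = FALSE) {
  ok <- dplyr::filter(fits, is.na(.data$refused), .data$amplitude >= 0)
  purrr::pmap(
    list(ok$patient_id, ok$cycle_index, ok$mesor, ok$amplitude, ok$acrophase),
    function(pid, cyc, m, a, phi) {
      dn <- day_night_means(list(mesor = m, amplitude = a, acrophase = phi),
                            day_window = day_window,
                            night_window = night_window, basis = "cosinor")
      dec <- nocturnal_decline(dn[["day"]], dn[["night"]])
      tibble::tibble(patient_id = pid, night_index = cyc,
                     daytime_mean_sbp = dn[["day"]],
                     nighttime_mean_sbp = dn[["night"]],
                     decline_pct = dec,
                     category = classify_dipping(dec, collapse_extreme),
                     basis = "cosinor-fitted")
    }) |>
    dplyr::bind_rows()
}

#' Dipping-category prevalence
#'
#' Counts and percentages per dipper category for one night.
#'
#' @param x either a vector of categories (factor/character) or a named
#'   integer vector of counts (names = categories).
#' @param denominator denominator for the percentages; defaults to the number
#'   of classified patients (the count sum). Published tables occasionally
#'   pair category counts with a classified-patient denominator that differs
#'   by one or two, so it can be overridden.
#' @param digits rounding for the printed percentage (default 1 d.p.).
#' @return tibble `category`, `n`, `prop` (exact) and `pct` (rounded).
#' @export
dipping_prevalence <- function(x, denominator = NULL, digits = 1) {
  if (is.numeric(x) && !is.null(names(x))) {
    counts <- x
  } else {
    if (length(x) == 0) stop("no classified patients", call. = FALSE)
    counts <- table(x)
  }
  n <- as.numeric(counts)
  if (is.null(denominator)) denominator <- sum(n)
  if (denominator <= 0) stop("denominator must be positive", call. = FALSE)
  tibble::tibble(
    category = names(counts),
    n = as.integer(n),
    prop = n / denominator,
    pct = round(100 * n / denominator, digits)
  )
}
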