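#' Single-component 24-h cosinor fit
#'
#' Ordinary least squares of `y = M + beta cos(w t) + gamma sin(w t)` with
#' `w = 2 pi / 24` and `t` in clock hours, the linearised form of
#' `M + A cos(w (t - phi))`. MESOR `M` is the rhythm-adjusted mean, amplitude
#' `A = sqrt(beta^2 + gamma^2)` half the peak-to-trough excursion, and
#' acrophase `phi = atan2(gamma, beta) / w` the clock time of the fitted peak.
#' The amplitude standard error uses the delta method on `(beta, gamma)`;
#' the acrophase of an exactly zero-amplitude fit is undefined (`NA`).
#'
#' @param t_clock clock hours of the readings.
#' @param y readings, mmHg.
#' @return a list of class `cosinor_fit`: `mesor`, `amplitude`, `acrophase`,
#'   `beta`, `gamma`, `r2`, `se_mesor`, `se_amplitude`, `n_points`.
#' @export
fit_cosinor <- function(t_clock, y) {
  keep <- !is.na(y) & !is.na(t_clock)
  t_clock <- t_clock[keep]
  y <- y[keep]
  if (length(y) < 4) stop("need at least 4 points for a cosinor fit", call. = FALSE)
  X <- cbind(1, cos(OMEGA24 * t_clock), sin(OMEGA24 * t_clock))
  fit <- lm.fit(X, y)
  b <- fit$coefficients
  mesor <- b[1]; beta <- b[2]; gamma <- b[3]
  amplitude <- sqrt(beta^2 + gamma^2)
  acrophase <- if (amplitude < 1e-9) NA_real_ else wrap24(atan2(gamma, beta) / OMEGA24)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 0 else max(0, 1 - rss / tss)
  dfree <- length(y) - 3
  sigma2 <- if (dfree > 0) rss / dfree else NA_real_
  V <- tryCatch(sigma2 * chol2inv(chol(crossprod(X))), error = function(e) NULL)
  se_mesor <- if (is.null(V)) NA_real_ else sqrt(V[1, 1])
  se_amp <- if (is.null(V) || amplitude < 1e-9) NA_real_ else {
    g <- c(beta, gamma) / amplitude
    sqrt(drop(t(g) %*% V[2:3, 2:3] %*% g))
  }
  # norm of a noisy coefficient vector is upward-biased; subtract the
  # coefficient variance, inflated for residual AR(1) autocorrelation
  amp_adj <- NA_real_
  if (!is.null(V)) {
    r <- fit$residuals
    rho <- if (length(r) > 4 && sd(r) > 0) {
      max(0, stats::cor(r[-1], r[-length(r)]))
    } else 0
    lambda <- (1 + rho) / (1 - min(rho, 0.95))
    amp_adj <- sqrt(max(0, beta^2 + gamma^2 - lambda * (V[2, 2] + V[3, 3])))
  }
  structure(list(mesor = unname(mesor), amplitude = unname(amplitude),
                 amplitude_adj = unname(amp_adj),
                 acrophase = unname(acrophase), beta = unname(beta),
                 gamma = unname(gamma), r2 = r2,
                 se_mesor = unname(se_mesor), se_amplitude = unname(se_amp),
                 n_points = length(y)),
            class = "cosinor_fit")
}

#' Per-patient, per-cycle cosinor fits
#'
#' Fits the 24-h cosinor to each admission-aligned full 24-h window
#' ("cycle"). A cycle fit is attempted only when at least `min_points`
#' valid or imputed readings cover at least `min_span_hours` of the window;
#' refused cycles are returned with `NA` parameters and a reason.
#'
#' @param series series tibble (flags applied; imputed readings enter with
#'   equal weight).
#' @param admissions optional admission-time table.
#' @param cycles which 24-h cycles to fit (1 = first 24 h after admission).
#' @param min_points,min_span_hours identifiability guards per window.
#' @param channel `"sbp"` (default) or `"dbp"`.
#' @return a tibble, one row per patient x cycle, with the `cosinor_fit`
#'   fields plus `patient_id`, `cycle_index`, `coverage_hours` and `refused`.
#' @export
cosinor_fits <- function(series, admissions = NULL, cycles = 1:3,
                         min_points = 24, min_span_hours = 18,
                         channel = "sbp") {
  stopifnot(channel %in% c("sbp", "dbp"))
  adm <- resolve_admissions(series, admissions)
  use <- series |>
    dplyr::filter(.data$flag %in% c("valid", "imputed")) |>
    dplyr::left_join(adm, by = "patient_id") |>
    dplyr::mutate(el = elapsed_hours(.data$time, .data$admission_time)) |>
    dplyr::filter(.data$el >= 0, .data$el < 24 * max(cycles)) |>
    dplyr::mutate(cycle_index = 1L + as.integer(floor(.data$el / 24)))

  grid <- tidyr::expand_grid(patient_id = adm$patient_id, cycle_index = as.integer(cycles))
  grid |>
    dplyr::left_join(
      use |> dplyr::group_by(.data$patient_id, .data$cycle_index) |>
        dplyr::summarise(data = list(dplyr::pick(dplyr::everything())),
                         .groups = "drop"),
      by = c("patient_id", "cycle_index")
    ) |>
    dplyr::mutate(fit = purrr::map(.data$data, function(d) {
      empty <- list(mesor = NA_real_, amplitude = NA_real_,
                    amplitude_adj = NA_real_, acrophase = NA_real_,
                    beta = NA_real_, gamma = NA_real_, r2 = NA_real_,
                    se_mesor = NA_real_, se_amplitude = NA_real_,
                    n_points = 0L, coverage_hours = 0, refused = "no_data")
      if (is.null(d)) return(empty)
      cov_h <- max(d$el) - min(d$el)
      if (nrow(d) < min_points || cov_h < min_span_hours) {
        empty$n_points <- nrow(d)
        empty$coverage_hours <- cov_h
        empty$refused <- if (nrow(d) < min_points) "too_few_points" else "short_span"
        return(empty)
      }
      f <- fit_cosinor(clock_hours(d$time), d[[channel]])
      c(unclass(f), list(coverage_hours = cov_h, refused = NA_character_))
    })) |>
    dplyr::select(-"data") |>
    tidyr::unnest_wider("fit")
}

#' Cohort-level rhythm summary
#'
#' Aggregates per-patient cosinor parameters: arithmetic means with t-based
#' 95% confidence intervals for MESOR and amplitude, and the circular mean
#' with a nonparametric patient-level bootstrap CI for acrophase. By default
#' cycles are first averaged within patient (circularly for acrophase), so
#' each patient contributes once.
#'
#' @param fits output of [cosinor_fits()].
#' @param by optional grouping column(s) of `fits` (e.g. `"cycle_index"`;
#'   disables the within-patient collapse).
#' @param conf confidence level.
#' @param n_boot bootstrap resamples for the acrophase CI.
#' @param seed seed for the bootstrap.
#' @param amplitude `"adjusted"` (default) averages the variance-subtraction
#'   debiased amplitude; `"raw"` the plain coefficient norm.
#' @return a tibble of group summaries with means and CI bounds.
#' @export
summarize_cohort_rhythm <- function(fits, by = NULL, conf = 0.95,
                                    n_boot = 1000, seed = 1L,
                                    amplitude = c("adjusted", "raw")) {
  amplitude <- match.arg(amplitude)
  ok <- dplyr::filter(fits, is.na(.data$refused))
  if (amplitude == "adjusted" && "amplitude_adj" %in% names(ok)) {
    ok$amplitude <- ifelse(is.na(ok$amplitude_adj), ok$amplitude,
                           ok$amplitude_adj)
  }
  if (is.null(by)) {
    ok <- ok |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(mesor = mean(.data$mesor),
                       amplitude = mean(.data$amplitude),
                       acrophase = circular_mean_hours(.data$acrophase),
                       .groups = "drop")
    groups <- list(ok)
    keys <- tibble::tibble(.rows = 1)
  } else {
    ok <- dplyr::group_by(ok, dplyr::across(dplyr::all_of(by)))
    keys <- dplyr::group_keys(ok)
    groups <- dplyr::group_split(ok)
  }
  alpha <- 1 - conf
  res <- purrr::map2(groups, seq_along(groups), function(g, i) {
    n <- nrow(g)
    mean_ci <- function(x) {
      x <- x[!is.na(x)]
      m <- mean(x)
      if (length(x) < 2) return(c(m, NA_real_, NA_real_))
      half <- qt(1 - alpha / 2, length(x) - 1) * sd(x) / sqrt(length(x))
      c(m, m - half, m + half)
    }
    me <- mean_ci(g$mesor); am <- mean_ci(g$amplitude)
    ac <- circular_mean_hours(g$acrophase)
    ac_ci <- c(NA_real_, NA_real_)
    if (n >= 2 && n_boot > 0) {
      boots <- withr::with_seed(child_seed(seed, i), {
        replicate(n_boot, circular_mean_hours(
          sample(g$acrophase, n, replace = TRUE)))
      })
      # quantiles of the bootstrap distribution re-centred on the estimate
      dev <- ((boots - ac + 12) %% 24) - 12
      qs <- quantile(dev, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
      ac_ci <- (ac + qs) %% 24
    }
    tibble::tibble(
      n = n,
      mean_mesor = me[1], mesor_lo = me[2], mesor_hi = me[3],
      mean_amplitude = am[1], amplitude_lo = am[2], amplitude_hi = am[3],
      mean_acrophase = ac, acrophase_lo = ac_ci[1], acrophase_hi = ac_ci[2]
    )
  }) |> dplyr::bind_rows()
  if (!is.null(by)) res <- dplyr::bind_cols(keys, res)
  res
}
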