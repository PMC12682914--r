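#' Nominal reading schedule
#'
#' Minute offsets (from admission) at which a monitoring source is expected to
#' produce a reading: every minute for invasive arterial lines; every 15 min
#' during the first 24 h and every 30 min thereafter for cuff monitoring
#' (defaults, configurable).
#'
#' @param source `"invasive"` or `"cuff"`.
#' @param span_hours monitored span in hours.
#' @param schedule list with `invasive_min`, `cuff_first24_min`,
#'   `cuff_later_min`.
#' @return numeric vector of minute offsets in `[0, span_hours * 60)`.
#' @export
schedule_offsets <- function(source, span_hours = 72,
                             schedule = list(invasive_min = 1,
                                             cuff_first24_min = 15,
                                             cuff_later_min = 30)) {
  stopifnot(source %in% c("invasive", "cuff"), span_hours > 0)
  end <- span_hours * 60
  if (source == "invasive") {
    seq(0, end - schedule$invasive_min, by = schedule$invasive_min)
  } else {
    first <- seq(0, min(1440, end) - schedule$cuff_first24_min,
                 by = schedule$cuff_first24_min)
    if (end <= 1440) return(first)
    c(first, seq(1440, end - schedule$cuff_later_min,
                 by = schedule$cuff_later_min))
  }
}

# Waveform construction. A patient-cycle waveform is
#   y(t) = Mc + Ac cos(w (t - phi)) + s * 1{t in night window},
# but the parameters users configure are on the scale the cosinor fit
# measures: the fitted MESOR (M*), the fitted amplitude (A*) and the raw
# night-1 nocturnal decline (d, percent). The night box contributes s*L/24 to
# the fitted mean and a first-harmonic vector of magnitude f1*|s| centred on
# the night midpoint, so (Mc, Ac, s) are solved so that the combined waveform
# has exactly the requested fitted parameters.

# geometry constants of a night window
night_geometry <- function(night_window = c(21, 9)) {
  n1 <- night_window[1]
  n2 <- night_window[2]
  if (n2 <= n1) n2 <- n2 + 24
  L <- n2 - n1
  list(L = L, center = ((n1 + n2) / 2) %% 24,
       f1 = 4 * sin(OMEGA24 * L / 2) / (24 * OMEGA24))
}

# cosine-component amplitude so that |Ac @ phi + f1*s @ center| = target_amp
cosine_amp_for_fitted <- function(target_amp, s, phi, geom) {
  b <- geom$f1 * s
  cd <- cos(OMEGA24 * (phi - geom$center))
  disc <- b^2 * cd^2 - b^2 + target_amp^2
  if (disc >= 0) max(0, -b * cd + sqrt(disc)) else max(0, -b * cd)
}

# solve (Mc, Ac, s) for one cycle; d_target = NULL means no night shift
solve_cycle_waveform <- function(mesor_f, amp_f, phi, d_target = NULL,
                                 s_fixed = NULL,
                                 day_window = c(9, 21),
                                 night_window = c(21, 9),
                                 s_max = 12) {
  geom <- night_geometry(night_window)
  if (is.null(d_target) && is.null(s_fixed)) {
    return(list(Mc = mesor_f, Ac = amp_f, s = 0))
  }
  c_d <- window_cos_frac(phi, day_window)
  c_n <- window_cos_frac(phi, night_window)
  frac_mean <- geom$L / 24
  # two caps: beyond the harmonic bound the shift's own first harmonic
  # exceeds the requested amplitude, and beyond s_max the shift stops being a
  # physiologic nocturnal offset (a night-peaked waveform cannot be forced
  # into a dipper; its target attenuates instead)
  s_bound <- min(
    0.999 * amp_f /
      (geom$f1 * max(abs(sin(OMEGA24 * (phi - geom$center))), 1e-9)),
    s_max
  )
  clamp <- function(s) sign(s) * min(abs(s), s_bound)
  if (!is.null(s_fixed)) {
    s <- clamp(s_fixed)
  } else {
    q <- d_target / 100
    k <- c_d * (1 - q) - c_n
    # s and Ac are linked: Ac follows from the fitted-amplitude quadratic,
    # s from the decline identity s = (Ac k - q M*) / (1 - q frac_mean)
    h <- function(s) {
      Ac <- cosine_amp_for_fitted(amp_f, clamp(s), phi, geom)
      s * (1 - q * frac_mean) - Ac * k + q * mesor_f
    }
    s <- tryCatch(
      stats::uniroot(h, c(-150, 80), extendInt = "yes", tol = 1e-10)$root,
      error = function(e) (cosine_amp_for_fitted(amp_f, 0, phi, geom) * k -
                             q * mesor_f) / (1 - q * frac_mean)
    )
    s <- clamp(s)
  }
  Ac <- cosine_amp_for_fitted(amp_f, s, phi, geom)
  list(Mc = mesor_f - s * frac_mean, Ac = Ac, s = s)
}

# realized fitted acrophase of the combined waveform (clock hours)
fitted_acrophase <- function(Ac, phi, s, geom) {
  b <- geom$f1 * s
  vx <- Ac * cos(OMEGA24 * phi) + b * cos(OMEGA24 * geom$center)
  vy <- Ac * sin(OMEGA24 * phi) + b * sin(OMEGA24 * geom$center)
  if (vx == 0 && vy == 0) return(NA_real_)
  wrap24(atan2(vy, vx) / OMEGA24)
}

# AR(1) residual process with marginal SD `sd` and lag-1 coefficient `rho`
ar1_noise <- function(n, sd, rho) {
  if (sd <= 0) return(numeric(n))
  if (rho == 0) return(rnorm(n, 0, sd))
  z <- rnorm(n) * sd * sqrt(1 - rho^2)
  as.numeric(stats::filter(z, rho, method = "recursive",
                           init = rnorm(1) * sd))
}

# deterministic trace core: exact (fitted-scale) waveform parameters in,
# one series out
make_trace <- function(params, offsets_min, admission_time, source,
                       gap_process = NULL, artifact_rate = 0,
                       sbp_bounds = c(60, 260),
                       day_window = c(9, 21), night_window = c(21, 9)) {
  time <- admission_time + offsets_min * 60
  ch <- clock_hours(time)
  # per-cycle waveform components; cycle 1 realises the decline target,
  # later cycles deepen the night shift by night_delta_per_cycle
  w1 <- solve_cycle_waveform(params$mesor, params$amplitude, params$acrophase,
                             d_target = params$dipping_target,
                             day_window = day_window,
                             night_window = night_window)
  waves <- lapply(0:2, function(cshift) {
    if (cshift == 0 ||
        (w1$s == 0 && params$night_delta_per_cycle == 0)) return(w1)
    solve_cycle_waveform(params$mesor, params$amplitude, params$acrophase,
                         s_fixed = w1$s + cshift * params$night_delta_per_cycle,
                         day_window = day_window, night_window = night_window)
  })
  cyc <- pmin(3L, 1L + as.integer(floor(offsets_min / 1440)))
  Mc <- vapply(waves, `[[`, numeric(1), "Mc")[cyc]
  Ac <- vapply(waves, `[[`, numeric(1), "Ac")[cyc]
  sc <- vapply(waves, `[[`, numeric(1), "s")[cyc]
  n1 <- night_window[1]; n2 <- night_window[2]
  in_night <- if (n2 <= n1) ch >= n1 | ch < n2 else ch >= n1 & ch < n2
  signal <- Mc + Ac * cos(OMEGA24 * (ch - params$acrophase)) +
    sc * as.numeric(in_night)
  e <- ar1_noise(length(signal), params$noise_sd, params$ar1)
  sbp <- signal + e
  ed <- ar1_noise(length(signal), 0.6 * params$noise_sd, params$ar1)
  dbp <- 0.55 * signal + 8 + ed

  keep <- rep(TRUE, length(offsets_min))
  if (!is.null(gap_process)) {
    n_gaps <- rpois(1, gap_process$rate * params$span_hours)
    if (n_gaps > 0) {
      starts <- runif(n_gaps, 0, params$span_hours * 60)
      durs <- pmin(rexp(n_gaps, 1 / gap_process$mean_minutes),
                   gap_process$max_minutes)
      for (g in seq_len(n_gaps)) {
        keep[offsets_min >= starts[g] & offsets_min < starts[g] + durs[g]] <- FALSE
      }
    }
  }
  out <- tibble::tibble(
    time = time[keep], sbp = sbp[keep], dbp = dbp[keep],
    source = source, flag = "valid", artifact_truth = 0L
  )
  if (artifact_rate > 0 && nrow(out) > 0) {
    hit <- runif(nrow(out)) < artifact_rate
    if (any(hit)) {
      lo <- runif(sum(hit)) < 0.5
      junk <- ifelse(lo, runif(sum(hit), 20, sbp_bounds[1] - 5),
                     runif(sum(hit), sbp_bounds[2] + 5, 320))
      out$sbp[hit] <- junk
      out$artifact_truth[hit] <- 1L
    }
  }
  out
}

#' Simulate one blood-pressure trace
#'
#' Samples the archetype's mean waveform (its `*_mean` parameters are used
#' directly, without between-patient draws) on a monitoring schedule:
#' readings are `MESOR + A cos(2 pi (t - acrophase) / 24) + night shift +
#' AR(1) noise`, where the night shift realises the archetype's nocturnal
#' decline target and drifts by `night_delta_per_cycle` per night.
#'
#' @param archetype an [archetype_spec()].
#' @param schedule minute offsets from admission (e.g. [schedule_offsets()]);
#'   must cover at least 72 h.
#' @param seed integer seed.
#' @param admission_time admission timestamp (`POSIXct`).
#' @param source monitoring source label stored with the readings.
#' @param gap_process,artifact_rate optional missingness/artifact injection;
#'   see [cohort_config()]. Default: none.
#' @return a tibble with columns `patient_id`, `time`, `sbp`, `dbp`,
#'   `source`, `flag`, `artifact_truth`.
#' @export
generate_bp_trace <- function(archetype, schedule, seed = 1L,
                              admission_time = as.POSIXct("2024-03-04 12:00:00",
                                                          tz = "UTC"),
                              source = "cuff",
                              gap_process = NULL, artifact_rate = 0) {
  stopifnot(inherits(archetype, "archetype_spec"))
  if (length(schedule) == 0) stop("`schedule` must be non-empty", call. = FALSE)
  if (max(schedule) - min(schedule) < 72 * 60 - 60) {
    stop("`schedule` must cover at least 72 h", call. = FALSE)
  }
  params <- list(
    mesor = archetype$mesor_mean, amplitude = archetype$amplitude_mean,
    acrophase = archetype$acrophase_mean,
    dipping_target = archetype$dipping_target,
    night_delta_per_cycle = archetype$night_delta_per_cycle,
    noise_sd = archetype$noise_sd, ar1 = archetype$ar1,
    span_hours = (max(schedule) + 1) / 60
  )
  gp <- if (!is.null(gap_process)) {
    list(rate = gap_process$rate_per_hour,
         mean_minutes = gap_process$mean_minutes,
         max_minutes = gap_process$max_minutes)
  }
  out <- withr::with_seed(seed, {
    make_trace(params, schedule, admission_time, source,
               gap_process = gp, artifact_rate = artifact_rate)
  })
  dplyr::mutate(out, patient_id = "P0001", .before = 1)
}

#' Generate a synthetic monitoring cohort
#'
#' Draws, for each patient: a hidden phenotype from the mixture, per-patient
#' waveform parameters around the archetype means, a monitoring source and
#' admission clock time, a 72-h (or longer) BP series with injected gap runs
#' and artefacts, phenotype-conditional covariates, and binary outcomes from
#' the configured logistic models. Identical configs and seeds give
#' byte-identical output.
#'
#' @param config a [cohort_config()].
#' @param with_series generate the BP reading tables (default). `FALSE`
#'   skips trace simulation and returns only covariates, outcomes and truth —
#'   handy for outcome-layer studies at large n. The random stream differs
#'   from a `with_series = TRUE` run at the same seed.
#' @return a list of class `bp_cohort` with elements `series` (long reading
#'   table, or `NULL`), `cohort` (one row per patient: covariates and
#'   outcomes) and `truth` (hidden phenotype and waveform parameters per
#'   patient).
#' @export
generate_cohort <- function(config, with_series = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  arch <- config$archetypes
  labels <- names(arch)
  if (is.null(labels)) labels <- vapply(arch, `[[`, character(1), "name")
  cm <- config$covariate_model

  withr::with_seed(config$seed, {
    comp <- sample.int(length(arch), n, replace = TRUE,
                       prob = config$mixture_weights)
    ids <- sprintf("P%04d", seq_len(n))
    base_day <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")
    admission <- base_day + round(runif(n, 0, 24 * 60)) * 60
    invasive <- runif(n) < config$invasive_fraction
    source <- ifelse(invasive, "invasive", "cuff")

    gap_rate <- rgamma(n, shape = config$gap_process$rate_shape,
                       rate = config$gap_process$rate_shape /
                         config$gap_process$rate_per_hour)

    series <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      a <- arch[[comp[i]]]
      params <- list(
        mesor = rnorm(1, a$mesor_mean, a$mesor_sd),
        amplitude = max(0, rnorm(1, a$amplitude_mean, a$amplitude_sd)),
        acrophase = rnorm(1, a$acrophase_mean, a$acrophase_sd) %% 24,
        dipping_target = if (is.null(a$dipping_target)) NULL else
          rnorm(1, a$dipping_target, a$dipping_sd),
        night_delta_per_cycle = a$night_delta_per_cycle,
        noise_sd = a$noise_sd, ar1 = a$ar1,
        span_hours = config$span_hours
      )
      if (with_series) {
        offs <- schedule_offsets(source[i], config$span_hours, config$schedule)
        tr <- make_trace(
          params, offs, admission[i], source[i],
          gap_process = list(rate = gap_rate[i],
                             mean_minutes = config$gap_process$mean_minutes,
                             max_minutes = config$gap_process$max_minutes),
          artifact_rate = config$artifact_rate
        )
        series[[i]] <- dplyr::mutate(tr, patient_id = ids[i], .before = 1)
      }
      w1 <- solve_cycle_waveform(params$mesor, params$amplitude,
                                 params$acrophase,
                                 d_target = params$dipping_target)
      truth[[i]] <- tibble::tibble(
        patient_id = ids[i], true_phenotype = labels[comp[i]],
        mesor = params$mesor, amplitude = params$amplitude,
        acrophase = fitted_acrophase(w1$Ac, params$acrophase, w1$s,
                                     night_geometry(c(21, 9))),
        dipping_target = params$dipping_target %||% NA_real_,
        night_delta_per_cycle = params$night_delta_per_cycle,
        noise_sd = params$noise_sd
      )
    }
    series <- if (with_series) dplyr::bind_rows(series) else NULL
    truth <- dplyr::bind_rows(truth)

    k <- comp  # 1 = Steady-High, 2 = Disrupted-Rhythmicity, 3 = Partial-Recovery
    cohort <- tibble::tibble(
      patient_id = ids,
      admission_time = admission,
      source = source,
      true_phenotype = labels[k],
      age = round(rnorm(n, cm$age_mean[k], cm$age_sd[k])),
      female = as.integer(runif(n) < cm$p_female[k]),
      hypertension = as.integer(runif(n) < cm$p_hypertension[k]),
      diabetes = as.integer(runif(n) < cm$p_diabetes[k]),
      af = as.integer(runif(n) < cm$p_af[k]),
      ckd = as.integer(runif(n) < cm$p_ckd[k]),
      nihss0 = pmin(42, round(rlnorm(n, log(cm$nihss_median[k]),
                                     cm$nihss_sdlog[k])))
    )
    for (oc in names(config$outcome_model)) {
      m <- config$outcome_model[[oc]]
      lp <- rep(m$intercept, n)
      hit <- match(cohort$true_phenotype, names(m$beta))
      lp <- lp + ifelse(is.na(hit), 0, m$beta[hit])
      for (cv in names(m$covariates)) {
        lp <- lp + m$covariates[[cv]] * cohort[[cv]]
      }
      cohort[[oc]] <- as.integer(runif(n) < plogis(lp))
    }
    cohort$mace_months <- ifelse(cohort$mace12 == 1, runif(n, 0, 12), 12)
    cohort$mace_event <- cohort$mace12

    structure(list(series = series, cohort = cohort, truth = truth),
              class = "bp_cohort")
  })
}

#' @export
print.bp_cohort <- function(x, ...) {
  cat(sprintf("<bp_cohort> %d patients, %d readings (%.1f%% invasive)\n",
              nrow(x$cohort), if (is.null(x$series)) 0L else nrow(x$series),
              100 * mean(x$cohort$source == "invasive")))
  print(table(x$truth$true_phenotype))
  invisible(x)
}
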