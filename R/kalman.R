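#' Fit a local-level state-space model
#'
#' Maximum-likelihood estimation of the local-level (random-walk level plus
#' observation noise) model on an irregular time grid. The level innovation
#' variance scales with the inter-reading interval, so the model is coherent
#' across 1-min invasive and 15/30-min cuff spacing:
#' `level_t = level_{t-dt} + N(0, q * dt)`, `y_t = level_t + N(0, r)`.
#'
#' @param y numeric readings (no `NA`).
#' @param times_min reading times in minutes (strictly increasing).
#' @return a list of class `state_space_params` with `level_variance` (`q`,
#'   mmHg^2 per minute), `obs_variance` (`r`, mmHg^2) and `loglik`.
#' @export
fit_local_level <- function(y, times_min) {
  keep <- !is.na(y)
  y <- y[keep]
  times_min <- times_min[keep]
  if (length(y) < 10) {
    stop("insufficient data: need >= 10 valid readings", call. = FALSE)
  }
  if (is.unsorted(times_min, strictly = TRUE)) {
    stop("`times_min` must be strictly increasing", call. = FALSE)
  }
  dt <- c(0, diff(times_min))
  floor_var <- 1e-8
  v <- var(diff(y)) / 2
  v <- max(v, 1e-4)
  nll <- function(par) {
    q <- exp(par[1]); r <- exp(par[2])
    ll <- ll_loglik(y, dt, q, r)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  med_dt <- stats::median(dt[-1])
  init <- log(c(max(v / med_dt, floor_var), v))
  fit <- optim(init, nll, method = "L-BFGS-B",
               lower = log(rep(floor_var, 2)), upper = log(rep(1e6, 2)))
  q <- max(exp(fit$par[1]), floor_var)
  r <- max(exp(fit$par[2]), floor_var)
  structure(list(level_variance = q, obs_variance = r, loglik = -fit$value),
            class = "state_space_params")
}

#' Kalman gap imputation
#'
#' Runs the fixed-interval (RTS) smoother of the fitted local-level model over
#' the union of observed reading times and the nominal schedule positions that
#' fall inside short gaps, then inserts smoothed means at those positions with
#' flag `"imputed"`. A gap is the interval between two consecutive valid
#' readings; only gaps of duration `<= max_gap_minutes` are filled — longer
#' gaps are left missing, and leading/trailing gaps are never extrapolated.
#' Existing readings are never altered. Artifact-flagged readings are treated
#' as missing. Systolic and diastolic BP are imputed from independently
#' fitted models.
#'
#' @param series a series tibble with artifact flags applied.
#' @param max_gap_minutes maximal gap duration that is imputed.
#' @param admissions optional admission-time table.
#' @param schedule nominal schedule parameters (imputation grid).
#' @param min_valid patients with fewer valid readings are passed through
#'   unimputed (with a message).
#' @return the series with imputed rows appended (time-sorted per patient).
#' @export
kalman_impute <- function(series, max_gap_minutes = 30, admissions = NULL,
                          schedule = list(invasive_min = 1,
                                          cuff_first24_min = 15,
                                          cuff_later_min = 30),
                          min_valid = 10) {
  adm <- resolve_admissions(series, admissions)
  out <- series |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_split() |>
    purrr::map(function(one) {
      a0 <- adm$admission_time[match(one$patient_id[1], adm$patient_id)]
      impute_one(one, a0, max_gap_minutes, schedule, min_valid)
    }) |>
    dplyr::bind_rows()
  dplyr::arrange(out, .data$patient_id, .data$time)
}

impute_one <- function(one, admission_time, max_gap_minutes, schedule,
                       min_valid) {
  one <- dplyr::arrange(one, .data$time)
  valid <- one$flag == "valid"
  if (sum(valid) < min_valid) {
    message(sprintf("patient %s: fewer than %d valid readings, not imputed",
                    one$patient_id[1], min_valid))
    return(one)
  }
  obs_min <- as.numeric(difftime(one$time, admission_time, units = "mins"))
  vt <- obs_min[valid]
  pt <- obs_min[one$flag %in% c("valid", "imputed")]  # slots already occupied

  span_h <- max(72, ceiling(max(obs_min) / 60))
  grid <- schedule_offsets(one$source[1], span_h, schedule)
  grid <- grid[grid <= max(vt) & grid >= min(vt)]
  step_of <- if (one$source[1] == "invasive") {
    rep(schedule$invasive_min, length(grid))
  } else {
    ifelse(grid < 1440, schedule$cuff_first24_min, schedule$cuff_later_min)
  }
  # nearest occupied slot per grid point (pt is sorted)
  nearest_dist <- function(g, x) {
    i <- findInterval(g, x)
    lo <- ifelse(i >= 1, g - x[pmax(i, 1)], Inf)
    hi <- ifelse(i < length(x), x[pmin(i + 1, length(x))] - g, Inf)
    pmin(lo, hi)
  }
  covered <- nearest_dist(grid, pt) <= step_of / 2
  miss <- grid[!covered]
  if (length(miss) > 0) {
    # gap duration = distance between the valid readings bracketing the slot
    i <- findInterval(miss, vt)
    prev_t <- vt[pmax(i, 1)]
    next_t <- vt[pmin(i + 1, length(vt))]
    fill <- i >= 1 & i < length(vt) &
      (next_t - prev_t) <= max_gap_minutes + 1e-9
    miss <- miss[fill]
  }
  if (length(miss) == 0) return(one)

  smooth_channel <- function(yv) {
    pars <- fit_local_level(yv, vt)
    ug <- sort(c(vt, miss))
    yy <- rep(NA_real_, length(ug))
    yy[match(vt, ug)] <- yv
    sm <- ll_smooth(yy, c(0, diff(ug)), pars$level_variance, pars$obs_variance)
    sm$mean[match(miss, ug)]
  }
  new <- tibble::tibble(
    patient_id = one$patient_id[1],
    time = admission_time + miss * 60,
    sbp = smooth_channel(one$sbp[valid]),
    dbp = smooth_channel(one$dbp[valid]),
    source = one$source[1],
    flag = "imputed"
  )
  if ("artifact_truth" %in% names(one)) new$artifact_truth <- 0L
  dplyr::bind_rows(one, new)
}
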