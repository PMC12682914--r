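#' Clock hour of a timestamp
#'
#' Hours since local midnight, in `[0, 24)`, used as the time basis of the
#' cosinor model so that acrophase is directly a clock time.
#'
#' @param time a `POSIXct` vector.
#' @return numeric vector of fractional clock hours.
#' @export
clock_hours <- function(time) {
  stopifnot(inherits(time, "POSIXct"))
  lt <- as.POSIXlt(time)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Elapsed monitoring hours
#'
#' @param time a `POSIXct` vector.
#' @param origin the admission timestamp.
#' @return numeric hours since `origin`.
#' @export
elapsed_hours <- function(time, origin) {
  as.numeric(difftime(time, origin, units = "hours"))
}

#' Circular mean of clock hours
#'
#' Mean direction on the 24-h circle, so e.g. hours 23 and 1 average to
#' midnight (0), not noon.
#'
#' @param hours numeric clock hours in `[0, 24)`; `NA` dropped.
#' @return a single clock hour in `[0, 24)`, or `NA` if no data.
#' @export
circular_mean_hours <- function(hours) {
  hours <- hours[!is.na(hours)]
  if (length(hours) == 0L) return(NA_real_)
  th <- hours * OMEGA24
  m <- atan2(mean(sin(th)), mean(cos(th))) / OMEGA24
  wrap24(m)
}

# wrap to [0, 24), collapsing the floating-point boundary at 24
wrap24 <- function(h) {
  h <- h %% 24
  h[!is.na(h) & h >= 24 - 1e-9] <- 0
  h
}

# admission time per patient: explicit table or first reading of the series
resolve_admissions <- function(series, admissions = NULL) {
  if (!is.null(admissions)) {
    stopifnot(all(c("patient_id", "admission_time") %in% names(admissions)))
    return(dplyr::distinct(admissions, .data$patient_id, .data$admission_time))
  }
  series |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(admission_time = min(.data$time), .groups = "drop")
}

# internal: derive a reproducible child seed (kept below 2^31)
child_seed <- function(seed, i) {
  (as.integer(seed) %% 100000L) * 20011L + as.integer(i) * 7L + 3L
}

assert_prob <- function(x, name) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
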