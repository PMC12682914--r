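#' Dispersion and complexity metrics
#'
#' Standard blood-pressure variability indices on a reading vector: sample SD
#' (n-1), coefficient of variation `SD/mean`, average real variability (mean
#' absolute successive difference), range, and sample entropy (template
#' length `m = 2`, tolerance `r = 0.2 * SD`). Metrics are `NA` with a reason
#' when fewer than 5 readings are available; entropy is `NA` for constant
#' series (zero tolerance).
#'
#' @param y numeric readings, in temporal order (ARV and entropy are
#'   order-sensitive; SD/CV/range are not).
#' @param entropy also compute sample entropy (quadratic cost; skip for very
#'   long vectors if unwanted).
#' @return a one-row tibble: `n`, `sd`, `cv`, `arv`, `range`,
#'   `sample_entropy`.
#' @export
variability_metrics <- function(y, entropy = TRUE) {
  y <- y[!is.na(y)]
  n <- length(y)
  if (n < 5) {
    return(tibble::tibble(n = n, sd = NA_real_, cv = NA_real_, arv = NA_real_,
                          range = NA_real_, sample_entropy = NA_real_))
  }
  s <- sd(y)
  tibble::tibble(
    n = n,
    sd = s,
    cv = s / mean(y),
    arv = mean(abs(diff(y))),
    range = max(y) - min(y),
    sample_entropy = if (entropy) sample_entropy_bp(y) else NA_real_
  )
}

#' Sample entropy of a BP series
#'
#' SampEn(m, r) with the field-standard parameters `m = 2`,
#' `r = 0.2 * SD(y)`; the negative log conditional probability that sequences
#' matching for `m` points (Chebyshev distance `<= r`) also match for
#' `m + 1`. Regular (e.g. sinusoidal) series score low, irregular series
#' high.
#'
#' @param y numeric vector.
#' @param m template length.
#' @param r_frac tolerance as a fraction of the SD.
#' @return sample entropy (dimensionless), `NA` when undefined.
#' @export
sample_entropy_bp <- function(y, m = 2, r_frac = 0.2) {
  y <- y[!is.na(y)]
  n <- length(y)
  if (n < m + 2 || sd(y) == 0) return(NA_real_)
  r <- r_frac * sd(y)
  # pairwise Chebyshev template distances, both template lengths restricted
  # to start indices 1..n-m so every m-template extends to m+1
  d0 <- abs(outer(y, y, "-"))
  N <- n - m
  dm <- d0[seq_len(N), seq_len(N)]
  for (k in seq_len(m - 1)) {
    dm <- pmax(dm, d0[seq_len(N) + k, seq_len(N) + k])
  }
  dm1 <- pmax(dm, d0[seq_len(N) + m, seq_len(N) + m])
  b <- (sum(dm <= r) - N) / 2
  a <- (sum(dm1 <= r) - N) / 2
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

#' Resample a series to a uniform grid
#'
#' Nearest-reading resampling of valid/imputed readings onto a uniform grid
#' from admission. Harmonising the sampling interval makes order-sensitive
#' metrics (ARV, sample entropy) comparable between 1-min invasive and
#' 15/30-min cuff monitoring.
#'
#' @param series series tibble.
#' @param step_min grid step, minutes.
#' @param admissions optional admission-time table.
#' @param span_hours grid span.
#' @return tibble `patient_id`, `el` (elapsed hours), `sbp` (NA where no
#'   reading lies within half a step of the grid point).
#' @export
resample_series <- function(series, step_min = 30, admissions = NULL,
                            span_hours = 72) {
  adm <- resolve_admissions(series, admissions)
  series |>
    dplyr::filter(.data$flag %in% c("valid", "imputed")) |>
    dplyr::left_join(adm, by = "patient_id") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_split() |>
    purrr::map(function(one) {
      el_min <- as.numeric(difftime(one$time, one$admission_time[1],
                                    units = "mins"))
      o <- order(el_min)
      el_min <- el_min[o]
      sbp <- one$sbp[o]
      grid <- seq(0, span_hours * 60 - step_min, by = step_min)
      i <- findInterval(grid, el_min)
      lo_d <- ifelse(i >= 1, grid - el_min[pmax(i, 1)], Inf)
      hi_d <- ifelse(i < length(el_min),
                     el_min[pmin(i + 1, length(el_min))] - grid, Inf)
      idx <- ifelse(lo_d <= hi_d, pmax(i, 1), pmin(i + 1, length(el_min)))
      idx[pmin(lo_d, hi_d) > step_min / 2] <- NA_integer_
      tibble::tibble(patient_id = one$patient_id[1], el = grid / 60,
                     sbp = sbp[idx])
    }) |>
    dplyr::bind_rows()
}

#' Assemble the clustering feature matrix
#'
#' One row per patient with the multiscale circadian feature set: cosinor
#' MESOR and amplitude per cycle, acrophase per cycle encoded as a
#' (sin, cos) pair (so midnight has no artificial boundary), nocturnal
#' decline per night, dispersion metrics (SD, CV, ARV, range) per cycle on a
#' 30-min harmonised grid, sample entropy of the full gridded series, and the
#' recovery slope `(decline_n3 - decline_n1) / 2` in percent per night.
#' Patients missing any cycle fit, any night, or any metric are excluded and
#' listed.
#'
#' @param fits output of [cosinor_fits()].
#' @param dips output of [dipping_results()].
#' @param series the (imputed) series tibble.
#' @param admissions optional admission-time table.
#' @param grid_min harmonisation grid step, minutes.
#' @return a list: `features` (tibble, `patient_id` + numeric columns) and
#'   `excluded` (tibble of dropped patients with reasons).
#' @export
assemble_features <- function(fits, dips, series, admissions = NULL,
                              grid_min = 30) {
  ok_fits <- dplyr::filter(fits, is.na(.data$refused))
  wide_fit <- ok_fits |>
    dplyr::mutate(acro_sin = sin(OMEGA24 * .data$acrophase),
                  acro_cos = cos(OMEGA24 * .data$acrophase)) |>
    dplyr::select("patient_id", "cycle_index", "mesor", "amplitude",
                  "acro_sin", "acro_cos") |>
    tidyr::pivot_wider(names_from = "cycle_index",
                       values_from = c("mesor", "amplitude", "acro_sin", "acro_cos"),
                       names_glue = "{.value}_c{cycle_index}")
  wide_dip <- dips |>
    dplyr::select("patient_id", "night_index", "decline_pct") |>
    tidyr::pivot_wider(names_from = "night_index",
                       values_from = "decline_pct",
                       names_glue = "decline_n{night_index}")

  grid <- resample_series(series, step_min = grid_min,
                          admissions = admissions)
  vm <- grid |>
    dplyr::mutate(cycle_index = 1L + pmin(2L, as.integer(floor(.data$el / 24)))) |>
    dplyr::group_by(.data$patient_id, .data$cycle_index) |>
    dplyr::summarise(m = list(variability_metrics(.data$sbp, entropy = FALSE)),
                     .groups = "drop") |>
    tidyr::unnest_wider("m") |>
    dplyr::select("patient_id", "cycle_index", "sd", "cv", "arv", "range") |>
    tidyr::pivot_wider(names_from = "cycle_index",
                       values_from = c("sd", "cv", "arv", "range"),
                       names_glue = "{.value}_c{cycle_index}")
  ent <- grid |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(sample_entropy = sample_entropy_bp(.data$sbp),
                     .groups = "drop")

  all_ids <- unique(series$patient_id)
  feats <- tibble::tibble(patient_id = all_ids) |>
    dplyr::left_join(wide_fit, by = "patient_id") |>
    dplyr::left_join(wide_dip, by = "patient_id") |>
    dplyr::left_join(vm, by = "patient_id") |>
    dplyr::left_join(ent, by = "patient_id")

  need_cycles <- paste0("mesor_c", 1:3)
  need_nights <- paste0("decline_n", 1:3)
  if (!all(c(need_cycles, need_nights) %in% names(feats))) {
    stop("inputs do not cover three cycles for any patient", call. = FALSE)
  }
  feats$recovery_slope <- (feats$decline_n3 - feats$decline_n1) / 2
  has_all <- stats::complete.cases(feats[setdiff(names(feats), "patient_id")])
  excluded <- tibble::tibble(
    patient_id = feats$patient_id[!has_all],
    reason = "incomplete cycles or metrics"
  )
  list(features = feats[has_all, , drop = FALSE], excluded = excluded)
}

#' Standardize a feature matrix
#'
#' Column z-scores on the fitting cohort; zero-variance columns are dropped
#' with a warning. The returned scaler reproduces the transformation on new
#' patients.
#'
#' @param features tibble from [assemble_features()] (with `patient_id`) or a
#'   plain numeric matrix/data frame.
#' @return a list of class `feature_scaler`: `z` (numeric matrix with
#'   patient ids as rownames), `center`, `scale`, `dropped`.
#' @export
standardize_features <- function(features) {
  if (is.data.frame(features) && "patient_id" %in% names(features)) {
    ids <- features$patient_id
    x <- as.matrix(features[setdiff(names(features), "patient_id")])
    rownames(x) <- ids
  } else {
    x <- as.matrix(features)
  }
  if (nrow(x) < 2) stop("need at least 2 rows to standardize", call. = FALSE)
  sds <- apply(x, 2, sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped) > 0) {
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  z <- scale(x, center = ctr, scale = scl)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  structure(list(z = z, center = ctr, scale = scl, dropped = dropped),
            class = "feature_scaler")
}

#' Apply a stored scaler to new data
#'
#' @param scaler a `feature_scaler`.
#' @param features new feature rows (same columns).
#' @return z-scored numeric matrix.
#' @export
apply_scaler <- function(scaler, features) {
  if (is.data.frame(features) && "patient_id" %in% names(features)) {
    ids <- features$patient_id
    x <- as.matrix(features[setdiff(names(features), "patient_id")])
    rownames(x) <- ids
  } else {
    x <- as.matrix(features)
  }
  x <- x[, names(scaler$center), drop = FALSE]
  z <- scale(x, center = scaler$center, scale = scaler$scale)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}
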