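#' Process raw BP series into per-patient circadian features
#'
#' The standard preprocessing chain: artifact flagging, eligibility QC,
#' Kalman gap imputation (gaps <= `max_gap_minutes`), per-cycle cosinor
#' fits, dipping classification, and feature assembly. Ineligible patients
#' are dropped before fitting.
#'
#' @param series long reading table (one row per reading).
#' @param admissions optional admission-time table; defaults to the first
#'   reading per patient.
#' @param max_gap_minutes imputation gap limit.
#' @param day_window,night_window clock windows for dipping.
#' @param min_points,min_span_hours cosinor identifiability guards.
#' @return a list of class `bp_features`: `qc` (eligibility report),
#'   `series` (flagged + imputed readings of eligible patients), `fits`,
#'   `dipping`, `features`, `excluded`.
#' @export
process_bp_series <- function(series, admissions = NULL,
                              max_gap_minutes = 30,
                              day_window = c(9, 21), night_window = c(21, 9),
                              min_points = 24, min_span_hours = 18) {
  adm <- resolve_admissions(series, admissions)
  flagged <- flag_artifacts(series)
  imputed <- kalman_impute(flagged, max_gap_minutes = max_gap_minutes,
                           admissions = adm)
  qc <- check_eligibility(imputed, admissions = adm)
  keep <- qc$patient_id[qc$eligible]
  use <- dplyr::filter(imputed, .data$patient_id %in% keep)
  fits <- cosinor_fits(use, admissions = adm, min_points = min_points,
                       min_span_hours = min_span_hours)
  dips <- dipping_results(fits, day_window = day_window,
                          night_window = night_window)
  fx <- assemble_features(fits, dips, use, admissions = adm)
  structure(list(qc = qc, series = use, fits = fits, dipping = dips,
                 features = fx$features, excluded = fx$excluded),
            class = "bp_features")
}

#' Derive circadian BP phenotypes from a feature table
#'
#' Standardizes the features, selects the number of clusters (silhouette
#' near-max set, then lowest BIC) unless `k` is fixed, fits the Gaussian
#' mixture, and (for three clusters) assigns the semantic labels
#' Steady-High / Disrupted-Rhythmicity / Partial-Recovery from centroid
#' evidence.
#'
#' @param features raw feature tibble (from [process_bp_series()] or
#'   [assemble_features()]).
#' @param k fixed number of clusters, or `NULL` to select over `k_range`.
#' @param k_range candidate cluster numbers when selecting.
#' @param seed integer seed for fitting.
#' @param n_init EM starts per fit.
#' @return a list of class `bp_phenotypes`: `scaler`, `model`, `selection`
#'   (metric table or `NULL`), `labeling`, `assignments` (tibble patient_id,
#'   cluster, phenotype).
#' @export
derive_phenotypes <- function(features, k = NULL, k_range = 2:6,
                              seed = 1L, n_init = 10) {
  scaler <- standardize_features(features)
  selection <- NULL
  if (is.null(k)) {
    sel <- select_k(scaler$z, k_range = k_range, seed = seed, n_init = n_init)
    selection <- sel$metrics
    model <- sel$models[[as.character(sel$k)]]
  } else {
    model <- fit_mixture(scaler$z, k, seed = seed, n_init = n_init)
  }
  labeling <- assign_labels(model, features)
  structure(list(
    scaler = scaler, model = model, selection = selection,
    labeling = labeling,
    assignments = tibble::tibble(
      patient_id = features$patient_id,
      cluster = model$assignments,
      phenotype = labeling$labels
    )
  ), class = "bp_phenotypes")
}
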