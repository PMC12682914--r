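#' Define a circadian BP archetype
#'
#' An archetype is the generative description of one circadian blood-pressure
#' phenotype: a 24-h cosinor waveform (MESOR, amplitude, acrophase) with
#' between-patient dispersion, a nocturnal-decline target realised through an
#' additive night-window shift, a per-cycle drift of that shift (so "recovery"
#' of dipping across nights is expressible), and short-term residual noise.
#'
#' @param name archetype label.
#' @param mesor_mean,mesor_sd rhythm-adjusted mean systolic BP, mmHg.
#' @param amplitude_mean,amplitude_sd half peak-to-trough of the 24-h
#'   component, mmHg; per-patient draws are truncated at 0.
#' @param acrophase_mean,acrophase_sd clock time of the fitted peak, hours in
#'   `[0, 24)` / hours.
#' @param night_delta_per_cycle additive change of the night-window shift per
#'   monitoring cycle, mmHg/cycle. Negative values deepen the nocturnal dip
#'   from night 1 to night 3 (partial recovery of dipping).
#' @param noise_sd marginal SD of the short-term residual process, mmHg.
#' @param dipping_target expected nocturnal systolic decline on night 1,
#'   percent, achieved exactly (in the noiseless limit) via the night shift;
#'   `NULL` disables the night shift so the waveform is a pure cosine.
#'   `mesor_mean` and `amplitude_mean` are on the fitted-cosinor scale: the
#'   cosine component and night shift are solved jointly so the waveform's
#'   fitted MESOR/amplitude equal the configured values exactly.
#' @param dipping_sd between-patient SD of the decline target, percent.
#' @param ar1 lag-1 autocorrelation of the residual process (0 = white noise).
#' @return an object of class `archetype_spec`.
#' @export
archetype_spec <- function(name,
                           mesor_mean, mesor_sd,
                           amplitude_mean, amplitude_sd,
                           acrophase_mean, acrophase_sd,
                           night_delta_per_cycle = 0,
                           noise_sd = 8,
                           dipping_target = 5,
                           dipping_sd = 4,
                           ar1 = 0.3) {
  if (mesor_mean <= 0) stop("`mesor_mean` must be positive", call. = FALSE)
  if (amplitude_mean < 0) stop("`amplitude_mean` must be non-negative", call. = FALSE)
  if (acrophase_mean < 0 || acrophase_mean >= 24) {
    stop("`acrophase_mean` must lie in [0, 24)", call. = FALSE)
  }
  sds <- c(mesor_sd, amplitude_sd, acrophase_sd, noise_sd, dipping_sd)
  if (any(sds < 0)) stop("all SD parameters must be non-negative", call. = FALSE)
  if (!is.null(dipping_target) && !is.finite(dipping_target)) {
    stop("`dipping_target` must be finite or NULL", call. = FALSE)
  }
  if (abs(ar1) >= 1) stop("`ar1` must lie in (-1, 1)", call. = FALSE)
  structure(
    list(name = name,
         mesor_mean = mesor_mean, mesor_sd = mesor_sd,
         amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
         acrophase_mean = acrophase_mean, acrophase_sd = acrophase_sd,
         night_delta_per_cycle = night_delta_per_cycle,
         noise_sd = noise_sd,
         dipping_target = dipping_target, dipping_sd = dipping_sd,
         ar1 = ar1),
    class = "archetype_spec"
  )
}

#' Shipped phenotype archetypes
#'
#' Three circadian phenotypes observed in acute-stroke monitoring cohorts:
#' *Steady-High* (persistently elevated nocturnal systolic BP, MESOR 148 mmHg,
#' blunted amplitude 5.1 mmHg, mostly non-dipping), *Disrupted-Rhythmicity*
#' (lowest amplitude 4.3 mmHg, largest short-term variability, frequent
#' reverse dipping) and *Partial-Recovery* (intermediate MESOR 134 mmHg,
#' preserved amplitude, dipping that deepens from night 1 to night 3). The
#' Disrupted-Rhythmicity MESOR (127 mmHg) and the Partial-Recovery amplitude
#' (10.7 mmHg) are fixed so that the mixture at the default weights
#' (0.38/0.34/0.28) reproduces cohort means of 137 mmHg (MESOR) and 6.4 mmHg
#' (amplitude).
#'
#' @return named list of three [archetype_spec()] objects.
#' @export
default_archetypes <- function() {
  list(
    `Steady-High` = archetype_spec(
      "Steady-High", mesor_mean = 148, mesor_sd = 5,
      amplitude_mean = 5.1, amplitude_sd = 1.2,
      acrophase_mean = 8, acrophase_sd = 3.5,
      night_delta_per_cycle = 0, noise_sd = 8,
      dipping_target = 4, dipping_sd = 4, ar1 = 0.3),
    `Disrupted-Rhythmicity` = archetype_spec(
      "Disrupted-Rhythmicity", mesor_mean = 127, mesor_sd = 5,
      amplitude_mean = 4.3, amplitude_sd = 1.2,
      acrophase_mean = 5, acrophase_sd = 4.5,
      night_delta_per_cycle = 0, noise_sd = 10,
      dipping_target = 1.5, dipping_sd = 5, ar1 = 0.3),
    `Partial-Recovery` = archetype_spec(
      "Partial-Recovery", mesor_mean = 134, mesor_sd = 5,
      amplitude_mean = 10.7, amplitude_sd = 1.2,
      acrophase_mean = 13.5, acrophase_sd = 2,
      night_delta_per_cycle = -2.5, noise_sd = 6.5,
      dipping_target = 8, dipping_sd = 3.5, ar1 = 0.3)
  )
}

#' Default per-phenotype covariate model
#'
#' Marginal covariate distributions conditional on the true phenotype,
#' mirroring the risk-factor gradient of published phenotype tables (Steady-High
#' oldest and most hypertensive, Partial-Recovery the mildest profile).
#'
#' @return a list with one named numeric vector per covariate, ordered
#'   Steady-High / Disrupted-Rhythmicity / Partial-Recovery.
#' @export
default_covariate_model <- function() {
  list(
    age_mean = c(76, 70, 68), age_sd = c(9, 9, 9),
    p_female = c(0.43, 0.43, 0.43),
    p_hypertension = c(0.82, 0.71, 0.69),
    p_diabetes = c(0.33, 0.26, 0.22),
    p_af = c(0.27, 0.21, 0.20),
    p_ckd = c(0.35, 0.31, 0.15),
    nihss_median = c(10, 8, 6), nihss_sdlog = c(0.55, 0.55, 0.55)
  )
}

#' Default outcome model
#'
#' Logistic models for the five binary outcomes with Partial-Recovery as the
#' reference phenotype. Intercepts and phenotype log-odds are fixed at values
#' whose implied marginal rates equal the published phenotype-wise outcome
#' rates (e.g. 1-year MACE 27.3% / 19.8% / 11.5%). Covariate effects default
#' to zero and can be set per outcome (named log-odds applied to the raw
#' covariate columns).
#'
#' @return a list with one entry per outcome, each holding `intercept`,
#'   `beta` (named phenotype log-odds) and `covariates` (named log-odds).
#' @export
default_outcome_model <- function() {
  rates <- list(
    end72     = c(0.215, 0.284, 0.126),
    sich      = c(0.091, 0.047, 0.021),
    mrs90_le2 = c(0.412, 0.458, 0.635),
    death90   = c(0.100, 0.044, 0.014),
    mace12    = c(0.273, 0.198, 0.115)
  )
  lapply(rates, function(p) {
    list(
      intercept = qlogis(p[3]),
      beta = c(`Steady-High` = qlogis(p[1]) - qlogis(p[3]),
               `Disrupted-Rhythmicity` = qlogis(p[2]) - qlogis(p[3])),
      covariates = numeric(0)
    )
  })
}

#' Configure a synthetic monitoring cohort
#'
#' @param n_patients number of patients (at least 7, so every candidate
#'   cluster number up to 6 remains fittable).
#' @param mixture_weights phenotype mixing proportions; must sum to 1.
#' @param archetypes list of [archetype_spec()]s, one per mixture component.
#' @param invasive_fraction probability of invasive (1-min) monitoring;
#'   default 0.099 as in stroke-unit practice, the remainder is cuff
#'   monitoring every 15 min in the first 24 h and every `cuff_later_min`
#'   thereafter.
#' @param span_hours monitored span per patient, hours (>= 72 so three full
#'   cycles exist).
#' @param schedule list with `invasive_min`, `cuff_first24_min`,
#'   `cuff_later_min` (minutes between scheduled readings).
#' @param gap_process list with `rate_per_hour` (mean gap onset rate),
#'   `rate_shape` (gamma shape of the patient-level rate, controlling
#'   between-patient density spread), `mean_minutes` (mean gap duration,
#'   exponential) and `max_minutes` (truncation). The defaults are calibrated
#'   so the cohort median measurement density is about 0.82 (IQR roughly
#'   0.75-0.88).
#' @param artifact_rate per-reading probability of an artefactual value
#'   (replaced by a draw outside physiologic bounds and tagged in the truth
#'   column).
#' @param outcome_model see [default_outcome_model()].
#' @param covariate_model see [default_covariate_model()].
#' @param seed integer seed; identical configs with identical seeds generate
#'   byte-identical cohorts.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          mixture_weights = c(0.38, 0.34, 0.28),
                          archetypes = default_archetypes(),
                          invasive_fraction = 0.099,
                          span_hours = 72,
                          schedule = list(invasive_min = 1,
                                          cuff_first24_min = 15,
                                          cuff_later_min = 30),
                          gap_process = list(rate_per_hour = 0.68,
                                             rate_shape = 4,
                                             mean_minutes = 18,
                                             max_minutes = 180),
                          artifact_rate = 0.01,
                          outcome_model = default_outcome_model(),
                          covariate_model = default_covariate_model(),
                          seed = 1L) {
  if (length(n_patients) != 1L || is.na(n_patients) || n_patients < 7) {
    stop("`n_patients` must be a single integer >= 7", call. = FALSE)
  }
  if (abs(sum(mixture_weights) - 1) > 1e-8) {
    stop("`mixture_weights` must sum to 1", call. = FALSE)
  }
  assert_prob(mixture_weights, "mixture_weights")
  assert_prob(invasive_fraction, "invasive_fraction")
  assert_prob(artifact_rate, "artifact_rate")
  if (length(archetypes) != length(mixture_weights)) {
    stop("one mixture weight per archetype is required", call. = FALSE)
  }
  if (!all(vapply(archetypes, inherits, logical(1), "archetype_spec"))) {
    stop("`archetypes` must be archetype_spec objects", call. = FALSE)
  }
  if (span_hours < 72) stop("`span_hours` must be >= 72", call. = FALSE)
  structure(
    list(n_patients = as.integer(n_patients),
         mixture_weights = mixture_weights,
         archetypes = archetypes,
         invasive_fraction = invasive_fraction,
         span_hours = span_hours,
         schedule = schedule,
         gap_process = gap_process,
         artifact_rate = artifact_rate,
         outcome_model = outcome_model,
         covariate_model = covariate_model,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}
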