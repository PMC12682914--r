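# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package (joint-Gaussian conditioning
# instead of sequential filtering, grid search instead of OLS, direct
# template counting instead of the vectorized distance matrices, quadrature
# instead of closed-form integrals).

OMEGA <- 2 * pi / 24

# --- local-level smoother by joint multivariate-normal conditioning --------
# states x_i at grid times t (minutes), x_1 ~ N(0, v0) diffuse,
# increments N(0, q dt); observations y = x + N(0, r) where obs = TRUE.
# Returns conditional mean of all states given the observations.
joint_gaussian_smoother <- function(y, t_min, q, r, v0 = 1e7) {
  n <- length(y)
  obs <- !is.na(y)
  cum <- c(0, cumsum(diff(t_min)))
  S <- v0 + q * outer(cum, cum, pmin)
  Syy <- S[obs, obs, drop = FALSE] + diag(r, sum(obs))
  Sxy <- S[, obs, drop = FALSE]
  drop(Sxy %*% solve(Syy, y[obs]))
}

# --- cosinor by coarse-to-fine grid search over (M, A, acrophase) ----------
grid_cosinor <- function(t, y, levels = 4) {
  sse <- function(M, A, phi) sum((y - M - A * cos(OMEGA * (t - phi)))^2)
  Mr <- range(y); Ar <- c(0, diff(range(y))); pr <- c(0, 24)
  best <- c(mean(y), diff(range(y)) / 2, 12)
  stepM <- diff(Mr) / 20; stepA <- diff(Ar) / 20; stepP <- 1.2
  for (lev in seq_len(levels)) {
    Ms <- seq(best[1] - 10 * stepM, best[1] + 10 * stepM, by = stepM)
    As <- seq(max(0, best[2] - 10 * stepA), best[2] + 10 * stepA, by = stepA)
    Ps <- seq(best[3] - 10 * stepP, best[3] + 10 * stepP, by = stepP) %% 24
    vals <- expand.grid(M = Ms, A = As, phi = Ps)
    ss <- mapply(sse, vals$M, vals$A, vals$phi)
    best <- as.numeric(vals[which.min(ss), ])
    stepM <- stepM / 5; stepA <- stepA / 5; stepP <- stepP / 5
  }
  list(mesor = best[1], amplitude = best[2], acrophase = best[3] %% 24,
       sse = sse(best[1], best[2], best[3]))
}

# --- sample entropy by direct template counting ----------------------------
sampen_oracle <- function(y, m = 2, r) {
  n <- length(y)
  N <- n - m
  count <- function(len) {
    cnt <- 0L
    for (i in seq_len(N - 1)) {
      for (j in seq(i + 1, N)) {
        if (max(abs(y[i:(i + len - 1)] - y[j:(j + len - 1)])) <= r) {
          cnt <- cnt + 1L
        }
      }
    }
    cnt
  }
  b <- count(m)
  a <- count(m + 1)
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

# --- window mean of a cosinor curve by 1-min quadrature --------------------
quadrature_window_mean <- function(mesor, amplitude, acrophase, window) {
  w1 <- window[1]; w2 <- window[2]
  if (w2 <= w1) w2 <- w2 + 24
  tt <- seq(w1, w2, by = 1 / 60)
  mean(mesor + amplitude * cos(OMEGA * (tt - acrophase)))
}

# --- multivariate Gaussian log density (k = 1 mixture baseline) ------------
mvtnorm_logdens <- function(z, mu, S) {
  p <- ncol(z)
  -0.5 * (p * log(2 * pi) + determinant(S, logarithm = TRUE)$modulus[1] +
            stats::mahalanobis(z, mu, S))
}

# --- hand chi-squared -------------------------------------------------------
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# --- small helpers ----------------------------------------------------------
t0_utc <- function(x = "2024-03-04 12:00:00") as.POSIXct(x, tz = "UTC")

# bare series tibble from offsets (minutes) and values
toy_series <- function(offsets_min, sbp, dbp = sbp * 0.6, id = "P0001",
                       source = "cuff", admission = t0_utc(),
                       flag = "valid") {
  tibble::tibble(
    patient_id = id,
    time = admission + offsets_min * 60,
    sbp = sbp, dbp = dbp, source = source, flag = flag
  )
}

# noiseless pure-cosine archetype
cosine_archetype <- function(mesor = 120, amplitude = 10, acrophase = 4,
                             noise_sd = 0) {
  archetype_spec("toy", mesor_mean = mesor, mesor_sd = 0,
                 amplitude_mean = amplitude, amplitude_sd = 0,
                 acrophase_mean = acrophase, acrophase_sd = 0,
                 noise_sd = noise_sd, dipping_target = NULL,
                 dipping_sd = 0, ar1 = 0)
}

small_cohort <- function(n = 40, seed = 1, ...) {
  generate_cohort(cohort_config(n_patients = n, seed = seed, ...))
}
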