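# three well-separated spherical Gaussians in 5 dimensions
sep_gaussians <- function(n = 300, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    centers <- rbind(c(0, 0, 0, 0, 0),
                     c(sep, 0, 0, 0, 0),
                     c(0, sep, 0, 0, 0))
    lab <- rep(1:3, length.out = n)
    z <- centers[lab, ] + matrix(rnorm(n * 5), n, 5)
    list(z = z, lab = lab)
  })
}

test_that("well-separated Gaussians are recovered almost perfectly at k=3", {
  g <- sep_gaussians()
  m <- fit_mixture(g$z, 3, seed = 2)
  expect_gte(mclust::adjustedRandIndex(m$assignments, g$lab), 0.99)
  expect_gt(m$silhouette, 0.5)
})

test_that("information criteria satisfy their defining identities", {
  g <- sep_gaussians(n = 120, seed = 3)
  m <- fit_mixture(g$z, 3, seed = 4)
  expect_equal(m$aic, 2 * m$df - 2 * m$loglik, tolerance = 1e-12)
  expect_equal(m$bic, m$df * log(m$n) - 2 * m$loglik, tolerance = 1e-12)
  # hard assignments are the responsibility argmax
  expect_equal(m$assignments, apply(m$responsibilities, 1, which.max))
})

test_that("a k=2 mixture never has lower loglik than the single-Gaussian fit", {
  withr::with_seed(5, z <- matrix(rnorm(200 * 3), 200, 3))
  m2 <- fit_mixture(z, 2, seed = 6)
  # k=1 baseline: MLE Gaussian loglik computed directly
  mu <- colMeans(z)
  S <- crossprod(sweep(z, 2, mu)) / nrow(z)
  ll1 <- sum(mvtnorm_logdens(z, mu, S))
  expect_gte(m2$loglik, ll1 - 1e-6)
})

test_that("duplicated rows receive identical assignments", {
  g <- sep_gaussians(n = 60, seed = 7)
  z <- rbind(g$z, g$z)
  m <- fit_mixture(z, 3, seed = 8)
  expect_equal(m$assignments[1:60], m$assignments[61:120])
})

test_that("mixture fitting and selection are reproducible bit for bit", {
  g <- sep_gaussians(n = 90, seed = 9)
  a <- fit_mixture(g$z, 3, seed = 10)
  b <- fit_mixture(g$z, 3, seed = 10)
  expect_identical(a$loglik, b$loglik)
  expect_identical(a$assignments, b$assignments)
  s1 <- select_k(g$z, k_range = 2:4, seed = 11)
  s2 <- select_k(g$z, k_range = 2:4, seed = 11)
  expect_identical(s1$metrics, s2$metrics)
})

test_that("select_k finds two clusters in two separated Gaussians", {
  withr::with_seed(12, {
    z <- rbind(matrix(rnorm(150 * 4), 150, 4),
               matrix(rnorm(150 * 4, mean = 6), 150, 4))
  })
  sel <- select_k(z, k_range = 2:5, seed = 13)
  expect_equal(sel$k, 2)
})

test_that("a degenerate k range returns its only candidate with metrics", {
  g <- sep_gaussians(n = 80, seed = 14)
  sel <- select_k(g$z, k_range = 3:3, seed = 15)
  expect_equal(sel$k, 3)
  expect_equal(nrow(sel$metrics), 1)
})

test_that("invalid k is rejected", {
  g <- sep_gaussians(n = 30, seed = 16)
  expect_error(fit_mixture(g$z, 1, seed = 1), "k")
  expect_error(fit_mixture(g$z, 30, seed = 1), "k")
})

test_that("perfectly separated clusters are maximally stable under resampling", {
  g <- sep_gaussians(n = 150, sep = 10, seed = 17)
  m <- fit_mixture(g$z, 3, seed = 18)
  st <- bootstrap_stability(g$z, m, n_bootstrap = 30, seed = 19)
  expect_gte(st$overall_mean_jaccard, 0.99)
  expect_true(all(st$per_cluster_jaccard >= 0 & st$per_cluster_jaccard <= 1))
})

test_that("an unstructured blob forced to k=3 is clearly less stable", {
  withr::with_seed(20, blob <- matrix(rnorm(150 * 5), 150, 5))
  mb <- fit_mixture(blob, 3, seed = 21)
  stb <- bootstrap_stability(blob, mb, n_bootstrap = 30, seed = 22)
  g <- sep_gaussians(n = 150, sep = 10, seed = 23)
  ms <- fit_mixture(g$z, 3, seed = 24)
  sts <- bootstrap_stability(g$z, ms, n_bootstrap = 30, seed = 25)
  expect_lt(stb$overall_mean_jaccard, sts$overall_mean_jaccard - 0.1)
})

test_that("centroid evidence maps clusters to the three phenotype labels", {
  ev <- tibble::tibble(cluster = 1:3,
                       mesor = c(148, 132, 134),
                       amplitude = c(5.1, 4.3, 7.0),
                       recovery_slope = c(0, 0.1, 1.5))
  out <- label_clusters(ev)
  expect_equal(out$label, c("Steady-High", "Disrupted-Rhythmicity",
                            "Partial-Recovery"))
  # permuting cluster order leaves the per-cluster labels unchanged
  perm <- label_clusters(ev[c(3, 1, 2), ])
  expect_equal(perm$label[perm$cluster == 1], "Steady-High")
  expect_equal(perm$label[perm$cluster == 2], "Disrupted-Rhythmicity")
  expect_equal(perm$label[perm$cluster == 3], "Partial-Recovery")
  # amplitude tie broken by recovery slope (higher slope -> Partial-Recovery)
  tie <- label_clusters(tibble::tibble(
    cluster = 1:3, mesor = c(150, 130, 131), amplitude = c(5, 6, 6),
    recovery_slope = c(0, -0.5, 2)))
  expect_equal(tie$label, c("Steady-High", "Disrupted-Rhythmicity",
                            "Partial-Recovery"))
})

test_that("labels are withheld for k other than 3", {
  g <- sep_gaussians(n = 60, seed = 26)
  m <- fit_mixture(g$z, 2, seed = 27)
  feats <- tibble::tibble(patient_id = as.character(seq_len(60)))
  lab <- assign_labels(m, feats)
  expect_null(lab$map)
  expect_true(all(grepl("^cluster_", lab$labels)))
})

test_that("phenotype labels recover the generating truth on a default cohort", {
  sim <- generate_cohort(cohort_config(n_patients = 220, seed = 29))
  fx <- suppressMessages(process_bp_series(sim$series))
  ph <- derive_phenotypes(fx$features, k = 3, seed = 30)
  tr <- sim$truth$true_phenotype[match(ph$assignments$patient_id,
                                       sim$truth$patient_id)]
  expect_gte(mean(ph$assignments$phenotype == tr), 0.95)
})
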