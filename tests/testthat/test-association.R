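test_that("a balanced 2x2 table gives chi-squared 0 and p = 1", {
  r <- group_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$method, "chi2")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("low expected counts route to Fisher's exact test", {
  tab <- matrix(c(1, 8, 9, 2), 2)  # min expected = 4.5
  r <- group_test(tab)
  expect_equal(r$method, "fisher")
  expect_true(min(r$expected) < 5)
})

test_that("the chi-squared statistic equals the textbook formula", {
  # in-hospital mortality, Steady-High (17/201) vs Partial-Recovery (2/148)
  tab <- rbind(c(17, 184), c(2, 146))
  r <- group_test(tab)
  expect_equal(r$method, "chi2")
  expect_equal(r$statistic, chisq_oracle(tab), tolerance = 1e-12)
  expect_equal(r$dof, 1)
})

test_that("Fisher and chi-squared p-values agree on large balanced tables", {
  tab <- rbind(c(510, 490), c(478, 522))
  pc <- group_test(tab)$p_value
  pf <- fisher.test(tab)$p.value
  expect_lt(abs(pc - pf), 0.02)
})

test_that("continuous comparisons dispatch by the normality declaration", {
  withr::with_seed(1, {
    x <- c(rnorm(40, 10), rnorm(40, 12))
    g <- rep(c("a", "b"), each = 40)
  })
  expect_equal(group_test(x, groups = g, normal = TRUE)$method, "anova")
  expect_equal(group_test(x, groups = g)$method, "kruskal")
  expect_error(group_test(x, groups = rep("a", 80)), "2 groups")
})

test_that("post hoc pairwise tests carry Bonferroni-adjusted p-values", {
  tab <- rbind(A = c(40, 160), B = c(52, 128), C = c(20, 128))
  r <- group_test(tab, posthoc = TRUE)
  expect_equal(nrow(r$posthoc), 3)
  expect_true(all(r$posthoc$p_adjusted >= r$posthoc$p_value))
  expect_equal(r$posthoc$p_adjusted,
               pmin(1, 3 * r$posthoc$p_value))
})

test_that("degenerate tables are rejected", {
  expect_error(group_test(rbind(c(0, 0), c(3, 4))), "margin")
})

test_that("Bonferroni is the capped product and BH matches hand computation", {
  expect_equal(bonferroni_adjust(0.01, m = 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, m = 3), 1)
  expect_equal(bonferroni_adjust(0.2, m = 1), 0.2)
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "m")
  # hand BH: (0.01,0.02,0.03,0.04) -> all 0.04
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.33), 0.33)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH never decreases a p-value and Bonferroni dominates BH", {
  withr::with_seed(2, {
    for (i in 1:20) {
      p <- runif(sample(3:12, 1))
      bh <- bh_fdr(p)
      bf <- bonferroni_adjust(p)
      expect_true(all(bh >= p - 1e-15))
      expect_true(all(bf >= bh - 1e-15))
    }
  })
})

test_that("Hosmer-Lemeshow p-values are uniform under a true model", {
  pvals <- withr::with_seed(3, {
    vapply(1:200, function(i) {
      x <- rnorm(5000)
      y <- rbinom(5000, 1, plogis(-1 + x))
      fit <- glm(y ~ x, family = binomial())
      hosmer_lemeshow(fitted(fit), y)$p_value
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("constant predictions reduce HL to the binomial chi-squared", {
  withr::with_seed(4, y <- rbinom(400, 1, 0.3))
  # constant p: all observations fall into one merged group; the statistic
  # equals the one-cell binomial chi-squared (O-E)^2 / (E(1-E/n))
  hl <- suppressMessages(hosmer_lemeshow(rep(0.3, 400), y, g = 10))
  e <- 400 * 0.3
  o <- sum(y)
  expect_equal(hl$statistic, (o - e)^2 / (e * (1 - 0.3)), tolerance = 1e-9)
  expect_false(hl$usable)
})

test_that("a two-group HL run returns zero degrees of freedom flagged unusable", {
  withr::with_seed(5, {
    p <- runif(60, 0.2, 0.8)
    y <- rbinom(60, 1, p)
  })
  hl <- hosmer_lemeshow(p, y, g = 2)
  expect_equal(hl$dof, 0)
  expect_false(hl$usable)
})

test_that("VIF matches closed forms and flags rank deficiency", {
  withr::with_seed(6, {
    x1 <- rnorm(500)
    x2 <- rnorm(500)
  })
  x1 <- x1 - mean(x1); x2 <- stats::resid(lm(x2 ~ x1))
  v <- vif(cbind(a = x1, b = x2))
  expect_equal(unname(v), c(1, 1), tolerance = 1e-9)

  withr::with_seed(7, {
    z <- rnorm(2000)
    a <- z + rnorm(2000, 0, sqrt(1 / 0.81 - 1))
  })
  # population correlation 0.9 -> VIF = 1/(1-0.81) = 5.26
  r <- stats::cor(z, a)
  v2 <- vif(cbind(z = z, a = a))
  expect_equal(unname(v2[1]), 1 / (1 - r^2), tolerance = 1e-9)
  expect_equal(unname(v2[1]), 5.26, tolerance = 0.15)

  expect_error(vif(cbind(x = x1, y = 2 * x1)), "collinear")
})

test_that("VIF agrees with the car reference implementation", {
  skip_if_not_installed("car")
  withr::with_seed(8, {
    d <- data.frame(y = rnorm(200), a = rnorm(200), b = rnorm(200))
    d$c <- 0.6 * d$a + rnorm(200)
  })
  ours <- vif(as.matrix(d[c("a", "b", "c")]))
  theirs <- car::vif(lm(y ~ a + b + c, data = d))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-9)
})

test_that("Cohen's h matches the arcsine closed form and is antisymmetric", {
  expect_equal(cohens_h(0.3, 0.3), 0)
  expect_equal(cohens_h(1, 0), pi)
  expect_equal(cohens_h(0.724, 0.336), 0.799, tolerance = 1e-3)
  expect_equal(cohens_h(0.724, 0.336),
               2 * asin(sqrt(0.724)) - 2 * asin(sqrt(0.336)), tolerance = 1e-12)
  withr::with_seed(9, {
    p1 <- runif(20); p2 <- runif(20)
  })
  expect_equal(cohens_h(p1, p2), -cohens_h(p2, p1))
  expect_error(cohens_h(1.2, 0.5), "\\[0, 1\\]")
})

test_that("the pooled two-proportion Z matches hand computation", {
  r <- two_prop_ztest(50, 100, 25, 100)
  pp <- 75 / 200
  z_hand <- (0.5 - 0.25) / sqrt(pp * (1 - pp) * (2 / 100))
  expect_equal(r$z, z_hand, tolerance = 1e-12)
  expect_equal(two_prop_ztest(30, 60, 30, 60)$z, 0)
  expect_equal(two_prop_ztest(25, 100, 50, 100)$z, -r$z)
  expect_error(two_prop_ztest(0, 50, 0, 60), "pooled")
})

test_that("percentage summaries use the tables' 1-decimal rounding", {
  expect_equal(proportion_summary(17, 201)$pct, 8.5)
  expect_equal(proportion_summary(94, 148)$pct, 63.5)
  expect_equal(proportion_summary(0, 10)$pct, 0)
  expect_error(proportion_summary(12, 10), "exceeds")
})

test_that("KM with no events is flat at 1; no censoring equals the empirical survivor", {
  suppressMessages(
    km0 <- km_logrank(rep(12, 30), rep(0, 30), rep(c("a", "b"), 15),
                      horizons = c(6, 12))
  )
  expect_true(all(km0$table$survival == 1))

  withr::with_seed(10, {
    t1 <- runif(200, 0, 10)
  })
  km1 <- km_logrank(t1, rep(1, 200), rep("a", 200), horizons = c(2, 5, 8))
  emp <- vapply(c(2, 5, 8), function(h) mean(t1 > h), numeric(1))
  expect_equal(km1$table$survival, emp, tolerance = 1e-12)
  expect_error(km_logrank(t1, rep(1, 200), factor(rep("a", 200),
                                                  levels = c("a", "b"))),
               "empty")
})

test_that("adjusted odds ratios cover the null in ~95% of null simulations", {
  cover <- withr::with_seed(11, {
    vapply(1:200, function(i) {
      n <- 2000
      d <- data.frame(
        phenotype = sample(c("Steady-High", "Disrupted-Rhythmicity",
                             "Partial-Recovery"), n, replace = TRUE),
        age = rnorm(n, 70, 9)
      )
      d$y <- rbinom(n, 1, plogis(-2 + 0.02 * (d$age - 70)))
      fit <- adjusted_models(d, "y", covariates = "age")
      row <- fit[grepl("Steady-High", fit$term), ]
      row$conf.low <= 1 && row$conf.high >= 1
    }, logical(1))
  })
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("a configured phenotype log-odds is recovered from the generator", {
  om <- default_outcome_model()
  om$mace12$covariates <- c(hypertension = 0.5)
  sim <- generate_cohort(cohort_config(n_patients = 2000, seed = 12,
                                       outcome_model = om),
                         with_series = FALSE)
  d <- sim$cohort
  d$phenotype <- d$true_phenotype
  fit <- adjusted_models(d, "mace12", covariates = "hypertension")
  bhat <- log(fit$estimate[grepl("Steady-High", fit$term)])
  btrue <- unname(om$mace12$beta["Steady-High"])
  se <- (log(fit$conf.high) - log(fit$conf.low))[grepl("Steady-High", fit$term)] / (2 * 1.96)
  expect_lt(abs(bhat - btrue), 3 * se)
  ghat <- log(fit$estimate[fit$term == "hypertension"])
  expect_lt(abs(ghat - 0.5), 0.25)
})

test_that("relabelling the reference category inverts the odds ratio", {
  withr::with_seed(13, {
    d <- data.frame(phenotype = sample(c("Steady-High", "Partial-Recovery"),
                                       800, replace = TRUE))
    d$y <- rbinom(800, 1, ifelse(d$phenotype == "Steady-High", 0.3, 0.15))
  })
  a <- adjusted_models(d, "y")
  b <- adjusted_models(d, "y", reference = "Steady-High")
  expect_equal(unname(a$estimate * b$estimate), 1, tolerance = 1e-9)
})

test_that("Cox models return hazard ratios with the same contract", {
  sim <- generate_cohort(cohort_config(n_patients = 600, seed = 14),
                         with_series = FALSE)
  d <- sim$cohort
  d$phenotype <- d$true_phenotype
  fit <- adjusted_models(d, "mace_event", covariates = "age",
                         family = "cox", time_col = "mace_months")
  expect_equal(attr(fit, "family"), "cox")
  expect_true(all(c("estimate", "conf.low", "conf.high") %in% names(fit)))
  sh <- fit[grepl("Steady-High", fit$term), ]
  expect_gt(sh$estimate, 1)  # configured excess hazard
})
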