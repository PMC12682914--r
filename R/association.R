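#' Group comparison with the expected-count selection rule
#'
#' Categorical data (a contingency table): Pearson chi-squared unless any
#' expected cell count is below `fisher_threshold`, in which case Fisher's
#' exact test is used (exact for 2x2; Monte-Carlo p with a fixed seed for
#' larger tables). Continuous data (`values` + `groups`): one-way ANOVA when
#' declared normal, Kruskal-Wallis otherwise. Optional post hoc pairwise
#' comparisons (rows of the table) with Bonferroni correction.
#'
#' @param x a contingency table (matrix/table, groups in rows) for the
#'   categorical path, or a numeric vector of values for the continuous path.
#' @param groups group labels, required for the continuous path.
#' @param normal declare the continuous variable normal (ANOVA) or not
#'   (Kruskal-Wallis).
#' @param fisher_threshold minimal expected cell count tolerated by the
#'   chi-squared test.
#' @param posthoc run pairwise row-wise tests (categorical, > 2 groups).
#' @param mc_draws Monte-Carlo draws for Fisher's test on tables larger than
#'   2x2.
#' @param seed seed for the Monte-Carlo p-value.
#' @return a list of class `assoc_result`: `method` (`chi2` / `fisher` /
#'   `anova` / `kruskal`), `statistic`, `dof`, `p_value`, `expected` (for
#'   tables) and `posthoc` (tibble or `NULL`).
#' @export
group_test <- function(x, groups = NULL, normal = FALSE,
                       fisher_threshold = 5, posthoc = FALSE,
                       mc_draws = 1e5, seed = 1L) {
  if (is.matrix(x) || is.table(x)) {
    tab <- as.matrix(x)
    if (any(tab < 0) || any(tab != round(tab))) {
      stop("table counts must be non-negative integers", call. = FALSE)
    }
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      stop("degenerate table: zero margin", call. = FALSE)
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    use_fisher <- any(expected < fisher_threshold)
    if (use_fisher) {
      ft <- if (all(dim(tab) == 2)) {
        fisher.test(tab)
      } else {
        withr::with_seed(seed,
          fisher.test(tab, simulate.p.value = TRUE, B = mc_draws))
      }
      out <- list(method = "fisher", statistic = NA_real_, dof = NA_integer_,
                  p_value = ft$p.value, expected = expected)
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      out <- list(method = "chi2", statistic = unname(ct$statistic),
                  dof = unname(ct$parameter), p_value = ct$p.value,
                  expected = expected)
    }
    out$posthoc <- NULL
    if (posthoc && nrow(tab) > 2) {
      pairs <- utils::combn(nrow(tab), 2, simplify = FALSE)
      ph <- purrr::map(pairs, function(pr) {
        sub <- group_test(tab[pr, , drop = FALSE],
                          fisher_threshold = fisher_threshold, seed = seed)
        tibble::tibble(group1 = rownames(tab)[pr[1]] %||% as.character(pr[1]),
                       group2 = rownames(tab)[pr[2]] %||% as.character(pr[2]),
                       method = sub$method, p_value = sub$p_value)
      }) |> dplyr::bind_rows()
      ph$p_adjusted <- bonferroni_adjust(ph$p_value)
      ph$correction <- "bonferroni"
      out$posthoc <- ph
    }
    return(structure(out, class = "assoc_result"))
  }
  # continuous path
  if (is.null(groups)) stop("`groups` required for continuous data", call. = FALSE)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (normal) {
    fit <- aov(x ~ groups)
    sm <- summary(fit)[[1]]
    structure(list(method = "anova", statistic = sm[["F value"]][1],
                   dof = sm[["Df"]][1], p_value = sm[["Pr(>F)"]][1],
                   expected = NULL, posthoc = NULL),
              class = "assoc_result")
  } else {
    kt <- kruskal.test(x, groups)
    structure(list(method = "kruskal", statistic = unname(kt$statistic),
                   dof = unname(kt$parameter), p_value = kt$p.value,
                   expected = NULL, posthoc = NULL),
              class = "assoc_result")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bonferroni correction
#'
#' `p_adj = min(1, m p)`, with `m` defaulting to the number of comparisons.
#'
#' @param p p-values in `[0, 1]`.
#' @param m number of comparisons (`m >= length(p)` allowed for families
#'   larger than the supplied list).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (m < length(p)) stop("`m` must be >= length(p)", call. = FALSE)
  pmin(1, m * p)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjusted p-values; never smaller than the input and monotone
#' non-decreasing in the p-value ranks.
#'
#' @param p p-values in `[0, 1]`.
#' @return BH-adjusted p-values, in the input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) stop("empty p-value list", call. = FALSE)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Decile-of-risk grouping of predicted probabilities; groups whose expected
#' event (or non-event) count is zero are merged with their neighbour. The
#' statistic is `sum (O - E)^2 / (E (1 - E/n_g))` with `g - 2` degrees of
#' freedom; `dof <= 0` is returned flagged as unusable.
#'
#' @param predicted_probs fitted event probabilities in (0, 1).
#' @param outcomes 0/1 outcomes.
#' @param g number of risk groups (default 10).
#' @return a list of class `hl_test`: `statistic`, `dof`, `p_value`,
#'   `n_groups`, `usable`, `table` (per-group observed/expected).
#' @export
hosmer_lemeshow <- function(predicted_probs, outcomes, g = 10) {
  p <- predicted_probs
  y <- outcomes
  stopifnot(length(p) == length(y))
  if (any(p <= 0 | p >= 1)) stop("probabilities must lie in (0, 1)", call. = FALSE)
  if (length(p) < 2 * g) stop("need n >= 2 g observations", call. = FALSE)
  br <- unique(quantile(p, probs = seq(0, 1, length.out = g + 1)))
  grp <- if (length(br) < 2) {
    factor(rep("all", length(p)))
  } else {
    cut(p, breaks = br, include.lowest = TRUE)
  }
  tab <- tibble::tibble(
    n = as.numeric(table(grp)),
    observed = as.numeric(tapply(y, grp, sum)),
    expected = as.numeric(tapply(p, grp, sum))
  )
  tab <- tab[tab$n > 0, ]
  # merge groups with no expected events (or non-events) into the neighbour
  merged <- FALSE
  i <- 1
  while (i <= nrow(tab)) {
    if (tab$expected[i] < 1e-9 || (tab$n[i] - tab$expected[i]) < 1e-9) {
      j <- if (i == 1) 2 else i - 1
      tab$n[j] <- tab$n[j] + tab$n[i]
      tab$observed[j] <- tab$observed[j] + tab$observed[i]
      tab$expected[j] <- tab$expected[j] + tab$expected[i]
      tab <- tab[-i, ]
      merged <- TRUE
    } else {
      i <- i + 1
    }
  }
  if (merged) message("merged risk group(s) with zero expected events")
  stat <- sum((tab$observed - tab$expected)^2 /
                (tab$expected * (1 - tab$expected / tab$n)))
  dof <- nrow(tab) - 2
  usable <- dof > 0
  structure(list(statistic = stat, dof = dof,
                 p_value = if (usable) pchisq(stat, dof, lower.tail = FALSE)
                           else NA_real_,
                 n_groups = nrow(tab), usable = usable, table = tab),
            class = "hl_test")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing covariate `j` on the remaining
#' covariates (with intercept). Rank-deficient designs raise an error naming
#' the collinear columns.
#'
#' @param x numeric design matrix or data frame of covariates (>= 2 columns,
#'   no intercept column).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 covariates", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  qx <- qr(cbind(`(Intercept)` = 1, x))
  if (qx$rank < ncol(x) + 1) {
    aliased <- setdiff(colnames(x),
                       colnames(qx$qr)[qx$pivot[seq_len(qx$rank)]])
    if (length(aliased) == 0) aliased <- "unidentified"
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  vapply(seq_len(ncol(x)), function(j) {
    fit <- lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - rss / tss
    1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(x))
}

#' Cohen's h effect size for two proportions
#'
#' `h = 2 asin(sqrt(p1)) - 2 asin(sqrt(p2))`; antisymmetric in its
#' arguments, ranging over `[-pi, pi]`.
#'
#' @param p1,p2 proportions in `[0, 1]`.
#' @return h (dimensionless).
#' @export
cohens_h <- function(p1, p2) {
  assert_prob(p1, "p1")
  assert_prob(p2, "p2")
  2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))
}

#' Two-sample Z-test for proportions
#'
#' Pooled-proportion Z statistic with two-sided normal p-value.
#'
#' @param x1,n1,x2,n2 successes and sizes of the two samples.
#' @return a list: `z`, `p_value`, `p1`, `p2`.
#' @export
two_prop_ztest <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) {
    stop("pooled proportion of 0 or 1: Z undefined", call. = FALSE)
  }
  z <- (x1 / n1 - x2 / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p_value = 2 * pnorm(-abs(z)), p1 = x1 / n1, p2 = x2 / n2)
}

#' Percentage summary with table rounding
#'
#' `100 count / denominator` at the conventional 1-decimal table precision.
#'
#' @param count event counts (vectorised).
#' @param denominator denominator(s), positive.
#' @param digits decimal places.
#' @return tibble `count`, `denominator`, `pct`.
#' @export
proportion_summary <- function(count, denominator, digits = 1) {
  if (any(denominator <= 0)) stop("denominator must be positive", call. = FALSE)
  if (any(count > denominator)) {
    stop("count exceeds denominator", call. = FALSE)
  }
  tibble::tibble(count = count, denominator = denominator,
                 pct = round(100 * count / denominator, digits))
}

#' Kaplan-Meier estimates and log-rank test
#'
#' Product-limit survival per group (delegated to the survival package) with
#' estimates extracted at requested horizons, plus the log-rank statistic.
#'
#' @param times event/censoring times.
#' @param events 1 = event, 0 = censored.
#' @param groups group labels.
#' @param horizons times at which survival estimates are reported (default:
#'   the largest observed time).
#' @return a list of class `km_result`: `table` (tibble group x horizon with
#'   `survival`), `chisq`, `dof`, `p_value`, `fit` (the survfit object).
#' @export
km_logrank <- function(times, events, groups, horizons = NULL) {
  groups <- if (is.factor(groups)) groups else factor(groups)
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  if (sum(events) < 1) message("no events observed; survival is 1 everywhere")
  if (is.null(horizons)) horizons <- max(times)
  df <- data.frame(t = times, e = events, g = groups)
  fit <- survival::survfit(survival::Surv(t, e) ~ g, data = df)
  tab <- purrr::map(levels(groups), function(lv) {
    sub <- df[df$g == lv, ]
    f1 <- survival::survfit(survival::Surv(t, e) ~ 1, data = sub)
    s <- summary(f1, times = horizons, extend = TRUE)
    tibble::tibble(group = lv, horizon = horizons, survival = s$surv)
  }) |> dplyr::bind_rows()
  lr <- if (nlevels(groups) >= 2 && sum(events) >= 1) {
    sd <- survival::survdiff(survival::Surv(t, e) ~ g, data = df)
    list(chisq = sd$chisq, dof = length(sd$n) - 1,
         p = pchisq(sd$chisq, length(sd$n) - 1, lower.tail = FALSE))
  } else {
    list(chisq = NA_real_, dof = NA_integer_, p = NA_real_)
  }
  structure(list(table = tab, chisq = lr$chisq, dof = lr$dof,
                 p_value = lr$p, fit = fit),
            class = "km_result")
}

#' Adjusted phenotype-outcome models
#'
#' Multivariable logistic regression (odds ratios) or Cox proportional
#' hazards (hazard ratios) for a binary/time-to-event outcome against the
#' phenotype (reference category: Partial-Recovery by default) plus
#' covariates. The operation's own logic is design assembly, reference
#' handling and report formatting; the fits delegate to `glm`/`coxph`.
#' Complete cases only (a missingness count is attached). Coefficients with
#' huge standard errors are flagged as possible separation rather than
#' raising.
#'
#' @param data per-patient table.
#' @param outcome outcome column (0/1 for logistic; event indicator for Cox).
#' @param covariates covariate column names.
#' @param phenotype_col column holding phenotype labels.
#' @param reference reference phenotype level.
#' @param family `"logistic"` or `"cox"`.
#' @param time_col follow-up time column (Cox only).
#' @param conf confidence level for Wald intervals.
#' @return tibble `term`, `estimate` (OR or HR), `conf.low`, `conf.high`,
#'   `p_value`, `flagged`; attributes `n_used`, `n_missing`, `family`.
#' @export
adjusted_models <- function(data, outcome, covariates = character(0),
                            phenotype_col = "phenotype",
                            reference = "Partial-Recovery",
                            family = c("logistic", "cox"),
                            time_col = NULL, conf = 0.95) {
  family <- match.arg(family)
  stopifnot(outcome %in% names(data), phenotype_col %in% names(data),
            all(covariates %in% names(data)))
  cols <- c(outcome, phenotype_col, covariates,
            if (family == "cox") time_col)
  d <- data[cols]
  cc <- complete.cases(d)
  d <- d[cc, , drop = FALSE]
  d[[phenotype_col]] <- stats::relevel(factor(d[[phenotype_col]]),
                                       ref = reference)
  rhs <- paste(c(phenotype_col, covariates), collapse = " + ")
  zq <- qnorm(1 - (1 - conf) / 2)
  if (family == "logistic") {
    fml <- stats::as.formula(paste(outcome, "~", rhs))
    fit <- glm(fml, data = d, family = binomial())
    est <- coef(fit)[-1]
    se <- sqrt(diag(vcov(fit)))[-1]
    pv <- 2 * pnorm(-abs(est / se))
  } else {
    if (is.null(time_col)) stop("`time_col` required for Cox models", call. = FALSE)
    fml <- stats::as.formula(sprintf("survival::Surv(%s, %s) ~ %s",
                                     time_col, outcome, rhs))
    fit <- survival::coxph(fml, data = d)
    est <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    pv <- 2 * pnorm(-abs(est / se))
  }
  out <- tibble::tibble(
    term = names(est),
    estimate = exp(est),
    conf.low = exp(est - zq * se),
    conf.high = exp(est + zq * se),
    p_value = pv,
    flagged = abs(est) > 10 | se > 10  # likely separation / unstable fit
  )
  attr(out, "n_used") <- nrow(d)
  attr(out, "n_missing") <- sum(!cc)
  attr(out, "family") <- family
  out
}
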