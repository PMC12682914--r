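#' Fit a Gaussian mixture to the standardized feature matrix
#'
#' EM-fitted Gaussian mixture (via mclust) with full covariance when the
#' per-cluster sample size supports it and a diagonal fallback otherwise;
#' the best of a deterministic model-based-hierarchical start plus
#' `n_init - 1` random-responsibility restarts by log-likelihood.
#' Deterministic given `seed`.
#'
#' @param z standardized numeric matrix (rows = patients).
#' @param k number of clusters (`2 <= k < n`).
#' @param seed integer seed.
#' @param n_init number of EM starts.
#' @param model `"auto"` (default), or an mclust model name such as
#'   `"VVV"` (full) / `"VVI"` (diagonal).
#' @return a list of class `cluster_model`: `k`, `model_name`,
#'   `assignments`, `responsibilities`, `centroids` (k x p, standardized
#'   space), `loglik`, `df`, `aic`, `bic`, `silhouette`, `n`, `seed`.
#'   `aic = 2 df - 2 loglik`, `bic = df log(n) - 2 loglik`.
#' @export
fit_mixture <- function(z, k, seed = 1L, n_init = 10, model = "auto") {
  z <- as.matrix(z)
  n <- nrow(z)
  p <- ncol(z)
  if (k <= 1 || k >= n) stop("`k` must satisfy 1 < k < n", call. = FALSE)
  if (model == "auto") {
    model <- if (n / k > p * (p + 3) / 2) "VVV" else "VVI"
  }

  run_em <- function(z0) {
    fit <- tryCatch(mclust::me(data = z, modelName = model, z = z0),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$loglik) || is.null(fit$z)) return(NULL)
    list(loglik = fit$loglik, par = fit$parameters, zmat = fit$z)
  }
  best <- withr::with_seed(seed, {
    cands <- list()
    # deterministic model-based hierarchical start
    hc0 <- tryCatch(mclust::hc(z, modelName = "VVV", use = "VARS"),
                    error = function(e) NULL)
    if (!is.null(hc0)) {
      cl0 <- mclust::hclass(hc0, k)
      cands[[1]] <- run_em(mclust::unmap(cl0, groups = seq_len(k)))
    }
    for (i in seq_len(max(0, n_init - 1))) {
      z0 <- matrix(rexp(n * k), n, k)
      cands[[length(cands) + 1]] <- run_em(z0 / rowSums(z0))
    }
    cands <- Filter(Negate(is.null), cands)
    if (length(cands) == 0) stop("mixture fit failed for every start", call. = FALSE)
    cands[[which.max(vapply(cands, `[[`, numeric(1), "loglik"))]]
  })

  assignments <- apply(best$zmat, 1, which.max)
  df <- mclust::nMclustParams(model, d = p, G = k)
  loglik <- best$loglik
  sil <- if (length(unique(assignments)) > 1) {
    mean(cluster::silhouette(assignments, dist(z))[, "sil_width"])
  } else NA_real_
  structure(list(
    k = k, model_name = model,
    assignments = as.integer(assignments),
    responsibilities = best$zmat,
    centroids = t(best$par$mean),
    parameters = best$par,
    loglik = loglik, df = df, n = n,
    aic = 2 * df - 2 * loglik,
    bic = df * log(n) - 2 * loglik,
    silhouette = sil, seed = as.integer(seed)
  ), class = "cluster_model")
}

#' Select the number of clusters
#'
#' Fits the mixture for each candidate `k`, then applies the selection rule:
#' among candidates whose mean silhouette width is within `sil_frac` of the
#' best silhouette, choose the one with the lowest BIC. The full per-k
#' metric table is returned so the rule is auditable.
#'
#' @param z standardized feature matrix.
#' @param k_range candidate cluster numbers (default 2:6).
#' @param seed,n_init,model passed to [fit_mixture()].
#' @param sil_frac silhouette near-max fraction defining the candidate set.
#' @return a list: `k` (selected), `metrics` (tibble of k, loglik, df, aic,
#'   bic, silhouette, candidate flag), `models` (list of `cluster_model`s,
#'   named by k).
#' @export
select_k <- function(z, k_range = 2:6, seed = 1L, n_init = 10,
                     model = "auto", sil_frac = 0.95) {
  stopifnot(nrow(z) > max(k_range))
  models <- lapply(seq_along(k_range), function(i) {
    fit_mixture(z, k_range[i], seed = child_seed(seed, i), n_init = n_init,
                model = model)
  })
  names(models) <- k_range
  metrics <- tibble::tibble(
    k = as.integer(k_range),
    loglik = vapply(models, `[[`, numeric(1), "loglik"),
    df = vapply(models, `[[`, numeric(1), "df"),
    aic = vapply(models, `[[`, numeric(1), "aic"),
    bic = vapply(models, `[[`, numeric(1), "bic"),
    silhouette = vapply(models, `[[`, numeric(1), "silhouette")
  )
  smax <- max(metrics$silhouette, na.rm = TRUE)
  thr <- if (smax > 0) sil_frac * smax else smax / sil_frac
  metrics$candidate <- !is.na(metrics$silhouette) & metrics$silhouette >= thr
  cand <- metrics[metrics$candidate, ]
  kstar <- cand$k[which.min(cand$bic)]
  list(k = kstar, metrics = metrics, models = models)
}

#' Bootstrap Jaccard cluster stability
#'
#' Clusterwise stability in the style of Hennig: for each bootstrap resample
#' of patients the mixture is refit at the reference `k`, and each reference
#' cluster is matched to the resample cluster maximising the Jaccard index
#' over the distinct patients present in the resample. Values near 1 mean
#' the cluster is recovered almost unchanged in resampled data.
#'
#' @param z standardized feature matrix the reference model was fitted on.
#' @param model reference `cluster_model`.
#' @param n_bootstrap number of resamples.
#' @param seed integer seed.
#' @param n_init EM starts per refit (model-based-hierarchical start only by
#'   default, which keeps 200+ refits affordable).
#' @return a list of class `stability_report`: `n_bootstrap`, `n_skipped`,
#'   `per_cluster_jaccard`, `overall_mean_jaccard`, `resamples` (matrix of
#'   per-resample, per-cluster Jaccard values).
#' @export
bootstrap_stability <- function(z, model, n_bootstrap = 200, seed = 1L,
                                n_init = 1) {
  z <- as.matrix(z)
  n <- nrow(z)
  k <- model$k
  ref_sets <- split(seq_len(n), model$assignments)
  res <- matrix(NA_real_, n_bootstrap, length(ref_sets))
  skipped <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(n_bootstrap)) {
      idx <- sample.int(n, n, replace = TRUE)
      present <- unique(idx)
      if (length(present) <= k || nrow(unique(z[present, , drop = FALSE])) <= k) {
        skipped <- skipped + 1L
        next
      }
      refit <- tryCatch(
        fit_mixture(z[idx, , drop = FALSE], k,
                    seed = sample.int(.Machine$integer.max / 2, 1),
                    n_init = n_init, model = model$model_name),
        error = function(e) NULL
      )
      if (is.null(refit)) {
        skipped <- skipped + 1L
        next
      }
      boot_sets <- lapply(split(seq_along(idx), refit$assignments),
                          function(s) unique(idx[s]))
      for (j in seq_along(ref_sets)) {
        A <- intersect(ref_sets[[j]], present)
        if (length(A) == 0) next
        res[b, j] <- max(vapply(boot_sets, function(B) {
          length(intersect(A, B)) / length(union(A, B))
        }, numeric(1)))
      }
    }
  })
  per_cluster <- colMeans(res, na.rm = TRUE)
  structure(list(
    n_bootstrap = n_bootstrap, n_skipped = skipped,
    per_cluster_jaccard = per_cluster,
    overall_mean_jaccard = mean(per_cluster),
    resamples = res
  ), class = "stability_report")
}

#' Label clusters from centroid evidence
#'
#' @param evidence tibble with one row per cluster: `cluster`, `mesor`,
#'   `amplitude`, and optionally `recovery_slope` (used to break amplitude
#'   ties). Rule: the cluster with the highest MESOR is *Steady-High*; of the
#'   remaining two, the one with the lower amplitude is
#'   *Disrupted-Rhythmicity* and the other *Partial-Recovery*.
#' @return the evidence tibble with a `label` column.
#' @export
label_clusters <- function(evidence) {
  stopifnot(nrow(evidence) == 3,
            all(c("cluster", "mesor", "amplitude") %in% names(evidence)))
  lab <- rep(NA_character_, 3)
  ih <- which.max(evidence$mesor)
  lab[ih] <- "Steady-High"
  rest <- setdiff(1:3, ih)
  amp <- evidence$amplitude[rest]
  if (amp[1] == amp[2] && "recovery_slope" %in% names(evidence)) {
    # tie: the cluster whose dipping deepens most across nights recovers
    rs <- evidence$recovery_slope[rest]
    idr <- rest[which.min(rs)]
  } else {
    idr <- rest[which.min(amp)]
  }
  lab[idr] <- "Disrupted-Rhythmicity"
  lab[setdiff(rest, idr)] <- "Partial-Recovery"
  evidence$label <- lab
  evidence
}

#' Assign semantic phenotype labels to a 3-cluster model
#'
#' Computes per-cluster centroid evidence (mean of the per-cycle MESOR and
#' amplitude features and of the recovery slope, on the original scale) from
#' the raw feature table and applies [label_clusters()]. For `k != 3` labels
#' are withheld and clusters reported numerically.
#'
#' @param model a `cluster_model`.
#' @param features raw (unstandardized) feature tibble whose rows align with
#'   the model's assignments.
#' @return a list of class `phenotype_labeling`: `map` (cluster -> label, or
#'   `NULL` when `k != 3`), `evidence`, `labels` (per-patient character
#'   vector).
#' @export
assign_labels <- function(model, features) {
  stopifnot(nrow(features) == length(model$assignments))
  if (model$k != 3) {
    return(structure(list(
      map = NULL, evidence = NULL,
      labels = paste0("cluster_", model$assignments)
    ), class = "phenotype_labeling"))
  }
  mes <- rowMeans(features[paste0("mesor_c", 1:3)])
  amp <- rowMeans(features[paste0("amplitude_c", 1:3)])
  rs <- features$recovery_slope
  evidence <- tibble::tibble(
    cluster = sort(unique(model$assignments)),
    mesor = tapply(mes, model$assignments, mean)[as.character(sort(unique(model$assignments)))],
    amplitude = tapply(amp, model$assignments, mean)[as.character(sort(unique(model$assignments)))],
    recovery_slope = tapply(rs, model$assignments, mean)[as.character(sort(unique(model$assignments)))]
  )
  evidence <- label_clusters(evidence)
  map <- setNames(evidence$label, evidence$cluster)
  structure(list(
    map = map, evidence = evidence,
    labels = unname(map[as.character(model$assignments)])
  ), class = "phenotype_labeling")
}
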