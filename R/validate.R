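## Model-evaluation metrics and the k-fold cross-validation scheme.

#' Point-prediction metrics
#'
#' Average bias mean(pred - obs), root mean square error, mean absolute
#' error and the Pearson correlation between observed and predicted
#' values.
#'
#' @param observed,predicted numeric vectors of equal length
#' @return list with \code{avbias}, \code{rmse}, \code{mae},
#'   \code{correlation} (NA with a warning when either vector has zero
#'   variance)
#' @export
point_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  resid <- predicted - observed
  corr <- NA_real_
  if (length(observed) >= 2 &&
      stats::sd(observed) > 0 && stats::sd(predicted) > 0) {
    corr <- stats::cor(observed, predicted)
  } else {
    warning("correlation undefined (zero variance); reported as NA")
  }
  list(avbias = mean(resid),
       rmse = sqrt(mean(resid^2)),
       mae = mean(abs(resid)),
       correlation = corr)
}

#' Actual coverage of prediction intervals, in percent
#'
#' 100 times the proportion of observations falling inside their
#' (closed) prediction interval. Upstream the limits are the equal-tailed
#' 2.5\% and 97.5\% posterior quantiles.
#'
#' @param observed truth values
#' @param lower,upper interval limits
#' @export
interval_coverage <- function(observed, lower, upper) {
  if (missing(lower) || missing(upper) || is.null(lower) || is.null(upper)) {
    stop("interval limits are required")
  }
  stopifnot(length(observed) == length(lower), length(observed) == length(upper))
  if (any(lower > upper)) stop("interval limits must satisfy lower <= upper")
  100 * mean(observed >= lower & observed <= upper)
}

#' Average prediction variance over grid cells
#'
#' The mean over cells of the posterior variance of the coverage
#' probability; smaller is better.
#'
#' @param p_draws S x L matrix of posterior draws over L cells
#' @export
apv <- function(p_draws) {
  p_draws <- as.matrix(p_draws)
  if (ncol(p_draws) < 1) stop("need at least one cell")
  mean(apply(p_draws, 2, stats::var))
}

#' Random k-fold split of cluster ids
#'
#' Partition into k folds of near-equal size (sizes differ by at most 1).
#'
#' @param cluster_ids character vector of ids
#' @param k number of folds (default 10)
#' @param seed RNG seed
#' @return named integer vector: fold index per cluster id
#' @export
kfold_split <- function(cluster_ids, k = 10, seed = NULL) {
  if (k < 2) stop("k must be >= 2")
  n <- length(cluster_ids)
  if (k > n) stop("k exceeds the number of clusters")
  if (!is.null(seed)) set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  names(folds) <- cluster_ids
  folds
}

#' k-fold cross-validation of the CP or RB pipeline
#'
#' For each fold, indicator datasets are built from the training clusters
#' only, the model is fitted, held-out clusters are predicted (with a
#' fresh nugget, since a held-out cluster is a new cluster), and the
#' predictions are scored against the held-out empirical proportions of
#' that indicator (successes / trials). Metrics are averaged over folds.
#'
#' @param ds a \code{cluster_dataset}
#' @param approach \code{"CP"} or \code{"RB"}
#' @param spec a \code{prior_spec}
#' @param k folds (default 10)
#' @param seed RNG seed (drives folds and sampler seeds)
#' @param settings sampler settings template; per-fold seeds are derived
#'   from \code{seed}
#' @return list per modelled indicator: data frame of fold-wise metrics
#'   plus a \code{"mean"} row
#' @export
crossvalidate <- function(ds, approach = c("CP", "RB"), spec = prior_spec(),
                          k = 10, seed = 1L,
                          settings = list(n_draws = 300, n_burn = 600, thin = 1)) {
  approach <- match.arg(approach)
  stopifnot(inherits(ds, "cluster_dataset"))
  folds <- kfold_split(ds$cluster_id, k = k, seed = seed)
  build <- if (approach == "CP") build_cp_datasets else build_rb_datasets
  ind_names <- names(build(ds))
  res <- lapply(ind_names, function(x) NULL)
  names(res) <- ind_names

  for (fold in seq_len(k)) {
    test_ids <- names(folds)[folds == fold]
    train <- structure(as.data.frame(ds)[!(ds$cluster_id %in% test_ids), , drop = FALSE],
                       covariate_names = covariate_names(ds),
                       class = c("cluster_dataset", "data.frame"))
    train_sets <- suppressMessages(build(train))
    full_sets <- suppressMessages(build(ds))
    for (nm in ind_names) {
      tr <- train_sets[[nm]]
      te <- full_sets[[nm]]
      te <- te[te$cluster_id %in% test_ids, , drop = FALSE]
      if (nrow(tr) < 10 || nrow(te) == 0) {
        warning("fold ", fold, ", indicator ", nm,
                ": too few rows; fold skipped")
        next
      }
      st <- fit_settings(n_draws = settings$n_draws, n_burn = settings$n_burn,
                         thin = settings$thin,
                         seed = seed + 1000L * fold + match(nm, ind_names),
                         store_latent = FALSE)
      f <- fit(tr, spec, st)
      pd <- predict_surface(f, te, predict_nugget = TRUE)
      obs <- te$successes / te$trials
      pm <- suppressWarnings(point_metrics(obs, colMeans(pd)))
      cov95 <- interval_coverage(obs,
                                 apply(pd, 2, stats::quantile, 0.025),
                                 apply(pd, 2, stats::quantile, 0.975))
      row <- data.frame(fold = fold, avbias = pm$avbias, rmse = pm$rmse,
                        mae = pm$mae, correlation = pm$correlation,
                        coverage95 = cov95)
      res[[nm]] <- rbind(res[[nm]], row)
    }
  }
  lapply(res, function(tab) {
    if (is.null(tab)) return(NULL)
    mean_row <- data.frame(fold = NA, t(colMeans(tab[, -1, drop = FALSE],
                                                 na.rm = TRUE)))
    names(mean_row) <- names(tab)
    rbind(tab, mean_row)
  })
}

#' Direct (unweighted) admin-level coverage estimates
#'
#' Per unit and dose, the ratio of summed successes to summed trials over
#' the member clusters: the design-unweighted analogue of a direct survey
#' estimate, used for scatter comparison against modelled admin
#' estimates.
#'
#' @param ds a \code{cluster_dataset}
#' @param cluster_units named character vector: admin unit id per cluster
#'   id
#' @return data frame unit_id x dose with the empirical coverage (NA where
#'   a unit has zero trials)
#' @export
direct_admin_estimates <- function(ds, cluster_units) {
  stopifnot(inherits(ds, "cluster_dataset"))
  if (!all(ds$cluster_id %in% names(cluster_units))) {
    stop("every cluster must be assigned to a unit")
  }
  unit <- cluster_units[ds$cluster_id]
  agg <- function(y) {
    num <- tapply(y, unit, sum)
    den <- tapply(ds$n, unit, sum)
    ifelse(den > 0, num / den, NA_real_)
  }
  out <- data.frame(unit_id = sort(unique(unit)))
  d1 <- agg(ds$y1); d2 <- agg(ds$y2); d3 <- agg(ds$y3)
  out$p1 <- d1[out$unit_id]; out$p2 <- d2[out$unit_id]; out$p3 <- d3[out$unit_id]
  rownames(out) <- NULL
  out
}

#' Write a metric report as delimited text
#' @param report output of \code{\link{crossvalidate}}
#' @param path destination file
#' @export
write_metric_report <- function(report, path) {
  rows <- do.call(rbind, lapply(names(report), function(nm) {
    tab <- report[[nm]]
    if (is.null(tab)) return(NULL)
    cbind(indicator = nm, tab)
  }))
  utils::write.table(rows, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
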