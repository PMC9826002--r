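## Synthetic-data generator for the simulation study: monotone coverage
## triples from the geostatistical model with incremental logit shifts,
## discrete-uniform cluster sample sizes, and deterministic (expected)
## counts, plus grid / population / admin fixtures for the mapping stage.

#' Simulation configuration
#'
#' Defaults reproduce the study design: a Matern field with sigma2 = 1,
#' effective range 2.62 and nugget variance 1 on the logit scale;
#' regression coefficients (0.5, 0.8, 0.8, 0.2) for an intercept and three
#' covariates drawn from N(0,1), Gamma(1,1) and t(2); incremental logit
#' shifts of -1.3 and -2.5 for the second and third doses; and cluster
#' sample sizes drawn from the discrete-uniform families U{2,10},
#' U{2,20}, ..., U{2,80}.
#'
#' @param m_obs number of observation (cluster) locations
#' @param grid_nx,grid_ny prediction-grid resolution over the window
#' @param window c(xmin, xmax, ymin, ymax) simulation window; the default
#'   10 x 10 window makes the default range (2.62) roughly a quarter of
#'   the domain, in line with a first-quartile-of-distances choice
#' @param beta true regression coefficients (intercept first)
#' @param sigma2,range,sigma2_eps true covariance parameters
#' @param increments logit shifts (delta2, delta3) for doses 2 and 3; must
#'   be decreasing so that p1 > p2 > p3
#' @param size_families upper bounds K of the U\{2, K\} sample-size
#'   families
#' @param spatial if FALSE, the spatial field is omitted (second study
#'   scenario); the nugget is kept
#' @param range_from_quartile recompute the range as the first quartile of
#'   the inter-point distances once locations are drawn
#' @param redraw_residuals draw fresh (omega, eps) realizations for each
#'   dose instead of sharing one (alternative reading of the incremental
#'   construction; default FALSE)
#' @param round_counts round the deterministic counts to integers
#'   (deviates from the exact-expectation construction; default FALSE)
#' @param seed RNG seed
#' @return object of class \code{sim_config}
#' @export
sim_config <- function(m_obs = 300, grid_nx = 15, grid_ny = 15,
                       window = c(0, 10, 0, 10),
                       beta = c(0.5, 0.8, 0.8, 0.2),
                       sigma2 = 1, range = 2.62, sigma2_eps = 1,
                       increments = c(-1.3, -2.5),
                       size_families = c(10, 20, 30, 40, 50, 60, 70, 80),
                       spatial = TRUE, range_from_quartile = FALSE,
                       redraw_residuals = FALSE, round_counts = FALSE,
                       seed = 1L) {
  if (increments[1] <= increments[2]) {
    stop("increments must be decreasing (delta2 > delta3) for p1 > p2 > p3")
  }
  if (any(size_families < 2)) stop("sample-size upper bounds must be >= 2")
  stopifnot(m_obs >= 1, sigma2 > 0, range > 0, sigma2_eps >= 0)
  structure(list(m_obs = m_obs, grid_nx = grid_nx, grid_ny = grid_ny,
                 window = window, beta = beta, sigma2 = sigma2, range = range,
                 sigma2_eps = sigma2_eps, increments = increments,
                 size_families = size_families, spatial = spatial,
                 range_from_quartile = range_from_quartile,
                 redraw_residuals = redraw_residuals,
                 round_counts = round_counts, seed = as.integer(seed)),
            class = "sim_config")
}

#' Preset: smaller sample-size families (sensitivity variant)
#' @param ... overrides passed to \code{\link{sim_config}}
#' @export
sim_config_small_sizes <- function(...) {
  sim_config(size_families = c(8, 10, 12, 15, 20, 25, 30, 35), ...)
}

#' Simulate the three covariates
#'
#' Columns are iid draws from N(0,1), Gamma(shape 1, rate 1) and
#' Student-t with 2 df.
#'
#' @param m number of rows
#' @param seed RNG seed
#' @return m x 3 matrix with columns \code{cov_norm, cov_gamma, cov_t}
#' @export
simulate_covariates <- function(m, seed = NULL) {
  stopifnot(m >= 1)
  if (!is.null(seed)) set.seed(seed)
  cbind(cov_norm = stats::rnorm(m),
        cov_gamma = stats::rgamma(m, shape = 1, rate = 1),
        cov_t = stats::rt(m, df = 2))
}

#' Draw cluster sample sizes from U{2, K}
#' @param m number of draws
#' @param K upper bound (>= 2)
#' @param seed RNG seed
#' @export
draw_sample_sizes <- function(m, K, seed = NULL) {
  if (K < 2) stop("K must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  # sample.int avoids the 1:n expansion surprise of sample(2:2)
  1L + sample.int(K - 1L, m, replace = TRUE)
}

#' Deterministic counts from sample sizes and monotone probabilities
#'
#' \code{y_k = n * p_k} exactly (no binomial sampling), so the counts are
#' fractional and the monotone ordering of the probabilities carries over
#' to the counts.
#'
#' @param n sample sizes (>= 2)
#' @param p1,p2,p3 monotone coverage probabilities
#' @param round_counts round to integers (deviation from the exact
#'   construction)
#' @return data frame with columns \code{y1, y2, y3}
#' @export
make_counts <- function(n, p1, p2, p3, round_counts = FALSE) {
  if (any(p1 < p2) || any(p2 < p3)) stop("probabilities must be monotone")
  y1 <- n * p1; y2 <- n * p2; y3 <- n * p3
  if (round_counts) {
    y1 <- round(y1); y2 <- pmin(round(y2), y1); y3 <- pmin(round(y3), y2)
  }
  data.frame(y1 = y1, y2 = y2, y3 = y3)
}

# one joint draw of the latent field over a set of locations
draw_field <- function(xy, sigma2, range, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- as.matrix(stats::dist(xy))
  S <- matern_cov(D, sigma2, range)
  diag(S) <- diag(S) + 1e-8 * sigma2
  drop(crossprod(chol(S), stats::rnorm(nrow(xy))))
}

#' Simulate the true coverage surfaces
#'
#' Draws one realization of the spatial field jointly over the observation
#' and grid locations (skipped when \code{spatial = FALSE}) and one nugget
#' per location, forms the dose-1 linear predictor eta1 = x'beta + omega +
#' eps, shifts it by the increments for doses 2 and 3, and inverts to the
#' probability scale. The shared-realization construction makes the three
#' surfaces differ only by the shift, which guarantees monotonicity.
#'
#' @param cfg a \code{sim_config}
#' @return list with \code{obs} and \code{grid} data frames (coordinates,
#'   covariates, p1, p2, p3), plus the realized \code{range} used
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  w <- cfg$window
  xy_obs <- cbind(x = stats::runif(cfg$m_obs, w[1], w[2]),
                  y = stats::runif(cfg$m_obs, w[3], w[4]))
  gx <- seq(w[1], w[2], length.out = cfg$grid_nx + 1)
  gy <- seq(w[3], w[4], length.out = cfg$grid_ny + 1)
  cx <- (gx[-1] + gx[-length(gx)]) / 2
  cy <- (gy[-1] + gy[-length(gy)]) / 2
  xy_grid <- as.matrix(expand.grid(x = cx, y = cy))
  m_o <- nrow(xy_obs); m_g <- nrow(xy_grid)
  all_xy <- rbind(xy_obs, xy_grid)

  rng <- cfg$range
  if (cfg$range_from_quartile) {
    rng <- unname(stats::quantile(stats::dist(xy_obs), 0.25))
  }

  covs <- simulate_covariates(m_o + m_g)
  X <- cbind(1, covs)
  n_doses <- 3L
  shifts <- c(0, cfg$increments)
  eta <- matrix(NA_real_, m_o + m_g, n_doses)
  if (cfg$redraw_residuals) {
    for (k in seq_len(n_doses)) {
      om <- if (cfg$spatial) draw_field(all_xy, cfg$sigma2, rng) else 0
      ep <- stats::rnorm(m_o + m_g, 0, sqrt(cfg$sigma2_eps))
      eta[, k] <- drop(X %*% cfg$beta) + om + ep + shifts[k]
    }
    # a fresh draw per dose does not guarantee monotone surfaces; enforce
    # by sorting the three linear predictors per location
    eta <- t(apply(eta, 1, sort, decreasing = TRUE))
  } else {
    om <- if (cfg$spatial) draw_field(all_xy, cfg$sigma2, rng) else 0
    ep <- stats::rnorm(m_o + m_g, 0, sqrt(cfg$sigma2_eps))
    base <- drop(X %*% cfg$beta) + om + ep
    for (k in seq_len(n_doses)) eta[, k] <- base + shifts[k]
  }
  p <- stats::plogis(eta)
  mk <- function(idx, xy) {
    data.frame(x = xy[, 1], y = xy[, 2], covs[idx, , drop = FALSE],
               p1 = p[idx, 1], p2 = p[idx, 2], p3 = p[idx, 3])
  }
  list(obs = mk(seq_len(m_o), xy_obs),
       grid = mk(m_o + seq_len(m_g), xy_grid),
       range = rng)
}

#' Generate the full simulation study
#'
#' One truth draw is shared by all datasets. For each sample-size family
#' U\{2, K\}, sample sizes are drawn per cluster and deterministic counts
#' formed for all three doses, yielding the point-level data of all three
#' target indicators per family (|families| x 3 datasets in the
#' bookkeeping of the study design; the rows live in one cluster table per
#' family, from which the per-indicator datasets are derived).
#'
#' @param cfg a \code{sim_config}
#' @return object of class \code{sim_study}: list with \code{truth},
#'   \code{datasets} (one \code{cluster_dataset} per size family, named
#'   \code{K<bound>}), \code{n_datasets} (families x 3), \code{config}
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- simulate_truth(cfg)
  obs <- truth$obs
  datasets <- list()
  for (K in cfg$size_families) {
    n <- draw_sample_sizes(nrow(obs), K)
    yy <- make_counts(n, obs$p1, obs$p2, obs$p3,
                      round_counts = cfg$round_counts)
    df <- data.frame(cluster_id = paste0("c", seq_len(nrow(obs))),
                     x = obs$x, y = obs$y, n = n,
                     y1 = yy$y1, y2 = yy$y2, y3 = yy$y3,
                     obs[, c("cov_norm", "cov_gamma", "cov_t")])
    datasets[[paste0("K", K)]] <- cluster_dataset(df)
  }
  structure(list(truth = truth, datasets = datasets,
                 n_datasets = 3L * length(cfg$size_families),
                 config = cfg),
            class = "sim_study")
}

#' Synthetic geography fixture: grid, nested admin rectangles, population
#'
#' Builds a rectangular prediction grid over the simulation window, two
#' nested levels of rectangular admin units partitioning it (a coarse
#' "state" level and a finer "district" level), and a log-normal
#' population per cell.
#'
#' @param cfg a \code{sim_config}
#' @param n_coarse number of blocks per axis at the coarse level (default 2)
#' @param n_fine number of blocks per axis at the fine level (default 4;
#'   must be a multiple of \code{n_coarse} for nesting)
#' @param truth optional output of \code{\link{simulate_truth}} whose grid
#'   covariates should be attached (defaults to fresh covariates)
#' @return list with \code{grid} (a \code{prediction_grid}) and
#'   \code{units} (admin units with \code{member_cells} assigned)
#' @export
make_fixture_geography <- function(cfg, n_coarse = 2, n_fine = 4,
                                   truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_fine %% n_coarse != 0) stop("n_fine must be a multiple of n_coarse")
  set.seed(cfg$seed + 1L)
  if (is.null(truth)) truth <- simulate_truth(cfg)
  g <- truth$grid
  grid <- prediction_grid(data.frame(
    cell_id = paste0("g", seq_len(nrow(g))),
    x = g$x, y = g$y,
    population = stats::rlnorm(nrow(g), meanlog = 5, sdlog = 0.5),
    g[, c("cov_norm", "cov_gamma", "cov_t")]))
  w <- cfg$window
  mk_units <- function(nb, level) {
    xs <- seq(w[1], w[2], length.out = nb + 1)
    ys <- seq(w[3], w[4], length.out = nb + 1)
    units <- list()
    for (i in seq_len(nb)) for (j in seq_len(nb)) {
      ring <- rbind(c(xs[i], ys[j]), c(xs[i + 1], ys[j]),
                    c(xs[i + 1], ys[j + 1]), c(xs[i], ys[j + 1]),
                    c(xs[i], ys[j]))
      units[[length(units) + 1L]] <- list(
        unit_id = paste0(level, "_", i, "_", j), level = level,
        rings = list(ring), member_cells = character(0))
    }
    units
  }
  units <- c(mk_units(n_coarse, "state"), mk_units(n_fine, "district"))
  units <- suppressWarnings(assign_cells_to_units(grid, units))
  list(grid = grid, units = units)
}

#' Write a simulation study to a directory
#'
#' Truth tables, one cluster-table file per dataset, a config echo and a
#' seed log, all as delimited text.
#'
#' @param study a \code{sim_study}
#' @param out_dir destination directory
#' @export
write_study <- function(study, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.table(study$truth$obs, file.path(out_dir, "truth_obs.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(study$truth$grid, file.path(out_dir, "truth_grid.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  for (nm in names(study$datasets)) {
    write_cluster_table(study$datasets[[nm]],
                        file.path(out_dir, paste0("clusters_", nm, ".csv")))
  }
  cfg <- study$config
  writeLines(c(paste0("seed=", cfg$seed),
               paste0("m_obs=", cfg$m_obs),
               paste0("range=", study$truth$range),
               paste0("sigma2=", cfg$sigma2),
               paste0("sigma2_eps=", cfg$sigma2_eps),
               paste0("beta=", paste(cfg$beta, collapse = ",")),
               paste0("increments=", paste(cfg$increments, collapse = ",")),
               paste0("size_families=", paste(cfg$size_families, collapse = ",")),
               paste0("spatial=", cfg$spatial)),
             file.path(out_dir, "config.txt"))
  invisible(out_dir)
}
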