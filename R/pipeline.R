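## Orchestration of the two workflows: the simulation study and the
## end-to-end coverage-mapping pipeline. These functions are the
## programmatic interface; a thin command-line wrapper around them lives
## in inst/cli/vaxmono.R.

#' Run the simulation study
#'
#' Generates the study with \code{\link{generate_study}}, fits the CP and
#' RB constructions to every dataset, and computes in-sample (observation
#' locations, against the true simulated surfaces) and out-of-sample
#' (prediction grid) metrics for both the modelled and the target
#' indicators.
#'
#' @param cfg a \code{sim_config}
#' @param spec a \code{prior_spec}
#' @param settings sampler settings template (list with n_draws, n_burn,
#'   thin); per-fit seeds are derived from \code{cfg$seed}
#' @param out_dir optional directory for the metric tables
#' @return data frame of metrics: one row per (size family, approach,
#'   scope in/out, indicator, metric type)
#' @export
run_simulation_study <- function(cfg, spec = prior_spec(),
                                 settings = list(n_draws = 250, n_burn = 700,
                                                 thin = 2),
                                 out_dir = NULL) {
  study <- generate_study(cfg)
  truth_obs <- study$truth$obs
  truth_grid <- study$truth$grid
  grid_new <- truth_grid[, c("x", "y", "cov_norm", "cov_gamma", "cov_t")]
  rows <- list()

  # true values of the modelled indicators (identical for CP and RB)
  truth_mod_obs <- data.frame(p1 = truth_obs$p1,
                              mid = truth_obs$p2 / truth_obs$p1,
                              last = truth_obs$p3 / truth_obs$p2)
  fit_seed <- 0L

  for (Knm in names(study$datasets)) {
    ds <- study$datasets[[Knm]]
    fits_by_approach <- list()
    for (appr in c("CP", "RB")) {
      build <- if (appr == "CP") build_cp_datasets else build_rb_datasets
      sets <- suppressMessages(build(ds))
      fits <- list()
      for (j in seq_along(sets)) {
        nm <- names(sets)[j]
        if (appr == "RB" && nm == "p1" && !is.null(fits_by_approach$CP$p1)) {
          fits[[nm]] <- fits_by_approach$CP$p1  # identical dataset: reuse
          next
        }
        fit_seed <- fit_seed + 1L
        st <- fit_settings(n_draws = settings$n_draws,
                           n_burn = settings$n_burn, thin = settings$thin,
                           seed = cfg$seed * 1000L + fit_seed,
                           store_latent = FALSE)
        fits[[nm]] <- fit(sets[[j]], spec, st)
      }
      fits_by_approach[[appr]] <- fits

      # in-sample: fitted draws at the observation locations
      fitted_draws <- lapply(fits, fitted)
      # align columns back to the full cluster set (drop-outs get NA)
      align <- function(fd, ids) {
        out <- matrix(NA_real_, nrow(fd), nrow(ds))
        out[, match(ids, ds$cluster_id)] <- fd
        out
      }
      fd_al <- Map(function(f, fd) align(fd, f$data$cluster_id),
                   fits, fitted_draws)
      mod_names <- c("p1", "mid", "last")
      for (j in 1:3) {
        fd <- fd_al[[j]]
        keep <- !is.na(fd[1, ])
        pm <- suppressWarnings(point_metrics(truth_mod_obs[[mod_names[j]]][keep],
                                             colMeans(fd[, keep, drop = FALSE])))
        rows[[length(rows) + 1L]] <- data.frame(
          family = Knm, approach = appr, scope = "in", kind = "modeled",
          indicator = mod_names[j], avbias = pm$avbias, rmse = pm$rmse,
          mae = pm$mae, correlation = pm$correlation, coverage95 = NA)
      }
      # in-sample target indicators (monotone composition at obs locations);
      # restrict to clusters present in all three indicator datasets
      common <- !is.na(fd_al[[1]][1, ]) & !is.na(fd_al[[2]][1, ]) &
        !is.na(fd_al[[3]][1, ])
      tg_in <- compose_targets(fd_al[[1]][, common, drop = FALSE],
                               fd_al[[2]][, common, drop = FALSE],
                               fd_al[[3]][, common, drop = FALSE])
      for (dose in 1:3) {
        tr <- truth_obs[[paste0("p", dose)]][common]
        dr <- tg_in[[paste0("p", dose)]]
        pm <- suppressWarnings(point_metrics(tr, colMeans(dr)))
        cov95 <- interval_coverage(tr, apply(dr, 2, stats::quantile, 0.025),
                                   apply(dr, 2, stats::quantile, 0.975))
        rows[[length(rows) + 1L]] <- data.frame(
          family = Knm, approach = appr, scope = "in", kind = "target",
          indicator = paste0("p", dose), avbias = pm$avbias, rmse = pm$rmse,
          mae = pm$mae, correlation = pm$correlation, coverage95 = cov95)
      }
      # out-of-sample: predict the grid, compose targets
      pg <- lapply(fits, function(f)
        predict_surface(f, grid_new, predict_nugget = TRUE))
      tg <- compose_targets(pg[[1]], pg[[2]], pg[[3]], locations = grid_new)
      for (dose in 1:3) {
        tr <- truth_grid[[paste0("p", dose)]]
        dr <- tg[[paste0("p", dose)]]
        pm <- suppressWarnings(point_metrics(tr, colMeans(dr)))
        cov95 <- interval_coverage(tr, apply(dr, 2, stats::quantile, 0.025),
                                   apply(dr, 2, stats::quantile, 0.975))
        rows[[length(rows) + 1L]] <- data.frame(
          family = Knm, approach = appr, scope = "out", kind = "target",
          indicator = paste0("p", dose), avbias = pm$avbias, rmse = pm$rmse,
          mae = pm$mae, correlation = pm$correlation, coverage95 = cov95)
      }
    }
  }
  report <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(report, file.path(out_dir, "simulation_metrics.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    write_study(study, file.path(out_dir, "study"))
  }
  report
}

#' Run the full coverage-mapping pipeline
#'
#' filter clusters -> build indicator datasets -> fit the three models ->
#' predict the grid -> compose monotone targets -> summarize surfaces ->
#' aggregate to admin units -> dropout rates -> zero-dose counts. All
#' artifacts are written with a checksum manifest when \code{out_dir} is
#' given.
#'
#' @param clusters a \code{cluster_dataset} (or path to a cluster table)
#' @param grid a \code{prediction_grid} (or path)
#' @param units admin units with member cells assigned (or GeoJSON path;
#'   requires \code{grid} to be assigned then)
#' @param approach \code{"CP"} or \code{"RB"}
#' @param reference \code{"first"} or \code{"last"} dose as reference
#' @param spec a \code{prior_spec}
#' @param settings sampler settings template
#' @param seed master seed
#' @param min_n minimum cluster sample size (default 2)
#' @param out_dir optional output directory
#' @return list with \code{targets} (a \code{target_draws}),
#'   \code{surfaces} (summaries per dose), \code{admin} (aggregates per
#'   dose), \code{dropout} (pairs 1-2, 2-3, 1-3), \code{zero_dose},
#'   \code{fits}
#' @export
run_mapping <- function(clusters, grid, units, approach = c("CP", "RB"),
                        reference = c("first", "last"), spec = prior_spec(),
                        settings = list(n_draws = 500, n_burn = 800, thin = 2),
                        seed = 1L, min_n = 2, out_dir = NULL) {
  approach <- match.arg(approach)
  reference <- match.arg(reference)
  if (is.character(clusters)) clusters <- read_cluster_table(clusters)
  if (is.character(grid)) grid <- read_grid_table(grid)
  if (is.character(units)) {
    units <- assign_cells_to_units(grid, read_admin_geojson(units))
  }
  clusters <- filter_clusters(clusters, min_n = min_n)
  build <- if (approach == "CP") build_cp_datasets else build_rb_datasets
  sets <- build(clusters, reference = reference)
  grid_new <- as.data.frame(grid)[, c("x", "y", covariate_names(grid)),
                                  drop = FALSE]
  fits <- list(); pg <- list()
  for (j in seq_along(sets)) {
    st <- fit_settings(n_draws = settings$n_draws, n_burn = settings$n_burn,
                       thin = settings$thin, seed = seed + j,
                       store_latent = TRUE)
    fits[[names(sets)[j]]] <- fit(sets[[j]], spec, st)
    pg[[j]] <- predict_surface(fits[[j]], grid_new, predict_nugget = TRUE,
                               seed = seed + 100L + j)
  }
  targets <- compose_targets(pg[[1]], pg[[2]], pg[[3]], locations = grid_new,
                             reference = reference)
  surfaces <- lapply(1:3, function(dose) {
    cbind(cell_id = grid$cell_id,
          summarize_surface(targets[[paste0("p", dose)]]))
  })
  names(surfaces) <- paste0("p", 1:3)
  admin <- lapply(1:3, function(dose)
    aggregate_admin(targets[[paste0("p", dose)]], grid, units))
  names(admin) <- paste0("p", 1:3)
  dropout <- list(
    d12 = dropout_rates(targets, c(1, 2)),
    d23 = dropout_rates(targets, c(2, 3)),
    d13 = dropout_rates(targets, c(1, 3)))
  unit_pop <- vapply(units, function(u) {
    sum(grid$population[match(u$member_cells, grid$cell_id)])
  }, 0)
  names(unit_pop) <- vapply(units, `[[`, "", "unit_id")
  zd <- zero_dose(admin$p1, unit_pop)
  out <- list(targets = targets, surfaces = surfaces, admin = admin,
              dropout = dropout, zero_dose = zd, fits = fits,
              approach = approach, seed = seed)
  if (!is.null(out_dir)) {
    summaries <- list(zero_dose = zd)
    for (dose in paste0("p", 1:3)) {
      summaries[[paste0("admin_", dose)]] <- do.call(rbind, lapply(
        admin[[dose]], function(u) data.frame(unit_id = u$unit_id,
                                              level = u$level,
                                              t(u$summary))))
    }
    out$manifest <- write_outputs(surfaces, summaries, out_dir)
  }
  out
}
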