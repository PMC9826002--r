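## Post-processing of posterior coverage surfaces: population-weighted
## admin aggregation, uncertainty summaries, dropout rates, zero-dose
## counts. All aggregation is done per posterior draw, then summarized,
## so uncertainty propagates through every derived quantity.

#' Population-weighted admin aggregation of coverage draws
#'
#' Per posterior draw and unit, the weighted mean of the cell-level
#' coverage draws with weights proportional to the cell populations of
#' the unit's member cells. Zero-population units fall back to an
#' unweighted mean with a warning; units with no member cells yield NA
#' with a warning.
#'
#' @param p_draws S x L matrix of coverage draws over the grid cells
#' @param grid a \code{prediction_grid} (cells in the column order of
#'   \code{p_draws})
#' @param units admin units with \code{member_cells} assigned
#' @return list per unit: \code{unit_id}, \code{level}, \code{draws}
#'   (length-S vector), and \code{summary} (mean, sd, q2.5, q97.5)
#' @export
aggregate_admin <- function(p_draws, grid, units) {
  stopifnot(inherits(grid, "prediction_grid"))
  p_draws <- as.matrix(p_draws)
  if (ncol(p_draws) != nrow(grid)) {
    stop("p_draws columns must match grid cells")
  }
  cell_index <- stats::setNames(seq_len(nrow(grid)), grid$cell_id)
  lapply(units, function(u) {
    idx <- cell_index[u$member_cells]
    if (length(idx) == 0L) {
      warning("unit '", u$unit_id, "' has no member cells; aggregate is NA")
      return(list(unit_id = u$unit_id, level = u$level,
                  draws = rep(NA_real_, nrow(p_draws)),
                  summary = c(mean = NA, sd = NA, q2.5 = NA, q97.5 = NA)))
    }
    pop <- grid$population[idx]
    if (sum(pop) <= 0) {
      warning("unit '", u$unit_id, "' has zero population; using unweighted mean")
      w <- rep(1 / length(idx), length(idx))
    } else {
      w <- pop / sum(pop)
    }
    dr <- drop(p_draws[, idx, drop = FALSE] %*% w)
    list(unit_id = u$unit_id, level = u$level, draws = dr,
         summary = c(mean = mean(dr), sd = stats::sd(dr),
                     q2.5 = unname(stats::quantile(dr, 0.025)),
                     q97.5 = unname(stats::quantile(dr, 0.975))))
  })
}

#' Relative dropout rates between two doses
#'
#' \code{100 * (p_i - p_j) / p_i} for doses i < j, computed per posterior
#' draw; lies in [0, 100] whenever the draws are monotone. Locations (or
#' units) with p_i = 0 yield NA.
#'
#' @param t a \code{target_draws} object (grid level) or a list of two
#'   matrices/vectors of draws for doses i and j (admin level)
#' @param pair integer pair c(i, j) with i < j, doses among 1..3
#' @return list with \code{draws} (S x L matrix of dropout percentages)
#'   and \code{summary} (per location: posterior mean, sd, q2.5, q97.5)
#' @export
dropout_rates <- function(t, pair = c(1, 3)) {
  if (pair[1] >= pair[2]) stop("dropout pair must satisfy i < j")
  if (inherits(t, "target_draws")) {
    pi_d <- t[[paste0("p", pair[1])]]
    pj_d <- t[[paste0("p", pair[2])]]
  } else {
    pi_d <- as.matrix(t[[1]]); pj_d <- as.matrix(t[[2]])
  }
  if (any(pj_d > pi_d + 1e-9)) stop("draws are not monotone for this pair")
  dr <- 100 * (pi_d - pj_d) / pi_d
  dr[pi_d == 0] <- NA_real_
  summ <- cbind(mean = colMeans(dr, na.rm = TRUE),
                sd = apply(dr, 2, stats::sd, na.rm = TRUE),
                q2.5 = apply(dr, 2, stats::quantile, 0.025, na.rm = TRUE),
                q97.5 = apply(dr, 2, stats::quantile, 0.975, na.rm = TRUE))
  list(draws = dr, summary = summ)
}

#' Zero-dose counts per admin unit
#'
#' Per posterior draw, population times (1 - p1); population is treated
#' as fixed. The default pathway works from admin-level aggregated p1
#' draws; a grid-level variant (aggregate cell-level zero-dose counts)
#' is available via \code{grid_level}.
#'
#' @param admin_p1 output of \code{\link{aggregate_admin}} for dose 1, or
#'   (when \code{grid_level = TRUE}) an S x L matrix of cell-level p1
#'   draws
#' @param populations named vector of unit populations (admin pathway), or
#'   for the grid pathway a \code{prediction_grid} plus \code{units}
#' @param grid_level use the grid-level pathway (default FALSE)
#' @param grid,units required when \code{grid_level = TRUE}
#' @return data frame per unit: mean, q2.5, q97.5, ci_width of the
#'   zero-dose count
#' @export
zero_dose <- function(admin_p1, populations = NULL, grid_level = FALSE,
                      grid = NULL, units = NULL) {
  if (!grid_level) {
    out <- do.call(rbind, lapply(admin_p1, function(u) {
      pop <- populations[[u$unit_id]]
      if (is.null(pop) || is.na(pop)) stop("missing population for unit ", u$unit_id)
      zd <- pop * (1 - u$draws)
      data.frame(unit_id = u$unit_id, level = u$level,
                 population = pop, mean = mean(zd),
                 q2.5 = unname(stats::quantile(zd, 0.025)),
                 q97.5 = unname(stats::quantile(zd, 0.975)))
    }))
  } else {
    stopifnot(!is.null(grid), !is.null(units))
    p_draws <- as.matrix(admin_p1)
    cell_index <- stats::setNames(seq_len(nrow(grid)), grid$cell_id)
    out <- do.call(rbind, lapply(units, function(u) {
      idx <- cell_index[u$member_cells]
      pop <- grid$population[idx]
      zd_cells <- sweep(1 - p_draws[, idx, drop = FALSE], 2, pop, "*")
      zd <- rowSums(zd_cells)
      data.frame(unit_id = u$unit_id, level = u$level,
                 population = sum(pop), mean = mean(zd),
                 q2.5 = unname(stats::quantile(zd, 0.025)),
                 q97.5 = unname(stats::quantile(zd, 0.975)))
    }))
  }
  out$ci_width <- out$q97.5 - out$q2.5
  rownames(out) <- NULL
  out
}

#' Cellwise posterior summaries of a coverage surface
#'
#' @param p_draws S x L matrix of draws (S >= 2)
#' @return data frame per cell: mean, sd, q2.5, q97.5
#' @export
summarize_surface <- function(p_draws) {
  p_draws <- as.matrix(p_draws)
  if (nrow(p_draws) < 2) stop("need at least 2 draws")
  data.frame(mean = colMeans(p_draws),
             sd = apply(p_draws, 2, stats::sd),
             q2.5 = apply(p_draws, 2, stats::quantile, 0.025),
             q97.5 = apply(p_draws, 2, stats::quantile, 0.975))
}
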