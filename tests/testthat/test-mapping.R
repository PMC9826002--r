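make_grid2 <- function() {
  prediction_grid(data.frame(cell_id = c("g1", "g2"), x = c(0.5, 1.5),
                             y = 0.5, population = c(250, 750)))
}

test_that("admin aggregation is the population-weighted mean per draw", {
  grid <- make_grid2()
  units <- list(list(unit_id = "U", level = "district",
                     rings = NULL, member_cells = c("g1", "g2")))
  p <- matrix(c(0.4, 0.8), nrow = 1)        # one draw, q = (0.25, 0.75)
  agg <- aggregate_admin(p, grid, units)
  expect_equal(agg[[1]]$draws, 0.7)
  # uniform surface is invariant to the weights
  pc <- matrix(0.37, nrow = 3, ncol = 2)
  expect_equal(aggregate_admin(pc, grid, units)[[1]]$draws, rep(0.37, 3))
  # empty unit -> NA with warning
  units0 <- list(list(unit_id = "E", level = "district", rings = NULL,
                      member_cells = character(0)))
  expect_warning(agg0 <- aggregate_admin(p, grid, units0), "no member cells")
  expect_true(is.na(agg0[[1]]$summary["mean"]))
  # zero population -> unweighted mean with warning
  gz <- prediction_grid(data.frame(cell_id = c("g1", "g2"), x = c(0.5, 1.5),
                                   y = 0.5, population = c(0, 0)))
  expect_warning(aggz <- aggregate_admin(p, gz, units), "zero population")
  expect_equal(aggz[[1]]$draws, 0.6)
})

test_that("nested aggregation is associative: districts combine to the state", {
  set.seed(8)
  grid <- prediction_grid(data.frame(cell_id = paste0("g", 1:6),
                                     x = seq(0.5, 5.5), y = 0.5,
                                     population = runif(6, 10, 100)))
  p <- matrix(runif(30), 5, 6)
  districts <- list(
    list(unit_id = "d1", level = "district", member_cells = paste0("g", 1:3)),
    list(unit_id = "d2", level = "district", member_cells = paste0("g", 4:6)))
  state <- list(list(unit_id = "s", level = "state",
                     member_cells = paste0("g", 1:6)))
  ad <- aggregate_admin(p, grid, districts)
  as_ <- aggregate_admin(p, grid, state)
  pop_d <- c(sum(grid$population[1:3]), sum(grid$population[4:6]))
  combined <- (ad[[1]]$draws * pop_d[1] + ad[[2]]$draws * pop_d[2]) / sum(pop_d)
  expect_equal(combined, as_[[1]]$draws, tolerance = 1e-12)
})

test_that("aggregation preserves monotonicity across doses per draw", {
  set.seed(15)
  grid <- prediction_grid(data.frame(cell_id = paste0("g", 1:10),
                                     x = 1:10, y = 0,
                                     population = runif(10, 1, 50)))
  units <- list(list(unit_id = "U", level = "state",
                     member_cells = paste0("g", 1:10)))
  tg <- compose_targets(matrix(runif(80), 8), matrix(runif(80), 8),
                        matrix(runif(80), 8))
  a1 <- aggregate_admin(tg$p1, grid, units)[[1]]$draws
  a2 <- aggregate_admin(tg$p2, grid, units)[[1]]$draws
  a3 <- aggregate_admin(tg$p3, grid, units)[[1]]$draws
  expect_true(all(a1 >= a2 & a2 >= a3))
})

test_that("dropout rates follow 100 (p_i - p_j) / p_i and stay in [0,100]", {
  # printed national proportions for doses 1 and 3
  d <- dropout_rates(list(matrix(0.654), matrix(0.499)), c(1, 3))
  expect_equal(round(d$draws[1, 1], 2), 23.70)
  expect_equal(dropout_rates(list(matrix(0.5), matrix(0.5)), c(1, 2))$draws[1, 1], 0)
  expect_equal(dropout_rates(list(matrix(0.3), matrix(0)), c(2, 3))$draws[1, 1], 100)
  # p_i = 0 -> missing
  expect_true(is.na(dropout_rates(list(matrix(0), matrix(0)), c(1, 3))$draws[1, 1]))
  expect_error(dropout_rates(list(matrix(0.5), matrix(0.5)), c(3, 1)), "i < j")
  expect_error(dropout_rates(list(matrix(0.3), matrix(0.6)), c(1, 2)),
               "not monotone")
  # random monotone draws stay inside [0, 100]
  tg <- compose_targets(matrix(runif(200), 10), matrix(runif(200), 10),
                        matrix(runif(200), 10))
  for (pr in list(c(1, 2), c(2, 3), c(1, 3))) {
    dd <- dropout_rates(tg, pr)$draws
    expect_true(all(dd >= 0 & dd <= 100, na.rm = TRUE))
  }
})

test_that("zero-dose counts scale population by 1 - p1 with fixed population", {
  admin <- list(list(unit_id = "U", level = "state",
                     draws = rep(0.6, 50),
                     summary = c(mean = 0.6, sd = 0, q2.5 = 0.6, q97.5 = 0.6)))
  zd <- zero_dose(admin, c(U = 1000))
  expect_equal(zd$mean, 400)
  expect_equal(zd$ci_width, 0)
  admin[[1]]$draws <- rep(1, 50)
  expect_equal(zero_dose(admin, c(U = 1000))$mean, 0)
})

test_that("grid- and admin-level zero-dose pathways agree for flat surfaces", {
  grid <- make_grid2()
  units <- list(list(unit_id = "U", level = "district",
                     member_cells = c("g1", "g2")))
  p <- matrix(0.35, nrow = 20, ncol = 2)   # spatially constant p1
  admin <- aggregate_admin(p, grid, units)
  zd_admin <- zero_dose(admin, c(U = sum(grid$population)))
  zd_grid <- zero_dose(p, grid_level = TRUE, grid = grid, units = units)
  expect_equal(zd_admin$mean, zd_grid$mean, tolerance = 1e-9)
})

test_that("zero-dose totals add up across a partition of the grid", {
  set.seed(31)
  grid <- prediction_grid(data.frame(cell_id = paste0("g", 1:8), x = 1:8,
                                     y = 0, population = runif(8, 100, 1000)))
  units <- list(
    list(unit_id = "A", level = "d", member_cells = paste0("g", 1:4)),
    list(unit_id = "B", level = "d", member_cells = paste0("g", 5:8)))
  p <- matrix(runif(8 * 30), 30, 8)
  admin <- aggregate_admin(p, grid, units)
  pops <- c(A = sum(grid$population[1:4]), B = sum(grid$population[5:8]))
  zd <- zero_dose(admin, pops)
  nat <- aggregate_admin(p, grid,
                         list(list(unit_id = "N", level = "n",
                                   member_cells = paste0("g", 1:8))))
  zd_nat <- zero_dose(nat, c(N = sum(grid$population)))
  expect_equal(sum(zd$mean), zd_nat$mean, tolerance = 1e-6 * zd_nat$mean)
})

test_that("surface summaries match a two-pass oracle", {
  set.seed(9)
  pd <- matrix(runif(120), 30, 4)
  s <- summarize_surface(pd)
  expect_equal(s$mean[2], sum(pd[, 2]) / 30, tolerance = 1e-12)
  mu <- mean(pd[, 3])
  expect_equal(s$sd[3], sqrt(sum((pd[, 3] - mu)^2) / 29), tolerance = 1e-12)
  expect_equal(summarize_surface(matrix(0.4, 5, 2))$sd, c(0, 0))
  expect_equal(summarize_surface(rbind(0.4, 0.6))$mean, 0.5)
  expect_error(summarize_surface(matrix(1, 1, 3)), "at least 2")
})
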