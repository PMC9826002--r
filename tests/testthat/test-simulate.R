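test_that("covariates follow the stated distributions and are reproducible", {
  X <- simulate_covariates(1e5, seed = 10)
  expect_equal(dim(X), c(1e5, 3))
  # N(0,1): mean ~ 0 within 3 SE
  expect_lt(abs(mean(X[, "cov_norm"])), 3 / sqrt(1e5))
  # Gamma(1,1): mean ~ 1 (sd 1) within 3 SE
  expect_lt(abs(mean(X[, "cov_gamma"]) - 1), 3 / sqrt(1e5))
  # t(2): infinite variance, use the median ~ 0
  expect_lt(abs(median(X[, "cov_t"])), 3 * 1.3 / sqrt(1e5))
  expect_identical(X, simulate_covariates(1e5, seed = 10))
  expect_equal(dim(simulate_covariates(1, seed = 1)), c(1, 3))
})

test_that("sample sizes are discrete uniform on {2..K}", {
  n <- draw_sample_sizes(1e5, 10, seed = 3)
  expect_gte(min(n), 2); expect_lte(max(n), 10)
  # mean of U{2,10} is 6, sd = sqrt((9^2-1)/12)
  se <- sqrt((9^2 - 1) / 12) / sqrt(1e5)
  expect_lt(abs(mean(n) - 6), 3 * se)
  expect_true(all(draw_sample_sizes(50, 2, seed = 1) == 2))
  expect_error(draw_sample_sizes(10, 1), ">= 2")
})

test_that("deterministic counts are exact expectations and monotone", {
  y <- make_counts(10, 0.654, 0.579, 0.499)
  expect_equal(unlist(y), c(y1 = 6.54, y2 = 5.79, y3 = 4.99))
  expect_equal(unlist(make_counts(7, 1, 1, 1)), c(y1 = 7, y2 = 7, y3 = 7))
  set.seed(5)
  p1 <- runif(100); p2 <- p1 * runif(100); p3 <- p2 * runif(100)
  yy <- make_counts(sample(2:50, 100, TRUE), p1, p2, p3)
  expect_true(all(yy$y1 >= yy$y2 & yy$y2 >= yy$y3))
  expect_error(make_counts(5, 0.2, 0.5, 0.1), "monotone")
})

test_that("truth surfaces apply the incremental shifts on the logit scale", {
  # with beta = 0, no field, no nugget the linear predictor is exactly 0,
  # so the triple is the inverse logit of (0, -1.3, -2.5)
  cfg <- sim_config(m_obs = 20, grid_nx = 3, grid_ny = 3,
                    beta = c(0, 0, 0, 0), spatial = FALSE, sigma2_eps = 1e-20,
                    seed = 2)
  tr <- simulate_truth(cfg)
  expect_lt(max(abs(tr$obs$p1 - 0.5)), 1e-8)
  expect_equal(tr$obs$p2[1], plogis(-1.3), tolerance = 1e-7)
  expect_equal(tr$obs$p3[1], plogis(-2.5), tolerance = 1e-7)
  expect_equal(tr$obs$p2[1], 0.2142, tolerance = 1e-3)
  expect_equal(tr$obs$p3[1], 0.0759, tolerance = 1e-3)
  # no shift -> all three surfaces identical
  cfg0 <- sim_config(m_obs = 10, increments = c(-1e-12, -2e-12), seed = 3)
  tr0 <- simulate_truth(cfg0)
  expect_equal(tr0$obs$p1, tr0$obs$p2, tolerance = 1e-9)
  # monotone everywhere, every seed
  for (s in 1:5) {
    tr_s <- simulate_truth(sim_config(m_obs = 50, seed = s))
    expect_true(all(tr_s$obs$p1 >= tr_s$obs$p2 & tr_s$obs$p2 >= tr_s$obs$p3))
    expect_true(all(tr_s$grid$p1 >= tr_s$grid$p2 & tr_s$grid$p2 >= tr_s$grid$p3))
  }
})

test_that("simulated field correlation decays per the Matern model", {
  # pairs at distance ~r should correlate at ~0.1-0.15 over many draws
  set.seed(77)
  r <- 2.62
  xy <- rbind(c(0, 0), c(r, 0), c(30, 30), c(30 + r, 30))
  draws <- t(replicate(3000, vaxmono:::draw_field(xy, sigma2 = 1, range = r)))
  c1 <- cor(draws[, 1], draws[, 2]); c2 <- cor(draws[, 3], draws[, 4])
  expect_gt(mean(c(c1, c2)), 0.08)
  expect_lt(mean(c(c1, c2)), 0.20)
  # distant pairs are uncorrelated
  expect_lt(abs(cor(draws[, 1], draws[, 3])), 0.06)
})

test_that("spatial = FALSE removes the spatial correlation", {
  cfg <- sim_config(m_obs = 400, spatial = FALSE, seed = 9)
  tr <- simulate_truth(cfg)
  # residual after removing the known fixed effects is pure nugget
  X <- cbind(1, as.matrix(tr$obs[, c("cov_norm", "cov_gamma", "cov_t")]))
  res <- qlogis(tr$obs$p1) - drop(X %*% cfg$beta)
  D <- as.matrix(dist(cbind(tr$obs$x, tr$obs$y)))
  near <- D > 0 & D < 1.5
  # correlation among near pairs ~ 0: Moran-style statistic
  num <- sum(outer(res, res)[near]) / sum(near)
  expect_lt(abs(num) / var(res), 0.15)
})

test_that("generate_study produces the full study design deterministically", {
  cfg <- sim_config(m_obs = 30, seed = 4)
  st <- generate_study(cfg)
  expect_equal(st$n_datasets, 24)          # 8 size families x 3 indicators
  expect_length(st$datasets, 8)
  st1 <- generate_study(sim_config(m_obs = 30, size_families = 10, seed = 4))
  expect_equal(st1$n_datasets, 3)
  # same seed -> byte-identical study directories
  d1 <- file.path(withr::local_tempdir(), "s1")
  d2 <- file.path(withr::local_tempdir(), "s2")
  write_study(generate_study(cfg), d1)
  write_study(generate_study(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # every dataset respects the cluster-table invariants by construction
  expect_true(all(vapply(st$datasets, inherits, TRUE, "cluster_dataset")))
})

test_that("fixture geography partitions the grid with positive population", {
  cfg <- sim_config(m_obs = 5, grid_nx = 10, grid_ny = 10, seed = 6)
  fx <- make_fixture_geography(cfg, n_coarse = 2, n_fine = 4)
  states <- Filter(function(u) u$level == "state", fx$units)
  expect_length(states, 4)
  expect_true(all(vapply(states, function(u) length(u$member_cells), 0L) == 25))
  districts <- Filter(function(u) u$level == "district", fx$units)
  expect_equal(sum(vapply(districts, function(u) length(u$member_cells), 0L)),
               100)
  expect_true(all(fx$grid$population > 0))
  fx2 <- make_fixture_geography(cfg, n_coarse = 2, n_fine = 4)
  expect_identical(fx$grid$population, fx2$grid$population)
  expect_error(make_fixture_geography(cfg, n_coarse = 2, n_fine = 5),
               "multiple")
})

test_that("range_from_quartile recomputes the range from the locations", {
  cfg <- sim_config(m_obs = 80, range_from_quartile = TRUE, seed = 12)
  tr <- simulate_truth(cfg)
  set.seed(cfg$seed)
  w <- cfg$window
  xy <- cbind(runif(80, w[1], w[2]), runif(80, w[3], w[4]))
  expect_equal(tr$range, unname(quantile(dist(xy), 0.25)), tolerance = 1e-12)
  # the default 10 x 10 window makes that quartile land near 2.62
  expect_lt(abs(tr$range - 2.62), 1)
})
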