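test_that("Matern covariance has the right limits and effective-range behavior", {
  expect_equal(matern_cov(0, sigma2 = 2.3, range = 5), 2.3)
  # independent evaluation at d = r: 2^(1-nu)/Gamma(nu) * x K_nu(x), x = sqrt(8)
  x <- sqrt(8)
  ref <- x * besselK(x, 1)
  expect_equal(matern_cov(7, sigma2 = 1, range = 7), ref, tolerance = 1e-12)
  expect_gt(ref, 0.10); expect_lt(ref, 0.15)
  # decay far beyond the range
  expect_lt(matern_cov(100 * 3, sigma2 = 1, range = 3), 1e-6)
  expect_error(matern_cov(-1, 1, 1), "nonnegative")
})

test_that("Matern covariance matrices are positive semi-definite", {
  set.seed(11)
  for (i in 1:50) {
    m <- sample(5:25, 1)
    D <- as.matrix(dist(cbind(runif(m, 0, 10), runif(m, 0, 10))))
    s2 <- runif(1, 0.1, 5)
    K <- matern_cov(D, s2, runif(1, 0.1, 8))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8 * s2)
  }
})

test_that("tabulated fast correlation matches exact besselK evaluation", {
  set.seed(2)
  x <- exp(runif(5000, log(1e-6), log(30)))
  exact <- x * besselK(x, 1)
  expect_lt(max(abs(vaxmono:::fast_corr_nu1(log(x)) - exact)), 1e-8)
})

test_that("PC prior rates solve their tail statements", {
  spec <- prior_spec(r0 = 1)
  rates <- pc_prior_rates(spec)
  expect_equal(rates$lambda_eps, -log(0.01) / 3, tolerance = 1e-12)
  expect_equal(rates$lambda_eps, 1.5351, tolerance = 1e-4)
  expect_equal(rates$lambda_sigma, -log(0.01) / 3, tolerance = 1e-12)
  # plug-back: P(sigma > 3) under Exp(lambda)
  expect_equal(exp(-rates$lambda_sigma * 3), 0.01, tolerance = 1e-12)
  # plug-back for the range: integrate the inverse-range density up to r0
  expect_equal(rates$lambda_r, 4.6052, tolerance = 1e-4)
  dens <- function(r) rates$lambda_r / r^2 * exp(-rates$lambda_r / r)
  expect_equal(stats::integrate(dens, 0, 1)$value, 0.01, tolerance = 1e-6)
  expect_error(prior_spec(alpha_r = 1.2), "\\(0, 1\\)")
  expect_warning(pc_prior_rates(prior_spec(r0 = 1, nugget_alpha = 0.999)),
                 "degenerate")
})

test_that("log posterior matches a brute-force oracle on random instances", {
  # oracle_log_post and random_instance come from helper-oracles.R
  spec <- prior_spec(r0 = 0.8)
  for (s in 1:100) {
    inst <- random_instance(s)
    got <- log_unnorm_posterior(inst$params, inst$latent, inst$data, spec)
    want <- oracle_log_post(inst$params, inst$latent, inst$data, spec)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("log posterior worked value and degenerate cases", {
  df <- data.frame(cluster_id = c("a", "b"), x = c(0, 1), y = c(0, 0),
                   trials = c(2, 4), successes = c(1, 2))
  d1 <- indicator_dataset(df[1, ], "p1", "CP", covariate_names = character(0))
  d2 <- indicator_dataset(df[2, ], "p1", "CP", covariate_names = character(0))
  spec <- prior_spec(r0 = 0.5)
  params <- list(beta = 0, sigma2 = 1, range = 1, sigma2_eps = 1)
  latent <- list(omega = 0, eps = 0)
  lp1 <- log_unnorm_posterior(params, latent, d1, spec)
  lp2 <- log_unnorm_posterior(params, latent, d2, spec)
  # likelihood parts at p = 0.5: 2*log(0.5) vs 4*log(0.5); all else equal
  expect_equal(lp1 - lp2, log(4), tolerance = 1e-12)
  # p driven to 0 against successes -> -Inf returned, not an error
  lp_deg <- log_unnorm_posterior(params, list(omega = -Inf, eps = 0), d1, spec)
  expect_identical(lp_deg, -Inf)
  # latent dimension mismatch -> error
  expect_error(
    log_unnorm_posterior(params, list(omega = c(0, 0), eps = c(0, 0)), d1, spec),
    "latent dimension")
})

test_that("intercept-only fit recovers a balanced proportion", {
  set.seed(31)
  m <- 50
  df <- data.frame(cluster_id = paste0("c", 1:m), x = runif(m, 0, 10),
                   y = runif(m, 0, 10), trials = 20, successes = 10)
  data <- indicator_dataset(df, "p1", "CP", covariate_names = character(0))
  f <- suppressWarnings(fit(data, prior_spec(),
                            fit_settings(n_draws = 200, n_burn = 300, thin = 1,
                                         seed = 5, store_latent = FALSE)))
  p0 <- mean(plogis(f$draws$beta[, 1]))
  expect_lt(abs(p0 - 0.5), 0.05)
})

test_that("degenerate and invalid designs are rejected; tiny data still runs", {
  set.seed(8)
  m <- 12
  df <- data.frame(cluster_id = paste0("c", 1:m), x = runif(m), y = runif(m),
                   trials = 5, successes = 2, cov1 = rnorm(m))
  df$cov2 <- 2 * df$cov1  # collinear
  data <- indicator_dataset(df, "p1", "CP")
  expect_error(suppressWarnings(fit(data, prior_spec(), tiny_settings(1))),
               "rank deficient.*cov2")
  # 5 rows: runs with a warning, wide posteriors, no error
  df5 <- df[1:5, c("cluster_id", "x", "y", "trials", "successes", "cov1")]
  d5 <- indicator_dataset(df5, "p1", "CP")
  msgs <- character(0)
  withCallingHandlers(
    f5 <- fit(d5, prior_spec(), tiny_settings(2)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_match(paste(msgs, collapse = "; "), "fewer than 10")
  expect_true(all(is.finite(f5$draws$beta)))
})

test_that("kriging conditional moments match closed-form bivariate conditioning", {
  xy_dat <- rbind(c(0, 0), c(1, 0))
  xy_new <- rbind(c(0.3, 0.4))
  s2 <- 1.7; r <- 2.2; e2 <- 0.6
  u <- c(0.9, -0.4)
  got <- vaxmono:::krige_conditional(xy_dat, xy_new, u, s2, r, e2)
  # closed form, coded independently
  cv <- function(d) s2 * ifelse(d > 0, (sqrt(8) / r * d) * besselK(sqrt(8) / r * d, 1), 1)
  K <- rbind(c(s2 * (1 + 1e-8) + e2, cv(1)),
             c(cv(1), s2 * (1 + 1e-8) + e2))
  cx <- c(cv(sqrt(0.3^2 + 0.4^2)), cv(sqrt(0.7^2 + 0.4^2)))
  mu_ref <- drop(cx %*% solve(K, u))
  var_ref <- s2 - drop(cx %*% solve(K, cx))
  expect_equal(got$mean, mu_ref, tolerance = 1e-10)
  expect_equal(got$cov[1, 1], var_ref, tolerance = 1e-10)
  # far target reverts to the prior: mean ~ 0, variance ~ sigma2
  far <- vaxmono:::krige_conditional(xy_dat, rbind(c(500, 500)), u, s2, r, e2)
  expect_lt(abs(far$mean), 1e-6)
  expect_equal(far$cov[1, 1], s2, tolerance = 1e-6)
})

test_that("prediction at data locations reproduces fitted draws without nugget", {
  set.seed(21)
  m <- 25
  df <- data.frame(cluster_id = paste0("c", 1:m), x = runif(m, 0, 5),
                   y = runif(m, 0, 5), trials = sample(5:30, m, TRUE),
                   cov1 = rnorm(m))
  df$successes <- df$trials * plogis(rnorm(m, 0.3 + 0.5 * df$cov1, 0.8))
  data <- indicator_dataset(df, "p1", "CP")
  f <- suppressWarnings(fit(data, prior_spec(), tiny_settings(3)))
  # suppress the nugget in the stored draws, then predict at the data sites
  f$draws$sigma2_eps[] <- 1e-12
  pd <- predict_surface(f, as.data.frame(data), predict_nugget = FALSE)
  expect_equal(unname(pd), unname(fitted(f)), tolerance = 1e-3)
  # covariate mismatch is caught
  expect_error(predict_surface(f, data.frame(x = 1, y = 1)), "missing column")
})

test_that("fit archives round-trip the draw table", {
  set.seed(4)
  m <- 15
  df <- data.frame(cluster_id = paste0("c", 1:m), x = runif(m), y = runif(m),
                   trials = 10, successes = rbinom(m, 10, 0.6), cov1 = rnorm(m))
  f <- suppressWarnings(fit(indicator_dataset(df, "p1", "CP"), prior_spec(),
                            tiny_settings(6)))
  base <- file.path(withr::local_tempdir(), "fit")
  write_fit(f, base)
  tab <- utils::read.table(paste0(base, "_draws.csv"), header = TRUE, sep = ",")
  expect_equal(nrow(tab), 60)
  expect_equal(tab$sigma2, f$draws$sigma2, tolerance = 1e-6)
  meta <- readLines(paste0(base, "_meta.txt"))
  expect_true(any(grepl("^seed=6$", meta)))
})
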