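# independently coded brute-force evaluation of the joint unnormalized
# log posterior (dense Matern Gaussian + nugget + binomial-form
# likelihood + priors); deliberately avoids every package internal except
# the data accessors
oracle_log_post <- function(params, latent, data, spec) {
  X <- cbind(1, as.matrix(as.data.frame(data)[, covariate_names(data),
                                              drop = FALSE]))
  p <- plogis(drop(X %*% params$beta) + latent$omega + latent$eps)
  ll <- sum(data$successes * log(p) + (data$trials - data$successes) * log(1 - p))
  D <- as.matrix(dist(cbind(data$x, data$y)))
  kap <- sqrt(8) / params$range
  S <- params$sigma2 * ifelse(D > 0, kap * D * besselK(pmax(kap * D, 1e-300), 1), 1)
  diag(S) <- params$sigma2 * (1 + 1e-8)
  m <- nrow(S)
  lp_om <- -0.5 * drop(t(latent$omega) %*% solve(S, latent$omega)) -
    0.5 * c(determinant(S)$modulus) - 0.5 * m * log(2 * pi)
  lp_eps <- sum(dnorm(latent$eps, 0, sqrt(params$sigma2_eps), log = TRUE))
  lp_beta <- sum(dnorm(params$beta, 0, sqrt(1 / spec$beta_prec), log = TRUE))
  l_e <- -log(spec$nugget_alpha) / spec$nugget_u
  l_s <- -log(spec$sigma_alpha) / spec$sigma_u
  l_r <- -spec$r0 * log(spec$alpha_r)
  sig <- sqrt(params$sigma2); se <- sqrt(params$sigma2_eps)
  lp_hyp <- log(l_s) - l_s * sig + log(l_r) - 2 * log(params$range) -
    l_r / params$range + log(l_e) - l_e * se
  ll + lp_om + lp_eps + lp_beta + lp_hyp
}

# random small model instance for oracle comparisons
random_instance <- function(seed, m = 5) {
  set.seed(seed)
  df <- data.frame(cluster_id = paste0("c", 1:m), x = runif(m, 0, 4),
                   y = runif(m, 0, 4), trials = sample(2:30, m, TRUE),
                   cov1 = rnorm(m), cov2 = rnorm(m))
  df$successes <- df$trials * runif(m)
  data <- indicator_dataset(df[, c("cluster_id", "x", "y", "trials",
                                   "successes", "cov1", "cov2")], "p1", "CP")
  params <- list(beta = rnorm(3, 0, 0.8), sigma2 = runif(1, 0.2, 3),
                 range = runif(1, 0.5, 5), sigma2_eps = runif(1, 0.1, 2))
  latent <- list(omega = rnorm(m), eps = rnorm(m, 0, 0.7))
  list(data = data, params = params, latent = latent)
}
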