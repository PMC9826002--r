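## Bayesian binomial geostatistical model:
##   y(s) | p(s) ~ Binomial(n(s), p(s))
##   logit p(s)  = x(s)'beta + omega(s) + eps(s)
## omega: zero-mean Gaussian field, Matern covariance (nu = 1);
## eps:   iid Gaussian nugget. Fully Bayesian fit by MCMC:
## elliptical slice sampling for the latent vector u = omega + eps
## (marginally Gaussian with covariance  Sigma_omega + sigma2_eps I),
## adaptive random-walk Metropolis for beta and for the covariance
## parameters on the log scale.

#' Matern covariance function (smoothness fixed at 1)
#'
#' \code{sigma2 * 2^(1-nu)/Gamma(nu) * (kappa d)^nu * K_nu(kappa d)} with
#' \code{kappa = sqrt(8 nu) / range}, so that \code{range} is the effective
#' range: the distance at which the correlation falls to roughly 0.1.
#'
#' @param d distances (scalar, vector or matrix), same units as \code{range}
#' @param sigma2 marginal variance, > 0
#' @param range effective range, > 0
#' @param nu smoothness (default 1)
#' @return covariance values with the shape of \code{d}
#' @export
matern_cov <- function(d, sigma2, range, nu = 1) {
  if (any(d < 0)) stop("distances must be nonnegative")
  stopifnot(sigma2 > 0, range > 0, nu > 0)
  kappa <- sqrt(8 * nu) / range
  kd <- kappa * d
  out <- d
  pos <- kd > 0
  out[!pos] <- sigma2
  if (any(pos)) {
    x <- kd[pos]
    out[pos] <- sigma2 * (2^(1 - nu) / gamma(nu)) * x^nu * besselK(x, nu)
  }
  out
}

#' Prior specification for the geostatistical model
#'
#' Regression coefficients get independent N(0, 1/beta_prec) priors.
#' The nugget standard deviation and the field's marginal standard
#' deviation get penalized-complexity (exponential-tail) priors calibrated
#' by P(sd > u) = alpha; the range gets the matching inverse-range tail
#' P(range < r0) = alpha_r (the two-dimensional joint PC prior for a
#' Matern field, applied with independent calibration of each tail).
#'
#' @param beta_prec prior precision per coefficient (default 1e-3,
#'   i.e. variance 1000)
#' @param nugget_u,nugget_alpha tail statement P(sigma_eps > nugget_u) =
#'   nugget_alpha (defaults 3, 0.01)
#' @param sigma_u,sigma_alpha tail statement P(sigma > sigma_u) =
#'   sigma_alpha for the field sd (defaults 3, 0.01)
#' @param r0,alpha_r tail statement P(range < r0) = alpha_r; \code{r0 =
#'   NULL} defers to the fit, which uses 5\% of the north-south extent of
#'   the data
#' @return object of class \code{prior_spec}
#' @export
prior_spec <- function(beta_prec = 1e-3, nugget_u = 3, nugget_alpha = 0.01,
                       sigma_u = 3, sigma_alpha = 0.01,
                       r0 = NULL, alpha_r = 0.01) {
  for (a in c(nugget_alpha, sigma_alpha, alpha_r)) {
    if (a <= 0 || a >= 1) stop("PC tail probabilities must lie in (0, 1)")
  }
  stopifnot(beta_prec > 0, nugget_u > 0, sigma_u > 0, is.null(r0) || r0 > 0)
  structure(list(beta_prec = beta_prec, nugget_u = nugget_u,
                 nugget_alpha = nugget_alpha, sigma_u = sigma_u,
                 sigma_alpha = sigma_alpha, r0 = r0, alpha_r = alpha_r),
            class = "prior_spec")
}

#' Exponential rates implied by the PC tail statements
#'
#' For the standard deviations, P(sd > u) = exp(-lambda u) gives
#' \code{lambda = -log(alpha)/u}. For the range, the inverse-range tail
#' P(range < r0) = exp(-lambda_r / r0) gives \code{lambda_r = -r0
#' log(alpha_r)}, i.e. the prior density pi(r) = (lambda_r / r^2)
#' exp(-lambda_r / r).
#'
#' @param spec a \code{prior_spec}; \code{r0} must be set
#' @return list with \code{lambda_eps}, \code{lambda_sigma},
#'   \code{lambda_r}
#' @export
pc_prior_rates <- function(spec) {
  stopifnot(inherits(spec, "prior_spec"))
  if (is.null(spec$r0)) stop("r0 is not set; supply it or let fit() derive it")
  l_eps <- -log(spec$nugget_alpha) / spec$nugget_u
  l_sig <- -log(spec$sigma_alpha) / spec$sigma_u
  l_r <- -spec$r0 * log(spec$alpha_r)
  if (spec$nugget_alpha > 0.99 || spec$sigma_alpha > 0.99 || spec$alpha_r > 0.99) {
    warning("alpha close to 1 gives a degenerate (near-flat) PC prior")
  }
  list(lambda_eps = l_eps, lambda_sigma = l_sig, lambda_r = l_r)
}

## fast Matern (nu = 1) correlation x*K1(x), tabulated once from besselK
## on a dense uniform grid in log(x) (2e5 knots; linear interpolation
## error ~1e-9). Direct index arithmetic avoids a binary search, so a
## 45k-element covariance build costs well under a millisecond. Used in
## the sampler's hot path; the exported matern_cov stays exact.
.matern_tab <- new.env(parent = emptyenv())

matern_tab_init <- function() {
  n_knots <- 200001L
  t0 <- log(1e-8); t1 <- log(40)
  tg <- seq(t0, t1, length.out = n_knots)
  xg <- exp(tg)
  .matern_tab$t0 <- t0
  .matern_tab$dt <- (t1 - t0) / (n_knots - 1L)
  .matern_tab$n <- n_knots
  .matern_tab$y <- xg * besselK(xg, 1)
}

fast_corr_nu1 <- function(log_kd) {
  if (is.null(.matern_tab$y)) matern_tab_init()
  # clamping to the table ends is exact at both extremes: the correlation
  # is 1 - O(1e-17) at x = 1e-8 and ~3e-17 at x = 40
  pos <- (log_kd - .matern_tab$t0) / .matern_tab$dt
  pos[pos < 0] <- 0
  top <- .matern_tab$n - 1 - 1e-9
  pos[pos > top] <- top
  i <- as.integer(pos)
  fr <- pos - i
  y <- .matern_tab$y
  y[i + 1L] * (1 - fr) + y[i + 2L] * fr
}

# symmetric Matern covariance from a precomputed lower-triangle
# log-distance vector and index; returns the full m x m matrix
fast_matern_from_logd <- function(log_dl, m, sigma2, range, ltri_idx) {
  kappa <- sqrt(8) / range
  v <- sigma2 * fast_corr_nu1(log_dl + log(kappa))
  K <- matrix(0, m, m)
  K[ltri_idx] <- v
  K <- K + t(K)
  diag(K) <- sigma2
  K
}

# fast Matern covariance for an arbitrary distance matrix
fast_matern_mat <- function(D, sigma2, range) {
  kappa <- sqrt(8) / range
  out <- sigma2 * fast_corr_nu1(log(pmax(as.vector(D), 1e-300)) + log(kappa))
  out[as.vector(D) == 0] <- sigma2
  matrix(out, nrow(D), ncol(D))
}

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  hi <- x > 18 & x < 33.3
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

# binomial-form log likelihood (combinatorial constant omitted; valid for
# fractional successes): sum y log p + (n-y) log(1-p) with logit p = eta.
# Degenerate probabilities against the data give -Inf, not NaN.
binom_loglik_eta <- function(eta, trials, successes) {
  logp <- -log1pexp(-eta)
  log1mp <- -log1pexp(eta)
  s1 <- ifelse(successes > 0, successes * logp, 0)
  s2 <- ifelse(trials - successes > 0, (trials - successes) * log1mp, 0)
  sum(s1 + s2)
}

# log prior for (sigma, range, sigma_eps) under the PC tails, on the
# natural scale (no Jacobians here)
pc_log_prior <- function(sigma, range, sigma_eps, rates) {
  if (sigma <= 0 || range <= 0 || sigma_eps <= 0) return(-Inf)
  (log(rates$lambda_sigma) - rates$lambda_sigma * sigma) +
    (log(rates$lambda_r) - 2 * log(range) - rates$lambda_r / range) +
    (log(rates$lambda_eps) - rates$lambda_eps * sigma_eps)
}

#' Unnormalized joint log posterior of the geostatistical model
#'
#' The sum of the binomial-form log likelihood (combinatorial constant
#' omitted, so fractional successes are valid), the Gaussian log density
#' of the spatial field under the dense Matern covariance, the Gaussian
#' log density of the nugget, and the log priors. Returns \code{-Inf}
#' (rather than raising) when a fitted probability is degenerate against
#' the data.
#'
#' @param params list with \code{beta} (including intercept, ordered as
#'   intercept then covariates), \code{sigma2}, \code{range},
#'   \code{sigma2_eps}
#' @param latent list with \code{omega} and \code{eps}, each of length
#'   equal to the number of data rows
#' @param data an \code{indicator_dataset}
#' @param spec a \code{prior_spec} with \code{r0} set
#' @return scalar log posterior (unnormalized)
#' @export
log_unnorm_posterior <- function(params, latent, data, spec) {
  stopifnot(inherits(data, "indicator_dataset"), inherits(spec, "prior_spec"))
  m <- nrow(data)
  if (length(latent$omega) != m || length(latent$eps) != m) {
    stop("latent dimension must equal the number of data rows (", m, ")")
  }
  X <- cbind(1, as.matrix(as.data.frame(data)[, covariate_names(data), drop = FALSE]))
  if (length(params$beta) != ncol(X)) {
    stop("beta has length ", length(params$beta), ", expected ", ncol(X))
  }
  eta <- drop(X %*% params$beta) + latent$omega + latent$eps
  ll <- binom_loglik_eta(eta, data$trials, data$successes)
  if (!is.finite(ll)) return(-Inf)
  D <- as.matrix(stats::dist(cbind(data$x, data$y)))
  S <- matern_cov(D, params$sigma2, params$range)
  diag(S) <- diag(S) + 1e-8 * params$sigma2
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  v <- backsolve(ch, latent$omega, transpose = TRUE)
  lp_om <- -0.5 * sum(v^2) - sum(log(diag(ch))) - 0.5 * m * log(2 * pi)
  lp_eps <- sum(stats::dnorm(latent$eps, 0, sqrt(params$sigma2_eps), log = TRUE))
  lp_beta <- sum(stats::dnorm(params$beta, 0, 1 / sqrt(spec$beta_prec), log = TRUE))
  rates <- pc_prior_rates(spec)
  lp_hyp <- pc_log_prior(sqrt(params$sigma2), params$range,
                         sqrt(params$sigma2_eps), rates)
  ll + lp_om + lp_eps + lp_beta + lp_hyp
}

#' Sampler settings
#'
#' @param n_draws posterior draws to retain (default 1000)
#' @param n_burn burn-in iterations (default 1000)
#' @param thin thinning interval (default 2)
#' @param seed RNG seed (required; every fit is reproducible)
#' @param store_latent decompose u into (omega, eps) per retained draw
#'   (needed for prediction; default TRUE)
#' @return list of settings
#' @export
fit_settings <- function(n_draws = 1000, n_burn = 1000, thin = 2, seed,
                         store_latent = TRUE) {
  if (missing(seed) || is.null(seed)) stop("a seed is required for every fit")
  stopifnot(n_draws >= 1, n_burn >= 0, thin >= 1)
  list(n_draws = n_draws, n_burn = n_burn, thin = thin, seed = as.integer(seed),
       store_latent = isTRUE(store_latent))
}

#' Fit the binomial geostatistical model to one indicator dataset
#'
#' Posterior sampling targets the joint posterior of (beta, sigma2, range,
#' sigma2_eps, omega, eps). The latent vector u = omega + eps (marginally
#' Gaussian with covariance Sigma_omega + sigma2_eps I) is updated by
#' elliptical slice sampling; beta by adaptive random-walk Metropolis;
#' the covariance parameters jointly on the log scale by adaptive
#' random-walk Metropolis against the Gaussian marginal of u. Covariates
#' are standardized internally and the coefficients back-transformed to
#' the original scale.
#'
#' @param data an \code{indicator_dataset}
#' @param spec a \code{prior_spec}; a NULL \code{r0} is replaced by 5\% of
#'   the north-south extent of the data
#' @param settings from \code{\link{fit_settings}}
#' @return object of class \code{vaxmono_fit} with elements \code{draws}
#'   (lists of posterior draws: \code{beta} S x p on the original
#'   covariate scale, \code{sigma2}, \code{range}, \code{sigma2_eps},
#'   \code{u}, and if requested \code{omega}, \code{eps}), \code{data},
#'   \code{prior}, \code{settings}, \code{diagnostics}
#' @export
fit <- function(data, spec = prior_spec(), settings) {
  stopifnot(inherits(data, "indicator_dataset"), inherits(spec, "prior_spec"))
  m <- nrow(data)
  if (m < 2) stop("need at least 2 data rows")
  if (m < 10) warning("fewer than 10 data rows; expect very wide posteriors")
  if (is.null(spec$r0)) {
    ext <- diff(range(data$y))
    if (ext <= 0) ext <- diff(range(data$x))
    if (ext <= 0) stop("degenerate geometry: cannot derive r0")
    spec$r0 <- 0.05 * ext
  }
  rates <- pc_prior_rates(spec)
  set.seed(settings$seed)

  cn <- covariate_names(data)
  C <- as.matrix(as.data.frame(data)[, cn, drop = FALSE])
  if (length(cn) > 0) {
    mu <- colMeans(C); sdv <- apply(C, 2, stats::sd)
    if (any(sdv == 0)) {
      stop("constant covariate column(s): ", paste(cn[sdv == 0], collapse = ", "))
    }
    Z <- sweep(sweep(C, 2, mu), 2, sdv, "/")
  } else {
    mu <- numeric(0); sdv <- numeric(0)
    Z <- matrix(0, m, 0)
  }
  X <- cbind("(Intercept)" = 1, Z)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  p <- ncol(X)
  trials <- data$trials; successes <- data$successes
  D <- as.matrix(stats::dist(cbind(data$x, data$y)))

  loglik <- function(beta, u) binom_loglik_eta(drop(X %*% beta) + u, trials, successes)

  # initial values: weighted logistic regression; latent initialized at
  # the empirical logit residuals so the covariance parameters see a
  # realistic field + nugget decomposition from the start
  init_fit <- suppressWarnings(stats::glm.fit(X, successes / trials,
    weights = trials, family = stats::quasibinomial()))
  beta <- init_fit$coefficients
  beta[!is.finite(beta)] <- 0
  emp_logit <- stats::qlogis((successes + 0.5) / (trials + 1))
  u <- pmin(pmax(emp_logit - drop(X %*% beta), -5), 5)
  # covariance inits: range at the first quartile of inter-point distances
  # (a standard variogram-scale heuristic), residual variance split evenly
  # between field and nugget
  v0 <- max(stats::var(u), 0.1)
  lam <- c(log_sigma = 0.5 * log(v0 / 2),
           log_range = log(max(stats::quantile(D[upper.tri(D)], 0.25), 1e-3)),
           log_eps = 0.5 * log(v0 / 2))

  ltri_idx <- which(lower.tri(D))
  log_dl <- log(pmax(D[ltri_idx], 1e-300))
  build_K <- function(lam) {
    s2 <- exp(2 * lam[1]); r <- exp(lam[2]); e2 <- exp(2 * lam[3])
    K <- fast_matern_from_logd(log_dl, m, s2, r, ltri_idx)
    diag(K) <- diag(K) + e2 + 1e-8 * s2
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    list(chol = ch, logdet = 2 * sum(log(diag(ch))))
  }
  gauss_marg <- function(Kc, u) {
    v <- backsolve(Kc$chol, u, transpose = TRUE)
    -0.5 * sum(v^2) - 0.5 * Kc$logdet - 0.5 * m * log(2 * pi)
  }
  hyper_log_prior <- function(lam) {
    pc_log_prior(exp(lam[1]), exp(lam[2]), exp(lam[3]), rates) +
      lam[1] + lam[2] + lam[3]  # Jacobians of the log transforms
  }

  Kc <- build_K(lam)
  if (is.null(Kc)) stop("initial covariance not positive definite")

  # Newton refinement of u toward its conditional mode given (beta, K):
  # maximizes loglik(u) - u' K^-1 u / 2. The empirical-logit start
  # undershoots near-saturated clusters; a few Newton steps fix that and
  # shorten burn-in considerably.
  Kinv0 <- chol2inv(Kc$chol)
  eta_fixed <- drop(X %*% beta)
  ll_pen <- function(u) loglik(beta, u) -
    0.5 * drop(crossprod(u, Kinv0 %*% u))
  obj <- ll_pen(u)
  for (nt in 1:12) {
    pv <- stats::plogis(eta_fixed + u)
    g <- (successes - trials * pv) - drop(Kinv0 %*% u)
    H <- Kinv0
    diag(H) <- diag(H) + pmax(trials * pv * (1 - pv), 1e-6)
    delta <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1
    repeat {
      u_try <- u + step * delta
      obj_try <- ll_pen(u_try)
      if (is.finite(obj_try) && obj_try >= obj) { u <- u_try; obj <- obj_try; break }
      step <- step / 2
      if (step < 1e-3) break
    }
    if (max(abs(step * delta)) < 1e-4) break
  }

  n_iter <- settings$n_burn + settings$n_draws * settings$thin
  S_out <- settings$n_draws
  beta_st <- matrix(NA_real_, S_out, p)
  u_st <- matrix(NA_real_, S_out, m)
  lam_st <- matrix(NA_real_, S_out, 3)

  # adaptation state
  ls_hyp <- log(0.3); ls_nc <- log(0.3)
  acc_hyp <- 0; acc_nc <- 0
  n_hyp <- 0; n_nc <- 0
  cur_ll <- loglik(beta, u)
  cur_marg <- gauss_marg(Kc, u)
  cur_hyp_prior <- hyper_log_prior(lam)
  keep_i <- 0

  for (it in seq_len(n_iter)) {
    ## -- elliptical slice sampling for u (a few sweeps; cheap relative
    ##    to the covariance updates, and the likelihood is strong) --
    for (sweep in 1:3) {
      nu_vec <- drop(crossprod(Kc$chol, stats::rnorm(m)))
      ly <- cur_ll + log(stats::runif(1))
      theta <- stats::runif(1, 0, 2 * pi)
      th_lo <- theta - 2 * pi; th_hi <- theta
      repeat {
        u_prop <- u * cos(theta) + nu_vec * sin(theta)
        ll_prop <- loglik(beta, u_prop)
        if (ll_prop > ly) break
        if (theta < 0) th_lo <- theta else th_hi <- theta
        theta <- stats::runif(1, th_lo, th_hi)
        if (th_hi - th_lo < 1e-10) { u_prop <- u; ll_prop <- cur_ll; break }
      }
      u <- u_prop; cur_ll <- ll_prop
    }

    ## -- exact Gibbs draw of beta given w = X beta + u --
    ## The likelihood depends on (beta, u) only through w, and given w the
    ## prior conditional of beta is Gaussian:
    ##   beta | w ~ N(V X' K^-1 w, V),  V = (X' K^-1 X + prec I)^-1
    w_vec <- drop(X %*% beta) + u
    KiX <- backsolve(Kc$chol, backsolve(Kc$chol, X, transpose = TRUE))
    A <- crossprod(X, KiX) + diag(spec$beta_prec, p)
    Ach <- chol((A + t(A)) / 2)
    b_mean <- backsolve(Ach, backsolve(Ach, crossprod(KiX, w_vec),
                                       transpose = TRUE))
    beta <- drop(b_mean) + backsolve(Ach, stats::rnorm(p))
    u <- w_vec - drop(X %*% beta)
    cur_marg <- gauss_marg(Kc, u)

    ## -- centered update of the covariance parameters (u fixed) --
    lam_prop <- lam + exp(ls_hyp) * stats::rnorm(3, 0, c(0.3, 0.3, 0.3))
    Kp <- build_K(lam_prop)
    if (!is.null(Kp)) {
      marg_p <- gauss_marg(Kp, u)
      prior_p <- hyper_log_prior(lam_prop)
      a <- marg_p + prior_p - cur_marg - cur_hyp_prior
      acc <- is.finite(a) && log(stats::runif(1)) < a
      if (acc) {
        lam <- lam_prop; Kc <- Kp; cur_marg <- marg_p; cur_hyp_prior <- prior_p
      }
    } else acc <- FALSE
    n_hyp <- n_hyp + 1; acc_hyp <- acc_hyp + acc
    if (it <= settings$n_burn) {
      ls_hyp <- ls_hyp + (as.numeric(acc) - 0.234) / it^0.6
    }

    ## -- interweaved non-centered update: keep the whitened latent
    ##    v = chol(K)^-T u fixed, move the covariance parameters against
    ##    the data likelihood (the Gaussian prior of u cancels) --
    lam_prop <- lam + exp(ls_nc) * stats::rnorm(3, 0, c(0.3, 0.3, 0.3))
    Kp <- build_K(lam_prop)
    if (!is.null(Kp)) {
      v_white <- backsolve(Kc$chol, u, transpose = TRUE)
      u_prop <- drop(crossprod(Kp$chol, v_white))
      ll_prop <- loglik(beta, u_prop)
      prior_p <- hyper_log_prior(lam_prop)
      a <- ll_prop + prior_p - cur_ll - cur_hyp_prior
      acc <- is.finite(a) && log(stats::runif(1)) < a
      if (acc) {
        lam <- lam_prop; Kc <- Kp; u <- u_prop; cur_ll <- ll_prop
        cur_hyp_prior <- prior_p
        cur_marg <- gauss_marg(Kc, u)
      }
    } else acc <- FALSE
    n_nc <- n_nc + 1; acc_nc <- acc_nc + acc
    if (it <= settings$n_burn) {
      ls_nc <- ls_nc + (as.numeric(acc) - 0.234) / it^0.6
    }

    if (it > settings$n_burn &&
        (it - settings$n_burn) %% settings$thin == 0) {
      keep_i <- keep_i + 1
      beta_st[keep_i, ] <- beta
      u_st[keep_i, ] <- u
      lam_st[keep_i, ] <- lam
    }
  }

  # back-transform coefficients to the original covariate scale
  beta_orig <- beta_st
  if (length(cn) > 0) {
    for (j in seq_along(cn)) beta_orig[, j + 1] <- beta_st[, j + 1] / sdv[j]
    beta_orig[, 1] <- beta_st[, 1] -
      if (length(cn) > 0) drop(beta_st[, -1, drop = FALSE] %*% (mu / sdv)) else 0
  }
  colnames(beta_orig) <- c("(Intercept)", cn)

  draws <- list(beta = beta_orig,
                sigma2 = exp(2 * lam_st[, 1]),
                range = exp(lam_st[, 2]),
                sigma2_eps = exp(2 * lam_st[, 3]),
                u = u_st)

  diagnostics <- list(accept_hyper = acc_hyp / n_hyp,
                      accept_noncentered = acc_nc / n_nc,
                      ess_beta = apply(beta_st, 2, ess_univariate))
  if (diagnostics$accept_hyper < 0.02 ||
      min(diagnostics$ess_beta) < 20) {
    warning("sampler mixing looks poor (low acceptance or effective size); ",
            "inspect diagnostics")
    diagnostics$converged <- FALSE
  } else diagnostics$converged <- TRUE

  out <- structure(list(draws = draws, data = data, prior = spec,
                        settings = settings,
                        standardization = list(mu = mu, sd = sdv, names = cn),
                        seed = settings$seed, diagnostics = diagnostics),
                   class = "vaxmono_fit")
  if (settings$store_latent) {
    lat <- decompose_latent(out)
    out$draws$omega <- lat$omega
    out$draws$eps <- lat$eps
  }
  out
}

# crude effective sample size from the empirical autocorrelation,
# truncated at the first negative lag
ess_univariate <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(ac < 0)
  if (length(pos)) ac <- ac[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(ac))
}

# split u = omega + eps per retained draw: omega | u is Gaussian with
# mean S (S + e2 I)^-1 u and covariance S - S (S + e2 I)^-1 S
decompose_latent <- function(fit) {
  d <- fit$draws
  m <- ncol(d$u); S_out <- nrow(d$u)
  D <- as.matrix(stats::dist(cbind(fit$data$x, fit$data$y)))
  omega <- matrix(NA_real_, S_out, m)
  key <- paste(signif(d$sigma2, 12), signif(d$range, 12), signif(d$sigma2_eps, 12))
  for (k in unique(key)) {
    idx <- which(key == k)
    i0 <- idx[1]
    Som <- fast_matern_mat(D, d$sigma2[i0], d$range[i0])
    K <- Som
    diag(K) <- diag(K) + d$sigma2_eps[i0] + 1e-8 * d$sigma2[i0]
    Kc <- chol(K)
    A <- Som %*% chol2inv(Kc)              # S K^-1
    covc <- Som - A %*% Som
    covc <- (covc + t(covc)) / 2
    cc <- tryCatch(chol(covc + 1e-10 * diag(m)), error = function(e) NULL)
    for (i in idx) {
      mn <- drop(A %*% d$u[i, ])
      z <- if (is.null(cc)) 0 else drop(crossprod(cc, stats::rnorm(m)))
      omega[i, ] <- mn + z
    }
  }
  list(omega = omega, eps = d$u - omega)
}

#' Fitted probability draws at the data locations
#' @param object a \code{vaxmono_fit}
#' @param ... unused
#' @return S x m matrix of posterior draws of p at the data locations
#' @export
fitted.vaxmono_fit <- function(object, ...) {
  C <- as.matrix(as.data.frame(object$data)[, covariate_names(object$data),
                                            drop = FALSE])
  X <- cbind(1, C)
  stats::plogis(tcrossprod(object$draws$beta, X) + object$draws$u)
}

# conditional (kriging) moments of the latent field at new locations
# given u = omega + eps at the data locations, for fixed covariance
# parameters: mean = C K^-1 u, cov = C_new - C K^-1 C'
krige_conditional <- function(xy_dat, xy_new, u, sigma2, range, sigma2_eps) {
  D_dat <- as.matrix(stats::dist(xy_dat))
  K <- matern_cov(D_dat, sigma2, range)
  diag(K) <- diag(K) + sigma2_eps + 1e-8 * sigma2
  Kc <- chol(K)
  Cx <- matern_cov(cross_dist(xy_new, xy_dat), sigma2, range)
  W <- backsolve(Kc, backsolve(Kc, t(Cx), transpose = TRUE))
  D_new <- as.matrix(stats::dist(xy_new))
  list(mean = drop(Cx %*% backsolve(Kc, backsolve(Kc, u, transpose = TRUE))),
       cov = matern_cov(D_new, sigma2, range) - Cx %*% W)
}

#' Predict coverage draws at new locations
#'
#' For each posterior draw, the spatial field at the new locations is drawn
#' from its Gaussian conditional given the fitted latent values (kriging
#' under the Matern covariance with that draw's parameters), a fresh
#' nugget is added when \code{predict_nugget} is TRUE, and the linear
#' predictor is inverted to the probability scale.
#'
#' @param object a \code{vaxmono_fit}
#' @param newdata a \code{prediction_grid}, \code{indicator_dataset} or
#'   data frame with columns \code{x, y} and the model's covariates
#' @param predict_nugget add a fresh nugget draw per location (default
#'   TRUE; the nugget is part of the model for a new cluster)
#' @param seed optional RNG seed for the prediction noise
#' @param ... unused
#' @return S x L matrix of posterior draws of p at the L new locations
#' @export
predict.vaxmono_fit <- function(object, newdata, predict_nugget = TRUE,
                                seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cn <- covariate_names(object$data)
  nd <- as.data.frame(newdata)
  missing_cov <- setdiff(c("x", "y", cn), names(nd))
  if (length(missing_cov) > 0L) {
    stop("newdata is missing column(s): ", paste(missing_cov, collapse = ", "))
  }
  Xn <- cbind(1, as.matrix(nd[, cn, drop = FALSE]))
  L <- nrow(nd)
  d <- object$draws
  S_out <- nrow(d$u)
  m <- ncol(d$u)
  xy_dat <- cbind(object$data$x, object$data$y)
  xy_new <- cbind(nd$x, nd$y)
  D_dat <- as.matrix(stats::dist(xy_dat))
  D_cross <- cross_dist(xy_new, xy_dat)
  D_new <- as.matrix(stats::dist(xy_new))

  p_draws <- matrix(NA_real_, S_out, L)
  key <- paste(signif(d$sigma2, 12), signif(d$range, 12), signif(d$sigma2_eps, 12))
  eta_fix <- tcrossprod(d$beta, Xn)       # S x L
  for (k in unique(key)) {
    idx <- which(key == k)
    i0 <- idx[1]
    s2 <- d$sigma2[i0]; r <- d$range[i0]; e2 <- d$sigma2_eps[i0]
    Som <- fast_matern_mat(D_dat, s2, r)
    K <- Som
    diag(K) <- diag(K) + e2 + 1e-8 * s2
    Kc <- chol(K)
    Cx <- fast_matern_mat(D_cross, s2, r)      # L x m
    W <- backsolve(Kc, backsolve(Kc, t(Cx), transpose = TRUE))  # m x L = K^-1 Cx'
    covc <- fast_matern_mat(D_new, s2, r) - Cx %*% W
    covc <- (covc + t(covc)) / 2
    cc <- tryCatch(chol(covc + 1e-10 * s2 * diag(L)), error = function(e) NULL)
    for (i in idx) {
      mn <- drop(crossprod(W, d$u[i, ]))
      z <- if (is.null(cc)) 0 else drop(crossprod(cc, stats::rnorm(L)))
      eta <- eta_fix[i, ] + mn + z
      if (predict_nugget) eta <- eta + stats::rnorm(L, 0, sqrt(d$sigma2_eps[i]))
      p_draws[i, ] <- stats::plogis(eta)
    }
  }
  p_draws
}

#' Kriging-style prediction (function form)
#' @inheritParams predict.vaxmono_fit
#' @param fit a \code{vaxmono_fit}
#' @param targets new locations (see \code{predict.vaxmono_fit})
#' @export
predict_surface <- function(fit, targets, predict_nugget = TRUE, seed = NULL) {
  predict.vaxmono_fit(fit, targets, predict_nugget = predict_nugget, seed = seed)
}

cross_dist <- function(a, b) {
  # euclidean distances, rows of a vs rows of b
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Serialize a fit to a delimited-text archive
#'
#' Parameter draws go to one file (one column per parameter, one row per
#' draw); metadata (seed, priors, data checksum) to a key-value header.
#'
#' @param fit a \code{vaxmono_fit}
#' @param path base path; writes \code{<path>_draws.csv} and
#'   \code{<path>_meta.txt}
#' @export
write_fit <- function(fit, path) {
  d <- fit$draws
  tab <- data.frame(d$beta, sigma2 = d$sigma2, range = d$range,
                    sigma2_eps = d$sigma2_eps, check.names = FALSE)
  utils::write.table(tab, paste0(path, "_draws.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  dat_chk <- digest_table(as.data.frame(fit$data))
  meta <- c(paste0("seed=", fit$seed),
            paste0("indicator=", attr(fit$data, "indicator")),
            paste0("approach=", attr(fit$data, "approach")),
            paste0("data_md5=", dat_chk),
            paste0("r0=", fit$prior$r0),
            paste0("n_draws=", fit$settings$n_draws))
  writeLines(meta, paste0(path, "_meta.txt"))
  invisible(path)
}

digest_table <- function(df) {
  f <- tempfile()
  on.exit(unlink(f))
  utils::write.table(df, f, sep = ",", row.names = FALSE, quote = FALSE)
  unname(tools::md5sum(f))
}
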