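#' Construct an indicator dataset
#'
#' An indicator dataset carries the (trial size, success count) pairs for a
#' single modelled indicator, together with locations and covariates. Rows
#' with zero trial size are excluded: a 0/0 proportion contributes no
#' likelihood information.
#'
#' @param df data frame with columns \code{cluster_id, x, y, trials,
#'   successes} plus covariates
#' @param indicator one of \code{"p1", "p2g1", "p3g2", "p21", "p32"}
#' @param approach \code{"CP"} or \code{"RB"}
#' @param covariate_names covariate columns
#' @return an \code{indicator_dataset}
#' @export
indicator_dataset <- function(df, indicator, approach,
                              covariate_names = NULL) {
  indicator <- match.arg(indicator, c("p1", "p2g1", "p3g2", "p21", "p32"))
  approach <- match.arg(approach, c("CP", "RB"))
  req <- c("cluster_id", "x", "y", "trials", "successes")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("indicator table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(covariate_names)) covariate_names <- setdiff(names(df), req)
  df <- as.data.frame(df)[, c(req, covariate_names), drop = FALSE]
  n_zero <- sum(df$trials == 0)
  if (n_zero > 0L) {
    message("indicator ", indicator, ": dropping ", n_zero,
            " row(s) with zero trial size")
    df <- df[df$trials > 0, , drop = FALSE]
    rownames(df) <- NULL
  }
  if (any(df$successes < 0 | df$successes > df$trials + 1e-9)) {
    stop("indicator ", indicator, ": successes outside [0, trials]")
  }
  df$successes <- pmin(df$successes, df$trials)
  structure(df, indicator = indicator, approach = approach,
            covariate_names = covariate_names, n_dropped = n_zero,
            class = c("indicator_dataset", "data.frame"))
}

#' Build the conditional-probability (CP) indicator datasets
#'
#' Under the CP construction the modelled indicators are the coverage of
#' the reference dose and the conditional probabilities of each subsequent
#' dose given the previous one. Their point-level data are
#' \code{(n, y1)}, \code{(y1, y2)} and \code{(y2, y3)}: the trial size of
#' each conditional indicator is the success count of the previous dose,
#' so clusters where nobody received the previous dose drop out of that
#' indicator's dataset.
#'
#' @param ds a \code{cluster_dataset}
#' @param reference \code{"first"} models (p1, p2|1, p3|2); \code{"last"}
#'   reverses the series: dose 3 becomes the reference, and the two
#'   intermediate datasets carry the downward ratios p3/p2 and p2/p1 with
#'   CP-style trial sizes (y3 and y2). Targets are then composed upward by
#'   \code{\link{compose_targets}} with \code{reference = "last"}.
#' @return named list of three \code{indicator_dataset}s
#' @export
build_cp_datasets <- function(ds, reference = c("first", "last")) {
  stopifnot(inherits(ds, "cluster_dataset"))
  reference <- match.arg(reference)
  cn <- covariate_names(ds)
  base_cols <- function(trials, successes) {
    cbind(data.frame(cluster_id = ds$cluster_id, x = ds$x, y = ds$y,
                     trials = trials, successes = successes),
          as.data.frame(ds)[, cn, drop = FALSE])
  }
  if (reference == "first") {
    list(
      p1   = indicator_dataset(base_cols(ds$n, ds$y1), "p1", "CP", cn),
      p2g1 = indicator_dataset(base_cols(ds$y1, ds$y2), "p2g1", "CP", cn),
      p3g2 = indicator_dataset(base_cols(ds$y2, ds$y3), "p3g2", "CP", cn)
    )
  } else {
    # reversed series: dose 3 is the reference; the intermediate datasets
    # carry the downward ratios p3/p2 ~ (y2, y3) and p2/p1 ~ (y1, y2)
    list(
      p1   = indicator_dataset(base_cols(ds$n, ds$y3), "p1", "CP", cn),
      p2g1 = indicator_dataset(base_cols(ds$y2, ds$y3), "p2g1", "CP", cn),
      p3g2 = indicator_dataset(base_cols(ds$y1, ds$y2), "p3g2", "CP", cn)
    )
  }
}

#' Build the ratio-based (RB) indicator datasets
#'
#' Under the RB construction the modelled indicators are the reference
#' coverage and the ratios of consecutive coverages, with pseudo binomial
#' counts \code{y21 = n * y2/y1} and \code{y32 = n * y3/y2} so that every
#' indicator keeps the full cluster sample size \code{n} as its trial
#' size. Clusters with a zero denominator are excluded from that
#' indicator only.
#'
#' @inheritParams build_cp_datasets
#' @return named list of three \code{indicator_dataset}s
#' @export
build_rb_datasets <- function(ds, reference = c("first", "last")) {
  stopifnot(inherits(ds, "cluster_dataset"))
  reference <- match.arg(reference)
  cn <- covariate_names(ds)
  base_cols <- function(trials, successes, keep) {
    df <- cbind(data.frame(cluster_id = ds$cluster_id, x = ds$x, y = ds$y,
                           trials = trials, successes = successes),
                as.data.frame(ds)[, cn, drop = FALSE])
    df[keep, , drop = FALSE]
  }
  if (reference == "first") {
    k21 <- ds$y1 > 0
    k32 <- ds$y2 > 0
    n21 <- sum(!k21); n32 <- sum(!k32)
    if (n21 > 0L) message("RB p21: excluding ", n21, " cluster(s) with y1 = 0")
    if (n32 > 0L) message("RB p32: excluding ", n32, " cluster(s) with y2 = 0")
    list(
      p1  = indicator_dataset(base_cols(ds$n, ds$y1, TRUE), "p1", "RB", cn),
      p21 = indicator_dataset(
        base_cols(ds$n, ifelse(k21, ds$n * ds$y2 / ds$y1, 0), k21), "p21", "RB", cn),
      p32 = indicator_dataset(
        base_cols(ds$n, ifelse(k32, ds$n * ds$y3 / ds$y2, 0), k32), "p32", "RB", cn)
    )
  } else {
    # reversed series: pseudo counts for the downward ratios p3/p2, p2/p1
    k32 <- ds$y2 > 0
    k21 <- ds$y1 > 0
    list(
      p1  = indicator_dataset(base_cols(ds$n, ds$y3, TRUE), "p1", "RB", cn),
      p21 = indicator_dataset(
        base_cols(ds$n, ifelse(k32, ds$n * ds$y3 / ds$y2, 0), k32), "p21", "RB", cn),
      p32 = indicator_dataset(
        base_cols(ds$n, ifelse(k21, ds$n * ds$y2 / ds$y1, 0), k21), "p32", "RB", cn)
    )
  }
}

#' Compose target-indicator draws from modelled-indicator draws
#'
#' The target coverages are recovered multiplicatively:
#' \code{p2 = p1 * mid} and \code{p3 = p2 * last}, elementwise per
#' posterior draw. The same formula serves the CP approach (mid = p2|1,
#' last = p3|2) and the RB approach (mid = p21, last = p32), since the two
#' parameterizations coincide. Because every factor lies in [0,1], the
#' monotone ordering p1 >= p2 >= p3 holds for every draw by construction.
#'
#' @param p1_draws,mid_draws,last_draws S x L matrices of probabilities
#'   (S posterior draws at L locations)
#' @param locations optional data frame of the L locations
#' @param reference \code{"first"} (default) composes downward from p1;
#'   \code{"last"} treats the inputs as (p3, p2/p3, p1/p2) and composes
#'   upward, returning draws labelled (p1, p2, p3) in dose order.
#' @return a \code{target_draws} object: list with S x L matrices
#'   \code{p1, p2, p3} and \code{locations}
#' @export
compose_targets <- function(p1_draws, mid_draws, last_draws, locations = NULL,
                            reference = c("first", "last")) {
  reference <- match.arg(reference)
  p1_draws <- as.matrix(p1_draws); mid_draws <- as.matrix(mid_draws)
  last_draws <- as.matrix(last_draws)
  if (!all(dim(p1_draws) == dim(mid_draws)) ||
      !all(dim(p1_draws) == dim(last_draws))) {
    stop("draw matrices must have identical dimensions")
  }
  rng <- range(p1_draws, mid_draws, last_draws)
  if (rng[1] < 0 || rng[2] > 1) stop("draws must lie in [0, 1]")
  if (reference == "first") {
    p1 <- p1_draws
    p2 <- p1 * mid_draws
    p3 <- p2 * last_draws
  } else {
    # upward composition: inputs are (p3, p3/p2, p2/p1); dividing by a
    # ratio in [0,1] preserves the ordering but can exceed 1, so clip.
    p3 <- p1_draws
    p2 <- p3 / pmax(mid_draws, .Machine$double.eps)
    p2[p2 > 1] <- 1
    p1 <- p2 / pmax(last_draws, .Machine$double.eps)
    p1[p1 > 1] <- 1
  }
  structure(list(p1 = p1, p2 = p2, p3 = p3, locations = locations),
            class = "target_draws")
}

#' Four-category probabilities from monotone target draws
#'
#' Splits each draw into the four mutually exclusive, exhaustive vaccination
#' categories: never vaccinated (1 - p1), first dose only (p1 - p2), second
#' dose but not third (p2 - p3), and all three doses (p3). The components
#' sum to one by construction.
#'
#' @param t a \code{target_draws} object
#' @return list of S x L matrices \code{p_none, p_d1only, p_d2only, p_all3}
#' @export
category_probabilities <- function(t) {
  stopifnot(inherits(t, "target_draws"))
  if (any(t$p1 < t$p2 - 1e-12) || any(t$p2 < t$p3 - 1e-12)) {
    stop("target draws are not monotone; cannot form category probabilities")
  }
  list(p_none = 1 - t$p1,
       p_d1only = t$p1 - t$p2,
       p_d2only = t$p2 - t$p3,
       p_all3 = t$p3)
}

#' Write an indicator dataset as delimited text
#' @param ids an \code{indicator_dataset}
#' @param path destination
#' @export
write_indicator_table <- function(ids, path) {
  utils::write.table(as.data.frame(ids), path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
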