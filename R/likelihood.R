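#' Longitudinal log-likelihood of one subject
#'
#' \eqn{\sum_j \log \mathrm{Normal}(y_{ij} \mid \mu_i(t_{ij}), \sigma_i^2)}.
#' The random-effects density is *not* included here; it belongs to the
#' hierarchy and is handled by the sampler (and by [log_prior] for `Sigma`).
#'
#' @param subject a [jm_subject].
#' @param params a [jm_parameters].
#' @param b random-effects vector for the subject (`NULL` = zero).
#' @return scalar log-likelihood.
#' @export
loglik_longitudinal <- function(subject, params, b = NULL) {
  b <- re_vector(b, params)
  n_i <- length(subject$y)
  sd_i <- error_sd(params, b, n_i)
  if (sd_i <= 0) stop("residual SD must be positive")
  mu <- logistic_mean(subject$times, params, b)
  sum(stats::dnorm(subject$y, mu, sd_i, log = TRUE))
}

#' Survival log-likelihood of one subject
#'
#' Interval-censored subjects (observed events) contribute
#' \eqn{\log\{(1-\eta)[S(t_L) - S(t_R)]\}}; right-censored subjects
#' contribute \eqn{\log\{\eta + (1-\eta) S(t_{cens})\}}, the population
#' survival reflecting that they may be cured. Survival differences are
#' floored at `1e-300` before taking logs to avoid `-Inf` during sampler
#' warm-up; an interval whose probability mass underflows entirely raises an
#' error when `strict = TRUE`.
#'
#' @inheritParams loglik_longitudinal
#' @param n_i number of longitudinal measurements (defaults to the subject's
#'   observed count); selects \eqn{\sigma_i} under the MELS variant.
#' @param order quadrature order for the cumulative hazard.
#' @param strict error (rather than floor) on zero-mass intervals.
#' @return scalar log-likelihood.
#' @export
loglik_survival <- function(subject, params, b = NULL,
                            n_i = length(subject$y), order = 31L,
                            strict = FALSE) {
  b <- re_vector(b, params)
  eta <- cure_fraction(params$nu)
  if (subject$censoring == "interval") {
    sL <- jm_survival(subject$t_left, params, b, n_i, order)
    sR <- jm_survival(subject$t_right, params, b, n_i, order)
    d <- sL - sR
    if (d <= 1e-300) {
      if (strict) {
        stop(sprintf("subject %s: interval (%g, %g] has numerically zero mass",
                     subject$id, subject$t_left, subject$t_right))
      }
      d <- 1e-300
    }
    log1p(-eta) + log(d)
  } else {
    log(eta + (1 - eta) *
          jm_survival(subject$t_cens, params, b, n_i, order))
  }
}

# log density of inverse-Wishart(scale S, df) at X
dinvwishart_log <- function(X, S, df) {
  p <- nrow(X)
  if (df <= p - 1) stop("inverse-Wishart df must exceed dim - 1")
  lgamma_p <- (p * (p - 1) / 4) * log(pi) +
    sum(lgamma((df + 1 - seq_len(p)) / 2))
  chol_X <- chol(X)
  chol_S <- chol(S)
  ldet_X <- 2 * sum(log(diag(chol_X)))
  ldet_S <- 2 * sum(log(diag(chol_S)))
  tr_SXinv <- sum(diag(chol2inv(chol_X) %*% S))
  (df / 2) * ldet_S - (df * p / 2) * log(2) - lgamma_p -
    ((df + p + 1) / 2) * ldet_X - tr_SXinv / 2
}

# log density of half-Cauchy(0, 1) at x > 0
dhalfcauchy_log <- function(x) {
  ifelse(x > 0, log(2 / pi) - log1p(x^2), -Inf)
}

#' Joint log-prior of the population parameters
#'
#' Independent weakly-informative priors: Normal(0, 10^2) on all location
#' parameters (\eqn{\theta_1..\theta_4, \nu, \lambda, \alpha_1, \alpha_2});
#' half-Cauchy(0, 1) on the Weibull shape \eqn{\phi} and, under the reference
#' variant, on the error *variance* \eqn{\sigma^2} (configurable to the SD
#' scale); inverse-Wishart on `Sigma` with identity scale of the model's
#' random-effects dimension and `df = dim + 2` (proper, weakly informative).
#'
#' @param params a [jm_parameters].
#' @param cauchy_on scale carrying the half-Cauchy prior for the reference
#'   variant's error term: `"variance"` (default) or `"sd"`.
#' @param iw_scale,iw_df inverse-Wishart hyperparameters; defaults identity
#'   and `n_re + 2`.
#' @return scalar log-prior density; `-Inf` outside the support.
#' @export
log_prior <- function(params, cauchy_on = c("variance", "sd"),
                      iw_scale = NULL, iw_df = NULL) {
  cauchy_on <- match.arg(cauchy_on)
  p <- params$n_re
  if (is.null(iw_scale)) iw_scale <- diag(p)
  if (is.null(iw_df)) iw_df <- p + 2
  loc <- c(params$theta, params$nu, params$lam, params$alpha1)
  if (params$variant == "mels") loc <- c(loc, params$theta4, params$alpha2)
  lp <- sum(stats::dnorm(loc, 0, 10, log = TRUE))
  lp <- lp + dhalfcauchy_log(params$phi)
  if (params$variant == "reference") {
    lp <- lp + if (cauchy_on == "variance") {
      dhalfcauchy_log(params$sigma^2)
    } else {
      dhalfcauchy_log(params$sigma)
    }
  }
  lp + dinvwishart_log(params$Sigma, iw_scale, iw_df)
}

#' Joint log-likelihood of a dataset
#'
#' Sum over subjects of longitudinal plus survival contributions, returned
#' both in total and pointwise (one entry per subject, the unit used for
#' leave-one-out cross-validation). Random-effects and prior densities are
#' excluded.
#'
#' @param data a `jm_data` object.
#' @param params a [jm_parameters].
#' @param b_all matrix of random effects, one row per subject (or `NULL` for
#'   all-zero).
#' @param order quadrature order.
#' @return list with `total` (scalar) and `pointwise` (data frame with
#'   columns `subject_id`, `loglik`).
#' @export
loglik_joint <- function(data, params, b_all = NULL, order = 31L) {
  n <- length(data)
  if (n == 0L) {
    return(list(total = 0,
                pointwise = data.frame(subject_id = character(0),
                                       loglik = numeric(0))))
  }
  if (is.null(b_all)) b_all <- matrix(0, n, params$n_re)
  b_all <- as.matrix(b_all)
  if (nrow(b_all) != n) stop("`b_all` must have one row per subject")
  pw <- vapply(seq_len(n), function(i) {
    s <- data[[i]]
    loglik_longitudinal(s, params, b_all[i, ]) +
      loglik_survival(s, params, b_all[i, ], order = order)
  }, numeric(1))
  list(total = sum(pw),
       pointwise = data.frame(
         subject_id = vapply(data, `[[`, character(1), "id"),
         loglik = pw, stringsAsFactors = FALSE, row.names = NULL))
}
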