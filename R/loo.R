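# Pareto-smoothed importance sampling (PSIS) leave-one-out cross-validation
# from subject-level pointwise log-likelihoods.

# Profile-likelihood generalized-Pareto fit (Zhang & Stephens 2009 style)
# to exceedances x > 0; returns shape k and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  bs <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  # profile likelihood in theta = -k/sigma; heavy tails have theta < 0
  ks <- vapply(bs, function(b) mean(log1p(-b * x)), numeric(1))
  ls <- n * (log(-bs / ks) - ks - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(ls - ls[j])), numeric(1))
  b_hat <- sum(bs * w)
  k_hat <- mean(log1p(-b_hat * x))
  sigma_hat <- -k_hat / b_hat
  # weak prior pulling k toward 0.5 stabilises small tails
  k_hat <- (n * k_hat + 10 * 0.5) / (n + 10)
  c(k = k_hat, sigma = sigma_hat)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# smooth the right tail of a log-weight vector; returns list(lw, k)
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- min(ceiling(0.2 * S), ceiling(3 * sqrt(S)))
  if (M < 5 || S < 25) return(list(lw = lw, k = 0))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exceed <- exp(lw[tail_ids]) - exp(cutoff)
  if (max(exceed) <= 0) return(list(lw = lw, k = 0))
  fitk <- gpd_fit(exceed)
  k <- fitk[["k"]]
  if (is.finite(k)) {
    pq <- (seq_len(M) - 0.5) / M
    smoothed <- log(exp(cutoff) + qgpd(pq, k, fitk[["sigma"]]))
    smoothed <- pmin(smoothed, 0)  # cap at the raw maximum (= 0 after shift)
    lw[tail_ids[order(lw[tail_ids])]] <- smoothed
  }
  list(lw = lw, k = k)
}

#' PSIS leave-one-out cross-validation
#'
#' Estimates subject-level leave-one-out expected log predictive density
#' from the pointwise log-likelihoods recorded by [jm_fit], using
#' Pareto-smoothed importance sampling. The pointwise unit is the subject
#' (longitudinal and survival contributions combined, conditional on the
#' sampled subject-level random effects), matching the likelihood
#' factorization of the joint model. Results are also reported on the
#' deviance scale (`looic = -2 * elpd`), where lower means better
#' out-of-sample fit.
#'
#' @param fit a `jm_fit` object (or an iterations-x-subjects pointwise
#'   log-likelihood matrix).
#' @return list of class `jm_loo`: `elpd`, `se`, `looic`, `pointwise`
#'   (per-subject elpd), `pareto_k` (per-subject tail-shape diagnostics).
#'   A warning is attached when more than 10% of the Pareto k exceed 0.7.
#' @export
psis_loo <- function(fit) {
  ll <- if (inherits(fit, "jm_fit")) {
    apply(fit$pointwise, 3L, as.vector)
  } else {
    as.matrix(fit)
  }
  n <- ncol(ll)
  elpd_i <- numeric(n)
  k_i <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[, i])
    k_i[i] <- sm$k
    lw <- sm$lw - log(sum(exp(sm$lw - max(sm$lw)))) - max(sm$lw)
    # log( sum w * exp(ll) ) with normalized weights, stably:
    a <- lw + ll[, i]
    elpd_i[i] <- log(sum(exp(a - max(a)))) + max(a)
  }
  out <- structure(
    list(elpd = sum(elpd_i), se = sqrt(n * stats::var(elpd_i)),
         looic = -2 * sum(elpd_i), pointwise = elpd_i, pareto_k = k_i,
         n = n),
    class = "jm_loo")
  frac_bad <- mean(k_i > 0.7)
  if (frac_bad > 0.1) {
    warning(sprintf(
      "%.0f%% of Pareto k estimates exceed 0.7; PSIS-LOO may be unreliable",
      100 * frac_bad), call. = FALSE)
    out$unreliable <- TRUE
  }
  out
}

#' @export
print.jm_loo <- function(x, ...) {
  cat("PSIS-LOO:", x$n, "subjects\n")
  cat(sprintf("  elpd_loo %.1f (SE %.1f)   looic %.1f\n",
              x$elpd, x$se, x$looic))
  cat(sprintf("  Pareto k > 0.7: %d subjects\n", sum(x$pareto_k > 0.7)))
  invisible(x)
}

#' Compare two fitted models by PSIS-LOO
#'
#' @param fit_a,fit_b `jm_fit` (or `jm_loo`) objects fitted to the same
#'   subjects.
#' @param labels length-2 labels for the report.
#' @return list of class `jm_loo_compare`: per-model `looic`, the elpd
#'   difference `elpd_diff` (A minus B) with its standard error, and
#'   `preferred` (the label of the lower-looic model).
#' @export
loo_compare_jm <- function(fit_a, fit_b, labels = c("A", "B")) {
  loo_of <- function(f) if (inherits(f, "jm_loo")) f else psis_loo(f)
  ids_of <- function(f) if (inherits(f, "jm_fit")) f$subject_ids else NULL
  ia <- ids_of(fit_a); ib <- ids_of(fit_b)
  if (!is.null(ia) && !is.null(ib) && !identical(ia, ib)) {
    stop("the two fits cover different subject sets")
  }
  la <- loo_of(fit_a); lb <- loo_of(fit_b)
  if (la$n != lb$n) stop("pointwise log-likelihoods have different lengths")
  d <- la$pointwise - lb$pointwise
  structure(
    list(looic = stats::setNames(c(la$looic, lb$looic), labels),
         elpd_diff = sum(d), se_diff = sqrt(la$n * stats::var(d)),
         preferred = labels[which.min(c(la$looic, lb$looic))],
         loo = stats::setNames(list(la, lb), labels)),
    class = "jm_loo_compare")
}

#' @export
print.jm_loo_compare <- function(x, ...) {
  cat("LOO-CV comparison (deviance scale, lower is better)\n")
  for (nm in names(x$looic)) {
    cat(sprintf("  %-10s looic %.1f\n", nm, x$looic[[nm]]))
  }
  cat(sprintf("  elpd difference (%s - %s): %.1f (SE %.1f); preferred: %s\n",
              names(x$looic)[1], names(x$looic)[2], x$elpd_diff, x$se_diff,
              x$preferred))
  invisible(x)
}
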