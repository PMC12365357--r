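#' MCMC run configuration
#'
#' @param chains number of Markov chains (>= 2 for convergence diagnostics).
#' @param iterations iterations per chain, including warm-up.
#' @param warmup_fraction fraction of iterations discarded as warm-up.
#' @param seed integer RNG seed; the whole run (initial values and all
#'   chains) is deterministic given the seed.
#' @param quadrature_order Gauss-Legendre order for the cumulative hazard.
#' @param prior_only if `TRUE` the data likelihood is switched off and the
#'   sampler explores the prior (useful for prior-predictive checks).
#' @param save_re keep the full random-effects draws (memory-heavy; the
#'   posterior mean is always kept).
#' @param rhat_warn,ess_warn thresholds for the post-fit convergence warning.
#' @return list of class `jm_control`.
#' @export
jm_control <- function(chains = 3L, iterations = 6000L,
                       warmup_fraction = 0.5, seed = 1L,
                       quadrature_order = 15L, prior_only = FALSE,
                       save_re = FALSE, rhat_warn = 1.01, ess_warn = 400) {
  if (chains < 1L) stop("`chains` must be >= 1")
  if (iterations < 20L) stop("`iterations` too small")
  if (warmup_fraction <= 0 || warmup_fraction >= 1) {
    stop("`warmup_fraction` must be in (0, 1)")
  }
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup_fraction = warmup_fraction,
                 seed = as.integer(seed),
                 quadrature_order = as.integer(quadrature_order),
                 prior_only = isTRUE(prior_only),
                 save_re = isTRUE(save_re),
                 rhat_warn = rhat_warn, ess_warn = ess_warn),
            class = "jm_control")
}

# flatten a jm_data object into the arrays the C++ sampler consumes
pack_data <- function(data) {
  n_len <- vapply(data, function(s) length(s$y), integer(1))
  list(
    y = unlist(lapply(data, `[[`, "y"), use.names = FALSE),
    tobs = unlist(lapply(data, `[[`, "times"), use.names = FALSE),
    sub_start = as.integer(cumsum(c(0L, n_len[-length(n_len)]))),
    sub_len = as.integer(n_len),
    cens = vapply(data, function(s) {
      if (s$censoring == "interval") 0L else 1L
    }, integer(1)),
    tL = vapply(data, function(s) {
      if (is.null(s$t_left)) 0 else s$t_left
    }, numeric(1)),
    tR = vapply(data, function(s) {
      if (is.null(s$t_right)) 0 else s$t_right
    }, numeric(1)),
    tc = vapply(data, function(s) {
      if (is.null(s$t_cens)) 0 else s$t_cens
    }, numeric(1))
  )
}

# crude data-driven initial values and centring constants
init_heuristics <- function(data, variant) {
  tab <- longitudinal_table(data)
  st <- survival_table(data)
  fit3 <- tryCatch(
    stats::nls(log10_value ~ SSlogis(time_days, Asym, xmid, scal),
               data = tab),
    error = function(e) NULL)
  if (!is.null(fit3)) {
    cf <- stats::coef(fit3)
    a <- pmax(c(cf[["Asym"]], cf[["xmid"]], cf[["scal"]]), 0.1)
    resid_sd <- max(stats::sd(stats::resid(fit3)), 0.02)
  } else {
    a <- pmax(c(stats::quantile(tab$log10_value, 0.95), 20, 8), 0.1)
    resid_sd <- max(stats::sd(tab$log10_value) / 2, 0.05, na.rm = TRUE)
  }
  theta <- log(a)
  p_right <- mean(st$censoring == "right")
  nu0 <- stats::qlogis(min(max(p_right, 0.02), 0.98))
  mids <- (st$t_left + st$t_right) / 2
  tref <- c(mids[st$censoring == "interval"],
            st$t_cens[st$censoring == "right"])
  t0 <- stats::median(tref, na.rm = TRUE)
  if (!is.finite(t0) || t0 <= 0) t0 <- 40

  # crude grid search for the Weibull shape and centred log-scale:
  # survival-only log-likelihood with b = 0 and associations off
  eta0 <- stats::plogis(nu0)
  Hfun <- function(t, phi, lcc) ifelse(t > 0, (t / t0)^phi * exp(lcc), 0)
  best <- c(2, -0.5, -Inf)  # phi, lam_cc, loglik
  for (phi in seq(1, 6.5, by = 0.5)) {
    for (lcc in seq(-3, 1.5, by = 0.25)) {
      sL <- exp(-Hfun(st$t_left, phi, lcc))
      sR <- exp(-Hfun(st$t_right, phi, lcc))
      sc <- exp(-Hfun(st$t_cens, phi, lcc))
      ll <- sum(ifelse(st$censoring == "interval",
                       log(pmax(sL - sR, 1e-12)) + log1p(-eta0),
                       log(eta0 + (1 - eta0) * sc)))
      if (is.finite(ll) && ll > best[3]) best <- c(phi, lcc, ll)
    }
  }
  list(theta = theta, resid_sd = resid_sd, nu = nu0,
       phi = best[[1]], lam_cc = best[[2]],
       t0 = t0, mu_c = mean(tab$log10_value),
       s2_c = if (variant == "mels") resid_sd^2 else 0)
}

#' Fit the Bayesian joint model
#'
#' Samples the posterior of all population parameters and subject random
#' effects by adaptive Metropolis-within-Gibbs: componentwise and joint
#' adaptive random-walk updates for the global parameters on an
#' unconstrained, covariate-centred scale; per-subject random-walk updates
#' for the random effects (conditionally independent given the globals); and
#' a conjugate inverse-Wishart Gibbs step for the random-effects covariance.
#' Proposal scales adapt during warm-up only. Per-subject pointwise
#' log-likelihoods (longitudinal + survival) are recorded for every retained
#' draw, for use by [psis_loo].
#'
#' @param data a `jm_data` object.
#' @param variant `"reference"` (shared mean only, common error SD) or
#'   `"mels"` (shared mean and subject-specific error variance).
#' @param control a [jm_control] object.
#' @return An object of class `jm_fit` with elements `draws`
#'   (iterations x chains x parameters array, natural scale), `pointwise`
#'   (iterations x chains x subjects log-likelihood array), `b_mean`
#'   (posterior-mean random effects), `diagnostics` (split-Rhat/bulk-ESS
#'   table), and sampler metadata. Warns (with the diagnostic table
#'   attached) if any split-Rhat exceeds `control$rhat_warn`.
#' @export
jm_fit <- function(data, variant = c("mels", "reference"),
                   control = jm_control()) {
  variant <- match.arg(variant)
  stopifnot(inherits(data, "jm_data"))
  if (!length(data)) stop("`data` is empty")
  mels <- variant == "mels"
  p <- if (mels) 4L else 3L
  N <- length(data)
  packed <- pack_data(data)
  rule <- gl_rule(control$quadrature_order)
  ih <- init_heuristics(data, variant)

  par_names <- c("theta1", "theta2", "theta3",
                 if (mels) "theta4" else "sigma",
                 "nu", "lam", "phi", "alpha1",
                 if (mels) "alpha2")
  # the sampler stores the upper triangle of Sigma row-wise
  sig_names <- unlist(lapply(seq_len(p), function(i) {
    sprintf("Sigma[%d,%d]", i, i:p)
  }))
  all_names <- c(par_names, sig_names)

  n_keep <- control$iterations -
    as.integer(floor(control$iterations * control$warmup_fraction))
  warmup <- control$iterations - n_keep
  draws <- array(NA_real_, c(n_keep, control$chains, length(all_names)),
                 dimnames = list(NULL, NULL, all_names))
  pointwise <- array(NA_real_, c(n_keep, control$chains, N),
                     dimnames = list(NULL, NULL,
                                     vapply(data, `[[`, character(1), "id")))
  b_mean <- matrix(0, N, p)
  b_draws <- if (control$save_re) vector("list", control$chains) else NULL
  accept <- vector("list", control$chains)

  set.seed(control$seed)
  for (ch in seq_len(control$chains)) {
    jit <- function(s) stats::rnorm(1, 0, s)
    g0 <- c(ih$theta + stats::rnorm(3, 0, 0.1),
            if (mels) log(ih$resid_sd) + jit(0.2) else
              2 * log(ih$resid_sd) + jit(0.2),
            ih$nu + jit(0.3),
            ih$lam_cc + jit(0.3),
            log(ih$phi) + jit(0.15),
            jit(0.1),                      # alpha1
            if (mels) jit(0.1))            # alpha2
    B0 <- matrix(stats::rnorm(N * p, 0, 0.05), N, p)
    Sigma0 <- diag(c(rep(0.05, 3), if (mels) 0.3))
    res <- run_jm_chain(packed, control$iterations, warmup,
                        g0, B0, Sigma0, rule$x, rule$w,
                        ih$t0, ih$mu_c, ih$s2_c,
                        mels, control$prior_only, control$save_re,
                        iw_df0 = p + 2)
    draws[, ch, ] <- res$draws
    pointwise[, ch, ] <- res$pointwise
    b_mean <- b_mean + res$b_mean / control$chains
    if (control$save_re) b_draws[[ch]] <- res$b_draws
    accept[[ch]] <- list(component = res$accept_component,
                         joint = res$accept_joint,
                         re_mean = res$accept_re_mean)
  }

  fit <- structure(
    list(draws = draws, pointwise = pointwise, b_mean = b_mean,
         b_draws = b_draws, variant = variant, control = control,
         subject_ids = vapply(data, `[[`, character(1), "id"),
         par_names = all_names,
         centring = list(t0 = ih$t0, mu_c = ih$mu_c, s2_c = ih$s2_c),
         accept = accept, n_keep = n_keep, warmup = warmup),
    class = "jm_fit")
  fit$diagnostics <- if (control$chains >= 2L) {
    mcmc_diagnostics(fit, warn = FALSE)
  } else {
    data.frame(parameter = all_names, rhat = NA_real_, ess = NA_real_,
               stringsAsFactors = FALSE)
  }
  if (control$chains >= 2L) {
    core <- fit$diagnostics[fit$diagnostics$parameter %in% par_names, ]
    bad <- core[is.finite(core$rhat) & core$rhat > control$rhat_warn, ]
    if (nrow(bad)) {
      warning(sprintf(
        "possible non-convergence: split-Rhat > %.3f for %s (max %.3f)",
        control$rhat_warn, paste(bad$parameter, collapse = ", "),
        max(bad$rhat)), call. = FALSE)
    }
  }
  fit
}

#' @export
print.jm_fit <- function(x, ...) {
  cat("Bayesian joint model fit (", x$variant, " variant)\n", sep = "")
  cat("  chains:", dim(x$draws)[2], " retained draws/chain:", dim(x$draws)[1],
      " subjects:", length(x$subject_ids), "\n")
  core <- x$diagnostics[!grepl("^Sigma", x$diagnostics$parameter), ]
  cat("  max split-Rhat:", format(max(core$rhat, na.rm = TRUE), digits = 4),
      " min bulk-ESS:", format(min(core$ess, na.rm = TRUE), digits = 4), "\n")
  print(posterior_summary(x), ...)
  invisible(x)
}

# iterations x chains matrix for one parameter
par_matrix <- function(fit, par) {
  if (!par %in% fit$par_names) stop("unknown parameter: ", par)
  fit$draws[, , par, drop = TRUE]
}

#' Convergence diagnostics table
#'
#' Split-\eqn{\widehat{R}} and bulk effective sample size per parameter,
#' computed on rank-normalized split chains (the standard published
#' estimators).
#'
#' @param fit a `jm_fit` object (>= 2 chains required).
#' @param warn unused hook for internal calls.
#' @return data frame with columns `parameter`, `rhat`, `ess`.
#' @export
mcmc_diagnostics <- function(fit, warn = TRUE) {
  if (dim(fit$draws)[2] < 2L) {
    stop("convergence diagnostics require at least 2 chains")
  }
  rows <- lapply(fit$par_names, function(pn) {
    m <- par_matrix(fit, pn)
    data.frame(parameter = pn, rhat = split_rhat(m), ess = bulk_ess(m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Posterior summary table
#'
#' Mean and central 95% credible interval per parameter, optionally after
#' per-draw transformations (e.g. back-transforming the log-scale logistic
#' parameters to `a10 = exp(theta1)` etc. as in the natural-scale reporting
#' convention).
#'
#' @param fit a `jm_fit` object.
#' @param pars parameters to include (default: all population parameters,
#'   excluding `Sigma` entries).
#' @param transform `NULL`, the string `"a_scale"` (reports
#'   `a10, a20, a30` = `exp(theta1..3)` together with the associations), or
#'   a named list of functions, each receiving the draws matrix (columns =
#'   parameters) and returning one transformed draw vector.
#' @param probs interval probabilities (default central 95%).
#' @return data frame with columns `parameter`, `mean`, `lower`, `upper`.
#' @export
posterior_summary <- function(fit, pars = NULL, transform = NULL,
                              probs = c(0.025, 0.975)) {
  flat <- apply(fit$draws, 3L, as.vector)  # (iter*chain) x par
  colnames(flat) <- fit$par_names
  if (is.character(transform) && identical(transform, "a_scale")) {
    transform <- list(
      a10 = function(d) exp(d[, "theta1"]),
      a20 = function(d) exp(d[, "theta2"]),
      a30 = function(d) exp(d[, "theta3"]),
      alpha1 = function(d) d[, "alpha1"])
    if ("alpha2" %in% fit$par_names) {
      transform$alpha2 <- function(d) d[, "alpha2"]
    }
  }
  if (!is.null(transform)) {
    cols <- lapply(transform, function(f) f(flat))
    flat <- do.call(cbind, cols)
    colnames(flat) <- names(transform)
    pars <- names(transform)
  }
  if (is.null(pars)) {
    pars <- setdiff(fit$par_names, grep("^Sigma", fit$par_names, value = TRUE))
  }
  missing <- setdiff(pars, colnames(flat))
  if (length(missing)) stop("unknown parameter(s): ",
                            paste(missing, collapse = ", "))
  out <- data.frame(
    parameter = pars,
    mean = colMeans(flat[, pars, drop = FALSE]),
    lower = apply(flat[, pars, drop = FALSE], 2, stats::quantile,
                  probs = probs[1]),
    upper = apply(flat[, pars, drop = FALSE], 2, stats::quantile,
                  probs = probs[2]),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Export posterior draws to CSV
#'
#' Standard interchange layout: one row per retained draw with `chain` and
#' `iteration` columns followed by one column per parameter. The per-subject
#' pointwise log-likelihoods are written alongside in the same layout.
#'
#' @param fit a `jm_fit` object.
#' @param draws_path,pointwise_path output CSV paths (`NULL` to skip one).
#' @return invisibly, the paths written.
#' @export
export_draws <- function(fit, draws_path, pointwise_path = NULL) {
  nk <- dim(fit$draws)[1]
  nc <- dim(fit$draws)[2]
  idx <- data.frame(chain = rep(seq_len(nc), each = nk),
                    iteration = rep(seq_len(nk), nc))
  flat <- apply(fit$draws, 3L, as.vector)
  colnames(flat) <- fit$par_names
  utils::write.csv(cbind(idx, flat), draws_path, row.names = FALSE)
  if (!is.null(pointwise_path)) {
    pw <- apply(fit$pointwise, 3L, as.vector)
    colnames(pw) <- fit$subject_ids
    utils::write.csv(cbind(idx, pw), pointwise_path, row.names = FALSE)
  }
  invisible(c(draws_path, pointwise_path))
}

# posterior-mean parameters of a fit as a jm_parameters object
posterior_mean_params <- function(fit) {
  flat <- apply(fit$draws, 3L, as.vector)
  colnames(flat) <- fit$par_names
  m <- colMeans(flat)
  p <- if (fit$variant == "mels") 4L else 3L
  Sigma <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in i:p) {
    Sigma[i, j] <- Sigma[j, i] <- m[sprintf("Sigma[%d,%d]", i, j)]
  }
  if (fit$variant == "mels") {
    jm_parameters("mels", theta = m[c("theta1", "theta2", "theta3")],
                  theta4 = m[["theta4"]], nu = m[["nu"]], lam = m[["lam"]],
                  phi = m[["phi"]], alpha1 = m[["alpha1"]],
                  alpha2 = m[["alpha2"]], Sigma = Sigma)
  } else {
    jm_parameters("reference", theta = m[c("theta1", "theta2", "theta3")],
                  sigma = m[["sigma"]], nu = m[["nu"]], lam = m[["lam"]],
                  phi = m[["phi"]], alpha1 = m[["alpha1"]], Sigma = Sigma)
  }
}
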