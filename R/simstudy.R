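# Replicate-level simulation-study harness: simulate under a scenario, fit
# one or both model variants, aggregate bias and 95% coverage probability.

#' Bias and coverage from replicate estimates
#'
#' @param estimates replicates x parameters matrix of point estimates
#'   (posterior means).
#' @param lower,upper matrices of 95% credible-interval bounds, same shape.
#' @param truth named vector of true values (names matching columns).
#' @return data frame with columns `parameter`, `bias`, `cp`, `bias_mcse`
#'   (Monte-Carlo SE of the bias), `cp_mcse`, `n_replicates`.
#' @export
bias_coverage <- function(estimates, lower, upper, truth) {
  estimates <- as.matrix(estimates)
  lower <- as.matrix(lower)
  upper <- as.matrix(upper)
  if (!all(dim(estimates) == dim(lower)) ||
      !all(dim(estimates) == dim(upper))) {
    stop("`estimates`, `lower`, `upper` must have identical dimensions")
  }
  pars <- colnames(estimates)
  if (is.null(pars)) pars <- names(truth)
  if (!all(pars %in% names(truth))) {
    stop("`truth` must be named for every estimated parameter")
  }
  R <- nrow(estimates)
  rows <- lapply(pars, function(pn) {
    est <- estimates[, pn]
    cov <- lower[, pn] <= truth[[pn]] & truth[[pn]] <= upper[, pn]
    cp <- mean(cov)
    data.frame(parameter = pn,
               bias = mean(est) - truth[[pn]],
               cp = cp,
               bias_mcse = stats::sd(est) / sqrt(R),
               cp_mcse = sqrt(cp * (1 - cp) / R),
               n_replicates = R,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# parameters whose recovery the study tracks, per fitted variant
study_params <- function(variant) {
  if (variant == "mels") {
    c("theta1", "theta2", "theta3", "theta4", "alpha1", "alpha2")
  } else {
    c("theta1", "theta2", "theta3", "alpha1")
  }
}

# truth vector on the fitted variant's parameter names (misspecified fits
# are judged against the generating values of the shared parameters)
truth_vector <- function(params, variant) {
  tv <- c(theta1 = params$theta[1], theta2 = params$theta[2],
          theta3 = params$theta[3], alpha1 = params$alpha1)
  if (variant == "mels") {
    tv <- c(tv,
            theta4 = if (is.null(params$theta4)) NA_real_ else params$theta4,
            alpha2 = if (is.null(params$alpha2)) NA_real_ else params$alpha2)
  }
  tv
}

#' Run a bias/coverage simulation study
#'
#' For each of `R` replicates: simulate a dataset from the scenario's true
#' model, fit the requested variant(s), and record the posterior mean and
#' central 95% credible interval of every tracked parameter. Replicates
#' whose fit fails to converge (any tracked-parameter split-Rhat above
#' `rhat_exclude`) are excluded from the aggregates and counted. Replicate
#' seeds are `seed + r`, making the study reproducible and extendable.
#'
#' @param scenario a [jm_scenario] (its parameter variant is the generating
#'   model).
#' @param variants character vector of model variants to fit
#'   (`"reference"`, `"mels"`).
#' @param R number of replicates.
#' @param control [jm_control] for the per-replicate fits; the default is a
#'   reduced protocol (2 chains, 1500 iterations) suited to repeated fitting.
#' @param seed base seed for the replicate stream.
#' @param rhat_exclude convergence-exclusion threshold.
#' @return list of class `jm_sim_study`, one element per fitted variant,
#'   each with the `bias_coverage` table, the raw per-replicate estimates,
#'   and the exclusion count.
#' @export
run_sim_study <- function(scenario, variants = c("reference", "mels"),
                          R = 50L, control = jm_control(chains = 2L,
                                                        iterations = 1500L),
                          seed = 1L, rhat_exclude = 1.1) {
  stopifnot(inherits(scenario, "jm_scenario"))
  variants <- match.arg(variants, c("reference", "mels"),
                        several.ok = TRUE)
  if (R < 1) stop("`R` must be >= 1")
  store <- lapply(variants, function(v) {
    pars <- study_params(v)
    list(est = matrix(NA_real_, R, length(pars),
                      dimnames = list(NULL, pars)),
         lo = matrix(NA_real_, R, length(pars),
                     dimnames = list(NULL, pars)),
         hi = matrix(NA_real_, R, length(pars),
                     dimnames = list(NULL, pars)),
         excluded = logical(R))
  })
  names(store) <- variants

  for (r in seq_len(R)) {
    dat <- simulate_jm_data(scenario, seed = seed + r)
    for (v in variants) {
      ctl <- control
      ctl$seed <- as.integer(seed + 131071L * r + match(v, variants))
      fit <- suppressWarnings(jm_fit(dat, v, ctl))
      pars <- study_params(v)
      dg <- fit$diagnostics
      bad <- any(!is.finite(dg$rhat[dg$parameter %in% pars])) ||
        any(dg$rhat[dg$parameter %in% pars] > rhat_exclude)
      if (bad) {
        store[[v]]$excluded[r] <- TRUE
        next
      }
      ps <- posterior_summary(fit, pars = pars)
      store[[v]]$est[r, ] <- ps$mean
      store[[v]]$lo[r, ] <- ps$lower
      store[[v]]$hi[r, ] <- ps$upper
    }
  }

  out <- lapply(variants, function(v) {
    s <- store[[v]]
    keep <- !s$excluded
    if (!any(keep)) stop("all replicates failed convergence for variant ", v)
    tv <- truth_vector(scenario$params, v)
    pars <- study_params(v)
    tracked <- pars[is.finite(tv[pars])]
    tab <- bias_coverage(s$est[keep, tracked, drop = FALSE],
                         s$lo[keep, tracked, drop = FALSE],
                         s$hi[keep, tracked, drop = FALSE],
                         tv[tracked])
    list(variant = v, table = tab, estimates = s$est, lower = s$lo,
         upper = s$hi, excluded = sum(s$excluded), truth = tv,
         visits_range = scenario$visits_range, N = scenario$N,
         n_replicates = sum(keep))
  })
  names(out) <- variants
  structure(out, class = "jm_sim_study",
            seed = seed, generating_variant = scenario$params$variant)
}

#' @export
print.jm_sim_study <- function(x, ...) {
  cat("Simulation study (generating model:",
      attr(x, "generating_variant"), ")\n")
  for (v in names(x)) {
    cat("\nFitted variant:", v, " (replicates:", x[[v]]$n_replicates,
        ", excluded:", x[[v]]$excluded, ")\n")
    print(x[[v]]$table, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Tidy data frame of a simulation-study result
#'
#' One row per (fitted variant, parameter): scenario metadata, bias,
#' coverage probability, Monte-Carlo SEs.
#'
#' @param study a `jm_sim_study` object.
#' @return data frame suitable for CSV export.
#' @export
sim_study_table <- function(study) {
  do.call(rbind, lapply(names(study), function(v) {
    s <- study[[v]]
    cbind(data.frame(generating = attr(study, "generating_variant"),
                     fitted = v,
                     visits = paste(s$visits_range, collapse = "-"),
                     N = s$N, stringsAsFactors = FALSE),
          s$table)
  }))
}
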