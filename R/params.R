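#' Joint-model parameter vector
#'
#' Bundles the population parameters of the joint model. Two variants are
#' supported:
#'
#' * `"reference"`: the longitudinal submodel has a single residual SD
#'   `sigma` shared by all subjects, and only the subject-specific mean
#'   trajectory \eqn{\mu_i(t)} enters the hazard (association `alpha1`).
#' * `"mels"`: a mixed-effects location-scale longitudinal submodel in which
#'   each subject with two or more measurements has their own residual SD
#'   \eqn{\sigma_i = \exp(\theta_4 + b_{i4})} (subjects with a single
#'   measurement use \eqn{\exp(\theta_4)}), and both \eqn{\mu_i(t)} and
#'   \eqn{\sigma_i^2} enter the hazard (associations `alpha1`, `alpha2`).
#'
#' The mean trajectory is the three-parameter logistic
#' \eqn{\mu_i(t) = a_{i1} / (1 + \exp\{-(t - a_{i2})/a_{i3}\})} with
#' \eqn{a_{ik} = \exp(\theta_k + b_{ik})}. The survival submodel is a mixture
#' cure model: cure probability \eqn{\eta = 1/(1+e^{-\nu})} and, for
#' susceptible subjects, a Weibull proportional-hazards latency model
#' \eqn{h(t) = \phi t^{\phi-1}\exp\{\lambda + \alpha_1\mu_i(t) +
#' \alpha_2\sigma_i^2\}}.
#'
#' @param variant `"reference"` or `"mels"`.
#' @param theta numeric length 3; log-scale logistic parameters
#'   \eqn{(\theta_1,\theta_2,\theta_3)}.
#' @param theta4 log residual-SD intercept (MELS variant only).
#' @param sigma residual SD (reference variant only, positive).
#' @param nu cure-fraction logit.
#' @param lam Weibull log-scale parameter \eqn{\lambda}.
#' @param phi Weibull shape parameter (positive).
#' @param alpha1 association of the hazard with \eqn{\mu_i(t)}.
#' @param alpha2 association of the hazard with \eqn{\sigma_i^2}
#'   (MELS variant only).
#' @param Sigma random-effects covariance matrix, 3x3 (reference) or 4x4
#'   (MELS), symmetric positive definite.
#' @return An object of class `jm_parameters`.
#' @examples
#' p <- jm_parameters("reference", theta = c(1.5, 2.7, 1.9), sigma = 0.25,
#'                    nu = 0.85, lam = -14.5, phi = 4, alpha1 = -0.6,
#'                    Sigma = diag(c(0.02, 0.08, 0.17)))
#' @export
jm_parameters <- function(variant = c("mels", "reference"),
                          theta,
                          theta4 = NULL,
                          sigma = NULL,
                          nu,
                          lam,
                          phi,
                          alpha1,
                          alpha2 = NULL,
                          Sigma) {
  variant <- match.arg(variant)
  if (length(theta) != 3L || !all(is.finite(theta))) {
    stop("`theta` must be a finite numeric vector of length 3")
  }
  for (nm in c("nu", "lam", "phi", "alpha1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number", nm))
    }
  }
  if (phi <= 0) stop("`phi` must be positive")
  if (variant == "mels") {
    if (is.null(theta4) || !is.finite(theta4)) {
      stop("MELS variant requires a finite `theta4`")
    }
    if (is.null(alpha2) || !is.finite(alpha2)) {
      stop("MELS variant requires a finite `alpha2`")
    }
    if (!is.null(sigma)) stop("`sigma` is not used by the MELS variant")
    p <- 4L
  } else {
    if (is.null(sigma) || !is.finite(sigma) || sigma <= 0) {
      stop("reference variant requires a positive `sigma`")
    }
    if (!is.null(theta4) || !is.null(alpha2)) {
      stop("`theta4`/`alpha2` are not used by the reference variant")
    }
    p <- 3L
  }
  Sigma <- as.matrix(Sigma)
  if (!isTRUE(all.equal(dim(Sigma), c(p, p))) ||
      !isTRUE(all.equal(Sigma, t(Sigma), tolerance = 1e-10))) {
    stop(sprintf("`Sigma` must be a symmetric %dx%d matrix", p, p))
  }
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("`Sigma` must be positive definite")
  structure(
    list(variant = variant, theta = as.numeric(theta),
         theta4 = if (variant == "mels") as.numeric(theta4) else NULL,
         sigma = if (variant == "reference") as.numeric(sigma) else NULL,
         nu = as.numeric(nu), lam = as.numeric(lam), phi = as.numeric(phi),
         alpha1 = as.numeric(alpha1),
         alpha2 = if (variant == "mels") as.numeric(alpha2) else NULL,
         Sigma = Sigma, n_re = p),
    class = "jm_parameters"
  )
}

#' @export
print.jm_parameters <- function(x, ...) {
  cat("Joint-model parameters (", x$variant, " variant)\n", sep = "")
  cat("  theta:", format(x$theta, digits = 4), "\n")
  if (x$variant == "mels") {
    cat("  theta4:", format(x$theta4, digits = 4), "\n")
  } else {
    cat("  sigma:", format(x$sigma, digits = 4), "\n")
  }
  cat("  nu:", format(x$nu, digits = 4),
      " (cure fraction ", format(cure_fraction(x$nu), digits = 4), ")\n",
      sep = "")
  cat("  lam:", format(x$lam, digits = 4), " phi:", format(x$phi, digits = 4),
      "\n")
  cat("  alpha1:", format(x$alpha1, digits = 4))
  if (x$variant == "mels") cat("  alpha2:", format(x$alpha2, digits = 4))
  cat("\n  Sigma diag:", format(diag(x$Sigma), digits = 4), "\n")
  invisible(x)
}

#' Built-in simulation truths
#'
#' Returns the parameter sets used as ground truth by the two built-in
#' simulation scenarios: one generated from the reference joint model
#' (shares the mean only) and one from the MELS joint model (shares mean
#' and within-subject variance). The cure-fraction logit defaults to
#' `qlogis(0.7)`, i.e. 70% of subjects immune to the event.
#'
#' @param variant `"reference"` or `"mels"` generating model.
#' @param cure_prob cure fraction used to set `nu`; default 0.7.
#' @return A [jm_parameters] object.
#' @export
scenario_truth <- function(variant = c("reference", "mels"),
                           cure_prob = 0.7) {
  variant <- match.arg(variant)
  if (variant == "reference") {
    jm_parameters("reference", theta = c(1.5, 2.7, 1.9), sigma = 0.25,
                  nu = stats::qlogis(cure_prob), lam = -14.5, phi = 4,
                  alpha1 = -0.6, Sigma = diag(c(0.02, 0.08, 0.17)))
  } else {
    jm_parameters("mels", theta = c(1.5, 2.7, 1.9), theta4 = -2,
                  nu = stats::qlogis(cure_prob), lam = -14.7, phi = 3.9,
                  alpha1 = -0.4, alpha2 = 3.1,
                  Sigma = diag(c(0.02, 0.07, 0.1, 0.6)))
  }
}

# normalise a random-effects argument: NULL -> zeros, vector -> checked length
re_vector <- function(b, params) {
  p <- params$n_re
  if (is.null(b)) return(numeric(p))
  b <- as.numeric(b)
  if (length(b) == 3L && p == 4L) b <- c(b, 0)
  if (length(b) != p) {
    stop(sprintf("random-effects vector must have length %d", p))
  }
  if (!all(is.finite(b))) stop("random effects must be finite")
  b
}
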