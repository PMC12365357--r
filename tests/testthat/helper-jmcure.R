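# Shared fixtures and independent oracles for the test suite.

# brute-force fine-grid cumulative hazard (composite Simpson on 1e5
# panels): independent of the package's quadrature path, composes the
# hazard formula directly
trapz_cumhaz <- function(t, params, b = NULL, n_i = 2L, panels = 1e5) {
  if (t == 0) return(0)
  if (is.null(b)) b <- numeric(params$n_re)
  a <- exp(params$theta + b[1:3])
  sig <- if (params$variant == "reference") params$sigma else {
    if (n_i == 1L) exp(params$theta4) else exp(params$theta4 + b[4])
  }
  lin_const <- params$lam +
    if (params$variant == "mels") params$alpha2 * sig^2 else 0
  u <- seq(0, t, length.out = panels + 1)
  mu <- a[1] / (1 + exp(-(u - a[2]) / a[3]))
  h <- params$phi * u^(params$phi - 1) * exp(lin_const + params$alpha1 * mu)
  if (params$phi > 1) h[1] <- 0  # limit at the origin
  w <- rep(c(2, 4), length.out = panels + 1)
  w[c(1, panels + 1)] <- 1
  sum(w * h) * (t / panels) / 3
}

# a tiny two-subject toy dataset (one interval, one right-censored)
toy_data <- function() {
  jm_data(list(
    jm_subject("a", times = c(12, 30), y = c(2.1, 4.0), censoring = "interval",
               t_left = 30, t_right = 40),
    jm_subject("b", times = c(15, 40, 62), y = c(2.5, 4.3, 4.4),
               censoring = "right", t_cens = 90)
  ))
}

ref_pars <- function(alpha1 = -0.6, lam = -14.5, phi = 4, nu = qlogis(0.7),
                     sigma = 0.25) {
  jm_parameters("reference", theta = c(1.5, 2.7, 1.9), sigma = sigma,
                nu = nu, lam = lam, phi = phi, alpha1 = alpha1,
                Sigma = diag(c(0.02, 0.08, 0.17)))
}

mels_pars <- function(alpha1 = -0.4, alpha2 = 3.1, lam = -14.7, phi = 3.9,
                      nu = qlogis(0.7), theta4 = -2) {
  jm_parameters("mels", theta = c(1.5, 2.7, 1.9), theta4 = theta4,
                nu = nu, lam = lam, phi = phi, alpha1 = alpha1,
                alpha2 = alpha2, Sigma = diag(c(0.02, 0.07, 0.1, 0.6)))
}

quiet_fit <- function(...) suppressWarnings(jm_fit(...))

# random valid parameter draw for property loops (fixed-seed callers)
random_ref_pars <- function() {
  jm_parameters("reference",
                theta = c(runif(1, 1, 2), runif(1, 2, 3.2), runif(1, 1.2, 2.3)),
                sigma = runif(1, 0.1, 0.5),
                nu = runif(1, -1, 1.5),
                lam = runif(1, -17, -11),
                phi = runif(1, 2, 5),
                alpha1 = runif(1, -1, 0.3),
                Sigma = diag(c(0.02, 0.08, 0.17)))
}
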