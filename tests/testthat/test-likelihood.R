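test_that("longitudinal log-likelihood matches direct density evaluation", {
  p <- ref_pars(sigma = 0.25)
  s <- jm_subject("x", times = 20, y = logistic_mean(20, p), "right",
                  t_cens = 20)
  expect_equal(loglik_longitudinal(s, p), log(1 / (0.25 * sqrt(2 * pi))),
               tolerance = 1e-12)
  # two observations: sum of independent per-point densities
  s2 <- jm_subject("y", times = c(15, 45), y = c(2.2, 4.1), "right",
                   t_cens = 45)
  b <- c(0.1, -0.05, 0.02)
  mu <- logistic_mean(c(15, 45), p, b)
  expect_equal(loglik_longitudinal(s2, p, b),
               sum(dnorm(c(2.2, 4.1), mu, 0.25, log = TRUE)),
               tolerance = 1e-12)
  # doubling sigma at zero residuals costs log 2 per observation
  s0 <- jm_subject("z", times = c(10, 30, 60),
                   y = logistic_mean(c(10, 30, 60), p), "right", t_cens = 60)
  p2 <- ref_pars(sigma = 0.5)
  expect_equal(loglik_longitudinal(s0, p) - loglik_longitudinal(s0, p2),
               3 * log(2), tolerance = 1e-12)
})

test_that("survival log-likelihood handles both censoring classes", {
  p <- ref_pars()
  eta <- cure_fraction(p$nu)
  # whole-line interval -> log(1 - eta)
  s_wide <- jm_subject("w", times = 20, y = 3, "interval",
                       t_left = 0, t_right = 1e7)
  expect_equal(loglik_survival(s_wide, p), log(1 - eta), tolerance = 1e-6)
  # right-censoring at 0 carries no information
  s_r0 <- jm_subject("r", times = 5, y = 2, "right", t_cens = 0)
  expect_equal(loglik_survival(s_r0, p), 0, tolerance = 1e-12)
  # interval (30, 40] composed from the oracle integrator
  s_int <- jm_subject("i", times = 20, y = 3, "interval",
                      t_left = 30, t_right = 40)
  expected <- log(1 - eta) +
    log(exp(-trapz_cumhaz(30, p)) - exp(-trapz_cumhaz(40, p)))
  expect_equal(loglik_survival(s_int, p), expected, tolerance = 1e-6)
  # degenerate interval raises in strict mode
  p_fast <- ref_pars(lam = 20, phi = 4, alpha1 = 0)
  expect_error(loglik_survival(s_int, p_fast, strict = TRUE), "zero mass")
})

test_that("cure monotonicity moves the two censoring classes oppositely", {
  s_int <- jm_subject("i", times = 20, y = 3, "interval",
                      t_left = 30, t_right = 40)
  s_rc <- jm_subject("r", times = 20, y = 3, "right", t_cens = 60)
  lo <- ref_pars(nu = 0)
  hi <- ref_pars(nu = 1)
  expect_lt(loglik_survival(s_int, hi), loglik_survival(s_int, lo))
  expect_gt(loglik_survival(s_rc, hi), loglik_survival(s_rc, lo))
})

test_that("interval contribution approaches the density limit", {
  p <- ref_pars()
  t0 <- 45
  w <- 1e-4
  s <- jm_subject("d", times = 20, y = 3, "interval",
                  t_left = t0, t_right = t0 + w)
  eta <- cure_fraction(p$nu)
  mass <- exp(loglik_survival(s, p)) / (1 - eta)
  dens <- jm_hazard(t0, p) * jm_survival(t0, p)
  expect_equal(mass / w, dens, tolerance = 1e-3)
})

test_that("log-prior matches independent density evaluations", {
  # all location parameters at zero sit at the Normal(0, 10^2) mode
  p0 <- jm_parameters("reference", theta = c(0, 0, 0), sigma = 1, nu = 0,
                      lam = 0, phi = 1, alpha1 = 0, Sigma = diag(3))
  lp <- log_prior(p0)
  norm_mode <- log(1 / (10 * sqrt(2 * pi)))
  # 6 location parameters (theta1..3, nu, lam, alpha1)
  # half-Cauchy(0,1) at 1: density 2/(pi * 2) = 1/pi, for sigma^2 and phi
  # inverse-Wishart(I3, 5) at I3: frozen scipy.stats.invwishart oracle
  expect_equal(lp, 6 * norm_mode + 2 * log(1 / pi) + (-8.579599315811365),
               tolerance = 1e-9)
  # MELS variant, 4x4 identity Sigma, df = 6
  pm <- jm_parameters("mels", theta = c(0, 0, 0), theta4 = 0, nu = 0,
                      lam = 0, phi = 1, alpha1 = 0, alpha2 = 0,
                      Sigma = diag(4))
  expect_equal(log_prior(pm),
               8 * norm_mode + log(1 / pi) + (-14.609003637665163),
               tolerance = 1e-9)
  # non-identity Sigma against the frozen oracle
  X <- rbind(c(0.5, 0.1, 0.0), c(0.1, 1.0, 0.1), c(0.0, 0.1, 2.0))
  p3 <- jm_parameters("reference", theta = c(0, 0, 0), sigma = 1, nu = 0,
                      lam = 0, phi = 1, alpha1 = 0, Sigma = X)
  expect_equal(log_prior(p3) - log_prior(p0),
               -8.750284564497445 - (-8.579599315811365), tolerance = 1e-9)
  # half-Cauchy on the SD scale when requested
  expect_equal(log_prior(p0, cauchy_on = "sd"), log_prior(p0),
               tolerance = 1e-12)  # sigma = 1 is a fixed point
  p_s <- jm_parameters("reference", theta = c(0, 0, 0), sigma = 2, nu = 0,
                      lam = 0, phi = 1, alpha1 = 0, Sigma = diag(3))
  expect_equal(log_prior(p_s, cauchy_on = "sd") -
                 log_prior(p_s, cauchy_on = "variance"),
               (log(2 / pi) - log1p(4)) - (log(2 / pi) - log1p(16)),
               tolerance = 1e-12)
})

test_that("joint log-likelihood is additive over subjects", {
  d <- toy_data()
  p <- ref_pars()
  out <- loglik_joint(d, p)
  expect_equal(out$total, sum(out$pointwise$loglik), tolerance = 1e-10)
  # pointwise entries compose the two submodel contributions
  for (i in 1:2) {
    s <- d[[i]]
    expect_equal(out$pointwise$loglik[i],
                 loglik_longitudinal(s, p) + loglik_survival(s, p),
                 tolerance = 1e-12)
  }
  # empty dataset
  e <- loglik_joint(jm_data(list()), p)
  expect_identical(e$total, 0)
  expect_identical(nrow(e$pointwise), 0L)
  # additivity at random effects, larger data
  sc <- jm_scenario(ref_pars(), N = 30, seed = 3)
  dd <- simulate_jm_data(sc)
  tr <- attr(dd, "truth")
  out2 <- loglik_joint(dd, ref_pars(), tr$b)
  expect_equal(out2$total, sum(out2$pointwise$loglik), tolerance = 1e-10)
})

test_that("compiled likelihood agrees with the R reference implementation", {
  for (variant in c("reference", "mels")) {
    p <- if (variant == "mels") mels_pars() else ref_pars()
    sc <- jm_scenario(p, N = 40, seed = 9)
    d <- simulate_jm_data(sc)
    tr <- attr(d, "truth")
    rule <- jmcure:::gl_rule(15)
    g <- if (variant == "mels") {
      c(p$theta, p$theta4, p$nu, p$lam, log(p$phi), p$alpha1, p$alpha2)
    } else {
      c(p$theta, 2 * log(p$sigma), p$nu, p$lam, log(p$phi), p$alpha1)
    }
    llc <- jmcure:::jm_loglik_cpp(jmcure:::pack_data(d), g, tr$b,
                                  rule$x, rule$w, 1, 0, 0,
                                  variant == "mels")
    expect_equal(llc, loglik_joint(d, p, tr$b, order = 15L)$total,
                 tolerance = 1e-8)
    # centred parameterization is an exact reparameterization
    t0 <- 40; mu_c <- 3.5; s2_c <- 0.02
    a2 <- if (variant == "mels") p$alpha2 else 0
    g_c <- g
    g_c[6] <- p$lam + p$phi * log(t0) + p$alpha1 * mu_c + a2 * s2_c
    llc2 <- jmcure:::jm_loglik_cpp(jmcure:::pack_data(d), g_c, tr$b,
                                   rule$x, rule$w, t0, mu_c, s2_c,
                                   variant == "mels")
    expect_equal(llc2, llc, tolerance = 1e-8)
  }
})
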