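test_that("IWRES are exact standardized residuals at plug-in values", {
  p <- ref_pars()
  sc <- jm_scenario(p, N = 40, seed = 21)
  d <- simulate_jm_data(sc)
  tr <- attr(d, "truth")
  r <- iwres(d, p, tr$b)
  expect_identical(nrow(r), nrow(longitudinal_table(d)))
  # zero residual when the observation equals the subject mean
  s <- jm_subject("m", times = 25, y = logistic_mean(25, p), "right",
                  t_cens = 90)
  expect_equal(iwres(jm_data(list(s)), p)$iwres, 0)
  # halving sigma doubles every residual
  p_half <- ref_pars(sigma = 0.125)
  r2 <- iwres(d, p_half, tr$b)
  expect_equal(r2$iwres, 2 * r$iwres, tolerance = 1e-12)
})

test_that("IWRES at truth on true-model data are standard normal", {
  p <- mels_pars()
  sc <- jm_scenario(p, N = 2500, visits_range = c(3, 5), seed = 22)
  d <- simulate_jm_data(sc)
  tr <- attr(d, "truth")
  r <- iwres(d, p, tr$b)$iwres
  n <- length(r)
  expect_gt(n, 5000)
  expect_lt(abs(mean(r)), 3 / sqrt(n))
  expect_gt(sd(r), 0.95)
  expect_lt(sd(r), 1.05)
})

test_that("Cox-Snell residuals define a censored unit-exponential sample", {
  p <- ref_pars()
  sc <- jm_scenario(p, N = 500, seed = 23)
  d <- simulate_jm_data(sc)
  tr <- attr(d, "truth")
  res <- cox_snell(d, p, tr$b)
  expect_identical(nrow(res), 500L)
  expect_identical(sort(unique(res$event)), c(0L, 1L))
  # latency-scale residuals at the latent event times are exactly Exp(1)
  sus <- which(!tr$cured)
  r_lat <- vapply(sus, function(i) {
    jm_cumhaz(tr$T_event[i], p, tr$b[i, ])
  }, numeric(1))
  ks <- suppressWarnings(ks.test(r_lat, "pexp"))
  expect_gt(ks$p.value, 0.01)
  # KM of the population-scale residuals tracks exp(-r) within its band
  km <- km_overlay(res)
  grid <- km$residual <= 2
  expect_gt(mean(km$lower[grid] <= km$theoretical[grid] &
                   km$theoretical[grid] <= km$upper[grid]), 0.9)
  # subject with survival 1 has residual 0
  s0 <- jm_subject("z", times = 5, y = 2, "right", t_cens = 0)
  expect_equal(cox_snell(jm_data(list(s0)), p)$residual, 0)
  # endpoint conventions are ordered
  r_l <- cox_snell(d, p, tr$b, convention = "left")$residual
  r_r <- cox_snell(d, p, tr$b, convention = "right")$residual
  ev <- res$event == 1
  expect_true(all(r_l[ev] <= res$residual[ev] & res$residual[ev] <= r_r[ev]))
})

test_that("KM overlay has the estimator's structural properties", {
  # single event at r = 1: KM drops from 1 to 0 there
  one <- data.frame(id = "a", residual = 1, event = 1L)
  km1 <- km_overlay(one)
  expect_equal(km1$km, 0)
  expect_equal(km1$residual, 1)
  # non-increasing step function on a mixed sample
  set.seed(3)
  mix <- data.frame(id = paste0("s", 1:200),
                    residual = rexp(200),
                    event = rbinom(200, 1, 0.6))
  km <- km_overlay(mix)
  expect_true(all(diff(km$km) <= 1e-12))
  # all-censored sample: KM stays at 1
  cens_only <- transform(mix, event = 0L)
  expect_true(all(km_overlay(cens_only)$km == 1))
  # KM of exact unit-exponential draws matches exp(-r)
  set.seed(4)
  big <- data.frame(id = paste0("b", 1:10000), residual = rexp(10000),
                    event = 1L)
  kmb <- km_overlay(big)
  sel <- kmb$residual <= 3
  expect_lt(max(abs(kmb$km[sel] - kmb$theoretical[sel])), 0.02)
})

test_that("PSIS-LOO matches the arviz oracle on a frozen problem", {
  # deterministic pseudo log-likelihood matrix (no RNG, same in any language)
  S <- 400; n <- 20
  x <- qnorm(seq_len(n) / (n + 1))
  m <- qnorm(seq_len(S) / (S + 1)) * 0.5
  ll <- t(vapply(seq_len(S), function(s) dnorm(x, m[s], 1, log = TRUE),
                 numeric(n)))
  loo <- psis_loo(ll)
  # frozen value computed with arviz.stats.psislw + log-sum-exp
  expect_equal(loo$elpd, -30.989491789112364, tolerance = 5e-3)
  expect_true(all(loo$pareto_k < 0.7))
})

test_that("PSIS-LOO matches exact refit LOO on a conjugate toy model", {
  # y_i | mu ~ N(mu, 1), mu ~ N(0, 1): everything closed-form
  set.seed(31)
  n <- 16
  y <- rnorm(n, 0.4, 1)
  post_var <- 1 / (n + 1)
  post_mean <- sum(y) * post_var
  S <- 8000
  mu_draws <- rnorm(S, post_mean, sqrt(post_var))
  ll <- vapply(seq_len(n),
               function(i) dnorm(y[i], mu_draws, 1, log = TRUE),
               numeric(S))
  loo <- psis_loo(ll)
  # exact LOO: leave-one-out posterior predictive is Normal
  exact <- vapply(seq_len(n), function(i) {
    v_i <- 1 / n
    m_i <- sum(y[-i]) * v_i
    dnorm(y[i], m_i, sqrt(1 + v_i), log = TRUE)
  }, numeric(1))
  expect_lt(abs(loo$elpd - sum(exact)), max(loo$se, 0.3))
  expect_equal(loo$looic, -2 * loo$elpd, tolerance = 1e-12)
})

test_that("LOO comparison is antisymmetric and detects identical models", {
  set.seed(41)
  ll <- matrix(rnorm(2000, -1, 0.3), 200, 10)
  a <- psis_loo(ll)
  same <- loo_compare_jm(a, psis_loo(ll))
  expect_equal(same$elpd_diff, 0, tolerance = 1e-12)
  ll2 <- ll - 0.2
  ab <- loo_compare_jm(psis_loo(ll), psis_loo(ll2), labels = c("A", "B"))
  ba <- loo_compare_jm(psis_loo(ll2), psis_loo(ll), labels = c("B", "A"))
  expect_equal(ab$elpd_diff, -ba$elpd_diff, tolerance = 1e-10)
  expect_identical(ab$preferred, "A")
  expect_identical(ba$preferred, "A")
})

test_that("the location-scale variant is LOO-preferred on its own data", {
  p <- mels_pars()
  sc <- jm_scenario(p, N = 150, visits_range = c(2, 5), seed = 55)
  d <- simulate_jm_data(sc)
  ctl <- function(s) jm_control(chains = 2, iterations = 2500, seed = s)
  fit_m <- quiet_fit(d, "mels", ctl(1))
  fit_r <- quiet_fit(d, "reference", ctl(2))
  cmp <- suppressWarnings(
    loo_compare_jm(fit_m, fit_r, labels = c("mels", "reference")))
  expect_identical(cmp$preferred, "mels")
  expect_lt(cmp$looic[["mels"]], cmp$looic[["reference"]])
})

test_that("residual helpers validate subject alignment", {
  d <- toy_data()
  sc <- jm_scenario(ref_pars(), N = 5, seed = 1)
  other <- simulate_jm_data(sc)
  fit <- quiet_fit(other, "reference",
                   jm_control(chains = 2, iterations = 200, seed = 1))
  expect_error(iwres(d, fit), "do not match")
  expect_error(cox_snell(d, fit), "do not match")
})
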