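# jmcure

Bayesian joint models coupling a **nonlinear mixed-effects location-scale
(MELS) longitudinal submodel** to a **mixture cure survival submodel for
interval-censored event times**, linked through the subject-specific
longitudinal mean and variance.

The package is built for the data structure of early-pregnancy biomarker
studies: log10 beta-HCG measured at a few irregular visits per woman, an
unobserved day of fetal death known only to lie in a detection window
after the last measurement, and a subpopulation of normal pregnancies
that will never miscarry. It is equally applicable to any biomarker/event
problem with a sigmoidal trajectory, an immune fraction, and
interval-censored detection.

## Model

Longitudinal submodel (three-parameter logistic with subject-specific
error variance):

    y_i(t) = mu_i(t) + e_i(t),   mu_i(t) = a_i1 / (1 + exp(-(t - a_i2)/a_i3)),
    a_ik = exp(theta_k + b_ik),  e_i(t) ~ N(0, sigma_i^2),
    sigma_i = exp(theta4)            if n_i = 1
            = exp(theta4 + b_i4)     if n_i >= 2

Survival submodel (mixture cure, Weibull latency, two shared terms):

    P(immune) = eta = 1 / (1 + exp(-nu))
    h_i(t) = phi t^(phi-1) exp{ lambda + alpha1 * mu_i(t) + alpha2 * sigma_i^2 }

`alpha1` measures how the current trajectory level shifts the miscarriage
hazard; `alpha2` how within-subject variability does. The *reference*
variant (`variant = "reference"`) shares the mean only and uses a common
error SD. Random effects are multivariate normal with covariance `Sigma`;
priors are Normal(0, 10^2) on location parameters, half-Cauchy(0, 1) on
`phi` and `sigma^2`, inverse-Wishart on `Sigma`. Posterior sampling is an
adaptive Metropolis-within-Gibbs sampler (RcppArmadillo) with conjugate
updates for `Sigma` and the latent cure indicators; see the methods
vignette (`vignettes/joint-mels-cure-model.Rmd`) for the sampler design
and all numerical conventions.

## Worked example

Simulate a cohort of 200 women from the built-in location-scale truth,
fit both model variants, and compare them:

```r
library(jmcure)

truth <- scenario_truth("mels")      # theta = (1.5, 2.7, 1.9), theta4 = -2,
                                     # lam = -14.7, phi = 3.9,
                                     # alpha1 = -0.4, alpha2 = 3.1
sc  <- jm_scenario(truth, N = 200, visits_range = c(1, 4), seed = 11)
dat <- simulate_jm_data(sc)
dat
#> Joint-model dataset: 200 subjects, 480 longitudinal measurements
#>   interval-censored (events): 54  right-censored: 146

fit <- jm_fit(dat, "mels", jm_control(chains = 3, iterations = 3000, seed = 9))
posterior_summary(fit, transform = "a_scale")
#>   parameter       mean       lower       upper
#> 1       a10  4.5096687  4.39931982  4.63054891
#> 2       a20 14.8107036 13.83462576 15.77992887
#> 3       a30  6.0752285  5.42458493  6.68726159
#> 4    alpha1 -0.4551957 -0.98217598  0.04831039
#> 5    alpha2  2.5899383  0.08496856  8.58063973
```

`a10`, `a20`, `a30` are the population logistic plateau (log10 units),
inflection day and time-scale (days) — compare the generating values
4.48, 14.88, 6.69 — and both associations recover their generating
values (`alpha1 = -0.4` protective level effect, `alpha2 = 3.1` harmful
variability effect) within their credible intervals. Convergence diagnostics (`mcmc_diagnostics(fit)`) report
rank-normalized split-Rhat and bulk ESS per parameter.

Goodness of fit and model comparison:

```r
res <- cox_snell(dat, fit)           # interval-censoring + cure aware
km  <- km_overlay(res)               # KM of residuals vs exp(-r)
iw  <- iwres(dat, fit)               # standardized longitudinal residuals

fit_ref <- jm_fit(dat, "reference", jm_control(chains = 3, iterations = 3000,
                                               seed = 10))
loo_compare_jm(fit, fit_ref, labels = c("mels", "reference"))
#> LOO-CV comparison (deviance scale, lower is better)
#>   mels       looic 438.4
#>   reference  looic 967.9
#>   elpd difference (mels - reference): 264.7 (SE 27.8); preferred: mels
```

A replicate-level bias/coverage study (the validation design used
throughout the package):

```r
study <- run_sim_study(sc, c("reference", "mels"), R = 50,
                       control = jm_control(chains = 2, iterations = 3000),
                       seed = 1)
sim_study_table(study)   # tidy bias / 95% coverage table per parameter
```

## Command-line use

A thin CLI over the same functions ships in `inst/cli/jmcure.R`:

    Rscript $(Rscript -e 'cat(system.file("cli", "jmcure.R", package = "jmcure"))') \
        simulate --config scenario.yaml --out data/
    ... fit --longitudinal data/longitudinal.csv --survival data/survival.csv \
            --variant mels --out fit/
    ... diagnose --longitudinal data/longitudinal.csv --survival data/survival.csv \
            --fit fit/ --out diag/
    ... simstudy --config study.yaml --out study/

Datasets travel as two CSVs: a long-format longitudinal table
(`id, time_days, log10_value`) and a per-subject survival table
(`id, censoring, t_left, t_right, t_cens`).

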