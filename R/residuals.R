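# Goodness-of-fit residuals: IWRES for the longitudinal submodel and
# Cox-Snell residuals (interval censoring + cure aware) for the survival
# submodel.

# resolve (params, b) plug-ins from either a jm_fit or explicit arguments
resolve_plugin <- function(data, object, b) {
  if (inherits(object, "jm_fit")) {
    if (!identical(vapply(data, `[[`, character(1), "id"),
                   object$subject_ids)) {
      stop("subjects in `data` do not match the fitted subjects")
    }
    list(params = posterior_mean_params(object), b = object$b_mean)
  } else if (inherits(object, "jm_parameters")) {
    n <- length(data)
    if (is.null(b)) b <- matrix(0, n, object$n_re)
    b <- as.matrix(b)
    if (nrow(b) != n) stop("`b` must have one row per subject")
    list(params = object, b = b)
  } else {
    stop("`object` must be a `jm_fit` or `jm_parameters`")
  }
}

#' Individual weighted residuals (IWRES)
#'
#' For each longitudinal observation,
#' \eqn{(y_{ij} - \hat\mu_i(t_{ij})) / \hat\sigma_i}, where the subject mean
#' and error SD are evaluated at the posterior means of the parameters and
#' subject random effects (or at supplied plug-in values). Approximately
#' standard normal under a correctly specified longitudinal submodel.
#'
#' @param data a `jm_data` object.
#' @param object a `jm_fit` for the same subjects, or a [jm_parameters]
#'   plug-in.
#' @param b optional random-effects matrix (rows = subjects) used with a
#'   parameter plug-in; defaults to zeros.
#' @return data frame with columns `id`, `time_days`, `iwres`.
#' @export
iwres <- function(data, object, b = NULL) {
  pl <- resolve_plugin(data, object, b)
  out <- lapply(seq_along(data), function(i) {
    s <- data[[i]]
    bi <- pl$b[i, ]
    mu <- logistic_mean(s$times, pl$params, bi)
    sd_i <- error_sd(pl$params, bi, length(s$y))
    data.frame(id = s$id, time_days = s$times,
               iwres = (s$y - mu) / sd_i, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cox-Snell residuals under interval censoring and cure
#'
#' \eqn{r_i = -\log S_{pop}(t^*_i)} at plug-in (posterior-mean) parameters
#' and random effects, with the cure-adjusted population survival
#' \eqn{S_{pop} = \eta + (1-\eta) S}. For interval-censored subjects
#' \eqn{t^*_i} is, by convention, the interval midpoint (configurable to
#' either endpoint) and the residual is treated as an event; right-censored
#' subjects use their censoring time and remain censored. Under a correct
#' model the residuals behave like a unit-exponential censored sample.
#'
#' @inheritParams iwres
#' @param convention imputed event time within the censoring interval:
#'   `"midpoint"` (default), `"left"`, or `"right"`.
#' @return data frame of class `jm_coxsnell` with columns `id`, `residual`,
#'   `event` (1 = interval-censored subject, 0 = right-censored).
#' @export
cox_snell <- function(data, object, b = NULL,
                      convention = c("midpoint", "left", "right")) {
  convention <- match.arg(convention)
  pl <- resolve_plugin(data, object, b)
  out <- lapply(seq_along(data), function(i) {
    s <- data[[i]]
    bi <- pl$b[i, ]
    if (s$censoring == "interval") {
      tstar <- switch(convention,
                      midpoint = (s$t_left + s$t_right) / 2,
                      left = s$t_left, right = s$t_right)
      ev <- 1L
    } else {
      tstar <- s$t_cens
      ev <- 0L
    }
    r <- -log(jm_pop_survival(tstar, pl$params, bi, length(s$y)))
    data.frame(id = s$id, residual = r, event = ev, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("jm_coxsnell", class(res))
  res
}

#' Kaplan-Meier overlay for Cox-Snell residuals
#'
#' Kaplan-Meier estimate (with Greenwood 95% confidence limits) of the
#' residual "survival" curve over residual time, paired with the
#' unit-exponential reference curve \eqn{e^{-r}}. Under a correct survival
#' submodel the KM curve tracks the reference within its band.
#'
#' @param residuals output of [cox_snell].
#' @return data frame with columns `residual`, `km`, `lower`, `upper`,
#'   `theoretical`.
#' @export
km_overlay <- function(residuals) {
  stopifnot(nrow(residuals) >= 1)
  sf <- survival::survfit(
    survival::Surv(residuals$residual, residuals$event) ~ 1,
    conf.type = "log")
  data.frame(residual = sf$time, km = sf$surv,
             lower = sf$lower, upper = sf$upper,
             theoretical = exp(-sf$time))
}
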