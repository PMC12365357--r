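#' Simulation scenario configuration
#'
#' Describes one data-generating condition: true parameters, number of
#' subjects, the range of planned visits per subject, the visit-time window,
#' and the event-detection window that produces interval censoring.
#'
#' @param params true [jm_parameters] (its variant is the generating model).
#' @param N number of subjects.
#' @param visits_range integer `c(min, max)` planned visits per subject,
#'   within `[1, 10]`.
#' @param visit_window `c(first, last)` days between which visit times are
#'   drawn uniformly.
#' @param detection_window length in days of the event-detection interval
#'   appended after the last visit (default 10).
#' @param followup_end administrative close-out time (days): a subject still
#'   event-free at the end of monitoring is right-censored here. Defaults to
#'   `visit_window[2] + detection_window`, i.e. the end of the scheduled
#'   monitoring period plus one detection window. This guarantees the
#'   sufficient-follow-up condition that makes the cure fraction
#'   identifiable (event-free status of a normal pregnancy is known through
#'   the end of the first trimester, not only up to the last hormone
#'   measurement).
#' @param truncate_visits if `TRUE`, a susceptible subject's visits at or
#'   after the event time are discarded (with rejection-resampling to keep
#'   at least one visit), mimicking the clinical impossibility of measuring
#'   the biomarker after fetal death. The default `FALSE` keeps the visit
#'   schedule exogenous, exactly matching the non-informative-observation
#'   assumption of the fitted likelihood; see the methods vignette for the
#'   trade-off.
#' @param seed RNG seed used by [simulate_jm_data] unless overridden.
#' @return An object of class `jm_scenario`.
#' @export
jm_scenario <- function(params, N = 200L, visits_range = c(1L, 4L),
                        visit_window = c(10, 80), detection_window = 10,
                        followup_end = NULL, truncate_visits = FALSE,
                        seed = 1L) {
  stopifnot(inherits(params, "jm_parameters"))
  if (N < 1) stop("`N` must be >= 1")
  visits_range <- as.integer(visits_range)
  if (length(visits_range) != 2L || visits_range[1] < 1L ||
      visits_range[2] > 10L || visits_range[1] > visits_range[2]) {
    stop("`visits_range` must be c(min, max) within [1, 10]")
  }
  if (detection_window <= 0) stop("`detection_window` must be positive")
  if (length(visit_window) != 2L || visit_window[1] <= 0 ||
      visit_window[1] >= visit_window[2]) {
    stop("`visit_window` must be c(first, last) with 0 < first < last")
  }
  if (is.null(followup_end)) {
    followup_end <- visit_window[2] + detection_window
  }
  if (followup_end < visit_window[2]) {
    stop("`followup_end` must not precede the end of the visit window")
  }
  structure(list(params = params, N = as.integer(N),
                 visits_range = visits_range,
                 visit_window = as.numeric(visit_window),
                 detection_window = as.numeric(detection_window),
                 followup_end = as.numeric(followup_end),
                 truncate_visits = isTRUE(truncate_visits),
                 seed = as.integer(seed)),
            class = "jm_scenario")
}

#' Draw a subject's latent variables
#'
#' Random effects \eqn{b \sim MVN(0, \Sigma)} and cure status
#' \eqn{Z \sim \mathrm{Bernoulli}(\eta)}, independent. Uses the current RNG
#' state.
#'
#' @param config a `jm_scenario`.
#' @return list with `b` (numeric vector) and `cured` (logical).
#' @export
draw_subject_latents <- function(config) {
  params <- config$params
  L <- chol(params$Sigma)
  b <- as.numeric(crossprod(L, stats::rnorm(params$n_re)))
  cured <- stats::runif(1) < cure_fraction(params$nu)
  list(b = b, cured = cured)
}

#' Simulate an event time by cumulative-hazard inversion
#'
#' Draws \eqn{E \sim \mathrm{Exponential}(1)} (or accepts one) and solves
#' \eqn{H(T) = E} by bracketed root finding on the quadrature-based
#' cumulative hazard, polished by Newton steps so that
#' \eqn{|H(T) - E| < 10^{-8}}.
#'
#' @param params true [jm_parameters].
#' @param b subject random effects.
#' @param n_i planned number of measurements (selects \eqn{\sigma_i}).
#' @param E optional unit-exponential draw (drawn internally if `NULL`).
#' @param t_cap upper bracket cap in days (error beyond it).
#' @param order quadrature order.
#' @return event time in days.
#' @export
simulate_event_time <- function(params, b = NULL, n_i = 2L, E = NULL,
                                t_cap = 1e4, order = 31L) {
  b <- re_vector(b, params)
  if (is.null(E)) E <- stats::rexp(1)
  H <- function(t) jm_cumhaz(t, params, b, n_i, order)
  hi <- 50
  while (H(hi) < E) {
    hi <- hi * 2
    if (hi > t_cap) {
      stop("event-time bracket exceeds the time cap; pathological parameters")
    }
  }
  root <- stats::uniroot(function(t) H(t) - E, c(1e-12, hi),
                         tol = 1e-10)$root
  # Newton polish on H(T) = E
  for (k in 1:4) {
    h <- jm_hazard(root, params, b, n_i)
    if (h <= 0) break
    step <- (H(root) - E) / h
    root <- max(root - step, 1e-12)
    if (abs(step) < 1e-12) break
  }
  root
}

#' Simulate a subject's visit schedule and responses
#'
#' Planned visit count is uniform on `visits_range`; visit times are sorted
#' uniform draws on `visit_window`. For a susceptible subject with event time
#' `T_event`, visits at or after `T_event` are discarded (the biomarker cannot
#' be measured after the event); the visit times are re-drawn (up to
#' `max_tries`) until at least one retained visit remains. Responses are
#' \eqn{y_{ij} = \mu_i(t_{ij}) + \mathrm{Normal}(0, \sigma_i^2)} with
#' \eqn{\sigma_i} determined by the *planned* visit count.
#'
#' @param config a `jm_scenario`.
#' @param b subject random effects.
#' @param T_event event time for susceptible subjects, `NULL` for cured.
#' @param n_planned planned visit count; drawn uniformly from
#'   `config$visits_range` when `NULL`.
#' @param max_tries rejection-resampling cap.
#' @return list with `times`, `y`, `n_planned`, `sd_used`.
#' @export
simulate_visits <- function(config, b, T_event = NULL, n_planned = NULL,
                            max_tries = 1000L) {
  params <- config$params
  if (is.null(n_planned)) n_planned <- draw_visit_count(config)
  sd_i <- error_sd(params, b, n_planned)
  for (try in seq_len(max_tries)) {
    times <- sort(stats::runif(n_planned, config$visit_window[1],
                               config$visit_window[2]))
    if (!is.null(T_event)) times <- times[times < T_event]
    if (length(times) >= 1L) {
      y <- logistic_mean(times, params, b) +
        stats::rnorm(length(times), 0, sd_i)
      return(list(times = times, y = y, n_planned = n_planned,
                  sd_used = sd_i))
    }
  }
  stop("could not place a visit before the event time within ", max_tries,
       " attempts (event precedes the visit window)")
}

draw_visit_count <- function(config) {
  vr <- config$visits_range
  if (vr[1] == vr[2]) vr[1] else
    sample.int(vr[2] - vr[1] + 1L, 1L) + vr[1] - 1L
}

#' Interval-censor an event time
#'
#' The detection interval opens at the last retained visit and closes at the
#' smallest `last_visit + k * window` (integer `k >= 1`) containing the event
#' time, mimicking detection delayed by whole missed detection windows.
#'
#' @param T_event latent event time, positive.
#' @param last_visit last retained visit time, `< T_event`.
#' @param window detection window length in days.
#' @return numeric `c(t_left, t_right)` with
#'   `t_left < T_event <= t_right`.
#' @export
interval_censor <- function(T_event, last_visit, window = 10) {
  if (T_event <= 0) stop("`T_event` must be positive")
  if (T_event <= last_visit) stop("`T_event` must exceed `last_visit`")
  k <- max(1, ceiling((T_event - last_visit) / window))
  c(t_left = last_visit, t_right = last_visit + k * window)
}

#' Simulate a full joint-model dataset
#'
#' Assembles `N` subjects: latent draws (random effects, cure status),
#' visit schedules and Gaussian responses, event times for susceptible
#' subjects via cumulative-hazard inversion, and censoring. Susceptible
#' subjects are interval-censored: the detection interval opens at the last
#' visit preceding the event (or at 0 if the event precedes all visits) and
#' closes after a whole number of detection windows. Cured subjects are
#' right-censored at the administrative close-out `followup_end`.
#'
#' By default the visit schedule is exogenous (independent of the event),
#' matching the non-informative-observation assumption of the fitted
#' likelihood, and the subject error SD uses the observed measurement
#' count. With `truncate_visits = TRUE` visits after the event are
#' discarded (clinically realistic, mildly informative observation) and the
#' error SD uses the planned count, which must be fixed before the event
#' time can be drawn. Deterministic given the seed. The latent truth
#' (generating parameters, random effects, cure status, event times) is
#' attached as attribute `"truth"`.
#'
#' @param config a `jm_scenario`.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return a `jm_data` object with a `"truth"` attribute (list: `params`,
#'   `b` matrix, `cured` logical vector, `T_event` numeric vector with `NA`
#'   for cured subjects, `seed`).
#' @export
simulate_jm_data <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "jm_scenario"))
  set.seed(seed)
  params <- config$params
  N <- config$N
  ids <- sprintf("s%03d", seq_len(N))
  b_mat <- matrix(NA_real_, N, params$n_re)
  cured <- logical(N)
  T_event <- rep(NA_real_, N)
  subjects <- vector("list", N)
  for (i in seq_len(N)) {
    lat <- draw_subject_latents(config)
    b_mat[i, ] <- lat$b
    cured[i] <- lat$cured
    n_i <- draw_visit_count(config)
    if (lat$cured) {
      vis <- simulate_visits(config, lat$b, NULL, n_i)
      subjects[[i]] <- jm_subject(ids[i], vis$times, vis$y, "right",
                                  t_cens = config$followup_end)
    } else if (config$truncate_visits) {
      # sigma_i is fixed by the planned count before the event time exists
      T_i <- simulate_event_time(params, lat$b, n_i)
      T_event[i] <- T_i
      if (T_i > config$followup_end) {
        vis <- simulate_visits(config, lat$b, NULL, n_i)
        subjects[[i]] <- jm_subject(ids[i], vis$times, vis$y, "right",
                                    t_cens = config$followup_end)
      } else {
        vis <- simulate_visits(config, lat$b, T_i, n_i)
        ic <- interval_censor(T_i, max(vis$times), config$detection_window)
        subjects[[i]] <- jm_subject(ids[i], vis$times, vis$y, "interval",
                                    t_left = ic[["t_left"]],
                                    t_right = ic[["t_right"]])
      }
    } else {
      vis <- simulate_visits(config, lat$b, NULL, n_i)
      T_i <- simulate_event_time(params, lat$b, n_i)
      T_event[i] <- T_i
      if (T_i > config$followup_end) {
        # susceptible but event-free at the administrative close-out:
        # right-censored there, exactly the likelihood's censoring model
        subjects[[i]] <- jm_subject(ids[i], vis$times, vis$y, "right",
                                    t_cens = config$followup_end)
      } else {
        before <- vis$times[vis$times < T_i]
        anchor <- if (length(before)) max(before) else 0
        # detection on the window grid anchored at the last visit before
        # the event: the emitted interval is the grid cell containing T,
        # so the bounds carry the information the likelihood assumes
        k <- max(1, ceiling((T_i - anchor) / config$detection_window))
        subjects[[i]] <- jm_subject(
          ids[i], vis$times, vis$y, "interval",
          t_left = anchor + (k - 1) * config$detection_window,
          t_right = anchor + k * config$detection_window)
      }
    }
  }
  out <- jm_data(subjects)
  attr(out, "truth") <- list(params = params, b = b_mat, cured = cured,
                             T_event = T_event, seed = seed)
  out
}
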