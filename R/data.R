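#' Construct a subject record
#'
#' One subject's longitudinal measurements and survival observation. Interval
#' censoring means the event is known to lie in `(t_left, t_right]` (here a
#' detection window after the last biomarker measurement); right censoring
#' means the subject was event-free at `t_cens`, conventionally their last
#' measurement time.
#'
#' @param id subject identifier (coerced to character).
#' @param times visit times in days, strictly increasing, non-negative.
#' @param y log10 biomarker values, same length as `times`.
#' @param censoring `"interval"` or `"right"`.
#' @param t_left,t_right interval bounds (interval censoring only),
#'   `0 <= t_left < t_right`.
#' @param t_cens right-censoring time (right censoring only).
#' @return An object of class `jm_subject`.
#' @export
jm_subject <- function(id, times, y, censoring = c("interval", "right"),
                       t_left = NULL, t_right = NULL, t_cens = NULL) {
  censoring <- match.arg(censoring)
  id <- as.character(id)
  times <- as.numeric(times)
  y <- as.numeric(y)
  if (length(times) < 1L || length(times) != length(y)) {
    stop(sprintf("subject %s: `times` and `y` must have equal length >= 1", id))
  }
  if (any(!is.finite(times)) || any(times < 0) ||
      is.unsorted(times, strictly = TRUE)) {
    stop(sprintf("subject %s: times must be finite, non-negative, strictly increasing", id))
  }
  if (any(!is.finite(y))) stop(sprintf("subject %s: non-finite response", id))
  if (censoring == "interval") {
    if (is.null(t_left) || is.null(t_right) ||
        !is.finite(t_left) || !is.finite(t_right) ||
        t_left < 0 || t_left >= t_right) {
      stop(sprintf("subject %s: interval censoring requires 0 <= t_left < t_right", id))
    }
    t_cens <- NULL
  } else {
    if (is.null(t_cens) || !is.finite(t_cens) || t_cens < 0) {
      stop(sprintf("subject %s: right censoring requires a finite t_cens >= 0", id))
    }
    t_left <- t_right <- NULL
  }
  structure(list(id = id, times = times, y = y, censoring = censoring,
                 t_left = t_left, t_right = t_right, t_cens = t_cens),
            class = "jm_subject")
}

#' Assemble subjects into a joint-model dataset
#'
#' @param subjects list of [jm_subject] objects with unique ids.
#' @return An object of class `jm_data` (a list of subjects).
#' @export
jm_data <- function(subjects) {
  if (!length(subjects)) return(structure(list(), class = "jm_data"))
  ok <- vapply(subjects, inherits, logical(1), "jm_subject")
  if (!all(ok)) stop("all elements must be `jm_subject` objects")
  ids <- vapply(subjects, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate subject ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(subjects) <- ids
  structure(subjects, class = "jm_data")
}

#' @export
print.jm_data <- function(x, ...) {
  n <- length(x)
  nobs <- sum(vapply(x, function(s) length(s$y), integer(1)))
  nint <- sum(vapply(x, function(s) s$censoring == "interval", logical(1)))
  cat("Joint-model dataset:", n, "subjects,", nobs, "longitudinal measurements\n")
  cat("  interval-censored (events):", nint, " right-censored:", n - nint, "\n")
  invisible(x)
}

#' Longitudinal measurements as a long-format data frame
#'
#' @param data a `jm_data` object.
#' @return data frame with columns `id`, `time_days`, `log10_value`.
#' @export
longitudinal_table <- function(data) {
  do.call(rbind, lapply(unname(data), function(s) {
    data.frame(id = s$id, time_days = s$times, log10_value = s$y,
               stringsAsFactors = FALSE)
  }))
}

#' Survival observations as a data frame
#'
#' @param data a `jm_data` object.
#' @return data frame with columns `id`, `censoring`, `t_left`, `t_right`,
#'   `t_cens` (unused cells `NA`).
#' @export
survival_table <- function(data) {
  do.call(rbind, lapply(unname(data), function(s) {
    data.frame(id = s$id, censoring = s$censoring,
               t_left = if (is.null(s$t_left)) NA_real_ else s$t_left,
               t_right = if (is.null(s$t_right)) NA_real_ else s$t_right,
               t_cens = if (is.null(s$t_cens)) NA_real_ else s$t_cens,
               stringsAsFactors = FALSE)
  }))
}
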