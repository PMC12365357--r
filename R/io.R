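#' Write a joint-model dataset to CSV files
#'
#' Long-format longitudinal table (`id`, `time_days`, `log10_value`) and a
#' per-subject survival table (`id`, `censoring`, `t_left`, `t_right`,
#' `t_cens`).
#'
#' @param data a `jm_data` object.
#' @param longitudinal_path,survival_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_jm_data <- function(data, longitudinal_path, survival_path) {
  utils::write.csv(longitudinal_table(data), longitudinal_path,
                   row.names = FALSE)
  utils::write.csv(survival_table(data), survival_path, row.names = FALSE)
  invisible(c(longitudinal_path, survival_path))
}

#' Read a joint-model dataset from CSV files
#'
#' Validates and joins the two tables written by [write_jm_data]: every
#' survival row must match longitudinal rows and vice versa, interval rows
#' must have `t_left < t_right`, and right-censored rows a `t_cens`.
#' Validation failures name the offending rows.
#'
#' @param longitudinal_path,survival_path input CSV paths.
#' @return a `jm_data` object, ordered as in the survival table.
#' @export
read_jm_data <- function(longitudinal_path, survival_path) {
  for (p in c(longitudinal_path, survival_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  long <- utils::read.csv(longitudinal_path, stringsAsFactors = FALSE)
  surv <- utils::read.csv(survival_path, stringsAsFactors = FALSE)
  need_long <- c("id", "time_days", "log10_value")
  need_surv <- c("id", "censoring", "t_left", "t_right", "t_cens")
  if (!all(need_long %in% names(long))) {
    stop("longitudinal file must have columns: ",
         paste(need_long, collapse = ", "))
  }
  if (!all(need_surv %in% names(surv))) {
    stop("survival file must have columns: ", paste(need_surv, collapse = ", "))
  }
  long$id <- as.character(long$id)
  surv$id <- as.character(surv$id)

  errs <- character(0)
  bad <- !is.finite(suppressWarnings(as.numeric(long$time_days))) |
    !is.finite(suppressWarnings(as.numeric(long$log10_value)))
  if (any(bad)) {
    errs <- c(errs, paste0("longitudinal rows with non-numeric fields: ",
                           paste(which(bad), collapse = ", ")))
  }
  dup <- duplicated(long[c("id", "time_days")])
  if (any(dup)) {
    errs <- c(errs, paste0("duplicate (id, time_days) longitudinal rows: ",
                           paste(which(dup), collapse = ", ")))
  }
  if (anyDuplicated(surv$id)) {
    errs <- c(errs, paste0("duplicate ids in survival file: ",
                           paste(unique(surv$id[duplicated(surv$id)]),
                                 collapse = ", ")))
  }
  orphan_long <- setdiff(long$id, surv$id)
  orphan_surv <- setdiff(surv$id, long$id)
  if (length(orphan_long)) {
    errs <- c(errs, paste0("longitudinal ids missing from survival file: ",
                           paste(orphan_long, collapse = ", ")))
  }
  if (length(orphan_surv)) {
    errs <- c(errs, paste0("survival ids missing from longitudinal file: ",
                           paste(orphan_surv, collapse = ", ")))
  }
  for (i in seq_len(nrow(surv))) {
    r <- surv[i, ]
    if (!r$censoring %in% c("interval", "right")) {
      errs <- c(errs, sprintf("survival row %d (id %s): unknown censoring '%s'",
                              i, r$id, r$censoring))
    } else if (r$censoring == "interval") {
      if (!is.finite(r$t_left) || !is.finite(r$t_right) ||
          r$t_left >= r$t_right) {
        errs <- c(errs, sprintf(
          "survival row %d (id %s): interval requires t_left < t_right", i, r$id))
      }
    } else if (!is.finite(r$t_cens)) {
      errs <- c(errs, sprintf(
        "survival row %d (id %s): right censoring requires t_cens", i, r$id))
    }
  }
  if (length(errs)) {
    stop("invalid dataset:\n  ", paste(errs, collapse = "\n  "))
  }

  subjects <- lapply(seq_len(nrow(surv)), function(i) {
    r <- surv[i, ]
    rows <- long[long$id == r$id, , drop = FALSE]
    rows <- rows[order(rows$time_days), , drop = FALSE]
    if (r$censoring == "interval") {
      jm_subject(r$id, rows$time_days, rows$log10_value, "interval",
                 t_left = r$t_left, t_right = r$t_right)
    } else {
      jm_subject(r$id, rows$time_days, rows$log10_value, "right",
                 t_cens = r$t_cens)
    }
  })
  jm_data(subjects)
}
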