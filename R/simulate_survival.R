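#' Right-censored survival table
#'
#' Builds/validates a survival table: one row per fly with its group label,
#' time-to-event in days and an event flag (1 = died, 0 = right-censored).
#'
#' @param subject_id vector of unique identifiers.
#' @param group character vector of group labels.
#' @param time_days positive times in days.
#' @param event 0/1 (or logical) event indicator.
#' @return A data.frame of class `SurvivalTable`.
#' @export
survival_table <- function(subject_id, group, time_days, event) {
  n <- length(subject_id)
  if (length(group) == 1L) group <- rep(group, n)
  if (length(group) != n || length(time_days) != n || length(event) != n) {
    stop_invalid("all columns must have equal length")
  }
  if (any(!is.finite(time_days)) || any(time_days <= 0)) {
    stop_invalid("`time_days` must be finite and > 0")
  }
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop_invalid("`event` must be 0/1")
  out <- data.frame(subject_id = as.character(subject_id),
                    group = as.character(group),
                    time_days = as.numeric(time_days),
                    event = event)
  class(out) <- c("SurvivalTable", "data.frame")
  out
}

# Gompertz event times by inverse-CDF: hazard a*exp(b*t),
# S(t) = exp(-(a/b)(exp(b t) - 1))
rgompertz <- function(n, scale, shape) {
  u <- runif(n)
  log1p(-(shape / scale) * log(u)) / shape
}

#' Simulate group lifespans with right censoring
#'
#' Draws per-fly event times from each group's Gompertz hazard
#' `a * exp(b t)` (`a = hazard_scale`, `b = hazard_shape`) and right-censors
#' any time exceeding `censor_time` at `censor_time` (end of observation).
#' Reproducible under `seed`.
#'
#' @param params_by_group named list of [cohort_params()] (names are used as
#'   group labels when present, else the params' own labels).
#' @param n_per_group flies per group (>= 1).
#' @param censor_time end of the observation window, days (> 0).
#' @param seed integer seed.
#' @return A [survival_table()].
#' @examples
#' p <- default_params("female_mated_sham")
#' tab <- simulate_survival(list(sham = p, inj = p), n_per_group = 60,
#'                          censor_time = 90, seed = 1)
#' @export
simulate_survival <- function(params_by_group, n_per_group, censor_time = 90,
                              seed) {
  if (!is.list(params_by_group) || length(params_by_group) == 0) {
    stop_invalid("`params_by_group` must be a non-empty list of CohortParams")
  }
  check_scalar(n_per_group, "n_per_group", 1)
  check_scalar(censor_time, "censor_time", 0, strict_lower = TRUE)
  labels <- names(params_by_group)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(params_by_group, function(p) p$label, character(1))
  }
  n_per_group <- as.integer(n_per_group)
  with_seed(seed, {
    rows <- lapply(seq_along(params_by_group), function(g) {
      p <- params_by_group[[g]]
      if (!inherits(p, "CohortParams")) {
        stop_invalid("all elements of `params_by_group` must be CohortParams")
      }
      t_raw <- rgompertz(n_per_group, p$hazard_scale, p$hazard_shape)
      ev <- as.integer(t_raw <= censor_time)
      data.frame(subject_id = sprintf("%s_%04d", labels[g],
                                      seq_len(n_per_group)),
                 group = labels[g],
                 time_days = pmin(t_raw, censor_time),
                 event = ev)
    })
    tab <- do.call(rbind, rows)
    survival_table(tab$subject_id, tab$group, tab$time_days, tab$event)
  })
}
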