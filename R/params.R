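#' Cohort parameter sets
#'
#' A `CohortParams` object bundles the generative parameters that encode an
#' experimental group (sex x mating status x age-at-injury x injury status)
#' for the synthetic-data generators: locomotor parameters for the climbing
#' simulator and Gompertz hazard parameters for the lifespan simulator.
#'
#' @param label group label, e.g. `"female_mated_D31Inj"`.
#' @param mean_speed mean climbing speed across flies, mm/s (> 0).
#' @param speed_shape gamma shape of the per-fly speed distribution
#'   (dimensionless, > 0); the per-fly mean speed is drawn from
#'   `Gamma(shape = speed_shape, mean = mean_speed)`.
#' @param heading_sd dispersion (degrees, >= 0) of the per-frame heading
#'   about the vertical (wrapped normal).
#' @param pause_prob per-frame probability of pausing, in `[0, 1]`.
#' @param startle_latency_mean mean of the exponential startle latency, s.
#' @param hazard_scale,hazard_shape Gompertz baseline hazard `a` (1/day) and
#'   rate of aging `b` (1/day); the hazard is `a * exp(b * t)`.
#' @param n_flies_default default number of flies per simulated trial.
#'
#' @return An object of class `CohortParams` (a named list).
#' @seealso [default_params()], [simulate_trial()], [simulate_survival()]
#' @export
cohort_params <- function(label, mean_speed, speed_shape = 6,
                          heading_sd = 18, pause_prob = 0.02,
                          startle_latency_mean = 0.3,
                          hazard_scale = 1e-4, hazard_shape = 0.1,
                          n_flies_default = 15L) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop_invalid("`label` must be a non-empty string")
  }
  check_scalar(mean_speed, "mean_speed", 0) # 0 allowed: motionless cohort
  if (!identical(speed_shape, Inf)) { # Inf = degenerate: all flies at mean
    check_scalar(speed_shape, "speed_shape", 0, strict_lower = TRUE)
  }
  check_scalar(heading_sd, "heading_sd", 0)
  check_scalar(pause_prob, "pause_prob", 0, 1)
  check_scalar(startle_latency_mean, "startle_latency_mean", 0)
  check_scalar(hazard_scale, "hazard_scale", 0, strict_lower = TRUE)
  check_scalar(hazard_shape, "hazard_shape", 0, strict_lower = TRUE)
  check_scalar(n_flies_default, "n_flies_default", 1)
  structure(list(
    label = label,
    mean_speed = mean_speed,
    speed_shape = speed_shape,
    heading_sd = heading_sd,
    pause_prob = pause_prob,
    startle_latency_mean = startle_latency_mean,
    hazard_scale = hazard_scale,
    hazard_shape = hazard_shape,
    n_flies_default = as.integer(n_flies_default)
  ), class = "CohortParams")
}

#' @export
print.CohortParams <- function(x, ...) {
  cat("CohortParams <", x$label, ">\n", sep = "")
  cat(sprintf("  speed: gamma(mean = %.2f mm/s, shape = %.1f)\n",
              x$mean_speed, x$speed_shape))
  cat(sprintf("  heading sd: %.1f deg, pause prob: %.3f/frame, latency: %.2f s\n",
              x$heading_sd, x$pause_prob, x$startle_latency_mean))
  cat(sprintf("  Gompertz hazard: %.2g * exp(%.2g t) per day\n",
              x$hazard_scale, x$hazard_shape))
  invisible(x)
}

preset_file <- function() {
  system.file("extdata", "cohort_presets.json", package = "flytrauma",
              mustWork = TRUE)
}

preset_env <- new.env(parent = emptyenv())

load_presets <- function() {
  if (is.null(preset_env$catalogue)) {
    raw <- jsonlite::read_json(preset_file(), simplifyVector = TRUE)
    cat <- lapply(seq_len(nrow(raw)), function(i) {
      do.call(cohort_params, as.list(raw[i, , drop = FALSE]))
    })
    names(cat) <- raw$label
    preset_env$catalogue <- cat
  }
  preset_env$catalogue
}

#' Preset cohort parameters for the standard experimental groups
#'
#' Returns the parameter preset for one of the documented cohorts:
#' sham or injured at day 3/17/31 post-eclosion, for males, mated females
#' and virgin females. The presets are stored in
#' `inst/extdata/cohort_presets.json` and satisfy the documented ordering:
#' within a sex, `mean_speed` is non-increasing and `heading_sd` and
#' `pause_prob` non-decreasing from sham through D3Inj, D17Inj to D31Inj;
#' virgin-female presets are nearly flat (injury has little late-life effect
#' in that group). Gompertz hazards are identical across injury groups within
#' a sex (lifespan is not altered by the mild injury).
#'
#' @param group_label one of `flytrauma_preset_labels()`.
#' @return A [cohort_params()] object.
#' @examples
#' default_params("male_sham")
#' default_params("female_mated_D31Inj")
#' @export
default_params <- function(group_label) {
  cat <- load_presets()
  if (!is.character(group_label) || length(group_label) != 1L ||
      !(group_label %in% names(cat))) {
    stop_invalid("unknown preset label ",
                 if (is.character(group_label) && length(group_label) == 1L)
                   paste0("'", group_label, "'") else "",
                 "; valid labels: ", paste(names(cat), collapse = ", "))
  }
  cat[[group_label]]
}

#' @rdname default_params
#' @export
flytrauma_preset_labels <- function() names(load_presets())
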