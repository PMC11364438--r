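#' Tracked-trajectory container
#'
#' A `TrajectorySet` holds per-fly, per-frame planar positions for one
#' startle-induced climbing trial, plus the arena geometry and frame rate.
#' Frame 0 is the trial start; the default trial is 601 frames (10 s at
#' 60 fps). The arena is the climbing vial: 28 mm wide, 90 mm tall, with
#' y = 0 at the floor and y increasing upward.
#'
#' @param x,y numeric matrices of positions in mm, one row per fly, one
#'   column per frame (frame 0 first).
#' @param fps frames per second (> 0), default 60.
#' @param arena_width,arena_height arena dimensions in mm.
#' @param trial_id,group optional identifiers carried through the pipeline.
#' @return An object of class `TrajectorySet`.
#' @export
trajectory_set <- function(x, y, fps = 60, arena_width = 28,
                           arena_height = 90, trial_id = "trial1",
                           group = NA_character_) {
  if (!is.matrix(x) || !is.matrix(y) || !all(dim(x) == dim(y))) {
    stop_invalid("`x` and `y` must be matrices of identical dimension")
  }
  check_scalar(fps, "fps", 0, strict_lower = TRUE)
  check_scalar(arena_width, "arena_width", 0, strict_lower = TRUE)
  check_scalar(arena_height, "arena_height", 0, strict_lower = TRUE)
  if (anyNA(x) || anyNA(y)) stop_invalid("positions must not contain NA")
  if (min(x) < 0 || max(x) > arena_width ||
      min(y) < 0 || max(y) > arena_height) {
    stop_invalid("positions fall outside the arena bounds")
  }
  structure(list(x = x, y = y, fps = fps, arena_width = arena_width,
                 arena_height = arena_height, trial_id = trial_id,
                 group = group),
            class = "TrajectorySet")
}

#' @export
print.TrajectorySet <- function(x, ...) {
  cat(sprintf(
    "TrajectorySet '%s' (%s): %d flies x %d frames @ %g fps, arena %g x %g mm\n",
    x$trial_id, x$group, nrow(x$x), ncol(x$x), x$fps,
    x$arena_width, x$arena_height))
  invisible(x)
}

#' @export
as.data.frame.TrajectorySet <- function(x, ...) {
  n_flies <- nrow(x$x)
  n_frames <- ncol(x$x)
  data.frame(
    frame = rep(seq_len(n_frames) - 1L, each = n_flies),
    fly_id = rep(seq_len(n_flies), times = n_frames),
    x_mm = as.vector(x$x),
    y_mm = as.vector(x$y)
  )
}

n_flies <- function(traj) nrow(traj$x)
n_frames <- function(traj) ncol(traj$x)

# fold a coordinate into [0, w] by reflection at both walls
reflect_into <- function(x, w) {
  x <- x %% (2 * w)
  ifelse(x > w, 2 * w - x, x)
}

#' Simulate one startle-induced climbing trial
#'
#' Agent-based simulation of the modified negative geotaxis assay: flies
#' start in the bottom 5 mm of the vial after the startle tap, and after an
#' exponential startle latency each fly climbs with a per-fly speed drawn
#' from a gamma distribution and a per-frame heading drawn from a wrapped
#' normal about the vertical, pausing with a per-frame Bernoulli probability.
#' The x coordinate reflects at the side walls; the y coordinate clamps at
#' the floor and ceiling (flies walk on walls and the assay only reads
#' height).
#'
#' Identical `(params, n_flies, seed)` yield bit-identical output.
#'
#' @param params a [cohort_params()] object.
#' @param n_flies number of flies (>= 1); default `params$n_flies_default`.
#' @param seed integer seed (required).
#' @param duration_frames number of frames including frame 0 (default 601,
#'   i.e. 10 s at 60 fps).
#' @param fps frame rate, default 60.
#' @param arena_width,arena_height vial geometry in mm (defaults 28 x 90).
#' @param trial_id identifier stored in the result.
#' @return A [trajectory_set()].
#' @examples
#' p <- default_params("female_mated_sham")
#' tr <- simulate_trial(p, n_flies = 10, seed = 1)
#' climbing_index(bin_positions(tr))
#' @export
simulate_trial <- function(params, n_flies = params$n_flies_default, seed,
                           duration_frames = 601L, fps = 60,
                           arena_width = 28, arena_height = 90,
                           trial_id = "trial1") {
  if (!inherits(params, "CohortParams")) {
    stop_invalid("`params` must be a CohortParams object")
  }
  if (!is.numeric(n_flies) || length(n_flies) != 1L || !is.finite(n_flies) ||
      n_flies < 1) {
    stop_invalid("`n_flies` must be >= 1")
  }
  n_flies <- as.integer(n_flies)
  check_scalar(duration_frames, "duration_frames", 2)
  n_steps <- as.integer(duration_frames) - 1L

  with_seed(seed, {
    # per-fly draws
    speeds <- if (params$mean_speed == 0 || !is.finite(params$speed_shape)) {
      rep(params$mean_speed, n_flies)
    } else {
      rgamma(n_flies, shape = params$speed_shape,
             rate = params$speed_shape / params$mean_speed)
    }
    latency <- if (params$startle_latency_mean == 0) rep(0, n_flies) else
      rexp(n_flies, rate = 1 / params$startle_latency_mean)
    x0 <- runif(n_flies, 0, arena_width)
    y0 <- runif(n_flies, 0, min(5, arena_height))

    # per-frame draws, pre-generated for a fixed draw order
    pauses <- matrix(runif(n_flies * n_steps) < params$pause_prob,
                     n_flies, n_steps)
    headings <- if (params$heading_sd == 0) {
      matrix(0, n_flies, n_steps)
    } else {
      matrix(wrap_degrees(rnorm(n_flies * n_steps, 0, params$heading_sd)),
             n_flies, n_steps)
    }

    x <- matrix(NA_real_, n_flies, n_steps + 1L)
    y <- matrix(NA_real_, n_flies, n_steps + 1L)
    x[, 1] <- x0
    y[, 1] <- y0
    step_len <- speeds / fps
    rad <- pi / 180
    for (i in seq_len(n_steps)) {
      active <- (i / fps) > latency
      len <- step_len * active * !pauses[, i]
      th <- headings[, i] * rad
      x[, i + 1L] <- reflect_into(x[, i] + len * sin(th), arena_width)
      y[, i + 1L] <- pmin(arena_height, pmax(0, y[, i] + len * cos(th)))
    }
    trajectory_set(x, y, fps = fps, arena_width = arena_width,
                   arena_height = arena_height, trial_id = trial_id,
                   group = params$label)
  })
}

#' Simulate a batch of trials for one cohort
#'
#' Convenience wrapper running [simulate_trial()] `n_trials` times with
#' sub-seeds derived from `seed` by fixed offsets (trials are treated as
#' independent).
#'
#' @inheritParams simulate_trial
#' @param n_trials number of trials (e.g. 9 = three experimental repeats of
#'   three trials).
#' @return A list of [trajectory_set()] objects.
#' @export
simulate_trials <- function(params, n_trials, n_flies = params$n_flies_default,
                            seed, ...) {
  check_scalar(n_trials, "n_trials", 1)
  lapply(seq_len(n_trials), function(k) {
    simulate_trial(params, n_flies = n_flies, seed = seed + k,
                   trial_id = sprintf("%s_trial%02d", params$label, k), ...)
  })
}
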