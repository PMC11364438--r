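#' Trajectory CSV I/O
#'
#' The tracker-output table shape: columns `frame` (0-based), `fly_id`,
#' `x_mm`, `y_mm`, one row per fly and frame.
#'
#' @param traj a [trajectory_set()].
#' @param path CSV file path.
#' @return `write_trajectory_csv`: the path, invisibly;
#'   `read_trajectory_csv`: a [trajectory_set()].
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param fps,arena_width,arena_height geometry to attach (the CSV holds
#'   only positions).
#' @param trial_id,group identifiers to attach.
#' @export
read_trajectory_csv <- function(path, fps = 60, arena_width = 28,
                                arena_height = 90, trial_id = NULL,
                                group = NA_character_) {
  d <- read.csv(path)
  needed <- c("frame", "fly_id", "x_mm", "y_mm")
  if (!all(needed %in% names(d))) {
    stop_invalid("trajectory CSV needs columns: ", paste(needed, collapse = ", "))
  }
  flies <- sort(unique(d$fly_id))
  frames <- sort(unique(d$frame))
  if (nrow(d) != length(flies) * length(frames)) {
    stop_invalid("trajectory CSV must have one row per fly and frame")
  }
  d <- d[order(d$frame, d$fly_id), ]
  x <- matrix(d$x_mm, length(flies), length(frames))
  y <- matrix(d$y_mm, length(flies), length(frames))
  trajectory_set(x, y, fps = fps, arena_width = arena_width,
                 arena_height = arena_height,
                 trial_id = if (is.null(trial_id))
                   sub("\\.csv$", "", basename(path)) else trial_id,
                 group = group)
}

#' Survival CSV I/O
#'
#' Columns: `subject_id`, `group`, `time_days`, `event` (0/1).
#'
#' @param tab a [survival_table()].
#' @param path CSV file path.
#' @export
write_survival_csv <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  d <- read.csv(path)
  survival_table(d$subject_id, d$group, d$time_days, d$event)
}

#' Per-trial CI curves as CSV
#'
#' Long format: `trial_id`, `t`, `ci`.
#'
#' @param curves list of [climbing_index()] results.
#' @param path CSV file path.
#' @export
write_ci_csv <- function(curves, path) {
  rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(trial_id = cv$trial_id, t = seq_along(cv$ci), ci = cv$ci)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full synthetic pipeline into a directory
#'
#' Exercises every stage end to end with one seed: simulates trials for two
#' cohorts, computes CI curves, the permutation test, kinematics summaries,
#' one synthetic brain with segmentation and vacuole detection (written and
#' re-read as TIFF), and a survival comparison. All outputs are plain text
#' (CSV/JSON) plus the TIFF stack; a fixed seed gives byte-identical output
#' files.
#'
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @param preset_a,preset_b cohort preset labels.
#' @param n_trials trials per cohort.
#' @param n_flies flies per trial.
#' @param brain_shape voxel dimensions of the simulated brain.
#' @param n_vacuoles lesions planted in the simulated brain.
#' @return Invisibly, a list of the output file paths.
#' @export
run_pipeline <- function(seed, out_dir, preset_a = "female_mated_sham",
                         preset_b = "female_mated_D31Inj", n_trials = 3,
                         n_flies = 10, brain_shape = c(96L, 72L, 48L),
                         n_vacuoles = 4L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  pa <- default_params(preset_a)
  pb <- default_params(preset_b)
  trials_a <- simulate_trials(pa, n_trials, n_flies = n_flies, seed = seed)
  trials_b <- simulate_trials(pb, n_trials, n_flies = n_flies,
                              seed = seed + 1000)
  for (tr in c(trials_a, trials_b)) {
    p <- file.path(out_dir, paste0(tr$trial_id, ".csv"))
    write_trajectory_csv(tr, p)
    paths[[tr$trial_id]] <- p
  }
  curves_a <- lapply(trials_a, function(tr) climbing_index(bin_positions(tr)))
  curves_b <- lapply(trials_b, function(tr) climbing_index(bin_positions(tr)))
  paths$ci <- write_ci_csv(c(curves_a, curves_b),
                           file.path(out_dir, "ci.csv"))
  perm <- ci_curve_permutation_test(curves_a, curves_b, n_perm = 199,
                                    seed = seed + 2000)
  kin_a <- compute_kinematics(trials_a[[1]])
  abn <- abnormal_direction_fraction(kin_a)
  brain <- simulate_brain(shape = brain_shape, n_vacuoles = n_vacuoles,
                          diameter_range = c(5, 18), seed = seed + 3000)
  paths$stack <- file.path(out_dir, "brain.tif")
  write_brain_tiff(brain$stack, paths$stack)
  reread <- read_brain_tiff(paths$stack, voxel_size = brain$stack$voxel_size)
  seg <- segment_brain(reread)
  vacs <- detect_vacuoles(reread, seg)
  paths$lesions <- file.path(out_dir, "lesions.csv")
  write.csv(vacs$lesions, paths$lesions, row.names = FALSE, quote = FALSE)
  surv <- simulate_survival(list(a = pa, b = pb), n_per_group = 40,
                            censor_time = 90, seed = seed + 4000)
  paths$survival <- file.path(out_dir, "survival.csv")
  write_survival_csv(surv, paths$survival)
  lr <- logrank_test(surv, "a", "b")
  report <- list(
    seed = seed,
    ci_permutation = list(statistic = perm$statistic, p = perm$p_value),
    normalized_accumulated_ci =
      normalized_accumulated_ci(curves_b, curves_a)$ratio,
    abnormal_fraction_first3s = abn$accumulated,
    vacuoles = list(count = vacs$count,
                    total_projected_area = vacs$total_projected_area),
    logrank = list(statistic = lr$statistic, p = lr$p_value)
  )
  paths$report <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(paths)
}
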