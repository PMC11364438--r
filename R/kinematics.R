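#' Per-frame kinematics from tracked positions
#'
#' Computes instantaneous speed and heading for every fly and frame of a
#' trial at the tracker's temporal resolution (1/fps s). Speed at frame i is
#' the displacement from frame i-1 times the frame rate, in mm/s. Heading is
#' the direction of that displacement relative to the vertical: 0 deg =
#' straight up, +90 deg = rightward, -90 deg = leftward, wrapped into
#' (-180, 180]. Frames whose displacement is below `min_disp` get an
#' undefined (NA) heading so that positional jitter of standing flies does
#' not masquerade as direction.
#'
#' @param traj a [trajectory_set()] with >= 2 frames.
#' @param min_disp minimum per-frame displacement (mm) for a defined heading;
#'   default 0.02 mm (= 1.2 mm/s at 60 fps).
#' @return A `KinematicsTable`: data.frame with columns `fly_id`, `frame`
#'   (1-based index of the frame the displacement ends at, 0-based frame
#'   numbering), `time_s`, `speed` (mm/s) and `heading` (degrees, NA when
#'   undefined), with attributes `fps` and `min_disp`.
#' @export
compute_kinematics <- function(traj, min_disp = 0.02) {
  if (!inherits(traj, "TrajectorySet")) {
    stop_invalid("`traj` must be a TrajectorySet")
  }
  if (n_frames(traj) < 2) stop_invalid("need at least 2 frames")
  check_scalar(min_disp, "min_disp", 0)
  nfly <- n_flies(traj)
  nfr <- n_frames(traj)
  dx <- traj$x[, -1, drop = FALSE] - traj$x[, -nfr, drop = FALSE]
  dy <- traj$y[, -1, drop = FALSE] - traj$y[, -nfr, drop = FALSE]
  disp <- sqrt(dx^2 + dy^2)
  heading <- atan2(dx, dy) * 180 / pi     # 0 = up, +90 = right
  heading[heading == -180] <- 180
  heading[disp < min_disp] <- NA_real_
  out <- data.frame(
    fly_id = rep(seq_len(nfly), times = nfr - 1L),
    frame = rep(seq_len(nfr - 1L), each = nfly),
    time_s = rep(seq_len(nfr - 1L), each = nfly) / traj$fps,
    speed = as.vector(disp) * traj$fps,
    heading = as.vector(heading)
  )
  attr(out, "fps") <- traj$fps
  attr(out, "min_disp") <- min_disp
  class(out) <- c("KinematicsTable", "data.frame")
  out
}

#' @rdname compute_kinematics
#' @export
instantaneous_speed <- function(traj) compute_kinematics(traj)

#' @rdname compute_kinematics
#' @export
heading_angle <- function(traj, min_disp = 0.02) {
  compute_kinematics(traj, min_disp = min_disp)
}

#' Fraction of movement outside the normal climbing direction
#'
#' Among frames with a defined heading in the analysis window (default the
#' first 3 s, during which the startle-induced climb happens), the fraction
#' whose heading lies outside the normal range (default (-30, 30) degrees
#' about vertical). Returned per second and accumulated over the whole
#' window. By default frames are pooled across flies (frame-weighted); with
#' `per_fly = TRUE` the accumulated value is the mean of per-fly fractions
#' instead.
#'
#' @param kin a [compute_kinematics()] table.
#' @param window analysis window in seconds (default 3: frames with
#'   `time_s <= window`).
#' @param normal_range half-open interval of normal headings, degrees.
#' @param per_fly if `TRUE`, average per-fly fractions for the accumulated
#'   value.
#' @return A list with `per_second` (named vector, one fraction per whole
#'   second of the window), `accumulated`, `n_frames_used`.
#' @export
abnormal_direction_fraction <- function(kin, window = 3,
                                        normal_range = c(-30, 30),
                                        per_fly = FALSE) {
  if (!inherits(kin, "KinematicsTable")) {
    stop_invalid("`kin` must be a KinematicsTable")
  }
  check_scalar(window, "window", 0, strict_lower = TRUE)
  if (length(normal_range) != 2 || normal_range[1] >= normal_range[2]) {
    stop_invalid("`normal_range` must be an increasing pair of degrees")
  }
  k <- kin[kin$time_s <= window & !is.na(kin$heading), , drop = FALSE]
  if (nrow(k) == 0) {
    stop_undefined_stat("no defined-heading frames in the analysis window")
  }
  abnormal <- k$heading < normal_range[1] | k$heading > normal_range[2]
  secs <- ceiling(k$time_s)
  per_second <- vapply(sort(unique(secs)), function(s) {
    mean(abnormal[secs == s])
  }, numeric(1))
  names(per_second) <- sort(unique(secs))
  accumulated <- if (per_fly) {
    mean(tapply(abnormal, k$fly_id, mean))
  } else {
    mean(abnormal)
  }
  list(per_second = per_second, accumulated = accumulated,
       n_frames_used = nrow(k))
}

#' Speed and angular histograms
#'
#' Normalized frequency histograms of the per-frame speeds and headings in
#' the analysis window, as plotted for tracked climbing trials: the speed
#' histogram uses bins of `bin_width` mm/s from zero; the angular histogram
#' covers (-180, 180] with bins aligned so that +/-30 degrees fall on bin
#' edges (default 15-degree bins), suitable for rose plots.
#'
#' @param kin a [compute_kinematics()] table.
#' @param bin_width bin width (mm/s for speed, degrees for angles; an
#'   angular `bin_width` must divide 360 and place 30 on an edge).
#' @param window analysis window in seconds (default 3).
#' @return A data.frame with columns `lower`, `upper`, `mid`, `frequency`
#'   (frequencies sum to 1), with attribute `n` = number of frames used.
#'   Empty input yields a zero-row data.frame with attribute `n = 0`.
#' @export
speed_histogram <- function(kin, bin_width = 2, window = 3) {
  check_scalar(bin_width, "bin_width", 0, strict_lower = TRUE)
  k <- kin[kin$time_s <= window, , drop = FALSE]
  v <- k$speed[is.finite(k$speed)]
  if (!length(v)) {
    return(empty_hist())
  }
  nb <- max(1L, ceiling(max(v) / bin_width + 1e-9))
  idx <- pmin(nb, floor(v / bin_width) + 1L)
  freq <- tabulate(idx, nbins = nb) / length(v)
  out <- data.frame(lower = (seq_len(nb) - 1) * bin_width,
                    upper = seq_len(nb) * bin_width,
                    mid = (seq_len(nb) - 0.5) * bin_width,
                    frequency = freq)
  attr(out, "n") <- length(v)
  out
}

#' @rdname speed_histogram
#' @export
angular_histogram <- function(kin, bin_width = 15, window = 3) {
  check_scalar(bin_width, "bin_width", 0, strict_lower = TRUE)
  if (abs(360 / bin_width - round(360 / bin_width)) > 1e-9 ||
      abs(30 / bin_width - round(30 / bin_width)) > 1e-9) {
    stop_invalid("`bin_width` must divide 360 and 30 so that +/-30 degrees ",
                 "are bin edges")
  }
  k <- kin[kin$time_s <= window & !is.na(kin$heading), , drop = FALSE]
  if (!nrow(k)) {
    return(empty_hist())
  }
  nb <- as.integer(round(360 / bin_width))
  # bins are (lower, upper] so that 180 lands in the last bin
  idx <- pmax(1L, ceiling((k$heading + 180) / bin_width))
  freq <- tabulate(idx, nbins = nb) / nrow(k)
  out <- data.frame(lower = -180 + (seq_len(nb) - 1) * bin_width,
                    upper = -180 + seq_len(nb) * bin_width,
                    mid = -180 + (seq_len(nb) - 0.5) * bin_width,
                    frequency = freq)
  attr(out, "n") <- nrow(k)
  out
}

empty_hist <- function() {
  out <- data.frame(lower = numeric(0), upper = numeric(0),
                    mid = numeric(0), frequency = numeric(0))
  attr(out, "n") <- 0L
  out
}
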