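#' Bin occupancy of a climbing trial
#'
#' Divides the vial height into `n_bins` equal bins (bin 1 = bottom, bin
#' `n_bins` = top) and counts the flies in each bin at every second of the
#' trial, i.e. at frames `fps * t` for t = 1..10 (frame 0 is the trial start
#' and is excluded because all flies begin at the bottom). Bins are
#' half-open, `[(b-1) h/n, b h/n)`, with the top boundary clamped into the
#' top bin.
#'
#' @param traj a [trajectory_set()].
#' @param n_bins number of height bins (default 10).
#' @param n_seconds number of sampling instants (default 10).
#' @return An object of class `BinOccupancy`: a list with `counts`
#'   (`n_seconds` x `n_bins` integer matrix), `n_flies`, `n_bins`, `group`
#'   and `trial_id`.
#' @export
bin_positions <- function(traj, n_bins = 10L, n_seconds = 10L) {
  if (!inherits(traj, "TrajectorySet")) {
    stop_invalid("`traj` must be a TrajectorySet")
  }
  check_scalar(n_bins, "n_bins", 1)
  check_scalar(n_seconds, "n_seconds", 1)
  n_bins <- as.integer(n_bins)
  n_seconds <- as.integer(n_seconds)
  frames <- round(traj$fps * seq_len(n_seconds)) # 0-based frame index
  if (max(frames) + 1L > n_frames(traj)) {
    stop_invalid("trajectory too short: needs at least ",
                 max(frames) + 1L, " frames, has ", n_frames(traj))
  }
  h <- traj$arena_height / n_bins
  counts <- matrix(0L, n_seconds, n_bins,
                   dimnames = list(second = seq_len(n_seconds),
                                   bin = seq_len(n_bins)))
  for (t in seq_len(n_seconds)) {
    yb <- pmin(n_bins, floor(traj$y[, frames[t] + 1L] / h) + 1L)
    tb <- tabulate(yb, nbins = n_bins)
    counts[t, ] <- tb
  }
  structure(list(counts = counts, n_flies = n_flies(traj), n_bins = n_bins,
                 group = traj$group, trial_id = traj$trial_id),
            class = "BinOccupancy")
}

#' Build a BinOccupancy from raw counts
#'
#' For manually scored data: a seconds-by-bins count matrix where every row
#' must sum to the number of flies.
#'
#' @param counts integer matrix, seconds in rows, bins in columns.
#' @param group,trial_id optional identifiers.
#' @return A `BinOccupancy`.
#' @export
bin_occupancy <- function(counts, group = NA_character_, trial_id = "trial1") {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop_invalid("`counts` must be non-negative integers")
  }
  rs <- rowSums(counts)
  if (length(unique(rs)) != 1L) {
    stop_invalid("every second must account for the same number of flies")
  }
  structure(list(counts = counts, n_flies = as.integer(rs[1]),
                 n_bins = ncol(counts), group = group, trial_id = trial_id),
            class = "BinOccupancy")
}

#' Climbing Index per second
#'
#' The Climbing Index (CI) at each second is the sum over bins of the bin
#' number multiplied by the number of flies in that bin, divided by the total
#' number of flies: the mean bin label of the group. CI = 1 means all flies
#' at the bottom; CI = `n_bins` all at the top.
#'
#' @param occ a [bin_positions()] / [bin_occupancy()] result.
#' @return An object of class `ClimbingCurve`: list with `ci` (numeric vector
#'   indexed by second), `n_flies`, `n_bins`, `group`, `trial_id`.
#' @export
climbing_index <- function(occ) {
  if (!inherits(occ, "BinOccupancy")) {
    stop_invalid("`occ` must be a BinOccupancy")
  }
  if (occ$n_flies == 0) {
    stop_undefined_stat("climbing index undefined for zero flies")
  }
  ci <- as.numeric(occ$counts %*% seq_len(occ$n_bins)) / occ$n_flies
  structure(list(ci = ci, n_flies = occ$n_flies, n_bins = occ$n_bins,
                 group = occ$group, trial_id = occ$trial_id),
            class = "ClimbingCurve")
}

#' @export
print.ClimbingCurve <- function(x, ...) {
  cat(sprintf("ClimbingCurve '%s' (%s), %d flies:\n", x$trial_id, x$group,
              x$n_flies))
  print(round(stats::setNames(x$ci, seq_along(x$ci)), 3))
  invisible(x)
}

#' Accumulated Climbing Index
#'
#' The sum of the per-second CI values over the trial; in `[10, 100]` for the
#' default 10 bins and 10 seconds.
#'
#' @param curve a [climbing_index()] result.
#' @return A single number.
#' @export
accumulated_ci <- function(curve) {
  if (!inherits(curve, "ClimbingCurve")) {
    stop_invalid("`curve` must be a ClimbingCurve")
  }
  sum(curve$ci)
}

#' Sham-normalized accumulated CI
#'
#' Mean accumulated CI of the test group divided by the mean accumulated CI
#' of the sham group; 1.0 means no climbing deficit. The standard error of
#' the ratio is propagated by the delta method:
#' `se^2 = r^2 (se_t^2/m_t^2 + se_s^2/m_s^2)` where `m` and `se` are the
#' group means and their standard errors.
#'
#' @param test_curves,sham_curves non-empty lists of [climbing_index()]
#'   results (one curve per trial).
#' @return A list with `ratio`, `se`, and the per-group means and ns.
#' @export
normalized_accumulated_ci <- function(test_curves, sham_curves) {
  acc <- function(curves, what) {
    if (!length(curves)) stop_invalid("empty ", what, " curve list")
    vapply(curves, accumulated_ci, numeric(1))
  }
  at <- acc(test_curves, "test")
  as_ <- acc(sham_curves, "sham")
  mt <- mean(at)
  ms <- mean(as_)
  if (ms == 0) stop_undefined_stat("sham mean accumulated CI is zero")
  r <- mt / ms
  se_t2 <- if (length(at) > 1) stats::var(at) / length(at) else 0
  se_s2 <- if (length(as_) > 1) stats::var(as_) / length(as_) else 0
  se <- abs(r) * sqrt(se_t2 / mt^2 + se_s2 / ms^2)
  list(ratio = r, se = se, mean_test = mt, mean_sham = ms,
       n_test = length(at), n_sham = length(as_))
}

curves_to_matrix <- function(curves) {
  m <- do.call(rbind, lapply(curves, function(cv) {
    if (!inherits(cv, "ClimbingCurve")) {
      stop_invalid("all curves must be ClimbingCurve objects")
    }
    cv$ci
  }))
  if (length(unique(vapply(curves, function(cv) length(cv$ci), integer(1)))) != 1L) {
    stop_invalid("curves must have equal length")
  }
  m
}

#' Permutation test comparing two sets of CI curves
#'
#' Tests whether two groups of per-trial CI curves differ, using the
#' statistic `T = mean over seconds of |mean_a CI(t) - mean_b CI(t)|` and a
#' label permutation null that resamples whole curves (the trial is the
#' exchangeable unit, preserving within-curve autocorrelation). The p-value
#' uses the add-one rule `p = (1 + #{T* >= T}) / (n_perm + 1)`.
#'
#' @param group_a,group_b lists of [climbing_index()] results, >= 2 curves
#'   each.
#' @param n_perm number of label permutations (>= 99).
#' @param seed integer seed.
#' @return A list with `statistic`, `p_value`, `n_perm`, `method`, and group
#'   sizes.
#' @export
ci_curve_permutation_test <- function(group_a, group_b, n_perm = 999L, seed) {
  na <- length(group_a)
  nb <- length(group_b)
  if (na < 2 || nb < 2) stop_invalid("need >= 2 curves per group")
  check_scalar(n_perm, "n_perm", 99)
  m <- curves_to_matrix(c(group_a, group_b))
  n <- na + nb
  t_stat <- function(idx_a) {
    mean(abs(colMeans(m[idx_a, , drop = FALSE]) -
             colMeans(m[-idx_a, , drop = FALSE])))
  }
  obs <- t_stat(seq_len(na))
  perm <- with_seed(seed, {
    vapply(seq_len(as.integer(n_perm)),
           function(k) t_stat(sample.int(n, na)), numeric(1))
  })
  p <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  list(statistic = obs, p_value = p, n_perm = as.integer(n_perm),
       method = "curve permutation (mean absolute per-second difference)",
       n_per_group = c(a = na, b = nb))
}
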