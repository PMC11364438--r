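# Independent brute-force oracles used across tests. These deliberately do
# NOT share code with the package implementation.

# CI as the mean bin label, computed per fly
oracle_ci <- function(counts) {
  apply(counts, 1, function(row) {
    mean(rep(seq_along(row), times = row))
  })
}

# log-rank O, E, Var accumulated event time by event time
oracle_logrank <- function(time, event, is_a) {
  ets <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t in ets) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & is_a)
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & is_a)
    o <- o + d_a
    e <- e + d * n_a / n
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) (o - e)^2 / v else 0
  list(observed = o, expected = e, variance = v, statistic = stat,
       p = if (v > 0) pchisq(stat, 1, lower.tail = FALSE) else 1)
}

# exact two-sided rank-sum p by enumeration over all assignments
oracle_ranksum_p <- function(x, y) {
  m <- length(x)
  N <- m + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(m)])
  mu <- m * (N + 1) / 2
  null_w <- colSums(combn(N, m))
  mean(abs(null_w - mu) >= abs(w - mu) - 1e-9)
}

# product-limit estimate at the distinct times, by direct risk-set counting
oracle_km <- function(time, event) {
  ts <- sort(unique(time))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    if (d > 0) s <- s * (1 - d / n)
    out[i] <- s
  }
  data.frame(time = ts, surv = out)
}

# quick ClimbingCurve construction from a numeric vector
make_curve <- function(ci, n_flies = 10, trial_id = "t", group = "g") {
  structure(list(ci = ci, n_flies = n_flies, n_bins = 10L,
                 group = group, trial_id = trial_id),
            class = "ClimbingCurve")
}

# a TrajectorySet from explicit per-frame displacements of one fly
traj_from_steps <- function(dx, dy, x0 = 50, y0 = 50, fps = 60,
                            arena = c(1000, 1000)) {
  x <- cumsum(c(x0, dx))
  y <- cumsum(c(y0, dy))
  trajectory_set(matrix(x, 1), matrix(y, 1), fps = fps,
                 arena_width = arena[1], arena_height = arena[2])
}

det_params <- function(mean_speed = 9, heading_sd = 0, pause_prob = 0,
                       latency = 0, ...) {
  cohort_params("deterministic", mean_speed = mean_speed, speed_shape = Inf,
                heading_sd = heading_sd, pause_prob = pause_prob,
                startle_latency_mean = latency, ...)
}
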