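#' Kaplan-Meier product-limit estimator
#'
#' Estimates the survival function for one group of a [survival_table()]
#' with Greenwood's variance formula. Censored subjects leave the risk set
#' without producing a step; `S(0) = 1` and the estimate is nonincreasing.
#'
#' @param tab a [survival_table()].
#' @param group group label present in `tab`.
#' @return An object of class `km_fit`: data.frame with columns `time`
#'   (distinct event/censoring times in increasing order), `n_risk`,
#'   `n_event`, `n_censor`, `surv` (estimate just after `time`) and `se`
#'   (Greenwood standard error), plus attribute `group`. Evaluate it with
#'   [km_survival()].
#' @export
km_estimate <- function(tab, group) {
  if (!inherits(tab, "SurvivalTable")) {
    stop_invalid("`tab` must be a SurvivalTable")
  }
  if (!(group %in% tab$group)) {
    stop_invalid("unknown group '", group, "'; groups: ",
                 paste(unique(tab$group), collapse = ", "))
  }
  d <- tab[tab$group == group, , drop = FALSE]
  times <- sort(unique(d$time_days))
  n <- nrow(d)
  surv <- 1
  gw <- 0 # running Greenwood sum of d_i / (n_i (n_i - d_i))
  out <- data.frame(time = times, n_risk = NA_real_, n_event = NA_real_,
                    n_censor = NA_real_, surv = NA_real_, se = NA_real_)
  for (i in seq_along(times)) {
    t_i <- times[i]
    n_risk <- sum(d$time_days >= t_i)
    n_event <- sum(d$time_days == t_i & d$event == 1L)
    n_censor <- sum(d$time_days == t_i & d$event == 0L)
    if (n_event > 0) {
      surv <- surv * (1 - n_event / n_risk)
      if (n_risk > n_event) {
        gw <- gw + n_event / (n_risk * (n_risk - n_event))
      } else {
        gw <- Inf
      }
    }
    out$n_risk[i] <- n_risk
    out$n_event[i] <- n_event
    out$n_censor[i] <- n_censor
    out$surv[i] <- surv
    out$se[i] <- if (surv == 0) 0 else surv * sqrt(min(gw, .Machine$double.xmax))
  }
  attr(out, "group") <- group
  attr(out, "n") <- n
  class(out) <- c("km_fit", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier fit at arbitrary times
#'
#' Right-continuous step function: `S(t)` = 1 before the first event.
#'
#' @param fit a [km_estimate()] result.
#' @param t times (days).
#' @return Survival probabilities.
#' @export
km_survival <- function(fit, t) {
  if (!inherits(fit, "km_fit")) stop_invalid("`fit` must be a km_fit")
  vapply(t, function(tt) {
    i <- which(fit$time <= tt)
    if (!length(i)) 1 else fit$surv[max(i)]
  }, numeric(1))
}

#' Mantel-Cox log-rank test for two groups
#'
#' At each distinct event time the observed number of deaths in group A is
#' compared to its expectation under the hypergeometric model given the risk
#' sets and total deaths (tied deaths handled through the standard
#' hypergeometric variance with multiplicities). The statistic is
#' `(sum(O - E))^2 / sum(Var)` and the p-value comes from the chi-square
#' distribution with 1 df. With no events the statistic is 0 and p = 1.
#'
#' @param tab a [survival_table()].
#' @param group_a,group_b group labels.
#' @return A `TestResult` list: `statistic`, `p_value`, `method`,
#'   `n_per_group`, and the summed `observed`, `expected` for group A.
#' @export
logrank_test <- function(tab, group_a, group_b) {
  if (!inherits(tab, "SurvivalTable")) {
    stop_invalid("`tab` must be a SurvivalTable")
  }
  for (g in c(group_a, group_b)) {
    if (sum(tab$group == g) < 1) stop_invalid("group '", g, "' has no subjects")
  }
  d <- tab[tab$group %in% c(group_a, group_b), , drop = FALSE]
  in_a <- d$group == group_a
  event_times <- sort(unique(d$time_days[d$event == 1L]))
  o_minus_e <- 0
  var_sum <- 0
  obs_a <- 0
  exp_a <- 0
  for (t_i in event_times) {
    at_risk <- d$time_days >= t_i
    n_tot <- sum(at_risk)
    n_a <- sum(at_risk & in_a)
    d_tot <- sum(d$time_days == t_i & d$event == 1L)
    d_a <- sum(d$time_days == t_i & d$event == 1L & in_a)
    e_a <- d_tot * n_a / n_tot
    v <- if (n_tot > 1) {
      d_tot * (n_a / n_tot) * (1 - n_a / n_tot) * (n_tot - d_tot) / (n_tot - 1)
    } else 0
    o_minus_e <- o_minus_e + (d_a - e_a)
    var_sum <- var_sum + v
    obs_a <- obs_a + d_a
    exp_a <- exp_a + e_a
  }
  stat <- if (var_sum > 0) o_minus_e^2 / var_sum else 0
  p <- if (var_sum > 0) pchisq(stat, df = 1, lower.tail = FALSE) else 1
  list(statistic = stat, p_value = p, p_adjusted = NA_real_,
       method = "Mantel-Cox log-rank",
       n_per_group = stats::setNames(c(sum(in_a), sum(!in_a)),
                                     c(group_a, group_b)),
       observed = obs_a, expected = exp_a)
}

#' Pairwise log-rank tests with Bonferroni correction
#'
#' Runs [logrank_test()] for every unordered pair of groups and multiplies
#' each p-value by the number of pairs (capped at 1). The Bonferroni family
#' is all pairwise comparisons within the supplied table.
#'
#' @param tab a [survival_table()] with >= 2 groups.
#' @return A data.frame with one row per pair: `group_a`, `group_b`,
#'   `statistic`, `p_value`, `p_adjusted`, `n_a`, `n_b`; attribute
#'   `n_comparisons` records the Bonferroni factor.
#' @export
pairwise_logrank_bonferroni <- function(tab) {
  if (!inherits(tab, "SurvivalTable")) {
    stop_invalid("`tab` must be a SurvivalTable")
  }
  groups <- unique(tab$group)
  if (length(groups) < 2) stop_invalid("need >= 2 groups")
  pairs <- combn(groups, 2)
  k <- ncol(pairs)
  rows <- lapply(seq_len(k), function(j) {
    r <- logrank_test(tab, pairs[1, j], pairs[2, j])
    data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
               statistic = r$statistic, p_value = r$p_value,
               p_adjusted = min(1, r$p_value * k),
               n_a = unname(r$n_per_group[1]), n_b = unname(r$n_per_group[2]))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_comparisons") <- k
  out
}

# null distribution of the rank-sum of x (size m) among N = m + n tie-free
# observations, by full enumeration of the C(N, m) assignments
ranksum_enumerate <- function(m, N) {
  combs <- combn(N, m)
  colSums(combs)
}

#' Wilcoxon rank-sum test (exact for small samples)
#'
#' Two-sided Wilcoxon/Mann-Whitney rank-sum test using midranks for ties.
#' When both samples have at most `exact_max_n` observations and there are
#' no ties, the p-value is exact, by full enumeration of all
#' `choose(n_x + n_y, n_x)` rank assignments (two-sided p = probability of a
#' rank-sum at least as far from its null mean as observed; the null
#' distribution is symmetric). Otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y non-empty numeric samples.
#' @param exact_max_n largest per-sample size for the exact branch.
#' @return A `TestResult` list: `statistic` (rank-sum W of `x`), `p_value`,
#'   `method`, `exact`, `n_per_group`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 10L) {
  if (!length(x) || !length(y)) stop_invalid("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop_invalid("samples must not contain NA")
  m <- length(x)
  n <- length(y)
  all_v <- c(x, y)
  r <- rank(all_v) # midranks
  w <- sum(r[seq_len(m)])
  ties <- any(duplicated(all_v))
  mu <- m * (m + n + 1) / 2
  if (!ties && m <= exact_max_n && n <= exact_max_n) {
    null_w <- ranksum_enumerate(m, m + n)
    p <- mean(abs(null_w - mu) >= abs(w - mu) - 1e-9)
    exact <- TRUE
  } else {
    tie_tab <- table(all_v)
    N <- m + n
    sigma2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1 # all observations identical
    } else {
      z <- (abs(w - mu) - 0.5) / sqrt(sigma2) # continuity correction
      z <- max(z, 0)
      p <- 2 * pnorm(z, lower.tail = FALSE)
      p <- min(1, p)
    }
    exact <- FALSE
  }
  list(statistic = w, p_value = p, p_adjusted = NA_real_,
       method = if (exact) "Wilcoxon rank-sum (exact)" else
         "Wilcoxon rank-sum (normal approximation)",
       exact = exact, n_per_group = c(x = m, y = n))
}
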