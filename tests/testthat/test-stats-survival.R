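test_that("KM matches hand-computed product-limit on worked examples", {
  # all events at 1, 2, 3
  tab <- survival_table(1:3, "a", c(1, 2, 3), c(1, 1, 1))
  fit <- km_estimate(tab, "a")
  expect_equal(fit$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km_survival(fit, c(0.5, 1, 2.5, 10)), c(1, 2 / 3, 1 / 3, 0))

  # censoring leaves the risk set without a step
  tab2 <- survival_table(1:3, "a", c(1, 2, 3), c(1, 0, 1))
  fit2 <- km_estimate(tab2, "a")
  expect_equal(fit2$surv, c(2 / 3, 2 / 3, 0))

  # all censored: S = 1 everywhere
  tab3 <- survival_table(1:4, "a", c(1, 2, 3, 4), rep(0, 4))
  expect_equal(km_estimate(tab3, "a")$surv, rep(1, 4))

  expect_error(km_estimate(tab3, "nope"), "unknown group")
})

test_that("KM reduces to the empirical survival function without censoring", {
  set.seed(10)
  for (rep in 1:20) {
    t <- round(rexp(30, 0.1) + 0.1, 2)
    tab <- survival_table(seq_along(t), "g", t, rep(1, length(t)))
    fit <- km_estimate(tab, "g")
    emp <- vapply(fit$time, function(tt) mean(t > tt), numeric(1))
    expect_equal(fit$surv, emp)
  }
})

test_that("KM agrees with the survival package on censored data", {
  skip_if_not_installed("survival")
  set.seed(11)
  t <- round(rexp(50, 0.05), 1) + 0.1
  ev <- rbinom(50, 1, 0.7)
  tab <- survival_table(1:50, "g", t, ev)
  fit <- km_estimate(tab, "g")
  sf <- survival::survfit(survival::Surv(t, ev) ~ 1)
  idx <- match(fit$time, sf$time)
  expect_equal(fit$surv, sf$surv[idx], tolerance = 1e-12)
  pos <- fit$surv > 0 # survfit's log-scale se is NaN once S hits 0
  expect_equal(fit$se[pos], (sf$std.err * sf$surv)[idx][pos],
               tolerance = 1e-8)
})

test_that("log-rank matches the brute-force O/E/Var oracle", {
  # toy table: A = {1+, 2+}, B = {3+, 4+}
  tab <- survival_table(1:4, c("A", "A", "B", "B"), 1:4, rep(1, 4))
  r <- logrank_test(tab, "A", "B")
  o <- oracle_logrank(tab$time_days, tab$event, tab$group == "A")
  expect_equal(r$statistic, o$statistic)
  expect_equal(r$p_value, o$p)
  expect_equal(r$observed, o$observed)
  expect_equal(r$expected, o$expected)

  # random censored tables with ties
  set.seed(12)
  for (rep in 1:25) {
    n <- 40
    t <- sample(1:15, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.8)
    g <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(g)) < 2) next
    tab <- survival_table(1:n, g, t, ev)
    r <- logrank_test(tab, "A", "B")
    o <- oracle_logrank(t, ev, g == "A")
    expect_equal(r$statistic, o$statistic)
  }
})

test_that("log-rank degenerate cases and invariances", {
  # identical groups: duplicate every subject under a second label
  tab <- survival_table(1:8, rep(c("A", "B"), each = 4),
                        rep(c(2, 4, 6, 8), 2), rep(1, 8))
  r <- logrank_test(tab, "A", "B")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # all censored: no events, statistic 0, p 1
  tabc <- survival_table(1:6, rep(c("A", "B"), 3), 1:6, rep(0, 6))
  rc <- logrank_test(tabc, "A", "B")
  expect_equal(rc$statistic, 0)
  expect_equal(rc$p_value, 1)

  # symmetry in group labels and invariance under monotone time transforms
  set.seed(14)
  t <- rexp(30, 0.1) + 0.01
  ev <- rbinom(30, 1, 0.7)
  g <- rep(c("A", "B"), 15)
  tab1 <- survival_table(1:30, g, t, ev)
  tab2 <- survival_table(1:30, g, t^2, ev) # monotone transform
  r1 <- logrank_test(tab1, "A", "B")
  r2 <- logrank_test(tab1, "B", "A")
  r3 <- logrank_test(tab2, "A", "B")
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$statistic, r3$statistic)
})

test_that("log-rank agrees with survival::survdiff", {
  skip_if_not_installed("survival")
  set.seed(15)
  t <- round(rexp(60, 0.08), 1) + 0.1
  ev <- rbinom(60, 1, 0.8)
  g <- rep(c("A", "B"), 30)
  tab <- survival_table(1:60, g, t, ev)
  r <- logrank_test(tab, "A", "B")
  sd <- survival::survdiff(survival::Surv(t, ev) ~ g)
  expect_equal(r$statistic, sd$chisq, tolerance = 1e-10)
})

test_that("pairwise Bonferroni uses the pair count as its family", {
  set.seed(16)
  mk <- function(gs) {
    n <- 20 * length(gs)
    survival_table(1:n, rep(gs, each = 20), rexp(n, 0.05) + 0.01,
                   rbinom(n, 1, 0.8))
  }
  two <- pairwise_logrank_bonferroni(mk(c("A", "B")))
  expect_equal(attr(two, "n_comparisons"), 1L)
  expect_equal(two$p_adjusted, two$p_value)

  four <- pairwise_logrank_bonferroni(mk(c("A", "B", "C", "D")))
  expect_equal(nrow(four), 6L)
  expect_equal(attr(four, "n_comparisons"), 6L)
  expect_equal(four$p_adjusted, pmin(1, four$p_value * 6))
  expect_true(all(four$p_adjusted >= four$p_value))

  one <- survival_table(1:5, "A", 1:5, rep(1, 5))
  expect_error(pairwise_logrank_bonferroni(one), ">= 2 groups")
})

test_that("survival simulator censors correctly and is reproducible", {
  p <- default_params("male_sham")
  tab <- simulate_survival(list(g1 = p, g2 = p), n_per_group = 30,
                           censor_time = 60, seed = 8)
  expect_equal(nrow(tab), 60L)
  expect_true(all(tab$time_days <= 60))
  expect_true(all(tab$event[tab$time_days < 60] == 1L))
  tab2 <- simulate_survival(list(g1 = p, g2 = p), n_per_group = 30,
                            censor_time = 60, seed = 8)
  expect_identical(tab, tab2)

  # tiny hazard + early censoring: everything censored
  tiny <- cohort_params("tiny", mean_speed = 5, hazard_scale = 1e-10,
                        hazard_shape = 0.01)
  tab3 <- simulate_survival(list(a = tiny), n_per_group = 20,
                            censor_time = 0.1, seed = 9)
  expect_true(all(tab3$event == 0L))
  expect_true(all(tab3$time_days == 0.1))

  expect_error(simulate_survival(list(), 10, 50, seed = 1), "non-empty")
})

test_that("Gompertz sampler matches the analytic survival function", {
  # inverse-CDF sanity: empirical S(t) tracks exp(-(a/b)(e^{bt}-1))
  p <- cohort_params("g", mean_speed = 5, hazard_scale = 1e-4,
                     hazard_shape = 0.1)
  tab <- simulate_survival(list(g = p), n_per_group = 4000,
                           censor_time = 1e6, seed = 10)
  a <- 1e-4; b <- 0.1
  for (tt in c(40, 65, 80)) {
    s_true <- exp(-(a / b) * (exp(b * tt) - 1))
    # absolute Monte-Carlo tolerance: ~6 binomial sd at n = 4000
    expect_lt(abs(mean(tab$time_days > tt) - s_true), 0.02)
  }
})
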