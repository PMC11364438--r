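test_that("bin assignment follows the half-open convention with clamped top", {
  # one fly parked at a fixed height; read its bin at each second
  bin_of <- function(y) {
    tr <- trajectory_set(matrix(0, 1, 601), matrix(y, 1, 601))
    occ <- bin_positions(tr)
    unname(which(occ$counts[1, ] == 1L))
  }
  expect_equal(bin_of(0), 1L)
  expect_equal(bin_of(8.999), 1L)
  expect_equal(bin_of(9), 2L)     # 9 mm is the lower edge of bin 2
  expect_equal(bin_of(45), 6L)    # 45 in [45, 54)
  expect_equal(bin_of(89.999), 10L)
  expect_equal(bin_of(90), 10L)   # top boundary clamps into bin 10
})

test_that("occupancy counts partition the flies at every second", {
  tr <- simulate_trial(default_params("female_mated_D17Inj"), n_flies = 15,
                       seed = 4)
  occ <- bin_positions(tr)
  expect_equal(unname(rowSums(occ$counts)), rep(15, 10))
  expect_true(all(occ$counts >= 0))
})

test_that("short trajectories are rejected", {
  tr <- trajectory_set(matrix(0, 2, 100), matrix(0, 2, 100))
  expect_error(bin_positions(tr), "too short")
})

test_that("climbing index equals hand-computed weighted means", {
  counts <- matrix(0L, 10, 10)
  counts[, 1] <- 12L # all 12 flies in bin 1 at every second
  expect_equal(climbing_index(bin_occupancy(counts))$ci, rep(1, 10))

  counts1 <- matrix(0L, 10, 10)
  counts1[, 1] <- 2L; counts1[, 2] <- 3L; counts1[, 10] <- 5L
  expect_equal(climbing_index(bin_occupancy(counts1))$ci[1], 5.8)

  counts2 <- matrix(1L, 10, 10) # one fly per bin
  expect_equal(climbing_index(bin_occupancy(counts2))$ci, rep(5.5, 10))
})

test_that("CI matches the per-fly brute-force oracle on random tables", {
  set.seed(42)
  for (rep in 1:200) {
    n_flies <- sample(5:40, 1)
    counts <- t(vapply(1:10, function(t) {
      tabulate(sample.int(10, n_flies, replace = TRUE), nbins = 10)
    }, integer(10)))
    got <- climbing_index(bin_occupancy(counts))$ci
    expect_identical(got, oracle_ci(counts))
  }
})

test_that("raising a fly to a higher bin never decreases CI", {
  set.seed(1)
  for (rep in 1:50) {
    counts <- t(vapply(1:10, function(t) {
      tabulate(sample.int(10, 12, replace = TRUE), nbins = 10)
    }, integer(10)))
    base <- climbing_index(bin_occupancy(counts))$ci
    t <- sample.int(10, 1)
    from <- sample(which(counts[t, ] > 0), 1)
    if (from == 10) next
    to <- sample(from:10, 1)
    counts[t, from] <- counts[t, from] - 1L
    counts[t, to] <- counts[t, to] + 1L
    expect_true(all(climbing_index(bin_occupancy(counts))$ci >= base))
  }
})

test_that("accumulated CI sums the curve and hits its range endpoints", {
  expect_equal(accumulated_ci(make_curve(rep(10, 10))), 100)
  expect_equal(accumulated_ci(make_curve(rep(1, 10))), 10)
  expect_equal(accumulated_ci(make_curve(1:10)), 55)
})

test_that("sham normalization is a ratio of group means with delta-method se", {
  sham <- lapply(1:5, function(i) make_curve(rep(8, 10)))
  test_same <- lapply(1:5, function(i) make_curve(rep(8, 10)))
  r <- normalized_accumulated_ci(test_same, sham)
  expect_equal(r$ratio, 1)
  expect_equal(r$se, 0)

  half <- lapply(1:5, function(i) make_curve(rep(4, 10)))
  expect_equal(normalized_accumulated_ci(half, sham)$ratio, 0.5)
  expect_error(normalized_accumulated_ci(half, list()), "sham")

  # delta-method se against direct formula on unequal curves
  set.seed(9)
  tc <- lapply(1:6, function(i) make_curve(runif(10, 3, 9)))
  sc <- lapply(1:7, function(i) make_curve(runif(10, 5, 10)))
  r2 <- normalized_accumulated_ci(tc, sc)
  at <- vapply(tc, accumulated_ci, numeric(1))
  as_ <- vapply(sc, accumulated_ci, numeric(1))
  se_expect <- (mean(at) / mean(as_)) *
    sqrt(var(at) / length(at) / mean(at)^2 + var(as_) / length(as_) / mean(as_)^2)
  expect_equal(r2$se, se_expect)
})

test_that("permutation test: identical groups give T = 0, p = 1", {
  g <- lapply(1:4, function(i) make_curve(rep(5, 10)))
  r <- ci_curve_permutation_test(g, g, n_perm = 199, seed = 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("permutation test separates disjoint groups at the attainable floor", {
  a <- lapply(1:9, function(i) make_curve(rep(1, 10)))
  b <- lapply(1:9, function(i) make_curve(rep(10, 10)))
  r <- ci_curve_permutation_test(a, b, n_perm = 999, seed = 2)
  expect_equal(r$statistic, 9)
  # only the two extreme label assignments reach T = 9; with random
  # permutations p is near (1 + 999 * 2/C(18,9)) / 1000, certainly <= 0.01
  expect_lte(r$p_value, 0.01)
})

test_that("permutation test is deterministic under seed and validates input", {
  set.seed(30)
  a <- lapply(1:5, function(i) make_curve(runif(10, 2, 6)))
  b <- lapply(1:5, function(i) make_curve(runif(10, 4, 8)))
  r1 <- ci_curve_permutation_test(a, b, n_perm = 499, seed = 7)
  r2 <- ci_curve_permutation_test(a, b, n_perm = 499, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_error(ci_curve_permutation_test(a[1], b, n_perm = 199, seed = 1),
               ">= 2 curves")
  expect_error(ci_curve_permutation_test(a, b, n_perm = 10, seed = 1),
               "n_perm")
})

test_that("zero-motion pipeline yields ci = 1 at every second", {
  p <- cohort_params("still", mean_speed = 0)
  tr <- simulate_trial(p, n_flies = 10, seed = 5)
  expect_equal(climbing_index(bin_positions(tr))$ci, rep(1, 10))
})

test_that("zero flies is an undefined statistic", {
  occ <- bin_occupancy(matrix(0L, 10, 10))
  expect_error(climbing_index(occ), "zero flies")
})
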