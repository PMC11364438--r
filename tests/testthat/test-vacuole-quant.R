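small_brain2 <- function(seed, n_vacuoles = 4L, diameter_range = c(5, 14),
                         ...) {
  simulate_brain(shape = c(96L, 72L, 48L), n_vacuoles = n_vacuoles,
                 diameter_range = diameter_range, seed = seed, ...)
}

test_that("segmentation recovers the phantom regions and handles edge cases", {
  b <- small_brain2(seed = 21)
  seg <- segment_brain(b$stack)
  fgv <- b$mask$labels %in% c(1L, 2L)
  expect_gte(mean(seg$labels[fgv] == b$mask$labels[fgv]), 0.95)

  # all-zero stack fails
  z <- array(0, c(32, 32, 32))
  expect_error(segment_brain(brain_stack(z, z)), "segmentation failure")

  # uniform bright single-channel stack: whole volume, one region label
  u <- array(200, c(24, 24, 24))
  seg_u <- segment_brain(brain_stack(u, array(0, dim(u))), closing_iter = 1L)
  expect_true(all(seg_u$labels == 1L))
})

test_that("a user-supplied exclusion mask is honoured", {
  b <- small_brain2(seed = 22)
  seg <- segment_brain(b$stack, exclusion = b$mask)
  truth_excl <- b$mask$labels == 3L
  expect_true(all(seg$labels[truth_excl & seg$labels != 0L] == 3L))
})

test_that("detector finds planted lesions with correct geometry", {
  b <- small_brain2(seed = 23, noise_sd = 10)
  vacs <- detect_vacuoles(b$stack, b$mask)
  ev <- evaluate_detections(vacs, b$truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  expect_true(all(abs(ev$matches$diameter_err_um) <= 2))
  expect_true(all(ev$matches$centroid_err_um <= 2))
})

test_that("projected area of a 20 um sphere is pi * 10^2 within 10%", {
  b <- simulate_brain(n_vacuoles = 1L, diameter_range = c(20, 20), seed = 77)
  vacs <- detect_vacuoles(b$stack, b$mask)
  expect_equal(vacs$count, 1L)
  expect_equal(vacs$lesions$projected_area_um2, pi * 100, tolerance = 0.1)
  expect_equal(vacs$lesions$eq_diameter_um, 20, tolerance = 0.05)
})

test_that("no dark candidates means zero lesions; scale invariance of count", {
  b0 <- small_brain2(seed = 24, n_vacuoles = 0L)
  v0 <- detect_vacuoles(b0$stack, b0$mask)
  expect_equal(v0$count, 0L)
  expect_equal(v0$total_projected_area, 0)

  b <- small_brain2(seed = 25)
  v1 <- detect_vacuoles(b$stack, b$mask)
  scaled <- brain_stack(b$stack$ch1 * 3.7, b$stack$ch2 * 3.7)
  v2 <- detect_vacuoles(scaled, b$mask)
  expect_equal(v2$count, v1$count)
})

test_that("size filters drop lesions outside [d_min, d_max]", {
  b <- small_brain2(seed = 26, n_vacuoles = 3L, diameter_range = c(8, 12))
  v_all <- detect_vacuoles(b$stack, b$mask)
  expect_equal(v_all$count, 3L)
  v_none <- detect_vacuoles(b$stack, b$mask, d_min = 20, d_max = 50)
  expect_equal(v_none$count, 0L)
  v_small <- detect_vacuoles(b$stack, b$mask, d_min = 2, d_max = 6)
  expect_equal(v_small$count, 0L)
  expect_error(detect_vacuoles(b$stack, b$mask, d_min = 5, d_max = 4),
               "d_min")
})

test_that("no detected lesion overlaps the exclusion corridor by >= 10%", {
  for (s in 27:29) {
    b <- small_brain2(seed = s)
    seg <- segment_brain(b$stack)
    v <- detect_vacuoles(b$stack, seg)
    if (v$count == 0) next
    truth_excl <- b$mask$labels == 3L
    d <- dim(truth_excl)
    for (i in seq_len(v$count)) {
      ctr <- round(c(v$lesions$centroid_x_um[i], v$lesions$centroid_y_um[i],
                     v$lesions$centroid_z_um[i]) / b$stack$voxel_size)
      expect_false(truth_excl[ctr[1], ctr[2], ctr[3]])
    }
  }
})

test_that("increasing dark_frac never shrinks the candidate set (count proxy)", {
  b <- small_brain2(seed = 30)
  v1 <- detect_vacuoles(b$stack, b$mask, dark_frac = 0.15)
  v2 <- detect_vacuoles(b$stack, b$mask, dark_frac = 0.3)
  v3 <- detect_vacuoles(b$stack, b$mask, dark_frac = 0.45)
  expect_lte(v1$count, v2$count)
  expect_lte(v2$count, v3$count)
  # volumes grow with the threshold as well
  expect_lte(sum(v1$lesions$volume_um3), sum(v2$lesions$volume_um3))
})

test_that("geometry mismatch between stack and mask is rejected", {
  b <- small_brain2(seed = 31)
  wrong <- brain_mask(array(0L, c(10, 10, 10)))
  expect_error(detect_vacuoles(b$stack, wrong), "geometry")
})

test_that("region distribution percentages are count-based and sum to 100", {
  mk <- function(regions) {
    n <- length(regions)
    vacuole_set(data.frame(
      centroid_x_um = seq_len(n), centroid_y_um = rep(1, n),
      centroid_z_um = rep(1, n), volume_um3 = rep(100, n),
      eq_diameter_um = rep(6, n), projected_area_um2 = rep(30, n),
      circularity = rep(0.9, n), region = regions))
  }
  expect_equal(region_distribution(mk(rep("neuropil", 4))),
               c(pct_neuropil = 100, pct_cortex = 0))
  expect_equal(region_distribution(mk(c(rep("neuropil", 3), "cortex"))),
               c(pct_neuropil = 75, pct_cortex = 25))
  expect_error(region_distribution(mk(character(0))), "empty")
})

test_that("group stats normalize to the sham mean and report pairwise tests", {
  mk_vs <- function(count) {
    df <- data.frame(
      centroid_x_um = seq_len(count) * 10, centroid_y_um = 1,
      centroid_z_um = 1, volume_um3 = 50, eq_diameter_um = 5,
      projected_area_um2 = 20, circularity = 0.9, region = "neuropil")
    vacuole_set(df[seq_len(count), , drop = FALSE])
  }
  sham <- lapply(c(4, 6, 5, 5), mk_vs)
  same <- lapply(c(5, 5, 4, 6), mk_vs)
  dbl <- lapply(c(10, 10, 10, 10), mk_vs)
  out <- vacuolation_group_stats(
    list(sham = sham, same = same, dbl = dbl), "sham")
  s <- out$summary
  expect_equal(s$count_norm[s$group == "sham"], 1)
  expect_equal(s$count_norm[s$group == "same"], 1)
  expect_equal(s$count_norm[s$group == "dbl"], 2)
  expect_equal(s$area_norm[s$group == "dbl"], 2)
  expect_equal(nrow(out$pairwise), 3L)
  expect_true(all(out$pairwise$p_count >= 0 & out$pairwise$p_count <= 1))
  expect_error(vacuolation_group_stats(list(a = sham), "missing"), "sham")
  expect_error(vacuolation_group_stats(list(sham = sham, bad = list()),
                                       "sham"), "at least one brain")
})
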