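#' Otsu threshold
#'
#' Global threshold maximizing between-class variance on a 256-bin
#' histogram. Used for foreground extraction of brain stacks.
#'
#' @param x numeric vector of intensities.
#' @return Threshold value; `-Inf` for (near-)constant input.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (!all(is.finite(rng)) || diff(rng) < .Machine$double.eps * 100) {
    return(-Inf)
  }
  h <- tabulate(pmin(n_bins, floor((x - rng[1]) / diff(rng) * n_bins) + 1L),
                nbins = n_bins)
  w <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * diff(rng) / n_bins
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  between[!is.finite(between)] <- 0
  mids[which.max(between)] + diff(rng) / n_bins / 2
}

blur3 <- function(arr, sigma_vox) {
  out <- .gauss_blur_3d(as.numeric(arr), dim(arr), sigma_vox)
  array(out, dim(arr))
}

cc3 <- function(mask, connectivity = 26L) {
  lab <- .cc_label_3d(as.logical(mask), dim(mask), connectivity)
  array(lab, dim(mask))
}

# morphological closing computed on a padded copy so that dilation clipped
# at the volume border does not let the erosion eat into genuine foreground
close_3d <- function(mask, iter) {
  d <- dim(mask)
  k <- as.integer(iter)
  dp <- d + 2L * k
  padded <- array(FALSE, dp)
  padded[k + seq_len(d[1]), k + seq_len(d[2]), k + seq_len(d[3])] <- mask
  out <- array(.box_erode_3d(.box_dilate_3d(as.logical(padded), dp, k),
                             dp, k), dp)
  out[k + seq_len(d[1]), k + seq_len(d[2]), k + seq_len(d[3])]
}

# binary erosion with the 6-neighbour (face-adjacency) cross: removes
# sheets up to 2 voxels thick but keeps the compact core of small blobs,
# unlike the 26-neighbour box which also needs the diagonal margin
cross_erode_3d <- function(mask, iter = 1L) {
  d <- dim(mask)
  out <- mask
  for (it in seq_len(iter)) {
    m <- out
    r <- m
    r[-1, , ] <- r[-1, , ] & m[-d[1], , ]
    r[1, , ] <- FALSE
    r[-d[1], , ] <- r[-d[1], , ] & m[-1, , ]
    r[d[1], , ] <- FALSE
    r[, -1, ] <- r[, -1, ] & m[, -d[2], ]
    r[, 1, ] <- FALSE
    r[, -d[2], ] <- r[, -d[2], ] & m[, -1, ]
    r[, d[2], ] <- FALSE
    r[, , -1] <- r[, , -1] & m[, , -d[3]]
    r[, , 1] <- FALSE
    r[, , -d[3]] <- r[, , -d[3]] & m[, , -1]
    r[, , d[3]] <- FALSE
    out <- r
  }
  out
}

fill_holes_3d <- function(mask) {
  # background components not touching the volume border are holes
  bg_lab <- cc3(!mask, 6L)
  d <- dim(mask)
  border <- unique(c(
    bg_lab[c(1, d[1]), , ], bg_lab[, c(1, d[2]), ], bg_lab[, , c(1, d[3])]))
  border <- border[border > 0]
  holes <- bg_lab > 0 & !(bg_lab %in% border)
  mask | holes
}

#' Segment a brain stack into cortex, neuropil and exclusion
#'
#' Foreground is the largest connected component of the smoothed combined
#' intensity above an Otsu threshold, morphologically closed and with
#' interior holes filled (so stain-devoid lesions stay inside the
#' foreground). Within the foreground each voxel is labelled cortex when the
#' normalized nuclear channel is at least the normalized F-actin channel,
#' else neuropil. The exclusion region is either supplied (e.g. a manually
#' traced esophagus, or the generator's ground truth) or detected as dark
#' corridors larger than any plausible vacuole (default: dark connected
#' regions extending > 60 um along some axis).
#'
#' @param stack a [brain_stack()].
#' @param exclusion optional logical 3-D array (or [brain_mask()] whose
#'   exclusion label is reused) marking voxels to exclude.
#' @param sigma_um Gaussian smoothing sigma in um (default 2).
#' @param dark_frac darkness cutoff for exclusion detection, as a fraction
#'   of the median foreground intensity.
#' @param exclusion_min_extent_um minimal axis extent for a detected dark
#'   region to count as a physiological corridor rather than a lesion.
#' @param closing_iter iterations of 3x3x3 morphological closing. The
#'   default (15) bridges stain-devoid lesions up to ~30 um that touch the
#'   brain surface, so they stay inside the foreground after hole filling;
#'   the brain outline is convex, so heavy closing barely distorts it.
#' @return A [brain_mask()].
#' @export
segment_brain <- function(stack, exclusion = NULL, sigma_um = 2,
                          dark_frac = 0.3, exclusion_min_extent_um = 60,
                          closing_iter = 15L) {
  if (!inherits(stack, "BrainStack")) {
    stop_invalid("`stack` must be a BrainStack")
  }
  d <- dim(stack$ch1)
  combined <- stack$ch1 + stack$ch2
  if (max(combined) <= 0) stop_invalid("segmentation failure: empty stack")
  sm <- blur3(combined, sigma_um / stack$voxel_size)
  thr <- otsu_threshold(as.numeric(sm))
  fg <- sm > thr
  if (!any(fg)) stop_invalid("segmentation failure: empty foreground")
  lab <- cc3(fg, 26L)
  sizes <- tabulate(lab[lab > 0])
  fg0 <- lab == which.max(sizes)
  # heavy closing + hole filling encloses lesions that bite into the brain
  # surface, but also deposits a thin artificial film of foreground just
  # outside the true surface; eroding the closed volume strips that film
  # while keeping the deep lesion cavities, and the union with the original
  # threshold foreground restores the true bright surface voxels
  closed <- close_3d(fg0, closing_iter)
  filled <- fill_holes_3d(closed)
  fg <- fg0 | array(.box_erode_3d(as.logical(filled), d, 1L), d)

  # region channels are smoothed only half as much as the foreground field:
  # lesion-intensity bleed into surrounding labels scales with the blur
  # radius, and the cortex/neuropil contrast is large enough that light
  # smoothing already controls the noise
  sigma_reg <- sigma_um / 2
  n1 <- blur3(stack$ch1, sigma_reg / stack$voxel_size)
  n2 <- blur3(stack$ch2, sigma_reg / stack$voxel_size)
  # Attenuation correction around dark structures: a stain-devoid lesion
  # depresses the locally dominant channel far more than the other, which
  # would tip a plain intensity-ratio rule toward the wrong region in the
  # lesion's blur halo. Model the observation near darkness as
  # (1 - w) * tissue + w * lesion, with w the blurred dark-mask weight and
  # the per-channel lesion level estimated from the dark voxels, and
  # classify on the recovered tissue intensities.
  med_fg <- median(sm[fg])
  dark0 <- fg & sm < 0.5 * med_fg
  if (any(dark0)) {
    w <- blur3(array(as.numeric(dark0), d), sigma_reg / stack$voxel_size)
    b1 <- median(n1[dark0])
    b2 <- median(n2[dark0])
    n1 <- pmax(0, (n1 - w * b1) / pmax(1 - w, 0.25))
    n2 <- pmax(0, (n2 - w * b2) / pmax(1 - w, 0.25))
  }
  q1 <- quantile(n1[fg], 0.95, names = FALSE)
  q2 <- quantile(n2[fg], 0.95, names = FALSE)
  if (q1 <= 0) q1 <- 1
  if (q2 <= 0) q2 <- 1
  labels <- array(MASK_BACKGROUND, dim = d)
  labels[fg] <- ifelse(n1[fg] / q1 >= n2[fg] / q2, MASK_CORTEX, MASK_NEUROPIL)
  # deep inside dark structures even the corrected ratio is noise; take the
  # label of the nearest reliably classified tissue instead
  core_dark <- fg & sm < 0.5 * med_fg
  if (any(core_dark)) {
    seeded <- labels
    seeded[core_dark] <- 0L
    grown <- array(.label_dilate_3d(as.integer(seeded), as.logical(fg), d,
                                    30L), d)
    keep <- core_dark & grown > 0L
    labels[keep] <- grown[keep]
  }

  excl <- NULL
  if (!is.null(exclusion)) {
    if (inherits(exclusion, "BrainMask")) {
      excl <- exclusion$labels == MASK_EXCLUSION
    } else {
      excl <- as.array(exclusion) > 0
    }
    if (!all(dim(excl) == d)) stop_invalid("exclusion geometry mismatch")
  } else {
    med_fg <- median(sm[fg])
    dark <- fg & sm < dark_frac * med_fg
    if (any(dark)) {
      dl <- cc3(dark, 26L)
      excl <- array(FALSE, d)
      min_vox <- exclusion_min_extent_um / stack$voxel_size
      for (k in seq_len(max(dl))) {
        idx <- which(dl == k)
        co <- arrayInd(idx, d)
        ext <- apply(co, 2, function(v) diff(range(v)) + 1)
        if (max(ext) > min_vox) excl[idx] <- TRUE
      }
      if (any(excl)) {
        # cover the partial-volume annulus around the dark core of the
        # corridor, which smoothing leaves above the darkness cutoff
        excl <- array(.box_dilate_3d(as.logical(excl), d, 3L), d) & fg
      }
    }
  }
  if (!is.null(excl)) labels[excl & labels != MASK_BACKGROUND] <- MASK_EXCLUSION
  brain_mask(labels, voxel_size = stack$voxel_size)
}

#' Detected lesion set
#'
#' Per-lesion geometry plus summary statistics; constructed by
#' [detect_vacuoles()] or directly from a per-lesion data.frame with columns
#' `centroid_x_um`, `centroid_y_um`, `centroid_z_um`, `volume_um3`,
#' `eq_diameter_um`, `projected_area_um2`, `circularity`, `region`.
#'
#' @param lesions per-lesion data.frame (zero rows allowed).
#' @param voxel_size um per voxel.
#' @return An object of class `VacuoleSet`; `summary()` gives `count` and
#'   `total_projected_area`.
#' @export
vacuole_set <- function(lesions, voxel_size = 1) {
  needed <- c("centroid_x_um", "centroid_y_um", "centroid_z_um", "volume_um3",
              "eq_diameter_um", "projected_area_um2", "circularity", "region")
  if (!all(needed %in% names(lesions))) {
    stop_invalid("lesion table must have columns: ",
                 paste(needed, collapse = ", "))
  }
  structure(list(lesions = lesions,
                 count = nrow(lesions),
                 total_projected_area = sum(lesions$projected_area_um2),
                 voxel_size = voxel_size),
            class = "VacuoleSet")
}

#' @export
print.VacuoleSet <- function(x, ...) {
  cat(sprintf("VacuoleSet: %d lesions, total projected area %.1f um^2\n",
              x$count, x$total_projected_area))
  if (x$count > 0) print(utils::head(x$lesions, 10))
  invisible(x)
}

# roundness of a set of 2-D pixel coordinates: 4A / (pi * feret^2), where
# feret is the maximal centre-to-centre distance plus one pixel
slice_roundness <- function(xy, voxel_size) {
  n <- nrow(xy)
  if (n == 1) return(1)
  # max pairwise distance over the convex-ish extremes; n is small enough
  dmax <- 0
  ch <- grDevices::chull(xy)
  pts <- xy[ch, , drop = FALSE]
  for (i in seq_len(nrow(pts))) {
    dd <- sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2)
    dmax <- max(dmax, max(dd))
  }
  feret <- (dmax + 1) * voxel_size
  area <- n * voxel_size^2
  min(1, 4 * area / (pi * feret^2))
}

#' Detect vacuoles in a segmented brain stack
#'
#' Implements the operational definition of a vacuole: a roughly round
#' region devoid of both stains that is not associated with physiological
#' structures such as the esophagus. Candidate voxels are brain voxels
#' (cortex, neuropil or exclusion label) whose lightly smoothed combined
#' intensity falls below `dark_frac` times the median intensity of the
#' cortex+neuropil foreground. Candidates are grouped by 26-connectivity;
#' components are kept when their equivalent spherical diameter lies in
#' `[d_min, d_max]`, the roundness of their maximal-area z-slice is at least
#' `min_circ`, and less than 10% of their voxels carry the exclusion label.
#' Each kept lesion is assigned to cortex or neuropil by majority vote of a
#' 2-voxel dilation shell around it.
#'
#' @param stack a [brain_stack()].
#' @param mask a [brain_mask()] of the same geometry (from [segment_brain()]
#'   or ground truth).
#' @param d_min,d_max lesion equivalent-diameter bounds in um. The biology
#'   bounds diameters by 50 um; `d_min` defaults to 2 um because a 1 um
#'   lesion is a single voxel at 1 um sampling and cannot be told from
#'   noise.
#' @param dark_frac darkness cutoff relative to the median foreground
#'   intensity (default 0.3).
#' @param min_circ minimal slice roundness (default 0.6).
#' @param max_excl_overlap maximal tolerated fraction of exclusion-labelled
#'   voxels (default 0.1, a hard filter).
#' @param sigma_um pre-smoothing sigma for candidate extraction (default
#'   1 um, enough to keep lesion boundaries connected at 15% noise).
#'   Thresholding the blurred edge shrinks the apparent lesion by a known
#'   amount (`sigma * qnorm(1 - f)` per side, with `f` the threshold's
#'   position in the edge profile); reported sizes are corrected for this
#'   bias.
#' @param core_erode,core_grow marker-reconstruction parameters: candidates
#'   are eroded `core_erode` times to cores (removing sliver artefacts at
#'   the segmented brain surface), cores are labelled, and labels grow back
#'   `core_grow` steps within the candidate mask so lesions recover their
#'   full boundary.
#' @param max_surface_frac drop components with at least this fraction of
#'   voxels adjacent to background (partial-volume rim noise, not cavities
#'   within tissue).
#' @return A [vacuole_set()].
#' @export
detect_vacuoles <- function(stack, mask, d_min = 2, d_max = 50,
                            dark_frac = 0.3, min_circ = 0.6,
                            max_excl_overlap = 0.1, sigma_um = 1,
                            core_erode = 1L, core_grow = 2L,
                            max_surface_frac = 0.5) {
  if (!inherits(stack, "BrainStack")) stop_invalid("`stack` must be a BrainStack")
  if (!inherits(mask, "BrainMask")) stop_invalid("`mask` must be a BrainMask")
  d <- dim(stack$ch1)
  if (!all(dim(mask$labels) == d)) stop_invalid("mask geometry mismatch")
  if (d_min <= 0 || d_min >= d_max) stop_invalid("need 0 < d_min < d_max")
  vs <- stack$voxel_size

  combined <- blur3(stack$ch1 + stack$ch2, sigma_um / vs)
  fg <- mask$labels == MASK_CORTEX | mask$labels == MASK_NEUROPIL
  brainv <- fg | mask$labels == MASK_EXCLUSION
  if (!any(fg)) stop_invalid("mask has no foreground")
  med <- median(combined[fg])
  cand <- brainv & combined < dark_frac * med
  # Threshold-erosion bias correction: thresholding a Gaussian-blurred step
  # edge (lesion level L -> tissue level ~med) at t = dark_frac * med marks
  # the boundary qnorm(1 - f) * sigma inside the true edge, where
  # f = (t - L) / (med - L). Sizes are corrected for this known bias.
  lesion_level <- if (any(cand)) quantile(combined[cand], 0.05, names = FALSE)
                  else 0
  f_edge <- min(0.95, max(0.05,
                          (dark_frac * med - lesion_level) /
                            max(med - lesion_level, 1e-9)))
  dr_bias <- sigma_um * stats::qnorm(1 - f_edge)
  # voxels within 2 of the background: partial-volume rim, prone to dark
  # noise clusters that are not cavities within tissue
  near_bg <- array(.box_dilate_3d(as.logical(mask$labels == MASK_BACKGROUND),
                                  d, 2L), d)

  lesions <- data.frame(
    centroid_x_um = numeric(0), centroid_y_um = numeric(0),
    centroid_z_um = numeric(0), volume_um3 = numeric(0),
    eq_diameter_um = numeric(0), projected_area_um2 = numeric(0),
    circularity = numeric(0), region = character(0))
  if (any(cand)) {
    # marker-based reconstruction: erode candidates to cores (sliver-like
    # films at the segmented surface and thin bridges between lesions and
    # physiological dark structures vanish), label the cores, then grow
    # labels back `core_grow` steps inside the candidate mask so each lesion
    # recovers its full boundary; unconnected film voxels stay unlabelled
    cores <- cross_erode_3d(cand, core_erode)
    lab <- cc3(cores, 26L)
    if (core_grow > 0) {
      lab <- array(.label_dilate_3d(as.integer(lab), as.logical(cand), d,
                                    core_grow), d)
    }
    ncomp <- max(lab)
    for (k in seq_len(ncomp)) {
      idx <- which(lab == k)
      vol_raw <- length(idx) * vs^3
      r_raw <- (3 * vol_raw / (4 * pi))^(1 / 3)
      size_corr <- (r_raw + dr_bias) / r_raw
      vol <- vol_raw * size_corr^3
      eq_d <- 2 * (r_raw + dr_bias)
      if (eq_d < d_min || eq_d > d_max) next
      excl_frac <- mean(mask$labels[idx] == MASK_EXCLUSION)
      if (excl_frac >= max_excl_overlap) next
      # surface-artefact filter: a lesion is a cavity within tissue, so a
      # component made mostly of background-adjacent rim voxels is noise
      if (mean(near_bg[idx]) >= max_surface_frac) next
      co <- arrayInd(idx, d)
      # roundness of the maximal-area z-slice
      zt <- table(co[, 3])
      zbest <- as.integer(names(zt)[which.max(zt)])
      circ <- slice_roundness(co[co[, 3] == zbest, 1:2, drop = FALSE], vs)
      if (circ < min_circ) next
      # region by majority vote of the 2-voxel shell around the estimated
      # lesion sphere (centroid + bias-corrected radius); only bright
      # tissue voxels vote (labels inside the lesion's dark halo are noise)
      cen <- colMeans(co)
      r_shell <- eq_d / 2 / vs
      rng <- lapply(1:3, function(a) {
        max(1, floor(cen[a] - r_shell - 2)):min(d[a],
                                                ceiling(cen[a] + r_shell + 2))
      })
      sg <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
      dd <- sqrt((sg[, 1] - cen[1])^2 + (sg[, 2] - cen[2])^2 +
                 (sg[, 3] - cen[3])^2)
      on_shell <- dd > r_shell & dd <= r_shell + 2
      lin_sh <- sg[on_shell, 1] + d[1] * (sg[on_shell, 2] - 1) +
        d[1] * d[2] * (sg[on_shell, 3] - 1)
      votes <- mask$labels[lin_sh]
      confident <- combined[lin_sh] >= 0.5 * med
      n_ctx <- sum(votes == MASK_CORTEX & confident)
      n_np <- sum(votes == MASK_NEUROPIL & confident)
      if (n_ctx + n_np == 0) { # fall back to all shell labels
        n_ctx <- sum(votes == MASK_CORTEX)
        n_np <- sum(votes == MASK_NEUROPIL)
      }
      region <- if (n_np >= n_ctx) "neuropil" else "cortex"
      proj <- nrow(unique(co[, 1:2, drop = FALSE])) * vs^2 * size_corr^2
      lesions <- rbind(lesions, data.frame(
        centroid_x_um = mean(co[, 1]) * vs,
        centroid_y_um = mean(co[, 2]) * vs,
        centroid_z_um = mean(co[, 3]) * vs,
        volume_um3 = vol, eq_diameter_um = eq_d,
        projected_area_um2 = proj, circularity = circ, region = region))
    }
  }
  vacuole_set(lesions, voxel_size = vs)
}

#' Percentage of lesions in neuropil vs cortex
#'
#' @param vacs a [vacuole_set()] with at least one lesion.
#' @return Named numeric vector `c(pct_neuropil, pct_cortex)` summing to 100.
#' @export
region_distribution <- function(vacs) {
  if (!inherits(vacs, "VacuoleSet")) stop_invalid("`vacs` must be a VacuoleSet")
  if (vacs$count == 0) {
    stop_undefined_stat("region distribution undefined for an empty lesion set")
  }
  p_np <- 100 * mean(vacs$lesions$region == "neuropil")
  c(pct_neuropil = p_np, pct_cortex = 100 - p_np)
}

#' Group-level vacuolation statistics with sham normalization
#'
#' Summarizes per-brain lesion counts and total projected areas by group,
#' normalizes group means to the sham group's means, and reports pairwise
#' Wilcoxon rank-sum p-values for both quantities.
#'
#' @param per_brain named list: one element per group, each a list of
#'   [vacuole_set()] objects (one per brain).
#' @param sham_group name of the sham group (must be present, non-empty).
#' @return A list with `summary` (per-group data.frame: n, mean/median count
#'   and area, `count_norm`, `area_norm`) and `pairwise` (data.frame of
#'   Wilcoxon p-values per group pair for count and area).
#' @export
vacuolation_group_stats <- function(per_brain, sham_group) {
  if (!is.list(per_brain) || is.null(names(per_brain))) {
    stop_invalid("`per_brain` must be a named list of VacuoleSet lists")
  }
  if (!(sham_group %in% names(per_brain))) {
    stop_invalid("sham group '", sham_group, "' not present")
  }
  if (any(vapply(per_brain, length, integer(1)) == 0)) {
    stop_invalid("every group must contain at least one brain")
  }
  counts <- lapply(per_brain, function(g) {
    vapply(g, function(v) as.numeric(v$count), numeric(1))
  })
  areas <- lapply(per_brain, function(g) {
    vapply(g, function(v) v$total_projected_area, numeric(1))
  })
  sham_count_mean <- mean(counts[[sham_group]])
  sham_area_mean <- mean(areas[[sham_group]])
  summary_df <- do.call(rbind, lapply(names(per_brain), function(g) {
    data.frame(group = g, n_brains = length(counts[[g]]),
               mean_count = mean(counts[[g]]),
               median_count = median(counts[[g]]),
               mean_area = mean(areas[[g]]),
               median_area = median(areas[[g]]),
               count_norm = if (sham_count_mean > 0)
                 mean(counts[[g]]) / sham_count_mean else NA_real_,
               area_norm = if (sham_area_mean > 0)
                 mean(areas[[g]]) / sham_area_mean else NA_real_)
  }))
  pairs <- combn(names(per_brain), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    data.frame(group_a = a, group_b = b,
               p_count = wilcoxon_rank_sum(counts[[a]], counts[[b]])$p_value,
               p_area = wilcoxon_rank_sum(areas[[a]], areas[[b]])$p_value)
  }))
  list(summary = summary_df, pairwise = pairwise)
}

#' Match detected lesions against generator ground truth
#'
#' Greedy nearest-pair matching: detection/truth pairs are accepted in order
#' of increasing centroid distance while the distance is below the truth
#' lesion's radius (at least `min_match_um`). Reports precision, recall,
#' centroid and diameter errors, and region-label agreement.
#'
#' @param vacs a [detect_vacuoles()] result.
#' @param truth the `truth` data.frame from [simulate_brain()].
#' @param voxel_size um per voxel of the truth coordinates.
#' @param min_match_um floor on the match radius.
#' @return A list: `precision`, `recall`, `n_matched`, `matches` (data.frame
#'   with `centroid_err_um`, `diameter_err_um`, `region_match`).
#' @export
evaluate_detections <- function(vacs, truth, voxel_size = 1,
                                min_match_um = 3) {
  det <- vacs$lesions
  nt <- nrow(truth)
  ndet <- nrow(det)
  if (nt == 0 || ndet == 0) {
    return(list(precision = if (ndet == 0) 1 else 0,
                recall = if (nt == 0) 1 else 0,
                n_matched = 0L,
                matches = data.frame(centroid_err_um = numeric(0),
                                     diameter_err_um = numeric(0),
                                     region_match = logical(0))))
  }
  tx <- truth$x * voxel_size
  ty <- truth$y * voxel_size
  tz <- truth$z * voxel_size
  dist <- outer(seq_len(ndet), seq_len(nt), Vectorize(function(i, j) {
    sqrt((det$centroid_x_um[i] - tx[j])^2 +
         (det$centroid_y_um[i] - ty[j])^2 +
         (det$centroid_z_um[i] - tz[j])^2)
  }))
  lim <- pmax(truth$diameter_um / 2, min_match_um)
  used_d <- logical(ndet)
  used_t <- logical(nt)
  matches <- NULL
  repeat {
    dd <- dist
    dd[used_d, ] <- Inf
    dd[, used_t] <- Inf
    ij <- arrayInd(which.min(dd), dim(dd))
    i <- ij[1]; j <- ij[2]
    if (!is.finite(dd[i, j]) || dd[i, j] > lim[j]) break
    used_d[i] <- TRUE
    used_t[j] <- TRUE
    matches <- rbind(matches, data.frame(
      det = i, truth = j, centroid_err_um = dd[i, j],
      diameter_err_um = det$eq_diameter_um[i] - truth$diameter_um[j],
      region_match = det$region[i] == truth$region[j]))
    if (all(used_d) || all(used_t)) break
  }
  n_matched <- if (is.null(matches)) 0L else nrow(matches)
  list(precision = n_matched / ndet, recall = n_matched / nt,
       n_matched = n_matched,
       matches = if (is.null(matches))
         data.frame(centroid_err_um = numeric(0),
                    diameter_err_um = numeric(0),
                    region_match = logical(0)) else matches)
}
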