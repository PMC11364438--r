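#' Two-channel 3-D brain stack container
#'
#' Holds a two-channel intensity volume: channel 1 is the nuclear stain
#' (bright in the cell-body-rich cortex), channel 2 the F-actin stain
#' (bright in the axon-rich neuropil). Voxels are assumed isotropic
#' (default 1 um), matching whole-brain two-photon stacks acquired at 1 um
#' steps.
#'
#' @param ch1,ch2 3-D numeric arrays of identical dimension, non-negative.
#' @param voxel_size voxel edge length in um (> 0).
#' @return An object of class `BrainStack`.
#' @export
brain_stack <- function(ch1, ch2, voxel_size = 1) {
  if (!is.array(ch1) || !is.array(ch2) || length(dim(ch1)) != 3 ||
      !all(dim(ch1) == dim(ch2))) {
    stop_invalid("`ch1` and `ch2` must be 3-D arrays of identical dimension")
  }
  check_scalar(voxel_size, "voxel_size", 0, strict_lower = TRUE)
  if (min(ch1) < 0 || min(ch2) < 0) stop_invalid("intensities must be >= 0")
  structure(list(ch1 = ch1, ch2 = ch2, voxel_size = voxel_size),
            class = "BrainStack")
}

#' @export
print.BrainStack <- function(x, ...) {
  d <- dim(x$ch1)
  cat(sprintf("BrainStack: %d x %d x %d voxels, 2 channels, %g um/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  invisible(x)
}

#' Brain region label mask
#'
#' Voxel labels partitioning a brain volume: 0 = background, 1 = cortex
#' (cell-body rim), 2 = neuropil (axon-rich core), 3 = exclusion
#' (physiological dark structures such as the esophagus that must not be
#' scored as vacuoles).
#'
#' @param labels integer 3-D array with values in 0..3.
#' @param voxel_size voxel edge length in um.
#' @return An object of class `BrainMask`.
#' @export
brain_mask <- function(labels, voxel_size = 1) {
  if (!is.array(labels) || length(dim(labels)) != 3) {
    stop_invalid("`labels` must be a 3-D array")
  }
  if (!all(labels %in% 0:3)) stop_invalid("labels must be in 0..3")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, voxel_size = voxel_size),
            class = "BrainMask")
}

MASK_BACKGROUND <- 0L
MASK_CORTEX <- 1L
MASK_NEUROPIL <- 2L
MASK_EXCLUSION <- 3L

# squared normalized ellipsoid coordinate for every voxel:
# value <= 1 inside the ellipsoid centred at `centre` with semi-axes `semi`
ellipsoid_field <- function(shape, centre, semi) {
  tx <- ((seq_len(shape[1]) - centre[1]) / semi[1])^2
  ty <- ((seq_len(shape[2]) - centre[2]) / semi[2])^2
  tz <- ((seq_len(shape[3]) - centre[3]) / semi[3])^2
  outer(outer(tx, ty, "+"), tz, "+")
}

#' Simulate a two-channel brain stack with planted vacuoles
#'
#' Generates an ellipsoidal fly-brain phantom: an outer cortex shell bright
#' in the nuclear channel, a neuropil core bright in the F-actin channel, a
#' dark cylindrical esophagus corridor through the centre (labelled as
#' exclusion in the returned ground-truth mask), and `n_vacuoles`
#' non-overlapping dark spheres (stain-devoid lesions) with diameters drawn
#' uniformly from `diameter_range`. Each vacuole centre is placed in the
#' neuropil with probability `p_neuropil`, otherwise in the cortex; a lesion
#' too large to fit inside the cortex shell is placed in the neuropil
#' (matching the observation that large vacuoles are neuropilar). Spheres
#' must lie inside the brain foreground, keep clear of the esophagus, and be
#' separated centre-to-centre by at least `min_sep_factor` times the sum of
#' their radii. Additive Gaussian noise (sd `noise_sd`) is applied to both
#' channels.
#'
#' @param shape voxel dimensions, default `c(200, 150, 80)`.
#' @param voxel_size um per voxel (isotropic), default 1.
#' @param n_vacuoles number of lesions to plant (>= 0).
#' @param diameter_range lesion diameter range in um, within (0, 50].
#' @param p_neuropil probability a lesion is placed in the neuropil.
#' @param noise_sd Gaussian noise sd in intensity units (foreground
#'   intensity is 200).
#' @param seed integer seed.
#' @param shell_um cortex shell thickness, um (default 15).
#' @param esophagus_radius_um radius of the exclusion cylinder, um.
#' @param min_sep_factor minimum separation between lesions as a multiple of
#'   the summed radii (default 1.5).
#' @param max_tries placement attempts per lesion before a placement-failure
#'   error.
#' @return A list with components `stack` ([brain_stack()]), `truth`
#'   (data.frame: `x`, `y`, `z` centre voxel coordinates, `diameter_um`,
#'   `region` — the majority label of the tissue shell surrounding the
#'   sphere, the quantity a detector estimates — and `placement_region`,
#'   the region the centre was drawn in), and `mask` (the ground-truth
#'   [brain_mask()]).
#' @export
simulate_brain <- function(shape = c(200L, 150L, 80L), voxel_size = 1,
                           n_vacuoles = 10L, diameter_range = c(5, 30),
                           p_neuropil = 0.85, noise_sd = 12, seed,
                           shell_um = 15, esophagus_radius_um = 8,
                           min_sep_factor = 1.5, max_tries = 5000L) {
  if (length(shape) != 3 || any(shape < 16)) {
    stop_invalid("`shape` must be three voxel dimensions >= 16")
  }
  shape <- as.integer(shape)
  check_scalar(n_vacuoles, "n_vacuoles", 0)
  if (length(diameter_range) != 2 || diameter_range[1] <= 0 ||
      diameter_range[2] > 50 || diameter_range[1] > diameter_range[2]) {
    stop_invalid("`diameter_range` must lie within (0, 50] um")
  }
  check_scalar(p_neuropil, "p_neuropil", 0, 1)
  check_scalar(noise_sd, "noise_sd", 0)

  centre <- (shape + 1) / 2
  semi <- pmax(4, 0.45 * shape)          # voxels
  shell_vox <- shell_um / voxel_size
  if (any(semi - shell_vox < 2)) {
    stop_invalid("`shape` too small to contain the brain model")
  }
  e_out <- ellipsoid_field(shape, centre, semi)
  e_in <- ellipsoid_field(shape, centre, semi - shell_vox)
  fg <- e_out <= 1
  neuropil <- e_in <= 1
  cortex <- fg & !neuropil

  # esophagus: cylinder along the y axis through the brain centre
  r_eso <- esophagus_radius_um / voxel_size
  dx2 <- (seq_len(shape[1]) - centre[1])^2
  dz2 <- (seq_len(shape[3]) - centre[3])^2
  cyl2d <- outer(dx2, dz2, "+") <= r_eso^2     # x-by-z
  cyl <- aperm(array(rep(cyl2d, shape[2]), dim = shape[c(1, 3, 2)]),
               c(1, 3, 2))
  exclusion <- cyl & fg

  labels <- array(MASK_BACKGROUND, dim = shape)
  labels[cortex] <- MASK_CORTEX
  labels[neuropil] <- MASK_NEUROPIL
  labels[exclusion] <- MASK_EXCLUSION

  bg_int <- 10; hi <- 200; lo <- 40
  ch1 <- array(bg_int, dim = shape)
  ch2 <- array(bg_int, dim = shape)
  ch1[cortex] <- hi; ch1[neuropil] <- lo
  ch2[cortex] <- lo; ch2[neuropil] <- hi
  ch1[exclusion] <- bg_int; ch2[exclusion] <- bg_int

  with_seed(seed, {
    truth <- data.frame(x = integer(0), y = integer(0), z = integer(0),
                        diameter_um = numeric(0), region = character(0),
                        placement_region = character(0))
    if (n_vacuoles > 0) {
      cortex_idx <- which(cortex & !exclusion)
      neuropil_idx <- which(neuropil & !exclusion)
      # plan all placements first (restarting the whole packing on failure
      # keeps generation reliable for any seed), carve afterwards
      plan <- NULL
      for (restart in 1:20) {
        placed <- matrix(numeric(0), 0, 4)   # x, y, z, radius (voxels)
        want_ctx <- logical(0)
        # placing large lesions first makes sequential packing under the
        # separation constraint reliable
        diams <- sort(runif(n_vacuoles, diameter_range[1],
                            diameter_range[2]), decreasing = TRUE)
        failed <- FALSE
        for (v in seq_len(n_vacuoles)) {
          d_um <- diams[v]
          r_vox <- d_um / 2 / voxel_size
          if (any(semi - r_vox - 1 <= 1)) {
            stop_invalid("placement failure: lesion of diameter ",
                         round(d_um), " um cannot fit inside this brain model")
          }
          want_cortex <- if (r_vox > shell_vox - 1) FALSE else
            runif(1) >= p_neuropil
          pool <- if (want_cortex) cortex_idx else neuropil_idx
          ok <- FALSE
          for (try in seq_len(max_tries)) {
            idx <- pool[sample.int(length(pool), 1L)]
            co <- arrayInd(idx, shape)
            # sphere fully inside the foreground (shrunken-ellipsoid test)
            ev <- sum(((co - centre) / (semi - r_vox - 1))^2)
            if (ev > 1) next
            # clear of the esophagus cylinder
            d_ax <- sqrt((co[1] - centre[1])^2 + (co[3] - centre[3])^2)
            if (d_ax < r_vox + r_eso + 2) next
            # separation from already-placed lesions
            if (nrow(placed)) {
              dd <- sqrt(colSums((t(placed[, 1:3, drop = FALSE]) -
                                  as.numeric(co))^2))
              if (any(dd < min_sep_factor * (placed[, 4] + r_vox))) next
            }
            ok <- TRUE
            break
          }
          if (!ok) {
            failed <- TRUE
            break
          }
          placed <- rbind(placed, c(co, r_vox))
          want_ctx <- c(want_ctx, want_cortex)
        }
        if (!failed) {
          plan <- list(placed = placed, diams = diams, want_ctx = want_ctx)
          break
        }
      }
      if (is.null(plan)) {
        stop_invalid("placement failure: could not place ", n_vacuoles,
                     " non-overlapping vacuoles after 20 restarts")
      }
      for (v in seq_len(n_vacuoles)) {
        co <- plan$placed[v, 1:3]
        r_vox <- plan$placed[v, 4]
        d_um <- plan$diams[v]
        rng2 <- lapply(1:3, function(a) {
          max(1, floor(co[a] - r_vox - 2)):
            min(shape[a], ceiling(co[a] + r_vox + 2))
        })
        sub <- expand.grid(x = rng2[[1]], y = rng2[[2]], z = rng2[[3]])
        d2 <- (sub$x - co[1])^2 + (sub$y - co[2])^2 + (sub$z - co[3])^2
        inside <- d2 <= r_vox^2
        lin <- sub$x[inside] + shape[1] * (sub$y[inside] - 1) +
          shape[1] * shape[2] * (sub$z[inside] - 1)
        ch1[lin] <- bg_int
        ch2[lin] <- bg_int
        # ground-truth region = the tissue surrounding the lesion: majority
        # true label over a 2-voxel shell just outside the sphere
        shell <- d2 > r_vox^2 & d2 <= (r_vox + 2)^2
        lin_sh <- sub$x[shell] + shape[1] * (sub$y[shell] - 1) +
          shape[1] * shape[2] * (sub$z[shell] - 1)
        reg_votes <- labels[lin_sh]
        region <- if (sum(reg_votes == MASK_NEUROPIL) >=
                      sum(reg_votes == MASK_CORTEX)) "neuropil" else "cortex"
        truth <- rbind(truth, data.frame(
          x = co[1], y = co[2], z = co[3], diameter_um = d_um,
          region = region,
          placement_region = if (plan$want_ctx[v]) "cortex" else "neuropil"))
      }
    }
    if (noise_sd > 0) {
      ch1 <- ch1 + array(rnorm(length(ch1), 0, noise_sd), dim = shape)
      ch2 <- ch2 + array(rnorm(length(ch2), 0, noise_sd), dim = shape)
      ch1[ch1 < 0] <- 0
      ch2[ch2 < 0] <- 0
    }
    list(stack = brain_stack(ch1, ch2, voxel_size = voxel_size),
         truth = truth,
         mask = brain_mask(labels, voxel_size = voxel_size))
  })
}
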