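---
title: "Methods: quantitative phenotyping of fly head-trauma experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative phenotyping of fly head-trauma experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flytrauma)
```

# Scope

`flytrauma` implements the quantitative phenotyping stack used in
*Drosophila* mild-head-trauma studies: the startle-induced climbing assay
(Climbing Index), tracking-derived kinematics (speed, heading, abnormal
directional movement), vacuole quantification in two-channel 3-D brain
stacks, and survival/group statistics. Because behavioral videos, brain
stacks and lifespan tables from such experiments are rarely deposited, the
package also ships synthetic-data generators with known ground truth; every
analysis stage is validated against those generators or against independent
oracles. This vignette records the models, the defaults, and the design
decisions a maintainer would want to know.

# Climbing Index

A climbing trial is 10 s of video at 60 fps, trimmed to 601 frames
(frame 0 = trial start), in a vial 28 mm wide and 90 mm tall. The vial
height is divided into 10 equal bins, bin 1 at the bottom. At every second
`t = 1..10` (frames 60, 120, ..., 600) each fly is assigned the bin
containing its height, and the Climbing Index is the mean bin label:

$$\mathrm{CI}(t) = \frac{1}{N}\sum_{b=1}^{10} b \, n_b(t),$$

where `n_b(t)` counts flies in bin `b`. CI ranges from 1 (all flies at the
bottom) to 10 (all at the top). The *accumulated CI* is
`sum_t CI(t) ∈ [10, 100]`, and the sham-normalized accumulated CI divides a
test group's mean accumulated CI by the sham group's mean.

Decisions that the assay description leaves open, fixed here:

* **Sampling instants.** Readings are at frames `60·t`, `t = 1..10`;
  `t = 0` is excluded because all flies start at the bottom by construction,
  so a `t = 0` term would add a constant 1 to every accumulated CI.
* **Bin boundaries.** Bins are half-open, `[(b-1)·9 mm, b·9 mm)`, and the
  top boundary (90 mm) clamps into bin 10. Any other tie-break moves only
  flies sitting exactly on a boundary.
* **Ratio uncertainty.** The standard error of the sham-normalized ratio
  `r = m_t / m_s` uses the delta method,
  `se(r) = |r| sqrt(se_t^2/m_t^2 + se_s^2/m_s^2)`, treating the two group
  means as independent.

## Inference on CI curves

Published analyses of per-second CI typically use repeated-measures ANOVA,
an off-the-shelf procedure. This package's native inference is a
**permutation test** that is exactly testable and assumption-free: the
statistic is the mean over seconds of the absolute difference of group mean
curves, and the null distribution resamples *whole curves* (the trial is
the exchangeable unit, which preserves within-curve autocorrelation). The
p-value uses the add-one rule `(1 + #{T* >= T})/(n_perm + 1)`, so the
smallest attainable p is `1/(n_perm + 1)`. With nine trials per group the
test has power above 0.9 for the clearly separated preset cohorts (sham vs
injury at day 31) at alpha = 0.05, mirroring the separation visible in
published CI curves without claiming their magnitudes.

# Kinematics

Speed at frame `i` is `||x_i - x_{i-1}|| * fps` (mm/s); heading is
`atan2(dx, dy)` in degrees, so 0 deg is straight up, +/-90 deg horizontal,
wrapped into (-180, 180]. Decisions:

* **Stationary frames.** Headings are undefined when the per-frame
  displacement is below `min_disp = 0.02 mm` (1.2 mm/s at 60 fps), so
  positional jitter of standing flies is not scored as direction. The
  tracked-data convention for such frames is not standardized; this
  threshold is a CLI-visible parameter.
* **Analysis window.** Quantitative summaries default to the first 3 s of
  the trial, the startle-response window (males typically reach the vial
  top by ~4 s, after which heading carries no climbing signal).
* **Abnormal direction.** A frame is abnormal when its heading falls
  outside (-30, 30) degrees. Fractions are computed over frames pooled
  across flies (frame-weighted) by default because per-fly frame counts
  are unequal; a per-fly average is available (`per_fly = TRUE`) since the
  phrasing "percentage of flies" is ambiguous between the two.
* **Angular histograms** use 15-degree bins so that +/-30 deg are bin
  edges; a threshold that bisects a bin would make the abnormal fraction
  depend on binning.

# Vacuole quantification

Brain stacks are two channels (nuclear stain bright in the cell-body
cortex; F-actin stain bright in the neuropil) at ~1 um isotropic voxels. A
vacuole is operationally a roughly round region devoid of both stains that
is not part of a physiological dark structure (esophagus). The pipeline:

1. **Foreground.** Otsu threshold on the Gaussian-smoothed (sigma 2 um)
   combined intensity; largest connected component; morphological closing
   (15 iterations of a 3x3x3 box, computed on a padded volume so the
   volume border does not distort the closing); interior holes filled so
   lesions stay inside the foreground. The closed-and-filled volume is
   eroded by one voxel and united with the raw threshold mask — heavy
   closing otherwise deposits a thin artificial film of "foreground" just
   outside the true surface, which is dark and would contaminate lesion
   detection.
2. **Regions.** Within the foreground, a voxel is cortex when its
   normalized channel-1 intensity (95th-percentile normalization) is at
   least the normalized channel-2 intensity, else neuropil. The region
   channels are smoothed only half as much as the foreground field (the
   cortex/neuropil contrast is large, and label bleed around lesions
   scales with the blur radius). A stain-devoid lesion depresses the
   locally dominant channel far more than the other, which would tip the
   ratio toward the wrong region in the lesion's blur halo; the observed
   intensities near darkness are therefore modelled as
   `(1 - w) * tissue + w * lesion` (with `w` the blurred dark-mask weight)
   and the classification runs on the recovered tissue intensities. Deep
   inside dark structures even that is noise, so those voxels take the
   label of the nearest reliably classified tissue (constrained label
   dilation).
3. **Exclusion.** Either supplied (ground truth in synthetic data, a traced
   mask for real stacks — the original criterion was human judgment) or
   detected as dark connected regions extending more than 60 um along some
   axis, longer than any plausible vacuole (upper size bound 50 um).
4. **Detection.** Candidate voxels are brain voxels whose smoothed
   (sigma 1 um) combined intensity is below `dark_frac = 0.3` times the
   median foreground intensity — relative to the foreground median, not a
   global threshold, for robustness to the bright cortex shell. One micron
   of smoothing is what keeps lesion boundaries connected at 15% noise;
   weaker smoothing lets noise fragment the rim band of large lesions into
   satellite detections. Candidates are eroded once to cores with the
   6-neighbour cross (sheets up to two voxels thick — the sliver artefacts
   at the segmented surface — vanish, while the compact cores of 5 um
   lesions survive, which the 26-neighbour box would destroy), cores are
   labelled with 26-connectivity, and labels grow back two constrained
   dilation steps so each lesion recovers its full boundary without
   re-absorbing films.
   Components mostly made of background-adjacent rim voxels are dropped
   (partial-volume noise, not cavities within tissue). Components are kept
   when the equivalent spherical diameter is in `[2, 50]` um, the maximal
   z-slice is roughly round, and fewer than 10% of voxels carry the
   exclusion label (hard filter).
5. **Size-bias correction.** Thresholding a Gaussian-blurred step edge at a
   fraction `f` of the edge height marks the apparent boundary
   `qnorm(1 - f) * sigma` inside the true one, so threshold-based sizing
   systematically shrinks lesions (~1.4 um in diameter at sigma 1). The
   reported diameter, volume and projected area are corrected for this
   known bias, with `f` estimated at run time from the darkness cutoff,
   the foreground median and the lesion intensity level.
6. **Geometry per lesion.** Volume, equivalent diameter, z-projected area
   (the figure-level "vacuole area" in publications is measured on
   z-projections; both volume and projection are reported), and a
   roundness score `4A/(pi * feret^2)` on the maximal-area z-slice with
   `feret` the maximal pixel-centre distance plus one pixel. Roundness is
   used instead of a perimeter-based circularity because digital perimeter
   estimators are biased for small lesions; threshold 0.6 accepts moderate
   ellipticity (axis ratio down to ~0.6) and rejects corridors and films.
7. **Region label.** Majority vote of cortex/neuropil labels in a 2-voxel
   dilation shell around the component, restricted to bright tissue voxels
   (labels inside the lesion's dark halo are unreliable) — the tissue
   *surrounding* a lesion defines where it sits. The synthetic ground
   truth uses the same surrounding-shell definition evaluated on the true
   labels, so the agreement check compares an estimated against a true
   quantity of the same meaning. Lesions whose surrounding tissue is an
   almost exact 50/50 cortex/neuropil split remain genuinely ambiguous;
   they bound the achievable agreement.

Deviations worth noting: the lower diameter default is 2 um although real
vacuoles start at 1 um, because a 1 um lesion is a single voxel at 1 um
sampling and indistinguishable from noise. `dark_frac`, the roundness
threshold and the exclusion-overlap cap are invented operational constants,
exposed as parameters.

# Survival and group statistics

Self-contained implementations, each validated against an independent
oracle in the test suite (`survival::survfit`/`survdiff` and enumeration):

* **Kaplan-Meier** product-limit estimator with Greenwood variance;
  censored subjects leave the risk set without a step.
* **Mantel-Cox log-rank** for two groups; tied deaths use the standard
  hypergeometric variance with multiplicities. Pairwise comparisons use
  Bonferroni with family = all pairs in the supplied table (the published
  family size per figure is not stated; the factor is recorded in the
  output).
* **Wilcoxon rank-sum** with midranks; exact two-sided p by full
  enumeration when both samples have at most 10 observations and no ties
  (the symmetric null makes the two-sided rule unambiguous), otherwise a
  normal approximation with tie and continuity corrections. The switch at
  n = 10 and the continuity correction are conventional choices.

# Synthetic data: the stated world

The generators encode the *qualitative* structure reported for these
experiments; all effect sizes are invented and documented in
`inst/extdata/cohort_presets.json`, chosen once and not tuned.

**Trajectories.** Flies start in the bottom 5 mm after the startle tap.
Each fly draws a mean speed from `Gamma(shape = 6, mean = mean_speed)`
(between-fly CV ~ 0.41), an exponential startle latency (mean 0.3 s, which
produces the rapid initial climb without extra parameters), and then per
frame: pauses with probability `pause_prob`, else steps at its speed with a
heading drawn from a wrapped normal about vertical (sd `heading_sd`). The x
coordinate reflects at the side walls; y clamps at floor and ceiling (flies
walk on walls; the assay reads only height). `speed_shape = Inf` gives a
degenerate, fully deterministic cohort used by closed-form tests. Trials
are simulated independently; trial-to-trial correlation within a video is
not modelled.

Preset ordering encodes the reported directions: within each sex,
`mean_speed` falls and `heading_sd`/`pause_prob` rise from sham through
injury at day 3, 17, 31; mated females are affected more than males;
virgin females are nearly flat. Presets for males are faster overall
(males reach the top by ~4 s, females ~7 s). What a green ordering test
establishes is only that the pipeline recovers these *directions*; the
magnitudes are ours, not the literature's.

**Brains.** An ellipsoidal phantom (semi-axes 0.45 of each dimension, by
default 200 x 150 x 80 voxels at 1 um): a 15 um cortex shell bright in
channel 1, a neuropil core bright in channel 2 (peak 200, off-tissue 40,
background 10), a dark esophagus corridor (radius 8 um cylinder along y)
labelled exclusion, additive Gaussian noise (default sd 12, i.e. 6% of
foreground; tests go up to 15%). Lesions are dark spheres (intensity =
background) with diameters uniform in `diameter_range`, centres placed in
neuropil with probability `p_neuropil = 0.85` (vacuoles are predominantly
neuropilar), else cortex; a lesion too large to fit inside the cortex
shell is placed in the neuropil, matching the observation that large
vacuoles are neuropilar. Spheres must fit inside the foreground, keep
clear of the corridor, and maintain centre separation of at least 1.5x the
summed radii. Real stacks differ in ways the phantom does not attempt:
anisotropic PSFs, intensity gradients with depth, irregular brain outline,
autofluorescence. A green detector test therefore establishes correctness
of the measurement pipeline, not field performance on real microscopy.

**Lifespans.** Gompertz event times (hazard `a e^{bt}`), inverted
analytically from uniform draws; times beyond the censoring horizon are
right-censored there. Presets use `b = 0.1/day` and `a` around `1e-4/day`
(median lifespan ~60-65 days); hazards are identical across injury groups
within a sex because lifespan is reported as unchanged by this mild injury
model. Power properties construct explicit hazard-ratio-2 parameter pairs
instead of abusing the presets.

**Seeds.** Every generator takes a seed, runs in a local RNG scope
(restoring the caller's `.Random.seed`), and is bit-reproducible. Batch
helpers derive per-trial seeds by fixed offsets from the top-level seed.

# Numerical choices and degenerate inputs

* Permutation and enumeration p-values are never zero (add-one rule /
  two-sided tail containing the observed value).
* Log-rank with no events (all censored) returns statistic 0, p = 1 rather
  than an error: a table with no deaths carries no information.
* `mean_speed = 0` is allowed (motionless cohort, a useful null);
  `climbing_index` on zero flies, sham normalization against a zero mean,
  and region percentages of an empty lesion set are *undefined-statistic*
  errors rather than NaNs.
* Otsu on a (near-)constant image returns `-Inf`, making the whole volume
  foreground; an all-zero stack is a segmentation failure.
* The TIFF codec implements the uncompressed little-endian grayscale
  baseline only (the package's own format needs); conformance is checked
  against an independent reader in the tests.

# Known limitations

* The locomotor model has no wall-following, grooming, or social
  interaction; it exposes exactly the three metric families the pipeline
  measures (height, speed, heading).
* Heading uses single-frame displacements without smoothing; at very low
  speeds direction is noisy and is masked by `min_disp` rather than
  filtered.
* The brain phantom's cortex/neuropil boundary is a perfect ellipsoid
  shell; region labelling of lesions straddling a convoluted real boundary
  will be harder than the ~96% agreement measured here.
* Repeated-measures ANOVA is deliberately not reimplemented; users wanting
  the published test should export per-second CI values and use standard
  software. The permutation test answers the same question (do the curves
  differ?) without sphericity assumptions.
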