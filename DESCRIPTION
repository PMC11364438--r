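Package: flytrauma
Title: Quantitative Phenotyping for Drosophila Mild Head Trauma Studies
Version: 0.1.0
Authors@R: person("flytrauma", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify sensorimotor and neuropathological phenotypes
    in Drosophila mild-head-trauma experiments: startle-induced climbing
    (per-second Climbing Index from 10 height bins, accumulated and
    sham-normalized CI, permutation inference on CI curves), tracking-derived
    kinematics (instantaneous speed, heading angle relative to vertical,
    abnormal-direction fractions, speed and angular histograms), detection
    and quantification of vacuolar lesions in two-channel 3-D brain stacks
    (segmentation into cortex/neuropil, dark-lesion detection with size and
    roundness filters, region assignment, sham-normalized group statistics),
    and self-contained survival and nonparametric statistics (Kaplan-Meier,
    Mantel-Cox log-rank with Bonferroni-corrected pairwise comparisons, exact
    Wilcoxon rank-sum). Synthetic-data generators with known ground truth
    (agent-based climbing trajectories, ellipsoidal brain volumes with
    planted vacuoles, Gompertz lifespans with right censoring) make the whole
    pipeline testable without raw videos, brains, or lifespan records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
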