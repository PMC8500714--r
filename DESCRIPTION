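Package: stnreach
Title: Analysis of Subthalamic Spiking and Field Potentials During Interrupted Reaches
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing intraoperative subthalamic nucleus (STN)
    microelectrode recordings collected during a cursor reach task in which
    some reaches are interrupted by a mid-movement turn cue.  Provides a
    synthetic session generator with known ground truth (trial schedule with
    truncated-exponential delays, minimum-jerk reach-then-turn trajectories,
    inhomogeneous-Poisson spiking driven by lagged kinematics, and LFP with
    movement-suppressed beta oscillations), kinematic event detection,
    censored alpha-kernel PSTHs, population PCA and unit clustering,
    an extended cluster-mass permutation framework for repeated-measures
    time series (one-factor, two-factor, multidimensional and single-unit
    variants), lagged kinematic encoding models, a cross-validated
    nearest-centroid ideal-observer decoder, dynamic-time-warping trajectory
    averaging, and beta-band spike-field coupling via the pairwise phase
    consistency (PPC) estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
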