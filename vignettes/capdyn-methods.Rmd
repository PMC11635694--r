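---
title: "Methods: CAP temporal dynamics and corticostriatal configuration profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAP temporal dynamics and corticostriatal configuration profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`capdyn` implements a pharmacological resting-state analysis pipeline in
two halves, plus the statistics that join them:

1. **Network temporal dynamics.** Each fMRI frame is assigned to one of
   eight predefined transient network states (co-activation patterns,
   CAPs, aligned with canonical networks: FI-DMN, FPN, DMN, DAN, SN-1,
   SMO, SM-DMN, SN-2). Per state we compute *total time*, *transitions*
   (entries), and *persistence* (mean visit duration), and test drug
   effects (placebo PBO vs methylphenidate MPH vs haloperidol HAL) with
   repeated-measures ANOVA and Bonferroni-corrected paired post hocs.
2. **Corticostriatal configuration profiles (CSCPs).** For every striatal
   voxel, the vector of Fisher-z connectivity with 53 cortical ROIs, and
   three per-voxel divergences between condition pairs: aggregate
   divergence (AD), rank-order rearrangement (ROR), entropy shift (ES),
   each compared with a within-session placebo split-half null.
3. **Linkage.** The per-subject absolute change in time-in-state is
   correlated with subject-wise CSCP scores; dependent overlapping
   correlations are compared with Steiger's z; and node x state
   correlations localize the association.

The pipeline runs end to end on synthetic cohorts with planted ground
truth; volumetric inputs (NIfTI image + atlas/mask) and tab-separated ROI
matrices are both supported as real-data entry points.

# Frame assignment and dwell metrics

Each ROI column is z-scored across time, then frame *t* receives the
label of the state whose centroid map has the highest Pearson spatial
correlation with the frame's ROI vector. This mirrors common CAP
practice; the metric is a package choice (Euclidean distance on the
z-scored frames is available via `method = "euclidean"`). Ties break
toward the lowest state index so assignment is deterministic; a frame
that is constant across ROIs after normalization has no defined
correlation and is assigned by the same tie-break rule with a logged
warning.

Dwell metrics are run-length statistics of the label sequence:

* `total_time = (frames in state) x TR`,
* `transitions` = number of maximal runs of the state — a run touching
  frame 1 counts as an entry, which makes the identity
  `total_time = transitions x persistence` hold for every visited state
  (exact in exact arithmetic; floating-point round-off is below 1e-12
  relative),
* `persistence` = mean run length x TR, and `NA` for a state never
  visited. `NA` — not 0 — because zero persistence would conflate absence
  with instantaneous visits; group tests drop such subjects pairwise and
  report the dropped count.

The DMN and DAN activity time courses are per-frame simple OLS slopes of
the frame's ROI vector on one state map at a time (two separate simple
regressions, not one joint fit); their Pearson correlation, Fisher
r-to-z transformed, is the DMN-DAN anticorrelation score. A
random-intercept mixed model (lme4/lmerTest) estimates that score from
combined DMN+DAN time controlling for age, sex, drug, and drug x time;
marginal and conditional R-squared follow the
variance-decomposition definitions
`var_fixed / (var_fixed + var_subject + var_resid)` and
`(var_fixed + var_subject) / (...)`.

# CSCP metrics

Connectivity is Pearson correlation between voxel and ROI time courses,
then `atanh`. A single-regressor OLS fit and correlation are equivalent
up to scaling, so correlation is implemented and documented as such.
`r` is clipped to `|r| <= 1 - 1e-7` before `atanh` so degenerate
noiseless constructions stay finite; zero-variance columns are flagged
`NA` and skipped downstream.

Per voxel, with matched ROI order across conditions:

* **AD** = sum over ROIs of `|z_drug - z_placebo|`.
* **ROR**: ROIs are ranked by connectivity strength (rank 1 = most
  positive z, ordinal ranks, ties broken by ROI order — ties have measure
  zero on real data but tests need determinism); ROR is the sum of
  absolute rank changes. It is invariant under any strictly monotone
  transform of z and bounded by `floor(K^2/2)` for K ROIs (full
  reversal).
* **ES** = `|H_drug - H_placebo|` where `H` is the Shannon entropy of the
  |z|-profile normalized to probabilities with an epsilon floor of 1e-12
  (an all-zero profile gets `H = ln K`). The absolute difference of
  entropies is this package's concrete functional form for "change in the
  distribution of connectivity strength"; the absolute value keeps all
  three metrics nonnegative divergences comparable against the same
  split-half null.

The within-session placebo null splits the placebo run at
`floor(N/2)` frames (first half shorter when N is odd; deterministic and
order-preserving) and computes both profiles with the same machinery.
Drug-placebo profiles use full-length runs while the null uses
half-length runs; that asymmetry makes the null *conservative upward*
(half-length profiles are noisier, inflating null ROR), and
`cohort_cscp(..., equalize_null_length = TRUE)` computes drug and placebo
profiles on half-runs too for calibration studies — with no planted
effects and equalized lengths, drug-pair and split-half ROR agree.

Localization uses a per-voxel paired t across subjects (one-sided,
drug-pair > null), thresholded at uncorrected p < 0.001, clustered by
6-connectivity (face neighbours) on the voxel grid with a minimum extent
of 10 voxels. These defaults are package choices for a documented,
reproducible thresholding rule; they are exposed as arguments. Anatomical
labelling of clusters is out of scope (a free-text label slot is
provided).

# Inferential layer

* Repeated-measures ANOVA: on a balanced complete design with no
  covariates, the classical within-subject error partitioning
  (`aov` with a subject error stratum), which reproduces `F = t^2` on
  two-level factors exactly; with between-subject covariates (age, sex),
  a subject-random-intercept mixed model with Satterthwaite denominator
  df and type-III tests. Partial eta squared is recovered from the F
  statistic as `F df1 / (F df1 + df2)`. Covariates observed at a single
  level are dropped (they carry no information and break the model
  matrix). Effect sizes for paired contrasts use the d_z variant
  (mean of differences / sd of differences).
* Bonferroni correction: per-comparison alpha = family alpha / m (0.05/8
  = 0.00625 for the per-state family, 0.05/2 = 0.025 for the two drug
  post hocs); corrected p = min(1, p x m). The node x state table applies
  one joint family of n_nodes x n_states tests.
* Steiger's z for dependent overlapping correlations (shared variable x):
  `z = (atanh r1 - atanh r2) sqrt((n-3) / (2(1-s)))` with the covariance
  term `s` evaluated at the pooled correlation `(r1+r2)/2`. The
  three-way comparison (all states vs significant vs non-significant
  subsets) is one-sided by default — the directional question is whether
  the all-states association is *stronger* — with a `sided` flag.
  Identical correlations short-circuit to z = 0 so the degenerate
  "compare y with itself" case is well defined. Node-level correlation
  tests are two-sided plain Pearson; a partialling option was considered
  and rejected to keep the exploratory table simple and symmetric with
  the whole-striatum analysis.

# The synthetic cohort generator

The generator is first-class, tested code; it defines the study
conditions under which the pipeline is validated.

* **Geometry**: 59 subjects x 3 conditions, 235 frames at TR = 2 s,
  129 ROIs of which the first 53 are cortical, 300 striatal voxels, eight
  states. Ages are Normal(39.3, 11.25) truncated to 18-55 and sex is
  drawn 17:42 male:female, giving covariate realism without external
  data.
* **Dynamics**: a first-order Markov chain per run. The initial state is
  drawn from the chain's stationary distribution (not uniformly) so
  expected occupancy equals the stationary eigenvector from frame 1 —
  this makes occupancy-recovery tests exact in expectation. The placebo
  chain has self-stay probability 0.55 with uniform off-diagonal mass.
  The simulated MPH multiplies entry probabilities into the DMN and DAN
  states by 1.26 and into the FPN state by 0.8 (then row-renormalizes);
  the simulated HAL multiplies entries into SM-DMN by 1.17. The 1.26
  boost was fixed by Monte-Carlo calibration (4000 chains) so the planted
  DMN dwell-time increase has a paired effect size d of 0.70 at these
  defaults, the size the validation suite is designed around; the HAL
  boost targets the smaller SM-DMN effect on the same scale.
* **Signals**: frame vectors are state centroids (standardized random
  maps, pairwise |spatial correlation| <= 0.5 by bounded redraw) plus
  i.i.d. Gaussian noise, default sd 0.5 — calibrated so frame assignment
  recovers planted labels with >= 99% accuracy — with an optional AR(1)
  coefficient for stress-testing the split-half null under temporal
  autocorrelation. Striatal voxels are weighted mixtures of the cortical
  ROI signals under per-voxel weight profiles (exponentially decaying
  weights over a random ROI order); the simulated MPH applies a random
  permutation to the weight vector at half of the voxels, which is the
  planted rank-order rearrangement. With `coupling = TRUE`, each subject
  receives a drug-effect multiplier (uniform on 0.25-1.75) scaling both
  the transition-matrix shift and the fraction of permuted voxels,
  planting the positive dynamics-reconfiguration association the linkage
  stage should recover.
* **What it does not emulate**: scanner physics, head motion,
  physiological noise, hemodynamic convolution, spatial autocorrelation
  between voxels, or non-Markov state dynamics. Passing tests therefore
  demonstrate the correctness and calibration of the estimators under a
  clean generative model, not robustness to real-data artifacts;
  preprocessing is assumed done upstream.

An emergent (not directly planted) property worth noting: because DMN
and DAN frames push the two network beta series in opposite directions,
cohorts whose chains spend more time in the two states show stronger
DMN-DAN anticorrelation — the mixed model recovers a negative
time-in-state slope without any anticorrelation parameter in the
generator.

# Validation experiments and problem sizes

The validation suite (also re-run by `scripts/acceptance.R`) uses these
sizes, chosen to make Monte-Carlo rates stable while keeping a full run
in minutes on one CPU:

* Detection power: 100 label-only cohorts of 59 subjects; the MPH-PBO
  paired t on DMN total time at alpha = 0.025. Dwell metrics are computed
  from the label sequences; frame assignment is validated separately at
  >= 99% accuracy, so the label-level and signal-level pipelines agree.
* ROR vs null: 50 single-subject replicates, 50 voxels, full 235-frame
  runs.
* Coupling recovery: 100 coupled cohorts of 59 subjects with 100 voxels
  and a 53-ROI (all-cortical) signal space.
* Type-I calibration: 100 null cohorts (identical transition matrices,
  no permutations); the drug x state interaction and the
  dynamics-CSCP correlation against independently drawn scores both
  reject at about the nominal 5%.

# Numerical choices and degenerate inputs

* Seeded determinism throughout: every generator draws from the current
  RNG stream unless given a seed, and one cohort seed reproduces the
  dataset bit-for-bit.
* Text writers emit `%.17g` so matrices round-trip through TSV to 1e-12
  or better.
* Voxel ordering from volumetric extraction is fixed to (k, j, i)
  ascending and carried in the output, since downstream maps must be
  reproducible and no convention is universal.
* TR is read from the NIfTI header when present; an explicit argument
  wins over a conflicting header with a warning.
* `atanh` inputs are clipped (profiles) or rejected (beta-series
  anticorrelation) near |r| = 1; paired tests distinguish "identical
  vectors" (t = 0, p = 1) from "constant nonzero difference"
  (degenerate-input error).

# Known limitations

* The transition analysis is reduced to entry counts per state; finer
  transition structure (conditional on source state, or normalized by
  scan length) is not modelled.
* CAP centroids are inputs; no k-means re-derivation or spatial
  re-definition of states is provided.
* The striatum mask and cortical atlas are user inputs; no mask
  construction or anatomical cluster labelling.
* Sphericity corrections beyond the classical partitioning are not
  implemented; the mixed-model path with Satterthwaite df is the
  recommended route for unbalanced data.
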