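---
title: "Methods: ROI functional connectivity for PET rCBF studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROI functional connectivity for PET rCBF studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

H215O PET produces one static 3D image of regional cerebral blood flow
(rCBF) per scan. In a longitudinal treatment study, each participant is
scanned repeatedly (several task conditions, replicate scans, several
treatment sessions), and the scientific questions are (i) where rCBF
changes between sessions, (ii) how the *functional connectivity* between a
small set of anatomically defined regions — here a medial frontal cortex
(MFC) sphere, bilateral nucleus accumbens (NAcc) and bilateral hippocampus
(Hip) — changes between an off-medication baseline and later treatment time
points, and (iii) whether connectivity predicts clinical response measured
by the change in a psychosis symptom score.

petfc implements this analysis end to end, together with a synthetic-cohort
generator with known ground truth, so every stage is testable without
access to patient data.

## Signal extraction

Scans are optionally smoothed with an isotropic Gaussian kernel
(`smooth_volume()`); the per-axis sigma in voxels is
$\sigma = \mathrm{FWHM} / (v \cdot 2\sqrt{2\ln 2})$ for voxel size $v$,
evaluated per axis for anisotropic grids. The kernel is truncated at
$4\sigma$ and zero-padded at the boundary; `fwhm = 0` is the identity. The
default analysis FWHM mirrors the 12 mm kernel conventional for this kind
of PET data.

Scans are grouped into 4D stacks (`stack_scans()`), one per session x
condition, plus one pooled "all tasks" stack per session. The two replicate
scans of a condition are voxelwise-averaged into one analysis unit by
default (`use_replicates = "average"`); the printed per-task degrees of
freedom in studies of this design imply one observation per participant per
condition, which this choice reproduces. `use_replicates = "first"` is
available for sensitivity checks.

For each ROI mask the region signal is the **first eigenvariate**
(`extract_eigenvariate()`): with $Y$ the units x masked-voxels matrix,
columns are mean-centred across units, and the returned signal is the
projection on the first right singular vector (computed via the units x
units Gram matrix, which is exact and cheap when voxels far outnumber
units). Conventions the package fixes, since "first eigenvariate" alone
does not determine them:

* centring is across units (so the signal has mean zero);
* the signal is scaled to unit *population* variance (divide by the
  $1/n$ standard deviation) — with two units the values are exactly
  $\pm 1$, and correlations downstream are unaffected by this choice;
* the sign is fixed so the signal correlates non-negatively with the
  mask-mean signal, making repeated runs bit-identical.

The whole-brain covariate ("total intracranial activation") is the same
operator applied to a whole-brain mask (`extract_global()`).

## Connectivity and its comparison between sessions

Edge connectivity is the partial Pearson correlation of two region signals
controlling for the global covariate (`partial_corr()`): both signals are
residualized on (intercept, global) and the residuals correlated. Each edge
gets $z = \operatorname{atanh}(r)$ (Fisher), $n$ from complete units,
$df = n - 3$ (one controlled covariate), and a two-sided p from
$t = r\sqrt{df/(1-r^2)}$ (`connection_pvalue()`). Combined-condition
("all tasks") edges are computed from eigenvariates extracted over the
pooled session stack, not by concatenating per-condition signals.

Between sessions, edges are compared with the Fisher z-difference
statistic

$$ z_{stat} = \frac{z_B - z_A}{\sqrt{1/(n_A-3) + 1/(n_B-3)}} $$

with a one-sided standard-normal tail in an explicitly supplied direction
(`compare_connections()`; the package never infers the tested direction
from the data). Although analyses of this design are sometimes described
as "paired t-tests on z-scores", the printed statistics and significances
of the motivating study are exact standard-normal tails of this
independent-samples z-difference, which is what the package implements;
the discrepancy is deliberate and documented. The six edges of a session
pair form one multiplicity family, adjusted with the Benjamini–Hochberg
step-up (`adjust_pvalues()`): sort ascending, take
$\min_{j \ge i}(m \, p_{(j)}/j)$, clip at 1.

Clinical response is `baseline - week6` of the psychosis subscale score,
computed once (`clinical_table()`). Because a group-level correlation has
no per-participant value, `participant_edge_connectivity()` offers two
surrogates: the participant's mean product of standardized global-residual
signals (default; these products average exactly to the group partial r)
or leave-one-out jackknife pseudo-values of the group z. Neither is claimed
to be the original study's (undisclosed) choice; the association itself is
a plain Pearson correlation with $r^2$ and a two-sided p
(`response_association()`).

## Voxelwise maps

`paired_t_map()` computes a per-voxel paired t between two sessions,
matching units by participant and condition. Cluster-level inference
(`cluster_fdr()`) replaces random-field theory with a **sign-flip
permutation** null: per-pair difference images are randomly sign-flipped
(exhaustively enumerated when $2^{pairs}$ is below the requested count),
the maximum suprathreshold cluster extent is recorded per permutation, and
each observed cluster gets $p = (1 + \#\{M_{null} \ge k_E\})/(1 + B)$,
followed by the step-up adjustment across observed clusters. Fixed choices:
6-connectivity (face adjacency; diagonal contact does not merge clusters),
a default forming threshold of two-sided voxelwise $p < 0.001$ at the
paired df (configurable — the original SPM primary threshold is not
stated), and adjustment per contrast per sign. This is an *emulation* of
cluster-level FDR with testable error control, not a reproduction of SPM's
random-field p-values.

## The synthetic cohort

`generate_cohort()` emulates the study design: 29 participants, three
sessions (SZ0 baseline, SZ1 week one, SZ6 week six), three conditions
(rest, sensorimotor control, auditory decision), two replicates per
condition, a 48 x 56 x 48 grid at 2 mm centred so the standard-space
coordinates of all five default regions fit (the MFC sphere reaches
y = 57 mm, so the origin voxel is (24, 25, 24)). Per scan, regional latent
signals are drawn from a zero-mean unit-variance multivariate normal whose
correlation matrix is, by default, the published combined-task connectivity
pattern of the corresponding session (all three matrices are positive
definite; the constructor verifies this before anything is written); a
global signal $g \sim N(0, 0.5^2)$ is added over a brain ellipsoid, and
iid $N(0, 1)$ voxel noise completes the image. A designated edge
(MFC–LHIP by default, the study's predictive edge, at week one) drives the
clinical change score linearly: `change = 6 + 5 * (mean latent product) +
N(0, 4^2)`, with baseline scores around 14 ± 3 — magnitudes chosen once to
give a realistic moderate association on a symptom subscale, and recorded
here. Fixed seeds give byte-identical outputs, including NIfTI files.

What the generator does **not** emulate: PET physics (attenuation, decay,
reconstruction), head motion, anatomical variability, and within-participant
correlation of scans across conditions (scans are exchangeable draws within
a session). A green test therefore establishes correctness of the
*statistical machinery* under the stated generative model, not robustness
to real-data artifacts.

## A caveat the tests forced us to document

With **no true global signal** (`global_sd = 0`), the first eigenvariate of
the whole-brain mask does not estimate "nothing": it latches onto the
strongest coherent structure in the brain, which is the planted region
common mode. The detection threshold follows spiked-covariance theory —
the coherent mode wins once its energy $C(1+\rho)$ (total region voxels
times per-voxel latent variance) exceeds roughly
$\sigma^2\sqrt{p/n}$ — about 10 region voxels at unit noise on desk-scale
grids. Partialling out such a covariate destroys the planted correlation
(we measured bias of order $-\rho$ and worse). Escaping by raising the
noise instead destroys ROI eigenvariate reliability; both conditions can
only be met jointly on grids far beyond desk scale. Consequently:

* the **operating assumption** of the pipeline is that a genuine global
  signal dominates the whole-brain PC (default `global_sd = 0.5` yields a
  global eigenvalue an order of magnitude above the region mode, and the
  extracted covariate correlates > 0.999 with the true $g$);
* the estimator-bias property is verified on the generator's recorded
  latent signals with an uninformative covariate;
* the conservation property (brain covariate uncorrelated with latents at
  `global_sd = 0`) is verified in a high-noise, tiny-region world where the
  brain PC is genuinely noise-dominated.

This mirrors the known global-signal-regression artifact in functional
imaging and is worth knowing about when applying the pipeline to data with
a weak global component.

## Numerical and scale choices

* Monte-Carlo acceptance checks keep the stated replicate counts
  (100 cohorts for CI coverage, 200 for cluster error control, 5000 null
  draws for the directional test) but run on reduced grids (14^3–28^3) to
  fit a single-CPU budget; the statistics under test are
  grid-size-invariant.
* The planted-effect power simulation uses 25 pairs built from 25
  participants with two averaged replicate scans (halving the latent
  difference variance exactly as replicate averaging does in the real
  design), a 1-latent-SD focal shift, and the default forming threshold.
* Degenerate inputs error loudly rather than returning NaN: constant
  masked data, zero residual variance in `partial_corr()`, |r| ≥ 1 in
  `fisher_z()`. The only guarded silent value is the 0/0 paired-t voxel,
  set to 0 with a warning.
* BH adjustment clips at 1 and guards the adjusted ≥ raw invariant against
  one-ulp round-off in the running minimum.
* One master seed drives every stage; stage-local substreams are derived
  deterministically so stages can be re-run in isolation.

## Known limitations

Real-data ingestion is limited to single-file NIfTI-1 with an sform affine
(reader and writer are self-contained and cross-validated against nibabel).
Realignment and spatial normalization are out of scope: volumes are assumed
to share a grid. Cohort-dependent results of the motivating study (cluster
peak coordinates, the specific $r^2$ of the response association) are not
reproducible from synthetic data and are covered instead by planted-effect
detection and planted-slope sign-recovery simulations.
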