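---
title: "Methods: dissociating nociceptive and self-regulatory pathways to pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissociating nociceptive and self-regulatory pathways to pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painpath)
```

## The scientific problem

Pain reports respond both to nociceptive input (how hot the stimulus is) and
to cognitive self-regulation (deliberately "turning the pain up or down").
The question this package's framework addresses is whether those two
influences travel through the same brain system or through separately
modifiable ones. The test logic is mediation: if a brain measure `m`
mediates the effect of a manipulation `x` on pain `y`, then `x` must move
`m` (path *a*), `m` must predict `y` controlling for `x` (path *b*), and
the indirect effect *a·b* must be reliably non-zero. Separate modifiability
is established when a nociception-tracking multivariate signature mediates
the temperature effect but not the regulation effect, while a two-step
striatal-prefrontal pathway (here abstractly `m1 -> m2`) mediates
regulation but not temperature.

Because the framework's correctness cannot be checked against private fMRI
data, the package ships a synthetic-data generator whose ground truth *is*
that dissociation, and the test suite verifies that every stage — trial
design, single-trial estimation, pattern scoring, multilevel modelling,
bootstrap inference, and cluster correction — recovers what was planted.

## The experimental design generator

`generate_design()` reproduces the nine-run thermal task per subject:

* Runs 1, 2, 4, 8, 9: eleven passive trials each over temperature levels
  1–5 (44.3–48.3 °C), 55 trials in total, each level occurring 11 times.
  Within-run ordered transitions between levels cover all 25 ordered pairs
  exactly twice (50 transitions), and the five runs start on five distinct
  levels, with runs 2 and 8 pinned to levels 4 and 2.
* Runs 5 and 6 repeat the sequences of runs 4 and 8 with every level raised
  by one (levels 2–6, up to 49.3 °C).
* Runs 3 and 7 are regulation runs (regulate-up / regulate-down, coded
  +1/−1 against passive 0): ten trials, two per level 1–5, identical
  stimulus order in both, with the up/down order alternating across
  subjects.

The transition constraint is solved exactly by viewing the 50 transitions
as the edge multiset of a directed multigraph on five nodes (two copies of
every ordered pair, self-loops included). That graph is balanced, so it has
an Eulerian circuit; a random circuit is cut at five equally spaced points,
and circuits are redrawn until some rotation of the cut produces start
nodes that are a permutation of 1–5. Those five 10-edge trails are the run
sequences. Each node is visited in-degree (10) times plus once when a trail
starts there, giving the required 11 occurrences per level. Transition
counting is strictly within-run: 5 runs × 10 transitions = 50 = 25 pairs ×
2 is the only arithmetically consistent reading of the constraint set, so
cross-run transitions are never counted.

## The generative model

`simulate_trial_responses()` draws, per subject, random effects around
every population path (`Normal(path, between-subject SD)`), then per trial
(temperature centred at the mid-level 46.3 °C, `tc = temp_c - 46.3`):

```
sig    = alpha_s + temp_to_sig_s * tc                + e_sig
m1     = d1_s * reg                                  + e_m1
m2     = d2_s * m1                                   + e_m2
rating = mu_s + temp_to_pain_s * tc + cprime_s * reg
         + sig_to_pain_s * (sig - alpha_s) + b3_s * m2 + e_y
```

ratings are clipped to [0, 100] and the binary pain decision is
`rating > 50`. The dissociation is structural: the signature never receives
a regulation path and the `m1 -> m2` chain never receives a temperature
path, so the true indirect effects are `temp_to_sig * sig_to_pain` for
temperature-through-signature and `d1 * d2 * b3` for
regulation-through-chain, with the reversed chain truly null.

Default population values (units in parentheses) were fixed once, at
magnitudes realistic for a 0–100 rating scale, and are deliberately smaller
than the behavioural slopes a real cohort shows: a per-degree rating slope
large enough to span the printed group effects would drive a five-degree
range past the bounded scale and induce censoring bias, which the design
decisions here explicitly avoid (simulated clipping affects ~1% of trials).

| parameter | default | meaning |
|---|---|---|
| `temp_to_pain` | 5 (rating/°C) | direct temperature path |
| `temp_to_sig` | 2.4 (sig/°C) | temperature → signature |
| `sig_to_pain` | 1.2 (rating/sig) | signature → pain (path *b*) |
| `reg_to_pain_direct` | 3 (rating/code) | direct regulation path *c′* |
| `reg_to_m1` | −0.5 | regulation → m1 (regulate-down raises m1) |
| `m1_to_m2` | 0.8 | m1 → m2 |
| `m2_to_pain` | −5 | m2 → pain (more m2, less pain) |

The signs encode the phenomenon being emulated — down-regulation raises the
first mediator, which drives the second, which predicts pain relief — so
the chain's indirect effect `(-0.5)(0.8)(-5) = +2` is positive, as a
regulate-up-minus-down contrast on pain should be. Between-subject SDs
(e.g. 8 rating points on the intercept, 1 on the temperature slope) and
residual SDs (10 rating points per trial, 3 signature units) give
subject-level *t* statistics in the range typical of a 30-subject thermal
pain study. Rating-scale clipping is applied after noise; the defaults keep
means far from the bounds.

What the generator does *not* emulate: scanner artifacts beyond idealized
spike volumes, head motion, physiological noise, spatial autocorrelation of
the voxel background (background noise is i.i.d.), and non-linear
psychophysics. Passing tests therefore certify the statistical machinery
against a faithful linear ground truth, not robustness to every real-data
pathology.

## Single-trial (beta series) estimation

`build_single_trial_design()` assembles one HRF-convolved 12.5-s boxcar per
trial, one regressor for the 11-s rating periods, a run intercept, linear
drift, and a discrete-cosine basis implementing a 180-s high-pass
(`floor(2T/180)` terms); fixation is the implicit baseline. The canonical
HRF is a difference of gamma densities with the peak at 6 s, undershoot at
16 s, a 1/6 undershoot ratio, and 32-s support, scaled to unit peak. Run
concatenation keeps every nuisance block run-specific (block-diagonal).

Trial timing follows the task: 18-s initial fixation, 12.5-s stimulation,
4.5–8.5-s jittered pre-rating gap, 11-s rating, 5–9-s inter-trial interval;
jitters are uniform over those ranges because only ranges are specified.

Per-trial collinearity is quantified by the variance inflation factor,
`VIF_j = 1/(1 - R²_j)` from regressing trial column *j* on all other
columns; trials with VIF > 2.5 are excluded. VIFs are computed after any
spike-indicator columns are added, since spikes are part of the design that
inflates trial uncertainty. Two numerical notes established by the test
suite: VIF grows monotonically as neighbouring trials are packed closer,
but only down to gaps of about 6 s — below that the HRF undershoot makes
the regressor correlation non-monotone; and the cosine high-pass, like any
DCT filter, rolls off gradually near its cutoff, so a sinusoid at a 300-s
period still leaks a few percent into trial betas while periods beyond
roughly twice the cutoff leak under 1%.

Outlier volumes are detected from slice-wise means and SDs concatenated per
volume: squared Mahalanobis distances to the sample moments are referred to
a χ² tail, and a volume is flagged only when it is significant under *both*
Bonferroni and Benjamini–Hochberg correction — the stricter set. Singular
feature covariances get a documented ridge (5% of the mean diagonal); fully
constant features mean no volume can be judged an outlier.

## Pattern expression and ROIs

A signature is a voxel-weight map on a binary support; the pattern response
of a beta image is the plain dot product over that support, with
vectorization fixed to ascending linear voxel index so serialized
diagnostics are reproducible. In-mask voxels missing from a beta image
contribute zero and are counted with a warning — the alternative (silent
renormalization) would change scores depending on coverage. No resampling
is ever performed; volumes must share the grid. Sub-region ("local")
responses restrict the dot product to a label partition and sum exactly to
the whole-pattern response. Sphere ROIs include voxels whose world-space
centers lie within the radius (inclusive); voxel-center inclusion is the
simplest auditable rule where no convention is stated.

## Multilevel models and inference

All multilevel models use the summary-statistics two-stage form: OLS (or
logistic ML) within subject, then a group stage across subject
coefficients. This matches inference reported with *t* on `n − 1` degrees
of freedom. The behavioral model regresses ratings on regulation code,
centred temperature, and their interaction, with the regulation-run order
(+1/−1) as a between-subject covariate; the logistic counterpart drops
subjects with one-class outcomes (e.g. "always pain") or separation,
detected by diverging coefficients.

Mediation fits per subject are systems of OLS equations: for two paths,
`y ~ x`, `m ~ x`, `y ~ x + m` (giving *c*, *a*, and *b*, *c′*); for three
paths, `m1 ~ x`, `m2 ~ x + m1`, `y ~ x + m1 + m2`, `y ~ x` (giving *b1*,
*b2*, *b3*, *c*). Trial-level covariates enter every equation as columns.
Without covariates the identity `c − c′ = a·b` holds to numerical
precision and is asserted at 1e-8.

Group inference bootstraps subject rows of the path-coefficient matrix
(10,000 draws by default), taking the weighted mean per column per draw;
two-tailed p-values are `2·min(share ≤ 0, share ≥ 0)`, floored at
`2/n_boot` so zero is never reported, with 95% percentile intervals.
Subjects are combined by inverse-variance weights — within-subject OLS
variance plus a DerSimonian–Laird method-of-moments between-subject
component — with an unweighted mode provided; weights are fixed at their
point estimates across bootstrap draws. The variance of a two-path product
uses the second-order form `a²v_b + b²v_a + v_a v_b` (exact for
independent normal estimates); the three-path product uses the first-order
multivariate delta `(b2b3)²v_1 + (b1b3)²v_2 + (b1b2)²v_3`. Both forms are
validated against brute-force Monte-Carlo product variances (10⁶ draws)
rather than treated as transcriptions, and the type-I error of the
indirect-effect test is verified to sit at its nominal 5% over 500 null
replicates.

Three-path mediation is declared only when two criteria hold jointly:
every path *b1*, *b2*, *b3* individually significant (joint significance)
*and* the bootstrap product test on `b1·b2·b3` significant. The conjunction
is never looser than either criterion alone — a property the suite checks
by containment over simulations. Reversing the mediator order on data
generated as `x -> m1 -> m2 -> y` must and does come out non-significant:
given `m2`, `m1` carries no additional information about the outcome, so
the reversed third path is null.

The voxel-wise search runs the same model at every voxel with that voxel's
beta series as the free mediator (first or second), implemented in closed
form through Frisch–Waugh residualization so a whole grid is a few matrix
products per subject; a single-voxel search is verified to agree with the
scalar pipeline to 1e-10. The search's group stage is unweighted — with
thousands of voxels, estimate-dependent weights would add an
estimate-correlated term at every voxel for little efficiency gain — and
the per-voxel significance flag is the same two-criterion conjunction.
Zero-variance voxels are skipped and recorded.

## Cluster-extent correction

Smoothness is estimated from residual volumes by the first-difference
relation `FWHM = Δ·sqrt(4 ln 2 · var/vardiff)` per axis — the small-lag
expansion of the Gaussian-autocorrelation model. It is defined for any
input, with white noise at its floor `Δ·sqrt(2 ln 2)`, and is mildly biased
upward when voxels are coarse relative to the true smoothness; the suite
bounds the bias at 20% for a 6-mm kernel on 2-mm voxels.

The Monte-Carlo cluster threshold simulates unit-variance Gaussian fields
with the requested smoothness on the mask (white noise smoothed by a
separable Gaussian kernel and renormalized pointwise, which handles mask
edges exactly for separable kernels), applies the two-tailed voxel
threshold, and records the maximum face-connected (6-neighbour) cluster
size per iteration; `k_min` is the smallest extent whose null exceedance
probability is at most the family-wise level. Face connectivity is a
deliberate, configurable choice — stricter than the 18/26-neighbour
defaults of some tools, and stated rather than inherited. The closed loop —
applying the returned `k_min` to fresh null fields — is verified to control
empirical FWER within Monte-Carlo error of the nominal 5% on a 20³ mask.
Analytic random-field and permutation corrections are out of scope.

## Problem sizes and reproducibility

Defaults throughout the analysis scripts are 30 subjects × 97 trials, a
14×14×10 voxel brain with 3³-voxel planted clusters, 10,000 bootstrap
draws, and 2,000-iteration cluster calibration; the replicate-level
validation uses 50 study replicates (500 for the type-I study at 2,000
bootstrap draws). These sizes make every claim in the test suite
recomputable on a laptop in minutes while keeping Monte-Carlo error well
inside the asserted bounds. Every stochastic function takes an explicit
seed and derives any internal stage seeds deterministically from it; no
global random state is consumed silently, and rerunning any script or the
full pipeline with the same config reproduces its outputs exactly.

## Known limitations

* The background of the synthetic brain is spatially independent noise, so
  searches there do not exercise spatially correlated false-positive
  structure (the cluster-correction module is validated on smooth fields
  separately).
* The group stage is a two-stage summary-statistics approximation, not a
  joint mixed model; with very few trials per subject its weights are
  noisy. Precision weighting can be disabled.
* Logistic separation handling flags and drops subjects rather than
  penalizing the likelihood.
* The 24-column movement block and tissue-signal regressors of a real
  nuisance model are accepted as precomputed inputs, never computed here.
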