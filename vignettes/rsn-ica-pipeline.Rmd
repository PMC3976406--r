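---
title: "Methods: ICA-based repeated-measures analysis of resting-state network amplitude"
author: "rsnica"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ICA-based repeated-measures analysis of resting-state network amplitude}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Resting-state fMRI activity fluctuates slowly (0.01–0.1 Hz) and is
organised into spatially distributed resting-state networks (RSNs). In a
repeated-measures design — here, each subject scanned five times: morning,
midday and late afternoon of a mentally fatiguing work day (WD-T1/T2/T3)
and morning and late afternoon of a free day (FD-T1/T3) — the question is
whether a day of sustained cognitive work *enhances* or *suppresses* the
amplitude of the spontaneous fluctuations in particular sub-regions of
particular networks, and whether those regional changes track the
subjects' self-rated exhaustion.

`rsnica` implements the complete chain: per-scan spatial ICA, hierarchical
clustering of components into group RSN templates built from the baseline
scans only, goodness-of-fit selection of each scan's best-matching
component, a combined within-subject contrast with Monte-Carlo
cluster-extent correction, regional-score extraction with an exhaustion
ANCOVA, and the behavioural VAS analysis. Because studies of this kind
rarely deposit raw data, the package is organised around a synthetic-study
generator that plants known effects, so every stage is verifiable against
ground truth. The `analysis/` scripts run the chain as a narrative
workflow; the package functions carry all computation.

## The synthetic-study generator

A study is simulated as

\[
y(v, t) \;=\; \sum_k a_k\, g_k(v, c)\, m_k(v)\, s_k(t)
\;+\; \text{drift}(v, t) \;+\; \text{physio}(v, t) \;+\; \varepsilon(v, t),
\]

where \(m_k\) is network \(k\)'s spatial weight map (Gaussian-smoothed
spherical cores, maximum 1), \(s_k(t)\) a band-limited (0.01–0.1 Hz,
FFT-filtered Gaussian noise, unit SD) network time course, \(a_k\) the
scan's amplitude draw, and \(g_k(v, c)\) a condition-dependent gain that
differs from 1 only inside a planted effect's target region — gain > 1 is
an enhancement, < 1 a suppression. Filtered noise rather than sinusoids is
used for \(s_k\) so the sources match the stated RSN band without being
degenerate for ICA.

Parameter choices, with reasons:

* **Grid and mask.** 24×24×16 voxels at 3 mm (isotropic, 27 mm³/voxel)
  with an inscribed ellipsoid brain mask (~3 500 voxels). The margin keeps
  FFT-based smoothing free of wrap-around artefacts.
* **Acquisition.** TR 2 s; 180 volumes by default (120 in the reference
  study, keeping each ICA well-conditioned while five scans × 8 subjects
  remain affordable).
* **Noise.** White Gaussian noise with SD 0.02 relative to unit network
  amplitude. This is a deliberately high-SNR regime: the generator's
  purpose is structural recoverability, and at this level the K leading
  principal components retain ≥ 99% of the data variance (the level the
  retention diagnostic asserts). Temporally white noise spreads evenly
  over all T temporal modes, so the retained fraction is governed almost
  entirely by this one parameter.
* **Physiological confounds.** Cardiac 1.05 Hz and respiratory 0.27 Hz
  sinusoids mixed through smooth spatial weight maps, sampled at TR 2 s
  and therefore aliased — the cardiac line lands at 0.05 Hz, *inside* the
  RSN band, which is exactly the situation RETROICOR-style regression has
  to handle. 0.27 Hz (16 breaths/min) rather than 0.30 is used because at
  TR 2 s the second respiratory harmonic of 0.30 Hz aliases exactly onto
  the second cardiac harmonic, which would make the nuisance design
  singular by construction rather than by data.
* **Drift.** Linear + quadratic polynomial drift with smooth spatial
  coefficient fields (SD 0.1); nothing beyond low order, per the
  generator's scope.
* **Subject variability.** Each subject's atlas is rigidly shifted by a
  seeded *sub-voxel* offset (per-axis uniform, Euclidean norm ≤ 1 voxel)
  applied by trilinear interpolation, and each scan draws lognormal
  amplitude jitter (SD 0.1 on the log scale). Sub-voxel rather than
  integer shifts: on a 3 mm grid an integer shift decorrelates compact
  network blobs so strongly that cross-subject clustering loses its
  meaning, while sub-voxel offsets emulate imperfect spatial normalisation.
* **Planted effects (reference study).** Single spherical cores of radius
  9 mm (~123 voxels) serve as the effect regions, with WD-T3 gains 1.5
  (enhancement, network 1) and 0.6 (suppression, network 2). A *connected*
  region is required for a face-connected cluster to recover it, and the
  radius is chosen so the jitter-consistent interior dominates the
  one-voxel edge layer that intersubject shifts blur.
* **Behaviour coupling.** Pooled exhaustion = 40 + subject offset +
  100 × (mean |gain − 1| of the condition) + Gaussian noise (SD 8) on the
  0–150 VAS scale, then split into a tiredness rating and a reversed
  restedness rating. Linear coupling is the simplest model the ANCOVA
  stage can recover.

What the generator does **not** emulate: hemodynamic convolution, head
motion image artefacts, scanner-specific drift spectra, anatomical
variability beyond rigid shifts, and non-Gaussian physiological noise.
Passing tests therefore demonstrate that the *pipeline machinery* is
correct and calibrated under its stated assumptions — not that any given
real dataset satisfies those assumptions.

## Preprocessing

The high-pass filter is a projection onto the complement of a
discrete-cosine drift basis: with cutoff \(c\) cycles per time-course
(default 2), the constant plus DCT functions \(k = 1, \dots, \lfloor 2c
\rfloor\) (frequencies ≤ \(c/(T\,\mathrm{TR})\) Hz) are regressed out of
every voxel. A projection (rather than an FFT brick wall) matches the
"cycles per time-course" parameterisation, is idempotent, and cannot ring.

RETROICOR-style nuisance regressors are cosine/sine expansions of the
supplied cardiac and respiratory phase series up to order 2 (8 columns,
fixed layout); phase *estimation* from raw pulse traces is out of scope —
the generator emits phases directly. Nuisance regression is ordinary
least-squares residualisation on intercept + motion + physio columns,
with a rank check that names offending columns. The pipeline order is
fixed: high-pass first, then confound regression (the package exposes
both steps separately if a user wants the other order).

The motion gate excludes a scan when any translation exceeds 4 mm in
absolute value — strictly, so exactly 4.0 mm is kept; rotations are
reported but do not gate, since the rule names millimetres.

## Per-scan spatial ICA

Each scan is decomposed independently (never concatenated across
sessions). The component count follows the one-sixth rule
\(K = \lceil T/6 \rceil\) (180 volumes → 30 components). The time × voxel
matrix is voxel-demeaned, reduced to its K leading principal components
via the T×T temporal eigendecomposition, spatially centred and re-whitened,
and unmixed with a symmetric fixed-point FastICA with tanh contrast.

Numerical choices worth knowing:

* **Stopping rule.** The classical criterion — the largest change in any
  component direction cosine below 1e-4 — is reachable only when K is
  close to the number of genuinely non-Gaussian sources. Components that
  capture near-Gaussian noise have statistically indifferent directions
  and wobble at O(1/√V) per sweep, so with K above the source count the
  maximum never settles. The implementation therefore stops at the strict
  tolerance when reached, and otherwise returns the most stable iterate
  seen within the iteration budget (200 sweeps), recording the achieved
  delta and a strictness flag on the result. Up to five further seeded
  restarts are attempted before a genuine failure is raised. This mirrors
  what production ICA tools do in practice, made explicit and
  deterministic.
* **Conventions.** Maps are z-scored over brain-mask voxels (mean 0,
  SD 1: the value at a voxel is its weight in SDs of the map's spatial
  distribution); each map is sign-flipped to nonnegative spatial skewness,
  fixing the enhancement/suppression interpretation; components are
  ordered by descending explained variance. Whether to z-score over the
  whole volume instead of the mask is moot here (the generator's data are
  masked), but the mask is the implemented convention.
* **Determinism.** Given the scan and seed, the decomposition is
  bit-reproducible; the unmixing initialisation is the only random
  ingredient.

## Hierarchical grouping and templates

Group networks are defined from the baseline scans only — FD-T1 and WD-T1
are pooled at the first level precisely so that neither day nor the
exhausted states can bias the templates; T2/T3 sets are structurally
rejected. Level 1 matches each subject's two baseline component sets and
averages matched pairs (sign-aligned, re-z-scored) into one representative
set per subject; level 2 clusters the representatives across subjects into
K groups with *exactly one member per subject*.

The clustering is a deterministic constraint-respecting procedure:
clusters are seeded with the first set's components (sets processed in
sorted subject/day/timepoint order, so input order is irrelevant); each
further set is matched to the current cluster centroids by an exact
one-to-one assignment (shortest augmenting path) maximising summed
absolute spatial correlation; centroids are updated after every set. The
similarity is |Pearson r| over brain voxels only — time courses from
separate sessions are not comparable, so no temporal term enters. The
self-organising group-ICA literature leaves metric, linkage and
tie-breaking to implementations; this explicit procedure is the package's
stand-in and is validated against exhaustive enumeration on small
instances.

Cluster t-maps are voxelwise one-sample t statistics across the n member
maps (df n−1, subjects as random observations). Template masks apply a
one-tailed positive Bonferroni threshold over brain voxels at α = 0.05 —
one-tailed because RSN membership is positive engagement; Bonferroni
because the original correction is unnamed and Bonferroni is the most
conservative defensible reading. Zero-variance voxels are capped at ±1e6
and flagged rather than crashing on degenerate synthetic input.

Goodness of fit of a component map to a template is the mean z-score
inside the mask minus the mean outside (outside = brain minus template),
and each scan contributes its GOF-argmax component (ties → lowest index).
Selection sees only the scan under evaluation; templates never see
non-baseline data. Labelling of clusters against anatomical tables is
replaced by labelling against the generator's true maps (or user-supplied
reference masks for real data).

## Inference

The exhaustion contrast pools three inequalities (WD-T3 > FD-T3,
WD-T3 > WD-T1, WD-T3 > FD-T1) into the single within-subject contrast
with weights {WD-T3: +3, WD-T1: −1, FD-T1: −1, FD-T3: −1}; WD-T2 is
excluded from the voxelwise test and flows only into the regional-score
ANCOVA. Rather than re-deriving the omnibus two-way repeated-measures
ANOVA, the implementation computes each subject's contrast score
\(c_s(v) = \sum_c w_c\, y_{s,c}(v)\) and a one-sample t (df n−1,
two-tailed) — exact for a single within-subject contrast, and invariant
to any subject-specific constant map.

Cluster-extent correction: an uncorrected voxel threshold p = 0.01
(two-tailed, since both enhancement and suppression are reported) is
combined with a Monte-Carlo minimum cluster size. Smoothness uses the
gradient estimator — per axis,
\(\mathrm{FWHM} = \Delta\sqrt{4 \ln 2\,\sigma^2 / s^2}\) with \(s^2\) the
variance of neighbour first differences — whose white-noise floor is
~1.18 voxels; the null simulator inverts the same estimator to pick its
kernel, so estimation and simulation are mutually consistent. Three
details matter for calibration and were chosen deliberately:

* smoothness is characterised from the *ingredient* fields — the
  per-subject contrast score maps with the group mean removed — not from
  the t ratio map, which is systematically rougher than the fields it is
  built from;
* inside the pipeline the null fields are coloured by the residual maps'
  *empirical spatial autocorrelation spectrum* rather than by a Gaussian
  kernel at the scalar FWHM. ICA-derived maps live in a low-rank spatial
  basis and carry autocorrelation tails far heavier than a Gaussian ACF
  fitted to lag-1 gradients; simulating at the scalar FWHM was measured
  (on null reference studies) to produce above-threshold clusters an
  order of magnitude too often, while ACF-matched nulls restore the
  nominal rate — the same correction the wider cluster-inference
  literature converged on after Gaussian-kernel nulls were shown to be
  anticonservative on real data. The scalar-FWHM Gaussian path remains
  available (and is what the independent-voxel oracle test exercises);
* the pipeline's null simulation reproduces the statistic itself: each
  iteration draws n = df + 1 independent coloured fields and forms their
  one-sample t-map, thresholded at the matching t quantile;
* simulated fields carry their exact analytic variance; standardising
  each realisation by its own empirical spatial SD — tempting but wrong —
  conditions away exactly the large-excursion realisations the maximum
  cluster size cares about and biases the threshold low.

Each null field is thresholded two-tailed, positive and negative voxels
are clustered separately by 6-connectivity (face neighbours only), and
the returned minimum size is the smallest k whose null exceedance
frequency falls below α. Testing N networks applies the α/N adjustment
(0.05/5 in the reference study). 500 iterations is the default;
calibration tests use 200 to fit their run-time envelope, and the
Monte-Carlo seed is an explicit, logged argument everywhere.

Surviving clusters are reported with |t|-weighted centre of mass in mm
(origin at the grid centre), extension in mm³ (voxels × 27 at 3 mm),
average t and signed maximum |t|. Regional scores are plain means of the
best-fit component z-maps over a cluster's voxels for WD-T2 and WD-T3,
and the ANCOVA fits score ~ scan + VAS + scan:VAS by OLS with partial F
tests from nested residual sums of squares (VAS against the scan-only
model, interaction against the additive model), reported uncorrected as
an exploratory analysis. A perfect reduced-model fit (to numerical
precision) returns F = 0 for the added term rather than a ratio of
rounding errors.

## Behavioural analysis

The two 0–150 VAS scales are pooled *before* standardisation — the rested
scale reversed, then averaged: (tired + (150 − rested))/2 — following the
order in which the design describes the scores; a flag could trivially
reverse this, and per-subject z-standardisation (sample SD, n−1) makes
the two orders nearly equivalent in practice. Standardisation uses all of
a subject's scans, then T1/T3 rows enter a univariate 2×2 ANOVA
(day × time-of-day) on the balanced table. Simple effects contrast the
two days at each time point against the full model's pooled error term,
with p doubled (two comparisons) and capped at 1. Constant ratings raise
an error naming the subject, mirroring the exclusion of unusable raters.

## Problem sizes used in the validation suite

The package's own validation runs at sizes chosen to exercise every stage
at full structure: the grouping-structure check uses 8 subjects × two
baseline scans at 180 volumes and K = 30; end-to-end recovery uses 20
replicate studies of 8 subjects × 4 contrast conditions at 120 volumes,
K = 10, with Monte-Carlo thresholds at 200 iterations; the null
calibration uses 40 replicate null studies of the same design. Unit tests
run on a 16×16×12 grid with 3 networks. These are the package's reference
conditions; nothing in the methods depends on them.

## Known limitations

* The sog-ICA stand-in is a deterministic assignment procedure, not a
  reproduction of any published sog-ICA objective; on data where
  components are not clearly separable its greedy sequential matching can
  differ from a global optimum (the tests cover the separable regime and
  tiny exhaustive cases).
* Cluster-extent correction assumes stationary null fields; the
  ACF-matched simulation captures the average spatial dependence of the
  contrast maps but not any residual nonstationarity, and the null
  calibration test measures — rather than proves — that the procedure
  holds its nominal rate under the generator's conditions.
* The t-map voxel threshold uses the t distribution while the null fields
  are Gaussian; suprathreshold *rates* match by construction (both at
  p = 0.01), which is what the cluster-size null requires.
* Real-data use assumes spatially aligned, same-grid inputs; no
  registration, slice-timing or motion estimation is provided.
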