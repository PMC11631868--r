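---
title: "Methods: dose-response phMRI, connectivity, lipidomics and behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response phMRI, connectivity, lipidomics and behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phmrikit)
```

# The study design this package models

phmrikit implements the statistical chain of a dose-response
pharmacological MRI (phMRI) experiment in awake rodents. A drug or
vehicle is injected mid-scan; the session acquires 250 BOLD volumes at
TR 6 s (25 min), the first 50 acquisitions forming the pre-injection
baseline. Signal change is assessed by comparing the response window
(acquisitions 150–200, 1-based inclusive, i.e. 51 volumes late in the
post-injection period) against the baseline window (acquisitions 5–45 —
the earliest and latest baseline volumes are dropped as settle-in
margin). Four groups (vehicle plus three doses) are compared region by
region over a segmented atlas. Resting-state connectivity is measured
in a separate scan; plasma/CNS lipid concentrations and behavioral
measures come from parallel cohorts.

The default group sizes (4/4/6/5 for imaging, 5 per group for
lipidomics, 6 per group for behavior) reflect the usual usable-subject
counts of such experiments after motion attrition.

# Activation analysis

## Percent change and per-voxel testing

Per voxel, `percent_change_map()` computes
$\Delta\% = 100\,(\bar{x}_{resp} - \bar{x}_{base})/\bar{x}_{base}$.
Voxels with a zero baseline mean have no defined percent change; they
are set `NA`, counted in a QC attribute, and never classified —
degraded data should cost a voxel, not a run. `voxel_ttest()` runs a
two-tailed two-sample Welch test per voxel (unequal variances — window
variances genuinely differ when a response is present). Degenerate
zero-variance voxels follow a fixed convention: p = 1 for equal window
means, p = 0 otherwise.

## The ranked-p false-positive filter

Within each region of $V$ voxels, p-values are ranked ascending and
voxel $i$ is admitted when $P_{(i)} \le (i/V)\,q\,c(V)$, applied
**step-up**: the largest rank satisfying the inequality admits all
smaller ranks. With $c(V)=1$ (the default, a conservative choice valid
under arbitrary dependence only with the harmonic-sum constant, which
users may supply via `cV`) this is the Benjamini–Hochberg step-up at
level $q = 0.2$ within the region. The step-up reading is the only one
consistent with the rule's FDR lineage; tied p-values share the better
rank automatically (the threshold is non-decreasing in rank). The
implementation is property-tested against an independent brute-force
step-up oracle on random p-vectors with forced ties.

## Thresholding and counting

Surviving voxels are classed positive/negative at an inclusive
$\pm 1\%$ threshold (a voxel at exactly $-1.0\%$ counts as negative;
strictness is a convention, and inclusiveness keeps the boundary case
stable under exact arithmetic). Counts per region and subject feed a
Kruskal–Wallis test across dose groups (via `kruskal.test`, with tie
correction; all-identical counts define H = 0, p = 1, since rank
statistics carry no information there).

## Effect size

The reported effect size is the rank-based epsilon-squared form
$(H - k + 1)/(n - k)$, floored at 0. Its anchors: the null expectation
$E[H] = k-1$ maps to 0, perfect separation approaches 1. Published
tables of this kind print an "omega squared" column without defining
the formula, and rank-test effect sizes cannot be reconstructed from
group means/SEs alone, so this documented stand-in is used and the
printed effect sizes of the bundled reference tables are not treated as
recomputable targets.

## Ranking and across-region FDR

`rank_table()` sorts by ascending p with ties broken by region name
(deterministic output), keeps `p < alpha` strictly in the significant
view, and reports a Benjamini–Hochberg summary across all tested
regions (`p_adj` plus the largest raw p still significant at the BH
cut). The strict `<` matters: a region printed at exactly p = 0.050
is excluded, which is how the bundled 70-row negative-VOA reference
table yields 69 significant regions.

## Composite maps

`composite_map()` maps every composite voxel through each subject's
inverse affine into the subject grid, samples the subject's
percent-change map by trilinear interpolation, and averages the
available contributions; locations outside a subject's grid (or on
invalid voxels) contribute nothing rather than zero, so the composite
is a mean of observed values only. Idempotence (one subject, identity
transform), symmetry (M and −M cancel) and subject-order invariance
are tested.

# Connectivity analysis

Band-pass: zero-phase (forward–backward) Butterworth, order 4 by
default, band 0.01–0.1 Hz; the series is demeaned first, so DC
rejection is exact. Order and band are configurable; the band must sit
inside the Nyquist range or the call fails loudly. Nuisance regression
is plain OLS projection (intercept always included; collinear columns
dropped with a warning); motion scrubbing uses one spike regressor per
censored frame, which equals deletion for correlation purposes and is
verified against a deletion oracle within 0.02.

Pearson matrices exclude self-edges (NA diagonal). Fisher Z is
`atanh`, with |r| = 1 clipped to 1 − 1e−7 and QC-flagged rather than
propagating infinities. Group edge statistics are one-sample t-tests
of subject Z values against zero, re-expressed as a signed
standard-normal-equivalent Z via the two-tailed p; edges with zero
across-subject variance are capped at ±8 (configurable) with a QC
count — a cap, not a fabricated significance, and flagged as such.
Binarization at |Z| ≥ 2.3 is inclusive. Degree centrality is the row
sum of the adjacency; the handshake lemma is property-tested.

"KNN clustering" of nodes is concretized as mutual k-nearest-neighbor
graph clustering: node connectivity profiles (matrix rows, NA→0) are
compared by Euclidean distance, two nodes join when each lies within
the other's k-neighborhood (ties at the k-th distance are all
included, so identical profiles form a clique), and clusters are
connected components. Default k = 5; for planted-block simulations we
use k = block size − 1, the largest k that cannot force
between-block edges in the noiseless limit. The method family name is
ambiguous in the field; this variant is the package's documented
choice.

Group comparison of regional degrees is paired over nodes (the only
pairing consistent with independent animal groups): Shapiro–Wilk on
the paired differences gates at p > 0.05 between a paired t-test and a
Wilcoxon signed-rank test, and the fired branch is reported.

# Lipidomics

The outlier rule is single-pass: group mean and sample SD computed
once, candidate included, values beyond 2 SD dropped, no re-iteration.
A structural consequence worth knowing: one point in a group of $n$
can deviate by at most $(n-1)/\sqrt{n}$ sample SDs, so the rule cannot
exclude a lone outlier below $n = 6$ — at the lipidomics cohort size
of 5 it is effectively vacuous, and tests exercising exclusion use
larger groups (e.g. the {0×9, 100} case, 2.85 SD).

The "type 2" t-test is the pooled-variance two-sample Student t
(spreadsheet TTEST convention). CNS-combined analysis sums a lipid
over the six brain compartments per subject (subjects missing a
compartment are dropped and logged), preserving n. Fold change is
reported as magnitude ≥ 1 plus a direction flag (arrows encode
magnitude, color carries direction); equal means tie-break to
"increase" with fold 1, one arrow, no shade. Arrow bins place boundary
folds in the upper bin (1.5 → 2 arrows, 2 → 3, 3 → 4, 10 → 5); shade
places the boundary p = 0.05 in the light band. Detection states: BDL
when no sample in either group is detectable, BAL when either group
has fewer than `n_required` (default 3, configurable — the analytic
minimum is a lab convention, not a published constant) detectable
samples. Heatmap means and folds are computed after outlier exclusion,
consistent with excluding a sample "from statistics for that
compound". The dose-curve ANOVA reports Fisher LSD pairwise tests
(pooled-MSE t, unadjusted) only when the omnibus p < 0.05.

# Behavior

One-way ANOVA per measure; investigation ratio IR = novel/(novel +
familiar), undefined (zero-total) subjects excluded and flagged,
mirroring the exclusion of non-attending animals; IR tested per group
against chance 0.5 with a two-tailed one-sample t. Post-hoc pairwise
comparisons use Fisher LSD through `dose_anova_lsd()` (an unadjusted
convention chosen to match the lipidomics chain; users wanting
family-wise control can run `TukeyHSD` on their own `aov` fit). The
session length (600 s) is a config field, not an assumption.

# The synthetic-data generators

The generators define the package's test surface: every downstream
stage is validated by recovering what was planted.

* **BOLD** — constant baseline of 100 arbitrary units (percent change
  becomes numerically transparent), a step of the specified percent
  change over the response window for a per-subject random subset of
  region voxels (the analysis compares window means, so richer
  hemodynamic shapes would add nothing testable), i.i.d. Gaussian
  noise per sample. Noise SD is a property of the scan and is an
  argument of `generate_bold()` rather than of the per-region effect
  spec. The synthetic atlas is a small slab-partitioned volume
  (24×24×8, 6 regions by default) standing in for a full segmented
  atlas; region count is configurable.
* **Resting state** — i.i.d. multivariate-normal time points under a
  block-compound correlation structure; PSD is checked and a non-PSD
  request fails naming the offending correlations. This emulates
  block-structured covariance only, not autocorrelated BOLD spectra —
  band-pass behavior is therefore tested on deterministic sinusoids
  instead.
* **Lipids** — log-normal concentrations around true group means with
  specified CV (exact at cv = 0), left-censored below-detection flags,
  and injected outliers placed 3 sample-SDs above the uncontaminated
  group mean.
* **Behavior** — per-group normal draws with floor/clamp to the
  measures' domains; defaults emulate a sedating high dose (distance
  drop, wall-to-corner time shift, above-chance IR only in vehicle, no
  tail-flick effect).

What passing these tests shows — and does not. Recovery at the planted
step effects demonstrates the chain's correctness and its behavior at
realistic SNR, but the generators omit temporal autocorrelation,
physiological noise, motion structure and registration error; absolute
sensitivity numbers on real data will differ. Determinism is exact:
identical seeds and specs give bit-identical outputs.

# Numerical choices and problem sizes

* Acquisition windows are exposed 1-based inclusive (matching how scan
  protocols are described); internal index arithmetic converts once,
  at validation.
* Degenerate-variance conventions (p ∈ {0, 1}) are applied uniformly
  across the Welch, pooled-t, ANOVA and IR tests.
* Oracle-established tolerances: the noisy BOLD recovery band (±15%)
  comes from Monte-Carlo runs of the generator at matched noise; the
  null heatmap dark-cell rate is checked against binomial 95% bounds
  around the nominal 0.05 (the pooled t under log-normal noise at
  n = 5 has true size ≈ 0.046, comfortably inside those bounds at the
  cell counts used).
* Test and acceptance problem sizes — a 24×24×8 grid with 4×5
  subjects and 250 acquisitions for the full activation run, 10–16
  node networks with 150 time points, 500 null lipid tables of 6
  cells — were chosen as the smallest sizes at which every effect of
  interest is comfortably detectable and every rate estimate stable.

# Known limitations

* The composite mapper handles affine transforms only; nonlinear
  registration is out of scope (inputs are assumed atlas-registered).
* The mutual-kNN clustering variant and the rank-based effect size are
  documented stand-ins for ambiguously specified conventions; both are
  isolated behind single functions so alternatives can be swapped.
* The across-region FDR summary is Benjamini–Hochberg; other FDR
  definitions would give different summary cuts on the same tables.
* Heatmap rendering is left to the caller (the grid CSV contains the
  complete encoding); the package computes, it does not draw.
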