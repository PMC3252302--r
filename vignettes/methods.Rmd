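---
title: "Group ICA, dual regression and functional network connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group ICA, dual regression and functional network connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`rsfnc` implements a complete resting-state fMRI network analysis — group
spatial independent component analysis (ICA), dual-regression
back-reconstruction, spectral component selection, voxelwise group
statistics, and functional network connectivity (FNC) by constrained
maximal time-lagged correlation — together with a synthetic-data generator
that plants known spatial networks, couplings, lags and group effects. This
vignette is the package's account of the models, the defaults, and the
design decisions that were genuinely open.

## The data model

A subject's run is a 4D array (x, y, z, t) at TR = 2 s. The analysis
operates on masked two-dimensional matrices, time x in-mask voxels. Voxel
columns follow R's native array order (`which(mask)`: x fastest-varying,
1-based indices); `to_matrix()` and `from_matrix()` are exact inverses on
in-mask voxels, and that round-trip is asserted in the test suite. Volumes
are assumed co-registered: affines are carried through but never
resampled — spatial normalization is explicitly out of scope.

## Preprocessing

The first 5 volumes of each run are discarded (steady-state
magnetization). Subjects move: when a realignment-parameter table is
present, a subject is excluded if, relative to the first volume, any
translation exceeds 2 mm on any axis or any rotation exceeds 1 degree. The
limits are read strictly ("greater than"): a value exactly at the limit
passes. Rotations in SPM-style `rp_*.txt` files are radians and are
converted to degrees on load.

Spatial smoothing is an isotropic Gaussian at 8 mm FWHM, applied per axis
with sigma = FWHM / (2 sqrt(2 ln 2)) divided by that axis's voxel size, so
anisotropic voxels are handled correctly. The kernel is truncated at 4
sigma (negligible mass beyond) with an edge-replicate boundary, which
preserves constant images exactly — a property the tests assert.

Each voxel's time series is then detrended (least-squares line removed).
Dividing by the residual standard deviation ("variance normalization") is
available (`detrend_and_standardize(standardize = TRUE)`) but the pipeline
default is detrend-only. The reason is measurable: on synthetic data whose
noise floor is spatially uniform, per-voxel variance normalization rescales
every voxel to unit variance *after* smoothing, which flattens the spatial
amplitude profile of the planted networks. End-to-end map recovery drops
from ~0.99 to ~0.90 spatial correlation, and — more damagingly — the
mismatch between the normalized data and the unnormalized group maps
injects deterministic cross-talk into the dual-regression time courses,
which surfaces as consistent spurious FNC edges (mean r up to −0.3). On
real data with spatially heterogeneous noise the trade-off may differ; the
flag exists for that reason.

## Group ICA

**Order selection.** `estimate_order_mdl()` implements the Wax–Kailath
minimum description length criterion on the eigenvalues of the temporal
covariance, treating in-mask voxels as i.i.d. samples:
MDL(k) = −N (p−k) log(g_k / a_k) + k (2p − k) log(N) / 2, minimized over
k = 1 … p−1, with g_k and a_k the geometric and arithmetic means of the
p−k smallest eigenvalues. The estimator is consistent when the voxel count
N is large relative to the number of time points p; at p = 40 and N = 4000
it recovers planted orders 3, 5 and 8 exactly at SNR 10. At the synthetic
grids used here (p = 200, N ≈ 4200) the Marchenko–Pastur spread of the
noise eigenvalues breaks the equal-tail assumption and the criterion
saturates near p−1; smoothing worsens this by correlating the "samples".
No smoothness correction is implemented. Consequently the pipeline default
is a fixed K = 8 (the number of networks this analysis is built around),
with `K = "mdl"` available where the voxel-to-timepoint ratio justifies it.

**Two-stage reduction.** Each subject is reduced by temporal PCA to
p1 = min(ceiling(1.5 K), t−1) dimensions (headroom above K); the reduced
matrices are concatenated along the reduced-time axis and reduced again to
K. With one subject and K = p1 the two stages collapse to the subject PCA
(same subspace), and with duplicated subjects the group spectrum doubles —
both tested closed-form properties.

**Infomax.** The unmixing matrix W is fit on whitened reduced data by
natural-gradient infomax with the logistic nonlinearity,
dW = lr (I + (1 − 2y) u' / n) W, in mini-batches; the learning rate anneals
by 0.9 whenever successive updates differ by more than 60 degrees, and
divergence triggers a restart at half the rate (at most 3). Two
hyperparameters were set empirically on known Laplace mixtures before the
validation thresholds were frozen: the initial rate lr0 = 0.00065 / log(K)
and a *small* block size, ceiling(min(5 log n, 0.3 n)). The natural
gradient step is tiny near the identity, so the number of weight updates
per pass — not their batch size — governs convergence; with a few large
batches the rotation between the last source pair can remain unresolved
for thousands of passes. With small blocks, all of 10 random 3-source
mixtures are recovered to |r| ≥ 0.998 within ~400 passes. The iteration
cap is 2048 passes because on the 8-network synthetic study the final
source-pair rotation resolves around pass 1550. Fixed seeds give
bit-identical results. Maps are z-scored over in-mask voxels and
sign-flipped to positive skewness (activation blobs are positive-tailed).
At group level the "time courses" of a component set are not meaningful —
the concatenated reduced axis is not time — so the reduced-space mixing
matrix is stored instead; real per-subject time courses come from dual
regression.

## Dual regression

Stage 1 regresses each time point's voxel vector on the K group maps
(demeaned over voxels): T = Y M' (M M')⁻¹. Stage 2 regresses each voxel's
time series on those time courses (demeaned over time) and z-scores the
resulting maps. Both stages are plain OLS; rank-deficient regressors error
with the collinear pairs named. On noiseless factorizable data the
composition reproduces the planted factors to machine precision (tested at
1e−10), and stage-1 estimates are unbiased under isotropic noise.
No variance normalization of stage-1 time courses is applied before
stage 2.

## Component selection

The periodogram of each (demeaned) component time course is computed per
subject; the high-frequency fraction is the share of non-DC power above
0.1 Hz, and power is normalized so it sums to the series' population
variance (Parseval, asserted to 1e−6). A component is discarded when the
*median across subjects* of this fraction exceeds 50% — the median because
the rule's level of application (group or subject time courses) was an
open choice, and the subject-level median is robust to single noisy
subjects. The boundary reads strictly: exactly half is kept. Visual
inspection of spatial maps cannot be automated faithfully; the manual
override lists (`override_discard`, `override_keep`) are the escape hatch
and are recorded in the selection report.

## Voxelwise statistics

One-sample t-tests (t = mean / (sd/√n), df = n−1, two-sided) define each
network per group; zero-variance voxels are flagged with t = 0, p = 1.
Between-group comparisons use the pooled-variance (Student) two-sample t —
the classical SPM default — rather than Welch, two-sided, computed only
inside a restriction mask: the control group's voxels with q < 0.05 *and*
t > 0 from the one-sample map. The positive side defines the mask because
an RSN is its positive loadings. FDR control is Benjamini–Hochberg
throughout (q via `p.adjust`, rejection at q ≤ alpha), verified against an
exhaustive step-up oracle on a thousand random p-vectors.

## FNC

Selected component time courses are cubic-spline interpolated from the TR
grid to a 1 s grid (sub-TR lag resolution), band-pass filtered with a
zero-phase order-5 Butterworth at 0.01–0.1 Hz, and correlated under
circular shifts of −5 … +5 s — 11 coefficients per pair, 28 pairs for 8
components. The pair statistic is the coefficient of maximal *absolute*
value with its sign retained ("maximal" is ambiguous between signed and
absolute; absolute-with-sign detects anticorrelation too). Ties break
toward |lag| = 0, then the negative lag. Shifting is genuinely circular,
so no samples are lost at window edges. A positive lag of pair (i, j)
means j lags i; r is symmetric and the lag antisymmetric by construction,
asserted on every run.

Group inference Fisher-z transforms the per-subject maxima
(variance-stabilizing) before one-sample t-tests across subjects, FDR over
the 28 pairs; `fisher_z = FALSE` reproduces the raw-correlation variant.
Between-group tests are pooled two-sample t on the z values. Each
significant edge is labeled intra- or inter-system under the partition
{1, 2, 4 | 5, 6 | 3, 7, 8} (integration/modulation, higher cognition,
primary function) and classified against the reference group as preserved,
lost or gained. Pearson correlations of each pair's z values with subject
age, FDR-corrected, serve as a heterogeneity check.

**A caveat that matters for interpretation:** the maximum over 11 lagged
correlations has an inflated null — under independence its magnitude
concentrates near 0.2 rather than 0 at these series lengths, with random
sign. The one-sample group test remains centred (the sign is symmetric),
but it is mildly anticonservative, and occasional false-positive edges
survive FDR, typically clustered on one component. Planted-graph recovery
at n = 14 subjects therefore achieves Jaccard ≥ 0.9 in most but not all
random cohorts (measured ~87% over 15 seeds, median 0.92).

## The synthetic cohort

The generator is first-class, tested code, and its defaults are the study
conditions: three groups (14 controls, 7 and 9 patient-like subjects), 205
volumes at TR = 2 s of which 5 are discarded, 3 mm isotropic voxels, and a
spherical "brain" of radius 10 voxels in a 24³ grid. Eight networks are
sums of two Gaussian blobs (8 mm FWHM) centred on a 7.5-voxel shell whose
16 directions come from spherical repulsion, giving a minimum
centre-to-centre distance of 5.4 voxels. That separation is deliberate:
with closer packing, 8 mm smoothing merges neighbouring blobs, and ICA's
spatial-independence objective then rotates the estimated maps away from
the planted ones by a fixed amount, which propagates into deterministic
(negative) cross-talk between dual-regression time courses.

Per-subject time courses are white Gaussian noise band-limited to
0.01–0.1 Hz by the same zero-phase Butterworth family the analysis uses,
generated on a 1 s grid, coupled, then decimated to the TR grid and
standardized. A coupling (i → j, ρ, δ) sets
tc_j(t) = ρ tc_i(t − δ) + sqrt(1 − ρ²) · independent band-limited noise,
with δ a circular shift on the same 1 s grid the analysis interpolates to,
so planted and recovered lags share one convention. Because each target is
defined once, coupling graphs must be forests (each network has at most
one parent; validated). Couplings are applied parents-first, so a chain
implies correlations equal to the product of strengths along the path —
the implied edges are part of the planted truth, not an artifact.

The default coupling graph is a tree rooted in the
integration/modulation subsystem: intra-system couplings at ρ = 0.7 with
lags of 1–2 s, plus two inter-system couplings at ρ = 0.5 (lags 2 and
3 s). Patient-like groups sever inter-system couplings only (one for the
smaller group, both for the larger) and carry attenuated voxel loadings
(0.8 and 0.7 respectively) on all networks — reduced within-network
connectivity with losses confined to inter-system edges, which is exactly
the phenotype the pipeline is meant to detect. Voxel noise is i.i.d.
Gaussian with sd 1 (SNR ≈ 1 at blob centres for controls, before
smoothing); a constant baseline of 100 keeps intensities positive and is
removed by detrending. Ages are uniform on [8, 35] years and drive only
the age-correlation check. Identical seeds yield bit-identical cohorts.

What the generator does *not* emulate — hemodynamic convolution,
physiological noise spectra, subject-specific anatomy or map variability,
motion (beyond optional parameter tables for testing the exclusion rule),
registration error — bounds what green tests prove: they validate the
estimators against their own assumptions, not robustness to the full
messiness of real BOLD data. In particular, per-subject spatial maps here
are identical up to loading scale, so between-subject variance in the
voxelwise tests is purely noise-driven and smaller than in real cohorts.

## Numerical choices and degenerate inputs

Eigenvalues are floored at machine epsilon before logs; whitening asserts
covariance = identity within 1e−6. Flat voxels (sd < 1e−10) are zeroed and
flagged rather than producing NaNs; |r| = 1 is clipped at 1 − 1e−12 before
Fisher z. The periodogram excludes DC. Ties in the lag scan are resolved
deterministically (above). `fwhm_mm = 0` smoothing and `n = 0` volume
discarding are exact identities. All stochastic stages take explicit
seeds, restored on exit, so pipeline runs are reproducible end to end; the
run directory's manifest records MD5 hashes of every artifact.

## Scale of the validation runs

The test suite exercises the full pipeline on a 10-subject, 60-volume
cohort and the module-level properties at the sizes quoted above; the
acceptance script runs the full 30-subject, 205-volume study plus a second
30-subject group-difference study, completing in about a minute on one
core. Problem sizes were chosen so the whole validation cycle stays
interactive while keeping every estimator in a regime where its
assumptions hold.

## Known limitations

MDL without a smoothness correction is unusable at low voxel-to-timepoint
ratios (hence the fixed-K default). The max-lagged-correlation null is
inflated and the package does not yet calibrate it (a circular-shift
permutation null is the natural extension). ICA identifiability degrades
when planted (or real) networks overlap heavily after smoothing — spatial
independence is then simply false. The subsystem partition is a fixed
mapping supplied by the user; nothing anatomical is inferred. Multiple runs per
subject are supported by `concat_runs()` — temporal concatenation after
per-run detrending, a simple but standard choice — though the simulated
cohorts emit one run per subject.
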