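---
title: "Annotated naturalistic fMRI: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotated naturalistic fMRI: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naturalfmri)
```

# The analysis problem

When subjects watch a film in the scanner, every brain system is driven at
once: speech, music, faces, hands, camera motion and scene cuts overlap
freely.  `naturalfmri` implements the two complementary analyses used to make
such data interpretable:

1. **Model-free group spatial ICA.**  Subject time series are temporally
   concatenated, reduced by PCA, and decomposed into spatially independent
   components.  Because a single ICA run depends on its random
   initialisation, estimation is repeated many times with bootstrap
   resampling, the pooled spatial maps are clustered by absolute spatial
   correlation, and only components reproduced in every run with high
   intra-cluster similarity are trusted.  Components are then screened by
   inter-subject correlation (ISC) of their back-reconstructed time courses
   and by the fit of a stimulus-annotation model.

2. **Model-driven voxel-wise GLM.**  Quantitative annotations of the
   stimulus — acoustic descriptors in 1-s windows, contrast-edge density,
   ordinal motion scores — are convolved with a canonical double-gamma HRF,
   resampled on the TR grid, and fitted to voxel (or component) time courses
   by ordinary least squares.  Significance of the model correlation is
   assessed with circular-shift permutation, which preserves the
   autocorrelation of BOLD noise while destroying stimulus alignment.

The package ships a synthetic-data generator with planted spatial networks
so the whole chain is testable end-to-end against known ground truth.

# Stimulus annotations

**Audio** (`extractAudioFeatures`): per non-overlapping 1-s window the
package computes the zero crossing rate (sign changes per second), RMS
energy, spectral spread (the standard deviation, in Hz, of the
magnitude-spectrum distribution over the non-negative frequency bins), and
spectral entropy.  The spectrum is the magnitude of the real FFT over the
full 1-s window with no taper by default; a Hann taper is available
(`window = "hann"`).  Entropy is normalised by `log(number of bins)` so a
flat spectrum maps to exactly 1; this fixes the otherwise arbitrary scale.
Entropy is undefined in silence, so silent windows (RMS below `1e-6` of the
track maximum) receive the entropy of the quietest window that still carries
signal, earliest window on ties (`substituteSilence`).

**Contrast edges** (`edgeDensity`): each frame is transformed with an
orthonormal 2-D DCT; coefficients whose radial frequency
$\sqrt{\omega_x^2+\omega_y^2}$ (with $\omega = \pi k / N$ per axis) falls
below the cutoff (default $2\pi/16$ rad/pixel) are zeroed; the inverse
transform is rectified and averaged over pixels, then over frames within 1-s
windows.  The cutoff is a scalar, which implies an isotropic (radial)
threshold; a separable per-axis mask is available as an option.  The measure
is invariant to adding a constant to every pixel and scales linearly with
contrast.

**Motion** (`scoreMotionManual`, `scoreMotionTracks`): manual scoring sums a
shot-size score (0–2) and a motion-strength score (0–2), except that an
object not in motion scores 0 regardless of its size.  Track-based scoring
maps bounding-box area fractions (breaks 1/10 and 1/6 of the frame) and the
summed instantaneous centroid speed per 1-s window (breaks 15 and 50 px/s)
to the same 0–2 scales, takes per-category maxima of the two measures
independently across objects, and sums them.  The zero-when-still rule is
stated for the manual procedure only; we apply it to track scoring as well
for parity between the two annotation routes, with
`zeroWhenStill = FALSE` to disable.  Instantaneous speed is accumulated
across window boundaries (the displacement from the last frame of the
previous window counts), so a rectangle moving 2 px/frame at 25 fps scores
50 px/s in every steady-state window.

# Design matrices and preprocessing

The HRF is a difference of two gamma densities parameterised by their
*modes*, so the kernel's argmax is exactly `peakDelay` (default 6 s), with an
undershoot peaking at 16 s weighted by 1/6.  The exact double-gamma
parameterisation is a package convention (exposed entirely through
`hrfSpec`); the mode parameterisation was chosen so the documented
six-second lag is literal.  Annotations are convolved at 1 Hz and resampled
on the TR grid by decimation (`resample = "linear"` interpolates instead;
the two differ only for non-integer TR).

Temporal high-pass filtering follows the Gaussian-weighted running-line
convention: at each time point a straight line is fitted to the whole series
with Gaussian weights (SD `sigma`, default 100 s) centred there, the fitted
value subtracted, and the global mean restored.  Two properties worth
knowing: constants and exact straight lines are fixed points, and as
`sigma` grows the filter converges to global OLS line removal.  The filter
is a *smoother*, not a projection, so it is not exactly idempotent — a
second pass removes a little more slow variance; tests pin the fixed-point
and limiting behaviour rather than a false idempotency claim.

`standardizeAndAverage` z-scores every voxel time course per subject and
averages across subjects; zero-variance voxels are set to 0 and flagged.

# Group ICA with stability selection

`groupICA` concatenates the standardised subjects along time, reduces to
`nComponents` dimensions with PCA, and runs a symmetric fixed-point ICA
(tanh contrast, maximising negentropy / minimising mutual information of
the source estimates) `nRuns` times from random orthogonal initialisations.
With `bootstrap = TRUE` each run (after the first) resamples the
concatenated time dimension with replacement; the PCA re-reduction reuses
the precomputed Gram matrix, so a bootstrap run costs one small
eigendecomposition.  A run that fails to converge within `maxIter` is
returned flagged, not dropped silently.

Pooled maps are clustered by average-linkage agglomeration on
$1-|\rho_{\text{spatial}}|$ into `nComponents` clusters.  Per cluster the
*stability index* is the mean pairwise intra-cluster $|\rho|$ (defined as 1
for a singleton, which the all-runs rule filters out anyway), the run count
is the number of distinct runs represented, and the representative map is
the cluster mean after aligning every member's sign to the centrotype (the
member with maximal summed similarity).  `selectStable` keeps components
with stability above 0.9 that appear in every run — the convention used for
the full-scale study at dimensionality 40, where the model order was chosen
by a stability sweep (`stabilitySweep` reproduces that utility).

Spatial maps are stored twice: z-scored for reporting and thresholding, and
on their estimation scale for **back-reconstruction**.  The distinction
matters: a component time course is the spatial-map-weighted average of
voxel time courses, computed by projecting subject data onto the
pseudo-inverse of the map matrix, and the per-map centering that z-scoring
introduces would contaminate that projection with a global-mean term.

# Inference

`fitAnnotationModel` is OLS with intercept; the model correlation `r` is the
Pearson correlation of fitted and observed series, and weights are
normalised so the feature with the largest $|\beta|$ receives weight 1 with
its sign preserved (a negative-dominant model yields $-1$, not a global
flip).  The intercept is always included and never reported among the
weights.  Collinear designs raise an error naming the dependent columns
rather than silently dropping them — with many overlapping annotations this
is a real failure mode that deserves a loud signal.

`circularNull` refits the model to **every** distinct rotation of every
series.  The identity rotation is included: this matches the realization
arithmetic of the full-scale analysis (40 components × 679 volumes = 27,160
realizations) and is conservative, since the observed statistic is always a
member of its own null.  The pooled realizations are summarised into a
100-bin lookup table with probability mass at bin centers and linear
interpolation in between (`thresholdAt`).  Single-annotation nulls use plain
Pearson correlation with rotations in two-step increments (half the
distribution), and per-modality visualization thresholds are the arithmetic
mean of the member thresholds.

ISC (`iscMean`) averages pairwise correlations in Fisher-z space after
clipping just inside $(-1, 1)$; dispersion across pairs is reported both as
variance and SD, since published "±" values are ambiguous between the two.
The p-value shifts each subject's series by an independent random rotation
(a circular-shift permutation; a parametric t-test on z-values would also be
defensible, but the permutation makes no normality assumption).  Note the
minimum attainable p is $1/(n_{\text{perm}}+1)$, so screening at
$\alpha = 0.001$ needs at least 2000 permutations — the pipeline default.

**Null population for component screening.**  At full scale the model-fit
threshold comes from rotations of all 40 component time courses.  At desk
scale only a handful of components exist and all of them are
stimulus-locked, so an IC-only null at $\alpha = 0.001$ would place the
threshold at the identity rotations of the very components being screened —
selection would be impossible by construction.  `runPipeline` therefore
builds its screening null from rotations of the standardized-average *voxel*
series (a ~200-series subsample), the same null population used for the
voxel-wise GLM threshold.  The IC-null route remains available through
`circularNull` applied to component time courses.

`selectComponents` keeps a component when (a) its ISC permutation p-value is
below $\alpha$, (b) its auditory or visual model correlation exceeds that
model's `thresholdAt(alpha)`, and (c) it passed the stability criteria.
Separate thresholds per model account for the different overfitting of
models with different regressor counts.

# Networks

`labelClusters` labels connected components of a binary mask under
18-connectivity (face- and edge-adjacent neighbours; vertex-only contact
does not connect) and keeps clusters **strictly larger** than
`minClusterSize` (default 125 voxels, so a solid 5×5×5 cube is discarded).
The IC-map binarisation rule (default $|z| \ge 3$) is a package convention —
no standard exists for thresholding IC maps for overlap displays — and is
fully configurable in `thresholdMap`.

`roiConnectivityThreshold` implements the max-correlation permutation: each
permutation picks a seed ROI uniformly, rotates its time course by at least
`minShift` samples (default 5), and records the maximum signed correlation
with all other ROIs (`absolute = TRUE` switches to $|r|$).  All
(seed, shift) values are precomputed by FFT cross-correlation, so the
full-scale permutation count (10^7) is reachable; the desk default is 10^5
and the Monte-Carlo SE of the tail probability is reported.  Snapshot maps
threshold the across-subject mean of standardised signals at one time point
at $z_{1-p}/\sqrt{n}$ (one-sided by default, as activation displays are;
`twoSided = TRUE` halves p and uses $|mean|$).

# The synthetic generator

`synthConfig` defaults describe a desk-scale study: 5 subjects, 300 volumes
at TR 2 s, 2000 mask voxels, 4 planted networks.  The full study geometry
(10 subjects, 689 volumes with the first 10 discarded, i.e. 679 retained) is
reachable through the same arguments and is used where the arithmetic of the
method depends on it (the 27,160-realization check).  Networks are Gaussian
blobs (SD ≈ 1.7 voxels, compact support) on a lattice with enough
separation that pairwise spatial $|\rho| < 0.3$, which keeps ICA recovery
well-posed.  Component time courses are unit-SD linear combinations of the
HRF-convolved auditory regressors plus shared AR(1) "network noise"
(SD 0.25) and per-subject AR(1) perturbations (SD 1, giving planted ISC
near 0.5, between the strongest and weakest published network ISCs); voxel
noise is AR(1) with SD 1 (CNR ≈ 1, a realistic BOLD regime).  All noise
shares one AR(1) coefficient (default $\phi = 0.4$): the minimal temporally
autocorrelated model that makes circular-shift nulls non-trivial.  What the
generator does *not* emulate: hemodynamic nonlinearity, head motion,
scanner drift beyond AR(1), spatial noise correlations, and inter-subject
anatomical variability — passing tests say nothing about robustness to
those.

One caution discovered while testing: with *zero* voxel noise, per-voxel
standardisation rescales blob tails to unit variance, which flattens the
spatial profiles and correlates the effective sources; ICA recovery then
degrades even though the data are "cleaner".  Realistic voxel noise avoids
the pathology, and the back-reconstruction projection itself is tested
separately with the true maps.

# Problem sizes used by the tests

The suite runs the ICA recovery check at the generator defaults with 20
bootstrapped runs; threshold calibration builds the null from 150 AR(1)
series of length 679 and evaluates type-I rates on 1000 fresh series; the
end-to-end selection experiment repeats the full pipeline over 20 seeds with
a 6-component, 8-run ICA; cluster labeling is compared against a flood-fill
oracle on 100 random 20³ masks.  These sizes were chosen so each property is
measured with useful statistical resolution while the whole suite stays
comfortably re-runnable on a laptop.

# Known limitations

* The ICA estimator is a fixed-point negentropy maximiser, not Infomax;
  both minimise the same class of objectives and the stability clustering
  is estimator-agnostic, but run-for-run outputs will not match a GIFT
  session.
* Bootstrap resamples the concatenated time dimension; other resampling
  units (within-subject blocks, voxels) are plausible and not implemented.
* The running-line high-pass filter is not idempotent (see above).
* Permutation thresholds interpolate a 100-bin lookup table; extreme tail
  quantiles (beyond ~1/realizations) saturate at the sample extremes.
* `labelClusters` supports only the 18-connectivity criterion.
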