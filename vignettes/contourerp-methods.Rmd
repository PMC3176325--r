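---
title: "Models and methods behind contourerp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind contourerp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`contourerp` implements the computational chain of a 2×2 within-subject
contour-integration EEG experiment: synthesis of the Gabor-array
stimuli under quantitative homogeneity constraints, constrained trial
sequencing, a synthetic multi-subject EEG generator with known ground
truth, the offline preprocessing chain, a spatiotemporal cluster-based
permutation test, and component-level repeated-measures inference. This
vignette explains the models, the parameters that matter, the numerical
choices, and what the synthetic-data tests do and do not establish.

## Stimulus model

**Shape outlines.** A radial-frequency (RF) shape is the closed polar
curve r(θ) = R₀ + Σᵢ aᵢ sin(fᵢ θ + φᵢ) with five components. The
frequencies fᵢ are drawn without replacement from the integers 2–8 and
the phases uniformly — the classic recipe for smooth, blob-like,
non-symmetric outlines. Amplitudes are uniform on [0, 0.35 R₀]; the
bound is a design choice that keeps r(θ) > 0 (a positive single-valued
radius guarantees a simple curve) while producing marked deviations
from circularity. Outlines violating r > 0 are rejected and resampled.
The boundary is stored as a 4096-vertex polyline; arc length is
cumulative chord length, which at this density reproduces arc-length
spacing far inside the 1% tolerance the sampler promises.

**Rescaling.** The enclosed area is set to ⅛ of the 496² px array
(“array size” read as pixel area: the stimulus is defined on a 496 px
raster) and the *center of mass of the enclosed lamina* — the polygon
centroid, not the mean of boundary points — is moved to the array
center. Both operations are exact up to floating point; tests enforce
0.1% on area and 0.5 px on the centroid.

**Viewing geometry.** All conversions assume 496 px = 14° of visual
angle, i.e. 1 arcmin = 496/840 ≈ 0.59 px. Gabor elements are a 4
cycles/° cosine carrier (period ≈ 8.86 px) under an isotropic Gaussian
envelope of SD 4 arcmin ≈ 2.36 px, truncated at ±3 SD, composited
additively on mid-grey (128) in floating point and quantized to 8 bits.
Carrier phase is random per element so that local luminance never cues
the contour; Michelson contrast defaults to 0.9. Both choices are
exposed as arguments.

**Element placement.** The 45 contour elements sit at equal arc-length
spacing with orientations equal to the local tangent (mod 180°).
Interior and exterior elements are placed by dart throwing with a
hard-core center-to-center distance d_min = 24 arcmin (6 envelope SDs ≈
14.2 px): candidates are drawn uniformly, classified by a
point-in-polygon test, and accepted only if they respect d_min against
everything placed so far. A stimulus is accepted only if the mean
5-nearest-neighbour distance (neighbours over *all* elements, focal
elements selected per region) of interior, contour and exterior
elements agrees pairwise within 1 arcmin.

Two structural facts make blind acceptance sampling impractical:
exterior elements near the array border have half-plane neighbourhoods
(inflating their 5-NN distances), and interior elements are crowded by
the 45 contour elements (a large fraction of the interior lies within
one neighbourhood radius of the outline). Under uniform count draws
from the allowed ranges (interior 60–72, exterior 507–542) the 1-arcmin
criterion accepts on the order of 1% of placements. The generator
therefore *adjusts the counts separately for each shape*, which is how
the experimental procedure itself is described: after each rejection
the interior and exterior counts are nudged toward the (fixed) contour
density — fewer elements where the region is locally too dense, more
where too sparse — clamped to the allowed ranges, and the placement is
redrawn with a fresh sub-seed. Shapes whose 45 contour positions
violate d_min (near-circular outlines with short perimeters) or whose
contour density cannot be matched within the count ranges are skipped
in favour of the next seeded shape. Acceptance then takes a handful of
placements (seconds per stimulus), and accepted stimuli satisfy the
criterion under independent all-pairs re-verification.

**Orientations across trials.** Successive no-contour arrays reuse
positions but re-randomize each element's orientation under a minimum
circular change of 25° (period 180°). Rejection sampling per element
makes the accepted orientations uniform on the allowed 130°-wide set.
The shared orientation of iso-oriented arrays is redrawn uniformly per
array (per-array rather than per-block, to avoid adaptation-like
confounds in simulation); this too is an exposed choice.

## Trial sequencing

Sequences are built from motifs of k no-contour trials followed by one
contour trial, all k + 1 sharing a position set. The target stimulus
frequencies (contour 0.28, no-contour 0.61, catch 0.11) fix the mean of
k at 0.61/0.28 ≈ 2.18, which a uniform k on {1..5} (mean 3) cannot
reach; k is therefore drawn with geometrically tilted weights
q^k (q = 0.64), chosen analytically so that E[k] ≈ 2.18. Catch trials
are inserted at uniform positions at rate 0.11/0.89 of the stimulus
count; they are never counted in the ordering constraints. A block
ending on a contour trial is closed with one fresh-position no-contour
trial. The first no-contour trial after every contour trial and all
catch trials carry `exclude_from_analysis`. Blocks default to ~270
trials (about five minutes at 106 ms stimulus + 1000 ms mean ISI);
block order follows the six distinct arrangements of two iso and two
random blocks, rotated by participant index.

## Synthetic EEG generator

The generator exists so that every analysis stage has a ground truth.
One epoch is

  ERP(cell) + spatially correlated 1/f noise (+ blink) (+ artifact),

where the ERP is the sum of three Gaussian-in-time components (P1:
100 ms / SD 12 ms / +3 µV; N1: 149 ms / 18 ms / −6 µV; P2: 220 ms /
25 ms / +4 µV at baseline) sharing a posterior-peaked spatial profile
(Gaussian on the projected layout, maximum on the 15-channel posterior
ROI). Cell effects are additive amplitude/latency deltas per design
term; the defaults reproduce the qualitative pattern this paradigm is
known for — N1 13 ms later (149→162 ms) and ~2.5 µV more negative with
a contour, a contour×context interaction that shrinks the contour
effect under random context, a P1 amplitude effect of context, and a
smaller, 9 ms later (220→229 ms) P2 with a contour. These are
*emulation settings for recovery testing*, not estimates of any
recorded data.

Noise is pink (1/f power) per channel, spatially mixed by one graph
diffusion step I + P/2 (P the row-normalized adjacency; the spectrum of
this operator lies in [½, 3⁄2], keeping the spatial covariance full
rank so whitening is well-posed), scaled to 8 µV RMS by default.
Between-subject variability jitters component amplitudes (SD 0.5 µV)
and latencies (SD 4 ms); all jitter is drawn up front so the cohort
ground truth depends only on the seed, not on noise settings. Blinks
are 300 ms half-sine transients with a frontal topography (written
largest to VEOG) at 4/min in continuous mode; artifact epochs receive
±150 µV square transients and are recorded in the ground-truth table.

What the generator does **not** emulate: realistic head geometry or
volume conduction (the topography is a schematic Gaussian), line noise,
muscle or channel-pop artifacts, autocorrelated single-trial latency
jitter, or overlap of responses from consecutive trials beyond what the
ISI produces. Passing tests therefore demonstrate the *pipeline's*
correctness and operating characteristics under a plausible noise
model, not performance on real recordings.

## Preprocessing chain

Fixed order: mastoid re-reference → 30 Hz lowpass → SOBI blink removal
→ epoching/baseline → ±100 µV rejection → (equalization) → robust
averaging.

* The lowpass is a 4th-order Butterworth run forward–backward
  (zero-phase, −3 dB at 30 Hz) — the standard offline choice. Its
  passband response is part of the chain's definition; the noiseless
  validation test compares against a filtered template and separately
  asserts that peak latencies are preserved to ±1 ms.
* SOBI whitens via the covariance eigendecomposition and jointly
  diagonalizes lagged covariances (lags 1–100 ms, 15 log-spaced steps —
  covering blink autocorrelation timescales) with Jacobi pairwise
  rotations; the off-diagonal objective is non-increasing over sweeps
  and the rotation tolerance is 1e−6. Components whose time course
  correlates with VEOG above 0.6 (at most 2, in decreasing correlation
  order) are zeroed before back-projection; blink-free data pass
  through with a warning and no change. Noiseless (rank-deficient)
  validation runs skip SOBI via the pipeline's `sobi = FALSE` switch.
* Epochs are 800 samples at 1000 Hz (−200…599 ms); the mean over the
  200 ms pre-stimulus window is subtracted per epoch and channel.
  Events too close to the recording edge are skipped and counted.
* Rejection drops epochs whose scalp channels *strictly* exceed
  ±100 µV ("exceeding" read literally, so a 100.0 µV peak survives);
  ocular channels are not scanned because blink handling belongs to
  SOBI.
* Robust averaging is bisquare IRLS across trials per channel × sample
  (tuning constant 4.685, at most 10 iterations). The robust scale is a
  MAD-type estimate about zero pooled per channel (over trials and
  samples) rather than per sample: per-sample MADs over a dozen trials
  are too unstable to be useful, while the per-channel scale keeps the
  weight function well calibrated and makes the estimator cheap enough
  to run per cell. Degenerate cases (zero residual spread) fall back to
  unit weights.
* Equalization trims every subject × condition cell to the global
  minimum count by seeded random removal. Peak-latency measures are
  computed on the equalized set (peak estimates are biased by unequal
  trial counts); mean amplitudes use the full artifact-free set.

## Cluster-based permutation test

First-level statistic: paired t across subjects at every channel ×
time point (zero-variance points get t = 0 with a warning).
Cluster-forming threshold: the two-sided 5% t quantile at n − 1 df.
Clustering links supra-threshold points of equal polarity that share a
time sample and neighbouring channels, or a channel and consecutive
samples — no diagonal steps. Channel neighbourhoods come from the
schematic 2-D layout: pairs within 0.26 projected units, augmented so
every channel keeps at least its two nearest neighbours (otherwise the
outlying inion electrode would be isolated); every channel ends up with
2–8 neighbours.

The null distribution of the maximum cluster mass (per polarity) is
built by per-subject sign flips of the difference waves: all 2ⁿ
patterns when 2ⁿ ≤ `n_perm` (exactly 4096 at n = 12, making the test
deterministic), Monte Carlo otherwise (+1 smoothing keeps p > 0; the
exact branch needs no smoothing because the identity pattern is
enumerated). Because each polarity is tested against its own null, a
cluster is declared significant at p ≤ α/2 — the standard two-tailed
correction — which the type-I simulation confirms calibrates the
familywise rate at α. The permutation inner loop (t maps via one matrix
product using the sign-flip invariance of Σd², connected components in
C++) keeps 4096 enumerations over 64 channels × hundreds of samples in
the seconds range.

## Component measures and ANOVA

Measures are computed on the ROI-averaged waveform (15 posterior
channels). Mean amplitude is the time average inside the component
window (P1 60–140, N1 120–220, P2 180–280 ms); peak latency is the
signed extremum matching the component's polarity — the N1 "largest
peak" is read as the most negative value, resolving the polarity
ambiguity of peak-picking — with ties broken by the earliest sample.

The 2×2 ANOVA fits a linear model with fixed per-subject intercepts and
sum-coded contour, context and interaction terms, and tests each 1-df
effect with a Wald F using the subject-clustered sandwich (CR1)
covariance; the denominator df convention is n_obs − n_subjects − 3
(33 for 12 subjects × 4 cells). This fixed-intercept + clustered-
sandwich formulation reproduces the random-intercept model's tests in a
balanced design without a REML fit; the classical balanced RM-ANOVA F
(each effect against its subject×effect stratum, df 1 and n − 1) is
reported alongside as a cross-check and is verified in tests against a
hand-computed sums-of-squares oracle.

## Problem sizes used by the test suite

Simulation-backed tests run at sizes chosen to make their statistical
assertions sharp while keeping the suite lightweight: the type-I
calibration uses 200 null cohorts of 12 subjects over 64 channels × 30
samples; effect recovery uses 100 cohorts on a 5 ms grid with a
1.2-SD effect on the posterior ROI at 145–250 ms; subject-level latency
recovery uses 99 trials per cell (the study-scale regime) at 1000 Hz
and cohort-level checks use 2 ms resolution. The synthetic-data
defaults themselves (noise RMS, effect sizes, trial frequencies,
layout) are never varied by tests.

## Known limitations

* The schematic layout is generated from ring geometry, not digitized
  electrode positions; adjacency and topographies are realistic in
  structure but not anatomically exact.
* SOBI assumes stationary sources with distinct lagged autocorrelation;
  it is validated for blink removal, not for general artifact
  decomposition.
* The sandwich ANOVA treats subjects as fixed intercepts; variance
  components themselves are not estimated.
* Continuous data live in memory as plain matrices; there is no EDF
  reader/writer, and event tables travel as data frames / CSV.
* The density-homogenization loop assumes the printed count ranges can
  bracket the contour density of the sampled shape; shapes where they
  cannot are skipped rather than force-fitted.
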