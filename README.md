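# contourerp

Stimulus synthesis and ERP analysis for contour-integration experiments
with Gabor arrays.

In the *snake detection* paradigm, observers view arrays of Gabor
elements in which a subset of elements is aligned along a closed shape
outline. Binding those locally aligned elements into a global contour —
contour integration — leaves a measurable electrophysiological
signature: the posterior N1 peaks later and larger, and the P2 smaller
and later, when a contour is present, and the orientation structure of
the surrounding elements (all iso-oriented vs independently random)
modulates these effects. `contourerp` implements the full computational
chain for a 2×2 (contour presence × context type) within-subject version
of this experiment:

* **Stimulus synthesis.** Closed radial-frequency (RF) shape outlines
  r(θ) = R₀ + Σᵢ aᵢ sin(fᵢθ + φᵢ), rescaled to ⅛ of the 496×496 px
  array area and centered by their center of mass; 45 Gabor elements at
  equal arc-length spacing along the outline; dart-throwing placement of
  interior (60–72) and exterior (507–542) elements with a hard-core
  minimum separation; acceptance of a stimulus only when the mean
  5-nearest-neighbour distances of interior, contour and exterior
  elements agree within 1 arcmin; condition-specific orientation
  assignment (contour elements tangent-parallel; surround iso or
  random); re-randomization of successive no-contour arrays by ≥ 25°
  per element; rendering as 4 cpd Gabors (Gaussian SD 4 arcmin) on
  mid-grey, with optional catch-trial circles.
* **Trial sequencing.** Four blocks (2 iso, 2 random context,
  counterbalanced) with contour / no-contour / catch frequencies
  0.28 / 0.61 / 0.11, every contour trial preceded by 1–5
  position-matched no-contour trials and followed by a fresh-position
  no-contour trial (excluded from analysis), ISIs uniform on
  800–1200 ms.
* **Synthetic EEG.** 64-channel 10-5 layout at 1000 Hz with a known
  ground-truth P1/N1/P2 template (posterior topography), cell-specific
  amplitude/latency effects, spatially correlated 1/f noise, eye
  blinks, and gross-amplitude artifact epochs — so every analysis stage
  is testable without real recordings.
* **Preprocessing.** Mastoid re-reference → 30 Hz zero-phase lowpass →
  SOBI (second-order blind source identification: whitening + joint
  diagonalization of lagged covariances) blink removal → 800 ms epochs
  (−200…599 ms) with baseline correction → ±100 µV rejection → robust
  (bisquare IRLS) averaging → optional trial-count equalization.
* **Inference.** Spatiotemporal cluster-based permutation test (paired
  t maps, adjacency clustering, sign-flip null with exact enumeration
  of all 2¹² patterns for n = 12); P1 (60–140 ms), N1 (120–220 ms), P2
  (180–280 ms) mean amplitudes and peak latencies on the 15-channel
  posterior ROI; 2×2 repeated-measures ANOVA with a subject-clustered
  sandwich covariance (Wald F on 1 and 33 df for 12 subjects) plus a
  classical RM-ANOVA cross-check.

## Worked example

Generate one accepted stimulus and inspect its density report:

```r
library(contourerp)

stim <- generate_stimulus(1)
stim$report
#> # A tibble: 1 × 5
#>   interior contour exterior max_pairwise_diff accepted
#>      <dbl>   <dbl>    <dbl>             <dbl> <lgl>
#> 1     34.3    34.9     35.2             0.887 TRUE
```

Interior, contour and exterior elements have mean 5-nearest-neighbour
distances of 34.3, 34.9 and 35.2 arcmin: the largest pairwise gap
(0.887 arcmin) is below the 1-arcmin homogeneity criterion, so no
region is detectably denser than another. Render the four array types
with `assign_orientations()` + `render_array()` (and `autoplot()` or
`write_array_png()` to look at them).

Simulate a 12-subject cohort, preprocess, and run the group analysis
(2 ms resolution keeps the example light; the simulator runs at
1000 Hz by default):

```r
library(dplyr)
L  <- make_layout()
tm <- seq(-200, 598, by = 2)
erps_list <- lapply(1:12, function(s) {
  ep <- simulate_subject(L, n_trials = 20, noise_rms = 8, seed = 100 + s,
                         subject = s, time = tm, fs = 500)
  robust_average(reject_artifacts(ep))
})
erps <- erp_set(do.call(contourerp:::abind1, lapply(erps_list, `[[`, "data")),
                erps_list[[1]]$channels, tm, 500,
                bind_rows(lapply(erps_list, `[[`, "meta")))

grp <- condition_arrays(erps)        # contour vs no-contour, pooled context
res <- permutation_test(grp$a, grp$b, L)
tidy(res) |> filter(significant)
#> # A tibble: 2 × 9
#>   cluster polarity   mass n_points n_channels time_min time_max        p significant
#> 1       1 negative -3278       713         32      177      219 0.000244 TRUE
#> 2       2 positive   436.      139         25      160      174 0.0208   TRUE
```

The dominant negative cluster spans posterior channels around
150–240 ms — displays with an embedded contour drive a stronger
posterior negativity in that window, which is exactly the structure the
synthetic generator injects (N1 later/larger, P2 smaller with contour).
Component-level inference on the posterior ROI:

```r
m <- erp_measures(erps, erps, L)
rm_anova_sandwich(m) |> tidy() |> filter(component == "N1")
#>   measure        term              F        p
#> 1 mean amplitude contour     140     1.96e-13
#> 2 mean amplitude context      18.8   1.29e- 4
#> 3 mean amplitude interaction   1.89  1.78e- 1
#> 4 peak latency   contour      38.7   5.05e- 7
#> 5 peak latency   context       0.352 5.57e- 1
#> 6 peak latency   interaction   0.561 4.59e- 1
```

F statistics are Wald tests on 1 and 33 degrees of freedom with a
subject-clustered sandwich covariance: the injected contour effects on
N1 amplitude and latency and the context effect on amplitude are
recovered; whether the (smaller) injected interaction reaches
significance depends on the noise draw, as expected at this SNR.

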