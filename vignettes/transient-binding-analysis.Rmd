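---
title: "Models and methods: super-resolution analysis of transient amyloid binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: super-resolution analysis of transient amyloid binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tabsr)
```

# The measurement

A fluorogenic dye (e.g. Nile blue) is dark in solution and bright while
transiently bound to an amyloid surface. A camera watching fibrils in such
a dye bath therefore records, per pixel, a stationary stream of intensity
bursts whose spatial statistics encode structure below the diffraction
limit and whose temporal statistics encode the binding kinetics. `tabsr`
analyzes these movies in three complementary ways — single-molecule
localization (PAINT), second-order fluctuation imaging (SOFI) and
pixel-wise fluorescence correlation spectroscopy (iFCS) — and ships a
simulator that generates movies with known ground truth so each analysis
can be checked quantitatively.

Two acquisition regimes are built into the defaults:

| regime      | frame time | pixel | length | purpose |
|-------------|-----------|-------|--------|---------|
| PAINT/SOFI  | 30 ms     | 92 nm | 10,000 frames | isolated single molecules |
| iFCS/SOFI   | 2.5 ms    | 46 nm | 36,000 frames (six 15 s segments) | fast fluctuation statistics |

# The simulator

**Geometry.** Fibril backbones are worm-like chains: fixed 25 nm steps
with Gaussian heading increments of variance `step/persistence`
(persistence 2000 nm by default, giving the nearly straight filaments
seen extending from cell bodies). Binding sites are a Poisson process
along the backbone with density 0.2 sites/nm by default — amyloid
surfaces present binding sites at nanometer spacing, and a micromolar dye
bath visits them densely.

**Kinetics.** Per site, arrivals are Poisson (default 2 events/s/site in
the iFCS regime, 0.03 in the single-molecule PAINT regime — the nM vs µM
dye concentrations of the two experiments). Each event draws its dwell
from a two-component exponential mixture, defaults τ_fast = 23 ms and
τ_slow = 482 ms. The event probability of the fast mode defaults to
`f_fast = 0.95`: because slow events last ~20× longer, this makes the
*bound population* split its residence time roughly evenly between the
modes (dwell-weighted fast fraction ≈ 0.5), which is the regime in which
both relaxation times are visible in the ACF and fitted weight fractions
are comparable. Arrivals are generated from five slow dwells *before*
frame 1 (burn-in), so occupancy is stationary from the first frame; without
this the localization rate ramps up detectably over the first ~τ_slow.

**Optics and camera.** Each bound molecule contributes an
error-function-integrated 2-D Gaussian PSF (σ = 130 nm default) — point
sampling would be wrong at 46–92 nm pixels — scaled by its per-event
brightness and by its fractional temporal overlap with each frame.
Brightness is log-normal with mean 690 photons/frame (at 30 ms; 57.5 at
2.5 ms) and CV 0.55, reproducing a 690 ± 380 spread. Poisson shot noise is
applied to signal + uniform background, then optional Gaussian read noise,
then clamping at zero. Unbound dye contributes only to the uniform
background: the fluorogenic contrast is treated as complete. The simulator
does not model defocus/3-D PSFs, photobleaching, or cellular
autofluorescence microstructure; fast photophysical blinking is not
distinguished from fast binding — both are absorbed in the fast dwell
component. Passing tests therefore demonstrate correctness of the
estimators on ideal two-mode binding data, not robustness to those
real-data effects.

The theoretical ACF of this generator (Poisson arrivals, mixture dwells —
an M/G/∞ occupancy process) is the *additive* two-exponential curve

```
G(τ) = G0 [ w_f e^{−τ/τ_f} + w_s e^{−τ/τ_s} ] + G∞ ,
w_f = f τ_f / (f τ_f + (1−f) τ_s),  G0 = 1 / ⟨occupancy⟩,
```

returned by `expected_acf()`. On well-separated timescales the fitted
product model (below) reduces to this form, so relaxation-time recovery is
unaffected by the difference.

# PAINT

Detection follows the standard LoG pipeline: a separable
Laplacian-of-Gaussian filter (σ = 1.5 px; second-derivative kernel
discretely zero-sum, so constant frames give exactly zero response),
per-frame threshold at 3 standard deviations of the filtered frame
(computed on all pixels, signal included — a deliberate fidelity choice
that mildly inflates the threshold in dense frames), 8-connected local
maxima, and deduplication within 2 filter sigmas keeping the brighter
candidate. Subpixel positions come from Levenberg–Marquardt least squares
of an integrated 2-D Gaussian (amplitude, x, y, σ, offset) on a window of
side `2⌈3σ_psf⌉+1` (σ_psf default 1.3 px; the window size is our choice —
standard practice rather than a published value). Localization on
noise-free renders is exact to ≪1 nm; with 690 photons over a 2
photon/pixel background the Monte-Carlo RMSE sits within 50% of the
pixelation- and background-corrected photon-limited bound.

Reconstructions are 5 nm 2-D histograms convolved with a unit-mass σ =
25 nm Gaussian kernel, so image mass equals the localization count up to
edge truncation.

On-times are measured by greedy nearest-neighbor linking between
consecutive frames within one pixel (92 nm), with *no* gap closing —
deliberately reproducing the linking interruptions that overlap and
blinking cause in real data. Run-length histograms are fitted by weighted
least squares (`weights 1/max(count, 1)`) with one or two exponential
terms `A e^{−kΔt/τ}`; the `k = 1` bin is included by default and can be
excluded by flag, since single-frame detections mix sub-frame events. The
companion sampler `sample_on_frame_counts()` defaults to frame-aligned
events (`k = ⌈dwell/Δt⌉`), which makes each component exactly geometric
and hence consistent with the exponential fitting model; the
`phase = "uniform"` option shows how a random arrival phase depresses the
`k = 1` bin relative to that law.

# SOFI

`second_order_cumulant()` computes `C2(τ) = Σ_t ΔI(t)ΔI(t+τ) / (n−τ)`
with the per-pixel temporal mean subtracted. The `1/(n−τ)` normalization
(FCS-style, per summed product) is what makes `C2` *exactly* the
numerator of the iFCS autocorrelation — the two modules share this
computation, and a test asserts the identity to machine precision.

For 30 ms acquisitions only the first nonzero lag is used (the fast
component decays within a frame); for 2.5 ms acquisitions cumulants are
summed for `0 < τ ≤ τ_max` with `τ_max` the ~50% decay point of the
SNR-gated mean ACF over the field of view (which pixels define the 50%
point is our declared convention). The reference amplitude for the decay
rule is the value at the first supplied lag: analytic curves supplied from
lag 0 give `τ_max = ⌈τ_d ln 2⌉`; empirical curves are supplied from lag 1
because the lag-0 value carries the shot-noise variance. Negative cumulant
values are estimator noise: they are kept in the raw output and clamped at
zero only for display, since clamping before the lag sum would bias it.
Lags enter the sum with unit weights. No cross-correlation (XC-SOFI) and
no cumulants above order 2 are computed.

For a single blinking emitter the cumulant image is the squared PSF, so
the fitted sigma shrinks by √2. Measured on the standard telegraph
scenario the enhancement factor is ≈1.45 rather than 1.414: both images
are fitted with the *pixel-integrated* Gaussian model, whose `a²/12`
pixelation term enters the temporal average once but the squared-PSF
image differently. The acceptance band (±0.1) covers this.

# iFCS

Per segment, `G(τ) = C2(τ)/⟨I⟩²` is computed at all lags of a
quasi-logarithmic grid (16 points/decade up to a third of the segment
length) by zero-padded FFT — contractually identical to direct summation
to better than 1e-10 relative, and tested against it. Zero-mean pixels are
flagged `NA`, never zero-filled. Six segments give a per-lag mean and SEM.

**SNR gate.** ACF amplitude is taken as the mean of the first three
nonzero lags of the averaged curve (a pre-fit surrogate for G0 — gating
must precede fitting), divided by the SD of the last five lags. Pixels
with SNR ≤ 10 (strict inequality for inclusion) are excluded from maps.

**Fitting.** Weighted least squares (weights `1/SEM²`, SEM floored at
`1e-6 max|G|`) of the product-form two-component binding model; the
one-component model is its `f_f = 1, f_s = 0` reduction. Initialization:
G0 from the early-lag amplitude, relaxation times from the 70%/30%
crossings, weights 0.5, offset from the tail; relaxation times are bounded
to [frame time, segment duration] and relabeled fast ≤ slow after the
fit. Restarts use fixed relaxation-time rescalings (×0.3/×3, ×3/×0.3,
×0.1/×10) rather than random jitter, so identical inputs reproduce
identical fits. The reported "fraction associated with the shorter
relaxation time" is `f_f/(f_f + f_s)` — a declared convention, since the
product form does not normalize the weights.

Two numerical facts about this model are worth knowing:

* **Offset degeneracy.** With a free offset G∞, a ≈1% shift of τ_fast can
  trade amplitude between the weights and the offset while changing the
  curve by ~1e-15 — the parameters are *practically* non-identifiable
  along that direction even though they are formally unique. The
  self-consistency test therefore pins the offset
  (`fit_acf(..., g_inf_fixed = 0)`) on fully decaying synthetic curves,
  where recovery is then exact to machine precision. Experimental fits
  keep G∞ free; their τ estimates are unaffected, but the individual
  weights inherit this softness.
* **Reduced χ² with 6-segment SEMs.** When the weights come from an SEM
  estimated on n = 6 segments, the per-lag normalized residual of a
  *correct* model is t(5)-distributed, whose squared median is ≈0.53 —
  so the two-component model's median reduced χ² sits near 0.5, not 1.
  Model comparison is therefore done on the χ² *ratio*: on the standard
  scenario the one-component model misfits by a median factor ≈5.

On the full 36,000-frame scenario (64 × 64 px, 46 nm, 2.5 ms, six 15 s
segments), the spatial medians over SNR-gated pixels recover τ_fast and
τ_slow with median absolute relative errors ≈0.15 and ≈0.19; the residual
bias is *downward* for τ_slow, dominated by finite-segment-length mean
subtraction (τ_slow/T ≈ 0.03 per segment). In a photon-poor region
(~2 photons/frame per molecule) the fitted relaxation times become
systematically low — the known artifact of least-squares ACF fitting with
noisy normalization — and the suite demonstrates it with a sign test at
α = 0.05 on pixels gated at SNR > 1.5, where such dim pixels live.

# FRC

Localizations (not frames) are split independently with probability 1/2;
each half is histogrammed at 5 nm *without* kernel smoothing (smoothing
would bias the spectrum), and

```
FRC(r_i) = Re Σ_{r∈ring_i} F1(r) F2*(r) / sqrt(Σ|F1|² Σ|F2|²)
```

is computed on rings one Fourier pixel wide up to Nyquist (taking the
real part is the standard convention; no DC exclusion beyond the r = 0
ring). The resolution is the inverse of the first crossing below 1/7,
located by linear interpolation between the neighboring rings. Because
one binding event yields repeated localizations that land in both halves,
the estimator inherits uncorrected spurious correlations — as in standard
practice — and so reads optimistically on slow-binding data; the
subsampling monotonicity test shows the expected degradation as
localizations are removed.

# Problem sizes and reproducibility

The test suite exercises full-scale problems where the estimator's
statistics require it (36,000-frame iFCS recovery; 50,000-event on-time
fits) and scaled-down movies elsewhere; the methods are size-agnostic.
All randomness flows from one master seed through deterministic,
purpose-tagged sub-streams (geometry, kinetics, brightness, per-segment
noise), so a pipeline run is bit-reproducible from its config + seed —
`run_pipeline()` writes a manifest and `validate_run()` re-checks the
artifacts. Note that rendering a movie segment-by-segment is reproducible
per segment but is not element-wise identical to rendering the full range
in one call (the noise sub-streams are tagged by frame range).

# Known limitations

* Single-emitter fitting only: overlapping emitters are deduplicated to
  the brighter candidate, not multi-fitted, so dense regions are
  under-sampled exactly as in conventional PAINT practice.
* No drift correction (appropriate for short, pad-mounted acquisitions).
* The FRC estimate carries uncorrected repeated-event correlations.
* The ACF weight fractions are soft against the offset (see above);
  relaxation times are the robust read-out.
* Fast photophysical blinking and fast binding are indistinguishable by
  construction, in the simulator as in the measurement.
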