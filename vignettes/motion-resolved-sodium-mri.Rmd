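---
title: "Self-gated motion-resolved radial MRI: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-gated motion-resolved radial MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sodiumgate)
```

Abdominal sodium (²³Na) MRI at ultra-high field acquires for tens of
minutes under free breathing, so respiratory motion blurs exactly the
structures — such as the renal corticomedullary sodium gradient — the
measurement is after. `sodiumgate` implements the full retrospective
self-gating chain for 3D center-out radial ("koosh-ball") acquisitions:
the repeatedly sampled k-space center provides a respiratory surrogate,
excitations are binned by surrogate amplitude, and each motion state is
reconstructed separately. This vignette explains the models behind each
stage, the tunable parameters and their defaults, and the design choices
made where the problem left real freedom.

## Trajectory

Spoke directions follow the two-dimensional golden means: with φ₂ the
real root of x³ + x = 1 (≈ 0.6823) and φ₁ = φ₂² (≈ 0.4656), projection
*i* has cos θ = 2·frac(i φ₁) − 1 and azimuth 2π·frac(i φ₂). The sequence
is deterministic and prefix-stable, so any temporal subset of spokes —
which is what motion binning creates — covers the sphere quasi-uniformly.
Spokes are generated (and assumed acquired) in natural golden-means
order; a reshuffled order would break the temporal uniformity the
self-gating analysis relies on.

`k_max` is fixed at the Nyquist limit of the nominal resolution
(0.5/voxel), with `n_readout = fov/(2·resolution) + 1` center-out samples
at spacing 1/FOV. Density compensation uses the 3D radial shell rule
(weight ∝ r²). Two details matter at the center:

* the r = 0 sample is kept (it carries the gating information) with the
  r² weight of half the first radial spacing, and
* that floor is divided by the number of projections, because every spoke
  re-samples the same k = 0 point; without the division the center cell
  is over-counted by the spoke count and the adjoint image acquires a
  strong uniform haze (we observed a background at ~40 % of the object
  peak before making this correction).

`apodize_weights()` optionally multiplies the weights with a radial
Hamming window — the usual practice in low-SNR X-nuclei imaging — trading
main-lobe width for strongly reduced truncation/undersampling ringing.

## Motion-phantom generator

The synthetic-data module emulates a programmable motion phantom: a
static oval body (tissue-mimicking saline, ~159 mM sodium equivalent), a
static cylindrical insert of the same solution, and a motor-driven
cylindrical insert containing a 4 %-agar "kidney" cylinder (175 mM,
radius 22 mm, length 80 mm) surrounded by deionized water, all inside a
320 mm FOV. The moving insert translates rigidly along z. Signal
amplitudes are per-compartment scalars — concentration-proportional for
sodium, water-content-proportional for protons; relaxation weighting is
not simulated dynamically because no downstream analysis uses it.

Rasterization is anti-aliased: voxels straddling a compartment face get
the fractional 1D overlap along z and a linear radial coverage ramp.
This matters for gating: with binary voxels the k-space-center signal
would change in staircase steps as the insert moves, whereas the
partial-volume raster makes it vary smoothly with sub-voxel displacement.
The forward model quantizes displacement to 0.25 mm (≪ the 15 mm stroke)
and caches one rasterization + FFT per unique level; readout samples are
interpolated from the oversampled Cartesian spectrum with the same
Kaiser-Bessel machinery used in reconstruction, and an exact
discrete-Fourier-sum oracle backs both directions on ≤ 16³ test grids.

The coil model places four anterior and four posterior Gaussian-profile
loop elements (σ = 70 mm, plus a 2 % magnitude floor so the
root-sum-of-squares never vanishes) around the body, with channel phases
stepping 45° per channel as a ring-splitter feed network does. The
anterior and posterior rows are staggered ±40 mm along z. A perfectly
z-symmetric synthetic array would have a vanishing first-order
k-space-center response to z-translation — an artifact of idealized
geometry that no real, hand-positioned flexible array exhibits — so the
stagger emulates the asymmetric placement that gives every channel a
usable motion response; with it, the best channel's center-signal is
linear in displacement to r ≈ 0.999 over the stroke.

Respiratory waveforms come in three modes: `regular` (raised-cosine
breathing at a set rate), `variable` (slow, seeded depth and rate
modulation of ±15 % while oscillating about the insert's home position,
as a motion stage executing a programmed trace does), and `apnea`
(breathing epochs of 20–40 s separated by 8–20 s pauses with occasional
deep breaths, for severely irregular patterns). The stroke defaults to a
physiologic 15 mm peak-to-peak; the fundamental to 0.25 Hz.

**Noise model.** Complex white Gaussian noise per sample. The
"self-gating-sample SNR" that defines the clean (proton-like, SNR 50)
and noisy (sodium-like, SNR 10) regimes is referenced to the RMS of the
motion-induced modulation of the k-space-center signal (best channel,
static mean removed): the absolute center-signal level depends on the
arbitrary amplitude units and is removed by detrending anyway, so the
modulation-to-noise ratio is the quantity that actually governs gating
fidelity. What the generator does *not* emulate: B₀ inhomogeneity, eddy
currents, biexponential T₂* decay along the readout, structured
(physiological or system) noise, and non-rigid motion. Passing tests
therefore demonstrate the correctness of the pipeline's algorithms under
a controlled forward model, not its robustness to every real-data
artifact; in particular the simulated gating correlations come out near
the top of the range reported for real acquisitions.

## Self-gating

Per channel: (1) average the n_sg k-space-center samples of each
excitation (10 per excitation in the phantom protocols, 6 for in vivo
sodium); (2) project the complex series onto the first principal
component of its (Re, Im) scatter — the PCA sign is arbitrary, so the
score is oriented to correlate positively with the magnitude series,
which makes bin labels reproducible; (3) Gaussian-smooth and subtract a
10 s moving average of the same input; (4) score the result with
Θ = P[0.1–1 Hz]/P[1–10 Hz] from a plain periodogram; (5) keep the
channel with the highest Θ. The Gaussian "window" parameter is read as
total kernel support with σ = window/4, truncated at ±2σ (≥ 95 % of the
kernel mass inside the window); presets are 0.2 s (proton phantom),
0.7 s (sodium phantom) and 1.5 s (in vivo). A constant (dead) channel
yields a zero score and Θ = 0 rather than an error, so it can never be
selected but never aborts the pipeline. The plain periodogram with
rectangular band integration is deliberate: only the Θ *ordering* across
channels matters, not its absolute value.

Binning is amplitude-based and equal-count: excitations are sorted by
gating amplitude and split into 24 quantile bins whose occupancies differ
by at most one (bin 1 = lowest amplitude). Equal-count binning makes a
12-of-24-bin motion state contain exactly half the data, matching the
in vivo protocol statement. Whether the original processing binned by
amplitude or by respiratory phase is not documented; amplitude binning
was adopted as the simpler rule consistent with every stated count.
Sliding windows of w consecutive bins form motion states: all
`24 − w + 1` windows (19 for w = 6), or a finite number with start bins
`round(seq(0, 24 − w, length.out = n_states))` — for six states of width
12 this gives starts {0, 2, 5, 7, 10, 12}, covering both extreme
(end-inspiration/end-expiration) states; the in vivo stride is not
stated, so even coverage including both extremes was chosen.

## Reconstruction

Adjoint (gridding) NUFFT with a Kaiser-Bessel kernel of width 4,
oversampling 1.25, and the Beatty β; deapodization uses the kernel's
analytic transform. Accuracy is enforced against an explicit DFT oracle
(relative L2 < 10⁻² on 16³ problems) rather than against kernel
particulars. Two practical notes: the 1.25× oversampled crop leaves a
ring of aliasing at the extreme FOV border (accuracy tests mask a
3-voxel border, standard for this oversampling), and the interior of a
static 8-channel reconstruction then agrees with the digital object to
~1 %.

Sensitivity maps use a lowpass-ratio estimator: `lowpass(I_c)/RSS`,
Gaussian σ = 1 voxel, with RSS = 1 on the support (voxels above 10 % of
the peak RSS) and zero outside. A full autocalibrating subspace method
would estimate the same unaccelerated combination weights at much higher
cost; for R = 1 combination the estimator affects only phase/shading,
and parameter recovery on simulation shows ~3 % median magnitude error
inside the object. Channel combination is SENSE1 — the unaccelerated
least-squares merge Σ conj(s)·I / Σ|s|² — and motion states reuse the
maps estimated from the all-data reconstruction, which stabilizes states
containing few excitations. Per-state weights are renormalized so state
volumes share one intensity scale.

## Resolution metric

Image sharpness is read from the two faces of the kidney cylinder: the
magnitude signal is averaged over an x–y cylinder ROI per z-slice, each
dark/light transition is fitted with the logistic edge model
S(z) = a/(1 + exp(−(z + z₀)/b)) + c (implemented via `plogis` for
numerical safety at steep edges), and the transition-width parameter b
(mm) is the resolution readout — both faces are fitted and pooled.
Initialization: a from the profile endpoints, c from the starting level,
z₀ at the half-rise crossing, b at 10 % of the span, with b bounded by
the span; non-convergence is flagged, not raised, and flagged fits are
excluded from medians (small motion states genuinely produce outliers,
as the boxplots of the original experiment also show). `b` values are
normalized to the median of the static-acquisition fits, so the static
distribution has median 1 by construction. NRMSE (for validation maps)
normalizes the RMSE by the reference mean.

## Desk-scale study conditions

The packaged studies run at a deliberate desk scale chosen once: 48³
grid over a 320 mm FOV, 20 000 projections at TR 10 ms (200 s of
breathing), 8 channels. The gating-fidelity study
(`run_gating_validation()`) needs only the k-space-center samples and
runs in seconds per seed; the motion-binning study
(`run_phantom_study()`) simulates full readouts, reconstructs sliding
windows at widths {24, 4, 1} (optionally subsampled to 7 windows per
width), applies the Hamming apodization typical of sodium protocols so
the edge readout is blur-dominated rather than ringing-dominated, and
completes in a few minutes. The full-width set {1, 2, 3, 4, 6, 8, 12,
24} is available through the `widths` argument. At this scale the
*absolute* medians of the relative resolution are acquisition-specific
(narrow motion states are far below their Nyquist spoke count, which
biases absolute sharpness); the reproduced findings are the ordering —
unbinned ≫ 4-bin > 1-bin — and the close agreement between
self-gating-based and ground-truth-based binning.

## Degenerate inputs and numerical conventions

All coordinates are physical millimetres, volume-centered, RAS-oriented;
k-space is in cycles/mm. Grids are even-sized with the object center at
index N/2 + 1. Detrending windows longer than the series fall back to
global mean subtraction with a warning; zero high-band power makes Θ
infinite with a warning; SENSE1 zeros (and masks) voxels with vanishing
sensitivity; ties in channel selection resolve to the lowest index.
Every stochastic component (waveform jitter, noise) is seeded
explicitly, and identical seeds reproduce bit-identical raw data.

## Known limitations

The reconstruction is a one-shot adjoint, not an iterative or
compressed-sensing solver, so heavily undersampled single-bin states
show streaking that inflates the spread of edge-fit outliers. The
sensitivity estimator assumes smooth maps and breaks down for arrays
with structured phase inside the object. The safety module implements
the *arithmetic* of SAR limits (thermometry conversion, worst-case
power caps, sinusoidal B₁⁺ calibration); electromagnetic field
simulation, 10 g-averaging over body models, and B₁⁺ mapping sequence
internals are out of scope.
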