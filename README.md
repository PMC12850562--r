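# sodiumgate

Respiratory self-gating and motion-resolved reconstruction for 3D
center-out radial (koosh-ball) MRI of X-nuclei such as sodium-23, plus
the RF-safety arithmetic that accompanies body imaging at ultra-high
field.

Abdominal ²³Na MRI acquires for tens of minutes under free breathing, so
respiratory motion blurs the very structures (e.g. the renal
corticomedullary sodium gradient) the scan is meant to quantify. Because
a center-out radial acquisition re-samples the k-space center every
repetition, the complex DC samples form a physiological surrogate: after
channel-wise averaging, projection onto the first principal component of
the (Re, Im) scatter, Gaussian smoothing and 10 s moving-average
detrending, the channel with the highest respiratory band-power ratio

    Theta = P[0.1, 1.0 Hz] / P[1.0, 10 Hz]

serves as the gating signal. Excitations are sorted into 24 equal-count
amplitude bins; sliding windows of `w` consecutive bins (`24 - w + 1`
windows, e.g. 19 for `w = 6`) define motion states, each reconstructed
by density-compensated Kaiser–Bessel gridding (adjoint NUFFT) and
unaccelerated sensitivity-weighted combination (SENSE1,
`sum conj(s_c) I_c / sum |s_c|^2`). Image sharpness is read from a
logistic edge-spread fit

    S(z) = a / (1 + exp(-(z + z0)/b)) + c

whose transition width `b` (mm), normalized to the median of a static
acquisition, is the relative-resolution metric. The safety module
implements SAR from MR thermometry (`SAR = cp * dT / dt`, normalized by
incident power), worst-case total power limits
(`cap / max(peak 10 g SAR per W)`, e.g. 20 / 0.16 -> 125 W for ²³Na and
20 / 0.48 -> 42 W for ¹H), the sinusoidal B₁⁺ calibration
`S(V) = S0 |sin(kappa V)|`, and Larmor-frequency bookkeeping
(11.26 MHz/T x 10.5 T -> 118 MHz).

A programmable-motion-phantom simulator (static oval body, moving
cylindrical insert with an agar "kidney" surrounded by water, 8-channel
transceiver model, seeded respiratory waveforms) generates raw k-space
with ground-truth motion, so every stage is testable end to end. See the
vignette in `vignettes/motion-resolved-sodium-mri.Rmd` for the models,
parameter defaults and design decisions.

## Worked example

Simulate a noisy sodium-like phantom acquisition, extract the gating
signal and compare it with the programmed motion:

```r
library(sodiumgate)

traj <- golden_means_trajectory(20000, fov = 320, resolution = 320/48,
                                tr = 10)
wf    <- make_respiratory_waveform(201, "variable", seed = 1)
ph    <- phantom_model("23Na", n = 48, fov = 320)
sens  <- make_sensitivity_maps(48, 320, 8)
nsd   <- noise_sd_for_snr(ph, traj, wf, sens, snr = 10)
ksp   <- simulate_acquisition(ph, traj, wf, sens, noise_sd = nsd,
                              seed = 1, compute_readout = FALSE)
sg    <- select_gating_signal(ksp, "phantom-na")
sg
#> selfgating_signal: 20000 excitations at 100 Hz, channel 7, Theta = 2.28e+03
gating_correlation(sg, ksp$truth)
#> [1] 0.9968866
```

The selected channel's smoothed PCA score tracks the 15 mm programmed
insert motion with Pearson r = 0.997 despite a per-sample modulation SNR
of only 10. Binning those excitations
(`group_bins(assign_bins(sg), width = 6)`) yields the 19 overlapping
motion states of the width-6 protocol, and
`run_phantom_study(widths = c(24, 4, 1), seed = 1, windows_per_width = 7)`
reproduces the motion-binning benefit: median relative resolution 1.38
(all 24 bins in one state) improving to 1.04 (4 bins) and 1.01 (single
bin), with self-gating-based and ground-truth-based binning agreeing to
within 0.03.

A thin CLI over the same functions lives in `inst/cli/sodiumgate`
(subcommands `traj`, `simulate`, `gate`, `recon`, `assess`, `safety`).

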