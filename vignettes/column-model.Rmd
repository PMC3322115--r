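---
title: "A feedforward rate model of a primary visual cortex column"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A feedforward rate model of a primary visual cortex column}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(v1column)
```

## The model

`v1column` simulates a single column of cat primary visual cortex as a
purely feedforward cascade of firing-rate neurons. The architecture has
seven stages. Stages 1–4 form `m` sub-cortical channels (photoreceptor,
bipolar cell, ganglion cell, geniculate relay cell), each channel anchored
to one X-type retinal ganglion cell. Stages 5–7 are three cortical grids;
every neuron in one stage feeds every neuron in the next through Gaussian
weights. There are no lateral connections, no feedback, and no explicit
inhibitory units.

Each neuron `k` is one first-order differential equation for its generator
potential `p` (membrane potential at the spike-initiation zone, measured
relative to spike threshold, in mV):

    tau * dp/dt = sum_j w_j * v_j + p0 - p

where `v_j` are the presynaptic drives, `w_j` the connection gains, and
`p0` a stimulus-independent static polarisation. Impulse rate is the
rectified potential, `a = g_rect * max(p, 0)`, with `g_rect = 7.2` Hz/mV.
This threshold-linear conversion is what produces the *iceberg effect*:
any selectivity present in the potential is sharpened in the spike rate
because only the supra-threshold tip of the response is expressed.

Three design assumptions carry all of the model's selectivity:

1. **Paired opposite-sign inputs.** The basic model has exactly two
   sub-cortical channels — one on-centre, one off-centre — separated by
   0.1 degrees, the nearest-neighbour distance of opposite-sign X cells at
   11 degrees eccentricity. Because the two channels enter cortex with
   opposite signs, the first cortical stage effectively differences two
   displaced Gaussian profiles, i.e. it approximates a spatial derivative
   (`spatial_profile_and_derivative_check()`); this yields oriented,
   spatially biphasic receptive fields.
2. **A small on/off latency difference.** The off channel filters with
   `tau_off = 9` ms, the on channel with `tau_on = 11` ms. Four cascaded
   first-order filters give the relay cells gamma-density impulse
   responses of shape 4, so the off response leads the on response by a
   few milliseconds at the leading edge. The channel difference then
   approximates a derivative with respect to the time constant
   (`temporal_profile_and_derivative_check()`), and this temporal
   asymmetry — nothing else — makes the model direction selective.
3. **Hyperpolarised first-stage cortical cells.** Stage-5 cells rest
   about 9 mV below threshold, so they are silent at rest and strongly
   rectify their responses (simple cells); stages 6–7 rest slightly
   depolarised and inherit only rectified input, which fills in their
   subfields and lowers their modulation ratios (complex-like cells).

Sub-cortical spatial pooling is a difference of Gaussians collapsed into
the first stage: the centre Gaussian (1/e radius `r_cen = 0.4` deg, gain
`g_cen = 62` mV per contrast-unit) minus, when enabled, the surround
(`r_sur = 1.1` deg, `g_sur = 48` mV/CU). Each Gaussian is unit-normalised
in two dimensions, so the full-field sensitivity equals the mechanism
gain. The basic model omits the surround and compensates by defining
stimuli in local-contrast units; the surround variant is used for
spatial-frequency bandwidths and for the geniculate sensitivity estimate.

## Parameters

All defaults are taken from published cat physiology and anatomy via
explicit derivation chains, implemented in `derive_retinal_geometry()`,
`cortical_linear_density()`, `calibrate_centre_gain()`,
`calibrate_geniculocortical_gain()` and
`calibrate_static_polarisations()`:

| symbol | value | units | origin |
|---|---|---|---|
| `g_cen` | 62 | mV/CU | 620 Hz/CU retinal centre sensitivity × 0.73 retino-geniculate attenuation / `g_rect` |
| `g_sur` | 48 | mV/CU | geniculate surround strength |
| `g_rect` | 7.2 | Hz/mV | intracellularly measured generator-function slope |
| `g_GC` | 4.21 (m=2), 1.47 (m=6) | – | solved so stage-5 grating sensitivity is 70 mV/CU |
| `g_cort` | 1 | – | no consistent simple/complex sensitivity difference |
| `r_cen`, `r_sur` | 0.4, 1.1 | deg | X-cell centre/surround radii at 11 deg eccentricity |
| `r_cort` | 2.8 | deg | half the geometric-mean simple-cell subfield length |
| `tau_on`, `tau_off` | 11, 9 | ms | off relay cells lead on cells by ~3 ms at the leading edge |
| `tau_cort` | 10 | ms | simple-cell impulse responses peak as early as 40 ms = 4·tau |
| `p0_sub` | 1.94 | mV | 14 Hz geniculate spontaneous rate / `g_rect` |
| `p0_stage1` | −25.5 (centre) | mV | sets stage-5 resting potential ~9 mV below threshold |
| `p0_late` | 0.646 | mV | depolarises stages 6–7 (spontaneous complex-cell activity) |

Two parameter constructors exist. `model_parameters()` holds exactly the
tabulated working values above. `calibrated_parameters()` re-runs the
calibration chain at full precision (`g_GC = 4.246`, `p0_sub = 14/7.2`,
with the stage-1 polarisation anchored at −25.5 mV at the patch centre).
The distinction is irrelevant for gratings but decisive for unit-contrast
flashed spots and bars: the central cell's light-spot response peaks
within ±0.2 mV of threshold, below it under the rounded values and above
it under the full-precision chain. The receptive-field experiments and
the acceptance script therefore use `calibrated_parameters()`; this is a
property of the model worth knowing — its light-evoked simple-cell
responses are genuinely marginal, which is also why dark-dominated maps
(off-domination) emerge so robustly.

`p0_late` deserves a note: solving the published 3.1 Hz mean spontaneous
cortical rate through the resting-state equations gives 0.287 mV (mean
over stages 6 and 7) or 0.431 mV (stage 6 alone), neither of which equals
the tabulated 0.646 mV. The package keeps the tabulated value as the
default — it only shifts complex-cell modulation ratios slightly — and
`calibrate_static_polarisations()` exposes the rate-based solver.

Conventions that the source material leaves open, fixed here and
documented because results depend on them:

* **Gaussian "radius"** means the 1/e radius of `exp(-(d/r)^2)`, the
  convention of the difference-of-Gaussians literature the radii come
  from.
* **Channel geometry**: the on-centre channel sits at +x, the off-centre
  channel at −x, 0.1 deg apart (the value quoted for the eccentricity of
  interest; the full-precision chain gives 0.097 deg). `drift_sign = +1`
  moves a grating towards the on channel, which is the preferred
  direction.
* **Direction-selectivity index**: both conventions are computed —
  `1 - a_anti/a_pref` and `(a_pref - a_anti)/(a_pref + a_anti)` — since
  the two laboratories being compared against used different forms; the
  normalised form is the default for histograms.
* **Spatial-frequency bandwidth** is the full width at half-height in
  octaves, `log2(f_high/f_low)`.

## Stimuli

All stimuli are local-contrast fields `c(x, y, t)` built by
`drifting_grating()`, `contrast_reversing_grating()`, `spot_stimulus()`
and `bar_stimulus()`; `make_standard_stimuli()` assembles the ensemble
for each experiment (0.38-deg spots of 40 ms for receptive-field maps,
0.8 deg for the six-channel variant; 0.25-deg bars at 16 locations;
gratings at 0.49 cycles/deg, 2 Hz, contrast 0.3 for tuning; contrast 1
for the phase scan; contrast 0.25 for modulation ratios). These are
idealised inputs: no luminance nonlinearity, no eye movements, no noise.
Tests passing on them show that the architecture produces the claimed
selectivities, not that it quantitatively predicts responses to natural
stimulation.

## Numerics

Sub-cortical spatial pooling is evaluated in closed form — Fourier
attenuation `exp(-(omega_s r / 2)^2)` for gratings, error-function edge
integrals for rectangles — with a pixel-grid quadrature fallback
(`dog_drive_numeric()`) that agrees to better than 0.1 %.

`simulate_network()` integrates the coupled equations with two engines:

* `"ode45"`: adaptive Dormand–Prince Runge–Kutta (4,5) on the full
  coupled system (`deSolve`), relative tolerance 1e-6, absolute 1e-9 mV,
  with the time span split at stimulus onset/offset discontinuities.
* `"staged"`: because the network is strictly feedforward, each stage is
  a set of scalar linear filters driven by the previous stage; they are
  advanced with the exact exponential update on the 1 ms output grid
  (exact for flashed stimuli, second-order for smooth drive). This is
  the default for population experiments, where it is orders of
  magnitude faster.

Both engines are validated against each other and against the analytic
steady-state oracle (`analytic_linear_response()`): at contrast 0.01 the
fundamental of the stage-5 potential agrees with the closed form to well
under 0.5 %, across spatial frequencies, orientations and both drift
directions — the same cross-validation strategy used to develop the
model.

Fourier analysis (`fourier_components()`) discards the first temporal
cycle as transient and analyses at least two whole subsequent cycles;
amplitude and phase follow the sine convention of the stimulus. Periodic
runs last 1.5 s (three cycles at 2 Hz). Tuning optima use the argmax
refined by a parabolic fit through the three surrounding samples, with
ties broken toward the smaller abscissa; half-widths and bandwidths are
found by linear interpolation to the half-height crossings and are
undefined (NA, with the neuron skipped) when a curve never crosses
half-height. Neurons enter population statistics only if the optimal
grating elevates their mean rate by at least 5 Hz.

Problem sizes: the cortical grid defaults to 0.1-deg spacing (21 × 21
neurons per stage) for population runs — the anatomical density would be
~97 cells/deg, i.e. ~37 000 neurons per stage, but population histograms
are computed per active neuron and are insensitive to grid density
(asserted in the tests), so the reduced grid is used throughout. Tests
use still coarser grids (0.25–0.5 deg) where only orderings matter.
Intracortical Gaussian weights (radius 2.8 deg on a 2-deg patch) are
nearly uniform; they are truncated at the patch edge and renormalised per
neuron so that the intracortical gain stays exactly `g_cort`, removing
edge artefacts.

## Receptive-field readout

Maps read the impulse-rate *elevation* above the resting rate. The
published protocol reads it at a fixed 85 ms after spot onset — the
latency of the light-spot response peak. In this implementation the
off-channel's faster kinetics make dark responses peak ~30 ms earlier and
decay below threshold again before 85 ms, so a fixed readout matched to
the light response misses the dark subfield almost entirely.
`map_receptive_field()` therefore also offers `readout = "peak"` (the
maximum elevation over the trace), which renders both subfields; the
figure presets use it. Relatedly, because every stage-5 cell shares the
same two (or six) sub-cortical inputs, light and dark subfields remain
essentially disjoint at *every* cortical stage; the growth of subfield
overlap across stages is weak here, and the simple-to-complex transition
is carried instead by the modulation ratio (F1/F0), which separates the
stages cleanly.

## Known limitations

* Orientation tuning is not contrast-invariant: raising contrast pushes
  more of the response above threshold and broadens tuning. Fixing this
  would need contrast-dependent (dynamic) inhibition, which the
  architecture deliberately omits.
* The basic model's two-channel receptive fields are small and barely
  elongated; the six-channel variant exists precisely to lengthen them.
* Rates are deterministic; there is no spiking noise, so population
  histograms reflect parameter diversity (e.g. the multi-column
  latency-difference draws), not trial-to-trial variability.
* Binocular input, multiple cortical areas, and the Y/W sub-cortical
  pathways are out of scope.

## Reproducing the headline numbers

`scripts/acceptance.R` recomputes, from a fresh build of the model: the
geniculate contrast sensitivity at the optimal spatial frequency with
surround antagonism, the latency of the stage-1 spot-response peak, the
optimal spatial frequency of the central stage-1 cell, and the median
orientation half-width across active stage-1 cells on the 21 × 21 grid.
The testthat suite (`tests/testthat/`) additionally pins the calibration
chains, the analytic-oracle agreement, the derivative approximations, and
every qualitative ordering discussed above.
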