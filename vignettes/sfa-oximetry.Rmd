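---
title: "Methods: SFA camera processing and occlusion oximetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SFA camera processing and occlusion oximetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfaox)
```

This vignette documents the models, assumptions and numerical choices
behind `sfaox`: the forward model of a spectral-filter-array (SFA) camera
imaging skin during a vascular occlusion test, the inverse chain that
recovers hemoglobin concentration changes from the raw mosaic frames, and
the analytics that compare the result against a reference oximeter.

## 1. The forward model

### 1.1 Occlusion dynamics

`simulate_occlusion_truth()` generates tissue oxygen saturation
$S(t)$ piecewise:

* a stable baseline at `baseline_sto2` (default 0.70 — a typical resting
  StO2 for peripheral tissue);
* a **linear** desaturation during cuff inflation, ending when saturation
  reaches `release_threshold_fraction` (default 0.40) of baseline — the
  cuff-release rule of the emulated protocol, equivalent to a ~60 % drop;
* a **linear** resaturation to an overshoot `overshoot_amplitude` above
  baseline, reached `overshoot_time_dt` seconds after release;
* an **exponential** return to baseline with time constant
  `return_time_constant`.

Linear de-/re-saturation segments are chosen deliberately: the downstream
analysis quantifies these phases by linear slope fitting, so the generator
and the estimator agree on the functional form and fitted slopes are
directly comparable with the generating rates. Phase boundaries are
snapped to the frame grid, so the release sample carries exactly the
threshold saturation regardless of the protocol durations.

Saturation is converted to concentrations through a constant total
hemoglobin pool `total_hb_mM` (default 0.10 mM, a realistic effective
tissue concentration): $c_{O2Hb} = S \cdot c_{tot}$,
$c_{HHb} = (1-S)\,c_{tot}$. Gaussian noise (`noise_sd`, StO2 units) is
applied to $S$, which keeps $c_{O2Hb}+c_{HHb}$ exactly constant — blood
volume is held fixed by default because it is a known confounder of
baseline-referenced estimators; `blood_volume_drift` re-enables it
explicitly for robustness experiments.

### 1.2 Skin reflectance

`reflectance_from_concentrations()` evaluates the modified Beer–Lambert
law on the wavelength grid (default 400–700 nm in 10 nm steps, 31
samples — the sampling also used for correction training):

$$A(\lambda,t) = \varepsilon(\lambda)\,c(t)\,\mathrm{DPF}(\lambda)\,d
  + G(\lambda) + A_{mel}(\lambda) + H(t), \qquad R = 10^{-A}.$$

Defaults: geometric path $d = 0.2$ cm (a plausible effective sampling
depth for visible-range diffuse reflectance of skin), $\mathrm{DPF}=1$,
$G = 0$, $H = 0$ (constant in time, per the estimator's own assumption),
and a power-law melanin offset anchored at 694 nm. With these defaults
absorbance changes depend *only* on concentration changes, which is what
makes the simulator an exact oracle for the estimator. Reflectances above
1 (possible with negative losses) are clamped and counted.

The packaged extinction table (`hb_extinction_synthetic.csv`) is a
synthetic approximation of compiled hemoglobin spectra. It reproduces the
structural features the method relies on — near-isosbestic behaviour
around 515 nm, strong oxy/deoxy contrast at 565 and 601 nm, the steep
oxyhemoglobin fall-off past 590 nm — and is user-replaceable; no test
depends on its specific values, only on this structure.

### 1.3 The sensor

`build_filter_bank()` models the 16 Fabry–Pérot channels as Gaussian
primary lobes (FWHM 20 nm) at peaks equally spaced over 470–630 nm, each
with a **second-order harmonic lobe** at a fixed offset below the primary
(default 115 nm, relative height 0.25), multiplied by a hard band-pass
window (455–645 nm) that models the hardware filter suppressing
out-of-range leakage, then mixed with spectrally adjacent channels
(crosstalk fraction 0.04) and peak-normalized. Gaussian lobes stand in
for true cavity transmission curves, which are camera-specific and not
publicly tabulated; every parameter is configurable so a measured bank
can be substituted.

`render_frame()` computes the discrete response
$P_i = \sum_\lambda Q_i(\lambda) E(\lambda) R(\lambda)\,\Delta\lambda$,
scales by gain × exposure (defaults 0.5 counts/(ms·unit), 50 ms — chosen
so bright skin stays below the 66 % linearity ceiling of the 10-bit
range), adds the dark level (12 counts) and Gaussian read noise
(2 counts), quantizes, and interleaves the 16 channels by the 4×4 mosaic
layout (row-major ascending wavelength by default; any bijection is
accepted since the true spatial order is camera-specific).
`render_references()` produces the dark frame and a flat grey
20 %-reflectance standard — grey rather than white so no channel
saturates relative to the brighter skin scene.

## 2. The inverse chain

### 2.1 Flat field and demosaicking

`flat_field_correct()` applies $(I_S - I_D)/(I_W - I_D)$ per pixel.
Pixels where the white reference does not exceed the dark are masked to
`NA`, counted, and excluded from ROI averages — masking is auditable,
silently patched values are not. Negative values are kept (they are
legitimate noise around zero) but counted; relative values above 1.5 are
counted as suspect. By default the result is multiplied by the standard's
0.20 albedo so values are absolute reflectance-scale responses (a perfect
white object reads 1.0); a flag disables the rescaling.

`demosaic_subsample()` is pure subsampling — each band keeps only its own
mosaic positions, quarter resolution per axis, no interpolation. The full
frame is 1088 × 2048 (16 sub-images of 272 × 512); any
multiple-of-four geometry is accepted.

### 2.2 Spectral correction

Reflectance spectra are modelled as $r \approx B\,w$ with $m = 10$ basis
functions, so the (flat-field-normalized) responses satisfy
$p \approx \tilde Q^T B\,w$. `fit_correction()` solves the joint
least-squares problem over $k \ge m$ training patches,

$$\min_M \textstyle\sum_p \lVert B M p - r_p \rVert^2,$$

and applies $M_{\mathrm{eff}} = B(\text{centers})\,M$, which evaluates
the reconstructed spectrum at the 10 virtual band centers (uniform over
470–630 nm, bracketing 515/565/601 nm).

Numerical choices, each of which was a genuinely open design point:

* **Basis**: cubic **B-splines** over the active band. They form a
  partition of unity, so flat (grey) spectra are represented exactly, and
  their smooth-approximation power is far better at $m = 10$ than
  same-width Gaussian bumps, which leave a comb ripple between bumps.
  Gaussian, box and PCA bases remain selectable for comparison.
* **Ridge**: the training-response Gram matrix is nearly singular (the 16
  overlapping channels carry roughly ten independent degrees of freedom),
  so a small ridge (`1e-6` of the mean Gram diagonal) stabilizes the
  solve. Data terms are patch-averaged, making the fit invariant to
  duplicating the training set.
* **Sensitivity localization**: within the near-null space of the
  response data many $M$ fit the training set equally well, and the pure
  least-squares pick has oscillatory, sinc-like effective sensitivities
  $M_{\mathrm{eff}} Q$. A secondary penalty (weight 0.005 relative to the
  per-patch data term) steers this freedom toward ideal narrow-band
  targets at the virtual centers, so the corrected system also *behaves
  spectrally* like the idealized camera it emulates — measurably more
  localized than the raw channels — at essentially no cost in held-out
  reconstruction accuracy.
* **Training patches**: 24 synthetic color-chart-like spectra (a
  six-step greyscale plus smooth random shapes), generated in code with a
  fixed seed. Greys anchor the flat response; the random shapes span
  diverse spectral slopes and bumps.
* **Channel exclusion**: crosstalk in a real camera's 600+ nm channels
  may be too severe to use; the simulated bank keeps all 16 channels and
  the training machinery accepts any channel count, so exclusion is a
  matter of subsetting the response matrix.

`identity_correction()` provides the spectrally *uncorrected* fallback
(raw channels, band centers at the channel peaks) that `cmd_run_all()`
uses — with a prominent warning — when no model is supplied.

### 2.3 Δt oxygenation estimation

`estimate_oxy_timeseries()` averages the absorbance
$A = -\log_{10} R$ of the first `baseline_frames` frames (default 5;
"a few frames" quantified once and kept) as the estimate of all
time-invariant contributions, then inverts

$$\Delta A(\lambda, t) = \varepsilon(\lambda)\,\mathrm{DPF}(\lambda)\,
  \Delta c(t)\, d$$

by least squares (pseudo-inverse of the wavelength × 2 matrix) for
$\Delta c_{O2Hb}, \Delta c_{HHb}$. Wavelength-constant ($G$) and
time-constant ($H$) losses cancel in the difference by construction; the
suite verifies this invariance explicitly.

* **Key wavelengths**: 515 nm (isosbestic reference), 565 and 601 nm
  (high contrast), resolved to the *nearest virtual band center* — an
  error is raised if the nearest center is farther than half a band
  spacing. An `"all"` mode uses every band; both modes agree exactly when
  all bands carry consistent signal, and band-specific noise favours
  whichever mode avoids the noisy bands (both directions are tested).
* **DPF**: defaults to 1 with a configuration hook. Published DPF values
  are tissue- and wavelength-specific; since only *relative* changes are
  interpreted and feature scaling removes global factors, a neutral
  default is the honest choice and is stated prominently rather than
  buried.
* **Saturation proxy**: the scalar plotted and compared is
  $\Delta c_{O2Hb} - \Delta c_{HHb}$ by default — the standard occlusion
  NIRS contrast, maximally sensitive to the desaturation/resaturation
  swing. $\Delta c_{O2Hb}$ alone and a normalized fraction are
  selectable.
* **ROI**: circular, in band-image coordinates; radius 0 degenerates to a
  single pixel. Masked pixels are excluded from the ROI mean. Per-pixel
  concentration maps (the colour-map source) are returned on request per
  frame, since a full map sequence is memory-heavy.

### 2.4 Curve analytics

`compare_curves()` implements the full comparison recipe: the 1 fps
camera curve is smoothed with a centered window-3 moving average (edge
windows shrink so length — and therefore alignability — is preserved),
both curves are aligned at their minima (the cuff-release point; ties
break to the earliest sample with a warning), the slower reference is
linearly interpolated onto the camera sampling over the overlap, both are
feature-scaled onto $[0, 1]$, and RMSE and GFC are computed on the full
overlap. GFC is the normalized absolute inner product — the standard
spectral-similarity convention; the value 1 means identical shape.

`fit_slopes()` fits least-squares lines from the baseline marker to the
minimum (desaturation) and from the minimum to the maximum within a
post-release window (resaturation), reporting both slopes and the
release-to-overshoot time `dt`. The post-release search window is an
explicit parameter (default 60 s) because in clinical practice it is
chosen by a physician; `cohort_correlation()` computes the Pearson
correlation of slope pairs across runs or subjects.

## 3. What the simulator does and does not show

The generator reproduces the features the pipeline must cope with:
interleaved mosaic geometry, second-order lobes and crosstalk,
quantization and read noise, dark/white referencing, amplitude-arbitrary
camera curves versus an absolute, slower, noisier reference, and the
characteristic VOT curve morphology. Passing tests therefore demonstrate
the *processing chain* is correct and self-consistent.

They do **not** demonstrate clinical performance: real skin adds
layered chromophore geometry, scattering-dependent pathlengths that vary
with wavelength and physiology, motion, specular reflections and
inter-subject variability, none of which are modelled (photon-transport
modelling is explicitly out of scope). Absolute StO2 is likewise out of
scope — the estimator reports relative concentration changes only.

## 4. Problem sizes and determinism

Default simulations use 64 × 64-pixel frames (16 × 16 in the test
cohort) over a 300 s protocol at 1 fps; the demosaic worked example runs
at the full 1088 × 2048 frame size. These sizes were chosen so the whole
validation suite exercises every stage, including a 20-run cohort, in
seconds on a single CPU while leaving all spectral dimensions (31 grid
points, 16 channels, 10 virtual bands) at full scale — spatial resolution
is irrelevant to the spectral pipeline beyond the mosaic geometry itself.

Every stochastic operation takes an explicit seed; per-stage seeds are
derived from the master seed by fixed offsets, and seeded operations
restore the caller's RNG state. Two runs with the same seed are
bit-identical, including the files written by `cmd_simulate()`.

## 5. Known limitations

* Gaussian stand-in filter shapes; measured transmission curves should
  replace them for a real camera.
* The flat-field model assumes the references and samples share optics
  and illumination; vignetting beyond what the white reference captures
  is not modelled.
* Demosaicking is pure subsampling; interpolation-based spatial
  reconstruction is intentionally out of scope.
* The correction matrix is static; application-tuned (e.g. skin-specific)
  training sets would likely improve reconstruction of subtle skin
  features.
* With `DPF = 1` the concentration axis is in units of
  mM × (true DPF); only shapes, slopes ratios and correlations are
  interpretable across devices, which is exactly how the analytics use
  them.
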