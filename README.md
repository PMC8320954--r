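# sfaox

Processing pipeline for snapshot **spectral filter array (SFA)** cameras
applied to dynamic skin-oxygenation imaging, with a complete forward
simulator so every stage can be validated without camera hardware or
clinical data.

## The problem

Snapshot mosaic multispectral cameras tile the sensor with a repeating 4×4
pattern of Fabry–Pérot interference filters, capturing 16 spectral channels
in a single exposure — fast enough to follow physiological dynamics such as
the de- and re-saturation of tissue during a vascular occlusion test (VOT).
The price is imperfect spectral data: each mosaic frame interleaves all
channels spatially, the interference filters transmit **second-order
harmonic lobes** in addition to their intended peak, and neighbouring
channels **crosstalk**. Turning raw frames into tissue oxygen saturation
curves therefore requires a dedicated chain:

1. **Flat-field correction** against dark and grey-standard references:
   `I = (I_S − I_D) / (I_W − I_D)`, removing illumination spectrum and
   spatial non-uniformity.
2. **Spatial rearrangement**: pure subsampling of the 4×4 mosaic into a
   16-band cube at quarter resolution per axis (a 1088 × 2048 frame becomes
   16 bands of 272 × 512).
3. **Spectral correction**: reflectance spectra are modelled as smooth
   combinations of basis functions, `r ≈ B w`, so the camera response is
   `p ≈ Qᵀ B w`. A correction matrix fitted on color-chart-like training
   patches maps the 16 imperfect channel responses to `m = 10` virtual
   narrow-band reflectance samples, undoing second-order lobes and
   crosstalk.
4. **Δt oximetry** via the modified Beer–Lambert law,

   `A(λ, t) = ε(λ) · c(t) · DPF(λ) · d + G(λ) + H(t)`,

   where `ε` are molar extinction coefficients of oxy-/deoxy-hemoglobin
   (mM⁻¹ cm⁻¹), `DPF` the differential pathlength factor, `d` the
   geometric path (cm) and `G`, `H` oxygen-independent losses. Absorbance
   changes relative to a baseline window cancel `G` and `H`, and the
   least-squares inversion of `ΔA = ε · DPF · Δc · d` at three key
   wavelengths (an isosbestic reference near 515 nm plus the
   high-contrast 565 and 601 nm bands) yields `Δc_O2Hb`, `Δc_HHb` per
   pixel and per region of interest.
5. **Curve analytics**: feature scaling `X′ = (X − Xmin)/(Xmax − Xmin)`,
   window-3 moving average, alignment of camera and reference-oximeter
   curves at the cuff-release minimum, linear de-/re-saturation slope
   fits, and agreement metrics — RMSE and the goodness-of-fit coefficient
   `GFC = |Σ aᵢbᵢ| / (√Σ aᵢ² √Σ bᵢ²)`.

The built-in simulator generates the whole study: ground-truth occlusion
dynamics (stable baseline, linear desaturation to 40 % of baseline
saturation, overshoot after release, exponential return), skin reflectance
through the same Beer–Lambert forward model, mosaic sensor frames with
second-order lobes, crosstalk, dark level, read noise and quantization,
and a slower (3.5 s) noisy reference oximeter trace.

## Worked example

```r
library(sfaox)
res <- run_occlusion_experiment(pipeline_config(), seed = 1)

res$model
#> <correction_model> 16 channels -> 10 virtual bands (bspline basis)
#>   training spectral RMSE: mean 1.17e-03, max 3.22e-03

round(c(GFC = res$comparison$gfc, RMSE = res$comparison$rmse), 3)
#>   GFC  RMSE
#> 0.999 0.038

res$slopes
#> <slope_report> desat -0.0001077/s, resat 0.000727/s, dt 23.0 s
```

The run simulates a 300 s occlusion protocol at 1 fps (64 × 64 mosaic
frames), calibrates a spectral-correction model on 24 synthetic training
patches, processes every frame through flat-field correction, demosaicking
and spectral correction, estimates the ROI-averaged oxygenation proxy
(`Δc_O2Hb − Δc_HHb`, the standard occlusion-NIRS contrast), and compares
the normalized curve against the simulated reference oximeter. GFC near 1
and small RMSE mean the camera curve reproduces the reference's shape;
the slope report gives the clinically interpreted de-/re-saturation rates
and the release-to-overshoot time `dt`.

A disk-based tool workflow with the same stages is available as
`cmd_simulate()` / `cmd_run_all()` or from a shell:

```sh
Rscript inst/cli/sfaox.R simulate --out acq --seed 1
Rscript inst/cli/sfaox.R run-all  --dir acq
```

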