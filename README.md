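# carapacer

Colour and pattern phenotyping of shore crabs (*Carcinus maenas*) — or any
animal photographed with a calibrated multispectral camera — from raw
four-channel (LW/MW/SW/UV) images to cohort-level statistics.

Shore crabs are famously polymorphic: brightness, saturation, hue and
carapace markings vary among individuals, sites, shore heights and life
stages. Measuring that variation objectively requires (i) images calibrated
to physical reflectance so the camera and the weather drop out, (ii) colour
and pattern metrics defined without assuming any particular receiver's
visual system, and (iii) statistics that compare groups and quantify
within-group diversity. `carapacer` implements the whole chain and ships
synthetic image and cohort generators with known ground truth, so every
stage is verifiable without field data.

## The measurements

With mean carapace reflectances $LW, MW, SW, UV$ on the calibrated 0–255
scale (255 = 100% reflectance):

* **brightness** $=(LW+MW+SW+UV)/4$
* **saturation** = distance of the colour from the achromatic centre of a
  regular tetrahedron whose vertices are exclusive stimulation of each
  channel (computed on channel proportions, so it is brightness-invariant)
* **hue1** $= UV/((LW+MW+SW)/3)$, **hue2** $=(LW+UV)/(MW+SW)$ — opponent
  style ratios; equal channels give saturation 0 and hues exactly 1

Pattern is quantified by a **granularity spectrum**: the image is Fourier
band-pass filtered into 23 half-octave bands of marking size 2–4096 px,
band energy is $\sum v^2/N$, and the spectrum is summarized as dominant
**marking size**, **total energy** (pattern contrast) and **proportion
energy** (how strongly one marking size dominates). Within-group diversity
is the **MDPS**: each crab's mean Euclidean distance to all others of its
site × life-stage group over the six max-standardized metrics, with
99-fold subsampling to control for sample size. Group comparisons use
jackknifed (leave-one-out) discriminant classification, Spearman
correlations against carapace width, and Box-Cox + fixed-effects GLMs with
stepwise removal of non-significant interactions.

## Worked example

Render a synthetic crab (base quad LW=120, MW=60, SW=20, UV=40, blob
pattern of 16-px scale) through a nonlinear camera (exponent 2.2) under
0.7× illumination, then calibrate and measure it:

```r
library(carapacer)

sc <- image_scenario(base_quad = c(LW = 120, MW = 60, SW = 20, UV = 40),
                     pattern_scale = 16, pattern_contrast = 20,
                     camera_exponent = 2.2, illumination = 0.7, seed = 1)
scene <- make_calibration_scene(sc)        # grey ladder + 40% standard
curve <- fit_linearization(scene$ladder)   # v = a * r^b per channel

cr  <- make_crab_image(sc)
cal <- calibrate_image(cr$raw, curve, roi_mask = cr$roi_mask,
                       target_mm_per_pixel = 0.1)
roi <- extract_roi(cal)
colour_metrics(roi$quad)
#>      LW    MW    SW    UV brightness saturation  hue1  hue2
#>    120.  59.8  19.9  39.9       59.9      0.271 0.599  2.00

spectrum_metrics(granularity_spectrum(roi$pattern,
                                      mm_per_pixel = roi$mm_per_pixel))
#>   marking_size marking_size_mm total_energy proportion_energy
#>             16             1.6         34.0             0.578
```

The channel means recover the generating quad despite the nonlinear camera
and dim light (hue2 = 2.00 is forced by the base quad: (120+40)/(60+20)),
and the dominant marking size lands in the 16-px band that generated the
pattern. `run_pipeline()` chains the same stages over a whole cohort and
writes `metrics.csv`, `spectra.csv`, `mdps.csv` and the statistics tables,
reproducibly under a fixed seed; `autoplot()` methods draw spectra,
diversity bars and confusion matrices, and `tidy()`/`glance()` methods
return model tables as tibbles.

## Layout

* `R/` — calibration, colour metrics, granularity, MDPS, statistics,
  synthetic generators, pipeline
* `tests/testthat/` — unit, property and end-to-end recovery tests with
  brute-force oracles
* `vignettes/carapace-phenotyping.Rmd` — the methods vignette: models,
  assumptions, parameter choices, limitations
* `inst/cli/carapace-pheno` — thin command-line wrapper (`run`, `simulate`)
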