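---
title: "Quantifying crab colour and pattern from calibrated multispectral images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying crab colour and pattern from calibrated multispectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carapacer)
library(dplyr)
```

# The measurement problem

Shore crabs (*Carcinus maenas*) are wildly variable in colour and pattern,
and quantifying that variation objectively — across sites, shore heights and
life stages — requires image measurements that reflect the physical
reflectance of the animal rather than the camera, the weather, or the
photographer. `carapacer` implements the full measurement chain:

1. **Calibration**: invert the camera's nonlinear response and equalize each
   photograph to an in-frame grey standard, so pixel values are physical
   reflectances.
2. **Colour metrics**: brightness, tetrahedral colour-space saturation, and
   opponent-style hue ratios from the four camera channels (LW, MW, SW, UV).
3. **Pattern granularity**: a Fourier band-pass energy spectrum over
   log-spaced marking sizes, summarized as dominant marking size, total
   energy (contrast) and proportion energy (marking-size dominance).
4. **Phenotypic diversity**: mean pairwise distances in a six-dimensional
   standardized phenotype space (MDPS), with resampling to control sample
   size.
5. **Statistics**: size-based age criteria, jackknifed (leave-one-out)
   discriminant classification, Spearman size correlations, and Box-Cox
   transformed fixed-effects models with stepwise interaction removal.

Everything is exercised end to end on synthetic images and cohorts with
known generating truth, so each stage's recovery properties are testable
without any field data.

# Calibration model

A camera maps scene radiance to 8-bit values nonlinearly. We model the
response per channel as a monotone power law,

$$v = a\,r^{\,b},$$

fitted by least squares on the log–log scale to a ladder of (nominally
eight) grey standards spanning 2–99% reflectance. Linearization inverts
this mapping; equalization then rescales each channel so the in-frame
standard of known reflectance (default 40%) reads its true value
($0.40 \times 255 = 102$). Because illumination enters the power law as a
pure scale factor, the equalized image is invariant to global exposure
changes — the package's tests verify recovery within 1% for exposures from
half to double the reference, under a camera exponent of 2.2.

Numerical choices worth knowing:

* Ladder points at zero carry no information on the log scale and points
  within ~2% of the 8-bit ceiling (value ≥ 250) are treated as clipped;
  both are excluded from the fit. Clipped image pixels are likewise flagged
  and excluded from ROI means — the numeric analogue of avoiding specular
  highlights when drawing measurement regions.
* The monotonicity check on the ladder tolerates inversions up to 1% of the
  value scale, since patch means jitter by sensor noise; larger inversions
  indicate a mis-assigned channel and are rejected.
* All images are resized to a common spatial scale (default 10 px/mm, from
  the ruler in each frame) so marking sizes are comparable between crabs.
  The value is arbitrary but fixed; changing it rescales marking sizes in
  pixels, not in mm.

# Colour metrics

With mean carapace reflectances $LW, MW, SW, UV$ (0–255 scale):

* brightness $= (LW+MW+SW+UV)/4$;
* channel proportions $p_i = c_i / \sum_j c_j$ remove overall brightness;
* saturation is the Euclidean distance of $\sum_i p_i \mathbf{v}_i$ from
  the origin, where $\mathbf{v}_{UV}, \mathbf{v}_{SW}, \mathbf{v}_{MW},
  \mathbf{v}_{LW}$ are vertices of a regular tetrahedron centred on the
  achromatic point;
* hue1 $= UV / ((LW+MW+SW)/3)$ and hue2 $= (LW+UV)/(MW+SW)$.

Equal proportions give saturation 0 and both hues exactly 1. The vertex
distance is set to 0.75, the convention of the tetrahedral colour-space
literature; any regular tetrahedron gives the same saturation up to a
global constant, so the constant is pinned (and configurable) purely for
reproducibility. The bracketing of hue2 as $(LW+UV)/(MW+SW)$ is forced by
its interpretation as longwave-plus-UV against mediumwave light and by the
achromatic value of 1.

`pca_colour_screen()` is a diagnostic, not a definition: it confirms on a
given cohort that the fixed hue ratios align with the main axes of
proportional colour variation. `correlation_screen()` (default threshold
$|r| \ge 0.7$, Pearson) flags collinear metric pairs; hue1 correlates
strongly with saturation in crab-like data and is therefore excluded from
the six-metric phenotype by default, leaving hue2 as "hue".

# Granularity spectrum

The pattern raster (per-pixel brightness over the carapace mask, with
outside-mask pixels set to the masked mean) is decomposed into ideal
annular Fourier bands whose nominal marking sizes follow a half-octave
ladder: $2 \cdot 2^{k/2}$ px for $k = 0,\dots,22$, i.e. 2 px up to 4096 px
in 23 bands (intermediate sizes rounded to three significant figures). A
"marking size of $s$ px" means a spatial period of $s$ px. Band energy is
$\sum v^2 / N$ of the filtered raster.

Design choices:

* **Ideal annuli with geometric-midpoint edges.** The first band's support
  is open upward (it absorbs the corner frequencies beyond the Nyquist
  radius) and the last band's is open downward, so the bands partition the
  whole discrete spectrum and band energies sum *exactly* to the raster's
  pixel variance (Parseval). Mean-filling outside the mask minimizes
  spurious low-frequency energy from the mask boundary.
* **Padding.** Non-square rasters are padded with their mean to a
  power-of-two square before the FFT; energies are defined on the padded
  raster so the spatial route (`bandpass()` + `band_energy()`) and the
  frequency-domain route used by `granularity_spectrum()` agree to machine
  precision.
* **Degenerate inputs.** A featureless (constant) raster has an all-zero
  spectrum; `spectrum_metrics()` refuses it rather than fabricating a
  dominant marking size.

Summary metrics: dominant `marking_size` (argmax band), `total_energy`
(pattern contrast; scales exactly as amplitude squared) and
`proportion_energy` (max/total; 1 when a single scale dominates, 1/23 for
a flat spectrum).

# Phenotypic diversity (MDPS)

Each crab is a point in six dimensions: hue, saturation, brightness,
marking size, total energy, proportion energy. Every metric is first
standardized as a proportion of its maximum over the *entire* dataset
(never per group), putting all axes on 0–1. Within each site × life-stage
dataset, each crab's mean Euclidean distance to all other crabs is
computed; the group MDPS is the mean of those means. Because larger samples
can look more diverse, `resample_mdps()` recomputes each group's MDPS over
99 random subsamples (without replacement — the procedure draws subsets,
not bootstrap resamples) of the smallest group's size and reports the
resampled mean and SD. The smallest group is labelled the reference; its
resampled value equals its full value with zero SD by construction. All
resampling is seed-deterministic and the seed is recorded on the result.

# Statistical stages

* **Age criteria**: the default 25-mm rule labels crabs adult at carapace
  width ≥ 25 mm; the sex-specific maturity rule uses 28 mm (females) and
  >21 mm (males). Comparing the two by LOOCV classification accuracy on
  the six appearance metrics reproduces the model-selection logic used to
  settle on the 25-mm rule.
* **Jackknifed DFA**: `lda_loocv()` wraps linear discriminant analysis with
  leave-one-out cross-validation (priors proportional to group sizes,
  pooled within-group covariance). The held-out observation never
  influences its own classifier; a single-feature outlier changes only its
  own prediction on a separable set. Note that under pure noise LOOCV
  accuracy is pessimistically biased slightly *below* chance — the tests
  bound it from above by the binomial interval only.
* **Spearman vs size**: midranks for ties, $t = \rho\sqrt{(n-2)/(1-\rho^2)}$
  on $n-2$ df; an exact permutation p-value is available for $n \le 10$.
* **Box-Cox**: $(v^\lambda - 1)/\lambda$ (log for $\lambda = 0$); powers
  may be supplied (to reproduce previously chosen transforms) or estimated
  by profile maximum likelihood over $\lambda \in [-3, 3]$ in steps of
  0.001.
* **Stepwise GLM**: ordinary least squares with site, zone and stage as
  fixed factors and all two-way interactions as candidates; the
  least-significant interaction at $p \ge \alpha$ (default 0.05) is removed
  and the model refitted, one term at a time. Marginal (Type II) F tests
  are used: the original software is unknowable from the outputs alone, and
  Type II is the standard choice for testing main effects in unbalanced
  factorials once non-significant interactions are gone. With balanced
  designs it coincides with the textbook two-way ANOVA, which is how the
  tests pin it to a closed-form oracle. Main effects are never removed, and
  no multiple-testing correction is applied across the six response models
  — a documented limitation, not an oversight.

# What the synthetic generators emulate — and what they do not

`make_calibration_scene()` and `make_crab_image()` render neutral grey
ladders, a 40% working standard and an elliptical carapace filled with
band-limited blob texture (thresholded band-pass noise, giving mottled
markings with a controllable dominant scale) through a power-law camera
with Gaussian sensor noise. `make_cohort()` draws site × stage cells from
multivariate normals with site- and stage-dependent means, a juvenile SD
inflation (default 1.5; juveniles are the more variable stage), roughly
three juveniles per adult, and carapace widths drawn so the 25-mm rule
separates the stages exactly. Metrics are clipped to their physical ranges
after sampling.

The generators deliberately do **not** emulate: spatially varying
illumination, channel misregistration, carapace segmentation error,
non-elliptical body outlines, background substrate, or correlated metric
noise. Passing tests therefore demonstrate that the *measurement chain* is
correct and that the *statistical machinery* recovers known structure at
realistic sizes — not that field photographs are free of those additional
error sources.

Problem sizes used in the test suite were chosen to make the checks sharp
but quick: 256²–512² rasters for spectral checks (one 1024² grating), 200
replicates for the GLM operating-characteristic simulations, 100
replicates for the cohort-level qualitative checks, and cohorts of 40–160
crabs per cell.

# Known limitations

* One shared ROI mask is assumed across the four channels (masks drawn per
  channel are not supported).
* The power-law response suits typical cameras; a monotone-spline mode for
  misbehaved ladders is not implemented — such ladders are rejected
  instead.
* Pattern analysis runs on the brightness raster by default; whether a
  single channel would be preferable is data-dependent, so the choice is
  recorded in the pipeline config.
* `run_pipeline()` generates synthetic cohorts; for real photographs, read
  them with `read_msimage()` and call the stage functions directly — the
  pipeline's orchestration is intentionally thin.

# A worked run

```{r pipeline, eval = FALSE}
out <- run_pipeline(list(seed = 1, out_dir = "run",
                         input = list(type = "synthetic", n_crabs = 12)))
readr::read_csv(file.path(out, "metrics.csv"))
```

The run directory contains `metrics.csv` (one row per crab: metadata, the
channel means and all six metrics), `spectra.csv` (long-format granularity
spectra), `mdps.csv`, `correlations.csv`, the fitted `response_curve.csv`,
a plain-text log and a `manifest.yaml` with the package version, config
hash and seed. Re-running the same config reproduces every CSV byte for
byte.
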