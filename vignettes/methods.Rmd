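---
title: "Quantitative MSI of surfactant peptides: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MSI of surfactant peptides: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfmsi)
```

`surfmsi` quantifies two synthetic surfactant peptides — an SP-C analog
(sodium adduct, m/z 3618) and an SP-B analog (protonated ion, m/z 3886) —
in MALDI-TOF images of lung sections, and relates section-level intensity
summaries to each animal's physiological response to surfactant
treatment.  This vignette documents the statistical model behind each
stage, the tunable parameters, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## Ion images

A dataset is a grid of pixels (350 µm raster by default), each carrying a
sparse peak list over m/z 1200–4500.  The ion image of a target m/z sums
all peak intensities within a ±1 Da window, **closed on both sides**; the
"1 Da tolerance" is read as a half-width, giving a 2 Da window.  Sum
rather than maximum is used because TOF peaks occasionally split across
neighbouring centroids; the choice is asserted against a brute-force
oracle in the tests.  Pixels never acquired are `NA`, distinct from an
acquired pixel with no in-window peak (0).

Files move through the imzML 1.1 standard: XML metadata plus a binary
`.ibd` with m/z stored as 64-bit and intensities as 32-bit little-endian
floats, linked by a UUID and protected by an MD5 checksum.  Both
continuous and processed encodings are supported and round-trip within
32-bit storage precision.

## Normalization chain

All statistics run on `log10(I + 1)`; the pseudocount of 1 raw unit is
negligible against typical TOF backgrounds of order 10²–10⁴ counts.

**Tissue segmentation** thresholds the log total ion current at its Otsu
optimum, closes small gaps morphologically, and keeps the largest
connected component.  If the thresholded foreground covers less than 20%
of the slide, the slide is treated as uniformly coated (a homogenate
calibration slide, whose only bright minority are the deposition spots)
and every acquired pixel is kept.  This guard means a genuine tissue
section occupying under a fifth of the grid would be misread; the
phantoms used here cover roughly 45%.

**Background identification** clusters the log intensities into two
populations with one-dimensional two-means, initialized deterministically
at the 10th and 90th percentiles (Lloyd's algorithm, so results are
reproducible); the lower-mean cluster is the background.  Constant input
degenerates to a single all-background cluster with a warning.

**Batch correction** subtracts, per sample and ion, the mode of the
log-intensity density — a Gaussian KDE with Silverman's bandwidth on a
512-point grid spanning the data range — which in practical terms sets
the mean background intensity to zero and makes samples from different
runs comparable.  The mode is estimated over **all** acquired pixels of
the slide, not tissue-only: on a strongly treated section the tissue
pixels are dominated by signal and their density mode would sit on the
signal peak.  Background dominance over the whole slide is an assumption;
a background-cluster-only variant is available via `mode_on =
"background"`.  Correction is a per-sample monotone shift: within-sample
pixel ranking is untouched.

**Noise threshold.**  The corrected tissue intensities of the untreated
control sections are pooled per ion and their empirical 99.5% quantile
becomes a hard threshold; a pixel counts as carrying signal only if its
corrected value exceeds it **strictly** (ties are background).  On
standard-normal input this reproduces Φ⁻¹(0.995) ≈ 2.576, and by
construction roughly 0.5% of control pixels land above it.

## Calibration and absolute quantification

Calibration slides carry six 0.5 µl spots of 1, 2.5, 5, 10, 25 and 50 ng
of both peptides on homogenate-coated glass, plus 6.25 ng of melittin as
a deposition marker; three independent experiments with two replicate
slides each.  Per slide:

1. two-means clustering of the analyte log intensities draws the
   signal/background boundary; the background average is taken over
   background-cluster pixels **outside** the melittin-marked areas and
   subtracted from every pixel.  (Averaging the raw background cluster
   lets the low-amount spots leak in and biases the intercept high by
   ~0.06 log units; clustering off-spot pixels alone splits the
   background Gaussian and biases it low by a similar amount.  The
   combination is unbiased to well within the fitted CIs.)
2. the melittin channel is clustered the same way and the connected
   components of its upper population, ranked by size, are the spotted
   pixel sets; spots are assigned to nominal amounts by the known stamp
   layout (row band, then column), never by intensity.
3. `c_pixel` = spot nanograms / detected spot pixel count — the areal
   allocation the "average concentration per pixel" requires.
4. the per-spot mean adjusted signal is fitted as
   `mean_signal ~ c_pixel + (1 | experiment)` by REML.  With only three
   experiments the intercept's between-experiment degrees of freedom are
   ~2, so normal-quantile Wald intervals undercover; 95% CIs therefore
   use Satterthwaite degrees of freedom.  A singular fit (zero estimated
   between-experiment variance) falls back to pooled OLS with a warning.

The per-spot-mean response (36 rows at the default design) is the
default; it keeps the residual structure simple while the experiment
random intercept carries the reproducibility information.  Quantification
inverts the fitted line per above-noise pixel, `amount = (signal −
intercept)/slope`, clamping negative estimates to zero (flagged); 95%
bounds take the extreme amounts over the four slope/intercept CI corner
combinations.  Random-effect uncertainty is deliberately ignored in the
inversion — a documented simplification.  Under the default noise
(pixel SD 0.1, experiment SD 0.05, batch SD 0.15) the recovered ng/pixel
has a median relative error around 5%, dominated by the smallest spots.

## Spatial statistics and section summaries

`distance_to_border` is the exact Euclidean distance transform of the
tissue mask, computed on a grid padded with one ring of background so the
grid edge counts as border (an all-tissue grid gets edge distance + 1);
it matches an exhaustive nearest-background search on every grid tested.
Profiles take 15 equal-width bins over 0.7–35.5 pixels (both endpoints
configurable; the defaults are the analysis range of the original
workflow) and report the median corrected signal per bin.

`Avg_log10_I` averages the corrected log10 intensity over all tissue
pixels; `Σ_log10_I` sums it over above-noise pixels.  The sum is taken on
the log scale, consistent with every other statistic in the chain; a
raw-scale variant (`sum_on = "raw"`) is available.  An empty above-noise
set gives Σ = 0 by convention.

## Physiology

`Cdyn = ΔV/(ΔP·weight)` in mL/kg/cmH₂O.  PaO2 and PaCO2 are
log10-transformed before analysis (their raw distributions are distinctly
non-normal); the transform records itself and refuses re-application.
Each animal × parameter series is summarized by its trapezoidal AUC over
the observed times (no extrapolation; log-scale AUC for the log-scale
parameters) and by the exact 120-min value (no interpolation — a series
ending early is an error).  Group comparison is a two-sided Student
t-test whose pooled/Welch branch is chosen by a Brown–Forsythe
(median-centred) Levene test at α = 0.05.  Associations between the
physiological AUCs (PaO2, Cdyn, PIP) and the MSI summaries are Spearman
correlations over treated animals with average ranks for ties; no
multiplicity correction by default, mirroring an exploratory screen (a
Benjamini–Hochberg flag exists).

## Synthetic-data generators

The generators produce the statistical structure the analysis assumes and
nothing more.  Sections: an elliptical tissue phantom; lognormal
background (normal on the log10 scale, SD 0.15) in every channel; peptide
signal on tissue with the SP-C:SP-B intensity ratio defaulting to 7.5
(the 1.5%:0.2% mass ratio of the formulation); a mild radial attenuation
toward the border (0.015 log10 units per pixel, giving the recoverable
centre-to-periphery gradient); three Gaussian hotspots of local
accumulation; an additive per-sample batch offset on the log10 scale; a
handful of decoy matrix peaks whose tissue-dependent component gives the
TIC its segmentation contrast.  Spectra are sparse peak lists with a
small m/z jitter (SD 0.1 Da, clipped at 0.35 Da) emulating TOF mass
scatter — no isotope envelopes, no ion suppression, no 3D geometry, no
MALDI physics.  Passing tests therefore certify the statistics of the
chain, not robustness to instrument artefacts absent from the simulation.

Calibration slides stamp the spot signal **on top of the slide's mean
background level** (default 2 log10 units ≈ 100 counts): the calibration
curve is defined on the background-subtracted scale, and an absolute
O(1)-count signal would be distorted by the log pseudocount.  With the
background level and all SDs set to zero the stamped per-pixel log10
signal is exactly `slope·c_pixel + intercept`, and OLS on the true spot
means recovers the generating line to floating-point.  The melittin
marker channel sits at m/z 2846 (the protonated average mass of
melittin), a simulation choice for a realistic marker position.

Cohorts follow the study design — 7 treated, 5 control, sampling at 0,
5, 30, 60, 90 and 120 minutes — with a latent lognormal
peripheral-deposition factor per treated animal that scales both the
section's peptide abundance and the physiological improvement (PaO2 and
Cdyn up, PaCO2 and PIP down, ramping to full effect over 30 min).
PaO2/PaCO2 noise is Gaussian on the log10 scale, other parameters on the
linear scale.  Controls get deposition 0.  With noise off, the PaO2 AUC
rank order equals the deposition rank order exactly.

All generators are deterministic given their seed and leave the caller's
RNG stream untouched.

## Problem sizes and numerical notes

The shipped studies use 50-seed calibration recoveries (full pipeline per
seed, ~30 s total), 100-seed association sign studies on 20×20-pixel
sections (the summaries only need enough pixels for stable ranks), and
500 null cohorts for the type-I check — sizes chosen so the whole suite
runs comfortably on a laptop while keeping the Monte-Carlo error of each
assertion well below its acceptance margin.  Quantile estimation uses R's
default type-7; the KDE grid step bounds the residual mode after batch
correction; two-means ties cannot occur with continuous data, and the
degenerate constant-input paths warn and fall back as described above.

## Known limitations

* The mode-subtraction batch model assumes background-dominated slides;
  slides where signal pixels dominate the density would be mis-centred
  (mitigated for strongly treated sections by pooling all pixels, but not
  eliminated for extreme coverage).
* The numeric coincidence of identical noise thresholds for both ions in
  the original workflow (0.20) cannot be checked without the original
  data; the package simply computes each ion's threshold independently.
* CI inversion in quantification ignores random-effect and residual
  uncertainty; the bounds are fixed-effect envelopes only.
* The uniformly-coated-slide guard in segmentation trades robustness for
  very small sections against correctness for calibration slides.
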