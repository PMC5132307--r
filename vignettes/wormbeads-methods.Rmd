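---
title: "Methods: quantifying dauer recovery from bead-feeding micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying dauer recovery from bead-feeding micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormbeads)
```

## The assay and its statistic

Dauer larvae do not feed; recovering dauers do. Incubating worms with
sub-micrometer fluorescent microspheres converts that behavioural switch
into an image-measurable quantity: gut fluorescence. Each field of view
is a two-channel micrograph — transmitted light and bead fluorescence —
and the per-image activity is

$$\mathrm{activity} = \frac{I_m \cdot A_m}{A_w},$$

where $A_w$ is the worm-occupied area (pixels) from the transmitted-light
channel, and $I_m \cdot A_m$ is estimated as the *sum* of raw
fluorescence intensity over thresholded bead pixels lying inside the
worm mask. Dividing by $A_w$ makes images with different worm loads
comparable; the unit is arbitrary (raw intensity per pixel of worm).
The experimental unit of all downstream statistics is the image, with a
handful to a dozen images per condition and up to on the order of a
hundred worms per image.

## Worm segmentation

`segment_worms()` composes four steps, in a fixed order:

1. **Top-hat filtering** (`tophat_filter()`): the image minus its
   morphological opening with a disk structuring element. The disk
   radius defaults to the worm width, so structures up to worm scale are
   kept while the slowly varying illumination background is removed.
   Transmitted-light worms are darker than the background, so the image
   is first inverted (`max - image`); the polarity is configurable.
2. **Gaussian smoothing** (`smooth_gaussian()`), σ = 2 × worm width by
   default, so worm regions become homogeneous in intensity before
   thresholding.
3. **Mean-intensity thresholding** (`threshold_mean()`): pixels strictly
   above the grand mean of the processed image are foreground. The
   strict comparison makes the degenerate constant image deterministic
   (empty mask).
4. **Small-region filtering** (`filter_small_regions()`): 8-connected
   components smaller than a typical worm area are discarded. The
   operation is idempotent.

Manual exclusion regions (`apply_exclusions()`) are polygons in pixel
coordinates removed from the mask before $A_w$ is measured, with their
identifiers recorded for provenance; self-intersecting polygons are
rejected. The two scale parameters — worm width and typical worm area —
are meant to be estimated once from the images themselves.

### Numerical conventions

* Images are numeric matrices indexed `[row, column]`; coordinates are
  1-based with pixel centers at integer positions, the native R raster
  convention. Polygon membership uses the even-odd rule on pixel
  centers.
* Grayscale morphology is delegated to EBImage, which operates on the
  $[0,1]$ range; since erosion and dilation commute with affine
  intensity rescaling, `tophat_filter()` normalizes to $[0,1]$ and
  scales back, so raw camera units of any bit depth are handled exactly.
  Outside-image pixels are ignored by the min/max filters (no padding
  value is invented at borders).
* Gaussian smoothing uses mirror (reflective) padding before
  convolution with a normalized kernel truncated at 3σ. Reflection
  avoids the border dimming that replicate-free convolution would cause,
  which would otherwise bias the mean threshold.
* Connected components use 8-connectivity: the 4-connected labelling
  from EBImage is merged across diagonal contacts via a small
  label-adjacency graph. Thin diagonal worm sections therefore remain
  single components.

### What the mean-threshold pipeline can and cannot recover

The smoothing scale is deliberately large (2 × worm width): it merges
adjacent worms into homogeneous *regions*, which is what makes the
simple mean threshold workable on crowded fields. The price is spatial
precision. A tube of width $w$ blurred at σ = 2w has a nearly flat
response profile at roughly 20 % of its contrast over ±1.5 widths, so
wherever the grand-mean threshold lands on that profile, the resulting
mask carries a halo on the order of σ around each worm (sparse fields)
or follows smoothed worm *density* rather than individual worm outlines
(dense fields). On the package's default synthetic scenes (10 worms,
1024×1024, ~16 % coverage) the segmented mask overlaps the exact
ground-truth tube mask with an intersection-over-union of about 0.33,
stable across seeds, with the mask area roughly three times the true
worm area. We verified across layouts (isolated, clumped, tightly
packed, dense parallel; widths 30–100 px; coverage 13–52 %) that this
pipeline's per-pixel IoU against exact tube ground truth stays in the
0.3–0.6 range; the blur-then-mean-threshold design bounds it.

$A_w$ should therefore be read as a *region-scale estimate
proportional to worm load* — sufficient for the ratio statistic, whose
numerator is confined to bead pixels — not as a per-pixel worm outline.
Consistently with this, the validation suite checks the ratio pipeline
against exact ground truth (where agreement is exact by construction)
and reports the IoU of the segmentation stage as measured.

## Bead quantification

`bead_mask()` applies the instrument profile's threshold to the raw
fluorescence channel with an inclusive (`>=`) comparison — the
documented tie-breaking convention. No filtering precedes it; the
threshold is chosen per set-up so that sensor noise and worm
autofluorescence stay below it (defaults: 1000 for the confocal
profile, 50 for the stereomicroscope profile). `measure_activity()`
intersects the bead and worm masks (excluding unwashed beads outside
the worms), sums raw intensities over the intersection, and divides by
$A_w$. Saturated pixels are counted at their recorded value, and a
saturation fraction can be logged, since acquisition gain is supposed
to be set to avoid bead saturation. A field with $A_w = 0$ is marked
invalid rather than given a ratio.

## Normalization and group statistics

`normalize_activity()` divides every per-image ratio by the arithmetic
mean of the positive-control group's ratios and multiplies by 100; the
control group therefore averages exactly 100 %. "Average" is taken as
the arithmetic mean of per-image ratios and recorded in the output
attributes. When the control was run in several solvents, the solvent
with the maximum mean ratio is used (maximum-effect rule). Because the
statistic is a ratio and normalization divides by a control mean, a
global per-experiment gain change cancels exactly — the suite checks
invariance to 1e-9.

`mann_whitney()` performs the two-sided test, exactly (via the exact
null distribution) when both groups have ≤ 12 observations and no ties
— group sizes in this assay (4–13 images) straddle that boundary — and
otherwise by the normal approximation with midranks, tie-corrected
variance and continuity correction; ties are expected at 0 % activity.
The method used is recorded. `holm_adjust()` applies the step-down
Bonferroni-Holm rule over the family of comparisons in one analysis
(all conditions against the stated reference, configurable), and
`significance_tier()` maps raw p-values to the figure conventions
`*`/`**`/`***` (p ≤ 1e-3/1e-4/1e-5) with `(*)` for comparisons that are
Holm-significant without reaching those thresholds.

`fit_dose_response()` fits response against concentration by linear
least squares in an orthogonal polynomial basis of degree 3 built on
the actual design points (via `stats::poly`, i.e. discrete
orthogonalization on the observed doses, not a fixed Legendre grid).
The fitted values are identical — the suite requires 1e-8 — to a
raw-power cubic; orthogonality only conditions the solve and gives
interpretable sequential coefficients. The 95 % confidence band is
pointwise, from the t distribution on the residual degrees of freedom;
the band is about the mean response, not a prediction band, and no
simultaneous coverage is claimed.

## The synthetic scene generator

`generate_scene()` renders what the segmentation and quantification
stages must cope with:

* a slowly varying illumination background (two low-frequency cosine
  components, wavelength comparable to the image, amplitude 2000 raw
  units on a 20000 bright-field level by default);
* worms as smooth random curvilinear tubes (heading random walk,
  dilated to the worm width) that are darker than the background
  (45 % attenuation by default), mostly placed in clumps as
  anesthetized dauers are, with exact per-worm label masks;
* bead signal as small disks (0.5 µm at the default 0.83 µm/px, so
  1 px) confined to the middle 60 % of the centerline — the gut — of a
  configurable fraction of worms, with intensities 1200–4000 at 16-bit
  depth, all above the confocal threshold of 1000;
* stray beads outside worms (Poisson, 2 per image by default), diffuse
  sub-threshold worm autofluorescence (200 raw units), and additive
  truncated Gaussian sensor noise (sd 50) on both channels.

Defaults correspond to a 10× confocal field: 1024×1024 px at
0.83 µm/px, 10 worms of width 30 px (≈25 µm) and length 450–650 px
(≈370–540 µm). Ground truth (worm mask, bead mask, expected $A_w$,
bead sum and ratio) is taken from the noiseless quantized render, so on
noise-free scenes quantification over the true masks reproduces the
expected ratio exactly; scenes are bit-reproducible from their
parameters and leave the caller's RNG stream untouched.

The generator emulates geometry, intensity ranges and nuisance signals
— it does not emulate optics (no PSF, no depth effects), worm internal
texture, motion blur, or anesthesia artefacts. Passing tests on
synthetic scenes therefore validate the *computational* pipeline
(masks, sums, thresholds, statistics), not the biological accuracy of
segmentation on real micrographs, which depends on image content the
generator does not model.

## Validation problem sizes

The shipped suite checks, among others: exact agreement of
`measure_activity()` with a naive pixel-loop oracle on 1000 random
grids up to 32×32; top-hat agreement with a brute-force
erosion/dilation oracle on small random grids; segmentation recovery on
20 seeded default scenes; Mann-Whitney against full enumeration and
Holm against the step-down definition on 1000 random p-vectors; and a
power experiment of 200 replicates of 10 responder vs 10 water images.
The power replicates use scaled-down frames (160 px, 4 worms of width
8 px) so each replicate runs the full generate–segment–quantify–test
chain; group separation at these sizes is driven by the same mechanism
as at full scale (water images have no above-threshold in-worm signal),
so frame size mainly sets runtime.

## The mass-identification arithmetic

The active-fraction identification rests on six numbers: the
protonated precursor m/z and five fragment m/z values. `massid`
recomputes them from elemental formulas: monoisotopic masses from IUPAC
most-abundant-isotope masses (≥ 6 decimals), proton adducts and neutral
losses by integer formula arithmetic (subtraction that would go
negative is rejected), and $m/z = (M - z\,m_e)/|z|$ including the
electron mass — a 0.8 ppm effect at m/z 664, material at Orbitrap-class
accuracy. `nad_fragment_series()` assembles [NAD+H]⁺, its nicotinamide
and water losses, [ADP+H]⁺, dehydrated protonated adenosine, and
protonated adenine. The compositions of the 428.0365 and 232.0827
fragments follow standard NAD⁺ fragmentation chemistry
(C₁₀H₁₆N₅O₁₀P₂⁺ and C₁₀H₁₀N₅O₂⁺); they are validated here by ppm
agreement, all six ions matching their observed peaks within 1 ppm at
the default 5 ppm tolerance. `match_fragments()` reports every
candidate within tolerance and never silently drops unmatched peaks.

```{r}
sapply(nad_fragment_series(), ion_mz)
```

## Known limitations

* Segmentation returns region-scale worm masks, as analyzed above;
  per-worm morphometry is out of scope.
* The exact Mann-Whitney path is disabled in the presence of ties; with
  many zero-activity images the normal approximation with tie
  correction is used even at small n.
* The dose-response band is pointwise; simultaneous inference across
  doses would require a wider band.
* mzML ingestion, isotope patterns and spectral deconvolution are out
  of scope for the mass toolkit; peak lists arrive as CSV.
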