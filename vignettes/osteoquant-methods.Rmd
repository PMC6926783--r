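---
title: "Quantifying bone-graft performance: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bone-graft performance: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

osteoquant quantifies how well particulate bone-substitute materials
(e.g. sintered or unsintered bovine hydroxyapatite granules, 250-1000 µm)
support bone regeneration, from two kinds of raw data: stained
non-decalcified histological sections, and powder X-ray diffractograms of
the raw materials. Because animal sections from such studies are rarely
deposited, the package also ships a first-class synthetic-data generator
that plants known ground truth, so every stage of the chain can be verified
end to end. This vignette explains the models and the choices behind them.

## Histomorphometry

A section is reduced to a three-class label mask — newly formed bone,
biomaterial, soft tissue — inside two nested regions of interest: ROI1, the
whole defect, and ROI2, the part of the defect colonized by new bone. From
the mask we compute the defect and regenerated areas, percent regeneration
(100·|ROI2|/|ROI1|), the three tissue area fractions (reported against both
denominators, since either convention appears in practice), and the
osteoconductivity statistic:

**Bone-to-material contact (BMC)** — the percentage of the biomaterial
particle perimeter in direct contact with newly formed bone within ROI2.

### The edge metric

BMC's numerator is necessarily a count of bone-material pixel adjacencies.
We therefore define *both* contact and perimeter on the same primitive: a
boundary edge is a unit edge between a material pixel and a 4-adjacent
non-material pixel, with both pixels inside the ROI. Contact edges are
those whose non-material pixel is bone. Consequences:

* contact ⊆ perimeter, so 0 ≤ BMC ≤ 100 holds by construction, not by
  clamping;
* the known absolute bias of staircase perimeter estimators cancels in the
  ratio (we deliberately do not use Crofton or diagonal-corrected lengths,
  which would break the ratio semantics);
* BMC is invariant under integer upscaling of the masks, since numerator
  and denominator scale by the same factor;
* particle arcs clipped by the ROI border leave numerator and denominator
  symmetrically (an edge needs both incident pixels inside the ROI).

Coordinates are 0-based, x rightward, y downward, with the center of pixel
(x, y) at the point (x, y); ROI polygons are rasterized by the even-odd
rule on pixel centers. Areas convert to mm² through the configured µm/pixel
scale; without a scale, results stay in pixel units and are flagged.

## Color segmentation

Stained sections show the three classes in three distinguishable hues
(classically red bone, green biomaterial, purple soft tissue with methylene
blue / basic fuchsin). Segmentation is nearest-centroid against a 3-color
palette, by default in CIELAB: stain hues separate better there than in raw
RGB, and Euclidean distance is closer to perceptual difference. The palette
is supplied by configuration (defaults match the synthetic generator); there
is no automatic palette learning. Exact distance ties are broken by the
fixed class order bone < biomaterial < soft and reported. An optional 3×3
majority filter exists but is off by default, so accuracy tests measure the
classifier alone.

## The synthetic-section generator

`make_histology_scene()` emulates a digitized section: a rectangular defect
(ROI1) with a contained regenerated area (ROI2), biomaterial particles as
non-overlapping discretized ellipses (eccentricity ≤ 2:1, random
orientation — simple to rasterize and giving realistic perimeter variety),
a bone rim laid along a contiguous arc of each particle boundary by disc
dilation (default thickness 3 px), soft tissue elsewhere, and per-pixel
palette color plus Gaussian color noise, clipped to [0, 255].

The per-particle contact fraction is controllable (a number, vector, or
sampling function). The realized arc is quantized to whole boundary edges
and the dilation extends bone slightly past the arc ends, so the *planted*
fraction is a target; the *truth* record is exact: it is measured from the
generated label mask itself with the same edge metric as the measurement
code, and independently cross-checked in the tests by scalar brute-force
edge enumeration. Truth is therefore exact by construction, and the
noise-free chain (generate → segment → measure) must reproduce it
bit-exactly — which the tests assert.

Defaults are chosen to emulate the study conditions at desk scale: 5
µm/pixel, 1024×1024 images (a ~5 mm defect), 8 particles of 250-1000 µm,
color noise s.d. 15. The source study does not state its digitization
scale or resolution; these are the package's choices, not reproduced facts.

What the phantom does *not* emulate: staining texture and gradients,
section artifacts (folds, debris), stain bleed-through, or 3D structure.
Passing phantom-recovery tests shows the measurement chain is correct given
a well-separated palette; it does not certify segmentation accuracy on real
slides, where palette calibration dominates.

## Powder diffraction and crystallite size

Peak positions follow Bragg's law from the unit cells of the expected
phases (hydroxyapatite, hexagonal a = 9.424 Å, c = 6.879 Å; the trace
phases NaCaPO₄, orthorhombic, and CaO, cubic a = 4.8152 Å, whose (200)
reflection computes to 37.32°). d-spacings use the standard closed forms
for cubic, hexagonal and orthorhombic systems; relative intensities are
user inputs, since structure-factor computation is out of scope.

Peak shape is a Voigt profile: a Gaussian *instrumental* contribution of
fixed FWHM (default 0.05° 2θ — a single-parameter stand-in for a full
instrument model, whose metadata we do not have) convolved with a
Lorentzian *size-broadening* component. The crystallite size CS relates to
the Lorentzian's integral breadth β (area/height; β = (π/2)·FWHM for a
Lorentzian) through the Scherrer relation

CS = λ / (β cos θ),

with λ the Cu Kα1 wavelength (1.540598 Å) and β, θ in radians. Fitting
(`fit_peak()`) is Levenberg-Marquardt least squares of a linear background
plus a unit-height Voigt with the Gaussian width held fixed; free
parameters are center, height, Lorentzian FWHM and the background.
Initialisation takes the center from the window maximum, the background
from the window edges, and the width from the background-corrected
half-maximum width minus the instrumental width. A window whose maximum
does not exceed the edge noise by 3 s.d. is rejected as peakless; a
negative width estimate is clamped to zero with a warning.

The Voigt kernel is evaluated through the Faddeeva function w(z) via
Weideman's 36-term rational approximation (validated to ~1e-15 against
adaptive quadrature in the tests). Two numerical facts the tests respect:
the Lorentzian's 1/x² tails mean grid integration of a pattern converges
only as 1/(window width), so breadth oracles use adaptive quadrature with
infinite limits; and the convergence of a Voigt to the pure instrumental
Gaussian is first-order in the Lorentzian/Gaussian width ratio, so
"indistinguishable" (< 1e-6 of peak height) is reached only for effectively
infinite crystallites (~10⁸ nm at the default instrument width).

Reported sizes for such materials span ~29 nm (unsintered) to ~230 nm
(sintered at 1200 °C); the parameter-recovery tests plant sizes across this
range and require 5% recovery at realistic signal-to-noise. Phase
identification assigns each observed peak to the candidate reflection with
minimal |Δ2θ| within a tolerance (default 0.2°), else leaves it unassigned.

## Group statistics

The study design has several defects per animal, so defect outcomes are not
independent. The comparison model is a Gaussian linear mixed model with
fixed material-group effects and a per-animal random intercept — the
minimal structure consistent with "measurements share an animal" (random
slopes would not be identifiable from 2 defects per material per animal).
Fitting is REML via lme4; on balanced data the variance components coincide
with the closed-form expected-mean-squares solution, which the tests verify
to 1e-6. Outcomes are analyzed untransformed on the percent scale, matching
how such results are reported; the Gaussian identity link is an assumption,
noted here because percentages near 0 or 100 would strain it.

Noise-free tables (zero residual variance) are detected and short-circuited
to ordinary least squares with both components reported as zero — REML is
undefined there and the group means are exact anyway.

Pairwise comparisons use the Scheffé criterion: for groups i, j the
contrast F statistic is referred to p = P(F(k−1, df) ≥ F/(k−1)), with the
error variance and df taken from the blocked-design residual
(df = N − a − k + 1 for a animals and k groups; the source convention is
not stated, and this is the natural within-animal choice). Scheffé is
conservative for every contrast by construction, which the tests assert
dataset by dataset. With zero error variance, p-values take their limits
(0 for unequal means, 1 for equal), flagged by a warning.

The a-priori design computation is the classical noncentral-F power
analysis for a one-way fixed-effects ANOVA: power
= P(F′(k−1, N−k, λ = f²N) ≥ F_crit(α; k−1, N−k)), searched over N in
multiples of k (equal allocation, matching the balanced within-animal
design). With k = 3, Cohen's f = 0.6, α = 0.05 and power 0.8 the smallest
such N is 30 — ten defects per material — which is the design actually
used.

```{r}
library(osteoquant)
anova_sample_size(k = 3, f = 0.6, alpha = 0.05, power = 0.8)
```

## The pipeline and problem sizes

`run_pipeline()` composes the stages: per-defect scene simulation (with
per-group contact-fraction means, an animal-level shift, and defect-level
variation), segmentation, measurement, tabulation, mixed-model fit and
Scheffé comparisons, plus a manifest (config hash, seed, package version,
defect accounting). Every stochastic stage draws its seed deterministically
from the run seed, so reruns are byte-identical — asserted in the tests.
The default configuration mirrors the in-vivo design: 5 animals × 6 defects
with the three materials balanced within each animal (30 defects, 10 per
condition) and one animal excluded from analysis (24 defects, 8 per
condition).

Problem sizes in the shipped tests are the package's own choices to keep
the suite interactive: pipeline scenes run at 160-320 px and the full
1024×1024 phantom-recovery check runs once; the Monte-Carlo suites use
1000 replicates (null calibration, random-mask oracle equivalence) or
20-500 seeds (parameter recovery). All tolerances asserted in the tests are
stated there explicitly.

## Known limitations

* Segmentation is nearest-centroid only; real slides with stain gradients
  or overlapping hues need palette calibration or stain deconvolution,
  which is out of scope.
* The edge-count perimeter is exact for the BMC ratio but biased as an
  absolute length; do not compare `perimeter_edges` across different
  rasterizations.
* The instrument profile is a single Gaussian; strain broadening, Kα1/Kα2
  splitting and full Rietveld refinement are out of scope, so crystallite
  sizes are comparable within this model, not absolute.
* The mixed model assumes Gaussian errors on the percent scale and a
  random intercept only; unbalanced exclusions are handled, but the overall
  F test is exact only for the balanced blocked layout.
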