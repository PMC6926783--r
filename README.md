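# osteoquant

Quantification chain for evaluating particulate bone-graft biomaterials —
the kind of study where 250-1000 µm hydroxyapatite granules are implanted
into standardized bone defects and judged by histomorphometry, with the raw
materials characterized by powder X-ray diffraction.

The package covers, as tested R functions:

* **Histomorphometry.** Three-class color segmentation of stained sections
  (nearest palette centroid in CIELAB), ROI polygon rasterization, tissue
  area fractions in the defect (ROI1) and regenerated (ROI2) areas, percent
  regeneration, and the osteoconductivity statistic **BMC**
  (bone-to-material contact): the percentage of biomaterial particle
  perimeter in contact with newly formed bone,

  BMC = 100 · (contact edges) / (perimeter edges),

  where both counts use the identical 4-connectivity pixel-edge metric, so
  0 ≤ BMC ≤ 100 holds by construction.
* **Synthetic phantoms.** Seeded generators for stained-section scenes with
  planted, exactly-bookkept ground truth (per-particle boundary and contact
  edges, true area fractions, true BMC) and for per-defect study tables
  with animal random effects — the substrate for verifying the whole chain.
* **Powder XRD.** d-spacings and Bragg angles for cubic / hexagonal /
  orthorhombic cells, Voigt peak simulation and fitting (fixed Gaussian
  instrument FWHM ⊗ Lorentzian size broadening), and crystallite size via
  the Scherrer relation CS = λ / (β cos θ) with β the Lorentzian integral
  breadth; phase identification by nearest d-spacing match.
* **Statistics.** Random-intercept mixed model (REML) for per-defect
  outcomes clustered in animals, Scheffé-adjusted pairwise group
  comparisons, correlations, and the noncentral-F a-priori sample-size
  computation for a one-way ANOVA.
* **Pipeline.** `run_pipeline()` composes simulate → segment → measure →
  tabulate → compare with deterministic seeding and a run manifest.

## Worked example

```r
library(osteoquant)

# a synthetic section with known truth: 5 particles, noisy colors
sp <- scene_spec(size = 512, scale_um_per_px = 10, n_particles = 5,
                 contact_fraction = function(n) runif(n, 0.2, 0.8),
                 noise_sd = 15, seed = 42)
scene <- make_histology_scene(sp)
scene$truth
#> <scene_truth: 5 particles, true BMC 63.00 % (722/1146 edges)>
#>   ROI1 fractions: bone 1.00 / biomaterial 5.94 / soft 93.05 %

# segment the rendered image and measure the defect
mask <- segment_colors(scene$image, roi = scene$truth$roi1)
measure_defect(mask, scene$truth$roi1_mask, scene$truth$roi2_mask,
               scale_um_per_px = 10)
#> Histomorphometric measurement
#>   defect area (ROI1): 222784 px = 22.278 mm^2  |  regenerated (ROI2): 152100 px = 15.210 mm^2
#>   regeneration: 68.27 %
#>   within ROI1:  bone 1.01 %, biomaterial 5.94 %, soft 93.04 %
#>   within ROI2:  bone 1.48 %, biomaterial 8.71 %, soft 89.81 %
#>   BMC: 722 / 1146 contact edges = 63.00 %
```

The measured BMC recovers the planted truth (63.00%) through the noisy
image — here bit-exactly, since color noise of s.d. 15 rarely flips a
pixel across the well-separated palette; with `noise_sd = 0` the whole
chain is always bit-exact.

```r
# crystallite size from a simulated diffractogram (planted CS = 120 nm)
pat <- simulate_pattern(data.frame(two_theta = 31.77, intensity = 1000),
                        cs_nm = 120, instrument_fwhm = 0.05,
                        noise_sd = 20, seed = 7)
fit_peak(pat, window = c(30.5, 33.5), instrument_fwhm = 0.05)
#> <peak_fit: center 31.7702 deg 2theta, height 1006.6, FWHM_L 0.04762 deg>
#>   integral breadth beta = 0.00130555 rad;  Scherrer CS = 122.7 nm

# the a-priori design computation: 3 groups, Cohen's f = 0.6, power 0.8
anova_sample_size(k = 3, f = 0.6, alpha = 0.05, power = 0.8)
#> [1] 30

# end-to-end synthetic study: 5 animals x 6 defects, 1 animal excluded
out <- run_pipeline(default_pipeline_config(), out_dir = "runs/demo")
out$bookkeeping$n_defects_analyzed
#> [1] 24
summary(out$fit)
```

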