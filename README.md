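# octaquant

Quantification of en-face OCT / OCT-angiography macular slabs, with the
paired-eye statistics used in study-vs-fellow-eye designs (for example
subclinical macular change in macula-on rhegmatogenous retinal detachment,
where the unaffected fellow eye serves as the paired control).

The package is aimed at retinal imaging researchers who export en-face slab
images (superficial and deep capillary plexus, choriocapillaris, ellipsoid
zone, plus vitreous and RNFL reference slabs) and want a reproducible,
scriptable alternative to manual ImageJ workflows — with every
quantification choice (thresholder, window, tie rule, ROI geometry)
explicit, recorded in provenance, and tested against brute-force oracles.

## What it computes

All vascular metrics are measured inside a circular foveal region of
interest (ROI) of radius 1.5 mm by default, built with pixel-center
geometry from the scan's physical width:

* **Perfusion density** `PD = 100 · |vessel ∩ ROI| / |ROI|` (%), after
  binarization — Otsu's between-class-variance threshold computed from ROI
  intensities for SCP/DCP (a ROI-mean threshold is available as an option).
* **Vessel length density** `VLD = 100 · |skeleton ∩ ROI| / |ROI|` (%),
  after topology-preserving Zhang–Suen-style thinning of the binarized
  network to 1-px centerlines.
* **Vessel diameter index** `VDI = |vessel ∩ ROI| / |skeleton ∩ ROI|`, a
  dimensionless surrogate for mean vessel caliber (average width in
  pixels). The identity `PD = VDI × VLD` holds by construction.
* **Choriocapillaris perfusion density (PDCC)**, using the Phansalkar local
  threshold designed for low-contrast images:
  `T = m · (1 + p·e^{−q·m} + k·(s/r − 1))` with window mean `m` and SD `s`
  (defaults: circular window of radius 15 px, k = 0.25, r = 0.5, p = 2,
  q = 10).
* **Normalized EZ reflectivity**
  `(mean_EZ − mean_vitreous) / (mean_RNFL − mean_vitreous)`, a two-point
  rescaling between a dark and a bright reference structure that cancels
  acquisition gain and offset across subjects and devices.
* **Paired statistics**: per-metric mean ± SD per eye, Shapiro–Wilk
  normality of the paired differences (advisory), two-sided paired
  Student's t-tests, optional Holm adjustment, and the exact noncentral-t
  power / minimal-sample-size calculation for paired designs.

Synthetic-data generators (`generate_vessel_slab()`, `generate_cc_texture()`,
`generate_reflectance_scene()`, `generate_cohort()`) produce every input the
pipeline needs with known ground truth, so the whole chain is testable
end to end.

## Worked example

```r
library(octaquant)

# a synthetic SCP slab with a known 20% vessel area fraction inside the ROI
g <- generate_vessel_slab(side_px = 304, area_fraction = 0.2, seed = 42)
quantify_slab(g$slab, radius_mm = 1.5)
#> # A tibble: 1 × 6
#>   slab_kind pd_percent vld_percent   vdi n_roi_px method
#>   <chr>          <dbl>       <dbl> <dbl>    <int> <chr>
#> 1 SCP             19.6        3.43  5.69    72580 otsu
```

The pipeline recovers the generated 20% perfusion density to 0.4
percentage points (the ground-truth mask fraction was 19.5%); VLD and VDI
land in the range reported for real superficial plexus scans, and
`19.6 ≈ 5.69 × 3.43` up to rounding.

```r
# a 21-subject paired cohort drawn from typical macula-on RD parameters
coh <- generate_cohort(n_subjects = 21, seed = 42)
summarize_cohort(coh)
#> Paired study-vs-fellow-eye comparison (n up to 21 pairs, alpha = 0.05, none adjustment)
#>  Metric                        Study eye    Fellow eye   P value
#>  SCP perfusion density (%)     18.19 ± 3.65 20.71 ± 4.89 0.009
#>  SCP vessel length density (%) 2.62 ± 0.54  3.43 ± 0.70  0.000
#>  SCP vessel diameter index     6.37 ± 0.38  6.19 ± 0.29  0.020
#>  DCP perfusion density (%)     15.66 ± 3.47 16.40 ± 2.83 0.218
#>  DCP vessel length density (%) 2.73 ± 0.69  2.97 ± 0.75  0.224
#>  DCP vessel diameter index     5.66 ± 0.53  5.85 ± 0.29  0.120
#>  CC perfusion density (%)      48.97 ± 6.45 57.29 ± 6.66 0.000
#>  EZ normalized reflectivity    0.30 ± 0.06  0.41 ± 0.11  0.000

required_sample_size(effect_size = 0.7, alpha = 0.05, target_power = 0.80)
#> # A tibble: 1 × 5
#>   effect_size alpha target_power n_required achieved_power
#>         <dbl> <dbl>        <dbl>      <dbl>          <dbl>
#> 1         0.7  0.05          0.8         19          0.823
```

Each row is one paired two-tailed t-test on the study − fellow differences;
p-values are uncorrected by default (use `adjust = "holm"` to opt in). The
sample-size row says 19 pairs suffice for 80% power at effect size 0.7 —
consistent with planning such a study around 20 patients.

Real data enter through `read_slab()` (8/16-bit single-channel TIFF or PNG,
rescaled to [0, 1] by the bit-depth maximum), a CSV manifest
(`read_cohort_manifest()`, filtered by `apply_inclusion_filter()` which
keeps scans with signal strength index strictly above 8/10), and results
leave through `write_cohort_table()`. `autoplot()` methods and
`plot_binarization()` render slabs, masks, skeletons and cohort summaries.

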