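---
title: "Methods: en-face OCT/OCTA quantification and paired-eye statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: en-face OCT/OCTA quantification and paired-eye statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaquant)
```

## The measurement model

OCT angiography resolves the retinal microvasculature as en-face slabs: the
superficial (SCP) and deep (DCP) capillary plexuses and the
choriocapillaris (CC). En-face structural OCT of the ellipsoid zone (EZ)
proxies photoreceptor integrity through its reflectivity. This package
quantifies those slabs inside a circular foveal region of interest and
compares study against fellow eyes within subjects.

Every image is normalized to $[0,1]$ at read time by dividing by the
bit-depth maximum, so the downstream math never depends on whether a device
exports 8 or 16 bits — physical intensity scales of different devices are
not comparable anyway, which is also why the EZ analysis is built entirely
on a within-eye normalization.

### ROI geometry

The ROI is a disc of radius 1.5 mm centered on the fovea (the radius
reflects the limited lateral resolution of en-face imaging; smaller regions
are too noisy, larger ones leave the 3 mm field). Choices that must be
pinned down for reproducible masks, and that we fix as package conventions:

* pixel coordinates are 0-based `(row, col)` and refer to **pixel centers**;
* a pixel belongs to the ROI when its center is within
  `radius_mm / pixel_pitch` of the fovea center, with
  `pixel_pitch = scan_width_mm / ncol` (for a 3 mm / 304 px scan: 152 px);
* the disc must fit inside the physical image extent
  $[-0.5,\,n-0.5]$; a fovea too close to an edge is an error, never a
  silently truncated ROI;
* the fovea center is operator-supplied metadata. Fovea localization is a
  human/device step (IR and B-scan correlates) that we deliberately do not
  automate.

Scans qualify only with a signal strength index **strictly** above 8/10;
rows with missing SSI are excluded and reported, never silently dropped.

### Binarization

SCP/DCP slabs are thresholded globally. The exact thresholder behind
published ImageJ workflows is typically unstated, so it must be an explicit,
swappable choice: the default is **Otsu's method computed from the ROI
intensities only** (256-bin histogram, exhaustive between-class-variance
maximization), with the ROI mean available as `method = "mean"`. Both are
recorded in the mask's provenance. Two conventions apply everywhere:

* **ties go to background** — foreground always means intensity strictly
  greater than the threshold;
* **outside-ROI pixels are never foreground**.

A constant ROI has no separable classes; the result is an all-background
mask plus a warning rather than an arbitrary split.

The CC is binarized with the **Phansalkar local threshold**, designed for
low-contrast images:

$$T = m\left(1 + p\,e^{-q m} + k\left(\frac{s}{r} - 1\right)\right)$$

with $m$ and $s$ the mean and standard deviation of the intensities in a
circular window around the pixel. Defaults follow the de-facto standard
implementation (window radius 15 px, $k = 0.25$, $r = 0.5$, $p = 2$,
$q = 10$); all are configurable. Numerical conventions we fix: the window
is **circular**, truncated (not padded) at image borders; $s$ is the
**population** SD (divide by $n$), matching common ImageJ/scikit-image
behavior. The implementation accumulates window sums by matrix shifts and
is tested for exact (bit-identical) agreement with a per-pixel brute-force
oracle.

### Skeletonization and the three vascular metrics

Vessel length density requires 1-px centerlines. We thin with the classic
two-subiteration Zhang–Suen rules (8-connected foreground), with one
refinement: candidate pixels are deleted **sequentially**, re-verifying the
deletion conditions against the partially thinned image. The textbook
fully parallel scheme can annihilate a 2×2 component outright and leave
staircase residue; the sequential recheck guarantees each deleted pixel is
still simple at deletion time, so the skeleton is a subset of its source
and preserves the 8-connected component count — the invariant that makes
VLD "count each vessel once". Like all thinning schemes, rounded bar ends
erode by up to half the local width; VLD tolerances in the tests reflect
that.

Inside the ROI:

$$\mathrm{PD} = 100\,\frac{|F \cap R|}{|R|},\qquad
  \mathrm{VLD} = 100\,\frac{|S \cap R|}{|R|},\qquad
  \mathrm{VDI} = \frac{|F \cap R|}{|S \cap R|}$$

with $F$ the foreground, $S$ the skeleton, $R$ the ROI. All three are
pixel-count ratios — pixel pitch cancels, so no physical-unit conversion
enters. VLD is reported as a percent of ROI area (values around 2.7–3.4%
for real plexuses), not mm/mm². VDI is dimensionless (reported values
around 5.7–6.5 are only coherent as a ratio — roughly mean vessel width in
pixels — even where the literature prints a percent sign on it). The
identity $\mathrm{PD} = \mathrm{VDI}\times\mathrm{VLD}$ holds to rounding
whenever the skeleton is non-empty; an empty skeleton flags VDI as `NA`
rather than inventing a value.

### Normalized EZ reflectivity

The EZ mean brightness is rescaled between a dark reference (vitreous) and
a bright reference (RNFL):

$$EZ_{norm} = \frac{\bar I_{EZ} - \bar I_{vit}}{\bar I_{RNFL} - \bar I_{vit}}$$

This two-point normalization is the only formula consistent with using
vitreous and RNFL as dark/bright references, and its value is invariant
under any global affine transform $aI + b$ ($a > 0$) applied jointly to the
three structures — that invariance is the normalization's entire purpose
and is verified to $10^{-10}$ over random transforms. Values are not
clamped to $[0,1]$: out-of-range results diagnose references that fail to
bracket the EZ signal. Whether reference means are taken over the whole
reference slab or inside the same ROI is genuinely underdetermined in the
literature; both are exposed (`reference_scope = "full"`, the default, or
`"roi"`). The `"roi"` scope makes a *spatially varying* shared
multiplicative gain cancel exactly, because all three means then weight the
gain field identically; `"full"` cancels it only approximately. Post-
vitrectomy eyes, where the vitreous reference is compromised, are out of
scope.

## Paired-eye statistics

Using both eyes of each subject creates nested paired data, so each metric
is analyzed with a two-sided paired Student's t-test on the differences
$d_i = \mathrm{study}_i - \mathrm{fellow}_i$:
$t = \bar d / (s_d/\sqrt n)$, $n-1$ df. Shapiro–Wilk on $d$ is attached as
an advisory diagnostic, never a gate. Zero-variance differences are
rejected with a diagnostic (the t statistic is undefined), not reported as
$p = 1$. The formatted summary prints mean ± SD to 2 decimals and p to 3
decimals, one row per metric. No multiple-testing correction is applied by
default — eight uncorrected tests mirror standard practice in this
literature — with `adjust = "holm"` as an explicit opt-in.

Power uses the exact noncentral-t formulation, not the normal
approximation: $\mathrm{power}(n) = P(|T'| > t_{1-\alpha/2,\,n-1})$ with
$T'$ noncentral t, ncp $= d\sqrt n$. `required_sample_size()` scans $n$
upward and returns the exact minimum; for $d = 0.7$, $\alpha = 0.05$, 80%
power that minimum is 19, consistent with (and slightly below) the common
practice of planning for 20 — planning figures are rounded up. Two facts
surprised us enough to test explicitly: Monte-Carlo power at the returned
$n$ matches the analytic value within simulation error, and at the $n = 2$
floor even $d = 10$ only reaches power 0.733 (df = 1 tails), so the true
minimum there is 3.

## What the synthetic generators emulate — and what they do not

All generators are pure functions of their spec including the seed (the
session RNG is saved and restored), and they emit their ground truth
alongside the images; truth is never re-estimated.

**Vessel slabs** are procedural branching strokes — smooth random walks
stamped with a circular brush of random width (3–9 px), rendered with a
0.7 px Gaussian blur (point-spread) and 8% multiplicative speckle over a
low background. The generator keeps adding strokes, adaptively shortening
them, until the mask's area fraction *inside the centered foveal ROI* is
within ±0.02 of target; the fraction is measured where PD is measured, so
"PD on the ground-truth mask equals the target" holds by construction.
These are not physiologic angiogenesis models: they exercise area/length/
width recovery, not capillary morphology, flow voids of disease, or
projection artifacts.

**CC textures** are smoothed-noise granule fields (base level 0.60,
modulation amplitude 0.10, granule correlation length 4 px) with darker
flow-void blobs occupying an exact, quantile-thresholded fraction. The
modulation amplitude was set once so that Phansalkar binarization marks
perfused granular tissue as foreground the way it does on real CC images;
with half the field voided at high contrast, PDCC lands in the 40–60%
band expected when the threshold tracks true voids.

**Reflectance scenes** are flat EZ/vitreous/RNFL reflectance levels
(defaults 0.40 / 0.10 / 0.75) under one shared smooth multiplicative gain
field plus additive Gaussian noise — exactly the disturbance the
normalization exists to cancel, and nothing else (no layer segmentation
error, no shadowing).

**Cohorts** draw per-subject, per-metric bivariate normal (study, fellow)
pairs. The default means and SDs are typical macula-on retinal-detachment
values for all eight metrics; the within-pair correlation is a free
parameter defaulting to 0.5 (a typical inter-eye correlation; published
reports rarely state it). Under a null parameterization the pipeline's
type-I error is nominal by construction of the t-test; the tests verify it
by simulation.

Passing tests on these generators show the *pipeline arithmetic* recovers
known truth under controlled degradation. They do not validate the
biological claim that any metric discriminates disease — that requires real
cohorts.

## Problem sizes and numerical tolerances

The test suite and acceptance script run at sizes chosen to keep a full
check-out under a few minutes on one core while preserving the study
geometry where it matters: 304 px / 3 mm slabs with the 1.5 mm ROI for
geometry- and texture-sensitive checks, 200 px fields with a scaled ROI for
the 20-seed recovery loops, 32–96 px images for bit-exact oracle
comparisons, 1,000 cohort replicates for type-I error, and 100,000
simulated paired samples for Monte-Carlo power. Tolerances: Phansalkar vs
oracle is exact (no tolerance); the PD identity holds to $10^{-6}$; PD
recovery is checked to ±2 percentage points; affine invariance to
$10^{-10}$; Monte-Carlo vs analytic power to ±1.5 points.

## Known limitations

* No proprietary device formats (Heidelberg E2E, Zeiss raw, DICOM), no
  B-scan segmentation, no ETDRS-grid or fovea localization, no
  projection-artifact removal, no multi-frame registration.
* The global SCP/DCP thresholder behind published ImageJ pipelines is not
  re-derivable from the literature; Otsu-within-ROI is a declared default,
  not an inference, and results depend on it.
* Thinning-based VLD is resolution-sensitive: on marginally sampled
  capillaries (pixel width near the focal-spot diameter) skeleton
  continuity, and hence VLD, degrades — a property of the method, not of
  this implementation.
* Fractal dimension, tortuosity, FAZ metrics and flow-void size
  distributions are out of scope.
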