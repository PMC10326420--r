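---
title: "Schlemm's canal morphometry and IOP-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Schlemm's canal morphometry and IOP-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmorph)
```

## The problem

Schlemm's canal (SC) is the circumferential vessel at the iridocorneal angle
that drains aqueous humor from the eye. Because the trabecular meshwork
between the anterior chamber and SC transmits pressure changes to the canal,
the degree to which the SC lumen collapses or dilates as intraocular pressure
(IOP) is clamped above or below baseline is a functional readout of outflow
tissue mechanics: a stiffer or malformed meshwork deforms less per mmHg.

In anterior-segment OCT, the SC appears in each cross-sectional B-scan as a
thin lumen immediately lateral to the iridocorneal angle. After (manual)
segmentation of the lumen, this package computes the morphometrics used to
quantify that response — cross-sectional area, width, height, and volume over
a fixed analyzed length — and fits linear models of these quantities against
the IOP offset, including slope-difference tests between genotype groups.
Because studies of this kind rarely deposit raw imaging volumes, the package
also generates synthetic mask stacks with exact analytic ground truth, so the
entire analysis chain can be validated by parameter recovery.

## Input data and conventions

The raw input is a `mask_stack`: an ordered series of binary per-B-scan
masks with physical calibration. Rows run along the axial (depth) direction,
columns along the lateral direction. Defaults mirror the emulated system:
7 µm/px laterally, 1.3 µm/px axially — a ~5× anisotropy that makes it
essential to compute all geometry in physical micrometers, not pixels. On
disk a stack is a directory of single-page PNG masks ordered by zero-padded
index with a `stack.json` calibration sidecar; an experiment adds
`manifest.csv` (eye, group, IOP offset, repeat, stack path) and, for
phantoms, `ground_truth.csv`.

## The morphometry pipeline

1. **Component extraction** (`extract_components`). Each 8-connected
   foreground region of a B-scan becomes a lumen component with pixel count,
   area, centroid, and central second moments over pixel centers in µm.
   8-connectivity is used because thin lumens routinely continue through
   diagonal pixel contacts.
2. **Part selection** (`select_sc_components`). The anchor is the
   largest-area component whose centroid lies in the region of interest (the
   whole frame by default; a rectangle can encode "immediately lateral to
   the iridocorneal angle" when other structures are present in the mask).
   Every in-ROI component with area at least 20% of the anchor's is kept —
   the threshold is inclusive, reading "at least" literally. The position
   filter is applied first, so the anchor itself is always in-ROI.
3. **Ellipse decomposition** (`fit_ellipse`). Each part gets the ellipse
   with the same normalized central second moments. With normalized moments
   `uxx = mu20/n + lat²/12`, `uyy = mu02/n + ax²/12`, `uxy = mu11/n`
   (the ±`px²/12` terms are the second moment of the finite pixel extent,
   applied per axis in µm *before* the eigen-decomposition so the
   convention survives anisotropic grids) and
   `c = sqrt((uxx − uyy)² + 4 uxy²)`, the axes are
   `major = 2√2·sqrt(uxx + uyy + c)` and `minor = 2√2·sqrt(uxx + uyy − c)`.
   A filled `a × a` square at 1 µm/px yields `major = minor = 2a/√3`; a
   single pixel yields the pixel's own ellipse, never zero.
4. **Cross-section summary** (`cross_section_morphometry`). Width is the
   *sum* of the included parts' major axes; height is the *area-weighted
   mean* of their minor axes; area is the part-area sum. The weighted height
   always lies between the extreme minors.
5. **Series aggregation** (`series_morphometry`). The analysis window is the
   first `floor(1500 µm / spacing)` sections, anchored at the first B-scan
   (no recentering rule is defensible without anatomy, so none is applied).
   Volume is the rectangle-rule integral `Σ area × spacing`, with empty
   sections contributing zero — volume is an integral, and absent lumen is
   zero lumen. Mean width/height/area are averaged over non-empty sections
   only, because they are properties of lumen that exists. Whether empty
   sections should instead enter those means is genuinely unstated in the
   protocols this mirrors; the exclusion choice is the package default and
   the sensitivity knob is simply to pre-filter the section table.

Auxiliary quantifications follow the same conventions:
`cornea_thickness` averages the axial anterior–posterior boundary
separation over (conventionally three) cross-sections, and
`sc_area_per_field` averages calibrated foreground area over 20X
high-power-field masks.

## Normalization and inference

Two normalization schemes are provided, matching the two ways a
volume-vs-IOP curve is usually reported:

* `normalize_relative`: divide by the *control group's mean at baseline*
  (offset 0), so the control baseline is 1 and group size differences
  remain visible.
* `normalize_per_eye`: divide each eye's series by *that eye's mean at the
  reference offset* (default −10 mmHg), which removes between-eye size
  differences and isolates the fractional response. By construction each
  eye's series averages exactly 1 at the reference level.

`iop_response(value ~ delta_iop_mmHg, data)` fits ordinary least squares
pooling all eyes and repeats of one group — with 5 offsets × 3 repeats this
is 15 points per eye — and reports the slope with a t-based 95% CI on
`n − 2` residual df. Per-eye random effects are deliberately out of scope;
the pooled fixed-effects fit is what the emulated analyses report. Each
repeat enters as one observation by default; fitting cycle means instead is
a matter of aggregating the measurement table before fitting.

`compare_slopes` tests whether two groups' slopes differ via the pooled
ANCOVA model `value ~ iop × group`, taking the two-sided t-test on the
interaction term. The interaction estimate equals the difference of the two
per-group OLS slopes exactly, so the reported `delta_slope` and the test
refer to the same quantity. When both groups lie on exact lines the residual
variance is numerical noise; the test is then reported as "no difference"
(p = 1) if the slopes agree to numerical precision.

`per_level_comparison` fits the two-factor (group × level) model on the
replicate values and tests the group contrast at each IOP level with the
pooled residual variance, adjusting over the `m` levels with the Šídák
formula `p_adj = 1 − (1 − p)^m` (m = 5, p = 0.01 gives 0.0490).

## The phantom: a stated world

`phantom_spec()` describes the synthetic eye. Defaults are fixed once and
are the conditions the emulated experiments state, or field-realistic
choices where nothing is stated:

| parameter | default | why |
|---|---|---|
| `length_um` | 1500 | the 1.5 mm analyzed SC segment |
| `width0_um` | 200 | realistic SC width (100–300 µm range) |
| `height0_um` | 25 | realistic SC height (10–40 µm range) |
| `slope_height_um_per_mmHg` | −0.85 | reported control height slope scale |
| `lateral_um_per_px`, `axial_um_per_px` | 7, 1.3 | stated system resolutions |
| `n_bscans` | 50 | 30 µm B-scan spacing over 1.5 mm, a typical raster density |
| IOP offsets | −10, −5, 0, +5, +10 mmHg | the five clamped levels |
| repeats per level | 3 | each level acquired three times |

Height deforms linearly in the IOP offset and area follows
`π/4 · width · height` with the width held fixed (whether SC width responds
to IOP is not established; the fixed-width default is a modeling choice, and
`slope_area_frac_per_mmHg` overrides it with a prescribed fractional area
slope). Rasterization marks a pixel foreground iff its center lies inside
the boundary. Boundary jitter perturbs the boundary radially by a smooth
zero-mean 6-harmonic Fourier field scaled to `noise_px` pixels SD, which
mimics manual-segmentation wobble without changing expected area to first
order. Septated stations replace the single ellipse by two side-by-side
ellipses of the same height whose widths split the deformed width by the
area fraction — chosen so total area, summed major axes and area-weighted
minor axis are conserved *exactly* in the analytic ground truth. (On the
raster, part-area sums differ from the unseptated raster by a
curvature-dependent discretization term, ~2% at the native 7 µm grid.)

What the phantom does **not** emulate: OCT speckle and intensity,
angiographic motion contrast, segmentation bias (as opposed to wobble),
anatomical curvature of the canal, or eye-to-eye biological variability
(eyes and repeats differ only by jitter realization). A green recovery test
therefore establishes that the measurement and inference chain is unbiased
and well calibrated for lumens of this geometry — not that segmentation of
real B-scans is accurate.

## Numerical choices and edge cases

* Degenerate inputs: empty masks are valid and flow through as empty
  sections; an all-empty series has volume 0 and undefined means; a
  non-positive deformed height aborts generation naming the offending IOP
  level; a fixed raster too small for the lumen is a sizing error.
* Convergence: rasterized axes converge to the analytic values as pixels
  shrink, but the discretization error oscillates with boundary–lattice
  alignment, so the convergence test averages over random sub-pixel
  placements rather than asserting per-shape monotonicity.
* Normalization equivariance: rescaling all volumes by a constant leaves
  normalized values mathematically unchanged; bit-identity is asserted for
  power-of-two factors (exact in IEEE arithmetic) and rounding-level
  agreement otherwise.
* RNG: all generators take explicit seeds; experiment generation derives
  per-stack child seeds from one master seed, and temporary seeding restores
  the caller's RNG state.

## Closed-loop validation

```{r recovery, eval = FALSE}
# measurement-level Monte Carlo: 200 experiments, 5 offsets x 3 repeats,
# measurement noise SD = 5% of baseline volume
r <- recover_slopes(phantom_spec(), n_experiments = 200, noise_frac = 0.05,
                    seed = 1)
r$coverage            # fraction of 95% CIs containing the true slope
r$mean_rel_abs_error  # mean |slope error| / |true slope|

# full image pipeline, fewer replicates (masks -> components -> ellipses ->
# volumes -> fit); slower, so scaled down
recover_slopes(phantom_spec(n_bscans = 10, noise_px = 0.5),
               n_experiments = 3, mode = "raster", seed = 1)
```

The test suite runs the 200-replicate measurement-level benchmark and a
scaled-down raster benchmark (fewer experiments and B-scans, stated here
to keep the suite fast); the acceptance script runs the full raster loop on
a two-group experiment. Power for the slope-difference test at the reported
effect scale (−0.044 vs −0.022 relative volume per mmHg, SD 0.05, 6 eyes
per group) is essentially 1, as `power_compare_slopes()` verifies by
simulation.

## Known limitations

* No intensity-based segmentation: the pipeline consumes masks.
* Fixed-effects pooling only; no mixed-effects eye/mouse hierarchy.
* The ROI rectangle is a declarative stand-in for the anatomical
  "immediately lateral to the iridocorneal angle" criterion.
* The analysis window is anchored at the first B-scan; no circumlimbal
  stitching of multiple raster scans.
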