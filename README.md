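# scmorph

Morphometry of Schlemm's canal (SC) from anterior-segment OCT segmentations,
and analysis of how SC geometry responds to intraocular pressure (IOP).

SC is the vessel at the iridocorneal angle that drains aqueous humor. When
IOP is clamped above or below an eye's baseline, the SC lumen collapses or
dilates; the slope of lumen volume or height against the IOP offset is a
functional readout of outflow-tissue mechanics, and a flattened slope
indicates a stiffer or malformed trabecular meshwork. `scmorph` implements
the measurement chain from per-B-scan binary lumen masks to those slopes,
for researchers doing anterior-segment OCT morphometry in rodents.

## What it computes

Per B-scan, after 8-connected component extraction and selection of SC
parts (anchor = largest in-ROI lumen; keep parts with area ≥ 20% of the
anchor), each part gets its equal-second-moment ellipse. With normalized
central moments in physical µm on the anisotropic grid,

    u_xx = μ20/n + lat²/12,  u_yy = μ02/n + ax²/12,  u_xy = μ11/n
    c    = √((u_xx − u_yy)² + 4 u_xy²)
    major = 2√2 √(u_xx + u_yy + c),   minor = 2√2 √(u_xx + u_yy − c)

Cross-section **width** = Σ major axes, **height** = area-weighted mean of
minor axes, **area** = Σ part areas; per acquisition, **volume** =
Σ area × B-scan spacing over a 1.5 mm analyzed length. Measurements are
normalized either to the control-group baseline mean ("relative") or to each
eye's mean at the −10 mmHg reference ("per-eye normalized"), then fitted by
OLS against the IOP offset (`iop_response`), compared between groups via the
ANCOVA interaction t-test (`compare_slopes`), and contrasted per level with
Šídák adjustment (`per_level_comparison`).

A synthetic phantom module (`phantom_spec`, `generate_experiment`) produces
mask stacks of linearly deforming elliptical lumens — optionally septated
into multiple parts, with smooth boundary jitter — together with exact
analytic ground truth, so the whole pipeline is validated by parameter
recovery without raw imaging data.

## Worked example

```r
library(scmorph)

specs <- list(control = phantom_spec(n_bscans = 10, noise_px = 0.5),
              stiff   = phantom_spec(n_bscans = 10, height0_um = 12.5,
                                     slope_height_um_per_mmHg = -0.34,
                                     noise_px = 0.5))
design     <- iop_experiment_design(specs, eyes_per_group = 2)
experiment <- generate_experiment(design, seed = 42)  # 60 mask stacks
meas       <- analyze_experiment(experiment)          # full morphometry

rel <- normalize_relative(meas, "control")
iop_response(value ~ delta_iop_mmHg, rel[rel$group == "control", ])
#> Linear IOP response fit
#>   value ~ delta_iop_mmHg, n = 30 (residual df 28)
#>   slope: -0.03386 per mmHg  [-0.0342, -0.03352] 95% CI
#>   intercept: 0.9991

compare_slopes(value ~ delta_iop_mmHg, rel)
#> IOP-response slope comparison
#>   control: slope -0.03386 per mmHg
#>   stiff: slope -0.01368 per mmHg
#>   difference (a - b): -0.02017, P = 6.99e-63 (two-sided t-test on the
#>   IOP-by-group interaction of the pooled linear model, df 56)
```

The control phantom deforms at −0.85 µm height per mmHg from a 25 µm
baseline, i.e. a fractional volume slope of −0.034 per mmHg; the fit
recovers −0.0339 from the rasterized masks. The "stiff" group deforms less
(−0.0137 per mmHg recovered) and the interaction test flags the slope
difference. `recover_slopes()` runs this loop as a Monte-Carlo benchmark
(CI coverage and relative slope error), and `power_compare_slopes()`
estimates the power of the slope-difference test by simulation.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

generates a fresh two-group synthetic experiment from the given seed, runs
the complete raster pipeline (masks → components → ellipses → volumes →
normalization → slope fits, slope-difference and per-level tests), prints
the fitted slopes, and writes the results JSON to `--out`.

## Layout

- `R/phantom.R` — phantom specs, deformation model, rasterization, experiment generation
- `R/segment.R` — mask-stack container and PNG/JSON I/O, component labeling, SC part selection
- `R/morpho.R` — ellipse fitting, cross-section/series morphometry, cornea thickness, HPF areas
- `R/iopfit.R` — normalizations, `iop_response` model class, slope comparison, per-level contrasts
- `R/experiment.R` — end-to-end drivers and Monte-Carlo benchmarks
- `vignettes/sc-morphometry.Rmd` — model, conventions, phantom assumptions, limitations
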