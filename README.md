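# oaentropy

Quantifying collagen fiber organization in skin from polarization-sensitive
optical coherence tomography (PS-OCT), for imaging scientists and
translational researchers studying dermal fibrosis (scleroderma, scarring,
bleomycin mouse models).

Classical PS-OCT readouts of fibrosis — local retardance and degree of
polarization (DOP) — depend strongly on the dermal depth at which they are
evaluated. This package implements a depth-robust alternative: the Shannon
entropy of optic-axis (OA) orientations inside tissue voxels. Each voxel's
OA angles are histogrammed into `n` equal bins over `[0, π)` and scored as

    H = − Σ_i p_i · log2(p_i)        [bits]

where `p_i` is the occupancy probability of bin `i`. Densely packed,
co-aligned fibrotic collagen concentrates the histogram (low `H`); normal,
heterogeneously oriented dermis — and the disorganized early phase of
fibril deposition — spreads it (high `H`).

The measured axes live on a great circle of the Poincaré sphere that is
rotated arbitrarily by the unknown birefringence of the system's fiber, so
the axes are first reduced to scalar angles via a least-squares plane fit
and the half-angle projection

    θ = ½ · atan2(S₂, S₁)  (mod π)

with `S₁`, `S₂` the axis components along the fitted plane's basis vectors.
The entropy is invariant under that unknown rotation, which is what makes
the metric calibration-free.

The package covers the full chain:

* **Phantom simulator** — Jones-calculus forward model of layered
  birefringent tissue (controllable orientation fields: uniform, random,
  von Mises, radial; depth-decaying SNR; unknown fiber rotation; speckle),
  including preset cohorts emulating a bleomycin fibrosis time course:
  `phantom_spec()`, `simulate_phantom()`, `preset_cohort()`.
* **Polarimetry** — Stokes formation, 28 µm transverse Gaussian filtering,
  DOP, and local retardance + optic axis by the two-state geometric
  solution with a 20 µm depth offset: `compute_stokes()`,
  `filter_stokes()`, `compute_dop()`, `local_birefringence()`.
* **Axis entropy** — Poincaré-sphere plane fit, angle projection, and
  voxel-wise entropy maps (100 µm blocks, 120–190 µm dermal window, 256
  bins by default): `fit_axis_plane()`, `project_angle()`,
  `voxel_entropy()`, `mean_entropy()`.
* **Pipeline** — surface detection, surface-referenced depth windows,
  extreme-mean block search ("best 1 mm²"), per-sample summaries, cohort
  ANOVA/Tukey statistics, and deterministic PNG/TIFF map rendering:
  `analyze_sample()`, `simulate_cohort()`, `summarize_cohort()`,
  `best_block()`, `render_map()`.

A thin command-line front end over these functions is installed at
`inst/cli/oaentropy.R` (`simulate` / `process` / `entropy` / `report`).

## Worked example

Simulate one late-fibrosis sample (day-28 preset: thick dermis, radial
collagen around the injection site) and run the full analysis:

```r
library(oaentropy)

tom <- simulate_phantom(preset_cohort("28", seed = 1))
res <- analyze_sample(tom, analysis_config(best_block_um = 200))
as.data.frame(res)
#>      sample_id group day_num thickness_um mean_retardance mean_dop mean_entropy
#> 1 sample_seed1 day28      28        393.7           1.147   0.8116        5.833
#>   n_voxels bb_retardance bb_entropy
#> 1       35         1.402      5.224
```

`mean_retardance` (1.15 deg/µm, double-pass) reflects the preset's 0.55
deg/µm single-pass rate plus heterogeneity bias; `mean_entropy` (5.8 bits)
is well below the disorganized-dermis regime (~7.2 bits), and
`bb_entropy` is the mean of the most organized 200 µm block.

A full synthetic cohort (3 samples × 5 groups) with group statistics:

```r
df <- simulate_cohort(n_per_group = 3, seed = 1,
                      config = analysis_config(best_block_um = 200))
summarize_cohort(df, c("mean_entropy", "thickness_um"))
#> <cohort_summary>
#>     group n mean_entropy_mean mean_entropy_sd thickness_um_mean ...
#>   control 3             7.226          0.1762             197.0
#>     day14 3             6.727          0.0336             294.3
#>     day21 3             5.992          0.1024             347.5
#>     day28 3             5.994          0.0744             399.7
#>      day7 3             6.739          0.1320             242.4
#> mean_entropy: one-way ANOVA F = 65.3, p = 3.95e-07
#> thickness_um: one-way ANOVA F = 227, p = 9.22e-10
```

The cohort reproduces the characteristic non-monotone entropy trajectory:
dermal thickness rises steadily with injection day, while OA entropy stays
high through the disorganized deposition phase (day 7–14) and then falls as
collagen organizes radially (day 21–28).

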