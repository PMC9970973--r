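# lsfmcoupling

Analysis of electromechanical coupling between stem-cell-derived and adult
cardiomyocytes imaged by oblique dual-channel light-sheet fluorescence
microscopy (LSFM), for researchers studying graft–host integration in
cardiac regenerative models.

Adult ventricular cardiomyocytes (adult-CM) seeded on a spontaneously
beating hiPSC-CM monolayer can synchronize their calcium transients with
the layer. `lsfmcoupling` provides the full computational chain for
quantifying that coupling:

* **Synthetic acquisition generator** — oblique 3D LSFM frame sequences,
  widefield timelapses, bead-calibration and dark frames, and whole
  imaging cohorts with known ground-truth labels (cell positions, event
  times, coupling/contraction flags).
* **Preprocessing** — fixed-pattern-noise estimation/subtraction from dark
  frames, spectral channel splitting, and bead-based affine
  co-registration of the ~0.9×-demagnified Fluo-4 channel onto the CMO
  channel.
* **Reconstruction** — plane-major (`N = Z × T`) hyperstack reordering,
  slit cropping, and single-pass resampling of the sheared stack into
  isotropic lab-frame volumes: axial rescale by `Δz′/px` (1.3 µm / 0.1477
  µm ≈ 8.8) followed by rotation by `θ_LS = 37°` about the y axis, plus
  orthogonal views, MIPs and depth-coded MIPs.
* **Transients** — ROI-mean traces, `ΔF/F₀ = (F − F₀)/F₀` with a
  lowest-decile baseline, prominence-based event detection,
  period/amplitude/decay-slope measurement and pacing-capture scoring.
* **Classification** — rule-based surrogates for visual screening:
  contraction from end-band enhancement of the transillumination std/mean
  activity map, transients from detected events, coupling from symmetric
  greedy peak matching (±0.5 s, ≥80% of the shorter train) with the
  pacing-frequency exclusion (synchrony seen only at stimulus times is not
  coupling).
* **Statistics** — per-condition cohort summaries and 2×2 Pearson
  chi-square comparisons,
  `χ² = N(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))`, uncorrected by default,
  with Yates and Fisher variants.

## Worked example

Simulate a 45-FOV co-culture cohort whose ground-truth counts follow the
published two-co-culture design, classify every FOV from its traces and
rendered transillumination, and run the coupling/contraction comparisons:

```r
library(lsfmcoupling)

coh     <- simulate_cohort(table1_design(), seed = 1, noise_sd = 0)
records <- classify_cohort(coh)
summ    <- summarize_cohort(records)
summ$totals[, c("level", "n_fov", "n_contr", "n_coupled", "pct_coupled")]
#>             level n_fov n_contr n_coupled pct_coupled
#> 1  decoupler:none    22      13         8    36.36364
#> 2 decoupler:nbleb    23       1         8    34.78261
#> 3           day:0    21       9         4    19.04762
#> 4           day:1    24       5        12    50.00000
#> 5             all    45      14        16    35.55556

report(records, list(
  list(group_by = "day",   outcome = "coupled"),
  list(group_by = "nbleb", outcome = "coupled"),
  list(group_by = "nbleb", outcome = "contracting")))
#>   group_by     outcome  a  b  c  d        chi2 p_value significant
#> 1      day     coupled  4 17 12 12  4.68288177  0.0305        TRUE
#> 2    nbleb     coupled  8 14  8 15  0.01226659  0.9118       FALSE
#> 3    nbleb contracting 13  9  1 22 15.72286935  0.0001        TRUE
```

Reading the output: coupling rises from 4/21 FOVs (19%) after 4 h of
co-culture to 12/24 (50%) after 24 h (p = 0.0305); myosin inhibition
abolishes contraction (1/23 vs 13/22, p = 0.0001) but leaves the coupled
fraction unchanged (8/23 vs 8/22, p = 0.91) — calcium coupling does not
require mechanotransduction.

Lower-level stages are exposed individually; e.g. a raw oblique
acquisition round trip:

```r
geo <- acquisition_geometry()            # 37 deg, 38 planes, 1.3 um, 0.1477 um px
opt <- optics_config(geo, frame_shape = c(64, 96))
fld <- build_cell_field(field_um = c(14, 9), n_adult = 0, seed = 1)
tr  <- simulate_traces(fld$cells, duration_s = 2, rate_hz = 4, seed = 1)
acq <- render_acquisition(fld$cells, tr, opt, seed = 1)
ch  <- split_channels(subtract_fpn(acq$frames, opt$fpn_map))
hs  <- deinterleave(ch$green, geo$n_planes, geo)
vol <- to_lab_frame(hs, geo)             # isotropic lab-frame volume
img <- depth_coded_mip(vol)              # depth-coloured projection
```

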