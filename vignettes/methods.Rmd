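---
title: "Models and methods behind lsfmcoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lsfmcoupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsfmcoupling)
```

# The problem

When adult ventricular cardiomyocytes (adult-CM) are seeded on top of a
confluent, spontaneously beating layer of human induced pluripotent stem
cell-derived cardiomyocytes (hiPSC-CM), the two cell types can couple
electromechanically: the normally quiescent adult cells begin to fire calcium
transients in synchrony with the layer. Quantifying how often that happens —
and whether it survives mechanical decoupling with the myosin inhibitor
para-nitroblebbistatin (NBleb) — requires volumetric calcium imaging of the
co-culture at several volumes per second, followed by a screening pipeline:
reconstruct the obliquely acquired volumes, extract per-cell
$\Delta F/F_0$ traces, decide which adult cells contract, show transients,
and are coupled, and compare the resulting counts between conditions with
2×2 chi-square tests.

`lsfmcoupling` implements that pipeline end to end, together with a
synthetic-acquisition generator that emulates the instrument and the biology
with known ground truth, so that every stage is testable without any raw
imaging data.

# Acquisition geometry and volume reconstruction

The microscope sweeps a light sheet inclined at $\theta_{LS}$ (default 37°)
to the horizontal sample surface; the detection axis is orthogonal to the
sheet, i.e. tilted $\theta_{LS}$ from vertical. A volume consists of
`n_planes` camera frames (default 38) at spacing $\Delta z' = 1.3\,\mu m$
along the detection axis. The lateral sample pixel is
$6.5\,\mu m / 44\times = 0.1477\,\mu m$.

Reconstruction maps the sheared stack $(x', y, k)$ to lab coordinates by an
axial rescale $z' = k\,\Delta z'/p$ (with $p$ the pixel size) followed by a
rotation by $\theta_{LS}$ about the $y$ axis, with $z$ increasing upwards
from the coverslip. `to_lab_frame()` performs both steps in a **single**
trilinear resampling pass (the rotation leaves $y$ untouched, so the 2-D
$(x,z)\to(x',k)$ map is computed once and reused for all rows). A
separately coded `"two-step"` mode materialises the axially rescaled volume
and then rotates it, exactly as an ImageJ rescale–reslice–rotate chain
would; it exists as the reference implementation for equivalence testing.

Numerical conventions:

* Coordinates are 0-based with voxel centres on the integer grid; the output
  volume spans the axis-aligned bounding box of the transformed input grid
  and records its `origin`.
* Out-of-volume samples are zero. The two methods differ in *how* values
  fade at the boundary (the composite blends over one plane spacing in $k$,
  the two-step over one voxel in $z'$), so each `lab_volume` carries a
  `support` mask marking voxels whose interpolation stencil is fully inside
  the acquired stack. On that interior the two methods agree to machine
  precision when $\Delta z'/p$ is an integer, and to about $6\times10^{-4}$
  relative RMS otherwise (double-interpolation error). The equivalence test
  therefore uses $p = 0.25\,\mu m$, $\Delta z' = 0.75\,\mu m$.
* Because plane spacing (1.3 µm) is ~9 voxels, linear interpolation cannot
  localise a point source *between* planes: its reconstructed argmax snaps
  to the nearest sampled plane. Round-trip localization tests therefore
  place emitters on sampled planes (lateral positions fractional), and use a
  thin test sheet (waist 1.5 µm instead of the 3 µm default) so the argmax
  probes the geometric mapping rather than the elongated axial profile of
  the emitter image.

`deinterleave()` (plane-major $N = Z \times T$ reordering) and
`crop_to_slit()` move pixels without touching their values;
`auto_slit_bounds()` finds the slit field from the temporal mean of the
static CMO channel with a midpoint threshold. Renderings (orthogonal
sections, MIPs, depth-coded MIPs with a strictly monotone cold-to-light
colormap) operate on the lab volume.

# Detector preprocessing

* **Fixed-pattern noise.** `estimate_fpn()` is the exact per-pixel mean of
  shutter-closed frames; `subtract_fpn()` clamps corrected counts at zero
  (the FPN is an additive offset, and a negative fluorescence baseline would
  be unphysical for the later $\Delta F/F_0$ step).
* **Channel splitting.** The two spectral images share one sensor; the
  default layout is top/bottom halves with Fluo-4 (green) on top,
  configurable.
* **Chromatic co-registration.** The Fluo-4 detection path carries an extra
  magnification of about $1/0.9$, so registration "demagnifies the Fluo-4
  channel by ~0.9×". We automate what is often done by manual overlay:
  detect bead centroids in both halves (isolated local maxima refined to
  intensity-weighted centroids), pair them by mutual nearest neighbour, and
  fit rotation + anisotropic scale + translation by least squares
  (`fit_affine()`), with a manual-override path via explicit
  `affine_params()`. The fitted object follows the resampling convention of
  registration toolkits: it maps fixed-image (CMO) coordinates into
  moving-image (Fluo-4) coordinates, and `apply_affine()` pulls the moving
  image back through it — hence the fitted scale is ~0.9 and applying it
  registers the green channel onto the red grid. Interpolation is bilinear
  by default (nearest available); an anisotropic rotation–scale transform
  has an inverse outside that family, so `affine_params` also carries its
  exact linear matrix and inverses/compositions stay exact.

# Transient analysis

$F_0$ is the mean of the samples at or below the 10th percentile of the ROI
trace (configurable percentile, or an explicit pre-stimulus window); a fixed
rather than sliding baseline is used throughout. $\Delta F/F_0 = (F -
F_0)/F_0$ is exactly invariant to multiplicative gain.

`detect_events()` finds local maxima with prominence at least five times a
robust noise scale (MAD of first differences, scaled by $\sqrt 2$; floored
at 0.05 $\Delta F/F_0$ so a noiseless trace cannot produce a zero
threshold), separated by at least 0.5 s. The initial decay slope is a
least-squares line over the first 30% of the post-peak fall; adult cells,
with their faster reuptake kinetics, give visibly steeper (more negative)
slopes than hiPSC-CM. `measure_period()` averages successive peak
intervals; `pacing_capture()` scores a stimulus as captured when a peak
falls within 0.5 s after it (windows must not overlap).

# Classification rules

The published screening was visual; this package replaces it with explicit,
auditable rules whose thresholds are exposed in the API:

* **Contraction** (`is_contracting()`): on the std/mean activity map of the
  transillumination timelapse, a rod-shaped cell is contracting when the two
  end bands of its long axis (15% of the length each) average more than 3×
  the background ring around the cell. The *population* (1/n) standard
  deviation is used so that a pixel alternating 90/110 gives exactly
  std/mean = 0.1.
* **Transients** (`has_transients()`): at least one detected event in the
  cell ROI (3-D path), or mean fluorescence std/mean over the cell body
  above 0.1 (widefield path).
* **Synchrony** (`is_synchronized()`): greedy one-to-one peak matching
  within ±0.5 s. Candidate pairs are taken in order of increasing time
  difference, which makes the procedure symmetric in the two trains and the
  match count non-decreasing in the tolerance (an earliest-first scan would
  not be symmetric). Trains are synchronized when both are non-empty and at
  least 80% of the shorter train is matched.
* **Coupling** (`classify_coupled()`): coupled if synchronized in the
  unpaced acquisition, or synchronized under pacing with at least one
  matched pair outside every stimulus capture window. Synchrony observed
  *only* at the pacing frequency is deliberately not scored as coupling —
  both cells may simply be responding to the field. The hiPSC reference
  train comes from the hiPSC ROI nearest the adult cell.

The 0.5 s tolerance and 0.8 fraction are this package's conventions: the
visual criterion they replace has no recoverable numeric definition. They
are deliberately loose relative to the ~6 s spontaneous period and strict
relative to the 2 s pacing period.

# The synthetic-data generator

The generator emulates the study conditions so the pipeline can be exercised
against ground truth:

* **Cell field** — hiPSC blobs tile the bottom layer on a jittered grid;
  rod-shaped adult cells (default 30 × 10 µm at these test field sizes) are
  scattered on top by rejection sampling with a circumscribed-circle
  non-overlap guarantee and explicit failure at unsatisfiable density.
* **Calcium dynamics** — transients are peak-normalised differences of
  exponentials, $A(e^{-t/\tau_d} - e^{-t/\tau_r})$; defaults
  $\tau_r/\tau_d = 0.15/0.8$ s (hiPSC) and $0.05/0.35$ s (adult), so adult
  decay is faster. Amplitude follows a negative force–frequency relation
  $A(f) = A_0 + s\,(f - f_{ref})$ with $s \le 0$, floored at 5% of $A_0$,
  so 0.5 Hz paced transients are smaller than ~0.16 Hz spontaneous ones.
  The confluent layer beats as a syncytium (one layer rhythm, default
  period 6.25 s); coupled adult cells reproduce it (configurable lag,
  default 0); uncoupled ones are quiescent, autonomous (default period
  4.3 s, phase chosen clear of the layer rhythm) or captured directly by
  field stimulation. Events are only generated up to 1.5 s before the end
  of a record: a transient truncated by the end of the acquisition could
  not be scored anyway.
* **Optics and detector** — plane $k$ of each volume weights every emitter
  by a Gaussian sheet profile around depth $k\,\Delta z'$ along the tilted
  detection axis; the sheet waist defaults to 3 µm (no published value
  exists; it is a convention, and localization fixtures use 1.5 µm as
  explained above). Both spectral half-images share the detector frame; the
  green half is pre-distorted by the chromatic affine (default 0.9× scale,
  0.3° rotation, ~1 px shift about the half-frame centre). Noise is
  Poisson shot noise on the photon signal, plus the fixed-pattern offset,
  plus Gaussian read noise; with zero photon scale and zero read noise a
  frame is exactly the FPN map. Bead-calibration frames place the same
  sparse bead field (jittered grid, so placement is feasible for any seed)
  in both halves.
* **Widefield** — transillumination shows adult cells as dark rectangles
  that shorten along the long axis (10% at full activation) when
  contracting; the hiPSC monolayer is treated as transparent in
  transillumination. Fluorescence is the unsectioned sum of the layer and
  the adult cells.
* **Cohort** — `table1_design()` encodes, per co-culture sample, the exact
  published counts of FOVs, contracting cells, unpaced/paced transients and
  coupled cells (45 FOVs, 16 coupled, 21/24 by day, 22/23 by decoupler).
  Fixed-count allocation draws *which* FOVs carry each label but keeps the
  totals exact, so the downstream contingency tables are reproducible to
  the count; a Bernoulli mode draws labels independently. Coupled cells
  whose unpaced-transient budget is exhausted are generated as
  "paced-only" coupled: quiescent unpaced, following the layer under
  pacing where the layer also produces non-stimulus events — exactly the
  situation the pacing-exclusion rule exists to adjudicate. One published
  total (45-row paced adult transients) is internally inconsistent with its
  own subtotals (42 vs 41); the generator reproduces the
  subtotal-consistent value.

Default trace noise (`noise_sd = 8` on a baseline of 100, i.e. peak SNR
well above 10) emulates a bright preparation. What the generator does *not*
emulate: diffraction and aberrations (emitters are Gaussian footprints, not
PSF-convolved), motion blur within a frame, intra-volume acquisition skew
(recorded but uncorrected, as in the original processing), photobleaching,
arrhythmic or propagating activation, and segmentation difficulty (cell
masks come from ground truth). Passing tests therefore validate the
*pipeline logic and numerics*, not performance on degraded real data.

# Statistics

`build_contingency()` forms 2×2 tables from per-FOV records;
`chi2_2x2()` computes the uncorrected Pearson statistic
$\chi^2 = N(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$ with $p$ from the
$\chi^2_1$ distribution, which reproduces the published values
($p = 0.0305$ for day-0 vs day-1 coupling from [[4,17],[12,12]],
$p = 0.91$ for NBleb vs control coupling, and $p = 0.0001$ at 4-dp rounding
for contraction — the uncorrected statistic gives $7.3\times10^{-5}$,
which prints as 0.0001, whereas the Yates-corrected variant would give
$\sim 3\times10^{-4}$). Yates correction and a two-sided Fisher exact test
are available as options. Reports round p-values to 4 decimal places and
flag significance at $\alpha = 0.05$; no multiple-testing correction is
applied, matching the original analysis.

# Problem sizes and design choices in the tests

Tests run entirely on generated data: detector halves of 24–128 px,
volumes of up to 38 planes, 15–30 s traces at 4–8 Hz, and a 45-FOV cohort
classified twice (noiseless and at default noise). These sizes were chosen
so the whole suite exercises every stage, including two full cohort
classifications with per-FOV widefield renders, in about a minute on a
laptop-class core. Oracles are independent by construction: brute-force
rectangle-overlap sampling, the two-step resampler, closed-form
amplitude/waveform identities, the $\Sigma(O-E)^2/E$ chi-square form, and
sampling-theory bounds for the FPN estimator.

Known limitations worth restating: axial localization between planes is
sampling-limited (see above); the synchrony defaults cannot be validated
against the original visual screening, only shown to be self-consistent;
and the day-2 "no coupled events" observation of the source study has no
quality-control analogue here — no such rule is implemented.
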