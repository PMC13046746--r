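---
title: "Methods: wireless-power coverage, SAR arithmetic and sensor qualification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wireless-power coverage, SAR arithmetic and sensor qualification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icptelemetry)
```

This vignette records the modelling assumptions, numerical choices and known
limitations behind each module. It is the long-form companion to the roxygen
reference documentation.

## The physical setting

A millimetre-scale intracranial pressure (ICP) sensor is implanted in the
brain and powered transcutaneously by a handheld wand whose transmit coil
(radius 0.075 m, up to 11 amp-turns RMS) generates a quasistatic magnetic
field. A measurement is possible wherever the field component along the
implant coil's normal reaches the powering threshold (28 µT RMS by default).
The package answers four engineering questions about this system:

1. **Coverage** — from which scalp positions, and for which implant
   orientations and depths, can the implant be powered?
2. **SAR compliance** — do worst-case wand exposures satisfy IEEE C95.1
   time-averaged limits, including for small children?
3. **Qualification** — do sensor accuracy and zero-point drift meet their
   tolerances, and how do accelerated-aging weeks map to equivalent years?
4. **ICP analytics** — what do home-monitoring readings say (mean ICP,
   cardiac pulse amplitude, posture-stratified trends)?

All inputs are produced by seeded synthetic generators, so the full pipeline
runs with no external data.

## Coil field model

The wand coil is modelled as an ideal circular filament with a lumped
amp-turn current. Its magnetostatic field has a closed form in complete
elliptic integrals $K(m)$ and $E(m)$, which the compiled kernel evaluates
with the arithmetic–geometric mean iteration (machine-precision, no lookup
tables). RMS current in gives RMS field out, directly comparable to the RMS
threshold.

Verification is by independent oracle: adaptive Biot–Savart quadrature over
the loop angle agrees with the closed form to better than $10^{-9}$ T at
random points, and the on-axis limit reproduces
$B = \mu_0 N I / (2R)$ exactly:

```{r}
coil <- coil_spec()   # defaults: radius 0.075 m, 11 AT
coil_field(coil, c(0, 0, 0))[3]
4e-7 * pi * 11 / (2 * 0.075)
```

Points closer to the filament than a guard distance are rejected rather than
evaluated, since the field diverges there.

One caution: the common rule of thumb that the dipole approximation is good
"beyond 10 radii" is too optimistic at the 1% level — the exact on-axis
field deviates from the dipole law by about $1.5\,(R/r)^2 \approx 1.5\%$ at
$r = 10R$. Far-field tests therefore run at 20 radii and beyond with a
tolerance that follows the $(R/r)^2$ correction.

## Worst-case orientation minimax

At a voxel reached by $P$ wand poses with field vectors $B_p$, the field
available to an implant with coil normal $a$ is $|B_p \cdot a|$ for the best
pose the operator can choose, i.e. $\max_p |B_p \cdot a|$. The worst case
over implant orientation is

$$W = \min_{\|a\| = 1} \max_p |B_p \cdot a|,$$

and the best case is $M = \max_p \|B_p\|$ (normal aligned with the strongest
pose). The orientation is minimized and the pose maximized in that order
because the implant's orientation is fixed at surgery while the operator is
free to move the wand; the reverse ordering would describe an adversarial
operator, which is not the clinical situation.

$h(a) = \max_p |B_p \cdot a|$ is piecewise linear on the sphere, so its
minimum sits at a point where up to three constraints are active, possibly in
a narrow valley. The implementation samples a level-4 icosphere (2,562
directions), keeps the best candidate in each of up to six distinct basins
(mutual angle > 15°), and refines each with a local descent:

* the scalar API (`worst_case_field`) uses Nelder–Mead on a tangent-plane
  chart with one restart;
* the per-voxel compiled kernel uses a rotating-stencil pattern search
  (rotate before shrinking: the descent cone at a kink can be narrower than
  the stencil spacing).

Both were validated against an exact oracle that enumerates active sets
(pose directions, equal-magnitude great circles, and sign-pattern solutions
of $M a = \mathbf{1}$ for all pose triples): relative errors are below
$10^{-8}$ for the scalar API and below $3 \times 10^{-4}$ for the kernel.
Analytic special cases hold exactly, e.g. three orthogonal vectors of equal
magnitude $b$ give $W = b/\sqrt{3}$:

```{r}
worst_case_field(diag(3) * 1e-5)$value * sqrt(3)
```

A note on brute-force verification: direction sampling alone (even $10^5$
directions) can miss a narrow valley by far more than 0.5%, so sampled
oracles are always polished with a local descent before comparison.

## Voxelization and pose placement

The head is a subdivided-icosahedron sphere or ellipsoid (watertight and
consistently oriented by construction; both properties are checked, not
assumed). Voxel centers follow the center-of-voxel convention
(`origin + (index + 0.5) * spacing`) with a one-voxel margin, and a center
counts as inside by scanline ray-crossing parity. At 1 mm spacing the voxel
count of a 50 mm sphere matches the analytic ball volume within 0.5%.

Wand poses are seeded from a randomly rotated Fibonacci sphere of directions
(seeded rotation, so pose sets are reproducible), projected to the scalp
along rays from the centroid, oriented along the barycentrically
interpolated vertex normal, and slid outward until the closest coil point
(16 rim samples plus the plane center) is exactly the standoff (5 mm
default) from the surface. Placements that fail (no root, rim penetration)
are dropped with a warning, never silently replaced. On a sphere of radius
$R$ this reduces to the closed form: the coil-plane center sits at $R + s$
and the rim at $\sqrt{(R+s)^2 + r_c^2}$, which the tests check to 1 mm.

Classification is exact at the threshold: `always_powered` iff
$W \ge$ threshold, `unreachable` iff $M <$ threshold,
`orientation_dependent` otherwise. Because $W$ and $M$ are both linear in
amp-turns, doubling the drive and the threshold together leaves the
classification unchanged — an invariant the acceptance suite checks at every
voxel.

Problem sizes are the package's choice, bounded by desk-scale budgets: the
demonstration configuration runs 120 poses at 4 mm spacing (minutes); the
acceptance configuration runs 120 poses at 2 mm (about 4 minutes); a
720-pose, 1 mm study-scale map is the same code path and scales linearly in
voxels × poses.

## SAR duty-cycle arithmetic

IEEE C95.1 limits are time averages: peak spatial-average SAR (psSAR, any
10 g of tissue) over 6 minutes against 2 W/kg, and whole-body SAR over 30
minutes against 0.08 W/kg. A single measurement of $t$ seconds therefore
scales a continuous exposure by $\min(t, T)/T$ for window $T$:

```{r}
psar_time_average(sar_exposure(3.61, 1.63, measurement_s = 120))  # -> 1.20
min_safe_mass(sar_exposure(3.59, 1.14, measurement_s = 120))      # -> 0.95 kg
```

Computations are exact internally; only reports round (W/kg to 2 decimals,
mass to 0.05 kg). The packaged worst-case table ships three simulated wand
placements (adult and two paediatric models); its columns are positional
inputs to `compliance_report()`.

## Qualification

**Zero-point drift.** The rig reference is the calibrated barometer plus the
fluid head at 0.73559 mmHg/cm (a fixed conversion constant, used verbatim).
Per-implant series are re-referenced to the first reading; qualification
passes iff the maximum absolute excursion stays under the limit (2 mmHg for
the one-year claim) — the conservative per-implant reading of a
"drift < limit" claim. Drift rates are ordinary least squares in mmHg/year
with standard errors; the synthetic rig recovers injected rates within 3 SE
in ≥ 95% of replicates.

**Accuracy.** A full-factorial grid over 475–950 mmHg absolute and
35–45 °C is evaluated cell by cell against ±2 mmHg and ±2 °C. Insufficient
range coverage is reported as a distinct failure mode from an
out-of-tolerance cell.

**Accelerated aging.** The ASTM F1980 Q10 shortcut:
$AF = Q_{10}^{(T_e - T_w)/10} \times \text{duty}$. At the defaults
(39 → 85 °C, $Q_{10} = 2$, duty 162/168):

```{r}
acceleration_factor(aging_protocol())          # 23.386 -> printed 23.4
equivalent_duration(22)                        # 22 weeks -> ~10 years
```

## ICP waveform analytics

The cardiac pulse is isolated with a zero-phase (forward–backward)
Butterworth band-pass, order 2, 0.67–3.0 Hz (40–180 bpm). Beats are peak
detections on the filtered signal; the amplitude is the **median** over
beats of peak minus following trough (peak-to-trough, the canonical mode),
and heart rate comes from the median inter-peak interval. A spectral
single-bin amplitude is provided as a cross-check mode; on a pure sinusoid
the two agree. Quality flags: fewer than 5 beats → `low_beats`; dominant
frequency at a band edge → `aliased`. Amplitude is invariant to constant
offsets and linear in signal scale, and the generator refuses cardiac
frequencies at or above Nyquist.

Longitudinal summaries are posture-stratified medians and IQRs over
consecutive windows, plus a stability statistic (largest deviation of a
window median from the posture's global median). Excursion flags compare
each reading to the trailing same-posture baseline median with a
$k \times$ IQR band ($k = 3$ default). These thresholds are invented
plumbing for demonstration, clearly non-clinical.

## Synthetic generators

Every generator is a pure function of its spec, including the seed: the
global RNG stream is saved and restored around each draw, and equal specs
give identical outputs. The drift rig shares one bounded barometer random
walk across implants (so zero-point errors cancel it exactly); the ICP
generator's cardiac sinusoid has peak-to-trough amplitude equal to
`pulse_amp` exactly when noise, respiration and harmonics are off; the
accuracy grid takes an injectable error model. Generator defaults are the
study conditions — tests and analyses use them as-is rather than tuning
them.

## File formats and the pipeline

Meshes are written/read as ASCII or binary STL and PLY, volumes as
ASCII-encoded NRRD with a JSON grid sidecar, and tables as CSV with
ISO-8601 UTC timestamps; all artifacts are text so runs diff cleanly.
Configuration is YAML with units encoded in key names (`spacing_mm`,
`threshold_ut`); unknown keys are rejected before any computation. Every run
directory is self-describing: resolved config, run log, and a manifest with
MD5 checksums of all outputs (the log itself is excluded, as it keeps
receiving lines after checksumming).

## Known limitations

* The head is a smooth ellipsoid, not an anatomical mesh; tissue is
  transparent to the quasistatic field (no eddy-current losses).
* The coil is a single filament; a physical pancake winding has finite
  build, which slightly smooths the near field.
* The 10⁵-direction brute-force check is only a valid oracle after local
  polish (see the minimax section).
* Excursion flagging and window lengths are descriptive defaults, not
  clinically validated decision rules.
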