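---
title: "Modelling perilymph pharmacokinetics after intratympanic delivery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling perilymph pharmacokinetics after intratympanic delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cochleaPK)
```

`cochleaPK` models the inner-ear pharmacokinetics of drugs injected into the
middle ear: permeation across the round window membrane (RWM), diffusion
along the perilymph of the scala tympani (ST), clearance to the vasculature,
prodrug dephosphorylation, and sequential capillary sampling. This vignette
is the package's account of the science: the model and its assumptions, the
parameters and where their defaults come from, the numerical choices, and
the limitations a user should know about.

## 1. The transport model

The ST is treated as a one-dimensional tapered duct parameterised by
distance $x$ (mm) from the round window, with cross-sectional area $A(x)$
(mm²). Each drug species has perilymph concentration $C(x,t)$ (µg/mL)
obeying

$$
\frac{\partial C}{\partial t}
 = \frac{1}{A}\frac{\partial}{\partial x}
   \Big( f\, D\, A \frac{\partial C}{\partial x} \Big)
 - k_{\mathrm{elim}} C + S,
$$

where $D$ is the free diffusion coefficient, $f \ge 1$ an optional
dispersion factor standing in for oscillation-enhanced mixing,
$k_{\mathrm{elim}}$ a first-order perilymph-to-blood clearance, and $S$ the
dephosphorylation coupling (DSP loses mass at $k_{\mathrm{hyd}}$, Dex gains
it 1:1). Assumptions worth making explicit:

* **Well-mixed middle ear.** The injected volume stays in place and decays
  as $C_{me}(t) = C_{me,0}\, e^{-k_{me} t}$; the injected volume (1 mL)
  exceeds the cavity volume, so the reservoir is treated as
  concentration-controlled rather than mass-limited.
* **Single basal entry.** RWM and oval-window entry are folded into one
  exchange area $A_{rwm}$ at $x = 0$ with flux
  $J = P A_{rwm} (C_{me} - C(0,t))$; the flux can reverse sign
  (back-diffusion late in a run).
* **No radial gradients.** Sections equilibrate radially much faster than
  the axial diffusion time (radius $\sim$0.5 mm vs length 33.5 mm), the
  usual 1D reduction for cochlear ducts.
* **No scala vestibuli / endolymph exchange.** Out of scope; this biases
  long-time apical predictions (some drug would detour through the
  vestibular scala in reality).
* **Aqueduct off by default.** CSF inflow at rest is not substantial; when
  enabled it enters the base as zero-concentration plug flow with a
  volume-conserving distributed outflow.

### Parameters and defaults

| parameter | default | units | provenance |
|---|---|---|---|
| $P$ (Dex / DSP) | 123e-9 / 12e-9 | m/s | ex vivo porcine RWM measurements |
| $D$ (Dex / DSP) | 4.4e-6 / 4.0e-6 | cm²/s | free-solution small-steroid scale |
| $A_{rwm}$ | 2.0 | mm² | porcine RWM anatomical scale |
| $k_{me}$ | 2.0 | 1/h | calibrated, see below |
| $k_{\mathrm{elim}}$ | 2.0 | 1/h | calibrated, see below |
| $f$ (dispersion) | 1 | — | molecular diffusion only |
| aqueduct flow | 0 | nL/s | resting CSF exchange negligible |
| dose (Dex / DSP) | 100 / 4000 | µg/mL | the clinical formulations modelled |

The two elimination rates are the only parameters without a measured or
structural anchor. They were chosen once, jointly, from a coarse scan of the
physiologically plausible 0.1–2/h band against the published FluidSim
predictions for this system at 30 min (shipped in
`inst/extdata/reference_predictions.csv`); the optimum sits at the fast end
(half-times of about 21 min in both compartments, consistent with rapid
middle-ear drainage of solutions and fast perilymph clearance of
dexamethasone). Both are plain fields of `drug_params()` and should be
re-fitted when perilymph time-series data are available.

### What the model reproduces, and where it deviates

With these defaults the package's own acceptance computation
(`scripts/acceptance.R`) gives, for the porcine geometry at 30 min:
whole-ST Dex 0.393 µg/mL and DSP (no dephosphorylation) 1.77 µg/mL —
against published FluidSim values of 0.39 and 1.27 — and at 1 mm from the
base, Dex 2.57 vs 1.72 and DSP 11.2 vs 5.84. The whole-duct averages agree
well; the near-window values run systematically high, i.e. the simulated
axial gradient is steeper than FluidSim's. The pattern is consistent with
the upstream simulator's (unpublished) defaults including stronger effective
axial mixing than molecular diffusion; we deliberately keep $f = 1$ rather
than tune an unmeasured dispersion toward agreement, and expose `f` as
`dispersion_factor` for sensitivity analyses.

### Base-to-apex diffusion time

`time_to_apex()` runs a pure-diffusion front experiment (constant source,
clearance off) and reports the first time the apical station reaches a
threshold fraction (default 1%) of the running basal maximum. Under this
definition the model gives 1.77 days (pig, 33.5 mm) and 1.33 days (human,
29 mm) — the expected $L^2$ ordering, but far below the published "total
diffusion time" of ~8 and ~6 days for the same comparison. Those published
times also scale as $L^2$ ($8/6 \approx (33.5/29)^2$), which any
fixed-fraction criterion reproduces; their magnitude, however, corresponds
to near-equilibration of the apex (threshold around 35–50% of the basal
level at $D = 4.4\times10^{-6}$ cm²/s), not to 1% front arrival. The
threshold is therefore an explicit argument, and reported times should
always be quoted together with the criterion used.

```{r time-to-apex}
time_to_apex(cochlear_geometry(make_default_profiles()$pig),
             default_drugs()$dex, dose_protocol(100),
             threshold_fraction = 0.01)
```

## 2. Numerical scheme

Finite volume on station centers (default $\Delta x$ = 0.1 mm), face
conductances $D A / \Delta x$ with harmonic-mean areas, so the scheme is
conservative on the tapered grid. Time stepping is Crank–Nicolson at
$\Delta t$ = 0.5 s with the first two steps taken as backward Euler — an
L-stable startup that damps the ringing CN would otherwise show against the
stiff membrane boundary. Aqueduct advection is first-order upwind inside the
same tridiagonal solve. An explicit Euler path exists for cross-checking and
refuses time steps above the diffusive limit.

Every run audits mass with the same quadrature as the integrator: influx −
backflux − eliminated − washout ± hydrolysed must equal the change in
perilymph content; the residual (relative to total turnover) is ~1e-14 and a
warning fires above 1e-6. Halving $\Delta x$ moves the 30-min whole-ST mean
by under 1%; the acceptance script uses $\Delta x$ = 0.025 mm, at which the
reported values are grid-converged to ~0.3%. Front-arrival runs use
$\Delta t$ = 0.5 min over up-to-30-day horizons (the dynamics there evolve
over hours, and Crank–Nicolson is unconditionally stable).

Degenerate inputs are first-class: empty masks, single-station profiles,
out-of-range queries and over-drawn columns raise classed conditions
(`empty_mask`, `invalid_profile`, `out_of_range`, `insufficient_volume`);
a straight tube raises `degenerate_geometry` from the spiral fit.

## 3. Geometry from segmented volumes

The centerline model is a conical helico-spiral: planar radius
$r(\theta) = a e^{b\theta}$ about a unit axis, with linear axial advance
$z = \mathrm{pitch}\cdot\theta$. This is the simplest 3D extension of a
logarithmic spiral and matches cochlear anatomy well; fitted objects are
normalised so $\theta = 0$ sits at the small-radius end and $b \ge 0$.

The fit has to survive not knowing the axis. Per-slab centroids
perpendicular to a guessed axis fail for a cochlea because axial and planar
extents are comparable and any slab crosses several turns. Instead:

1. voxels are wedged into 72 azimuthal bins about a candidate axis and each
   wedge is clustered (single linkage in the radius–height plane, cutoff 3
   voxels) into tube cross-section blobs whose centroids sample the
   centerline;
2. blobs are chained by nearest-neighbour walking — an ordering that uses
   only 3D distances, so it is robust to a poor axis guess;
3. the axis is re-estimated from cross products of consecutive chain
   segments (for a winding path these all point along the spiral axis) and
   the extraction repeats once if the guess was off by more than ~3°;
4. the unwrapped angle, anchored to the measured azimuths, initialises
   linear fits of $\log r$ and $z$ against $\theta$, followed by
   Nelder–Mead refinement of all eight parameters (center, axis tilts,
   $\log a$, $b$, pitch) against point-to-curve distances with per-point
   Newton projection.

All three principal axes of the voxel cloud are tried as candidates
(smallest-variance first) and the lowest-residual fit wins; a sub-voxel
residual short-circuits the search. On synthetic phantoms the recovered
$a$, $b$ and pitch are within 5% of truth across a 3×3 grid of shapes at
3.5 turns (usually within 1–2%), with RMS residuals of a fraction of a
voxel.

Cross-sections are measured every 100 µm of **arc length** (equal-angle
stations would crowd the narrow end) on planes normal to the local tangent,
by trilinear resampling of the mask at half-voxel resolution, thresholding
at 0.5, and keeping only the in-plane connected component containing the
centerline point — adjacent turns also intersect the plane and must not
contribute. Two guards handle the tube ends, where the fitted curve can
overshoot the physical duct by a fraction of a percent of arc length:
stations whose center sample is not solidly interior are clipped, and a
terminal station more than 5% below its interior neighbour (impossible from
the taper alone) is dropped as an end-cap artifact. The basal end of the
returned profile is identified as the wider end by default (`basal_end =
"auto"`), overridable when anatomy says otherwise. Regions outside the
fitted spiral (e.g. the hook) are supplied as manual CSV profiles and
concatenated by the caller.

## 4. Sequential sampling

Capillary draws (~60 s each) are fast compared to diffusion (hours), so
draws are quasi-static: tube $k$ receives the contiguous slice of the
original column spanning cumulative volume $((k-1)V_t, kV_t]$ from the base,
the column sliding basally as fluid is removed. By default the column is
refilled apically with zero-concentration CSF (`replacement = "csf_zero"`),
matching the observation that rapid extraction pulls CSF through the
aqueduct; `"none"` instead errors when draws exceed the available
perilymph. Integrals are exact for the piecewise-linear area and
concentration interpolants, so tube masses, column mass and pooled values
agree to 1e-10.

One caution this model makes quantitative: on a 30-min post-injection field
the basal gradient is so steep that the first 5 µL tube dominates the
drawn mass by orders of magnitude. Experimentally reported *equality* of a
first 5 µL sample and a pooled 15 µL follow-up is not reproducible from a
clean quasi-static draw of any plausibly steep field; it requires mechanisms
outside this model (middle-ear fluid contamination at the sampling site,
shortcutting through the vestibule, or much stronger in-duct mixing).

## 5. The synthetic data generator

`make_cochlea_mask()` voxelizes a tube of linearly tapering radius swept
along the helico-spiral, returning the mask together with the exact spiral
parameters and analytic area profile. The defaults (33.5 mm arc length,
3.5 turns, basal/apical tube radii 450/200 µm, 20 µm voxels) emulate a
porcine ST at light-sheet scale. What it deliberately does **not** emulate:
non-circular (flattened) real cross-sections, surface roughness and
segmentation noise, imaging anisotropy and clearing distortion, and the
basal hook. Passing the recovery suites therefore demonstrates correctness
of the geometric algorithms on clean topology — not robustness to
real-world segmentation artifacts, which should be validated against
manually traced data. `make_default_profiles()` provides approximate
species-scale ST profiles (pig: 33.5 mm, 2.2→0.4 mm² log-linear taper,
35.4 µL; human: 29 mm, 2.0→0.36 mm², 27.7 µL); these are composites at the
species scale, not measurements of an individual ear, and are flagged
`synthetic` in their provenance field. `simulate_measurements()` adds
log-normal multiplicative noise (concentrations are positive and spread
over orders of magnitude between animals) with an exact coefficient of
variation.

## 6. Known limitations

* Single-scala model: no scala vestibuli, endolymph, or modiolar routes.
* The elimination defaults are calibrated to a simulator, not fitted to
  perilymph assay time-series; treat absolute concentrations as
  order-of-magnitude until refitted.
* Near-window (ST:1-type) predictions are sensitive to unmodelled local
  mixing; whole-duct averages are the robust output.
* The spiral fit assumes a single tube winding >1 full turn about one axis;
  straight or branched structures are rejected rather than mis-fitted.
* Isotropic voxels only; anisotropic stacks must be resampled upstream.
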