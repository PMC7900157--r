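---
title: "Quantifying post-AVR aortic hemodynamics from voxel velocity fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying post-AVR aortic hemodynamics from voxel velocity fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortaflow)
```

## The measurement problem

After surgical aortic valve replacement (AVR), the hemodynamic quality of
the result is judged by a handful of parameters: the maximum velocity in
the transvalvular jet, the pressure gradient derived from it, the
eccentricity of the jet, the amount of secondary (swirling) motion in the
ascending aorta, and the effective orifice area of the prosthesis relative
to the patient's body size. Two modalities produce the velocity data these
parameters are computed from — 4D flow MRI on the implanted patient, and
CFD on a virtual implantation — and a central methodological question is
how well parameters computed from one agree with the other.

`aortaflow` implements the parameter layer that both modalities share. Its
input is deliberately minimal: a steady, voxelized, three-component
velocity field with a lumen mask (`velocity_field()`), plus a description
of the vessel centerline and lumen radius (`aorta_geometry`). Everything
else — cross sections, statistics, reports, comparison tables — is derived
from those two objects.

## Parameters and conventions

**Maximum velocity and pressure gradient.** `max_velocity()` returns the
strict maximum of the voxel speed over a region; the default analysis
region in `analyze_case()` is the lumen between the valve plane and the
mid-ascending section, which is where the jet lives. The gradient is the
simplified Bernoulli form Δp = 4·v² (mmHg with v in m/s) — the clinical
convention, not the physically recovered pressure drop, which the package
deliberately does not model. A strict maximum is the right default for
clean (CFD-like) fields but is inflated by additive noise in MRI-like
fields, since it is the maximum over many noisy samples; `max_velocity()`
therefore accepts an optional `quantile_guard` (e.g. 0.999) that reports a
high speed quantile instead. The strict maximum remains the default
because it is what clinical practice reports.

**Cross sections.** SFD and NFD are evaluated on three planes normal to
the centerline: at the sinotubular junction, directly proximal to the
brachiocephalic artery, and midway between the two. `lumen_cross_section()`
samples the lumen–plane intersection on a regular in-plane grid and
measures area and perimeter with marching squares on a signed
inside/outside function. Both A and P are measured on the *same*
piecewise-linear contour (crossing chords for P, per-cell clipped polygons
for A), so the isoperimetric inequality P² ≥ 4πA — hence
D_h = 4A/P ≤ 2√(A/π) — holds by construction rather than approximately;
the estimates converge at second order in the sampling step (default
0.5 mm).

**Secondary flow degree.** SFD is the area-weighted mean of the per-point
in-plane speeds divided by the area-weighted mean of the per-point
*absolute* through-plane velocities. Mean-of-magnitudes is used on both
sides: averaging the in-plane velocity *vector* first would cancel any
symmetric swirl and make the SFD of a perfect vortex zero, defeating the
parameter's purpose of quantifying secondary motion.

**Normalized flow displacement.** The center of flow is the in-plane
centroid weighted by *forward* (positive) through-plane velocity;
retrograde samples are excluded from the weighting (a `"signed"` variant
is available). The vessel center is the unweighted centroid of the lumen
samples, and the displacement is normalized by the hydraulic diameter of
the same section. NFD is dimensionless in [0, 1).

**Effective orifice area and mismatch.** EOA = Q/(51.6·√Δp) with Q in
ml/s, Δp in mmHg, EOA in cm². The constant 51.6 is the Gorlin-type
continuity value; it is an explicit argument so an alternative form can be
swapped in. IEOA = EOA/BSA, and the mismatch classes use the standard
echocardiographic thresholds with both boundary values (0.85, 0.65
cm²/m²) assigned to *moderate*, because the neighboring classes are
defined by strict inequalities ("above 0.85", "below 0.65").

**Prosthesis orifice and Reynolds number.** The prosthesis model scales
linearly with nominal size (19–29 mm in 2 mm steps). The internal
(narrowest, leaflet-bounded) orifice diameter is not published, so it is
recovered by inverting Re = 4ρQ/(π·μ_∞·D) on a reference size-23 case
(354 ml/s at Re = 6,997), giving D = 19.325 mm and an internal ratio of
0.84022. The same ratio reproduces the Reynolds numbers of all ten
packaged cohort rows — four different nominal sizes — to within the
rounding of the printed inputs, which is the evidence that a single linear
scaling is adequate. Reynolds numbers use the infinite-shear viscosity and
the mean orifice velocity Q/(πD²/4).

**Rheology.** Blood is a ρ = 1050 kg/m³ Carreau–Yasuda fluid
(μ₀ = 0.16 Pa·s, μ_∞ = 0.0035 Pa·s, n = 0.2128, a = 0.64, λ = 8.2 s);
`carreau_yasuda_viscosity()` is monotone non-increasing with exact limits
μ(0) = μ₀ and μ(∞) = μ_∞.

**Outflow splits.** `murray_outflow_split()` distributes the arch flow
under two constraints: the brachiocephalic artery receives as much as the
left common carotid and left subclavian together (hence exactly half the
arch flow), and the remaining half splits between carotid and subclavian
in proportion to diameter cubed (Murray's law). Conservation is exact by
construction.

## The synthetic-data generator

Real post-AVR fields cannot ship with the package, so the generator
produces fields whose section statistics are known in closed form.

The idealized aorta is a candy-cane: a straight ascending segment from the
valve plane, a circular arch (default 180° at 3.5 cm centerline radius),
and a straight descending segment, with lumen radius linear in arclength
(defaults 1.5 → 1.2 cm — adult scale). The three standard sections lie in
the ascending segment, where cross sections are exactly circular, so the
analytic ground truth is exact there.

The jet is a blunted power law about a center offset from the lumen axis:
with x = r′/r_jet, axial speed v_peak·(1 − x^p) inside the jet and zero
outside, and an optional solid-body swirl about the jet axis,
w = swirl_ratio·v_peak·x, confined to the jet like the axial profile. An
optional e-folding decay relaxes the jet toward a full-lumen profile
downstream; the parameterization guarantees the jet never leaves the
lumen. Because every cross-sectional profile is axisymmetric about the jet
center:

- NFD = e/(2R) exactly (the flow-weighted centroid *is* the jet center);
- SFD = swirl_ratio · 2(p + 2)/(3p), independent of jet radius;
- the speed maximum is v_peak·max_x √((1 − x^p)² + (swirl_ratio·x)²),
  which exceeds v_peak slightly whenever swirl is on — the ground truth
  uses this analytic maximum, not the nominal peak.

MRI-like degradation is box-average resampling (partial-volume emulation:
velocities are zero outside the lumen and participate in the average) to a
typical 4D-flow voxel size of 2.80 × 2.25 × 2.25 mm, keeping a coarse
voxel in the mask if at least half its volume was lumen, followed by
seeded i.i.d. Gaussian noise per component inside the mask. Box averaging
can only lower the peak speed (convexity), so the v_max degradation bias
is one-sided at zero noise. All randomness sits behind explicit integer
seeds; no global RNG state is touched.

What the generator does *not* emulate: velocity aliasing (VENC wrap),
eddy-current phase offsets, segmentation error, turbulent fluctuations,
and time resolution. Passing recovery tests on synthetic fields therefore
demonstrates the correctness of the estimators, not the fidelity of any
acquisition; conclusions about real MRI/CFD agreement still require real
paired data.

## Numerical choices

- **Units**: SI everywhere internally (m, m/s, Pa·s, m³/s); mm, ml/s,
  mmHg, cm² only at I/O boundaries, flagged by unit-suffixed names.
- **Grids**: 0-based voxel indexing in files, cell-centered coordinates;
  trilinear interpolation for all off-grid evaluation, with velocity
  treated as zero outside the mask.
- **Streamlines**: classical RK4 on the *normalized* direction field
  dx/ds = v/|v| at a fixed arc-length step, so the step controls geometric
  resolution independent of local speed and integration is stable in slow
  recirculation zones; speeds are stored separately for color coding.
  Termination on mask exit, on speed below a threshold, or at a length or
  step cap, reported per streamline. Fourth-order convergence is verified
  on a solid-body-rotation helix, where trilinear interpolation is exact
  and the error is purely the integrator's.
- **Statistics**: R² is the squared Pearson correlation (equal to the
  unadjusted coefficient of determination of the simple regression); RMSE
  is the root mean squared *regression residual* with denominator n by
  default (the n − 2 form is available — with cohorts of ten the choice is
  material, so it is explicit). The residual convention is the one under
  which a regression RMSE can be far smaller than the mean paired offset.
  Quartiles interpolate linearly between order statistics
  (`quantile(type = 7)`).
- **Degenerate inputs** error with typed conditions rather than returning
  infinities: empty sections, zero mean through-plane velocity (SFD), no
  forward flow (NFD), zero gradient (EOA), constant regressors. A constant
  column inside a cohort comparison table yields NA agreement statistics
  instead of aborting the table.

## Validation problem sizes

The test suite validates parameter recovery on 20 seeded jets on the
default aorta voxelized at 1 mm (about 150,000 lumen voxels), with jet
parameters drawn uniformly from realistic post-AVR ranges: v_peak
1.5–3 m/s, offset 0–0.35 of the lumen radius, swirl ratio 0–0.5, bluntness
exponent 2–8, jet radius 0.5–0.65 of the lumen radius. At this resolution
the recovered v_max lies within 2 % of truth and NFD within 0.02; at
MRI-grade spacing with 5 % velocity noise the median NFD error stays below
0.05. Cross-section estimators are exercised at 0.125–0.5 mm in-plane
steps; streamline checks use 0.1–0.8 mm arc-length steps.

## Known limitations

- The idealized geometry supports section placement and synthetic flow; it
  is not a substitute for patient-specific segmentation, and parameters
  sensitive to local anatomy (SFD/NFD especially) will differ on real
  vessels.
- The strict-maximum v_max is noise-inflated on MRI-like fields (visible
  in the README example); comparisons across noise levels should fix the
  acquisition model.
- The EOA constant and flow-rate convention are configurable because
  published cohort IEOA values depend on the exact equation variant used;
  the packaged reference IEOA table ships as data only and is not
  bit-reproduced by the default formula.
- Steady (peak-systolic) fields only: no cine data, no pathlines, no
  leaflet dynamics, no wall shear stress, no pressure-field recovery.
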