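---
title: "Methods: hyperelastic characterization and compliance-based phantom design"
author: "aortaphantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperelastic characterization and compliance-based phantom design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortaphantom)
```

## Scope

Silicone replicas ("phantoms") of the aortic arch are used in pulse
duplicators to test valves, stents and surgical techniques in vitro. For a
phantom to be hemodynamically faithful its wall must match the *compliance*
of the living vessel, which depends jointly on the wall material and the
wall thickness. This package implements the desk-scale part of that design
workflow:

1. constitutive models for the two candidate wall materials — an isotropic
   one-term **Ogden** model for moulding silicone and the anisotropic
   **Holzapfel–Gasser–Ogden (HGO)** model for aortic tissue;
2. **calibration** of those models from uniaxial / equibiaxial
   stress–strain test curves;
3. a **pressurized-pipe experiment**: static inflation of a thick-walled
   hyperelastic cylinder, from which compliance `C = ΔV/Δp` and
   distensibility `AD = C/V0` select the wall thickness;
4. the **pulsatile inlet waveform** used as the flow boundary condition,
   and post-processing **flow metrics** (helicity, kinetic energy,
   normalized velocity profiles, peak timing) for gridded velocity fields;
5. **synthetic-data generators** that stand in for the ex vivo tests and
   for CFD velocity fields, so the entire pipeline is testable without
   laboratory data.

The 3D fluid–structure-interaction simulation of a full aorta is out of
scope; the package covers everything around it that can be computed on a
desk.

## Constitutive models

Both models are hyperelastic: stress derives from a strain-energy density
`W` of the principal stretches `λ1, λ2, λ3` (with volumetric ratio `J`).

**Ogden (one term).**
`W = (2μ/α²)(λ1^α + λ2^α + λ3^α − 3) + (1/D)(J − 1)²`.
We read the leading coefficient as `2μ/α²`, the standard
reduced-polynomial normalization under which `μ` is the small-strain shear
modulus for every `α` (the `α → 2` limit is neo-Hookean, which the tests
verify). Parameters: `μ` (MPa), `α` (–), `D` (MPa⁻¹). The calibrated
silicone values shipped as `reference_material("silicone")` are
`μ = 0.173 MPa`, `α = 4.39`, `D = 1.193 MPa⁻¹`.

**HGO.** An isotropic neo-Hookean matrix plus two dispersed collagen-fiber
families at `±θ` from the circumferential axis in the
circumferential–longitudinal sheet plane:

```
W = C(I1 − 3) + (1/D)((J² − 1)/2 − ln J)
    + k1/(2 k2) Σ_families { exp[k2 ⟨Ē⟩²] − 1 },
Ē  = κ(I1 − 3) + (1 − 3κ)(I4 − 1).
```

`I4` is the squared stretch along a family's mean direction; `κ ∈ [0, 1/3]`
measures dispersion (0 aligned, 1/3 isotropic); the Macaulay bracket
`⟨x⟩ = max(x, 0)` switches fibers off in compression, which the tests check
exactly. The calibrated porcine values (`reference_material("porcine")`) are
`C = 0.0289 MPa`, `k1 = 0.12 MPa`, `k2 = 0.4`, `κ = 0.25`, `θ = 27°`,
`D = 0.7 MPa⁻¹`.

**Kinematic conventions.** Test deformation is engineering strain
(clamp displacement over initial length), so `λ = 1 + ε`; test stress is
nominal (force over undeformed section), `P = σ/λ` under uniaxial loading.
All analytic responses enforce incompressibility (`J = 1`) exactly: both
materials are nearly incompressible and the mechanical tests carry no
volumetric information, so `D` is carried but never fitted and never
contributes. Uniaxial responses solve transverse equilibrium (zero
transverse Cauchy stress with `J = 1`) by a damped, vectorized Newton
iteration with a bracketed `uniroot` fallback, to a residual below
`1e-10` relative to the material stress scale; for the anisotropic HGO
material the two transverse stretches are unequal and this solve is
essential. An independent oracle (numerically minimizing the energy over
the transverse stretch and differentiating the minimized energy) confirms
the equilibrium route in the tests.

## Calibration

`fit_ogden()` and `fit_hgo()` replace trial-and-error tuning with bounded
Levenberg–Marquardt least squares (`minpack.lm`) on nominal stress,
restarted from a deterministic log-spaced grid (9 starts over
`μ ∈ [1e-3, 10] MPa × α ∈ [0.5, 12]`; 16 starts over `C, k1, k2`). The
objective is unweighted absolute stress misfit — the simplest defensible
choice absent a reported weighting. Ties are broken by lowest residual,
then lowest `k2`. Because the start grid is fixed, fits are bit-for-bit
reproducible.

With only two uniaxial directions, `(κ, θ)` trade off against `(k1, k2)`;
`fit_hgo()` therefore fixes `κ` and `θ` at user-supplied values by default
and frees `(C, k1, k2)`. A five-parameter mode exists but warns that it is
weakly identifiable. On noise-free self-generated curves both fits recover
the generating parameters to better than 0.1% (relative), which is the
package's round-trip consistency guarantee; it does not certify accuracy
on real, noisy, inhomogeneous dog-bone data, where clamp end effects (not
modeled here — the gauge region is treated as homogeneous) bias the
measured curves.

## The pressurized-pipe experiment

The phantom wall thickness is chosen on a straight pipe: length 50 mm,
inner diameter 30 mm (reference inner volume `V0 = π·15²·50 ≈ 35,340 mm³`),
wall thickness swept over 1–4 mm. The pipe is filled at `p0 = 80 mmHg` in
"unstressed" conditions and pressurized to 120 mmHg; compliance is
`C = ΔV/Δp` and distensibility `AD = C/V0`.

`inflate()` solves the finite-deformation inflation of an incompressible
thick-walled cylinder at fixed axial stretch `λz`: with deformed radii
`r(R) = sqrt(ri² + (R² − Ri²)/λz)`, the inner radius satisfies

```
p = ∫_{ri}^{ro} (σθθ − σrr) / r dr
```

with zero external traction. The integral is evaluated with adaptive
quadrature (relative tolerance 1e-9) and the root found by bracketed
bisection/Brent iteration to 1e-10 relative. HGO fibers at `±θ` in the
hoop–axial surface stiffen `σθθ` and `σzz`. Modeling choices, all
recorded here because the original test conditions are underdetermined:

* the tube is axially fixed (`λz = 1`) and end effects are neglected
  (infinitely long pipe);
* "unstressed at `p0`" is taken literally: the stated geometry is
  stress-free at 80 mmHg and only the overpressure `p − p0` loads the wall
  (`pressure_reference_mode = "stress-free-at-p0"`); the alternative
  zero-referenced mode is available;
* 1 mmHg = 133.322 Pa exactly.

At small loads the solver reproduces the incompressible Lamé thick-wall
closed form to 0.03% and converges to the thin-wall membrane limit; both
are regression-tested.

**The physiological band and its scale.** The target distensibility range
for a young healthy aorta is quoted in the design literature as
"5 ÷ 9.1 /mmHg". Taken literally that is five orders of magnitude away
from any measured aortic distensibility; in vivo values for young healthy
ascending aortas are of order `10⁻³ mmHg⁻¹` (roughly 3–10 × 10⁻³).
Dimensional analysis therefore fixes the band scale at `10⁻³ mmHg⁻¹`, and
`thickness_sweep()` uses `band = c(5e-3, 9.1e-3)` by default, reporting
`AD` both in `mmHg⁻¹` and ×10³.

With the shipped calibrated materials at 2.5 mm wall the package computes
`AD ≈ 3.40 × 10⁻³ mmHg⁻¹` for silicone and `≈ 8.69 × 10⁻³ mmHg⁻¹` for
porcine tissue. Two qualitative design statements reproduce robustly: `AD`
decreases monotonically with wall thickness, and the silicone wall is less
distensible than the porcine one at every thickness. The porcine tube
falls inside the physiological band near 2.5 mm; the silicone tube does
not — a Lamé-type bound shows that a homogeneous cylinder with
`μ = 0.173 MPa` at these dimensions cannot exceed `AD ≈ 3.5 × 10⁻³ mmHg⁻¹`
under any standard end condition, so under this package's idealized
(axially fixed, end-effect-free) pipe model the silicone/porcine
thickness-band intersection is empty. `thickness_sweep()` reports an empty
intersection explicitly rather than erroring, and the discrepancy with
FE-based pipe results is documented as a known fidelity limit of the
homogeneous-cylinder idealization.

## Inlet waveform and flow metrics

The pulsatile inlet flow has period `T = 1 s` (60 bpm), a systolic
fraction of 37%, a backflow notch at end systole whose magnitude is 10% of
the peak, and a forward-phase ("ejected") volume of `SV = 60 mL`. No
analytic waveform shape accompanies those constraints, so
`make_inlet_waveform()` uses a half-sine forward lobe on
`[0, 0.37 s]` — whose amplitude `q_max = SV·π/(2·0.37) ≈ 254.6 mL/s`
follows from the integral constraint — a negative half-sine backflow lobe
of amplitude `0.1·q_max` over a configurable `backflow_duration`
(default 0.08 s), and zero flow through diastole. "Stroke volume" is read
as the forward-lobe integral, not the net integral. All four constraints
hold to 1e-9 (relative) by construction and are asserted in the tests; the
forward peak falls at half the systolic duration, 0.185 s.

Flow post-processing operates on rectilinear-grid velocity snapshots
(SI units):

* **helicity** `He = v · (∇×v)` (m/s²), node-wise, with vorticity from
  second-order finite differences — centered three-point stencils in the
  interior (exact for quadratics, also on non-uniform spacing) and
  one-sided second-order stencils at grid boundaries. Derivatives are
  taken on the full grid and masked nodes are excluded from the output
  only; values adjacent to a mask edge therefore inherit whatever field
  values lie outside the mask (zero for the shipped generators). This is
  simpler than mask-aware stencils and is exact for the analytic test
  fields, but near-wall helicity on masked CFD imports should be read with
  that caveat;
* **kinetic energy** `ρ|u|²/2` with trapezoidal volume weights over the
  masked domain, reported both as a volume-weighted mean density (J/m³)
  and a total (J), since the two are often conflated in summary plots;
* **normalized profiles**: axial velocity on a cross-section divided by
  the section-averaged axial velocity `Ū`, plus the peak ratio
  `u_max/Ū` (≈ 2 for Poiseuille flow, ≈ 1 for plug flow);
* **peak timing** by three-point parabolic interpolation around the
  discrete maximum, earliest-time tie-break.

Helicity and kinetic energy converge at second order in grid spacing on
smooth fields (verified by grid-refinement tests at 17/33/65 nodes).

## Synthetic data

`gen_mechanical_tests()` evaluates the exact forward response on a uniform
strain grid up to 100% engineering strain (the tested deformation range)
and multiplies each replicate by lognormal noise, `sdlog = 0.02` by
default — multiplicative because mechanical-test errors scale with load.
The default replicate counts are 5 for equibiaxial (silicone) and 4 for
uniaxial (porcine) tests, matching the experimental sample counts. The
noise level is a stand-in chosen to bracket the published min–max spread
bars visually; no quantitative spread is published, so no test asserts
against it. `gen_velocity_field()` provides Poiseuille flow, solid-body
rotation with axial drift (constant helicity `2Ωw`), and superpositions.
All generators restore the caller's RNG state and are pure functions of
`(parameters, seed)`.

What the synthetic data does *not* emulate: inhomogeneous dog-bone strain
fields, viscoelastic rate effects at the 0.5 mm/s test speed, layered
(intima/media/adventitia) wall structure, residual stress, and turbulent
or secondary-flow structure in the velocity fields. Green tests on
synthetic data therefore certify the numerics and the self-consistency of
the pipeline, not fidelity to any particular ex vivo data set.

## Problem sizes and numerical defaults

Default problem sizes were chosen as the smallest that leave discretization
visibly below the assertion tolerances: 50-point strain grids for
calibration; 5 pressure samples for a compliance evaluation (the
compliance uses only the endpoints); 13–81 nodes per axis for field
metrics; 1000 replicates for the noise-level Monte-Carlo check; 100
replicates for the noisy-fit recovery study. Degenerate inputs error
loudly rather than coerce: non-monotone strain grids, mixed curve modes,
non-unit fiber directions, all-masked fields, walls too soft to carry the
load, and constant series in `peak_time()` are all rejected with
diagnostic messages.

## Known limitations

* The pipe model neglects end effects and residual stress; distensibility
  of short clamped pipes will differ (see the band discussion above).
* Uniaxial calibration assumes a homogeneous gauge region; inverse
  finite-element calibration is out of scope.
* The five-parameter HGO fit is supported but not identifiable from two
  uniaxial directions; fix `κ` and `θ` whenever possible.
* Velocity-field input is limited to rectilinear structured grids
  (CSV; one snapshot at a time).
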