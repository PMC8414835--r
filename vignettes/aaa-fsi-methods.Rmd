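---
title: "Methods: desk-scale FSI modeling of abdominal aortic aneurysms with pre-stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale FSI modeling of abdominal aortic aneurysms with pre-stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model overview

`aaafsi` implements a complete, desk-scale pipeline for patient-specific
fluid-structure interaction (FSI) simulation of abdominal aortic aneurysms
(AAA) from ultrasound-style lumen segmentations:

1. **Geometry** -- synthetic contour-stack segmentations (stacked elliptical
   lumen contours along a curved centerline), Bezier elongation to circular
   20 mm ends, a structured quadrangular lumen surface, and a two-layer
   triquadratic (27-node) hexahedral wall mesh of 2 mm thickness.
2. **Wall mechanics** -- an incompressible Neo-Hookean wall under a follower
   (deformation-dependent, surface-normal) luminal pressure with
   cylindrical end constraints, and Backward-Incremental pre-stress
   estimation (BIM) of the stress already present in the imaged, pressurized
   geometry.
3. **Hemodynamics** -- brachial-to-abdominal-aortic pressure conversion, a
   generic triphasic inlet waveform, Carreau blood rheology, and a
   three-element Windkessel outlet tuned per patient with an added sac
   compliance.
4. **FSI** -- a partitioned coupling of the 3D wall and a reduced-order 1D
   distensible-lumen flow model, stabilized by interface quasi-Newton
   (IQN-ILS) iterations.
5. **Metrics** -- TAWSS, OSI, percentile summaries of displacement and von
   Mises stress over the AAA region, corrected displacement,
   pressure-scaled cross-arm spatial differences, and paired Wilcoxon
   statistics comparing the pre-stressed (PSE) and non-pre-stressed
   (no-PSE) arms.

The deliberate simplification relative to full 3D FSI is the fluid side:
there is no 3D Navier-Stokes solve. The lumen is discretized axially; mass
conservation distributes the prescribed inlet flow against the wall's
volume storage, a Poiseuille/Carreau friction law plus fluid inertia set
the axial pressure gradient, and wall shear stress is recovered from the
Poiseuille wall shear rate `4q/(pi a^3)` evaluated with the Carreau
viscosity. Consequences: secondary flows, vortex impingement and
Womersley-profile corrections are absent, so absolute WSS values are
smoother and systematically closer to quasi-steady values than a 3D CFD
solution would give. Direction-of-effect comparisons between the two arms
remain meaningful because both arms share the identical fluid model.

## Synthetic segmentation generator

The generator emulates what an automated 3D ultrasound lumen segmentation
delivers at the diastolic frame: one planar elliptical contour per axial
station. The default profile is a fusiform sac representative of the middle
of a surveillance cohort:

* maximum diameter 45 mm, native neck diameter 22 mm, sac length 70 mm
  with 10 mm straight necks (cohort lengths are 4-10 cm);
* anterior asymmetry 0.35 (AAA sacs bulge anteriorly because the spine
  constrains posterior growth) applied as an anterior center offset
  proportional to the local dilation;
* centerline bow 8 mm in the sagittal plane (moderate tortuosity);
* optional radius noise (`noise_sd`), applied as an axially correlated
  (3-contour moving-average) jitter with a small Gaussian ellipse-rotation
  wobble -- tracking-filter segmentation output is smooth frame to frame,
  and uncorrelated per-contour spikes would be artifacts, not anatomy. The
  realized maximum diameter is kept within `noise_sd` of the profile value.
  The default fixture is noise-free so that all desk-scale checks are
  deterministic.

What the generator does **not** emulate: intraluminal thrombus, local wall
blebs, branch ostia, twist irregularities, and the spatial error structure
of real speckle-tracked ultrasound. Tests that pass on these fixtures
therefore validate the numerics and the direction of the pre-stress
effect, not patient-level magnitudes.

## Meshing choices

Elongation adds exactly 50 mm of arc length per side: a cubic Bezier blend
(20 mm) turns the end tangent into the target direction -- parallel to the
spine (global z) proximally, the local centerline direction distally --
followed by a straight segment; contour shape blends linearly to a 10 mm
circle along the blend. The surface grid shares one even circumferential
node count across rings (median perimeter / target edge) and resamples
axially at the target edge, giving quads within 20% of the target size.
Extrusion offsets the surface along outward normals; each surface quad
becomes one 27-node hexahedron per layer (two layers, five node sheets,
3x3x3 Gauss quadrature). The triquadratic element was chosen over the
20-node serendipity variant because the structured extrusion provides the
extra nodes for free and the tensor-product quadrature is simpler.

The full-resolution element size is 0.8 mm; the test suite and the shipped
examples run at 5-7 mm. That choice is a problem-size decision of this
package: the analytic oracles (cylinder inflation, Laplace hoop stress,
annulus volume) show discretization errors well below the tolerances at
those sizes, and a refinement-trend test verifies that halving the edge
length shrinks the enclosed-volume error.

## Wall material and solver

The wall is isotropic, incompressible Neo-Hookean,
`sigma = -p I + G (B - I)`, with group shear moduli G = 0.92 / 1.02 /
1.36 MPa for small / moderate / large maximum diameter. Incompressibility
is imposed by a nearly-incompressible volumetric penalty with numerical
Poisson ratio 0.499 and bulk modulus `kappa = 2G(1+nu)/(3(1-2nu))`, rather
than a mixed displacement-pressure formulation: the penalty keeps the BIM
stress-transfer contract simple (one stress field per quadrature point). The
solver's strain-energy form is the standard compressible Neo-Hookean
potential `W = G/2 (I1 - 3) - G ln J + kappa/2 (ln J)^2`, whose Cauchy
stress `(1/J)(G(B - I) + kappa ln J I)` coincides with the stated relation
up to O(|J-1|) ~ 1e-3; hyperelasticity buys an energy-consistency test
(external pressure work equals stored strain energy to < 1%) and a
symmetric material tangent.

Newton details (not given by the source material, chosen here): relative
residual tolerance 1e-8 against the external load norm, iteration cap 50,
backtracking line search, follower-load stiffness included in the tangent.
The assembled tangent (material + initial-stress + follower-load terms) is
mildly asymmetric; its symmetric part is factorized -- supernodal LL' when
positive definite (near stable equilibria), simplicial LDL' otherwise --
and frozen across iterations (modified Newton) until progress degrades,
because a residual evaluation costs ~1% of a refactorization at these mesh
sizes. Static inflations ramp the load in ~25 mmHg increments from the
warm-start pressure.

End constraints: all inlet-ring and outlet-ring nodes (all five sheets) may
move only radially in the local cylindrical frame of their end (axis = local
centerline tangent), implemented exactly by a reduced-coordinate
transformation rather than by penalties.

## Backward-Incremental pre-stress

The measured geometry is a pressurized configuration, not a stress-free
one. The BIM applies the measured (AA diastolic) pressure in 20 increments
`p_i = p_m sin(i pi / (2 i_max))`; at each increment the nodal coordinates
are reset to the measured geometry, the previous increment's total Cauchy
stress is carried as an initial stress in the residual (entering as
`P0 = J sigma0 F^-T`), and one equilibrium solve is performed. Two
interpretation points that the source leaves open are resolved as follows:

* the carried stress is treated as a spatial Cauchy field held at the
  material point (an additive transfer); the push-forward correction is
  second order in the per-increment displacement, which the sine schedule
  makes small in the late increments;
* displacement is reset to zero at each increment together with the
  geometry (the previous displacement serves only as the Newton initial
  guess).

At the final increment the wall carries a stress field in equilibrium with
`p_m` on the measured geometry with near-zero displacement; re-solving at
`p_m` from that state moves no node by more than 1% of the wall thickness
(an acceptance property), and on a thin tube the mean hoop stress is within
5% of the Laplace value `p r / h`.

## Hemodynamics

* Brachial cuff pressures are converted to abdominal-aortic values as
  `0.88 p_dia` and `1.05 p_sys`.
* The inlet waveform is a C1 piecewise sin^2 template -- systolic forward
  peak (35% of the period), early-diastolic reverse flow (20%, amplitude
  25% of the peak), low diastolic forward flow (amplitude 10%) -- at 75 bpm,
  normalized analytically so the mean flow is exactly 0.96 L/min. Only the
  period and mean are contractual; the shape is this package's documented
  template for infrarenal aortic flow.
* Carreau parameters: 0.056 / 0.00345 Pa s, 3.313 s, 0.3568.
* The characteristic impedance uses the minimal-reflection formula with the
  **actual** outlet radius of the mesh (10 mm for the standard 20 mm
  outlet); the printed 1 mm value appears inconsistent with the 2 cm outlet
  and Z only seeds the tuner, where the total resistance constraint absorbs
  the difference.
* Windkessel construction: `R_T = p_mean/q_mean`, `R = R_T - Z`,
  `C = tau/R` with RC-time 0.6 s. The added sac compliance `C_A` is the
  finite difference `(V_sys - V_dia)/(P_sys - P_dia)` of enclosed lumen
  volumes computed per arm from static solves (with PSE: BIM state and
  systolic solve; without: direct inflations of the unloaded geometry).
* Tuning iterates two multiplicative updates -- total resistance by the
  ratio of target to simulated mean pressure, compliance by the ratio of
  simulated to target pulse pressure -- until simulated diastolic and
  systolic pressures at the AAA node are within 0.5 mmHg of the converted
  targets. The update rule is this package's choice; it converges in a
  handful of iterations for the whole cohort. The 0D circuit (inflow into
  `C_A` to ground, then Z in series with R || C) is integrated with a
  stiff-capable solver (`deSolve::lsoda`), warm-started between tuner
  iterations.

## Partitioned FSI

The interface fields are the axial profile of luminal cross-sectional area
(wall to fluid; ring-polygon areas at every fine axial station) and the
axial luminal pressure profile (fluid to wall; broadcast per face). Each
time step alternates a wall equilibrium solve and a 1D fluid solve until
the relative interface pressure residual drops below the coupling
tolerance. The first iteration of a step uses relaxation (omega = 0.5) when
no secant information exists; subsequent iterations apply IQN-ILS with a
least-squares inverse-Jacobian approximation whose difference columns are
reused across the last 8 time steps (never differencing across time-step
seams). Two practical safeguards: second-order predictors for both the
interface pressure and the wall displacement, and a 30 mmHg trust region on
the interface update. Without pre-stress the wall starts unstressed at the
measured geometry and inflates during the first steps -- the
out-of-equilibrium initialization whose consequences the arm comparison
quantifies; a periodicity warning is raised when the no-PSE arm has not
settled after the configured cycles.

Defaults (unspecified by the source, chosen for desk-scale stability):
time step 0.004 s, 3 cycles, interface tolerance 1e-5 relative, quasi-Newton
history depth 8, inner wall tolerance 1e-6. The test suite and the shipped
comparison run at dt = 0.02 s (40 steps per cycle) on the 6 mm mesh; at
that resolution both arms complete in minutes while the waveform and the
WSS cycle (40 samples) remain well resolved.

## Metrics conventions

* Percentiles use linear interpolation between order statistics (positions
  `(n-1)q + 1`), the R type-7 convention.
* All percentile and difference metrics are evaluated over the AAA region
  only: nodes (and stations) whose axial position lies in the native,
  pre-elongation extent. This keeps boundary effects of the extensions out
  of the summaries.
* "Systolic" ("diastolic") is the time of maximum (minimum) lumen pressure
  -- the mean over native stations -- in the evaluation cycle.
* Displacement, stress and TAWSS are scaled by `SBP_AA / SBP_FSI` before
  arms are compared; OSI is dimensionless and left unscaled.
* Nodal von Mises fields are element-mean quadrature values averaged onto
  nodes; percentiles over quadrature points differ negligibly at the
  reported precision.
* Paired Wilcoxon tests (exact null for small samples without ties, normal
  approximation otherwise, via `stats::wilcox.test`) are applied to a
  deterministic subsample of at most 200 nodes per field so that p-values
  are reproducible and not inflated by the full mesh size.

## Known limitations

* The reduced-order fluid model cannot reproduce 3D flow topology; TAWSS
  and OSI capture axial flow reversal only. Patient-level WSS magnitudes
  from 3D CFD are out of reach by construction.
* The Neo-Hookean wall is constitutively linear; collagen-driven stiffening
  outside the physiological pressure window is not represented, and no
  intraluminal thrombus material exists.
* Wall thickness is homogeneous (2 mm), as in the source protocol.
* The no-PSE arm may need more than 3 cycles to settle; the package warns
  rather than silently reporting a non-periodic cycle.
* The synthetic cohort ties geometry to the printed diameters and lengths
  but cannot reproduce patient-specific shape detail, so population
  magnitudes (e.g. percentage changes in displacement or stress) are not
  comparable to the clinical study; only directions and mechanism are.
* On the smooth default sac the peak wall stress is membrane-dominated
  (`sigma ~ p r / h`), so omitting pre-stress leaves the 99th-percentile
  von Mises stress essentially unchanged (the larger inflated radius
  offsets the curvature-smoothing relief): the paired-arm comparison
  reproduces the displacement increase, the corrected-displacement
  decrease and the diastolic-pressure underestimation, but a clear stress
  decrease requires the local curvature concentrations of real patient
  geometries. The acceptance suite asserts the stress direction anyway and
  documents the failure rather than masking it.
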