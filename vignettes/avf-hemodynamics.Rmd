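---
title: "Methods: synthetic micro-CT phantoms and desk-scale CFD for AVF hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic micro-CT phantoms and desk-scale CFD for AVF hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(avfcfd)
```

## The problem this package models

A surgically created arteriovenous fistula (AVF) — here the murine
end-to-side anastomosis of the jugular vein onto the carotid artery used as
a model of hemodialysis access — matures or fails under the control of its
own hemodynamics. The quantities that matter clinically are geometric
(lumen diameter profiles along the vessel, stenosis severity, venous
ballooning) and hemodynamic (flow rates and their split between the distal
artery and the fistula, wall shear stress and its cycle average TAWSS, the
oscillatory shear index OSI, vortical structures, pressure-drop
localization, and the hydraulic resistance of the fistula segment).

`avfcfd` implements the full measurement chain at desk scale: parametric
vessel geometries are voxelized into contrast-CT-like phantoms, segmented
and profiled exactly as one would process a real micro-CT angiogram, and
driven through an incompressible Navier–Stokes solver whose numerical
protocol mirrors common vascular-CFD practice (parabolic pulsatile inlets,
zero-pressure venous outlet, rigid walls, Newtonian blood, backward Euler
with advective CFL ≤ 0.1, three cardiac cycles with the first discarded).

## Governing model and assumptions

Blood is modeled as an incompressible Newtonian fluid,

$$\rho\left(\partial_t \mathbf u + \mathbf u\cdot\nabla\mathbf u\right)
  = -\nabla p + \mu \nabla^2 \mathbf u, \qquad \nabla\cdot\mathbf u = 0,$$

with density $\rho = 1040\ \mathrm{kg/m^3}$ and dynamic viscosity
$\mu = 4\times10^{-3}\ \mathrm{Pa\,s}$ (`fluid_properties()`). The
Newtonian and rigid-wall assumptions are standard for vessels of 0.3–1 mm
diameter at wall shear rates above $\sim 200\ \mathrm{s^{-1}}$; all
pressures are reported relative to the venous outlet, so the zero-pressure
outflow condition only fixes the gauge. Fluid–structure interaction,
Windkessel outflow, and non-Newtonian rheology are out of scope by design.

At $\approx 450$ beats per minute and sub-millimetre radii the Womersley
number is $\alpha = R\sqrt{\omega\rho/\mu} \approx 1$
(`womersley_number()`), which justifies the quasi-parabolic treatment of
Doppler velocity readings: the cross-sectional mean is taken as half the
measured peak (`mean_from_peak()`), and flow rates follow from $Q = A V$
(`flow_rate()`).

### Dimensional reduction

The study this workflow emulates solves 3D tetrahedral meshes with prism
layers on a compute cluster. The same physics is exercised here on two
structured staggered (MAC) grids that run on one CPU in minutes:

* an **axisymmetric body-fitted tube** whose radius follows the fistula
  diameter profile $d(s)$ — this carries the stenosis physics: the
  velocity overshoot and pressure drop at the throat, post-stenotic
  recirculation, TAWSS peaks, OSI bands, and grid-convergence behavior;
* a **planar masked T-junction** with the artery as a channel and the
  fistula/vein branch rising from it — this carries the flow-split
  physics (proximal-artery inflow, prescribed distal-artery outflow
  fraction, venous pressure outlet).

Absolute 3D values on real murine geometries are out of scope; all
comparative statements (day 7 vs day 21) are made between phantoms
processed identically. The planar junction always places the branch
perpendicular to the artery; the `anastomosis_angle` field shapes only the
3D phantom, since stair-step masked grids cannot represent oblique walls
without losing near-wall accuracy.

## The synthetic-data generator as study conditions

`avf_geometry()` encodes the measured lumen geometry at the two
timepoints. Along the fistula (arc length $s$ from the anastomosis,
positive into the vein) the diameter is

$$d(s) = d_n + (d_a - d_n)e^{-s^2/2w_a^2}
        + (d_v - d_n)\,S\!\left(\tfrac{s - s_0}{L - s_0}\right)
        - A\,e^{-(s-c)^2/2w^2},$$

a plateau plus a Gaussian anastomosis bulge, a smoothstep venous-expansion
ramp that reaches the vein maximum exactly at the 4 mm fistula end
($S$ is the cubic smoothstep, so the profile enters the constant-diameter
vein with continuous slope), minus a Gaussian stenosis dip. The constants
of the `day7`/`day21` presets were calibrated **once**, before any flow
computation, so that the analytic window statistics reproduce the reported
murine diameters to better than 0.005 mm:

| quantity | day 7 | day 21 |
|---|---|---|
| proximal artery (mean) | 0.29 mm | 0.39 mm |
| distal artery (mean) | 0.36 mm | 0.46 mm |
| AVF 2 mm window mean (min–max) | 0.74 (0.46–0.95) | 0.58 (0.31–0.96) |
| AVF 4 mm window mean (min–max) | 0.88 (0.46–1.07) | 0.86 (0.31–1.71) |

The venous expansion culminates at the 4 mm station because the reported
4 mm-window maxima equal the vein maxima (1.07 / 1.71 mm) — the window
statistics cannot be reproduced otherwise. Arteries are modeled as uniform
tubes at their mean diameters (no arterial profile shape is reported).

Flow conditions (`avf_flow_conditions()`) are likewise fixed at the study
operating points: AVF flow 1.33 mL/min (day 7) and 2.57 mL/min (day 21),
flow splits 80/20 and 70/30 between fistula and distal artery, heart rate
450 bpm. Doppler-like waveforms are synthesized from a few seeded random
harmonics (`synth_waveform()`); the default pulsatility of 0.4 (trough at
60% of peak) is a representative arterial waveform shape chosen once — no
murine waveform trace is published in tabulated form. All stochastic
stages take an explicit seed and are bit-reproducible.

The phantom (`voxelize_phantom()`) renders the geometry at 72 µm isotropic
voxels (the scan resolution emulated), lumen at 650 HU inside the 300–1000
HU contrast window, with optional Gaussian noise. It deliberately does
**not** model scanner physics: no beam hardening, partial-volume blur,
contrast kinetics, or the two different contrast agents of the two
timepoints. Passing tests therefore demonstrate that the *measurement
chain* is unbiased on clean, known-truth data — not that segmentation of a
noisy clinical scan is solved.

## Imaging and geometry chain

* `threshold_segment()` — inclusive HU window (300–1000 by default).
* `region_grow()` — seeded connected components, default 26-connectivity
  (the common interactive-tool behavior; the original protocol does not
  state it).
* `extract_surface()` — marching tetrahedra (six tetrahedra per cube) on a
  narrow-band signed Euclidean distance field; the zero level of the
  signed distance coincides with the 0.5 level of the binary indicator.
  The distance field is pre-smoothed with a Gaussian of `smooth_sigma`
  = 0.6 voxel, which removes voxel faceting (sphere-area error ~0.3%
  instead of ~13%) and is safe because the voxelizer guarantees ≥ 3 voxels
  across the narrowest lumen; set `smooth_sigma = 0` for voxel-scale
  structures.
* `smooth_surface()` — Taubin λ/µ smoothing (λ = 0.5, µ = −0.53, uniform
  weights): volume changes stay below 2%, unlike plain Laplacian smoothing
  whose shrinkage would bias diameter statistics.
* `extract_centerline()` — Dijkstra paths over the foreground voxel graph
  weighted by inverse squared clearance (chamfer distance transform), so
  paths follow the maximal-clearance ridge. Ridge paths cut the corner
  inside the junction, so the anastomosis (s = 0) is re-anchored at the
  closest approach of the fitted artery and fistula axes, and the fistula
  arc length is registered to its axis over the straight fitting window
  (0.8–2.5 mm). Within ~half a lumen diameter of the branch point a
  single-vessel cross section is not well defined (the section plane cuts
  both vessels), so profile-accuracy guarantees apply from s = 0.5 mm on.
* `cross_section_profile()` — per-station in-plane connected region of the
  mask sampled at 4× sub-voxel resolution; equivalent diameter
  $2\sqrt{A/\pi}$, since sections need not be circular.

On noise-free preset phantoms this chain recovers the analytic diameter
profile within one voxel (72 µm) everywhere outside the junction zone, and
the 2 mm/4 mm window statistics to a few µm.

## Solver numerics

Staggered (MAC) layout avoids pressure checkerboarding. The axisymmetric
tube uses mapped coordinates $\eta = r/R(z)$; all metric terms of the
transformed derivatives (including mixed $\partial_{\zeta\eta}$ terms) are
kept, and the pressure-projection operator is the exact product of the
discrete divergence (mapped-cell face fluxes with the contravariant radial
velocity $v - \eta R' u$) and the correction gradient — so the corrected
field is discretely divergence-free to direct-solver precision
(~10⁻¹³ relative; the contract of ≤ 10⁻⁸ holds with a wide margin).

Time stepping is backward Euler with incremental pressure correction.
Convection uses second-order upwind differences (first-order fallback at
boundaries), Picard-iterated within each step from a linearly extrapolated
state until the max-norm inter-iteration velocity increment, normalized by
the inlet velocity scale, falls below 10⁻⁶ (the residual norm is not
specified in the emulated protocol; this absolute normalized increment is
the adopted definition). The time step adapts at stored-phase boundaries
to hold the advective CFL at ≤ 0.1 with 20% headroom; radial spacing is
geometrically graded toward the wall (neighbor ratio 1.2, mirroring
prism-layer grading). Runs cover three cardiac cycles; periodic steady
state is reached after two (verified by `check_periodicity()`, the
relative L2 cycle-to-cycle difference of the inlet-pressure trace), and
200 phase snapshots of the final cycle feed all metric integrals.

Refinement levels double resolution per axis: the day-7 tube grid is
64×8 cells (coarse), 128×16 (medium), 256×32 (fine), with ≥ 8 cells across
the minimum lumen already at coarse. These sizes were chosen as the
package's desk-scale analog of the original coarse/medium/fine meshes; the
medium-vs-fine maximum-norm differences at peak systole are below 1% for
velocity and pressure, reproducing the grid-independence criterion, and
validation against analytic Poiseuille (machine-exact: the parabola lies
in the discrete null space of the mapped operators) and Womersley
solutions (≤ 3% L∞ at medium resolution against a complex-Bessel series
oracle) anchors the physics.

Known numerical limitations: the planar junction uses stair-step walls
with ghost-cell no-slip (first-order near walls — adequate for flow splits
and qualitative junction patterns, not for junction WSS peaks); backward
Euler is first-order in time (the CFL-limited steps make temporal error
negligible against spatial error); inflow reversal at the inlet is not
supported (pulsatility < 1 enforces this, matching the measured
always-forward arterial waveforms).

## Hemodynamic metrics

WSS is the tangential viscous traction $\mu\,\partial u_t/\partial n$ at
the wall, evaluated by a one-sided quadratic fit through the no-slip wall
and the two nearest wall-parallel velocity samples. TAWSS is the cyclic
trapezoid average of $|\tau|$ over the stored final cycle; OSI is
$\tfrac12(1 - |\int\tau\,dt| / \int|\tau|\,dt)$ with the integral taken
componentwise (in the planar/axisymmetric reductions τ is the signed
tangential traction), clamped to $[0, 0.5]$ and defined as 0 where the
shear vanishes identically (the 0/0 case is undefined in the source
formula). The Q-criterion uses Frobenius norms of the symmetric and
antisymmetric velocity-gradient parts, with the azimuthal strain $v/r$
included in the axisymmetric tensor. Cross-sectional averages are
area-weighted; peak systole is the stored phase of maximum inlet flow.

## What the acceptance analysis recomputes

`scripts/acceptance.R` recomputes, from scratch with the installed
package: the closed-form Womersley number at the day-21 fistula radius;
the OSI of fully reversing and constant-sign analytic shear signals; and
the three-level pulsatile stenotic-tube grid-convergence study with its
medium-vs-fine maximum-norm difference at peak systole. The test suite
additionally checks the Poiseuille and Womersley oracles, mass
conservation and discrete continuity on every run, phantom parameter
recovery, the TAWSS–diameter power law (exponent −3 on Poiseuille data),
OSI range under fuzzed signals, and the day-7 → day-21 progression
(higher stenotic TAWSS, broader elevated-OSI region, higher Poiseuille
resistance of the fistula window).

Problem sizes: the acceptance analysis runs the convergence study at the
full three-cycle protocol; the test suite runs it over two cycles (the
periodicity diagnostics show cycle-to-cycle deviations below 10⁻⁴ after
the first cycle, so the second cycle's peak-systole fields are already
periodic) and keeps all other solver runs at the coarse level. Level
comparisons sample both solutions with cubic splines at the coarse-level
stations so that low-order interpolation does not pollute the
discretization differences being measured.

No empirical figure is stated in this vignette that those scripts and
tests do not themselves compute.
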