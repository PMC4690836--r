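---
title: "Virtual flow-diverter rehearsal at desk scale: models and numerics"
author: "stentflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual flow-diverter rehearsal at desk scale: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stentflow` is a desk-scale rehearsal suite for endovascular treatment of
wide-necked bifurcation aneurysms with braided flow-diverting stents. It
chains four models: parametric braid generation and crimping, spring-mass
virtual deployment, reduced-scale pulsatile hemodynamics with the device as
a porous screen, and scalar contrast transport for virtual angiography.
This vignette records the modeling assumptions, the numerical choices, and
what the synthetic test geometries can and cannot say about patient data.

## The braided device

A flow-diverter is modeled as two counter-wound families of helical strands
(`n_strands/2` each) on a cylindrical envelope of nominal diameter $D$ and
length $L$, discretized into straight struts between crossing points. The
struts are centerlines with no physical thickness; the wire diameter $w$
(default 30 µm) enters only through measurement (porosity, pore size) and
the swept-tube export. The free geometric parameter is the turn count $N_t$
per strand. The surface porosity of the diamond lattice has the closed form
$1 - (2c - c^2)$ with per-family coverage $c = w/s_\perp$ and perpendicular
strand spacing $s_\perp = \pi D \cos\psi / (n/2)$, $\tan\psi = N_t \pi D/L$.
`generate_device()` solves $N_t$ by bisection so this closed form matches
the target porosity (default 70%); `measure_porosity()` then checks the
built mesh independently by rasterizing the widened struts on the unrolled
envelope (deterministic grid, at least 8 pixels across the wire).
`measure_pore_diameter()` labels the open cells of the same raster and
takes the median largest-inscribed-disk diameter via a distance transform.
Commercial 48-strand, 30 µm devices at 70% porosity yield pores within the
120–260 µm band across the 2.0–5.0 mm diameter family, which the tests
verify.

Crimping into a delivery catheter is an affine radial map plus the axial
elongation that conserves helical strand arc length
$S = \sqrt{L^2 + (\pi D N_t)^2}$ (inextensible wire), preserving the turn
count and per-node winding phase. A 3.0 mm device in a 1.0 mm catheter
therefore sits at 33% of nominal diameter, storing bending energy relative
to the reference braid.

## Virtual deployment

Deployment relaxes the crimped braid inside a rigid lumen. Each strut is a
linear spring in the $EA/L$ form ($k = \pi (w/2)^2 E / L_0$), each interior
along-strand node triple a bending spring in the $EI/L$ form with rest
angles from the reference braid. Two departures from a plain force-descent
scheme proved necessary and are deliberate design choices:

* **Crossing interlock.** Strut lengths plus bend angles leave a discrete
  strand free to writhe — the dihedral degrees of freedom are
  unconstrained, so a braid can fold up isometrically at no energy cost.
  Real braids resist cell scissoring at their interlocked crossings. We add
  weak linear springs along both diagonals of every diamond cell, with
  stiffness at the bending scale, $\gamma = (w/L_0)^2$ relative to the
  axial springs; this is also how the package resolves the open choice of
  how crossings should be stiffened.
* **Inextensible-wire projection.** The axial-to-bending stiffness ratio
  $\sim (L_0/w)^2$ is $10^2$–$10^4$, which makes explicit descent on the
  summed forces crawl along the collective expansion mode. The solver
  instead treats strand inextensibility as a constraint (Jacobi projection
  each iteration — the same assumption the crimp kinematics already make)
  and takes damped, momentum-accelerated steps on the bending and interlock
  forces, with the step factor halved whenever the energy trend turns
  upward. With momentum disabled and a small step the iteration is plainly
  monotone in energy, which the property tests check.

The relaxation is initialized on the inextensional helix family at the
diameter that just fits the local lumen clearance along the target
centerline (the crimped state is a member of the same family). This removes
a slow global pitch/untwist mode from the iteration; the relaxation then
resolves local adaptation — bends, tapers, and wall contact. Alignment to a
curved centerline uses parallel-transport frames. Contact is permanent
fixation: a node whose signed distance to the lumen reaches the wire radius
is projected onto the wall offset and no longer moves (a no-slip wall
condition). Release proceeds distal to proximal in axial bands, mimicking
unsheathing. Convergence is declared when the per-iteration maximum node
displacement falls below 0.1 wire diameters.

`apposition()` summarizes wall gaps; `local_metal_coverage()` projects the
near-neck struts onto the neck plane and rasterizes them to the local metal
fraction, which parameterizes the flow screen below. Uniform pre-expansion
to the narrowest clearance slightly under-estimates local bulging into the
neck; the effect is a conservative (denser) local coverage.

## Reduced-scale hemodynamics

The study-scale solver is a staggered-grid (MAC) incompressible
finite-volume code on a uniform Cartesian grid, in a 2D symmetry-plane
slice and a coarse-3D companion. Blood is Newtonian with
$\rho = 1000\ \mathrm{kg/m^3}$, $\mu = 0.004\ \mathrm{Pa\,s}$; walls are
rigid and no-slip; the parent inlet carries a parabolic profile scaled to a
pulsatile waveform (75 BPM default); outlets hold fixed pressures,
optionally augmented by distal resistances $p_{out} = p_{set} + R\,Q$ that
stand in for trimmed distal vasculature. Time stepping is incremental
pressure correction: explicit advection, Crank–Nicolson diffusion, and an
exact sparse-Cholesky pressure projection each substep, so mass is
conserved to solver precision every step. Two numerical choices matter:

* **Hybrid advection.** Pure central differencing of the convective terms
  is unstable under explicit time integration at the cell Péclet numbers of
  these flows (about 10–20); the advected face value therefore blends from
  central to first-order upwind above a face Péclet of 2 (classic hybrid
  differencing). The Poiseuille oracles bound the cost of this choice: the
  channel solution is within 2% of the closed form.
* **Automatic explicit diffusion.** The advective CFL limit forces
  substepping of the 0.01 s output step; once the substep diffusion number
  falls below 0.12 the Crank–Nicolson solves are replaced by the explicit
  update, which is then identical at solver tolerance and much cheaper.

The deployed device enters the flow as a porous pressure-jump screen across
the aneurysm neck and each jailed ostium:
$\Delta p = \tfrac{\rho}{2} K u_n |u_n| + \tfrac{\mu}{\alpha} u_n$.
The viscous permeability comes from the Tamada–Fujikawa transverse
creeping-flow drag of a wire row (two crossed rows in series, per-row
coverage $1-\sqrt{\beta}$ for braid porosity $\beta$); the inertial
coefficient is the standard screen loss $K = (1-\beta^2)/\beta^2$. Both
vanish as $\beta \to 1$, and a near-transparent screen leaves the solution
unchanged, which is tested. The constants are configurable; nothing in them
was fitted to the flow results.

Waveforms are parametric surrogates — a systolic lobe plus dicrotic bump,
rescaled so the cycle minimum/maximum match the site envelope (ICA:
130–570 mL/min around a 230 mL/min mean; BA: 105–180 around 120) and the
cycle mean is exact to 0.5%; the true 1D-arterial-tree source curves are
not available, so only these printed constraints anchor the shape. In the
2D slice, the inlet profile carries the three-dimensional mean velocity
$4Q/(\pi D^2)$ and all fluxes are per unit slab depth; ratios (inflow
reduction, flow splits) are the meaningful outputs.

Aneurysm inflow is the integral of the into-dome-directed velocity through
a neck-offset plane (0.5 mm above the screen by default — the solver warns
if the plane sits within two wire diameters of a screen, where strut-edge
vorticity contaminates the flux). Wall shear stress uses the tangential
speed at wall-adjacent cells over the true signed-distance wall gap; dome
WSS summaries exclude the first millimetre above the neck plane for the
same screen-edge reason. `independence_check()` applies the 1% successive
-change criterion to mesh or time-step series; `solve_lumped()` provides
the exact single-junction resistor solve used both as an oracle for the
solver's flow splits and for outlet-pressure reasoning.

## Contrast transport and virtual angiography

Contrast is a passive scalar (diffusivity $10^{-7}\ \mathrm{m^2/s}$, no
feedback on the flow) advanced over the stored velocity snapshots with
conservative superbee-limited upwind fluxes (bounded, no new extrema;
the scheme choice is configurable in principle but the limiter is fixed
here), explicit diffusion, zero-flux walls, advective outflow, and an inlet
bolus of unit concentration held for exactly one cardiac cycle starting
after two cycles (1.60 s), the run extending to five cycles (4.00 s). The
dome residence curve is the volume-weighted mean concentration over the
sac; its decay is fitted by ordinary least squares on the log concentration
from the peak to the first crossing of 10% of peak. At desk scale the
idealized fixture washes out more slowly than patient geometries, so the
curve can end above the 10% threshold within the fixed 4.00 s window; the
fit then uses the available decay and flags itself truncated rather than
extending the schedule. Virtual angiograms are Beer–Lambert parallel
projections $I = 1 - e^{-\kappa \int \phi\, dl}$, grayscale-inverted in the
PNG export to mimic subtraction angiography, with $\kappa$ defaulting to
the value that maps one fully opacified parent diameter to 90% intensity.

## The synthetic fixture, study sizes, and what they show

The canonical fixture is an idealized symmetric wide-necked bifurcation
aneurysm: 4 mm parent, two 3 mm daughters taking off at ±60° and bending to
a common horizontal outflow plane, an 8 mm spherical dome over a 5 mm neck,
branch lengths of five local diameters, all blended as a smooth implicit
union (blend radius 0.25 × neck diameter) and triangulated by marching
tetrahedra. The dome is lifted along the parent axis until it clears every
daughter lumen by a wall margin, so the sac communicates only through the
neck; a basilar-like four-daughter variant is available. Surfaces are
watertight with volumes converging at first order or better to the analytic
values, which the tests verify.

Study sizes, chosen as the package's reference configurations: steady
device-off/on and pressure-sweep solves use 16 cells per daughter diameter
in 2D; the five-cycle pulsatile contrast run uses 10 cells per diameter;
the coarse-3D oracle runs use tubes at 10–14 cells per diameter. The
pressure-sweep study adds equal distal resistances sized so the device-on
inlet–outlet gradient sits inside the post-treatment physiological band
(144–528 Pa); jailed-outlet pressures are then biased in +100 Pa steps to
+300 Pa.

These synthetic geometries emulate the morphology class — wide neck over a
bifurcation apex, jailed daughter, 1–5 mm vessels — but not the features
that dominate patient-to-patient variation: lumen tortuosity and surface
irregularity, asymmetric daughter calibers and take-off angles, inflow-jet
obliquity, and true 3D swirl. Passing the desk-scale checks shows the
pipeline is internally consistent and reproduces the study's idealized
quantitative structure (crimp kinematics, braid porosity and pore band,
screen-induced inflow reduction, weak bias coupling with strong jailed-flow
sensitivity, exponential dome washout); it does not validate predictions
for any individual patient geometry. One concrete example: on this
symmetric 2D fixture a +300 Pa jailed bias *lowers* the device-induced
inflow reduction slightly (the redirected sweep past the neck drives a
stronger recirculation into the sac), whereas the patient geometries the
study reports show small increases — both sit within the same ≤ 11-point
weak-coupling envelope, but the sign is geometry-dependent.

## Known limitations

No wire-on-wire sliding, friction, or nitinol constitutive model; no vessel
deformation by the device; uniform pre-expansion limits local device
bulging into the neck. The flow solver is laminar, Newtonian and
Cartesian-staircase-bounded; patient-scale body-fitted meshes (millions of
elements) are out of scope, and the 2D slice cannot represent out-of-plane
swirl. The screen correlation is a surrogate for resolved struts;
coefficients are published wire-screen physics, not calibrated to any
patient data. Imported STL geometries require a companion centerline file
and use a voxelized signed distance for contact, with correspondingly
coarser contact tolerance than the analytic synthetic geometries.
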