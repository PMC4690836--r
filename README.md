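# stentflow

Desk-scale rehearsal of flow-diverter treatment for wide-necked
bifurcation aneurysms.

Bifurcation aneurysms — saccular aneurysms sitting on an arterial branch
point such as the basilar tip or the internal-carotid terminus — are hard
to treat endovascularly: a braided flow-diverting stent must starve the
sac of inflow while keeping the daughter vessel it "jails" patent.
`stentflow` implements the full virtual-treatment modeling chain for this
problem at a scale that runs on a laptop, for simulation engineers and
students of computational hemodynamics:

* **Device factory** — parametric braided ("rhomboid"-cell) stents as
  strut-centerline graphs: two counter-wound helical strand families whose
  braid angle is solved so the surface porosity `1 − (2c − c²)`
  (per-family wire coverage `c = w/s⊥`) hits a target, default 70%;
  porosity and pore diameter are then re-measured independently by
  rasterizing the widened struts. Crimping into a delivery catheter
  conserves helical strand arc length `S = √(L² + (πD·Nt)²)`.
* **Vascular synthesis** — idealized wide-necked bifurcation aneurysms
  (parent, 2 or 4 daughters, spherical dome over a circular neck) as
  smooth implicit unions with analytic centerlines, triangulated by
  marching tetrahedra; STL import/export.
* **Virtual deployment** — spring-mass relaxation of the crimped braid
  inside the lumen: axial `EA/L` springs, bending `EI/L` angle springs,
  crossing-interlock diagonals, inextensible-wire constraint projection,
  distal-to-proximal staged release, and permanent wall-contact fixation.
* **Hemodynamics** — staggered-grid incompressible projection solver (2D
  slice and coarse 3D) with pulsatile parent waveforms, fixed-pressure or
  resistance outlets, and the deployed device as a porous pressure-jump
  screen `Δp = ½ρK·un|un| + (μ/α)·un` across the neck and jailed ostia
  (wire-row viscous drag + screen inertial loss). Outputs: neck-plane
  aneurysm inflow, the inflow-reduction ratio
  `100·(Q_nd − Q_d)/Q_nd`, wall shear stress, flow splits under jailed
  outlet-pressure biases (0…300 Pa), and a lumped junction network.
* **Virtual angiography** — passive scalar contrast (diffusivity
  1e-7 m²/s) with a one-cycle unit bolus, dome residence curves, log-linear
  exponential washout fits over the 100%→10%-of-peak window, and
  Beer–Lambert projection frames.

## Worked example

```r
library(stentflow)

# the commercial-class device
dev <- generate_device(device_spec(3.5, 20))   # 48 strands, 30 um wire
measure_porosity(dev)        # 0.7000723
measure_pore_diameter(dev)   # 151.8634 um
crimp_device(dev, 1.0)$report
#> <crimp_report> diameter 1.000 mm, length 48.150 mm, strand length error 0.000549

# full rehearsal on the idealized fixture (coarse demo settings)
rep <- run_pipeline(system.file("extdata/demo_config.yaml",
                                package = "stentflow"))
rep
#> <run_report> stages: geometry, device, crimp, deploy, flow
#>   inflow reduction: 72.5%
```

The demo deploys a crimped 3.5 mm braid from the parent into the right
daughter, measures its metal coverage over the neck, and solves steady
device-off/on hemodynamics at 8 cells per daughter diameter: the screen cuts
aneurysm inflow by ~72% here (the reference resolution of 16 cells per
diameter, used by the reproduction script below, gives ~89%). The report
also carries crimp kinematics, apposition statistics, dome wall-shear
summaries, and the jailed-outlet pressure sweep.

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/stentflow make-device --porosity 0.7 --strands 48 --wire-um 30 --out dev
Rscript inst/scripts/stentflow run --config inst/extdata/demo_config.yaml
```

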