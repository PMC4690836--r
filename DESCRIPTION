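Package: stentflow
Title: Virtual Flow-Diverter Deployment and Reduced-Scale Aneurysm Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale rehearsal suite for endovascular flow-diverter
    treatment of wide-necked bifurcation aneurysms. Generates parametric
    braided ("rhomboid") stent meshes as strut-centerline graphs, crimps
    them into a delivery catheter with strand-length conservation, and
    deploys them inside synthetic or imported vessel lumens by damped
    spring-mass relaxation with distal-to-proximal staged release and
    wall-contact fixation. Hemodynamics are computed with a Cartesian
    immersed-boundary finite-volume projection solver (2D slices and
    coarse 3D) with pulsatile parent-vessel waveforms, fixed- or
    resistance-pressure outlets, and the device represented as a porous
    pressure-jump screen across the aneurysm neck and jailed ostia.
    Includes jailed-vessel outlet-pressure sweeps, a lumped junction
    network, wall-shear-stress and neck-plane inflow metrics, scalar
    contrast transport for virtual angiography, dome residence curves,
    and exponential washout-rate fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    png,
    EBImage,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
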