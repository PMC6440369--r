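Package: laaoplan
Title: Left Atrial Appendage Occluder Implantation Planning and
    Hemodynamic Risk Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for pre-interventional planning of left atrial
    appendage occlusion (LAAO). Provides labelled surface/volume mesh
    input-output (STL, PLY, VTK legacy, VTP/VTU, MSH v2.2), Taubin
    smoothing, heat-propagation centreline extraction with arc-length
    parameterisation, cross-sectional morphometry (maximal D1 and
    minimal D2 Feret diameters, ostium area and principal axes),
    parametric occluder device models with size catalogs, automatic
    device sizing and positioning with compression filtering, virtual
    implantation scenario generation, solver-agnostic CFD case export,
    and post-CFD thrombus-risk indices (TAWSS, OSI, ECAP) with
    region-of-interest histograms and velocity probes. Includes a
    seed-deterministic synthetic left-atrium generator with analytic
    ground truth so every pipeline stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tidyr,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
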