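# laaoplan

Pre-interventional planning toolkit for **left atrial appendage occlusion
(LAAO)**. In atrial fibrillation most intracardiac thrombi form in the left
atrial appendage (LAA); patients with contraindications to anticoagulants
receive an occluder device instead. Whether the implant actually prevents
clots depends on the chosen size and landing zone: an undersized or
misplaced device leaves a pocket between the LAA ostium and the device
where slow, oscillatory flow promotes thrombosis.

`laaoplan` is for biomedical engineers and modelling groups who support
that decision computationally. It covers everything around the flow solve
(the Navier–Stokes solve itself is delegated to an external solver):

* **Geometry core** — labelled surface/volume meshes (STL, PLY, VTK
  legacy, VTP/VTU, MSH v2.2), Taubin smoothing (λ = 0.6, μ = −0.53,
  10 iterations), plane slicing, watertightness and volume utilities.
* **Centreline** — heat-propagation scalar field on an internal
  voxelization of the appendage (Dirichlet 1 at the ostium orifice,
  Neumann walls, volumetric sink) with gradient marching and
  cross-section recentring; arc-length parameterised from the ostium.
* **Morphometry** — maximal/minimal Feret diameters D1/D2 of centreline-
  perpendicular cross-sections, area, perimeter, ostium metrics.
* **Devices** — parametric Amplatzer-Amulet-like and Watchman-like
  occluders as watertight surfaces of revolution, with size catalogs and
  the D1 sizing chart.
* **Planner** — automatic configuration: device centre at 10 mm (Amulet
  type) / 13 mm (Watchman type) geodesic depth, axis along the
  centreline tangent, size = mean(D1, D2) + modality offset (CT 2–5 mm,
  TEE 3–6 mm) with ≥ 10 % compression filtering; scenario generation
  (20 % smaller, misplaced, manual override, device-free), virtual
  implantation, solver-agnostic CFD case export (systole 0.40 s /
  diastole 0.65 s, MV outlet 8 mmHg, ρ = 1060 kg/m³, μ = 0.0035 Pa·s).
* **Hemodynamics** — thrombus-risk indices from wall-shear-stress time
  series,

  TAWSS = (1/T) ∫₀ᵀ |τ_w| dt,  OSI = ½(1 − |∫₀ᵀ τ_w dt| / ∫₀ᵀ |τ_w| dt),
  ECAP = OSI / TAWSS,

  region-of-interest maps between ostium and device, ECAP histograms
  (high-risk share above 3 Pa⁻¹), velocity probes, ranked scenario
  reports.
* **Synthetic data** — seed-deterministic left-atrium anatomies
  (ellipsoid body, 4 pulmonary-vein inlets, mitral outlet, tubular LAA
  with taper/bend/neck/lobes) and closed-form WSS fields with analytic
  TAWSS/OSI/ECAP ground truth, so the whole pipeline is testable without
  patient data.

## Worked example

Plan a Watchman-type implant on a synthetic 20 mm × 40 mm appendage:

```r
library(laaoplan)

laa <- make_laa_tube(laa_spec(tube_length_mm = 40, proximal_diameter_mm = 20,
                              distal_diameter_mm = 20, edge_length_mm = 1.2))
gt  <- attr(laa, "ground_truth")

cl <- extract_centreline(laa, gt$ostium, voxel_mm = 1)
#> <laa_centreline> 73 points, length 40.00 mm (ostium -> tip)

candidates <- propose_configuration(laa, cl, "watchman")
#> <device_configuration> watchman 24 mm [vidaa_init] depth 13.0 mm, compression 16.7 %
#> <device_configuration> watchman 27 mm [vidaa_init] depth 13.0 mm, compression 26.0 %

cross_section_at(laa, cl, 13)
#> <cross_section> s = 13.0 mm: D1 19.99, D2 19.98 mm, area 313.4 mm^2, perimeter 62.8 mm
```

The landing section of the 20 mm lumen is recovered to within 0.1 %
(D1 = 19.99 mm against the analytic 20 mm). With D1 just under 20 mm the
sizing chart proposes the 24 mm device (20.0–22.9 → 24) plus the next
size up, both passing the 10 % compression filter: the 24 mm device is
compressed by 16.7 % at the landing zone, enough for anchoring without
overstressing the wall.

Index post-processing on a synthetic fully-oscillatory shear field
recovers the closed forms (TAWSS = 2/π ≈ 0.637 Pa, OSI = ½,
ECAP = π/4 ≈ 0.785 Pa⁻¹):

```r
sph <- make_sphere_mesh(10)
idx <- compute_indices(make_wss_series(sph,
         flow_spec(steady = 0, oscillatory = 1, samples_per_cycle = 256)))
glance(idx)
#> # A tibble: 1 x 7
#>   n_nodes n_valid invalid_fraction mean_tawss_pa mean_osi mean_ecap_inv_pa ...
#> 1     130     130                0         0.637      0.5            0.785
```

`tidy()` returns the per-node index tibble, `autoplot()` draws ECAP
histograms and probe traces, and `render_report()` writes per-scenario
VTP risk maps, histogram/probe CSVs and a ranking by the percentage of
region-of-interest area with ECAP > 3 Pa⁻¹.

A thin command-line wrapper for shell use lives at `inst/cli/laao.R`
(subcommands `plan`, `synth`, `export-cfd`, `indices`).

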