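---
title: "Planning left atrial appendage occlusion: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning left atrial appendage occlusion: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laaoplan)
```

## The clinical problem

In atrial fibrillation the left atrial appendage (LAA) — a blind, highly
variable pouch of the left atrium — is where most intracardiac thrombi
form. Patients who cannot take anticoagulants may receive an occluder
device (a disc-and-lobe design such as the Amplatzer Amulet, or a
single-plug design such as the Watchman) that seals the appendage. Success
depends on choosing a size and landing zone that fit an anatomy which
differs markedly between patients; a poorly seated or undersized device
leaves a pocket between the ostium (the LAA orifice) and the device in
which slow, recirculating blood can still clot.

`laaoplan` implements the computational side of that planning task: shape
analysis of the appendage, automatic device sizing and positioning,
virtual-implantation scenario generation with solver-agnostic CFD export,
and post-CFD thrombus-risk indices. The flow solve itself is out of scope:
an external incompressible Navier–Stokes solver consumes the exported case
and its wall-shear output comes back in for post-processing.

## Centreline by heat propagation

Device depth is measured geodesically along the appendage centreline, so
the centreline is extracted first. The package solves a steady diffusion
("heat") problem on an internal voxelization of the appendage region
distal to the operator-defined ostium plane: Dirichlet value 1 on the
voxel layer inside the ostium contour, homogeneous Neumann on the walls,
and a uniform volumetric sink. Without the sink the solution would be
identically 1 (one Dirichlet face, insulated walls); the sink makes the
field decay monotonically with depth, so its minimum marks the appendage
tip (the "furthest point"). The sink constant is set from the region
extent so the field spans at least three orders of magnitude; the 1-D
solution decays like $\cosh(\sqrt{\kappa}(L-s))/\cosh(\sqrt{\kappa}L)$,
and a $\log 4$ margin covers the discrete deviation from it.

The centreline marches from the tip along the field gradient toward the
ostium, recentring each point at the area centroid of the local
cross-section contour that contains it (only that connected slice
component is used, so a secondary lobe cannot pull the line sideways).
Numerical safeguards that matter in practice, all deterministic:

* flat tips (e.g. a capped cylinder) give a near-degenerate field minimum
  slab; the seed is the barycentre of the near-minimum band (one decay
  length deep), restricted to the band's connected component holding the
  argmin, and is later replaced by the wall point hit by the local
  tangent — the anatomical tip lies *on* the wall;
* recentring is a lateral correction; when a slice runs through a cap or
  junction the centroid can jump, so corrections larger than 1.5 steps
  fall back to the raw gradient step;
* the marched direction carries 50 % momentum and the final polyline gets
  two passes of 3-point averaging, because recentring jitter inflates arc
  length (depth is *defined* as arc length, so jitter would bias every
  landing zone deeper).

On a whole-chamber mesh the half-space distal to the ostium plane also
clips a cap of the atrial body. The solve region is therefore anchored at
the orifice: the Dirichlet layer is restricted to the ostium contour
(taken one voxel distal of the junction plane, where the lumen has
separated cleanly from the body) and only the voxel component reached
through it is kept. A genuinely disconnected appendage region — two
components both anchored at the orifice — is still an error.

Defaults: voxel 0.5 mm, marching step 0.5 mm, at most 10,000 steps. The
test and acceptance runs use 1 mm voxels on ~20 mm-diameter fixtures,
which keeps every heat solve under a few seconds while staying far inside
the recovery tolerances (axis error below 0.4 % of the radius on a
cylinder).

## Morphometry: D1, D2 and the ostium

At a geodesic station $d$ the cross-section is the slice contour
perpendicular to the centreline tangent that encloses the centreline
point. `D1` is the maximal Feret diameter (largest point-pair distance;
computed on the convex hull, where the maximum is always attained) and
`D2` the minimal Feret width (smallest projected extent over all in-plane
directions; the minimum over hull edge normals, since projection extents
of a polygon and of its hull coincide). The contour is resampled to 0.2 mm
segments before the Feret search so the minimum is stable. Area is by the
planar shoelace formula, perimeter by segment sum. Both are computed on
the contour as measured — not its convex hull — because device sizing
concerns the lumen boundary.

The ostium patch supports two labelling conventions. A disk patch (the
capped appendage-only fixture) uses the labelled-face area sum and its
single boundary ring; the combined synthetic anatomy labels a narrow
*band* of wall faces at the junction plane — a watertight LA+LAA shell has
no physical capping disk — and there the orifice is the band's larger
boundary ring, with area from the ring polygon. Principal axes default to
extreme-point extents along the PCA directions of the boundary ring; a
`method = "pca"` variant returns $2\sqrt{\lambda_i}$ instead (for an
ellipse the covariance eigenvalue form gives half-axis/$\sqrt 2$ scale, so
extents are the clinically interpretable default).

A small sensitivity harness (`station_sensitivity()`) reports how D1
changes when the station shifts by ±1 mm: on tapered anatomies a small
plane shift changes the measured maximum diameter by several millimetres,
which is exactly why the planner filters candidates by compression rather
than trusting one plane.

## Sizing and positioning rules

The planner encodes the clinical protocol as data
(`sizing_rule()`):

* landing depth 10 mm (Amulet type) / 13 mm (Watchman type) from the
  ostium along the centreline; the device axis is the centreline tangent
  there, i.e. the device's transversal plane is perpendicular to the
  centreline;
* Amulet-type target size = mean(D1, D2) plus an imaging offset, 2–5 mm
  for CT and 3–6 mm for TEE; if the target is below D1 another 2–5 mm is
  added. The rule needs a scalar to rank candidates, so the midpoint of
  each range is used and the full range is preserved in the rule object;
* Watchman-type sizes come from the public D1 sizing chart
  (17–19.9 → 21, 20–22.9 → 24, 23–25.9 → 27, 26–28.9 → 30,
  29–31.9 → 33 mm), read as contiguous intervals so a landing diameter in
  a chart gap (e.g. 19.95 mm) maps to the lower row;
* only candidates achieving at least 10 % compression,
  $100\,(\text{nominal} - \text{mean}(D1,D2))/\text{nominal}$, are kept —
  the anchoring criterion; three candidates are proposed for the Amulet
  type (nearest catalog sizes above the target) and two for the Watchman
  type.

Scenario generation mirrors the simulation protocol: the automatic
proposal (`vidaa_init`), the same device at 80 % nominal size
(`smaller_20`; unsnapped by default because the scenario scales the
device, not the catalog choice), a mispositioned device (default +5 mm
depth and 15° tilt — magnitudes are package defaults, config-overridable,
since only the scenario's existence is protocol), a manually overridden
configuration (`vidaa_end`, with an `ostium_flush` preset that seats the
proximal face in the ostium plane), and the device-free baseline as the
absence of a configuration.

## Devices

Occluders are surfaces of revolution built from closed profile polylines:
the Watchman type a plug (flat proximal face, cylinder at the nominal
diameter, ellipsoidal distal cap, depth 0.8 × nominal), the Amulet type a
proximal disc (nominal + 6 mm for sizes ≤ 22, + 7 mm above; 2.5 mm thick)
joined by a 4 mm waist to a cylindrical lobe at the nominal diameter.
These proportions follow the public product manuals and are all
overridable through `geometry_params`; the disc–lobe gap in particular is
a documented default, not a manufacturer figure. Devices are modelled as
impermeable closed walls — no fabric porosity, struts or anchors — which
matches how the CFD treats them. Meshes are watertight by construction
(every edge shared by exactly two faces, Euler characteristic 2), and
`implant()` reports radial interference with the wall (faces with a
vertex inside the device) as a diagnostic rather than an error, because
interference *is* compression.

## Boundary conditions and CFD export

The exported case describes one cardiac cycle of a persistent-AF atrium
with rigid no-slip walls: systole for the first 0.40 s with the pulmonary
veins as velocity inlets and the closed mitral valve as a wall, then
0.65 s of diastole with the mitral valve as a pressure outlet at 8 mmHg.
Blood is incompressible Newtonian, density 1060 kg/m³, dynamic viscosity
0.0035 Pa·s. The inlet waveform is a half-sine per phase, sampled and
embedded in the manifest; its peak (default 0.4 m/s) is a package default
labelled as such. The bundle is a labelled VTP surface plus a YAML
manifest with fixed field order and formatting, so identical inputs
export byte-identically — no proprietary solver dialect.

## Thrombus-risk indices

From per-node wall-shear-stress vectors $\tau_w(t)$ over one cycle of
length $T$ (trapezoidal rule on the given sampling):

$$\mathrm{TAWSS} = \frac 1T \int_0^T |\tau_w|\,dt,\qquad
 \mathrm{OSI} = \frac 12\left(1 -
   \frac{|\int_0^T \tau_w\,dt|}{\int_0^T |\tau_w|\,dt}\right),\qquad
 \mathrm{ECAP} = \frac{\mathrm{OSI}}{\mathrm{TAWSS}}.$$

These are the standard endothelial-activation definitions from the
aneurysm literature; OSI is provably in $[0, \tfrac12]$ and ECAP is high
exactly where flow is slow *and* oscillatory. Nodes with vanishing shear
integral get OSI 0 and an invalid-ECAP flag (finite histograms matter
more than formal infinities); the invalid count is reported. One cycle is
assumed periodic — no multi-cycle averaging.

The region of interest for risk maps is the pocket between the ostium
plane and the device's proximal station, excluding device nodes — thrombi
*outside* the device are the clinically dangerous ones. Histograms over
that region default to bin edges $[0, 0.5, 1, 2, 3, \infty)$ so the
high-risk ">3 Pa⁻¹" share is a single bin, and support both surface-area
weighting (default, physically meaningful) and node-count weighting —
both conventions circulate, so both are implemented behind a flag. The
velocity probe sits on the centreline direction 5 mm outside the ostium
(the distance is a package default; only the direction is protocol).

## The synthetic generator

`make_la_with_laa()` builds a watertight labelled whole-chamber anatomy
from an implicit union — ellipsoidal body (half-axes 30/25/22 mm), four
6 mm-radius pulmonary-vein inlets, one 12.5 mm mitral outlet, and a
tubular appendage with taper, bend, neck and optional extra lobes,
attached at a configurable angle (default oblique, so slicing is never
axis-aligned) — meshed by marching tetrahedra on a Kuhn 6-tet cube
subdivision, which has no ambiguous cases and shares edge vertices, hence
is closed by construction. Everything is deterministic for a given spec;
the only randomness (optional fixture noise) is seed-controlled. Analytic
ground truth rides along: the true centreline (extended to the apex of
the rounded implicit tip), per-station diameters and the ostium plane.
Closed-form fixtures (cylinders, tapered and bent tubes with exact radii)
are exact surfaces of revolution, not implicit meshes, so 1 %-level
recovery assertions are meaningful.

`make_wss_series()` evaluates
$\tau_w(x,t) = [a(x) + c(x)\sin(2\pi t/T)]\,d(x)$ per node and attaches
the closed-form indices: $a \ge c$ gives TAWSS $=a$, OSI $=0$; $a = 0$
gives TAWSS $=2c/\pi$, OSI $=\tfrac12$, ECAP $=\pi/4c$; the mixed regime
is evaluated by fine quadrature of the same integrand. This is what makes
end-to-end index recovery testable at $O(\Delta t^2)$ without a flow
solver.

What the generator does *not* emulate: real wall trabeculation and
surface roughness, population shape statistics, moving walls, and —
critically — actual hemodynamics. Passing recovery tests demonstrates the
geometry and index pipelines are correct; it says nothing about how close
a synthetic WSS field is to a patient's.

## Problem sizes and tolerances used in the checks

The shipped test-suite and acceptance runs use: fixtures at 1.2–1.5 mm
edge length (~2,000–28,000 vertices), heat-solve voxels at 1 mm, marching
step 0.5 mm, 32–512 time samples per cycle. Tolerances follow the
analytic error sources: 1 % for quantities limited by mesh faceting
(Feret diameters, ostium metrics), 2.5–3 % for marched arc lengths, 0.5 %
for the divergence-theorem vs ray-casting volume cross-check, and
second-order convergence ratios (≥3× per step halving) for the
trapezoidal integrals. Degenerate inputs are tested explicitly: planes
that miss the mesh, tangent slices (components under 10⁻⁹ mm² are
discarded), zero shear fields, empty regions of interest, out-of-range
stations, catalogs that cannot satisfy the compression filter.

## Known limitations

* The centreline is a single line; multi-branch centreline trees for
  secondary lobes are out of scope.
* The heat solve is a finite-difference voxel method; a linear-FEM path
  on tetrahedral meshes would avoid voxelization error for very thin
  lobes (below ~3 voxels across, the gradient flattens).
* Binary PLY and VTK appended-data dialects are not parsed (ASCII and
  binary STL are); files from typical mesh tools in those encodings must
  be converted.
* The circumflex artery, deployment mechanics, fabric leakage and
  image-based peri-device leak scoring are deliberately outside the
  package.
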