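test_that("every mesh format round-trips geometry and labels", {
  cyl <- make_cylinder_mesh(10, 40, n_around = 32, n_along = 9)
  td <- withr::local_tempdir()
  for (fmt in c("ply", "vtk", "vtp", "vtu", "msh")) {
    p <- file.path(td, paste0("m.", fmt))
    write_mesh(cyl, p)
    m2 <- read_mesh(p)
    expect_equal(m2$vertices, cyl$vertices, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_identical(m2$faces, cyl$faces)
    expect_identical(m2$face_labels, cyl$face_labels)
  }
  # STL: geometry only (labels cannot travel), binary is bit-exact
  p <- file.path(td, "m.stl")
  expect_warning(write_mesh(cyl, p), "labels")
  m2 <- read_mesh(p)
  expect_equal(sort(round(as.vector(m2$vertices), 5)),
               sort(round(as.vector(cyl$vertices), 5)))
  suppressWarnings(write_mesh(cyl, p, "stl_binary"))
  m3 <- read_mesh(p)
  expect_equal(nrow(m3$faces), nrow(cyl$faces))
  expect_equal(mesh_volume(m3), mesh_volume(cyl), tolerance = 1e-6)
})

test_that("unit cube STL reads as 8 vertices / 12 faces and writers are bit-stable", {
  cube <- laaoplan:::unit_cube_mesh()
  td <- withr::local_tempdir()
  p <- file.path(td, "cube.stl")
  write_mesh(cube, p)
  m <- read_mesh(p)
  expect_equal(nrow(m$vertices), 8)
  expect_equal(nrow(m$faces), 12)
  expect_equal(mesh_volume(m), 1, tolerance = 1e-9)
  # identical input -> byte-identical output
  p2 <- file.path(td, "cube2.stl")
  write_mesh(cube, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("a hand-written VTU with a label cell array recovers face_labels", {
  td <- withr::local_tempdir()
  p <- file.path(td, "lab.vtu")
  writeLines(c(
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    "  <UnstructuredGrid>",
    '  <Piece NumberOfPoints="4" NumberOfCells="2">',
    "    <Points>",
    '      <DataArray type="Float64" Name="Points" NumberOfComponents="3" format="ascii">',
    "        0 0 0 1 0 0 1 1 0 0 1 0",
    "      </DataArray>",
    "    </Points>",
    "    <Cells>",
    '      <DataArray type="Int64" Name="connectivity" format="ascii">0 1 2 0 2 3</DataArray>',
    '      <DataArray type="Int64" Name="offsets" format="ascii">3 6</DataArray>',
    '      <DataArray type="UInt8" Name="types" format="ascii">5 5</DataArray>',
    "    </Cells>",
    "    <CellData>",
    '      <DataArray type="Int32" Name="label" format="ascii">0 1</DataArray>',
    "    </CellData>",
    "  </Piece>",
    "  </UnstructuredGrid>",
    "</VTKFile>"), p)
  m <- read_mesh(p)
  expect_identical(m$face_labels, c(0L, 1L))
  expect_equal(nrow(m$vertices), 4)
})

test_that("MSH v2.2 output follows the section grammar and round-trips tets", {
  cube <- laaoplan:::unit_cube_mesh()
  # 5-tet decomposition of the cube for a volume fixture
  tets <- rbind(c(1, 2, 3, 5), c(2, 4, 3, 8), c(2, 8, 5, 6),
                c(3, 8, 5, 7), c(2, 3, 5, 8))
  vm <- volume_mesh(cube$vertices, tets, boundary = cube)
  td <- withr::local_tempdir()
  p <- file.path(td, "cube.msh")
  write_mesh(vm, p)
  txt <- readLines(p)
  expect_identical(txt[1:3], c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"))
  expect_true(all(c("$Nodes", "$EndNodes", "$Elements", "$EndElements")
                  %in% txt))
  n_decl <- as.integer(txt[match("$Nodes", txt) + 1])
  expect_equal(n_decl, 8)
  e_decl <- as.integer(txt[match("$Elements", txt) + 1])
  expect_equal(e_decl, match("$EndElements", txt) -
                 match("$Elements", txt) - 2)
  vm2 <- read_mesh(p)
  expect_s3_class(vm2, "volume_mesh")
  expect_equal(sum(laaoplan:::tet_signed_volumes(vm2$vertices, vm2$tets)), 1,
               tolerance = 1e-9)
})

test_that("unreadable or unknown-format input fails with a clear error", {
  td <- withr::local_tempdir()
  p <- file.path(td, "bad.ply")
  writeLines(c("not a ply"), p)
  expect_error(read_mesh(p), "PLY")
  expect_error(read_mesh(file.path(td, "missing.stl")), "not found")
  cube <- laaoplan:::unit_cube_mesh()
  expect_error(write_mesh(cube, file.path(td, "m.xyz")), "supported")
})

test_that("taubin smoothing: identity at 0 iterations, denoising without shrink", {
  noisy <- make_sphere_mesh(10, n_theta = 24, n_phi = 48, noise_sd = 0.4,
                            seed = 7)
  expect_identical(taubin_smooth(noisy, smoothing_params(iterations = 0)),
                   noisy)
  sm <- taubin_smooth(noisy, smoothing_params(0.6, -0.53, 10))
  expect_identical(sm$faces, noisy$faces)
  rms_dev <- function(m) stats::sd(sqrt(rowSums(m$vertices^2)))
  expect_lt(rms_dev(sm), rms_dev(noisy))
  # the lambda/mu pair is anti-shrink: enclosed volume within 5 %
  expect_lt(abs(mesh_volume(sm) - mesh_volume(noisy)) / mesh_volume(noisy),
            0.05)
})

test_that("taubin lambda step moves a fan's interior vertex toward the neighbour centroid", {
  # flat fan: centre vertex + 5 ring vertices, centre displaced off-plane
  ring <- cbind(cos(2 * pi * (0:4) / 5), sin(2 * pi * (0:4) / 5), 0)
  v <- rbind(c(0, 0, 0.5), ring)
  f <- cbind(1, 1 + (1:5), 1 + c(2:5, 1))
  fan <- surface_mesh(v, f)
  lambda <- 0.6; mu <- -0.53
  sm <- taubin_smooth(fan, smoothing_params(lambda, mu, 1),
                      fix_labelled = FALSE)
  # hand-computed umbrella updates: neighbours of the centre are the 5 ring
  # vertices; each ring vertex neighbours the centre and its two ring
  # neighbours; lambda step on all vertices simultaneously, then mu step
  nbrs <- list(2:6, c(1, 6, 3), c(1, 2, 4), c(1, 3, 5), c(1, 4, 6),
               c(1, 5, 2))
  umbrella <- function(V, factor) {
    out <- V
    for (i in seq_along(nbrs))
      out[i, ] <- V[i, ] + factor * (colMeans(V[nbrs[[i]], , drop = FALSE]) -
                                       V[i, ])
    out
  }
  expected <- umbrella(umbrella(v, lambda), mu)
  expect_equal(sm$vertices, expected, tolerance = 1e-12, ignore_attr = TRUE)
  # the lambda step alone pulls the raised centre toward the ring centroid
  after_lambda <- umbrella(v, lambda)
  expect_lt(abs(after_lambda[1, 3]), abs(v[1, 3]))
})

test_that("slicing a cylinder yields one closed polygon with the analytic perimeter", {
  cyl <- make_cylinder_mesh(10, 40, n_around = 64)
  plane <- list(origin = c(0, 0, 20), normal = c(0, 0, 1))
  polys <- slice_with_plane(cyl, plane)
  expect_length(polys, 1)
  # 64-gon perimeter, not 2*pi*r: tolerance covers the mesh resolution
  expect_equal(laaoplan:::polygon_perimeter(polys[[1]]), 2 * pi * 10,
               tolerance = 0.01)
  # planarity
  devn <- abs(polys[[1]][, 3] - 20)
  expect_lt(max(devn), 1e-6)
})

test_that("slice perimeter equals the independent per-face clipping oracle", {
  laa <- fx_cyl_laa()
  for (z in c(7.3, 21.1, 33.8)) {
    plane <- ostium_plane(c(0.5, -0.4, z), c(0.2, 0.1, 0.97))
    polys <- slice_with_plane(laa, plane)
    total <- sum(vapply(polys, laaoplan:::polygon_perimeter, numeric(1)))
    expect_equal(total, oracle_slice_perimeter(laa, plane),
                 tolerance = 1e-9)
  }
})

test_that("tangent planes and misses give empty slices; lobes give two polygons", {
  sph <- make_sphere_mesh(10, n_theta = 16, n_phi = 24)
  expect_length(slice_with_plane(sph, list(origin = c(0, 0, 30),
                                           normal = c(0, 0, 1))), 0)
  # two disjoint tubes side by side, sliced across both
  t1 <- make_tube(outer(seq(0, 20, 2), c(0, 0, 1)), 3)
  t2m <- make_tube(outer(seq(0, 20, 2), c(0, 0, 1)), 3)
  t2 <- surface_mesh(sweep(t2m$vertices, 2, c(12, 0, 0), `+`), t2m$faces,
                     t2m$face_labels)
  both <- laaoplan:::merge_meshes(t1, t2)
  polys <- slice_with_plane(both, list(origin = c(0, 0, 10),
                                       normal = c(0, 0, 1)))
  expect_length(polys, 2)
})

test_that("polygons come back counter-clockwise about the plane normal", {
  cyl <- make_cylinder_mesh(5, 10, n_around = 24)
  polys <- slice_with_plane(cyl, list(origin = c(0, 0, 5),
                                      normal = c(0, 0, 1)))
  uv <- polys[[1]][, 1:2]
  expect_gt(laaoplan:::polygon_signed_area(uv), 0)
})

test_that("rigid transforms preserve volume and labels; watertightness detects open meshes", {
  laa <- fx_cyl_laa()
  R <- laaoplan:::rotation_between(c(0, 0, 1), c(1, 1, 1) / sqrt(3))
  m2 <- transform_mesh(laa, R, c(5, -3, 2))
  expect_equal(mesh_volume(m2), mesh_volume(laa), tolerance = 1e-9)
  expect_identical(m2$face_labels, laa$face_labels)
  open <- laaoplan:::subset_faces(laa, seq_len(nrow(laa$faces) - 10))
  expect_false(is_watertight(open))
  expect_true(is_watertight(laa))
})
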