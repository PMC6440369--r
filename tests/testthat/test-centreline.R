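test_that("heat field is in [0,1], exactly 1 on the ostium layer, monotone along a cylinder", {
  laa <- fx_cyl_laa()
  gt <- attr(laa, "ground_truth")
  fld <- solve_heat_field(laa, gt$ostium, voxel_mm = 1)
  expect_true(all(fld$values >= 0 & fld$values <= 1))
  sd <- as.numeric(laaoplan:::plane_signed_distance(fld$grid$centers,
                                                    gt$ostium))
  expect_true(all(fld$values[sd >= -1] == 1))
  # monotone decay with depth: bin voxels by z and check mean field decreases
  z <- fld$grid$centers[, 3]
  zb <- cut(z, seq(0, 40, 5))
  mu <- tapply(fld$values, zb, mean)
  expect_true(all(diff(mu) < 0))
  # spans >= 3 orders of magnitude before normalisation
  expect_lt(min(fld$values), 1e-3)
  # argmin depth agrees with the geodesic-farthest point (the far cap)
  expect_gt(fld$tip[3], 33)
})

test_that("cylinder centreline stays on the axis with the analytic arc length", {
  cl <- fx_cyl_centreline()
  expect_equal(max(cl$arc_length), 40, tolerance = 0.025)
  axis_dev <- sqrt(cl$points[, 1]^2 + cl$points[, 2]^2)
  expect_lt(max(axis_dev), 0.5)          # within 0.5 mm of the true axis
  expect_lt(max(axis_dev), 0.05 * 10)    # < 5 % of the local radius
  # arc_length is exactly the cumulative segment length and increases
  seg <- sqrt(rowSums(diff(cl$points)^2))
  expect_equal(cl$arc_length, c(0, cumsum(seg)), tolerance = 1e-12)
  expect_true(all(diff(cl$arc_length) > 0))
  # tangents are unit
  expect_equal(sqrt(rowSums(cl$tangents^2)), rep(1, nrow(cl$tangents)),
               tolerance = 1e-9)
})

test_that("bent-tube centreline arc length matches the generating path within 3 %", {
  laab <- make_laa_tube(laa_spec(40, 14, 14, bend_angle_deg = 90,
                                 edge_length_mm = 1.5))
  gtb <- attr(laab, "ground_truth")
  clb <- extract_centreline(laab, gtb$ostium, voxel_mm = 1)
  expect_equal(max(clb$arc_length), max(gtb$arc_length), tolerance = 0.03)
  # the tip is found at the geometric far end, not at the elbow
  true_tip <- gtb$centreline[nrow(gtb$centreline), ]
  tip_err <- sqrt(sum((clb$points[nrow(clb$points), ] - true_tip)^2))
  expect_lt(tip_err, 7)   # within one tube radius of the flat cap centre
})

test_that("marching is deterministic: identical inputs give identical polylines", {
  laa <- fx_cyl_laa()
  gt <- attr(laa, "ground_truth")
  cl1 <- extract_centreline(laa, gt$ostium, voxel_mm = 1)
  cl2 <- extract_centreline(laa, gt$ostium, voxel_mm = 1)
  expect_identical(cl1$points, cl2$points)
  expect_identical(cl1$arc_length, cl2$arc_length)
})

test_that("two-lobed appendage: the centreline follows the longer lobe only", {
  spec <- laa_spec(tube_length_mm = 38, proximal_diameter_mm = 18,
                   distal_diameter_mm = 12, edge_length_mm = 1.4,
                   lobes = list(list(station_mm = 14, length_mm = 12,
                                     diameter_mm = 8, angle_deg = 55)))
  la <- make_la_with_laa(spec)
  gt <- attr(la, "ground_truth")
  cl <- extract_centreline(la, gt$ostium, voxel_mm = 1.1)
  # the global minimum lies in the main (longer) lobe: every centreline
  # point stays within the main tube's radius of the true main path
  err <- vapply(seq_len(nrow(cl$points)), function(i)
    min(sqrt(rowSums(sweep(gt$centreline, 2, cl$points[i, ])^2))),
    numeric(1))
  expect_lt(max(err), 9)
  expect_equal(max(cl$arc_length), max(gt$arc_length), tolerance = 0.15)
})

test_that("point_at_geodesic_distance interpolates ends, interior, and errors out of range", {
  cl <- fx_cyl_centreline()
  p0 <- point_at_geodesic_distance(cl, 0)
  expect_equal(as.numeric(p0$point), as.numeric(cl$points[1, ]))
  p13 <- point_at_geodesic_distance(cl, 13)
  expect_equal(p13$point[3], 13, tolerance = 0.15)
  pend <- point_at_geodesic_distance(cl, max(cl$arc_length))
  expect_equal(as.numeric(pend$point),
               as.numeric(cl$points[nrow(cl$points), ]))
  expect_error(point_at_geodesic_distance(cl, -1), "range")
  expect_error(point_at_geodesic_distance(cl, 1e4), "range")
})

test_that("the heat-solve region is anchored at the orifice, not the half-space", {
  # a second shell far from the orifice is excluded from the solve
  t1 <- make_tube(outer(seq(0, 20, 2), c(0, 0, 1)), 4)
  t2m <- make_tube(outer(seq(0, 20, 2), c(0, 0, 1)), 4)
  t2 <- surface_mesh(sweep(t2m$vertices, 2, c(30, 0, 0), `+`), t2m$faces,
                     t2m$face_labels)
  both <- laaoplan:::merge_meshes(t1, t2)
  expect_message(
    fld <- solve_heat_field(both, ostium_plane(c(0, 0, 0), c(0, 0, -1)),
                            voxel_mm = 1),
    "dropped")
  # every retained voxel belongs to the tube holding the plane origin
  expect_true(all(fld$grid$centers[, 1] < 15))
  # a plane origin outside every lumen contour is refused
  expect_error(
    solve_heat_field(t1, ostium_plane(c(20, 0, 0), c(0, 0, -1)),
                     voxel_mm = 1),
    "outside every lumen contour|plane")
})

test_that("centreline export writes a VTK polyline and a 4-column table", {
  cl <- fx_cyl_centreline()
  td <- withr::local_tempdir()
  pv <- file.path(td, "cl.vtk")
  write_centreline(cl, pv)
  txt <- readLines(pv)
  expect_true(any(grepl("^LINES 1", txt)))
  expect_true(any(grepl("arc_length", txt)))
  pt <- file.path(td, "cl.txt")
  write_centreline(cl, pt)
  tab <- utils::read.table(pt, header = TRUE)
  expect_identical(names(tab), c("x", "y", "z", "s"))
  expect_equal(nrow(tab), nrow(cl$points))
  expect_equal(tab$s, cl$arc_length, tolerance = 1e-6)
})
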