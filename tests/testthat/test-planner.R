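test_that("auto-proposal lands at family depths with compliant sizes and counts", {
  laa <- fx_cyl_laa()           # D1 = D2 = 20 mm cylinder
  cl <- fx_cyl_centreline()
  pa <- propose_configuration(laa, cl, "amulet", sizing_rule("CT"))
  expect_length(pa, 3)          # three amulet candidates
  expect_equal(pa[[1]]$pose$depth, 10)
  expect_true(all(vapply(pa, function(p) p$spec$nominal_size, 1) >= 22))
  expect_true(all(vapply(pa, function(p) p$compression_pct, 1) >= 10))
  expect_true(all(vapply(pa, function(p) p$scenario_tag, "") == "vidaa_init"))
  # candidates ordered by |size - target| (target = mean(D1,D2) + 3.5 mm,
  # no escalation here since the target already exceeds D1)
  cs10 <- cross_section_at(laa, cl, 10)
  target <- mean(c(cs10$d1_max_diameter, cs10$d2_min_diameter)) + 3.5
  target_dist <- abs(vapply(pa, function(p) p$spec$nominal_size, 1) - target)
  expect_true(all(diff(target_dist) >= 0))
  pw <- propose_configuration(laa, cl, "watchman")
  expect_length(pw, 2)          # two watchman candidates
  expect_equal(pw[[1]]$pose$depth, 13)
  expect_true(all(vapply(pw, function(p) p$compression_pct, 1) >= 10))
  # device axis along the centreline tangent at the landing station
  expect_equal(as.numeric(pw[[1]]$pose$axis),
               point_at_geodesic_distance(cl, 13)$tangent,
               tolerance = 1e-9)
})

test_that("proposal is invariant to face ordering of the input mesh", {
  laa <- fx_cyl_laa()
  cl <- fx_cyl_centreline()
  perm <- rev(seq_len(nrow(laa$faces)))
  shuffled <- surface_mesh(laa$vertices, laa$faces[perm, ],
                           laa$face_labels[perm])
  p1 <- propose_configuration(laa, cl, "watchman")
  p2 <- propose_configuration(shuffled, cl, "watchman")
  expect_equal(vapply(p1, function(p) p$spec$nominal_size, 1),
               vapply(p2, function(p) p$spec$nominal_size, 1))
  expect_equal(p1[[1]]$compression_pct, p2[[1]]$compression_pct,
               tolerance = 1e-9)
})

test_that("compression grows with nominal size and the 10 % filter screens candidates", {
  laa <- fx_cyl_laa()
  cl <- fx_cyl_centreline()
  cs <- cross_section_at(laa, cl, 10)
  mean_d <- mean(c(cs$d1_max_diameter, cs$d2_min_diameter))
  sizes <- c(16, 18, 20, 22, 25, 28, 31, 34)
  comp <- 100 * (sizes - mean_d) / sizes
  expect_true(all(diff(comp) > 0))      # monotone in nominal size
  # a catalog capped below the required compression yields no candidates
  tiny_cat <- catalog("amulet", sizes = c(16, 18, 20))
  expect_warning(
    out <- propose_configuration(laa, cl, "amulet", cat = tiny_cat),
    class = "laaoplan_no_candidate")
  expect_length(out, 0)
})

test_that("too-short centrelines are refused with the landing depth in the message", {
  short <- make_laa_tube(laa_spec(tube_length_mm = 11,
                                  proximal_diameter_mm = 20,
                                  distal_diameter_mm = 18,
                                  edge_length_mm = 1.2))
  gt <- attr(short, "ground_truth")
  cl <- extract_centreline(short, gt$ostium, voxel_mm = 1)
  expect_error(propose_configuration(short, cl, "watchman"), "13")
})

test_that("scenario builder: exact 20 % shrink, tilted deeper misplacement, three scenarios", {
  laa <- fx_cyl_laa()
  cl <- fx_cyl_centreline()
  base <- propose_configuration(laa, cl, "watchman")[[1]]
  sc <- make_scenarios(base)
  expect_identical(names(sc), c("vidaa_init", "smaller_20", "misplaced"))
  expect_equal(sc$smaller_20$spec$nominal_size, 0.8 * base$spec$nominal_size)
  expect_identical(sc$vidaa_init, base)
  # defaults: +5 mm depth, 15 degree tilt
  expect_equal(sc$misplaced$pose$depth, base$pose$depth + 5)
  cosang <- sum(sc$misplaced$pose$axis *
                  point_at_geodesic_distance(cl, base$pose$depth + 5)$tangent)
  expect_equal(acos(pmin(cosang, 1)) * 180 / pi, 15, tolerance = 0.5)
  # a nominal 30 base shrinks to 24.0 unsnapped
  base30 <- base
  base30$spec <- device_spec("watchman", 30)
  expect_equal(make_scenarios(base30)$smaller_20$spec$nominal_size, 24)
  # snapping maps onto the catalog
  snapped <- make_scenarios(base30, snap = TRUE)
  expect_true(snapped$smaller_20$spec$nominal_size %in%
                catalog("watchman")$sizes)
  expect_error(make_scenarios(sc$misplaced), "vidaa_init")
})

test_that("overrides retag, recompute compression, and the flush preset hits the ostium plane", {
  laa <- fx_cyl_laa()
  cl <- fx_cyl_centreline()
  base <- propose_configuration(laa, cl, "watchman")[[1]]
  same <- apply_override(base)
  expect_identical(same$scenario_tag, "vidaa_end")
  expect_equal(same$spec$nominal_size, base$spec$nominal_size)
  expect_equal(same$pose, base$pose)
  expect_equal(same$compression_pct, base$compression_pct, tolerance = 1e-9)
  flush <- apply_override(base, preset = "ostium_flush", mesh = laa)
  gt <- attr(laa, "ground_truth")
  dist_to_plane <- abs(sum((flush$pose$centre - gt$ostium$origin) *
                             gt$ostium$normal))
  expect_lt(dist_to_plane, 0.5)  # proximal face centroid in the ostium plane
  # undersized override reports negative compression
  expect_warning(small <- apply_override(base, new_size = 16, mesh = laa),
                 "negative compression")
  expect_lt(small$compression_pct, 0)
})

test_that("implantation builds a labelled two-surface domain and preserves device volume", {
  laa <- fx_cyl_laa()
  cl <- fx_cyl_centreline()
  cfg <- propose_configuration(laa, cl, "watchman")[[1]]
  dom <- implant(laa, cfg, resolution = 1.2)
  labs <- unique(label_name(dom$face_labels))
  expect_true(all(c("wall", "ostium", "device") %in% labs))
  # nominal 24 in a 20 mm lumen: radial interference expected and reported
  expect_gt(attr(dom, "interference_faces"), 0)
  # the rigid transform preserves the device volume
  dev0 <- build_device_mesh(cfg$spec, resolution = 1.2)
  expect_equal(attr(dom, "device_volume_mm3"), mesh_volume(dev0),
               tolerance = 1e-6)
  # implant of a trivial override equals implant of the base
  dom2 <- implant(laa, apply_override(cfg), resolution = 1.2)
  expect_equal(dom2$vertices, dom$vertices, tolerance = 1e-12,
               ignore_attr = TRUE)
  # poses outside the lumen are refused
  bad <- cfg
  bad$pose$centre <- c(50, 50, 50)
  expect_error(implant(laa, bad), "placement")
})
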