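test_that("constant, sinusoidal and zero shear fields give the closed-form indices", {
  sph <- fx_sphere()
  n <- nrow(sph$vertices)
  # constant tau = (1, 0, 0) Pa
  wconst <- make_wss_series(sph, flow_spec(steady = 1, oscillatory = 0))
  ic <- compute_indices(wconst)$data
  expect_equal(ic$tawss_pa, rep(1, n), tolerance = 1e-12)
  expect_equal(ic$osi, rep(0, n), tolerance = 1e-9)
  expect_equal(ic$ecap_inv_pa, rep(0, n), tolerance = 1e-9)
  # pure sinusoid tau = sin(2 pi t / T) (1,0,0): TAWSS 2/pi, OSI 1/2,
  # ECAP pi/4 (dense sampling for the quadrature)
  wsin <- make_wss_series(sph, flow_spec(steady = 0, oscillatory = 1,
                                         samples_per_cycle = 512))
  is <- compute_indices(wsin)$data
  expect_equal(is$tawss_pa, rep(2 / pi, n), tolerance = 1e-4)
  expect_equal(is$osi, rep(0.5, n), tolerance = 1e-6)
  expect_equal(is$ecap_inv_pa, rep(pi / 4, n), tolerance = 2e-4)
  # zero field: OSI 0, ECAP invalid everywhere
  wzero <- make_wss_series(sph, flow_spec(steady = 0, oscillatory = 0))
  iz <- compute_indices(wzero)$data
  expect_equal(iz$tawss_pa, rep(0, n))
  expect_equal(iz$osi, rep(0, n))
  expect_true(all(!iz$valid))
  expect_true(all(is.na(iz$ecap_inv_pa)))
})

test_that("trapezoidal integration converges to a fine-Riemann oracle at second order", {
  sph <- fx_sphere()
  # fine midpoint-Riemann oracle for TAWSS of |sin|
  tt <- seq(0, 1.05, length.out = 2e5 + 1)
  mid <- (tt[-1] + tt[-length(tt)]) / 2
  oracle <- sum(abs(sin(2 * pi * mid / 1.05))) * diff(tt)[1] / 1.05
  errs <- vapply(c(16, 32, 64), function(ns) {
    w <- make_wss_series(sph, flow_spec(steady = 0, oscillatory = 1,
                                        samples_per_cycle = ns))
    abs(compute_indices(w)$data$tawss_pa[1] - oracle)
  }, numeric(1))
  # halving the step shrinks the error ~4x (allow 3x for safety)
  expect_gt(errs[1] / errs[2], 3)
  expect_gt(errs[2] / errs[3], 3)
})

test_that("OSI stays within [0, 1/2] on randomized fields; indices scale as expected", {
  set.seed(42)
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      matrix(c(1, 2, 3), 1))
  times <- seq(0, 1, length.out = 9)
  for (rep in 1:1000) {
    arr <- array(stats::rnorm(3 * 9 * 3), c(3, 9, 3))
    osi <- compute_indices(wss_series(tri, times, arr))$data$osi
    if (any(osi < 0 | osi > 0.5)) fail("OSI out of [0, 0.5]")
  }
  succeed()
  # homogeneity: doubling tau doubles TAWSS, keeps OSI, halves ECAP
  arr <- array(stats::rnorm(3 * 9 * 3), c(3, 9, 3))
  i1 <- compute_indices(wss_series(tri, times, arr))$data
  i2 <- compute_indices(wss_series(tri, times, 2 * arr))$data
  expect_equal(i2$tawss_pa, 2 * i1$tawss_pa, tolerance = 1e-12)
  expect_equal(i2$osi, i1$osi, tolerance = 1e-12)
  expect_equal(i2$ecap_inv_pa, i1$ecap_inv_pa / 2, tolerance = 1e-12)
})

test_that("non-monotone times and malformed arrays are rejected", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      matrix(c(1, 2, 3), 1))
  arr <- array(1, c(3, 4, 3))
  expect_error(wss_series(tri, c(0, 0.2, 0.1, 0.3), arr), "increasing")
  expect_error(wss_series(tri, c(0, 1), array(1, c(3, 2, 3))), "3 time")
  expect_error(wss_series(tri, c(0, 0.5, 1), array(1, c(2, 3, 3))), "array")
})

test_that("the ROI mask keeps the pocket between ostium and device only", {
  laa <- fx_cyl_laa()
  cl <- fx_cyl_centreline()
  cfg <- propose_configuration(laa, cl, "watchman")[[1]]   # depth 13
  dom <- implant(laa, cfg, resolution = 1.2)
  w <- make_wss_series(dom, flow_spec(steady = 1))
  field <- compute_indices(w)
  gt <- attr(laa, "ground_truth")
  mask <- roi_between_ostium_and_device(field, gt$ostium, cfg, cl)
  v <- dom$vertices
  expect_true(any(mask))
  # a wall node at depth ~6 mm is included; nodes beyond 13 mm are not
  expect_true(all(v[mask, 3] <= 13 + 1.5))
  expect_true(all(v[mask, 3] >= -1e-6))
  # device nodes are excluded even though they sit in the depth interval
  dev_nodes <- unique(as.vector(
    dom$faces[dom$face_labels == label_codes()[["device"]], ]))
  expect_true(all(!mask[dev_nodes]))
  # the device-free ROI contains every device-scenario ROI
  mask_free <- roi_between_ostium_and_device(field, gt$ostium, NULL, cl)
  expect_true(all(mask_free[mask]))
})

test_that("ECAP histograms honour weighting, binning and reordering", {
  # all nodes at ECAP 0.1 with edges [0, 1, Inf): everything in bin 1
  sph <- fx_sphere()
  w <- make_wss_series(sph, flow_spec(steady = 0, oscillatory = pi / 4 / 0.1,
                                      samples_per_cycle = 256))
  f <- compute_indices(w)
  h <- ecap_histogram(f, bin_edges = c(0, 1, Inf))
  expect_equal(h$pct, c(100, 0), tolerance = 1e-6)
  # hand-built two-node field: ECAP 0.5 and 5, equal areas -> 50/50
  f2 <- f
  f2$data <- tibble::tibble(node = 1:2, tawss_pa = c(1, 1), osi = c(0.5, 0.5),
                            ecap_inv_pa = c(0.5, 5),
                            node_area_mm2 = c(2, 2), valid = c(TRUE, TRUE))
  h2 <- ecap_histogram(f2, bin_edges = c(0, 3, Inf))
  expect_equal(h2$pct, c(50, 50))
  expect_equal(pct_above_ecap(h2, 3), 50)
  # skewed areas: area weighting differs from node counting as hand-computed
  f3 <- f2
  f3$data$node_area_mm2 <- c(3, 1)
  ha <- ecap_histogram(f3, bin_edges = c(0, 3, Inf))
  hn <- ecap_histogram(f3, bin_edges = c(0, 3, Inf),
                       weighting = "node_count")
  expect_equal(ha$pct, c(75, 25))
  expect_equal(hn$pct, c(50, 50))
  # invariant to node reordering
  f4 <- f3
  f4$data <- f3$data[2:1, ]
  expect_equal(ecap_histogram(f4, bin_edges = c(0, 3, Inf))$pct, ha$pct)
  expect_error(ecap_histogram(f2, mask = c(FALSE, FALSE)), "empty")
  expect_error(pct_above_ecap(h2, 1.7), "bin edge")
})

test_that("the velocity probe sits on the reversed centreline axis and recovers waveforms", {
  cl <- fx_cyl_centreline()
  gt <- attr(fx_cyl_laa(), "ground_truth")
  times <- seq(0, 1.05, length.out = 22)
  # uniform steady field: constant speed
  pr <- probe_velocity(function(p, t) matrix(0.3 / sqrt(3), nrow(p), 3),
                       cl, gt$ostium, offset_mm = 5, times = times)
  expect_equal(pr$speed_m_s, rep(0.3, 22), tolerance = 1e-12)
  # the probe point is 5 mm outside the ostium along the centreline
  expect_equal(as.numeric(attr(pr, "location")),
               as.numeric(point_at_geodesic_distance(cl, 0)$point -
                            5 * point_at_geodesic_distance(cl, 0)$tangent),
               tolerance = 1e-9)
  # offset 0 lies in the ostium plane
  pr0 <- probe_velocity(function(p, t) matrix(0, nrow(p), 3), cl,
                        gt$ostium, offset_mm = 0, times = times)
  expect_lt(abs(sum((attr(pr0, "location") - gt$ostium$origin) *
                      gt$ostium$normal)), 0.5)
  # known sinusoid recovered through the sampled-field path
  bc <- boundary_conditions()
  ff <- make_flow_field(bc)
  loc <- attr(pr, "location")
  sampled <- list(points = rbind(loc, loc + c(10, 0, 0)),
                  times = times,
                  velocities = array(0, c(2, 22, 3)))
  for (k in seq_along(times))
    sampled$velocities[, k, ] <- rbind(ff(matrix(loc, 1, 3), times[k]),
                                       0)
  prs <- probe_velocity(sampled, cl, gt$ostium, offset_mm = 5)
  expect_equal(max(prs$speed_m_s), bc$peak_inlet_velocity_m_s,
               tolerance = 0.02)
})

test_that("reports rank scenarios by high-ECAP area and regenerate byte-identically", {
  sph <- fx_sphere()
  mk <- function(c_amp) compute_indices(make_wss_series(
    sph, flow_spec(steady = 0, oscillatory = c_amp,
                   samples_per_cycle = 64)))
  # ECAP = pi/(4c): c = 0.05 -> 15.7 (high risk), c = 1 -> 0.79 (low)
  fields <- list(no_laao = mk(0.05), vidaa_init = mk(1))
  hists <- lapply(fields, ecap_histogram)
  td <- withr::local_tempdir()
  s1 <- render_report(fields, hists, out_dir = file.path(td, "r1"))
  expect_identical(s1$scenario, c("vidaa_init", "no_laao"))
  expect_true(all(diff(s1$pct_ecap_gt3) >= 0))
  files <- list.files(file.path(td, "r1"))
  expect_true(all(c("no_laao.vtp", "vidaa_init.vtp",
                    "no_laao_ecap_histogram.csv", "summary.csv") %in% files))
  # ranking equals a manual sort of the histogram tail
  manual <- sort(vapply(hists, pct_above_ecap, numeric(1)))
  expect_equal(s1$pct_ecap_gt3, as.numeric(manual), tolerance = 1e-12)
  # regeneration is byte-identical
  s2 <- render_report(fields, hists, out_dir = file.path(td, "r2"))
  for (fn in files)
    expect_identical(readLines(file.path(td, "r1", fn)),
                     readLines(file.path(td, "r2", fn)))
  # the VTP carries the three index arrays
  txt <- readLines(file.path(td, "r1", "no_laao.vtp"))
  expect_true(any(grepl("TAWSS_Pa", txt)))
  expect_true(any(grepl("OSI", txt)))
  expect_true(any(grepl("ECAP_invPa", txt)))
})
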