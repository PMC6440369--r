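# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# Capped cylindrical appendage, diameter 20 mm, length 40 mm.
fx_cyl_laa <- function() fixture("cyl_laa", function()
  make_laa_tube(laa_spec(tube_length_mm = 40, proximal_diameter_mm = 20,
                         distal_diameter_mm = 20, edge_length_mm = 1.2)))

fx_cyl_centreline <- function() fixture("cyl_cl", function() {
  gt <- attr(fx_cyl_laa(), "ground_truth")
  extract_centreline(fx_cyl_laa(), gt$ostium, voxel_mm = 1)
})

# Straight analytic centreline along +z (for morphometry-only tests).
fx_axis_centreline <- function(length_mm = 40) {
  s <- seq(0, length_mm, by = 0.5)
  structure(list(points = outer(s, c(0, 0, 1)),
                 tangents = matrix(rep(c(0, 0, 1), length(s)), ncol = 3,
                                   byrow = TRUE),
                 arc_length = s,
                 ostium = ostium_plane(c(0, 0, 0), c(0, 0, -1))),
            class = "laa_centreline")
}

# Full synthetic left atrium (ellipsoid body + 4 PVs + MV + appendage).
fx_anatomy <- function() fixture("anatomy", function()
  make_la_with_laa(laa_spec(edge_length_mm = 1.5)))

# Small sphere wall for index tests.
fx_sphere <- function() fixture("sphere", function()
  make_sphere_mesh(10, n_theta = 10, n_phi = 16))

# Brute-force slice perimeter: sum of per-triangle plane-clip segment
# lengths, independent of the polygon assembly in slice_with_plane.
oracle_slice_perimeter <- function(mesh, plane) {
  v <- mesh$vertices
  d <- as.numeric((sweep(v, 2, plane$origin) %*% plane$normal))
  d[d == 0] <- 1e-12
  total <- 0
  for (fi in seq_len(nrow(mesh$faces))) {
    tri <- mesh$faces[fi, ]
    dd <- d[tri]
    if (all(dd > 0) || all(dd < 0)) next
    pts <- list()
    for (pair in list(c(1, 2), c(2, 3), c(3, 1))) {
      d1 <- dd[pair[1]]; d2 <- dd[pair[2]]
      if (sign(d1) != sign(d2)) {
        t <- d1 / (d1 - d2)
        p1 <- v[tri[pair[1]], ]; p2 <- v[tri[pair[2]], ]
        pts[[length(pts) + 1]] <- p1 + t * (p2 - p1)
      }
    }
    if (length(pts) == 2)
      total <- total + sqrt(sum((pts[[1]] - pts[[2]])^2))
  }
  total
}

# Independent volume oracle: cast a grid of x-rays through the triangle
# soup and integrate chord lengths (column quadrature; no divergence
# theorem involved).
oracle_column_volume <- function(mesh, h = 0.4) {
  # tilt the mesh so no face is grid-aligned (volume is rotation-invariant;
  # axis-aligned flat faces otherwise give an O(h) phase error)
  R1 <- laaoplan:::rotation_between(c(0, 0, 1), c(0.31, 0.22, 0.92))
  mesh <- transform_mesh(mesh, R1)
  v <- mesh$vertices; f <- mesh$faces
  lo <- apply(v, 2, min) - h; hi <- apply(v, 2, max) + h
  ys <- seq(lo[2] + h * 0.503, hi[2], by = h)
  zs <- seq(lo[3] + h * 0.497, hi[3], by = h)
  ny <- length(ys)
  crossings <- vector("list", ny * length(zs))
  for (t in seq_len(nrow(f))) {
    a <- v[f[t, 1], ]; b <- v[f[t, 2], ]; d <- v[f[t, 3], ]
    det <- (b[2] - a[2]) * (d[3] - a[3]) - (d[2] - a[2]) * (b[3] - a[3])
    if (abs(det) < 1e-12) next
    iy <- which(ys >= min(a[2], b[2], d[2]) & ys <= max(a[2], b[2], d[2]))
    iz <- which(zs >= min(a[3], b[3], d[3]) & zs <= max(a[3], b[3], d[3]))
    if (!length(iy) || !length(iz)) next
    gy <- rep(ys[iy], times = length(iz))
    gz <- rep(zs[iz], each = length(iy))
    l1 <- ((gy - a[2]) * (d[3] - a[3]) - (d[2] - a[2]) * (gz - a[3])) / det
    l2 <- ((b[2] - a[2]) * (gz - a[3]) - (gy - a[2]) * (b[3] - a[3])) / det
    keep <- l1 >= 0 & l2 >= 0 & l1 + l2 <= 1
    if (!any(keep)) next
    xc <- a[1] + l1[keep] * (b[1] - a[1]) + l2[keep] * (d[1] - a[1])
    cid <- (rep(iz, each = length(iy))[keep] - 1L) * ny +
      rep(iy, times = length(iz))[keep]
    for (m in seq_along(cid))
      crossings[[cid[m]]] <- c(crossings[[cid[m]]], xc[m])
  }
  total <- 0
  for (cr in crossings) {
    if (length(cr) >= 2 && length(cr) %% 2 == 0) {
      cr <- sort(cr)
      total <- total + sum(cr[seq(2, length(cr), 2)] -
                             cr[seq(1, length(cr), 2)])
    }
  }
  total * h^2
}

# Exhaustive O(n^2) maximum point-pair distance.
oracle_max_pairwise <- function(pts) {
  n <- nrow(pts)
  best <- 0
  for (i in seq_len(n - 1)) {
    d2 <- rowSums(sweep(pts[(i + 1):n, , drop = FALSE], 2, pts[i, ])^2)
    best <- max(best, max(d2))
  }
  sqrt(best)
}

expect_watertight <- function(mesh) {
  expect_true(is_watertight(mesh))
}
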