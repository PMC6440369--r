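# Exact surfaces of revolution / extrusion used as analytic fixtures:
# tubes along a path with a known radius profile, spheres, cubes.

# Parallel-transport frames along a polyline (n x 3). Returns list(u, v)
# of n x 3 basis matrices orthogonal to the local tangent.
transport_frames <- function(path) {
  n <- nrow(path)
  seg <- diff(path)
  tang <- rbind(seg, seg[nrow(seg), , drop = FALSE])
  tang <- tang / rownorms(tang)
  u <- matrix(0, n, 3); v <- matrix(0, n, 3)
  b <- plane_basis(tang[1, ])
  u[1, ] <- b$u; v[1, ] <- b$v
  for (i in 2:n) {
    R <- rotation_between(tang[i - 1, ], tang[i, ])
    u[i, ] <- as.numeric(R %*% u[i - 1, ])
    v[i, ] <- as.numeric(R %*% v[i - 1, ])
  }
  list(u = u, v = v, tangent = tang)
}

#' Tube mesh along a path with a radius profile
#'
#' Watertight extrusion of a circle along a polyline with per-station radius,
#' capped with triangle fans at both ends. The start cap is labelled
#' `ostium`, everything else `wall` -- this is the canonical analytic
#' appendage fixture: its centreline and per-station diameters are known in
#' closed form.
#'
#' @param path n x 3 polyline of centre points (mm), ostium end first.
#' @param radius Scalar or length-n vector of radii (mm).
#' @param n_around Number of vertices per ring (default 48).
#' @param cap_start,cap_end Close the ends (default `TRUE`).
#' @param start_label Label for the start cap (default `"ostium"`).
#' @return Labelled [surface_mesh()] with a `ground_truth` attribute
#'   (`centreline` points, `radius` per station).
#' @export
make_tube <- function(path, radius, n_around = 48L, cap_start = TRUE,
                      cap_end = TRUE, start_label = "ostium") {
  path <- matrix(as.numeric(path), ncol = 3)
  n <- nrow(path)
  if (length(radius) == 1L) radius <- rep(radius, n)
  stopifnot(length(radius) == n, all(radius > 0), n >= 2)
  fr <- transport_frames(path)
  th <- 2 * pi * (seq_len(n_around) - 1L) / n_around
  verts <- matrix(0, n * n_around, 3)
  for (i in seq_len(n)) {
    ring <- outer(cos(th), fr$u[i, ]) + outer(sin(th), fr$v[i, ])
    verts[(i - 1L) * n_around + seq_len(n_around), ] <-
      sweep(radius[i] * ring, 2, path[i, ], `+`)
  }
  faces <- list(); labels <- integer(0)
  for (i in seq_len(n - 1L)) {
    a <- (i - 1L) * n_around + seq_len(n_around)
    b <- i * n_around + seq_len(n_around)
    nx <- c(seq_len(n_around)[-1], 1L)
    faces[[i]] <- rbind(cbind(a, b[nx], b), cbind(a, a[nx], b[nx]))
  }
  faces <- do.call(rbind, faces)
  labels <- rep(0L, nrow(faces))
  lc <- label_codes()
  if (cap_start) {
    cidx <- nrow(verts) + 1L
    verts <- rbind(verts, path[1, ])
    ring <- seq_len(n_around)
    nx <- c(ring[-1], 1L)
    capf <- cbind(rep(cidx, n_around), ring[nx], ring)
    faces <- rbind(faces, capf)
    labels <- c(labels, rep(lc[[start_label]], n_around))
  }
  if (cap_end) {
    cidx <- nrow(verts) + 1L
    verts <- rbind(verts, path[n, ])
    ring <- (n - 1L) * n_around + seq_len(n_around)
    nx <- c(seq_len(n_around)[-1], 1L)
    capf <- cbind(rep(cidx, n_around), ring, ring[nx])
    faces <- rbind(faces, capf)
    labels <- c(labels, rep(0L, n_around))
  }
  m <- surface_mesh(verts, faces, labels)
  attr(m, "ground_truth") <- list(centreline = path, radius = radius)
  m
}

#' Straight cylinder fixture
#'
#' @param radius_mm,length_mm Cylinder dimensions.
#' @param axis Unit direction (default +z); the ostium cap is at the origin.
#' @param n_around,n_along Discretisation.
#' @return Labelled [surface_mesh()] (start cap labelled `ostium`).
#' @export
make_cylinder_mesh <- function(radius_mm, length_mm, axis = c(0, 0, 1),
                               n_around = 64L, n_along = 33L) {
  axis <- normalize(axis)
  s <- seq(0, length_mm, length.out = n_along)
  path <- outer(s, axis)
  make_tube(path, radius_mm, n_around = n_around)
}

#' UV-sphere fixture mesh
#'
#' Closed sphere, optionally with radial noise (deterministic for a given
#' seed) -- the standard smoothing and index-field fixture.
#'
#' @param radius_mm Radius (mm).
#' @param center Length-3 centre.
#' @param n_theta,n_phi Latitudinal / longitudinal resolution.
#' @param noise_sd Radial Gaussian noise standard deviation (mm; 0 = exact).
#' @param seed Seed for the noise.
#' @return Watertight [surface_mesh()].
#' @export
make_sphere_mesh <- function(radius_mm = 10, center = c(0, 0, 0),
                             n_theta = 32L, n_phi = 64L, noise_sd = 0,
                             seed = 1L) {
  th <- seq(0, pi, length.out = n_theta)[-c(1, n_theta)]
  ph <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  grid <- expand.grid(ph = ph, th = th)
  verts <- cbind(sin(grid$th) * cos(grid$ph),
                 sin(grid$th) * sin(grid$ph),
                 cos(grid$th))
  verts <- rbind(c(0, 0, 1), verts, c(0, 0, -1))
  r <- rep(radius_mm, nrow(verts))
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    set.seed(seed)
    r <- r + stats::rnorm(nrow(verts), 0, noise_sd)
    .Random.seed_restore(old)
  }
  verts <- sweep(verts * r, 2, center, `+`)
  nb <- n_theta - 2L
  ring <- function(i) 1L + (i - 1L) * n_phi + seq_len(n_phi)
  faces <- list()
  top <- 1L; bottom <- nrow(verts)
  r1 <- ring(1); nx <- c(seq_len(n_phi)[-1], 1L)
  faces[[1]] <- cbind(top, r1, r1[nx])
  for (i in seq_len(nb - 1L)) {
    a <- ring(i); b <- ring(i + 1L)
    faces[[length(faces) + 1L]] <- rbind(cbind(a, b[nx], b),
                                         cbind(a, a[nx], b[nx]))
  }
  rl <- ring(nb)
  faces[[length(faces) + 1L]] <- cbind(bottom, rl[nx], rl)
  surface_mesh(verts, do.call(rbind, faces))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # 12 triangles, outward-oriented
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),     # z = 0
    c(5, 6, 7), c(6, 8, 7),     # z = 1
    c(1, 2, 5), c(2, 6, 5),     # y = 0
    c(3, 7, 4), c(4, 7, 8),     # y = 1
    c(1, 5, 3), c(3, 5, 7),     # x = 0
    c(2, 4, 6), c(4, 8, 6))     # x = 1
  surface_mesh(v, f)
}

#' Synthetic appendage specification
#'
#' Parameters of the tubular left atrial appendage used by the anatomy
#' generator: overall length, proximal-to-distal taper, an optional bend, an
#' optional narrowed neck, and optional secondary lobes -- the shape features
#' (size, bending, number of lobes) along which real appendages vary.
#'
#' @param tube_length_mm Centreline length of the appendage.
#' @param proximal_diameter_mm,distal_diameter_mm Lumen taper endpoints.
#' @param bend_angle_deg Total in-plane bend distributed over the middle
#'   half of the tube (0 = straight).
#' @param neck_station_mm,neck_diameter_mm Optional localized narrowing
#'   (`NA` = none).
#' @param lobes List of lobe specs, each
#'   `list(station_mm=, length_mm=, diameter_mm=, angle_deg=)`.
#' @param edge_length_mm Target mesh edge length.
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `laa_spec`.
#' @export
laa_spec <- function(tube_length_mm = 40, proximal_diameter_mm = 20,
                     distal_diameter_mm = 12, bend_angle_deg = 0,
                     neck_station_mm = NA, neck_diameter_mm = NA,
                     lobes = list(), edge_length_mm = 1.2, seed = 1L) {
  stopifnot(tube_length_mm > 0, proximal_diameter_mm > 0,
            distal_diameter_mm > 0)
  if (!is.na(neck_station_mm))
    stopifnot(neck_station_mm > 0, neck_station_mm < tube_length_mm,
              neck_diameter_mm > 0)
  structure(list(tube_length_mm = tube_length_mm,
                 proximal_diameter_mm = proximal_diameter_mm,
                 distal_diameter_mm = distal_diameter_mm,
                 bend_angle_deg = bend_angle_deg,
                 neck_station_mm = neck_station_mm,
                 neck_diameter_mm = neck_diameter_mm,
                 lobes = lobes, edge_length_mm = edge_length_mm,
                 seed = as.integer(seed)),
            class = "laa_spec")
}

# Radius profile r(s) of an laa_spec (vectorised over stations s).
laa_radius_profile <- function(spec, s) {
  L <- spec$tube_length_mm
  r <- (spec$proximal_diameter_mm +
          (spec$distal_diameter_mm - spec$proximal_diameter_mm) * s / L) / 2
  if (!is.na(spec$neck_station_mm)) {
    sigma <- L / 12
    dip <- (r - spec$neck_diameter_mm / 2) *
      exp(-(s - spec$neck_station_mm)^2 / (2 * sigma^2))
    r <- r - pmax(dip, 0)
  }
  r
}

# Centreline path of an laa_spec: starts at origin along +z, bend applied
# over the middle half in the xz-plane.
laa_path <- function(spec, n = 81L) {
  L <- spec$tube_length_mm
  s <- seq(0, L, length.out = n)
  if (spec$bend_angle_deg == 0) return(outer(s, c(0, 0, 1)))
  span <- c(L / 4, 3 * L / 4)
  total <- spec$bend_angle_deg * pi / 180
  dtheta <- ifelse(s >= span[1] & s <= span[2], total / (span[2] - span[1]), 0)
  ds <- diff(s)
  theta <- cumsum(c(0, dtheta[-1] * ds))
  dirs <- cbind(sin(theta), 0, cos(theta))
  pts <- apply(rbind(0, dirs[-1, ] * ds), 2, cumsum)
  pts
}

#' Capped appendage-only fixture mesh
#'
#' The appendage of an [laa_spec()] as a standalone watertight tube, ostium
#' disk labelled, with analytic ground truth attached (true centreline,
#' radius and diameters per station, ostium plane and area).
#'
#' @param spec An [laa_spec()].
#' @return Labelled [surface_mesh()] with `ground_truth` attribute.
#' @export
make_laa_tube <- function(spec = laa_spec()) {
  n_along <- max(17L, 2L * as.integer(ceiling(
    spec$tube_length_mm / spec$edge_length_mm / 2)) + 1L)
  path <- laa_path(spec, n_along)
  s <- c(0, cumsum(rownorms(diff(path))))
  r <- laa_radius_profile(spec, s)
  n_around <- max(24L, as.integer(ceiling(
    pi * spec$proximal_diameter_mm / spec$edge_length_mm)))
  m <- make_tube(path, r, n_around = n_around)
  gt <- attr(m, "ground_truth")
  gt$arc_length <- s
  gt$diameter <- 2 * r
  gt$ostium <- ostium_plane(path[1, ], -normalize(path[2, ] - path[1, ]))
  gt$ostium_area_mm2 <- pi * r[1]^2
  gt$ostium_perimeter_mm <- 2 * pi * r[1]
  gt$spec <- spec
  attr(m, "ground_truth") <- gt
  m
}
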