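#' Device size catalog
#'
#' Default nominal sizes (lobe diameter for the Amulet-type disc-and-lobe
#' occluder, frame diameter for the Watchman-type plug), overridable for
#' custom device generations. The Watchman-type catalog also carries the
#' landing-diameter lookup used for D1-based sizing: the public sizing
#' chart 17-19.9 -> 21, 20-22.9 -> 24, 23-25.9 -> 27, 26-28.9 -> 30,
#' 29-31.9 -> 33 mm (overridable).
#'
#' @param family `"amulet"` or `"watchman"`.
#' @param sizes Optional custom vector of nominal sizes (mm), strictly
#'   increasing.
#' @param d1_map Optional custom Watchman lookup: tibble/data.frame with
#'   columns `d1_min`, `d1_max`, `size`.
#' @return Object of class `size_catalog`.
#' @export
#' @examples
#' catalog("watchman")$sizes
catalog <- function(family, sizes = NULL, d1_map = NULL) {
  if (!family %in% c("amulet", "watchman"))
    stop("unknown device family '", family,
         "'; available: amulet, watchman", call. = FALSE)
  if (is.null(sizes))
    sizes <- switch(family,
                    watchman = c(21, 24, 27, 30, 33),
                    amulet = c(16, 18, 20, 22, 25, 28, 31, 34))
  if (any(diff(sizes) <= 0))
    stop("catalog sizes must be strictly increasing", call. = FALSE)
  if (family == "watchman" && is.null(d1_map))
    d1_map <- tibble::tibble(
      d1_min = c(17, 20, 23, 26, 29),
      d1_max = c(19.9, 22.9, 25.9, 28.9, 31.9),
      size = c(21, 24, 27, 30, 33))
  structure(list(family = family, sizes = sizes, d1_map = d1_map),
            class = "size_catalog")
}

#' @export
print.size_catalog <- function(x, ...) {
  cat("<size_catalog> ", x$family, ": ",
      paste(x$sizes, collapse = ", "), " mm\n", sep = "")
  invisible(x)
}

#' Parametric occluder specification
#'
#' Geometry parameters default to public product-manual proportions:
#' Amulet-type -- disc diameter = lobe + 6 mm for nominal <= 22 and
#' + 7 mm above, lobe length 7.5 mm (<= 22) or 10 mm, disc thickness
#' 2.5 mm, disc-lobe axial gap 4 mm; Watchman-type -- plug depth
#' 0.8 x nominal. All overridable through `geometry_params`.
#'
#' @param family `"amulet"` or `"watchman"`.
#' @param nominal_size Nominal device diameter (mm); need not be a catalog
#'   size (scenario generation scales it continuously).
#' @param geometry_params Named list overriding any default above
#'   (`lobe_length`, `disc_diameter`, `disc_thickness`, `disc_gap`,
#'   `plug_depth`, `shoulder_radius`, all mm).
#' @return Object of class `device_spec`.
#' @export
device_spec <- function(family, nominal_size, geometry_params = list()) {
  if (!family %in% c("amulet", "watchman"))
    stop("unknown device family '", family, "'", call. = FALSE)
  stopifnot(nominal_size > 0)
  gp <- if (family == "amulet") {
    list(lobe_length = if (nominal_size <= 22) 7.5 else 10,
         disc_diameter = nominal_size + if (nominal_size <= 22) 6 else 7,
         disc_thickness = 2.5,
         disc_gap = 4,
         shoulder_radius = 1.5)
  } else {
    list(plug_depth = 0.8 * nominal_size,
         shoulder_radius = 0.35 * nominal_size)
  }
  gp[names(geometry_params)] <- geometry_params
  if (any(unlist(gp) <= 0))
    stop("all geometry parameters must be positive", call. = FALSE)
  structure(list(family = family, nominal_size = nominal_size,
                 geometry_params = gp),
            class = "device_spec")
}

#' @export
print.device_spec <- function(x, ...) {
  cat("<device_spec> ", x$family, " ", x$nominal_size, " mm\n", sep = "")
  invisible(x)
}

# Profile polyline (r, z) of the device, proximal face at z = 0, device
# axis +z pointing distally (deeper into the appendage). r(0) = r(end) = 0.
device_profile <- function(spec) {
  R <- spec$nominal_size / 2
  gp <- spec$geometry_params
  if (spec$family == "watchman") {
    depth <- gp$plug_depth
    sh <- min(gp$shoulder_radius, depth / 2, R)
    # flat proximal face, cylinder, ellipsoidal distal cap
    phi <- seq(0, pi / 2, length.out = 13)[-1]
    cap_r <- R * cos(phi)
    cap_z <- (depth - sh) + sh * sin(phi)
    rz <- rbind(c(0, 0), c(R, 0),
                c(R, depth - sh),
                cbind(cap_r, cap_z))
    rz[nrow(rz), 1] <- 0
  } else {
    Rd <- gp$disc_diameter / 2
    waist_r <- max(0.15 * spec$nominal_size, 1.5)
    z1 <- gp$disc_thickness
    z2 <- z1 + gp$disc_gap
    z3 <- z2 + gp$lobe_length
    rz <- rbind(c(0, 0), c(Rd, 0), c(Rd, z1), c(waist_r, z1),
                c(waist_r, z2), c(R, z2), c(R, z3), c(0, z3))
  }
  rz
}

#' Build a watertight occluder surface mesh
#'
#' Surface of revolution of the family profile about the +z device axis,
#' proximal face in the z = 0 plane. All faces are labelled `device`.
#'
#' @param spec A [device_spec()].
#' @param resolution Target edge length in mm (default `nominal_size / 24`);
#'   values coarser than `nominal_size / 8` are refused (self-intersection
#'   risk on the waist).
#' @return Watertight [surface_mesh()].
#' @export
build_device_mesh <- function(spec, resolution = NULL) {
  resolution <- resolution %||% (spec$nominal_size / 24)
  if (resolution > spec$nominal_size / 8)
    stop(sprintf(paste0("resolution %.2f mm too coarse for a %g mm device ",
                        "(must be <= nominal/8 = %.2f mm)"),
                 resolution, spec$nominal_size, spec$nominal_size / 8),
         call. = FALSE)
  rz <- device_profile(spec)
  # subdivide profile segments to the target edge length
  fine <- list(rz[1, , drop = FALSE])
  for (i in seq_len(nrow(rz) - 1)) {
    seg <- rz[i + 1, ] - rz[i, ]
    len <- vnorm(c(seg, 0))
    k <- max(1L, ceiling(len / resolution))
    t <- seq_len(k) / k
    fine[[i + 1]] <- cbind(rz[i, 1] + t * seg[1], rz[i, 2] + t * seg[2])
  }
  rz <- do.call(rbind, fine)
  rmax <- max(rz[, 1])
  n_around <- max(16L, ceiling(2 * pi * rmax / resolution))
  revolve_profile(rz, n_around)
}

# Revolve an (r, z) polyline with r = 0 at both ends about +z.
revolve_profile <- function(rz, n_around) {
  stopifnot(rz[1, 1] == 0, rz[nrow(rz), 1] == 0)
  inner <- rz[-c(1, nrow(rz)), , drop = FALSE]
  keep <- inner[, 1] > 1e-9
  inner <- inner[keep, , drop = FALSE]
  th <- 2 * pi * (seq_len(n_around) - 1) / n_around
  nring <- nrow(inner)
  verts <- matrix(0, nring * n_around + 2, 3)
  for (i in seq_len(nring)) {
    verts[(i - 1) * n_around + seq_len(n_around), ] <-
      cbind(inner[i, 1] * cos(th), inner[i, 1] * sin(th), inner[i, 2])
  }
  pole0 <- nring * n_around + 1L   # proximal pole (z of first profile point)
  pole1 <- nring * n_around + 2L
  verts[pole0, ] <- c(0, 0, rz[1, 2])
  verts[pole1, ] <- c(0, 0, rz[nrow(rz), 2])
  nx <- c(seq_len(n_around)[-1], 1L)
  faces <- list()
  ring <- function(i) (i - 1L) * n_around + seq_len(n_around)
  r1 <- ring(1)
  faces[[1]] <- cbind(pole0, r1[nx], r1)        # proximal cap, -z outward
  for (i in seq_len(nring - 1)) {
    a <- ring(i); b <- ring(i + 1)
    faces[[length(faces) + 1L]] <- rbind(cbind(a, b[nx], b),
                                         cbind(a, a[nx], b[nx]))
  }
  rl <- ring(nring)
  faces[[length(faces) + 1L]] <- cbind(pole1, rl, rl[nx])
  f <- do.call(rbind, faces)
  surface_mesh(verts, f,
               rep(label_codes()[["device"]], nrow(f)))
}

# Closed-form enclosed volume of the revolved profile: V = pi * int r(z)^2 dz
# (linear r between profile points; vertical faces contribute zero).
device_profile_volume <- function(spec) {
  rz <- device_profile(spec)
  v <- 0
  for (i in seq_len(nrow(rz) - 1)) {
    r0 <- rz[i, 1]; r1 <- rz[i + 1, 1]
    dz <- rz[i + 1, 2] - rz[i, 2]
    v <- v + dz * (r0^2 + r0 * r1 + r1^2) / 3
  }
  pi * abs(v)
}

#' Watchman-type size from the D1 lookup chart
#'
#' @param cat A watchman [catalog()].
#' @param d1 Maximal landing-zone diameter D1 (mm).
#' @return The mapped nominal size, or `NA` when D1 falls outside the chart.
#' @export
watchman_size_for_d1 <- function(cat, d1) {
  stopifnot(inherits(cat, "size_catalog"), cat$family == "watchman")
  # intervals are treated as contiguous [min_i, min_{i+1}) so that a
  # landing diameter in a chart gap (e.g. 19.95) maps to the lower row
  if (d1 < cat$d1_map$d1_min[1] || d1 > max(cat$d1_map$d1_max))
    return(NA_real_)
  cat$d1_map$size[findInterval(d1, cat$d1_map$d1_min)]
}
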