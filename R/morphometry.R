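#' Cross-section of the appendage at a geodesic station
#'
#' Slices the wall perpendicular to the centreline at geodesic depth `d` and
#' measures the lumen contour that encloses the centreline point: maximal
#' Feret diameter D1 (largest point-pair distance), minimal Feret width D2
#' (smallest projected extent over all in-plane directions), shoelace area
#' and perimeter. Contours are resampled to at most 0.2 mm segment length
#' before the Feret search so minima are stable.
#'
#' @param mesh Labelled [surface_mesh()] of the anatomy.
#' @param cl An `laa_centreline` from [extract_centreline()].
#' @param d Geodesic distance from the ostium (mm).
#' @return Object of class `cross_section`: `station_arclength`, `plane`
#'   (origin, normal), `contour` (n x 3), `d1_max_diameter`,
#'   `d2_min_diameter`, `area`, `perimeter` (mm / mm^2).
#' @export
cross_section_at <- function(mesh, cl, d) {
  smax <- max(cl$arc_length)
  # nudge end stations inside so a plane coincident with an end cap still
  # cuts a proper ring of wall faces
  at <- point_at_geodesic_distance(cl, min(max(d, 1e-4), smax - 1e-4))
  polys <- slice_with_plane(mesh, list(origin = at$point, normal = at$tangent))
  if (!length(polys))
    stop("no cross-section at station ", d, " mm (plane misses the mesh)",
         call. = FALSE)
  enclosing <- which(vapply(polys, function(pg)
    point_in_polygon3(at$point, pg, at$tangent), logical(1)))
  if (!length(enclosing))
    stop("centreline point at station ", d,
         " mm lies outside every slice component (topology error)",
         call. = FALSE)
  # smallest enclosing component (nested contours can both contain the point)
  areas <- vapply(polys[enclosing], polygon_area3, numeric(1),
                  normal = at$tangent)
  contour <- polys[[enclosing[which.min(areas)]]]
  measure_contour(contour, at$tangent, d, at$point)
}

measure_contour <- function(contour, normal, station, origin) {
  fine <- resample_polygon(contour, 0.2)
  basis <- plane_basis(normal)
  rel <- sweep(fine, 2, colMeans(fine))
  uv <- cbind(rel %*% basis$u, rel %*% basis$v)
  fer <- feret_diameters(uv)
  structure(list(
    station_arclength = station,
    plane = list(origin = origin, normal = normal),
    contour = contour,
    d1_max_diameter = fer$d1,
    d2_min_diameter = fer$d2,
    area = polygon_area3(contour, normal),
    perimeter = polygon_perimeter(contour)), class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf(paste0("<cross_section> s = %.1f mm: D1 %.2f, D2 %.2f mm, ",
                     "area %.1f mm^2, perimeter %.1f mm\n"),
              x$station_arclength, x$d1_max_diameter, x$d2_min_diameter,
              x$area, x$perimeter))
  invisible(x)
}

# Insert points so no segment exceeds max_len (keeps original vertices).
resample_polygon <- function(poly, max_len) {
  n <- nrow(poly)
  nxt <- poly[c(2:n, 1), , drop = FALSE]
  lens <- rownorms(nxt - poly)
  pieces <- pmax(1L, ceiling(lens / max_len))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    t <- (seq_len(pieces[i]) - 1L) / pieces[i]
    out[[i]] <- poly[rep(i, pieces[i]), , drop = FALSE] +
      outer(t, nxt[i, ] - poly[i, ])
  }
  do.call(rbind, out)
}

# Max Feret diameter and min Feret width of a 2D point set.
# D1 over convex-hull vertex pairs (the maximum is attained on the hull);
# D2 as the smallest hull width over hull-edge directions (projected extents
# of the contour and of its hull coincide for every direction).
feret_diameters <- function(uv) {
  hull <- grDevices::chull(uv)
  hp <- uv[hull, , drop = FALSE]
  m <- nrow(hp)
  if (m < 2) return(list(d1 = 0, d2 = 0))
  d1 <- sqrt(max(as.vector(stats::dist(hp))^2))
  nxt <- hp[c(2:m, 1), , drop = FALSE]
  edges <- nxt - hp
  keep <- rownorms(edges) > 1e-12
  dirs <- edges[keep, , drop = FALSE] / rownorms(edges[keep, , drop = FALSE])
  widths <- vapply(seq_len(nrow(dirs)), function(i) {
    nrm <- c(-dirs[i, 2], dirs[i, 1])
    pr <- hp %*% nrm
    max(pr) - min(pr)
  }, numeric(1))
  list(d1 = d1, d2 = min(widths))
}

#' Diameter profile along the appendage
#'
#' Cross-sections at stations `0, spacing, 2 spacing, ...` up to the tip.
#' Stations where no valid enclosing contour exists (tip tangency) are
#' skipped with a warning.
#'
#' @param mesh,cl As in [cross_section_at()].
#' @param spacing Station spacing in mm (default 1).
#' @return A tibble with columns `station_mm`, `d1_mm`, `d2_mm`, `area_mm2`,
#'   `perimeter_mm`; the `cross_section` objects ride along in attribute
#'   `sections`.
#' @export
diameter_profile <- function(mesh, cl, spacing = 1) {
  stopifnot(spacing > 0)
  stations <- seq(0, max(cl$arc_length), by = spacing)
  secs <- list()
  for (d in stations) {
    cs <- tryCatch(cross_section_at(mesh, cl, d), error = function(e) NULL)
    if (is.null(cs)) {
      warning(sprintf("station %.1f mm skipped (degenerate section)", d))
    } else secs[[length(secs) + 1L]] <- cs
  }
  out <- tibble::tibble(
    station_mm = vapply(secs, `[[`, numeric(1), "station_arclength"),
    d1_mm = vapply(secs, `[[`, numeric(1), "d1_max_diameter"),
    d2_mm = vapply(secs, `[[`, numeric(1), "d2_min_diameter"),
    area_mm2 = vapply(secs, `[[`, numeric(1), "area"),
    perimeter_mm = vapply(secs, `[[`, numeric(1), "perimeter"))
  attr(out, "sections") <- secs
  out
}

#' Export a diameter profile as CSV
#'
#' @param profile Tibble from [diameter_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Ostium metrics from labelled faces
#'
#' Area, perimeter and principal axes of the mesh patch labelled `ostium`.
#' For a disk-like patch (one boundary ring) the area is the labelled-face
#' area sum and the perimeter the boundary-ring length. When the label marks
#' an annular band at the junction (two boundary rings, as in the combined
#' synthetic anatomy), the orifice is taken as the band's larger boundary
#' ring and area/perimeter are measured on that ring.
#'
#' Principal axes default to extreme-point extents along the two principal
#' directions of the boundary points (PCA axes of their in-plane
#' covariance); `method = "pca"` instead returns `2 * sqrt(eigenvalue)` per
#' axis.
#'
#' @param mesh Labelled [surface_mesh()].
#' @param method `"extent"` (default) or `"pca"`.
#' @return Object of class `ostium_metrics`: `area`, `perimeter`,
#'   `principal_axis_major`, `principal_axis_minor`, `plane`.
#' @export
ostium_metrics <- function(mesh, method = c("extent", "pca")) {
  method <- match.arg(method)
  sel <- mesh$face_labels == label_codes()[["ostium"]]
  if (!any(sel))
    stop("no faces labelled 'ostium' in this mesh", call. = FALSE)
  patch <- subset_faces(mesh, sel)
  rings <- boundary_rings(patch)
  if (!length(rings))
    stop("ostium patch has no boundary ring (labelling error)", call. = FALSE)
  ring_pts <- lapply(rings, function(r) patch$vertices[r, , drop = FALSE])
  ctr <- colMeans(do.call(rbind, ring_pts))
  normal <- patch_normal(patch)
  ring_areas <- vapply(ring_pts, polygon_area3, numeric(1), normal = normal)
  outer_ring <- ring_pts[[which.max(ring_areas)]]
  if (length(rings) == 1L) {
    area <- sum(face_areas(patch))
  } else {
    area <- max(ring_areas)        # annular band: orifice = larger ring
  }
  perim <- polygon_perimeter(outer_ring)
  basis <- plane_basis(normal)
  rel <- sweep(outer_ring, 2, colMeans(outer_ring))
  uv <- cbind(rel %*% basis$u, rel %*% basis$v)
  ev <- eigen(stats::cov(uv), symmetric = TRUE)
  pr1 <- uv %*% ev$vectors[, 1]
  pr2 <- uv %*% ev$vectors[, 2]
  axes <- if (method == "extent") {
    c(max(pr1) - min(pr1), max(pr2) - min(pr2))
  } else 2 * sqrt(pmax(ev$values, 0))
  structure(list(area = area, perimeter = perim,
                 principal_axis_major = max(axes),
                 principal_axis_minor = min(axes),
                 plane = ostium_plane(ctr, normal)),
            class = "ostium_metrics")
}

#' @export
print.ostium_metrics <- function(x, ...) {
  cat(sprintf(paste0("<ostium_metrics> area %.1f mm^2, perimeter %.1f mm, ",
                     "axes %.1f x %.1f mm\n"),
              x$area, x$perimeter, x$principal_axis_major,
              x$principal_axis_minor))
  invisible(x)
}

# Mean face normal of a patch, unitized.
patch_normal <- function(patch) {
  n <- face_normals(patch)
  a <- face_areas(patch)
  normalize(colSums(n * a))
}

# Ordered boundary rings (lists of vertex indices) of an open patch.
boundary_rings <- function(patch) {
  f <- patch$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  once <- names(which(table(key) == 1L))
  be <- e[key %in% once, , drop = FALSE]
  if (!nrow(be)) return(list())
  nxt <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  visited_edge <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  rings <- list()
  for (srow in seq_len(nrow(be))) {
    a <- be[srow, 1]; b <- be[srow, 2]
    if (!is.null(visited_edge[[ekey(a, b)]])) next
    visited_edge[[ekey(a, b)]] <- TRUE
    ring <- c(a, b)
    repeat {
      tail <- ring[length(ring)]
      cand <- nxt[[as.character(tail)]]
      cand <- cand[vapply(cand, function(x)
        is.null(visited_edge[[ekey(tail, x)]]), logical(1))]
      if (!length(cand)) break
      nn <- cand[1]
      visited_edge[[ekey(tail, nn)]] <- TRUE
      if (nn == ring[1]) break
      ring <- c(ring, nn)
    }
    if (length(ring) >= 3) rings[[length(rings) + 1L]] <- ring
  }
  rings
}

#' Station-sensitivity harness for D1
#'
#' Measures how a +/- `delta` mm shift of the landing-zone station changes
#' the maximal diameter D1 -- small plane shifts on strongly tapered
#' appendages can change the measured maximum diameter by several mm, which
#' is exactly the sizing pitfall the planner's compression filter guards
#' against. The harness reports, it does not judge.
#'
#' @param mesh,cl As in [cross_section_at()].
#' @param d Station (mm).
#' @param delta Shift magnitude (default 1 mm).
#' @return Tibble with one row per probed station: `station_mm`, `d1_mm`,
#'   and `dd1_mm` (change relative to the nominal station).
#' @export
station_sensitivity <- function(mesh, cl, d, delta = 1) {
  stations <- c(d - delta, d, d + delta)
  stations <- stations[stations >= 0 & stations <= max(cl$arc_length)]
  rows <- lapply(stations, function(s) {
    cs <- cross_section_at(mesh, cl, s)
    tibble::tibble(station_mm = s, d1_mm = cs$d1_max_diameter)
  })
  out <- dplyr::bind_rows(rows)
  ref <- out$d1_mm[out$station_mm == d][1]
  out$dd1_mm <- out$d1_mm - ref
  message(sprintf("D1 sensitivity at %.1f +/- %.1f mm: %s",
                  d, delta,
                  paste(sprintf("%+.2f", out$dd1_mm), collapse = ", ")))
  out
}
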