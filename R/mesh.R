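#' Face label code table
#'
#' Integer codes used for anatomical face labels in every supported mesh
#' format. Labels travel as an integer cell-data array named `"label"`, which
#' survives VTK, VTP/VTU, MSH and PLY round trips; STL cannot carry cell data
#' and drops labels on write (a warning is emitted).
#'
#' @return Named integer vector: `wall = 0`, `ostium = 1`, `pv_inlet = 2`,
#'   `mv_outlet = 3`, `device = 4`.
#' @export
#' @examples
#' label_codes()
label_codes <- function() {
  c(wall = 0L, ostium = 1L, pv_inlet = 2L, mv_outlet = 3L, device = 4L)
}

label_name <- function(code) {
  lc <- label_codes()
  out <- names(lc)[match(code, lc)]
  out[is.na(out)] <- "wall"
  out
}

#' Construct a labelled triangular surface mesh
#'
#' The basic geometric container of the package: vertices in millimetres and
#' triangular faces, with an optional per-face anatomical label (see
#' [label_codes()]).
#'
#' @param vertices Numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces Integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param face_labels Optional integer vector of length m with values from
#'   [label_codes()]; defaults to all `wall`.
#' @param validate Check invariants (finite coordinates, index bounds)?
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces`, `face_labels`.
#' @export
surface_mesh <- function(vertices, faces, face_labels = NULL, validate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = NULL)
  faces <- matrix(as.integer(faces), ncol = 3, dimnames = NULL)
  if (is.null(face_labels)) {
    face_labels <- rep(0L, nrow(faces))
  } else {
    face_labels <- as.integer(face_labels)
    if (length(face_labels) != nrow(faces))
      stop("face_labels must have one entry per face", call. = FALSE)
  }
  m <- structure(list(vertices = vertices, faces = faces,
                      face_labels = face_labels),
                 class = "surface_mesh")
  if (validate) validate_mesh(m)
  m
}

#' Construct a labelled tetrahedral volume mesh
#'
#' @param vertices Numeric matrix, n x 3, in mm.
#' @param tets Integer matrix, m x 4, 1-based vertex indices per tetrahedron.
#' @param boundary A `surface_mesh` describing the labelled boundary surface,
#'   or `NULL`.
#' @return An object of class `volume_mesh`.
#' @export
volume_mesh <- function(vertices, tets, boundary = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  tets <- matrix(as.integer(tets), ncol = 4)
  if (any(tets < 1L) || any(tets > nrow(vertices)))
    stop("tetrahedron references vertex out of range", call. = FALSE)
  # orient so every tet has positive signed volume
  v6 <- tet_signed_volumes(vertices, tets)
  flip <- which(v6 < 0)
  if (length(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  if (any(abs(v6) < 1e-12))
    stop("degenerate tetrahedra (zero volume) present", call. = FALSE)
  structure(list(vertices = vertices, tets = tets, boundary = boundary),
            class = "volume_mesh")
}

tet_signed_volumes <- function(v, tets) {
  a <- v[tets[, 2], , drop = FALSE] - v[tets[, 1], , drop = FALSE]
  b <- v[tets[, 3], , drop = FALSE] - v[tets[, 1], , drop = FALSE]
  d <- v[tets[, 4], , drop = FALSE] - v[tets[, 1], , drop = FALSE]
  rowSums(cross3m(a, b) * d) / 6
}

validate_mesh <- function(m) {
  if (!all(is.finite(m$vertices)))
    stop("mesh has non-finite vertex coordinates", call. = FALSE)
  if (nrow(m$faces) > 0 && (min(m$faces) < 1L || max(m$faces) > nrow(m$vertices)))
    stop("face references vertex index out of range", call. = FALSE)
  invisible(m)
}

#' @export
print.surface_mesh <- function(x, ...) {
  lbl <- table(label_name(x$face_labels))
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces\n", sep = "")
  cat("  labels:", paste(names(lbl), lbl, sep = "=", collapse = ", "), "\n")
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [mm]: x %.1f..%.1f, y %.1f..%.1f, z %.1f..%.1f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat("<volume_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$tets), " tetrahedra\n", sep = "")
  invisible(x)
}

#' Per-face areas of a surface mesh
#' @param mesh A `surface_mesh`.
#' @return Numeric vector of triangle areas in mm^2.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  rownorms(cross3m(a, b)) / 2
}

face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cross3m(a, b)
  n / pmax(rownorms(n), 1e-300)
}

face_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

# Lumped nodal areas: one third of each incident face area.
node_areas <- function(mesh) {
  fa <- face_areas(mesh)
  out <- numeric(nrow(mesh$vertices))
  for (k in 1:3) {
    s <- tapply(fa, mesh$faces[, k], sum)
    idx <- as.integer(names(s))
    out[idx] <- out[idx] + s
  }
  out / 3
}

# Undirected edge table: one row per unique edge, with incidence count.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  list(count = as.integer(tab), key = names(tab))
}

#' Is a surface mesh watertight?
#'
#' A mesh is watertight (closed, manifold along edges) when every edge is
#' shared by exactly two faces.
#'
#' @param mesh A `surface_mesh`.
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  all(mesh_edges(mesh)$count == 2L)
}

#' Enclosed volume of a closed surface mesh
#'
#' Divergence-theorem signed volume; the absolute value is returned so the
#' result is orientation-independent.
#'
#' @param mesh A watertight `surface_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  d <- v[f[, 3], , drop = FALSE]
  abs(sum(rowSums(a * cross3m(b, d))) / 6)
}

#' Rigidly transform a surface mesh
#'
#' @param mesh A `surface_mesh`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 translation vector (mm), applied after rotation.
#' @return Transformed `surface_mesh` with labels preserved.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, `+`)
  surface_mesh(v, mesh$faces, mesh$face_labels, validate = FALSE)
}

# Merge meshes, concatenating labels.
merge_meshes <- function(a, b) {
  off <- nrow(a$vertices)
  surface_mesh(rbind(a$vertices, b$vertices),
               rbind(a$faces, b$faces + off),
               c(a$face_labels, b$face_labels), validate = FALSE)
}

# Keep the faces in `keep` (logical or index); drops unused vertices.
subset_faces <- function(mesh, keep) {
  f <- mesh$faces[keep, , drop = FALSE]
  lab <- mesh$face_labels[keep]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[f], ncol = 3), lab, validate = FALSE)
}

#' Ostium plane
#'
#' The operator-defined 2D plane separating the left atrial appendage from
#' the atrial body. All geodesic depths are measured from this plane. The
#' normal is oriented from the appendage toward the atrial body.
#'
#' @param origin Length-3 point on the plane (mm).
#' @param normal Length-3 normal vector; normalised internally.
#' @return An object of class `ostium_plane`.
#' @export
ostium_plane <- function(origin, normal) {
  structure(list(origin = as.numeric(origin),
                 normal = normalize(as.numeric(normal))),
            class = "ostium_plane")
}

#' @export
print.ostium_plane <- function(x, ...) {
  cat(sprintf("<ostium_plane> origin (%.2f, %.2f, %.2f) normal (%.3f, %.3f, %.3f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Signed distance of points to a plane
#'
#' Positive on the side the normal points to; for an [ostium_plane()] that
#' is the atrial-body side, so appendage points come out negative.
#'
#' @param points n x 3 matrix (or length-3 vector) of points in mm.
#' @param plane An [ostium_plane()] or any list with `origin` and `normal`.
#' @return Numeric vector of signed distances (mm).
#' @export
plane_signed_distance <- function(points, plane) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  sweep(points, 2, plane$origin, `-`) %*% plane$normal
}

# Are points inside a closed mesh? Ray-parity along +x with triangle
# bounding-box prefilter. `points` is n x 3.
points_in_mesh <- function(points, mesh) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  ymin <- pmin(p1[, 2], p2[, 2], p3[, 2]); ymax <- pmax(p1[, 2], p2[, 2], p3[, 2])
  zmin <- pmin(p1[, 3], p2[, 3], p3[, 3]); zmax <- pmax(p1[, 3], p2[, 3], p3[, 3])
  xmax <- pmax(p1[, 1], p2[, 1], p3[, 1])
  out <- logical(nrow(points))
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    cand <- which(ymin <= p[2] & ymax >= p[2] & zmin <= p[3] & zmax >= p[3] &
                    xmax >= p[1])
    if (!length(cand)) next
    hits <- 0L
    for (j in cand) {
      # Moller-Trumbore with ray direction (1,0,0)
      e1 <- v[f[j, 2], ] - v[f[j, 1], ]
      e2 <- v[f[j, 3], ] - v[f[j, 1], ]
      # h = dir x e2 with dir = (1,0,0)
      h <- c(0, -e2[3], e2[2])
      a <- sum(e1 * h)
      if (abs(a) < 1e-12) next
      s <- p - v[f[j, 1], ]
      u <- sum(s * h) / a
      if (u < 0 || u > 1) next
      q <- cross3(s, e1)
      vv <- q[1] / a
      if (vv < 0 || u + vv > 1) next
      t <- sum(e2 * q) / a
      if (t > 1e-9) hits <- hits + 1L
    }
    out[i] <- (hits %% 2L) == 1L
  }
  out
}
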