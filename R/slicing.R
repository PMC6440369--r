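#' Intersect a surface mesh with a plane
#'
#' Returns every closed intersection contour as an ordered planar polygon.
#' Separate connected components (for example the two lumens of a bi-lobed
#' appendage) come back as separate polygons, each oriented counter-clockwise
#' about the plane normal. Degenerate components with area below 1e-9 mm^2
#' (tangency) are discarded. A plane that misses the mesh yields an empty
#' list, not an error.
#'
#' @param mesh A [surface_mesh()].
#' @param plane An [ostium_plane()] or any list with `origin` and `normal`.
#' @return List of closed polygons; each an n x 3 matrix of points (the first
#'   vertex is not repeated at the end).
#' @export
slice_with_plane <- function(mesh, plane) {
  if (!inherits(plane, "ostium_plane"))
    plane <- ostium_plane(plane$origin, plane$normal)
  v <- mesh$vertices
  d <- as.numeric(plane_signed_distance(v, plane))
  d[d == 0] <- 1e-12            # nudge on-plane vertices off the plane
  f <- mesh$faces
  s1 <- d[f[, 1]]; s2 <- d[f[, 2]]; s3 <- d[f[, 3]]
  crossed <- which(!(sign(s1) == sign(s2) & sign(s2) == sign(s3)))
  if (!length(crossed)) return(list())

  edge_key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  # per crossed face, the two crossing edges and their intersection points
  seg_a_key <- character(0); seg_b_key <- character(0)
  pts <- new.env(parent = emptyenv())
  edge_point <- function(i, j) {
    key <- edge_key(i, j)
    if (is.null(pts[[key]])) {
      t <- d[i] / (d[i] - d[j])
      pts[[key]] <- v[i, ] + t * (v[j, ] - v[i, ])
    }
    key
  }
  for (fi in crossed) {
    tri <- f[fi, ]
    dd <- d[tri]
    cross_edges <- list()
    for (pair in list(c(1, 2), c(2, 3), c(3, 1))) {
      if (sign(dd[pair[1]]) != sign(dd[pair[2]]))
        cross_edges[[length(cross_edges) + 1L]] <- tri[pair]
    }
    if (length(cross_edges) != 2L) next
    seg_a_key <- c(seg_a_key, edge_point(cross_edges[[1]][1], cross_edges[[1]][2]))
    seg_b_key <- c(seg_b_key, edge_point(cross_edges[[2]][1], cross_edges[[2]][2]))
  }
  # link segments into loops: nodes are edge keys, segments connect two keys
  nseg <- length(seg_a_key)
  if (!nseg) return(list())
  nodes <- unique(c(seg_a_key, seg_b_key))
  a <- match(seg_a_key, nodes); b <- match(seg_b_key, nodes)
  adj_seg <- split(rep(seq_len(nseg), 2L), c(a, b))
  used <- logical(nseg)
  loops <- list()
  for (start in seq_len(nseg)) {
    if (used[start]) next
    used[start] <- TRUE
    loop_nodes <- c(a[start], b[start])
    repeat {
      tail_node <- loop_nodes[length(loop_nodes)]
      nxt <- adj_seg[[as.character(tail_node)]]
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break
      sgm <- nxt[1]
      used[sgm] <- TRUE
      nn <- if (a[sgm] == tail_node) b[sgm] else a[sgm]
      if (nn == loop_nodes[1]) break  # closed
      loop_nodes <- c(loop_nodes, nn)
    }
    if (length(loop_nodes) >= 3)
      loops[[length(loops) + 1L]] <- loop_nodes
  }
  basis <- plane_basis(plane$normal)
  out <- list()
  for (ln in loops) {
    poly <- do.call(rbind, lapply(nodes[ln], function(k) pts[[k]]))
    uv <- cbind(sweep(poly, 2, plane$origin) %*% basis$u,
                sweep(poly, 2, plane$origin) %*% basis$v)
    area2 <- polygon_signed_area(uv)
    if (abs(area2) < 1e-9) next
    if (area2 < 0) poly <- poly[nrow(poly):1, , drop = FALSE]
    out[[length(out) + 1L]] <- poly
  }
  out
}

# Shoelace signed area of 2D polygon (n x 2, not closed).
polygon_signed_area <- function(uv) {
  n <- nrow(uv)
  j <- c(2:n, 1)
  sum(uv[, 1] * uv[j, 2] - uv[j, 1] * uv[, 2]) / 2
}

# Perimeter of a closed 3D polygon (n x 3, not closed).
polygon_perimeter <- function(poly) {
  n <- nrow(poly)
  sum(rownorms(poly[c(2:n, 1), , drop = FALSE] - poly))
}

# Area of a planar 3D polygon via projection onto its plane.
polygon_area3 <- function(poly, normal) {
  basis <- plane_basis(normal)
  uv <- cbind(poly %*% basis$u, poly %*% basis$v)
  abs(polygon_signed_area(uv))
}

# Area centroid of a planar 3D polygon.
polygon_centroid3 <- function(poly, normal) {
  o <- colMeans(poly)
  basis <- plane_basis(normal)
  rel <- sweep(poly, 2, o)
  uv <- cbind(rel %*% basis$u, rel %*% basis$v)
  n <- nrow(uv); j <- c(2:n, 1)
  cr <- uv[, 1] * uv[j, 2] - uv[j, 1] * uv[, 2]
  A <- sum(cr) / 2
  if (abs(A) < 1e-12) return(o)
  cu <- sum((uv[, 1] + uv[j, 1]) * cr) / (6 * A)
  cv <- sum((uv[, 2] + uv[j, 2]) * cr) / (6 * A)
  o + cu * basis$u + cv * basis$v
}

# Even-odd point-in-polygon test in the polygon's own plane.
point_in_polygon3 <- function(point, poly, normal) {
  basis <- plane_basis(normal)
  rel <- sweep(poly, 2, point)
  u <- rel %*% basis$u; w <- rel %*% basis$v
  n <- length(u); j <- c(2:n, 1)
  crossings <- (w > 0) != (w[j] > 0)
  xi <- u[crossings] - w[crossings] *
    (u[j][crossings] - u[crossings]) / (w[j][crossings] - w[crossings])
  (sum(xi > 0) %% 2) == 1
}
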