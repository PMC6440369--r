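#' Voxelize the interior of a closed surface mesh
#'
#' Column-parity voxelization: for every (y, z) grid column the crossings of
#' the column ray with the mesh are computed and interior x-intervals filled.
#' Used by the heat-field solver and as a volume oracle. The grid is offset by
#' an irrational fraction of a voxel so rays never hit triangle edges exactly.
#'
#' @param mesh A closed [surface_mesh()].
#' @param voxel_mm Voxel edge length (mm).
#' @param region Optional function `(points) -> logical` restricting interior
#'   voxels (e.g. to one side of the ostium plane).
#' @return List with `origin`, `voxel_mm`, `dims`, `centers` (k x 3 matrix of
#'   interior voxel centers) and `index` (k x 3 integer grid indices).
#' @export
voxelize_mesh <- function(mesh, voxel_mm = 0.5, region = NULL) {
  v <- mesh$vertices
  lo <- apply(v, 2, min) - 1.5 * voxel_mm
  hi <- apply(v, 2, max) + 1.5 * voxel_mm
  jitter <- voxel_mm * (sqrt(2) - 1.41)   # ~2e-4 * voxel, breaks exact hits
  origin <- lo + jitter
  dims <- pmax(1L, as.integer(ceiling((hi - origin) / voxel_mm)))
  xs <- origin[1] + (seq_len(dims[1]) - 0.5) * voxel_mm
  ys <- origin[2] + (seq_len(dims[2]) - 0.5) * voxel_mm
  zs <- origin[3] + (seq_len(dims[3]) - 0.5) * voxel_mm
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  # per-column crossing lists, keyed by column id iy + (iz-1)*ny
  ny <- dims[2]; nz <- dims[3]
  cross_col <- vector("list", ny * nz)
  for (t in seq_len(nrow(f))) {
    a <- p1[t, ]; b <- p2[t, ]; d <- p3[t, ]
    ylo <- min(a[2], b[2], d[2]); yhi <- max(a[2], b[2], d[2])
    zlo <- min(a[3], b[3], d[3]); zhi <- max(a[3], b[3], d[3])
    iy <- which(ys >= ylo & ys <= yhi)
    iz <- which(zs >= zlo & zs <= zhi)
    if (!length(iy) || !length(iz)) next
    gy <- rep(ys[iy], times = length(iz))
    gz <- rep(zs[iz], each = length(iy))
    # barycentric in the (y, z) projection
    det <- (b[2] - a[2]) * (d[3] - a[3]) - (d[2] - a[2]) * (b[3] - a[3])
    if (abs(det) < 1e-14) next
    l1 <- ((gy - a[2]) * (d[3] - a[3]) - (d[2] - a[2]) * (gz - a[3])) / det
    l2 <- ((b[2] - a[2]) * (gz - a[3]) - (gy - a[2]) * (b[3] - a[3])) / det
    keep <- l1 >= 0 & l2 >= 0 & (l1 + l2) <= 1
    if (!any(keep)) next
    xc <- a[1] + l1[keep] * (b[1] - a[1]) + l2[keep] * (d[1] - a[1])
    cid <- (rep(iz, each = length(iy))[keep] - 1L) * ny +
      rep(iy, times = length(iz))[keep]
    for (m in seq_along(cid)) {
      cross_col[[cid[m]]] <- c(cross_col[[cid[m]]], xc[m])
    }
  }
  idx <- vector("list", ny * nz)
  for (cid in which(lengths(cross_col) > 0)) {
    cr <- sort(cross_col[[cid]])
    if (length(cr) %% 2L != 0L) next      # grazing contact; skip column
    ins <- logical(dims[1])
    for (k in seq(1, length(cr), by = 2)) {
      ins <- ins | (xs > cr[k] & xs < cr[k + 1])
    }
    ii <- which(ins)
    if (length(ii)) {
      iy <- ((cid - 1L) %% ny) + 1L
      iz <- ((cid - 1L) %/% ny) + 1L
      idx[[cid]] <- cbind(ii, iy, iz)
    }
  }
  index <- do.call(rbind, idx)
  if (is.null(index)) index <- matrix(integer(0), 0, 3)
  centers <- cbind(xs[index[, 1]], ys[index[, 2]], zs[index[, 3]])
  if (!is.null(region) && nrow(centers)) {
    keep <- region(centers)
    centers <- centers[keep, , drop = FALSE]
    index <- index[keep, , drop = FALSE]
  }
  list(origin = origin, voxel_mm = voxel_mm, dims = dims,
       centers = centers, index = index)
}

#' Solve the heat-propagation field over the appendage
#'
#' Steady diffusion on an internal voxelization of the appendage region
#' distal to the ostium plane: Dirichlet value 1 on the voxel layer touching
#' the ostium orifice (the plane's intersection contour that contains its
#' origin), homogeneous Neumann on the walls, regularised by a uniform
#' volumetric sink so the field decays with depth (a pure Laplace solve
#' with one Dirichlet face and insulated walls would be constant). On a
#' whole-chamber mesh the distal half-space also clips a cap of the atrial
#' body; only the voxel component reached through the orifice is kept.
#' The sink constant is chosen so the field spans at least three orders of
#' magnitude across the region. The field minimum marks the appendage tip.
#'
#' @param mesh Closed labelled [surface_mesh()] of the anatomy (or of the
#'   appendage alone).
#' @param ostium An [ostium_plane()] with the normal oriented from the
#'   appendage toward the atrial body.
#' @param voxel_mm Voxel size of the internal discretisation (default 0.5).
#' @param decades Target dynamic range of the field in orders of magnitude.
#' @return Object of class `heat_field`: voxel grid, `values` in [0, 1]
#'   (exactly 1 on the ostium layer), `tip` (3D point of the field argmin).
#' @export
solve_heat_field <- function(mesh, ostium, voxel_mm = 0.5, decades = 3) {
  vox <- voxelize_mesh(mesh, voxel_mm, region = function(p)
    as.numeric(plane_signed_distance(p, ostium)) <= 0)
  n <- nrow(vox$centers)
  if (n < 8) stop("appendage region too small to discretise; ",
                  "refine voxel_mm", call. = FALSE)
  # connectivity check + 6-neighbour graph
  key <- function(ijk) paste(ijk[, 1], ijk[, 2], ijk[, 3])
  id <- new.env(parent = emptyenv(), size = n)
  kk <- key(vox$index)
  for (i in seq_len(n)) id[[kk[i]]] <- i
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  nb_i <- integer(0); nb_j <- integer(0)
  for (o in seq_len(6)) {
    sh <- sweep(vox$index, 2, offs[o, ], `+`)
    hit <- vapply(key(sh), function(k) id[[k]] %||% 0L, integer(1),
                  USE.NAMES = FALSE)
    got <- which(hit > 0L)
    nb_i <- c(nb_i, got); nb_j <- c(nb_j, hit[got])
  }
  comp <- connected_components(n, nb_i, nb_j)
  # The appendage region is anchored at the orifice: Dirichlet voxels are
  # near-plane voxels lying laterally inside the ostium contour (the slice
  # component containing the plane origin). On a whole-chamber mesh the
  # distal half-space also clips a cap of the atrial body; those components
  # carry no Dirichlet voxel and are dropped.
  sdist <- as.numeric(plane_signed_distance(vox$centers, ostium))
  near_plane <- sdist >= -voxel_mm
  # the orifice contour is taken one voxel distal of the plane, where the
  # appendage lumen has separated cleanly from the atrial body
  off_origin <- ostium$origin - voxel_mm * ostium$normal
  orifice <- slice_with_plane(mesh, list(origin = off_origin,
                                         normal = ostium$normal))
  holds_origin <- vapply(orifice, function(pg)
    point_in_polygon3(off_origin, pg, ostium$normal), logical(1))
  if (!any(holds_origin))
    stop("the ostium plane origin lies outside every lumen contour; ",
         "check the plane", call. = FALSE)
  contour <- orifice[[which(holds_origin)[1]]]
  # expand the contour by ~3/4 voxel so boundary voxels stay inside
  ctr <- colMeans(contour)
  rmax <- max(sqrt(rowSums(sweep(contour, 2, ctr)^2)))
  contour <- sweep(sweep(contour, 2, ctr) * (1 + 0.75 * voxel_mm / rmax),
                   2, ctr, `+`)
  in_orifice <- near_plane
  in_orifice[near_plane] <- vapply(which(near_plane), function(i)
    point_in_polygon3(vox$centers[i, ], contour, ostium$normal), logical(1))
  if (!any(in_orifice))
    stop("no voxels adjacent to the ostium plane; check plane orientation",
         call. = FALSE)
  anchored <- unique(comp[in_orifice])
  if (length(anchored) > 1L) {
    sizes <- sort(tabulate(comp)[anchored], decreasing = TRUE)
    stop("appendage region is disconnected (component sizes: ",
         paste(sizes, collapse = ", "), ")", call. = FALSE)
  }
  keep <- comp == anchored
  if (!all(keep)) {
    message(sum(!keep), " voxels outside the orifice-anchored region dropped")
    remap <- cumsum(keep)
    sel <- keep[nb_i] & keep[nb_j]
    nb_i <- remap[nb_i[sel]]; nb_j <- remap[nb_j[sel]]
    vox$centers <- vox$centers[keep, , drop = FALSE]
    vox$index <- vox$index[keep, , drop = FALSE]
    sdist <- sdist[keep]
    in_orifice <- in_orifice[keep]
    n <- sum(keep)
  }
  dirichlet <- in_orifice
  depth_extent <- max(-sdist)
  # 1D solution decays like cosh(sqrt(k)(L-s))/cosh(sqrt(k)L) ~ 2 exp(-sqrt(k)L);
  # the log(4) margin keeps the span above `decades` orders of magnitude
  kappa <- ((decades * log(10) + log(4)) / depth_extent)^2
  deg <- tabulate(nb_i, nbins = n)
  free <- which(!dirichlet)
  if (!length(free)) stop("appendage region is all boundary; refine voxel_mm",
                          call. = FALSE)
  ridx <- integer(n); ridx[free] <- seq_along(free)
  sel <- !dirichlet[nb_i] & !dirichlet[nb_j]
  A <- Matrix::sparseMatrix(i = ridx[nb_i[sel]], j = ridx[nb_j[sel]], x = -1,
                            dims = c(length(free), length(free)))
  diagv <- deg[free] + kappa * voxel_mm^2
  A <- A + Matrix::Diagonal(length(free), diagv)
  rhs <- numeric(length(free))
  selb <- !dirichlet[nb_i] & dirichlet[nb_j]
  if (any(selb)) {
    add <- tapply(rep(1, sum(selb)), ridx[nb_i[selb]], sum)
    rhs[as.integer(names(add))] <- add    # Dirichlet value 1 moved to RHS
  }
  u <- rep(1, n)
  sol <- tryCatch(as.numeric(Matrix::solve(A, rhs)),
                  error = function(e) stop(
                    "singular heat system (", conditionMessage(e),
                    "); try a finer voxel_mm", call. = FALSE))
  u[free] <- sol
  u <- pmin(pmax(u / max(u), 0), 1)
  ordmin <- order(u, seq_len(n))[1]       # deterministic tie-break
  # a flat tip (e.g. a capped cylinder) gives a near-degenerate minimum
  # slab; recentre the tip at the barycentre of the near-minimum band
  # Voxels within ~5 mm geodesic depth of the minimum (field decays like
  # exp(-sqrt(kappa) s), so that depth maps to a multiplicative band).
  band <- which(u <= u[ordmin] * exp(sqrt(kappa) * 5))
  # lobe safety: keep only the band's connected component holding the argmin
  inband <- logical(n); inband[band] <- TRUE
  bsel <- inband[nb_i] & inband[nb_j]
  bmap <- integer(n); bmap[band] <- seq_along(band)
  bcomp <- connected_components(length(band), bmap[nb_i[bsel]],
                                bmap[nb_j[bsel]])
  near <- band[bcomp == bcomp[bmap[ordmin]]]
  tip <- colMeans(vox$centers[near, , drop = FALSE])
  structure(list(grid = vox, values = u, tip = tip,
                 ostium = ostium, kappa = kappa),
            class = "heat_field")
}

# Distance along `dir` from `origin` to the first mesh triangle hit
# (Moller-Trumbore); Inf when nothing is hit.
ray_mesh_hit <- function(mesh, origin, dir) {
  v <- mesh$vertices; f <- mesh$faces
  best <- Inf
  for (j in seq_len(nrow(f))) {
    e1 <- v[f[j, 2], ] - v[f[j, 1], ]
    e2 <- v[f[j, 3], ] - v[f[j, 1], ]
    h <- cross3(dir, e2)
    a <- sum(e1 * h)
    if (abs(a) < 1e-12) next
    s <- origin - v[f[j, 1], ]
    u <- sum(s * h) / a
    if (u < 0 || u > 1) next
    q <- cross3(s, e1)
    vv <- sum(dir * q) / a
    if (vv < 0 || u + vv > 1) next
    t <- sum(e2 * q) / a
    if (t > 1e-9 && t < best) best <- t
  }
  best
}

connected_components <- function(n, ei, ej) {
  adj <- split(ej, ei)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- adj[[as.character(x)]]
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  comp
}

#' @export
print.heat_field <- function(x, ...) {
  cat("<heat_field> ", nrow(x$grid$centers), " voxels @ ",
      x$grid$voxel_mm, " mm, range [",
      fmt_num(min(x$values)), ", 1]\n", sep = "")
  invisible(x)
}

#' March the centreline from tip to ostium along the heat-field gradient
#'
#' Starting at the field minimum (the appendage tip), repeatedly steps along
#' the field gradient (ascent toward the ostium) and recentres each point at
#' the area centroid of the local cross-section contour containing it --
#' only that connected slice component is used, so a secondary lobe cannot
#' pull the line sideways. Marching stops when the ostium plane is crossed;
#' the returned polyline is ordered from the ostium (index 1, arc length 0)
#' to the tip.
#'
#' @param field A `heat_field` from [solve_heat_field()].
#' @param mesh The surface mesh the field was solved in (used to recentre).
#' @param step_mm Marching step (default 0.5 mm).
#' @param max_steps Abort threshold (default 10000).
#' @return Object of class `laa_centreline`: `points` (n x 3), unit
#'   `tangents` (pointing tip-ward), strictly increasing `arc_length`, and
#'   the `ostium` plane.
#' @export
march_centreline <- function(field, mesh, step_mm = 0.5, max_steps = 10000L) {
  stopifnot(inherits(field, "heat_field"), step_mm > 0)
  g <- field$grid
  h <- g$voxel_mm
  # fast lookup from grid index to voxel row
  lut <- new.env(parent = emptyenv())
  kk <- paste(g$index[, 1], g$index[, 2], g$index[, 3])
  for (i in seq_len(nrow(g$index))) lut[[kk[i]]] <- i
  val_at <- function(p) {
    ijk0 <- floor((p - g$origin) / h + 0.5)   # lower corner of the cell of centers

    num <- 0; den <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ijk <- ijk0 + c(dx, dy, dz) + c(0L, 0L, 0L)
      row <- lut[[paste(ijk[1], ijk[2], ijk[3])]]
      if (!is.null(row)) {
        w <- 1 / max(vnorm(p - g$centers[row, ]), 1e-9)
        num <- num + w * field$values[row]; den <- den + w
      }
    }
    if (den == 0) NA_real_ else num / den
  }
  grad_at <- function(p) {
    d <- h / 2
    gvec <- numeric(3)
    for (ax in 1:3) {
      e <- c(0, 0, 0); e[ax] <- d
      up <- val_at(p + e); dn <- val_at(p - e)
      if (is.na(up) || is.na(dn)) return(NULL)
      gvec[ax] <- (up - dn) / (2 * d)
    }
    gvec
  }
  recentre <- function(p, dir) {
    polys <- slice_with_plane(mesh, list(origin = p, normal = dir))
    if (!length(polys)) return(p)
    containing <- which(vapply(polys, function(pg)
      point_in_polygon3(p, pg, dir), logical(1)))
    pick <- if (length(containing)) containing[1] else
      which.min(vapply(polys, function(pg)
        vnorm(colMeans(pg) - p), numeric(1)))
    polygon_centroid3(polys[[pick]], dir)
  }
  p <- field$tip
  pts <- list(p)
  dir_prev <- NULL
  crossed <- FALSE
  for (it in seq_len(max_steps)) {
    gvec <- grad_at(p)
    if (is.null(gvec) || vnorm(gvec) < 1e-12) {
      if (is.null(dir_prev)) {
        # flat minimum at the tip: head for the best neighbouring voxel
        d2 <- rowSums(sweep(g$centers, 2, p)^2)
        near <- which(d2 < (3 * h)^2 & d2 > 1e-12)
        if (!length(near)) stop("marching exited the field at (",
                                paste(fmt_num(p), collapse = ", "), ")",
                                call. = FALSE)
        best <- near[which.max(field$values[near])]
        dirn <- normalize(g$centers[best, ] - p)
      } else dirn <- dir_prev
    } else dirn <- normalize(gvec)
    if (!is.null(dir_prev)) {
      if (sum(dirn * dir_prev) < 0) dirn <- dir_prev
      else dirn <- normalize(0.5 * dirn + 0.5 * dir_prev)  # damp jitter
    }
    p_raw <- p + step_mm * dirn
    p_next <- recentre(p_raw, dirn)
    # recentring is a lateral correction; a large jump means the slice ran
    # through a cap or junction -- fall back to the raw step
    if (vnorm(p_next - p_raw) > 1.5 * step_mm) p_next <- p_raw
    sd <- as.numeric(plane_signed_distance(p_next, field$ostium))
    if (sd >= 0) {
      # exact crossing of the ostium plane along the last segment
      sd0 <- as.numeric(plane_signed_distance(p, field$ostium))
      t <- if (abs(sd - sd0) < 1e-12) 0 else -sd0 / (sd - sd0)
      pts[[length(pts) + 1L]] <- p + t * (p_next - p)
      crossed <- TRUE
      break
    }
    if (vnorm(p_next - p) < 1e-9) {
      p_next <- p + step_mm * dirn   # recentring stalled; take the raw step
    }
    pts[[length(pts) + 1L]] <- p_next
    dir_prev <- normalize(p_next - p + 1e-12 * dirn)
    p <- p_next
  }
  if (!crossed)
    stop("centreline marching did not reach the ostium within ",
         max_steps, " steps", call. = FALSE)
  # the raw seed (field-argmin barycentre) is biased toward the outer rim
  # on curved tips; replace it with the wall point hit by the local tangent
  if (length(pts) >= 3) {
    dir_tip <- pts[[2]] - pts[[3]]
    if (vnorm(dir_tip) > 1e-9) {
      t_hit <- ray_mesh_hit(mesh, pts[[2]], normalize(dir_tip))
      if (is.finite(t_hit) && t_hit > 1e-6)
        pts[[1]] <- pts[[2]] + t_hit * normalize(dir_tip)
    }
  }
  pmat <- do.call(rbind, rev(pts))       # index 1 at the ostium
  # drop consecutive duplicates
  keep <- c(TRUE, rownorms(diff(pmat)) > 1e-9)
  pmat <- pmat[keep, , drop = FALSE]
  # two passes of 3-point averaging on interior points: removes recentring
  # jitter (which inflates arc length) without moving the endpoints
  for (pass in 1:2) {
    n <- nrow(pmat)
    if (n < 5) break
    mid <- (pmat[1:(n - 2), ] + pmat[2:(n - 1), ] + pmat[3:n, ]) / 3
    pmat[2:(n - 1), ] <- mid
  }
  seg <- diff(pmat)
  arc <- c(0, cumsum(rownorms(seg)))
  tangents <- rbind(seg, seg[nrow(seg), , drop = FALSE])
  mid <- (rbind(seg[1, , drop = FALSE], seg) +
            rbind(seg, seg[nrow(seg), , drop = FALSE])) / 2
  tangents <- mid / rownorms(mid)
  structure(list(points = pmat, tangents = tangents, arc_length = arc,
                 ostium = field$ostium),
            class = "laa_centreline")
}

#' Extract the appendage centreline in one call
#'
#' Convenience wrapper: [solve_heat_field()] then [march_centreline()].
#'
#' @inheritParams solve_heat_field
#' @inheritParams march_centreline
#' @return An `laa_centreline`.
#' @export
extract_centreline <- function(mesh, ostium, voxel_mm = 0.5, step_mm = 0.5,
                               max_steps = 10000L) {
  field <- solve_heat_field(mesh, ostium, voxel_mm = voxel_mm)
  march_centreline(field, mesh, step_mm = step_mm, max_steps = max_steps)
}

#' @export
print.laa_centreline <- function(x, ...) {
  cat(sprintf("<laa_centreline> %d points, length %.2f mm (ostium -> tip)\n",
              nrow(x$points), max(x$arc_length)))
  invisible(x)
}

#' Point and tangent at a geodesic distance along the centreline
#'
#' @param cl An `laa_centreline`.
#' @param d Geodesic distance from the ostium in mm, within
#'   `[0, max(cl$arc_length)]`.
#' @return List with `point` (length-3) and unit `tangent`.
#' @export
point_at_geodesic_distance <- function(cl, d) {
  smax <- max(cl$arc_length)
  if (d < 0 || d > smax)
    stop(sprintf("distance %.3f mm outside centreline range [0, %.3f]",
                 d, smax), call. = FALSE)
  i <- findInterval(d, cl$arc_length, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(cl$points) - 1L)
  s0 <- cl$arc_length[i]; s1 <- cl$arc_length[i + 1]
  t <- if (s1 > s0) (d - s0) / (s1 - s0) else 0
  pt <- cl$points[i, ] + t * (cl$points[i + 1, ] - cl$points[i, ])
  tg <- normalize((1 - t) * cl$tangents[i, ] + t * cl$tangents[i + 1, ])
  list(point = as.numeric(pt), tangent = tg)
}

#' Write a centreline to disk
#'
#' Either a VTK legacy polyline with `arc_length` point-data, or a
#' plain-text 4-column table `x y z s`.
#'
#' @param cl An `laa_centreline`.
#' @param path Output path.
#' @param format `"vtk"` or `"table"` (default from extension: `.vtk` ->
#'   vtk, otherwise table).
#' @return `path`, invisibly.
#' @export
write_centreline <- function(cl, path, format = NULL) {
  fmt <- format %||% (if (tolower(tools::file_ext(path)) == "vtk") "vtk"
                      else "table")
  n <- nrow(cl$points)
  if (fmt == "vtk") {
    lines <- c("# vtk DataFile Version 3.0", "laaoplan centreline", "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", n, "float"),
               apply(cl$points, 1, function(r) paste(fmt_num(r), collapse = " ")),
               paste("LINES 1", n + 1),
               paste(c(n, 0:(n - 1)), collapse = " "),
               paste("POINT_DATA", n),
               "SCALARS arc_length float 1", "LOOKUP_TABLE default",
               fmt_num(cl$arc_length))
    writeLines(lines, path)
  } else {
    writeLines(c("x y z s",
                 paste(fmt_num(cl$points[, 1]), fmt_num(cl$points[, 2]),
                       fmt_num(cl$points[, 3]), fmt_num(cl$arc_length))),
               path)
  }
  invisible(path)
}
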