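# Implicit-surface synthetic anatomy: signed-distance fields for the atrial
# body, vessels and appendage, meshed watertight by marching tetrahedra
# (Kuhn 6-tet cube subdivision -- no ambiguous cases, shared edge vertices,
# hence closed by construction).

# Approximate ellipsoid signed distance (Quilez scaling bound).
sdf_ellipsoid <- function(p, center, radii) {
  q <- sweep(p, 2, center)
  k0 <- sqrt(rowSums(sweep(q, 2, radii, `/`)^2))
  k1 <- sqrt(rowSums(sweep(q, 2, radii^2, `/`)^2))
  ifelse(k1 > 0, k0 * (k0 - 1) / k1, -min(radii))
}

# Capped cylinder from a to b, radius r (exact).
sdf_cylinder <- function(p, a, b, r) {
  ba <- b - a
  h <- vnorm(ba)
  u <- ba / h
  q <- sweep(p, 2, a)
  x <- q %*% u
  rad <- sqrt(pmax(rowSums(q^2) - as.numeric(x)^2, 0))
  dx <- rad - r
  dy <- pmax(abs(x - h / 2) - h / 2, 0)
  dxc <- pmax(dx, 0)
  sqrt(dxc^2 + dy^2) + pmin(pmax(dx, abs(x - h / 2) - h / 2), 0)
}

# Tube of varying radius along a polyline: distance to the path minus the
# local radius (radius indexed by nearest-point arc length).
sdf_polytube <- function(p, path, radii) {
  n <- nrow(path)
  best <- rep(Inf, nrow(p))
  best_r <- rep(radii[1], nrow(p))
  for (i in seq_len(n - 1)) {
    a <- path[i, ]; b <- path[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    q <- sweep(p, 2, a)
    t <- pmin(pmax((q %*% ab) / len2, 0), 1)
    diff <- q - outer(as.numeric(t), ab)
    d <- sqrt(rowSums(diff^2))
    r_here <- radii[i] + as.numeric(t) * (radii[i + 1] - radii[i])
    upd <- d - r_here < best - best_r   # compare surface distances
    best[upd] <- d[upd]
    best_r[upd] <- r_here[upd]
  }
  best - best_r
}

# Marching tetrahedra over a regular grid. f: vectorised implicit function
# (negative inside). Returns a watertight surface_mesh.
march_tetrahedra <- function(f, lower, upper, h) {
  nx <- as.integer(ceiling((upper[1] - lower[1]) / h)) + 1L
  ny <- as.integer(ceiling((upper[2] - lower[2]) / h)) + 1L
  nz <- as.integer(ceiling((upper[3] - lower[3]) / h)) + 1L
  xs <- lower[1] + (0:(nx - 1)) * h
  ys <- lower[2] + (0:(ny - 1)) * h
  zs <- lower[3] + (0:(nz - 1)) * h
  pts <- cbind(rep(xs, times = ny * nz),
               rep(rep(ys, each = nx), times = nz),
               rep(zs, each = nx * ny))
  vals <- as.numeric(f(pts))
  vals[vals == 0] <- 1e-12
  nid <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  # Kuhn subdivision: each tet is a monotone lattice path 000 -> 111
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  tet_offsets <- lapply(perms, function(pm) {
    o <- matrix(0L, 4, 3)
    for (s in 1:3) { o[s + 1, ] <- o[s, ]; o[s + 1, pm[s]] <- 1L }
    o
  })
  ci <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  cj <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  ck <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  vkey <- new.env(parent = emptyenv())
  verts <- list(); nvert <- 0L
  tris <- list()
  edge_vertex <- function(g1, g2) {
    if (g1 > g2) { tmp <- g1; g1 <- g2; g2 <- tmp }
    key <- paste(g1, g2)
    idx <- vkey[[key]]
    if (is.null(idx)) {
      f1 <- vals[g1]; f2 <- vals[g2]
      t <- f1 / (f1 - f2)
      p1 <- pts[g1, ]; p2 <- pts[g2, ]
      nvert <<- nvert + 1L
      verts[[nvert]] <<- p1 + t * (p2 - p1)
      vkey[[key]] <- nvert
      idx <- nvert
    }
    idx
  }
  emit <- function(v1, v2, v3, inside_pt) {
    a <- verts[[v1]]; b <- verts[[v2]]; d <- verts[[v3]]
    n <- cross3(b - a, d - a)
    ctr <- (a + b + d) / 3
    if (sum(n * (ctr - inside_pt)) < 0) {
      tris[[length(tris) + 1L]] <<- c(v1, v3, v2)
    } else tris[[length(tris) + 1L]] <<- c(v1, v2, v3)
  }
  for (to in tet_offsets) {
    g <- cbind(nid(ci + to[1, 1], cj + to[1, 2], ck + to[1, 3]),
               nid(ci + to[2, 1], cj + to[2, 2], ck + to[2, 3]),
               nid(ci + to[3, 1], cj + to[3, 2], ck + to[3, 3]),
               nid(ci + to[4, 1], cj + to[4, 2], ck + to[4, 3]))
    ins <- matrix(vals[g] < 0, ncol = 4)
    ninside <- rowSums(ins)
    act <- which(ninside > 0L & ninside < 4L)
    for (row in act) {
      gg <- g[row, ]
      ii <- ins[row, ]
      inn <- gg[ii]; out <- gg[!ii]
      if (length(inn) == 1L) {
        ip <- pts[inn, ]
        e <- vapply(out, function(o) edge_vertex(inn, o), integer(1))
        emit(e[1], e[2], e[3], ip)
      } else if (length(inn) == 3L) {
        ip <- colMeans(pts[inn, , drop = FALSE])
        e <- vapply(inn, function(i) edge_vertex(i, out), integer(1))
        emit(e[1], e[2], e[3], ip)
      } else {
        ip <- colMeans(pts[inn, , drop = FALSE])
        eAC <- edge_vertex(inn[1], out[1])
        eAD <- edge_vertex(inn[1], out[2])
        eBC <- edge_vertex(inn[2], out[1])
        eBD <- edge_vertex(inn[2], out[2])
        emit(eAC, eAD, eBD, ip)
        emit(eAC, eBD, eBC, ip)
      }
    }
  }
  surface_mesh(do.call(rbind, verts), do.call(rbind, tris))
}

#' Generate a synthetic left atrium with appendage
#'
#' Parametric whole-chamber anatomy meshed from an implicit union: an
#' ellipsoidal atrial body, four pulmonary-vein inlet cylinders, one
#' mitral-valve outlet cylinder, and a tubular appendage built from an
#' [laa_spec()] (taper, bend, neck, optional extra lobes), attached at a
#' configurable angle. Faces are labelled (`pv_inlet` caps, `mv_outlet`
#' cap, an `ostium` band at the junction plane, `wall` elsewhere) and
#' analytic ground truth is attached: the true appendage centreline with
#' per-station diameters, and the ostium plane. Generation is fully
#' deterministic for a given spec.
#'
#' @param spec An [laa_spec()].
#' @param body_radii Ellipsoid half-axes of the atrial body (mm).
#' @param laa_direction Unit attachment direction of the appendage.
#' @param mesh_h Marching-tetrahedra grid step (mm; default
#'   `spec$edge_length_mm`).
#' @return Labelled watertight [surface_mesh()] with attribute
#'   `ground_truth` (`centreline`, `arc_length`, `diameter`, `ostium`,
#'   `spec`).
#' @export
make_la_with_laa <- function(spec = laa_spec(),
                             body_radii = c(30, 25, 22),
                             laa_direction = c(0.35, -0.7, 0.62),
                             mesh_h = NULL) {
  h <- mesh_h %||% spec$edge_length_mm
  dir_laa <- normalize(laa_direction)
  center <- c(0, 0, 0)
  # vessels: 4 PV inlets posterior, 1 MV outlet inferior
  pv_dirs <- lapply(list(c(0.75, 0.55, 0.37), c(0.75, 0.55, -0.37),
                         c(0.75, -0.2, 0.62), c(0.62, -0.62, -0.48)),
                    normalize)
  pv_r <- 6; pv_len <- 16
  mv_dir <- normalize(c(-0.25, 0.2, -0.95)); mv_r <- 12.5; mv_len <- 10
  surf_pt <- function(d) d / sqrt(sum((d / body_radii)^2))
  vessels <- lapply(pv_dirs, function(d) {
    s <- surf_pt(d)
    list(a = s - 4 * d, b = s + pv_len * d, r = pv_r, label = "pv_inlet",
         dir = d, cap = s + pv_len * d)
  })
  mv_s <- surf_pt(mv_dir)
  vessels[[5]] <- list(a = mv_s - 4 * mv_dir, b = mv_s + mv_len * mv_dir,
                       r = mv_r, label = "mv_outlet", dir = mv_dir,
                       cap = mv_s + mv_len * mv_dir)
  # appendage path: local laa_spec path rotated onto the attachment axis
  R <- rotation_between(c(0, 0, 1), dir_laa)
  ost_origin <- surf_pt(dir_laa)
  local_path <- laa_path(spec, 81L)
  s_local <- c(0, cumsum(rownorms(diff(local_path))))
  world_path <- sweep(local_path %*% t(R), 2, ost_origin, `+`)
  r_main <- laa_radius_profile(spec, s_local)
  # extend the tube proximally into the body for a clean junction
  pre <- sweep(outer(c(-6, -3), dir_laa), 2, ost_origin, `+`)
  tube_path <- rbind(pre, world_path)
  tube_r <- c(r_main[1], r_main[1], r_main)
  lobes <- lapply(spec$lobes, function(lb) {
    i0 <- which.min(abs(s_local - lb$station_mm))
    base <- world_path[i0, ]
    dir0 <- normalize(world_path[min(i0 + 1, nrow(world_path)), ] -
                        world_path[max(i0 - 1, 1), ])
    ang <- lb$angle_deg * pi / 180
    ortho <- plane_basis(dir0)$u
    ldir <- normalize(cos(ang) * dir0 + sin(ang) * ortho)
    list(path = rbind(base - 2 * ldir,
                      base + outer(seq(0, lb$length_mm, length.out = 17),
                                   ldir)),
         r = rep(lb$diameter_mm / 2, 18))
  })
  fimp <- function(p) {
    d <- sdf_ellipsoid(p, center, body_radii)
    for (vs in vessels) d <- pmin(d, sdf_cylinder(p, vs$a, vs$b, vs$r))
    d <- pmin(d, sdf_polytube(p, tube_path, tube_r))
    for (lb in lobes) d <- pmin(d, sdf_polytube(p, lb$path, lb$r))
    d
  }
  allpts <- rbind(sweep(rbind(diag(3), -diag(3)), 2, body_radii * 1.05, `*`),
                  do.call(rbind, lapply(vessels, function(v) v$b)),
                  world_path,
                  do.call(rbind, lapply(lobes, function(l) l$path)))
  lower <- apply(allpts, 2, min) - max(pv_r, mv_r, r_main) - 3 * h
  upper <- apply(allpts, 2, max) + max(pv_r, mv_r, r_main) + 3 * h
  mesh <- march_tetrahedra(fimp, lower, upper, h)
  if (!is_watertight(mesh))
    stop("synthetic anatomy generation produced a non-watertight surface ",
         "(spec primitives may collide degenerately); adjust the spec",
         call. = FALSE)
  # labels
  ost_plane <- ostium_plane(ost_origin, -dir_laa)
  ctr <- face_centroids(mesh)
  lab <- rep(0L, nrow(mesh$faces))
  lc <- label_codes()
  for (vs in vessels) {
    proj <- sweep(ctr, 2, vs$cap) %*% vs$dir
    radial2 <- rowSums(sweep(ctr, 2, vs$cap)^2) - as.numeric(proj)^2
    hit <- abs(proj) < 0.75 * h & radial2 < (vs$r * 1.02)^2
    lab[hit] <- lc[[vs$label]]
  }
  sd_ost <- abs(as.numeric(plane_signed_distance(ctr, ost_plane)))
  lateral2 <- rowSums(sweep(ctr, 2, ost_origin)^2) - sd_ost^2
  near_ost <- sd_ost < 0.9 * h & lateral2 < (r_main[1] * 1.15)^2
  lab[near_ost & lab == 0L] <- lc[["ostium"]]
  mesh$face_labels <- lab
  n_pv <- sum(lab == lc[["pv_inlet"]]); n_mv <- sum(lab == lc[["mv_outlet"]])
  if (n_pv == 0 || n_mv == 0 || !any(lab == lc[["ostium"]]))
    stop("labelling failed (pv: ", n_pv, ", mv: ", n_mv,
         "); refine edge_length_mm", call. = FALSE)
  # the implicit tube ends in a spherical cap one radius beyond the path:
  # the true centreline continues to the cap apex
  end_dir <- normalize(world_path[nrow(world_path), ] -
                         world_path[nrow(world_path) - 1, ])
  r_end <- r_main[length(r_main)]
  apex <- world_path[nrow(world_path), ] + r_end * end_dir
  attr(mesh, "ground_truth") <- list(
    centreline = rbind(world_path, apex),
    arc_length = c(s_local, max(s_local) + r_end),
    diameter = c(2 * r_main, 0),
    ostium = ost_plane, spec = spec,
    pv_caps = lapply(vessels[1:4], function(v) v$cap),
    mv_cap = vessels[[5]]$cap)
  mesh
}

#' Count of labelled inlet/outlet patches
#'
#' Edge-connected components of the faces carrying a given label -- e.g. 4
#' `pv_inlet` patches and 1 `mv_outlet` patch on the default synthetic
#' anatomy.
#'
#' @param mesh Labelled [surface_mesh()].
#' @param label Label name (see [label_codes()]).
#' @return Integer patch count.
#' @export
count_label_patches <- function(mesh, label) {
  sel <- mesh$face_labels == label_codes()[[label]]
  if (!any(sel)) return(0L)
  patch <- subset_faces(mesh, sel)
  f <- patch$faces
  nf <- nrow(f)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- rbind(data.frame(k = ekey(f[, 1], f[, 2]), f = seq_len(nf)),
                 data.frame(k = ekey(f[, 2], f[, 3]), f = seq_len(nf)),
                 data.frame(k = ekey(f[, 3], f[, 1]), f = seq_len(nf)))
  sp <- split(edges$f, edges$k)
  ei <- integer(0); ej <- integer(0)
  for (v in sp) if (length(v) == 2L) { ei <- c(ei, v[1]); ej <- c(ej, v[2]) }
  comp <- connected_components(nf, c(ei, ej), c(ej, ei))
  max(comp)
}
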