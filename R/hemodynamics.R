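#' Wall-shear-stress time series
#'
#' Per-node wall-shear-stress vectors over one cardiac cycle, as produced by
#' an external flow solver and re-imported for post-processing.
#'
#' @param mesh Wall [surface_mesh()] whose vertices are the WSS nodes.
#' @param times Strictly increasing sample times (s) spanning one cycle
#'   (at least 3 samples).
#' @param vectors Numeric array `n_nodes x n_times x 3`, Pa.
#' @return Object of class `wss_series`.
#' @export
wss_series <- function(mesh, times, vectors) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (length(times) < 3) stop("need at least 3 time samples", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  vectors <- as.array(vectors)
  if (length(dim(vectors)) != 3 ||
      dim(vectors)[1] != nrow(mesh$vertices) ||
      dim(vectors)[2] != length(times) || dim(vectors)[3] != 3)
    stop("vectors must be an n_nodes x n_times x 3 array", call. = FALSE)
  structure(list(mesh = mesh, times = as.numeric(times), vectors = vectors),
            class = "wss_series")
}

#' @export
print.wss_series <- function(x, ...) {
  cat(sprintf("<wss_series> %d nodes x %d times over [%g, %g] s\n",
              dim(x$vectors)[1], dim(x$vectors)[2],
              min(x$times), max(x$times)))
  invisible(x)
}

#' Read a WSS time series from a long-format CSV
#'
#' Expected columns: `node_id` (1-based), `t`, `tau_x`, `tau_y`, `tau_z`.
#'
#' @param path CSV path.
#' @param mesh Wall mesh whose vertex count matches the node ids.
#' @return A [wss_series()].
#' @export
read_wss_csv <- function(path, mesh) {
  df <- utils::read.csv(path)
  need <- c("node_id", "t", "tau_x", "tau_y", "tau_z")
  if (!all(need %in% names(df)))
    stop("WSS CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  times <- sort(unique(df$t))
  n <- nrow(mesh$vertices)
  arr <- array(NA_real_, c(n, length(times), 3))
  ti <- match(df$t, times)
  arr[cbind(df$node_id, ti, 1L)] <- df$tau_x
  arr[cbind(df$node_id, ti, 2L)] <- df$tau_y
  arr[cbind(df$node_id, ti, 3L)] <- df$tau_z
  if (any(is.na(arr)))
    stop("WSS CSV does not cover every node at every time", call. = FALSE)
  wss_series(mesh, times, arr)
}

trapz_weights <- function(times) {
  n <- length(times)
  dt <- diff(times)
  w <- numeric(n)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dt[-(n - 1)] + dt[-1]) / 2
  w
}

#' Thrombus-risk indices from a WSS time series
#'
#' Computes, per wall node, over one cycle of length `T` (trapezoidal rule
#' on the given sampling):
#' \deqn{TAWSS = \frac{1}{T}\int_0^T |\tau_w|\,dt, \qquad
#'       OSI = \frac{1}{2}\Big(1 -
#'         \frac{|\int_0^T \tau_w\,dt|}{\int_0^T |\tau_w|\,dt}\Big), \qquad
#'       ECAP = \frac{OSI}{TAWSS}.}
#' Low TAWSS (slow flow) combined with high OSI (oscillatory, complex flow)
#' yields high ECAP -- the signature of thrombus-prone regions. Nodes where
#' the shear magnitude integral vanishes get OSI 0 and are flagged invalid
#' for ECAP (rather than infinite).
#'
#' @param wss A [wss_series()].
#' @return Object of class `hemo_index_field`: the wall mesh plus a tibble
#'   `data` with `node`, `tawss_pa`, `osi`, `ecap_inv_pa`, `node_area_mm2`,
#'   `valid`.
#' @export
compute_indices <- function(wss) {
  stopifnot(inherits(wss, "wss_series"))
  times <- wss$times
  T_cycle <- max(times) - min(times)
  w <- trapz_weights(times)
  mag <- sqrt(wss$vectors[, , 1]^2 + wss$vectors[, , 2]^2 +
                wss$vectors[, , 3]^2)
  int_mag <- as.numeric(mag %*% w)
  int_vec <- vapply(1:3, function(k) as.numeric(wss$vectors[, , k] %*% w),
                    numeric(dim(wss$vectors)[1]))
  mag_int_vec <- sqrt(rowSums(int_vec^2))
  tawss <- int_mag / T_cycle
  osi <- ifelse(int_mag > 0, 0.5 * (1 - mag_int_vec / int_mag), 0)
  osi <- pmin(pmax(osi, 0), 0.5)
  valid <- tawss > 0
  ecap <- ifelse(valid, osi / tawss, NA_real_)
  structure(list(
    mesh = wss$mesh,
    data = tibble::tibble(
      node = seq_len(nrow(wss$mesh$vertices)),
      tawss_pa = tawss, osi = osi, ecap_inv_pa = ecap,
      node_area_mm2 = node_areas(wss$mesh), valid = valid)),
    class = "hemo_index_field")
}

#' @export
print.hemo_index_field <- function(x, ...) {
  cat(sprintf(paste0("<hemo_index_field> %d nodes (%d valid): TAWSS ",
                     "%.3g-%.3g Pa, OSI %.3g-%.3g\n"),
              nrow(x$data), sum(x$data$valid),
              min(x$data$tawss_pa), max(x$data$tawss_pa),
              min(x$data$osi), max(x$data$osi)))
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy hemo_index_field
#' @export
tidy.hemo_index_field <- function(x, ...) x$data

#' @importFrom generics glance
#' @method glance hemo_index_field
#' @export
glance.hemo_index_field <- function(x, ...) {
  d <- x$data
  w <- d$node_area_mm2
  ok <- d$valid
  tibble::tibble(
    n_nodes = nrow(d),
    n_valid = sum(ok),
    invalid_fraction = 1 - mean(ok),
    mean_tawss_pa = sum(d$tawss_pa * w) / sum(w),
    mean_osi = sum(d$osi * w) / sum(w),
    mean_ecap_inv_pa = sum(d$ecap_inv_pa[ok] * w[ok]) / sum(w[ok]),
    pct_area_ecap_gt3 = 100 * sum(w[ok & d$ecap_inv_pa > 3]) / sum(w[ok]))
}

#' Region of interest between the ostium and the device
#'
#' Thrombi that matter clinically form outside the occluder, in the pocket
#' between the device's proximal face and the ostium. This mask selects
#' wall nodes on the appendage side of the ostium plane whose geodesic
#' projection onto the centreline lies between 0 and the device's proximal
#' station; device-labelled nodes are excluded. Without a configuration
#' (device-free scenario) the whole appendage distal to the ostium is the
#' region of interest.
#'
#' @param field A `hemo_index_field` computed on the (implanted) wall.
#' @param ostium An [ostium_plane()].
#' @param cfg A `device_configuration`, or `NULL` for the device-free case.
#' @param cl An `laa_centreline`.
#' @return Logical mask over field nodes.
#' @export
roi_between_ostium_and_device <- function(field, ostium, cfg, cl) {
  stopifnot(inherits(field, "hemo_index_field"))
  mesh <- field$mesh
  v <- mesh$vertices
  distal <- as.numeric(plane_signed_distance(v, ostium)) <= 0
  # geodesic projection: arc length of the nearest centreline vertex
  proj_s <- vapply(seq_len(nrow(v)), function(i) {
    d2 <- rowSums(sweep(cl$points, 2, v[i, ])^2)
    cl$arc_length[which.min(d2)]
  }, numeric(1))
  s_max <- if (is.null(cfg)) max(cl$arc_length) else cfg$pose$depth
  mask <- distal & proj_s >= 0 & proj_s <= s_max
  dev_nodes <- unique(as.vector(
    mesh$faces[mesh$face_labels == label_codes()[["device"]], ]))
  if (length(dev_nodes)) mask[dev_nodes] <- FALSE
  mask
}

#' ECAP histogram over a region of interest
#'
#' Percentage of the region falling in each ECAP interval, weighted by
#' lumped node surface area (default, the physically meaningful weighting)
#' or by node count. The default bin edges `[0, 0.5, 1, 2, 3, Inf)` make
#' the "ECAP above 3" high-risk summary a single bin. Invalid nodes are
#' excluded; their count is attached as attribute `n_invalid`.
#'
#' @param field A `hemo_index_field`.
#' @param mask Logical node mask (e.g. from
#'   [roi_between_ostium_and_device()]); default: all nodes.
#' @param bin_edges Increasing edges; the final bin is open-ended.
#' @param weighting `"surface_area"` (default) or `"node_count"`.
#' @return Tibble of class `ecap_histogram` with `bin_lo`, `bin_hi`, `pct`.
#' @export
ecap_histogram <- function(field, mask = NULL,
                           bin_edges = c(0, 0.5, 1, 2, 3, Inf),
                           weighting = c("surface_area", "node_count")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(field, "hemo_index_field"))
  d <- field$data
  mask <- mask %||% rep(TRUE, nrow(d))
  if (!any(mask)) stop("empty region-of-interest mask", call. = FALSE)
  sel <- mask & d$valid
  n_invalid <- sum(mask & !d$valid)
  if (!any(sel)) stop("no valid ECAP values inside the mask", call. = FALSE)
  if (is.finite(bin_edges[length(bin_edges)]))
    bin_edges <- c(bin_edges, Inf)
  x <- d$ecap_inv_pa[sel]
  w <- if (weighting == "surface_area") d$node_area_mm2[sel]
       else rep(1, sum(sel))
  bin <- findInterval(x, bin_edges, rightmost.closed = FALSE)
  bin[bin < 1] <- 1L
  nb <- length(bin_edges) - 1L
  pct <- vapply(seq_len(nb), function(b) sum(w[bin == b]), numeric(1))
  pct <- 100 * pct / sum(w)
  out <- tibble::tibble(bin_lo = bin_edges[-length(bin_edges)],
                        bin_hi = bin_edges[-1], pct = pct)
  class(out) <- c("ecap_histogram", class(out))
  attr(out, "weighting") <- weighting
  attr(out, "n_invalid") <- n_invalid
  out
}

#' Percentage of ROI area above an ECAP threshold
#'
#' @param hist An [ecap_histogram()].
#' @param threshold Threshold that must coincide with a bin edge
#'   (default 3).
#' @return Percentage (scalar).
#' @export
pct_above_ecap <- function(hist, threshold = 3) {
  if (!any(hist$bin_lo == threshold))
    stop("threshold ", threshold, " is not a bin edge of this histogram",
         call. = FALSE)
  sum(hist$pct[hist$bin_lo >= threshold])
}

#' Blood-velocity probe outside the device
#'
#' Samples the flow at a single point placed on the centreline direction,
#' `offset` mm from the ostium centroid toward the main atrial cavity (the
#' reversed centreline tangent) -- a 1D summary of whether a configuration
#' keeps flow moving in front of the occluder.
#'
#' @param flow Either a function `f(points, t)` returning an n x 3 velocity
#'   matrix (m/s), or a sampled field: list with `points` (n x 3), `times`,
#'   `velocities` (n x n_times x 3); nearest-point interpolation is used.
#' @param cl An `laa_centreline`.
#' @param ostium An [ostium_plane()].
#' @param offset_mm Displacement into the atrial body (default 5).
#' @param times Sample times (required for functional `flow`).
#' @return Tibble of class `velocity_probe` with `time_s`, `speed_m_s`;
#'   probe location in attribute `location`.
#' @export
probe_velocity <- function(flow, cl, ostium, offset_mm = 5, times = NULL) {
  at0 <- point_at_geodesic_distance(cl, 0)
  loc <- at0$point - offset_mm * at0$tangent
  if (is.function(flow)) {
    if (is.null(times)) stop("times required for a functional flow field",
                             call. = FALSE)
    speed <- vapply(times, function(t)
      vnorm(as.numeric(flow(matrix(loc, 1, 3), t))), numeric(1))
  } else {
    stopifnot(all(c("points", "times", "velocities") %in% names(flow)))
    d2 <- rowSums(sweep(flow$points, 2, loc)^2)
    if (min(d2) > 25)
      stop("probe point is more than 5 mm from every flow sample ",
           "(outside the domain?)", call. = FALSE)
    i <- which.min(d2)
    times <- flow$times
    speed <- sqrt(flow$velocities[i, , 1]^2 + flow$velocities[i, , 2]^2 +
                    flow$velocities[i, , 3]^2)
  }
  out <- tibble::tibble(time_s = times, speed_m_s = speed)
  class(out) <- c("velocity_probe", class(out))
  attr(out, "location") <- loc
  out
}

#' Write per-scenario risk maps, histograms, probes and a ranking summary
#'
#' For each scenario: a VTP surface with point-data arrays `TAWSS_Pa`,
#' `OSI`, `ECAP_invPa`; a histogram CSV; optionally a probe CSV. A single
#' `summary.csv` ranks scenarios by the percentage of region-of-interest
#' area with ECAP above 3 (ascending: safest first). All files use fixed
#' numeric formatting, so regeneration from identical inputs is
#' byte-identical.
#'
#' @param fields Named list of `hemo_index_field`, one per scenario.
#' @param histograms Named list of [ecap_histogram()] (same names).
#' @param probes Optional named list of [probe_velocity()] tibbles.
#' @param out_dir Output directory.
#' @return The summary tibble (`scenario`, `pct_ecap_gt3`, `rank`),
#'   invisibly.
#' @export
render_report <- function(fields, histograms, probes = NULL, out_dir) {
  stopifnot(length(fields) >= 1, !is.null(names(fields)),
            identical(sort(names(fields)), sort(names(histograms))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(fields)) {
    fl <- fields[[nm]]
    d <- fl$data
    ec <- ifelse(is.na(d$ecap_inv_pa), -1, d$ecap_inv_pa)  # -1 marks invalid
    write_vtk_xml(fl$mesh, file.path(out_dir, paste0(nm, ".vtp")), "vtp",
                  point_data = list(TAWSS_Pa = d$tawss_pa, OSI = d$osi,
                                    ECAP_invPa = ec))
    h <- histograms[[nm]]
    writeLines(c("bin_lo,bin_hi,pct",
                 paste(fmt_num(h$bin_lo), fmt_num(h$bin_hi), fmt_num(h$pct),
                       sep = ",")),
               file.path(out_dir, paste0(nm, "_ecap_histogram.csv")))
    if (!is.null(probes) && nm %in% names(probes)) {
      pr <- probes[[nm]]
      writeLines(c("time_s,speed_m_s",
                   paste(fmt_num(pr$time_s), fmt_num(pr$speed_m_s), sep = ",")),
                 file.path(out_dir, paste0(nm, "_probe.csv")))
    }
  }
  pct <- vapply(names(fields), function(nm)
    pct_above_ecap(histograms[[nm]]), numeric(1))
  ord <- order(pct, names(fields))
  summary <- tibble::tibble(scenario = names(fields)[ord],
                            pct_ecap_gt3 = unname(pct[ord]),
                            rank = seq_along(ord))
  writeLines(c("scenario,pct_ecap_gt3,rank",
               paste(summary$scenario, fmt_num(summary$pct_ecap_gt3),
                     summary$rank, sep = ",")),
             file.path(out_dir, "summary.csv"))
  invisible(summary)
}
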