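#' Clinical sizing rule
#'
#' Imaging-modality-dependent oversizing added to the mean landing diameter
#' (mean of D1 and D2): 2-5 mm for CT, 3-6 mm for TEE; if the resulting
#' target is still smaller than D1, a further 2-5 mm escalation is added.
#' Only devices achieving at least 10 % compression of their nominal size at
#' the landing zone are retained. The rule ranks candidates by a scalar
#' target taken at the midpoint of the offset range; the full range is kept
#' for reporting.
#'
#' @param modality `"CT"` or `"TEE"`.
#' @param offset_range Length-2 mm interval added to mean(D1, D2).
#' @param undersize_escalation Length-2 mm interval added when target < D1.
#' @param min_compression_pct Anchoring threshold (default 10).
#' @return Object of class `sizing_rule`.
#' @export
sizing_rule <- function(modality = c("CT", "TEE"), offset_range = NULL,
                        undersize_escalation = c(2, 5),
                        min_compression_pct = 10) {
  modality <- match.arg(modality)
  offset_range <- offset_range %||% switch(modality, CT = c(2, 5),
                                           TEE = c(3, 6))
  stopifnot(offset_range[1] <= offset_range[2],
            undersize_escalation[1] <= undersize_escalation[2],
            min_compression_pct >= 0)
  structure(list(modality = modality, offset_range = offset_range,
                 undersize_escalation = undersize_escalation,
                 min_compression_pct = min_compression_pct),
            class = "sizing_rule")
}

# Landing depth of each family: geodesic mm from the ostium to the device
# centre along the centreline.
landing_depth_mm <- function(family) switch(family, amulet = 10,
                                            watchman = 13)

compression_pct <- function(nominal, landing_mean_diameter) {
  100 * (nominal - landing_mean_diameter) / nominal
}

new_device_configuration <- function(spec, pose, landing_section,
                                     compression, tag, cl) {
  structure(list(spec = spec, pose = pose, landing_section = landing_section,
                 compression_pct = compression, scenario_tag = tag,
                 centreline = cl),
            class = "device_configuration")
}

#' @export
print.device_configuration <- function(x, ...) {
  cat(sprintf(paste0("<device_configuration> %s %g mm [%s] depth %.1f mm, ",
                     "compression %.1f %%\n"),
              x$spec$family, x$spec$nominal_size, x$scenario_tag,
              x$pose$depth, x$compression_pct))
  invisible(x)
}

#' Automatically propose device configurations
#'
#' Places the device centre at the family landing depth along the centreline
#' (10 mm Amulet-type, 13 mm Watchman-type), aligns the device axis with the
#' centreline tangent there (so the device's transversal plane is
#' perpendicular to the centreline), measures D1/D2 of the landing
#' cross-section, and selects candidate sizes: by the mean-diameter + offset
#' rule for the Amulet type (three candidates) and by the D1 lookup chart
#' for the Watchman type (two candidates), keeping only candidates with
#' compression at or above the rule threshold.
#'
#' @param mesh Labelled [surface_mesh()] of the anatomy.
#' @param cl An `laa_centreline`.
#' @param family `"amulet"` or `"watchman"`.
#' @param rules A [sizing_rule()] (default CT).
#' @param cat A [catalog()] for the family.
#' @param n_candidates Number of candidates to return (default 3 for
#'   amulet, 2 for watchman).
#' @return List of `device_configuration` objects tagged `vidaa_init`,
#'   ordered by distance of nominal size from the sizing target. Empty list
#'   (with a `laaoplan_no_candidate` warning) when no catalog size passes
#'   the compression filter.
#' @export
propose_configuration <- function(mesh, cl, family,
                                  rules = sizing_rule("CT"),
                                  cat = catalog(family),
                                  n_candidates = NULL) {
  stopifnot(inherits(cl, "laa_centreline"), inherits(rules, "sizing_rule"))
  depth <- landing_depth_mm(family)
  if (max(cl$arc_length) <= depth)
    stop(sprintf("centreline (%.1f mm) shorter than the %s landing depth %g mm",
                 max(cl$arc_length), family, depth), call. = FALSE)
  n_candidates <- n_candidates %||% switch(family, amulet = 3L, watchman = 2L)
  cs <- cross_section_at(mesh, cl, depth)
  at <- point_at_geodesic_distance(cl, depth)
  pose <- list(centre = at$point, axis = at$tangent, depth = depth)
  mean_d <- mean(c(cs$d1_max_diameter, cs$d2_min_diameter))
  if (family == "amulet") {
    target <- mean_d + mean(rules$offset_range)
    if (target < cs$d1_max_diameter)
      target <- target + mean(rules$undersize_escalation)
    sizes <- sort(cat$sizes[cat$sizes >= target])
  } else {
    s0 <- watchman_size_for_d1(cat, cs$d1_max_diameter)
    if (is.na(s0)) {
      warning(structure(class = c("laaoplan_no_candidate", "warning",
                                  "condition"),
                        list(message = sprintf(
                          "D1 = %.1f mm outside the %s sizing chart",
                          cs$d1_max_diameter, family), call = NULL)))
      return(list())
    }
    sizes <- cat$sizes[cat$sizes >= s0]
    target <- s0
  }
  sizes <- sizes[compression_pct(sizes, mean_d) >= rules$min_compression_pct]
  sizes <- utils::head(sizes, n_candidates)
  if (!length(sizes)) {
    warning(structure(class = c("laaoplan_no_candidate", "warning",
                                "condition"),
                      list(message = sprintf(
                        paste0("no %s catalog size achieves >= %g%% ",
                               "compression at D = %.1f mm"),
                        family, rules$min_compression_pct, mean_d),
                        call = NULL)))
    return(list())
  }
  sizes <- sizes[order(abs(sizes - target), sizes)]
  lapply(sizes, function(sz)
    new_device_configuration(device_spec(family, sz), pose, cs,
                             compression_pct(sz, mean_d), "vidaa_init", cl))
}

#' Generate the simulation scenarios for a proposed configuration
#'
#' From a `vidaa_init` base configuration: a device scaled to 80 % of
#' nominal size (`smaller_20`; kept unsnapped by default because the
#' scenario scales the device, not the catalog choice), and a sub-optimally
#' placed device (`misplaced`: deeper by `extra_depth_mm`, axis tilted by
#' `tilt_deg`). The base rides along unchanged; the device-free baseline is
#' represented by absence of a configuration.
#'
#' @param base A `device_configuration` tagged `vidaa_init`.
#' @param misplace_opts List with `extra_depth_mm` (default 5) and
#'   `tilt_deg` (default 15).
#' @param snap Snap the 80 % size to the nearest catalog size?
#' @param cat Catalog used when `snap = TRUE`.
#' @return Named list `vidaa_init`, `smaller_20`, `misplaced`.
#' @export
make_scenarios <- function(base, misplace_opts = list(), snap = FALSE,
                           cat = NULL) {
  stopifnot(inherits(base, "device_configuration"))
  if (base$scenario_tag != "vidaa_init")
    stop("scenarios are generated from a vidaa_init configuration",
         call. = FALSE)
  opts <- utils::modifyList(list(extra_depth_mm = 5, tilt_deg = 15),
                            misplace_opts)
  small_size <- 0.8 * base$spec$nominal_size
  if (snap) {
    cat <- cat %||% catalog(base$spec$family)
    small_size <- cat$sizes[which.min(abs(cat$sizes - small_size))]
  }
  mean_d <- mean(c(base$landing_section$d1_max_diameter,
                   base$landing_section$d2_min_diameter))
  smaller <- new_device_configuration(
    device_spec(base$spec$family, small_size), base$pose,
    base$landing_section, compression_pct(small_size, mean_d),
    "smaller_20", base$centreline)
  cl <- base$centreline
  new_depth <- min(base$pose$depth + opts$extra_depth_mm,
                   max(cl$arc_length) - 1e-4)
  at <- point_at_geodesic_distance(cl, new_depth)
  tilt <- opts$tilt_deg * pi / 180
  ortho <- plane_basis(at$tangent)$u
  axis <- normalize(cos(tilt) * at$tangent + sin(tilt) * ortho)
  mis_pose <- list(centre = at$point, axis = axis, depth = new_depth)
  misplaced <- new_device_configuration(
    base$spec, mis_pose, base$landing_section, base$compression_pct,
    "misplaced", cl)
  list(vidaa_init = base, smaller_20 = smaller, misplaced = misplaced)
}

#' Interactive-style override of a configuration
#'
#' Emulates manual adjustment after the automatic proposal: replaces pose
#' and/or size and retags the configuration `vidaa_end`. With a mesh, the
#' landing section and compression are recomputed at the new depth. The
#' `"ostium_flush"` preset centres the device on the ostium plane so its
#' proximal face lies in that plane (uniformly covering the LA/LAA union).
#'
#' @param cfg A `device_configuration`.
#' @param new_pose Optional pose list (`centre`, `axis`, `depth`).
#' @param new_size Optional nominal size (mm).
#' @param preset Optional `"ostium_flush"`.
#' @param mesh Optional anatomy mesh for compression recomputation and
#'   placement checking.
#' @return A `device_configuration` tagged `vidaa_end`.
#' @export
apply_override <- function(cfg, new_pose = NULL, new_size = NULL,
                           preset = NULL, mesh = NULL) {
  stopifnot(inherits(cfg, "device_configuration"))
  cl <- cfg$centreline
  pose <- cfg$pose
  if (!is.null(preset)) {
    if (preset != "ostium_flush")
      stop("unknown preset '", preset, "'", call. = FALSE)
    at0 <- point_at_geodesic_distance(cl, 0)
    pose <- list(centre = at0$point, axis = at0$tangent, depth = 0)
  }
  if (!is.null(new_pose)) pose <- utils::modifyList(pose, new_pose)
  spec <- cfg$spec
  if (!is.null(new_size)) spec <- device_spec(spec$family, new_size,
                                              spec$geometry_params)
  landing <- cfg$landing_section
  compression <- cfg$compression_pct
  if (!is.null(mesh)) {
    if (!is.null(new_pose) &&
        !any(points_in_mesh(matrix(pose$centre, 1, 3), mesh)))
      stop("override pose centre lies outside the lumen", call. = FALSE)
    d_eff <- min(max(pose$depth, 1e-4), max(cl$arc_length) - 1e-4)
    landing <- cross_section_at(mesh, cl, d_eff)
  }
  mean_d <- mean(c(landing$d1_max_diameter, landing$d2_min_diameter))
  compression <- compression_pct(spec$nominal_size, mean_d)
  if (compression < 0)
    warning(sprintf("negative compression (%.1f %%): device smaller than the landing zone",
                    compression))
  new_device_configuration(spec, pose, landing, compression, "vidaa_end", cl)
}

#' Virtually implant a device into the anatomy
#'
#' Builds the device mesh, rigidly transforms it (canonical +z axis onto the
#' pose axis, origin onto the pose centre) and merges it with the anatomy as
#' a second closed surface, faces labelled `device` -- the two-surface
#' domain a volume mesher consumes. Radial interference with the wall is
#' expected under compression: the count of wall faces with a vertex inside
#' the device is attached as attribute `interference_faces`, not treated as
#' an error.
#'
#' @param mesh Labelled anatomy [surface_mesh()].
#' @param cfg A `device_configuration`.
#' @param resolution Device mesh resolution (mm), see [build_device_mesh()].
#' @return Combined `surface_mesh` with attributes `interference_faces` and
#'   `device_volume_mm3`.
#' @export
implant <- function(mesh, cfg, resolution = NULL) {
  stopifnot(inherits(cfg, "device_configuration"))
  if (!any(points_in_mesh(matrix(cfg$pose$centre, 1, 3), mesh)))
    stop("device proximal face lies outside the lumen (placement error)",
         call. = FALSE)
  dev <- build_device_mesh(cfg$spec, resolution)
  R <- rotation_between(c(0, 0, 1), cfg$pose$axis)
  dev_t <- transform_mesh(dev, R, cfg$pose$centre)
  # interference diagnostic: anatomy vertices inside the closed device
  bb_lo <- apply(dev_t$vertices, 2, min); bb_hi <- apply(dev_t$vertices, 2, max)
  vin <- mesh$vertices
  cand <- which(vin[, 1] >= bb_lo[1] & vin[, 1] <= bb_hi[1] &
                  vin[, 2] >= bb_lo[2] & vin[, 2] <= bb_hi[2] &
                  vin[, 3] >= bb_lo[3] & vin[, 3] <= bb_hi[3])
  inside <- rep(FALSE, nrow(vin))
  if (length(cand))
    inside[cand] <- points_in_mesh(vin[cand, , drop = FALSE], dev_t)
  interference <- sum(inside[mesh$faces[, 1]] | inside[mesh$faces[, 2]] |
                        inside[mesh$faces[, 3]])
  out <- merge_meshes(mesh, dev_t)
  attr(out, "interference_faces") <- interference
  attr(out, "device_volume_mm3") <- mesh_volume(dev_t)
  attr(out, "configuration") <- cfg
  out
}
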