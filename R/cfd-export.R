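#' Boundary-condition specification for the haemodynamic simulation
#'
#' Solver-agnostic description of one cardiac cycle: atrial systole (first
#' 0.40 s, pulmonary veins as velocity inlets, closed mitral valve modelled
#' as a wall) followed by diastole (0.65 s, mitral valve as a pressure
#' outlet at 8 mmHg), blood as an incompressible Newtonian fluid (density
#' 1060 kg/m^3, dynamic viscosity 0.0035 Pa s) and rigid no-slip walls --
#' the worst-case persistent-AF setting in which the atrium barely
#' contracts. The device, when present, is a wall too: no flow through it.
#'
#' @param systole_duration_s,diastole_duration_s Phase durations (s).
#' @param mv_outlet_pressure_mmHg Diastolic mitral outlet pressure (mmHg).
#' @param blood_density_kg_m3,blood_viscosity_pa_s Fluid constants.
#' @param rigid_walls No-slip rigid wall model flag.
#' @param peak_inlet_velocity_m_s Scale of the sinusoidal inlet waveform.
#' @param waveform_samples Samples per cycle of the default waveform.
#' @return Object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(systole_duration_s = 0.40,
                                diastole_duration_s = 0.65,
                                mv_outlet_pressure_mmHg = 8,
                                blood_density_kg_m3 = 1060,
                                blood_viscosity_pa_s = 0.0035,
                                rigid_walls = TRUE,
                                peak_inlet_velocity_m_s = 0.4,
                                waveform_samples = 64L) {
  stopifnot(systole_duration_s > 0, diastole_duration_s > 0,
            blood_density_kg_m3 > 0, blood_viscosity_pa_s > 0,
            waveform_samples >= 8)
  structure(list(systole_duration_s = systole_duration_s,
                 diastole_duration_s = diastole_duration_s,
                 mv_outlet_pressure_mmHg = mv_outlet_pressure_mmHg,
                 blood_density_kg_m3 = blood_density_kg_m3,
                 blood_viscosity_pa_s = blood_viscosity_pa_s,
                 rigid_walls = rigid_walls,
                 peak_inlet_velocity_m_s = peak_inlet_velocity_m_s,
                 waveform_samples = as.integer(waveform_samples)),
            class = "boundary_conditions")
}

#' @export
print.boundary_conditions <- function(x, ...) {
  cat(sprintf(paste0("<boundary_conditions> cycle %.2f s (systole %.2f + ",
                     "diastole %.2f), MV outlet %g mmHg, rho %g kg/m^3, ",
                     "mu %g Pa s\n"),
              x$systole_duration_s + x$diastole_duration_s,
              x$systole_duration_s, x$diastole_duration_s,
              x$mv_outlet_pressure_mmHg, x$blood_density_kg_m3,
              x$blood_viscosity_pa_s))
  invisible(x)
}

#' Sinusoidal inlet waveform over one cardiac cycle
#'
#' One-cycle velocity multiplier sampled at `samples` uniform times:
#' a half-sine per phase, phase-aligned with the systole/diastole partition
#' of the cycle and non-negative throughout the systolic inlet phase. The
#' multiplier scales `peak_inlet_velocity_m_s`.
#'
#' @param bc A [boundary_conditions()].
#' @param samples Samples per cycle (>= 8; default from `bc`).
#' @return Tibble with columns `time_s` and `multiplier`.
#' @export
make_inlet_waveform <- function(bc = boundary_conditions(), samples = NULL) {
  samples <- samples %||% bc$waveform_samples
  stopifnot(samples >= 8)
  T_sys <- bc$systole_duration_s
  T_dia <- bc$diastole_duration_s
  t <- (seq_len(samples) - 1) / samples * (T_sys + T_dia)
  mult <- ifelse(t < T_sys,
                 sin(pi * t / T_sys),
                 sin(pi * (t - T_sys) / T_dia))
  tibble::tibble(time_s = t, multiplier = mult)
}

#' Export a CFD-ready case bundle
#'
#' Writes the labelled two-surface domain and a machine-readable YAML
#' manifest describing both phases, the inlet waveform, the blood constants
#' and the wall model -- everything an external incompressible Navier-Stokes
#' solver needs, in no solver's proprietary dialect. The export refuses
#' non-watertight domains and reports any missing label class by name.
#'
#' @param domain Labelled [surface_mesh()] (from [implant()] or the bare
#'   anatomy for the device-free scenario).
#' @param bc A [boundary_conditions()].
#' @param out_dir Output directory (created if needed).
#' @param require_device Require a `device` label class (default: off).
#' @return Invisible list with `mesh_path` and `manifest_path`.
#' @export
export_cfd_case <- function(domain, bc = boundary_conditions(), out_dir,
                            require_device = FALSE) {
  stopifnot(inherits(domain, "surface_mesh"),
            inherits(bc, "boundary_conditions"))
  if (!is_watertight(domain))
    stop("CFD export requires a watertight domain", call. = FALSE)
  need <- c("wall", "pv_inlet", "mv_outlet", if (require_device) "device")
  have <- unique(label_name(domain$face_labels))
  missing <- setdiff(need, have)
  if (length(missing))
    stop("domain is missing label class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mesh_path <- file.path(out_dir, "domain.vtp")
  write_mesh(domain, mesh_path, "vtp")
  wf <- make_inlet_waveform(bc)
  manifest <- list(
    case = "laaoplan-cfd",
    mesh = "domain.vtp",
    units = "mm",
    label_codes = as.list(label_codes()),
    blood = list(density_kg_m3 = bc$blood_density_kg_m3,
                 dynamic_viscosity_pa_s = bc$blood_viscosity_pa_s,
                 model = "incompressible-newtonian"),
    wall_model = if (bc$rigid_walls) "rigid-no-slip" else "compliant",
    phases = list(
      systole = list(
        duration_s = bc$systole_duration_s,
        pv_inlet = list(type = "velocity-inlet",
                        peak_velocity_m_s = bc$peak_inlet_velocity_m_s,
                        waveform = "inlet_waveform"),
        mv_outlet = list(type = "wall"),
        wall = list(type = "wall"),
        device = list(type = "wall")),
      diastole = list(
        duration_s = bc$diastole_duration_s,
        pv_inlet = list(type = "velocity-inlet",
                        peak_velocity_m_s = bc$peak_inlet_velocity_m_s,
                        waveform = "inlet_waveform"),
        mv_outlet = list(type = "pressure-outlet",
                         pressure_mmHg = bc$mv_outlet_pressure_mmHg),
        wall = list(type = "wall"),
        device = list(type = "wall"))),
    inlet_waveform = list(time_s = wf$time_s, multiplier = wf$multiplier))
  manifest_path <- file.path(out_dir, "case.yaml")
  yaml::write_yaml(manifest, manifest_path, precision = 12)
  invisible(list(mesh_path = mesh_path, manifest_path = manifest_path))
}

#' Read back an exported CFD case
#'
#' @param case_dir Directory written by [export_cfd_case()].
#' @return List with `manifest` (parsed YAML) and `mesh`.
#' @export
read_cfd_case <- function(case_dir) {
  manifest_path <- file.path(case_dir, "case.yaml")
  if (!file.exists(manifest_path))
    stop("no case.yaml in ", case_dir, call. = FALSE)
  manifest <- yaml::read_yaml(manifest_path)
  mesh <- read_mesh(file.path(case_dir, manifest$mesh))
  list(manifest = manifest, mesh = mesh)
}
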