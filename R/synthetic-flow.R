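#' Synthetic flow specification
#'
#' Closed-form wall-shear and velocity fields over one cardiac cycle, with
#' analytic TAWSS/OSI/ECAP ground truth per node: each node carries a steady
#' shear component `a(x)`, an oscillatory amplitude `c(x)` and a unit
#' direction `d(x)`, giving
#' `tau_w(x, t) = [a(x) + c(x) sin(2 pi t / T)] d(x)`.
#'
#' @param steady Function `(n x 3 points) -> a` (Pa), or a scalar.
#' @param oscillatory Function or scalar for `c` (Pa).
#' @param direction Function `(points) -> n x 3` unit directions, or a
#'   length-3 vector.
#' @param cycle_s Cycle length T (s); default 1.05 (0.40 systole + 0.65
#'   diastole).
#' @param samples_per_cycle Time samples (>= 8, default 32).
#' @return Object of class `flow_spec`.
#' @export
flow_spec <- function(steady = 1, oscillatory = 0,
                      direction = c(1, 0, 0), cycle_s = 1.05,
                      samples_per_cycle = 32L) {
  stopifnot(samples_per_cycle >= 8, cycle_s > 0)
  as_fun <- function(v, dim1 = FALSE) {
    if (is.function(v)) return(v)
    if (dim1) function(p) matrix(rep(normalize(v), each = nrow(p)),
                                 ncol = 3)
    else function(p) rep(v, nrow(p))
  }
  structure(list(steady = as_fun(steady),
                 oscillatory = as_fun(oscillatory),
                 direction = as_fun(direction, dim1 = TRUE),
                 cycle_s = cycle_s,
                 samples_per_cycle = as.integer(samples_per_cycle)),
            class = "flow_spec")
}

#' Synthetic wall-shear-stress series with analytic ground truth
#'
#' Evaluates the [flow_spec()] on the mesh nodes over one cycle and attaches
#' the closed-form indices as attribute `ground_truth`: with `a >= c`
#' (unidirectional shear) `TAWSS = a`, `OSI = 0`; with `a = 0` (fully
#' oscillatory) `TAWSS = 2c/pi`, `OSI = 1/2`, `ECAP = pi/(4c)`. Nodes with
#' `0 < a < c` are evaluated by high-resolution numerical quadrature of the
#' same closed-form integrand.
#'
#' @param mesh Wall [surface_mesh()].
#' @param spec A [flow_spec()].
#' @return A [wss_series()] with `ground_truth` attribute (tibble: `node`,
#'   `tawss_pa`, `osi`, `ecap_inv_pa`).
#' @export
make_wss_series <- function(mesh, spec = flow_spec()) {
  stopifnot(inherits(spec, "flow_spec"))
  pts <- mesh$vertices
  n <- nrow(pts)
  a <- spec$steady(pts)
  cc <- spec$oscillatory(pts)
  stopifnot(all(a >= 0), all(cc >= 0))
  dirs <- spec$direction(pts)
  dirs <- dirs / rownorms(dirs)
  T_ <- spec$cycle_s
  times <- seq(0, T_, length.out = spec$samples_per_cycle + 1L)
  amp <- outer(a, rep(1, length(times))) +
    outer(cc, rep(1, length(times))) * rep(sin(2 * pi * times / T_),
                                           each = n)
  arr <- array(0, c(n, length(times), 3))
  for (k in 1:3) arr[, , k] <- amp * dirs[, k]
  gt_one <- function(ai, ci) {
    if (ci <= 1e-300) return(c(ai, 0, 0))
    if (ai >= ci) return(c(ai, 0, 0))             # |.| never changes sign
    if (ai == 0) return(c(2 * ci / pi, 0.5, pi / (4 * ci)))
    # mixed regime: fine quadrature of |a + c sin|
    tt <- seq(0, T_, length.out = 20001L)
    f <- abs(ai + ci * sin(2 * pi * tt / T_))
    int_mag <- sum(trapz_weights(tt) * f)
    tawss <- int_mag / T_
    osi <- 0.5 * (1 - abs(ai * T_) / int_mag)
    c(tawss, osi, osi / tawss)
  }
  gt <- t(vapply(seq_len(n), function(i) gt_one(a[i], cc[i]), numeric(3)))
  out <- wss_series(mesh, times, arr)
  attr(out, "ground_truth") <- tibble::tibble(
    node = seq_len(n), tawss_pa = gt[, 1], osi = gt[, 2],
    ecap_inv_pa = gt[, 3])
  out
}

#' Closed-form velocity field for probe tests
#'
#' A uniform-direction field whose speed follows the inlet waveform phase
#' partition: `v(x, t) = peak * m(t) * e`, with `m(t)` the sinusoidal cycle
#' multiplier of [make_inlet_waveform()].
#'
#' @param bc A [boundary_conditions()].
#' @param direction Length-3 flow direction.
#' @return Function `(points, t) -> n x 3` velocity matrix (m/s).
#' @export
make_flow_field <- function(bc = boundary_conditions(),
                            direction = c(1, 0, 0)) {
  e <- normalize(direction)
  T_sys <- bc$systole_duration_s; T_dia <- bc$diastole_duration_s
  peak <- bc$peak_inlet_velocity_m_s
  function(points, t) {
    t <- t %% (T_sys + T_dia)
    m <- if (t < T_sys) sin(pi * t / T_sys) else
      sin(pi * (t - T_sys) / T_dia)
    matrix(rep(peak * m * e, each = nrow(points)), ncol = 3)
  }
}
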