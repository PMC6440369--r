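# Small vector helpers shared across modules. All geometry is in millimetres.

vnorm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rowwise cross product for n x 3 matrices.
cross3m <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rownorms <- function(m) sqrt(rowSums(m^2))

# Any two unit vectors spanning the plane orthogonal to unit vector n.
plane_basis <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- normalize(cross3(n, ref))
  v <- cross3(n, u)
  list(u = u, v = v)
}

# Rotation matrix taking unit vector `from` onto unit vector `to` (Rodrigues).
rotation_between <- function(from, to) {
  from <- normalize(from); to <- normalize(to)
  v <- cross3(from, to)
  c_ <- sum(from * to)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees: rotate about any axis orthogonal to `from`
    axis <- plane_basis(from)$u
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

# Deterministic float formatting used by all ASCII writers (bit-stable output).
fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 9)
  gsub("^\\s+", "", out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
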