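#' Taubin smoothing parameters
#'
#' Defaults follow the standard anatomical pre-processing setting
#' lambda = 0.6, mu = -0.53, 10 iterations: the lambda/mu pair smooths
#' without the volume shrinkage of plain Laplacian smoothing.
#'
#' @param lambda_factor Positive shrink step in (0, 1).
#' @param mu_factor Negative inflate step.
#' @param iterations Number of (lambda, mu) passes; 0 is a no-op.
#' @return An object of class `smoothing_params`.
#' @export
smoothing_params <- function(lambda_factor = 0.6, mu_factor = -0.53,
                             iterations = 10L) {
  stopifnot(lambda_factor > 0, lambda_factor < 1, mu_factor < 0,
            iterations >= 0)
  structure(list(lambda_factor = lambda_factor, mu_factor = mu_factor,
                 iterations = as.integer(iterations)),
            class = "smoothing_params")
}

#' Taubin smoothing of a surface mesh
#'
#' Alternates an umbrella-operator shrink step (`lambda`) and inflate step
#' (`mu`) per iteration: `v <- v + factor * (mean(neighbours) - v)`.
#' Connectivity and labels are untouched. Isolated vertices (no incident
#' face) are left in place with a warning.
#'
#' @param mesh A [surface_mesh()].
#' @param params A [smoothing_params()].
#' @param fix_labelled Hold every vertex incident to a non-`wall` face fixed
#'   (preserves inlet/outlet rims and the ostium boundary ring). Default
#'   `TRUE`.
#' @return Smoothed `surface_mesh`.
#' @export
#' @examples
#' cube <- laaoplan:::unit_cube_mesh()
#' sm <- taubin_smooth(cube, smoothing_params(iterations = 2))
taubin_smooth <- function(mesh, params = smoothing_params(),
                          fix_labelled = TRUE) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(params, "smoothing_params"))
  if (nrow(mesh$vertices) < 4)
    stop("mesh must have at least 4 vertices", call. = FALSE)
  if (params$iterations == 0L) return(mesh)
  nv <- nrow(mesh$vertices)
  f <- mesh$faces
  # adjacency via sparse incidence: neighbour sum / degree
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)],
             f[, c(2, 1)], f[, c(3, 2)], f[, c(1, 3)])
  e <- unique(e)
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1, dims = c(nv, nv))
  deg <- Matrix::rowSums(A)
  isolated <- which(deg == 0)
  if (length(isolated)) {
    warning(length(isolated), " isolated vertices left unmoved")
    deg[isolated] <- 1
  }
  fixed <- rep(FALSE, nv)
  if (fix_labelled && any(mesh$face_labels != 0L)) {
    fixed[unique(as.vector(f[mesh$face_labels != 0L, ]))] <- TRUE
  }
  fixed[isolated] <- TRUE
  v <- mesh$vertices
  step <- function(v, factor) {
    nb_mean <- as.matrix(A %*% v) / deg
    upd <- v + factor * (nb_mean - v)
    upd[fixed, ] <- v[fixed, , drop = FALSE]
    upd
  }
  for (it in seq_len(params$iterations)) {
    v <- step(v, params$lambda_factor)
    v <- step(v, params$mu_factor)
  }
  surface_mesh(v, f, mesh$face_labels, validate = FALSE)
}
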