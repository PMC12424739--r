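#' Build the ellipsoidal egg-chamber geometry
#'
#' Places `N` follicle-cell anchor points on the surface
#' \eqn{x^2 + y^2 + (z/e)^2 = 1} (lengths rescaled by the equatorial radius,
#' long axis along the body AP axis \eqn{\hat d_3 = \hat z}), and constructs a
#' tangent frame at each point.  Placement uses a deterministic Fibonacci
#' lattice on the unit sphere, scaled by `(1, 1, e)`, so the layout is
#' approximately equi-areal and reproducible without randomness; `jitter_sd`
#' optionally perturbs the spherical pre-image (then reprojected to the
#' surface) using `seed`.
#'
#' Each tangent frame consists of `t1`, the unit projection of \eqn{\hat d_3}
#' onto the tangent plane (meridional, pointing anterior), `t2 = t1 x n`
#' (azimuthal, right-handed: for a sphere `t2` is the normalized
#' \eqn{\hat d_3 \times \hat r}), and the outward unit normal `n`.  The
#' protrusion angle \eqn{\beta} is measured from `t1` towards `t2`, so
#' counterclockwise rotation (\eqn{\omega_3 > 0}) moves cells along `+t2` and
#' the trailing edge of a counterclockwise-moving cell sits at
#' \eqn{\beta = -\pi/2}.
#'
#' @param e aspect ratio of the long to the equatorial semi-axis (>= 1; 1 is a
#'   sphere).
#' @param N number of cells (>= 4).
#' @param seed integer seed, used only when `jitter_sd > 0`.
#' @param jitter_sd standard deviation (in rescaled length units) of optional
#'   anchor jitter; 0 (default) gives the deterministic lattice.
#' @return an object of class `egg_geometry` with fields `e`, `N`,
#'   `positions` (N x 3), `normals` (N x 3), `t1` (N x 3), `t2` (N x 3).
#' @examples
#' geom <- make_geometry(e = 1.2, N = 100)
#' range(rowSums(geom$positions[, 1:2]^2) + (geom$positions[, 3] / geom$e)^2)
#' @export
make_geometry <- function(e, N, seed = NULL, jitter_sd = 0) {
  stopifnot_scalar(e, "e", lower = 1)
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N < 4 ||
      N != round(N))
    stop("`N` must be an integer >= 4")
  N <- as.integer(N)
  stopifnot_scalar(jitter_sd, "jitter_sd", lower = 0)

  # Fibonacci lattice on the unit sphere
  k <- seq_len(N) - 0.5
  z <- 1 - 2 * k / N
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(N) - 1)
  rho <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(rho * cos(phi), rho * sin(phi), z)

  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    pts <- pts + matrix(rnorm(3L * N, sd = jitter_sd), ncol = 3L)
    pts <- pts / sqrt(rowSums(pts^2))
  }

  positions <- cbind(pts[, 1L], pts[, 2L], e * pts[, 3L])

  # outward normal from the implicit surface gradient (x, y, z/e^2)
  grad <- cbind(positions[, 1L], positions[, 2L], positions[, 3L] / e^2)
  normals <- grad / sqrt(rowSums(grad^2))

  # t1: projection of d3 = z-hat onto tangent plane; poles fall back to the
  # projected body x-axis (t1 is undefined where d3 is parallel to n)
  d3 <- c(0, 0, 1)
  t1 <- matrix(0, N, 3L)
  for (i in seq_len(N)) {
    n <- normals[i, ]
    proj <- d3 - sum(d3 * n) * n
    if (norm3(proj) < 1e-8) proj <- c(1, 0, 0) - n[1L] * n
    t1[i, ] <- proj / norm3(proj)
  }
  t2 <- cbind(t1[, 2L] * normals[, 3L] - t1[, 3L] * normals[, 2L],
              t1[, 3L] * normals[, 1L] - t1[, 1L] * normals[, 3L],
              t1[, 1L] * normals[, 2L] - t1[, 2L] * normals[, 1L])

  structure(list(e = e, N = N, positions = positions, normals = normals,
                 t1 = t1, t2 = t2),
            class = "egg_geometry")
}

#' @export
print.egg_geometry <- function(x, ...) {
  cat(sprintf("<egg_geometry> N = %d cells on ellipsoid with aspect ratio e = %g\n",
              x$N, x$e))
  cat(sprintf("  rotational drag Pi(e) = %.4f\n", drag_coefficient(x$e, x$N)))
  invisible(x)
}

#' Rotational drag coefficient of the confined ellipsoid
#'
#' Non-dimensional drag opposing rotation about the long axis,
#' \deqn{\Pi(e) = N \pi (40 + 26 (e - 1)) / 15,}
#' so \eqn{\Pi(1) = 8 N \pi / 3} for a sphere.  Linear in the cell count `N`
#' and strictly increasing in the aspect ratio `e`.
#'
#' @param e aspect ratio (>= 1).
#' @param N cell count (>= 1).
#' @return the scalar drag coefficient.
#' @examples
#' drag_coefficient(1, 15)   # 40 * pi
#' drag_coefficient(2, 15)   # 66 * pi
#' @export
drag_coefficient <- function(e, N) {
  stopifnot_scalar(e, "e", lower = 1)
  stopifnot_scalar(N, "N", lower = 1)
  N * pi * (40 + 26 * (e - 1)) / 15
}

#' Unit tangent along an in-plane angle
#'
#' Returns \eqn{m(\beta) = \cos\beta \, t_1 + \sin\beta \, t_2}, the unit
#' tangent at a cell anchor along the in-plane direction `beta` (measured from
#' the meridional `t1` towards the azimuthal `t2`).
#'
#' @param geometry an `egg_geometry`.
#' @param i cell index.
#' @param beta angle in radians.
#' @return a length-3 unit vector in body coordinates.
#' @export
tangent_unit <- function(geometry, i, beta) {
  stopifnot(inherits(geometry, "egg_geometry"))
  stopifnot_scalar(beta, "beta")
  cos(beta) * geometry$t1[i, ] + sin(beta) * geometry$t2[i, ]
}

#' Serialize a geometry to JSON
#'
#' Writes `{e, N, positions, normals}` for external inspection.
#'
#' @param geometry an `egg_geometry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geometry_json <- function(geometry, path) {
  stopifnot(inherits(geometry, "egg_geometry"))
  jsonlite::write_json(
    list(e = geometry$e, N = geometry$N,
         positions = geometry$positions, normals = geometry$normals),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
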