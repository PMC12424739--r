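#' Initialize the simulation state
#'
#' Sets the isotropic (symmetric) initial condition: every Fat2 bin at
#' `1/(2*pi)`, all crawling forces zero, no rotation, clock at zero, and
#' seeds the RNG from `params$seed`.
#'
#' @param params an [model_params()] object.
#' @param geometry an [make_geometry()] object.
#' @return a list of class `egg_state` with fields `t`, `fat2` (N x M
#'   matrix), `forces` (N x 3 matrix, body frame), `beta` (last sampled
#'   protrusion angles, `NA` until first draw), `omega3`.
#' @export
init_state <- function(params, geometry) {
  stopifnot(inherits(params, "egg_params"), inherits(geometry, "egg_geometry"))
  set.seed(params$seed)
  structure(list(
    t = 0,
    fat2 = matrix(1 / (2 * pi), geometry$N, params$M),
    forces = matrix(0, geometry$N, 3L),
    beta = rep(NA_real_, geometry$N),
    omega3 = 0
  ), class = "egg_state")
}

#' Sample per-cell protrusion angles from the Fat2 field
#'
#' Each cell's protrusion direction \eqn{\beta_i} is a stochastic variable
#' drawn from the distribution proportional to its Fat2 field \eqn{c_i(\beta)}
#' by inverse-CDF sampling over the angular bins (equal bin widths, so the
#' bin values are the weights); the bin-center angle is returned.  Consumes
#' exactly one uniform variate per cell, in cell order, from the R RNG
#' stream.
#'
#' @param fat2 N x M matrix of bin values (all >= the configured floor).
#' @param mirror if `TRUE`, draw from the mirrored field \eqn{c(-\beta)} and
#'   negate the result; with mirrored initial conditions this reflects the
#'   whole stochastic trajectory (used to verify chiral sign symmetry).
#' @return vector of N angles (bin centers, in `(-pi, pi)`).
#' @export
sample_protrusion_angles <- function(fat2, mirror = FALSE) {
  if (!all(is.finite(fat2)) || any(fat2 < 0))
    stop("Fat2 field must be finite and non-negative")
  N <- nrow(fat2)
  M <- ncol(fat2)
  centers <- beta_centers(M)
  u <- runif(N)
  beta <- numeric(N)
  for (i in seq_len(N)) {
    w <- if (mirror) fat2[i, M:1L] else fat2[i, ]
    cs <- cumsum(w)
    target <- u[i] * cs[M]
    k <- sum(cs < target) + 1L
    if (k > M) k <- M
    beta[i] <- if (mirror) -centers[k] else centers[k]
  }
  beta
}

#' Advance the crawling forces by one Euler step
#'
#' Explicit-Euler update of the force-relaxation dynamics
#' \eqn{db_i/dt = -\tau_1 (\eta_i + b_i)} in each cell's co-rotating tangent
#' frame (the advective rotation term is implicit in the frame), where
#' \eqn{\eta_i = \cos\beta_i \, t_1 + \sin\beta_i \, t_2} points towards the
#' Fat2-enriched edge, followed by projection onto the tangent plane.  The
#' fixed point for frozen \eqn{\eta_i} is \eqn{b_i = -\eta_i}: protrusion
#' (and force) opposite the Fat2-rich edge.
#'
#' @param state an `egg_state` whose `beta` field holds fresh protrusion
#'   angles.
#' @param params,geometry model parameters and geometry.
#' @param dt step size (defaults to `params$dt`).
#' @return the state with updated `forces`.
#' @export
step_forces <- function(state, params, geometry, dt = params$dt) {
  if (dt * params$tau1 >= 1) stop("unstable: dt * tau1 must be < 1")
  if (anyNA(state$beta)) stop("protrusion angles not sampled yet")
  eta <- cos(state$beta) * geometry$t1 + sin(state$beta) * geometry$t2
  b <- state$forces - dt * params$tau1 * (eta + state$forces)
  bn <- rowSums(b * geometry$normals)
  b <- b - bn * geometry$normals
  state$forces <- b
  state
}

#' Angular speed about the AP axis from the torque balance
#'
#' Overdamped rigid-body balance about the long axis:
#' \deqn{\Pi(e)\,\omega_3 = \sum_i (r_i \times b_i) \cdot \hat d_3.}
#'
#' @param geometry an `egg_geometry`.
#' @param forces N x 3 matrix of tangent crawling forces (body frame).
#' @return the signed scalar `omega3`.
#' @export
compute_omega3 <- function(geometry, forces) {
  r <- geometry$positions
  tz <- sum(r[, 1L] * forces[, 2L] - r[, 2L] * forces[, 1L])
  tz / drag_coefficient(geometry$e, geometry$N)
}

#' Rigid-body velocity of one cell
#'
#' \eqn{v_i = \omega \times r_i} with \eqn{\omega = \omega_3 \hat d_3}, in
#' body coordinates.
#'
#' @param omega3 signed angular speed about the AP axis.
#' @param geometry an `egg_geometry`.
#' @param i cell index.
#' @return length-3 velocity vector.
#' @export
cell_velocity <- function(omega3, geometry, i) {
  r <- geometry$positions[i, ]
  omega3 * c(-r[2L], r[1L], 0)
}

#' Advance the Fat2 field by one Euler step
#'
#' Explicit-Euler update of the mechanosensitive Fat2 dynamics
#' \deqn{\partial c_i(\beta)/\partial t =
#'   -\tau_2 [\tau_3\, v_i \cdot m(\beta, r_i) + c_i(\beta)]\, c_i(\beta),}
#' applied per angular bin and floored at `params$c_floor`.  Fat2 grows on
#' the trailing side (\eqn{v_i \cdot m < 0}), saturating at
#' \eqn{c^* = -\tau_3 v_i \cdot m}, and decays to the floor on the leading
#' side.
#'
#' @param state an `egg_state` with current `omega3`.
#' @param params,geometry model parameters and geometry.
#' @param dt step size (defaults to `params$dt`).
#' @return the state with updated `fat2`.
#' @export
step_fat2 <- function(state, params, geometry, dt = params$dt) {
  r <- geometry$positions
  # v_i = omega3 * (z-hat x r_i)
  v <- cbind(-state$omega3 * r[, 2L], state$omega3 * r[, 1L], 0)
  state$fat2 <- update_fat2_field(state$fat2, v, params, geometry, dt)
  state
}

# Euler update of the per-cell Fat2 field given N x 3 body-frame velocities.
update_fat2_field <- function(fat2, v, params, geometry, dt) {
  if (!all(is.finite(fat2))) stop("non-finite Fat2 field")
  centers <- beta_centers(params$M)
  v_t1 <- rowSums(v * geometry$t1)
  v_t2 <- rowSums(v * geometry$t2)
  vm <- outer(v_t1, cos(centers)) + outer(v_t2, sin(centers))  # v_i . m(beta_k)
  cnew <- fat2 - dt * params$tau2 * (params$tau3 * vm + fat2) * fat2
  cnew[cnew < params$c_floor] <- params$c_floor
  cnew
}

#' One full step of the base model (reference implementation)
#'
#' Composes [sample_protrusion_angles()] (on schedule), [step_forces()],
#' [compute_omega3()] and [step_fat2()] exactly as the compiled integrator
#' does, consuming the same RNG stream.  Useful for inspection and as the
#' independent reference the fast path is tested against.
#'
#' @param state an `egg_state`.
#' @param params,geometry model parameters and geometry.
#' @param step_index 0-based index of this step (controls the resampling
#'   schedule: angles are redrawn when `step_index %% resample_every == 0`).
#' @param mirror propagate the chirality-mirrored stochastic trajectory.
#' @return the advanced state.
#' @export
step_base_model <- function(state, params, geometry, step_index = 0L,
                            mirror = FALSE) {
  if (step_index %% params$resample_every == 0L || anyNA(state$beta))
    state$beta <- sample_protrusion_angles(state$fat2, mirror = mirror)
  state <- step_forces(state, params, geometry)
  state$omega3 <- compute_omega3(geometry, state$forces)
  state <- step_fat2(state, params, geometry)
  state$t <- state$t + params$dt
  state
}

#' Run the base (axis-constrained) model
#'
#' Integrates the full feedback loop with rotation constrained to the AP
#' axis, from the isotropic initial condition, using the compiled inner loop.
#' Per step: redraw protrusion angles on schedule, relax crawling forces,
#' solve the torque balance for `omega3`, update the Fat2 field from the
#' local migration velocities.
#'
#' @param params an [model_params()] object.
#' @param geometry an [make_geometry()] object.
#' @param mirror if `TRUE`, run the chirality-mirrored realization of the
#'   same seed (flips the sign of `omega3` exactly).
#' @return an object of class `egg_trajectory`: `times`, `omega3`,
#'   `snapshot_times`, `snapshots` (rows: cell-averaged Fat2 distribution),
#'   `beta_centers`, `final_state`, `diagnostics` (`max_abs_bn`, `min_c`),
#'   `params`, `model = "base"`.
#' @examples
#' \donttest{
#' geom <- make_geometry(e = 1.2, N = 200)
#' traj <- run_base_model(model_params(T = 100, seed = 7), geom)
#' rotation_direction(traj)
#' }
#' @export
run_base_model <- function(params, geometry, mirror = FALSE) {
  stopifnot(inherits(params, "egg_params"), inherits(geometry, "egg_geometry"))
  n_steps <- as.integer(round(params$T / params$dt))
  set.seed(params$seed)
  res <- cpp_run_base(
    geometry$positions, geometry$normals, geometry$t1, geometry$t2,
    drag_coefficient(geometry$e, geometry$N),
    params$tau1, params$tau2, params$tau3, params$dt, n_steps,
    params$M, params$resample_every, params$c_floor,
    params$record_every, params$snapshot_every, mirror, params$omega_max)
  structure(list(
    times = res$times, omega3 = res$omega3,
    snapshot_times = res$snapshot_times, snapshots = res$snapshots,
    beta_centers = beta_centers(params$M),
    final_state = structure(list(t = n_steps * params$dt, fat2 = res$fat2,
                                 forces = res$forces, beta = res$beta,
                                 omega3 = res$omega3[length(res$omega3)]),
                            class = "egg_state"),
    diagnostics = list(max_abs_bn = res$max_abs_bn, min_c = res$min_c),
    params = params, model = "base"
  ), class = "egg_trajectory")
}

#' @export
print.egg_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<egg_trajectory> model '%s', %d samples, t in [%g, %g]\n",
              x$model, n, x$times[1L], x$times[n]))
  w <- x$omega3[x$times >= 0.8 * x$times[n]]
  cat(sprintf("  mean omega3 over final 20%%: %.5f\n", mean(w)))
  invisible(x)
}

#' @export
plot.egg_trajectory <- function(x, ...) {
  plot(x$times, x$omega3, type = "l", xlab = "t (units of onset time)",
       ylab = expression(omega[3]), ...)
  abline(h = 0, lty = 3)
  invisible(x)
}
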