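#' Total active torque in the lab frame
#'
#' Generalizes the right-hand side of the axis-constrained torque balance to
#' full 3-D rotation: \eqn{\sum_i (R r_i) \times (R b_i) = R \sum_i r_i
#' \times b_i}, where `R` is the body-to-lab rotation.
#'
#' @param geometry an `egg_geometry`.
#' @param forces N x 3 matrix of body-frame tangent forces.
#' @param q unit quaternion `c(w, x, y, z)` giving the body-to-lab rotation
#'   (identity by default).
#' @return length-3 lab-frame torque vector.
#' @export
total_torque <- function(geometry, forces, q = c(1, 0, 0, 0)) {
  r <- geometry$positions
  tb <- c(sum(r[, 2L] * forces[, 3L] - r[, 3L] * forces[, 2L]),
          sum(r[, 3L] * forces[, 1L] - r[, 1L] * forces[, 3L]),
          sum(r[, 1L] * forces[, 2L] - r[, 2L] * forces[, 1L]))
  as.vector(quat_to_matrix(q) %*% tb)
}

#' Elastic torque aligning the AP axis with the pre-stalk axis
#'
#' The flattened interface with the stationary pre-stalk cells resists motion
#' normal to itself elastically; at the rigid-body level this acts as a
#' restoring torque \eqn{T = k_s (\hat d_3 \times \hat e_3)} that rotates the
#' co-moving AP axis `d3` towards the fixed pre-stalk axis `e3`, vanishing at
#' alignment.  `T` is perpendicular to both axes.
#'
#' @param d3 unit AP-axis vector (lab frame).
#' @param ks elastic stiffness (>= 0).
#' @param e3 fixed pre-stalk axis (default lab z).
#' @return length-3 torque vector.
#' @export
elastic_alignment_torque <- function(d3, ks, e3 = c(0, 0, 1)) {
  ks * cross3(d3, e3)
}

#' Viscous drag torque from the pre-stalk interface
#'
#' Cells within the anterior cap (lab-frame polar angle from `e3` smaller
#' than `theta_s`) slide tangentially past the stationary pre-stalk cells and
#' feel viscous drag; the resulting torque is
#' \deqn{-\mu_s \sum_{j \in cap} r_j' \times (\omega \times r_j'), \quad
#'   r_j' = R r_j.}
#' It is purely dissipative: its dot product with \eqn{\omega} is never
#' positive.
#'
#' @param geometry an `egg_geometry` (unit sphere).
#' @param q body-to-lab unit quaternion.
#' @param omega lab-frame angular velocity.
#' @param theta_s cap polar half-angle (radians).
#' @param mus drag coefficient (>= 0).
#' @param e3 fixed pre-stalk axis.
#' @return length-3 torque vector.
#' @export
prestalk_drag <- function(geometry, q, omega, theta_s, mus, e3 = c(0, 0, 1)) {
  -as.vector(prestalk_drag_operator(geometry, q, theta_s, mus, e3) %*% omega)
}

# 3x3 PSD operator A with drag torque = -A %*% omega
prestalk_drag_operator <- function(geometry, q, theta_s, mus,
                                   e3 = c(0, 0, 1)) {
  R <- quat_to_matrix(q)
  rp <- geometry$positions %*% t(R)
  incap <- as.vector(rp %*% e3) >= cos(theta_s) * sqrt(rowSums(rp^2))
  A <- matrix(0, 3L, 3L)
  for (j in which(incap)) {
    p <- rp[j, ]
    A <- A + mus * (sum(p * p) * diag(3L) - outer(p, p))
  }
  A
}

# One step of the free-sphere / pre-stalk dynamics (reference implementation;
# ks = mus = 0 gives the unconstrained sphere).  Matches the compiled loop on
# the same RNG stream.
step_sphere_generic <- function(state, params, geometry, step_index = 0L,
                                ks = 0, mus = 0, theta_s = 0,
                                e3 = c(0, 0, 1)) {
  dt <- params$dt
  if (step_index %% params$resample_every == 0L || anyNA(state$beta))
    state$beta <- sample_protrusion_angles(state$fat2)
  state <- step_forces(state, params, geometry)
  R <- quat_to_matrix(state$q)
  Tlab <- total_torque(geometry, state$forces, state$q)
  d3 <- R[, 3L]
  Pi_iso <- drag_coefficient(1, geometry$N)
  if (ks > 0 || mus > 0) {
    Tlab <- Tlab + elastic_alignment_torque(d3, ks, e3)
    A <- diag(Pi_iso, 3L) + prestalk_drag_operator(geometry, state$q, theta_s,
                                                   mus, e3)
    omega <- solve(A, Tlab)
  } else {
    omega <- Tlab / Pi_iso
  }
  state$omega <- as.vector(omega)
  # advance orientation, then update Fat2 with the pre-update frame
  wn <- norm3(state$omega)
  if (wn > 0)
    state$q <- quat_normalize(quat_multiply(quat_from_omega(state$omega, dt),
                                            state$q))
  wb <- as.vector(t(R) %*% state$omega)
  v <- t(apply(geometry$positions, 1L, function(r) cross3(wb, r)))
  state$fat2 <- update_fat2_field(state$fat2, v, params, geometry, dt)
  state$t <- state$t + dt
  state
}

#' One step of the unconstrained spherical model
#'
#' Reference single-step integrator for the sphere (`e = 1`) with a free
#' rotation axis: the overdamped isotropic balance \eqn{\omega =
#' T / \Pi(1)}, a quaternion exponential-map orientation update, and the
#' usual force/Fat2 dynamics in the co-rotating frame.
#'
#' @param state an `egg_state` carrying a unit quaternion `q` and lab-frame
#'   `omega` (see [init_orientation_state()]).
#' @param params,geometry model parameters and geometry (`geometry$e` must
#'   be 1).
#' @param step_index 0-based step index (resampling schedule).
#' @return the advanced state.
#' @export
step_free_sphere <- function(state, params, geometry, step_index = 0L) {
  if (geometry$e != 1)
    stop("free-axis rotation is defined for a sphere (e = 1) only")
  step_sphere_generic(state, params, geometry, step_index)
}

#' Initialize a state with orientation degrees of freedom
#'
#' As [init_state()], plus an identity body-to-lab quaternion and zero
#' angular velocity vector.
#'
#' @inheritParams init_state
#' @return an `egg_state` with extra fields `q` and `omega`.
#' @export
init_orientation_state <- function(params, geometry) {
  state <- init_state(params, geometry)
  state$q <- c(1, 0, 0, 0)
  state$omega <- c(0, 0, 0)
  state
}

run_sphere_cpp <- function(params, geometry, ks, mus, theta_s, model) {
  stopifnot(inherits(params, "egg_params"), inherits(geometry, "egg_geometry"))
  if (geometry$e != 1)
    stop("the spherical models require e = 1")
  n_steps <- as.integer(round(params$T / params$dt))
  set.seed(params$seed)
  res <- cpp_run_sphere(
    geometry$positions, geometry$normals, geometry$t1, geometry$t2,
    drag_coefficient(1, geometry$N),
    params$tau1, params$tau2, params$tau3, params$dt, n_steps,
    params$M, params$resample_every, params$c_floor, params$record_every,
    ks, mus, theta_s, params$omega_max)
  omega_norm <- sqrt(rowSums(res$omega^2))
  structure(list(
    times = res$times, omega3 = res$omega3, omega = res$omega,
    omega_norm = omega_norm, d3 = res$d3,
    beta_centers = beta_centers(params$M),
    final_state = structure(list(t = n_steps * params$dt, fat2 = res$fat2,
                                 forces = res$forces, beta = res$beta,
                                 omega3 = res$omega3[length(res$omega3)],
                                 q = res$quat,
                                 omega = res$omega[nrow(res$omega), ]),
                            class = "egg_state"),
    diagnostics = list(min_c = res$min_c),
    params = params, model = model
  ), class = "egg_trajectory")
}

#' Run the unconstrained spherical model
#'
#' Full 3-D rotation of a spherical chamber with no external constraint: the
#' epithelium still breaks symmetry, but the rotation axis is free and its
#' final direction varies from seed to seed.
#'
#' @param params an [model_params()] object.
#' @param geometry a spherical [make_geometry()] (`e = 1`).
#' @return an `egg_trajectory` with `omega` (K x 3, lab frame), `omega_norm`,
#'   `omega3` (\eqn{\omega \cdot \hat d_3}) and `d3` (K x 3).
#' @export
run_free_sphere <- function(params, geometry) {
  run_sphere_cpp(params, geometry, ks = 0, mus = 0, theta_s = 0,
                 model = "sphere")
}

#' Run the stage-1 pre-stalk interface model
#'
#' Spherical chamber with the anterior cap in contact with stationary
#' pre-stalk cells: elastic restoring torque for normal motion (stiffness
#' `ks`), viscous drag for tangential sliding (`mus`) over the cap of polar
#' half-angle `theta_s`.  Symmetry breaks as in the free model, and the
#' rotation axis is drawn towards the fixed pre-stalk axis `e3`; stronger
#' `ks` aligns it faster.
#'
#' @param params a [prestalk_params()] object.
#' @param geometry a spherical [make_geometry()] (`e = 1`).
#' @return an `egg_trajectory` (model `"prestalk"`) with the same fields as
#'   [run_free_sphere()].
#' @export
run_prestalk_model <- function(params, geometry) {
  stopifnot(inherits(params, "egg_prestalk_params"))
  run_sphere_cpp(params, geometry, ks = params$ks, mus = params$mus,
                 theta_s = params$theta_s, model = "prestalk")
}

#' Angle between the rotation axis and the pre-stalk axis over time
#'
#' Treats the rotation axis as undirected (clockwise and counterclockwise
#' rotation about the pre-stalk axis are both "aligned"), folding angles
#' above 90 degrees.
#'
#' @param traj an `egg_trajectory` from a spherical model.
#' @param e3 reference axis.
#' @return vector of angles in radians, `NA` where `|omega| = 0`.
#' @export
axis_alignment_angle <- function(traj, e3 = c(0, 0, 1)) {
  stopifnot(!is.null(traj[["omega"]]))
  apply(traj[["omega"]], 1L, function(w) {
    if (norm3(w) == 0) return(NA_real_)
    axis_angle(w, e3)
  })
}

#' First time the rotation axis aligns with the pre-stalk axis
#'
#' @param traj an `egg_trajectory` from [run_prestalk_model()].
#' @param threshold alignment threshold in radians (default 10 degrees).
#' @param e3 reference axis.
#' @return the first recorded time at which the (undirected) angle between
#'   `omega` and `e3` drops below `threshold`, or `NA` if it never does.
#' @export
alignment_time <- function(traj, threshold = 10 * pi / 180, e3 = c(0, 0, 1)) {
  ang <- axis_alignment_angle(traj, e3)
  hit <- which(!is.na(ang) & ang < threshold)
  if (length(hit) == 0L) return(NA_real_)
  traj$times[hit[1L]]
}
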