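#' Non-dimensional model parameters
#'
#' Collects the parameters of the mechanochemical feedback model in
#' non-dimensional form (time in units of the characteristic rotation-onset
#' time, lengths in units of the equatorial radius, Fat2 concentration in
#' units of its characteristic scale):
#'
#' \describe{
#'   \item{tau1}{relaxation rate of the crawling force towards the
#'     protrusion direction set by Fat2 (ratio of the rotation-onset time to
#'     the force-reorientation time).}
#'   \item{tau2}{overall rate of Fat2 turnover (saturation dynamics).}
#'   \item{tau3}{gain of the mechanosensitive Fat2 recruitment relative to
#'     saturation; the feedback loop breaks symmetry only when this gain
#'     outweighs turnover.}
#'   \item{dt}{explicit-Euler step; `dt * tau1 < 1` is required for
#'     stability.}
#'   \item{T}{total simulated time.}
#'   \item{M}{number of angular bins of the per-cell Fat2 field (>= 8).}
#'   \item{resample_every}{steps between redraws of the stochastic protrusion
#'     angles.}
#'   \item{c_floor}{lower floor of the Fat2 field (keeps the sampling weights
#'     strictly positive; the dynamics do not conserve Fat2 mass).}
#'   \item{seed}{integer RNG seed.}
#'   \item{record_every}{steps between recorded `omega3` samples.}
#'   \item{snapshot_every}{steps between recorded cell-averaged Fat2
#'     snapshots.}
#'   \item{omega_max}{divergence guard: the run aborts if `|omega|` exceeds
#'     this bound.}
#' }
#'
#' @param tau1,tau2,tau3,dt,T,M,resample_every,c_floor,seed,record_every,snapshot_every,omega_max
#'   see Details.
#' @return a validated list of class `egg_params`.
#' @export
model_params <- function(tau1 = 1, tau2 = 1, tau3 = 40, dt = 0.01, T = 200,
                         M = 64L, resample_every = 1L, c_floor = 1e-8,
                         seed = 1L, record_every = 20L, snapshot_every = 500L,
                         omega_max = 100) {
  stopifnot_scalar(tau1, "tau1", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(tau2, "tau2", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(tau3, "tau3", lower = 0)
  stopifnot_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(T, "T", lower = 0, strict_lower = TRUE)
  if (dt * tau1 >= 1)
    stop("unstable integration: dt * tau1 must be < 1")
  if (!is.numeric(M) || M < 8 || M != round(M))
    stop("`M` must be an integer >= 8")
  if (!is.numeric(resample_every) || resample_every < 1 ||
      resample_every != round(resample_every))
    stop("`resample_every` must be an integer >= 1")
  stopifnot_scalar(c_floor, "c_floor", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(omega_max, "omega_max", lower = 0, strict_lower = TRUE)
  structure(list(tau1 = tau1, tau2 = tau2, tau3 = tau3, dt = dt, T = T,
                 M = as.integer(M), resample_every = as.integer(resample_every),
                 c_floor = c_floor, seed = as.integer(seed),
                 record_every = as.integer(record_every),
                 snapshot_every = as.integer(snapshot_every),
                 omega_max = omega_max),
            class = "egg_params")
}

#' Parameters of the stage-1 pre-stalk interface model
#'
#' Extends [model_params()] with the mechanical interaction between the
#' anterior cap of the (spherical) egg chamber and the stationary pre-stalk
#' cells: motion normal to the flattened interface is resisted elastically,
#' motion tangential to it viscously.
#'
#' @param theta_s polar half-angle (radians, in (0, pi/2)) of the interface
#'   cap around the fixed pre-stalk axis `e3 = (0, 0, 1)` in the lab frame.
#' @param ks elastic alignment stiffness (dimensionless torque per radian of
#'   misalignment between the co-moving AP axis `d3` and `e3`).
#' @param mus viscous drag coefficient of interface cells sliding past the
#'   stationary pre-stalk cells.
#' @param ... passed to [model_params()].
#' @return a validated list of class `c("egg_prestalk_params", "egg_params")`.
#' @export
prestalk_params <- function(theta_s = 0.6, ks = 500, mus = 30, ...) {
  base <- model_params(...)
  stopifnot_scalar(theta_s, "theta_s", lower = 0, strict_lower = TRUE)
  if (theta_s >= pi / 2) stop("`theta_s` must be < pi/2")
  stopifnot_scalar(ks, "ks", lower = 0)
  stopifnot_scalar(mus, "mus", lower = 0)
  base$theta_s <- theta_s
  base$ks <- ks
  base$mus <- mus
  class(base) <- c("egg_prestalk_params", "egg_params")
  base
}

#' Angular bin centers of the Fat2 field
#'
#' Bin-center angles in `(-pi, pi)`, width `2*pi/M`.  For even `M` the grid
#' is constructed symmetrically so that `centers[M + 1 - k]` is the exact
#' floating-point negation of `centers[k]`; the chirality-mirror symmetry of
#' the model then holds bitwise, not just analytically.
#'
#' @param M number of bins.
#' @return numeric vector of `M` angles.
#' @export
beta_centers <- function(M) {
  M <- as.integer(M)
  h <- 2 * pi / M
  if (M %% 2L == 0L) {
    half <- M %/% 2L
    pos <- (seq_len(half) - 0.5) * h
    c(rev(-pos), pos)
  } else {
    -pi + (seq_len(M) - 0.5) * h
  }
}
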