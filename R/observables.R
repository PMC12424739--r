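#' Direction of sustained rotation
#'
#' Classifies a run by the sign of the time-averaged `omega3` over the final
#' 20% of the trajectory: `"CCW"` (\eqn{\omega_3 > 0}), `"CW"`
#' (\eqn{\omega_3 < 0}), or `"none"` when the mean is not clearly away from
#' zero.  When `typical` (an ensemble-typical steady \eqn{|\omega_3|}) is
#' supplied, "clearly away" means larger than `frac_of_typical * typical`;
#' otherwise any exactly-zero mean is `"none"`.
#'
#' @param traj an `egg_trajectory`.
#' @param typical optional ensemble-typical steady magnitude.
#' @param frac_of_typical threshold fraction of `typical` (default 0.1).
#' @param window fraction of the run treated as the steady window (default
#'   final 0.2).
#' @return one of `"CW"`, `"CCW"`, `"none"`.
#' @export
rotation_direction <- function(traj, typical = NULL, frac_of_typical = 0.1,
                               window = 0.2) {
  m <- steady_omega3(traj, window)
  thr <- if (is.null(typical)) 0 else frac_of_typical * typical
  if (abs(m) <= thr) return("none")
  if (m > 0) "CCW" else "CW"
}

#' Time-averaged omega3 over the steady (final) window
#'
#' @param traj an `egg_trajectory`.
#' @param window fraction of the run used (default final 0.2).
#' @return mean signed `omega3` over the window.
#' @export
steady_omega3 <- function(traj, window = 0.2) {
  if (is.null(traj$times) || length(traj$times) == 0L)
    stop("empty trajectory")
  tmax <- traj$times[length(traj$times)]
  sel <- traj$times >= (1 - window) * tmax
  mean(traj$omega3[sel])
}

#' Onset time of sustained rotation
#'
#' The onset is the first time \eqn{|\omega_3|} exceeds `frac` times the
#' steady magnitude and remains above it for the rest of the run
#' (rotation starts with switch-like dynamics, so a sustained
#' threshold-crossing is a natural definition).
#'
#' @param traj an `egg_trajectory`.
#' @param frac fraction of the steady \eqn{|\omega_3|} (default 0.5).
#' @param window steady window fraction passed to [steady_omega3()].
#' @return the onset time.
#' @export
onset_time <- function(traj, frac = 0.5, window = 0.2) {
  steady <- abs(steady_omega3(traj, window))
  if (steady == 0) stop("no sustained rotation: onset time undefined")
  thr <- frac * steady
  above <- abs(traj$omega3) >= thr
  # last index below threshold; onset is the next sample (0 if never below)
  below <- which(!above)
  if (length(below) == 0L) return(0)
  idx <- below[length(below)] + 1L
  if (idx > length(traj$times)) stop("threshold never sustained: no onset")
  traj$times[idx]
}

#' Circular mean of a Fat2 distribution
#'
#' Argument of the complex resultant \eqn{\sum_k c(\beta_k)
#' e^{i \beta_k}} of a (cell-averaged) Fat2 distribution over the angular
#' bins; in a counterclockwise-rotating chamber the distribution polarizes
#' around \eqn{-\pi/2} (the trailing edge), in a clockwise one around
#' \eqn{+\pi/2}.
#'
#' @param c_beta non-negative weights per bin.
#' @param centers bin-center angles (defaults to [beta_centers()] of
#'   `length(c_beta)`).
#' @return angle in `(-pi, pi]`.
#' @export
fat2_circular_mean <- function(c_beta, centers = beta_centers(length(c_beta))) {
  if (any(!is.finite(c_beta)) || any(c_beta < 0))
    stop("distribution must be finite and non-negative")
  x <- sum(c_beta * cos(centers))
  y <- sum(c_beta * sin(centers))
  if (x == 0 && y == 0) stop("distribution has no resultant: mean undefined")
  atan2(y, x)
}

#' Summarize an ensemble of model runs
#'
#' @param trajs list of >= 2 `egg_trajectory` objects.
#' @param window steady-window fraction.
#' @return a list of class `egg_ensemble`: `n_runs`, `fraction_ccw`,
#'   `directions`, `steady_omega3` (signed), `onset_times` (`NA` where no
#'   sustained rotation), `fat2_means` (circular means of the final
#'   cell-averaged distributions, `NA` where unavailable).
#' @export
summarize_ensemble <- function(trajs, window = 0.2) {
  if (length(trajs) < 2L) stop("an ensemble needs at least 2 runs")
  steady <- vapply(trajs, steady_omega3, numeric(1L), window = window)
  typical <- median(abs(steady))
  dirs <- vapply(trajs, rotation_direction, character(1L),
                 typical = typical, window = window)
  onsets <- vapply(trajs, function(tr) {
    out <- tryCatch(onset_time(tr, window = window), error = function(e) NA_real_)
    out
  }, numeric(1L))
  fat2_means <- vapply(trajs, function(tr) {
    if (is.null(tr$snapshots)) {
      if (is.null(tr$final_state$fat2)) return(NA_real_)
      return(fat2_circular_mean(colMeans(tr$final_state$fat2),
                                tr$beta_centers))
    }
    fat2_circular_mean(tr$snapshots[nrow(tr$snapshots), ], tr$beta_centers)
  }, numeric(1L))
  structure(list(
    n_runs = length(trajs),
    fraction_ccw = mean(dirs == "CCW"),
    directions = dirs,
    steady_omega3 = steady,
    typical_steady = typical,
    onset_times = onsets,
    fat2_means = fat2_means
  ), class = "egg_ensemble")
}

#' @export
print.egg_ensemble <- function(x, ...) {
  cat(sprintf("<egg_ensemble> %d runs: %.1f%% CCW, typical steady |omega3| = %.4g\n",
              x$n_runs, 100 * x$fraction_ccw, x$typical_steady))
  invisible(x)
}
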