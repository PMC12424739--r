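#' Configuration for the synthetic track generator
#'
#' Emulates the three experimental regimes seen in basal-surface centroid
#' tracking: `"rotating"` (rigid drift of the whole field plus small
#' isotropic jitter), `"pre_rotation"` (no drift, large zero-mean local
#' jitter — dynamic basal surfaces before rotation starts) and `"null_like"`
#' (no drift, near-static jitter, as in *fat2* null tissue).  Mode-specific
#' defaults: drift 0.2 µm/min in `"rotating"` (the measured stage-1
#' rotation rate) and 0 otherwise; per-frame jitter standard deviation
#' 0.05 µm (`rotating`), 0.15 µm (`pre_rotation`), 0.02 µm (`null_like`).
#'
#' @param mode one of `"rotating"`, `"pre_rotation"`, `"null_like"`.
#' @param n_cells number of cells (placed on a jittered hexagonal lattice).
#' @param n_frames number of frames.
#' @param frame_interval_s frame interval in seconds (default 15, as in the
#'   30-minute basal-surface movies).
#' @param drift_um_min common drift speed in µm/min (`NULL` = mode default).
#' @param jitter_sd_um per-frame isotropic Gaussian jitter SD in µm
#'   (`NULL` = mode default).
#' @param dropout_frac fraction of cells truncated to `short_len` frames
#'   (below the 10-consecutive-frame filter threshold).
#' @param short_len length of dropout tracks (< 10).
#' @param field_um side of the square field of view in µm.
#' @param seed integer seed.
#' @return a validated list of class `track_gen_config`.
#' @export
track_gen_config <- function(mode = c("rotating", "pre_rotation", "null_like"),
                             n_cells = 80L, n_frames = 121L,
                             frame_interval_s = 15,
                             drift_um_min = NULL, jitter_sd_um = NULL,
                             dropout_frac = 0.1, short_len = 6L,
                             field_um = 50, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(drift_um_min))
    drift_um_min <- if (mode == "rotating") 0.2 else 0
  if (is.null(jitter_sd_um))
    jitter_sd_um <- switch(mode, rotating = 0.05, pre_rotation = 0.15,
                           null_like = 0.02)
  stopifnot_scalar(n_cells, "n_cells", lower = 1)
  stopifnot_scalar(n_frames, "n_frames", lower = 2)
  stopifnot_scalar(frame_interval_s, "frame_interval_s", lower = 0,
                   strict_lower = TRUE)
  stopifnot_scalar(drift_um_min, "drift_um_min", lower = 0)
  stopifnot_scalar(jitter_sd_um, "jitter_sd_um", lower = 0)
  stopifnot_scalar(dropout_frac, "dropout_frac", lower = 0)
  if (dropout_frac >= 1) stop("`dropout_frac` must be < 1")
  stopifnot_scalar(field_um, "field_um", lower = 0, strict_lower = TRUE)
  structure(list(mode = mode, n_cells = as.integer(n_cells),
                 n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s,
                 drift_um_min = drift_um_min, jitter_sd_um = jitter_sd_um,
                 dropout_frac = dropout_frac, short_len = as.integer(short_len),
                 field_um = field_um, seed = as.integer(seed)),
            class = "track_gen_config")
}

#' Generate synthetic centroid tracks
#'
#' Cells start on a jittered hexagonal lattice inside the square field; each
#' frame every cell moves by the common drift vector (drift speed times the
#' frame interval, along one random direction fixed per realization) plus
#' independent isotropic Gaussian jitter.  A `dropout_frac` fraction of
#' cells is truncated to `short_len` frames, and cells within one median
#' nearest-neighbour spacing of the field edge are flagged as boundary
#' cells.
#'
#' @param cfg a [track_gen_config()].
#' @return a track data.frame (`cell_id, frame, t_min, x_um, y_um,
#'   boundary`).
#' @examples
#' tr <- gen_tracks(track_gen_config("rotating", jitter_sd_um = 0, seed = 2))
#' polar_order(filter_tracks(tr))   # pure drift: 1
#' @export
gen_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "track_gen_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cells

  # hexagonal lattice filling the field, lightly jittered
  spacing <- sqrt(cfg$field_um^2 / n * 2 / sqrt(3))
  ncol_ <- ceiling(cfg$field_um / spacing) + 2L
  nrow_ <- ceiling(cfg$field_um / (spacing * sqrt(3) / 2)) + 2L
  gx <- as.vector(outer(seq_len(ncol_) - 1.5, rep(1, nrow_)) * spacing)
  gy <- as.vector(outer(rep(1, ncol_),
                        (seq_len(nrow_) - 1.5) * spacing * sqrt(3) / 2))
  odd <- rep(rep(c(0, 1), length.out = nrow_), each = ncol_)
  gx <- gx + odd * spacing / 2
  # take the n candidates closest to the field centre
  half <- cfg$field_um / 2
  ord <- order(pmax(abs(gx - half), abs(gy - half)))[seq_len(n)]
  gx <- gx[ord]
  gy <- gy[ord]
  gx <- gx + rnorm(n, sd = spacing * 0.1)
  gy <- gy + rnorm(n, sd = spacing * 0.1)

  # boundary flag: within one median nearest-neighbour spacing of the edge
  d <- as.matrix(stats::dist(cbind(gx, gy)))
  diag(d) <- Inf
  nn <- apply(d, 1L, min)
  margin <- median(nn)
  boundary <- gx < margin | gx > cfg$field_um - margin |
    gy < margin | gy > cfg$field_um - margin

  dt_min <- cfg$frame_interval_s / 60
  theta <- runif(1L, 0, 2 * pi)
  step_drift <- cfg$drift_um_min * dt_min * c(cos(theta), sin(theta))

  frames <- seq_len(cfg$n_frames)
  dx <- matrix(rnorm(n * (cfg$n_frames - 1L), sd = cfg$jitter_sd_um),
               nrow = n) + step_drift[1L]
  dy <- matrix(rnorm(n * (cfg$n_frames - 1L), sd = cfg$jitter_sd_um),
               nrow = n) + step_drift[2L]
  x <- cbind(gx, gx + t(apply(dx, 1L, cumsum)))
  y <- cbind(gy, gy + t(apply(dy, 1L, cumsum)))

  n_drop <- floor(cfg$dropout_frac * n)
  dropped <- if (n_drop > 0) sample.int(n, n_drop) else integer(0)

  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    len <- if (i %in% dropped) min(cfg$short_len, cfg$n_frames) else cfg$n_frames
    data.frame(cell_id = i, frame = frames[seq_len(len)],
               t_min = (frames[seq_len(len)] - 1L) * dt_min,
               x_um = x[i, seq_len(len)], y_um = y[i, seq_len(len)],
               boundary = boundary[i])
  }))
  rownames(out) <- NULL
  out
}

#' Generate synthetic cell-edge intensity records
#'
#' Edge angles are uniform on `[0, 90]` degrees; intensities are lognormal
#' with mean `ratio` for leading/trailing-like edges (angle <= 10 deg),
#' mean 1 for lateral edges (angle >= 80 deg), and linear interpolation of
#' the mean in between.  `noise_cv = 0` gives noiseless intensities equal to
#' the local mean.
#'
#' @param n number of edges.
#' @param ratio target leading/lateral polarity ratio (> 0).
#' @param noise_cv lognormal coefficient of variation.
#' @param seed integer seed.
#' @return an edge data.frame (`edge_id, angle_deg, mean_intensity`).
#' @export
gen_edges <- function(n, ratio = 1.5, noise_cv = 0.2, seed = 1L) {
  stopifnot_scalar(n, "n", lower = 1)
  stopifnot_scalar(ratio, "ratio", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(noise_cv, "noise_cv", lower = 0)
  set.seed(as.integer(seed))
  angle <- runif(n, 0, 90)
  frac <- pmin(1, pmax(0, (angle - 10) / 70))
  m <- ratio + (1 - ratio) * frac
  intensity <- if (noise_cv == 0) {
    m
  } else {
    sdlog <- sqrt(log(1 + noise_cv^2))
    rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  }
  data.frame(edge_id = seq_len(n), angle_deg = angle,
             mean_intensity = intensity)
}
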