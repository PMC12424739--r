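# Centroid-track and edge-intensity quantification.
#
# Tracks are plain data.frames with columns cell_id, frame, t_min, x_um,
# y_um, boundary (logical); edges have edge_id, angle_deg (0..90, relative
# to the AP axis), mean_intensity.

track_columns <- c("cell_id", "frame", "t_min", "x_um", "y_um", "boundary")
edge_columns <- c("edge_id", "angle_deg", "mean_intensity")

validate_tracks <- function(tracks) {
  missing <- setdiff(track_columns, names(tracks))
  if (length(missing) > 0L)
    stop("track table is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(tracks[, c("cell_id", "frame")]))
    stop("duplicate (cell_id, frame) pairs in track table")
  if (!all(is.finite(tracks$x_um)) || !all(is.finite(tracks$y_um)))
    stop("non-finite coordinates in track table")
  invisible(tracks)
}

validate_edges <- function(edges) {
  missing <- setdiff(edge_columns, names(edges))
  if (length(missing) > 0L)
    stop("edge table is missing column(s): ", paste(missing, collapse = ", "))
  if (any(edges$angle_deg < 0 | edges$angle_deg > 90))
    stop("edge angles must lie in [0, 90] degrees")
  if (!all(is.finite(edges$mean_intensity)) || any(edges$mean_intensity < 0))
    stop("edge intensities must be finite and >= 0")
  invisible(edges)
}

#' Filter centroid tracks
#'
#' Applies the standard track filters: cells present for fewer than
#' `min_len` consecutive frames are discarded (for each cell only its
#' longest run of consecutive frames is kept), and boundary-flagged cells
#' are dropped.  Idempotent.
#'
#' @param tracks a track data.frame (`cell_id, frame, t_min, x_um, y_um,
#'   boundary`).
#' @param min_len minimum number of consecutive frames (default 10).
#' @param drop_boundary drop cells flagged as lying at the tissue boundary.
#' @return the filtered track data.frame.
#' @export
filter_tracks <- function(tracks, min_len = 10, drop_boundary = TRUE) {
  validate_tracks(tracks)
  if (drop_boundary) {
    bnd <- tapply(tracks$boundary, tracks$cell_id, any)
    keep_cells <- names(bnd)[!bnd]
    tracks <- tracks[as.character(tracks$cell_id) %in% keep_cells, ,
                     drop = FALSE]
  }
  pieces <- lapply(split(tracks, tracks$cell_id, drop = TRUE), function(df) {
    df <- df[order(df$frame), , drop = FALSE]
    run_id <- cumsum(c(1L, diff(df$frame) != 1L))
    runs <- split(seq_len(nrow(df)), run_id)
    lens <- lengths(runs)
    best <- runs[[which.max(lens)]]
    if (length(best) < min_len) return(NULL)
    df[best, , drop = FALSE]
  })
  out <- do.call(rbind, pieces)
  if (is.null(out) || nrow(out) == 0L)
    stop("no tracks remain after filtering")
  rownames(out) <- NULL
  out
}

#' Remove tissue drift by per-frame centering
#'
#' Subtracts, in each frame, the mean position of all cells present in that
#' frame (a centroid-table proxy for centering on the tissue-mask centroid),
#' so rigid translation of the whole tissue is removed.
#'
#' @param tracks a track data.frame.
#' @return the centered track data.frame.
#' @export
center_tracks <- function(tracks) {
  validate_tracks(tracks)
  cx <- ave(tracks$x_um, tracks$frame)
  cy <- ave(tracks$y_um, tracks$frame)
  tracks$x_um <- tracks$x_um - cx
  tracks$y_um <- tracks$y_um - cy
  tracks
}

#' Polar order parameter of centroid movements
#'
#' Computes
#' \deqn{\alpha = \frac{\left| \sum_j \sum_i p_i^j \right|}
#'                     {\sum_j \sum_i |p_i^j|},}
#' where \eqn{p_i^j = x_{i+1}^j - x_i^j} are the per-cell centroid
#' displacements between consecutive sampling times, summed over every cell
#' present at both times.  \eqn{\alpha = 1} when all movements are perfectly
#' aligned and \eqn{\alpha \to 0} for isotropic movements.  Tracks are
#' decimated to the sampling interval by frame selection (not averaging) and
#' restricted to the stated duration.
#'
#' @param tracks a (filtered) track data.frame.
#' @param interval sampling interval in minutes (default 1).
#' @param duration analysis window in minutes from the first frame (default
#'   30).
#' @return `alpha` in `[0, 1]`.
#' @export
polar_order <- function(tracks, interval = 1, duration = 30) {
  validate_tracks(tracks)
  rel <- tracks$t_min - min(tracks$t_min)
  on_grid <- abs(rel / interval - round(rel / interval)) < 1e-9
  sub <- tracks[on_grid & rel <= duration + 1e-9, , drop = FALSE]
  sub$slot <- as.integer(round((sub$t_min - min(tracks$t_min)) / interval))
  vx <- 0; vy <- 0; mag <- 0
  for (df in split(sub, sub$cell_id, drop = TRUE)) {
    df <- df[order(df$slot), , drop = FALSE]
    if (nrow(df) < 2L) next
    ok <- diff(df$slot) == 1L
    dx <- diff(df$x_um)[ok]
    dy <- diff(df$y_um)[ok]
    vx <- vx + sum(dx)
    vy <- vy + sum(dy)
    mag <- mag + sum(sqrt(dx^2 + dy^2))
  }
  if (mag == 0) stop("all displacements are zero: polar order undefined")
  sqrt(vx^2 + vy^2) / mag
}

#' Net displacement of each cell and the tissue mean
#'
#' The per-cell net displacement is the distance between the first and last
#' centroid position; the tissue value is the mean over cells.
#'
#' @param tracks a (filtered) track data.frame.
#' @return list with `per_cell` (named vector, µm) and `mean` (µm).
#' @export
displacement_stats <- function(tracks) {
  validate_tracks(tracks)
  per_cell <- vapply(split(tracks, tracks$cell_id, drop = TRUE), function(df) {
    df <- df[order(df$frame), , drop = FALSE]
    n <- nrow(df)
    sqrt((df$x_um[n] - df$x_um[1L])^2 + (df$y_um[n] - df$y_um[1L])^2)
  }, numeric(1L))
  list(per_cell = per_cell, mean = mean(per_cell))
}

#' Mean migration rate from centroid displacement
#'
#' For each cell, the path-integrated frame-to-frame displacement divided by
#' the elapsed time at the native frame interval (`method = "path"`,
#' default), or the net first-to-last displacement over elapsed time
#' (`method = "net"`); the tissue rate is the mean over cells.
#'
#' @param tracks a (filtered, centered) track data.frame.
#' @param method `"path"` or `"net"`.
#' @return mean migration rate in µm/min.
#' @export
migration_rate <- function(tracks, method = c("path", "net")) {
  method <- match.arg(method)
  validate_tracks(tracks)
  rates <- vapply(split(tracks, tracks$cell_id, drop = TRUE), function(df) {
    df <- df[order(df$frame), , drop = FALSE]
    n <- nrow(df)
    elapsed <- df$t_min[n] - df$t_min[1L]
    if (elapsed <= 0) stop("zero elapsed time for cell ", df$cell_id[1L])
    dist <- if (method == "path") {
      sum(sqrt(diff(df$x_um)^2 + diff(df$y_um)^2))
    } else {
      sqrt((df$x_um[n] - df$x_um[1L])^2 + (df$y_um[n] - df$y_um[1L])^2)
    }
    dist / elapsed
  }, numeric(1L))
  mean(rates)
}

#' Fat2 planar-polarity ratio from edge intensities
#'
#' Ratio of the mean fluorescence intensity of cell-cell edges nearly
#' parallel to the migration (AP) axis — angles in `[0, 10]` degrees,
#' the leading/trailing edges — to that of nearly perpendicular (lateral)
#' edges, angles in `[80, 90]` degrees.  Both bins are closed; edges outside
#' them are ignored.
#'
#' @param edges an edge data.frame (`edge_id, angle_deg, mean_intensity`).
#' @param leading_max upper angle of the leading/trailing bin (degrees).
#' @param lateral_min lower angle of the lateral bin (degrees).
#' @return the scalar intensity ratio.
#' @export
fat2_polarity_ratio <- function(edges, leading_max = 10, lateral_min = 80) {
  validate_edges(edges)
  lead <- edges$mean_intensity[edges$angle_deg >= 0 &
                                 edges$angle_deg <= leading_max]
  lat <- edges$mean_intensity[edges$angle_deg >= lateral_min &
                                edges$angle_deg <= 90]
  if (length(lead) == 0L)
    stop("no edges in the leading/trailing bin [0, ", leading_max, "] deg")
  if (length(lat) == 0L)
    stop("no edges in the lateral bin [", lateral_min, ", 90] deg")
  mean(lead) / mean(lat)
}
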