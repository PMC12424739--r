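# Configuration and file I/O (plain CSV/JSON/YAML; all artifacts are
# inspectable text).

config_defaults <- function() {
  list(
    geometry = list(e = 1.2, N = 200L, jitter_sd = 0),
    model = list(tau1 = 1, tau2 = 1, tau3 = 40, dt = 0.01, T = 200, M = 64L,
                 resample_every = 1L, c_floor = 1e-8, seed = 1L,
                 record_every = 20L, snapshot_every = 500L, omega_max = 100),
    prestalk = list(theta_s = 0.6, ks = 500, mus = 30),
    analysis = list(min_len = 10L, drop_boundary = TRUE, interval = 1,
                    duration = 30)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration with sections `geometry`, `model`,
#' `prestalk` and `analysis`, fills defaults for anything omitted, rejects
#' unknown sections or keys, and reports every violation at once.  An empty
#' file yields the full default configuration.
#'
#' @param path path to a YAML/JSON file.
#' @return a validated config list of class `egg_config` with the four
#'   sections plus `params()`/`pparams()` already constructed.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- config_defaults()
  errors <- character(0)
  unknown_sections <- setdiff(names(raw), names(defaults))
  if (length(unknown_sections) > 0L)
    errors <- c(errors, paste0("unknown section(s): ",
                               paste(unknown_sections, collapse = ", ")))
  cfg <- defaults
  for (sec in intersect(names(raw), names(defaults))) {
    unknown <- setdiff(names(raw[[sec]]), names(defaults[[sec]]))
    if (length(unknown) > 0L)
      errors <- c(errors, paste0("unknown key(s) in `", sec, "`: ",
                                 paste(unknown, collapse = ", ")))
    cfg[[sec]] <- modifyList(defaults[[sec]],
                             raw[[sec]][setdiff(names(raw[[sec]]), unknown)])
  }
  params <- tryCatch(do.call(model_params, cfg$model),
                     error = function(e) {
                       errors <<- c(errors, conditionMessage(e))
                       NULL
                     })
  pparams <- tryCatch(do.call(prestalk_params, c(cfg$prestalk, cfg$model)),
                      error = function(e) {
                        errors <<- c(errors, conditionMessage(e))
                        NULL
                      })
  if (!is.numeric(cfg$geometry$e) || cfg$geometry$e < 1)
    errors <- c(errors, "`geometry.e` must be a number >= 1")
  if (!is.numeric(cfg$geometry$N) || cfg$geometry$N < 4)
    errors <- c(errors, "`geometry.N` must be an integer >= 4")
  if (length(errors) > 0L)
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  structure(c(cfg, list(params = params, pparams = pparams)),
            class = "egg_config")
}

#' Save a configuration
#'
#' Writes the four config sections back to YAML; `load_config()` of the
#' result round-trips.
#'
#' @param config an `egg_config` (or plain list with the same sections).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config[c("geometry", "model", "prestalk", "analysis")],
                   path)
  invisible(path)
}

#' Read and write centroid-track tables
#'
#' CSV dialect: header `cell_id,frame,t_min,x_um,y_um,boundary`, UTF-8.
#' Reading validates column presence and numeric content and reports
#' offending rows.
#'
#' @param path CSV file path.
#' @param tracks a track data.frame.
#' @return `read_tracks`: the validated data.frame; `write_tracks`: `path`,
#'   invisibly.
#' @export
read_tracks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(track_columns, names(df))
  if (length(missing) > 0L)
    stop("track file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("frame", "t_min", "x_um", "y_um")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad) > 0L)
      stop("non-numeric `", col, "` in ", path, " at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    df[[col]] <- as.numeric(df[[col]])
  }
  df$boundary <- as.logical(df$boundary)
  validate_tracks(df)
  df
}

#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  validate_tracks(tracks)
  write.csv(tracks[, track_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read and write cell-edge intensity tables
#'
#' CSV dialect: header `edge_id,angle_deg,mean_intensity`.
#'
#' @param path CSV file path.
#' @param edges an edge data.frame.
#' @return `read_edges`: the validated data.frame; `write_edges`: `path`,
#'   invisibly.
#' @export
read_edges <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(edge_columns, names(df))
  if (length(missing) > 0L)
    stop("edge file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("angle_deg", "mean_intensity")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad) > 0L)
      stop("non-numeric `", col, "` in ", path, " at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    df[[col]] <- as.numeric(df[[col]])
  }
  validate_edges(df)
  df
}

#' @rdname read_edges
#' @export
write_edges <- function(edges, path) {
  validate_edges(edges)
  write.csv(edges[, edge_columns], path, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory to CSV (with JSON metadata sidecar)
#'
#' Axis-constrained runs produce columns `t,omega3`; spherical runs add
#' `omega_norm` and the spherical angles (polar `theta`, azimuth `phi`) of
#' the rotation axis and the co-moving AP axis in the inertial frame.  A
#' long-format CSV of cell-averaged Fat2 snapshots
#' (`t,beta_bin_center,c_mean`) and a JSON sidecar with the parameters are
#' written alongside when requested.
#'
#' @param traj an `egg_trajectory`.
#' @param path output CSV path; the sidecars use suffixes `_fat2.csv` and
#'   `_meta.json`.
#' @param sidecars write the Fat2 snapshot and metadata files too.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, sidecars = TRUE) {
  df <- data.frame(t = traj$times, omega3 = traj$omega3)
  if (!is.null(traj[["omega"]])) {
    sph <- function(v) {
      n <- sqrt(rowSums(v^2))
      cbind(theta = acos(pmin(1, pmax(-1, ifelse(n > 0, v[, 3L] / n, NA)))),
            phi = atan2(v[, 2L], v[, 1L]))
    }
    so <- sph(traj[["omega"]])
    sd3 <- sph(traj$d3)
    df$omega_norm <- traj$omega_norm
    df$theta_omega <- so[, "theta"]
    df$phi_omega <- so[, "phi"]
    df$theta_d3 <- sd3[, "theta"]
    df$phi_d3 <- sd3[, "phi"]
  }
  write.csv(df, path, row.names = FALSE)
  if (sidecars) {
    base <- sub("\\.csv$", "", path)
    if (!is.null(traj$snapshots)) {
      snaps <- data.frame(
        t = rep(traj$snapshot_times, each = length(traj$beta_centers)),
        beta_bin_center = rep(traj$beta_centers, length(traj$snapshot_times)),
        c_mean = as.vector(t(traj$snapshots)))
      write.csv(snaps, paste0(base, "_fat2.csv"), row.names = FALSE)
    }
    meta <- list(model = traj$model, params = unclass(traj$params),
                 package_version = as.character(utils::packageVersion("eggspin")))
    jsonlite::write_json(meta, paste0(base, "_meta.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
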