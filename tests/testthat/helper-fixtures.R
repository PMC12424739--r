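# Shared fixtures: small geometries and quick parameter sets.

small_geom <- function(e = 1.2, N = 20) make_geometry(e, N)

quick_params <- function(...) {
  args <- list(...)
  defaults <- list(T = 1, dt = 0.01, M = 16L, seed = 1L, record_every = 1L,
                   snapshot_every = 50L)
  do.call(model_params, modifyList(defaults, args))
}

# hand-built trajectory object for observable tests
fake_traj <- function(times, omega3, snapshots = NULL, centers = NULL) {
  structure(list(times = times, omega3 = omega3, snapshots = snapshots,
                 beta_centers = centers, model = "base"),
            class = "egg_trajectory")
}

# straight-line track table: one row per frame per cell
make_track_df <- function(cells, n_frames, step_xy, start = c(0, 0),
                          dt_min = 1, boundary = FALSE) {
  do.call(rbind, lapply(seq_along(cells), function(j) {
    fr <- seq_len(n_frames)
    data.frame(cell_id = cells[j], frame = fr, t_min = (fr - 1) * dt_min,
               x_um = start[1] + (fr - 1) * step_xy[j, 1],
               y_um = start[2] + (fr - 1) * step_xy[j, 2],
               boundary = boundary)
  }))
}
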