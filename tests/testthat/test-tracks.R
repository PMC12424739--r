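test_that("track filtering enforces the 10-consecutive-frame rule", {
  nine <- make_track_df("a", 9, rbind(c(1, 0)))
  ten <- make_track_df("b", 10, rbind(c(1, 0)))
  both <- rbind(nine, ten)
  kept <- filter_tracks(both)
  expect_equal(unique(kept$cell_id), "b")
  expect_error(filter_tracks(nine), "no tracks")
  # gapped track: the longest consecutive run is kept
  gapped <- make_track_df("c", 30, rbind(c(1, 0)))
  gapped <- gapped[!(gapped$frame %in% 7:8), ]
  kept <- filter_tracks(gapped)
  expect_equal(kept$frame, 9:30)
  # boundary cells are dropped unless asked otherwise
  bnd <- make_track_df("d", 20, rbind(c(1, 0)), boundary = TRUE)
  expect_error(filter_tracks(bnd), "no tracks")
  expect_equal(nrow(filter_tracks(bnd, drop_boundary = FALSE)), 20)
})

test_that("track filtering is idempotent", {
  set.seed(4)
  df <- gen_tracks(track_gen_config("pre_rotation", n_cells = 40,
                                    n_frames = 40, seed = 9))
  once <- filter_tracks(df)
  twice <- filter_tracks(once)
  expect_equal(once, twice)
})

test_that("per-frame centering removes rigid translation", {
  steps <- rbind(c(5, 0), c(5, 0), c(5, 0))
  df <- make_track_df(c("a", "b", "c"), 10, steps)
  df$y_um <- df$y_um + as.numeric(factor(df$cell_id))   # distinct cells
  centered <- center_tracks(df)
  for (cell in split(centered, centered$cell_id)) {
    expect_lt(max(abs(diff(cell$x_um))), 1e-12)
    expect_lt(max(abs(diff(cell$y_um))), 1e-12)
  }
  single <- make_track_df("solo", 5, rbind(c(2, 1)))
  cs <- center_tracks(single)
  expect_equal(cs$x_um, rep(0, 5))
  expect_equal(cs$y_um, rep(0, 5))
})

test_that("centering leaves rotation about the tissue centroid unchanged", {
  th0 <- seq(0, 2 * pi, length.out = 9)[-9]
  frames <- 1:12
  df <- do.call(rbind, lapply(seq_along(th0), function(j) {
    th <- th0[j] + 0.05 * (frames - 1)
    data.frame(cell_id = j, frame = frames, t_min = frames - 1,
               x_um = 3 * cos(th), y_um = 3 * sin(th), boundary = FALSE)
  }))
  centered <- center_tracks(df)
  # cells are arranged symmetrically, so the centroid is already the origin
  expect_equal(centered$x_um, df$x_um, tolerance = 1e-9)
  expect_equal(centered$y_um, df$y_um, tolerance = 1e-9)
})

test_that("polar order matches hand-computed cases", {
  # identical displacements: alpha = 1 exactly
  df <- make_track_df(c("a", "b", "c"), 31, rbind(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(polar_order(df), 1, tolerance = 1e-12)
  # equal and opposite displacements cancel
  df <- make_track_df(c("a", "b"), 31, rbind(c(1, 0), c(-1, 0)))
  expect_equal(polar_order(df), 0)
  # three displacements (1,0), (0,1), (-1,0) -> |(0,1)| / 3
  df <- data.frame(cell_id = rep(c("a", "b", "c"), each = 2),
                   frame = rep(1:2, 3), t_min = rep(0:1, 3),
                   x_um = c(0, 1, 0, 0, 0, -1), y_um = c(0, 0, 0, 1, 0, 0),
                   boundary = FALSE)
  expect_equal(polar_order(df), 1 / 3)
  expect_error(polar_order(make_track_df("a", 5, rbind(c(0, 0)))), "undefined")
})

test_that("polar order decimates to the sampling interval by frame selection", {
  # 15-s frames, drift 1 um per frame: only the 1-min subsamples count
  df <- make_track_df("a", 121, rbind(c(1, 0)), dt_min = 0.25)
  expect_equal(polar_order(df, interval = 1, duration = 30), 1)
  # a cell present at only one grid time contributes no displacement
  df2 <- rbind(df, make_track_df("b", 3, rbind(c(0, 1)), dt_min = 0.25))
  expect_equal(polar_order(df2), 1)
})

test_that("polar order is invariant to global rotation and rescaling", {
  set.seed(11)
  n <- 15
  steps <- matrix(rnorm(2 * n), ncol = 2)
  df <- make_track_df(sprintf("c%02d", 1:n), 31, steps)
  a0 <- polar_order(df)
  phi <- 0.77
  rot <- steps %*% rbind(c(cos(phi), sin(phi)), c(-sin(phi), cos(phi)))
  expect_equal(polar_order(make_track_df(sprintf("c%02d", 1:n), 31, rot)), a0,
               tolerance = 1e-12)
  expect_equal(polar_order(make_track_df(sprintf("c%02d", 1:n), 31,
                                         3.7 * steps)), a0, tolerance = 1e-12)
})

test_that("displacement statistics use first-to-last positions", {
  df <- make_track_df("a", 11, rbind(c(0.3, 0.4)))
  st <- displacement_stats(df)
  expect_equal(unname(st$per_cell["a"]), 5 * sqrt(0.3^2 + 0.4^2) * 2)
  # closed loop returns to start
  th <- seq(0, 2 * pi, length.out = 13)
  loop <- data.frame(cell_id = "loop", frame = 1:13, t_min = 0:12,
                     x_um = cos(th), y_um = sin(th), boundary = FALSE)
  expect_equal(displacement_stats(loop)$per_cell[["loop"]], 0, tolerance = 1e-12)
  # mean over cells
  two <- rbind(make_track_df("a", 11, rbind(c(0.2, 0))),
               make_track_df("b", 11, rbind(c(0.4, 0))))
  expect_equal(displacement_stats(two)$mean, 3)
})

test_that("migration rate averages per-cell speeds", {
  df <- make_track_df("a", 11, rbind(c(0.2, 0)))   # 0.2 um/min straight
  expect_equal(migration_rate(df), 0.2)
  two <- rbind(make_track_df("a", 11, rbind(c(0.1, 0))),
               make_track_df("b", 11, rbind(c(0, 0.3))))
  expect_equal(migration_rate(two), 0.2)
  static <- make_track_df("s", 11, rbind(c(0, 0)))
  expect_equal(migration_rate(static), 0)
  # net vs path: a zig-zag has zero net rate but positive path rate
  zig <- data.frame(cell_id = "z", frame = 1:11, t_min = 0:10,
                    x_um = rep(c(0, 1), length.out = 11), y_um = 0,
                    boundary = FALSE)
  expect_equal(migration_rate(zig, method = "net"), 0)
  expect_equal(migration_rate(zig, method = "path"), 1)
})

test_that("rate and displacement are unchanged by centering off a static frame", {
  set.seed(2)
  steps <- matrix(rnorm(20, sd = 0.1), ncol = 2)
  df <- make_track_df(sprintf("c%d", 1:10), 21, steps)
  shifted <- df
  shifted$x_um <- shifted$x_um + 12.3
  shifted$y_um <- shifted$y_um - 4.5
  expect_equal(migration_rate(center_tracks(df)),
               migration_rate(center_tracks(shifted)), tolerance = 1e-12)
  expect_equal(displacement_stats(center_tracks(df))$mean,
               displacement_stats(center_tracks(shifted))$mean,
               tolerance = 1e-12)
})

test_that("polarity ratio uses the closed angle bins", {
  edges <- data.frame(edge_id = 1:4, angle_deg = c(5, 10, 80, 90),
                      mean_intensity = c(2, 2, 1, 1))
  expect_equal(fat2_polarity_ratio(edges), 2)
  flat <- data.frame(edge_id = 1:6, angle_deg = c(0, 7, 10, 80, 85, 90),
                     mean_intensity = rep(3, 6))
  expect_equal(fat2_polarity_ratio(flat), 1)
  # edges outside both bins are ignored; empty bins are an error
  mid <- data.frame(edge_id = 1, angle_deg = 45, mean_intensity = 1)
  expect_error(fat2_polarity_ratio(mid), "leading")
  skew <- rbind(mid, data.frame(edge_id = 2, angle_deg = 5, mean_intensity = 4))
  expect_error(fat2_polarity_ratio(skew), "lateral")
  expect_error(fat2_polarity_ratio(
    data.frame(edge_id = 1, angle_deg = 95, mean_intensity = 1)), "90")
})
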