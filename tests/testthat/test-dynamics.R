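test_that("initial state is isotropic with zero forces and seeded RNG", {
  g <- small_geom()
  p <- quick_params()
  st <- init_state(p, g)
  expect_equal(unique(as.vector(st$fat2)), 1 / (2 * pi))
  expect_equal(st$forces, matrix(0, g$N, 3))
  expect_equal(st$omega3, 0)
  b1 <- sample_protrusion_angles(st$fat2)   # stream seeded by init_state
  st2 <- init_state(p, g)                   # re-seeds identically
  b2 <- sample_protrusion_angles(st2$fat2)
  expect_identical(b1, b2)                  # same seed, same draws
})

test_that("protrusion sampling follows the Fat2 distribution", {
  M <- 16L
  centers <- beta_centers(M)
  # degenerate: nearly all mass in one bin
  f <- matrix(1e-8, 40, M)
  f[, 5] <- 1
  set.seed(2)
  beta <- sample_protrusion_angles(f)
  expect_true(all(beta == centers[5]))
  # uniform field: empirical CDF within Kolmogorov distance 0.01 of uniform,
  # evaluated at bin edges where the binned and continuous CDFs coincide
  M <- 64L
  n <- 1e5L
  set.seed(7)
  draws <- sample_protrusion_angles(matrix(1 / (2 * pi), n, M))
  edges <- seq(-pi, pi, length.out = M + 1)
  emp <- vapply(edges, function(e) mean(draws <= e), numeric(1))
  expect_lt(max(abs(emp - (edges + pi) / (2 * pi))), 0.01)
  # same rng state, same draws
  f <- matrix(runif(5 * 8) + 0.1, 5, 8)
  set.seed(3); d1 <- sample_protrusion_angles(f)
  set.seed(3); d2 <- sample_protrusion_angles(f)
  expect_identical(d1, d2)
  expect_error(sample_protrusion_angles(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("force relaxation has fixed point -eta and the exponential closed form", {
  g <- make_geometry(1, 8)
  p <- quick_params(tau1 = 1, dt = 0.01)
  st <- init_state(p, g)
  st$beta <- rep(0, g$N)          # frozen eta = t1
  for (s in seq_len(1000)) st <- step_forces(st, p, g)   # t = 10 / tau1
  expect_equal(st$forces, -g$t1, tolerance = 1e-3)
  # closed form b(t) = -eta (1 - exp(-tau1 t)) at t = 1/tau1, O(dt) accuracy
  st <- init_state(p, g)
  st$beta <- rep(0, g$N)
  for (s in seq_len(100)) st <- step_forces(st, p, g)
  expect_equal(st$forces, -g$t1 * (1 - exp(-1)), tolerance = 5e-3)
  # at the fixed point, forces are unchanged
  st$forces <- -cos(st$beta) * g$t1 - sin(st$beta) * g$t2
  before <- st$forces
  st <- step_forces(st, p, g)
  expect_equal(st$forces, before, tolerance = 1e-12)
  expect_error(step_forces(st, p, g, dt = 2), "unstable")
})

test_that("torque balance reproduces hand-computed cases", {
  # single equatorial cell with an azimuthal unit force on the unit sphere
  g1 <- structure(list(e = 1, N = 1, positions = rbind(c(1, 0, 0)),
                       normals = rbind(c(1, 0, 0)), t1 = rbind(c(0, 0, 1)),
                       t2 = rbind(c(0, 1, 0))), class = "egg_geometry")
  expect_equal(compute_omega3(g1, rbind(c(0, 1, 0))), 15 / (40 * pi))
  # meridional forces exert no torque about the long axis
  g <- make_geometry(1.4, 50)
  s <- rep(c(1, -1), length.out = 50)
  expect_equal(compute_omega3(g, s * g$t1), 0, tolerance = 1e-12)
  # two antipodal equatorial cells with opposite azimuthal forces cancel
  g2 <- structure(list(e = 1, N = 2,
                       positions = rbind(c(1, 0, 0), c(-1, 0, 0)),
                       normals = rbind(c(1, 0, 0), c(-1, 0, 0)),
                       t1 = rbind(c(0, 0, 1), c(0, 0, 1)),
                       t2 = rbind(c(0, 1, 0), c(0, -1, 0))),
                  class = "egg_geometry")
  forces <- rbind(c(0, 1, 0), c(0, 1, 0))  # +t2 for one, -t2 for the other
  brute <- sum(vapply(1:2, function(i) {
    rxb <- c(g2$positions[i, 2] * forces[i, 3] - g2$positions[i, 3] * forces[i, 2],
             g2$positions[i, 3] * forces[i, 1] - g2$positions[i, 1] * forces[i, 3],
             g2$positions[i, 1] * forces[i, 2] - g2$positions[i, 2] * forces[i, 1])
    rxb[3]
  }, numeric(1))) / drag_coefficient(1, 2)
  expect_equal(compute_omega3(g2, forces), brute, tolerance = 1e-15)
  expect_equal(compute_omega3(g2, forces), 0, tolerance = 1e-15)
})

test_that("vectorized torque sum equals a per-cell brute-force loop", {
  g <- make_geometry(1.6, 120)
  set.seed(5)
  b <- matrix(rnorm(120 * 3), ncol = 3)
  bn <- rowSums(b * g$normals)
  b <- b - bn * g$normals
  brute <- 0
  for (i in seq_len(120)) {
    r <- g$positions[i, ]
    brute <- brute + (r[1] * b[i, 2] - r[2] * b[i, 1])
  }
  brute <- brute / drag_coefficient(g$e, g$N)
  expect_equal(compute_omega3(g, b), brute, tolerance = 1e-12)
})

test_that("cell velocity follows rigid-body kinematics", {
  g1 <- structure(list(e = 1, N = 1, positions = rbind(c(1, 0, 0)),
                       normals = rbind(c(1, 0, 0)), t1 = rbind(c(0, 0, 1)),
                       t2 = rbind(c(0, 1, 0))), class = "egg_geometry")
  expect_equal(cell_velocity(1, g1, 1), c(0, 1, 0))
  expect_equal(cell_velocity(0, g1, 1), c(0, 0, 0))
  g <- small_geom(e = 1.5, N = 30)
  for (i in c(1, 10, 30)) {
    v <- cell_velocity(0.3, g, i)
    rho <- sqrt(sum(g$positions[i, 1:2]^2))
    expect_equal(sqrt(sum(v^2)), 0.3 * rho, tolerance = 1e-12)
  }
})

test_that("Fat2 dynamics match the closed-form decay and fixed points", {
  g <- make_geometry(1, 8)
  p <- quick_params(tau2 = 1, tau3 = 20, dt = 0.01)
  # v = 0: pure saturation decay c(t) = c0 / (1 + tau2 c0 t)
  st <- init_state(p, g)
  c0 <- 1 / (2 * pi)
  n_steps <- round(1 / (p$tau2 * c0) / p$dt)
  for (s in seq_len(n_steps)) st <- step_fat2(st, p, g)
  expect_equal(unique(round(as.vector(st$fat2), 12)), c0 / 2,
               tolerance = 1e-2)
  # with motion: growth bins approach c* = tau3 * s, decay bins hit the floor
  st <- init_state(p, g)
  st$omega3 <- 0.1
  for (s in seq_len(2000)) st <- step_fat2(st, p, g)
  centers <- beta_centers(p$M)
  i <- which.max(abs(g$positions[, 1]))   # near-equatorial cell
  v <- cell_velocity(st$omega3, g, i)
  vm <- vapply(centers, function(b) sum(v * tangent_unit(g, i, b)), numeric(1))
  grow <- which.min(vm)                   # most trailing bin
  expect_equal(st$fat2[i, grow], -p$tau3 * vm[grow], tolerance = 0.01)
  shrink <- which.max(vm)
  expect_equal(st$fat2[i, shrink], p$c_floor)
})

test_that("compiled integrator reproduces the composed R reference steps", {
  g <- small_geom(e = 1.2, N = 20)
  p <- quick_params(T = 0.5, M = 16L, seed = 9, resample_every = 2L)
  traj <- run_base_model(p, g)
  st <- init_state(p, g)
  w <- numeric(50)
  for (s in 0:49) {
    st <- step_base_model(st, p, g, step_index = s)
    w[s + 1] <- st$omega3
  }
  expect_equal(traj$omega3, w, tolerance = 1e-12)
  expect_equal(traj$final_state$fat2, st$fat2, tolerance = 1e-12)
  expect_equal(traj$final_state$forces, st$forces, tolerance = 1e-12)
})

test_that("force tangency and the Fat2 floor hold over many steps", {
  g <- small_geom(e = 1.3, N = 12)
  p <- quick_params(T = 100, M = 16L, seed = 4, tau3 = 40)
  st <- init_state(p, g)
  max_bn <- 0
  for (s in 0:9999) {
    st <- step_base_model(st, p, g, step_index = s)
    bn <- max(abs(rowSums(st$forces * g$normals)))
    if (bn > max_bn) max_bn <- bn
    if (s %% 1000 == 0) expect_true(all(st$fat2 >= p$c_floor))
  }
  expect_lt(max_bn, 1e-6)
  expect_true(all(st$fat2 >= p$c_floor))
  expect_true(all(is.finite(st$fat2)))
})
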