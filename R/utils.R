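# Small vector/quaternion helpers shared across modules.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

norm3 <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- norm3(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

# Quaternions stored as c(w, x, y, z); identity is c(1, 0, 0, 0).
quat_multiply <- function(p, q) {
  c(p[1L] * q[1L] - p[2L] * q[2L] - p[3L] * q[3L] - p[4L] * q[4L],
    p[1L] * q[2L] + p[2L] * q[1L] + p[3L] * q[4L] - p[4L] * q[3L],
    p[1L] * q[3L] - p[2L] * q[4L] + p[3L] * q[1L] + p[4L] * q[2L],
    p[1L] * q[4L] + p[2L] * q[3L] - p[3L] * q[2L] + p[4L] * q[1L])
}

# exp map: rotation by |w|*dt about w/|w|
quat_from_omega <- function(omega, dt) {
  angle <- norm3(omega) * dt
  if (angle < 1e-300) return(c(1, 0, 0, 0))
  axis <- omega / norm3(omega)
  c(cos(angle / 2), sin(angle / 2) * axis)
}

quat_normalize <- function(q) q / sqrt(sum(q * q))

quat_to_matrix <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

# angle between two unit-ish vectors, radians
angle_between <- function(a, b) {
  ca <- sum(unit3(a) * unit3(b))
  acos(max(-1, min(1, ca)))
}

# angle between undirected axes (0 .. pi/2-ish, folds antiparallel onto parallel)
axis_angle <- function(a, b) {
  th <- angle_between(a, b)
  min(th, pi - th)
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("`%s` must be > %g (got %g)", name, lower, x), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("`%s` must be >= %g (got %g)", name, lower, x), call. = FALSE)
  if (x > upper)
    stop(sprintf("`%s` must be <= %g (got %g)", name, upper, x), call. = FALSE)
  invisible(x)
}
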