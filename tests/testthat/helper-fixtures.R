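# Trajectory and session fixtures, built in code.

# circle/ellipse drawn with a controllable speed profile: speed_power != 1
# concentrates samples near the start (slow finish), exercising the
# arc-length resampling.
ellipse_traj <- function(a = 1, b = 1, center = c(0, 0), n = 200,
                         phase = 0, sweep = 2 * pi, speed_power = 1,
                         rotate = 0) {
  u <- seq(0, 1, length.out = n)
  th <- phase + sweep * u^speed_power
  x0 <- a * cos(th)
  y0 <- b * sin(th)
  x <- center[1] + cos(rotate) * x0 - sin(rotate) * y0
  y <- center[2] + sin(rotate) * x0 + cos(rotate) * y0
  raw_trajectory((seq_len(n) - 1) / 60, x, y)
}

circle_traj <- function(radius = 1, center = c(0, 0), n = 200, ...) {
  ellipse_traj(a = radius, b = radius, center = center, n = n, ...)
}

segment_traj <- function(from = c(0, 0), to = c(1, 0), n = 50) {
  u <- seq(0, 1, length.out = n)
  raw_trajectory((seq_len(n) - 1) / 60,
                 from[1] + u * (to[1] - from[1]),
                 from[2] + u * (to[2] - from[2]))
}

# minimal session around a radius/reward sequence (no geometry columns)
session_from_radii <- function(radii, rewarded = rep(FALSE, length(radii)),
                               target = 1, group = "adult", age = 30L,
                               is_circular = NA) {
  trials <- tibble::tibble(
    trial = seq_along(radii), radius = radii, target_radius = target,
    rel_error = relative_radius_error(radii, target), rewarded = rewarded,
    aspect_ratio = NA_real_, path_length = NA_real_,
    start_end_distance = NA_real_, center_x = NA_real_, center_y = NA_real_,
    is_circular = is_circular
  )
  circle_session(paste0("p", length(radii)), group, age, trials)
}

# mean distance of an arc-length-uniform ellipse to its center, by
# quadrature: mean = (integral of r(theta) ds) / (integral of ds),
# ds = sqrt(a^2 sin^2 + b^2 cos^2) dtheta — independent of the package's
# resampling code.
ellipse_mean_radius_oracle <- function(a, b) {
  ds <- function(th) sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2)
  r <- function(th) sqrt(a^2 * cos(th)^2 + b^2 * sin(th)^2)
  num <- stats::integrate(function(th) r(th) * ds(th), 0, 2 * pi,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(ds, 0, 2 * pi, rel.tol = 1e-10)$value
  num / den
}

# brute-force rank statistics: V as the count of positive Walsh averages
# (no-tie identity), U as a direct pair count.
walsh_V <- function(d) {
  n <- length(d)
  v <- 0
  for (i in seq_len(n)) for (j in i:n) v <- v + ((d[i] + d[j]) / 2 > 0)
  v
}
pair_U <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}
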