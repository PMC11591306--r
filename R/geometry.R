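#' Construct a raw pen trajectory
#'
#' A raw trajectory is one trial's pen path: parallel vectors of timestamps
#' (seconds, monotone nondecreasing) and x/y positions in cm, as recorded by
#' the tablet at 60 Hz. No smoothing or filtering is applied anywhere in the
#' pipeline.
#'
#' @param t numeric vector of timestamps in seconds, monotone nondecreasing.
#' @param x,y numeric vectors of pen positions in cm, same length as `t`.
#' @return An object of class `raw_trajectory`: a list with elements `t`,
#'   `x`, `y`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 100)
#' traj <- raw_trajectory(seq_along(th) / 60, cos(th), sin(th))
#' compute_radius(traj)
#' @export
raw_trajectory <- function(t, x, y) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(t) != length(x) || length(t) != length(y)) {
    stop_domain("t, x and y must have equal length")
  }
  if (length(t) < 2L) stop_degenerate("a trajectory needs at least 2 samples")
  if (!all(is.finite(t)) || !all(is.finite(x)) || !all(is.finite(y))) {
    stop_domain("trajectory samples must be finite")
  }
  if (any(diff(t) < 0)) stop_domain("timestamps must be monotone nondecreasing")
  structure(list(t = t, x = x, y = y), class = "raw_trajectory")
}

#' @export
print.raw_trajectory <- function(x, ...) {
  cat(sprintf("<raw_trajectory: %d samples, %.2f s, path %.2f cm>\n",
              length(x$t), diff(range(x$t)), path_length(x)))
  invisible(x)
}

is_raw_trajectory <- function(x) inherits(x, "raw_trajectory")

# condition helpers shared across modules
stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("circlelearn_degenerate_error",
                                     "circlelearn_error")))
}
stop_domain <- function(msg) {
  stop(errorCondition(msg, class = c("circlelearn_domain_error",
                                     "circlelearn_error")))
}

#' Center of a drawn trajectory
#'
#' The center is the midpoint of the bounding box: the mean of the maximum
#' and minimum horizontal and vertical positions.
#'
#' @param traj a [raw_trajectory()].
#' @return Named numeric vector `c(x = , y = )` in cm.
#' @export
compute_center <- function(traj) {
  stopifnot(is_raw_trajectory(traj))
  if (all(traj$x == traj$x[1]) && all(traj$y == traj$y[1])) {
    stop_degenerate("all trajectory points coincide; no center defined")
  }
  c(x = (min(traj$x) + max(traj$x)) / 2,
    y = (min(traj$y) + max(traj$y)) / 2)
}

#' Total polyline length of a trajectory, in cm
#' @param traj a [raw_trajectory()].
#' @export
path_length <- function(traj) {
  stopifnot(is_raw_trajectory(traj))
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Distance between the start and end point of a trajectory, in cm
#' @param traj a [raw_trajectory()].
#' @export
start_end_distance <- function(traj) {
  stopifnot(is_raw_trajectory(traj))
  n <- length(traj$x)
  sqrt((traj$x[n] - traj$x[1])^2 + (traj$y[n] - traj$y[1])^2)
}

#' Resample a trajectory uniformly in arc length
#'
#' Participants draw at variable speed, so time-uniform samples oversample
#' slow parts of the path. Resampling to `n` points equally spaced in arc
#' length removes the speed profile from all downstream geometry. Points sit
#' at arc lengths s_i = i * L / n for i = 0..n-1 (half-open: a closed curve's
#' coincident start/end point is not double-weighted).
#'
#' @param traj a [raw_trajectory()].
#' @param n number of output points (default 50).
#' @return A `n` x 2 matrix with columns `x`, `y` (class
#'   `resampled_trajectory`).
#' @export
resample_spatial <- function(traj, n = 50L) {
  stopifnot(is_raw_trajectory(traj), n >= 2L)
  seg <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  L <- sum(seg)
  if (L <= 0) stop_degenerate("zero path length; cannot resample")
  s <- c(0, cumsum(seg))
  keep <- c(TRUE, seg > 0)          # drop repeated points so s is strictly increasing
  s <- s[keep]; xs <- traj$x[keep]; ys <- traj$y[keep]
  si <- (seq_len(n) - 1L) * L / n
  out <- cbind(x = stats::approx(s, xs, xout = si)$y,
               y = stats::approx(s, ys, xout = si)$y)
  class(out) <- c("resampled_trajectory", class(out))
  out
}

#' Radius of a drawn circle
#'
#' Mean Euclidean distance between each arc-length-resampled point and the
#' trajectory center. Because of the resampling, slow parts of the drawing
#' do not bias the radius.
#'
#' @param traj a [raw_trajectory()].
#' @param n number of resampled points (default 50).
#' @return Radius in cm (> 0).
#' @export
compute_radius <- function(traj, n = 50L) {
  ctr <- compute_center(traj)
  pts <- resample_spatial(traj, n)
  mean(sqrt((pts[, 1] - ctr[["x"]])^2 + (pts[, 2] - ctr[["y"]])^2))
}

#' Aspect ratio of a drawn trajectory
#'
#' The ratio of two perpendicular extents of the drawing that deviates the
#' most from one. Orientations are scanned on a 1-degree grid over
#' \[0, 90) degrees; at each orientation the extent is the max-minus-min of
#' the resampled points projected on that direction, and the returned value
#' is the ratio extent(theta)/extent(theta + 90) whose |log| is maximal. A
#' perfect circle gives 1; an elongated or collapsed drawing gives a value
#' far from 1 (possibly below 1 or above 1 depending on orientation).
#'
#' @param traj a [raw_trajectory()].
#' @param n number of resampled points (default 50).
#' @param step_deg angular grid resolution in degrees (default 1).
#' @return Dimensionless aspect ratio (> 0, possibly `Inf` for a segment).
#' @export
compute_aspect_ratio <- function(traj, n = 50L, step_deg = 1) {
  pts <- resample_spatial(traj, n)
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  proj <- pts %*% rbind(cos(th), sin(th))
  ext <- apply(proj, 2, function(p) max(p) - min(p))
  half <- length(th) %/% 2L
  e1 <- ext[seq_len(half)]
  e2 <- ext[seq_len(half) + half]
  ratio <- e1 / e2
  dev <- abs(log(ratio))
  dev[is.nan(dev)] <- Inf           # 0/0: totally degenerate direction pair
  ratio[which.max(dev)]
}

#' Per-trial geometry summary
#'
#' Computes every geometric quantity a trial contributes to the analysis:
#' center, radius, aspect ratio, path length, start-end distance, and the
#' circularity flag.
#'
#' @param traj a [raw_trajectory()].
#' @param n number of resampled points (default 50).
#' @return An object of class `trial_geometry`: list with `center`, `radius`,
#'   `aspect_ratio`, `path_length`, `start_end_distance`, `is_circular`.
#' @export
trial_geometry <- function(traj, n = 50L) {
  ctr <- compute_center(traj)
  pts <- resample_spatial(traj, n)
  radius <- mean(sqrt((pts[, 1] - ctr[["x"]])^2 + (pts[, 2] - ctr[["y"]])^2))
  g <- structure(list(
    center = ctr,
    radius = radius,
    aspect_ratio = compute_aspect_ratio(traj, n),
    path_length = path_length(traj),
    start_end_distance = start_end_distance(traj),
    is_circular = NA
  ), class = "trial_geometry")
  g$is_circular <- classify_circular(g)
  g
}

#' Circularity gate for a drawn trial
#'
#' A drawing is regarded as non-circular when its aspect ratio is below 0.1
#' or above 10, or when the trajectory length is smaller than twice the
#' distance between the start and end point (an open stroke rather than a
#' loop). Non-circular trials still carry radii; the flag feeds the
#' participant-level exclusion rule (more than 20% non-circular trials).
#'
#' @param g a `trial_geometry` object from [trial_geometry()].
#' @param lower,upper aspect-ratio gates (defaults 0.1 and 10).
#' @return `TRUE` if the trial counts as circular, else `FALSE`.
#' @export
classify_circular <- function(g, lower = 0.1, upper = 10) {
  stopifnot(inherits(g, "trial_geometry"))
  !(g$aspect_ratio < lower || g$aspect_ratio > upper ||
      g$path_length < 2 * g$start_end_distance)
}

#' @export
print.trial_geometry <- function(x, ...) {
  cat(sprintf(paste0("<trial_geometry: r = %.3f cm, aspect = %.3f, ",
                     "path = %.2f cm, circular = %s>\n"),
              x$radius, x$aspect_ratio, x$path_length, x$is_circular))
  invisible(x)
}
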