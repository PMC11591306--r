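#' Target-radius rule
#'
#' The first `n_baseline_trials` trials are rewarded against a fixed initial
#' target of 4.3 cm; afterwards the target is set to `multiplier` times the
#' mean drawn radius of those baseline trials (by default, double).
#'
#' @param initial_target initial target radius in cm (default 4.3).
#' @param multiplier target multiplier applied to the baseline mean
#'   (default 2).
#' @param n_baseline_trials number of baseline trials (default 5).
#' @return Object of class `target_rule`.
#' @export
target_rule <- function(initial_target = 4.3, multiplier = 2,
                        n_baseline_trials = 5L) {
  stopifnot(initial_target > 0, multiplier > 0, n_baseline_trials >= 1)
  structure(list(initial_target = initial_target, multiplier = multiplier,
                 n_baseline_trials = as.integer(n_baseline_trials)),
            class = "target_rule")
}

#' Relative radius error
#'
#' max(radius/target, target/radius) - 1: zero when the drawn radius equals
#' the target, positive otherwise, and symmetric so that circles drawn twice
#' too large and twice too small score the same error (both 1).
#'
#' @param radius drawn radius in cm (> 0); vectorized.
#' @param target target radius in cm (> 0).
#' @return Dimensionless error >= 0.
#' @export
relative_radius_error <- function(radius, target) {
  if (any(radius <= 0) || any(target <= 0)) {
    stop_domain("radius and target must be positive")
  }
  pmax(radius / target, target / radius) - 1
}

#' Set the post-baseline target radius
#'
#' @param baseline_radii drawn radii of the baseline trials, in cm; length
#'   must equal `rule$n_baseline_trials`.
#' @param rule a [target_rule()].
#' @return Target radius in cm.
#' @export
set_target <- function(baseline_radii, rule = target_rule()) {
  if (length(baseline_radii) != rule$n_baseline_trials) {
    stop_domain(sprintf("expected %d baseline radii, got %d",
                        rule$n_baseline_trials, length(baseline_radii)))
  }
  if (any(baseline_radii <= 0)) stop_domain("baseline radii must be positive")
  rule$multiplier * mean(baseline_radii)
}

#' Adaptive-criterion state
#'
#' Sliding window of up to `window_size` past relative radius errors plus
#' the order statistic used as the reward threshold: the fifth entry of the
#' window sorted from small to large ("close to the median"), which holds
#' the long-run success rate near one half. The task sorts the past ten
#' errors ascending and rewards errors beating the fifth one; with i.i.d.
#' errors the implied reward probability is `order_index / (window_size +
#' 1)` = 5/11. Set `order_side = "largest"` for the variant that counts the
#' order statistic from the top instead (implied probability 6/11).
#'
#' @param window numeric vector of past errors, oldest first (default empty).
#' @param window_size maximum window length (default 10).
#' @param order_index rank of the threshold in the full sorted window
#'   (default 5, the fifth).
#' @param order_side `"smallest"` (default: rank counted from the bottom of
#'   the ascending sort) or `"largest"` (from the top).
#' @return Object of class `criterion_state`.
#' @export
criterion_state <- function(window = numeric(0), window_size = 10L,
                            order_index = 5L,
                            order_side = c("smallest", "largest")) {
  order_side <- match.arg(order_side)
  stopifnot(window_size >= 1, order_index >= 1, order_index <= window_size,
            length(window) <= window_size, all(window >= 0))
  structure(list(window = as.numeric(window),
                 window_size = as.integer(window_size),
                 order_index = as.integer(order_index),
                 order_side = order_side),
            class = "criterion_state")
}

#' Current reward threshold of the adaptive criterion
#'
#' With a full window the threshold is the `order_index`-th smallest stored
#' error (fifth of ten sorted ascending, by default). While the window is
#' still filling (the first trials), the ceil(n/2)-th smallest of the n
#' available errors is used, which keeps the implied reward probability
#' near one half from the second trial on. The returned value is always an
#' element of the window.
#'
#' @param state a [criterion_state()].
#' @return The threshold error value.
#' @export
criterion_threshold <- function(state) {
  stopifnot(inherits(state, "criterion_state"))
  n <- length(state$window)
  if (n == 0L) {
    stop(errorCondition("empty criterion window (cold start)",
                        class = c("circlelearn_cold_start", "circlelearn_error")))
  }
  k <- if (n >= state$window_size) state$order_index else ceiling(n / 2)
  sort(state$window, decreasing = identical(state$order_side, "largest"))[k]
}

#' Reward decision for one trial
#'
#' A trial is rewarded iff its relative radius error is strictly smaller than
#' the current threshold (only errors smaller than the fifth of the sorted
#' window win): ties are not rewarded. On a cold start (empty window, the very first trial) the
#' trial is rewarded iff the error is below `cold_start_threshold` (default
#' 1, i.e. the drawn radius is within a factor two of the target).
#'
#' @param error relative radius error of the current trial (>= 0).
#' @param state a [criterion_state()].
#' @param cold_start_threshold reward bound used when the window is empty.
#' @return `TRUE`/`FALSE`.
#' @export
assign_reward <- function(error, state, cold_start_threshold = 1) {
  stopifnot(error >= 0)
  if (length(state$window) == 0L) return(error < cold_start_threshold)
  error < criterion_threshold(state)
}

#' Push an error into the criterion window
#'
#' Appends the newest error and evicts the oldest beyond `window_size`.
#'
#' @param state a [criterion_state()].
#' @param error the error to store (>= 0).
#' @return Updated `criterion_state`.
#' @export
update_criterion <- function(state, error) {
  stopifnot(inherits(state, "criterion_state"), error >= 0)
  w <- c(state$window, error)
  if (length(w) > state$window_size) {
    w <- w[(length(w) - state$window_size + 1L):length(w)]
  }
  state$window <- w
  state
}

#' Run one closed-loop session
#'
#' Plays `n_trials` trials of the task: the radius source produces each
#' trial's drawing (a bare radius in cm, or a [raw_trajectory()] which is run
#' through [trial_geometry()]), the engine scores it against the current
#' target, decides reward via the adaptive criterion, and feeds the outcome
#' back to the source. After the baseline trials the target switches to
#' `rule$multiplier` times the baseline mean; by default the criterion
#' window is rebuilt from the baseline radii re-scored against the new
#' target so the criterion compares like with like (set
#' `recompute_errors_on_target_switch = FALSE` to keep the originally
#' experienced errors in the window instead). Trial records always keep the
#' target and error as played.
#'
#' @param radius_source function `(trial, prev_record)` returning either a
#'   positive radius (cm) or a `raw_trajectory`. `prev_record` is `NULL` on
#'   trial 1 and otherwise a one-row list with at least `radius` and
#'   `rewarded` for the previous trial.
#' @param rule a [target_rule()].
#' @param n_trials number of main-phase trials (default 80).
#' @param window_size,order_index,order_side criterion parameters, see
#'   [criterion_state()].
#' @param cold_start_threshold see [assign_reward()].
#' @param recompute_errors_on_target_switch logical (default `TRUE`).
#' @return A tibble with one row per trial: `trial`, `radius`,
#'   `target_radius`, `rel_error`, `rewarded`, `aspect_ratio`, `path_length`,
#'   `start_end_distance`, `center_x`, `center_y`, `is_circular` (geometry
#'   columns are `NA` when the source yields bare radii).
#' @export
run_session <- function(radius_source, rule = target_rule(), n_trials = 80L,
                        window_size = 10L, order_index = 5L,
                        order_side = "smallest", cold_start_threshold = 1,
                        recompute_errors_on_target_switch = TRUE) {
  n_trials <- as.integer(n_trials)
  stopifnot(is.function(radius_source), n_trials >= 1)
  radius <- target <- err <- numeric(n_trials)
  rewarded <- logical(n_trials)
  aspect <- plen <- sed <- cx <- cy <- rep(NA_real_, n_trials)
  circ <- rep(NA, n_trials)

  state <- criterion_state(window_size = window_size,
                           order_index = order_index,
                           order_side = order_side)
  cur_target <- rule$initial_target
  prev <- NULL
  nb <- rule$n_baseline_trials

  for (i in seq_len(n_trials)) {
    if (i == nb + 1L && n_trials > nb) {
      cur_target <- set_target(radius[seq_len(nb)], rule)
      if (recompute_errors_on_target_switch) {
        # rebuild the criterion window against the new target so it compares
        # like with like; the trial records keep the history as played
        keep <- max(1L, nb - window_size + 1L):nb
        state <- criterion_state(relative_radius_error(radius[keep],
                                                       cur_target),
                                 window_size, order_index, order_side)
      }
    }
    drawn <- radius_source(i, prev)
    if (is_raw_trajectory(drawn)) {
      g <- trial_geometry(drawn)
      radius[i] <- g$radius
      aspect[i] <- g$aspect_ratio
      plen[i] <- g$path_length
      sed[i] <- g$start_end_distance
      cx[i] <- g$center[["x"]]
      cy[i] <- g$center[["y"]]
      circ[i] <- g$is_circular
    } else {
      if (!is.numeric(drawn) || length(drawn) != 1L || drawn <= 0) {
        stop_domain("radius source must yield a positive radius or a raw_trajectory")
      }
      radius[i] <- drawn
    }
    target[i] <- cur_target
    err[i] <- relative_radius_error(radius[i], cur_target)
    rewarded[i] <- assign_reward(err[i], state, cold_start_threshold)
    state <- update_criterion(state, err[i])
    prev <- list(index = i, radius = radius[i], target_radius = cur_target,
                 rel_error = err[i], rewarded = rewarded[i])
  }

  tibble::tibble(
    trial = seq_len(n_trials), radius = radius, target_radius = target,
    rel_error = err, rewarded = rewarded, aspect_ratio = aspect,
    path_length = plen, start_end_distance = sed,
    center_x = cx, center_y = cy, is_circular = circ
  )
}
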