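#' Segment a pen-sample stream into trials
#'
#' A trial starts when the pen touches the tablet and ends once the pen is
#' lifted for longer than `lift_threshold` seconds (500 ms by default):
#' shorter lifts are merged into the surrounding trial. Only pen-down
#' samples enter the trial trajectories.
#'
#' @param stream data.frame with columns `t` (seconds, strictly increasing),
#'   `x`, `y` (cm) and logical `pen_down`.
#' @param lift_threshold lift duration in seconds that terminates a trial;
#'   strictly longer lifts split (default 0.5).
#' @return List of [raw_trajectory()] objects, ordered by time (possibly
#'   empty).
#' @export
segment_trials <- function(stream, lift_threshold = 0.5) {
  need <- c("t", "x", "y", "pen_down")
  if (!all(need %in% names(stream))) {
    stop_domain(paste("stream must contain columns:",
                      paste(need, collapse = ", ")))
  }
  if (is.unsorted(stream$t, strictly = TRUE)) {
    stop_domain("stream timestamps must be strictly increasing")
  }
  down <- which(stream$pen_down)
  if (!length(down)) return(list())
  # runs of consecutive pen-down samples
  run_id <- cumsum(c(1L, diff(down) != 1L))
  runs <- split(down, run_id)
  # merge runs whose separating lift lasted <= threshold
  trial_id <- integer(length(runs))
  trial_id[1] <- 1L
  for (i in seq_along(runs)[-1]) {
    gap <- stream$t[runs[[i]][1]] - stream$t[runs[[i - 1]][length(runs[[i - 1]])]]
    trial_id[i] <- trial_id[i - 1] + (gap > lift_threshold)
  }
  lapply(split(runs, trial_id), function(rr) {
    idx <- unlist(rr, use.names = FALSE)
    raw_trajectory(stream$t[idx], stream$x[idx], stream$y[idx])
  })
}

#' Read per-trial trajectories from CSV
#'
#' Native trajectory format: header `participant_id, trial, t_s, x_cm, y_cm`
#' (UTF-8, '.' decimal). Returns a nested list: per participant, per trial,
#' one [raw_trajectory()].
#'
#' @param path CSV file path.
#' @return Named list (participant) of named lists (trial) of trajectories.
#' @export
read_trajectories_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "trial", "t_s", "x_cm", "y_cm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_domain(sprintf("%s: missing columns: %s", path,
                        paste(miss, collapse = ", ")))
  }
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad)) {
    stop_domain(sprintf("%s: malformed row at line %d", path, bad[1] + 1L))
  }
  lapply(split(df, df$participant_id), function(dp) {
    lapply(split(dp, dp$trial), function(dt) {
      raw_trajectory(dt$t_s, dt$x_cm, dt$y_cm)
    })
  })
}

#' Write per-trial trajectories to CSV
#'
#' @param trajectories nested list as returned by [read_trajectories_csv()],
#'   or a list of trajectories for a single participant.
#' @param path output CSV path.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  if (is_raw_trajectory(trajectories[[1]])) {
    trajectories <- list(p01 = trajectories)
  }
  rows <- do.call(rbind, lapply(names(trajectories), function(pid) {
    trials <- trajectories[[pid]]
    ids <- if (is.null(names(trials))) seq_along(trials) else names(trials)
    do.call(rbind, lapply(seq_along(trials), function(k) {
      tr <- trials[[k]]
      data.frame(participant_id = pid, trial = ids[k],
                 t_s = tr$t, x_cm = tr$x, y_cm = tr$y)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

trial_summary_cols <- c("participant_id", "trial", "radius_cm", "target_cm",
                        "rel_error", "rewarded", "aspect_ratio",
                        "path_length_cm", "is_circular")

#' Write per-trial summaries for a cohort
#'
#' One row per trial with columns `participant_id, trial, radius_cm,
#' target_cm, rel_error, rewarded, aspect_ratio, path_length_cm,
#' is_circular`. Continuous fields are serialized at 6 significant digits,
#' which makes the native round-trip bit-stable at that precision.
#'
#' @param sessions list of [circle_session()] objects.
#' @param path output CSV path.
#' @export
write_trial_summaries <- function(sessions, path) {
  sig <- function(v) signif(v, 6)
  rows <- do.call(rbind, lapply(sessions, function(s) {
    tr <- s$trials
    data.frame(participant_id = s$participant_id, trial = tr$trial,
               radius_cm = sig(tr$radius), target_cm = sig(tr$target_radius),
               rel_error = sig(tr$rel_error), rewarded = tr$rewarded,
               aspect_ratio = sig(tr$aspect_ratio),
               path_length_cm = sig(tr$path_length),
               is_circular = tr$is_circular)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write participant metadata for a cohort
#'
#' Columns `participant_id, group, age, handedness, language,
#' n_main_trials`.
#'
#' @param sessions list of [circle_session()] objects.
#' @param path output CSV path.
#' @export
write_session_metadata <- function(sessions, path) {
  rows <- do.call(rbind, lapply(sessions, function(s) {
    data.frame(participant_id = s$participant_id, group = s$group,
               age = s$age, handedness = s$handedness,
               language = s$language, n_main_trials = s$n_main_trials)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

default_dialects <- list(
  native = list(columns = as.list(stats::setNames(trial_summary_cols,
                                                  trial_summary_cols)),
                unit_scale = 1),
  # Field mapping for externally deposited data is data, not code: override
  # via a descriptor JSON once the deposit's layout is confirmed. The
  # shipped descriptor mirrors the native schema and is unverified.
  osf = NULL
)

read_dialect <- function(dialect, descriptor = NULL) {
  if (!is.null(descriptor)) return(jsonlite::read_json(descriptor))
  if (identical(dialect, "native")) return(default_dialects$native)
  if (identical(dialect, "osf")) {
    return(jsonlite::read_json(system.file("extdata", "osf_dialect.json",
                                           package = "circlelearn")))
  }
  stop_domain(sprintf("unknown dialect '%s'", dialect))
}

#' Read sessions from a trial-summary CSV
#'
#' The reader is table-driven by a dialect descriptor mapping the file's
#' column names onto the native schema (`participant_id, trial, radius_cm,
#' target_cm, rel_error, rewarded, aspect_ratio, path_length_cm,
#' is_circular`) plus an optional unit scale for lengths. Dialect `"native"`
#' round-trips [write_trial_summaries()] losslessly at the serialized
#' precision; dialect `"osf"` loads a descriptor from the package's extdata.
#'
#' @param path trial-summary CSV.
#' @param dialect `"native"` or `"osf"`.
#' @param metadata optional path to a metadata CSV as written by
#'   [write_session_metadata()].
#' @param descriptor optional path to a dialect-descriptor JSON overriding
#'   the built-in mapping.
#' @return List of [circle_session()] objects.
#' @export
read_sessions <- function(path, dialect = "native", metadata = NULL,
                          descriptor = NULL) {
  dia <- read_dialect(dialect, descriptor)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- dia$columns
  need <- unlist(cols[c("participant_id", "trial", "radius_cm", "target_cm",
                        "rel_error", "rewarded")])
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_domain(sprintf("%s: missing columns: %s", path,
                        paste(miss, collapse = ", ")))
  }
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad)) {
    stop_domain(sprintf("%s: malformed row at line %d (field %s)", path,
                        bad[1] + 1L,
                        need[which(is.na(df[bad[1], need]))[1]]))
  }
  scale <- if (is.null(dia$unit_scale)) 1 else dia$unit_scale
  meta <- NULL
  if (!is.null(metadata)) {
    meta <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  }
  lapply(split(seq_len(nrow(df)), df[[cols$participant_id]]), function(idx) {
    d <- df[idx, ]
    d <- d[order(d[[cols$trial]]), ]
    getcol <- function(key) {
      nm <- cols[[key]]
      if (!is.null(nm) && nm %in% names(d)) d[[nm]] else rep(NA, nrow(d))
    }
    trials <- tibble::tibble(
      trial = d[[cols$trial]],
      radius = d[[cols$radius_cm]] * scale,
      target_radius = d[[cols$target_cm]] * scale,
      rel_error = d[[cols$rel_error]],
      rewarded = as.logical(d[[cols$rewarded]]),
      aspect_ratio = as.numeric(getcol("aspect_ratio")),
      path_length = as.numeric(getcol("path_length_cm")) * scale,
      start_end_distance = NA_real_,
      center_x = NA_real_, center_y = NA_real_,
      is_circular = as.logical(getcol("is_circular"))
    )
    pid <- as.character(d[[cols$participant_id]][1])
    m <- if (!is.null(meta)) meta[meta$participant_id == pid, ] else NULL
    if (!is.null(m) && nrow(m) == 1L) {
      circle_session(pid, m$group, m$age, trials, m$handedness, m$language,
                     n_main_trials = m$n_main_trials)
    } else {
      circle_session(pid, "adult", NA_integer_, trials)
    }
  })
}

#' Write participant summaries to CSV
#'
#' Missing medians (a participant with no trials in one reward condition)
#' are written as empty fields.
#'
#' @param summaries tibble from [summarize_cohort()].
#' @param path output CSV path.
#' @export
write_participant_summaries <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write group-level results to JSON
#'
#' @param results named list of numbers/lists (e.g. medians, IQRs, z, p).
#' @param path output JSON path.
#' @export
write_results <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

run_config_keys <- c("initial_target_cm", "multiplier", "n_baseline_trials",
                     "n_trials", "window_size", "order_index",
                     "cold_start_threshold",
                     "recompute_errors_on_target_switch", "seed",
                     "n_agents", "profile", "render", "out", "log_level")

#' Read and validate a run configuration JSON
#'
#' Recognized keys: `initial_target_cm, multiplier, n_baseline_trials,
#' n_trials, window_size, order_index, cold_start_threshold,
#' recompute_errors_on_target_switch, seed, n_agents, profile, render, out,
#' log_level`. Unknown keys are rejected so typos cannot silently change a
#' run.
#'
#' @param path JSON config path.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown)) {
    stop_domain(sprintf("unknown config keys: %s",
                        paste(unknown, collapse = ", ")))
  }
  cfg
}
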