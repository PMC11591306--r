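#' One participant's session
#'
#' Bundles the ordered per-trial records (as produced by [run_session()] or
#' read from disk) with participant metadata. Ages are rounded-down integer
#' years; the group label must be consistent with age (children are under
#' 18).
#'
#' @param participant_id character id.
#' @param group `"child"` or `"adult"`.
#' @param age age in years (rounded down).
#' @param trials a tibble/data.frame of per-trial records with at least
#'   `trial`, `radius`, `target_radius`, `rel_error`, `rewarded` (geometry
#'   columns optional), ordered by `trial`.
#' @param handedness,language optional metadata strings.
#' @param n_main_trials number of main-phase trials (default: all rows).
#' @return Object of class `circle_session`.
#' @export
circle_session <- function(participant_id, group = c("adult", "child"),
                           age = NA_integer_, trials,
                           handedness = NA_character_,
                           language = NA_character_,
                           n_main_trials = nrow(trials)) {
  group <- match.arg(group)
  need <- c("trial", "radius", "target_radius", "rel_error", "rewarded")
  if (!all(need %in% names(trials))) {
    stop_domain(paste("trials must contain columns:",
                      paste(need, collapse = ", ")))
  }
  if (is.unsorted(trials$trial, strictly = TRUE)) {
    stop_domain("trials must be strictly ordered by trial index")
  }
  if (!is.na(age) && ((group == "child") != (age < 18))) {
    stop_domain("group label inconsistent with age (child < 18)")
  }
  structure(list(participant_id = as.character(participant_id),
                 group = group, age = as.integer(age),
                 handedness = handedness, language = language,
                 trials = tibble::as_tibble(trials),
                 n_main_trials = as.integer(n_main_trials)),
            class = "circle_session")
}

#' @export
print.circle_session <- function(x, ...) {
  cat(sprintf("<circle_session %s (%s, age %s): %d trials>\n",
              x$participant_id, x$group, x$age, nrow(x$trials)))
  invisible(x)
}

main_trials <- function(s) {
  stopifnot(inherits(s, "circle_session"))
  s$trials[seq_len(min(s$n_main_trials, nrow(s$trials))), , drop = FALSE]
}

#' Baseline radius of a session
#'
#' Mean drawn radius of the first five main-phase trials — the same trials
#' that set the target radius, so the target is `multiplier` times this
#' value. There is no separate baseline block.
#'
#' @param s a [circle_session()].
#' @param n_baseline number of baseline trials (default 5).
#' @return Baseline radius in cm.
#' @export
baseline_radius <- function(s, n_baseline = 5L) {
  tr <- main_trials(s)
  if (nrow(tr) < n_baseline) {
    stop_domain(sprintf("need at least %d main-phase trials", n_baseline))
  }
  mean(tr$radius[seq_len(n_baseline)])
}

#' Fraction learned
#'
#' (mean radius of the last `n_last` main-phase trials) / baseline radius
#' - 1. Because the target is set at twice the baseline, 0 means no change
#' from baseline and 1 means the target radius was reached exactly; values
#' above 1 mean overshooting the target, below 0 shrinking below baseline.
#'
#' @param s a [circle_session()].
#' @param n_last number of final trials averaged (default 10).
#' @param n_baseline number of baseline trials (default 5).
#' @return Dimensionless fraction learned.
#' @export
fraction_learned <- function(s, n_last = 10L, n_baseline = 5L) {
  tr <- main_trials(s)
  if (nrow(tr) < max(n_last, n_baseline)) {
    stop_domain(sprintf("need at least %d main-phase trials",
                        max(n_last, n_baseline)))
  }
  last <- tr$radius[(nrow(tr) - n_last + 1L):nrow(tr)]
  mean(last) / baseline_radius(s, n_baseline) - 1
}

fold_ratio <- function(a, b) pmax(a / b, b / a)

#' Reward-conditioned trial-to-trial radius ratios
#'
#' For every interior trial t, the change from trial t-1 to trial t+1 is
#' summarized as the folded ratio max(r[t+1]/r[t-1], r[t-1]/r[t+1]) (>= 1:
#' halving and doubling count the same), and assigned to the after-reward or
#' after-no-reward sequence according to the reward at trial t. Skipping
#' trial t itself avoids the sampling bias that the reward zone imposes on
#' rewarded radii.
#'
#' @param s a [circle_session()].
#' @return List with numeric vectors `after_reward` and `after_no_reward`
#'   (either may be empty).
#' @export
trial_to_trial_ratios <- function(s) {
  tr <- main_trials(s)
  n <- nrow(tr)
  if (n < 3L) stop_domain("need at least 3 main-phase trials")
  t_mid <- 2:(n - 1L)
  ratio <- fold_ratio(tr$radius[t_mid + 1L], tr$radius[t_mid - 1L])
  rew <- tr$rewarded[t_mid]
  list(after_reward = ratio[rew], after_no_reward = ratio[!rew])
}

#' Reward-conditioned changes in task-irrelevant dimensions
#'
#' Circle location and aspect ratio do not influence reward, yet
#' participants modulate them too. Uses the same t-1 / t+1 pairing as
#' [trial_to_trial_ratios()]: aspect-ratio changes as folded ratios >= 1 and
#' center displacements as Euclidean distances (cm), split by the reward at
#' trial t. Requires sessions with geometry columns.
#'
#' @param s a [circle_session()].
#' @return List of two lists (`after_reward`, `after_no_reward`), each with
#'   `aspect_change` and `center_displacement`.
#' @export
task_irrelevant_changes <- function(s) {
  tr <- main_trials(s)
  n <- nrow(tr)
  if (n < 3L) stop_domain("need at least 3 main-phase trials")
  need <- c("aspect_ratio", "center_x", "center_y")
  if (!all(need %in% names(tr)) || anyNA(tr$aspect_ratio)) {
    stop_domain("session lacks per-trial geometry")
  }
  t_mid <- 2:(n - 1L)
  asp <- fold_ratio(tr$aspect_ratio[t_mid + 1L], tr$aspect_ratio[t_mid - 1L])
  disp <- sqrt((tr$center_x[t_mid + 1L] - tr$center_x[t_mid - 1L])^2 +
                 (tr$center_y[t_mid + 1L] - tr$center_y[t_mid - 1L])^2)
  rew <- tr$rewarded[t_mid]
  list(after_reward = list(aspect_change = asp[rew],
                           center_displacement = disp[rew]),
       after_no_reward = list(aspect_change = asp[!rew],
                              center_displacement = disp[!rew]))
}

#' Summarize one participant
#'
#' Computes every participant-level outcome: baseline radius, fraction
#' learned, median trial-to-trial ratio after rewarded and after
#' non-rewarded trials, success frequency (rewarded trials / main-phase
#' trials, including the initial-target trials), percentage of non-circular
#' trials, and the exclusion flag (excluded iff strictly more than 20% of
#' trials are non-circular). Sessions without geometry have unknown
#' circularity: `pct_noncircular` is 0 over zero gated trials and the
#' participant is not excluded.
#'
#' @param s a [circle_session()].
#' @param exclusion_pct exclusion threshold in percent (default 20).
#' @return One-row tibble (class-free) with the summary plus metadata.
#' @export
summarize_session <- function(s, exclusion_pct = 20) {
  tr <- main_trials(s)
  ratios <- trial_to_trial_ratios(s)
  med <- function(v) if (length(v)) stats::median(v) else NA_real_
  gated <- !is.na(tr$is_circular)
  pct_nc <- if (any(gated)) 100 * mean(!tr$is_circular[gated]) else 0
  tibble::tibble(
    participant_id = s$participant_id,
    group = s$group,
    age = s$age,
    handedness = s$handedness,
    language = s$language,
    baseline_radius = baseline_radius(s),
    fraction_learned = fraction_learned(s),
    median_ratio_after_reward = med(ratios$after_reward),
    median_ratio_after_no_reward = med(ratios$after_no_reward),
    success_frequency = mean(tr$rewarded),
    pct_noncircular = pct_nc,
    excluded = pct_nc > exclusion_pct
  )
}

#' Summarize a cohort of sessions
#'
#' @param sessions list of [circle_session()] objects.
#' @param exclusion_pct see [summarize_session()].
#' @return Tibble with one row per participant.
#' @export
summarize_cohort <- function(sessions, exclusion_pct = 20) {
  do.call(rbind, lapply(sessions, summarize_session,
                        exclusion_pct = exclusion_pct))
}
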