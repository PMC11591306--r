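#' Generative parameters of a simulated participant
#'
#' The simulated learner keeps an intended circle radius in log space (size
#' changes are multiplicative, matching the ratio-based analysis of the
#' task) and updates it by reward-gated exploration: after each trial the
#' intended log-radius relaxes toward the intended radius of the most
#' recent rewarded trial with weight `retention`, plus a zero-mean Gaussian
#' exploration step whose SD is larger after failure (`explore_sd_fail`)
#' than after success (`explore_sd_success`). Because the task gives no
#' visual feedback, the agent reinforces the motor command it intended, not
#' the (invisible) radius it actually produced. Two execution-side
#' processes shape realism: multiplicative motor noise (`motor_noise_sd` on
#' the log scale) present regardless of feedback, occasionally replaced by
#' an attentional lapse (probability `lapse_rate`, noise SD `lapse_sd`),
#' and a use-dependent pull of the intended radius back toward the habitual
#' baseline size (`habit_decay` per trial), which keeps reward-driven
#' growth gradual and incomplete.
#'
#' @param baseline_radius intended radius at the start of the session, cm.
#' @param motor_noise_sd SD of log-radius execution noise (dimensionless).
#' @param explore_sd_fail SD of the log-radius exploration step after a
#'   non-rewarded trial.
#' @param explore_sd_success SD after a rewarded trial (usually smaller).
#' @param retention weight in \[0, 1\] pulling the intended radius toward the
#'   intended radius of the last rewarded trial.
#' @param lapse_rate probability per trial of an attentional lapse.
#' @param lapse_sd log-radius execution-noise SD on lapse trials.
#' @param habit_decay per-trial relaxation rate in \[0, 1\] of the intended
#'   log-radius toward the habitual baseline size.
#' @return Object of class `agent_params`.
#' @export
agent_params <- function(baseline_radius = 2.15, motor_noise_sd = 0.085,
                         explore_sd_fail = 0.15, explore_sd_success = 0.06,
                         retention = 0.08, lapse_rate = 0.12,
                         lapse_sd = 0.6, habit_decay = 0.015) {
  stopifnot(baseline_radius > 0, motor_noise_sd >= 0, explore_sd_fail >= 0,
            explore_sd_success >= 0, retention >= 0, retention <= 1,
            lapse_rate >= 0, lapse_rate <= 1, lapse_sd >= 0,
            habit_decay >= 0, habit_decay <= 1)
  structure(list(baseline_radius = baseline_radius,
                 motor_noise_sd = motor_noise_sd,
                 explore_sd_fail = explore_sd_fail,
                 explore_sd_success = explore_sd_success,
                 retention = retention,
                 lapse_rate = lapse_rate,
                 lapse_sd = lapse_sd,
                 habit_decay = habit_decay),
            class = "agent_params")
}

#' Named reference parameter sets
#'
#' Profiles calibrated once against the task's observed group-level
#' operating point (success frequency near one half, gradual incomplete
#' convergence toward the doubled target, larger trial-to-trial changes
#' after failure than after success; children more variable than adults in
#' every respect). `"reference"` equals `"default_child"`, since children
#' dominate the study population the simulator emulates; `"default_adult"`
#' has lower motor noise and exploration, a lower lapse rate and faster,
#' more complete learning.
#'
#' @param profile one of `"reference"`, `"default_child"`,
#'   `"default_adult"`.
#' @return An [agent_params()] object.
#' @export
reference_agent_params <- function(profile = c("reference", "default_child",
                                               "default_adult")) {
  profile <- match.arg(profile)
  switch(profile,
    reference = ,
    default_child = agent_params(),
    default_adult = agent_params(motor_noise_sd = 0.06,
                                 explore_sd_fail = 0.11,
                                 explore_sd_success = 0.04,
                                 retention = 0.12,
                                 lapse_rate = 0.08,
                                 habit_decay = 0)
  )
}

#' Style of the synthesized pen path
#'
#' Controls how an intended circle is rendered as a realistic trajectory:
#' trial-to-trial jitter of the ellipse axis ratio and of the circle center
#' (the task-irrelevant dimensions), sinusoidal modulation of angular speed
#' (participants do not draw at constant speed), sampling density (120
#' samples, about 2 s at the tablet's 60 Hz), and a closure gap so that
#' start and end of the stroke do not exactly coincide.
#'
#' @param aspect_jitter_sd SD of the log axis ratio (dimensionless).
#' @param center_jitter_sd SD of each center coordinate, cm.
#' @param angular_speed_modulation depth in \[0, 1) of the sinusoidal speed
#'   modulation along the stroke.
#' @param samples_per_trial samples per trajectory (>= 10; default 120).
#' @param closure_gap_deg unswept arc in degrees (default 10).
#' @return Object of class `trajectory_style`.
#' @export
trajectory_style <- function(aspect_jitter_sd = 0.08, center_jitter_sd = 0.5,
                             angular_speed_modulation = 0.3,
                             samples_per_trial = 120L, closure_gap_deg = 10) {
  stopifnot(aspect_jitter_sd >= 0, center_jitter_sd >= 0,
            angular_speed_modulation >= 0, angular_speed_modulation < 1,
            samples_per_trial >= 10, closure_gap_deg >= 0,
            closure_gap_deg < 360)
  structure(list(aspect_jitter_sd = aspect_jitter_sd,
                 center_jitter_sd = center_jitter_sd,
                 angular_speed_modulation = angular_speed_modulation,
                 samples_per_trial = as.integer(samples_per_trial),
                 closure_gap_deg = closure_gap_deg),
            class = "trajectory_style")
}

#' One learning update of the intended log-radius
#'
#' The reward-gated update is
#' `(1 - retention) * current + retention * last_rewarded + eps`, with
#' `eps ~ Normal(0, explore_sd_fail)` if the previous trial went unrewarded
#' and `Normal(0, explore_sd_success)` if it was rewarded, followed by the
#' habitual-size relaxation `next <- next - habit_decay * (next -
#' log(baseline_radius))`. Uses R's global random number generator; seed
#' with [set.seed()] for reproducibility.
#'
#' @param current_log_radius current intended log-radius.
#' @param last_rewarded_log_radius intended log-radius of the most recent
#'   rewarded trial (the movement worth repeating).
#' @param rewarded_prev was the previous trial rewarded?
#' @param p an [agent_params()].
#' @return The next intended log-radius.
#' @export
step_intended_radius <- function(current_log_radius, last_rewarded_log_radius,
                                 rewarded_prev, p) {
  stopifnot(is.finite(current_log_radius),
            is.finite(last_rewarded_log_radius))
  sd <- if (isTRUE(rewarded_prev)) p$explore_sd_success else p$explore_sd_fail
  nxt <- (1 - p$retention) * current_log_radius +
    p$retention * last_rewarded_log_radius +
    stats::rnorm(1, 0, sd)
  nxt - p$habit_decay * (nxt - log(p$baseline_radius))
}

# executed log-radius: motor noise, or lapse noise on lapse trials
execute_log_radius <- function(intended_log_radius, p) {
  sd <- if (stats::runif(1) < p$lapse_rate) p$lapse_sd else p$motor_noise_sd
  intended_log_radius + stats::rnorm(1, 0, sd)
}

#' Render one intended circle as a pen trajectory
#'
#' The executed radius is `exp(intended + execution noise)` (motor noise,
#' or lapse noise on lapse trials). The stroke is an ellipse with log axis
#' ratio Normal(0, aspect_jitter_sd) and jittered center, swept over
#' 360 - closure_gap degrees from a random start angle with sinusoidally
#' modulated angular speed, sampled at 60 Hz.
#'
#' @param intended_log_radius intended log-radius for this trial.
#' @param p an [agent_params()].
#' @param style a [trajectory_style()].
#' @return A [raw_trajectory()].
#' @export
execute_trial <- function(intended_log_radius, p = agent_params(),
                          style = trajectory_style()) {
  render_trajectory(execute_log_radius(intended_log_radius, p), style)
}

# deterministic-given-rng ellipse sweep for a fixed executed log-radius
render_trajectory <- function(executed_log_radius, style) {
  r <- exp(executed_log_radius)
  q <- exp(stats::rnorm(1, 0, style$aspect_jitter_sd))
  a <- r * sqrt(q)
  b <- r / sqrt(q)
  ctr <- stats::rnorm(2, 0, style$center_jitter_sd)
  ns <- style$samples_per_trial
  u <- seq(0, 1, length.out = ns)
  sweep <- (360 - style$closure_gap_deg) * pi / 180
  m <- style$angular_speed_modulation
  phase0 <- stats::runif(1, 0, 2 * pi)
  theta <- phase0 + sweep * (u + m * sin(2 * pi * u) / (2 * pi))
  raw_trajectory(t = (seq_len(ns) - 1L) / 60,
                 x = ctr[1] + a * cos(theta),
                 y = ctr[2] + b * sin(theta))
}

#' Build a closed-loop radius source from agent parameters
#'
#' Returns a function suitable for [run_session()]: on each call it updates
#' the intended radius from the previous trial's outcome (repeat after
#' reward, explore after failure), executes the trial, and returns either
#' the rendered trajectory (`render = TRUE`) or the executed radius alone
#' (`render = FALSE`; identical radius and reward dynamics, no geometry).
#'
#' @param p an [agent_params()].
#' @param style a [trajectory_style()].
#' @param render render full trajectories? (default `TRUE`)
#' @return A function `(trial, prev_record)`.
#' @export
make_learning_agent <- function(p = agent_params(),
                                style = trajectory_style(), render = TRUE) {
  intended <- log(p$baseline_radius)
  anchor <- log(p$baseline_radius)
  prev_intended <- log(p$baseline_radius)
  function(trial, prev) {
    if (!is.null(prev)) {
      if (isTRUE(prev$rewarded)) anchor <<- prev_intended
      intended <<- step_intended_radius(intended, anchor, prev$rewarded, p)
    }
    prev_intended <<- intended
    executed <- execute_log_radius(intended, p)
    if (render) render_trajectory(executed, style) else exp(executed)
  }
}

#' Simulate one participant end to end
#'
#' @param p an [agent_params()].
#' @param rule a [target_rule()].
#' @param n_trials main-phase trials (default 80).
#' @param style a [trajectory_style()].
#' @param render render trajectories through the geometry module?
#' @param participant_id,group,age,handedness,language session metadata.
#' @param seed optional seed applied before the session.
#' @return A `circle_session` (see [circle_session()]).
#' @export
simulate_session <- function(p = reference_agent_params(),
                             rule = target_rule(), n_trials = 80L,
                             style = trajectory_style(), render = TRUE,
                             participant_id = "sim01", group = "adult",
                             age = 25L, handedness = "right",
                             language = "dutch", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trials <- run_session(make_learning_agent(p, style, render), rule, n_trials)
  circle_session(participant_id, group, age, trials,
                 handedness = handedness, language = language)
}

#' Simulate a cohort of learners
#'
#' Each agent plays a full closed-loop session (trajectory -> geometry ->
#' error -> adaptive reward -> learning update). A single master seed spawns
#' one independent substream per agent: per-agent seeds are drawn up front
#' with `sample.int` under the master seed, and each agent's sampler and
#' session run under its own seed, so cohorts are reproducible and agents
#' are insensitive to cohort size or order of execution.
#'
#' @param n_agents number of simulated participants.
#' @param params_sampler function `(i)` returning an [agent_params()] for
#'   agent `i`; the default draws a lognormal baseline radius (median
#'   2.15 cm, sdlog `baseline_sdlog`) around the profile's parameters.
#' @param profile parameter profile used by the default sampler; see
#'   [reference_agent_params()].
#' @param rule a [target_rule()].
#' @param n_trials main-phase trials per agent (default 80).
#' @param master_seed integer master seed.
#' @param style a [trajectory_style()].
#' @param render render full trajectories? (default `TRUE`)
#' @param baseline_sdlog sdlog of the default sampler's baseline jitter
#'   (default 0.25).
#' @return List of `circle_session` objects.
#' @export
simulate_cohort <- function(n_agents, params_sampler = NULL,
                            profile = "reference", rule = target_rule(),
                            n_trials = 80L, master_seed = 1L,
                            style = trajectory_style(), render = TRUE,
                            baseline_sdlog = 0.25) {
  stopifnot(n_agents >= 1)
  if (is.null(params_sampler)) {
    params_sampler <- function(i) {
      p <- reference_agent_params(profile)
      p$baseline_radius <- stats::rlnorm(1, log(p$baseline_radius),
                                         baseline_sdlog)
      p
    }
  }
  group <- if (identical(profile, "default_adult")) "adult" else "child"
  set.seed(master_seed)
  agent_seeds <- sample.int(.Machine$integer.max - 1L, n_agents)
  ages <- if (group == "child") sample(7:17, n_agents, replace = TRUE)
          else sample(18:69, n_agents, replace = TRUE)
  lapply(seq_len(n_agents), function(i) {
    set.seed(agent_seeds[i])
    simulate_session(params_sampler(i), rule, n_trials, style, render,
                     participant_id = sprintf("sim%03d", i),
                     group = group, age = ages[i])
  })
}
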