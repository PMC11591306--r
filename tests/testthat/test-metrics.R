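test_that("baseline radius averages the first five main-phase trials", {
  expect_equal(baseline_radius(session_from_radii(c(rep(2, 5), 7, 8))), 2)
  expect_equal(baseline_radius(session_from_radii(c(1:5, 9, 9))), 3)
  expect_error(baseline_radius(session_from_radii(c(1, 2, 3, 4))),
               class = "circlelearn_domain_error")
})

test_that("fraction learned anchors at 0 (baseline) and 1 (target)", {
  flat <- session_from_radii(rep(2, 15))
  expect_identical(fraction_learned(flat), 0)
  reached <- session_from_radii(c(rep(2, 5), rep(3, 5), rep(4, 10)))
  expect_identical(fraction_learned(reached), 1)
  over <- session_from_radii(c(rep(2, 5), rep(3, 5), rep(6, 10)))
  expect_identical(fraction_learned(over), 2)
  # invariance under global rescaling of all radii
  set.seed(6)
  radii <- rlnorm(30, log(2), 0.3)
  expect_equal(fraction_learned(session_from_radii(radii)),
               fraction_learned(session_from_radii(radii * 3.7)))
})

test_that("trial-to-trial ratios fold halving and doubling together", {
  s <- session_from_radii(c(1, 5, 2, 5, 4),
                          rewarded = c(FALSE, TRUE, FALSE, TRUE, FALSE))
  rt <- trial_to_trial_ratios(s)
  # t = 2 (rewarded): max(2/1, 1/2) = 2; t = 4 (rewarded): max(4/2, 2/4) = 2
  expect_equal(rt$after_reward, c(2, 2))
  # t = 3 (not rewarded): max(5/5, 5/5) = 1
  expect_equal(rt$after_no_reward, 1)

  # doubling and halving give the same folded ratio
  up <- session_from_radii(c(1, 1, 2), rewarded = c(FALSE, TRUE, FALSE))
  dn <- session_from_radii(c(1, 1, 0.5), rewarded = c(FALSE, TRUE, FALSE))
  expect_equal(trial_to_trial_ratios(up)$after_reward,
               trial_to_trial_ratios(dn)$after_reward)

  # all folded ratios are >= 1, equality only for equal radii
  set.seed(7)
  s2 <- session_from_radii(rlnorm(40, 0, 0.4),
                           rewarded = sample(c(TRUE, FALSE), 40, TRUE))
  r2 <- unlist(trial_to_trial_ratios(s2))
  expect_true(all(r2 >= 1))
})

test_that("summaries count rewards, flag exclusion, handle empty groups", {
  # exactly 20% non-circular is kept; more is excluded
  s20 <- session_from_radii(rep(2, 10), is_circular = rep(c(FALSE, TRUE),
                                                          c(2, 8)))
  expect_false(summarize_session(s20)$excluded)
  expect_equal(summarize_session(s20)$pct_noncircular, 20)
  s21 <- session_from_radii(rep(2, 10), is_circular = rep(c(FALSE, TRUE),
                                                          c(3, 7)))
  expect_true(summarize_session(s21)$excluded)
  sall <- session_from_radii(rep(2, 10), is_circular = rep(FALSE, 10))
  expect_true(summarize_session(sall)$excluded)

  # constant radii: both conditional medians are exactly 1
  frozen <- session_from_radii(rep(2, 20),
                               rewarded = rep(c(TRUE, FALSE), 10))
  sm <- summarize_session(frozen)
  expect_equal(sm$median_ratio_after_reward, 1)
  expect_equal(sm$median_ratio_after_no_reward, 1)
  expect_equal(sm$success_frequency, 0.5)

  # a session with no rewarded interior trial reports a missing median
  none <- session_from_radii(rep(2, 10), rewarded = rep(FALSE, 10))
  expect_true(is.na(summarize_session(none)$median_ratio_after_reward))

  # brute-force recount of the exclusion decision on random fixtures
  set.seed(8)
  for (k in 1:10) {
    circ <- sample(c(TRUE, FALSE), 25, replace = TRUE, prob = c(0.8, 0.2))
    s <- session_from_radii(rlnorm(25, log(2), 0.2),
                            rewarded = sample(c(TRUE, FALSE), 25, TRUE),
                            is_circular = circ)
    expect_identical(summarize_session(s)$excluded,
                     sum(!circ) / length(circ) > 0.2)
  }
})

test_that("task-irrelevant changes use the same pairing as the radii", {
  tr <- tibble::tibble(
    trial = 1:4, radius = rep(2, 4), target_radius = 4,
    rel_error = relative_radius_error(rep(2, 4), 4),
    rewarded = c(FALSE, TRUE, TRUE, FALSE),
    aspect_ratio = c(1.2, 1.0, 0.6, 1.1),
    path_length = rep(12, 4), start_end_distance = rep(0.5, 4),
    center_x = c(0, 1, 3, 0), center_y = c(0, 1, 4, 0),
    is_circular = rep(TRUE, 4)
  )
  s <- circle_session("p1", "adult", 30L, tr)
  ch <- task_irrelevant_changes(s)
  # t = 2 (rewarded): centers (0,0) -> (3,4): displacement 5;
  # aspect 1.2 -> 0.6 folds to 2
  expect_equal(ch$after_reward$center_displacement[1], 5)
  expect_equal(ch$after_reward$aspect_change[1], 2)
  # identical geometry on both sides gives 1 and 0
  flat <- tibble::tibble(
    trial = 1:3, radius = rep(2, 3), target_radius = 4,
    rel_error = relative_radius_error(rep(2, 3), 4),
    rewarded = c(FALSE, TRUE, FALSE),
    aspect_ratio = rep(1.3, 3), path_length = rep(12, 3),
    start_end_distance = rep(0.5, 3),
    center_x = rep(2, 3), center_y = rep(1, 3), is_circular = rep(TRUE, 3)
  )
  ch2 <- task_irrelevant_changes(circle_session("p2", "adult", 30L, flat))
  expect_equal(ch2$after_reward$aspect_change, 1)
  expect_equal(ch2$after_reward$center_displacement, 0)
  # sessions without geometry refuse the computation
  expect_error(task_irrelevant_changes(session_from_radii(rep(2, 5))),
               class = "circlelearn_domain_error")
})

test_that("simulated conditional medians are recovered by the summary", {
  co <- simulate_cohort(20, n_trials = 80, master_seed = 61, render = FALSE)
  sm <- summarize_cohort(co)
  # recompute one session's medians by hand
  s <- co[[7]]
  r <- s$trials$radius; rew <- s$trials$rewarded
  tm <- 2:(length(r) - 1)
  rat <- pmax(r[tm + 1] / r[tm - 1], r[tm - 1] / r[tm + 1])
  expect_equal(sm$median_ratio_after_reward[7], median(rat[rew[tm]]))
  expect_equal(sm$median_ratio_after_no_reward[7], median(rat[!rew[tm]]))
  expect_equal(sm$success_frequency[7], mean(rew))
})
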