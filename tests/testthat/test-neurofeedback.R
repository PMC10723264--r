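test_that("the wobble level is a pure function of the above-threshold count", {
  expect_identical(sapply(0:5, inceptr:::wobble_level_for),
                   c(13L, 9L, 5L, 1L, 1L, 1L))
  # trial progression: starts maximal, steps down as TRs clear threshold
  st <- feedback_trial_state()
  expect_equal(st$wobble_level, 13L)
  st <- wobble_step(st, e_c = 0.4, theta = 0.55)   # below
  expect_equal(st$wobble_level, 13L)
  st <- wobble_step(st, e_c = 0.7, theta = 0.55)   # 1 above
  expect_equal(st$wobble_level, 9L)
  st <- wobble_step(st, e_c = 0.8, theta = 0.55)   # 2 above
  expect_equal(st$wobble_level, 5L)
  st <- wobble_step(st, e_c = 0.9, theta = 0.55)   # 3 above
  expect_equal(st$wobble_level, 1L)
  st <- wobble_step(st, e_c = 0.9, theta = 0.55)   # 4 above
  expect_equal(st$wobble_level, 1L)
  expect_equal(st$above_count, 4L)
  expect_error(wobble_step(st, 0.9, 0.55), "complete")
  # evidence exactly at threshold does not count as above
  st2 <- wobble_step(feedback_trial_state(), e_c = 0.55, theta = 0.55)
  expect_equal(st2$above_count, 0L)
})

test_that("trial outcomes map above-threshold counts to bonus and emoji", {
  out <- lapply(0:5, trial_outcome)
  expect_equal(sapply(out, `[[`, "bonus_cents"), c(0, 0, 5, 5, 10, 10))
  expect_equal(sapply(out, `[[`, "emoji"),
               c("unhappy", "neutral", "smiling", "smiling", "laughing",
                 "laughing"))
  expect_error(trial_outcome(6), "0..5")
  expect_error(trial_outcome(-1), "0..5")
})

test_that("the staircase raises, lowers, or holds the threshold and stays in bounds", {
  st <- new_staircase(theta = 0.55, step_up = 0.03, step_down = 0.05,
                      bounds = c(0.5, 0.95))
  expect_equal(staircase_update(st, 5)$theta, 0.58)   # strong run -> up
  expect_equal(staircase_update(st, 0)$theta, 0.50)   # weak run -> down
  expect_equal(staircase_update(st, 2)$theta, 0.55)   # dead zone -> hold
  # boundedness after an arbitrary update sequence, with full history
  withr::with_seed(9, updates <- runif(50, 0, 5))
  for (u in updates) st <- staircase_update(st, u)
  expect_true(st$theta >= 0.5 && st$theta <= 0.95)
  expect_equal(nrow(st$history), 50)
  # clamping at the ceiling
  hi <- new_staircase(theta = 0.94, bounds = c(0.5, 0.95))
  expect_equal(staircase_update(hi, 5)$theta, 0.95)
})

test_that("the competition index is the mean per-TR evidence product", {
  expect_equal(competition_index(rep(0.5, 8), rep(0.5, 8)), 0.25)
  expect_equal(competition_index(c(0.9, 0.8), c(0, 0)), 0)
  expect_equal(competition_index(c(0.5, 1), c(0.2, 0.4)), 0.25)
  expect_error(competition_index(numeric(0), numeric(0)), "non-empty")
  expect_error(competition_index(1:3 / 10, 1:2 / 10), "equal length")
})

test_that("noise-free feedback trials carry presented + ability * competitor", {
  gt <- tiny_gt(noise_sd = 0, drift_amp = 0, seed = 81)
  ps <- recognition_patterns(sim_runs(gt, 2, seed = 81))
  clfs <- train_all_pairs(ps)
  sched <- make_feedback_schedule(5, n_trials = 4)
  fb <- simulate_feedback_run(gt, sched, ability = 1, clfs,
                              roi = seq_len(48), theta = 0.55, seed = 82)
  os <- gt$object_set
  expected <- gt$prototypes[os$presented, ] + gt$prototypes[os$competitor, ]
  for (tr in trial_trs(sched)$tr) {
    expect_equal(fb$run$data[tr, ], unname(expected))
  }
  expect_error(simulate_feedback_run(gt, sched, 1, NULL, 1:48, 0.55),
               "not ready")
})

test_that("the closed-loop trace matches an open-loop prefix-z oracle (causality)", {
  gt <- tiny_gt(seed = 83, ability = rep(0.5, 5))
  ps <- recognition_patterns(sim_runs(gt, 2, seed = 83))
  roi <- parcel_voxels(gt$parcellation, c("p01", "p02"))
  clfs <- train_all_pairs(list(x = ps$x[, roi], object = ps$object,
                               run = ps$run))
  sched <- make_feedback_schedule(6, n_trials = 5)
  fb <- simulate_feedback_run(gt, sched, 0.5, clfs, roi, theta = 0.6,
                              seed = 84)
  os <- gt$object_set
  # oracle: for each scored TR, z-score against from-scratch statistics of
  # the preceding volumes only; evidence must agree exactly, proving no
  # engine step reads the scored volume or any later one
  x <- fb$run$data[, roi]
  for (i in seq_len(nrow(fb$trace))) {
    tr <- fb$trace$tr[i]
    prior <- x[seq_len(tr - 1), , drop = FALSE]
    sds <- apply(prior, 2, sd)
    z <- (x[tr, ] - colMeans(prior)) / pmax(sds, 1e-6)
    z[sds < 1e-6] <- 0
    expect_equal(fb$trace$e_c[i],
                 object_evidence(z, os$competitor, os$controls, clfs),
                 tolerance = 1e-8)
    expect_equal(fb$trace$e_p[i],
                 object_evidence(z, os$presented, os$controls, clfs),
                 tolerance = 1e-8)
  }
  # per-trial outcomes follow the trace's final counts
  last <- fb$trace[fb$trace$tr_in_trial == 5, ]
  expect_equal(fb$outcomes$above_count, last$above_count)
})

test_that("competitor evidence rises with the agent's ability", {
  gt <- tiny_gt(seed = 85)
  ps <- recognition_patterns(sim_runs(gt, 2, seed = 85))
  roi <- seq_len(48)
  clfs <- train_all_pairs(ps)
  sched <- make_feedback_schedule(7, n_trials = 8)
  mean_ec <- sapply(c(0, 0.5, 1), function(a) {
    mean(sapply(1:3, function(s) {
      mean(simulate_feedback_run(gt, sched, a, clfs, roi, 0.55,
                                 seed = 90 + s)$trace$e_c)
    }))
  })
  expect_true(all(diff(mean_ec) > 0))
  # ability 0: competitor evidence matches the open-loop evidence computed
  # on held-out presented-object recognition patterns (the competitor looks
  # no more active than it does when only the presented object is shown)
  os <- gt$object_set
  probe <- recognition_patterns(sim_runs(gt, 1, seed = 99))
  pres <- probe$x[probe$object == os$presented, ]
  e_open <- mean(object_evidence(pres, os$competitor, os$controls, clfs))
  expect_lt(abs(mean_ec[1] - e_open), 0.15)
})

test_that("a learning agent drives the staircase threshold up; an inert one earns nothing", {
  gt_ramp <- tiny_gt(seed = 86, ability = seq(0.2, 1, length.out = 6))
  ps <- recognition_patterns(sim_runs(gt_ramp, 2, seed = 86))
  clfs <- train_all_pairs(ps)
  ups <- sapply(1:8, function(s) {
    loop <- run_closed_loop(gt_ramp, clfs, seq_len(48),
                            sessions = 2:4, runs_per_session = 2,
                            n_trials = 8, seed = 200 + s)
    loop$staircase$theta > loop$threshold$theta[1]
  })
  expect_gte(mean(ups), 0.95)
  gt_flat <- tiny_gt(seed = 86, ability = rep(0, 6))
  loop0 <- run_closed_loop(gt_flat, clfs, seq_len(48), sessions = 2,
                           runs_per_session = 2, n_trials = 8, seed = 300)
  gt_able <- tiny_gt(seed = 86, ability = rep(1, 6))
  loop1 <- run_closed_loop(gt_able, clfs, seq_len(48), sessions = 2,
                           runs_per_session = 2, n_trials = 8, seed = 300)
  # inert agent: competitor evidence stays at chance and earns less than a
  # fully able agent facing the same thresholds
  expect_lt(sum(loop0$outcomes$bonus_cents), sum(loop1$outcomes$bonus_cents))
  expect_lt(abs(loop0$session_summary$mean_e_c - 0.5), 0.15)
  expect_gt(loop1$session_summary$mean_e_c,
            loop0$session_summary$mean_e_c + 0.1)
  expect_error(run_closed_loop(gt_flat, clfs, seq_len(48), sessions = 2:4,
                               runs_per_session = 10, seed = 1),
               "ability_curve")
})
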