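#' Start-of-trial feedback state
#'
#' Each 5-TR feedback trial starts at the maximal wobble level 13 with no
#' above-threshold TRs; [wobble_step()] advances the state one TR at a
#' time.
#'
#' @return A `feedback_trial_state` with `tr_index` (TRs consumed, 0..5),
#'   `above_count`, and `wobble_level`.
#' @export
feedback_trial_state <- function() {
  structure(list(tr_index = 0L, above_count = 0L, wobble_level = 13L),
            class = "feedback_trial_state")
}

wobble_level_for <- function(above_count) {
  c(13L, 9L, 5L, 1L)[pmin(above_count, 3L) + 1L]
}

#' Advance the wobble state by one scored TR
#'
#' The on-screen wobble is the per-TR feedback signal: a trial begins at
#' level 13 (maximal) and the level drops to 9 after one above-threshold
#' TR, 5 after two, and 1 (minimal) after three to five. A TR counts as
#' above threshold when the competitor evidence `e_c` exceeds the current
#' staircase threshold `theta`.
#'
#' @param state A [feedback_trial_state()].
#' @param e_c Competitor evidence for this TR, in \[0, 1\].
#' @param theta Current staircase threshold.
#' @return Updated `feedback_trial_state`.
#' @export
#' @examples
#' st <- feedback_trial_state()
#' st <- wobble_step(st, e_c = 0.8, theta = 0.55)
#' st$wobble_level  # 9 after one above-threshold TR
wobble_step <- function(state, e_c, theta) {
  stopifnot(inherits(state, "feedback_trial_state"))
  if (state$tr_index >= 5L) abort("Feedback trial already complete (5 TRs).")
  above <- isTRUE(e_c > theta)
  state$tr_index <- state$tr_index + 1L
  state$above_count <- state$above_count + as.integer(above)
  state$wobble_level <- wobble_level_for(state$above_count)
  state
}

#' End-of-trial reward mapping
#'
#' Maps the final number of above-threshold TRs of a feedback trial to the
#' monetary bonus and emoji: 0 TRs gives no money and an unhappy face,
#' 1 TR no money and a neutral face, 2--3 TRs a 5-cent bonus and a smiling
#' face, and 4--5 TRs a 10-cent bonus and a laughing face.
#'
#' @param above_count Final above-threshold TR count, 0..5.
#' @return A `trial_outcome` list: `above_count`, `bonus_cents`, `emoji`.
#' @export
#' @examples
#' trial_outcome(3)$bonus_cents  # 5
trial_outcome <- function(above_count) {
  if (!above_count %in% 0:5) abort("`above_count` must be in 0..5.")
  bonus <- c(0L, 0L, 5L, 5L, 10L, 10L)[above_count + 1L]
  emoji <- c("unhappy", "neutral", "smiling", "smiling", "laughing",
             "laughing")[above_count + 1L]
  structure(list(above_count = as.integer(above_count),
                 bonus_cents = bonus, emoji = emoji),
            class = "trial_outcome")
}

#' Initialise the adaptive staircase
#'
#' The staircase tracks the participant's competitor-activation ability by
#' moving the evidence threshold: it is raised to create room for further
#' improvement after strong runs and lowered after weak runs so the
#' participant can catch up, and is always clamped to its bounds.
#'
#' @param theta Initial threshold.
#' @param step_up,step_down Threshold increments after strong / weak runs.
#' @param bounds Length-2 vector `[theta_min, theta_max]`, inside (0, 1).
#' @return A `staircase_state` with an empty per-run history.
#' @export
new_staircase <- function(theta = 0.55, step_up = 0.03, step_down = 0.05,
                          bounds = c(0.5, 0.95)) {
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2],
            bounds[1] > 0, bounds[2] < 1)
  assert_scalar_number(theta, "theta", bounds[1], bounds[2])
  structure(list(theta = theta, step_up = step_up, step_down = step_down,
                 bounds = bounds,
                 history = tibble::tibble(run = integer(),
                                          theta = numeric(),
                                          mean_above = numeric())),
            class = "staircase_state")
}

#' @export
print.staircase_state <- function(x, ...) {
  cat("<staircase_state> theta =", x$theta, "after", nrow(x$history),
      "runs\n")
  invisible(x)
}

#' Per-run staircase update
#'
#' After each feedback run, the threshold moves according to the run's
#' mean above-threshold TR count per trial: a mean of 3 or more raises the
#' threshold by `step_up`, a mean of 1 or less lowers it by `step_down`,
#' and intermediate performance leaves it unchanged; the result is clamped
#' to the staircase bounds.
#'
#' @param state A [new_staircase()] state.
#' @param mean_above Mean above-threshold TRs per trial in the completed
#'   run.
#' @return Updated `staircase_state` with the run appended to `history`.
#' @export
staircase_update <- function(state, mean_above) {
  stopifnot(inherits(state, "staircase_state"))
  assert_scalar_number(mean_above, "mean_above", 0, 5)
  state$history <- dplyr::bind_rows(state$history, tibble::tibble(
    run = nrow(state$history) + 1L, theta = state$theta,
    mean_above = mean_above
  ))
  delta <- if (mean_above >= 3) state$step_up else
    if (mean_above <= 1) -state$step_down else 0
  state$theta <- clamp(state$theta + delta, state$bounds[1], state$bounds[2])
  state
}

#' Competition (coactivation) index
#'
#' The per-TR product of presented- and competitor-object evidence,
#' averaged over the scored TRs. High values require *both* objects to be
#' active at once, which is the coactivation the neurofeedback procedure
#' aims to induce.
#'
#' @param e_p,e_c Equal-length evidence traces in \[0, 1\].
#' @return Scalar index in \[0, 1\].
#' @export
#' @examples
#' competition_index(rep(0.5, 10), rep(0.5, 10))  # 0.25
competition_index <- function(e_p, e_c) {
  if (length(e_p) == 0L) abort("Evidence traces must be non-empty.")
  if (length(e_p) != length(e_c)) abort("Traces must have equal length.")
  mean(e_p * e_c)
}

#' Simulate one closed-loop feedback run
#'
#' Generates the run's volumes and drives the real-time engine through
#' them TR by TR, exactly as the scanner loop would: each feedback-trial
#' TR carries `proto(presented) + ability * proto(competitor)` on top of
#' baseline noise, and each incoming volume is incrementally z-scored
#' (prior TRs only), masked to the feedback ROI, converted to presented
#' and competitor evidence via the control-referenced classifier averages,
#' and compared with the staircase threshold to update the wobble state.
#' No step reads a future volume.
#'
#' @param gt A [ground_truth()].
#' @param schedule A feedback [make_feedback_schedule()].
#' @param ability Agent's competitor-activation amplitude in \[0, 1\] for
#'   this run.
#' @param classifiers Named list from [train_all_pairs()] (trained on the
#'   ROI-masked patterns).
#' @param roi Voxel indices of the feedback ROI.
#' @param theta Staircase threshold in force for this run.
#' @param seed Integer seed.
#' @return List with `run` (the `run_timeseries`), `trace` (per scored TR:
#'   `trial`, `tr_in_trial`, `tr`, `e_p`, `e_c`, `theta`, `above`,
#'   `above_count`, `wobble_level`), and `outcomes` (per trial:
#'   `above_count`, `bonus_cents`, `emoji`).
#' @export
simulate_feedback_run <- function(gt, schedule, ability, classifiers, roi,
                                  theta, seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"))
  if (schedule$run_type != "feedback") {
    abort("`schedule` must be a feedback schedule.")
  }
  if (is.null(classifiers) || !length(classifiers) ||
      !inherits(classifiers[[1]], "pair_classifier")) {
    abort("Classifiers are not ready: train them on Session-1 data first.")
  }
  assert_scalar_number(ability, "ability", 0, 1)
  os <- gt$object_set
  proto <- gt$prototypes      # feedback sessions use Session-1 patterns
  stim <- proto[os$presented, ] + ability * proto[os$competitor, ]
  nv <- gt$parcellation$n_voxels
  data <- with_seed(seed, {
    baseline_matrix(schedule$n_volumes, nv, gt$noise_sd, gt$drift_amp,
                    gt$ar1_rho)
  })
  scored <- trial_trs(schedule)
  for (tr in scored$tr) data[tr, ] <- data[tr, ] + stim

  # --- real-time loop ---
  st <- running_stats(length(roi))
  trial_state <- NULL
  n_scored <- nrow(scored)
  tr_map <- integer(schedule$n_volumes)         # TR -> scored-row index
  tr_map[scored$tr] <- seq_len(n_scored)
  tr_e_p <- tr_e_c <- numeric(n_scored)
  tr_above_count <- tr_wobble <- integer(n_scored)
  out_count <- integer(nrow(schedule$trials))
  for (tr in seq_len(schedule$n_volumes)) {
    step <- incremental_zscore(st, data[tr, roi])
    st <- step$stats
    k <- tr_map[tr]
    if (k > 0L) {
      tr_in_trial <- scored$tr_in_trial[k]
      if (tr_in_trial == 1L) trial_state <- feedback_trial_state()
      e_p <- object_evidence(step$z, os$presented, os$controls, classifiers)
      e_c <- object_evidence(step$z, os$competitor, os$controls, classifiers)
      trial_state <- wobble_step(trial_state, e_c, theta)
      tr_e_p[k] <- e_p
      tr_e_c[k] <- e_c
      tr_above_count[k] <- trial_state$above_count
      tr_wobble[k] <- trial_state$wobble_level
      if (tr_in_trial == 5L) {
        out_count[scored$trial[k]] <- trial_state$above_count
      }
    }
  }
  trace <- tibble::tibble(
    trial = scored$trial, tr_in_trial = scored$tr_in_trial, tr = scored$tr,
    e_p = tr_e_p, e_c = tr_e_c, theta = theta, above = tr_e_c > theta,
    above_count = tr_above_count, wobble_level = tr_wobble
  )
  outs <- purrr::map(out_count, trial_outcome)
  outcomes <- tibble::tibble(
    trial = schedule$trials$trial,
    above_count = purrr::map_int(outs, "above_count"),
    bonus_cents = purrr::map_int(outs, "bonus_cents"),
    emoji = purrr::map_chr(outs, "emoji")
  )
  events <- tibble::tibble(
    onset = (schedule$trials$onset - 1L) * schedule$tr_s,
    duration = 5L * schedule$tr_s,
    trial_type = "feedback",
    object = os$presented,
    onset_tr = schedule$trials$onset
  )
  list(run = new_run_timeseries(data, "feedback", events),
       trace = trace, outcomes = outcomes)
}

#' Run the closed loop over the feedback sessions
#'
#' Orchestrates the neurofeedback phase of the protocol: for each feedback
#' run of each feedback session it draws the agent's ability from the
#' ground-truth ability curve, simulates the run through the real-time
#' engine at the current staircase threshold, and applies the per-run
#' staircase update. Ten feedback runs per session across Sessions 2--4 is
#' the default protocol.
#'
#' @param gt A [ground_truth()] whose `ability_curve` has one entry per
#'   feedback run overall.
#' @param classifiers Session-1 pairwise classifiers over `roi`.
#' @param roi Feedback-ROI voxel indices.
#' @param staircase A [new_staircase()] state.
#' @param sessions Feedback session numbers.
#' @param runs_per_session Feedback runs per session.
#' @param n_trials,n_volumes Feedback-run geometry.
#' @param seed Integer seed; per-run seeds are derived stably from it.
#' @return A `closed_loop_result`: `trace` (all scored TRs with `session`
#'   and `run` columns), `outcomes`, `threshold` (per run: `theta` in
#'   force, `mean_above`), `staircase` (final state), and
#'   `session_summary` (per session: mean competition index, mean
#'   competitor evidence, mean theta, total bonus).
#' @export
run_closed_loop <- function(gt, classifiers, roi, staircase = new_staircase(),
                            sessions = 2:4, runs_per_session = 10L,
                            n_trials = 20L, n_volumes = 176L, seed = 1L) {
  n_runs <- length(sessions) * runs_per_session
  if (length(gt$ability_curve) < n_runs) {
    abort(sprintf("`ability_curve` has %d entries but %d feedback runs.",
                  length(gt$ability_curve), n_runs))
  }
  traces <- list()
  outcomes <- list()
  thresholds <- list()
  g <- 0L
  for (s in sessions) {
    for (r in seq_len(runs_per_session)) {
      g <- g + 1L
      sched <- make_feedback_schedule(
        derive_seed(seed, sprintf("fb-sched-%d-%d", s, r)),
        n_trials = n_trials, n_volumes = n_volumes,
        object = gt$object_set$presented
      )
      fb <- simulate_feedback_run(
        gt, sched, gt$ability_curve[g], classifiers, roi,
        theta = staircase$theta,
        seed = derive_seed(seed, sprintf("fb-run-%d-%d", s, r))
      )
      mean_above <- mean(fb$outcomes$above_count)
      thresholds[[g]] <- tibble::tibble(
        session = s, run = r, global_run = g, theta = staircase$theta,
        ability = gt$ability_curve[g], mean_above = mean_above
      )
      staircase <- staircase_update(staircase, mean_above)
      traces[[g]] <- dplyr::mutate(fb$trace, session = s, run = r,
                                   .before = 1)
      outcomes[[g]] <- dplyr::mutate(fb$outcomes, session = s, run = r,
                                     .before = 1)
    }
  }
  trace <- dplyr::bind_rows(traces)
  outcome_tbl <- dplyr::bind_rows(outcomes)
  session_summary <- trace |>
    dplyr::group_by(.data$session) |>
    dplyr::summarise(
      competition = competition_index(.data$e_p, .data$e_c),
      mean_e_c = mean(.data$e_c),
      mean_theta = mean(.data$theta),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      outcome_tbl |>
        dplyr::group_by(.data$session) |>
        dplyr::summarise(bonus_cents = sum(.data$bonus_cents),
                         .groups = "drop"),
      by = "session"
    )
  structure(list(trace = trace, outcomes = outcome_tbl,
                 threshold = dplyr::bind_rows(thresholds),
                 staircase = staircase,
                 session_summary = session_summary),
            class = "closed_loop_result")
}

#' @export
print.closed_loop_result <- function(x, ...) {
  cat("<closed_loop_result>", nrow(x$threshold), "feedback runs over",
      length(unique(x$threshold$session)), "sessions | final theta",
      x$staircase$theta, "\n")
  print(x$session_summary)
  invisible(x)
}
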