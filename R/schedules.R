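new_trial_schedule <- function(trials, run_type, n_volumes, tr_s = 2) {
  structure(list(trials = trials, run_type = run_type,
                 n_volumes = as.integer(n_volumes), tr_s = tr_s),
            class = "trial_schedule")
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat("<trial_schedule>", x$run_type, "run:", nrow(x$trials), "trials,",
      x$n_volumes, "volumes\n")
  invisible(x)
}

#' Generate a recognition-run trial schedule
#'
#' A recognition run shows the four objects one at a time: 48 trials, 12
#' repetitions per object, three repetitions of each object in each quarter
#' of the run, no identical back-to-back objects, and a jittered
#' inter-trial interval of 4, 6 or 8 s (2, 3 or 4 TRs at TR = 2 s, drawn
#' uniformly). Onsets are laid out to fit 145 volumes with room for the
#' hemodynamic lag after the final trial.
#'
#' Both the object order (per quarter) and the interval sequence are drawn
#' by rejection sampling with a bounded retry budget; the constraints are
#' always satisfiable, so in practice the budget is never exhausted.
#'
#' @param seed Integer seed; schedules are deterministic given the seed.
#' @param objects Four object identifiers.
#' @param n_volumes Run length in TRs.
#' @param lag_trs Lag reserved after the final onset so the lagged pattern
#'   volume still falls inside the run.
#' @param max_retries Retry budget for each rejection-sampling stage.
#' @return A `trial_schedule` with `$trials` a tibble
#'   (`trial`, `onset` 1-based TR, `object`), `run_type = "recognition"`.
#' @export
#' @examples
#' sched <- make_recognition_schedule(seed = 1)
#' table(sched$trials$object)
make_recognition_schedule <- function(seed,
                                      objects = c("bed", "chair", "table",
                                                  "bench"),
                                      n_volumes = 145L,
                                      lag_trs = 2L,
                                      max_retries = 1000L) {
  stopifnot(length(objects) == 4L)
  n_trials <- 48L
  per_quarter <- 3L
  with_seed(seed, {
    # object order: quarters of 12 with 3 repetitions of each object and
    # no repeats, including across quarter boundaries
    order <- character(0)
    for (q in 1:4) {
      base <- rep(objects, per_quarter)
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        cand <- sample(base)
        prev <- if (length(order)) order[length(order)] else NA_character_
        if (!any(cand[-1] == cand[-length(cand)]) &&
            (is.na(prev) || cand[1] != prev)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) abort("Could not satisfy the no-repeat constraint.")
      order <- c(order, cand)
    }
    # onsets: first trial after a 1-TR lead-in; jittered gaps of 2/3/4 TRs;
    # resample the gap vector until the run (plus lag) fits n_volumes
    for (try in seq_len(max_retries)) {
      gaps <- sample(c(2L, 3L, 4L), n_trials - 1L, replace = TRUE)
      onsets <- 2L + c(0L, cumsum(gaps))
      if (onsets[n_trials] + lag_trs <= n_volumes) break
      if (try == max_retries) abort("Could not fit onsets in the run.")
    }
  })
  trials <- tibble::tibble(trial = seq_len(n_trials), onset = onsets,
                           object = order)
  new_trial_schedule(trials, "recognition", n_volumes)
}

#' Generate a feedback-run trial schedule
#'
#' Feedback trials occupy 5 consecutive TRs each, during which the
#' presented object wobbles on screen and each incoming volume is scored
#' against the adaptive threshold. Trials are separated by short 2--3 TR
#' gaps after a 4-TR lead-in (which also warms up the running z-score);
#' the default 20 trials fit the 176-volume feedback run.
#'
#' @param seed Integer seed.
#' @param n_trials Feedback trials per run.
#' @param n_volumes Run length in TRs.
#' @param object Object shown on every trial (the presented object), if
#'   known at scheduling time.
#' @return A `trial_schedule` with `run_type = "feedback"`; each trial row
#'   gives the onset of its first TR, and `trial_trs()` expands to the five
#'   scored TRs.
#' @export
make_feedback_schedule <- function(seed, n_trials = 20L, n_volumes = 176L,
                                   object = NA_character_) {
  trial_len <- 5L
  with_seed(seed, {
    gaps <- sample(c(2L, 3L), n_trials - 1L, replace = TRUE)
  })
  onsets <- 5L + c(0L, cumsum(trial_len + gaps))
  if (onsets[n_trials] + trial_len - 1L > n_volumes) {
    abort("Feedback trials do not fit in `n_volumes`.")
  }
  trials <- tibble::tibble(trial = seq_len(n_trials), onset = onsets,
                           object = object)
  new_trial_schedule(trials, "feedback", n_volumes)
}

#' TRs scored within each feedback trial
#'
#' @param schedule A feedback `trial_schedule`.
#' @return Tibble (`trial`, `tr_in_trial` 1..5, `tr` 1-based volume index).
#' @export
trial_trs <- function(schedule) {
  stopifnot(schedule$run_type == "feedback")
  tidyr::crossing(trial = schedule$trials$trial, tr_in_trial = 1:5) |>
    dplyr::left_join(schedule$trials[c("trial", "onset")], by = "trial") |>
    dplyr::mutate(tr = .data$onset + .data$tr_in_trial - 1L) |>
    dplyr::select("trial", "tr_in_trial", "tr")
}

#' Generate a categorical-perception morph schedule
#'
#' Morphs between the two endpoint objects of an axis are sampled at 13
#' fixed steps of the morph-percent continuum
#' (18, 26, 34, 38, 42, 46, 50, 54, 58, 62, 66, 74, 82), each shown 12
#' times from a trial-unique viewpoint, in an order shuffled by the seed.
#'
#' @param seed Integer seed.
#' @param reps Repetitions per morph level.
#' @return Tibble (`trial`, `morph`, `viewpoint`), 156 rows by default.
#' @export
#' @examples
#' table(make_morph_schedule(1)$morph)
make_morph_schedule <- function(seed, reps = 12L) {
  levels <- morph_levels()
  n <- length(levels) * reps
  with_seed(seed, {
    morph <- sample(rep(levels, reps))
    viewpoint <- sample.int(n)
  })
  tibble::tibble(trial = seq_len(n), morph = morph, viewpoint = viewpoint)
}

#' The fixed morph-percent sampling grid
#'
#' @return Integer vector of the 13 morph percentages.
#' @export
morph_levels <- function() {
  c(18L, 26L, 34L, 38L, 42L, 46L, 50L, 54L, 58L, 62L, 66L, 74L, 82L)
}
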