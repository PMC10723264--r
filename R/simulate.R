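new_run_timeseries <- function(data, run_type, events, session = NA_integer_,
                               tr_s = 2) {
  structure(list(data = data, run_type = run_type, events = events,
                 session = as.integer(session), tr_s = tr_s),
            class = "run_timeseries")
}

#' @export
print.run_timeseries <- function(x, ...) {
  cat("<run_timeseries>", x$run_type, "run:", nrow(x$data), "volumes x",
      ncol(x$data), "voxels,", nrow(x$events), "events\n")
  invisible(x)
}

#' @export
dim.run_timeseries <- function(x) dim(x$data)

# Baseline signal: i.i.d. (or optional AR(1)) Gaussian noise per voxel plus
# a slow one-cycle sinusoidal drift with random per-voxel phase. Consumes
# the active RNG stream.
baseline_matrix <- function(n_volumes, n_voxels, noise_sd, drift_amp,
                            ar1_rho = 0) {
  if (ar1_rho != 0) {
    innov_sd <- noise_sd * sqrt(1 - ar1_rho^2)
    eps <- matrix(rnorm(n_volumes * n_voxels, 0, innov_sd),
                  n_volumes, n_voxels)
    noise <- apply(eps, 2, function(e) {
      as.numeric(stats::filter(e, ar1_rho, method = "recursive"))
    })
  } else {
    noise <- matrix(rnorm(n_volumes * n_voxels, 0, noise_sd),
                    n_volumes, n_voxels)
  }
  if (drift_amp > 0) {
    phase <- runif(n_voxels)
    t_frac <- (seq_len(n_volumes) - 1) / n_volumes
    noise <- noise + drift_amp * sin(2 * pi * outer(t_frac, phase, `+`))
  }
  noise
}

#' Simulate one recognition run
#'
#' Emits a TR-by-voxel matrix of baseline noise and drift in which each
#' trial's object prototype (for the requested session) is injected at
#' `onset + lag_trs`, modelling the hemodynamic lag as a pure shift of the
#' single pattern-carrying volume. Session 5 uses the integration-shifted
#' trained-axis prototypes (see [session_prototypes()]).
#'
#' @param gt A [ground_truth()].
#' @param schedule A recognition [make_recognition_schedule()].
#' @param session 1 or 5 (feedback-session recognition runs use 1).
#' @param seed Integer seed for noise and drift.
#' @return A `run_timeseries` whose `$events` tibble carries BIDS-style
#'   columns (`onset` seconds, `duration`, `trial_type`, `object`) next to
#'   the TR-resolution `onset_tr`.
#' @export
simulate_recognition_run <- function(gt, schedule, session = 1, seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"), inherits(schedule, "trial_schedule"))
  if (schedule$run_type != "recognition") {
    abort("`schedule` must be a recognition schedule.")
  }
  if (any(schedule$trials$onset + gt$lag_trs > schedule$n_volumes)) {
    abort("Trial onset + lag falls beyond the end of the run.")
  }
  proto <- session_prototypes(gt, session)
  nv <- gt$parcellation$n_voxels
  data <- with_seed(seed, {
    baseline_matrix(schedule$n_volumes, nv, gt$noise_sd, gt$drift_amp,
                    gt$ar1_rho)
  })
  for (i in seq_len(nrow(schedule$trials))) {
    tr <- schedule$trials$onset[i] + gt$lag_trs
    data[tr, ] <- data[tr, ] + proto[schedule$trials$object[i], ]
  }
  events <- tibble::tibble(
    onset = (schedule$trials$onset - 1L) * schedule$tr_s,
    duration = 1,
    trial_type = "recognition",
    object = schedule$trials$object,
    onset_tr = schedule$trials$onset
  )
  new_run_timeseries(data, "recognition", events, session = session,
                     tr_s = schedule$tr_s)
}

#' Simulate categorical-perception responses
#'
#' Draws forced-choice responses from a true logistic observer: the
#' probability of choosing the second endpoint object at morph percent `x`
#' is `1 / (1 + exp(-slope * (x - mu)))`.
#'
#' @param responder Numeric vector `c(mu = , slope = )` with `slope > 0`.
#' @param morph_schedule Tibble from [make_morph_schedule()].
#' @param seed Integer seed.
#' @return The schedule with `p_true` and a binary `choice` column
#'   (1 = second endpoint object) appended.
#' @export
#' @examples
#' resp <- simulate_behavior(c(mu = 50, slope = 0.2),
#'                           make_morph_schedule(1), seed = 2)
#' mean(resp$choice[resp$morph > 50])
simulate_behavior <- function(responder, morph_schedule, seed = 1L) {
  mu <- responder[["mu"]]
  slope <- responder[["slope"]]
  if (!is.finite(slope) || slope <= 0) abort("Responder `slope` must be > 0.")
  p <- plogis(slope * (morph_schedule$morph - mu))
  choice <- with_seed(seed, rbinom(length(p), 1L, p))
  dplyr::mutate(morph_schedule, p_true = p, choice = choice)
}
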