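#' Ground truth for the synthetic scanner
#'
#' Collects everything the generator needs to emit multivoxel runs and
#' behavioural responses with a known answer key: per-object voxel
#' prototypes (separated in informative parcels, zero elsewhere), the
#' hemodynamic lag, noise and drift scales, the Session-5 integration shift,
#' the psychometric responder, and the closed-loop agent's ability curve.
#'
#' The integration shift `lambda` operationalises learning-induced
#' integration: in Session 5 the presented- and competitor-object prototypes
#' are moved symmetrically toward their common midpoint,
#' `proto5(P) = proto1(P) + (lambda / 2) * (proto1(C) - proto1(P))` (and
#' symmetrically for C), so `lambda = 0` leaves Session 5 identical to
#' Session 1 and `lambda = 1` collapses the two prototypes onto the
#' midpoint. Control-object prototypes never move.
#'
#' @param object_set An [object_set()].
#' @param parcellation A [make_parcellation()].
#' @param informative_parcels Parcel ids whose voxels carry object
#'   information; the rest hold identical (zero) prototypes for all objects.
#' @param signal_sd Per-voxel scale of prototype draws in informative
#'   parcels (z-scored signal units).
#' @param noise_sd Per-voxel i.i.d. Gaussian noise scale.
#' @param drift_amp Amplitude of the slow sinusoidal drift added to every
#'   voxel (one cycle per run, random per-voxel phase).
#' @param lag_trs Hemodynamic lag as a pure shift, in TRs (2 TRs = 4 s at
#'   TR = 2 s).
#' @param lambda Session-5 trained-axis integration shift in \[0, 1\].
#' @param responder Named list with per-axis true psychometric parameters,
#'   as returned by [make_responder()].
#' @param ability_curve Numeric vector in \[0, 1\], one entry per feedback
#'   run in session order: the agent's competitor-activation amplitude.
#' @param ar1_rho Optional AR(1) coefficient for temporally correlated
#'   noise; the default 0 keeps noise i.i.d.
#' @param seed Seed for the prototype draws.
#'
#' @return A `ground_truth` list; `prototypes` is an object-by-voxel matrix
#'   of Session-1 prototypes.
#' @seealso [session_prototypes()], [simulate_recognition_run()]
#' @export
ground_truth <- function(object_set,
                         parcellation,
                         informative_parcels = names(parcellation$parcels)[1],
                         signal_sd = 0.3,
                         noise_sd = 1,
                         drift_amp = 0.5,
                         lag_trs = 2L,
                         lambda = 0,
                         responder = make_responder(),
                         ability_curve = rep(0, 30),
                         ar1_rho = 0,
                         seed = 1L) {
  stopifnot(inherits(object_set, "object_set"),
            inherits(parcellation, "parcellation"))
  assert_scalar_number(lambda, "lambda", 0, 1)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(drift_amp, "drift_amp", min = 0)
  assert_scalar_number(lag_trs, "lag_trs", min = 0)
  assert_scalar_number(ar1_rho, "ar1_rho", -0.99, 0.99)
  if (any(ability_curve < 0 | ability_curve > 1)) {
    abort("`ability_curve` values must lie in [0, 1].")
  }
  objs <- object_set$objects
  nv <- parcellation$n_voxels
  info_vox <- parcel_voxels(parcellation, informative_parcels)
  proto <- matrix(0, nrow = 4L, ncol = nv, dimnames = list(objs, NULL))
  with_seed(seed, {
    for (o in objs) proto[o, info_vox] <- rnorm(length(info_vox), 0, signal_sd)
  })
  structure(list(
    object_set = object_set,
    parcellation = parcellation,
    prototypes = proto,
    informative_parcels = informative_parcels,
    signal_sd = signal_sd,
    noise_sd = noise_sd,
    drift_amp = drift_amp,
    lag_trs = as.integer(lag_trs),
    lambda = lambda,
    responder = responder,
    ability_curve = as.numeric(ability_curve),
    ar1_rho = ar1_rho,
    seed = as.integer(seed)
  ), class = "ground_truth")
}

#' True psychometric parameters of the simulated responder
#'
#' One (mu, slope) pair per axis and session on the morph-percent axis.
#' `slope` is the logistic steepness coefficient (per morph-%), i.e. `1/s`
#' in the `p(x) = 1 / (1 + exp(-(x - mu)/s))` parameterisation. A Session-5
#' trained-axis slope below the Session-1 slope encodes behavioural
#' integration (a shallower post-training curve).
#'
#' @param mu Point of subjective equality, morph percent.
#' @param slope1 Session-1 slope for both axes.
#' @param slope5_trained,slope5_untrained Session-5 slopes per axis.
#' @return Nested list `responder[[axis]][[session]] = c(mu, slope)` with
#'   axes `trained`/`untrained` and sessions `"1"`/`"5"`.
#' @export
make_responder <- function(mu = 50, slope1 = 0.2,
                           slope5_trained = slope1,
                           slope5_untrained = slope1) {
  per_axis <- function(s5) list(`1` = c(mu = mu, slope = slope1),
                                `5` = c(mu = mu, slope = s5))
  list(trained = per_axis(slope5_trained),
       untrained = per_axis(slope5_untrained))
}

#' Session-specific object prototypes
#'
#' Applies the trained-axis integration shift for Session 5; Session 1 (and
#' the feedback sessions, which use Session-1 representations) returns the
#' prototypes unchanged.
#'
#' @param gt A [ground_truth()].
#' @param session Session number; only 5 triggers the shift.
#' @return Object-by-voxel prototype matrix.
#' @export
session_prototypes <- function(gt, session = 1) {
  proto <- gt$prototypes
  if (session == 5 && gt$lambda > 0) {
    p <- gt$object_set$presented
    c_ <- gt$object_set$competitor
    p1 <- proto[p, ]
    c1 <- proto[c_, ]
    proto[p, ] <- p1 + (gt$lambda / 2) * (c1 - p1)
    proto[c_, ] <- c1 + (gt$lambda / 2) * (p1 - c1)
  }
  proto
}
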