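# Shared fixtures, built in code at test time.

# A small ground truth: 6 parcels x 8 voxels, signal in the first `n_info`.
tiny_gt <- function(n_info = 2, lambda = 0, noise_sd = 1, drift_amp = 0.5,
                    signal_sd = 1, seed = 1, batch = 1,
                    ability = rep(0, 30)) {
  parc <- make_parcellation(6, 8)
  ground_truth(
    object_set(batch = batch), parc,
    informative_parcels = sprintf("p%02d", seq_len(n_info)),
    signal_sd = signal_sd, noise_sd = noise_sd, drift_amp = drift_amp,
    lambda = lambda, ability_curve = ability, seed = seed
  )
}

# n_runs recognition runs for a ground truth, as a list.
sim_runs <- function(gt, n_runs = 3, session = 1, seed = 1) {
  lapply(seq_len(n_runs), function(r) {
    sched <- make_recognition_schedule(seed * 100 + r)
    simulate_recognition_run(gt, sched, session = session,
                             seed = seed * 1000 + r)
  })
}

# Gaussian two-class pattern set: n per class, p voxels, class means +/- mu.
two_cluster <- function(n = 30, p = 10, mu = 1.5, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n * p, mu), n, p),
               matrix(rnorm(n * p, -mu), n, p))
    list(x = x, labels = rep(c("a", "b"), each = n))
  })
}

# Pure-noise four-object pattern set with run structure.
noise_pattern_set <- function(n_runs = 3, per_object = 6, p = 12, seed = 1) {
  objs <- c("bed", "bench", "chair", "table")
  n <- n_runs * per_object * 4
  withr::with_seed(seed, {
    list(x = matrix(rnorm(n * p), n, p),
         object = rep(rep(objs, each = per_object), n_runs),
         run = rep(seq_len(n_runs), each = per_object * 4))
  })
}

# A pair classifier with hand-set weights (for evidence arithmetic tests).
manual_pair_classifier <- function(a, b, weights, intercept = 0) {
  structure(list(object_a = a, object_b = b, weights = weights,
                 intercept = intercept, penalty = 1),
            class = "pair_classifier")
}
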