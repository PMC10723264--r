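#' Running per-voxel statistics for real-time z-scoring
#'
#' Welford-style single-pass accumulator: per voxel it tracks the count of
#' absorbed volumes, the running mean, and the running sum of squared
#' deviations, so each incoming volume can be standardised against the
#' statistics of the *prior* TRs only.
#'
#' @param n_voxels Number of voxels tracked.
#' @return A `running_stats` object.
#' @seealso [incremental_zscore()]
#' @export
running_stats <- function(n_voxels) {
  structure(list(n = 0L,
                 mean = numeric(n_voxels),
                 m2 = numeric(n_voxels)),
            class = "running_stats")
}

#' @export
print.running_stats <- function(x, ...) {
  cat("<running_stats>", length(x$mean), "voxels,", x$n, "volumes absorbed\n")
  invisible(x)
}

# floor below which a standard deviation is treated as degenerate
.sd_eps <- 1e-6

#' Real-time (incremental) z-scoring of one volume
#'
#' Standardises the incoming volume with the running mean and sample
#' standard deviation computed from the prior TRs of the run only; the new
#' volume is absorbed into the statistics *after* scoring, so the closed
#' loop never conditions a score on the volume being scored. With fewer
#' than two prior volumes, or where the prior sd falls below the
#' degeneracy floor (1e-6), the output is 0 for that voxel.
#'
#' @param stats A [running_stats()] accumulator.
#' @param volume Numeric voxel vector for the new TR.
#' @return List with `z` (the standardised volume) and `stats` (the updated
#'   accumulator, now including `volume`).
#' @export
#' @examples
#' st <- running_stats(1)
#' st <- incremental_zscore(st, 0)$stats
#' st <- incremental_zscore(st, 2)$stats
#' incremental_zscore(st, 1)$z  # prior mean 1, sd sqrt(2): z = 0
incremental_zscore <- function(stats, volume) {
  stopifnot(inherits(stats, "running_stats"))
  volume <- as.numeric(volume)
  if (length(volume) != length(stats$mean)) {
    abort("`volume` length does not match the tracked voxel count.")
  }
  if (stats$n < 2L) {
    z <- numeric(length(volume))
  } else {
    sd_prior <- sqrt(stats$m2 / (stats$n - 1L))
    z <- (volume - stats$mean) / pmax(sd_prior, .sd_eps)
    z[sd_prior < .sd_eps] <- 0
  }
  # Welford update, absorbing the new volume
  n_new <- stats$n + 1L
  delta <- volume - stats$mean
  mean_new <- stats$mean + delta / n_new
  m2_new <- stats$m2 + delta * (volume - mean_new)
  list(z = z,
       stats = structure(list(n = n_new, mean = mean_new, m2 = m2_new),
                         class = "running_stats"))
}

#' Offline (full-run) z-scoring
#'
#' Standardises each voxel's time series to mean 0 and sample sd 1 using
#' the full run, the offline counterpart of [incremental_zscore()]. Voxels
#' whose sd falls below the degeneracy floor come out all-zero.
#'
#' @param run A `run_timeseries` or a TR-by-voxel matrix.
#' @return Same type as the input, with standardised data.
#' @export
batch_zscore <- function(run) {
  x <- if (inherits(run, "run_timeseries")) run$data else run
  if (is.null(dim(x)) || nrow(x) < 2L) {
    abort("`run` must contain at least 2 volumes.")
  }
  mu <- colMeans(x)
  sds <- apply(x, 2, sd)
  z <- sweep(sweep(x, 2, mu), 2, pmax(sds, .sd_eps), `/`)
  z[, sds < .sd_eps] <- 0
  if (inherits(run, "run_timeseries")) {
    run$data <- z
    run
  } else {
    z
  }
}

#' Extract the lagged single-volume trial pattern
#'
#' The multivoxel pattern for a trial is the volume acquired `lag_trs` TRs
#' after trial onset (4 s at TR = 2 s), masked to the ROI.
#'
#' @param run A `run_timeseries` or TR-by-voxel matrix.
#' @param onset_tr 1-based onset TR of the trial.
#' @param lag_trs Hemodynamic lag in TRs.
#' @param roi Integer voxel indices; `NULL` means all voxels.
#' @return Numeric pattern vector of length `length(roi)`.
#' @export
extract_trial_pattern <- function(run, onset_tr, lag_trs = 2L, roi = NULL) {
  x <- if (inherits(run, "run_timeseries")) run$data else run
  idx <- onset_tr + lag_trs
  if (idx < 1L || idx > nrow(x)) {
    abort(sprintf("Pattern volume %d is outside the run (1..%d).",
                  idx, nrow(x)))
  }
  v <- x[idx, ]
  if (!is.null(roi)) v <- v[roi]
  v
}

# All trial patterns of a set of recognition runs for the given objects,
# from batch z-scored data: returns list(x = trials-by-voxels matrix,
# object, run).
extract_pattern_set <- function(runs, lag_trs = 2L, roi = NULL,
                                objects = NULL) {
  pats <- list()
  labs <- character(0)
  run_id <- integer(0)
  for (r in seq_along(runs)) {
    run <- batch_zscore(runs[[r]])
    ev <- run$events
    if (!is.null(objects)) ev <- ev[ev$object %in% objects, ]
    for (i in seq_len(nrow(ev))) {
      pats[[length(pats) + 1L]] <-
        extract_trial_pattern(run, ev$onset_tr[i], lag_trs, roi)
      labs <- c(labs, ev$object[i])
      run_id <- c(run_id, r)
    }
  }
  list(x = do.call(rbind, pats), object = labs, run = run_id)
}
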