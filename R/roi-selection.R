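new_mega_roi <- function(parcels, parcellation, cv_accuracy = NA_real_) {
  structure(list(parcels = parcels,
                 voxels = parcel_voxels(parcellation, parcels),
                 cv_accuracy = cv_accuracy),
            class = "mega_roi")
}

#' @export
print.mega_roi <- function(x, ...) {
  cat("<mega_roi>", length(x$parcels), "parcels,", length(x$voxels),
      "voxels | cv accuracy", round(x$cv_accuracy, 3), "\n")
  invisible(x)
}

# mean 4-way leave-one-run-out accuracy of a voxel set, averaged over
# subjects (each a full-voxel pattern set)
cohort_accuracy <- function(subjects, voxels, penalty = 1) {
  mean(purrr::map_dbl(subjects, function(ps) {
    fourway_loro(list(x = ps$x[, voxels, drop = FALSE],
                      object = ps$object, run = ps$run), penalty)
  }))
}

#' Rank parcels by reference-cohort decoding accuracy
#'
#' For every parcel, trains and tests a 4-way (one-vs-rest logistic)
#' classifier on that parcel's voxels with leave-one-run-out
#' cross-validation within each reference subject, averages accuracy
#' across subjects, and sorts parcels by decreasing accuracy (ties broken
#' by parcel id). Empty parcels are excluded with a warning.
#'
#' @param subjects List of reference subjects, each a full-voxel pattern
#'   set (see [recognition_patterns()]) with at least 2 runs.
#' @param parcellation A [make_parcellation()].
#' @param penalty Inverse L2 regularisation strength.
#' @return A `parcel_ranking` tibble (`parcel`, `accuracy`), best first.
#' @export
rank_parcels <- function(subjects, parcellation, penalty = 1) {
  if (any(purrr::map_int(subjects, ~ length(unique(.x$run))) < 2L)) {
    abort("Every reference subject needs at least 2 runs.")
  }
  ids <- names(parcellation$parcels)
  empty <- ids[lengths(parcellation$parcels) == 0L]
  if (length(empty)) {
    warn(paste0("Excluding empty parcel(s): ", paste(empty, collapse = ", ")))
    ids <- setdiff(ids, empty)
  }
  acc <- purrr::map_dbl(ids, function(p) {
    cohort_accuracy(subjects, parcellation$parcels[[p]], penalty)
  })
  out <- tibble::tibble(parcel = ids, accuracy = acc) |>
    dplyr::arrange(dplyr::desc(.data$accuracy), .data$parcel)
  class(out) <- c("parcel_ranking", class(out))
  out
}

#' Best top-N mega-ROI over a parcel ranking
#'
#' Builds nested mega-ROIs from the top-1, top-2, ..., top-P ranked
#' parcels, recomputes the reference cohort's leave-one-run-out 4-way
#' accuracy at each size, and returns the N with the best accuracy
#' (smallest N on ties) along with the full accuracy-vs-N curve.
#'
#' @param ranking A [rank_parcels()] result.
#' @param subjects The reference cohort (full-voxel pattern sets).
#' @param parcellation The parcellation behind the ranking.
#' @param penalty Inverse L2 regularisation strength.
#' @return A `topn_curve`: list with `curve` tibble (`n`, `accuracy`),
#'   `best_n`, and `best` (a `mega_roi`).
#' @export
build_topn_curve <- function(ranking, subjects, parcellation, penalty = 1) {
  if (nrow(ranking) == 0L) abort("`ranking` is empty.")
  ids <- ranking$parcel
  acc <- purrr::map_dbl(seq_along(ids), function(n) {
    cohort_accuracy(subjects, parcel_voxels(parcellation, ids[seq_len(n)]),
                    penalty)
  })
  best_n <- which.max(acc)                     # ties -> smallest N
  structure(list(
    curve = tibble::tibble(n = seq_along(ids), accuracy = acc),
    best_n = best_n,
    best = new_mega_roi(ids[seq_len(best_n)], parcellation, acc[best_n])
  ), class = "topn_curve")
}

#' @export
print.topn_curve <- function(x, ...) {
  cat("<topn_curve> best N =", x$best_n, "of", nrow(x$curve),
      "| accuracy", round(x$best$cv_accuracy, 3), "\n")
  invisible(x)
}

#' Greedy backward elimination of parcels
#'
#' Per-participant refinement of the starting mega-ROI: at the current
#' size k, every leave-one-parcel-out candidate is scored by 4-way
#' leave-one-run-out accuracy on the participant's Session-1 recognition
#' runs; the best candidate is recorded and elimination recurses on it
#' down to a single parcel. The returned ROI is the best-accuracy set over
#' all visited sizes, *including the starting set*. Score ties at an
#' elimination step are broken by removing the lowest parcel id.
#'
#' @param start A `mega_roi` (or character vector of parcel ids).
#' @param runs The participant's recognition runs (or full-voxel pattern
#'   set) with at least 2 runs.
#' @param parcellation The parcellation.
#' @param penalty Inverse L2 regularisation strength.
#' @param lag_trs Hemodynamic lag used when `runs` are raw runs.
#' @return A `mega_roi` whose `trace` attribute is a tibble
#'   (`size`, `accuracy`, `removed`, `parcels` list-column) with one row
#'   per visited size (the starting size first).
#' @export
greedy_refine <- function(start, runs, parcellation, penalty = 1,
                          lag_trs = 2L) {
  parcels <- if (inherits(start, "mega_roi")) start$parcels else start
  if (length(parcels) < 1L) abort("`start` must contain at least one parcel.")
  ps <- as_pattern_set(runs, lag_trs)
  score <- function(pids) {
    vox <- parcel_voxels(parcellation, pids)
    fourway_loro(list(x = ps$x[, vox, drop = FALSE], object = ps$object,
                      run = ps$run), penalty)
  }
  current <- sort(parcels)
  trace <- tibble::tibble(size = length(current), accuracy = score(current),
                          removed = NA_character_,
                          parcels = list(current))
  while (length(current) > 1L) {
    cand_acc <- purrr::map_dbl(current, function(p) {
      score(setdiff(current, p))
    })
    # best candidate; ties resolved by removing the lowest parcel id
    # (`current` is sorted, so which.max's first-max rule does exactly that)
    drop_idx <- which.max(cand_acc)
    removed <- current[drop_idx]
    current <- setdiff(current, removed)
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      size = length(current), accuracy = cand_acc[drop_idx],
      removed = removed, parcels = list(current)
    ))
  }
  best <- which.max(trace$accuracy)            # ties -> largest size (first)
  out <- new_mega_roi(trace$parcels[[best]], parcellation,
                      trace$accuracy[best])
  attr(out, "trace") <- trace
  out
}
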