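#' Write a simulated run to disk
#'
#' Writes the TR-by-voxel matrix as a 4-D NIfTI image (1-voxel-thick
#' geometry: x = voxel, y = z = 1, t = TR), the events as a BIDS-style
#' TSV (`onset` in seconds, `duration`, `trial_type`, `object`), and a
#' JSON sidecar with run metadata.
#'
#' @param run A `run_timeseries`.
#' @param prefix Output path prefix; writes `<prefix>_bold.nii.gz`,
#'   `<prefix>_events.tsv`, `<prefix>_bold.json`.
#' @return Invisibly, the three paths written.
#' @export
write_run <- function(run, prefix) {
  stopifnot(inherits(run, "run_timeseries"))
  nv <- ncol(run$data)
  nt <- nrow(run$data)
  arr <- array(t(run$data), dim = c(nv, 1L, 1L, nt))
  paths <- c(bold = paste0(prefix, "_bold.nii.gz"),
             events = paste0(prefix, "_events.tsv"),
             sidecar = paste0(prefix, "_bold.json"))
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(3, 3, 3, run$tr_s)),
                     paths["bold"])
  ev <- run$events
  ev$onset_tr <- NULL
  readr::write_tsv(ev, paths["events"])
  jsonlite::write_json(
    list(RepetitionTime = run$tr_s, RunType = run$run_type,
         Session = run$session, Volumes = nt, Voxels = nv),
    paths["sidecar"], auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}

#' Read a run written by [write_run()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `run_timeseries`.
#' @export
read_run <- function(prefix) {
  arr <- RNifti::readNifti(paste0(prefix, "_bold.nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, "_bold.json"),
                              simplifyVector = TRUE)
  data <- t(matrix(arr, nrow = dim(arr)[1], ncol = dim(arr)[4]))
  events <- readr::read_tsv(paste0(prefix, "_events.tsv"),
                            show_col_types = FALSE)
  events$onset_tr <- as.integer(events$onset / meta$RepetitionTime + 1L)
  new_run_timeseries(data, meta$RunType, events,
                     session = meta$Session %||% NA_integer_,
                     tr_s = meta$RepetitionTime)
}

#' Serialise a classifier bundle to JSON
#'
#' Stores weights, intercepts, object labels, the penalty, and a hash of
#' the ROI voxel set so a bundle is never applied to the wrong ROI.
#'
#' @param classifiers Named list from [train_all_pairs()].
#' @param roi Voxel indices the classifiers were trained over.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_classifiers <- function(classifiers, roi, path) {
  payload <- list(
    roi = as.integer(roi),
    roi_hash = digest_voxels(roi),
    classifiers = purrr::map(classifiers, function(clf) {
      list(object_a = clf$object_a, object_b = clf$object_b,
           weights = clf$weights, intercept = clf$intercept,
           penalty = clf$penalty)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a classifier bundle written by [write_classifiers()]
#'
#' @param path JSON path.
#' @return List with `classifiers` (named `pair_classifier` list) and
#'   `roi`.
#' @export
read_classifiers <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  clfs <- purrr::map(payload$classifiers, function(cl) {
    structure(list(object_a = cl$object_a, object_b = cl$object_b,
                   weights = as.numeric(cl$weights),
                   intercept = cl$intercept, penalty = cl$penalty),
              class = "pair_classifier")
  })
  list(classifiers = clfs, roi = as.integer(payload$roi))
}

# cheap stable hash of a voxel index set
digest_voxels <- function(roi) {
  h <- 0
  for (v in as.integer(roi)) h <- (h * 131 + v) %% 2147483647
  sprintf("%x", h)
}

#' Write a closed-loop trace to TSV
#'
#' @param result A `closed_loop_result`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(result, path) {
  readr::write_tsv(result$trace, path)
  invisible(path)
}
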