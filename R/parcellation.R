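#' Build an abstract voxel parcellation
#'
#' The feedback ROI machinery works on an atlas-style parcellation: a voxel
#' space of `n_voxels` voxels carved into disjoint parcels. Geometry is
#' irrelevant to the decoding pipeline, so parcels are plain index sets.
#'
#' @param n_parcels Number of parcels.
#' @param voxels_per_parcel Voxels in each parcel (recycled to `n_parcels`).
#' @param n_voxels Total voxel count; defaults to the sum of parcel sizes.
#'   May exceed it (leaving unparcellated voxels) but not be smaller.
#' @return A `parcellation`: list with `n_voxels` and `parcels`, a named
#'   list mapping parcel id (`"p01"`, ...) to a disjoint integer voxel set.
#' @export
#' @examples
#' p <- make_parcellation(n_parcels = 4, voxels_per_parcel = 10)
#' lengths(p$parcels)
make_parcellation <- function(n_parcels, voxels_per_parcel = 10,
                              n_voxels = NULL) {
  assert_scalar_number(n_parcels, "n_parcels", min = 1)
  sizes <- rep_len(as.integer(voxels_per_parcel), n_parcels)
  total <- sum(sizes)
  n_voxels <- n_voxels %||% total
  if (n_voxels < total) abort("`n_voxels` smaller than the union of parcels.")
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  ids <- sprintf("p%02d", seq_len(n_parcels))
  parcels <- purrr::map2(starts, stops, seq.int)
  names(parcels) <- ids
  structure(list(n_voxels = as.integer(n_voxels), parcels = parcels),
            class = "parcellation")
}

#' Union of parcel voxel sets
#'
#' @param parcellation A [make_parcellation()] object.
#' @param parcel_ids Character vector of parcel ids.
#' @return Sorted integer vector of voxel indices.
#' @export
parcel_voxels <- function(parcellation, parcel_ids) {
  missing <- setdiff(parcel_ids, names(parcellation$parcels))
  if (length(missing)) {
    abort(paste0("Unknown parcel id(s): ", paste(missing, collapse = ", ")))
  }
  sort(unique(unlist(parcellation$parcels[parcel_ids], use.names = FALSE)))
}

#' @export
print.parcellation <- function(x, ...) {
  cat("<parcellation>", length(x$parcels), "parcels over", x$n_voxels,
      "voxels\n")
  invisible(x)
}
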