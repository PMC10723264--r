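#' Assign the four objects to experimental roles
#'
#' A study uses four objects. One ("presented") is viewed during feedback
#' trials, one ("competitor") is the object whose representation the
#' participant learns to activate covertly, and the remaining two are
#' untrained controls that provide the neutral evidence baseline. The
#' assignment is counterbalanced across participants in two batches with
#' reversed role assignments.
#'
#' @param objects Character vector of four distinct object identifiers.
#' @param batch `1` or `2`. Batch 1 assigns `objects[1]` as presented,
#'   `objects[2]` as competitor and `objects[3:4]` as controls; batch 2
#'   reverses the assignment (`objects[3]` presented, `objects[4]`
#'   competitor, `objects[1:2]` controls).
#'
#' @return An `object_set`: a list with elements `objects`, `presented`,
#'   `competitor`, `controls` (ordered pair) and `batch`. The four roles
#'   partition the four objects exactly.
#' @export
#' @examples
#' object_set(batch = 2)
object_set <- function(objects = c("bed", "chair", "table", "bench"),
                       batch = 1) {
  if (length(objects) != 4L || anyDuplicated(objects) ||
      !is.character(objects)) {
    abort("`objects` must be four distinct object identifiers.")
  }
  if (!batch %in% c(1, 2)) abort("`batch` must be 1 or 2.")
  roles <- if (batch == 1) {
    list(presented = objects[1], competitor = objects[2],
         controls = objects[3:4])
  } else {
    list(presented = objects[3], competitor = objects[4],
         controls = objects[1:2])
  }
  structure(
    c(list(objects = objects), roles, list(batch = as.integer(batch))),
    class = "object_set"
  )
}

#' @export
print.object_set <- function(x, ...) {
  cat("<object_set> batch", x$batch, "\n")
  cat("  presented:  ", x$presented, "\n")
  cat("  competitor: ", x$competitor, "\n")
  cat("  controls:   ", paste(x$controls, collapse = ", "), "\n")
  invisible(x)
}

#' Trained and untrained object axes
#'
#' The trained axis is the presented--competitor pair (the pair whose
#' coactivation is induced by neurofeedback); the untrained axis is the
#' control pair, measured identically but never trained.
#'
#' @param os An [object_set()].
#' @return Named list of two character pairs, `trained` and `untrained`.
#' @export
object_axes <- function(os) {
  stopifnot(inherits(os, "object_set"))
  list(trained = c(os$presented, os$competitor), untrained = os$controls)
}
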