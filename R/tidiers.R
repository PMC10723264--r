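#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a psychometric fit
#'
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @return One row per parameter (`term`, `estimate`) in broom style.
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "slope", "s"),
                 estimate = c(x$mu, x$slope, x$s))
}

#' @rdname tidy.psychometric_fit
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, slope = x$slope, s = x$s, logLik = x$loglik,
                 nobs = x$n, mu_fixed = x$mu_fixed,
                 identifiable = x$identifiable, session = x$session,
                 axis = x$axis)
}

#' Tidy a bootstrap test
#'
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `ci_lower`, `ci_upper`,
#'   `p.value`, `n`, `n_iter`.
#' @export
tidy.bootstrap_result <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, ci_lower = x$ci_lower,
                 ci_upper = x$ci_upper, p.value = x$p, n = x$n,
                 n_iter = x$n_iter)
}

#' Tidy leave-one-run-out decoding results
#'
#' @param x A `loro_result`.
#' @param ... Unused.
#' @return Per-fold tibble (`held_out_run`, `accuracy`).
#' @export
tidy.loro_result <- function(x, ...) x$fold_accuracy

#' @rdname tidy.loro_result
#' @export
glance.loro_result <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n_folds = nrow(x$fold_accuracy),
                 axis = paste(x$axis, collapse = "|"))
}

#' Tidy a study-result bundle
#'
#' @param x A `study_result` from [run_study()].
#' @param ... Unused.
#' @return Long tibble of per-participant integration indices
#'   (`participant`, `axis`, `measure`, `index`).
#' @export
tidy.study_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::transmute(x$behavior, participant = .data$participant,
                     axis = .data$axis, measure = "behavioral",
                     index = .data$index),
    dplyr::transmute(x$neural, participant = .data$participant,
                     axis = .data$axis, measure = "neural",
                     index = .data$index)
  )
}

#' @rdname tidy.study_result
#' @export
glance.study_result <- function(x, ...) {
  g <- x$group
  tibble::tibble(
    n = x$config$participants,
    behavioral_trained = g$behavioral_trained$estimate,
    behavioral_trained_p = g$behavioral_trained$p,
    neural_trained = g$neural_trained$estimate,
    neural_trained_p = g$neural_trained$p,
    neural_diff_p = g$neural_diff$p,
    threshold_slope = g$threshold_trend$bootstrap$estimate,
    threshold_trend_p = g$threshold_trend$bootstrap$p,
    competition_slope = g$competition_trend$bootstrap$estimate,
    competition_trend_p = g$competition_trend$bootstrap$p,
    brain_behavior_r = g$brain_behavior$r,
    brain_behavior_p = g$brain_behavior$p
  )
}
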