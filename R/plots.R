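#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_hline geom_errorbar labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot a psychometric fit
#'
#' Observed per-level choice fractions with the fitted logistic curve.
#'
#' @param object A `psychometric_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  obs <- object$responses |>
    dplyr::group_by(.data$morph) |>
    dplyr::summarise(p = mean(.data$choice), .groups = "drop")
  grid <- tibble::tibble(morph = seq(min(obs$morph), max(obs$morph),
                                     length.out = 200))
  grid$p <- predict(object, grid$morph)
  ggplot(obs, aes(x = .data$morph, y = .data$p)) +
    geom_point() +
    geom_line(data = grid) +
    geom_hline(yintercept = 0.5, linetype = "dotted") +
    labs(x = "morph (%)", y = "P(choose second object)",
         title = sprintf("mu = %.1f, slope = %.3f", object$mu,
                         object$slope)) +
    theme_minimal()
}

#' Plot the accuracy-vs-N mega-ROI curve
#'
#' @param object A `topn_curve`.
#' @param ... Unused.
#' @return A ggplot with the selected N marked.
#' @export
autoplot.topn_curve <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$n, y = .data$accuracy)) +
    geom_line() +
    geom_point() +
    geom_point(data = object$curve[object$best_n, ], colour = "red",
               size = 3) +
    geom_hline(yintercept = 0.25, linetype = "dotted") +
    labs(x = "top-N parcels", y = "4-way LORO accuracy") +
    theme_minimal()
}

#' Plot closed-loop threshold and competition trajectories
#'
#' Threshold in force per feedback run, with the per-session competition
#' index overlaid on a second panel.
#'
#' @param object A `closed_loop_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.closed_loop_result <- function(object, ...) {
  th <- dplyr::mutate(object$threshold,
                      session = factor(.data$session))
  ggplot(th, aes(x = .data$global_run, y = .data$theta,
                 colour = .data$session)) +
    geom_line() +
    geom_point() +
    labs(x = "feedback run", y = "staircase threshold",
         colour = "session") +
    theme_minimal()
}

#' Plot group integration indices of a study
#'
#' Bootstrap means and 95% intervals of the behavioral and neural
#' integration indices, by axis.
#'
#' @param object A `study_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.study_result <- function(object, ...) {
  g <- object$group
  rows <- purrr::imap_dfr(
    list(behavioral_trained = g$behavioral_trained,
         behavioral_untrained = g$behavioral_untrained,
         neural_trained = g$neural_trained,
         neural_untrained = g$neural_untrained),
    function(b, nm) {
      parts <- strsplit(nm, "_")[[1]]
      tibble::tibble(measure = parts[1], axis = parts[2],
                     estimate = b$estimate, lo = b$ci_lower,
                     hi = b$ci_upper)
    })
  ggplot(rows, aes(x = .data$axis, y = .data$estimate)) +
    geom_col(fill = "grey70") +
    geom_errorbar(aes(ymin = .data$lo, ymax = .data$hi), width = 0.2) +
    geom_hline(yintercept = 0) +
    facet_wrap(~.data$measure, scales = "free_y") +
    labs(x = NULL, y = "integration index (bootstrap mean, 95% CI)") +
    theme_minimal()
}
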