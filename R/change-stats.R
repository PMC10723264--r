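#' Neural integration index
#'
#' Session-1 leave-one-run-out decoding accuracy minus Session-5
#' cross-session accuracy for one ROI and object axis. Integration (more
#' pattern overlap after training) makes the Session-1 classifiers worse
#' on Session-5 data, so a positive index reflects integration and a
#' negative one differentiation.
#'
#' @param a1 Session-1 accuracy in \[0, 1\].
#' @param a5 Session-5 (cross-session) accuracy in \[0, 1\].
#' @return Scalar index in \[-1, 1\].
#' @export
neural_integration_index <- function(a1, a5) {
  assert_scalar_number(a1, "a1", 0, 1)
  assert_scalar_number(a5, "a5", 0, 1)
  a1 - a5
}

#' Group-level bootstrap mean test
#'
#' Resamples participants with replacement `n_iter` times, averaging the
#' per-participant effect on each iteration. The 95% interval is the
#' 2.5/97.5 percentile band of the resampled means, and the p-value is the
#' proportion of iterations whose mean has the opposite sign from the
#' observed mean — a one-tailed, sign-based bootstrap test (no two-tailed
#' doubling).
#'
#' @param values Per-participant effect values (length >= 2).
#' @param n_iter Bootstrap iterations (1000 by default).
#' @param seed Integer seed.
#' @return A `bootstrap_result`: `estimate` (observed mean), `ci_lower`,
#'   `ci_upper`, `p`, `n`, `n_iter`, `seed`, and the resampled `means`.
#'   With an all-zero input the sign test is undefined and `p` is `NA`
#'   (flagged with a warning).
#' @export
#' @examples
#' bootstrap_mean_test(c(0.4, 0.1, 0.3, -0.1), n_iter = 1000, seed = 1)
bootstrap_mean_test <- function(values, n_iter = 1000L, seed = 1L) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) abort("Need at least 2 values.")
  est <- mean(values)
  means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_iter, replace = TRUE), nrow = n_iter)
    rowMeans(matrix(values[idx], nrow = n_iter))
  })
  if (all(values == 0)) {
    warn("All values are zero: the sign-based p-value is undefined.")
    p <- NA_real_
  } else {
    p <- mean(means * sign(est) < 0)
  }
  ci <- unname(quantile(means, c(0.025, 0.975)))
  structure(list(estimate = est, ci_lower = ci[1], ci_upper = ci[2],
                 p = p, n = n, n_iter = as.integer(n_iter),
                 seed = as.integer(seed), means = means),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> mean %.4f [%.4f, %.4f], p = %.3f (n = %d, %d iter)\n",
    x$estimate, x$ci_lower, x$ci_upper, x$p, x$n, x$n_iter))
  invisible(x)
}

#' Per-participant session trend with group bootstrap
#'
#' Fits an ordinary-least-squares slope over session number for every
#' participant (e.g. the staircase threshold or the competition index over
#' the three feedback sessions) and tests the group of slopes with the
#' sign-based bootstrap. Participants missing a session are excluded with
#' a warning.
#'
#' @param data Data frame with columns `participant`, `session`, `value`.
#' @param n_iter,seed Passed to [bootstrap_mean_test()].
#' @return List with `slopes` (tibble `participant`, `slope`) and
#'   `bootstrap` (a `bootstrap_result` over the slopes).
#' @export
session_trend <- function(data, n_iter = 1000L, seed = 1L) {
  n_sessions <- length(unique(data$session))
  counts <- data |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::count(.data$participant)
  incomplete <- counts$participant[counts$n < n_sessions]
  if (length(incomplete)) {
    warn(paste0("Excluding participant(s) with missing sessions: ",
                paste(incomplete, collapse = ", ")))
    data <- dplyr::filter(data, !.data$participant %in% incomplete)
  }
  slopes <- data |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      slope = {
        s <- .data$session - mean(.data$session)
        sum(s * (.data$value - mean(.data$value))) / sum(s^2)
      },
      .groups = "drop"
    )
  list(slopes = slopes,
       bootstrap = bootstrap_mean_test(slopes$slope, n_iter = n_iter,
                                       seed = seed))
}

#' Brain--behavior correlation
#'
#' Pearson correlation across participants between the neural and
#' behavioral integration indices; the p-value comes from the standard
#' parametric t transform of r (`method = "parametric"`) or from a
#' participant-level bootstrap of r (`method = "bootstrap"`, sign-based,
#' matching the package's group tests).
#'
#' @param neural,behavioral Paired per-participant index vectors
#'   (length >= 3).
#' @param method `"parametric"` (default) or `"bootstrap"`.
#' @param n_iter,seed Bootstrap controls (bootstrap method only).
#' @return Tibble with `r`, `p`, `n`, `method`.
#' @export
brain_behavior_corr <- function(neural, behavioral,
                                method = c("parametric", "bootstrap"),
                                n_iter = 1000L, seed = 1L) {
  method <- match.arg(method)
  ok <- complete.cases(neural, behavioral)
  neural <- neural[ok]
  behavioral <- behavioral[ok]
  if (length(neural) < 3L) abort("Need at least 3 paired participants.")
  if (sd(neural) == 0 || sd(behavioral) == 0) {
    warn("Zero variance in an index: correlation undefined.")
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = length(neural),
                          method = method))
  }
  r <- stats::cor(neural, behavioral)
  if (method == "parametric") {
    p <- cor.test(neural, behavioral)$p.value
  } else {
    n <- length(neural)
    rs <- with_seed(seed, {
      vapply(seq_len(n_iter), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        if (sd(neural[idx]) == 0 || sd(behavioral[idx]) == 0) return(NA_real_)
        stats::cor(neural[idx], behavioral[idx])
      }, numeric(1))
    })
    p <- mean(rs * sign(r) < 0, na.rm = TRUE)
  }
  tibble::tibble(r = r, p = p, n = length(neural), method = method)
}
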