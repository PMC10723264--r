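#' Fit the logistic psychometric function
#'
#' Models the forced-choice categorisation of morphs between two endpoint
#' objects as `p(x) = 1 / (1 + exp(-(x - mu) / s))`, where `x` is the
#' morph percent, `mu` the point of subjective equality and `s` the scale;
#' the reported `slope` is the steepness coefficient `1/s` (per morph-%),
#' so a shallower curve — reduced discriminability — has a smaller slope.
#' Fitting is by penalised maximum likelihood with a weak ridge on the
#' slope (1e-4) to stabilise separable response sets; with `fixed_mu`
#' given, only the slope is free (the Session-5 convention, which reduces
#' slope-estimate noise).
#'
#' One-sided response sets (all choices identical) leave the slope
#' unidentifiable: the fit is flagged, the slope capped at `slope_max`,
#' and a warning raised.
#'
#' @param responses Data frame with columns `morph` (percent) and `choice`
#'   (0/1, 1 = second endpoint object).
#' @param fixed_mu Optional fixed point of subjective equality.
#' @param slope_max Upper bound on the slope (per morph-%).
#' @param ridge Ridge penalty weight on the slope.
#' @param session,axis Optional metadata stored on the fit.
#' @return A `psychometric_fit`: `mu`, `slope`, `s` (= 1/slope), `loglik`
#'   (unpenalised, at the optimum), `n`, `mu_fixed`, `identifiable`,
#'   plus the metadata. Methods: [predict()], [tidy()], [glance()],
#'   [autoplot()].
#' @export
#' @examples
#' resp <- simulate_behavior(c(mu = 50, slope = 0.2),
#'                           make_morph_schedule(1), seed = 7)
#' fit <- fit_psychometric(resp)
#' c(fit$mu, fit$slope)
fit_psychometric <- function(responses, fixed_mu = NULL, slope_max = 10,
                             ridge = 1e-4, session = NA_integer_,
                             axis = NA_character_) {
  x <- responses$morph
  y <- responses$choice
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(x)) < 2L) abort("Need at least 2 distinct morph levels.")
  n <- length(y)
  one_sided <- length(unique(y)) < 2L
  if (one_sided) {
    warn("One-sided responses: psychometric slope is not identifiable; slope capped.")
    mu_hat <- fixed_mu %||% 50
    fit <- list(mu = mu_hat, slope = slope_max)
  } else {
    nll <- function(mu, slope) {
      eta <- slope * (x - mu)
      sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + ridge * slope^2
    }
    if (is.null(fixed_mu)) {
      opt <- optim(c(mu = 50, slope = 0.1),
                   function(p) nll(p[1], p[2]),
                   method = "L-BFGS-B",
                   lower = c(0, 1e-8), upper = c(100, slope_max),
                   control = list(factr = 1e2))
      fit <- list(mu = unname(opt$par[1]), slope = unname(opt$par[2]))
    } else {
      assert_scalar_number(fixed_mu, "fixed_mu", 0, 100)
      opt <- optim(c(slope = 0.1), function(p) nll(fixed_mu, p[1]),
                   method = "L-BFGS-B", lower = 1e-8, upper = slope_max,
                   control = list(factr = 1e2))
      fit <- list(mu = fixed_mu, slope = unname(opt$par[1]))
    }
  }
  eta <- fit$slope * (x - fit$mu)
  loglik <- -sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
  structure(list(mu = fit$mu, slope = fit$slope, s = 1 / fit$slope,
                 loglik = loglik, n = n,
                 mu_fixed = !is.null(fixed_mu),
                 identifiable = !one_sided,
                 session = session, axis = axis,
                 responses = tibble::as_tibble(responses[c("morph", "choice")])),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("<psychometric_fit>",
      if (!is.na(x$axis)) paste0(x$axis, " axis,"),
      if (!is.na(x$session)) paste0("session ", x$session, ","),
      sprintf("mu = %.2f%s, slope = %.4f (n = %d)\n",
              x$mu, if (x$mu_fixed) " (fixed)" else "", x$slope, x$n))
  invisible(x)
}

#' @export
predict.psychometric_fit <- function(object, morph, ...) {
  plogis(object$slope * (morph - object$mu))
}

#' Behavioral integration index
#'
#' Session-1 psychometric slope minus Session-5 slope for one axis: a
#' positive index means the post-training curve is shallower (the two
#' objects are harder to tell apart — integration); negative means
#' differentiation. The Session-5 fit must have used the Session-1 `mu`.
#'
#' @param fit1,fit5 `psychometric_fit`s for Sessions 1 and 5 of the same
#'   axis.
#' @return Scalar index (slope difference, per morph-%).
#' @export
behavioral_integration_index <- function(fit1, fit5) {
  stopifnot(inherits(fit1, "psychometric_fit"),
            inherits(fit5, "psychometric_fit"))
  if (!identical(fit1$axis, fit5$axis)) {
    abort("Fits are from different axes.")
  }
  if (!fit5$mu_fixed) {
    warn("Session-5 fit did not fix mu at the Session-1 estimate.")
  }
  fit1$slope - fit5$slope
}
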