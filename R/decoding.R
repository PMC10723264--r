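#' L2-regularised logistic regression (IRLS)
#'
#' The decoding workhorse: binary logistic regression with a ridge penalty
#' on the weights (intercept unpenalised), fitted by Newton/IRLS with step
#' halving. `penalty` is the inverse regularisation strength `C` in the
#' conventional parameterisation, i.e. the objective is
#' `sum(log(1 + exp(eta)) - y * eta) + ||w||^2 / (2 * C)`; the decoders in
#' this package all use `penalty = 1`. The penalty makes the objective
#' strictly convex, so the fit is unique and deterministic given the data,
#' including on linearly separable patterns.
#'
#' @param x Numeric matrix, observations by features.
#' @param y Binary 0/1 response vector.
#' @param penalty Inverse regularisation strength `C` (> 0).
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Newton iteration cap.
#' @return List with `weights`, `intercept`, `penalty`, `converged`.
#' @export
ridge_logistic <- function(x, y, penalty = 1, tol = 1e-10, max_iter = 100L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(x) == length(y))
  if (length(unique(y)) < 2L) abort("Both classes must be present.")
  n <- nrow(x)
  p <- ncol(x)
  xt <- cbind(1, x)
  lam <- 1 / penalty
  pen <- c(0, rep(lam, p))            # intercept unpenalised
  beta <- numeric(p + 1L)
  obj <- function(b) {
    eta <- drop(xt %*% b)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      sum(pen * b^2) / 2
  }
  f_old <- obj(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(xt %*% beta)
    mu <- plogis(eta)
    g <- drop(crossprod(xt, mu - y)) + pen * beta
    if (max(abs(g)) < tol) {
      converged <- TRUE
      break
    }
    w <- pmax(mu * (1 - mu), 1e-12)
    h <- crossprod(xt * w, xt)
    diag(h) <- diag(h) + pen
    step <- solve(h, g)
    # backtracking line search on the penalised deviance
    t_step <- 1
    repeat {
      beta_new <- beta - t_step * step
      f_new <- obj(beta_new)
      if (f_new <= f_old || t_step < 1e-8) break
      t_step <- t_step / 2
    }
    beta <- beta_new
    f_old <- f_new
  }
  list(weights = beta[-1L], intercept = beta[1L], penalty = penalty,
       converged = converged)
}

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Train a binary pair classifier
#'
#' Fits an L2-regularised logistic discriminator between two objects over
#' the supplied (ROI-masked, z-scored) patterns. The classifier's graded
#' output for an object is a probability in \[0, 1\], and the outputs for
#' the two objects of the pair sum to 1 by construction.
#'
#' @param x Pattern matrix, trials by voxels.
#' @param labels Character vector of object labels (exactly two distinct).
#' @param penalty Inverse L2 regularisation strength (default 1).
#' @return A `pair_classifier` with fields `object_a`, `object_b`
#'   (alphabetical), `weights`, `intercept`, `penalty`.
#' @export
train_pair_classifier <- function(x, labels, penalty = 1) {
  objs <- sort(unique(labels))
  if (length(objs) != 2L) {
    abort("`labels` must contain exactly two distinct objects.")
  }
  fit <- ridge_logistic(as.matrix(x), as.numeric(labels == objs[2L]), penalty)
  structure(list(object_a = objs[1L], object_b = objs[2L],
                 weights = fit$weights, intercept = fit$intercept,
                 penalty = penalty),
            class = "pair_classifier")
}

#' @export
print.pair_classifier <- function(x, ...) {
  cat("<pair_classifier>", x$object_a, "vs", x$object_b, "|",
      length(x$weights), "voxels, penalty", x$penalty, "\n")
  invisible(x)
}

#' Graded classifier evidence for one object of a pair
#'
#' @param clf A [train_pair_classifier()] object.
#' @param pattern Numeric voxel pattern, or a trials-by-voxels matrix.
#' @param object Which object of the pair to report evidence for.
#' @return Evidence in \[0, 1\] (vector if `pattern` is a matrix);
#'   evidence for the two objects of the pair sums to 1.
#' @export
pair_evidence <- function(clf, pattern, object) {
  stopifnot(inherits(clf, "pair_classifier"))
  if (!object %in% c(clf$object_a, clf$object_b)) {
    abort(sprintf("Object '%s' is not part of this classifier.", object))
  }
  x <- if (is.matrix(pattern)) pattern else matrix(pattern, nrow = 1L)
  if (ncol(x) != length(clf$weights)) {
    abort("Pattern length does not match the classifier's ROI.")
  }
  p_b <- plogis(drop(x %*% clf$weights) + clf$intercept)
  if (object == clf$object_b) p_b else 1 - p_b
}

#' Hard label prediction of a pair classifier
#'
#' @inheritParams pair_evidence
#' @return Character vector of predicted object labels (evidence ties at
#'   0.5 go to the alphabetically first object).
#' @export
pair_predict <- function(clf, pattern) {
  e_b <- pair_evidence(clf, pattern, clf$object_b)
  ifelse(e_b > 0.5, clf$object_b, clf$object_a)
}

#' Train all six pairwise classifiers
#'
#' One binary L2 logistic classifier per unordered pair of the four
#' objects (choose(4, 2) = 6), trained on Session-1 recognition patterns.
#'
#' @param pattern_set List with `x` (trials by voxels), `object`, `run`,
#'   e.g. from [recognition_patterns()].
#' @param penalty Inverse L2 regularisation strength.
#' @return Named list of 6 `pair_classifier`s keyed `"a|b"` (alphabetical).
#' @export
train_all_pairs <- function(pattern_set, penalty = 1) {
  objs <- sort(unique(pattern_set$object))
  if (length(objs) != 4L) {
    abort("All four objects must be present in the training data.")
  }
  pairs <- combn(objs, 2, simplify = FALSE)
  clfs <- purrr::map(pairs, function(pr) {
    keep <- pattern_set$object %in% pr
    train_pair_classifier(pattern_set$x[keep, , drop = FALSE],
                          pattern_set$object[keep], penalty)
  })
  names(clfs) <- purrr::map_chr(pairs, ~ pair_key(.x[1], .x[2]))
  clfs
}

#' Control-referenced object evidence
#'
#' The activation level of a target object is the arithmetic mean of the
#' graded outputs of the two classifiers that discriminate the target from
#' each control object. The classifier directly pitting presented against
#' competitor is never consulted, so presented and competitor evidence are
#' estimated independently against the common neutral baseline.
#'
#' @param pattern Voxel pattern (or trials-by-voxels matrix).
#' @param target Object whose evidence is wanted.
#' @param controls Character pair of control objects.
#' @param classifiers Named list from [train_all_pairs()].
#' @return Evidence in \[0, 1\].
#' @export
object_evidence <- function(pattern, target, controls, classifiers) {
  if (target %in% controls) abort("`target` must not be a control object.")
  if (length(controls) != 2L) abort("`controls` must be a pair.")
  e <- purrr::map(controls, function(ctrl) {
    clf <- classifiers[[pair_key(target, ctrl)]]
    if (is.null(clf)) {
      abort(sprintf("No classifier for pair %s.", pair_key(target, ctrl)))
    }
    pair_evidence(clf, pattern, target)
  })
  (e[[1]] + e[[2]]) / 2
}

# ---- 4-way classification (ROI selection) ---------------------------------

# One-vs-rest logistic 4-way classifier over a voxel subset.
train_fourway <- function(x, labels, penalty = 1) {
  objs <- sort(unique(labels))
  fits <- purrr::map(objs, function(o) {
    ridge_logistic(x, as.numeric(labels == o), penalty)
  })
  names(fits) <- objs
  structure(list(objects = objs, fits = fits, penalty = penalty),
            class = "fourway_classifier")
}

predict_fourway <- function(clf, x) {
  x <- as.matrix(x)
  scores <- vapply(clf$fits, function(f) {
    drop(x %*% f$weights) + f$intercept
  }, numeric(nrow(x)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  # ties broken toward the alphabetically first object (columns are sorted)
  clf$objects[max.col(scores, ties.method = "first")]
}

# Mean leave-one-run-out 4-way accuracy on one pattern set.
fourway_loro <- function(pattern_set, penalty = 1) {
  runs <- sort(unique(pattern_set$run))
  if (length(runs) < 2L) abort("Need at least 2 runs for leave-one-run-out.")
  acc <- vapply(runs, function(r) {
    tr <- pattern_set$run != r
    clf <- train_fourway(pattern_set$x[tr, , drop = FALSE],
                         pattern_set$object[tr], penalty)
    pred <- predict_fourway(clf, pattern_set$x[!tr, , drop = FALSE])
    mean(pred == pattern_set$object[!tr])
  }, numeric(1))
  mean(acc)
}

# ---- leave-one-run-out and cross-session accuracy -------------------------

as_pattern_set <- function(runs, lag_trs = 2L, roi = NULL, objects = NULL) {
  if (is.list(runs) && !is.null(runs$x)) {
    ps <- runs
    if (!is.null(objects)) {
      keep <- ps$object %in% objects
      ps <- list(x = ps$x[keep, , drop = FALSE], object = ps$object[keep],
                 run = ps$run[keep])
    }
    if (!is.null(roi)) ps$x <- ps$x[, roi, drop = FALSE]
    return(ps)
  }
  extract_pattern_set(runs, lag_trs = lag_trs, roi = roi, objects = objects)
}

#' Recognition-run trial patterns
#'
#' Batch z-scores each run, extracts the lagged single-volume pattern of
#' every trial and stacks them into a trials-by-voxels matrix with object
#' and run labels — the input format of all decoding functions.
#'
#' @param runs List of recognition `run_timeseries`.
#' @param lag_trs Hemodynamic lag in TRs.
#' @param roi Optional voxel index subset.
#' @param objects Optional subset of objects to keep.
#' @return List with `x`, `object`, `run`.
#' @export
recognition_patterns <- function(runs, lag_trs = 2L, roi = NULL,
                                 objects = NULL) {
  extract_pattern_set(runs, lag_trs = lag_trs, roi = roi, objects = objects)
}

#' Within-session leave-one-run-out pair decoding accuracy
#'
#' For one object axis, trains a pair classifier on all but one run and
#' tests on the held-out run, rotating the held-out run over all runs
#' (eight in a standard session); the session score is the mean of the
#' per-fold accuracies. The per-fold classifiers are returned for reuse in
#' the cross-session analysis.
#'
#' @param runs List of recognition `run_timeseries` (or a pattern set).
#' @param axis Character pair of objects to discriminate.
#' @param roi Voxel indices of the ROI (applied when `runs` are raw runs or
#'   a full-voxel pattern set).
#' @param lag_trs Hemodynamic lag in TRs.
#' @param penalty Inverse L2 regularisation strength.
#' @return A `loro_result`: list with `accuracy`, `fold_accuracy` tibble,
#'   and `classifiers` (one per held-out run).
#' @export
loro_accuracy <- function(runs, axis, roi = NULL, lag_trs = 2L, penalty = 1) {
  stopifnot(length(axis) == 2L)
  ps <- as_pattern_set(runs, lag_trs, roi, objects = axis)
  run_ids <- sort(unique(ps$run))
  if (length(run_ids) < 2L) abort("Need at least 2 runs.")
  folds <- purrr::map(run_ids, function(r) {
    tr <- ps$run != r
    clf <- train_pair_classifier(ps$x[tr, , drop = FALSE], ps$object[tr],
                                 penalty)
    pred <- pair_predict(clf, ps$x[!tr, , drop = FALSE])
    list(clf = clf, acc = mean(pred == ps$object[!tr]))
  })
  accs <- purrr::map_dbl(folds, "acc")
  structure(list(
    accuracy = mean(accs),
    fold_accuracy = tibble::tibble(held_out_run = run_ids, accuracy = accs),
    classifiers = purrr::map(folds, "clf"),
    axis = sort(axis)
  ), class = "loro_result")
}

#' @export
print.loro_result <- function(x, ...) {
  cat("<loro_result>", paste(x$axis, collapse = " vs "), "| accuracy",
      round(x$accuracy, 3), "over", nrow(x$fold_accuracy), "folds\n")
  invisible(x)
}

#' Cross-session decoding accuracy
#'
#' Tests the Session-1 fold classifiers on Session-5 recognition runs. In
#' the default `"all_pairs"` mode every classifier is evaluated on every
#' Session-5 run and the classifier-by-run accuracies are averaged (the
#' lower-variance reading); `"paired"` matches classifier *k* with run *k*
#' only.
#'
#' @param classifiers List of `pair_classifier`s (e.g. from
#'   [loro_accuracy()]`$classifiers`).
#' @param runs Session-5 recognition runs (or pattern set).
#' @param axis Character pair of objects.
#' @param roi Voxel indices; must give patterns of the same length the
#'   classifiers were trained on.
#' @param lag_trs Hemodynamic lag in TRs.
#' @param mode `"all_pairs"` (default) or `"paired"`.
#' @return Mean accuracy in \[0, 1\].
#' @export
cross_session_accuracy <- function(classifiers, runs, axis, roi = NULL,
                                   lag_trs = 2L,
                                   mode = c("all_pairs", "paired")) {
  mode <- match.arg(mode)
  ps <- as_pattern_set(runs, lag_trs, roi, objects = axis)
  if (ncol(ps$x) != length(classifiers[[1]]$weights)) {
    abort("ROI size differs between the classifiers and the test patterns.")
  }
  run_ids <- sort(unique(ps$run))
  if (mode == "paired" && length(run_ids) != length(classifiers)) {
    abort("Paired mode needs as many runs as classifiers.")
  }
  acc_one <- function(clf, r) {
    te <- ps$run == r
    mean(pair_predict(clf, ps$x[te, , drop = FALSE]) == ps$object[te])
  }
  if (mode == "all_pairs") {
    accs <- purrr::map(classifiers, function(clf) {
      purrr::map_dbl(run_ids, ~ acc_one(clf, .x))
    })
    mean(unlist(accs))
  } else {
    mean(purrr::map2_dbl(classifiers, run_ids, acc_one))
  }
}
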