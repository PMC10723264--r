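test_that("the IRLS ridge-logistic fit agrees with glmnet at the matched lambda", {
  skip_if_not_installed("glmnet")
  for (seed in 1:3) {
    withr::with_seed(seed, {
      n <- 50
      x <- matrix(rnorm(n * 6), n, 6)
      y <- rbinom(n, 1, plogis(drop(x %*% rnorm(6))))
    })
    if (length(unique(y)) < 2) next
    fit <- ridge_logistic(x, y, penalty = 1)
    g <- glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = 1 / n,
                        standardize = FALSE, thresh = 1e-14, maxit = 1e6)
    expect_equal(c(fit$intercept, fit$weights),
                 as.numeric(stats::coef(g)), tolerance = 1e-6)
  }
})

test_that("pair evidence for the two objects always sums to one", {
  cl <- two_cluster(seed = 3)
  clf <- train_pair_classifier(cl$x, cl$labels)
  withr::with_seed(4, probe <- matrix(rnorm(50 * 10, sd = 3), 50, 10))
  e_a <- pair_evidence(clf, probe, "a")
  e_b <- pair_evidence(clf, probe, "b")
  expect_true(all(e_a >= 0 & e_a <= 1))
  expect_equal(e_a + e_b, rep(1, 50), tolerance = 1e-10)
})

test_that("pair classifiers separate clusters, fail on shuffled labels, and replay exactly", {
  cl <- two_cluster(n = 40, mu = 1.5, seed = 5)
  clf <- train_pair_classifier(cl$x, cl$labels)
  test <- two_cluster(n = 50, mu = 1.5, seed = 6)
  expect_gte(mean(pair_predict(clf, test$x) == test$labels), 0.95)
  # label permutation destroys the signal: held-out accuracy within
  # binomial noise of 0.5 (99.9% bound for 100 test patterns)
  shuf <- withr::with_seed(7, sample(cl$labels))
  clf_null <- train_pair_classifier(cl$x, shuf)
  acc_null <- mean(pair_predict(clf_null, test$x) == test$labels)
  expect_lt(abs(acc_null - 0.5), 3.3 * sqrt(0.25 / 100))
  # determinism
  expect_identical(clf, train_pair_classifier(cl$x, cl$labels))
  expect_error(train_pair_classifier(cl$x, rep("a", 80)), "two distinct")
})

test_that("all six pairwise classifiers are trained, three per object", {
  gt <- tiny_gt(seed = 8)
  ps <- recognition_patterns(sim_runs(gt, 2, seed = 8))
  clfs <- train_all_pairs(ps)
  expect_length(clfs, 6)
  members <- c(sapply(clfs, `[[`, "object_a"), sapply(clfs, `[[`, "object_b"))
  expect_true(all(table(members) == 3))
  ps$object[ps$object == "bed"] <- "chair"
  expect_error(train_all_pairs(ps), "four objects")
})

test_that("object evidence averages the two control-referenced classifiers only", {
  # two manual classifiers whose outputs for the target are 0.6 and 0.8
  c1 <- manual_pair_classifier("ctrl1", "tgt", weights = 0,
                               intercept = qlogis(0.6))
  c2 <- manual_pair_classifier("ctrl2", "tgt", weights = 0,
                               intercept = qlogis(0.8))
  # a decoy direct classifier that would give a wildly different answer
  decoy <- manual_pair_classifier("comp", "tgt", weights = 0,
                                  intercept = qlogis(0.999))
  clfs <- list(c1, c2, decoy)
  names(clfs) <- c("ctrl1|tgt", "ctrl2|tgt", "comp|tgt")
  e <- object_evidence(0, "tgt", c("ctrl1", "ctrl2"), clfs)
  expect_equal(e, 0.7)
  expect_error(object_evidence(0, "tgt", c("tgt", "ctrl1"), clfs), "control")
})

test_that("evidence is high on the target prototype and low on a control prototype", {
  gt <- tiny_gt(n_info = 3, seed = 9)
  ps <- recognition_patterns(sim_runs(gt, 3, seed = 9))
  clfs <- train_all_pairs(ps)
  os <- gt$object_set
  e_tgt <- object_evidence(gt$prototypes[os$competitor, ], os$competitor,
                           os$controls, clfs)
  e_ctl <- object_evidence(gt$prototypes[os$controls[1], ], os$competitor,
                           os$controls, clfs)
  expect_gt(e_tgt, 0.9)
  expect_lt(e_ctl, 0.5)
})

test_that("leave-one-run-out accuracy matches a fold-wise oracle recomputation", {
  gt <- tiny_gt(seed = 10)
  ps <- recognition_patterns(sim_runs(gt, 4, seed = 10))
  axis <- c("bed", "chair")
  res <- loro_accuracy(ps, axis)
  expect_length(res$classifiers, 4)
  # oracle: refit each fold independently and score by hand
  keep <- ps$object %in% axis
  x <- ps$x[keep, ]; obj <- ps$object[keep]; run <- ps$run[keep]
  oracle <- sapply(1:4, function(r) {
    clf <- train_pair_classifier(x[run != r, ], obj[run != r])
    mean(pair_predict(clf, x[run == r, ]) == obj[run == r])
  })
  expect_equal(res$fold_accuracy$accuracy, oracle)
  expect_equal(res$accuracy, mean(oracle))
})

test_that("decoding is at chance on pure noise and perfect on separable data", {
  ps <- noise_pattern_set(n_runs = 4, per_object = 12, seed = 11)
  acc <- loro_accuracy(ps, c("bed", "chair"))$accuracy
  # 4 runs x 24 axis trials: 99.9% binomial band around 0.5
  expect_lt(abs(acc - 0.5), 3.3 * sqrt(0.25 / 96))
  gt <- tiny_gt(noise_sd = 0.05, drift_amp = 0, seed = 12)
  expect_equal(loro_accuracy(recognition_patterns(sim_runs(gt, 3, seed = 12)),
                             c("bed", "chair"))$accuracy, 1.0)
  expect_error(loro_accuracy(noise_pattern_set(n_runs = 1), c("bed", "chair")),
               "2 runs")
})

test_that("accuracy is invariant to a consistent voxel permutation", {
  gt <- tiny_gt(seed = 13)
  ps <- recognition_patterns(sim_runs(gt, 3, seed = 13))
  perm <- withr::with_seed(14, sample(ncol(ps$x)))
  ps_perm <- list(x = ps$x[, perm], object = ps$object, run = ps$run)
  expect_equal(loro_accuracy(ps, c("bench", "table"))$accuracy,
               loro_accuracy(ps_perm, c("bench", "table"))$accuracy)
})

test_that("cross-session accuracy degrades with the integration shift", {
  accs <- sapply(c(0, 1), function(lam) {
    vals <- sapply(1:5, function(s) {
      gt <- tiny_gt(lambda = lam, signal_sd = 0.6, seed = 100 + s)
      axis <- c(gt$object_set$presented, gt$object_set$competitor)
      ps1 <- recognition_patterns(sim_runs(gt, 3, session = 1, seed = s))
      ps5 <- recognition_patterns(sim_runs(gt, 3, session = 5, seed = 50 + s))
      l1 <- loro_accuracy(ps1, axis)
      c(a1 = l1$accuracy,
        a5 = cross_session_accuracy(l1$classifiers, ps5, axis))
    })
    rowMeans(vals)
  })
  # lambda = 0: session 5 is statistically identical to session 1
  expect_lt(abs(accs["a5", 1] - accs["a1", 1]), 0.1)
  # lambda = 1: prototypes collapsed, cross-session accuracy near chance
  expect_lt(abs(accs["a5", 2] - 0.5), 0.1)
  expect_gt(accs["a1", 2] - accs["a5", 2], 0.2)
})

test_that("paired cross-session mode matches one classifier to one run", {
  gt <- tiny_gt(seed = 15)
  ps1 <- recognition_patterns(sim_runs(gt, 3, seed = 15))
  ps5 <- recognition_patterns(sim_runs(gt, 3, session = 5, seed = 16))
  l1 <- loro_accuracy(ps1, c("bed", "chair"))
  a_paired <- cross_session_accuracy(l1$classifiers, ps5, c("bed", "chair"),
                                     mode = "paired")
  expect_true(a_paired >= 0 && a_paired <= 1)
  expect_error(cross_session_accuracy(l1$classifiers[1:2], ps5,
                                      c("bed", "chair"), mode = "paired"),
               "as many runs")
  ps5_small <- list(x = ps5$x[, 1:10], object = ps5$object, run = ps5$run)
  expect_error(cross_session_accuracy(l1$classifiers, ps5_small,
                                      c("bed", "chair")), "ROI size")
})
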