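default_config <- function() {
  list(
    participants = 20L,
    objects = c("bed", "chair", "table", "bench"),
    sessions = list(recognition_runs_pre = 8L,
                    feedback_sessions = 3L,
                    feedback_runs = 10L,
                    recognition_runs_mid = 2L,
                    recognition_runs_post = 8L),
    run = list(recognition_volumes = 145L, feedback_volumes = 176L,
               feedback_trials = 20L, tr_s = 2, lag_trs = 2L),
    space = list(n_parcels = 10L, voxels_per_parcel = 12L,
                 informative_parcels = 3L),
    signal = list(signal_sd = 0.3, noise_sd = 1, drift_amp = 0.5,
                  ar1_rho = 0),
    effects = list(lambda_trained = 0.6, lambda_sd = 0.15,
                   behavior_coupling = 0.7, mu = 50, slope1 = 0.2,
                   ability_start = 0.1, ability_end = 0.9),
    staircase = list(theta = 0.55, step_up = 0.03, step_down = 0.05,
                     bounds = c(0.5, 0.95)),
    decoder = list(penalty = 1),
    roi = list(method = "greedy", reference_subjects = 3L,
               reference_runs = 3L, parcels = NULL),
    measurement = list(parcels = NULL),
    stats = list(n_boot = 1000L),
    schema_version = 1L
  )
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) {
      abort(sprintf("Unknown config field `%s`.", here))
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]])) {
        abort(sprintf("Config field `%s` must be a list.", here))
      }
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], here)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Validate and normalise a study configuration
#'
#' Merges the user's (possibly partial) configuration into the full
#' default — which reproduces the five-session protocol composition
#' (8 recognition runs pre, three feedback sessions of 2 + 10 + 2 runs,
#' 8 recognition runs post) — and checks ranges, rejecting contradictory
#' settings with the offending field path.
#'
#' @param config Named list of overrides (possibly nested); `list()` or
#'   `NULL` yields the full defaults. May also be a path to a YAML or JSON
#'   file holding such a list.
#' @return The normalised config (class `study_config`).
#' @export
#' @examples
#' cfg <- validate_config(list(participants = 4))
#' cfg$sessions$feedback_runs
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_study_config(config)
  }
  cfg <- merge_config(default_config(), config %||% list())
  with(cfg, {
    assert_scalar_number(participants, "participants", min = 1)
    if (length(objects) != 4L || anyDuplicated(objects)) {
      abort("`objects` must be four distinct identifiers.")
    }
    for (f in names(sessions)) {
      assert_scalar_number(sessions[[f]], paste0("sessions.", f), min = 1)
    }
    assert_scalar_number(run$recognition_volumes, "run.recognition_volumes",
                         min = 10)
    assert_scalar_number(run$feedback_volumes, "run.feedback_volumes",
                         min = 10)
    assert_scalar_number(run$lag_trs, "run.lag_trs", 0,
                         run$recognition_volumes - 1)
    assert_scalar_number(space$informative_parcels,
                         "space.informative_parcels", 1, space$n_parcels)
    assert_scalar_number(signal$noise_sd, "signal.noise_sd", min = 0)
    assert_scalar_number(signal$drift_amp, "signal.drift_amp", min = 0)
    assert_scalar_number(effects$lambda_trained, "effects.lambda_trained",
                         0, 1)
    assert_scalar_number(effects$lambda_sd, "effects.lambda_sd", min = 0)
    assert_scalar_number(effects$slope1, "effects.slope1", min = 1e-6)
    assert_scalar_number(effects$ability_start, "effects.ability_start", 0, 1)
    assert_scalar_number(effects$ability_end, "effects.ability_end", 0, 1)
    assert_scalar_number(staircase$theta, "staircase.theta",
                         staircase$bounds[1], staircase$bounds[2])
    if (!roi$method %in% c("greedy", "topn", "fixed", "all")) {
      abort("`roi.method` must be one of greedy, topn, fixed, all.")
    }
    assert_scalar_number(stats$n_boot, "stats.n_boot", min = 10)
  })
  structure(cfg, class = c("study_config", "list"))
}

#' Read a study configuration file
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON (`.json`) file holding
#'   configuration overrides.
#' @return Named list suitable for [validate_config()].
#' @export
read_study_config <- function(path) {
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' The per-participant session plan
#'
#' Expands the configured run composition into the ordered five-session
#' protocol: Session 1 is all recognition runs (classifier training and
#' the pre snapshot), Sessions 2--4 sandwich the feedback runs between
#' recognition runs, and Session 5 mirrors Session 1 (the post snapshot).
#'
#' @param config A [validate_config()] result (or overrides).
#' @return Tibble (`session`, `phase`, `run_type`, `n_runs`).
#' @export
study_plan <- function(config = list()) {
  cfg <- if (inherits(config, "study_config")) config else
    validate_config(config)
  s <- cfg$sessions
  fb_sessions <- seq_len(s$feedback_sessions) + 1L
  dplyr::bind_rows(
    tibble::tibble(session = 1L, phase = "pre", run_type = "recognition",
                   n_runs = s$recognition_runs_pre),
    purrr::map_dfr(fb_sessions, function(ss) {
      tibble::tibble(
        session = ss,
        phase = c("feedback_pre", "feedback", "feedback_post"),
        run_type = c("recognition", "feedback", "recognition"),
        n_runs = c(s$recognition_runs_mid, s$feedback_runs,
                   s$recognition_runs_mid)
      )
    }),
    tibble::tibble(session = s$feedback_sessions + 2L, phase = "post",
                   run_type = "recognition",
                   n_runs = s$recognition_runs_post)
  )
}

# Build the reference-cohort ROI start (ranking + top-N) shared by all
# participants; returns list(start_parcels, ranking, curve or NULLs).
reference_roi_start <- function(cfg, parc, seed) {
  if (cfg$roi$method %in% c("fixed", "all")) {
    parcels <- if (cfg$roi$method == "all") names(parc$parcels) else
      cfg$roi$parcels %||% informative_ids(cfg)
    return(list(start = parcels, ranking = NULL, curve = NULL))
  }
  subjects <- purrr::map(seq_len(cfg$roi$reference_subjects), function(j) {
    os <- object_set(cfg$objects, batch = 1L + (j %% 2L))
    gt <- ground_truth(
      os, parc, informative_parcels = informative_ids(cfg),
      signal_sd = cfg$signal$signal_sd, noise_sd = cfg$signal$noise_sd,
      drift_amp = cfg$signal$drift_amp, lag_trs = cfg$run$lag_trs,
      ar1_rho = cfg$signal$ar1_rho,
      seed = derive_seed(seed, paste0("ref-gt-", j))
    )
    runs <- purrr::map(seq_len(cfg$roi$reference_runs), function(r) {
      sched <- make_recognition_schedule(
        derive_seed(seed, sprintf("ref-sched-%d-%d", j, r)),
        objects = cfg$objects, n_volumes = cfg$run$recognition_volumes,
        lag_trs = cfg$run$lag_trs
      )
      simulate_recognition_run(gt, sched, session = 1,
                               seed = derive_seed(seed,
                                                  sprintf("ref-run-%d-%d",
                                                          j, r)))
    })
    recognition_patterns(runs, lag_trs = cfg$run$lag_trs)
  })
  ranking <- rank_parcels(subjects, parc, penalty = cfg$decoder$penalty)
  curve <- build_topn_curve(ranking, subjects, parc,
                            penalty = cfg$decoder$penalty)
  list(start = curve$best$parcels, ranking = ranking, curve = curve)
}

informative_ids <- function(cfg) {
  sprintf("p%02d", seq_len(cfg$space$informative_parcels))
}

#' Replicate the five-session study on a synthetic cohort
#'
#' Runs the whole protocol end to end for every simulated participant:
#' Session-1 recognition runs; feedback-ROI construction (reference-cohort
#' parcel ranking, top-N mega-ROI, per-participant greedy backward
#' elimination, per the configured `roi$method`); training of the six
#' pairwise classifiers; closed-loop feedback Sessions 2--4 with the
#' adaptive staircase; Session-5 recognition runs with the ground-truth
#' integration shift applied; psychometric fits and behavioral indices for
#' both axes; neural integration indices; and group-level bootstrap
#' statistics, session trends and the brain--behavior correlation.
#'
#' Everything is reproducible from `(config, seed)`: per-stage seeds are
#' derived stably from the master seed.
#'
#' @param config Configuration overrides (see [validate_config()]).
#' @param seed Master integer seed.
#' @return A `study_result` bundle: `participants` (per-participant ROI
#'   sizes, true effect parameters), `behavior` (fits and indices),
#'   `neural` (accuracies and indices), `feedback` (per-session threshold
#'   and competition summaries), `group` (named `bootstrap_result`s,
#'   trend tests, correlation), `config`, `seed`.
#' @export
run_study <- function(config = list(), seed = 1L) {
  cfg <- if (inherits(config, "study_config")) config else
    validate_config(config)
  parc <- make_parcellation(cfg$space$n_parcels, cfg$space$voxels_per_parcel)
  roi_ref <- reference_roi_start(cfg, parc, derive_seed(seed, "reference"))
  n_fb_runs <- cfg$sessions$feedback_sessions * cfg$sessions$feedback_runs
  fb_sessions <- seq_len(cfg$sessions$feedback_sessions) + 1L
  post_session <- cfg$sessions$feedback_sessions + 2L

  participants <- list()
  behavior <- list()
  neural <- list()
  feedback <- list()

  for (i in seq_len(cfg$participants)) {
    sd_ <- function(stage) derive_seed(seed, sprintf("sub%02d-%s", i, stage))
    lambda_i <- if (cfg$effects$lambda_sd > 0) {
      with_seed(sd_("lambda"),
                clamp(rnorm(1, cfg$effects$lambda_trained,
                            cfg$effects$lambda_sd), 0, 1))
    } else cfg$effects$lambda_trained
    slope5_tr <- cfg$effects$slope1 *
      (1 - cfg$effects$behavior_coupling * lambda_i)
    responder <- make_responder(
      mu = cfg$effects$mu, slope1 = cfg$effects$slope1,
      slope5_trained = max(slope5_tr, 1e-3),
      slope5_untrained = cfg$effects$slope1
    )
    ability <- if (n_fb_runs > 1) {
      cfg$effects$ability_start +
        (cfg$effects$ability_end - cfg$effects$ability_start) *
        (seq_len(n_fb_runs) - 1) / (n_fb_runs - 1)
    } else rep(cfg$effects$ability_end, n_fb_runs)
    os <- object_set(cfg$objects, batch = 1L + (i %% 2L))
    gt <- ground_truth(
      os, parc, informative_parcels = informative_ids(cfg),
      signal_sd = cfg$signal$signal_sd, noise_sd = cfg$signal$noise_sd,
      drift_amp = cfg$signal$drift_amp, lag_trs = cfg$run$lag_trs,
      lambda = lambda_i, responder = responder, ability_curve = ability,
      ar1_rho = cfg$signal$ar1_rho, seed = sd_("gt")
    )

    sim_recog <- function(session, n_runs, stage) {
      purrr::map(seq_len(n_runs), function(r) {
        sched <- make_recognition_schedule(
          sd_(sprintf("%s-sched-%d", stage, r)), objects = cfg$objects,
          n_volumes = cfg$run$recognition_volumes, lag_trs = cfg$run$lag_trs
        )
        simulate_recognition_run(gt, sched, session = session,
                                 seed = sd_(sprintf("%s-run-%d", stage, r)))
      })
    }

    runs1 <- sim_recog(1, cfg$sessions$recognition_runs_pre, "ses1")
    ps1 <- recognition_patterns(runs1, lag_trs = cfg$run$lag_trs)

    roi <- switch(cfg$roi$method,
      greedy = greedy_refine(roi_ref$start, ps1, parc,
                             penalty = cfg$decoder$penalty),
      topn = ,
      fixed = ,
      all = new_mega_roi(roi_ref$start, parc)
    )
    vox <- roi$voxels

    ps1_roi <- list(x = ps1$x[, vox, drop = FALSE], object = ps1$object,
                    run = ps1$run)
    classifiers <- train_all_pairs(ps1_roi, penalty = cfg$decoder$penalty)

    loop <- run_closed_loop(
      gt, classifiers, vox,
      staircase = new_staircase(cfg$staircase$theta, cfg$staircase$step_up,
                                cfg$staircase$step_down,
                                cfg$staircase$bounds),
      sessions = fb_sessions,
      runs_per_session = cfg$sessions$feedback_runs,
      n_trials = cfg$run$feedback_trials,
      n_volumes = cfg$run$feedback_volumes,
      seed = sd_("loop")
    )
    feedback[[i]] <- loop$threshold |>
      dplyr::group_by(.data$session) |>
      dplyr::summarise(mean_theta = mean(.data$theta),
                       mean_above = mean(.data$mean_above),
                       .groups = "drop") |>
      dplyr::left_join(loop$session_summary[c("session", "competition")],
                       by = "session") |>
      dplyr::mutate(participant = i, .before = 1)

    runs5 <- sim_recog(5, cfg$sessions$recognition_runs_post, "ses5")
    # Neural change is measured in an a-priori ROI (the measurement
    # parcels), never in the data-driven feedback ROI: selecting the ROI
    # on the Session-1 runs and then scoring Session-1 accuracy on those
    # same runs would bias the integration index.
    meas_vox <- parcel_voxels(parc,
                              cfg$measurement$parcels %||%
                                informative_ids(cfg))
    ps1_meas <- list(x = ps1$x[, meas_vox, drop = FALSE],
                     object = ps1$object, run = ps1$run)
    ps5 <- recognition_patterns(runs5, lag_trs = cfg$run$lag_trs,
                                roi = meas_vox)

    axes <- object_axes(os)
    neural[[i]] <- purrr::imap_dfr(axes, function(pair, axis) {
      l1 <- loro_accuracy(ps1_meas, pair, penalty = cfg$decoder$penalty)
      a5 <- cross_session_accuracy(l1$classifiers, ps5, pair)
      tibble::tibble(participant = i, axis = axis, a1 = l1$accuracy,
                     a5 = a5, index = neural_integration_index(l1$accuracy,
                                                               a5))
    })

    behavior[[i]] <- purrr::imap_dfr(axes, function(pair, axis) {
      resp1 <- simulate_behavior(gt$responder[[axis]][["1"]],
                                 make_morph_schedule(sd_(paste0("morph1-",
                                                                axis))),
                                 seed = sd_(paste0("beh1-", axis)))
      resp5 <- simulate_behavior(gt$responder[[axis]][["5"]],
                                 make_morph_schedule(sd_(paste0("morph5-",
                                                                axis))),
                                 seed = sd_(paste0("beh5-", axis)))
      fit1 <- fit_psychometric(resp1, session = 1, axis = axis)
      fit5 <- fit_psychometric(resp5, fixed_mu = fit1$mu, session = 5,
                               axis = axis)
      tibble::tibble(participant = i, axis = axis, mu = fit1$mu,
                     slope1 = fit1$slope, slope5 = fit5$slope,
                     index = behavioral_integration_index(fit1, fit5))
    })

    participants[[i]] <- tibble::tibble(
      participant = i, batch = os$batch, lambda = lambda_i,
      slope5_trained_true = max(slope5_tr, 1e-3),
      roi_parcels = length(roi$parcels), roi_voxels = length(vox)
    )
  }

  behavior <- dplyr::bind_rows(behavior)
  neural <- dplyr::bind_rows(neural)
  feedback <- dplyr::bind_rows(feedback)
  participants <- dplyr::bind_rows(participants)

  nb <- cfg$stats$n_boot
  boot <- function(v, stage) {
    bootstrap_mean_test(v, n_iter = nb, seed = derive_seed(seed, stage))
  }
  idx <- function(tbl, ax) tbl$index[tbl$axis == ax][order(
    tbl$participant[tbl$axis == ax])]
  group <- list(
    behavioral_trained = boot(idx(behavior, "trained"), "g-beh-tr"),
    behavioral_untrained = boot(idx(behavior, "untrained"), "g-beh-un"),
    behavioral_diff = boot(idx(behavior, "trained") -
                             idx(behavior, "untrained"), "g-beh-diff"),
    neural_trained = boot(idx(neural, "trained"), "g-neu-tr"),
    neural_untrained = boot(idx(neural, "untrained"), "g-neu-un"),
    neural_diff = boot(idx(neural, "trained") - idx(neural, "untrained"),
                       "g-neu-diff"),
    threshold_trend = session_trend(
      dplyr::transmute(feedback, participant = .data$participant,
                       session = .data$session, value = .data$mean_theta),
      n_iter = nb, seed = derive_seed(seed, "g-theta-trend")
    ),
    competition_trend = session_trend(
      dplyr::transmute(feedback, participant = .data$participant,
                       session = .data$session, value = .data$competition),
      n_iter = nb, seed = derive_seed(seed, "g-comp-trend")
    ),
    brain_behavior = if (cfg$participants >= 3) {
      brain_behavior_corr(idx(neural, "trained"), idx(behavior, "trained"))
    } else {
      tibble::tibble(r = NA_real_, p = NA_real_, n = cfg$participants,
                     method = "parametric")
    }
  )

  structure(list(
    participants = participants, behavior = behavior, neural = neural,
    feedback = feedback, group = group,
    roi_reference = roi_ref[c("ranking", "curve")],
    plan = study_plan(cfg), config = cfg, seed = as.integer(seed)
  ), class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>", x$config$participants, "participants, seed",
      x$seed, "\n")
  g <- x$group
  cat(sprintf("  behavioral integration (trained):   %+.4f  p = %.3f\n",
              g$behavioral_trained$estimate, g$behavioral_trained$p))
  cat(sprintf("  behavioral integration (untrained): %+.4f  p = %.3f\n",
              g$behavioral_untrained$estimate, g$behavioral_untrained$p))
  cat(sprintf("  neural integration (trained):       %+.4f  p = %.3f\n",
              g$neural_trained$estimate, g$neural_trained$p))
  cat(sprintf("  neural integration (untrained):     %+.4f  p = %.3f\n",
              g$neural_untrained$estimate, g$neural_untrained$p))
  cat(sprintf("  threshold trend:                    %+.4f  p = %.3f\n",
              g$threshold_trend$bootstrap$estimate,
              g$threshold_trend$bootstrap$p))
  cat(sprintf("  competition trend:                  %+.4f  p = %.3f\n",
              g$competition_trend$bootstrap$estimate,
              g$competition_trend$bootstrap$p))
  cat(sprintf("  brain-behavior r (trained):         %+.3f  p = %.3f\n",
              g$brain_behavior$r, g$brain_behavior$p))
  invisible(x)
}
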