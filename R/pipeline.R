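#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end demonstration pipeline in one
#' validated document. Unknown keys are rejected. The session-level task
#' defaults mirror the study task (4 targets per arm, 10 trials per target,
#' 750 ms fixation, 900 ms hold, 5% catch trials); the cohort and model
#' sizes default to a desk-scale demonstration: 5 participants per
#' hemisphere, 8 electrodes each, one block per arm, a +/-0.2 s lag window at
#' 100 Hz, and a noise ceiling of R^2 = 0.5 on contralateral samples. The
#' hemispheric contrast is injected through the generator: left-hemisphere
#' electrodes get a high ipsilateral gain and high across-arm filter overlap,
#' right-hemisphere electrodes low gain and low overlap.
#'
#' @param ... Overrides of the defaults listed above (partial matching is not
#'   performed; unknown keys are an error).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    participants_per_hemisphere = 5L,
    electrodes_per_participant = 8L,
    blocks_per_arm = 1L,
    trials_per_target = 10L,
    catch_fraction = 0.05,
    rate_hz = 100,
    beta_shape = c(3, 3),
    touch_sd_cm = 0.5,
    lag_window = c(-0.2, 0.2),
    lambda_grid = 10^(0:7),
    n_outer = 5L, n_inner = 5L,
    target_r2 = 0.5,
    gains = list(left = c(contra = 1, ipsi = 0.8),
                 right = c(contra = 1, ipsi = 0.3)),
    overlap = list(left = 0.9, right = 0.2),
    r2_criterion = 0.05,
    good_threshold = 0.80,
    poor_threshold = 0.50,
    band_lo = 70, band_hi = 200, n_bands = 5,
    n_perm = 999L,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown pipeline_config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, dots)
  stopifnot(cfg$participants_per_hemisphere >= 1,
            cfg$electrodes_per_participant >= 1,
            cfg$target_r2 > 0, cfg$target_r2 <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Simulate and analyse one participant
#'
#' Runs the full single-participant path: simulate the session events,
#' reconstruct kinematic features, draw ground-truth filters for the
#' participant's hemisphere, generate the session HFA at the configured noise
#' ceiling, fit within-arm encoding models for both arms, fit the across-arm
#' model (trained on ipsilateral reaches, tested on contralateral reaches),
#' and assemble per-electrode scores.
#'
#' @param config A [pipeline_config()].
#' @param hemisphere `"left"` or `"right"`.
#' @param participant Participant label.
#' @param seed Integer seed.
#' @return List with `scores` (a tibble, one row per electrode), the fits,
#'   the bank and the events.
#' @export
analyze_participant <- function(config, hemisphere, participant, seed) {
  tc <- task_config(blocks_per_arm = config$blocks_per_arm,
                    trials_per_target = config$trials_per_target,
                    catch_fraction = config$catch_fraction,
                    rate_hz = config$rate_hz,
                    beta_shape = config$beta_shape,
                    touch_sd_cm = config$touch_sd_cm)
  ev <- simulate_task_events(tc, seed = seed)
  feats <- compute_features(ev, tc)
  n_lags <- length(lag_grid(config$lag_window, config$rate_hz))
  bank <- simulate_ground_truth_filters(
    config$electrodes_per_participant,
    overlap = config$overlap[[hemisphere]],
    gains = config$gains[[hemisphere]],
    n_lags = n_lags, lag_window = config$lag_window,
    rate_hz = config$rate_hz, hemisphere = hemisphere,
    features = feats, seed = seed + 1L
  )
  hfa <- simulate_session_hfa(feats, bank, target_r2 = config$target_r2,
                              seed = seed + 2L)
  design <- build_lagged_design(feats, config$lag_window)
  Y <- t(hfa$hfa)
  fit_c <- nested_cv_fit(design, Y, arm = "contra", n_outer = config$n_outer,
                         n_inner = config$n_inner,
                         lambda_grid = config$lambda_grid, seed = seed + 3L)
  fit_i <- nested_cv_fit(design, Y, arm = "ipsi", n_outer = config$n_outer,
                         n_inner = config$n_inner,
                         lambda_grid = config$lambda_grid, seed = seed + 4L)
  fit_x <- across_arm_fit(design, Y, train_arm = "ipsi", test_arm = "contra",
                          n_outer = config$n_outer, n_inner = config$n_inner,
                          lambda_grid = config$lambda_grid, seed = seed + 5L)

  n_e <- ncol(Y)
  phase_c <- lapply(seq_len(n_e), function(e) {
    folds <- lapply(fit_c$outer_folds, function(tr) which(fit_c$trial %in% tr))
    suppressWarnings(epoch_scores(Y[, e], fit_c$yhat[, e], design$epoch, folds))
  })
  phase_i <- lapply(seq_len(n_e), function(e) {
    folds <- lapply(fit_i$outer_folds, function(tr) which(fit_i$trial %in% tr))
    suppressWarnings(epoch_scores(Y[, e], fit_i$yhat[, e], design$epoch, folds))
  })

  gen <- suppressWarnings(classify_generalization(fit_c$r2, fit_x$r2))
  scores <- tibble::tibble(
    participant = participant,
    hemisphere = hemisphere,
    electrode = seq_len(n_e),
    r2_contra = fit_c$r2,
    r2_ipsi = fit_i$r2,
    r2_across = fit_x$r2,
    r2_instruction_contra = vapply(phase_c, `[[`, numeric(1), "instruction"),
    r2_movement_contra = vapply(phase_c, `[[`, numeric(1), "movement"),
    r2_instruction_ipsi = vapply(phase_i, `[[`, numeric(1), "instruction"),
    r2_movement_ipsi = vapply(phase_i, `[[`, numeric(1), "movement"),
    difference = difference_score(fit_c$r2, fit_i$r2),
    gen_index = gen$index,
    gen_class = gen$class,
    predictive = fit_c$r2 > config$r2_criterion | fit_i$r2 > config$r2_criterion,
    ceiling_contra = attr(hfa, "ceiling_r2")[, "contra"],
    ceiling_ipsi = attr(hfa, "ceiling_r2")[, "ipsi"]
  )
  list(scores = scores, fit_contra = fit_c, fit_ipsi = fit_i,
       fit_across = fit_x, bank = bank, events = ev)
}

#' Run the end-to-end demonstration pipeline
#'
#' Simulates a cohort (both hemispheres), runs the per-participant encoding
#' analysis, pools electrode scores, and performs the study's headline
#' permutation tests on the predictive electrodes: a paired
#' (participant-blocked) test of the arm main effect on within-arm R^2,
#' sign-flip tests of the contralateral bias per hemisphere, and the
#' between-participant arm-by-hemisphere interaction test on the
#' per-participant difference scores.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed; overrides `config$seed` when given.
#' @param keep_fits Keep the per-participant fit objects (larger output).
#' @return A list of class `pipeline_result` with `metrics` (tibble, one row
#'   per electrode), `stats`, and a reproducibility `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = NULL,
                         keep_fits = FALSE) {
  seed <- as.integer(seed %||% config$seed)
  hemis <- rep(c("left", "right"), each = config$participants_per_hemisphere)
  labels <- paste0(ifelse(hemis == "left", "L", "R"),
                   sequence(rep(config$participants_per_hemisphere, 2)))
  runs <- vector("list", length(hemis))
  for (i in seq_along(hemis)) {
    runs[[i]] <- analyze_participant(config, hemis[i], labels[i],
                                     seed = seed + 1000L * i)
  }
  metrics <- do.call(rbind, lapply(runs, `[[`, "scores"))

  pred <- metrics[metrics$predictive, ]
  long <- tibble::tibble(
    value = c(pred$r2_contra, pred$r2_ipsi),
    arm = rep(c("contra", "ipsi"), each = nrow(pred)),
    participant = rep(pred$participant, 2),
    hemisphere = rep(pred$hemisphere, 2)
  )
  stats_out <- list(
    arm_main = block_permutation_test(long$value, long$arm, long$participant,
                                      design = "paired", n_perm = config$n_perm,
                                      seed = seed + 11L),
    bias_left = sign_flip_test(pred$difference[pred$hemisphere == "left"],
                               n_perm = config$n_perm, seed = seed + 12L),
    bias_right = sign_flip_test(pred$difference[pred$hemisphere == "right"],
                                n_perm = config$n_perm, seed = seed + 13L),
    arm_by_hemisphere = block_permutation_test(
      long$value, long$arm, long$participant, group = long$hemisphere,
      design = "interaction", n_perm = config$n_perm, seed = seed + 14L),
    good_generalization = table(hemisphere = pred$hemisphere,
                                class = pred$gen_class)
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("reachenc")),
    config_hash = rlang::hash(unclass(config)),
    seed = seed,
    n_participants = length(hemis),
    n_electrodes = nrow(metrics),
    n_predictive = sum(metrics$predictive)
  )
  out <- list(metrics = metrics, stats = stats_out, manifest = manifest)
  if (keep_fits) out$runs <- runs
  structure(out, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d electrodes (%d predictive) from %d participants\n",
              x$manifest$n_electrodes, x$manifest$n_predictive,
              x$manifest$n_participants))
  cat(sprintf("  arm main effect p = %.4g; arm x hemisphere interaction p = %.4g\n",
              x$stats$arm_main$p, x$stats$arm_by_hemisphere$p))
  invisible(x)
}
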