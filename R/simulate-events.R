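#' Simulate the event table of one instructed-delay reaching session
#'
#' Produces one row per trial with the task event times recorded by the rig:
#' cue (target) onset, imperative, movement onset (home-switch release), touch
#' time and touch location on the screen, and the return press. Blocks
#' alternate between the contralateral and ipsilateral arm, starting with the
#' contralateral arm; each block presents every target `trials_per_target`
#' times in shuffled order. On catch trials the imperative is withheld and no
#' movement events occur. A reach is unsuccessful when the touch lands outside
#' the target radius plus the hit buffer.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; identical seeds give identical event tables.
#' @return A tibble of class `session_events` with one row per trial.
#' @export
simulate_task_events <- function(config = task_config(), seed = NULL) {
  cfg <- validate_task_config(config)
  n_block <- trials_per_block(cfg)
  arms <- rep(c("contra", "ipsi"), times = cfg$blocks_per_arm)

  with_seed(seed, {
    rows <- vector("list", length(arms))
    t_clock <- 0
    trial_no <- 0L
    for (b in seq_along(arms)) {
      arm <- arms[b]
      tg <- cfg$targets[cfg$targets$arm == arm, ]
      order_ids <- sample(rep(tg$target, each = cfg$trials_per_target))
      n_catch <- round(cfg$catch_fraction * n_block)
      catch_idx <- if (n_catch > 0) sample(n_block, n_catch) else integer(0)
      home <- cfg$home[[arm]]

      block <- vector("list", n_block)
      for (i in seq_len(n_block)) {
        trial_no <- trial_no + 1L
        tid <- order_ids[i]
        trow <- tg[tg$target == tid, ]
        cue <- t_clock + cfg$ready_s + cfg$fixation_s
        imper <- cue + cfg$hold_s
        is_catch <- i %in% catch_idx
        if (is_catch) {
          ## imperative withheld; trial times out and advances
          t_clock <- imper + 1.5 + cfg$feedback_s + cfg$blank_s
          block[[i]] <- tibble::tibble(
            trial = trial_no, block = b, arm = arm,
            target = tid, target_x = trow$x, target_y = trow$y,
            target_z = trow$z, central = trow$central,
            cue_onset_s = cue, imperative_s = NA_real_,
            movement_onset_s = NA_real_, touch_s = NA_real_,
            touch_x = NA_real_, touch_y = NA_real_,
            return_press_s = NA_real_,
            success = FALSE, catch = TRUE
          )
          next
        }
        rt <- rlnorm_ms(1, cfg$rt_mean_s, cfg$rt_sd_s)
        dur_out <- rlnorm_ms(1, cfg$outbound_mean_s, cfg$outbound_sd_s)
        dur_in <- rlnorm_ms(1, cfg$inbound_mean_s, cfg$inbound_sd_s)
        mo <- imper + rt
        touch <- mo + dur_out
        rp <- touch + dur_in
        touch_xy <- c(trow$x, trow$y) + stats::rnorm(2, 0, cfg$touch_sd_cm)
        dist <- sqrt(sum((touch_xy - c(trow$x, trow$y))^2))
        ok <- dist <= cfg$target_diameter_cm / 2 + cfg$hit_buffer_cm
        t_clock <- rp + cfg$feedback_s + cfg$blank_s
        block[[i]] <- tibble::tibble(
          trial = trial_no, block = b, arm = arm,
          target = tid, target_x = trow$x, target_y = trow$y,
          target_z = trow$z, central = trow$central,
          cue_onset_s = cue, imperative_s = imper,
          movement_onset_s = mo, touch_s = touch,
          touch_x = touch_xy[1], touch_y = touch_xy[2],
          return_press_s = rp,
          success = ok, catch = FALSE
        )
      }
      rows[[b]] <- do.call(rbind, block)
    }
    ev <- do.call(rbind, rows)
    attr(ev, "task_config") <- cfg
    class(ev) <- c("session_events", class(ev))
    ev
  })
}

## Trials usable for model fitting: successful, non-catch.
usable_trials <- function(events) {
  events$trial[events$success & !events$catch]
}
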