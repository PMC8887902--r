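#' Task configuration for the instructed-delay reaching session
#'
#' Bundles the geometry and timing of the out-and-back reaching task: four
#' touchscreen targets per arm in a vertical screen plane 13 cm beyond the home
#' buttons, 40-trial blocks (10 reaches per target) alternating between arms,
#' a 750 ms fixation and 900 ms instructed-delay hold, and a 5% rate of catch
#' trials on which the imperative is withheld.
#'
#' Reaction times and movement durations are drawn from lognormal
#' distributions parameterized by their natural-scale mean and sd (seconds).
#' Touch locations scatter isotropically around the target centre
#' (`touch_sd_cm`); a reach is successful when the touch lands within the
#' target radius plus `hit_buffer_cm`.
#'
#' @param n_targets_per_arm Targets per arm (default 4).
#' @param trials_per_target Reaches per target per block (default 10).
#' @param blocks_per_arm Blocks per arm (default 2); blocks alternate arms.
#' @param target_diameter_cm Diameter of the imperative-size target (2.5 cm).
#' @param hit_buffer_cm Buffer around the target still counted as a hit (1 cm).
#' @param screen_distance_cm Distance from home buttons to the screen plane.
#' @param fixation_s,hold_s Fixation (0.75 s) and instructed-delay (0.9 s)
#'   durations.
#' @param ready_s,feedback_s,blank_s Inter-trial housekeeping intervals.
#' @param catch_fraction Fraction of trials with the imperative withheld.
#' @param rt_mean_s,rt_sd_s Reaction-time distribution (s).
#' @param outbound_mean_s,outbound_sd_s Outbound reach duration (s).
#' @param inbound_mean_s,inbound_sd_s Inbound reach duration (s).
#' @param touch_sd_cm Isotropic touch scatter around the target centre (cm).
#' @param beta_shape Length-2 shape of the beta velocity profile.
#' @param rate_hz Analysis sampling rate (Hz).
#' @param targets Optional custom target table (tibble with columns `arm`,
#'   `target`, `x`, `y`, `z`, `central`); defaults to the built-in layout with
#'   two central targets shared by the arms and two eccentric targets per arm.
#' @param home Optional named list with `contra` and `ipsi` home-button
#'   3-coordinates (cm).
#'
#' @return An object of class `task_config` (a validated list).
#' @export
task_config <- function(n_targets_per_arm = 4,
                        trials_per_target = 10,
                        blocks_per_arm = 2,
                        target_diameter_cm = 2.5,
                        hit_buffer_cm = 1.0,
                        screen_distance_cm = 13,
                        fixation_s = 0.75,
                        hold_s = 0.9,
                        ready_s = 0.5,
                        feedback_s = 0.75,
                        blank_s = 0.25,
                        catch_fraction = 0.05,
                        rt_mean_s = 0.5, rt_sd_s = 0.15,
                        outbound_mean_s = 0.75, outbound_sd_s = 0.15,
                        inbound_mean_s = 1.0, inbound_sd_s = 0.25,
                        touch_sd_cm = 0.5,
                        beta_shape = c(3, 3),
                        rate_hz = 100,
                        targets = NULL,
                        home = NULL) {
  cfg <- list(
    n_targets_per_arm = as.integer(n_targets_per_arm),
    trials_per_target = as.integer(trials_per_target),
    blocks_per_arm = as.integer(blocks_per_arm),
    target_diameter_cm = target_diameter_cm,
    hit_buffer_cm = hit_buffer_cm,
    screen_distance_cm = screen_distance_cm,
    fixation_s = fixation_s, hold_s = hold_s,
    ready_s = ready_s, feedback_s = feedback_s, blank_s = blank_s,
    catch_fraction = catch_fraction,
    rt_mean_s = rt_mean_s, rt_sd_s = rt_sd_s,
    outbound_mean_s = outbound_mean_s, outbound_sd_s = outbound_sd_s,
    inbound_mean_s = inbound_mean_s, inbound_sd_s = inbound_sd_s,
    touch_sd_cm = touch_sd_cm,
    beta_shape = beta_shape,
    rate_hz = rate_hz,
    home = home %||% list(contra = c(7, 0, 0), ipsi = c(-7, 0, 0))
  )
  cfg$targets <- targets %||% default_targets(cfg)
  class(cfg) <- "task_config"
  validate_task_config(cfg)
}

## Default target layout (cm, screen frame: X lateral, Y vertical, Z toward
## the screen). Two central targets are shared by the arms; the two eccentric
## targets per arm sit on that arm's side of the screen.
default_targets <- function(cfg) {
  if (cfg$n_targets_per_arm != 4) {
    stop("the built-in target layout requires 4 targets per arm; ",
         "supply `targets` for other layouts", call. = FALSE)
  }
  z <- cfg$screen_distance_cm
  tibble::tibble(
    arm = rep(c("contra", "ipsi"), each = 4),
    target = rep(1:4, 2),
    x = c(-2.5, 2.5, 8, 13, -2.5, 2.5, -8, -13),
    y = 8,
    z = z,
    central = rep(c(TRUE, TRUE, FALSE, FALSE), 2)
  )
}

validate_task_config <- function(cfg) {
  stopifnot(
    cfg$n_targets_per_arm >= 1, cfg$trials_per_target >= 1,
    cfg$blocks_per_arm >= 1,
    cfg$target_diameter_cm > 0, cfg$hit_buffer_cm >= 0,
    cfg$rate_hz > 0, length(cfg$beta_shape) == 2, all(cfg$beta_shape > 0)
  )
  if (cfg$catch_fraction < 0 || cfg$catch_fraction >= 1) {
    stop("catch_fraction must lie in [0, 1)", call. = FALSE)
  }
  tg <- cfg$targets
  req <- c("arm", "target", "x", "y", "z", "central")
  if (!all(req %in% names(tg))) {
    stop("target table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(tg$z != cfg$screen_distance_cm)) {
    stop("configuration error: all targets must lie in the screen plane ",
         "(z = ", cfg$screen_distance_cm, " cm)", call. = FALSE)
  }
  for (a in c("contra", "ipsi")) {
    n <- sum(tg$arm == a)
    if (n != cfg$n_targets_per_arm) {
      stop(sprintf("configuration error: %d targets for arm '%s', expected %d",
                   n, a, cfg$n_targets_per_arm), call. = FALSE)
    }
  }
  cfg
}

trials_per_block <- function(cfg) cfg$n_targets_per_arm * cfg$trials_per_target

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat(sprintf("  %d targets/arm, %d trials/target, %d blocks/arm (%d trials/block)\n",
              x$n_targets_per_arm, x$trials_per_target, x$blocks_per_arm,
              trials_per_block(x)))
  cat(sprintf("  screen at %.1f cm; target diameter %.2f cm (+%.1f cm buffer)\n",
              x$screen_distance_cm, x$target_diameter_cm, x$hit_buffer_cm))
  cat(sprintf("  catch fraction %.2f; analysis rate %g Hz\n",
              x$catch_fraction, x$rate_hz))
  invisible(x)
}
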