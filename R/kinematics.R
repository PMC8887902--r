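#' Reconstruct the continuous out-and-back trajectory of one trial
#'
#' The hand path is taken as the straight line home -> touch point -> home.
#' The speed profile of each segment is a beta density over the segment
#' duration, scaled so that the path integral equals the straight-line travel
#' distance: for normalized time `u` in a segment of duration `T` and length
#' `D`, speed(u) = D * dbeta(u; a, b) / T and the travelled fraction is
#' pbeta(u; a, b). With the default symmetric shape (3, 3) this gives a
#' smooth, bell-shaped profile that is zero at the segment endpoints and peaks
#' at the midpoint.
#'
#' @param trial One row of a `session_events` table (successful, non-catch).
#' @param config The session's [task_config()] (geometry + beta shape).
#' @param shape Length-2 beta shape parameters; defaults to the config's.
#' @return A list of class `trajectory` with elements `time` (s, on the global
#'   `rate_hz` grid), `position` (n x 3, cm), `velocity` (n x 3, cm/s) and
#'   `speed` (cm/s).
#' @export
reconstruct_trajectory <- function(trial, config, shape = config$beta_shape) {
  if (isTRUE(trial$catch) || !isTRUE(trial$success)) {
    stop("trajectory reconstruction requires a successful non-catch trial",
         call. = FALSE)
  }
  mo <- trial$movement_onset_s; tt <- trial$touch_s; rp <- trial$return_press_s
  if (!(is.finite(mo) && is.finite(tt) && is.finite(rp)) || !(mo < tt && tt < rp)) {
    stop("trial rejected: event times must satisfy movement_onset < touch < return_press",
         call. = FALSE)
  }
  rate <- config$rate_hz
  home <- config$home[[trial$arm]]
  touch3 <- c(trial$touch_x, trial$touch_y, config$screen_distance_cm)
  dvec <- touch3 - home
  D <- sqrt(sum(dvec^2))
  udir <- dvec / D
  a <- shape[1]; b <- shape[2]

  idx <- seq(ceiling(mo * rate), floor(rp * rate))
  t <- idx / rate
  out <- t <= tt
  pos <- matrix(0, length(t), 3)
  spd <- numeric(length(t))

  u1 <- (t[out] - mo) / (tt - mo)
  frac1 <- stats::pbeta(u1, a, b)
  pos[out, ] <- rep(home, each = sum(out)) + outer(frac1, udir) * D
  spd[out] <- D * stats::dbeta(u1, a, b) / (tt - mo)

  u2 <- (t[!out] - tt) / (rp - tt)
  frac2 <- 1 - stats::pbeta(u2, a, b)
  pos[!out, ] <- rep(home, each = sum(!out)) + outer(frac2, udir) * D
  spd[!out] <- D * stats::dbeta(u2, a, b) / (rp - tt)

  vel <- outer(spd, udir)
  vel[!out, ] <- -vel[!out, , drop = FALSE]

  structure(list(time = t, position = pos, velocity = vel, speed = spd,
                 travel_distance = D, direction = udir,
                 segments = c(movement_onset = mo, touch = tt, return_press = rp)),
            class = "trajectory")
}

## Exact path integral of the implemented speed profile over one segment,
## evaluated by pbeta differences (not numerical quadrature).
segment_path_length <- function(traj, segment = c("outbound", "inbound"),
                                shape = c(3, 3)) {
  segment <- match.arg(segment)
  s <- traj$segments
  tt <- if (segment == "outbound") c(s["movement_onset"], s["touch"])
        else c(s["touch"], s["return_press"])
  ## the continuous profile integrates to D * (pbeta(1) - pbeta(0)) = D
  traj$travel_distance * (stats::pbeta(1, shape[1], shape[2]) -
                          stats::pbeta(0, shape[1], shape[2]))
}

#' Kinematic feature time series for a whole session
#'
#' Derives the four model features on the analysis-rate grid for the full
#' session of one arm (or both): position along Z (toward the screen), speed
#' along Z (the nonnegative magnitude of the Z velocity component of the
#' reconstructed trajectory), and the two spherical angles theta (elevation)
#' and phi (azimuth) of the target direction from the reaching arm's home
#' button. The angles are per-trial constants applied as a step function that
#' is nonzero between movement onset and the return press; between trials all
#' features are held at rest (hand at home, speed zero, angles zero). Catch
#' and unsuccessful trials contribute rest values only.
#'
#' @param events A `session_events` table (optionally already subset by arm).
#' @param config The session's [task_config()].
#' @param arm Optional arm label to subset to (`"contra"` or `"ipsi"`).
#' @return A list of class `kinematic_features`: matrix `features`
#'   (samples x 4, columns `z_position`, `z_speed`, `theta`, `phi`), `rate_hz`,
#'   `time`, per-sample `trial` index, `epoch` factor
#'   (`iti`/`instruction`/`movement`) and per-sample `usable` flag.
#' @export
compute_features <- function(events, config, arm = NULL) {
  if (!is.null(arm)) events <- events[events$arm == arm, ]
  if (nrow(events) == 0) stop("no trials to compute features for", call. = FALSE)
  rate <- config$rate_hz
  t_end <- max(events$return_press_s, events$imperative_s, events$cue_onset_s,
               na.rm = TRUE) + config$feedback_s + config$blank_s
  n <- floor(t_end * rate) + 1L
  time <- (seq_len(n) - 1L) / rate

  z_pos <- numeric(n); z_spd <- numeric(n)
  theta <- numeric(n); phi <- numeric(n)
  epoch <- rep("iti", n)

  ## per-sample trial ownership: sample belongs to the trial whose
  ## [cue-ready window start, next trial's start) interval contains it
  starts <- events$cue_onset_s - config$fixation_s - config$ready_s
  trial_of <- events$trial[pmax(findInterval(time, starts), 1L)]

  ok <- events$success & !events$catch
  for (i in which(ok)) {
    tr <- events[i, ]
    traj <- reconstruct_trajectory(tr, config)
    idx <- round(traj$time * rate) + 1L
    keep <- idx >= 1 & idx <= n
    z_pos[idx[keep]] <- traj$position[keep, 3]
    z_spd[idx[keep]] <- abs(traj$velocity[keep, 3])
    ang <- target_angles(tr, config)
    theta[idx[keep]] <- ang["theta"]
    phi[idx[keep]] <- ang["phi"]
    instr <- time >= tr$cue_onset_s & time < tr$movement_onset_s
    move <- time >= tr$movement_onset_s & time <= tr$return_press_s
    epoch[instr] <- "instruction"
    epoch[move] <- "movement"
  }

  feats <- cbind(z_position = z_pos, z_speed = z_spd, theta = theta, phi = phi)
  arm_of <- events$arm[match(trial_of, events$trial)]
  structure(list(
    features = feats, rate_hz = rate, time = time,
    trial = trial_of,
    arm = arm_of,
    epoch = factor(epoch, levels = c("iti", "instruction", "movement")),
    usable = trial_of %in% usable_trials(events),
    events = events
  ), class = "kinematic_features")
}

## Spherical direction of the target from the arm's home button:
## theta = elevation above the horizontal (XZ) plane, phi = azimuth within it.
## A target straight ahead of the home button has theta = phi = 0.
target_angles <- function(trial, config) {
  home <- config$home[[trial$arm]]
  d <- c(trial$target_x, trial$target_y, trial$target_z) - home
  c(theta = atan2(d[2], sqrt(d[1]^2 + d[3]^2)),
    phi = atan2(d[1], d[3]))
}

#' Reach accuracy: distance from target centre to touch location
#'
#' Euclidean distance in the screen plane between each successful touch and
#' the centre of its target.
#'
#' @param events A `session_events` table.
#' @return A tibble with `trial`, `arm`, `target` and `center_distance_cm`
#'   for successful, non-catch trials.
#' @export
reach_accuracy <- function(events) {
  ok <- events$success & !events$catch
  ev <- events[ok, ]
  tibble::tibble(
    trial = ev$trial, arm = ev$arm, target = ev$target,
    center_distance_cm = sqrt((ev$touch_x - ev$target_x)^2 +
                              (ev$touch_y - ev$target_y)^2)
  )
}
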