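#' Raw multichannel recording container
#'
#' @param signal electrodes x samples matrix (microvolts).
#' @param fs Sampling rate (Hz).
#' @param labels Optional electrode labels.
#' @param bad Logical mask of bad electrodes (excluded from referencing and
#'   from the HFA output).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(signal, fs, labels = NULL, bad = NULL) {
  signal <- as.matrix(signal)
  stopifnot(is.numeric(fs), fs > 0)
  labels <- labels %||% paste0("e", seq_len(nrow(signal)))
  bad <- bad %||% rep(FALSE, nrow(signal))
  if (length(bad) != nrow(signal)) {
    stop("bad-electrode mask length must equal the electrode count", call. = FALSE)
  }
  structure(list(signal = signal, fs = fs, labels = labels, bad = bad),
            class = "raw_recording")
}

#' z-scored high-frequency-activity matrix
#'
#' @param hfa electrodes x samples matrix of z-scored HFA.
#' @param fs Sampling rate (Hz), 100 by default.
#' @param labels Optional electrode labels.
#' @return An object of class `hfa_matrix`.
#' @export
hfa_matrix <- function(hfa, fs = 100, labels = NULL) {
  hfa <- as.matrix(hfa)
  structure(list(hfa = hfa, fs = fs,
                 labels = labels %||% paste0("e", seq_len(nrow(hfa)))),
            class = "hfa_matrix")
}

#' Simulate ground-truth encoding filters with controlled across-arm overlap
#'
#' Each electrode receives a smooth lag-weight matrix (4 kinematic features x
#' `n_lags` lags) for the contralateral arm, built from Gaussian bumps whose
#' centres sit at positive lags (neural activity leading the kinematics, near
#' +150 ms) plus smoothed noise. The ipsilateral filter is the unit mixture
#' `overlap * w_contra + sqrt(1 - overlap^2) * w_perp` rescaled to the
#' contralateral norm, where `w_perp` is a random filter orthogonalized
#' against the contralateral filter, so the realized cosine similarity between
#' the two arms' filters equals `overlap` exactly.
#'
#' If `features` is supplied, the filters are constructed in the
#' standardized design coordinates (each lagged column scaled to unit
#' variance, the space the encoding model is actually fit in) and two extra
#' constraints are applied there. First, both filters are projected onto the
#' identifiable subspace of the session design (eigenvectors of the
#' standardized-design Gram with eigenvalue above `identifiable_tol` times
#' the largest): lagged copies of the step-function angle features are
#' nearly collinear, so weight structure outside this subspace cannot be
#' recovered from any session and would make parameter-recovery tests
#' ill-posed. Second, `w_perp` is decorrelated against the Gram image of the
#' contralateral filter, so that at `overlap = 0` the two arms' noiseless
#' HFA predictions are uncorrelated, not merely coefficient-orthogonal.
#' The reported `realized_cosine` (and the `overlap` invariant) refer to the
#' standardized-coordinate filters in `weights_std`; without `features` the
#' two coordinate systems coincide.
#'
#' @param n_electrodes Number of electrodes.
#' @param overlap Across-arm filter overlap in `[0, 1]` (cosine similarity).
#' @param gains Length-2 nonnegative gains `c(contra, ipsi)`.
#' @param n_lags Lags per feature (>= 1).
#' @param lag_window Length-2 lag window (s) the filter lives on.
#' @param rate_hz Sampling rate of the lag grid (Hz).
#' @param hemisphere Hemisphere label stored with the bank.
#' @param feature_mass Optional length-4 vector; if given, each contralateral
#'   filter's absolute weight mass is rescaled to these proportions by feature.
#' @param features Optional [compute_features()] output for identifiability
#'   projection and design decorrelation (see Details).
#' @param identifiable_tol Relative eigenvalue cutoff of the identifiable
#'   subspace (used only with `features`).
#' @param seed Integer seed.
#' @return A list of class `ground_truth_bank`.
#' @export
simulate_ground_truth_filters <- function(n_electrodes,
                                          overlap = 0.5,
                                          gains = c(contra = 1, ipsi = 0.5),
                                          n_lags = 40,
                                          lag_window = NULL,
                                          rate_hz = 100,
                                          hemisphere = "left",
                                          feature_mass = NULL,
                                          features = NULL,
                                          identifiable_tol = 1e-3,
                                          seed = NULL) {
  if (n_lags < 1) stop("n_lags must be >= 1", call. = FALSE)
  if (overlap < 0 || overlap > 1) stop("overlap must lie in [0, 1]", call. = FALSE)
  if (any(gains < 0)) stop("gains must be nonnegative", call. = FALSE)
  lag_window <- lag_window %||% c(-(n_lags / 2) / rate_hz, (n_lags / 2) / rate_hz)
  lags <- lag_grid(lag_window, rate_hz)
  if (length(lags) != n_lags) {
    stop("lag_window and n_lags disagree: window implies ", length(lags),
         " lags", call. = FALSE)
  }
  p <- 4L * n_lags

  ## standardized-design Gram: identifiable-subspace projector + the
  ## decorrelation directions (all in standardized coordinates). Per-arm
  ## Grams are included so that at overlap 0 the two filters' predictions
  ## are uncorrelated on either arm's samples, not just session-wide.
  grams <- list(); Vk <- NULL; col_sd <- rep(1, p)
  if (!is.null(features)) {
    dz <- build_lagged_design(features, lag_window, zscore = TRUE)
    col_sd <- dz$col_sd
    G <- crossprod(dz$X) / nrow(dz$X)
    eg <- eigen(G, symmetric = TRUE)
    keep <- eg$values > identifiable_tol * max(eg$values)
    Vk <- eg$vectors[, keep, drop = FALSE]
    grams <- list(G)
    for (a in c("contra", "ipsi")) {
      rows <- which(features$arm == a)
      if (length(rows) > p) {
        Xa <- scale(dz$X[rows, , drop = FALSE], center = TRUE, scale = FALSE)
        grams <- c(grams, list(crossprod(Xa) / nrow(Xa)))
      }
    }
  }
  project <- function(w) if (is.null(Vk)) w else Vk %*% crossprod(Vk, w)

  with_seed(seed, {
    Wstd_contra <- matrix(0, n_electrodes, p)
    Wstd_ipsi <- matrix(0, n_electrodes, p)
    for (e in seq_len(n_electrodes)) {
      w <- project(smooth_filter(lags, feature_mass))
      v <- project(smooth_filter(lags, feature_mass))
      basis <- cbind(w)
      for (Gm in grams) basis <- cbind(basis, project(Gm %*% w))
      v <- orthogonalize(v, basis, keep_orthogonal_to = w)
      wu <- w / sqrt(sum(w^2))
      vu <- v / sqrt(sum(v^2))
      wi <- (overlap * wu + sqrt(1 - overlap^2) * vu) * sqrt(sum(w^2))
      Wstd_contra[e, ] <- w
      Wstd_ipsi[e, ] <- wi
    }
    cosines <- rowSums(Wstd_contra * Wstd_ipsi) /
      (sqrt(rowSums(Wstd_contra^2)) * sqrt(rowSums(Wstd_ipsi^2)))
    ## raw-scale filters drive the forward model on unscaled features
    W_contra <- sweep(Wstd_contra, 2, col_sd, `/`)
    W_ipsi <- sweep(Wstd_ipsi, 2, col_sd, `/`)
    structure(list(
      weights = list(contra = W_contra, ipsi = W_ipsi),
      weights_std = list(contra = Wstd_contra, ipsi = Wstd_ipsi),
      col_sd = col_sd, identifiable_basis = Vk,
      contra_gain = rep(unname(gains[1]), n_electrodes),
      ipsi_gain = rep(unname(gains[2]), n_electrodes),
      overlap = overlap, realized_cosine = cosines,
      hemisphere = hemisphere,
      n_lags = n_lags, lag_window = lag_window, rate_hz = rate_hz,
      feature_names = c("z_position", "z_speed", "theta", "phi")
    ), class = "ground_truth_bank")
  })
}

## One smooth random filter over the lag grid, feature-major (4 blocks).
smooth_filter <- function(lags, feature_mass = NULL) {
  L <- length(lags)
  blocks <- lapply(1:4, function(f) {
    mu <- stats::rnorm(1, 0.15, 0.05)
    s <- stats::runif(1, 0.05, 0.15)
    a <- stats::rnorm(1)
    bump <- a * exp(-(lags - mu)^2 / (2 * s^2))
    ## smoothed noise floor keeps filters full rank across electrodes
    eps <- stats::rnorm(L)
    k <- stats::dnorm(seq(-3, 3, length.out = min(21L, L)))
    eps <- stats::filter(eps, k / sum(k), circular = TRUE)
    bump + 0.1 * as.numeric(eps)
  })
  w <- unlist(blocks)
  if (!is.null(feature_mass)) {
    stopifnot(length(feature_mass) == 4, all(feature_mass >= 0))
    target <- feature_mass / sum(feature_mass)
    for (f in 1:4) {
      idx <- ((f - 1) * L + 1):(f * L)
      m <- sum(abs(w[idx]))
      if (m > 0) w[idx] <- w[idx] * target[f] / m
    }
  }
  w
}

## Gram-Schmidt v against the columns of `basis`; re-enforce exact Euclidean
## orthogonality to `keep_orthogonal_to` last (the invariant that matters).
orthogonalize <- function(v, basis, keep_orthogonal_to) {
  for (j in seq_len(ncol(basis))) {
    b <- basis[, j]
    nb <- sum(b^2)
    if (nb > 0) v <- v - sum(v * b) / nb * b
  }
  w <- keep_orthogonal_to
  v <- v - sum(v * w) / sum(w^2) * w
  if (sum(v^2) == 0) stop("degenerate orthogonal filter draw", call. = FALSE)
  v
}

#' Simulate z-scored HFA from kinematic features and ground-truth filters
#'
#' Forward model mirroring the encoding model's functional form: for electrode
#' e, `HFA_e(t) = gain_arm * sum_f sum_l W_e[f, l] * feature_f(t + lag_l)`
#' plus iid Gaussian noise, z-scored per electrode over the concatenated
#' session. The noise sd can be given directly or derived per electrode from
#' a target noise ceiling: `target_r2` sets the squared correlation between
#' the noiseless signal and the noisy HFA (the best attainable held-out R^2).
#'
#' @param features A [compute_features()] object at the bank's sampling rate.
#' @param bank A [simulate_ground_truth_filters()] bank.
#' @param arm Which arm's filters and gain to use.
#' @param noise_sd Noise sd (scalar or per electrode); ignored if
#'   `target_r2` is given.
#' @param target_r2 Optional noise ceiling in (0, 1]; noise sd is set per
#'   electrode so that `Var(signal) / (Var(signal) + noise_sd^2) = target_r2`.
#' @param seed Integer seed.
#' @return An `hfa_matrix` with attributes `noise_sd` (per electrode) and
#'   `ceiling_r2`.
#' @export
simulate_hfa <- function(features, bank, arm = c("contra", "ipsi"),
                         noise_sd = 0, target_r2 = NULL, seed = NULL) {
  arm <- match.arg(arm)
  if (features$rate_hz != bank$rate_hz) {
    stop(sprintf("rate mismatch: features at %g Hz, filter bank at %g Hz",
                 features$rate_hz, bank$rate_hz), call. = FALSE)
  }
  X <- build_lagged_design(features, bank$lag_window, zscore = FALSE)$X
  W <- bank$weights[[arm]]
  gain <- if (arm == "contra") bank$contra_gain else bank$ipsi_gain
  S <- X %*% t(W) # samples x electrodes
  S <- sweep(S, 2, gain, `*`)
  n_e <- ncol(S)
  sig_var <- apply(S, 2, stats::var)
  if (!is.null(target_r2)) {
    stopifnot(target_r2 > 0, target_r2 <= 1)
    noise_sd <- sqrt(sig_var * (1 - target_r2) / target_r2)
  } else {
    noise_sd <- rep_len(noise_sd, n_e)
  }
  Y <- with_seed(seed, S + matrix(stats::rnorm(length(S)), nrow(S), n_e) %*%
                   diag(noise_sd, n_e))
  Y <- apply(Y, 2, zscore)
  out <- hfa_matrix(t(Y), fs = features$rate_hz)
  attr(out, "noise_sd") <- noise_sd
  attr(out, "ceiling_r2") <- sig_var / (sig_var + noise_sd^2)
  out
}

#' Synthesize raw broadband ECoG carrying a known HFA envelope
#'
#' Each electrode's raw trace is the sum over the five logarithmically spaced
#' 70-200 Hz bands of a band-centre sinusoidal carrier amplitude-modulated by
#' a rectified affine transform of the target envelope
#' (`pmax(offset + scale * env, 0)`), plus 1/f (pink) background noise and
#' optional 60/120/180 Hz line components. An amplitude modulation confined
#' to a band of width W can only carry modulation frequencies up to W/2, so
#' the envelope is low-pass filtered at `env_bandwidth_hz` (zero phase)
#' before modulating; the envelope actually written onto the carriers is
#' returned in the `effective_envelope` attribute (electrodes x samples at
#' the input envelope rate), and it is this envelope that
#' [preprocess_raw()] + [extract_hfa()] recover.
#'
#' @param hfa An `hfa_matrix` holding the target envelopes (z-units).
#' @param band_edges Band edges in Hz (defaults to [log_band_edges()] on
#'   70-200 Hz with 5 bands).
#' @param fs_raw Raw sampling rate (Hz); must be at least twice the highest
#'   band edge.
#' @param am_offset,am_scale Affine envelope transform before rectification.
#' @param env_bandwidth_hz Envelope low-pass cutoff (Hz); keep below half the
#'   narrowest band's width.
#' @param noise_sd Pink-noise sd relative to unit carrier amplitude.
#' @param line_amp Amplitude of the 60/120/180 Hz line components.
#' @param seed Integer seed.
#' @return A `raw_recording` at `fs_raw` with attribute `effective_envelope`.
#' @export
simulate_raw_ecog <- function(hfa, band_edges = log_band_edges(70, 200, 5),
                              fs_raw = 1000, am_offset = 5, am_scale = 1,
                              env_bandwidth_hz = 5,
                              noise_sd = 0, line_amp = 0, seed = NULL) {
  if (fs_raw < 2 * max(band_edges)) {
    stop("fs_raw must be at least twice the highest carrier frequency",
         call. = FALSE)
  }
  env <- hfa$hfa
  n_e <- nrow(env)
  n_raw <- ncol(env) * round(fs_raw / hfa$fs)
  t_raw <- (seq_len(n_raw) - 1) / fs_raw
  t_env <- (seq_len(ncol(env)) - 1) / hfa$fs
  centers <- sqrt(band_edges[-length(band_edges)] * band_edges[-1])
  ## keep carriers clear of the line-noise notches applied in preprocessing
  for (f0 in c(60, 120, 180)) {
    hit <- abs(centers - f0) < 8
    lo_edge <- band_edges[-length(band_edges)][hit]
    centers[hit] <- ifelse(f0 - 8 > lo_edge + 1, f0 - 8, f0 + 8)
  }

  lp <- signal::butter(4, env_bandwidth_hz / (fs_raw / 2), type = "low")
  env_step <- round(fs_raw / hfa$fs)

  with_seed(seed, {
    sig <- matrix(0, n_e, n_raw)
    eff_env <- matrix(0, n_e, ncol(env))
    for (e in seq_len(n_e)) {
      a0 <- am_offset + am_scale *
        stats::approx(t_env, env[e, ], xout = t_raw, rule = 2)$y
      a <- pmax(signal::filtfilt(lp, a0), 0)
      eff_env[e, ] <- a[seq(1, n_raw, by = env_step)][seq_len(ncol(env))]
      tr <- numeric(n_raw)
      for (fc in centers) {
        phase <- stats::runif(1, 0, 2 * pi)
        tr <- tr + a * cos(2 * pi * fc * t_raw + phase)
      }
      if (noise_sd > 0) tr <- tr + noise_sd * pink_noise(n_raw, fs_raw)
      if (line_amp > 0) {
        for (fl in c(60, 120, 180)) tr <- tr + line_amp * sin(2 * pi * fl * t_raw)
      }
      sig[e, ] <- tr
    }
    out <- raw_recording(sig, fs = fs_raw)
    attr(out, "effective_envelope") <- eff_env
    out
  })
}

## Unit-sd 1/f-amplitude noise via spectral shaping.
pink_noise <- function(n, fs) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # symmetric frequency index
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  as.numeric(zscore(x))
}

#' Simulate one continuous session of HFA with arm-specific filters
#'
#' Like [simulate_hfa()], but the forward model switches filters with the
#' reaching arm: samples belonging to contralateral trials are generated from
#' the contralateral filters and gain, ipsilateral samples from the
#' ipsilateral ones. Noise is added over the whole session and the result is
#' z-scored per electrode over the concatenated recording, as in the
#' acquisition pipeline. When `target_r2` is given, the noise sd is set per
#' electrode so the noise ceiling on *contralateral* samples equals
#' `target_r2`; the ipsilateral ceiling then falls out of the gain ratio.
#'
#' @inheritParams simulate_hfa
#' @return An `hfa_matrix` with attributes `noise_sd` and `ceiling_r2`
#'   (electrodes x 2 matrix, per arm).
#' @export
simulate_session_hfa <- function(features, bank, noise_sd = 0,
                                 target_r2 = NULL, seed = NULL) {
  if (features$rate_hz != bank$rate_hz) {
    stop(sprintf("rate mismatch: features at %g Hz, filter bank at %g Hz",
                 features$rate_hz, bank$rate_hz), call. = FALSE)
  }
  X <- build_lagged_design(features, bank$lag_window, zscore = FALSE)$X
  S_c <- sweep(X %*% t(bank$weights$contra), 2, bank$contra_gain, `*`)
  S_i <- sweep(X %*% t(bank$weights$ipsi), 2, bank$ipsi_gain, `*`)
  is_ipsi <- features$arm == "ipsi"
  S <- S_c
  S[is_ipsi, ] <- S_i[is_ipsi, ]
  n_e <- ncol(S)
  var_c <- apply(S[!is_ipsi, , drop = FALSE], 2, stats::var)
  var_i <- apply(S[is_ipsi, , drop = FALSE], 2, stats::var)
  if (!is.null(target_r2)) {
    stopifnot(target_r2 > 0, target_r2 <= 1)
    noise_sd <- sqrt(var_c * (1 - target_r2) / target_r2)
  } else {
    noise_sd <- rep_len(noise_sd, n_e)
  }
  Y <- with_seed(seed, S + matrix(stats::rnorm(length(S)), nrow(S), n_e) %*%
                   diag(noise_sd, n_e))
  Y <- apply(Y, 2, zscore)
  out <- hfa_matrix(t(Y), fs = features$rate_hz)
  attr(out, "noise_sd") <- noise_sd
  attr(out, "ceiling_r2") <- cbind(contra = var_c / (var_c + noise_sd^2),
                                   ipsi = var_i / (var_i + noise_sd^2))
  out
}
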