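#' Logarithmically spaced band edges
#'
#' `n_bands + 1` edges in geometric progression from `lo` to `hi`. With the
#' defaults used for HFA extraction (70-200 Hz, five bands) the rounded edges
#' are 70, 86, 107, 131, 162, 200 Hz.
#'
#' @param lo,hi Band limits in Hz (`0 < lo < hi`).
#' @param n_bands Number of bands (>= 1).
#' @param round Round edges to integer Hz.
#' @return Numeric vector of `n_bands + 1` edges.
#' @export
log_band_edges <- function(lo = 70, hi = 200, n_bands = 5, round = FALSE) {
  stopifnot(lo > 0, hi > lo, n_bands >= 1)
  edges <- exp(seq(log(lo), log(hi), length.out = n_bands + 1))
  if (round) edges <- base::round(edges)
  edges
}

#' Preprocess a raw recording: antialias/resample, re-reference, notch
#'
#' Applies, in order: a 4th-order Butterworth low-pass at 500 Hz (zero phase)
#' followed by downsampling when the input rate exceeds `target_fs`; common
#' average referencing over the good electrodes; and zero-phase 4th-order
#' Butterworth band-stop notches at 60, 120 and 180 Hz (2 Hz half-width).
#' Bad electrodes are excluded from the common average and dropped from the
#' output.
#'
#' @param rec A [raw_recording()].
#' @param target_fs Target sampling rate (default 1000 Hz); the input rate
#'   must be an integer multiple of it.
#' @param notch_hz Notch centre frequencies (Hz).
#' @param notch_halfwidth_hz Half-width of each band-stop (Hz).
#' @param car Apply the common average reference (default TRUE; disable for
#'   recordings that are already referenced).
#' @return A preprocessed `raw_recording` at `target_fs` containing only the
#'   good electrodes.
#' @export
preprocess_raw <- function(rec, target_fs = 1000, notch_hz = c(60, 120, 180),
                           notch_halfwidth_hz = 2, car = TRUE) {
  stopifnot(inherits(rec, "raw_recording"))
  if (all(rec$bad)) stop("all electrodes are marked bad", call. = FALSE)
  if (rec$fs < target_fs) {
    stop(sprintf("input rate %g Hz is below the target rate %g Hz",
                 rec$fs, target_fs), call. = FALSE)
  }
  sig <- rec$signal[!rec$bad, , drop = FALSE]
  labels <- rec$labels[!rec$bad]
  fs <- rec$fs

  if (fs > target_fs) {
    if (fs %% target_fs != 0) {
      stop(sprintf("rate %g Hz is not an integer multiple of %g Hz",
                   fs, target_fs), call. = FALSE)
    }
    q <- fs %/% target_fs
    lp <- signal::butter(4, min(500 / (fs / 2), 0.99), type = "low")
    sig <- t(apply(sig, 1, function(x) {
      y <- signal::filtfilt(lp, x)
      y[seq(1, length(y), by = q)]
    }))
    fs <- target_fs
  }

  ## common average reference over good electrodes
  if (car) sig <- sweep(sig, 2, colMeans(sig), `-`)

  for (f0 in notch_hz) {
    bs <- signal::butter(4, c(f0 - notch_halfwidth_hz, f0 + notch_halfwidth_hz) /
                           (fs / 2), type = "stop")
    sig <- t(apply(sig, 1, function(x) signal::filtfilt(bs, x)))
  }

  raw_recording(sig, fs = fs, labels = labels)
}

#' Extract the z-scored high-frequency-activity envelope
#'
#' For each of the logarithmically spaced bands between `lo` and `hi`
#' (default: five bands over 70-200 Hz): zero-phase 4th-order Butterworth
#' band-pass, analytic-signal magnitude (Hilbert envelope), z-score over the
#' full concatenated recording; the per-band z-scored envelopes are then
#' averaged and the result downsampled with antialiasing to `out_fs`.
#'
#' @param rec A preprocessed [raw_recording()].
#' @param lo,hi,n_bands Band-split parameters (see [log_band_edges()]).
#' @param out_fs Output rate (default 100 Hz); `rec$fs` must be an integer
#'   multiple of it.
#' @return An `hfa_matrix` at `out_fs`. The attribute `hfa_fullrate` holds the
#'   averaged z-scored envelope before downsampling.
#' @export
extract_hfa <- function(rec, lo = 70, hi = 200, n_bands = 5, out_fs = 100) {
  stopifnot(inherits(rec, "raw_recording"))
  edges <- log_band_edges(lo, hi, n_bands)
  if (max(edges) >= rec$fs / 2) {
    stop(sprintf("band edge %g Hz is at or above the Nyquist rate %g Hz",
                 max(edges), rec$fs / 2), call. = FALSE)
  }
  if (rec$fs %% out_fs != 0) {
    stop(sprintf("recording rate %g Hz is not an integer multiple of the output rate %g Hz",
                 rec$fs, out_fs), call. = FALSE)
  }
  sig <- rec$signal
  n_e <- nrow(sig)
  acc <- matrix(0, n_e, ncol(sig))
  for (b in seq_len(n_bands)) {
    bp <- signal::butter(4, c(edges[b], edges[b + 1]) / (rec$fs / 2),
                         type = "pass")
    for (e in seq_len(n_e)) {
      env <- hilbert_envelope(signal::filtfilt(bp, sig[e, ]))
      acc[e, ] <- acc[e, ] + zscore(env)
    }
  }
  acc <- acc / n_bands
  q <- rec$fs %/% out_fs
  out <- t(apply(acc, 1, function(x) signal::decimate(x, q)))
  res <- hfa_matrix(out, fs = out_fs, labels = rec$labels)
  attr(res, "hfa_fullrate") <- acc
  res
}

## Magnitude of the analytic signal via the FFT half-spectrum construction.
hilbert_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}
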