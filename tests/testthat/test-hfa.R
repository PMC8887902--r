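test_that("log band edges match the published five-band split", {
  expect_equal(log_band_edges(70, 200, 5, round = TRUE),
               c(70, 86, 107, 131, 162, 200))
  expect_equal(log_band_edges(70, 200, 1), c(70, 200))
  expect_equal(log_band_edges(100, 400, 2), c(100, 200, 400))
  expect_error(log_band_edges(0, 200, 5))
})

test_that("preprocessing resamples only when needed and notches line noise", {
  t <- seq(0, 4, by = 1 / 1000)
  rec <- raw_recording(matrix(rnorm(2 * length(t)), 2), fs = 1000)
  pp <- preprocess_raw(rec, car = FALSE)
  expect_equal(ncol(pp$signal), length(t))

  # 2000 Hz input is antialiased and decimated to 1000 Hz
  rec2 <- raw_recording(matrix(rnorm(2 * 8000), 2), fs = 2000)
  pp2 <- preprocess_raw(rec2, car = FALSE)
  expect_equal(pp2$fs, 1000)
  expect_equal(ncol(pp2$signal), 4000)

  # pure 60 Hz attenuated by >= 20 dB (edges trimmed to avoid transients)
  pure <- raw_recording(matrix(sin(2 * pi * 60 * t), 1), fs = 1000)
  pn <- preprocess_raw(pure, car = FALSE)
  core <- 500:3500
  att_db <- 20 * log10(sqrt(mean(pure$signal[1, core]^2)) /
                         sqrt(mean(pn$signal[1, core]^2)))
  expect_gte(att_db, 20)
})

test_that("the common average reference removes common-mode signal", {
  t <- seq(0, 2, by = 1 / 1000)
  x <- sin(2 * pi * 7 * t)
  rec <- raw_recording(rbind(x, x, x), fs = 1000)
  pp <- preprocess_raw(rec, notch_hz = numeric(0))
  expect_equal(max(abs(pp$signal)), 0)
  # bad electrodes are excluded from the average and the output
  rec_bad <- raw_recording(rbind(x, x, 5 * x), fs = 1000,
                           bad = c(FALSE, FALSE, TRUE))
  pp_bad <- preprocess_raw(rec_bad, notch_hz = numeric(0))
  expect_equal(nrow(pp_bad$signal), 2)
  expect_equal(max(abs(pp_bad$signal)), 0)
  expect_error(preprocess_raw(raw_recording(rbind(x), fs = 1000,
                                            bad = TRUE)), "bad")
})

test_that("the Hilbert envelope recovers an analytic AM modulator", {
  t <- seq(0, 5, by = 1 / 1000)
  mod <- 1 + 0.5 * sin(2 * pi * 2 * t)
  am <- raw_recording(matrix(mod * cos(2 * pi * 100 * t), 1), fs = 1000)
  ex <- extract_hfa(am, lo = 80, hi = 120, n_bands = 1)
  expect_gt(cor(attr(ex, "hfa_fullrate")[1, ], mod), 0.99)
})

test_that("extraction is z-scored over the full concatenated recording", {
  set.seed(30)
  rec <- raw_recording(matrix(rnorm(2 * 20000), 2), fs = 1000)
  ex <- extract_hfa(rec)
  full <- attr(ex, "hfa_fullrate")
  expect_lt(max(abs(rowMeans(full))), 0.01)
  expect_true(all(apply(full, 1, sd) <= 1 + 1e-6))

  # blocks with a 2:1 amplitude ratio keep their difference only because the
  # z-score uses the whole concatenation, not per-block scaling
  t <- seq(0, 20, by = 1 / 1000)
  amp <- ifelse(t < 10, 1, 2)
  x <- amp * cos(2 * pi * 100 * t)
  exb <- extract_hfa(raw_recording(matrix(x, 1), fs = 1000),
                     lo = 80, hi = 120, n_bands = 1)
  env <- attr(exb, "hfa_fullrate")[1, ]
  half <- seq_along(t) <= length(t) / 2
  core1 <- which(half)[1000:9000]; core2 <- which(!half)[1000:9000]
  expect_gt(mean(env[core2]) - mean(env[core1]), 1)
  # control: per-block z-scoring would erase the difference
  env_blocked <- c(scale(env[half]), scale(env[!half]))
  expect_lt(abs(mean(env_blocked[core2]) - mean(env_blocked[core1])), 0.2)
})

test_that("band edges above Nyquist are rejected", {
  rec <- raw_recording(matrix(rnorm(1000), 1), fs = 300)
  expect_error(extract_hfa(rec), "Nyquist")
})

test_that("extraction inverts the raw-signal generator (round-trip oracle)", {
  tc <- task_config(blocks_per_arm = 1, trials_per_target = 3)
  ev <- simulate_task_events(tc, seed = 31)
  fe <- compute_features(ev, tc)
  bank <- simulate_ground_truth_filters(2, overlap = 0.5, n_lags = 40,
                                        lag_window = c(-0.2, 0.2),
                                        features = fe, seed = 32)
  h <- simulate_session_hfa(fe, bank, noise_sd = 0, seed = 33)
  raw <- simulate_raw_ecog(h, fs_raw = 1000, noise_sd = 0, line_amp = 0,
                           seed = 34)
  eff <- attr(raw, "effective_envelope")
  ex <- extract_hfa(preprocess_raw(raw, car = FALSE))
  n <- ncol(eff)
  r0 <- sapply(1:2, function(e) cor(ex$hfa[e, 1:n], eff[e, ]))
  expect_true(all(r0 > 0.99))

  # constant envelope -> the z-scored extraction is structure-free: a
  # constant-amplitude carrier's band envelope is flat away from the filter
  # edge transients, so the z-scored core is flat too
  tt <- seq(0, 20, by = 1 / 1000)
  tone <- raw_recording(matrix(cos(2 * pi * 100 * tt), 1), fs = 1000)
  exc <- extract_hfa(tone, lo = 80, hi = 120, n_bands = 1)
  core <- exc$hfa[1, 200:1800]
  expect_lt(diff(range(core)), 0.02)
  expect_lt(sd(core), 0.01)

  # a strong 60 Hz line barely degrades post-notch extraction
  raw_line <- simulate_raw_ecog(h, fs_raw = 1000, noise_sd = 0,
                                line_amp = 50, seed = 34)
  ex_line <- extract_hfa(preprocess_raw(raw_line, car = FALSE))
  r1 <- sapply(1:2, function(e) cor(ex_line$hfa[e, 1:n], eff[e, ]))
  expect_true(all(r0 - r1 < 0.05))
})
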