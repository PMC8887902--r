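test_that("modulation depth is the population sd of target means", {
  expect_equal(modulation_depth(c(0.2, 0.2, 0.2, 0.2)), 0)
  expect_equal(modulation_depth(c(1, -1)), 1)
  expect_equal(modulation_depth(c(0.1, 0.3, 0.5, 0.7)), sqrt(0.05),
               tolerance = 1e-12) # 0.2236
  expect_error(modulation_depth(0.5), "2 targets")
  # property: matches direct evaluation of the formula on random inputs
  set.seed(70)
  for (i in 1:20) {
    x <- rnorm(sample(2:8, 1))
    expect_equal(modulation_depth(x),
                 sqrt(sum((x - mean(x))^2) / length(x)), tolerance = 1e-12)
  }
})

test_that("tuning similarity min-max scales SSE over shared targets", {
  # three electrodes engineered to SSE {0, 1, 4} on the two shared targets
  contra <- rbind(c(1, 1, 9, 9), c(1, 1, 9, 9), c(1, 1, 9, 9))
  ipsi <- rbind(c(1, 1, 0, 0), c(1, 2, 0, 0), c(1, 3, 0, 0))
  r <- tuning_similarity(contra, ipsi, shared_targets = 1:2)
  expect_equal(unname(r$sse), c(0, 1, 4))
  expect_equal(unname(r$si), c(1, 0.75, 0))
  # si rank order is the inverse of the sse rank order
  expect_equal(cor(rank(r$si), rank(r$sse), method = "spearman"), -1)
  # identical arms attain si = 1; eccentric targets are ignored
  expect_equal(unname(r$si[1]), 1)
  # degenerate population flagged
  rd <- tuning_similarity(contra, contra)
  expect_true(rd$flagged)
  expect_error(tuning_similarity(contra[1, , drop = FALSE],
                                 ipsi[1, , drop = FALSE]), "2 electrodes")
})

test_that("generalization classes follow the 0.80 / 0.50 index thresholds", {
  g <- classify_generalization(c(0.20, 0.20, 0.20), c(0.18, 0.08, 0.13))
  expect_equal(g$index, c(0.90, 0.40, 0.65))
  expect_equal(as.character(g$class), c("good", "poor", "intermediate"))
  # scale invariance
  g2 <- classify_generalization(3 * c(0.20, 0.20, 0.20),
                                3 * c(0.18, 0.08, 0.13))
  expect_equal(as.character(g2$class), as.character(g$class))
  expect_warning(g0 <- classify_generalization(0, 0.1), "undefined")
  expect_true(is.na(g0$index))
})

test_that("feature contributions are absolute-mass proportions", {
  w <- matrix(0, 4, 10)
  w[2, ] <- rnorm(10)
  expect_equal(unname(feature_contribution(w)), c(0, 1, 0, 0))
  w2 <- matrix(1, 4, 10); w2[2, ] <- -1
  expect_equal(unname(feature_contribution(w2)), rep(0.25, 4))
  expect_warning(fc0 <- feature_contribution(matrix(0, 4, 5)), "zero")
  expect_true(all(is.na(fc0)))
})

test_that("ground-truth feature mass is recovered at high SNR", {
  bank <- simulate_ground_truth_filters(
    3, overlap = 0.5, n_lags = 40, lag_window = c(-0.2, 0.2),
    feature_mass = c(0.7, 0.1, 0.1, 0.1), features = fx$fe, seed = 71)
  h <- simulate_session_hfa(fx$fe, bank, target_r2 = 0.95, seed = 72)
  fit <- nested_cv_fit(fx$design, t(h$hfa), arm = "contra",
                       lambda_grid = 10^(0:7), seed = 73)
  for (e in 1:3) {
    truth <- feature_contribution(rbind(
      bank$weights_std$contra[e, 1:40], bank$weights_std$contra[e, 41:80],
      bank$weights_std$contra[e, 81:120], bank$weights_std$contra[e, 121:160]))
    got <- feature_contribution(fit$weights_std[e, , ])
    expect_equal(unname(got[1]), unname(truth[1]), tolerance = 0.05 / 0.7)
  }
})

test_that("cross-correlation finds constructed delays with the lead convention", {
  set.seed(74)
  hfa <- as.numeric(stats::filter(rnorm(600), rep(1, 20) / 20, circular = TRUE))
  # kinematics delayed by 200 ms (20 samples at 100 Hz): HFA leads
  kin <- c(rep(0, 20), hfa[1:580])
  cc <- cross_correlate(hfa, kin, rate_hz = 100, max_lag_s = 0.5)
  expect_equal(cc$lag_ms, 200)
  expect_gt(cc$r, 0.95)
  cc0 <- cross_correlate(hfa, hfa, rate_hz = 100)
  expect_equal(cc0$lag_ms, 0)
  expect_equal(cc0$r, 1)
  expect_error(cross_correlate(rep(1, 100), rnorm(100), 100), "constant")
})

test_that("filter mass at a positive lag appears as an HFA lead", {
  # a pure z-position filter with its mass centred at +150 ms: the
  # trial-averaged HFA must lead the trial-averaged kinematics by ~150 ms
  bank <- fx$bank
  lags_s <- lag_grid(bank$lag_window, bank$rate_hz)
  bump <- exp(-(lags_s - 0.15)^2 / (2 * 0.03^2))
  w <- c(bump, rep(0, 3 * length(lags_s)))
  for (arm in c("contra", "ipsi")) {
    bank$weights[[arm]] <- matrix(w, 4, length(w), byrow = TRUE)
  }
  h <- simulate_session_hfa(fx$fe, bank, target_r2 = 0.98, seed = 75)
  ev_ok <- fx$ev[fx$ev$success & !fx$ev$catch & fx$ev$arm == "contra", ]
  onsets <- ev_ok$movement_onset_s
  lags <- sapply(1:4, function(e) {
    hs <- stack_trials(h$hfa[e, ], 100, onsets, c(-1, 2))
    ks <- stack_trials(fx$fe$features[, "z_position"], 100, onsets, c(-1, 2))
    cross_correlate(colMeans(hs), colMeans(ks), 100, max_lag_s = 0.4)$lag_ms
  })
  expect_true(all(abs(lags - 150) <= 20))
})

test_that("distance to the dorsal central sulcus matches geometry oracles", {
  # straight vertical sulcus from y=0 to y=10; dorsal half is y in [5, 10]
  cs <- cbind(rep(0, 11), 0:10)
  expect_equal(distance_to_dorsal_cs(c(0, 7), cs), 0)
  expect_equal(distance_to_dorsal_cs(c(5, 8), cs), 5)
  # an electrode level with the ventral half is measured to the midpoint
  expect_equal(distance_to_dorsal_cs(c(3, 1), cs), sqrt(9 + 16))
  expect_error(distance_to_dorsal_cs(c(0, 0), cs[1, , drop = FALSE]), "2 sulcus")

  # dense-sampling oracle on random polylines
  set.seed(76)
  for (i in 1:5) {
    cs_r <- cbind(cumsum(rnorm(30, 0, 0.5)), sort(runif(30, 0, 10)))
    p <- c(runif(1, -3, 3), runif(1, 0, 10))
    got <- distance_to_dorsal_cs(p, cs_r)
    # brute force: densely sample the dorsal sub-polyline
    seg <- diff(cs_r); len <- sqrt(rowSums(seg^2)); cum <- c(0, cumsum(len))
    smid <- max(cum) / 2
    ss <- seq(smid, max(cum), length.out = 10000)
    pts <- t(sapply(ss, function(s) {
      i <- findInterval(s, cum, rightmost.closed = TRUE)
      i <- min(i, nrow(cs_r) - 1)
      f <- if (len[i] > 0) (s - cum[i]) / len[i] else 0
      cs_r[i, ] + f * seg[i, ]
    }))
    oracle <- min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2))
    expect_equal(got, oracle, tolerance = 1e-3)
  }
})

test_that("difference scores expose a contralateral encoding bias", {
  expect_equal(difference_score(0.3, 0.3), 0)
  expect_equal(difference_score(0.3, 0.1), 0.2)
  # ipsilateral gain 0: difference ~ within-arm ceiling
  bank0 <- simulate_ground_truth_filters(
    4, overlap = 0.5, gains = c(contra = 1, ipsi = 0), n_lags = 40,
    lag_window = c(-0.2, 0.2), features = fx$fe, seed = 77)
  h0 <- simulate_session_hfa(fx$fe, bank0, target_r2 = 0.5, seed = 78)
  fc <- nested_cv_fit(fx$design, t(h0$hfa), arm = "contra",
                      lambda_grid = 10^(0:7), seed = 79)
  fi <- nested_cv_fit(fx$design, t(h0$hfa), arm = "ipsi",
                      lambda_grid = 10^(0:7), seed = 80)
  d <- difference_score(fc$r2, fi$r2)
  expect_gt(mean(d), 0.4)
})
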