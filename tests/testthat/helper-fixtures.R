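# Shared small-session fixtures, built once per test run. Sizes are kept
# small (one block per arm, +/-0.2 s lag window) so the whole suite runs on
# one CPU in minutes; the simulator's task structure itself (4 targets, 10
# trials/target, 750/900 ms delays, 5% catch) is the study configuration.

fx <- local({
  tc <- task_config(blocks_per_arm = 1)
  ev <- simulate_task_events(tc, seed = 101)
  fe <- compute_features(ev, tc)
  design <- build_lagged_design(fe, c(-0.2, 0.2))
  bank <- simulate_ground_truth_filters(
    4, overlap = 0.5, gains = c(contra = 1, ipsi = 0.5),
    n_lags = 40, lag_window = c(-0.2, 0.2), features = fe, seed = 102)
  hfa <- simulate_session_hfa(fe, bank, target_r2 = 0.5, seed = 103)
  list(tc = tc, ev = ev, fe = fe, design = design, bank = bank, hfa = hfa,
       Y = t(hfa$hfa))
})

# tiny features object for structural design checks (no simulation needed)
make_toy_features <- function(n = 200, rate = 100, values = NULL) {
  f <- values %||% matrix(stats::rnorm(n * 4), n, 4)
  colnames(f) <- c("z_position", "z_speed", "theta", "phi")
  structure(list(
    features = f, rate_hz = rate, time = (seq_len(n) - 1) / rate,
    trial = rep(seq_len(max(1, n %/% 20)), each = 20, length.out = n),
    arm = rep("contra", n),
    epoch = factor(rep("movement", n), levels = c("iti", "instruction", "movement")),
    usable = rep(TRUE, n),
    events = NULL
  ), class = "kinematic_features")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
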