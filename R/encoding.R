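## Lag grid: left-closed, right-open multiples of 1/rate, so a window of
## (-2, 2) s at 100 Hz gives 400 lags -2.00, -1.99, ..., +1.99.
lag_grid <- function(lag_window, rate_hz) {
  stopifnot(length(lag_window) == 2, lag_window[2] > lag_window[1])
  n <- round((lag_window[2] - lag_window[1]) * rate_hz)
  if (n < 1) stop("empty lag window", call. = FALSE)
  lag_window[1] + (seq_len(n) - 1) / rate_hz
}

#' Build the time-lagged feature design matrix
#'
#' Expands the four kinematic features into a samples x (4 x n_lags) design:
#' the column for feature f at lag l holds `feature_f(t + l)`, feature-major
#' then lag. Positive lags therefore pair the neural sample at `t` with
#' future kinematics (neural activity leading the movement). Out-of-range
#' samples are zero-padded. Columns are z-scored by default (constant columns
#' are centred and left unscaled).
#'
#' @param features A [compute_features()] object.
#' @param lag_window Length-2 window in seconds (default `c(-2, 2)`, i.e. 400
#'   lags per feature at 100 Hz); endpoints must be multiples of the sample
#'   step.
#' @param zscore z-score the columns (default TRUE).
#' @return An object of class `lagged_design`: the design `X`, the lag grid
#'   `lags`, `rate_hz`, feature/lag column bookkeeping, the z-scoring
#'   constants, and the per-sample `trial`, `arm`, `epoch` and `usable`
#'   vectors carried over from `features`.
#' @export
build_lagged_design <- function(features, lag_window = c(-2, 2), zscore = TRUE) {
  rate <- features$rate_hz
  lags <- lag_grid(lag_window, rate)
  Fm <- features$features
  n <- nrow(Fm)
  L <- length(lags)
  shifts <- round(lags * rate)
  X <- matrix(0, n, 4L * L)
  for (f in 1:4) {
    col0 <- (f - 1L) * L
    v <- Fm[, f]
    for (j in seq_len(L)) {
      k <- shifts[j]
      src <- seq_len(n) + k
      ok <- src >= 1L & src <= n
      X[ok, col0 + j] <- v[src[ok]]
    }
  }
  col_mean <- colMeans(X)
  col_sd <- rep(1, ncol(X))
  if (zscore) {
    col_sd <- apply(X, 2, stats::sd)
    col_sd[!is.finite(col_sd) | col_sd == 0] <- 1
    X <- sweep(sweep(X, 2, col_mean, `-`), 2, col_sd, `/`)
  }
  structure(list(
    X = X, lags = lags, rate_hz = rate, n_lags = L,
    feature_names = colnames(Fm),
    zscored = zscore, col_mean = col_mean, col_sd = col_sd,
    trial = features$trial, arm = features$arm,
    epoch = features$epoch, usable = features$usable
  ), class = "lagged_design")
}

#' Closed-form ridge regression
#'
#' Solves `beta = (X'X + lambda I)^-1 X'y` by Cholesky factorization of the
#' regularized Gram matrix (deterministic; no iterative solver).
#'
#' @param X Design matrix (or a `lagged_design`).
#' @param y Response vector or samples x electrodes matrix.
#' @param lambda Nonnegative ridge penalty.
#' @param on_singular What to do when `lambda = 0` and the Gram matrix is not
#'   positive definite: `"error"` (default) or `"pseudoinverse"`.
#' @return Weight vector (or p x electrodes matrix).
#' @export
ridge_solve <- function(X, y, lambda, on_singular = c("error", "pseudoinverse")) {
  on_singular <- match.arg(on_singular)
  if (inherits(X, "lagged_design")) X <- X$X
  stopifnot(lambda >= 0, nrow(X) == NROW(y))
  G <- crossprod(X)
  C <- crossprod(X, y)
  beta <- gram_ridge_solve(G, C, lambda, on_singular)
  if (is.null(dim(y))) beta <- drop(beta)
  beta
}

gram_ridge_solve <- function(G, C, lambda, on_singular = "error") {
  A <- G
  if (lambda > 0) diag(A) <- diag(A) + lambda
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    if (identical(on_singular, "pseudoinverse")) {
      s <- svd(A)
      tol <- max(dim(A)) * max(s$d) * .Machine$double.eps
      pos <- s$d > tol
      return(s$v[, pos, drop = FALSE] %*%
               (t(s$u[, pos, drop = FALSE]) %*% C / s$d[pos]))
    }
    stop("Gram matrix is singular at lambda = 0; set on_singular = \"pseudoinverse\" or use lambda > 0",
         call. = FALSE)
  }
  backsolve(R, forwardsolve(t(R), C))
}

## Per-trial Gram pieces so fold Grams are sums/differences, not repeated
## crossproducts over the full design.
trial_grams <- function(X, Y, trial, trial_ids) {
  idx_of <- split(seq_along(trial), trial)[as.character(trial_ids)]
  G <- lapply(idx_of, function(i) crossprod(X[i, , drop = FALSE]))
  C <- lapply(idx_of, function(i) crossprod(X[i, , drop = FALSE],
                                            Y[i, , drop = FALSE]))
  list(G = G, C = C, idx = idx_of)
}

sum_grams <- function(pieces, ids) {
  ids <- as.character(ids)
  G <- Reduce(`+`, pieces$G[ids])
  C <- Reduce(`+`, pieces$C[ids])
  list(G = G, C = C)
}

cor_cols <- function(pred, obs) {
  ## per-column Pearson correlation; 0 when either side is constant
  r <- suppressWarnings(
    vapply(seq_len(ncol(obs)),
           function(j) stats::cor(pred[, j], obs[, j]), numeric(1)))
  r[!is.finite(r)] <- 0
  r
}

## lambda maximizing r, ties (within 1e-12) broken toward larger lambda;
## `grid` must be ascending.
select_lambda <- function(r, grid) {
  grid[max(which(r >= max(r) - 1e-12))]
}

#' Nested cross-validated ridge encoding fit
#'
#' Fits the kinematic encoding model with fivefold nested cross-validation at
#' trial granularity. The usable trials are shuffled (seeded) into
#' `n_outer` mutually exclusive outer folds. Within each outer estimation set,
#' `n_inner` inner folds select, per electrode, the penalty from
#' `lambda_grid` that maximizes the linear correlation between validation
#' predictions and observed HFA (per inner fold, then the selected penalties
#' are averaged across the inner folds). The model is refit on the full
#' estimation set at that averaged penalty and evaluated on the outer test
#' fold. Prediction performance R^2 is the squared Pearson correlation on
#' each outer test fold, averaged across the five folds.
#'
#' @param design A [build_lagged_design()] (z-scored).
#' @param Y Response matrix samples x electrodes (z-scored HFA) or a vector.
#' @param arm Optional arm label: restricts fitting to that arm's trials.
#' @param n_outer,n_inner Fold counts (default 5/5).
#' @param lambda_grid Ascending ridge penalty grid (default `10^(0:7)`).
#' @param seed Integer seed for the fold shuffles.
#' @return An object of class `encoding_fit`: per-electrode `r2` (mean over
#'   outer folds), `r2_folds`, selected `lambda` per fold, averaged raw-scale
#'   `weights` (electrodes x 4 x n_lags), full-session held-out predictions
#'   `yhat` (NA outside the fitted samples), fold assignments and bookkeeping.
#' @export
nested_cv_fit <- function(design, Y, arm = NULL, n_outer = 5, n_inner = 5,
                          lambda_grid = 10^(0:7), seed = NULL) {
  stopifnot(inherits(design, "lagged_design"), length(lambda_grid) >= 1)
  lambda_grid <- sort(lambda_grid)
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == nrow(design$X))
  keep <- design$usable
  if (!is.null(arm)) keep <- keep & design$arm == arm
  trial_ids <- sort(unique(design$trial[keep]))
  if (length(trial_ids) < n_outer) {
    stop(sprintf("only %d usable trials for %d outer folds",
                 length(trial_ids), n_outer), call. = FALSE)
  }
  X <- design$X
  n_e <- ncol(Y)
  sample_keep <- keep & design$trial %in% trial_ids

  pieces <- trial_grams(X[sample_keep, , drop = FALSE],
                        Y[sample_keep, , drop = FALSE],
                        design$trial[sample_keep], trial_ids)
  ## index maps back into the full session
  full_idx <- split(which(sample_keep), design$trial[sample_keep])

  outer_folds <- split_folds(trial_ids, n_outer, seed = seed)
  r2_folds <- matrix(NA_real_, n_outer, n_e)
  lambda_used <- matrix(NA_real_, n_outer, n_e)
  W_acc <- matrix(0, ncol(X), n_e)
  yhat <- matrix(NA_real_, nrow(Y), n_e)

  for (k in seq_len(n_outer)) {
    test_tr <- outer_folds[[k]]
    est_tr <- setdiff(trial_ids, test_tr)
    est <- sum_grams(pieces, est_tr)
    inner_seed <- if (is.null(seed)) NULL else seed + 1000L * k
    inner_folds <- split_folds(est_tr, n_inner, seed = inner_seed)

    sel <- matrix(NA_real_, n_inner, n_e)
    for (j in seq_len(n_inner)) {
      val_tr <- inner_folds[[j]]
      val <- sum_grams(pieces, val_tr)
      Gtr <- est$G - val$G
      Ctr <- est$C - val$C
      val_idx <- unlist(full_idx[as.character(val_tr)], use.names = FALSE)
      Yv <- Y[val_idx, , drop = FALSE]
      Xv <- X[val_idx, , drop = FALSE]
      rmat <- matrix(NA_real_, length(lambda_grid), n_e)
      for (li in seq_along(lambda_grid)) {
        beta <- gram_ridge_solve(Gtr, Ctr, lambda_grid[li])
        rmat[li, ] <- cor_cols(Xv %*% beta, Yv)
      }
      sel[j, ] <- vapply(seq_len(n_e),
                         function(e) select_lambda(rmat[, e], lambda_grid),
                         numeric(1))
    }
    lam_bar <- colMeans(sel)
    lambda_used[k, ] <- lam_bar

    test_idx <- unlist(full_idx[as.character(test_tr)], use.names = FALSE)
    Xt <- X[test_idx, , drop = FALSE]
    Yt <- Y[test_idx, , drop = FALSE]
    for (lam in unique(lam_bar)) {
      cols <- which(lam_bar == lam)
      beta <- gram_ridge_solve(est$G, est$C[, cols, drop = FALSE], lam)
      W_acc[, cols] <- W_acc[, cols] + beta
      pred <- Xt %*% beta
      yhat[test_idx, cols] <- pred
      r2_folds[k, cols] <- cor_cols(pred, Yt[, cols, drop = FALSE])^2
    }
  }

  ## average weights over folds; report both the standardized-design scale
  ## (the space the model is fit in) and the raw feature scale
  W_bar <- W_acc / n_outer
  W_raw <- W_bar / design$col_sd
  L <- design$n_lags
  weights <- array(NA_real_, c(n_e, 4L, L),
                   dimnames = list(NULL, design$feature_names, NULL))
  weights_std <- weights
  for (f in 1:4) {
    block <- ((f - 1) * L + 1):(f * L)
    weights[, f, ] <- t(W_raw[block, , drop = FALSE])
    weights_std[, f, ] <- t(W_bar[block, , drop = FALSE])
  }

  structure(list(
    r2 = colMeans(r2_folds), r2_folds = r2_folds,
    lambda = lambda_used, weights = weights, weights_std = weights_std,
    yhat = yhat, outer_folds = outer_folds,
    trial = design$trial, epoch = design$epoch,
    sample_keep = sample_keep, arm = arm,
    lags = design$lags, rate_hz = design$rate_hz,
    lambda_grid = lambda_grid, seed = seed
  ), class = "encoding_fit")
}

#' Across-arm generalization fit
#'
#' Trains the encoding model on one arm and evaluates it on held-out
#' partitions of the other arm's data: the training arm is split into five
#' 80% estimation sets (the same outer structure as the within-arm fit, with
#' the penalty chosen by inner fivefold cross-validation on each estimation
#' set); each estimation set's model predicts one of five mutually exclusive
#' 20% test partitions of the *test arm's* trials. R^2 is the squared
#' correlation per test partition, averaged over the five partitions.
#'
#' @param design A [build_lagged_design()] covering both arms' samples.
#' @param Y Response matrix samples x electrodes.
#' @param train_arm,test_arm Arm labels; must differ.
#' @inheritParams nested_cv_fit
#' @return An `encoding_fit` whose `r2` is the across-arm R^2 and whose
#'   `yhat` holds predictions over the test arm's samples.
#' @export
across_arm_fit <- function(design, Y, train_arm, test_arm, n_outer = 5,
                           n_inner = 5, lambda_grid = 10^(0:7), seed = NULL) {
  if (identical(train_arm, test_arm)) {
    stop("train and test arms must differ", call. = FALSE)
  }
  stopifnot(inherits(design, "lagged_design"))
  lambda_grid <- sort(lambda_grid)
  Y <- as.matrix(Y)
  X <- design$X
  n_e <- ncol(Y)

  keep_tr <- design$usable & design$arm == train_arm
  keep_te <- design$usable & design$arm == test_arm
  train_trials <- sort(unique(design$trial[keep_tr]))
  test_trials <- sort(unique(design$trial[keep_te]))
  if (length(train_trials) < n_outer || length(test_trials) < n_outer) {
    stop("fewer trials than folds in one of the arms", call. = FALSE)
  }

  pieces <- trial_grams(X[keep_tr, , drop = FALSE], Y[keep_tr, , drop = FALSE],
                        design$trial[keep_tr], train_trials)
  full_idx_tr <- split(which(keep_tr), design$trial[keep_tr])
  full_idx_te <- split(which(keep_te), design$trial[keep_te])

  outer_tr <- split_folds(train_trials, n_outer, seed = seed)
  outer_te <- split_folds(test_trials, n_outer,
                          seed = if (is.null(seed)) NULL else seed + 77L)
  r2_folds <- matrix(NA_real_, n_outer, n_e)
  lambda_used <- matrix(NA_real_, n_outer, n_e)
  W_acc <- matrix(0, ncol(X), n_e)
  yhat <- matrix(NA_real_, nrow(Y), n_e)

  for (k in seq_len(n_outer)) {
    est_tr <- setdiff(train_trials, outer_tr[[k]])
    est <- sum_grams(pieces, est_tr)
    inner_seed <- if (is.null(seed)) NULL else seed + 1000L * k
    inner_folds <- split_folds(est_tr, n_inner, seed = inner_seed)
    sel <- matrix(NA_real_, n_inner, n_e)
    for (j in seq_len(n_inner)) {
      val_tr <- inner_folds[[j]]
      val <- sum_grams(pieces, val_tr)
      Gtr <- est$G - val$G
      Ctr <- est$C - val$C
      val_idx <- unlist(full_idx_tr[as.character(val_tr)], use.names = FALSE)
      Yv <- Y[val_idx, , drop = FALSE]
      Xv <- X[val_idx, , drop = FALSE]
      rmat <- matrix(NA_real_, length(lambda_grid), n_e)
      for (li in seq_along(lambda_grid)) {
        beta <- gram_ridge_solve(Gtr, Ctr, lambda_grid[li])
        rmat[li, ] <- cor_cols(Xv %*% beta, Yv)
      }
      sel[j, ] <- vapply(seq_len(n_e),
                         function(e) select_lambda(rmat[, e], lambda_grid),
                         numeric(1))
    }
    lam_bar <- colMeans(sel)
    lambda_used[k, ] <- lam_bar

    test_idx <- unlist(full_idx_te[as.character(outer_te[[k]])], use.names = FALSE)
    Xt <- X[test_idx, , drop = FALSE]
    Yt <- Y[test_idx, , drop = FALSE]
    for (lam in unique(lam_bar)) {
      cols <- which(lam_bar == lam)
      beta <- gram_ridge_solve(est$G, est$C[, cols, drop = FALSE], lam)
      W_acc[, cols] <- W_acc[, cols] + beta
      pred <- Xt %*% beta
      yhat[test_idx, cols] <- pred
      r2_folds[k, cols] <- cor_cols(pred, Yt[, cols, drop = FALSE])^2
    }
  }

  W_bar <- W_acc / n_outer
  W_raw <- W_bar / design$col_sd
  L <- design$n_lags
  weights <- array(NA_real_, c(n_e, 4L, L),
                   dimnames = list(NULL, design$feature_names, NULL))
  weights_std <- weights
  for (f in 1:4) {
    block <- ((f - 1) * L + 1):(f * L)
    weights[, f, ] <- t(W_raw[block, , drop = FALSE])
    weights_std[, f, ] <- t(W_bar[block, , drop = FALSE])
  }

  structure(list(
    r2 = colMeans(r2_folds), r2_folds = r2_folds,
    lambda = lambda_used, weights = weights, weights_std = weights_std,
    yhat = yhat, outer_folds = outer_te,
    trial = design$trial, epoch = design$epoch,
    sample_keep = keep_te, arm = test_arm, train_arm = train_arm,
    lags = design$lags, rate_hz = design$rate_hz,
    lambda_grid = lambda_grid, seed = seed
  ), class = "encoding_fit")
}

#' Task-phase prediction scores
#'
#' Splits held-out predictions into the instruction (cue onset to movement
#' onset) and movement (movement onset to return press) phases and scores
#' each phase as the squared Pearson correlation between the concatenated
#' observed and predicted segments. When fold assignments are supplied the
#' score is computed per outer fold and averaged, matching the overall R^2
#' convention; an empty phase yields `NA` with a warning.
#'
#' @param y,yhat Observed and predicted series (equal length; `yhat` may
#'   contain NA outside the scored samples).
#' @param epoch Per-sample factor with levels `iti`, `instruction`,
#'   `movement`.
#' @param folds Optional list of per-fold sample indices.
#' @return Named list with `instruction` and `movement` R^2.
#' @export
epoch_scores <- function(y, yhat, epoch, folds = NULL) {
  stopifnot(length(y) == length(yhat), length(epoch) == length(y))
  score_one <- function(idx, phase) {
    sel <- idx[epoch[idx] == phase & !is.na(yhat[idx])]
    if (length(sel) < 3) return(NA_real_)
    r <- suppressWarnings(stats::cor(y[sel], yhat[sel]))
    if (!is.finite(r)) return(NA_real_)
    r^2
  }
  phases <- c("instruction", "movement")
  out <- lapply(phases, function(ph) {
    if (is.null(folds)) {
      score_one(seq_along(y), ph)
    } else {
      mean(vapply(folds, score_one, numeric(1), phase = ph), na.rm = TRUE)
    }
  })
  names(out) <- phases
  if (any(vapply(out, is.nan, logical(1))) || any(is.na(unlist(out)))) {
    warning("a task phase had too few scored samples; score flagged NA",
            call. = FALSE)
  }
  out
}

#' Signal-power-normalized prediction correlation (CC_norm)
#'
#' From N time-aligned repeated trials, signal power is
#' `SP = (Var(sum_n R_n) - sum_n Var(R_n)) / (N (N - 1))` (variances over
#' time), the trial-repeatable part of the response variance.
#' `CC_abs` is the Pearson correlation between the trial-averaged response
#' and the prediction, and
#' `CC_norm = Cov(ybar, yhat) / sqrt(Var(yhat) * SP)` normalizes that
#' correlation by the explainable ceiling. A nonpositive SP estimate (noise
#' dominated) flags CC_norm as undefined.
#'
#' @param trial_stack N x T matrix of time-aligned responses (N >= 2 trials).
#' @param prediction Length-T prediction.
#' @return List with `cc_abs`, `cc_norm`, `sp` and logical `flagged`.
#' @export
cc_norm <- function(trial_stack, prediction) {
  trial_stack <- as.matrix(trial_stack)
  N <- nrow(trial_stack)
  stopifnot(N >= 2, ncol(trial_stack) == length(prediction))
  Rsum <- colSums(trial_stack)
  sp <- (stats::var(Rsum) - sum(apply(trial_stack, 1, stats::var))) /
    (N * (N - 1))
  ybar <- Rsum / N
  cc_abs <- stats::cor(ybar, prediction)
  if (!is.finite(sp) || sp <= 0) {
    return(list(cc_abs = cc_abs, cc_norm = NA_real_, sp = sp, flagged = TRUE))
  }
  ccn <- stats::cov(ybar, prediction) /
    sqrt(stats::var(prediction) * sp)
  list(cc_abs = cc_abs, cc_norm = ccn, sp = sp, flagged = FALSE)
}

#' Stack a per-electrode series into time-aligned trials
#'
#' @param x Length-S series at `fs` Hz.
#' @param fs Sampling rate (Hz).
#' @param onsets_s Alignment times (s), one per trial.
#' @param window Length-2 window around each onset (s).
#' @return N x T matrix (trials dropped if the window exceeds the series).
#' @export
stack_trials <- function(x, fs, onsets_s, window) {
  offs <- seq(round(window[1] * fs), round(window[2] * fs))
  rows <- lapply(onsets_s, function(t0) {
    idx <- round(t0 * fs) + 1L + offs
    if (min(idx) < 1 || max(idx) > length(x)) return(NULL)
    x[idx]
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
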