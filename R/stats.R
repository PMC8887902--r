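permutation_result <- function(observed, null, p, n_perm, seed, details = list()) {
  structure(c(list(observed = observed, null = null, p = p,
                   n_perm = n_perm, seed = seed), details),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed = %.4g, p = %.4g (n_perm = %d)\n",
              x$observed, x$p, x$n_perm))
  invisible(x)
}

#' Sign-flip permutation test on per-electrode scores
#'
#' Tests whether the mean of a vector of electrode scores (for example
#' contralateral-minus-ipsilateral difference scores) differs from zero. The
#' null distribution flips the sign of each electrode's score independently;
#' the two-sided p-value uses the add-one correction
#' `p = (b + 1) / (n_perm + 1)` and is therefore never exactly zero.
#'
#' @param scores Numeric vector (>= 5 electrodes).
#' @param n_perm Number of permutations (warning below 100).
#' @param seed Integer seed.
#' @return A `permutation_result`.
#' @export
sign_flip_test <- function(scores, n_perm = 1000, seed = NULL) {
  if (length(scores) < 5) stop("need at least 5 electrodes", call. = FALSE)
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value", call. = FALSE)
  obs <- mean(scores)
  null <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * length(scores), replace = TRUE),
                n_perm)
    as.numeric(S %*% scores) / length(scores)
  })
  p <- (sum(abs(null) >= abs(obs)) + 1) / (n_perm + 1)
  permutation_result(obs, null, p, n_perm, seed)
}

#' Participant-blocked permutation test
#'
#' Approximates a mixed-effects comparison with participant as the random
#' effect by permuting at the level at which observations are exchangeable:
#'
#' * `design = "paired"` (a within-participant factor such as reaching arm):
#'   the statistic is the mean over participants of the per-participant
#'   condition difference; the null flips the sign of each participant's
#'   difference.
#' * `design = "between"` (a between-participant factor such as hemisphere):
#'   the statistic is the difference of group means of per-participant
#'   averages; the null permutes the participant-to-group assignment.
#' * `design = "interaction"` (within x between): the statistic is the
#'   between-group difference of the per-participant within-factor
#'   differences (a difference of differences); the null permutes the
#'   participant-to-group assignment.
#'
#' This is an approximation to a permuted nested-model comparison, not a
#' replication of it: it preserves the participant exchangeability structure
#' with transparent mechanics. Note the null for between-participant factors
#' is supported on the participant assignments only, so very small cohorts
#' give coarse p-values.
#'
#' @param values Numeric vector of electrode-level values.
#' @param condition Within-participant condition label per value (two levels;
#'   required for `paired` and `interaction`).
#' @param participant Participant label per value.
#' @param group Between-participant group label per value (two levels;
#'   required for `between` and `interaction`).
#' @param design `"paired"`, `"between"` or `"interaction"`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A `permutation_result` with the per-participant summaries attached.
#' @export
block_permutation_test <- function(values, condition = NULL, participant,
                                   group = NULL,
                                   design = c("paired", "between", "interaction"),
                                   n_perm = 1000, seed = NULL) {
  design <- match.arg(design)
  participant <- as.character(participant)
  parts <- unique(participant)

  per_part_diff <- function() {
    lv <- sort(unique(as.character(condition)))
    if (length(lv) != 2) stop("condition must have exactly 2 levels", call. = FALSE)
    vapply(parts, function(p) {
      sel <- participant == p
      a <- values[sel & condition == lv[1]]
      b <- values[sel & condition == lv[2]]
      if (length(a) == 0 || length(b) == 0) {
        stop(sprintf("participant %s lacks one condition; design unpermutable", p),
             call. = FALSE)
      }
      mean(a) - mean(b)
    }, numeric(1))
  }

  part_group <- function() {
    g <- vapply(parts, function(p) {
      gg <- unique(as.character(group[participant == p]))
      if (length(gg) != 1) {
        stop("each participant must belong to exactly one group", call. = FALSE)
      }
      gg
    }, character(1))
    lv <- sort(unique(g))
    if (length(lv) != 2 || min(table(g)) < 2) {
      stop("between-participant permutation needs 2 groups with >= 2 participants each",
           call. = FALSE)
    }
    list(g = g, levels = lv)
  }

  if (design == "paired") {
    d <- per_part_diff()
    obs <- mean(d)
    null <- with_seed(seed, {
      S <- matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE), n_perm)
      as.numeric(S %*% d) / length(d)
    })
    p <- (sum(abs(null) >= abs(obs)) + 1) / (n_perm + 1)
    return(permutation_result(obs, null, p, n_perm, seed,
                              list(design = design, participant_effects = d)))
  }

  summaries <- if (design == "between") {
    vapply(parts, function(p) mean(values[participant == p]), numeric(1))
  } else {
    per_part_diff()
  }
  pg <- part_group()
  g <- pg$g; lv <- pg$levels
  stat_fun <- function(gg) {
    mean(summaries[gg == lv[1]]) - mean(summaries[gg == lv[2]])
  }
  obs <- stat_fun(g)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat_fun(sample(g)), numeric(1))
  })
  p <- (sum(abs(null) >= abs(obs)) + 1) / (n_perm + 1)
  permutation_result(obs, null, p, n_perm, seed,
                     list(design = design, participant_effects = summaries,
                          groups = g))
}

#' Cluster-based permutation test on paired time series
#'
#' Compares two paired conditions (electrodes x time) pointwise with paired
#' t statistics, forms clusters as maximal contiguous runs whose |t| exceeds
#' the two-sided cluster-forming threshold (`threshold_p` under the t
#' distribution), and scores each cluster by its summed t (mass). The null
#' distribution of the maximum absolute cluster mass is built by flipping
#' each electrode's condition labels, which controls the familywise error
#' over time points.
#'
#' @param groupA,groupB Electrodes x time matrices, paired by row.
#' @param threshold_p Two-sided cluster-forming p threshold (default 0.05).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List of class `cluster_result`: tibble `clusters`
#'   (`start`, `end`, `mass`, `p`), the t series, threshold and null maxima.
#' @export
cluster_permutation_timeseries <- function(groupA, groupB, threshold_p = 0.05,
                                           n_perm = 1000, seed = NULL) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  stopifnot(dim(groupA) == dim(groupB))
  Tn <- ncol(groupA)
  if (Tn < 3) stop("need at least 3 time points", call. = FALSE)
  E <- nrow(groupA)
  D <- groupA - groupB
  thresh <- stats::qt(1 - threshold_p / 2, df = E - 1)

  t_series <- paired_t_cols(colMeans(D), colSums(D^2), E)
  obs_clusters <- find_clusters(t_series, thresh)

  null_max <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * E, replace = TRUE), n_perm)
    M <- S %*% D / E
    SSq <- colSums(D^2) # invariant under sign flips
    vapply(seq_len(n_perm), function(i) {
      max_cluster_mass(paired_t_cols(M[i, ], SSq, E), thresh)
    }, numeric(1))
  })

  if (nrow(obs_clusters) > 0) {
    obs_clusters$p <- vapply(obs_clusters$mass, function(m) {
      (sum(null_max >= abs(m)) + 1) / (n_perm + 1)
    }, numeric(1))
  } else {
    obs_clusters$p <- numeric(0)
  }
  structure(list(clusters = obs_clusters, t = t_series, threshold = thresh,
                 threshold_p = threshold_p, null_max = null_max,
                 n_perm = n_perm, seed = seed),
            class = "cluster_result")
}

## paired t per column from column means and (flip-invariant) sums of squares
paired_t_cols <- function(m, ssq, n) {
  v <- (ssq - n * m^2) / (n - 1)
  t <- m / sqrt(v / n)
  t[!is.finite(t)] <- 0
  t
}

## max |summed t| over suprathreshold runs, allocation-light for the null loop
max_cluster_mass <- function(t_series, thresh) {
  lab <- ifelse(abs(t_series) > thresh, sign(t_series), 0)
  r <- rle(lab)
  if (all(r$values == 0)) return(0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values != 0)
  max(vapply(keep, function(i) abs(sum(t_series[starts[i]:ends[i]])), numeric(1)))
}

find_clusters <- function(t_series, thresh) {
  above <- abs(t_series) > thresh
  ## split runs where the sign changes so clusters are one-signed
  sgn <- sign(t_series)
  runs <- rle(ifelse(above, sgn, 0))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values != 0
  tibble::tibble(
    start = starts[keep], end = ends[keep],
    mass = vapply(which(keep),
                  function(i) sum(t_series[starts[i]:ends[i]]), numeric(1))
  )
}
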