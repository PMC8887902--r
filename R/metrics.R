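#' Modulation depth of target tuning
#'
#' Population standard deviation (divide by n, not n - 1) of the per-target
#' mean HFA predictions: `MD = sqrt(sum_i (x_i - xbar)^2 / n)`.
#'
#' @param target_means Mean prediction per target (n >= 2).
#' @return MD (nonnegative scalar).
#' @export
modulation_depth <- function(target_means) {
  n <- length(target_means)
  if (n < 2) stop("modulation depth needs at least 2 targets", call. = FALSE)
  sqrt(sum((target_means - mean(target_means))^2) / n)
}

#' Across-arm tuning similarity index
#'
#' For each electrode, the sum of squared differences between the two arms'
#' mean predictions for the shared (central) targets,
#' `SSE_e = sum_i (contra_i - ipsi_i)^2`, is min-max scaled over electrodes
#' and inverted: `SI = 1 - (SSE_e - min SSE) / (max SSE - min SSE)`. SI = 1
#' marks the most similar tuning in the population, SI = 0 the least.
#'
#' @param contra_means,ipsi_means Electrodes x targets matrices of mean
#'   predictions per target.
#' @param shared_targets Column indices of the targets common to both arms
#'   (default the first two, the central pair).
#' @return List with per-electrode `sse`, `si`, and logical `flagged`
#'   (TRUE when all SSE are identical so the scaling is undefined).
#' @export
tuning_similarity <- function(contra_means, ipsi_means, shared_targets = 1:2) {
  contra_means <- as.matrix(contra_means)
  ipsi_means <- as.matrix(ipsi_means)
  stopifnot(dim(contra_means) == dim(ipsi_means))
  if (nrow(contra_means) < 2) {
    stop("tuning similarity needs at least 2 electrodes for min-max scaling",
         call. = FALSE)
  }
  d <- contra_means[, shared_targets, drop = FALSE] -
    ipsi_means[, shared_targets, drop = FALSE]
  sse <- rowSums(d^2)
  rng <- range(sse)
  if (diff(rng) == 0) {
    return(list(sse = sse, si = rep(NA_real_, length(sse)), flagged = TRUE))
  }
  si <- 1 - (sse - rng[1]) / diff(rng)
  list(sse = sse, si = si, flagged = FALSE)
}

#' Classify across-arm generalization
#'
#' The generalization index is the ratio of across-arm to within-arm R^2.
#' Electrodes keeping more than 80% of their within-arm performance
#' (index > 0.80, a decrease of up to 20%) generalize well; electrodes losing
#' more than half (index < 0.50) generalize poorly; the rest are
#' intermediate.
#'
#' @param r2_within,r2_across Vectors of within- and across-arm R^2.
#' @return Tibble with `r2_within`, `r2_across`, `index` and `class`
#'   (`good`/`intermediate`/`poor`; `NA` where `r2_within <= 0`).
#' @export
classify_generalization <- function(r2_within, r2_across) {
  stopifnot(length(r2_within) == length(r2_across))
  index <- ifelse(r2_within > 0, r2_across / r2_within, NA_real_)
  cls <- ifelse(is.na(index), NA_character_,
                ifelse(index > 0.80, "good",
                       ifelse(index < 0.50, "poor", "intermediate")))
  if (any(is.na(index))) {
    warning("generalization index undefined where within-arm R^2 <= 0",
            call. = FALSE)
  }
  tibble::tibble(r2_within = r2_within, r2_across = r2_across,
                 index = index,
                 class = factor(cls, levels = c("good", "intermediate", "poor")))
}

#' Relative contribution of each kinematic feature
#'
#' Sums the absolute weights across time lags per feature and normalizes by
#' the total absolute weight mass, giving proportions that sum to 1.
#'
#' @param weights 4 x n_lags weight matrix (features in rows), or an
#'   electrodes x 4 x n_lags array (averaged over electrodes first).
#' @return Named length-4 vector of proportions (`NA` if all weights are 0).
#' @export
feature_contribution <- function(weights) {
  if (length(dim(weights)) == 3) {
    weights <- apply(weights, c(2, 3), mean)
  }
  stopifnot(nrow(weights) == 4)
  mass <- rowSums(abs(weights))
  total <- sum(mass)
  if (total == 0) {
    warning("all weights are zero; feature contributions undefined", call. = FALSE)
    return(stats::setNames(rep(NA_real_, 4),
                           rownames(weights) %||% c("z_position", "z_speed", "theta", "phi")))
  }
  stats::setNames(mass / total,
                  rownames(weights) %||% c("z_position", "z_speed", "theta", "phi"))
}

#' Lagged cross-correlation between HFA and a kinematic trace
#'
#' Pearson correlation on the overlapping segment at every integer-sample lag
#' within `max_lag_s`. Positive lags mean the neural series leads the
#' kinematic series: `r(k) = cor(hfa(t), kin(t + k))`, so a kinematic trace
#' that is a delayed copy of the HFA peaks at a positive lag equal to the
#' delay.
#'
#' @param hfa,kin Equal-length series time-locked to movement onset.
#' @param rate_hz Sampling rate (Hz).
#' @param max_lag_s Maximum absolute lag (s).
#' @return List with `lag_s`, `lag_ms`, `r` at the best lag, and the full
#'   `lags`/`r_all` profile.
#' @export
cross_correlate <- function(hfa, kin, rate_hz, max_lag_s = 0.5) {
  stopifnot(length(hfa) == length(kin))
  if (stats::sd(hfa) == 0 || stats::sd(kin) == 0) {
    stop("cross-correlation undefined for a constant series", call. = FALSE)
  }
  n <- length(hfa)
  L <- round(max_lag_s * rate_hz)
  ks <- seq(-L, L)
  r <- vapply(ks, function(k) {
    if (k >= 0) {
      a <- hfa[seq_len(n - k)]; b <- kin[seq_len(n - k) + k]
    } else {
      a <- hfa[seq_len(n + k) - k]; b <- kin[seq_len(n + k)]
    }
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  best <- which.max(r)
  list(lag_s = ks[best] / rate_hz, lag_ms = 1000 * ks[best] / rate_hz,
       r = r[best], lags = ks / rate_hz, r_all = r)
}

#' Distance from an electrode to the dorsal central sulcus
#'
#' The demarcated sulcus coordinates are treated as a polyline; its
#' arc-length midpoint splits it into two halves, and the dorsal half is the
#' one whose far endpoint has the larger y (dorsal) coordinate. The distance
#' is the minimum Euclidean distance from the electrode to any point of the
#' dorsal sub-polyline (exact point-to-segment geometry).
#'
#' @param electrode_xy Length-2 electrode coordinate.
#' @param cs_points n x 2 matrix of sulcus coordinates in order (n >= 2).
#' @return Distance (same units as the coordinates).
#' @export
distance_to_dorsal_cs <- function(electrode_xy, cs_points) {
  cs_points <- as.matrix(cs_points)
  if (nrow(cs_points) < 2) {
    stop("need at least 2 sulcus points to form a polyline", call. = FALSE)
  }
  seg <- diff(cs_points)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  s_mid <- cum[length(cum)] / 2
  i <- findInterval(s_mid, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(cs_points) - 1L)
  frac <- if (len[i] > 0) (s_mid - cum[i]) / len[i] else 0
  M <- cs_points[i, ] + frac * seg[i, ]

  first_half <- rbind(cs_points[seq_len(i), , drop = FALSE], M)
  second_half <- rbind(M, cs_points[(i + 1):nrow(cs_points), , drop = FALSE])
  dorsal <- if (cs_points[1, 2] >= cs_points[nrow(cs_points), 2]) first_half
            else second_half

  p <- as.numeric(electrode_xy)
  dmin <- Inf
  for (j in seq_len(nrow(dorsal) - 1)) {
    dmin <- min(dmin, point_segment_distance(p, dorsal[j, ], dorsal[j + 1, ]))
  }
  dmin
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  denom <- sum(ab^2)
  t <- if (denom == 0) 0 else max(0, min(1, sum((p - a) * ab) / denom))
  sqrt(sum((a + t * ab - p)^2))
}

#' Contralateral-minus-ipsilateral encoding difference score
#'
#' A per-electrode proxy of encoding bias between the arms: positive values
#' mean stronger contralateral encoding.
#'
#' @param r2_contra,r2_ipsi Within-arm R^2 for the two arms.
#' @return `r2_contra - r2_ipsi` (vectorized).
#' @export
difference_score <- function(r2_contra, r2_ipsi) {
  r2_contra - r2_ipsi
}
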