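#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
## caller's RNG afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

## Convert a (mean, sd) pair on the natural scale to lognormal parameters.
lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(c(meanlog = log(mean), sdlog = 0))
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

rlnorm_ms <- function(n, mean, sd) {
  p <- lognormal_params(mean, sd)
  stats::rlnorm(n, meanlog = p["meanlog"], sdlog = p["sdlog"])
}

## Near-equal split of `ids` into `k` folds after a seeded shuffle.
split_folds <- function(ids, k, seed = NULL) {
  if (length(ids) < k) {
    stop(sprintf("cannot split %d trials into %d folds", length(ids), k),
         call. = FALSE)
  }
  shuffled <- with_seed(seed, sample(ids))
  split(shuffled, rep_len(seq_len(k), length(shuffled)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
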