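# Independent oracles, deliberately written without reusing package internals.

# Benjamini-Hochberg by exhaustive threshold search: try every observed p as
# the cutoff and keep the largest satisfying the step-up inequality.
oracle_bh_reject <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k_star <- 0L
  for (k in seq_len(m)) if (ps[k] <= k / m * alpha) k_star <- k
  rejected <- rep(FALSE, m)
  if (k_star > 0L) rejected[ord[seq_len(k_star)]] <- TRUE
  rejected
}

oracle_bh_q <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(m * ps[i:m] / (i:m), 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# exhaustive circular lag scan; max |r| with sign, ties to smallest |lag|
# then negative lag
oracle_max_lag <- function(x, y, dt_s, max_lag_s) {
  L <- round(max_lag_s / dt_s)
  n <- length(x)
  best <- NULL
  for (l in (-L):L) {
    idx <- ((seq_len(n) - 1 + l) %% n) + 1   # y advanced by l samples
    r <- stats::cor(x, y[idx])
    better <- is.null(best) ||
      abs(r) > abs(best$r) ||
      (abs(r) == abs(best$r) &&
         (abs(l * dt_s) < abs(best$lag_s) ||
            (abs(l * dt_s) == abs(best$lag_s) && l * dt_s < best$lag_s)))
    if (better) best <- list(r = r, lag_s = l * dt_s)
  }
  best
}

# band-limited test signal on a dt grid (independent of the generator:
# sum of random sinusoids inside the band)
oracle_band_signal <- function(n, dt_s, low_hz = 0.01, high_hz = 0.1,
                               n_tones = 12) {
  f <- stats::runif(n_tones, low_hz, high_hz)
  ph <- stats::runif(n_tones, 0, 2 * pi)
  a <- stats::rnorm(n_tones)
  t <- (seq_len(n) - 1) * dt_s
  x <- numeric(n)
  for (j in seq_len(n_tones)) x <- x + a[j] * sin(2 * pi * f[j] * t + ph[j])
  as.numeric(scale(x))
}

# independent circular delay (out[t] = x[t - k]) by modular indexing
circ_shift_oracle <- function(x, k) {
  n <- length(x)
  x[((seq_len(n) - 1 - k) %% n) + 1]
}

# brute-force voxel count inside a sphere, plain triple loop
oracle_sphere_count <- function(shape, radius) {
  ctr <- (shape + 1) / 2
  cnt <- 0L
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
    for (k in seq_len(shape[3]))
      if (sqrt(sum((c(i, j, k) - ctr)^2)) <= radius) cnt <- cnt + 1L
  cnt
}

# Laplace sources for ICA recovery checks
laplace_sources <- function(k, n) {
  matrix(ifelse(stats::runif(k * n) < 0.5, 1, -1) * stats::rexp(k * n), k, n)
}

# greedy matched minimum |correlation| between estimated and true sources
min_matched_cor <- function(est, truth) {
  min(abs(match_components(est, truth)$correlation))
}
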