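#' Spectral profile and high-frequency power fraction of a time course
#'
#' Raw periodogram of the demeaned series. `high_freq_fraction` is the share
#' of total (non-DC) power at frequencies above `cutoff_hz`; resting-state
#' components concentrate power below 0.1 Hz, so a large fraction marks a
#' likely artifact. Power is normalized so it sums to the population
#' variance of the series (Parseval).
#'
#' @param tc numeric time series (>= 8 points).
#' @param tr_s sampling interval, seconds.
#' @param cutoff_hz high-frequency cutoff (default 0.1 Hz).
#' @return A `spectral_profile` list: `freqs` (Hz), `power`,
#'   `high_freq_fraction`.
#' @export
spectral_fraction <- function(tc, tr_s, cutoff_hz = 0.1) {
  n <- length(tc)
  if (n < 8L) stop("need at least 8 time points", call. = FALSE)
  nyq <- 1 / (2 * tr_s)
  if (nyq <= cutoff_hz)
    stop(sprintf("Nyquist %g Hz is not above the %g Hz cutoff; TR too long",
                 nyq, cutoff_hz), call. = FALSE)
  x <- tc - mean(tc)
  xf <- stats::fft(x)
  k <- seq_len(n - 1L)                       # DC excluded
  power <- Mod(xf[k + 1L])^2 / n^2
  freqs <- pmin(k, n - k) / (n * tr_s)
  total <- sum(power)
  if (total <= 0) stop("zero-variance time course", call. = FALSE)
  structure(list(freqs = freqs, power = power,
                 high_freq_fraction = sum(power[freqs > cutoff_hz]) / total),
            class = "spectral_profile")
}

#' Select resting-state-like components by spectral power
#'
#' A component is discarded when the median across subjects of its
#' high-frequency power fraction exceeds `threshold` (strictly greater, so a
#' fraction of exactly 0.5 is kept). Visual inspection of the spatial maps
#' is not automated; `override_discard` / `override_keep` provide the manual
#' escape hatch and are recorded in the report.
#'
#' @param subject_tcs list of time x K subject time-course matrices.
#' @param tr_s sampling interval, seconds.
#' @param cutoff_hz spectral cutoff (default 0.1 Hz).
#' @param threshold discard when median fraction > threshold (default 0.5).
#' @param override_discard,override_keep integer component ids forced out/in.
#' @return List: `kept` (integer ids), `report` (data.frame: component,
#'   median_fraction, keep, overridden).
#' @export
select_components <- function(subject_tcs, tr_s, cutoff_hz = 0.1,
                              threshold = 0.5, override_discard = NULL,
                              override_keep = NULL) {
  if (!length(subject_tcs)) stop("no subject time courses", call. = FALSE)
  K <- ncol(subject_tcs[[1]])
  if (K < 1L) stop("need at least one component", call. = FALSE)
  frac <- sapply(subject_tcs, function(tc)
    vapply(seq_len(K), function(k)
      spectral_fraction(tc[, k], tr_s, cutoff_hz)$high_freq_fraction,
      numeric(1)))
  med <- apply(matrix(frac, nrow = K), 1L, stats::median)
  keep <- med <= threshold
  overridden <- rep(FALSE, K)
  if (length(override_discard)) {
    overridden[override_discard] <- keep[override_discard]
    keep[override_discard] <- FALSE
  }
  if (length(override_keep)) {
    overridden[override_keep] <- overridden[override_keep] | !keep[override_keep]
    keep[override_keep] <- TRUE
  }
  if (!any(keep))
    stop("all components discarded; inspect spectra and overrides",
         call. = FALSE)
  list(kept = which(keep),
       report = data.frame(component = seq_len(K), median_fraction = med,
                           keep = keep, overridden = overridden))
}
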