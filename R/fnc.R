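#' Interpolate a time course onto a finer uniform grid
#'
#' Cubic-spline interpolation onto a `target_dt_s` grid spanning the
#' original duration, enabling detection of sub-TR lag differences. If the
#' series is already sampled at or below `target_dt_s` it is returned
#' unchanged with a warning.
#'
#' @param tc numeric time series.
#' @param tr_s original sampling interval, seconds.
#' @param target_dt_s target grid spacing, seconds (default 1).
#' @return Numeric series on the target grid; attribute `dt_s` records the
#'   spacing.
#' @export
interpolate_tc <- function(tc, tr_s, target_dt_s = 1) {
  if (tr_s <= target_dt_s) {
    warning("series already at or below the target grid; returning unchanged")
    return(structure(tc, dt_s = tr_s))
  }
  n <- length(tc)
  times <- (seq_len(n) - 1) * tr_s
  xout <- seq(0, times[n], by = target_dt_s)
  structure(stats::spline(times, tc, xout = xout, method = "fmm")$y,
            dt_s = target_dt_s)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-5 Butterworth applied forwards and backwards
#' ([signal::filtfilt()]), then the mean is removed.
#'
#' @param tc numeric series.
#' @param dt_s sampling interval, seconds.
#' @param low_hz,high_hz passband edges (default 0.01-0.1 Hz).
#' @return Filtered, demeaned series.
#' @export
bandpass <- function(tc, dt_s, low_hz = 0.01, high_hz = 0.1) {
  y <- butter_bandpass(tc, dt_s, low_hz, high_hz)
  y - mean(y)
}

#' Constrained maximal time-lagged correlation of two time courses
#'
#' Pearson correlation of `tc_i` with `tc_j` circularly shifted by every
#' integer multiple of `dt_s` in `[-max_lag_s, +max_lag_s]` (11 lags for a
#' 1 s grid and a 5 s window). Returns the coefficient of maximal absolute
#' value with its sign, and the lag at which it occurred. A positive lag
#' means `tc_j` lags `tc_i`. Ties go to the smaller |lag|, then to the
#' negative lag.
#'
#' @param tc_i,tc_j equal-length numeric series.
#' @param dt_s grid spacing, seconds (default 1).
#' @param max_lag_s half-width of the lag window, seconds (default 5).
#' @return List: `r` (signed maximal correlation), `lag_s`, `lags_s` (the
#'   grid), `r_all` (correlation at each lag), `n_lags`.
#' @export
max_lagged_corr <- function(tc_i, tc_j, dt_s = 1, max_lag_s = 5) {
  nl <- as.integer(round(max_lag_s / dt_s))
  n <- length(tc_i)
  if (length(tc_j) != n) stop("series lengths differ", call. = FALSE)
  if (n < 2L * nl)
    stop("series too short for the requested lag window", call. = FALSE)
  if (stats::sd(tc_i) < 1e-14 || stats::sd(tc_j) < 1e-14)
    stop("zero-variance time course", call. = FALSE)
  lags <- (-nl):nl
  r_all <- vapply(lags, function(l)
    stats::cor(tc_i, circ_shift(tc_j, -l)), numeric(1))
  ord <- order(abs(lags), lags)          # 0, -1, 1, -2, 2, ...
  best <- ord[1L]
  for (o in ord[-1L]) if (abs(r_all[o]) > abs(r_all[best])) best <- o
  list(r = r_all[best], lag_s = lags[best] * dt_s, lags_s = lags * dt_s,
       r_all = r_all, n_lags = length(lags))
}

#' Per-subject functional network connectivity
#'
#' For every unordered pair of selected components: interpolate both time
#' courses to the 1 s grid, band-pass filter, and take the maximal lagged
#' correlation. `r_max` is symmetric, `lag_s` antisymmetric
#' (lag(i,j) = -lag(j,i)).
#'
#' @param tcs time x K matrix of subject component time courses (TR grid).
#' @param tr_s repetition time, seconds.
#' @param selected component ids (columns of `tcs`) to analyse.
#' @param band passband, Hz.
#' @param max_lag_s lag window half-width, seconds.
#' @param target_dt_s interpolation grid, seconds.
#' @return An `fnc_subject` list: `r_max` and `lag_s` (K' x K' matrices,
#'   NA diagonal), `pairs` (long data.frame i, j, r, lag_s), `selected`,
#'   `n_pairs`, `n_lags`.
#' @export
fnc_subject <- function(tcs, tr_s, selected = seq_len(ncol(tcs)),
                        band = c(0.01, 0.1), max_lag_s = 5,
                        target_dt_s = 1) {
  k <- length(selected)
  if (k < 2L) stop("need at least 2 selected components", call. = FALSE)
  prepped <- lapply(selected, function(id) {
    x <- interpolate_tc(tcs[, id], tr_s, target_dt_s)
    bandpass(x, target_dt_s, band[1], band[2])
  })
  r_max <- lag_s <- matrix(NA_real_, k, k,
                           dimnames = list(selected, selected))
  pairs <- utils::combn(k, 2L)
  rows <- vector("list", ncol(pairs))
  n_lags <- NA_integer_
  for (c_i in seq_len(ncol(pairs))) {
    a <- pairs[1L, c_i]; b <- pairs[2L, c_i]
    mlc <- max_lagged_corr(prepped[[a]], prepped[[b]], target_dt_s, max_lag_s)
    n_lags <- mlc$n_lags
    r_max[a, b] <- r_max[b, a] <- mlc$r
    lag_s[a, b] <- mlc$lag_s
    lag_s[b, a] <- -mlc$lag_s
    rows[[c_i]] <- data.frame(i = selected[a], j = selected[b],
                              r = mlc$r, lag_s = mlc$lag_s)
  }
  structure(list(r_max = r_max, lag_s = lag_s,
                 pairs = do.call(rbind, rows), selected = selected,
                 n_pairs = ncol(pairs), n_lags = n_lags),
            class = "fnc_subject")
}

# stack a list of fnc_subject results into a pair x subject matrix of r
fnc_pair_matrix <- function(results) {
  pairs <- results[[1]]$pairs[, c("i", "j")]
  r <- vapply(results, function(fr) fr$pairs$r, numeric(nrow(pairs)))
  list(pairs = pairs, r = matrix(r, nrow = nrow(pairs)))
}

clip_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

#' One-sample group test of FNC
#'
#' Per pair, Fisher z-transformed maximal lagged correlations across
#' subjects are tested against zero with a one-sample t-test; BH-FDR over
#' the pairs. `fisher_z = FALSE` tests the raw correlations.
#'
#' @param results list of `fnc_subject` results (one group).
#' @param alpha FDR level.
#' @param fisher_z variance-stabilize before testing (default TRUE).
#' @return data.frame: i, j, mean_r, mean_z, t, p, q, significant.
#' @export
fnc_group_test <- function(results, alpha = 0.05, fisher_z = TRUE) {
  if (length(results) < 2L) stop("need >= 2 subjects", call. = FALSE)
  pm <- fnc_pair_matrix(results)
  z <- if (fisher_z) clip_z(pm$r) else pm$r
  n <- ncol(z)
  mu <- rowMeans(z)
  s <- sqrt(rowSums((z - mu)^2) / (n - 1))
  tval <- mu / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tval), n - 1L)
  bh <- fdr_bh(p, alpha)
  data.frame(i = pm$pairs$i, j = pm$pairs$j,
             mean_r = rowMeans(pm$r), mean_z = mu,
             t = tval, p = p, q = bh$q, significant = bh$rejected)
}

#' Between-group comparison of FNC
#'
#' Pooled-variance two-sample t-test on the Fisher-z values per pair
#' (sign = group a - group b), BH-FDR over pairs.
#'
#' @param results_a,results_b lists of `fnc_subject` results per group.
#' @param alpha FDR level.
#' @param fisher_z variance-stabilize before testing (default TRUE).
#' @return data.frame: i, j, mean_z_a, mean_z_b, t, p, q, significant.
#' @export
fnc_between_groups <- function(results_a, results_b, alpha = 0.05,
                               fisher_z = TRUE) {
  pa <- fnc_pair_matrix(results_a); pb <- fnc_pair_matrix(results_b)
  if (!identical(pa$pairs, pb$pairs))
    stop("groups analysed different component pairs", call. = FALSE)
  za <- if (fisher_z) clip_z(pa$r) else pa$r
  zb <- if (fisher_z) clip_z(pb$r) else pb$r
  na <- ncol(za); nb <- ncol(zb)
  if (na < 2L || nb < 2L) stop("need >= 2 subjects per group", call. = FALSE)
  ma <- rowMeans(za); mb <- rowMeans(zb)
  ss <- rowSums((za - ma)^2) + rowSums((zb - mb)^2)
  df <- na + nb - 2L
  se <- sqrt(ss / df * (1 / na + 1 / nb))
  tval <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(tval), df)
  bh <- fdr_bh(p, alpha)
  data.frame(i = pa$pairs$i, j = pa$pairs$j, mean_z_a = ma, mean_z_b = mb,
             t = tval, p = p, q = bh$q, significant = bh$rejected)
}

#' Default three-subsystem partition of eight networks
#'
#' Components 1, 2, 4: information integration and modulation (anterior +
#' posterior default mode, self-referential); 5, 6: higher cognition
#' (bilateral frontoparietal / dorsal attention); 3, 7, 8: primary function
#' (sensorimotor, visual, auditory).
#'
#' @return Named character vector: component id -> subsystem label.
#' @export
default_subsystem_partition <- function() {
  c(`1` = "integration_modulation", `2` = "integration_modulation",
    `4` = "integration_modulation",
    `5` = "higher_cognition", `6` = "higher_cognition",
    `3` = "primary_function", `7` = "primary_function",
    `8` = "primary_function")
}

#' Classify significant FNC edges by subsystem and track reorganization
#'
#' Each component pair is labeled intra- (both ends in the same subsystem)
#' or inter-system; each is classified against a reference group as
#' preserved (significant in both), lost (reference only), gained (target
#' only) or absent.
#'
#' @param target group-test data.frame (from [fnc_group_test()]) for the
#'   group of interest.
#' @param reference group-test data.frame for the reference (control) group.
#' @param partition named vector: component id -> subsystem label (see
#'   [default_subsystem_partition()]).
#' @return List: `pairs` (data.frame i, j, class, status), `counts`
#'   (class x status table), `n_intra`, `n_inter`.
#' @export
subsystem_summary <- function(target, reference,
                              partition = default_subsystem_partition()) {
  if (!identical(target[, c("i", "j")], reference[, c("i", "j")]))
    stop("target and reference cover different pairs", call. = FALSE)
  ids <- unique(c(target$i, target$j))
  unmapped <- setdiff(as.character(ids), names(partition))
  if (length(unmapped))
    stop(sprintf("component(s) not in the partition: %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  cls <- ifelse(partition[as.character(target$i)] ==
                  partition[as.character(target$j)], "intra", "inter")
  status <- ifelse(reference$significant & target$significant, "preserved",
            ifelse(reference$significant & !target$significant, "lost",
            ifelse(!reference$significant & target$significant, "gained",
                   "absent")))
  pairs <- data.frame(i = target$i, j = target$j, class = cls,
                      status = status)
  counts <- table(factor(cls, levels = c("intra", "inter")),
                  factor(status, levels = c("preserved", "lost", "gained",
                                            "absent")))
  list(pairs = pairs, counts = counts,
       n_intra = sum(cls == "intra"), n_inter = sum(cls == "inter"))
}

#' Correlation of FNC with subject age
#'
#' Pearson correlation, per pair, between the Fisher-z connectivity values
#' and age across subjects; BH-FDR over pairs. A heterogeneity check: with
#' wide age ranges, connectivity should not track age if groups are to be
#' compared directly.
#'
#' @param results list of `fnc_subject` results (one group).
#' @param ages numeric ages, one per subject.
#' @param alpha FDR level.
#' @return data.frame: i, j, r, p, q, significant.
#' @export
fnc_age_correlation <- function(results, ages, alpha = 0.05) {
  if (length(ages) != length(results))
    stop("one age per subject required", call. = FALSE)
  if (length(ages) < 3L) stop("need >= 3 subjects", call. = FALSE)
  if (any(!is.finite(ages))) stop("ages must be finite", call. = FALSE)
  if (stats::sd(ages) < 1e-12) stop("ages are constant", call. = FALSE)
  pm <- fnc_pair_matrix(results)
  z <- clip_z(pm$r)
  n <- length(ages)
  r <- as.numeric(stats::cor(t(z), ages))
  r <- pmin(pmax(r, -1), 1)
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-15))
  p <- 2 * stats::pt(-abs(tval), n - 2L)
  bh <- fdr_bh(p, alpha)
  data.frame(i = pm$pairs$i, j = pm$pairs$j, r = r, p = p, q = bh$q,
             significant = bh$rejected)
}
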