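test_that("interpolation reproduces polynomials, sinusoids and constants", {
  ramp <- 2 + 0.5 * (0:49) * 2
  out <- interpolate_tc(ramp, tr_s = 2)
  expect_equal(out, 2 + 0.5 * seq(0, 98, by = 1), tolerance = 1e-10,
               ignore_attr = TRUE)
  tt <- (0:99) * 2
  s <- sin(2 * pi * 0.05 * tt)
  si <- interpolate_tc(s, tr_s = 2)
  grid <- seq(0, 198, by = 1)
  inner <- grid > 4 & grid < 194       # spline end conditions are free
  expect_lt(max(abs(si[inner] - sin(2 * pi * 0.05 * grid[inner]))), 1e-3)
  expect_equal(interpolate_tc(rep(3, 50), tr_s = 2), rep(3, 99),
               ignore_attr = TRUE)
  expect_warning(out2 <- interpolate_tc(s, tr_s = 1), "unchanged")
  expect_equal(out2, s, ignore_attr = TRUE)
})

test_that("band-pass keeps in-band tones and rejects out-of-band power", {
  tt <- seq(0, 499, by = 1)
  x_in <- sin(2 * pi * 0.05 * tt)
  y_in <- bandpass(x_in, 1)
  mid <- 100:400
  amp_ratio <- sd(y_in[mid]) / sd(x_in[mid])
  expect_gt(amp_ratio, 0.95)
  x_hi <- sin(2 * pi * 0.5 * seq(0, 499, by = 0.5))
  y_hi <- bandpass(x_hi, 0.5)
  expect_lt(sd(y_hi) / sd(x_hi), 0.05)
  y_dc <- bandpass(rep(10, 500) + rnorm(500, sd = 0.1), 1)
  expect_lt(abs(mean(y_dc)), 1e-6)
  expect_error(bandpass(x_in, 1, 0.01, 0.6), "band")
})

test_that("max lagged correlation is exact on identities and planted shifts", {
  set.seed(71)
  x <- oracle_band_signal(400, 1)
  r_id <- max_lagged_corr(x, x)
  expect_equal(r_id$r, 1.0, tolerance = 1e-12)
  expect_equal(r_id$lag_s, 0)
  expect_equal(r_id$n_lags, 11L)           # 1 s grid, +/-5 s window
  expect_equal(r_id$lags_s, -5:5)
  # planted circular shift: x delayed by 3 s appears at lag +3
  y <- c(x[(400 - 2):400], x[1:(400 - 3)])  # y[t] = x[t - 3]
  r_sh <- max_lagged_corr(x, y)
  expect_equal(r_sh$lag_s, 3)
  expect_gt(r_sh$r, 0.99)
  expect_error(max_lagged_corr(x, rep(1, 400)), "zero-variance")
})

test_that("max lagged correlation equals the brute-force oracle on random pairs", {
  set.seed(72)
  for (rep in 1:100) {
    n <- sample(60:200, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- max_lagged_corr(x, y)
    want <- oracle_max_lag(x, y, 1, 5)
    expect_identical(got$r, want$r)
    expect_identical(got$lag_s, want$lag_s)
  }
})

test_that("planted lags are recovered exactly across the whole window", {
  cs <- cohort_spec(c(A = 1), n_volumes = 220, tr_s = 2, noise_sd = 0)
  for (lag in -5:5) {
    set.seed(700 + lag)
    tc <- make_coupled_timecourses(cs, list(coupling_spec(c(1, 2), 0.8, lag)),
                                   K = 2)[[1]]
    f <- fnc_subject(tc, tr_s = 2)
    expect_equal(f$lag_s[1, 2], lag)
    expect_gt(f$r_max[1, 2], 0.5)
  }
})

test_that("subject FNC fills symmetric/antisymmetric matrices over all pairs", {
  set.seed(73)
  tcs <- sapply(1:8, function(k) oracle_band_signal(100, 2, n_tones = 8))
  f <- fnc_subject(tcs, tr_s = 2)
  expect_equal(f$n_pairs, 28L)
  expect_equal(nrow(f$pairs), 28L)
  expect_equal(f$n_lags, 11L)
  expect_equal(f$r_max, t(f$r_max))
  expect_equal(f$lag_s[upper.tri(f$lag_s)],
               -t(f$lag_s)[upper.tri(f$lag_s)])
  # max dominates the zero-lag member of its set
  for (rw in seq_len(nrow(f$pairs))) {
    i <- f$pairs$i[rw]; j <- f$pairs$j[rw]
    a <- bandpass(interpolate_tc(tcs[, i], 2), 1)
    b <- bandpass(interpolate_tc(tcs[, j], 2), 1)
    expect_gte(abs(f$r_max[i, j]), abs(cor(a, b)) - 1e-12)
  }
  f2 <- fnc_subject(tcs[, 1:2], tr_s = 2)
  expect_equal(f2$n_pairs, 1L)
  expect_error(fnc_subject(tcs[, 1, drop = FALSE], tr_s = 2), "2 selected")
})

test_that("group test flags a single planted edge and ignores near-null pairs", {
  set.seed(74)
  subs <- lapply(1:8, function(s) {
    f <- fnc_subject(sapply(1:4, function(k) oracle_band_signal(150, 2)),
                     tr_s = 2)
    # overwrite with controlled r values: pair (1,2) strong, others jitter
    f$pairs$r <- rnorm(6, 0, 0.02)
    f$pairs$r[f$pairs$i == 1 & f$pairs$j == 2] <- 0.5 + rnorm(1, 0, 0.02)
    f
  })
  gt <- fnc_group_test(subs)
  expect_true(gt$significant[gt$i == 1 & gt$j == 2])
  expect_equal(sum(gt$significant), 1)
  # tiny-n null: no significance
  subs3 <- subs[1:3]
  for (s in 1:3) subs3[[s]]$pairs$r <- c(0.1, -0.1, 0, 0.05, -0.05, 0)[s %% 6 + 1]
  gt3 <- fnc_group_test(subs3)
  expect_false(any(gt3$significant[gt3$i == 1 & gt3$j == 2] &
                     abs(gt3$mean_z[gt3$i == 1 & gt3$j == 2]) < 0.1))
})

test_that("between-group FNC comparison is antisymmetric and null-safe", {
  set.seed(75)
  mk_group <- function(n, rho12) lapply(1:n, function(s) {
    f <- fnc_subject(sapply(1:4, function(k) oracle_band_signal(120, 2)),
                     tr_s = 2)
    f$pairs$r <- rnorm(6, 0, 0.05)
    f$pairs$r[1] <- rho12 + rnorm(1, 0, 0.05)
    f
  })
  ga <- mk_group(8, 0.6); gb <- mk_group(8, 0.0)
  ab <- fnc_between_groups(ga, gb)
  ba <- fnc_between_groups(gb, ga)
  expect_equal(ab$t, -ba$t)
  expect_true(ab$significant[1])
  same <- fnc_between_groups(ga, ga)
  expect_false(any(same$significant))
})

test_that("subsystem partition classifies pairs and tracks reorganization", {
  part <- default_subsystem_partition()
  expect_equal(unname(part["1"]), unname(part["2"]))   # (1,2) intra
  expect_false(part["1"] == part["5"])                 # (1,5) inter
  pairs <- t(combn(1:8, 2))
  mk <- function(sig) data.frame(i = pairs[, 1], j = pairs[, 2],
                                 significant = sig)
  all_sig <- mk(rep(TRUE, 28))
  ss_id <- subsystem_summary(all_sig, all_sig, part)
  expect_equal(ss_id$n_intra, 7)
  expect_equal(ss_id$n_inter, 21)
  expect_equal(sum(ss_id$counts[, "lost"]), 0)
  expect_equal(sum(ss_id$counts[, "gained"]), 0)
  # intra-only target against a fully connected reference loses all 21 inter
  intra_sig <- mk(ss_id$pairs$class == "intra")
  ss <- subsystem_summary(intra_sig, all_sig, part)
  expect_equal(unname(ss$counts["inter", "lost"]), 21)
  expect_equal(unname(ss$counts["intra", "lost"]), 0)
  expect_equal(unname(ss$counts["intra", "preserved"]), 7)
  bad_part <- part[-1]
  expect_error(subsystem_summary(all_sig, all_sig, bad_part), "partition")
})

test_that("FNC-age correlation behaves on perfect, null and degenerate input", {
  set.seed(76)
  subs <- lapply(1:10, function(s) {
    f <- fnc_subject(sapply(1:3, function(k) oracle_band_signal(100, 2)),
                     tr_s = 2)
    f$pairs$r <- c(tanh(s / 10), 0.01 * rnorm(1), 0.01 * rnorm(1))
    f
  })
  ages <- 1:10                      # pair 1 z equals a linear map of age
  ac <- fnc_age_correlation(subs, ages)
  expect_equal(ac$r[1], 1.0, tolerance = 1e-10)
  expect_error(fnc_age_correlation(subs, rep(20, 10)), "constant")
  expect_error(fnc_age_correlation(subs, ages[1:5]), "one age")
  # independent ages: no significant pair in most random draws
  set.seed(77)
  hits <- replicate(20, {
    subs2 <- lapply(1:12, function(s) {
      f <- subs[[1]]; f$pairs$r <- rnorm(3, 0, 0.2); f
    })
    sum(fnc_age_correlation(subs2, rnorm(12, 20, 5))$significant)
  })
  expect_gte(mean(hits == 0), 0.9)
})
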