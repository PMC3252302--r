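test_that("spherical masks match brute-force geometry", {
  m <- make_mask(c(20, 20, 20), 8)
  ctr <- (c(20, 20, 20) + 1) / 2
  idx <- arrayInd(which(m), dim(m))
  d <- sqrt(rowSums(sweep(idx, 2, ctr)^2))
  expect_true(all(d <= 8))
  expect_equal(sum(m), oracle_sphere_count(c(20, 20, 20), 8))
  expect_equal(sum(make_mask(c(10, 10, 10), 4)),
               oracle_sphere_count(c(10, 10, 10), 4))
  # degenerate: radius 0.5 on an odd grid keeps exactly the centre voxel
  expect_equal(sum(make_mask(c(11, 11, 11), 0.5)), 1L)
  expect_error(make_mask(c(10, 10, 10), 20), "fit")
})

test_that("network maps are unit-max Gaussian blobs with closed-form decay", {
  mask <- make_mask(c(15, 15, 15), 6)
  sp <- network_spec(1, list(c(8, 8, 8)), blob_fwhm_mm = 8)
  maps <- make_network_maps(list(sp), mask, voxel_size_mm = c(3, 3, 3))
  vox <- arrayInd(which(mask), dim(mask))
  at <- function(x, y, z)
    unname(maps[1, which(vox[, 1] == x & vox[, 2] == y & vox[, 3] == z)])
  expect_equal(at(8, 8, 8), 1.0)
  sigma <- 8 / (2 * sqrt(2 * log(2)))           # mm
  expect_equal(at(9, 8, 8), exp(-9 / (2 * sigma^2)), tolerance = 1e-12)
  # two distant blobs: two local maxima, both ~1 after unit-max rescale
  sp2 <- network_spec(2, list(c(4, 8, 8), c(12, 8, 8)), blob_fwhm_mm = 6)
  maps2 <- make_network_maps(list(sp2), mask)
  expect_gt(unname(maps2[1, which(vox[, 1] == 4 & vox[, 2] == 8 & vox[, 3] == 8)]), 0.99)
  expect_gt(unname(maps2[1, which(vox[, 1] == 12 & vox[, 2] == 8 & vox[, 3] == 8)]), 0.99)
  expect_error(make_network_maps(list(network_spec(3, list(c(1, 1, 1)))), mask),
               "network 3")
})

test_that("coupled time courses carry the planted correlation and lag", {
  cs <- cohort_spec(c(A = 1), n_volumes = 200, tr_s = 2, noise_sd = 0)
  # rho = 1, lag 0: exact copy
  set.seed(1)
  tc <- make_coupled_timecourses(cs, list(coupling_spec(c(1, 2), 1, 0)), K = 2)[[1]]
  expect_equal(cor(tc[, 1], tc[, 2]), 1.0, tolerance = 1e-12)
  # rho = 0: independent
  set.seed(2)
  tc0 <- make_coupled_timecourses(cs, list(coupling_spec(c(1, 2), 0, 3)), K = 2)[[1]]
  expect_lt(abs(cor(tc0[, 1], tc0[, 2])), 3 / sqrt(nrow(tc0)) * 3)
  # rho = 0.7 at lag 4 s: brute-force scan on the interpolated grid recovers
  # both, averaged over seeds
  rs <- lags <- numeric(10)
  for (s in seq_len(10)) {
    set.seed(100 + s)
    tcs <- make_coupled_timecourses(cs, list(coupling_spec(c(1, 2), 0.7, 4)), K = 2)[[1]]
    a <- bandpass(interpolate_tc(tcs[, 1], 2), 1)
    b <- bandpass(interpolate_tc(tcs[, 2], 2), 1)
    o <- oracle_max_lag(a, b, 1, 5)
    rs[s] <- o$r; lags[s] <- o$lag_s
  }
  expect_lt(abs(mean(rs) - 0.7), 0.1)
  expect_gte(mean(lags == 4), 0.8)     # the occasional off-by-one at rho 0.7
  # invalid inputs
  expect_error(coupling_spec(c(1, 2), 1.2, 0), "strength")
  expect_error(make_coupled_timecourses(
    cs, list(coupling_spec(c(1, 2), 0.5, 2.5)), K = 2), "grid")
})

test_that("generated time courses are band-limited", {
  cs <- cohort_spec(c(A = 2), n_volumes = 205, tr_s = 2)
  set.seed(5)
  tcs <- make_coupled_timecourses(cs, list(), K = 3)
  for (tc in tcs) {
    fine <- attr(tc, "fine")
    for (k in seq_len(ncol(fine))) {
      x <- fine[, k] - mean(fine[, k])
      sp <- Mod(stats::fft(x))^2
      n <- length(x)
      f <- pmin(0:(n - 1), n - (0:(n - 1))) / n   # Hz on the 1 s grid
      inband <- sum(sp[f >= 0.01 & f <= 0.1]) / sum(sp[f > 0])
      expect_gt(inband, 0.9)
    }
  }
})

test_that("rendering is an exact factorization without noise", {
  mask <- make_mask(c(12, 12, 12), 5)
  specs <- list(network_spec(1, list(c(6, 6, 8))),
                network_spec(2, list(c(8, 6, 4))))
  maps <- make_network_maps(specs, mask)
  set.seed(3)
  tc <- matrix(rnorm(40 * 2), 40, 2)
  vs <- render_subject(maps, tc, c(1, 1), noise_sd = 0, mask)
  dm <- to_matrix(vs, mask)
  recon <- tc %*% maps + 100
  expect_equal(dm$values, recon, tolerance = 1e-12)
  expect_equal(qr(dm$values - 100)$rank, 2)
  # zero loading leaves no trace of the silenced network (regression with
  # intercept to absorb the baseline)
  vs0 <- render_subject(maps, tc, c(1, 0), noise_sd = 0, mask)
  x <- cbind(1, tc)
  beta <- solve(crossprod(x), crossprod(x, to_matrix(vs0, mask)$values))
  expect_lt(max(abs(beta[3, ])), 1e-10)
  expect_error(render_subject(maps, tc, c(1, 1), noise_sd = -1, mask), ">= 0")
})

test_that("cohorts are reproducible and carry planted group effects", {
  st <- small_study(n_per_group = c(HC = 2, TLE = 2, MPE = 2), n_volumes = 30)
  a <- generate_cohort(st$cohort, st$specs, st$couplings_by_group,
                       st$loading_scales_by_group, mask = st$mask, seed = 9)
  b <- generate_cohort(st$cohort, st$specs, st$couplings_by_group,
                       st$loading_scales_by_group, mask = st$mask, seed = 9)
  expect_identical(a$subjects[[1]]$data, b$subjects[[1]]$data)
  expect_identical(a$metadata, b$metadata)
  expect_true(all(a$metadata$age >= 8 & a$metadata$age <= 35))
  # control couplings are a superset; difference is exactly the severed pairs
  key <- function(cl) vapply(cl, function(cp) paste(cp$pair, collapse = "-"), "")
  lost <- setdiff(key(st$couplings_by_group$HC), key(st$couplings_by_group$MPE))
  expect_setequal(lost, c("1-5", "1-3"))
  expect_error(generate_cohort(st$cohort, st$specs,
                               st$couplings_by_group[c("HC", "TLE")],
                               mask = st$mask),
               "MPE")
})

test_that("halved loading scale quarters the network's projected variance", {
  mask <- make_mask(c(12, 12, 12), 5)
  specs <- list(network_spec(1, list(c(6, 6, 8))),
                network_spec(2, list(c(8, 6, 4))))
  maps <- make_network_maps(specs, mask)
  set.seed(8)
  tc <- scale(matrix(rnorm(300 * 2), 300, 2))
  v_at <- function(scale_k) {
    vs <- render_subject(maps, tc, c(scale_k, 1), noise_sd = 0, mask)
    y <- to_matrix(vs, mask)$values
    beta <- solve(crossprod(tc), crossprod(tc, y))    # projection oracle
    mean((tc[, 1] %*% beta[1, , drop = FALSE])^2)
  }
  expect_equal(v_at(0.5) / v_at(1), 0.25, tolerance = 1e-10)
})
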