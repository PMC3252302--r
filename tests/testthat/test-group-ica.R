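test_that("MDL recovers the signal rank of spiked covariance data", {
  est_for <- function(q, sd0) {
    set.seed(sd0)
    p <- 40; n_vox <- 4000
    u <- qr.Q(qr(matrix(rnorm(p * q), p, q)))
    y <- u %*% matrix(rnorm(q * n_vox, sd = sqrt(10)), q, n_vox) +
      matrix(rnorm(p * n_vox), p, n_vox)
    as.integer(estimate_order_mdl(y))
  }
  for (q in c(3, 5, 8)) {
    hits <- vapply(1:5, function(s) est_for(q, s), integer(1))
    expect_gt(mean(hits == q), 0.5)
  }
  # pure noise: order stays near zero signal
  nulls <- vapply(1:5, function(s) {
    set.seed(s); as.integer(estimate_order_mdl(matrix(rnorm(40 * 4000), 40)))
  }, integer(1))
  expect_gte(mean(nulls <= 2), 0.9)
  # near-rank-1 data
  set.seed(1)
  v <- rnorm(30); w <- rnorm(2000)
  y1 <- outer(v, w) + matrix(rnorm(30 * 2000, sd = 1e-4), 30)
  expect_equal(as.integer(estimate_order_mdl(y1)), 1L)
  # exactly isotropic covariance: orthonormal rows give equal eigenvalues
  q_iso <- t(qr.Q(qr(matrix(rnorm(400 * 10), 400, 10))))
  expect_warning(k_iso <- estimate_order_mdl(q_iso), "degenerate")
  expect_equal(as.integer(k_iso), 1L)
})

test_that("subject PCA reduction is lossless at full rank and tracks variance", {
  set.seed(21)
  y <- matrix(rnorm(20 * 500), 20, 500)
  full <- reduce_subject(y, 20)
  expect_equal(full$basis %*% full$reduced_data, y, tolerance = 1e-8)
  expect_equal(crossprod(full$basis), diag(20), tolerance = 1e-8)
  expect_true(all(diff(full$eigenvalues) <= 1e-10))
  # exact-rank data reconstructs exactly from 2 components
  y2 <- matrix(rnorm(20 * 2), 20, 2) %*% matrix(rnorm(2 * 500), 2, 500)
  red2 <- reduce_subject(y2, 2)
  expect_equal(red2$basis %*% red2$reduced_data, y2, tolerance = 1e-8)
  # retained variance fraction matches an independent eigendecomposition
  red5 <- reduce_subject(y, 5)
  ev <- eigen(tcrossprod(y) / ncol(y), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(red5$reduced_data^2) / sum(y^2),
               sum(ev[1:5]) / sum(ev), tolerance = 1e-8)
  expect_error(reduce_subject(y, 21), "exceeds")
})

test_that("group reduction concatenates and reduces consistently", {
  set.seed(22)
  y <- matrix(rnorm(15 * 400), 15, 400)
  r1 <- reduce_subject(y, 6)
  # one subject, K = p1: same subspace (principal angles ~ 0)
  g1 <- reduce_group(list(r1), 6)
  sv <- svd(crossprod(r1$basis %*% diag(6), r1$basis %*% diag(6)))$d
  cross <- svd(crossprod(g1$basis))$d   # orthonormality
  expect_equal(cross, rep(1, 6), tolerance = 1e-8)
  # subspace spanned by g1$reduced_data equals r1$reduced_data's row space
  pr <- function(m) crossprod(m, solve(tcrossprod(m), m))
  expect_equal(pr(g1$reduced_data), pr(r1$reduced_data), tolerance = 1e-6)
  # two identical subjects double the spectrum
  g2 <- reduce_group(list(r1, r1), 6)
  expect_equal(g2$eigenvalues[1:6], 2 * r1$eigenvalues[1:6], tolerance = 1e-8)
  # rank-1 concatenation explained fully by K = 1
  yr1 <- outer(rnorm(15), rnorm(400))
  rr <- reduce_subject(yr1, 3)
  gg <- reduce_group(list(rr, rr), 1)
  expect_equal(sum(gg$reduced_data^2) / sum(rbind(rr$reduced_data,
                                                  rr$reduced_data)^2),
               1, tolerance = 1e-8)
  expect_error(reduce_group(list(r1, reduce_subject(matrix(rnorm(15 * 100),
                                                           15), 6)), 4),
               "voxel")
})

test_that("infomax separates super-Gaussian mixtures", {
  for (s in 1:3) {
    set.seed(s)
    src <- laplace_sources(3, 5000)
    mix <- matrix(rnorm(9), 3, 3)
    fit <- infomax(mix %*% src, seed = s)
    x <- mix %*% src
    est <- fit$W %*% fit$whitening %*% (x - rowMeans(x))
    expect_gt(min_matched_cor(est, src), 0.95)
  }
})

test_that("infomax on already-independent whitened sources is a signed permutation", {
  set.seed(31)
  src <- laplace_sources(3, 6000)
  fit <- infomax(src, seed = 31)
  g <- fit$W %*% fit$whitening
  m <- g %*% (src - rowMeans(src))
  cc <- abs(cor(t(m), t(src)))
  # each row/column has exactly one entry ~ 1
  expect_equal(sort(apply(cc, 1, max)), rep(1, 3), tolerance = 0.02)
  expect_equal(colSums(cc > 0.9), rep(1, 3), ignore_attr = TRUE)
})

test_that("infomax is deterministic under a fixed seed and whitens internally", {
  set.seed(32)
  x <- matrix(rnorm(4 * 2000), 4, 2000) + laplace_sources(4, 2000)
  f1 <- infomax(x, seed = 7)
  f2 <- infomax(x, seed = 7)
  expect_identical(f1$W, f2$W)
  xw <- f1$whitening %*% (x - rowMeans(x))
  expect_equal(tcrossprod(xw) / ncol(xw), diag(4), tolerance = 1e-6)
  # maps are z-scored with positive skewness
  set.seed(33)
  src <- laplace_sources(3, 4000)^2   # strongly skewed sources
  fit <- infomax(matrix(rnorm(9), 3, 3) %*% src, seed = 1)
  expect_equal(rowMeans(fit$components$maps), rep(0, 3), tolerance = 1e-8)
  expect_equal(apply(fit$components$maps, 1, sd), rep(1, 3), tolerance = 1e-8)
  sk <- rowMeans((fit$components$maps)^3)
  expect_true(all(sk > 0))
})

test_that("unmixing error shrinks with sample size (Amari-like check)", {
  err_at <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      set.seed(s)
      src <- laplace_sources(3, n)
      mix <- matrix(rnorm(9), 3, 3)
      fit <- infomax(mix %*% src, seed = s)
      x <- mix %*% src
      est <- fit$W %*% fit$whitening %*% (x - rowMeans(x))
      1 - min_matched_cor(est, src)
    }, numeric(1)))
  }
  expect_lt(err_at(10000, 1:3), err_at(500, 1:3) + 1e-9)
  expect_lt(err_at(10000, 1:3), 0.05)
})
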