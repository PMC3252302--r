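#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: q_i = min over j >= i of m * p_(j) / j (computed via
#' [stats::p.adjust()]); the rejection set is all hypotheses with q <= alpha.
#'
#' @param p numeric p-values in \[0, 1\] (no NAs).
#' @param alpha FDR level (default 0.05).
#' @return List: `q`, `rejected` (logical), `n_rejected`, `alpha`.
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  rejected <- q <= alpha
  list(q = q, rejected = rejected, n_rejected = sum(rejected), alpha = alpha)
}

#' Voxelwise one-sample t-test across subjects
#'
#' Per voxel: t = mean / (sd / sqrt(n)), df = n - 1, two-sided p, BH q over
#' the tested voxels. Zero-variance voxels get t = 0, p = 1 and are flagged.
#'
#' @param maps subject x voxel matrix (typically z-scored subject maps).
#' @return A `stat_map` list: `t`, `p`, `q`, `df`, `n`, `flagged`,
#'   `sign_convention`.
#' @export
one_sample_t <- function(maps) {
  n <- nrow(maps)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  mu <- colMeans(maps)
  s <- sqrt(colSums(sweep(maps, 2L, mu, `-`)^2) / (n - 1))
  flat <- s < 1e-12
  tval <- ifelse(flat, 0, mu / (s / sqrt(n)))
  df <- n - 1L
  p <- 2 * stats::pt(-abs(tval), df)
  p[flat] <- 1
  structure(list(t = tval, p = p, q = fdr_bh(p)$q, df = df, n = n,
                 flagged = which(flat), sign_convention = "mean"),
            class = "stat_map")
}

#' Voxelwise two-sample t-test, restricted to a mask
#'
#' Pooled-variance (Student) two-sample t with sign `a - b`,
#' df = n_a + n_b - 2, two-sided p. Only voxels inside `restrict` are
#' tested and enter the BH correction; others are NA.
#'
#' @param maps_a,maps_b subject x voxel matrices for the two groups.
#' @param restrict logical vector over voxels (e.g. from
#'   [make_network_mask()]); `NULL` tests every voxel.
#' @return A `stat_map` list (`t`, `p`, `q`, `df`, `restrict`, ...).
#' @export
two_sample_t <- function(maps_a, maps_b, restrict = NULL) {
  na <- nrow(maps_a); nb <- nrow(maps_b)
  if (na < 2L || nb < 2L) stop("need >= 2 subjects per group", call. = FALSE)
  nv <- ncol(maps_a)
  if (ncol(maps_b) != nv) stop("voxel counts differ", call. = FALSE)
  if (is.null(restrict)) restrict <- rep(TRUE, nv)
  if (length(restrict) != nv)
    stop("restrict mask length does not match voxel count", call. = FALSE)
  if (!any(restrict)) stop("restriction mask is empty", call. = FALSE)
  a <- maps_a[, restrict, drop = FALSE]
  b <- maps_b[, restrict, drop = FALSE]
  ma <- colMeans(a); mb <- colMeans(b)
  ssa <- colSums(sweep(a, 2L, ma, `-`)^2)
  ssb <- colSums(sweep(b, 2L, mb, `-`)^2)
  df <- na + nb - 2L
  sp2 <- (ssa + ssb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  flat <- se < 1e-12
  tin <- ifelse(flat, 0, (ma - mb) / se)
  pin <- 2 * stats::pt(-abs(tin), df)
  pin[flat] <- 1
  qin <- fdr_bh(pin)$q
  tval <- p <- q <- rep(NA_real_, nv)
  tval[restrict] <- tin; p[restrict] <- pin; q[restrict] <- qin
  structure(list(t = tval, p = p, q = q, df = df, n_a = na, n_b = nb,
                 restrict = restrict, flagged = which(restrict)[flat],
                 sign_convention = "group1 - group2"),
            class = "stat_map")
}

#' Network mask from a one-sample statistical map
#'
#' Voxels with q < alpha and t > 0: the positive-loading support of the
#' network in the reference (control) group, used to restrict between-group
#' comparisons.
#'
#' @param sm a `stat_map` from [one_sample_t()].
#' @param alpha FDR level (default 0.05).
#' @return Logical vector over voxels.
#' @export
make_network_mask <- function(sm, alpha = 0.05) {
  sm$q < alpha & sm$t > 0
}
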