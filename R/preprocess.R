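#' Discard initial volumes of a series
#'
#' The first `n` time points are dropped, the usual guard against
#' non-steady-state longitudinal magnetization at the start of a run.
#'
#' @param vs a [volume_series()].
#' @param n number of leading volumes to drop (default 5).
#' @return A [volume_series()] with `t - n` volumes.
#' @export
discard_initial_volumes <- function(vs, n = 5) {
  nt <- dim(vs$data)[4]
  n <- as.integer(n)
  if (n < 0L) stop("`n` must be >= 0", call. = FALSE)
  if (n >= nt)
    stop(sprintf("cannot discard %d of %d volumes", n, nt), call. = FALSE)
  if (n == 0L) return(vs)
  volume_series(vs$data[, , , (n + 1L):nt, drop = FALSE],
                voxel_size_mm = vs$voxel_size_mm, tr_s = vs$tr_s,
                subject_id = vs$subject_id)
}

#' Read a motion-parameter table
#'
#' Expects the realignment-parameter text dialect: whitespace- or
#' comma-separated, 6 columns per volume (3 translations in mm, then 3
#' rotations). Rotations are converted to degrees when `rotations =
#' "radians"` (the SPM `rp_*.txt` convention).
#'
#' @param path text file path.
#' @param rotations `"radians"` (default, converted) or `"degrees"`.
#' @return Numeric matrix with columns trans_x/y/z (mm), rot_x/y/z (deg).
#' @export
read_motion_table <- function(path, rotations = c("radians", "degrees")) {
  rotations <- match.arg(rotations)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  mt <- as.matrix(utils::read.table(path, sep = sep))
  if (ncol(mt) != 6L)
    stop(sprintf("motion table '%s' has %d columns; 6 expected",
                 path, ncol(mt)), call. = FALSE)
  if (rotations == "radians") mt[, 4:6] <- mt[, 4:6] * 180 / pi
  colnames(mt) <- c("trans_x", "trans_y", "trans_z",
                    "rot_x", "rot_y", "rot_z")
  mt
}

#' Motion-based subject exclusion check
#'
#' A subject fails when, relative to the first volume, any translation
#' exceeds `trans_limit_mm` on any axis or any rotation exceeds
#' `rot_limit_deg` (strict inequality: a value exactly at the limit passes).
#'
#' @param mt numeric matrix, 6 columns: translations mm, rotations degrees.
#' @param trans_limit_mm translation limit (default 2 mm).
#' @param rot_limit_deg rotation limit (default 1 degree).
#' @return List with `pass` (logical), `offending_axes` (character),
#'   `max_trans_mm`, `max_rot_deg`.
#' @export
check_motion <- function(mt, trans_limit_mm = 2, rot_limit_deg = 1) {
  mt <- as.matrix(mt)
  if (ncol(mt) != 6L || nrow(mt) < 1L || any(!is.finite(mt)))
    stop("motion table must be a finite numeric matrix with 6 columns",
         call. = FALSE)
  rel <- sweep(mt, 2L, mt[1L, ], `-`)
  mx <- apply(abs(rel), 2L, max)
  axes <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  bad <- c(mx[1:3] > trans_limit_mm, mx[4:6] > rot_limit_deg)
  list(pass = !any(bad), offending_axes = axes[bad],
       max_trans_mm = max(mx[1:3]), max_rot_deg = max(mx[4:6]))
}

# 1D Gaussian smoothing operator (n x n) with edge-replicate boundary;
# kernel truncated at 4 sigma. sigma in voxels; sigma 0 -> identity.
gaussian_operator <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma))
  w <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  w <- w / sum(w)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    src <- pmin(pmax(i + seq(-half, half), 1L), n)  # replicate edges
    for (j in seq_along(src)) a[i, src[j]] <- a[i, src[j]] + w[j]
  }
  a
}

#' Isotropic Gaussian spatial smoothing
#'
#' Each volume is convolved with a separable Gaussian of the given FWHM
#' (sigma per axis = fwhm / (2 sqrt(2 ln 2)) / voxel size, so anisotropic
#' voxels are handled per axis). The kernel is truncated at 4 sigma with an
#' edge-replicate boundary, which preserves constants exactly. `fwhm_mm = 0`
#' is the identity.
#'
#' @param vs a [volume_series()].
#' @param fwhm_mm full width at half maximum, mm (default 8).
#' @param mask optional logical 3D array; when given, output is zeroed
#'   outside the mask after smoothing.
#' @return A smoothed [volume_series()].
#' @export
smooth_gaussian <- function(vs, fwhm_mm = 8, mask = NULL) {
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0", call. = FALSE)
  d <- dim(vs$data)
  if (fwhm_mm == 0) return(vs)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs$voxel_size_mm
  ax <- gaussian_operator(d[1], sig[1])
  ay <- gaussian_operator(d[2], sig[2])
  az <- gaussian_operator(d[3], sig[3])
  a <- vs$data
  # axis 1: (x, y*z*t) product
  a <- array(ax %*% matrix(a, d[1]), d)
  # axis 2: permute y first
  a <- aperm(array(ay %*% matrix(aperm(a, c(2, 1, 3, 4)), d[2]),
                   d[c(2, 1, 3, 4)]), c(2, 1, 3, 4))
  # axis 3
  a <- aperm(array(az %*% matrix(aperm(a, c(3, 1, 2, 4)), d[3]),
                   d[c(3, 1, 2, 4)]), c(2, 3, 1, 4))
  if (!is.null(mask)) {
    mask <- check_mask(mask, d[1:3])
    a <- a * array(rep(mask, d[4]), d)
  }
  volume_series(a, voxel_size_mm = vs$voxel_size_mm, tr_s = vs$tr_s,
                subject_id = vs$subject_id)
}

#' Concatenate multiple runs of one subject along time
#'
#' Runs are detrended (and optionally standardized) individually, then
#' stacked, so slow drifts and scale differences between runs do not leak
#' into the concatenated series.
#'
#' @param dms list of `data_matrix` objects with identical voxel sets.
#' @param standardize passed to [detrend_and_standardize()] per run.
#' @return A single `data_matrix` with the runs stacked along time.
#' @export
concat_runs <- function(dms, standardize = FALSE) {
  if (!length(dms)) stop("no runs given", call. = FALSE)
  nv <- vapply(dms, function(d) ncol(d$values), integer(1))
  if (length(unique(nv)) != 1L)
    stop("runs disagree on voxel count", call. = FALSE)
  det <- lapply(dms, detrend_and_standardize, standardize = standardize)
  out <- det[[1]]
  out$values <- do.call(rbind, lapply(det, `[[`, "values"))
  out
}

#' Remove per-voxel linear trends and standardize variance
#'
#' Each column (voxel time series) has its least-squares linear trend
#' removed and is divided by its residual standard deviation. Voxels with
#' residual sd below `1e-10` are set to zero and flagged in the
#' `flat_voxels` attribute.
#'
#' @param dm a `data_matrix` from [to_matrix()].
#' @param standardize divide each voxel by its residual sd (default TRUE);
#'   `FALSE` detrends only, preserving the voxelwise amplitude profile.
#' @return A `data_matrix` whose columns have mean ~0 (and sd ~1 when
#'   standardized).
#' @export
detrend_and_standardize <- function(dm, standardize = TRUE) {
  y <- dm$values
  nt <- nrow(y)
  if (nt < 3L) stop("need at least 3 time points", call. = FALSE)
  x <- cbind(1, seq_len(nt))
  beta <- solve(crossprod(x), crossprod(x, y))
  r <- y - x %*% beta
  s <- sqrt(colSums(r^2) / (nt - 1))
  flat <- s < 1e-10
  s[flat] <- 1
  if (standardize) {
    r <- sweep(r, 2L, s, `/`)
    r[, flat] <- 0
  }
  out <- dm
  out$values <- r
  attr(out, "flat_voxels") <- which(flat)
  out
}
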