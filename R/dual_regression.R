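#' Dual regression stage 1: subject time courses
#'
#' Ordinary least squares of every time point's voxel vector on the K group
#' spatial maps. Maps are demeaned over voxels before use (standard dual
#' regression practice): `T = Y M' (M M')^-1`.
#'
#' @param dm a `data_matrix` or time x voxel matrix.
#' @param group_maps K x voxel matrix of group component maps.
#' @return time x K matrix of subject-specific component time courses.
#' @export
stage1_timecourses <- function(dm, group_maps) {
  y <- if (inherits(dm, "data_matrix")) dm$values else dm
  m <- group_maps
  if (ncol(y) != ncol(m))
    stop("voxel counts of data and group maps differ", call. = FALSE)
  m <- m - rowMeans(m)
  g <- tcrossprod(m)
  if (rcond(g) < 1e-12) {
    cc <- stats::cor(t(m))
    bad <- which(abs(cc) > 0.999 & upper.tri(cc), arr.ind = TRUE)
    stop(sprintf("group maps are rank deficient; collinear pairs: %s",
                 paste(apply(bad, 1L, paste, collapse = "-"), collapse = ", ")),
         call. = FALSE)
  }
  tc <- y %*% t(m) %*% solve(g)
  colnames(tc) <- rownames(group_maps)
  tc
}

#' Dual regression stage 2: subject spatial maps
#'
#' OLS of every voxel's time series on the K subject time courses (columns
#' demeaned over time). Returns the raw coefficient maps and the z-scored
#' version (per map: zero mean, unit sd over in-mask voxels).
#'
#' @param dm a `data_matrix` or time x voxel matrix.
#' @param tc time x K matrix from [stage1_timecourses()].
#' @return List with `maps` (K x voxel raw betas) and `zmaps` (z-scored).
#' @export
stage2_maps <- function(dm, tc) {
  y <- if (inherits(dm, "data_matrix")) dm$values else dm
  if (nrow(y) != nrow(tc))
    stop("time points of data and time courses differ", call. = FALSE)
  tcd <- sweep(tc, 2L, colMeans(tc), `-`)
  g <- crossprod(tcd)
  if (rcond(g) < 1e-12)
    stop("subject time courses are rank deficient", call. = FALSE)
  beta <- solve(g, crossprod(tcd, y))
  zmaps <- (beta - rowMeans(beta)) / apply(beta, 1L, stats::sd)
  rownames(beta) <- rownames(zmaps) <- colnames(tc)
  list(maps = beta, zmaps = zmaps)
}

#' Back-reconstruct one subject from group maps
#'
#' Runs both dual-regression stages and packages the result.
#'
#' @param dm the subject's `data_matrix`.
#' @param group_maps K x voxel group component maps.
#' @return A [component_set()] (subject level) whose `maps` are the z-scored
#'   stage-2 maps; raw betas in `$raw_maps`.
#' @export
dual_regression <- function(dm, group_maps) {
  tc <- stage1_timecourses(dm, group_maps)
  st2 <- stage2_maps(dm, tc)
  out <- component_set(st2$zmaps, timecourses = tc, level = "subject")
  out$raw_maps <- st2$maps
  out
}
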