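#' Construct a 4D BOLD volume series
#'
#' Container for one subject's 4D resting-state data plus its voxel geometry
#' and repetition time (TR).
#'
#' @param data numeric 4D array, dimensions (x, y, z, t).
#' @param voxel_size_mm positive length-3 numeric, voxel edge lengths in mm.
#' @param tr_s positive scalar, repetition time in seconds.
#' @param subject_id character label.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, voxel_size_mm = c(3, 3, 3), tr_s = 2,
                          subject_id = "subject") {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)", call. = FALSE)
  if (dim(data)[4] < 1L) stop("need at least one time point", call. = FALSE)
  if (any(!is.finite(data)))
    stop("volume contains non-finite values", call. = FALSE)
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be > 0", call. = FALSE)
  stopifnot_scalar_num(tr_s, "tr_s", positive = TRUE)
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 tr_s = as.numeric(tr_s), subject_id = as.character(subject_id)),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series '%s'> %dx%dx%d voxels, %d volumes, voxel %.3gx%.3gx%.3g mm, TR %.3g s\n",
              x$subject_id, d[1], d[2], d[3], d[4],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3], x$tr_s))
  invisible(x)
}

#' Read a 4D NIfTI-1 file as a volume series
#'
#' TR is taken from the header (`pixdim[4]`) unless `tr_s` is supplied, which
#' always wins; a header TR of 0 with no override is an error. Volumes are
#' assumed already co-registered: the affine is not interpreted.
#'
#' @param path path to a `.nii` / `.nii.gz` file containing a 4D image.
#' @param tr_s optional TR override in seconds.
#' @param subject_id label; defaults to the file name without extension.
#' @return A [volume_series()].
#' @export
load_series <- function(path, tr_s = NULL, subject_id = NULL) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 4L)
    stop(sprintf("'%s' is %dD; a 4D volume series is required",
                 path, length(dim(a))), call. = FALSE)
  if (any(!is.finite(a)))
    stop(sprintf("'%s' contains non-finite voxel values", path), call. = FALSE)
  pd <- RNifti::pixdim(img)
  hdr_tr <- if (length(pd) >= 4) pd[4] else 0
  tr <- if (!is.null(tr_s)) tr_s else hdr_tr
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("TR not available from header; supply `tr_s`", call. = FALSE)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  volume_series(a, voxel_size_mm = pd[1:3], tr_s = tr, subject_id = subject_id)
}

#' Write a volume series (or 3D map) as NIfTI-1
#'
#' @param x a [volume_series()], or a 3D/4D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm voxel sizes when `x` is a bare array.
#' @param tr_s TR stored in `pixdim[4]` for 4D data.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path, voxel_size_mm = c(3, 3, 3), tr_s = 2) {
  if (inherits(x, "volume_series")) {
    a <- x$data; voxel_size_mm <- x$voxel_size_mm; tr_s <- x$tr_s
  } else a <- x
  nd <- length(dim(a))
  pix <- c(-1, rep_len(voxel_size_mm, 3), if (nd >= 4) tr_s else 1, 0, 0, 0)
  img <- RNifti::asNifti(a, reference = list(pixdim = pix))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert an in-mask 4D series to a time x voxel matrix
#'
#' Columns are the `TRUE` voxels of `mask` in R's native array order
#' (column-major: x fastest-varying), recorded in `voxel_index` as 1-based
#' (x, y, z) triples. `to_matrix()` followed by [from_matrix()] is the
#' identity on in-mask voxels.
#'
#' @param vs a [volume_series()].
#' @param mask logical 3D array matching the spatial dimensions.
#' @return An object of class `data_matrix` with fields `values`
#'   (time x voxel), `voxel_index` (voxel x 3 integer matrix), `tr_s`,
#'   `mask_dim`, and `voxel_size_mm`.
#' @export
to_matrix <- function(vs, mask) {
  if (!inherits(vs, "volume_series")) stop("`vs` must be a volume_series", call. = FALSE)
  d <- dim(vs$data)
  mask <- check_mask(mask, d[1:3])
  idx <- which(mask)
  nt <- d[4]
  m <- matrix(vs$data, nrow = prod(d[1:3]), ncol = nt)[idx, , drop = FALSE]
  structure(list(values = t(m),
                 voxel_index = arrayInd(idx, d[1:3]),
                 tr_s = vs$tr_s, mask_dim = d[1:3],
                 voxel_size_mm = vs$voxel_size_mm,
                 subject_id = vs$subject_id),
            class = "data_matrix")
}

#' Reconstruct a volume series (or 3D map) from a data matrix
#'
#' Out-of-mask voxels are set to 0. Inverse of [to_matrix()].
#'
#' @param values time x voxel matrix, or a length-V vector for a single 3D map.
#' @param mask logical 3D array.
#' @param voxel_size_mm,tr_s,subject_id geometry for the rebuilt series.
#' @return A [volume_series()] when `values` has more than one row (or is a
#'   matrix), otherwise a 3D array.
#' @export
from_matrix <- function(values, mask, voxel_size_mm = c(3, 3, 3), tr_s = 2,
                        subject_id = "subject") {
  mask <- check_mask(mask, dim(mask))
  idx <- which(mask)
  vec_in <- is.null(dim(values))
  if (vec_in) values <- matrix(values, nrow = 1L)
  if (ncol(values) != length(idx))
    stop(sprintf("matrix has %d columns but mask has %d TRUE voxels",
                 ncol(values), length(idx)), call. = FALSE)
  nt <- nrow(values)
  flat <- matrix(0, nrow = prod(dim(mask)), ncol = nt)
  flat[idx, ] <- t(values)
  a <- array(flat, dim = c(dim(mask), nt))
  if (vec_in) return(array(a[, , , 1L], dim = dim(mask)))
  volume_series(a, voxel_size_mm = voxel_size_mm, tr_s = tr_s,
                subject_id = subject_id)
}

#' @rdname from_matrix
#' @param dm a `data_matrix` from [to_matrix()]; geometry is taken from it.
#' @export
matrix_to_series <- function(dm, mask) {
  from_matrix(dm$values, mask, voxel_size_mm = dm$voxel_size_mm,
              tr_s = dm$tr_s, subject_id = dm$subject_id)
}

check_mask <- function(mask, spatial_dim) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a logical 3D array", call. = FALSE)
  if (!identical(as.integer(dim(mask)), as.integer(spatial_dim)))
    stop(sprintf("mask dimensions (%s) do not match data (%s)",
                 paste(dim(mask), collapse = "x"),
                 paste(spatial_dim, collapse = "x")), call. = FALSE)
  storage.mode(mask) <- "logical"
  mask
}
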