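#' Ellipsoidal brain mask on a voxel grid
#'
#' @param shape integer length-3 grid dimensions.
#' @param radius_vox semi-axis lengths in voxels; a scalar gives a sphere.
#' @return Logical 3D array; voxels within the ellipsoid centred on the grid
#'   centre are `TRUE`.
#' @export
make_mask <- function(shape, radius_vox) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be three positive integers", call. = FALSE)
  r <- rep_len(as.numeric(radius_vox), 3L)
  if (any(r <= 0)) stop("`radius_vox` must be > 0", call. = FALSE)
  if (any(2 * r > shape))
    stop("radius does not fit inside the grid", call. = FALSE)
  ctr <- (shape + 1) / 2
  gx <- ((seq_len(shape[1]) - ctr[1]) / r[1])^2
  gy <- ((seq_len(shape[2]) - ctr[2]) / r[2])^2
  gz <- ((seq_len(shape[3]) - ctr[3]) / r[3])^2
  d2 <- outer(outer(gx, gy, `+`), gz, `+`)
  mask <- array(d2 <= 1, dim = shape)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  mask
}

#' Specify a synthetic network's spatial pattern
#'
#' A network map is a sum of isotropic Gaussian blobs. `loading_scale` is a
#' group-specific multiplier applied to the whole map at rendering time; it
#' is how attenuated within-network connectivity is planted in patient-like
#' groups.
#'
#' @param network_id integer id.
#' @param blob_centers list of 1-based (x, y, z) voxel triples, all in-mask.
#' @param blob_fwhm_mm blob full width at half maximum in mm.
#' @param loading_scale positive multiplier on voxel loadings (default 1).
#' @return A `network_spec` list.
#' @export
network_spec <- function(network_id, blob_centers, blob_fwhm_mm = 8,
                         loading_scale = 1) {
  stopifnot_scalar_num(blob_fwhm_mm, "blob_fwhm_mm", positive = TRUE)
  stopifnot_scalar_num(loading_scale, "loading_scale", positive = TRUE)
  if (!is.list(blob_centers)) blob_centers <- list(blob_centers)
  structure(list(network_id = as.integer(network_id),
                 blob_centers = lapply(blob_centers, as.numeric),
                 blob_fwhm_mm = blob_fwhm_mm,
                 loading_scale = loading_scale),
            class = "network_spec")
}

#' Specify a planted lagged coupling between two networks
#'
#' The second network's time course is the first's, delayed by `lag_s`
#' seconds, mixed at correlation `strength` with independent band-limited
#' noise: tc_j(t) = rho * tc_i(t - lag) + sqrt(1 - rho^2) * noise.
#'
#' @param pair length-2 integer, network ids with `pair[1] < pair[2]`.
#' @param strength planted correlation in \[-1, 1\].
#' @param lag_s lag in seconds, within the analysis window (|lag| <= 5).
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(pair, strength, lag_s = 0) {
  pair <- as.integer(pair)
  if (length(pair) != 2L || pair[1] >= pair[2])
    stop("`pair` must be two network ids with pair[1] < pair[2]", call. = FALSE)
  if (abs(strength) > 1) stop("|strength| must be <= 1", call. = FALSE)
  if (abs(lag_s) > 5) stop("|lag_s| must be <= 5 s", call. = FALSE)
  structure(list(pair = pair, strength = as.numeric(strength),
                 lag_s = as.numeric(lag_s)),
            class = "coupling_spec")
}

#' Specify a synthetic cohort
#'
#' Defaults mirror a typical 3T resting-state acquisition: 205 volumes at
#' TR = 2 s, three groups (14 controls, 7 + 9 patients), unit-sd voxel noise.
#'
#' @param n_subjects_per_group integer vector, one entry per group label.
#' @param group_labels character vector of group names.
#' @param n_volumes volumes per run (>= 20).
#' @param tr_s repetition time, seconds.
#' @param noise_sd additive i.i.d. Gaussian voxel noise sd.
#' @param age_range ages drawn uniformly from this range (years).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects_per_group = c(HC = 14, TLE = 7, MPE = 9),
                        group_labels = names(n_subjects_per_group),
                        n_volumes = 205, tr_s = 2, noise_sd = 1,
                        age_range = c(8, 35)) {
  if (is.null(group_labels))
    group_labels <- paste0("group", seq_along(n_subjects_per_group))
  n_subjects_per_group <- as.integer(n_subjects_per_group)
  if (any(n_subjects_per_group < 1L))
    stop("each group needs at least one subject", call. = FALSE)
  if (length(group_labels) != length(n_subjects_per_group))
    stop("one label per group required", call. = FALSE)
  if (n_volumes < 20L) stop("`n_volumes` must be >= 20", call. = FALSE)
  stopifnot_scalar_num(tr_s, "tr_s", positive = TRUE)
  stopifnot_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  structure(list(n_subjects_per_group = n_subjects_per_group,
                 group_labels = as.character(group_labels),
                 n_volumes = as.integer(n_volumes), tr_s = tr_s,
                 noise_sd = noise_sd, age_range = as.numeric(age_range)),
            class = "cohort_spec")
}

#' Render network spatial maps from blob specs
#'
#' Each row is a sum of isotropic Gaussian blobs
#' (sigma = fwhm / (2 sqrt(2 ln 2))) evaluated at in-mask voxels and rescaled
#' to unit maximum absolute value.
#'
#' @param specs list of [network_spec()].
#' @param mask logical 3D array.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @return K x voxel matrix; columns follow the [to_matrix()] voxel order.
#' @export
make_network_maps <- function(specs, mask, voxel_size_mm = c(3, 3, 3)) {
  if (length(specs) < 1L) stop("need at least one network spec", call. = FALSE)
  mask <- check_mask(mask, dim(mask))
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  vox <- arrayInd(which(mask), dim(mask))
  vox_mm <- sweep(vox, 2L, voxel_size_mm, `*`)
  maps <- matrix(0, nrow = length(specs), ncol = nrow(vox))
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    sigma <- sp$blob_fwhm_mm / (2 * sqrt(2 * log(2)))
    row <- numeric(nrow(vox))
    for (ctr in sp$blob_centers) {
      ci <- round(ctr)
      if (any(ci < 1) || any(ci > dim(mask)) || !mask[ci[1], ci[2], ci[3]])
        stop(sprintf("network %d: blob center (%s) is outside the mask",
                     sp$network_id, paste(ctr, collapse = ",")), call. = FALSE)
      d2 <- colSums((t(vox_mm) - ctr * voxel_size_mm)^2)
      row <- row + exp(-d2 / (2 * sigma^2))
    }
    maps[k, ] <- row / max(abs(row))
  }
  rownames(maps) <- vapply(specs, function(s) as.character(s$network_id), "")
  maps
}

# zero-phase order-5 Butterworth band-pass of a vector sampled at dt_s
butter_bandpass <- function(x, dt_s, low_hz, high_hz, order = 5) {
  nyq <- 1 / (2 * dt_s)
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < nyq))
    stop(sprintf("invalid band [%g, %g] Hz for Nyquist %g Hz",
                 low_hz, high_hz, nyq), call. = FALSE)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  signal::filtfilt(bf, x)
}

#' Generate coupled band-limited subject time courses
#'
#' Base signals are white Gaussian noise band-limited with a zero-phase
#' order-5 Butterworth filter on a 1 s grid; couplings are planted by
#' circular delay on that grid, then the series are decimated to the TR grid
#' and standardized (zero mean, unit variance). Each network may be the
#' target of at most one coupling (the coupling graph is a forest); chained
#' couplings induce indirect correlations equal to the product of strengths.
#'
#' @param cohort a [cohort_spec()] (uses `n_volumes`, `tr_s`); the number of
#'   subjects generated is `sum(cohort$n_subjects_per_group)` unless
#'   `n_subjects` is given.
#' @param couplings list of [coupling_spec()].
#' @param K number of networks.
#' @param band length-2 passband in Hz.
#' @param n_subjects optional override of the subject count.
#' @param fine_dt_s internal generation grid, seconds; lags must be integer
#'   multiples of it.
#' @return List of per-subject time x K matrices (TR grid). Attribute
#'   `fine` holds the 1 s-grid versions used to plant lags.
#' @export
make_coupled_timecourses <- function(cohort, couplings = list(), K,
                                     band = c(0.01, 0.1), n_subjects = NULL,
                                     fine_dt_s = 1) {
  n_sub <- if (is.null(n_subjects)) sum(cohort$n_subjects_per_group) else n_subjects
  n_fine <- as.integer(round(cohort$n_volumes * cohort$tr_s / fine_dt_s))
  step <- as.integer(round(cohort$tr_s / fine_dt_s))
  targets <- integer(0)
  for (cp in couplings) {
    if (abs(cp$strength) > 1) stop("|strength| must be <= 1", call. = FALSE)
    lag_samp <- cp$lag_s / fine_dt_s
    if (abs(lag_samp - round(lag_samp)) > 1e-9)
      stop(sprintf("lag %g s is not representable on the %g s grid",
                   cp$lag_s, fine_dt_s), call. = FALSE)
    if (cp$pair[2] %in% targets)
      stop(sprintf("network %d is the target of more than one coupling",
                   cp$pair[2]), call. = FALSE)
    targets <- c(targets, cp$pair[2])
  }
  # apply parents before children so a chained coupling acts on the final
  # parent course; implied correlation along a path is the strength product
  if (length(couplings) > 1L) {
    ordered <- list(); done <- integer(0); pending <- couplings
    while (length(pending)) {
      src_ok <- vapply(pending, function(cp)
        !(cp$pair[1] %in% vapply(pending, function(q) q$pair[2], integer(1))),
        logical(1))
      if (!any(src_ok))
        stop("couplings contain a cycle", call. = FALSE)
      ordered <- c(ordered, pending[src_ok])
      pending <- pending[!src_ok]
    }
    couplings <- ordered
  }
  out <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    base <- matrix(0, n_fine, K)
    for (k in seq_len(K))
      base[, k] <- butter_bandpass(stats::rnorm(n_fine), fine_dt_s,
                                   band[1], band[2])
    base <- scale(base)
    tc <- base
    for (cp in couplings) {
      i <- cp$pair[1]; j <- cp$pair[2]
      rho <- cp$strength
      lag_samp <- as.integer(round(cp$lag_s / fine_dt_s))
      tc[, j] <- rho * circ_shift(tc[, i], lag_samp) +
        sqrt(1 - rho^2) * base[, j]
    }
    fine <- scale(tc)
    coarse <- fine[seq(1L, n_fine, by = step)[seq_len(cohort$n_volumes)], ,
                   drop = FALSE]
    out[[s]] <- scale(coarse)
    attr(out[[s]], "scaled:center") <- NULL
    attr(out[[s]], "scaled:scale") <- NULL
    attr(out[[s]], "fine") <- fine
  }
  out
}

#' Render one subject's 4D data from maps and time courses
#'
#' In-mask signal is `timecourses %*% diag(loading_scales) %*% maps` plus
#' i.i.d. Gaussian noise and a constant positive baseline; out-of-mask
#' voxels are zero. Draws from the current RNG stream.
#'
#' @param maps K x voxel matrix (unit-max rows, see [make_network_maps()]).
#' @param timecourses time x K matrix.
#' @param loading_scales length-K positive multipliers.
#' @param noise_sd Gaussian noise sd (>= 0).
#' @param mask logical 3D array matching the map voxel order.
#' @param voxel_size_mm,tr_s,subject_id geometry for the output series.
#' @param baseline constant offset added everywhere in-mask (default 100).
#' @return A [volume_series()].
#' @export
render_subject <- function(maps, timecourses, loading_scales, noise_sd,
                           mask, voxel_size_mm = c(3, 3, 3), tr_s = 2,
                           subject_id = "subject", baseline = 100) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  K <- nrow(maps)
  if (ncol(timecourses) != K || length(loading_scales) != K)
    stop("maps, timecourses and loading_scales disagree on K", call. = FALSE)
  y <- timecourses %*% (loading_scales * maps) + baseline
  if (noise_sd > 0)
    y <- y + matrix(stats::rnorm(length(y), sd = noise_sd), nrow(y), ncol(y))
  from_matrix(y, mask, voxel_size_mm = voxel_size_mm, tr_s = tr_s,
              subject_id = subject_id)
}

#' Generate a full multi-group synthetic cohort with ground truth
#'
#' Patient-like group effects are planted through `loading_scales_by_group`
#' (attenuated within-network voxel loadings) and `couplings_by_group`
#' (severed inter-network couplings). Ages are drawn uniformly from the
#' cohort's `age_range`. The same seed yields bit-identical output.
#'
#' @param cohort a [cohort_spec()].
#' @param specs list of [network_spec()] (shared spatial layout).
#' @param couplings_by_group named list (one entry per group label) of
#'   coupling lists.
#' @param loading_scales_by_group named list of length-K scale vectors;
#'   missing groups default to all 1.
#' @param mask logical 3D array; default a 20^3 sphere of radius 8 voxels.
#' @param voxel_size_mm voxel size, mm.
#' @param band generator passband, Hz.
#' @param seed integer seed.
#' @return List with `subjects` (list of [volume_series()]), `metadata`
#'   (data.frame: subject_id, group, age), and `ground_truth` (true maps,
#'   per-subject true time courses, couplings, loading scales, mask).
#' @export
generate_cohort <- function(cohort, specs, couplings_by_group,
                            loading_scales_by_group = NULL,
                            mask = make_mask(c(20, 20, 20), 8),
                            voxel_size_mm = c(3, 3, 3),
                            band = c(0.01, 0.1), seed = 1) {
  K <- length(specs)
  labs <- cohort$group_labels
  missing_grp <- setdiff(labs, names(couplings_by_group))
  if (length(missing_grp))
    stop(sprintf("no couplings given for group(s): %s",
                 paste(missing_grp, collapse = ", ")), call. = FALSE)
  extra <- setdiff(names(couplings_by_group), labs)
  if (length(extra))
    stop(sprintf("unknown group label(s): %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  scales <- lapply(labs, function(g) {
    s <- loading_scales_by_group[[g]]
    if (is.null(s)) rep(1, K) else rep_len(as.numeric(s), K)
  })
  names(scales) <- labs
  maps <- make_network_maps(specs, mask, voxel_size_mm)
  with_seed(seed, {
    subjects <- list(); meta <- list(); true_tcs <- list()
    sid <- 0L
    for (gi in seq_along(labs)) {
      g <- labs[gi]
      n_g <- cohort$n_subjects_per_group[gi]
      tcs <- make_coupled_timecourses(cohort, couplings_by_group[[g]], K,
                                      band = band, n_subjects = n_g)
      for (s in seq_len(n_g)) {
        sid <- sid + 1L
        id <- sprintf("sub-%03d", sid)
        subjects[[sid]] <- render_subject(
          maps, tcs[[s]], scales[[g]], cohort$noise_sd, mask,
          voxel_size_mm = voxel_size_mm, tr_s = cohort$tr_s, subject_id = id)
        true_tcs[[id]] <- tcs[[s]]
        meta[[sid]] <- data.frame(subject_id = id, group = g,
                                  age = stats::runif(1, cohort$age_range[1],
                                                     cohort$age_range[2]),
                                  stringsAsFactors = FALSE)
      }
    }
    list(subjects = subjects,
         metadata = do.call(rbind, meta),
         ground_truth = list(true_maps = maps, true_timecourses = true_tcs,
                             couplings = couplings_by_group,
                             loading_scales = scales, mask = mask,
                             specs = specs, band = band, seed = seed))
  })
}

#' Write a generated cohort to disk
#'
#' One 4D NIfTI per subject, the mask as 3D NIfTI, metadata as CSV and the
#' ground-truth record (maps and couplings) as JSON.
#'
#' @param cohort_data result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_cohort <- function(cohort_data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- cohort_data$ground_truth
  files <- character(0)
  for (vs in cohort_data$subjects) {
    f <- file.path(dir, paste0(vs$subject_id, ".nii.gz"))
    write_series(vs, f); files <- c(files, f)
  }
  f <- file.path(dir, "mask.nii.gz")
  write_series(array(as.numeric(gt$mask), dim = dim(gt$mask)), f)
  files <- c(files, f)
  f <- file.path(dir, "metadata.csv")
  utils::write.csv(cohort_data$metadata, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(
    true_maps = gt$true_maps,
    couplings = lapply(gt$couplings, function(cl)
      lapply(cl, function(cp) cp[c("pair", "strength", "lag_s")])),
    loading_scales = gt$loading_scales, band = gt$band, seed = gt$seed),
    f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}
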