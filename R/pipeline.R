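#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable default: 5
#' discarded volumes, 8 mm smoothing, MDL order selection (override with a
#' fixed integer `K`), the 0.1 Hz / 50% spectral selection rule, a
#' 0.01-0.1 Hz band with a +/-5 s lag window on a 1 s grid for FNC, and
#' FDR level 0.05 throughout.
#'
#' @param ... named overrides merged over the defaults.
#' @return A configuration list for [run_pipeline()].
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    out_dir = NULL,            # run directory; NULL = tempdir()
    seed = 1,
    simulate = NULL,           # a demo_study()-shaped list, or NULL
    data_dir = NULL,           # else: directory from write_cohort()
    tr_s = NULL,               # TR override when loading from disk
    discard_n = 5,
    motion_limits = c(trans_mm = 2, rot_deg = 1),
    fwhm_mm = 8,
    variance_normalize = FALSE,
    K = 8,                     # integer, or "mdl" for order estimation
    selection_cutoff_hz = 0.1,
    selection_threshold = 0.5,
    override_discard = NULL,
    override_keep = NULL,
    band = c(0.01, 0.1),
    max_lag_s = 5,
    target_dt_s = 1,
    alpha = 0.05,
    fisher_z = TRUE,
    reference_group = NULL,    # default: first group in the metadata
    partition = default_subsystem_partition(),
    match_ground_truth = TRUE, # reorder components to planted networks
    write_subject_maps = FALSE)
  ovr <- list(...)
  cfg[names(ovr)] <- ovr
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [pipeline_config()].
#' @return Configuration list (defaults filled in).
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full resting-state network analysis pipeline
#'
#' Stages, in order: simulate (or load) the cohort; discard initial
#' volumes; motion screening (when motion tables are present); Gaussian
#' smoothing; masking and voxelwise detrending/standardization; MDL order
#' selection; two-stage PCA reduction; infomax ICA; dual regression;
#' spectral component selection; voxelwise one-sample maps per group, a
#' control-group network mask, and restricted two-sample comparisons;
#' per-subject FNC, group and between-group FNC tests, subsystem
#' reorganization against the reference group, and FNC-age correlations.
#' Every file written is listed in `manifest.csv` with its MD5 hash, and
#' the configuration is serialized into the run directory.
#'
#' @param cfg configuration list from [pipeline_config()] or [read_config()].
#' @return (Invisibly) a list with all stage results and `out_dir`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  out_dir <- cfg$out_dir %||% file.path(tempfile("rsfnc_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(fmt, ...) {
    msg <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    cat(msg, "\n", file = log_path, sep = "", append = TRUE)
  }
  yaml::write_yaml(serializable_config(cfg), file.path(out_dir, "config.yaml"))

  ## --- input stage -------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    st <- cfg$simulate
    logf("simulate: %d groups, %d volumes, seed %d",
         length(st$cohort$group_labels), st$cohort$n_volumes, cfg$seed)
    cohort_data <- generate_cohort(st$cohort, st$specs,
                                   st$couplings_by_group,
                                   st$loading_scales_by_group,
                                   mask = st$mask, seed = cfg$seed)
    mask <- st$mask
  } else if (!is.null(cfg$data_dir)) {
    cohort_data <- load_cohort(cfg$data_dir, tr_s = cfg$tr_s)
    mask <- cohort_data$mask
    logf("loaded %d subjects from %s", length(cohort_data$subjects),
         cfg$data_dir)
  } else stop("config must provide either `simulate` or `data_dir`",
              call. = FALSE)
  meta <- cohort_data$metadata
  groups <- unique(meta$group)
  ref_group <- cfg$reference_group %||% groups[1]

  ## --- preprocessing -----------------------------------------------------
  logf("preprocess: discard %d, smooth %g mm", cfg$discard_n, cfg$fwhm_mm)
  dms <- vector("list", length(cohort_data$subjects))
  for (s in seq_along(cohort_data$subjects)) {
    vs <- cohort_data$subjects[[s]]
    if (is.null(vs))
      stop(sprintf("missing data for subject %s", meta$subject_id[s]),
           call. = FALSE)
    mt <- cohort_data$motion[[meta$subject_id[s]]]
    if (!is.null(mt)) {
      chk <- check_motion(mt, cfg$motion_limits[["trans_mm"]],
                          cfg$motion_limits[["rot_deg"]])
      if (!chk$pass) {
        logf("subject %s excluded for motion (%s)", meta$subject_id[s],
             paste(chk$offending_axes, collapse = ","))
        dms[[s]] <- NULL
        next
      }
    }
    vs <- discard_initial_volumes(vs, cfg$discard_n)
    vs <- smooth_gaussian(vs, cfg$fwhm_mm)
    dms[[s]] <- detrend_and_standardize(to_matrix(vs, mask),
                                        standardize = cfg$variance_normalize)
  }
  excluded <- vapply(dms, is.null, logical(1))
  if (any(excluded)) {
    meta <- meta[!excluded, , drop = FALSE]
    dms <- dms[!excluded]
  }
  n_sub <- length(dms)
  if (n_sub < 4L) stop("fewer than 4 usable subjects", call. = FALSE)

  ## --- group ICA ---------------------------------------------------------
  if (identical(cfg$K, "mdl")) {
    orders <- vapply(dms, function(d) as.integer(estimate_order_mdl(d)),
                     integer(1))
    K <- max(2L, as.integer(round(stats::median(orders))))
    logf("MDL orders per subject: %s -> K = %d",
         paste(orders, collapse = ","), K)
  } else K <- as.integer(cfg$K)
  p1 <- min(ceiling(1.5 * K), nrow(dms[[1]]$values) - 1L)
  logf("two-stage PCA: p1 = %d, K = %d", p1, K)
  reductions <- lapply(dms, reduce_subject, p1 = p1)
  grp_red <- reduce_group(reductions, K)
  ica <- infomax(grp_red, seed = cfg$seed)
  logf("infomax: %d iterations, converged = %s, restarts = %d",
       ica$iterations, ica$converged, ica$restarts)
  group_maps <- ica$components$maps

  ## when ground truth is known, relabel components so component k is the
  ## planted network k (resolves ICA's permutation/sign ambiguity and makes
  ## the subsystem partition meaningful on simulated cohorts)
  gt <- cohort_data$ground_truth
  if (isTRUE(cfg$match_ground_truth) && !is.null(gt) &&
      nrow(group_maps) >= nrow(gt$true_maps)) {
    ref_maps <- gt$true_maps
    if (cfg$fwhm_mm > 0)
      ref_maps <- to_matrix(smooth_gaussian(
        from_matrix(ref_maps, mask, tr_s = 1), cfg$fwhm_mm), mask)$values
    mm <- match_components(group_maps, ref_maps)
    ord <- mm$est[order(mm$ref)]
    sgn <- sign(mm$correlation[order(mm$ref)])
    sgn[sgn == 0] <- 1
    rest <- setdiff(seq_len(nrow(group_maps)), ord)
    group_maps <- rbind(sgn * group_maps[ord, , drop = FALSE],
                        group_maps[rest, , drop = FALSE])
    logf("relabeled components to planted networks (est order: %s)",
         paste(ord, collapse = ","))
  }

  ## --- dual regression ---------------------------------------------------
  subject_sets <- lapply(dms, dual_regression, group_maps = group_maps)
  names(subject_sets) <- meta$subject_id

  ## --- component selection -----------------------------------------------
  sel <- select_components(lapply(subject_sets, `[[`, "timecourses"),
                           tr_s = dms[[1]]$tr_s,
                           cutoff_hz = cfg$selection_cutoff_hz,
                           threshold = cfg$selection_threshold,
                           override_discard = cfg$override_discard,
                           override_keep = cfg$override_keep)
  logf("selected %d/%d components: %s", length(sel$kept), K,
       paste(sel$kept, collapse = ","))

  ## --- voxelwise statistics ----------------------------------------------
  zstack <- function(grp, k)
    t(vapply(subject_sets[meta$group == grp],
             function(ss) ss$maps[k, ], numeric(ncol(group_maps))))
  voxel <- list()
  for (k in sel$kept) {
    comp <- list(one_sample = list(), two_sample = list())
    for (g in groups) comp$one_sample[[g]] <- one_sample_t(zstack(g, k))
    net_mask <- make_network_mask(comp$one_sample[[ref_group]], cfg$alpha)
    comp$network_mask <- net_mask
    if (any(net_mask)) {
      cmb <- utils::combn(groups, 2L)
      for (ci in seq_len(ncol(cmb))) {
        ga <- cmb[1L, ci]; gb <- cmb[2L, ci]
        comp$two_sample[[paste(ga, "vs", gb)]] <-
          two_sample_t(zstack(ga, k), zstack(gb, k), net_mask)
      }
    }
    voxel[[as.character(k)]] <- comp
  }

  ## --- FNC ---------------------------------------------------------------
  fnc_subj <- lapply(subject_sets, function(ss)
    fnc_subject(ss$timecourses, tr_s = dms[[1]]$tr_s, selected = sel$kept,
                band = cfg$band, max_lag_s = cfg$max_lag_s,
                target_dt_s = cfg$target_dt_s))
  by_group <- split(seq_len(n_sub), meta$group)[groups]
  fnc_group <- lapply(by_group, function(ix)
    fnc_group_test(fnc_subj[ix], alpha = cfg$alpha, fisher_z = cfg$fisher_z))
  fnc_between <- list()
  cmb <- utils::combn(groups, 2L)
  for (ci in seq_len(ncol(cmb))) {
    ga <- cmb[1L, ci]; gb <- cmb[2L, ci]
    fnc_between[[paste(ga, "vs", gb)]] <-
      fnc_between_groups(fnc_subj[by_group[[ga]]], fnc_subj[by_group[[gb]]],
                         alpha = cfg$alpha, fisher_z = cfg$fisher_z)
  }
  partition_ok <- all(as.character(sel$kept) %in% names(cfg$partition))
  subsystems <- if (partition_ok)
    lapply(setdiff(groups, ref_group), function(g)
      subsystem_summary(fnc_group[[g]], fnc_group[[ref_group]],
                        cfg$partition))
  else NULL
  if (!is.null(subsystems)) names(subsystems) <- setdiff(groups, ref_group)
  age_corr <- lapply(by_group, function(ix)
    fnc_age_correlation(fnc_subj[ix], meta$age[ix], alpha = cfg$alpha))

  ## --- outputs -----------------------------------------------------------
  vs_geom <- cohort_data$subjects[[which(!excluded)[1]]]
  write_map <- function(vals, file) {
    write_series(from_matrix(vals, mask), file.path(out_dir, file),
                 voxel_size_mm = vs_geom$voxel_size_mm)
  }
  dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
  write_series(from_matrix(group_maps, mask,
                           voxel_size_mm = vs_geom$voxel_size_mm, tr_s = 1),
               file.path(out_dir, "maps", "group_components.nii.gz"))
  utils::write.csv(sel$report,
                   file.path(out_dir, "tables", "component_selection.csv"),
                   row.names = FALSE)
  utils::write.csv(meta, file.path(out_dir, "tables", "subjects.csv"),
                   row.names = FALSE)
  for (k in names(voxel)) {
    comp <- voxel[[k]]
    for (g in groups)
      write_map(comp$one_sample[[g]]$t,
                file.path("maps", sprintf("comp%s_%s_onesample_t.nii.gz", k, g)))
    for (nm in names(comp$two_sample)) {
      sm <- comp$two_sample[[nm]]
      tag <- gsub(" ", "_", nm)
      tv <- sm$t; tv[is.na(tv)] <- 0
      qv <- sm$q; qv[is.na(qv)] <- 1
      write_map(tv, file.path("maps", sprintf("comp%s_%s_t.nii.gz", k, tag)))
      write_map(qv, file.path("maps", sprintf("comp%s_%s_q.nii.gz", k, tag)))
    }
  }
  if (isTRUE(cfg$write_subject_maps)) {
    dir.create(file.path(out_dir, "subject_maps"), showWarnings = FALSE)
    for (id in names(subject_sets))
      write_series(from_matrix(subject_sets[[id]]$maps, mask,
                               voxel_size_mm = vs_geom$voxel_size_mm, tr_s = 1),
                   file.path(out_dir, "subject_maps", paste0(id, ".nii.gz")))
  }
  fnc_long <- do.call(rbind, lapply(names(fnc_subj), function(id)
    cbind(subject_id = id, fnc_subj[[id]]$pairs)))
  utils::write.csv(fnc_long, file.path(out_dir, "tables", "fnc_subject.csv"),
                   row.names = FALSE)
  for (g in groups)
    utils::write.csv(fnc_group[[g]],
                     file.path(out_dir, "tables",
                               sprintf("fnc_group_%s.csv", g)),
                     row.names = FALSE)
  for (nm in names(fnc_between))
    utils::write.csv(fnc_between[[nm]],
                     file.path(out_dir, "tables",
                               sprintf("fnc_between_%s.csv",
                                       gsub(" ", "_", nm))),
                     row.names = FALSE)
  if (!is.null(subsystems))
    jsonlite::write_json(
      lapply(subsystems, function(ss)
        list(pairs = ss$pairs, counts = as.data.frame(ss$counts))),
      file.path(out_dir, "tables", "subsystem_report.json"),
      auto_unbox = TRUE, digits = NA)
  for (g in groups)
    utils::write.csv(age_corr[[g]],
                     file.path(out_dir, "tables",
                               sprintf("fnc_age_%s.csv", g)),
                     row.names = FALSE)

  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.csv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  logf("done: %d files in manifest", nrow(manifest))

  invisible(list(out_dir = out_dir, config = cfg, metadata = meta,
                 mask = mask, K = K, ica = ica, group_maps = group_maps,
                 subject_sets = subject_sets, selection = sel,
                 voxel = voxel, fnc_subjects = fnc_subj,
                 fnc_group = fnc_group, fnc_between = fnc_between,
                 subsystems = subsystems, age_correlation = age_corr,
                 manifest = manifest,
                 ground_truth = cohort_data$ground_truth))
}

#' Load a cohort previously written with [write_cohort()]
#'
#' @param dir directory containing `sub-*.nii.gz`, `mask.nii.gz`,
#'   `metadata.csv`, and optionally `sub-*_motion.txt` tables.
#' @param tr_s optional TR override.
#' @return List shaped like [generate_cohort()] output (without ground
#'   truth), plus `mask` and `motion`.
#' @export
load_cohort <- function(dir, tr_s = NULL) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  mask_img <- as.array(RNifti::readNifti(file.path(dir, "mask.nii.gz")))
  mask <- array(mask_img > 0.5, dim = dim(mask_img))
  subjects <- lapply(meta$subject_id, function(id) {
    f <- file.path(dir, paste0(id, ".nii.gz"))
    if (!file.exists(f))
      stop(sprintf("missing subject file: %s", f), call. = FALSE)
    load_series(f, tr_s = tr_s, subject_id = id)
  })
  motion <- list()
  for (id in meta$subject_id) {
    f <- file.path(dir, paste0(id, "_motion.txt"))
    if (file.exists(f)) motion[[id]] <- read_motion_table(f)
  }
  list(subjects = subjects, metadata = meta, mask = mask, motion = motion,
       ground_truth = NULL)
}

serializable_config <- function(cfg) {
  cfg$simulate <- if (is.null(cfg$simulate)) NULL else "inline study object"
  cfg$partition <- as.list(cfg$partition)
  cfg[!vapply(cfg, is.null, logical(1))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
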