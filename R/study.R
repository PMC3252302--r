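#' Canonical synthetic study design
#'
#' Eight Gaussian-blob networks inside a spherical mask, three groups
#' (controls and two patient-like groups), lagged couplings forming a tree
#' rooted in the integration/modulation subsystem, and planted group
#' effects: patient groups have attenuated voxel loadings on every network
#' and severed inter-system couplings, while intra-system couplings are left
#' intact. This mirrors the phenotype the pipeline is built to detect:
#' reduced within-network connectivity plus loss confined to inter-system
#' FNC edges.
#'
#' @param n_per_group named integer vector of group sizes.
#' @param n_volumes volumes per run.
#' @param tr_s repetition time, seconds.
#' @param noise_sd additive voxel noise sd.
#' @param grid cubic grid edge, voxels.
#' @param radius_vox spherical mask radius, voxels.
#' @return List: `cohort` ([cohort_spec()]), `specs` (network specs),
#'   `couplings_by_group`, `loading_scales_by_group`, `mask`,
#'   `partition`, `reference_group`.
#' @export
demo_study <- function(n_per_group = c(HC = 14, TLE = 7, MPE = 9),
                       n_volumes = 205, tr_s = 2, noise_sd = 1,
                       grid = 24, radius_vox = 10) {
  mask <- make_mask(c(grid, grid, grid), radius_vox)
  ctr <- (grid + 1) / 2
  off <- function(dx, dy, dz) round(c(ctr + dx, ctr + dy, ctr + dz))
  # blob centres on a ~6-voxel shell, spread by spherical repulsion so that
  # no two blobs of different networks merge under 8 mm smoothing
  specs <- list(
    network_spec(1, list(off(5, -5, 1), off(0, -5, 5))),
    network_spec(2, list(off(-1, -3, -7), off(7, 1, 0))),
    network_spec(3, list(off(4, 4, -4), off(4, 6, 3))),
    network_spec(4, list(off(-4, -6, 0), off(4, -1, 6))),
    network_spec(5, list(off(-1, 3, 7), off(-7, 0, -3))),
    network_spec(6, list(off(-6, 4, 1), off(4, -1, -6))),
    network_spec(7, list(off(1, -7, -3), off(-3, 4, -6))),
    network_spec(8, list(off(-5, -1, 5), off(0, 8, 0))))
  intra <- list(coupling_spec(c(1, 2), 0.7, 1),
                coupling_spec(c(1, 4), 0.7, -2),
                coupling_spec(c(5, 6), 0.7, 2),
                coupling_spec(c(3, 7), 0.7, 1),
                coupling_spec(c(3, 8), 0.7, -1))
  inter <- list(coupling_spec(c(1, 5), 0.5, 3),
                coupling_spec(c(1, 3), 0.5, 2))
  couplings <- list(HC = c(intra, inter),
                    TLE = c(intra, inter[1]),   # 1-3 severed
                    MPE = intra)                # 1-3 and 1-5 severed
  names(couplings$TLE) <- NULL
  labs <- names(n_per_group)
  couplings <- couplings[labs]
  scales <- list(HC = rep(1, 8), TLE = rep(0.8, 8), MPE = rep(0.7, 8))[labs]
  list(cohort = cohort_spec(n_per_group, n_volumes = n_volumes, tr_s = tr_s,
                            noise_sd = noise_sd),
       specs = specs, couplings_by_group = couplings,
       loading_scales_by_group = scales, mask = mask,
       partition = default_subsystem_partition(),
       reference_group = labs[1])
}
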