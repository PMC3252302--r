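# a scaled-down cohort for fast end-to-end tests: same geometry and coupling
# graph as the full demo study, fewer subjects and volumes
small_study <- function(n_per_group = c(HC = 4, TLE = 3, MPE = 3),
                        n_volumes = 60, noise_sd = 1) {
  demo_study(n_per_group = n_per_group, n_volumes = n_volumes,
             noise_sd = noise_sd)
}
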