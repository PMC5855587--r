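# shared fixtures built in code

# Gaussian draws truncated below (rupture forces are positive)
rnorm_pos <- function(n, mean, sd, lower = 1) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x < lower)) x[x < lower] <- stats::rnorm(sum(x < lower), mean, sd)
  x
}

# a config producing exactly one noise-free specific curve with a known
# rupture force and contour length
exact_specific_config <- function(force_pN, Lc_nm, noise_sd_pN = 0, ...) {
  simulation_config(
    n_curves = 1, p_specific = 1, p_nonspecific = 0,
    rupture_force_model = list(mean_pN = force_pN, sd_pN = 0, weight = 1),
    tether = wlc_params(0.1, Lc_nm, 298),
    contour_length_jitter_nm = 0,
    noise_sd_pN = noise_sd_pN,
    ...
  )
}

# noise-free single-plateau config
exact_plateau_config <- function(force_pN = 55, detach_nm = 100,
                                 noise_sd_pN = 0, ...) {
  simulation_config(
    n_curves = 1, p_specific = 0, p_nonspecific = 0, p_plateau = 1,
    plateau_model = list(
      force_mean_pN = force_pN, force_sd_pN = 0,
      detach_length_mean_nm = detach_nm, detach_length_sd_nm = 0
    ),
    noise_sd_pN = noise_sd_pN,
    ...
  )
}
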