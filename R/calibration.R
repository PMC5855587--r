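#' Thermal-noise (equipartition) spring-constant calibration
#'
#' By equipartition, a free cantilever in thermal equilibrium has
#' kB T / 2 of energy in its deflection mode, so
#' k = kB T / var(deflection).  This is the simple equipartition form of
#' the thermal-noise method, without spectral (Lorentzian) fitting or
#' cantilever-shape correction factors; those corrections rescale k by a
#' known constant and are out of scope here.  The relative uncertainty
#' reported is the sampling uncertainty of a variance estimate,
#' sqrt(2/(n-1)); instrumental uncertainty of the method in practice is
#' about 10%.
#'
#' @param deflection_nm Baseline (non-contact) deflection samples, nm.
#' @param temperature_K Temperature in K.
#' @return An object of class `calibration_result`: `k_nN_per_nm`,
#'   `n_samples`, `temperature_K`, `relative_uncertainty`,
#'   `insufficient` (`TRUE`, with a warning, below 1000 samples).
#' @examples
#' d <- simulate_thermal_deflections(1e4, 0.02, 298, seed = 1)
#' equipartition_k(d, 298)
#' @export
equipartition_k <- function(deflection_nm, temperature_K = 298) {
  n <- length(deflection_nm)
  stopifnot(n >= 2, temperature_K > 0)
  v <- stats::var(deflection_nm)
  if (!is.finite(v) || v <= 0) {
    stop("zero-variance deflection record: cannot calibrate", call. = FALSE)
  }
  k_pN_per_nm <- kBT_pN_nm(temperature_K) / v
  insufficient <- n < 1000L
  if (insufficient) {
    warning(sprintf("only %d samples: variance estimate has %.0f%% relative uncertainty",
                    n, 100 * sqrt(2 / (n - 1))), call. = FALSE)
  }
  structure(
    list(
      k_nN_per_nm = k_pN_per_nm / 1000,
      n_samples = n,
      temperature_K = temperature_K,
      relative_uncertainty = sqrt(2 / (n - 1)),
      insufficient = insufficient
    ),
    class = "calibration_result"
  )
}

#' Simulate thermal deflection fluctuations of a cantilever
#'
#' Gaussian deflection samples with the equipartition variance
#' kB T / k, the forward model inverted by [equipartition_k()].
#'
#' @param n Number of samples.
#' @param k_nN_per_nm True spring constant, nN/nm.
#' @param temperature_K Temperature, K.
#' @param seed Optional seed.
#' @return Deflection samples in nm.
#' @export
simulate_thermal_deflections <- function(n, k_nN_per_nm,
                                         temperature_K = 298, seed = NULL) {
  stopifnot(n >= 1, k_nN_per_nm > 0, temperature_K > 0)
  if (!is.null(seed)) set.seed(seed)
  sd_nm <- sqrt(kBT_pN_nm(temperature_K) / (k_nN_per_nm * 1000))
  stats::rnorm(n, 0, sd_nm)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Equipartition calibration: k = %.4g nN/nm (n = %d, T = %g K, +/- %.1f%% sampling)%s\n",
              x$k_nN_per_nm, x$n_samples, x$temperature_K,
              100 * x$relative_uncertainty,
              if (x$insufficient) " [insufficient samples]" else ""))
  invisible(x)
}
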