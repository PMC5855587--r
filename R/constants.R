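#' Physical constants and unit conventions
#'
#' All internal quantities use a single unit system: lengths in nm, forces
#' in pN, spring constants in nN/nm (so 1 nN/nm = 1000 pN/nm), pulling
#' speeds in um/s, temperatures in K.  Conversions to SI happen only at
#' reporting boundaries (e.g. peeling work in J).
#'
#' @name afmpull-units
#' @keywords internal
NULL

## Boltzmann constant, SI (J/K)
.kB_J_per_K <- 1.380649e-23

## Avogadro's number (1/mol)
.N_avogadro <- 6.02214076e23

#' Thermal energy in pN nm
#'
#' @param temperature_K Temperature in kelvin.
#' @return Thermal energy kB*T in pN nm (4.11 pN nm at 298 K).
#' @examples
#' kBT_pN_nm(298)
#' @export
kBT_pN_nm <- function(temperature_K) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  # 1 J = 1e21 pN nm
  .kB_J_per_K * temperature_K * 1e21
}
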