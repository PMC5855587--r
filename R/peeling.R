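#' Peeling work and adsorption energies from a force-extension segment
#'
#' Core computation behind [peeling_work()]: trapezoidal integration of
#' the adhesion force over extension, with the segment endpoints placed
#' exactly by linear interpolation, followed by the unit conversions to
#' molar and per-residue energies.  For a constant force F over a
#' segment of width L the work equals F*L to machine precision.
#'
#' @param extension_nm Extension axis, nm (monotone increasing).
#' @param force_pN Baseline-corrected adhesion force, pN (positive =
#'   adhesive).
#' @param segment_nm Length-2 integration segment `[x_start, x_end]` nm.
#' @param residues_per_nm Monomer line density of the polymer (default 3
#'   residues per nm).
#' @return An object of class `peeling_result`: `segment_nm`,
#'   `mean_force_pN`, `work_J`, `work_per_nm_J`, `molar_work_per_nm_J`
#'   (J per nm per mol), `per_residue_energy_kJ_per_mol`,
#'   `residues_per_nm`.
#' @examples
#' x <- seq(0, 100, by = 0.5)
#' f <- rep(55, length(x))
#' peeling_result(x, f, c(20, 80))  # work 3.3e-18 J, about 11 kJ/mol
#' @export
peeling_result <- function(extension_nm, force_pN, segment_nm = c(20, 80),
                           residues_per_nm = 3) {
  stopifnot(length(extension_nm) == length(force_pN),
            length(segment_nm) == 2L, segment_nm[1] < segment_nm[2],
            residues_per_nm > 0)
  o <- order(extension_nm)
  x <- extension_nm[o]
  f <- force_pN[o]
  if (segment_nm[1] < min(x) || segment_nm[2] > max(x)) {
    stop("integration segment lies outside the recorded extension range",
         call. = FALSE)
  }
  inside <- x > segment_nm[1] & x < segment_nm[2]
  f_ends <- stats::approx(x, f, xout = segment_nm)$y
  xg <- c(segment_nm[1], x[inside], segment_nm[2])
  fg <- c(f_ends[1], f[inside], f_ends[2])
  mean_force <- pracma::trapz(xg, fg) / diff(segment_nm)
  if (mean_force < 0) {
    stop("negative mean force on segment: peeling force must oppose retraction",
         call. = FALSE)
  }
  work_J <- pracma::trapz(xg * 1e-9, fg * 1e-12)     # m x N
  work_per_nm <- work_J / diff(segment_nm)
  molar <- work_per_nm * .N_avogadro
  structure(
    list(
      segment_nm = segment_nm,
      mean_force_pN = mean_force,
      work_J = work_J,
      work_per_nm_J = work_per_nm,
      molar_work_per_nm_J = molar,
      per_residue_energy_kJ_per_mol = molar / residues_per_nm / 1000,
      residues_per_nm = residues_per_nm
    ),
    class = "peeling_result"
  )
}

#' Quantify polymer peeling from a plateau force curve
#'
#' Baseline-corrects the retract trace, builds the extension axis,
#' verifies that a detected peeling plateau overlaps the requested
#' segment, and integrates the adhesion force over the segment.
#'
#' @param curve A [force_curve()] with a peeling plateau.
#' @param segment_nm Integration segment in nm of extension (default
#'   `c(20, 80)`, skipping the complicated initial region).
#' @param residues_per_nm Monomer line density (default 3 per nm).
#' @param baseline Optional precomputed
#'   [estimate_baseline_and_contact()] result.
#' @param require_plateau Verify with [detect_plateau()] that a plateau
#'   overlaps the segment (default `TRUE`).
#' @param min_force_pN Detection floor passed to [detect_plateau()].
#' @return A `peeling_result` (see [peeling_result()]).
#' @export
peeling_work <- function(curve, segment_nm = c(20, 80), residues_per_nm = 3,
                         baseline = NULL, require_plateau = TRUE,
                         min_force_pN = 10) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(baseline)) {
    baseline <- suppressWarnings(estimate_baseline_and_contact(curve))
  }
  if (require_plateau) {
    pl <- detect_plateau(curve, baseline, min_force_pN = min_force_pN)
    if (is.null(pl) || pl$end_nm <= segment_nm[1] || pl$start_nm >= segment_nm[2]) {
      stop("no peeling plateau overlapping the requested segment",
           call. = FALSE)
    }
  }
  tr <- .adhesion_trace(curve, baseline)
  peeling_result(tr$x, tr$a, segment_nm, residues_per_nm)
}

#' Per-residue adsorption energy
#'
#' Converts the molar peeling work per nm into an energy per monomeric
#' residue, assuming `residues_per_nm` residues per nm of contour all
#' participate in adsorption.
#'
#' @param result A `peeling_result`.
#' @param residues_per_nm Residue line density (default 3 per nm).
#' @return Energy per residue in kJ/mol.
#' @examples
#' x <- seq(0, 100, 0.5)
#' r <- peeling_result(x, rep(55, length(x)), c(20, 80))
#' per_residue_energy(r)  # about 11 kJ/mol
#' @export
per_residue_energy <- function(result, residues_per_nm = 3) {
  stopifnot(inherits(result, "peeling_result"), residues_per_nm > 0)
  result$molar_work_per_nm_J / residues_per_nm / 1000
}

#' @export
print.peeling_result <- function(x, ...) {
  cat(sprintf(
    paste0("Peeling over [%g, %g] nm: mean force %.1f pN, work %.3g J ",
           "(%.3g J/nm; %.3g J/nm/mol; %.1f kJ/mol per residue at %g residues/nm)\n"),
    x$segment_nm[1], x$segment_nm[2], x$mean_force_pN, x$work_J,
    x$work_per_nm_J, x$molar_work_per_nm_J,
    x$per_residue_energy_kJ_per_mol, x$residues_per_nm
  ))
  invisible(x)
}
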