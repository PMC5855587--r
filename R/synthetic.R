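#' Simulation configuration for synthetic force curves
#'
#' Defines the statistical structure of a simulated pulling experiment.
#' The defaults emulate a penta-glycine-like tip chemistry pulled from a
#' mineral surface: specific tether-mediated ruptures with forces drawn
#' from a Gaussian with mean 76 pN and sigma 10 pN, observed on 12.5% of
#' curves; occasional near-contact non-specific adhesion artefacts; a PEG
#' tether of contour length 35 +/- 5 nm with persistence length 0.1 nm;
#' 5 pN Gaussian baseline noise; and 0.75 um of retract travel.
#'
#' @param n_curves Number of curves to simulate.
#' @param p_specific Probability a curve carries a specific tether-mediated
#'   rupture.
#' @param p_nonspecific Probability of a near-contact adhesion artefact
#'   (rupture at < 15 nm tether extension).
#' @param p_plateau Probability of a polymer-peeling plateau curve
#'   (requires `plateau_model`).
#' @param rupture_force_model List with numeric vectors `mean_pN`, `sd_pN`
#'   and `weight` (recycled; weights normalised): a Gaussian or Gaussian
#'   mixture from which specific rupture forces are drawn (truncated at
#'   1 pN).
#' @param tether A [wlc_params()] object for the tether; its contour
#'   length is the mean of the per-curve draw.
#' @param contour_length_jitter_nm SD of the per-curve contour length,
#'   emulating molecular-weight heterogeneity of the crosslinker.
#' @param noise_sd_pN SD of Gaussian baseline force noise.
#' @param baseline_drift_pN_per_um Linear baseline drift along the piezo
#'   axis.
#' @param nonspecific_model List with `force_mean_pN`, `force_sd_pN`,
#'   `detach_range_nm` (length-2): near-contact artefact model.
#' @param plateau_model `NULL`, or a list with `force_mean_pN`,
#'   `force_sd_pN`, `detach_length_mean_nm`, `detach_length_sd_nm` for
#'   constant-force peeling curves.
#' @param curve_length_um Piezo travel of the retract segment, in um.
#' @param points_per_curve Samples per segment.
#' @param spring_constant_nN_per_nm Cantilever spring constant.
#' @param pulling_speed_um_per_s Pulling speed.
#' @param temperature_K Temperature.
#' @param sample_label Species label stamped on every curve.
#' @param include_approach Also synthesise an approach segment (mirror of
#'   baseline plus contact wall); only needed for contact-point tests.
#' @param contact_depth_nm How far into the repulsive wall the retract
#'   segment starts.
#' @param seed Master seed fixing the entire output stream.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_curves = 1000,
                              p_specific = 0.125,
                              p_nonspecific = 0.2,
                              p_plateau = 0,
                              rupture_force_model = list(
                                mean_pN = 76, sd_pN = 10, weight = 1
                              ),
                              tether = wlc_params(0.1, 35, 298),
                              contour_length_jitter_nm = 5,
                              noise_sd_pN = 5,
                              baseline_drift_pN_per_um = 0,
                              nonspecific_model = list(
                                force_mean_pN = 80, force_sd_pN = 30,
                                detach_range_nm = c(2, 10)
                              ),
                              plateau_model = NULL,
                              curve_length_um = 0.75,
                              points_per_curve = 2000,
                              spring_constant_nN_per_nm = 0.02,
                              pulling_speed_um_per_s = 5,
                              temperature_K = 298,
                              sample_label = "synthetic",
                              include_approach = FALSE,
                              contact_depth_nm = 20,
                              seed = 1L) {
  stopifnot(
    n_curves >= 1,
    p_specific >= 0, p_specific <= 1,
    p_nonspecific >= 0, p_nonspecific <= 1,
    p_plateau >= 0, p_plateau <= 1,
    p_specific + p_nonspecific + p_plateau <= 1,
    inherits(tether, "wlc_params"),
    contour_length_jitter_nm >= 0,
    noise_sd_pN >= 0,
    curve_length_um > 0,
    points_per_curve >= 100,
    spring_constant_nN_per_nm > 0
  )
  rfm <- rupture_force_model
  stopifnot(all(rfm$sd_pN >= 0), all(rfm$mean_pN > 0))
  n_comp <- max(lengths(rfm))
  rfm$mean_pN <- rep_len(rfm$mean_pN, n_comp)
  rfm$sd_pN <- rep_len(rfm$sd_pN, n_comp)
  rfm$weight <- rep_len(if (is.null(rfm$weight)) 1 else rfm$weight, n_comp)
  rfm$weight <- rfm$weight / sum(rfm$weight)
  if (p_plateau > 0 && is.null(plateau_model)) {
    stop("p_plateau > 0 requires a plateau_model", call. = FALSE)
  }
  if (!is.null(plateau_model)) {
    if (plateau_model$detach_length_mean_nm >= curve_length_um * 1000) {
      stop("plateau detach length exceeds the curve length", call. = FALSE)
    }
  }
  structure(
    list(
      n_curves = as.integer(n_curves),
      p_specific = p_specific,
      p_nonspecific = p_nonspecific,
      p_plateau = p_plateau,
      rupture_force_model = rfm,
      tether = tether,
      contour_length_jitter_nm = contour_length_jitter_nm,
      noise_sd_pN = noise_sd_pN,
      baseline_drift_pN_per_um = baseline_drift_pN_per_um,
      nonspecific_model = nonspecific_model,
      plateau_model = plateau_model,
      curve_length_um = curve_length_um,
      points_per_curve = as.integer(points_per_curve),
      spring_constant_nN_per_nm = spring_constant_nN_per_nm,
      pulling_speed_um_per_s = pulling_speed_um_per_s,
      temperature_K = temperature_K,
      sample_label = sample_label,
      include_approach = isTRUE(include_approach),
      contact_depth_nm = contact_depth_nm,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# Solve the tether force balance F = wlc(z - F/k) for each retract
# position z (nm), by vectorised bisection on the extension.
# Returns the tether force (pN) at each z.
.solve_tether_force <- function(z_nm, params, k_pN_per_nm) {
  Lc <- params$contour_length_nm
  lo <- rep(0, length(z_nm))
  hi <- pmin(z_nm, Lc * (1 - 1e-12))
  for (i in seq_len(100)) {
    mid <- (lo + hi) / 2
    # g(x) = x + F(x)/k - z, strictly increasing in x
    g <- mid + wlc_force(mid, params) / k_pN_per_nm - z_nm
    take_lo <- g < 0
    lo[take_lo] <- mid[take_lo]
    hi[!take_lo] <- mid[!take_lo]
  }
  wlc_force((lo + hi) / 2, params)
}

# truncated-normal draw (lower bound), by resampling
.rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  for (tries in seq_len(1000)) {
    bad <- x < lower
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(x, lower)
}

#' Simulate one retract (plus optional approach) curve
#'
#' Draws a curve class (no-adhesion, non-specific, specific, or plateau)
#' and synthesises the corresponding retract trace: a linear repulsive
#' wall in contact, a WLC tether ramp solved self-consistently with the
#' cantilever compliance and terminated by an instantaneous force step to
#' baseline at the drawn rupture force, a near-contact triangular
#' adhesion artefact, or a constant-force peeling plateau.  One retract
#' sample is placed exactly at the rupture point so the drawn rupture
#' force is exactly the maximum tether force in the labelled region.
#'
#' @param config A [simulation_config()].
#' @param curve_id Identifier for the curve.
#' @param seed Optional per-curve seed (set by [simulate_ensemble()]).
#' @param force_class Optionally fix the curve class instead of drawing it.
#' @return A list with elements `curve` (a [force_curve()]) and `label`
#'   (one-row data.frame: `curve_id`, `true_class`, `true_rupture_force_pN`,
#'   `true_rupture_extension_nm`, `true_plateau_force_pN`).
#' @export
simulate_retract_curve <- function(config, curve_id = "curve_0001",
                                   seed = NULL, force_class = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  k_pN <- config$spring_constant_nN_per_nm * 1000
  n <- config$points_per_curve
  z0 <- -config$contact_depth_nm
  z1 <- config$curve_length_um * 1000 + z0
  z <- seq(z0, z1, length.out = n)

  if (is.null(force_class)) {
    u <- stats::runif(1)
    cls <- if (u < config$p_specific) {
      "specific"
    } else if (u < config$p_specific + config$p_plateau) {
      "plateau"
    } else if (u < config$p_specific + config$p_plateau + config$p_nonspecific) {
      "nonspecific"
    } else {
      "no_adhesion"
    }
  } else {
    cls <- match.arg(force_class,
                     c("no_adhesion", "nonspecific", "specific", "plateau"))
  }

  true_force <- NA_real_
  true_ext <- NA_real_
  true_plateau <- NA_real_
  signal <- numeric(n)            # signed force, pN (adhesion negative)

  # repulsive contact wall: linear in penetration depth
  wall_compliance <- 0.8          # nm deflection per nm penetration
  in_wall <- z < 0
  signal[in_wall] <- -z[in_wall] * wall_compliance * k_pN

  if (cls == "specific") {
    rfm <- config$rupture_force_model
    comp <- sample.int(length(rfm$weight), 1, prob = rfm$weight)
    Fr <- .rnorm_trunc(1, rfm$mean_pN[comp], rfm$sd_pN[comp], lower = 1)
    Lc <- max(5, stats::rnorm(1, config$tether$contour_length_nm,
                              config$contour_length_jitter_nm))
    pars <- wlc_params(config$tether$persistence_length_nm, Lc,
                       config$temperature_K)
    x_r <- wlc_extension(Fr, pars)
    z_r <- x_r + Fr / k_pN
    # snap the last tethered sample onto the exact rupture point
    j <- findInterval(z_r, z)
    if (j >= 1 && j < n) z[j] <- z_r
    tethered <- z > 0 & z <= z_r
    signal[tethered] <- -.solve_tether_force(z[tethered], pars, k_pN)
    true_force <- Fr
    true_ext <- x_r
  } else if (cls == "nonspecific") {
    nm <- config$nonspecific_model
    Fn <- .rnorm_trunc(1, nm$force_mean_pN, nm$force_sd_pN, lower = 20)
    z_det <- stats::runif(1, nm$detach_range_nm[1], nm$detach_range_nm[2])
    held <- z > 0 & z <= z_det
    signal[held] <- -Fn * z[held] / z_det
    true_force <- Fn
    true_ext <- max(0, z_det - Fn / k_pN)
  } else if (cls == "plateau") {
    pm <- config$plateau_model
    Fp <- .rnorm_trunc(1, pm$force_mean_pN, pm$force_sd_pN, lower = 1)
    Ld <- .rnorm_trunc(1, pm$detach_length_mean_nm, pm$detach_length_sd_nm,
                       lower = 30)
    Ld <- min(Ld, 0.9 * (config$curve_length_um * 1000))
    held <- z > 0 & z <= Ld
    signal[held] <- -Fp
    true_plateau <- Fp
  }

  drift <- config$baseline_drift_pN_per_um * (z - z0) / 1000
  noise <- stats::rnorm(n, 0, config$noise_sd_pN)
  deflection <- (signal + drift + noise) / k_pN

  seg <- rep("retract", n)
  piezo <- z
  if (config$include_approach) {
    # approach: wall + baseline only, piezo decreasing toward the surface
    z_a <- rev(z)
    sig_a <- numeric(n)
    sig_a[z_a < 0] <- -z_a[z_a < 0] * wall_compliance * k_pN
    defl_a <- (sig_a + config$baseline_drift_pN_per_um * (z_a - z0) / 1000 +
                 stats::rnorm(n, 0, config$noise_sd_pN)) / k_pN
    seg <- c(rep("approach", n), seg)
    piezo <- c(z_a, piezo)
    deflection <- c(defl_a, deflection)
  }

  curve <- force_curve(
    curve_id = curve_id,
    segment = seg,
    piezo_position_nm = piezo,
    deflection_nm = deflection,
    spring_constant_nN_per_nm = config$spring_constant_nN_per_nm,
    pulling_speed_um_per_s = config$pulling_speed_um_per_s,
    temperature_K = config$temperature_K,
    sample_label = config$sample_label
  )
  label <- data.frame(
    curve_id = curve_id,
    true_class = cls,
    true_rupture_force_pN = true_force,
    true_rupture_extension_nm = true_ext,
    true_plateau_force_pN = true_plateau,
    stringsAsFactors = FALSE
  )
  list(curve = curve, label = label)
}

#' Simulate a labelled ensemble of force curves
#'
#' Reproducible at two levels: the master seed fixes the whole stream, and
#' each curve gets its own derived sub-seed so any single curve can be
#' regenerated in isolation.
#'
#' @param config A [simulation_config()].
#' @return A list of class `simulated_ensemble`: `curves` (list of
#'   [force_curve()]), `labels` (data.frame, one row per curve), `config`.
#' @examples
#' sim <- simulate_ensemble(simulation_config(n_curves = 5, seed = 42))
#' sim$labels$true_class
#' @export
simulate_ensemble <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  curve_seeds <- sample.int(.Machine$integer.max - 1L, config$n_curves)
  ids <- sprintf("curve_%05d", seq_len(config$n_curves))
  out <- vector("list", config$n_curves)
  for (i in seq_len(config$n_curves)) {
    out[[i]] <- simulate_retract_curve(config, ids[i], seed = curve_seeds[i])
  }
  labels <- do.call(rbind, lapply(out, `[[`, "label"))
  rownames(labels) <- NULL
  structure(
    list(
      curves = lapply(out, `[[`, "curve"),
      labels = labels,
      config = config
    ),
    class = "simulated_ensemble"
  )
}

#' @export
print.simulated_ensemble <- function(x, ...) {
  tab <- table(x$labels$true_class)
  cat(sprintf("Simulated ensemble: %d curves (seed %d)\n",
              length(x$curves), x$config$seed))
  print(tab)
  invisible(x)
}

#' Write an ensemble to disk (curves, labels, manifest)
#'
#' @param ensemble A [simulate_ensemble()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "simulated_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cv in ensemble$curves) {
    write_curve(cv, file.path(dir, paste0(cv$curve_id, ".tsv")))
  }
  utils::write.table(
    ensemble$labels, file.path(dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_manifest(ensemble$curves, dir)
  invisible(dir)
}
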