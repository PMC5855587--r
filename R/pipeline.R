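#' Pipeline configuration
#'
#' Bundles every stage's parameters: simulation (or an existing curve
#' directory for analysis-only runs), detection thresholds, histogram
#' binning, confidence levels, and the peeling segment.  Defaults equal
#' the corresponding module-level defaults throughout.
#'
#' @param simulation A [simulation_config()], or `NULL` for an
#'   analysis-only run on `curves_dir`.
#' @param curves_dir Directory with curve TSVs and a `manifest.json`
#'   (used when `simulation` is `NULL`).
#' @param min_force_pN Rupture detection floor (pN).
#' @param window_nm Extension acceptance window (nm).
#' @param fit_tether Store per-event WLC contour length and residual.
#' @param min_plateau_nm Minimum peeling-plateau length (nm).
#' @param bin_width_pN Histogram bin width (pN).
#' @param n_peaks Number of Gaussian peaks fitted to the force histogram.
#' @param conf_level Confidence level for intervals.
#' @param peeling_segment_nm Integration segment for peeling work (nm).
#' @param residues_per_nm Polymer residue line density (per nm).
#' @param outdir Output directory, or `NULL` to keep results in memory.
#' @param write_curves Also write every simulated curve TSV (slow for
#'   large ensembles).
#' @param seed Master seed; overrides the simulation config's seed so one
#'   number fixes the whole run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            curves_dir = NULL,
                            min_force_pN = 10,
                            window_nm = c(15, 60),
                            fit_tether = FALSE,
                            min_plateau_nm = 20,
                            bin_width_pN = 10,
                            n_peaks = 1,
                            conf_level = 0.95,
                            peeling_segment_nm = c(20, 80),
                            residues_per_nm = 3,
                            outdir = NULL,
                            write_curves = FALSE,
                            seed = NULL) {
  if (is.null(simulation) && is.null(curves_dir)) {
    stop("either a simulation config or a curve directory is required",
         call. = FALSE)
  }
  if (!is.null(simulation)) {
    stopifnot(inherits(simulation, "simulation_config"))
    if (!is.null(seed)) simulation$seed <- as.integer(seed)
  }
  structure(
    list(
      simulation = simulation,
      curves_dir = curves_dir,
      min_force_pN = min_force_pN,
      window_nm = window_nm,
      fit_tether = isTRUE(fit_tether),
      min_plateau_nm = min_plateau_nm,
      bin_width_pN = bin_width_pN,
      n_peaks = as.integer(n_peaks),
      conf_level = conf_level,
      peeling_segment_nm = peeling_segment_nm,
      residues_per_nm = residues_per_nm,
      outdir = outdir,
      write_curves = isTRUE(write_curves)
    ),
    class = "pipeline_config"
  )
}

#' Write a pipeline configuration to YAML
#'
#' @param config A [pipeline_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- rapply(unclass(config), identity, how = "replace")
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Round-trips losslessly with [write_pipeline_config()].
#'
#' @param path YAML file written by [write_pipeline_config()].
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(lst$simulation)) {
    s <- lst$simulation
    sim <- simulation_config(
      n_curves = s$n_curves,
      p_specific = s$p_specific,
      p_nonspecific = s$p_nonspecific,
      p_plateau = s$p_plateau,
      rupture_force_model = s$rupture_force_model,
      tether = wlc_params(s$tether$persistence_length_nm,
                          s$tether$contour_length_nm,
                          s$tether$temperature_K),
      contour_length_jitter_nm = s$contour_length_jitter_nm,
      noise_sd_pN = s$noise_sd_pN,
      baseline_drift_pN_per_um = s$baseline_drift_pN_per_um,
      nonspecific_model = s$nonspecific_model,
      plateau_model = s$plateau_model,
      curve_length_um = s$curve_length_um,
      points_per_curve = s$points_per_curve,
      spring_constant_nN_per_nm = s$spring_constant_nN_per_nm,
      pulling_speed_um_per_s = s$pulling_speed_um_per_s,
      temperature_K = s$temperature_K,
      sample_label = s$sample_label,
      include_approach = s$include_approach,
      contact_depth_nm = s$contact_depth_nm,
      seed = s$seed
    )
  }
  pipeline_config(
    simulation = sim,
    curves_dir = lst$curves_dir,
    min_force_pN = lst$min_force_pN,
    window_nm = unlist(lst$window_nm),
    fit_tether = lst$fit_tether,
    min_plateau_nm = lst$min_plateau_nm,
    bin_width_pN = lst$bin_width_pN,
    n_peaks = lst$n_peaks,
    conf_level = lst$conf_level,
    peeling_segment_nm = unlist(lst$peeling_segment_nm),
    residues_per_nm = lst$residues_per_nm,
    outdir = lst$outdir,
    write_curves = lst$write_curves
  )
}

#' Run the simulate / detect / summarise pipeline
#'
#' Simulates (or loads) an ensemble, classifies every curve, builds the
#' unbinding-force histogram and fits the most probable force(s),
#' computes the binding frequency with its Wilson interval, integrates
#' peeling work on plateau curves, and assembles a per-sample summary
#' table (sample, MPF(s), relative frequency).  Deterministic for a
#' fixed seed.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `pipeline_result` with elements `labels`
#'   (`NULL` for analysis-only runs), `classifications`, `events`,
#'   `histogram`, `mpf` (list of [mpf_result()]), `frequency`
#'   ([binding_frequency()]), `peeling` (list of `peeling_result`),
#'   `summary` (data.frame), `performance` (when labels exist), `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  labels <- NULL
  if (!is.null(config$simulation)) {
    sim <- simulate_ensemble(config$simulation)
    curves <- sim$curves
    labels <- sim$labels
    say("simulate: %d curves (seed %d): %s", length(curves),
        config$simulation$seed,
        paste(sprintf("%s=%d", names(table(labels$true_class)),
                      as.integer(table(labels$true_class))), collapse = ", "))
  } else {
    curves <- read_manifest(file.path(config$curves_dir, "manifest.json"))
    say("load: %d curves from %s", length(curves), config$curves_dir)
  }
  sample_label <- if (length(curves)) curves[[1]]$sample_label else "unknown"

  cl <- classify_ensemble(
    curves,
    min_force_pN = config$min_force_pN, window_nm = config$window_nm,
    fit_tether = config$fit_tether, min_plateau_nm = config$min_plateau_nm
  )
  n_rejected <- sum(vapply(cl$details, function(d) nrow(d$rejected), 0L))
  say("detect: %d accepted events on %d specific curves; %d candidates rejected by the %g-%g nm window",
      nrow(cl$events), sum(cl$classifications$class == "specific"),
      n_rejected, config$window_nm[1], config$window_nm[2])

  freq <- binding_frequency(cl$classifications, config$conf_level)
  forces <- cl$classifications$rupture_force_pN[
    cl$classifications$class == "specific"]
  histogram <- NULL
  mpf <- list()
  if (length(forces) >= 1L) {
    histogram <- build_histogram(forces, config$bin_width_pN)
    mpf <- tryCatch(
      fit_multi_mpf(histogram, config$n_peaks),
      error = function(e) {
        say("stats: MPF fit skipped (%s)", conditionMessage(e))
        list()
      }
    )
  }
  if (length(mpf)) {
    say("stats: MPF %s pN from %d events",
        paste(sprintf("%.1f", vapply(mpf, `[[`, 0, "mode_pN")), collapse = "/"),
        length(forces))
  }

  plateau_ids <- cl$classifications$curve_id[cl$classifications$class == "plateau"]
  peeling <- list()
  for (id in plateau_ids) {
    cv <- curves[[match(id, vapply(curves, `[[`, "", "curve_id"))]]
    pr <- tryCatch(
      peeling_work(cv, config$peeling_segment_nm, config$residues_per_nm),
      error = function(e) NULL
    )
    if (!is.null(pr)) peeling[[id]] <- pr
  }
  if (length(plateau_ids)) {
    say("peel: %d plateau curves, %d integrable over [%g, %g] nm",
        length(plateau_ids), length(peeling),
        config$peeling_segment_nm[1], config$peeling_segment_nm[2])
  }

  performance <- if (!is.null(labels)) {
    detection_performance(labels, cl$classifications)
  }

  summary <- data.frame(
    sample_label = sample_label,
    n_total = freq$n_total,
    n_specific = freq$n_specific,
    MPF_pN = if (length(mpf)) {
      paste(sprintf("%.0f", vapply(mpf, `[[`, 0, "mode_pN")), collapse = ", ")
    } else "-",
    relative_frequency_pct = round(100 * freq$fraction, 1),
    frequency_ci_pct = sprintf("%.1f-%.1f", 100 * freq$ci[1], 100 * freq$ci[2]),
    stringsAsFactors = FALSE
  )

  result <- structure(
    list(
      labels = labels, classifications = cl$classifications,
      events = cl$events, histogram = histogram, mpf = mpf,
      frequency = freq, peeling = peeling, summary = summary,
      performance = performance, config = config
    ),
    class = "pipeline_result"
  )
  if (!is.null(config$outdir)) {
    write_pipeline_result(result, config$outdir,
                          curves = if (config$write_curves) curves)
  }
  result
}

#' Write the result bundle of a pipeline run
#'
#' @param result A `pipeline_result`.
#' @param outdir Output directory (created if needed).
#' @param curves Optional curve list to write alongside.
#' @return `outdir`, invisibly.
#' @export
write_pipeline_result <- function(result, outdir, curves = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) utils::write.table(
    df, file.path(outdir, name), sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(result$labels)) wt(result$labels, "labels.tsv")
  wt(result$classifications, "classifications.tsv")
  if (!is.null(result$events) && nrow(result$events)) wt(result$events, "events.tsv")
  wt(result$summary, "summary.tsv")
  res <- list(
    sample_label = result$summary$sample_label,
    n_total = result$frequency$n_total,
    n_specific = result$frequency$n_specific,
    frequency = result$frequency$fraction,
    frequency_ci = result$frequency$ci,
    peaks = lapply(result$mpf, function(m) {
      list(MPF_pN = m$mode_pN, sigma_pN = m$sigma_pN, n = m$n_events)
    }),
    peeling = lapply(result$peeling, function(p) {
      list(mean_force_pN = p$mean_force_pN, work_J = p$work_J,
           per_residue_energy_kJ_per_mol = p$per_residue_energy_kJ_per_mol)
    })
  )
  jsonlite::write_json(res, file.path(outdir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(curves)) {
    cdir <- file.path(outdir, "curves")
    dir.create(cdir, showWarnings = FALSE)
    for (cv in curves) write_curve(cv, file.path(cdir, paste0(cv$curve_id, ".tsv")))
    write_manifest(curves, cdir)
  }
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Simulate a ligand-length series with multivalent binding frequencies
#'
#' Runs one pipeline per oligomer length with the per-curve specific
#' binding probability set to the multivalency predictor 1 - (1-p)^n,
#' reproducing the qualitative monomer < dimer < trimer < pentamer
#' frequency ordering.
#'
#' @param n_sites Integer vector of site counts (default `c(1, 2, 3, 5)`).
#' @param per_site_probability Per-site binding probability p.
#' @param base_config A [simulation_config()] template.
#' @param seed Master seed (one sub-seed per series member).
#' @param quiet Passed to [run_pipeline()].
#' @return A data.frame: `n_sites`, `W`, `predicted_probability`,
#'   `observed_frequency`, `n_specific`, `n_total`.
#' @export
run_length_series <- function(n_sites = c(1, 2, 3, 5),
                              per_site_probability = 0.03,
                              base_config = simulation_config(n_curves = 400),
                              seed = 1L, quiet = TRUE) {
  pred <- multivalency_result(n_sites, per_site_probability)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(n_sites))
  rows <- lapply(seq_along(n_sites), function(i) {
    cfg <- base_config
    cfg$p_specific <- pred$predicted_binding_probability[i]
    cfg$seed <- sub_seeds[i]
    cfg$sample_label <- sprintf("n%d", n_sites[i])
    res <- run_pipeline(pipeline_config(simulation = cfg), quiet = quiet)
    data.frame(
      n_sites = n_sites[i],
      W = pred$W[i],
      predicted_probability = pred$predicted_binding_probability[i],
      observed_frequency = res$frequency$fraction,
      n_specific = res$frequency$n_specific,
      n_total = res$frequency$n_total
    )
  })
  do.call(rbind, rows)
}
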