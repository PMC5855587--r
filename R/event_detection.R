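#' Baseline and contact-point estimation for a retract trace
#'
#' The baseline (free-cantilever force level) is fitted by least squares
#' on the final 20% of the retract trace, farthest from the surface.  The
#' contact point is the first piezo position at which the smoothed,
#' baseline-corrected force crosses zero coming down from the repulsive
#' contact wall; the extension axis is zeroed there.  The baseline noise
#' SD is estimated from the residuals of the baseline fit.
#'
#' @param curve A [force_curve()] with a retract segment spanning well
#'   beyond the last contact.
#' @param smooth_n Savitzky-Golay window (samples, odd); order is 2.
#' @details
#' The tail fit alone extrapolates poorly into the event region (a small
#' slope error grows over hundreds of nm), so a second pass refits the
#' line on every sample of the whole retract trace lying within 4 noise
#' SDs of the first-pass line; events and the contact wall are excluded
#' automatically by that cut.  The contact point is located by fitting a
#' straight line to the raw repulsive-wall samples and taking its
#' baseline crossing, which avoids the bias a smoothing filter puts on a
#' sharp corner; if the wall is too short to fit, the first
#' smoothed-trace zero crossing is used instead.
#' @return A list of class `baseline_fit`: `offset_pN`, `slope_pN_per_nm`,
#'   `contact_nm` (`NA` if no repulsive wall is found), `noise_pN`,
#'   `drift_warning`.
#' @export
estimate_baseline_and_contact <- function(curve, smooth_n = 11) {
  stopifnot(inherits(curve, "force_curve"))
  d <- curve_segment(curve, "retract")
  n <- nrow(d)
  if (n < 50L) stop("retract segment too short", call. = FALSE)
  z <- d$piezo_position_nm
  f <- d$force_pN

  # pass 1: the final 20% of the trace, farthest from the surface
  tail_idx <- which(z >= z[n] - 0.2 * (z[n] - z[1]))
  fit <- stats::lm.fit(cbind(1, z[tail_idx]), f[tail_idx])
  offset <- fit$coefficients[[1]]
  slope <- fit$coefficients[[2]]
  noise <- stats::sd(fit$residuals)
  if (!is.finite(noise) || noise < 1e-9) noise <- 1e-9

  # pass 2: refit on all quiet samples to pin the slope over the full span.
  # Quiet = within 4 noise SDs of the pass-1 line AND no smoothed signal:
  # the second (symmetric) cut keeps the low-force foot of an adhesion
  # ramp out of the fit, which would otherwise drag the baseline down.
  resid1 <- f - (offset + slope * z)
  s1 <- signal::sgolayfilt(resid1, p = 2, n = smooth_n)
  gain <- sqrt(sum(signal::sgolay(p = 2, n = smooth_n)[(smooth_n + 1) / 2, ]^2))
  quiet <- abs(resid1) < 4 * noise & abs(s1) < 3 * gain * noise
  if (sum(quiet) >= 100L) {
    fit2 <- stats::lm.fit(cbind(1, z[quiet]), f[quiet])
    offset <- fit2$coefficients[[1]]
    slope <- fit2$coefficients[[2]]
    noise2 <- stats::sd(fit2$residuals)
    if (is.finite(noise2) && noise2 > 1e-9) noise <- noise2
  }

  drift_warning <- abs(slope) * 100 > 2 * noise
  if (drift_warning) {
    warning(sprintf("curve '%s': baseline drift %.3g pN per 100 nm exceeds 2x noise",
                    curve$curve_id, abs(slope) * 100), call. = FALSE)
  }

  corrected <- f - (offset + slope * z)
  s <- signal::sgolayfilt(corrected, p = 2, n = smooth_n)
  contact <- NA_real_
  # repulsive wall present if the trace starts well above the noise
  if (s[1] > 5 * noise) {
    wall <- which(cumsum(corrected <= 8 * noise) == 0)  # leading run above
    if (length(wall) >= 5L) {
      w <- wall[max(1L, length(wall) - 19L):length(wall)]
      wfit <- stats::lm.fit(cbind(1, z[w]), corrected[w])
      if (is.finite(wfit$coefficients[[2]]) && wfit$coefficients[[2]] < 0) {
        contact <- -wfit$coefficients[[1]] / wfit$coefficients[[2]]
      }
    }
    if (is.na(contact) || contact < z[1] ||
        contact > z[min(n, max(1L, length(wall)) + 50L)]) {
      below <- which(s <= 0)
      below <- below[below > 1]
      contact <- if (length(below)) z[below[1]] else NA_real_
    }
  }
  structure(
    list(
      offset_pN = offset, slope_pN_per_nm = slope,
      contact_nm = contact, noise_pN = noise,
      drift_warning = drift_warning
    ),
    class = "baseline_fit"
  )
}

# Baseline-corrected adhesion trace for the retract segment:
# positive values = adhesive (tensile) load. Returns z, adhesion (raw and
# smoothed), and the tether extension axis x = (z - contact) - |defl|.
.adhesion_trace <- function(curve, baseline, smooth_n = 11) {
  d <- curve_segment(curve, "retract")
  z <- d$piezo_position_nm
  corr <- d$force_pN - (baseline$offset_pN + baseline$slope_pN_per_nm * z)
  a <- -corr
  s <- signal::sgolayfilt(a, p = 2, n = smooth_n)
  k_pN <- curve$spring_constant_nN_per_nm * 1000
  contact <- if (is.na(baseline$contact_nm)) z[1] else baseline$contact_nm
  x <- (z - contact) - pmax(a, 0) / k_pN
  list(z = z, a = a, s = s, x = x, contact = contact, k_pN = k_pN)
}

#' Detect rupture events in a retract curve and classify it
#'
#' Candidate ruptures are contiguous stretches where the smoothed
#' adhesion force stays at or above `min_force_pN` and then drops
#' abruptly to within twice the baseline noise.  The rupture index is
#' refined on the unsmoothed trace as the largest single-sample force
#' drop near the end of the stretch, and the rupture force is read from
#' the unsmoothed data at that index, so smoothing never attenuates the
#' reported force.  Events whose tether extension falls inside the
#' acceptance window are accepted; events below the window mark the
#' curve as non-specific adhesion (unless an accepted event coexists);
#' no candidates at all means no adhesion.
#'
#' @param curve A [force_curve()].
#' @param baseline Optional [estimate_baseline_and_contact()] result.
#' @param min_force_pN Detection floor: ruptures shallower than this are
#'   below the instrument's resolution (default 10 pN).
#' @param window_nm Extension acceptance window, default `c(15, 60)` nm:
#'   below it adhesion is considered non-specific, above it the tether
#'   cannot reach.
#' @param fit_tether Fit a WLC to the stretch preceding each accepted
#'   event and store contour length and residual RMS (plausibility score,
#'   not a rejection rule).
#' @param smooth_n Savitzky-Golay window (samples).
#' @return A list of class `curve_events`: `curve_id`, `class` (one of
#'   `no_adhesion`, `nonspecific`, `specific`), `events` (data.frame of
#'   accepted events: `curve_id`, `rupture_force_pN`,
#'   `rupture_extension_nm`, `step_height_pN`, `wlc_Lc_nm`,
#'   `wlc_residual_pN`), `rejected` (candidates outside the window),
#'   `headline_force_pN` (force of the final accepted rupture, the
#'   largest-extension one), `baseline`.
#' @export
detect_ruptures <- function(curve, baseline = NULL, min_force_pN = 10,
                            window_nm = c(15, 60), fit_tether = FALSE,
                            smooth_n = 11) {
  stopifnot(inherits(curve, "force_curve"),
            length(window_nm) == 2L, window_nm[1] < window_nm[2])
  if (is.null(baseline)) {
    baseline <- suppressWarnings(estimate_baseline_and_contact(curve, smooth_n))
  }
  tr <- .adhesion_trace(curve, baseline, smooth_n)
  n <- length(tr$z)
  noise <- baseline$noise_pN
  no_contact <- is.na(baseline$contact_nm)

  # candidate stretches: smoothed adhesion >= min_force, past the contact.
  # The stretch peak must additionally clear the smoothed-noise ceiling:
  # smoothing attenuates the baseline noise by a known gain, and the
  # per-curve maximum of that residual reaches ~4.5 of its SDs, so a
  # 5.5-SD peak threshold keeps noise-only curves out without touching
  # ruptures at or above the 10 pN instrument floor in quiet data.
  sg_gain <- sqrt(sum(signal::sgolay(p = 2, n = smooth_n)[(smooth_n + 1) / 2, ]^2))
  peak_floor <- max(min_force_pN, 5.5 * noise * sg_gain)
  eligible <- tr$s >= min_force_pN & tr$z > tr$contact
  ev <- list()
  seen_idx <- integer(0)
  if (any(eligible)) {
    r <- rle(eligible)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    step_win <- max(15L, smooth_n + 4L)
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      if (i1 >= n - 1L) next               # runs off the end of the trace
      if (max(tr$s[i0:i1]) < peak_floor) next
      post <- tr$s[(i1 + 1L):min(i1 + step_win, n)]
      if (min(post) > 2 * noise) next      # no step back to baseline
      # refine the rupture index on the raw trace: largest one-sample drop
      jr <- max(i0, i1 - 10L):min(i1 + step_win, n - 1L)
      j <- jr[which.max(tr$a[jr] - tr$a[jr + 1L])]
      if (j %in% seen_idx) next
      seen_idx <- c(seen_idx, j)
      force <- tr$a[j]
      if (!is.finite(force) || force < min_force_pN) next
      ev[[length(ev) + 1L]] <- data.frame(
        curve_id = curve$curve_id,
        rupture_force_pN = force,
        rupture_extension_nm = max(0, tr$x[j]),
        step_height_pN = tr$a[j] - tr$a[j + 1L],
        ramp_start_idx = i0, rupture_idx = j,
        stringsAsFactors = FALSE
      )
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else data.frame(
    curve_id = character(), rupture_force_pN = numeric(),
    rupture_extension_nm = numeric(), step_height_pN = numeric(),
    ramp_start_idx = integer(), rupture_idx = integer(),
    stringsAsFactors = FALSE
  )

  inside <- events$rupture_extension_nm >= window_nm[1] &
    events$rupture_extension_nm <= window_nm[2]
  accepted <- events[inside, , drop = FALSE]
  rejected <- events[!inside, , drop = FALSE]

  accepted$wlc_Lc_nm <- rep(NA_real_, nrow(accepted))
  accepted$wlc_residual_pN <- rep(NA_real_, nrow(accepted))
  if (fit_tether && nrow(accepted)) {
    for (i in seq_len(nrow(accepted))) {
      idx <- accepted$ramp_start_idx[i]:accepted$rupture_idx[i]
      if (length(idx) >= 10L) {
        wf <- fit_wlc(tr$x[idx], tr$a[idx], curve$temperature_K)
        if (wf$converged) {
          accepted$wlc_Lc_nm[i] <- wf$params$contour_length_nm
          accepted$wlc_residual_pN[i] <- wf$residual_rms_pN
        }
      }
    }
  }
  accepted$ramp_start_idx <- NULL
  accepted$rupture_idx <- NULL
  rejected$ramp_start_idx <- NULL
  rejected$rupture_idx <- NULL

  cls <- if (nrow(accepted)) {
    "specific"
  } else if (nrow(rejected) &&
             any(rejected$rupture_extension_nm < window_nm[1])) {
    "nonspecific"
  } else {
    "no_adhesion"
  }
  if (no_contact && nrow(accepted) == 0L && nrow(rejected) == 0L) {
    cls <- "no_adhesion"
  }

  headline <- NA_real_
  if (nrow(accepted)) {
    # single-tether interpretation: the final rupture (largest extension)
    # is the curve's unbinding force; ties on extension go to the larger force
    o <- order(accepted$rupture_extension_nm, accepted$rupture_force_pN)
    headline <- accepted$rupture_force_pN[o[length(o)]]
  }
  structure(
    list(
      curve_id = curve$curve_id, class = cls,
      events = accepted, rejected = rejected,
      headline_force_pN = headline,
      baseline = baseline
    ),
    class = "curve_events"
  )
}

#' Detect a constant-force peeling plateau
#'
#' Searches for the longest contiguous stretch of at least
#' `min_length_nm` where the smoothed adhesion force stays at or above
#' `min_force_pN`, remains within +/- 2 baseline-noise SDs of its own
#' mean (tested on the smoothed trace, with the smeared rise/fall edges
#' trimmed), and terminates in a step back to baseline.
#'
#' @inheritParams detect_ruptures
#' @param min_length_nm Minimum plateau length (default 20 nm).
#' @return `NULL` if no plateau, else a list of class `plateau_segment`:
#'   `start_nm`, `end_nm` (extension axis), `mean_force_pN`, `length_nm`.
#' @export
detect_plateau <- function(curve, baseline = NULL, min_force_pN = 10,
                           min_length_nm = 20, smooth_n = 11) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(baseline)) {
    baseline <- suppressWarnings(estimate_baseline_and_contact(curve, smooth_n))
  }
  tr <- .adhesion_trace(curve, baseline, smooth_n)
  n <- length(tr$z)
  noise <- baseline$noise_pN
  eligible <- tr$s >= min_force_pN & tr$z > tr$contact
  if (!any(eligible)) return(NULL)
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- NULL
  trim <- smooth_n + 4L
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i1 >= n - 1L) next
    j0 <- i0 + trim; j1 <- i1 - trim
    if (j1 <= j0) next
    span <- tr$x[j1] - tr$x[j0]
    if (span < min_length_nm) next
    seg_s <- tr$s[j0:j1]
    if (max(seg_s) - mean(seg_s) > 2 * noise) next
    if (mean(seg_s) - min(seg_s) > 2 * noise) next
    # terminal step to baseline
    post <- tr$s[(i1 + 1L):min(i1 + trim + 15L, n)]
    if (min(post) > 2 * noise) next
    if (is.null(best) || span > best$length_nm) {
      best <- structure(
        list(
          start_nm = tr$x[j0], end_nm = tr$x[j1],
          mean_force_pN = mean(tr$a[j0:j1]),
          length_nm = span
        ),
        class = "plateau_segment"
      )
    }
  }
  best
}

#' Classify a retract curve
#'
#' Applies the full taxonomy used for curve bookkeeping: `specific`
#' (accepted tether-mediated rupture inside the extension window),
#' `plateau` (constant-force peeling segment), `nonspecific` (adhesion
#' only below the window), or `no_adhesion`.  A detected plateau takes
#' precedence over an accepted event: a constant-force segment ending in
#' a detachment step is a peeling curve, not a tether rupture, even when
#' the detachment happens to fall inside the window.
#'
#' @inheritParams detect_ruptures
#' @param min_plateau_nm Minimum plateau length passed to
#'   [detect_plateau()].
#' @return A `curve_events` object (see [detect_ruptures()]) whose
#'   `class` may additionally be `"plateau"`, with a `plateau` element.
#' @export
classify_curve <- function(curve, baseline = NULL, min_force_pN = 10,
                           window_nm = c(15, 60), fit_tether = FALSE,
                           min_plateau_nm = 20, smooth_n = 11) {
  if (is.null(baseline)) {
    baseline <- suppressWarnings(estimate_baseline_and_contact(curve, smooth_n))
  }
  res <- detect_ruptures(curve, baseline, min_force_pN, window_nm,
                         fit_tether, smooth_n)
  pl <- detect_plateau(curve, baseline, min_force_pN, min_plateau_nm, smooth_n)
  res$plateau <- pl
  if (!is.null(pl)) res$class <- "plateau"
  res
}

#' Classify every curve of an ensemble
#'
#' @param curves List of [force_curve()] objects (or a
#'   `simulated_ensemble`).
#' @inheritParams classify_curve
#' @return A list with `classifications` (data.frame: `curve_id`, `class`,
#'   headline `rupture_force_pN`, `rupture_extension_nm`,
#'   `plateau_force_pN`), `events` (data.frame of all accepted events),
#'   and `details` (list of `curve_events`).
#' @export
classify_ensemble <- function(curves, min_force_pN = 10,
                              window_nm = c(15, 60), fit_tether = FALSE,
                              min_plateau_nm = 20, smooth_n = 11) {
  if (inherits(curves, "simulated_ensemble")) curves <- curves$curves
  details <- lapply(curves, classify_curve,
                    min_force_pN = min_force_pN, window_nm = window_nm,
                    fit_tether = fit_tether, min_plateau_nm = min_plateau_nm,
                    smooth_n = smooth_n)
  classifications <- do.call(rbind, lapply(details, function(d) {
    last_ext <- if (nrow(d$events)) max(d$events$rupture_extension_nm) else NA_real_
    data.frame(
      curve_id = d$curve_id,
      class = d$class,
      rupture_force_pN = d$headline_force_pN,
      rupture_extension_nm = last_ext,
      plateau_force_pN = if (!is.null(d$plateau)) d$plateau$mean_force_pN else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  events <- do.call(rbind, lapply(details, `[[`, "events"))
  list(classifications = classifications, events = events, details = details)
}

#' Detection performance against ground-truth labels
#'
#' Sensitivity is the fraction of specific curves whose true event meets
#' the acceptance criteria -- rupture force at or above the floor and
#' true extension inside the window -- that were classified specific.
#' Specific events whose true extension falls outside the window are
#' excluded from the denominator: the window filter rejects them by
#' design, so they are not detection failures (the filter's exactness is
#' a separate check).  The false-positive rate is the fraction of curves
#' with no specific event (no-adhesion or non-specific labels) that were
#' classified specific.
#'
#' @param labels Ground-truth label data.frame from
#'   [simulate_ensemble()].
#' @param classifications Classification data.frame from
#'   [classify_ensemble()].
#' @param min_true_force_pN Restrict the sensitivity denominator to true
#'   forces at or above this value (default 30 pN).
#' @param window_nm Extension acceptance window used in detection.
#' @return A list: `sensitivity`, `false_positive_rate`,
#'   `force_bias_pN` (mean of detected minus true force over matched
#'   specific curves), `n_true_specific` (denominator of sensitivity),
#'   `n_out_of_window` (specific curves excluded from it), `n_negatives`.
#' @export
detection_performance <- function(labels, classifications,
                                  min_true_force_pN = 30,
                                  window_nm = c(15, 60)) {
  m <- merge(labels, classifications, by = "curve_id")
  spec <- m$true_class == "specific" &
    m$true_rupture_force_pN >= min_true_force_pN
  in_win <- m$true_rupture_extension_nm >= window_nm[1] &
    m$true_rupture_extension_nm <= window_nm[2]
  pos <- spec & in_win
  neg <- m$true_class %in% c("no_adhesion", "nonspecific")
  sens <- mean(m$class[pos] == "specific")
  fpr <- mean(m$class[neg] == "specific")
  matched <- pos & m$class == "specific"
  bias <- mean(m$rupture_force_pN[matched] - m$true_rupture_force_pN[matched])
  list(
    sensitivity = sens, false_positive_rate = fpr,
    force_bias_pN = bias,
    n_true_specific = sum(pos),
    n_out_of_window = sum(spec & !in_win),
    n_negatives = sum(neg)
  )
}
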