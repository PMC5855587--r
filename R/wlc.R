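#' Worm-like-chain (WLC) tether parameters
#'
#' Parameter container for the Marko-Siggia interpolation of the worm-like
#' chain force-extension relation, used to model the PEG crosslinker that
#' tethers the ligand to the AFM tip.
#'
#' @param persistence_length_nm Persistence length Lp in nm. The package
#'   default elsewhere is 0.1 nm, the value used to model the PEG spacer.
#' @param contour_length_nm Contour length Lc in nm (PEG of MW ~4000 is
#'   maximally ~30-40 nm long).
#' @param temperature_K Temperature in K.
#' @return An object of class `wlc_params`.
#' @seealso [wlc_force()], [wlc_extension()], [fit_wlc()]
#' @examples
#' wlc_params(0.1, 35, 298)
#' @export
wlc_params <- function(persistence_length_nm, contour_length_nm,
                       temperature_K = 298) {
  stopifnot(
    is.numeric(persistence_length_nm), length(persistence_length_nm) == 1L,
    persistence_length_nm > 0,
    is.numeric(contour_length_nm), length(contour_length_nm) == 1L,
    contour_length_nm > 0,
    is.numeric(temperature_K), length(temperature_K) == 1L,
    temperature_K > 0
  )
  structure(
    list(
      persistence_length_nm = persistence_length_nm,
      contour_length_nm = contour_length_nm,
      temperature_K = temperature_K
    ),
    class = "wlc_params"
  )
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf(
    "WLC parameters: Lp = %g nm, Lc = %g nm, T = %g K (kBT = %.4g pN nm)\n",
    x$persistence_length_nm, x$contour_length_nm, x$temperature_K,
    kBT_pN_nm(x$temperature_K)
  ))
  invisible(x)
}

#' WLC force at a given extension
#'
#' Marko-Siggia interpolation:
#' F(x) = (kB T / Lp) * (1 / (4 (1 - x/Lc)^2) - 1/4 + x/Lc).
#' F(0) = 0, F is strictly increasing, and diverges as x approaches Lc.
#'
#' @param x_nm Extension(s) in nm; must satisfy 0 <= x < Lc.
#' @param params A [wlc_params()] object.
#' @return Force(s) in pN.
#' @examples
#' p <- wlc_params(0.1, 40, 298)
#' wlc_force(20, p)  # 51.4 pN
#' @export
wlc_force <- function(x_nm, params) {
  stopifnot(inherits(params, "wlc_params"), is.numeric(x_nm))
  Lc <- params$contour_length_nm
  if (any(x_nm < 0)) stop("extension must be >= 0", call. = FALSE)
  if (any(x_nm >= Lc)) {
    stop("extension must be strictly below the contour length", call. = FALSE)
  }
  t <- x_nm / Lc
  kBT_pN_nm(params$temperature_K) / params$persistence_length_nm *
    (1 / (4 * (1 - t)^2) - 0.25 + t)
}

#' Extension at a given WLC force (numerical inverse)
#'
#' Inverts [wlc_force()] by vectorised bisection on [0, Lc). Round-trips
#' satisfy `wlc_force(wlc_extension(F)) == F` to better than 1e-9 relative.
#'
#' @param force_pN Force(s) in pN, >= 0.
#' @param params A [wlc_params()] object.
#' @return Extension(s) in nm.
#' @examples
#' p <- wlc_params(0.1, 40, 298)
#' wlc_extension(51.425, p)  # 20 nm
#' @export
wlc_extension <- function(force_pN, params) {
  stopifnot(inherits(params, "wlc_params"), is.numeric(force_pN))
  if (any(force_pN < 0)) stop("force must be >= 0", call. = FALSE)
  Lc <- params$contour_length_nm
  lo <- rep(0, length(force_pN))
  hi <- rep(Lc * (1 - 1e-12), length(force_pN))
  # 100 bisection steps: interval width Lc * 2^-100, far below any tolerance
  for (i in seq_len(100)) {
    mid <- (lo + hi) / 2
    f_mid <- wlc_force(mid, params)
    take_lo <- f_mid < force_pN
    lo[take_lo] <- mid[take_lo]
    hi[!take_lo] <- mid[!take_lo]
  }
  out <- (lo + hi) / 2
  out[force_pN == 0] <- 0
  out
}

#' Fit a WLC model to an extension-force segment
#'
#' Least-squares fit of the Marko-Siggia relation to a tether-stretch
#' segment, estimating the contour length Lc (and optionally the
#' persistence length Lp). The residual RMS is retained as a plausibility
#' score for specific tether-mediated events; it is reported, not used to
#' reject events, because experimental PEG stretches deviate systematically
#' from the ideal WLC shape.
#'
#' @param extension_nm Extensions in nm.
#' @param force_pN Forces in pN (same length).
#' @param temperature_K Temperature in K.
#' @param Lp_fixed_nm Persistence length held fixed during the fit
#'   (default 0.1 nm); pass `NULL` to fit Lp as a free parameter.
#' @return A list of class `wlc_fit` with elements `params`
#'   ([wlc_params()]), `residual_rms_pN`, `converged`, and `flagged`
#'   (`TRUE` when the fit failed or the residual exceeds `flag_rms_pN`).
#' @param flag_rms_pN Residual RMS (pN) above which the fit is flagged as
#'   implausible for a tether stretch (default 10 pN, twice the typical
#'   baseline noise).
#' @examples
#' p <- wlc_params(0.1, 35, 298)
#' x <- seq(2, 28, length.out = 50)
#' fit_wlc(x, wlc_force(x, p), 298)$params$contour_length_nm
#' @export
fit_wlc <- function(extension_nm, force_pN, temperature_K = 298,
                    Lp_fixed_nm = 0.1, flag_rms_pN = 10) {
  stopifnot(length(extension_nm) == length(force_pN))
  keep <- is.finite(extension_nm) & is.finite(force_pN) & extension_nm >= 0
  x <- extension_nm[keep]
  f <- force_pN[keep]
  if (length(x) < 10L) {
    stop("need at least 10 points to fit a WLC segment", call. = FALSE)
  }
  xmax <- max(x)
  if (xmax <= 0) stop("segment has no positive extension", call. = FALSE)
  kBT <- kBT_pN_nm(temperature_K)
  ms <- function(x, Lp, Lc) {
    t <- pmin(x / Lc, 1 - 1e-9)
    kBT / Lp * (1 / (4 * (1 - t)^2) - 0.25 + t)
  }
  dat <- data.frame(x = x, f = f)
  fit <- NULL
  if (is.null(Lp_fixed_nm)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        f ~ ms(x, Lp, Lc), data = dat,
        start = list(Lp = 0.1, Lc = xmax * 1.2),
        lower = c(1e-4, xmax * 1.0001),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      est <- stats::coef(fit)
      Lp_hat <- est[["Lp"]]
      Lc_hat <- est[["Lc"]]
    }
  } else {
    Lp_hat <- Lp_fixed_nm
    fit <- tryCatch(
      minpack.lm::nlsLM(
        f ~ ms(x, Lp_hat, Lc), data = dat,
        start = list(Lc = xmax * 1.2),
        lower = xmax * 1.0001,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) Lc_hat <- stats::coef(fit)[["Lc"]]
  }
  if (is.null(fit)) {
    return(structure(
      list(params = NULL, residual_rms_pN = NA_real_,
           converged = FALSE, flagged = TRUE),
      class = "wlc_fit"
    ))
  }
  rms <- sqrt(mean(stats::resid(fit)^2))
  structure(
    list(
      params = wlc_params(Lp_hat, Lc_hat, temperature_K),
      residual_rms_pN = rms,
      converged = TRUE,
      flagged = rms > flag_rms_pN
    ),
    class = "wlc_fit"
  )
}
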