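#' Statistical factor for an n-site multivalent ligand
#'
#' A ligand with n identical, independent binding sites has 2^n - 1
#' distinct bound configurations (every non-empty subset of sites)
#' against a single unbound state: W = 7 for n = 3, W = 31 for n = 5.
#'
#' @param n Number of binding sites (integer >= 1; vectorised).
#' @return W = 2^n - 1.
#' @examples
#' statistical_factor(c(1, 3, 5))
#' @export
statistical_factor <- function(n) {
  if (any(n < 1) || any(n != floor(n))) {
    stop("n must be a positive integer", call. = FALSE)
  }
  2^n - 1
}

#' Configurational entropy of binding
#'
#' Delta S = kB ln W, the entropy gain from the multiplicity of bound
#' configurations; zero when W = 1.
#'
#' @param W Number of bound configurations (>= 1; vectorised).
#' @return Entropy in J/K.
#' @examples
#' configurational_entropy(statistical_factor(3))
#' @export
configurational_entropy <- function(W) {
  if (any(W < 1)) stop("W must be >= 1", call. = FALSE)
  .kB_J_per_K * log(W)
}

#' Enumerate the bound states of an n-site ligand
#'
#' Brute-force oracle for [statistical_factor()]: lists every non-empty
#' subset of the n sites.
#'
#' @param n Number of sites (<= 20; use the closed form beyond that).
#' @return A list of integer vectors, one per bound configuration.
#' @examples
#' enumerate_bound_states(3)
#' @export
enumerate_bound_states <- function(n) {
  stopifnot(length(n) == 1L, n >= 1, n == floor(n))
  if (n > 20) {
    stop("refusing to enumerate beyond n = 20; use statistical_factor()",
         call. = FALSE)
  }
  unlist(
    lapply(seq_len(n), function(k) {
      m <- utils::combn(n, k)
      lapply(seq_len(ncol(m)), function(j) m[, j])
    }),
    recursive = FALSE
  )
}

#' Multivalent binding summary for an n-site ligand
#'
#' Combines the statistical factor and configurational entropy with an
#' optional per-site binding probability p, from which a predicted
#' binding probability 1 - (1 - p)^n is computed.  The predictor is an
#' extrapolation beyond the configurational-statistics argument itself
#' (the mapping from W to an observed frequency is not specified by the
#' model) and is flagged as such in the result.
#'
#' @param n_sites Number of binding sites.
#' @param per_site_probability Optional per-site binding probability p in
#'   (0, 1).
#' @return An object of class `multivalency_result`: `n_sites`, `W`,
#'   `delta_S_J_per_K`, and when p is supplied `per_site_probability`,
#'   `predicted_binding_probability`, `predictor_is_extrapolation = TRUE`.
#' @examples
#' multivalency_result(5, per_site_probability = 0.03)
#' @export
multivalency_result <- function(n_sites, per_site_probability = NULL) {
  W <- statistical_factor(n_sites)
  out <- list(
    n_sites = n_sites,
    W = W,
    delta_S_J_per_K = configurational_entropy(W)
  )
  if (!is.null(per_site_probability)) {
    p <- per_site_probability
    stopifnot(all(p > 0), all(p < 1))
    out$per_site_probability <- p
    out$predicted_binding_probability <- 1 - (1 - p)^n_sites
    out$predictor_is_extrapolation <- TRUE
  }
  structure(out, class = "multivalency_result")
}

#' @export
print.multivalency_result <- function(x, ...) {
  cat(sprintf("n = %s sites: W = %s bound states, delta S = %s J/K\n",
              paste(x$n_sites, collapse = ","),
              paste(x$W, collapse = ","),
              paste(signif(x$delta_S_J_per_K, 4), collapse = ",")))
  if (!is.null(x$predicted_binding_probability)) {
    cat(sprintf("predicted binding probability (extrapolated, p = %s): %s\n",
                paste(x$per_site_probability, collapse = ","),
                paste(signif(x$predicted_binding_probability, 4),
                      collapse = ",")))
  }
  invisible(x)
}
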