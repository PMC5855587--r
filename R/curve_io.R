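#' Construct a force curve
#'
#' The raw unit of analysis: one approach/retract cycle of an AFM force
#' measurement. Force in pN is derived on demand as
#' `spring_constant (nN/nm) * deflection (nm) * 1000`.
#'
#' Sign convention: cantilever deflection is negative while an adhesive
#' load bends the tip toward the surface during retraction, and positive
#' in the repulsive contact region.  Reported unbinding forces are
#' magnitudes (positive pN).  Piezo position increases as the tip is
#' retracted away from the surface.
#'
#' @param curve_id Unique curve identifier (character scalar).
#' @param segment Character vector, one of `"approach"`/`"retract"` per row.
#' @param piezo_position_nm Piezo position in nm, strictly monotone within
#'   each segment.
#' @param deflection_nm Cantilever deflection in nm.
#' @param spring_constant_nN_per_nm Cantilever spring constant in nN/nm.
#' @param pulling_speed_um_per_s Pulling speed in um/s.
#' @param temperature_K Temperature in K.
#' @param sample_label Label of the molecular species on the tip.
#' @return An object of class `force_curve`.
#' @examples
#' z <- seq(0, 100, by = 1)
#' force_curve("c1", rep("retract", length(z)), z, rnorm(length(z), 0, 0.1),
#'             spring_constant_nN_per_nm = 0.02)
#' @export
force_curve <- function(curve_id, segment, piezo_position_nm, deflection_nm,
                        spring_constant_nN_per_nm,
                        pulling_speed_um_per_s = 5,
                        temperature_K = 298,
                        sample_label = "unknown") {
  stopifnot(
    is.character(curve_id), length(curve_id) == 1L, nzchar(curve_id),
    length(segment) == length(piezo_position_nm),
    length(deflection_nm) == length(piezo_position_nm)
  )
  obj <- structure(
    list(
      curve_id = curve_id,
      data = data.frame(
        segment = as.character(segment),
        piezo_position_nm = as.numeric(piezo_position_nm),
        deflection_nm = as.numeric(deflection_nm),
        stringsAsFactors = FALSE
      ),
      spring_constant_nN_per_nm = as.numeric(spring_constant_nN_per_nm),
      pulling_speed_um_per_s = as.numeric(pulling_speed_um_per_s),
      temperature_K = as.numeric(temperature_K),
      sample_label = as.character(sample_label)
    ),
    class = "force_curve"
  )
  validate_force_curve(obj)
}

#' Validate a force curve
#'
#' Checks the structural invariants: known segment labels, strictly
#' monotone piezo position within each segment, positive spring constant
#' and temperature.
#'
#' @param curve A `force_curve`.
#' @return The curve, invisibly usable, after validation; errors name the
#'   offending `curve_id`.
#' @export
validate_force_curve <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  id <- curve$curve_id
  d <- curve$data
  if (!all(d$segment %in% c("approach", "retract"))) {
    stop(sprintf("curve '%s': unknown segment label", id), call. = FALSE)
  }
  for (seg in unique(d$segment)) {
    z <- d$piezo_position_nm[d$segment == seg]
    if (length(z) >= 2L && !(all(diff(z) > 0) || all(diff(z) < 0))) {
      stop(sprintf("curve '%s': piezo position not strictly monotone in %s segment",
                   id, seg), call. = FALSE)
    }
  }
  if (!is.finite(curve$spring_constant_nN_per_nm) ||
      curve$spring_constant_nN_per_nm <= 0) {
    stop(sprintf("curve '%s': spring constant must be > 0", id), call. = FALSE)
  }
  if (!is.finite(curve$temperature_K) || curve$temperature_K <= 0) {
    stop(sprintf("curve '%s': temperature must be > 0", id), call. = FALSE)
  }
  curve
}

#' Extract one segment of a force curve with derived force
#'
#' @param curve A `force_curve`.
#' @param segment `"retract"` (default) or `"approach"`.
#' @return A data.frame with `piezo_position_nm`, `deflection_nm` and the
#'   derived signed `force_pN` (negative under adhesion).
#' @export
curve_segment <- function(curve, segment = "retract") {
  stopifnot(inherits(curve, "force_curve"),
            segment %in% c("approach", "retract"))
  d <- curve$data[curve$data$segment == segment,
                  c("piezo_position_nm", "deflection_nm"), drop = FALSE]
  d <- d[order(d$piezo_position_nm), , drop = FALSE]
  rownames(d) <- NULL
  d$force_pN <- d$deflection_nm * curve$spring_constant_nN_per_nm * 1000
  d
}

#' @export
print.force_curve <- function(x, ...) {
  n_r <- sum(x$data$segment == "retract")
  n_a <- sum(x$data$segment == "approach")
  cat(sprintf(
    "Force curve '%s' (%s): %d retract + %d approach points, k = %g nN/nm, v = %g um/s, T = %g K\n",
    x$curve_id, x$sample_label, n_r, n_a,
    x$spring_constant_nN_per_nm, x$pulling_speed_um_per_s, x$temperature_K
  ))
  invisible(x)
}

# metadata keys written to / required from the "#" header
.curve_meta_keys <- c(
  "curve_id", "spring_constant_nN_per_nm", "pulling_speed_um_per_s",
  "temperature_K", "sample_label"
)

#' Write a force curve to delimited text
#'
#' One TSV per curve: "#"-prefixed header lines carry the acquisition
#' metadata, then columns `segment`, `piezo_position_nm`, `deflection_nm`.
#' Numbers are written with 17 significant digits and a locale-independent
#' decimal point, so `read_curve(write_curve(x))` reproduces every field
#' bit-identically.
#'
#' @param curve A `force_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_curve()]
#' @export
write_curve <- function(curve, path) {
  validate_force_curve(curve)
  if (sum(curve$data$segment == "retract") == 0L) {
    stop(sprintf("curve '%s': refusing to write a curve with an empty retract segment",
                 curve$curve_id), call. = FALSE)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  meta <- c(
    curve_id = curve$curve_id,
    spring_constant_nN_per_nm = sprintf("%.17g", curve$spring_constant_nN_per_nm),
    pulling_speed_um_per_s = sprintf("%.17g", curve$pulling_speed_um_per_s),
    temperature_K = sprintf("%.17g", curve$temperature_K),
    sample_label = curve$sample_label
  )
  writeLines(sprintf("# %s\t%s", names(meta), meta), con)
  writeLines("segment\tpiezo_position_nm\tdeflection_nm", con)
  writeLines(sprintf("%s\t%.17g\t%.17g", curve$data$segment,
                     curve$data$piezo_position_nm, curve$data$deflection_nm),
             con)
  invisible(path)
}

#' Read a force curve from delimited text
#'
#' Inverse of [write_curve()]; validates the result.
#'
#' @param path File written by [write_curve()] (or any TSV with the same
#'   layout).
#' @return A `force_curve`.
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- startsWith(lines, "#")
  meta_lines <- sub("^#\\s*", "", lines[is_meta])
  parts <- strsplit(meta_lines, "\t", fixed = TRUE)
  meta <- stats::setNames(
    vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "", ""),
    vapply(parts, `[[`, "", 1)
  )
  missing_meta <- setdiff(.curve_meta_keys, names(meta))
  if (length(missing_meta)) {
    stop("curve file missing metadata key(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  body <- lines[!is_meta]
  body <- body[nzchar(body)]
  tab <- tryCatch(
    utils::read.table(
      text = body, header = TRUE, sep = "\t",
      colClasses = c("character", "numeric", "numeric"),
      stringsAsFactors = FALSE
    ),
    error = function(e) {
      stop("curve file format error: need tab-separated columns ",
           "segment, piezo_position_nm, deflection_nm", call. = FALSE)
    }
  )
  needed <- c("segment", "piezo_position_nm", "deflection_nm")
  if (!all(needed %in% names(tab))) {
    stop("curve file format error: need columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  force_curve(
    curve_id = meta[["curve_id"]],
    segment = tab$segment,
    piezo_position_nm = tab$piezo_position_nm,
    deflection_nm = tab$deflection_nm,
    spring_constant_nN_per_nm = as.numeric(meta[["spring_constant_nN_per_nm"]]),
    pulling_speed_um_per_s = as.numeric(meta[["pulling_speed_um_per_s"]]),
    temperature_K = as.numeric(meta[["temperature_K"]]),
    sample_label = meta[["sample_label"]]
  )
}

#' Write an experiment manifest
#'
#' A JSON index of curve files with their per-curve metadata, used for
#' analysis-only runs on a directory of curves.
#'
#' @param curves List of `force_curve` objects already written to `dir`.
#' @param dir Directory containing the curve files (one
#'   `<curve_id>.tsv` each).
#' @param path Manifest path (default `manifest.json` inside `dir`).
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(curves, dir, path = file.path(dir, "manifest.json")) {
  ids <- vapply(curves, function(cv) cv$curve_id, "")
  if (anyDuplicated(ids)) stop("duplicate curve_ids in manifest", call. = FALSE)
  entries <- lapply(curves, function(cv) {
    list(
      curve_id = cv$curve_id,
      file = paste0(cv$curve_id, ".tsv"),
      sample_label = cv$sample_label,
      spring_constant_nN_per_nm = cv$spring_constant_nN_per_nm,
      pulling_speed_um_per_s = cv$pulling_speed_um_per_s,
      temperature_K = cv$temperature_K
    )
  })
  jsonlite::write_json(list(curves = entries), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an experiment manifest and its curves
#'
#' @param path Manifest JSON written by [write_manifest()].
#' @return A list of `force_curve` objects; errors if any referenced file
#'   is missing or any curve_id is duplicated.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  dir <- dirname(path)
  ids <- vapply(m$curves, function(e) e$curve_id, "")
  if (anyDuplicated(ids)) stop("duplicate curve_ids in manifest", call. = FALSE)
  lapply(m$curves, function(e) {
    f <- file.path(dir, e$file)
    if (!file.exists(f)) {
      stop("manifest references missing curve file: ", f, call. = FALSE)
    }
    read_curve(f)
  })
}
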