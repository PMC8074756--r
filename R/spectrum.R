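#' Construct a Raman spectrum
#'
#' A spectrum couples a strictly increasing wavenumber axis (cm^-1) with
#' measured intensities (arbitrary units) and carries sample metadata
#' through the preprocessing chain.
#'
#' @param wavenumber Numeric vector of wavenumbers (cm^-1), strictly
#'   increasing, length >= 8.
#' @param intensity Numeric vector of intensities, same length as
#'   `wavenumber`.
#' @param sample_id Optional sample identifier.
#' @param group Optional group label (e.g. `"SI"`, `"PBI"`, `"WBI"`).
#'
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumber`, `intensity` and `metadata` (which records `sample_id`,
#'   `group` and the `stages` already applied).
#' @export
spectrum <- function(wavenumber, intensity, sample_id = NA_character_,
                     group = NA_character_) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity)) {
    stop("`wavenumber` and `intensity` must have the same length")
  }
  if (length(wavenumber) < 8L) {
    stop("a spectrum needs at least 8 points")
  }
  if (any(!is.finite(wavenumber)) || any(!is.finite(intensity))) {
    stop("wavenumbers and intensities must be finite")
  }
  if (any(diff(wavenumber) <= 0)) {
    stop("`wavenumber` must be strictly increasing")
  }
  structure(
    list(
      wavenumber = wavenumber,
      intensity = intensity,
      metadata = list(
        sample_id = sample_id,
        group = group,
        stages = character()
      )
    ),
    class = "raman_spectrum"
  )
}

is_spectrum <- function(x) inherits(x, "raman_spectrum")

assert_spectrum <- function(x) {
  if (!is_spectrum(x)) stop("expected a `raman_spectrum` object")
  invisible(x)
}

# Replace intensities (and optionally the axis), preserving metadata and
# appending `stage` to the processing record.
update_spectrum <- function(s, intensity, wavenumber = NULL, stage = NULL) {
  out <- s
  if (!is.null(wavenumber)) out$wavenumber <- as.numeric(wavenumber)
  out$intensity <- as.numeric(intensity)
  if (!is.null(stage)) {
    out$metadata$stages <- c(out$metadata$stages, stage)
  }
  out
}

#' @export
print.raman_spectrum <- function(x, ...) {
  rng <- range(x$wavenumber)
  cat(sprintf(
    "Raman spectrum: %d points, %.1f-%.1f cm-1\n",
    length(x$wavenumber), rng[1], rng[2]
  ))
  if (!is.na(x$metadata$sample_id)) {
    cat("  sample:", x$metadata$sample_id, "\n")
  }
  if (!is.na(x$metadata$group)) cat("  group:", x$metadata$group, "\n")
  if (length(x$metadata$stages)) {
    cat("  stages:", paste(x$metadata$stages, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Crop a spectrum to a wavenumber window
#'
#' Retains axis points in the closed interval `[lo, hi]`; the fingerprint
#' region used throughout is 400-1800 cm^-1.
#'
#' @param s A `raman_spectrum`.
#' @param lo,hi Window bounds in cm^-1, `lo < hi`.
#' @return The cropped `raman_spectrum`.
#' @export
crop <- function(s, lo = 400, hi = 1800) {
  assert_spectrum(s)
  if (!(lo < hi)) stop("`lo` must be less than `hi`")
  keep <- s$wavenumber >= lo & s$wavenumber <= hi
  if (sum(keep) == 0L) stop("crop window contains no axis points")
  if (sum(keep) < 8L) {
    stop("crop window retains fewer than 8 points")
  }
  update_spectrum(s, s$intensity[keep], s$wavenumber[keep], stage = "crop")
}

#' Vector-normalize a spectrum to unit Euclidean norm
#'
#' @param s A `raman_spectrum`.
#' @return The spectrum scaled so that `sqrt(sum(intensity^2)) == 1`.
#' @export
vector_normalize <- function(s) {
  assert_spectrum(s)
  nrm <- sqrt(sum(s$intensity^2))
  if (nrm == 0) stop("cannot normalize an all-zero spectrum")
  update_spectrum(s, s$intensity / nrm, stage = "vector_normalize")
}

#' Read a spectrum from a two-column text file
#'
#' Files hold wavenumber (cm^-1) and intensity columns, whitespace or
#' comma delimited; lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param sample_id,group Metadata attached to the result.
#' @return A `raman_spectrum`.
#' @export
read_spectrum <- function(path, sample_id = basename(path),
                          group = NA_character_) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[,\\s]+")
  mat <- do.call(rbind, lapply(parts, function(p) as.numeric(p[1:2])))
  ord <- order(mat[, 1])
  spectrum(mat[ord, 1], mat[ord, 2], sample_id = sample_id, group = group)
}

#' Write a spectrum as two-column whitespace-delimited text
#'
#' @param s A `raman_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  assert_spectrum(s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wavenumber_cm-1 intensity (sample %s)",
                     s$metadata$sample_id), con)
  writeLines(sprintf("%.6f %.10g", s$wavenumber, s$intensity), con)
  invisible(path)
}
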