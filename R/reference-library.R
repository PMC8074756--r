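#' Specify a spectral peak
#'
#' Helper for building pure-component reference spectra as sums of peaked
#' band shapes.
#'
#' @param center Band center (cm^-1); must fall inside the library axis.
#' @param width Full width at half maximum (cm^-1), > 0.
#' @param amplitude Nonnegative peak height (a.u.).
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return A one-row data frame describing the peak.
#' @export
peak_spec <- function(center, width, amplitude = 1, shape = "gaussian") {
  shape <- match.arg(shape, c("gaussian", "lorentzian"))
  if (width <= 0) stop("peak `width` must be > 0")
  if (amplitude < 0) stop("peak `amplitude` must be >= 0")
  data.frame(center = center, width = width, amplitude = amplitude,
             shape = shape, stringsAsFactors = FALSE)
}

peak_profile <- function(axis, center, width, amplitude, shape) {
  if (shape == "gaussian") {
    amplitude * exp(-4 * log(2) * ((axis - center) / width)^2)
  } else {
    amplitude / (1 + (2 * (axis - center) / width)^2)
  }
}

#' Build a pure-component reference library from peak lists
#'
#' Each component spectrum is a sum of Gaussian/Lorentzian bands on a
#' common wavenumber axis, vector-normalized to unit Euclidean norm. The
#' library supplies the pure-component spectra a_1...a_n against which
#' tissue spectra are unmixed by classical least squares.
#'
#' @param component_names Character vector of distinct component names.
#' @param peak_specs List (one element per component) of data frames with
#'   columns `center`, `width`, `amplitude`, `shape` (rows bind-able
#'   output of [peak_spec()]).
#' @param axis Strictly increasing wavenumber grid, conventionally within
#'   400-1800 cm^-1.
#' @return An object of class `reference_library`: list with `axis`,
#'   `names`, and `spectra` (matrix, one unit-norm column per component).
#' @export
make_reference_library <- function(component_names, peak_specs, axis) {
  if (any(diff(axis) <= 0)) stop("`axis` must be strictly increasing")
  if (length(component_names) != length(peak_specs)) {
    stop("`component_names` and `peak_specs` must have equal length")
  }
  if (anyDuplicated(component_names)) stop("duplicate component names")
  rng <- range(axis)
  spectra <- vapply(peak_specs, function(pk) {
    pk <- as.data.frame(pk)
    if (nrow(pk) == 0L) stop("each component needs at least one peak")
    if (any(pk$center < rng[1] | pk$center > rng[2])) {
      stop("peak center outside the axis range")
    }
    if (any(pk$width <= 0)) stop("peak `width` must be > 0")
    if (any(pk$amplitude < 0)) stop("peak `amplitude` must be >= 0")
    y <- rowSums(vapply(seq_len(nrow(pk)), function(i) {
      peak_profile(axis, pk$center[i], pk$width[i], pk$amplitude[i],
                   match.arg(pk$shape[i], c("gaussian", "lorentzian")))
    }, numeric(length(axis))))
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) stop("component spectrum is identically zero")
    y / nrm
  }, numeric(length(axis)))
  colnames(spectra) <- component_names
  # degenerate library: two components with (numerically) identical shape
  gram <- crossprod(spectra)
  off <- gram[upper.tri(gram)]
  if (any(off > 1 - 1e-10)) {
    stop("degenerate library: two components have identical spectra")
  }
  structure(
    list(axis = as.numeric(axis), names = component_names, spectra = spectra),
    class = "reference_library"
  )
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("Reference library: %d components on %d-point axis\n",
              length(x$names), length(x$axis)))
  cat("  components:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Default five-component reference library
#'
#' A compact library of the molecular species that dominate the radiation
#' response contrasts in hippocampal tissue spectra: DNA, histone 2A,
#' TNF-alpha, TGF-beta and uric acid. Band positions follow standard
#' Raman assignments (nucleic-acid backbone and ring breathing modes for
#' DNA; amide I/III and CH deformation bands for the proteins; purine
#' ring modes for uric acid). Bands are synthetic stand-ins for measured
#' pure-compound spectra, adequate for exercising unmixing and group
#' contrasts.
#'
#' @param axis Wavenumber grid (default 400-1800 cm^-1 at 2 cm^-1).
#' @return A `reference_library` with 5 components.
#' @export
default_reference_library <- function(axis = seq(400, 1800, by = 2)) {
  peaks <- list(
    DNA = rbind(
      peak_spec(785, 18, 1.0),   # O-P-O backbone / pyrimidine ring
      peak_spec(1095, 20, 0.8),  # PO2- symmetric stretch
      peak_spec(1340, 22, 0.6),  # adenine/guanine
      peak_spec(1480, 20, 0.7),  # purine ring
      peak_spec(1580, 18, 0.6)   # guanine/adenine ring
    ),
    `Histone 2A` = rbind(
      peak_spec(852, 16, 0.5),   # tyrosine ring breathing
      peak_spec(1004, 10, 0.9),  # phenylalanine
      peak_spec(1250, 40, 0.5, "lorentzian"), # amide III
      peak_spec(1450, 24, 0.8),  # CH2 deformation
      peak_spec(1658, 30, 1.0)   # amide I
    ),
    `TNF-alpha` = rbind(
      peak_spec(760, 14, 0.4),
      peak_spec(1003, 10, 0.7),
      peak_spec(1235, 36, 0.7, "lorentzian"), # beta-sheet amide III
      peak_spec(1550, 20, 0.4),
      peak_spec(1672, 26, 1.0)   # beta-sheet amide I
    ),
    `TGF-beta` = rbind(
      peak_spec(830, 16, 0.5),
      peak_spec(1032, 12, 0.6),
      peak_spec(1270, 34, 0.6, "lorentzian"),
      peak_spec(1340, 20, 0.5),
      peak_spec(1650, 28, 0.9)
    ),
    `Uric acid` = rbind(
      peak_spec(626, 14, 0.8),
      peak_spec(1040, 14, 0.7),
      peak_spec(1123, 14, 0.5),
      peak_spec(1400, 18, 0.6),
      peak_spec(1645, 16, 0.5)
    )
  )
  make_reference_library(names(peaks), unname(peaks), axis)
}
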