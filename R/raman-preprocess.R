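#' Calibrate a wavenumber axis against known reference lines
#'
#' With one matched peak pair the axis is rigidly shifted; with two or
#' more pairs it is remapped by a least-squares polynomial of degree
#' `min(pairs - 1, 3)`. Intensities are untouched. The canonical single
#' anchor is the 520.7 cm^-1 line of crystalline silicon.
#'
#' @param s A `raman_spectrum`.
#' @param observed Observed positions of the reference lines on the
#'   uncalibrated axis (cm^-1).
#' @param known True (certified) positions of the same lines (cm^-1).
#' @return The spectrum with a remapped axis.
#' @export
calibrate_axis <- function(s, observed, known) {
  assert_spectrum(s)
  if (length(observed) != length(known)) {
    stop("`observed` and `known` must have equal length")
  }
  if (length(observed) == 0L) stop("at least one matched peak pair is required")
  if (length(observed) == 1L) {
    new_axis <- s$wavenumber + (known - observed)
  } else {
    deg <- min(length(observed) - 1L, 3L)
    fit <- lm(known ~ poly(observed, deg, raw = TRUE))
    new_axis <- drop(cbind(1, outer(s$wavenumber, seq_len(deg), `^`)) %*%
                       coef(fit))
  }
  if (any(diff(new_axis) <= 0)) {
    stop("calibration produced a non-monotone axis")
  }
  update_spectrum(s, s$intensity, new_axis, stage = "calibrate_axis")
}

#' Correct for the instrument spectral response
#'
#' Divides the spectrum by the instrument response curve, estimated as
#' the ratio of a measured intensity standard to its certified emission
#' curve (as with NIST SRM 2242 for 532 nm excitation):
#' `corrected = spectrum * certified / measured`.
#'
#' @param s A `raman_spectrum`.
#' @param measured_standard Measured standard intensities on the same
#'   axis as `s` (numeric vector or `raman_spectrum`), > 0 everywhere.
#' @param certified_standard Certified standard curve on the same axis.
#' @return The response-corrected spectrum.
#' @export
correct_instrument_response <- function(s, measured_standard,
                                        certified_standard) {
  assert_spectrum(s)
  m <- if (is_spectrum(measured_standard)) measured_standard$intensity else measured_standard
  cert <- if (is_spectrum(certified_standard)) certified_standard$intensity else certified_standard
  if (length(m) != length(s$intensity) || length(cert) != length(s$intensity)) {
    stop("standards must share the spectrum axis (interpolate first)")
  }
  if (any(m <= 0)) stop("measured standard must be positive everywhere")
  update_spectrum(s, s$intensity * cert / m,
                  stage = "correct_instrument_response")
}

# Lower convex hull (Andrew monotone chain over strictly increasing x):
# indices of hull vertices, always including both endpoints.
lower_hull_indices <- function(x, y) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1L]
      b <- hull[length(hull)]
      # drop b if it lies on or above the chord a--i
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) <= 0) {
        hull <- hull[-length(hull)]
      } else {
        break
      }
    }
    hull <- c(hull, i)
  }
  hull
}

#' Rubberband baseline correction
#'
#' Estimates the slowly varying (fluorescence) background as the
#' piecewise-linear interpolation of the lower convex hull of the
#' (wavenumber, intensity) points, anchored at both endpoints, and
#' subtracts it. The corrected spectrum is >= 0 everywhere and exactly 0
#' at every hull vertex; adding a constant to all intensities leaves the
#' corrected spectrum unchanged.
#'
#' @param s A `raman_spectrum` with >= 3 points.
#' @return List with `baseline` (numeric vector) and `corrected` (a
#'   `raman_spectrum`).
#' @export
rubberband_baseline <- function(s) {
  assert_spectrum(s)
  x <- s$wavenumber
  y <- s$intensity
  if (length(x) < 3L) stop("rubberband needs at least 3 points")
  idx <- lower_hull_indices(x, y)
  baseline <- approx(x[idx], y[idx], xout = x, method = "linear")$y
  corrected <- y - baseline
  corrected[abs(corrected) < 1e-12] <- 0
  list(
    baseline = baseline,
    corrected = update_spectrum(s, corrected, stage = "rubberband_baseline")
  )
}

#' Savitzky-Golay smoothing
#'
#' Replaces each interior point by the center value of a local
#' least-squares polynomial fit; the terminal half-windows are handled by
#' evaluating the first and last full-window polynomial fits at the edge
#' positions, preserving vector length. Defaults follow the 7-point,
#' 5th-order convention for Raman tissue spectra.
#'
#' @param s A `raman_spectrum`.
#' @param window Odd window length (points).
#' @param polyorder Polynomial order, < `window`.
#' @return The smoothed spectrum.
#' @export
savgol_smooth <- function(s, window = 7L, polyorder = 5L) {
  assert_spectrum(s)
  if (window %% 2L == 0L) stop("`window` must be odd")
  if (polyorder >= window) stop("`polyorder` must be < `window`")
  if (length(s$intensity) < window) {
    stop("spectrum shorter than the smoothing window")
  }
  sm <- signal::sgolayfilt(s$intensity, p = polyorder, n = window)
  update_spectrum(s, sm, stage = "savgol_smooth")
}

#' Full Raman preprocessing chain
#'
#' Applies, in order: axis calibration, instrument-response correction,
#' cropping to the fingerprint window, rubberband baseline subtraction,
#' vector normalization and Savitzky-Golay smoothing. Stages with `NULL`
#' inputs (calibration, response standards) are skipped; the applied
#' stage list is recorded in the spectrum metadata.
#'
#' @param s A `raman_spectrum`.
#' @param calibration Optional list with `observed` and `known` peak
#'   positions for [calibrate_axis()].
#' @param standards Optional list with `measured` and `certified` curves
#'   for [correct_instrument_response()].
#' @param lo,hi Crop window (cm^-1).
#' @param window,polyorder Savitzky-Golay parameters.
#' @return The fully preprocessed `raman_spectrum`.
#' @export
preprocess <- function(s, calibration = NULL, standards = NULL,
                       lo = 400, hi = 1800, window = 7L, polyorder = 5L) {
  assert_spectrum(s)
  if (!is.null(calibration)) {
    s <- calibrate_axis(s, calibration$observed, calibration$known)
  }
  if (!is.null(standards)) {
    s <- correct_instrument_response(s, standards$measured,
                                     standards$certified)
  }
  s <- crop(s, lo, hi)
  s <- rubberband_baseline(s)$corrected
  s <- vector_normalize(s)
  savgol_smooth(s, window = window, polyorder = polyorder)
}
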