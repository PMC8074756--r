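make_s <- function(y, x = seq_along(y)) spectrum(x, y)

test_that("axis calibration shifts and remaps as specified", {
  s <- spectrum(seq(400, 1800, by = 4), rep(1, 351))
  # silicon line observed 2 cm-1 high: rigid shift by -2
  cal <- calibrate_axis(s, observed = 522.7, known = 520.7)
  expect_equal(cal$wavenumber, s$wavenumber - 2.0)
  expect_equal(cal$intensity, s$intensity)
  # observed == known: identity
  expect_equal(calibrate_axis(s, 520.7, 520.7)$wavenumber, s$wavenumber)
  expect_error(calibrate_axis(s, numeric(), numeric()), "at least one")
})

test_that("polynomial calibration inverts a known quadratic distortion", {
  true_axis <- seq(400, 1800, by = 4)
  distort <- function(w) w + 1e-6 * (w - 1100)^2 / 50
  s <- spectrum(distort(true_axis), rep(1, length(true_axis)))
  anchors <- c(520.7, 1001.4, 1602.3)
  cal <- calibrate_axis(s, observed = distort(anchors), known = anchors)
  expect_lt(max(abs(cal$wavenumber - true_axis)), 1e-6)
})

test_that("instrument response correction divides out the response curve", {
  x <- seq(400, 1800, by = 4)
  y <- 1 + exp(-((x - 1000) / 50)^2)
  s <- spectrum(x, y)
  flat <- rep(1, length(x))
  expect_equal(correct_instrument_response(s, flat, flat)$intensity, y)
  # constant response 2 halves the spectrum; correcting the measured
  # standard itself returns the certified curve
  half <- correct_instrument_response(s, rep(2, length(x)), flat)
  expect_equal(half$intensity, y / 2)
  meas <- spectrum(x, 2 * flat)
  expect_equal(correct_instrument_response(meas, rep(2, length(x)), flat)$intensity,
               flat)
  # forward-then-inverse with a ramp response
  resp <- seq(0.5, 2, length.out = length(x))
  observed <- spectrum(x, y * resp)
  corrected <- correct_instrument_response(observed, resp, rep(1, length(x)))
  expect_lt(max(abs(corrected$intensity - y)), 1e-10)
  expect_error(correct_instrument_response(s, rep(0, length(x)), flat),
               "positive")
})

test_that("crop keeps the closed window and rejects degenerate windows", {
  x <- seq(350, 1850, by = 2)
  s <- spectrum(x, seq_along(x))
  cr <- crop(s, 400, 1800)
  expect_equal(range(cr$wavenumber), c(400, 1800))
  expect_error(crop(s, 2000, 2100), "no axis points")
  expect_error(crop(s, 1000, 1001), "fewer than 8")
  expect_error(crop(s, 1000, 900), "less than")
})

test_that("rubberband baseline is the lower convex hull", {
  # pure linear ramp lies on its own chord: corrected is identically 0
  ramp <- make_s(seq(2, 30, length.out = 10))
  rb <- rubberband_baseline(ramp)
  expect_equal(rb$corrected$intensity, rep(0, 10))
  # convex (upward-opening) parabola: every point is a hull vertex, so
  # the baseline is the curve itself and the correction removes it all
  x <- 1:11
  par <- make_s((x - 6)^2 + 1, x)
  rb2 <- rubberband_baseline(par)
  expect_equal(rb2$baseline, (x - 6)^2 + 1)
  expect_equal(rb2$corrected$intensity, rep(0, 11))
  # concave spectrum lies above its chord: baseline touches endpoints only
  conc <- make_s(-(x - 6)^2 + 30, x)
  rb2b <- rubberband_baseline(conc)
  expect_equal(rb2b$baseline, rep(5, 11))
  # zigzag: hull vertices are the two minima and the endpoints; interior
  # peaks above the chords are never baseline anchors
  zig <- make_s(c(0, 5, 1, 6, 0, 2, 7, 3), 1:8)
  rb3 <- rubberband_baseline(zig)
  expect_equal(rb3$baseline, c(0, 0, 0, 0, 0, 1, 2, 3))
  expect_equal(rb3$corrected$intensity[c(1, 5, 8)], c(0, 0, 0))
  # additive constants do not change the corrected spectrum
  rb4 <- rubberband_baseline(make_s(c(0, 5, 1, 6, 0, 2, 7, 3) + 13.7, 1:8))
  expect_equal(rb4$corrected$intensity, rb3$corrected$intensity)
})

test_that("rubberband agrees with an independent convex hull oracle", {
  set.seed(42)
  for (i in 1:100) {
    x <- sort(runif(50, 400, 1800))
    x <- x + seq_along(x) * 1e-6 # guard strict monotonicity
    y <- runif(50) + 0.002 * (x - 1000)^2 / 100
    s <- spectrum(x, y)
    rb <- rubberband_baseline(s)
    expect_equal(rb$baseline, chull_lower_baseline(x, y), tolerance = 1e-9)
    expect_true(all(rb$corrected$intensity >= -1e-12))
    expect_true(all(rb$baseline <= y + 1e-9))
  }
})

test_that("vector normalization is a pure rescaling to unit norm", {
  s <- make_s(c(3, 4, 0, 0, 0, 0, 0, 0))
  expect_equal(vector_normalize(s)$intensity, c(0.6, 0.8, rep(0, 6)))
  u <- vector_normalize(s)
  expect_equal(vector_normalize(u)$intensity, u$intensity)
  expect_equal(vector_normalize(make_s(7.3 * c(3, 4, 0, 0, 0, 0, 0, 0)))$intensity,
               u$intensity)
  expect_error(vector_normalize(make_s(rep(0, 8))), "all-zero")
})

test_that("Savitzky-Golay smoothing matches a per-window least-squares oracle", {
  x <- seq(0, 2, length.out = 60)
  # degree-5 polynomials are reproduced exactly at interior points
  y5 <- 1 - x + 0.5 * x^2 + x^3 - 0.2 * x^4 + 0.05 * x^5
  sm <- savgol_smooth(spectrum(400 + 100 * x, y5), window = 7, polyorder = 5)
  expect_lt(max(abs(sm$intensity[4:57] - y5[4:57])), 1e-9)
  # constant signal is unchanged (including edges)
  smc <- savgol_smooth(spectrum(400 + 100 * x, rep(2.5, 60)))
  expect_equal(smc$intensity, rep(2.5, 60))
  # noisy sine: every interior point equals the centered window fit
  set.seed(8)
  y <- sin(4 * x) + rnorm(60, 0, 0.1)
  sm2 <- savgol_smooth(spectrum(400 + 100 * x, y), window = 7, polyorder = 5)
  for (i in 4:57) {
    idx <- (i - 3):(i + 3)
    fit <- lm(y[idx] ~ poly(idx - i, 5, raw = TRUE)) # centered basis
    oracle <- unname(coef(fit)[1])
    expect_equal(sm2$intensity[i], oracle, tolerance = 1e-10)
  }
  expect_error(savgol_smooth(spectrum(400 + 100 * x, y), window = 7,
                             polyorder = 7), "polyorder")
  expect_error(savgol_smooth(spectrum(400 + 100 * x, y), window = 6),
               "odd")
})

test_that("the preprocessing chain composes the stages in order", {
  lib <- two_component_library()
  d <- mixture_design("SI", matrix(c(0.5, 0.5), 1),
                      baseline = c(0.2, 0.3, -0.1, 0.15),
                      noise_sd = 0.002, spectra_per_sample = 1)
  sim <- simulate_tissue_spectra(lib, d, seed = 21)
  out <- preprocess(sim$spectra[[1]])
  expect_identical(out$metadata$stages,
                   c("crop", "rubberband_baseline", "vector_normalize",
                     "savgol_smooth"))
  # output stays close to unit norm despite smoothing
  expect_true(abs(sqrt(sum(out$intensity^2)) - 1) < 0.05)
  # baseline-free truth is recovered up to scale
  truth <- drop(lib$spectra %*% c(0.5, 0.5))
  expect_gt(cor(out$intensity, truth), 0.99)

  # near-identity composition on an already-clean spectrum
  clean <- vector_normalize(spectrum(lib$axis, truth))
  out2 <- preprocess(clean)
  expect_gt(cor(out2$intensity, clean$intensity), 0.999)

  # stage errors propagate
  expect_error(
    preprocess(sim$spectra[[1]],
               calibration = list(observed = numeric(), known = numeric())),
    "at least one"
  )
})
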