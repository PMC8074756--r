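# Shared fixtures, built in code at test time.

fixture_axis <- seq(400, 1800, by = 4)

two_component_library <- function(axis = fixture_axis) {
  make_reference_library(
    c("compA", "compB"),
    list(
      rbind(peak_spec(700, 30, 1), peak_spec(1200, 40, 0.6)),
      rbind(peak_spec(900, 25, 1), peak_spec(1500, 35, 0.8))
    ),
    axis
  )
}

# Brute-force lower-hull oracle built on grDevices::chull (an
# implementation independent of the package's monotone chain).
chull_lower_baseline <- function(x, y) {
  n <- length(x)
  # append a point far above the spectrum so the upper hull never uses
  # spectrum points, then take the hull vertices that are not it; the
  # sentinel must dwarf the data range or near-edge points can land on
  # the ascending hull chains
  top <- max(y) + 1e9 * (max(y) - min(y) + 1)
  h <- grDevices::chull(c(x, mean(x)), c(y, top))
  h <- sort(h[h <= n])
  if (!1 %in% h) h <- c(1, h)
  if (!n %in% h) h <- c(h, n)
  approx(x[h], y[h], xout = x)$y
}

# Student two-sample t p-value from the textbook closed form.
student_p_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(tstat), na + nb - 2)
}
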