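#' Describe a synthetic tissue-spectrum mixture design
#'
#' The generative model behind simulated tissue spectra: each measured
#' spectrum is a nonnegative linear combination of the library's
#' pure-component spectra (the true concentrations C_1...C_n), plus a
#' slowly varying polynomial baseline emulating fluorescence background,
#' plus iid Gaussian noise, truncated at zero.
#'
#' @param group Character vector of group labels, one per sample (the
#'   sample is the animal; each contributes `spectra_per_sample` spectra).
#' @param weights Matrix of true nonnegative component weights, one row
#'   per sample, one column per library component.
#' @param baseline Numeric vector of polynomial coefficients (constant
#'   term first) evaluated on the axis rescaled to [0, 1]; default cubic.
#'   Use `c(0)` for no baseline.
#' @param noise_sd Standard deviation of additive Gaussian noise (a.u.),
#'   >= 0.
#' @param spectra_per_sample Number of spectra recorded per sample, >= 1.
#' @return An object of class `mixture_design`.
#' @export
mixture_design <- function(group, weights,
                           baseline = c(0.05, 0.1, -0.05, 0.02),
                           noise_sd = 0.005, spectra_per_sample = 3L) {
  weights <- as.matrix(weights)
  if (nrow(weights) != length(group)) {
    stop("`weights` must have one row per sample")
  }
  if (any(weights < 0)) stop("mixture weights must be >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (spectra_per_sample < 1L) stop("every sample needs >= 1 spectrum")
  structure(
    list(group = as.character(group), weights = weights,
         baseline = as.numeric(baseline), noise_sd = noise_sd,
         spectra_per_sample = as.integer(spectra_per_sample)),
    class = "mixture_design"
  )
}

eval_baseline <- function(coef, axis) {
  x <- (axis - min(axis)) / diff(range(axis))
  drop(outer(x, seq_along(coef) - 1, `^`) %*% coef)
}

#' Simulate tissue Raman spectra with known component weights
#'
#' Draws `spectra_per_sample` spectra per sample from the mixture model
#' S = sum_i C_i a_i + baseline + noise (truncated at zero), where the
#' a_i are the library's pure-component spectra. Reproducible for a fixed
#' seed; the true weights are returned alongside the spectra.
#'
#' @param library A `reference_library`.
#' @param design A `mixture_design` with `ncol(weights)` equal to the
#'   library size.
#' @param seed Mandatory integer seed.
#' @return List with `spectra` (list of `raman_spectrum`) and `truth`
#'   (data frame: spectrum_id, sample_id, group, one column per
#'   component's true weight).
#' @export
simulate_tissue_spectra <- function(library, design, seed) {
  if (!inherits(library, "reference_library")) {
    stop("`library` must be a reference_library")
  }
  if (!inherits(design, "mixture_design")) {
    stop("`design` must be a mixture_design")
  }
  if (ncol(design$weights) != length(library$names)) {
    stop("design weights length must equal the library size")
  }
  n_samples <- length(design$group)
  base <- eval_baseline(design$baseline, library$axis)
  with_seed(seed, {
    spectra <- list()
    rows <- list()
    k <- 0L
    for (i in seq_len(n_samples)) {
      clean <- drop(library$spectra %*% design$weights[i, ]) + base
      for (j in seq_len(design$spectra_per_sample)) {
        k <- k + 1L
        y <- clean
        if (design$noise_sd > 0) {
          y <- y + rnorm(length(y), 0, design$noise_sd)
        }
        y <- pmax(y, 0)
        sid <- sprintf("sample%02d", i)
        spectra[[k]] <- spectrum(library$axis, y,
                                 sample_id = sprintf("%s_rep%d", sid, j),
                                 group = design$group[i])
        rows[[k]] <- data.frame(
          spectrum_id = sprintf("%s_rep%d", sid, j),
          sample_id = sid, group = design$group[i],
          stringsAsFactors = FALSE
        )
      }
    }
    truth <- do.call(rbind, rows)
    w <- design$weights[rep(seq_len(n_samples),
                            each = design$spectra_per_sample), , drop = FALSE]
    colnames(w) <- library$names
    list(spectra = spectra, truth = cbind(truth, as.data.frame(w)))
  })
}
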