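#' Principal component analysis of a spectrum set
#'
#' Mean-centers the intensity matrix (spectra as rows) and extracts the
#' leading eigenvectors of its covariance. The sign of each loading is
#' fixed deterministically: the largest-magnitude element is made
#' positive, so loadings plots are reproducible across runs.
#'
#' @param spectra List of `raman_spectrum` objects on a shared axis, or a
#'   numeric matrix with one spectrum per row.
#' @param n_components Number of components to retain; at most
#'   `min(n_spectra - 1, axis length)`.
#' @return An object of class `spectra_pca`: list with `mean` (mean
#'   spectrum), `loadings` (axis x components, orthonormal), `scores`
#'   (spectra x components, zero column means), `explained_variance`
#'   (fractions, non-increasing) and `axis`.
#' @export
fit_pca <- function(spectra, n_components = 2L) {
  if (is.list(spectra) && all(vapply(spectra, is_spectrum, logical(1)))) {
    axis <- spectra[[1]]$wavenumber
    for (s in spectra) {
      if (!isTRUE(all.equal(s$wavenumber, axis))) {
        stop("all spectra must share one axis")
      }
    }
    X <- do.call(rbind, lapply(spectra, `[[`, "intensity"))
  } else {
    X <- as.matrix(spectra)
    axis <- as.numeric(colnames(X) %||% seq_len(ncol(X)))
  }
  if (nrow(X) < 2L) stop("PCA needs at least 2 spectra")
  max_k <- min(nrow(X) - 1L, ncol(X))
  if (n_components > max_k) {
    stop("`n_components` must be <= min(n spectra - 1, axis length)")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  loadings <- pc$rotation[, k, drop = FALSE]
  scores <- pc$x[, k, drop = FALSE]
  # deterministic sign convention
  for (j in k) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2
  structure(
    list(mean = pc$center, loadings = loadings, scores = scores,
         explained_variance = (ev / sum(ev))[k], axis = axis),
    class = "spectra_pca"
  )
}

#' Classical least squares unmixing of a spectrum
#'
#' Decomposes a measured spectrum S into a weighted sum of the library's
#' pure-component spectra, S = sum_i C_i a_i + E, choosing the weights
#' C_i that minimize ||S - sum_i C_i a_i||^2. By default the weights are
#' constrained nonnegative (they play the role of concentrations); the
#' unconstrained ordinary least-squares solution is available via
#' `nonnegative = FALSE`. The residual E is returned in full, so the
#' reconstruction identity S = sum_i C_i a_i + E is exact.
#'
#' @param s A `raman_spectrum`. If its axis differs from the library
#'   axis it is linearly interpolated onto it first (with a warning when
#'   the grids differ substantially).
#' @param library A `reference_library` of full column rank.
#' @param nonnegative Constrain weights >= 0 (default `TRUE`).
#' @return An object of class `cls_fit`: list with `weights` (named),
#'   `fitted`, `residual`, `residual_norm` and `nonnegative`.
#' @export
cls_fit <- function(s, library, nonnegative = TRUE) {
  assert_spectrum(s)
  if (!inherits(library, "reference_library")) {
    stop("`library` must be a reference_library")
  }
  A <- library$spectra
  y <- s$intensity
  if (!isTRUE(all.equal(s$wavenumber, library$axis))) {
    step_s <- mean(diff(s$wavenumber))
    step_l <- mean(diff(library$axis))
    if (abs(step_s - step_l) / step_l > 0.25) {
      warning("spectrum and library grids differ by more than 25%; ",
              "interpolation error may be appreciable")
    }
    y <- approx(s$wavenumber, s$intensity, xout = library$axis,
                rule = 2)$y
  }
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    cors <- crossprod(A)
    pairs <- which(abs(cors) > 1 - 1e-8 & upper.tri(cors), arr.ind = TRUE)
    bad <- if (nrow(pairs)) {
      paste(library$names[pairs[, 1]], "~", library$names[pairs[, 2]],
            collapse = "; ")
    } else "unidentified"
    stop("rank-deficient library; collinear components: ", bad)
  }
  w <- if (nonnegative) {
    pracma::lsqnonneg(A, y)$x
  } else {
    qr.coef(qrA, y)
  }
  fitted <- drop(A %*% w)
  residual <- y - fitted
  structure(
    list(weights = setNames(as.numeric(w), library$names),
         fitted = fitted, residual = residual,
         residual_norm = sqrt(sum(residual^2)),
         nonnegative = nonnegative),
    class = "cls_fit"
  )
}

star_code <- function(p) {
  if (is.na(p)) "" else if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*" else ""
}

#' Compare CLS component weights between two groups
#'
#' Two-tailed two-sample Student t test on per-sample component weights,
#' with the conventional significance star codes (* p <= 0.05,
#' ** p <= 0.01, *** p <= 0.001). Weights should be aggregated to one
#' value per experimental unit (animal) before testing; see
#' [aggregate_weights()].
#'
#' @param weights Data frame or matrix of component weights (one row per
#'   unit) or numeric vector when `component` is `NULL`.
#' @param groups Group label per row of `weights`.
#' @param component Component (column) name to compare.
#' @param group_a,group_b The two group labels to contrast.
#' @return Data frame with group means, standard errors, t statistic,
#'   two-sided p-value and star code.
#' @export
compare_component_weights <- function(weights, groups, component = NULL,
                                      group_a, group_b) {
  x <- if (is.null(component)) as.numeric(weights) else {
    as.numeric(as.data.frame(weights, check.names = FALSE)[[component]])
  }
  a <- x[groups == group_a]
  b <- x[groups == group_b]
  if (length(a) < 2L || length(b) < 2L) {
    stop("at least 2 observations per group are required")
  }
  if (var(a) == 0 && var(b) == 0) {
    # degenerate: no within-group variability; equal means are a perfect
    # null, unequal means a perfect separation
    p <- if (mean(a) == mean(b)) 1 else 0
    tstat <- if (mean(a) == mean(b)) 0 else Inf
  } else {
    tt <- t.test(a, b, var.equal = TRUE)
    p <- tt$p.value
    tstat <- unname(tt$statistic)
  }
  data.frame(
    component = component %||% NA_character_,
    group_a = group_a, group_b = group_b,
    mean_a = mean(a), mean_b = mean(b),
    se_a = sd(a) / sqrt(length(a)), se_b = sd(b) / sqrt(length(b)),
    t = tstat, p_value = p, stars = star_code(p),
    stringsAsFactors = FALSE
  )
}

#' Average CLS weights within experimental units
#'
#' Multiple spectra are recorded per animal; weights are averaged within
#' animal before group testing so that the animal, not the spectrum, is
#' the experimental unit.
#'
#' @param weights Matrix/data frame of per-spectrum weights.
#' @param unit Unit (animal) identifier per row.
#' @return List with `weights` (one row per unit) and `unit`.
#' @export
aggregate_weights <- function(weights, unit) {
  w <- as.data.frame(weights, check.names = FALSE)
  agg <- aggregate(w, by = list(.unit = unit), FUN = mean)
  out <- agg[, -1, drop = FALSE]
  names(out) <- names(w)
  list(weights = out, unit = agg$.unit)
}
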