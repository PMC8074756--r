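#' Per-animal cell density along the subgranular zone
#'
#' Positive-cell counts are expressed per mm of SGZ length; sections from
#' the same animal are combined by a length-weighted mean, i.e. total
#' cells over total measured length, so the animal is the experimental
#' unit.
#'
#' @param counts Data frame with columns `animal`, `group`, `cells`
#'   (integer >= 0) and `length_mm` (> 0); optionally `marker` and
#'   `section`.
#' @return Data frame with one row per animal: animal, group (and
#'   marker, if present), density (cells per mm).
#' @export
density_per_mm <- function(counts) {
  if (any(counts$length_mm <= 0)) stop("SGZ lengths must be > 0")
  if (any(counts$cells < 0)) stop("cell counts must be >= 0")
  form <- if (!is.null(counts$marker)) {
    cbind(cells, length_mm) ~ animal + marker + group
  } else {
    cbind(cells, length_mm) ~ animal + group
  }
  tot <- aggregate(form, data = counts, FUN = sum)
  tot$density <- tot$cells / tot$length_mm
  tot[, setdiff(names(tot), c("cells", "length_mm")), drop = FALSE]
}

#' Percent change of treated relative to control densities
#'
#' `100 * (mean(control) - mean(treated)) / mean(control)`: positive
#' values are reductions, negative values increases.
#'
#' @param treated,control Numeric vectors of per-animal densities;
#'   `mean(control)` must be > 0.
#' @return Percent reduction (scalar).
#' @export
percent_change <- function(treated, control) {
  mc <- mean(control)
  if (mc <= 0) stop("control mean must be > 0")
  100 * (mc - mean(treated)) / mc
}

#' Two-sample t test on per-animal densities
#'
#' Two-tailed two-sample Student t test (pooled variance by default,
#' matching the convention for comparing pairs of group means; Welch via
#' `welch = TRUE`). Significance is flagged at p <= `alpha`.
#'
#' @param treated,control Numeric vectors of per-animal densities, >= 2
#'   animals each.
#' @param welch Use the Welch (unequal-variance) test.
#' @param alpha Significance level (default 0.05).
#' @return List with `p_value`, `t`, `df`, `significant` and `stars`.
#' @export
group_ttest <- function(treated, control, welch = FALSE, alpha = 0.05) {
  if (length(treated) < 2L || length(control) < 2L) {
    stop("at least 2 animals per group are required")
  }
  tt <- t.test(treated, control, var.equal = !welch)
  list(p_value = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter), significant = tt$p.value <= alpha,
       stars = star_code(tt$p.value))
}

#' Neurogenesis summary per marker
#'
#' Densities, percent change and t test for each stage-specific marker
#' in an SGZ count table.
#'
#' @param counts Data frame as for [density_per_mm()], with a `marker`
#'   column.
#' @param control Control group label.
#' @param treated Treated group label.
#' @return Data frame per marker: mean densities, percent change,
#'   p-value, significance stars.
#' @export
neurogenesis_summary <- function(counts, control = "control",
                                 treated = "treated") {
  dens <- density_per_mm(counts)
  do.call(rbind, lapply(split(dens, dens$marker), function(d) {
    trt <- d$density[d$group == treated]
    ctl <- d$density[d$group == control]
    tt <- group_ttest(trt, ctl)
    data.frame(
      marker = d$marker[1],
      mean_control = mean(ctl), mean_treated = mean(trt),
      percent_change = percent_change(trt, ctl),
      p_value = tt$p_value, significant = tt$significant,
      stars = tt$stars, stringsAsFactors = FALSE, row.names = NULL
    )
  }))
}
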