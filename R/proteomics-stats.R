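#' Median-ratio normalization of protein abundances
#'
#' Removes per-sample loading differences by scaling each abundance
#' column with a median-of-ratios factor against a pseudo-reference (the
#' row-wise geometric mean over proteins quantified in every sample).
#' The factors are constrained to unit geometric mean, which makes the
#' operation idempotent and leaves an already-balanced table unchanged.
#'
#' @param abundances Matrix of nonnegative abundances, proteins x
#'   samples; each sample needs at least one nonzero value.
#' @return The normalized matrix, with the applied per-sample scale
#'   factors in attribute `scale_factors`.
#' @export
normalize_abundances <- function(abundances) {
  a <- as.matrix(abundances)
  if (any(a < 0)) stop("abundances must be >= 0")
  if (any(colSums(a) == 0)) stop("a sample has all-zero abundances")
  pos <- rowSums(a > 0) == ncol(a)
  if (!any(pos)) stop("no protein is quantified in every sample")
  ref <- exp(rowMeans(log(a[pos, , drop = FALSE])))
  s <- apply(a[pos, , drop = FALSE] / ref, 2, median)
  s <- s / exp(mean(log(s))) # unit geometric mean => idempotent
  out <- sweep(a, 2, s, "/")
  attr(out, "scale_factors") <- s
  out
}

#' Protein abundance ratio with capping
#'
#' The ratio of median abundances over replicates, treated over control,
#' clamped into [0.01, 100]: a zero control median is reported as the
#' 100 cap, a zero treated median as the 0.01 floor, and both zero as a
#' missing value.
#'
#' @param treated,control Numeric vectors of replicate abundances
#'   (>= 1 replicate each).
#' @param cap Upper cap (default 100); the floor is its reciprocal.
#' @return The capped ratio (scalar).
#' @export
protein_ratio <- function(treated, control, cap = 100) {
  if (length(treated) < 1L || length(control) < 1L) {
    stop("at least one replicate per side is required")
  }
  mt <- median(treated)
  mc <- median(control)
  if (mt == 0 && mc == 0) return(NA_real_)
  if (mc == 0) return(cap)
  if (mt == 0) return(1 / cap)
  min(max(mt / mc, 1 / cap), cap)
}

#' Background-variance significance test for protein ratios
#'
#' Exploits the quantification variability of the non-changing
#' "background" proteins: since only a small fraction of proteins is
#' expected to change, the spread of all per-protein log-ratios
#' estimates the null variability. The null standard deviation sigma_0
#' is estimated robustly (median absolute deviation x 1.4826, on the
#' replicate scale) and each protein's statistic
#' z = log-ratio * sqrt(n) / sigma_0 is referred to the standard normal,
#' two-sided.
#'
#' @param log_ratios Per-protein log ratios (any log base; mean over
#'   replicates), length >= 100 so the background is estimable.
#' @param n_replicates Replicate count per protein (scalar or vector);
#'   used to place proteins with different depth on a common scale.
#' @param estimator `"mad"` (default) or `"trimmed"` (sd of the central
#'   80% of scaled log-ratios).
#' @return List with `p_value` (per protein, two-sided), `z` and
#'   `sigma0`.
#' @export
background_ttest <- function(log_ratios, n_replicates = 4,
                             estimator = c("mad", "trimmed")) {
  estimator <- match.arg(estimator)
  if (length(log_ratios) < 100L) {
    stop("background variance needs >= 100 proteins")
  }
  n_replicates <- rep_len(n_replicates, length(log_ratios))
  scaled <- log_ratios * sqrt(n_replicates)
  sigma0 <- if (estimator == "mad") {
    mad(scaled, constant = 1.4826)
  } else {
    lo <- quantile(scaled, 0.1)
    hi <- quantile(scaled, 0.9)
    sd(scaled[scaled >= lo & scaled <= hi])
  }
  if (sigma0 == 0) stop("degenerate table: background variance is zero")
  z <- scaled / sigma0
  list(p_value = 2 * pnorm(-abs(z)), z = z, sigma0 = sigma0)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false discovery rate adjustment with monotonicity
#' enforcement, order-preserving in the input.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Filter proteins by the deregulation criteria
#'
#' A protein is significantly deregulated when it passes all three
#' gates: (i) q-value at most `q_thr`, (ii) identified with at least
#' `min_up` unique peptides, (iii) ratio outside the dead band
#' (`fc <= low` or `fc >= high`).
#'
#' @param results Data frame with columns `accession`, `fc` (capped
#'   ratio), `q_value` and `unique_peptides`.
#' @param q_thr q-value gate (default 0.05).
#' @param low,high Dead-band bounds (defaults 0.77 and 1.3; requires
#'   `low < 1 < high`).
#' @param min_up Unique-peptide gate (default 2).
#' @return List with `table` (passing rows plus `direction`),
#'   `deregulated` (accessions) and `direction` (per accession).
#' @export
filter_deregulated <- function(results, q_thr = 0.05, low = 0.77,
                               high = 1.3, min_up = 2L) {
  if (!(low < 1 && 1 < high)) stop("`low < 1 < high` is required")
  keep <- !is.na(results$fc) & !is.na(results$q_value) &
    results$q_value <= q_thr &
    results$unique_peptides >= min_up &
    (results$fc <= low | results$fc >= high)
  tab <- results[keep, , drop = FALSE]
  tab$direction <- ifelse(tab$fc >= high, "up", "down")
  list(table = tab, deregulated = as.character(tab$accession),
       direction = setNames(tab$direction, tab$accession))
}

#' Full proteomics significance analysis for one contrast
#'
#' Median-ratio normalization, capped median ratios, background-variance
#' test, BH adjustment and the three-gate deregulation filter.
#'
#' @param table Data frame with columns `accession`, `unique_peptides`
#'   and abundance columns.
#' @param groups Group label per abundance column.
#' @param group_a,group_b Contrast (A = control).
#' @param abundance_cols Names or indices of the abundance columns;
#'   defaults to all numeric columns other than `unique_peptides`.
#' @param q_thr,low,high,min_up Filter parameters (see
#'   [filter_deregulated()]).
#' @return Data frame: accession, unique_peptides, fc, p_value, q_value,
#'   deregulated, direction.
#' @export
protein_de <- function(table, groups, group_a = "control",
                       group_b = "treated", abundance_cols = NULL,
                       q_thr = 0.05, low = 0.77, high = 1.3,
                       min_up = 2L) {
  if (is.null(abundance_cols)) {
    num <- vapply(table, is.numeric, logical(1))
    num[names(table) %in% c("unique_peptides")] <- FALSE
    abundance_cols <- names(table)[num]
  }
  a <- normalize_abundances(as.matrix(table[, abundance_cols]))
  ctl <- a[, groups == group_a, drop = FALSE]
  trt <- a[, groups == group_b, drop = FALSE]
  fc <- vapply(seq_len(nrow(a)), function(i) {
    protein_ratio(trt[i, ], ctl[i, ])
  }, numeric(1))
  n <- min(ncol(ctl), ncol(trt))
  lr <- log2(pmin(pmax(fc, 0.01), 100))
  ok <- !is.na(lr)
  bt <- background_ttest(lr[ok], n_replicates = n)
  p <- rep(NA_real_, nrow(a))
  p[ok] <- bt$p_value
  q <- rep(NA_real_, nrow(a))
  q[ok] <- bh_adjust(bt$p_value)
  res <- data.frame(
    accession = table$accession,
    unique_peptides = table$unique_peptides,
    fc = fc, p_value = p, q_value = q,
    stringsAsFactors = FALSE
  )
  filt <- filter_deregulated(res, q_thr, low, high, min_up)
  res$deregulated <- res$accession %in% filt$deregulated
  res$direction <- ifelse(!res$deregulated, "none",
                          ifelse(res$fc >= high, "up", "down"))
  res
}

#' Direction concordance between two deregulation result sets
#'
#' For accessions shared between two conditions, counts pairs deregulated
#' in the same direction (both ratios at or above `high`, or both at or
#' below `low`), pairs on opposite sides of the dead band, and pairs with
#' at least one ratio inside it; reports the upregulated fraction among
#' concordant pairs.
#'
#' @param a,b Data frames with columns `accession` and `fc`.
#' @param low,high Dead-band bounds (defaults 0.77, 1.3).
#' @return List with `n_shared`, `concordant`, `discordant`, `in_band`,
#'   `fraction_up_concordant` and the per-accession classification.
#' @export
direction_concordance <- function(a, b, low = 0.77, high = 1.3) {
  shared <- intersect(a$accession, b$accession)
  if (length(shared) == 0L) {
    return(list(n_shared = 0L, concordant = 0L, discordant = 0L,
                in_band = 0L, fraction_up_concordant = NA_real_,
                classification = character()))
  }
  fa <- a$fc[match(shared, a$accession)]
  fb <- b$fc[match(shared, b$accession)]
  up <- fa >= high & fb >= high
  down <- fa <= low & fb <= low
  disc <- (fa >= high & fb <= low) | (fa <= low & fb >= high)
  cls <- rep("in_band", length(shared))
  cls[up] <- "concordant_up"
  cls[down] <- "concordant_down"
  cls[disc] <- "discordant"
  list(
    n_shared = length(shared),
    concordant = sum(up | down),
    discordant = sum(disc),
    in_band = sum(cls == "in_band"),
    fraction_up_concordant = if (any(up | down)) sum(up) / sum(up | down) else NA_real_,
    classification = setNames(cls, shared)
  )
}
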