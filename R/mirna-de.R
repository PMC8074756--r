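#' Filter a count matrix on counts per million
#'
#' Keeps features expressed above `min_cpm` counts per million (strictly)
#' in at least `min_samples` samples, the standard abundance filter for
#' small-RNA sequencing libraries.
#'
#' @param counts Matrix of raw counts, features x samples.
#' @param min_cpm CPM threshold (strict).
#' @param min_samples Minimum number of samples exceeding the threshold.
#' @param lib_sizes Library sizes; defaults to column sums.
#' @return The filtered count matrix.
#' @export
cpm_filter <- function(counts, min_cpm = 1, min_samples = 2L,
                       lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  cpm <- 1e6 * sweep(counts, 2, lib_sizes, "/")
  keep <- rowSums(cpm > min_cpm) >= min_samples
  if (!any(keep)) stop("no features pass the CPM filter")
  counts[keep, , drop = FALSE]
}

# Scale columns to a common (geometric-mean) library size and round,
# giving the equalized pseudo-counts the conditional NB test assumes.
equalize_lib_sizes <- function(counts, lib_sizes = colSums(counts)) {
  target <- exp(mean(log(lib_sizes)))
  round(sweep(counts, 2, target / lib_sizes, "*"))
}

# Conditional (Dirichlet-multinomial) log-likelihood of one group's
# counts given their total, for NB size r per sample; summed over rows.
cond_loglik_group <- function(counts, r) {
  n <- ncol(counts)
  z <- rowSums(counts)
  rowSums(lgamma(counts + r)) - n * lgamma(r) +
    lgamma(n * r) - lgamma(z + n * r)
}

#' Estimate a common NB dispersion by conditional maximum likelihood
#'
#' Maximizes the negative-binomial conditional likelihood (each group's
#' counts conditioned on its total, which removes the mean parameter)
#' pooled over all features and replicated groups, after equalizing
#' library sizes by proportional scaling to the geometric-mean depth.
#' The dispersion phi parameterizes Var = mu + phi * mu^2; phi = 0
#' (Poisson) is admissible.
#'
#' @param counts Matrix of raw counts, features x samples.
#' @param groups Group label per sample; at least one group must have
#'   >= 2 samples.
#' @param lib_sizes Library sizes; defaults to column sums.
#' @return The estimated common dispersion (scalar >= 0).
#' @export
estimate_dispersion <- function(counts, groups,
                                lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  tab <- table(groups)
  rep_groups <- names(tab)[tab >= 2]
  if (length(rep_groups) == 0L) {
    stop("dispersion estimation needs a group with >= 2 samples")
  }
  eq <- equalize_lib_sizes(counts, lib_sizes)
  nll <- function(delta) {
    r <- (1 - delta) / delta # phi = delta / (1 - delta); r = 1 / phi
    -sum(vapply(rep_groups, function(g) {
      sum(cond_loglik_group(eq[, groups == g, drop = FALSE], r))
    }, numeric(1)))
  }
  # delta = phi / (1 + phi) maps phi in [0, Inf) to [0, 1)
  opt <- optimize(nll, interval = c(1e-6, 0.95))
  phi <- opt$minimum / (1 - opt$minimum)
  # boundary check: Poisson limit
  if (nll(1e-6) <= opt$objective) phi <- 1e-6 / (1 - 1e-6)
  if (phi < 1e-4) phi <- 0
  phi
}

# Exact two-sided p-value for one feature: conditional distribution of
# the group-A total given the overall total under NB(size = n_a * r) vs
# NB(size = n_b * r); phi = 0 is the binomial (Poisson) limit. Two-sided
# by summing all outcome probabilities <= the observed one. For very
# large totals the support is restricted to a window holding all but
# < 1e-30 of the conditional mass (always containing the observation).
exact_p_one <- function(za, z, na, nb, phi) {
  if (z == 0) return(1)
  k <- 0:z
  if (z > 10000) {
    pr <- na / (na + nb)
    width <- ceiling(50 * sqrt(z * pr * (1 - pr) *
                                 (1 + phi * z / (na + nb))))
    lo <- max(0, min(za, round(z * pr) - width))
    hi <- min(z, max(za, round(z * pr) + width))
    k <- lo:hi
  }
  logp <- if (phi == 0) {
    dbinom(k, z, na / (na + nb), log = TRUE)
  } else {
    r <- 1 / phi
    lgamma(k + na * r) - lgamma(k + 1) +
      lgamma(z - k + nb * r) - lgamma(z - k + 1)
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(za, k)]
  min(1, max(sum(p[p <= p_obs * (1 + 1e-10)]), .Machine$double.xmin))
}

#' Negative-binomial exact test for two-group count comparison
#'
#' For each feature, computes the two-sided exact p-value of the group-A
#' total conditioned on the overall total under a common-dispersion NB
#' model, after equalizing library sizes. At phi = 0 this reduces to the
#' conditional binomial (Poisson) exact test. Two-sided p sums all
#' outcomes with probability not exceeding the observed one.
#'
#' @param counts Matrix of raw counts, features x samples.
#' @param groups Group label per sample.
#' @param group_a,group_b The two groups to compare.
#' @param dispersion Common NB dispersion phi >= 0 (see
#'   [estimate_dispersion()]).
#' @param lib_sizes Library sizes; defaults to column sums.
#' @return Named numeric vector of p-values in (0, 1], one per feature.
#' @export
nb_exact_test <- function(counts, groups, group_a, group_b,
                          dispersion = 0, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  sel_a <- groups == group_a
  sel_b <- groups == group_b
  if (!any(sel_a) || !any(sel_b)) stop("both groups must be non-empty")
  if (dispersion < 0) stop("`dispersion` must be >= 0")
  sel <- sel_a | sel_b
  eq <- equalize_lib_sizes(counts[, sel, drop = FALSE], lib_sizes[sel])
  ga <- sel_a[sel]
  za <- rowSums(eq[, ga, drop = FALSE])
  z <- rowSums(eq)
  na <- sum(ga)
  nb <- sum(!ga)
  p <- vapply(seq_along(z), function(i) {
    exact_p_one(za[i], z[i], na, nb, dispersion)
  }, numeric(1))
  setNames(p, rownames(counts))
}

#' Signed fold change between two group means
#'
#' Ratio convention used for reporting miRNA deregulation: the raw ratio
#' r = (mean_b + eps) / (mean_a + eps) is reported as r when r >= 1 and
#' as -1/r otherwise, so |FC| >= 1 always and a signed FC of -3 denotes
#' a 3-fold decrease. The pseudo-offset eps guards against zero means.
#'
#' @param mean_a Baseline (control) mean, >= 0.
#' @param mean_b Comparison (treated) mean, >= 0.
#' @param eps Pseudo-count offset added to both means (default 0.5).
#' @return Signed fold change (vectorized).
#' @export
signed_fold_change <- function(mean_a, mean_b, eps = 0.5) {
  if (any(mean_a < 0 | mean_b < 0)) stop("means must be >= 0")
  if (any(mean_a == 0 & mean_b == 0)) {
    stop("signed fold change undefined when both means are 0")
  }
  r <- (mean_b + eps) / (mean_a + eps)
  ifelse(r >= 1, r, -1 / r)
}

#' Run the full small-count DE comparison
#'
#' CPM filter, common-dispersion estimate, exact test and signed fold
#' changes for one two-group contrast; the deregulation call applies the
#' raw-p and fold-change criteria via [classify_deregulated()].
#'
#' @param counts Matrix of raw counts, features x samples.
#' @param groups Group label per sample.
#' @param group_a,group_b Contrast (A = baseline).
#' @param min_cpm,min_samples CPM filter parameters.
#' @param p_thr,fc_thr Deregulation criteria (defaults p <= 0.1,
#'   |FC| >= 3).
#' @return Data frame: feature, mean_a, mean_b, fc (signed), p_value,
#'   q_value (Benjamini-Hochberg, reported for transparency; the call
#'   uses the raw p), call.
#' @export
mirna_de <- function(counts, groups, group_a, group_b, min_cpm = 1,
                     min_samples = 2L, p_thr = 0.1, fc_thr = 3) {
  counts <- cpm_filter(counts, min_cpm, min_samples)
  phi <- estimate_dispersion(counts, groups)
  p <- nb_exact_test(counts, groups, group_a, group_b, dispersion = phi)
  eq <- equalize_lib_sizes(counts)
  ma <- rowMeans(eq[, groups == group_a, drop = FALSE])
  mb <- rowMeans(eq[, groups == group_b, drop = FALSE])
  fc <- signed_fold_change(ma, mb)
  res <- data.frame(
    feature = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    mean_a = ma, mean_b = mb, fc = fc, p_value = p,
    q_value = bh_adjust(p), stringsAsFactors = FALSE,
    row.names = NULL
  )
  res$call <- classify_deregulated(res, p_thr, fc_thr)$call
  attr(res, "dispersion") <- phi
  res
}

#' Classify features as up-, down- or non-deregulated
#'
#' Applies the raw-p and signed fold-change deregulation criteria:
#' up if p <= `p_thr` and FC >= `fc_thr`; down if p <= `p_thr` and
#' FC <= -`fc_thr`; none otherwise.
#'
#' @param results Data frame with columns `feature`, `fc` and `p_value`.
#' @param p_thr P-value threshold (default 0.1).
#' @param fc_thr Fold-change threshold (default 3).
#' @return List with `table` (results plus `call` column), `call`
#'   (factor per feature) and `deregulated` (character vector of up or
#'   down feature ids).
#' @export
classify_deregulated <- function(results, p_thr = 0.1, fc_thr = 3) {
  if (p_thr <= 0 || fc_thr <= 0) stop("thresholds must be > 0")
  up <- results$p_value <= p_thr & results$fc >= fc_thr
  down <- results$p_value <= p_thr & results$fc <= -fc_thr
  call <- rep("none", nrow(results))
  call[up] <- "up"
  call[down] <- "down"
  tab <- results
  tab$call <- call
  list(table = tab, call = call,
       deregulated = as.character(results$feature[up | down]))
}

#' Delta-delta-Ct quantification for a PCR array
#'
#' Normalizes each feature's Ct by a per-sample normalizer Ct (default:
#' the global mean Ct of the sample), forms delta-Ct values, and reports
#' per-feature relative expression 2^-(ddCt) between treated and control
#' with a two-tailed two-sample Student t p-value on the delta-Ct values.
#' Deregulation is called at p <= `p_thr` (default 0.1).
#'
#' @param ct Matrix of Ct values, features x samples (finite).
#' @param groups Group label per sample; >= 2 samples per group.
#' @param control Label of the control group.
#' @param normalizer Optional numeric vector of normalizer Ct values,
#'   one per sample; defaults to each sample's mean Ct across features.
#' @param p_thr Deregulation threshold on the raw p-value.
#' @return Data frame: feature, ddct, relative_expression, p_value,
#'   deregulated; the normalizer used is recorded in attribute
#'   `normalizer`.
#' @export
ddct_quantify <- function(ct, groups, control, normalizer = NULL,
                          p_thr = 0.1) {
  ct <- as.matrix(ct)
  if (any(!is.finite(ct))) stop("Ct values must be finite")
  groups <- as.character(groups)
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  norm_label <- "global_mean_ct"
  if (is.null(normalizer)) {
    normalizer <- colMeans(ct)
  } else {
    norm_label <- "user_supplied"
    if (length(normalizer) != ncol(ct) || any(!is.finite(normalizer))) {
      stop("`normalizer` must supply one finite Ct per sample")
    }
  }
  dct <- sweep(ct, 2, normalizer, "-")
  ctl <- groups == control
  if (!any(ctl)) stop("control group not found")
  trt <- !ctl
  out <- do.call(rbind, lapply(seq_len(nrow(ct)), function(i) {
    a <- dct[i, ctl]
    b <- dct[i, trt]
    ddct <- mean(b) - mean(a)
    p <- if (var(a) == 0 && var(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else {
      t.test(a, b, var.equal = TRUE)$p.value
    }
    data.frame(
      feature = rownames(ct)[i] %||% as.character(i),
      ddct = ddct, relative_expression = 2^(-ddct),
      p_value = p, deregulated = p <= p_thr,
      stringsAsFactors = FALSE
    )
  }))
  attr(out, "normalizer") <- norm_label
  out
}
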