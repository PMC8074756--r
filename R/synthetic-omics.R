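#' Configuration for simulating miRNA count matrices
#'
#' Counts follow a negative binomial with Var = mu + phi * mu^2; phi = 0
#' gives the Poisson limit. Designated features carry a true signed fold
#' change between the two groups (|FC| >= 1 convention: a signed FC of
#' -3 means a 3-fold decrease).
#'
#' @param n_per_group Samples per group (two groups: control/treated).
#' @param n_features Number of miRNA features.
#' @param lib_sizes Library sizes; scalar (recycled) or one per sample.
#' @param baseline_mean Nonnegative expected relative abundance weight
#'   per feature; scalar or length `n_features`. Internally rescaled to
#'   proportions.
#' @param dispersion NB dispersion phi >= 0.
#' @param de Data frame with columns `feature` (index) and `fc` (true
#'   signed fold change, |fc| >= 1) for designated DE features; may be
#'   empty.
#' @return An object of class `count_sim_config`.
#' @export
count_sim_config <- function(n_per_group = 3L, n_features = 200L,
                             lib_sizes = 1e6, baseline_mean = NULL,
                             dispersion = 0.1, de = NULL) {
  if (dispersion < 0) stop("`dispersion` must be >= 0")
  if (is.null(baseline_mean)) {
    # log-uniform abundance spread typical of miRNA libraries
    baseline_mean <- exp(seq(log(1), log(2000), length.out = n_features))
  }
  baseline_mean <- rep_len(baseline_mean, n_features)
  if (any(baseline_mean < 0)) stop("`baseline_mean` must be >= 0")
  lib_sizes <- rep_len(lib_sizes, 2L * n_per_group)
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  if (is.null(de)) {
    de <- data.frame(feature = integer(), fc = numeric())
  }
  if (nrow(de) && any(abs(de$fc) < 1)) {
    stop("true signed fold changes must satisfy |FC| >= 1")
  }
  structure(
    list(n_per_group = as.integer(n_per_group),
         n_features = as.integer(n_features),
         lib_sizes = lib_sizes, baseline_mean = baseline_mean,
         dispersion = dispersion, de = de),
    class = "count_sim_config"
  )
}

signed_to_ratio <- function(fc) ifelse(fc >= 1, fc, -1 / fc)

#' Simulate a miRNA count matrix with known DE truth
#'
#' @param config A `count_sim_config`.
#' @param seed Mandatory integer seed.
#' @return List with `counts` (matrix features x samples), `groups`
#'   (character vector per sample, `"control"`/`"treated"`), and `truth`
#'   (data frame of designated DE features and their true signed FC).
#' @export
simulate_mirna_counts <- function(config, seed) {
  if (!inherits(config, "count_sim_config")) {
    stop("`config` must be a count_sim_config")
  }
  n <- config$n_per_group
  groups <- rep(c("control", "treated"), each = n)
  rel <- config$baseline_mean / sum(config$baseline_mean)
  ratio <- rep(1, config$n_features)
  if (nrow(config$de)) {
    ratio[config$de$feature] <- signed_to_ratio(config$de$fc)
  }
  with_seed(seed, {
    counts <- matrix(0L, config$n_features, 2L * n)
    for (j in seq_len(2L * n)) {
      mu <- config$lib_sizes[j] * rel * (if (groups[j] == "treated") ratio else 1)
      counts[, j] <- if (config$dispersion == 0) {
        rpois(config$n_features, mu)
      } else {
        rnbinom(config$n_features, size = 1 / config$dispersion, mu = mu)
      }
    }
    rownames(counts) <- sprintf("mir-%04d", seq_len(config$n_features))
    colnames(counts) <- sprintf("%s_%d", groups, rep(seq_len(n), 2))
    truth <- config$de
    if (nrow(truth)) truth$feature_id <- rownames(counts)[truth$feature]
    list(counts = counts, groups = groups, truth = truth)
  })
}

#' Configuration for simulating protein quantification tables
#'
#' Log2 abundances are Gaussian around protein-specific group means with
#' a common background standard deviation; a small changed subset carries
#' true abundance ratios against a stable background. Unique-peptide
#' counts are drawn as 1 + Poisson(`up_lambda`).
#'
#' @param n_proteins Number of proteins.
#' @param n_per_group Replicates per group, >= 2.
#' @param background_sd Per-replicate standard deviation of log2
#'   abundance, > 0.
#' @param changed Data frame with columns `protein` (index) and `ratio`
#'   (true treated/control ratio, > 0); may be empty.
#' @param up_lambda Poisson rate for unique peptide counts above 1.
#' @return An object of class `protein_sim_config`.
#' @export
protein_sim_config <- function(n_proteins = 2000L, n_per_group = 4L,
                               background_sd = 0.2, changed = NULL,
                               up_lambda = 4) {
  if (n_per_group < 2L) stop("at least 2 replicates per group are required")
  if (background_sd <= 0) stop("`background_sd` must be > 0")
  if (is.null(changed)) {
    changed <- data.frame(protein = integer(), ratio = numeric())
  }
  if (nrow(changed) && any(changed$ratio <= 0)) {
    stop("true ratios must be > 0")
  }
  structure(
    list(n_proteins = as.integer(n_proteins),
         n_per_group = as.integer(n_per_group),
         background_sd = background_sd, changed = changed,
         up_lambda = up_lambda),
    class = "protein_sim_config"
  )
}

#' Simulate a protein quantification table with known truth
#'
#' @param config A `protein_sim_config`.
#' @param seed Mandatory integer seed.
#' @return List with `table` (data frame: accession, gene, unique
#'   peptides, abundance columns), `groups` (per abundance column), and
#'   `truth` (changed proteins with true ratios).
#' @export
simulate_protein_table <- function(config, seed) {
  if (!inherits(config, "protein_sim_config")) {
    stop("`config` must be a protein_sim_config")
  }
  n <- config$n_per_group
  p <- config$n_proteins
  groups <- rep(c("control", "treated"), each = n)
  log_ratio <- rep(0, p)
  if (nrow(config$changed)) {
    log_ratio[config$changed$protein] <- log2(config$changed$ratio)
  }
  with_seed(seed, {
    base <- runif(p, 18, 30) # log2 abundance range of label-free MS
    ab <- matrix(0, p, 2L * n)
    for (j in seq_len(2L * n)) {
      mu <- base + if (groups[j] == "treated") log_ratio else 0
      ab[, j] <- 2^(mu + rnorm(p, 0, config$background_sd))
    }
    up <- 1L + rpois(p, config$up_lambda)
    acc <- sprintf("P%05d", seq_len(p))
    tab <- data.frame(
      accession = acc, gene = sprintf("Gene%d", seq_len(p)),
      unique_peptides = up, stringsAsFactors = FALSE
    )
    ab_df <- as.data.frame(ab)
    names(ab_df) <- sprintf("%s_%d", groups, rep(seq_len(n), 2))
    truth <- config$changed
    if (nrow(truth)) truth$accession <- acc[truth$protein]
    list(table = cbind(tab, ab_df), groups = groups, truth = truth)
  })
}

#' Configuration for simulating SGZ cell-count tables
#'
#' Per-animal cell densities (positive cells per mm of subgranular-zone
#' length) are Gaussian around the control density reduced by a true
#' percent effect, with a between-animal coefficient of variation.
#'
#' @param n_per_group Animals per group.
#' @param control_density Control density, cells per mm SGZ, > 0.
#' @param reduction True percent reduction in the treated group,
#'   0 <= reduction < 100.
#' @param cv Between-animal coefficient of variation (fraction), >= 0.
#' @param marker Marker label (`"GFAP"`, `"Sox2"` or `"DCX"`).
#' @param sections Sections scored per animal.
#' @return An object of class `cellcount_sim_config`.
#' @export
cellcount_sim_config <- function(n_per_group = 6L, control_density = 15,
                                 reduction = 37.22, cv = 0.1,
                                 marker = "GFAP", sections = 3L) {
  if (control_density <= 0) stop("`control_density` must be > 0")
  if (reduction < 0 || reduction >= 100) {
    stop("`reduction` must be in [0, 100)")
  }
  if (cv < 0) stop("`cv` must be >= 0")
  structure(
    list(n_per_group = as.integer(n_per_group),
         control_density = control_density, reduction = reduction,
         cv = cv, marker = marker, sections = as.integer(sections)),
    class = "cellcount_sim_config"
  )
}

#' Simulate an SGZ cell-count table
#'
#' @param config A `cellcount_sim_config`.
#' @param seed Mandatory integer seed.
#' @return Data frame: animal, group, marker, section, cells, length_mm.
#'   Section counts are the (rounded) product of the animal's density and
#'   the section length.
#' @export
simulate_sgz_counts <- function(config, seed) {
  if (!inherits(config, "cellcount_sim_config")) {
    stop("`config` must be a cellcount_sim_config")
  }
  with_seed(seed, {
    rows <- list()
    k <- 0L
    for (grp in c("control", "treated")) {
      mu <- config$control_density *
        (if (grp == "treated") 1 - config$reduction / 100 else 1)
      for (i in seq_len(config$n_per_group)) {
        dens <- max(rnorm(1, mu, config$cv * mu), 0)
        for (s in seq_len(config$sections)) {
          k <- k + 1L
          len <- if (config$cv == 0) 2 else round(runif(1, 1.5, 3.5), 2)
          rows[[k]] <- data.frame(
            animal = sprintf("%s_%d", grp, i), group = grp,
            marker = config$marker, section = s,
            cells = round(dens * len), length_mm = len,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    do.call(rbind, rows)
  })
}
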