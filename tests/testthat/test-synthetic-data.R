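test_that("reference library construction places peaks and validates input", {
  axis <- fixture_axis
  lib <- make_reference_library(
    "solo", list(peak_spec(1000, 20, 1)), axis
  )
  expect_equal(axis[which.max(lib$spectra[, 1])], axis[which.min(abs(axis - 1000))])
  expect_equal(sum(lib$spectra[, 1]^2), 1, tolerance = 1e-12)

  # identical peak lists under different names: degenerate library
  pk <- rbind(peak_spec(800, 30), peak_spec(1400, 25))
  expect_error(
    make_reference_library(c("x", "y"), list(pk, pk), axis),
    "degenerate"
  )
  expect_error(
    make_reference_library("x", list(pk[0, ]), axis),
    "at least one peak"
  )
  expect_error(
    make_reference_library("x", list(peak_spec(2500, 20)), axis),
    "outside the axis"
  )
})

test_that("default five-component library has distinct, unit-norm spectra", {
  lib <- default_reference_library()
  expect_setequal(
    lib$names,
    c("DNA", "Histone 2A", "TNF-alpha", "TGF-beta", "Uric acid")
  )
  gram <- crossprod(lib$spectra)
  expect_equal(diag(gram), setNames(rep(1, 5), lib$names), tolerance = 1e-12)
  expect_true(all(gram[upper.tri(gram)] < 1))
})

test_that("tissue spectrum simulation reproduces the mixture model", {
  lib <- two_component_library()
  # identity case: no noise, no baseline, weight on the first component
  d <- mixture_design("SI", matrix(c(1, 0), 1), baseline = 0,
                      noise_sd = 0, spectra_per_sample = 1)
  sim <- simulate_tissue_spectra(lib, d, seed = 11)
  expect_equal(sim$spectra[[1]]$intensity, unname(lib$spectra[, 1]))

  # determinism: same seed gives bit-identical output
  d2 <- mixture_design(c("SI", "PBI"), rbind(c(0.4, 0.6), c(0.8, 0.2)),
                       noise_sd = 0.01)
  s1 <- simulate_tissue_spectra(lib, d2, seed = 7)
  s2 <- simulate_tissue_spectra(lib, d2, seed = 7)
  expect_identical(s1, s2)

  # seed is mandatory
  expect_error(simulate_tissue_spectra(lib, d2), "seed")

  # weight dimension must match the library
  d3 <- mixture_design("SI", matrix(1, 1, 1), noise_sd = 0)
  expect_error(simulate_tissue_spectra(lib, d3, seed = 1), "library size")
})

test_that("noisy simulated mixtures close the loop with CLS fitting", {
  lib <- two_component_library()
  d <- mixture_design("SI", matrix(c(0.3, 0.7), 1), baseline = 0,
                      noise_sd = 0.01, spectra_per_sample = 1)
  sim <- simulate_tissue_spectra(lib, d, seed = 5)
  fit <- cls_fit(sim$spectra[[1]], lib)
  expect_lt(max(abs(fit$weights - c(0.3, 0.7)) / c(0.3, 0.7)), 0.05)
})

test_that("simulated counts follow the NB mean-variance law", {
  # Poisson limit: per-feature sample variance tracks the mean
  cfg <- count_sim_config(n_per_group = 20L, n_features = 1000L,
                          lib_sizes = 1e5, dispersion = 0)
  sim <- simulate_mirna_counts(cfg, seed = 3)
  m <- rowMeans(sim$counts)
  v <- apply(sim$counts, 1, var)
  keep <- m > 20
  expect_equal(median(v[keep] / m[keep]), 1, tolerance = 0.15)

  # NB moments at 1e4 draws: Var = mu + phi mu^2
  cfg2 <- count_sim_config(n_per_group = 5000L, n_features = 2L,
                           lib_sizes = 1e5,
                           baseline_mean = c(1, 1), dispersion = 0.2)
  sim2 <- simulate_mirna_counts(cfg2, seed = 9)
  mu <- rowMeans(sim2$counts)
  vv <- apply(sim2$counts, 1, var)
  expect_equal(vv, mu + 0.2 * mu^2, tolerance = 0.1)

  expect_error(count_sim_config(dispersion = -1), ">= 0")
  expect_error(count_sim_config(de = data.frame(feature = 1, fc = 0.5)),
               "\\|FC\\| >= 1")
})

test_that("null count simulations yield essentially no deregulation calls", {
  calls <- vapply(1:40, function(i) {
    cfg <- count_sim_config(n_per_group = 3L, n_features = 100L,
                            lib_sizes = 5e4, dispersion = 0.1)
    sim <- simulate_mirna_counts(cfg, seed = 1000 + i)
    res <- mirna_de(sim$counts, sim$groups, "control", "treated")
    sum(res$call != "none")
  }, numeric(1))
  expect_lt(mean(calls), 1)
})

test_that("a strong designated fold change is recovered across seeds", {
  hits <- vapply(1:100, function(i) {
    cfg <- count_sim_config(
      n_per_group = 3L, n_features = 100L, lib_sizes = 1e6,
      dispersion = 0.1, de = data.frame(feature = 50L, fc = 8)
    )
    sim <- simulate_mirna_counts(cfg, seed = 2000 + i)
    res <- mirna_de(sim$counts, sim$groups, "control", "treated")
    res$call[res$feature == sim$truth$feature_id] == "up"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("protein table simulation is deterministic and null-calibrated", {
  cfg <- protein_sim_config(n_proteins = 2000L)
  s1 <- simulate_protein_table(cfg, seed = 4)
  s2 <- simulate_protein_table(cfg, seed = 4)
  expect_identical(s1, s2)

  # all ratios 1: essentially no discoveries at q <= 0.05
  res <- protein_de(s1$table, s1$groups)
  expect_lte(sum(res$deregulated), 2)

  expect_error(protein_sim_config(n_per_group = 1L), "2 replicates")
  expect_error(protein_sim_config(changed = data.frame(protein = 1, ratio = -2)),
               "> 0")
})

test_that("SGZ count simulation reproduces designed densities", {
  cfg0 <- cellcount_sim_config(reduction = 0, cv = 0, control_density = 15)
  tab <- simulate_sgz_counts(cfg0, seed = 6)
  dens <- density_per_mm(tab)
  expect_true(all(dens$density == 15))

  # designed 37.22% reduction is recovered on average across seeds
  est <- vapply(1:100, function(i) {
    cfg <- cellcount_sim_config(n_per_group = 6L, reduction = 37.22,
                                cv = 0.1)
    d <- density_per_mm(simulate_sgz_counts(cfg, seed = 3000 + i))
    percent_change(d$density[d$group == "treated"],
                   d$density[d$group == "control"])
  }, numeric(1))
  expect_lt(abs(mean(est) - 37.22), 10)

  expect_error(cellcount_sim_config(control_density = -5), "> 0")
  expect_error(cellcount_sim_config(cv = -0.1), ">= 0")
  expect_error(cellcount_sim_config(reduction = 100), "\\[0, 100\\)")
})
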