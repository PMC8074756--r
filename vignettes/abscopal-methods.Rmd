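---
title: "Methods: multi-omics quantification of out-of-field radiation effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics quantification of out-of-field radiation effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abscopal)
```

This package implements the analysis chain used to compare in-field and
out-of-field radiation responses in mouse hippocampus across four data
layers — Raman spectral biochemistry, miRNA counts, label-free protein
abundances and subgranular-zone (SGZ) cell counts — together with the
set-overlap arithmetic that turns per-condition deregulation lists into
cross-condition comparisons. This vignette describes the models, the
parameters that matter, the synthetic-data generators used for
validation, and the numerical choices behind each stage.

## Raman spectral chain

### Preprocessing

A spectrum is a strictly increasing wavenumber axis (cm⁻¹) with
intensities in arbitrary units. The chain applies, in order:

1. **Axis calibration** (`calibrate_axis`). One matched reference line
   (typically the 520.7 cm⁻¹ line of crystalline silicon) gives a rigid
   shift; *k* ≥ 2 matched lines give a least-squares polynomial remap of
   degree min(*k* − 1, 3). Degree is capped at 3 because grating
   distortions are smooth and higher orders oscillate between anchors.
   A remap that breaks axis monotonicity is an error, not a warning.
2. **Instrument response correction**
   (`correct_instrument_response`): division by the response curve,
   i.e. multiplication by certified/measured intensity of a fluorescence
   standard. Tests use synthetic response curves; certified standard
   curves are instrument-specific inputs.
3. **Crop** to the 400–1800 cm⁻¹ fingerprint window (closed interval).
4. **Rubberband baseline** (`rubberband_baseline`): the baseline is the
   piecewise-linear interpolation of the *lower convex hull* of the
   (wavenumber, intensity) points, computed by a monotone-chain scan.
   The corrected spectrum is nonnegative, vanishes at every hull vertex,
   and is invariant under addition of a constant. This removes the
   slowly varying fluorescence background; it deliberately also removes
   any genuinely convex low-frequency signal, which is the standard
   trade-off of hull baselines.
5. **Vector normalization** to unit Euclidean norm, making spectra
   comparable across acquisitions.
6. **Savitzky–Golay smoothing** with a 7-point window and 5th-order
   polynomial (`signal::sgolayfilt`). The terminal half-windows are
   evaluated from the first/last full-window polynomial fits, which
   preserves vector length for PCA. A 5th-order/7-point filter is a
   very light smoother: it reproduces degree-5 polynomials exactly and
   mostly suppresses single-pixel noise.

Normalization precedes smoothing, matching the conventional ordering of
tissue-Raman pipelines. The effect of swapping the two stages is tiny —
smoothing changes the norm by well under 5% (the pipeline asserts
‖output‖ ∈ [0.95, 1.05]) — but the order is fixed and recorded in the
spectrum's stage metadata rather than silently chosen per run.

### PCA and CLS unmixing

`fit_pca` mean-centers the intensity matrix and extracts leading
eigenvectors (via `stats::prcomp`). Loadings signs are fixed
deterministically (largest-magnitude element positive) so loading plots
reproduce across runs and platforms.

`cls_fit` solves the classical least squares model
*S* = Σᵢ *aᵢCᵢ* + *E* for the component weights *Cᵢ*. Although the
model equation is linear and unconstrained, the weights are
concentrations of molecular species, so the default solver is
nonnegative least squares (`pracma::lsqnonneg`); `nonnegative = FALSE`
gives the ordinary least-squares solution, whose residual is orthogonal
to the library span. Reference spectra are vector-normalized at library
construction so weights are comparable across components. Spectra on a
different grid are linearly interpolated onto the library axis, with a
warning when grid spacing differs by more than 25%. A rank-deficient
library is an error naming the collinear components.

Because several spectra are recorded per animal but the animal is the
experimental unit, `aggregate_weights` averages CLS weights within
animal before `compare_component_weights` runs the two-tailed two-sample
Student t test with the conventional star codes (* p ≤ 0.05, ** p ≤
0.01, *** p ≤ 0.001). When both groups are exactly constant the test is
degenerate: equal means report p = 1, unequal means p = 0.

## miRNA differential expression

Raw counts are filtered to features with CPM strictly above 1 in at
least 2 samples. The test is a re-implemented common-dispersion
negative-binomial exact test:

- **Dispersion** (`estimate_dispersion`): library sizes are equalized by
  proportional scaling to the geometric-mean depth (with rounding), and
  the common dispersion φ maximizes the conditional
  (Dirichlet-multinomial) likelihood of each replicated group's counts
  given its total, pooled over features. The conditioning removes the
  per-feature mean, leaving φ as the only parameter; φ = 0 (Poisson) is
  admissible and estimates below 10⁻⁴ are truncated to 0.
- **Exact test** (`nb_exact_test`): for each feature, the two-sided
  exact p-value of the group-A total given the overall total, which
  under NB sampling with equalized libraries is an NB-conditional
  distribution (binomial in the Poisson limit). Two-sided p sums all
  outcomes with probability ≤ the observed one. For totals above 10⁴
  the support is restricted to a ±50-standard-deviation window (always
  containing the observation); the truncated mass is below 10⁻³⁰, far
  under the precision of any reported p.
- **Fold change** (`signed_fold_change`): the ratio
  (mean_B + ε)/(mean_A + ε) with pseudo-count ε = 0.5, reported as a
  signed value (−1/r when r < 1) so |FC| ≥ 1 and thresholds read
  symmetrically. ε is configurable; 0.5 is the standard half-count
  offset for zero handling.
- **Deregulation criteria** (`classify_deregulated`): up ⟺ p ≤ 0.1 and
  FC ≥ 3; down ⟺ p ≤ 0.1 and FC ≤ −3. The p-values are deliberately
  *not* multiplicity-adjusted — the criteria operate on raw p — but a
  BH-adjusted column is emitted for transparency. The ≥ (rather than >)
  convention is used for both gates.

An exact conditional test is discrete: at shallow sequencing depth the
attainable p-values are coarse and the test is conservative (empirical
type-I error at p ≤ 0.1 can drop toward 0.06 when per-feature totals are
in the tens). At the synthetic module's default depth (10⁶ reads per
library) calibration is close to nominal (≈ 0.08–0.10).

`ddct_quantify` implements ΔΔCt quantification for the PCR-array
follow-up: ΔCt against a per-sample normalizer (default: the sample's
global mean Ct, recorded in the output metadata; a dedicated normalizer
assay can be supplied), relative expression 2^−ΔΔCt, and a two-sample
Student t test on ΔCt with deregulation called at p ≤ 0.1.

## Proteomics statistics

Quantification tables carry per-sample normalized abundances and
unique-peptide (UP) counts. The stage applies:

1. **Median-ratio normalization** against a geometric-mean
   pseudo-reference over proteins quantified in all samples. The scale
   factors are constrained to unit geometric mean, which makes the
   operation exactly idempotent. This is a table-level simplification of
   retention-time-dependent loading normalization, which needs
   feature-level RT data not present post-quantification; both serve the
   same purpose of removing sample loading errors.
2. **Ratios** (`protein_ratio`): treated/control median abundances over
   replicates, clamped into [0.01, 100]. Zero control medians report the
   100 cap and zero treated medians the 0.01 floor, so extreme
   on/off proteins carry a defined, bounded ratio.
3. **Background-variance test** (`background_ttest`): with only a small
   fraction of proteins expected to change, the spread of all
   per-protein log-ratios estimates the null variability. The null sd is
   estimated robustly (MAD × 1.4826 on the √n-scaled log-ratios; a
   trimmed-sd estimator is available) and z = log-ratio·√n/σ₀ is
   referred to the standard normal, two-sided. The robust estimator
   tolerates a contaminated background (up to ~50% changed proteins in
   principle, far beyond any realistic table).
4. **BH adjustment** (`bh_adjust`, backed by `stats::p.adjust`) and the
   three-gate filter: q ≤ 0.05, UP ≥ 2, FC ≤ 0.77 or ≥ 1.3. The ≤/≥
   conventions follow the methods-style statement of the criteria.
   Tightening any gate can only shrink the deregulated set.

`direction_concordance` classifies proteins shared between two
conditions as concordant (same side of the dead band), discordant
(opposite sides) or in-band, reporting raw counts rather than enforcing
any expected number of exceptions.

## Neurogenesis statistics

Positive-cell counts per marker (GFAP for radial-glia-like stem cells,
Sox2 for transient amplifying progenitors, DCX for immature neurons) are
expressed per mm of SGZ length. Sections within an animal are combined
by total cells over total length (a length-weighted mean), making the
animal the experimental unit. `percent_change` reports
100·(mean_control − mean_treated)/mean_control, so reductions are
positive. `group_ttest` is a pooled-variance Student t test by default —
matching the named convention for comparing pairs of means — with Welch
available via a flag; both are two-tailed with significance at p ≤ 0.05.

## Overlap arithmetic and reporting

`venn` computes exact region cardinalities for 2–4 deregulation sets by
set algebra (more than 4 sets is an error: region counts stop being
readable). Feature identity is case-insensitive by default because gene
symbol capitalization varies across sources; accession-keyed sets can
disable this. Region counts always satisfy inclusion-exclusion.
`shared_fraction` and `count_change` carry an explicit rounding
convention (integer or one-decimal percent) so that printed percentages
reproduce exactly; both conventions appear in published tables, and the
choice is a parameter rather than a hidden default. `shielded_dose`
converts a total dose and shield transmission fraction into the
out-of-field dose in mGy.

`build_report` packages stage outputs into one structured object with
explicit "absent" markers for missing stages and a config hash for
traceability; stage inputs carrying `condition` attributes are checked
for consistency, and mismatches are an error listing both keys.
`write_report` serializes to JSON and Markdown with numbers at 10
significant digits, so a seeded pipeline rerun is byte-identical.

## Synthetic data: what it emulates and what it does not

All generators require an explicit seed and never touch global RNG
state; identical configurations and seeds give byte-identical outputs.

- **Spectra** (`simulate_tissue_spectra`): nonnegative mixtures of
  peaked component spectra (Gaussian/Lorentzian bands) over 400–1800
  cm⁻¹, plus a polynomial fluorescence-like baseline (default cubic)
  and iid Gaussian noise truncated at zero. The default library holds
  five components — DNA, histone 2A, TNF-α, TGF-β, uric acid — the
  species that dominate the reported tissue contrasts; band positions
  follow standard Raman assignments but are synthetic stand-ins, not
  measured pure-compound spectra. Not emulated: cosmic-ray spikes,
  detector etaloning, spatial heterogeneity.
- **Counts** (`simulate_mirna_counts`): NB draws with mean = library
  size × relative abundance × fold-change effect and Var = μ + φμ²;
  defaults are 3 animals per group, 10⁶ reads per library, φ = 0.1 and a
  log-uniform abundance ladder spanning 1–2000, which reproduces the
  skewed abundance profile of miRNA libraries. Not emulated: isomiRs,
  mapping artifacts, sample-specific composition bias.
- **Proteins** (`simulate_protein_table`): log2-normal abundances around
  protein-specific means (uniform over a realistic label-free dynamic
  range), a common per-replicate background sd (default 0.2), changed
  subsets with specified true ratios, and UP counts 1 + Poisson(4).
  Not emulated: missing values, shared-peptide ambiguity,
  intensity-dependent variance.
- **SGZ counts** (`simulate_sgz_counts`): per-animal densities Gaussian
  around control × (1 − reduction/100) with a between-animal CV
  (default 0.1), distributed over sections with integer-rounded counts.
  Defaults use 6 animals per group and the published GFAP effect size
  (37.22% reduction) as the canonical validation condition.

Passing tests on these generators demonstrate that each statistical
stage behaves as designed under its own model assumptions; they do not
certify behavior under real-data pathologies the generators exclude
(batch effects, heavy-tailed noise, missingness).

## Validation problem sizes and power

The test suite and acceptance script use problem sizes chosen to make
Monte-Carlo bounds sharp while keeping runs quick: 2000 features or
proteins for calibration checks, 50–100 seeds for replication-rate
checks, 100 random spectra for the hull equivalence check. The
histone-2A parameter-recovery simulation uses 10 synthetic animals per
group: with an effect of twice the per-animal sd, a two-sided Student t
at α = 0.05 has ≈ 79% power at n = 5 and ≈ 98% at n = 10, so a ≥ 90%
detection-rate requirement is only meaningful at the larger synthetic
group size. The acceptance checks on neurogenesis and proteomics run at
their stated conditions (n = 6 animals, cv 0.1; n = 4 replicates,
sd 0.2), where power is essentially 1.

## Known limitations

- The rubberband hull baseline removes convex broad signal along with
  fluorescence; narrow-band quantities (CLS weights on peaked
  references) are robust to this, broad-band ones are not.
- CLS weights after vector normalization are relative, not absolute,
  concentrations; only ratios and group contrasts are interpretable.
- The NB exact test assumes a common dispersion across features;
  strongly feature-specific overdispersion inflates its type-I error
  for the most variable features.
- The background-variance z test assumes approximately normal
  log-ratios of non-changing proteins; heavy-tailed backgrounds make it
  anticonservative despite the robust scale estimate.
- Set-overlap arithmetic treats published set sizes as exact inputs; it
  reproduces printed percentages but cannot re-derive the sets
  themselves without the raw data.
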