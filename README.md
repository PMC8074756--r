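# abscopal

Multi-omics analysis of out-of-field (abscopal) radiation effects in the
mouse hippocampus.

When one part of the body is irradiated while the rest is shielded,
molecular and cellular changes can still appear in the shielded tissue —
the out-of-field or abscopal response, a form of radiation-induced
bystander effect mediated by intercellular signalling. Quantifying it in
the hippocampus requires comparing sham-irradiated (SI), partial-body
(PBI) and whole-body (WBI) exposed animals across several layers:

- **Raman microspectroscopy** of tissue sections: preprocessing
  (wavenumber calibration, instrument-response correction, rubberband
  baseline subtraction, vector normalization, Savitzky–Golay smoothing),
  PCA, and classical least squares (CLS) unmixing. CLS models a tissue
  spectrum *S* as a weighted sum of pure-component reference spectra,
  *S* = Σᵢ *aᵢCᵢ* + *E*, where the *Cᵢ* ≥ 0 are component weights
  (concentrations) minimizing ‖*S* − Σᵢ *aᵢCᵢ*‖² and *E* is the
  residual. Group differences in component weights (e.g. histone 2A,
  uric acid) are tested with two-sample t tests.
- **miRNA differential expression** from small-RNA counts: CPM filtering
  (> 1 read per million in ≥ 2 samples), a common-dispersion
  negative-binomial exact test (conditional on feature totals after
  library-size equalization; dispersion φ with Var = μ + φμ², φ = 0
  giving the Poisson limit), signed fold changes, and the deregulation
  criteria *p* ≤ 0.1 with |FC| ≥ 3. ΔΔCt quantification handles PCR
  array follow-up.
- **Label-free proteomics statistics**: median-ratio normalization,
  median-abundance ratios capped into [0.01, 100], a background-variance
  z test (the spread of non-changing background proteins estimates the
  null variability of log-ratios), Benjamini–Hochberg adjustment, and
  the three-gate filter q ≤ 0.05, ≥ 2 unique peptides, FC ≤ 0.77 or
  ≥ 1.3.
- **Adult neurogenesis**: stage-specific marker counts (GFAP, Sox2, DCX)
  expressed per mm of subgranular-zone length, percent reductions, and
  Student t tests.
- **Overlap arithmetic**: Venn region counts across exposure modality,
  dose and time, shared-fraction percentages, time-course percent
  changes, and the shielded-dose computation.

A synthetic-data module generates inputs for every stage from explicit
statistical models with known ground truth and a mandatory seed, so the
whole pipeline is testable without any external data.

## Worked example

Simulate Raman spectra for two groups of five animals that differ in
histone 2A and uric acid content, run the preprocessing + CLS chain, and
test the group contrast on per-animal mean weights:

```r
library(abscopal)
lib <- default_reference_library()

w_si  <- c(0.45, 0.30, 0.20, 0.15, 0.30)        # DNA, H2A, TNFa, TGFb, UA
w_wbi <- w_si + c(0, 0.12, 0, 0, -0.10)          # irradiated contrast
design <- mixture_design(
  group   = rep(c("SI", "WBI"), each = 5),
  weights = rbind(matrix(w_si, 5, 5, byrow = TRUE),
                  matrix(w_wbi, 5, 5, byrow = TRUE)),
  noise_sd = 0.004, spectra_per_sample = 3
)
sim <- simulate_tissue_spectra(lib, design, seed = 20)

weights <- t(vapply(sim$spectra,
                    function(s) cls_fit(preprocess(s), lib)$weights,
                    numeric(5)))
agg <- aggregate_weights(weights, sim$truth$sample_id)
grp <- sim$truth$group[match(agg$unit, sim$truth$sample_id)]
compare_component_weights(agg$weights, grp, "Histone 2A", "SI", "WBI")
```

```
   component group_a group_b mean_a mean_b     se_a    se_b     t  p_value stars
1 Histone 2A      SI     WBI  0.324   0.42 0.000881 0.00164 -51.3 2.31e-11   ***
```

The recovered per-animal histone 2A weight rises from 0.324 (SI) to
0.420 (WBI) — the simulated 0.12 shift, attenuated by vector
normalization — and the contrast is highly significant (`***`,
p ≤ 0.001). The same call with `"Uric acid"` reports the simulated
decrease (0.353 → 0.253, `***`).

The overlap arithmetic works directly on deregulation set sizes:

```r
shared_fraction(87, 180)   # shared deregulated proteins, % of PBI set -> 48
count_change(12, 25)       # deregulated miRNAs, 6 months vs 15 days -> -52
shielded_dose(2.0, 0.002)  # 2 Gy at 0.2% shield transmission -> 4 (mGy)
```

## Vignette

`vignettes/abscopal-methods.Rmd` documents the statistical models, the
synthetic-data generators and their defaults, numerical choices, and
known limitations.
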