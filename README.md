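# mrcoloc

Two-sample Mendelian randomisation (MR) with Bayesian colocalisation
follow-up, from GWAS summary statistics.

Observational associations between circulating biomarkers (adipokines,
C-reactive protein, ...) and disease are vulnerable to confounding and
reverse causation. MR uses germline variants as instrumental variables:
SNP–exposure effects from one GWAS and SNP–outcome effects from an
independent GWAS are combined at the summary level to estimate the causal
effect of the exposure on the outcome. `mrcoloc` is a complete, tested
pipeline for that design, aimed at analysts running biomarker–disease
screens (for example adipokines/CRP against overall and
oestrogen-receptor-stratified breast cancer):

* **I/O** — headered TSV summary statistics (`SNP CHR POS EA OA EAF BETA
  SE P N`, remappable via YAML schema), signed-`r` LD matrices, formatted
  results tables.
* **Instruments** — genome-wide significance filtering (p < 5×10⁻⁸),
  monogenic-cis (±1 Mb of the TSS) or polygenic modes, greedy LD clumping
  (r² < 0.01, or < 0.15 for weakly-correlated cis sets).
* **Harmonisation** — common effect-allele orientation with swap/strand
  resolution and frequency-based handling of palindromic SNPs, full
  per-SNP provenance.
* **Estimators** — Wald ratio with delta-method SE; IVW (fixed and
  multiplicative random-effects with the underdispersion floor
  φ = max{1, √(RSS/(k−1))}); correlation-adjusted IVW for cis sets;
  MR-Egger (slope + intercept pleiotropy test); weighted median with
  parametric-bootstrap SE; leave-one-out; R²/F instrument-strength
  diagnostics (F = R²(n−k−1)/(k(1−R²))); odds-ratio conversion.
* **Colocalisation** — Wakefield approximate Bayes factors, posterior
  probabilities of hypotheses H0–H4 in log space, ±100 kb windows,
  PP ≥ 0.80 reporting convention, secondary-peak checks of the
  single-causal-variant assumption, regional Manhattan plot data.
* **Orchestration** — `run_study()` routes each (factor, endpoint) pair
  to the right estimator, applies a per-endpoint Bonferroni correction
  across factors, triggers colocalisation for nominal hits, and logs
  every decision.
* **Synthetic data** — a generator of two-sample GWAS and regional
  profiles with known ground truth, including a seven-factor ×
  three-endpoint toy study with a planted shared-variant causal factor
  and a planted genomic-confounding scenario.

## Worked example

```r
library(mrcoloc)

# an 8-SNP instrument with a true causal effect of 0.3 (log-odds per SD)
g <- simulate_two_sample_gwas(sim_config(seed = 42, m_snps = 8,
                                         causal_effect = 0.3,
                                         exposure_h2 = 0.1))
h <- harmonise_pair(g$exposure, g$outcome, ld = g$ld)
mr_ivw(h)
#> MR estimate [ivw_re], 8 SNP(s)
#>   beta = 0.3138 (se 0.0201), 95% CI [0.2744, 0.3533], p = 7.75e-55
#>   OR = 1.37 (1.32-1.42), dispersion phi = 1.000
mr_egger(h)$intercept$pvalue   # no evidence of directional pleiotropy
#> [1] 0.455
```

The estimate recovers the planted 0.3 within its standard error; `phi = 1`
records that the random-effects model hit the underdispersion floor (no
excess heterogeneity). The full synthetic study exercises the whole
design:

```r
sim    <- simulate_study(seed = 1)
report <- run_study(sim$study, seed = 1)
report$primary[report$primary$risk_factor == "hgf" &
               report$primary$endpoint == "er_negative",
               c("method", "or", "ci_low_or", "ci_high_or", "pvalue")]
#>   method   or ci_low_or ci_high_or  pvalue
#> 9   wald 1.17      1.06       1.29 0.00222
report$coloc[report$coloc$risk_factor %in% c("hgf", "resistin"),
             c("risk_factor", "endpoint", "pp3", "pp4")]
#>   risk_factor    endpoint      pp3      pp4
#> 2         hgf er_negative 1.00e+00 7.33e-13
#> 3    resistin     overall 4.58e-04 1.00e+00
#> 4    resistin er_positive 8.26e-05 1.00e+00
#> 5    resistin er_negative 1.35e-02 9.86e-01
```

The two planted scenarios separate cleanly: the genuinely causal factor
(`resistin`, shared causal variant) is an MR hit that colocalises
(PP(H4) ≈ 1), while the genomically confounded factor (`hgf`, distinct
causal variants in LD, r² ≈ 0.15) is a nominal MR hit whose
colocalisation decisively favours distinct variants (PP(H3) ≈ 1) — the
signature that distinguishes a causal biomarker from LD confounding.
`write_results_table()` formats the primary table (OR and 95% CI to two
decimals, p to two significant figures); `make_fixture_tables()`
materialises the whole study as TSV/YAML files, and the thin CLI in
`inst/scripts/mrcoloc` wraps `simulate`/`run`/`coloc` for shell use.

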