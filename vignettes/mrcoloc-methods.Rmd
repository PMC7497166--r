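---
title: "Methods: two-sample MR with colocalisation follow-up"
author: "mrcoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with colocalisation follow-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcoloc)
```

# The problem

Circulating biomarkers such as adipokines and C-reactive protein correlate
with disease risk in observational cohorts, but confounding and reverse
causation make those correlations unreliable guides to intervention.
Two-sample Mendelian randomisation (MR) instead uses germline variants as
instrumental variables: SNP–exposure associations from one GWAS and
SNP–outcome associations from an independent GWAS are combined at the
summary level to estimate the causal effect of the exposure on the
outcome. `mrcoloc` implements that pipeline end to end — instrument
construction, allele harmonisation, a suite of estimators with
diagnostics, family-wise error control, and Bayesian colocalisation as a
sensitivity analysis against genomic confounding — together with a
synthetic summary-statistics generator so every stage is testable against
known ground truth without any external download.

# Instrument construction

Candidate instruments are SNPs associated with the exposure at genome-wide
significance (`p_threshold`, default $5\times 10^{-8}$). Two modes are
supported:

* **monogenic cis** — SNPs within `cis_window_bp` (default 1 Mb, closed
  interval) of the protein-coding gene's transcription start site. Cis
  instruments are preferred when few SNPs are available because they are
  less likely to act through pleiotropic pathways.
* **polygenic** — cis and trans SNPs genome-wide.

Survivors are greedily LD-clumped: sort ascending by p-value (ties broken
by chromosome, position, SNP id, so the output is deterministic and
invariant to input row order) and accept a SNP iff its $r^2$ with every
accepted SNP is below `r2_threshold` — 0.01 for independent instruments,
0.15 for weakly-correlated cis sets, which are then analysed with the
correlation-adjusted estimator rather than treated as independent.

# Harmonisation

Exposure and outcome records are aligned to a common effect allele.
Matching alleles are kept; swapped alleles flip the outcome beta and eaf;
strand complements are complemented first (non-palindromic SNPs only).
Palindromic (A/T, C/G) SNPs cannot be strand-resolved from alleles alone:
they are resolved by allele frequency when both eafs fall outside the
configurable band (0.42, 0.58) around 0.5, and dropped otherwise. A
missing eaf disables frequency resolution and the SNP is dropped.
Instruments absent from the outcome GWAS are dropped and logged; no proxy
search is attempted. Every decision is recorded per SNP in the
`provenance` attribute.

# Estimators

With $\hat\beta_{Xj}, \hat\beta_{Yj}$ the harmonised per-allele effects
and $\sigma_{Yj}$ the outcome standard errors:

* **Wald ratio** (single SNP): $\hat\theta = \hat\beta_Y/\hat\beta_X$,
  with the two-term first-order delta-method standard error
  $\sqrt{\sigma_Y^2/\beta_X^2 + \beta_Y^2\sigma_X^2/\beta_X^4}$. No
  covariance term is included because the two samples are independent.
* **IVW**: weighted regression of $\hat\beta_Y$ on $\hat\beta_X$ through
  the origin with weights $w_j = \sigma_{Yj}^{-2}$. The fixed-effect
  standard error is $(\sum w_j \beta_{Xj}^2)^{-1/2}$; the multiplicative
  random-effects model scales it by
  $\varphi = \max\{1, \sqrt{\mathrm{RSS}_w/(k-1)}\}$. The floor at 1 is
  the underdispersion rule — the residual standard error is never allowed
  below 1 — so random-effects intervals are never narrower than
  fixed-effect ones. Cochran's $Q$ (the weighted RSS) and $\varphi$ are
  reported for audit.
* **Correlation-adjusted IVW**: generalised least squares with
  $\Omega_{ij} = \sigma_{Yi}\sigma_{Yj} r_{ij}$ for weakly-correlated cis
  sets, with the same $\varphi$ floor. When $\Omega$ is numerically
  singular a relative ridge starting at $10^{-8}$ (escalating tenfold) is
  added; a condition number above $10^{12}$ after the largest ridge is an
  error rather than a silent answer.
* **MR-Egger**: SNPs are oriented so $\hat\beta_X \ge 0$, then
  $\hat\beta_Y$ is regressed on $\hat\beta_X$ with a free intercept. The
  slope is the pleiotropy-corrected estimate (valid under InSIDE); the
  intercept is the directional-pleiotropy test. The slope standard error
  carries the $\varphi$ floor ($k-2$ denominator); the intercept test is
  the plain weighted-regression t-test with residual scale
  $\hat\sigma$ — flooring it too makes the test conservative (observed
  size ~3–4% instead of 5%), and a significance test should hold its
  nominal size. Egger p-values use a $t_{k-2}$ reference; all other
  estimators use the normal reference.
* **Weighted median**: per-SNP ratio estimates sorted ascending with
  normalised inverse-variance weights $w_i$; the estimate interpolates
  the ratios where the cumulative midpoint weight
  $s_i = \sum_{j<i} w_j + w_i/2$ crosses $1/2$. Consistent when at least
  half the weight comes from valid instruments. Its standard error is a
  parametric bootstrap (default 1000 resamples, explicit seed): both
  betas are perturbed by their standard errors and the estimator is
  recomputed.
* **Leave-one-out**: random-effects IVW on every $(k-1)$-subset, to
  expose single influential SNPs.

Instrument strength is summarised by
$R^2 = \sum_j 2\,\mathrm{eaf}_j(1-\mathrm{eaf}_j)\beta_{Xj}^2$ (exposure
in SD units, independent SNPs) and
$F = R^2(n-k-1)/\,[k(1-R^2)]$; $F \lesssim 10$ conventionally signals
weak-instrument bias. The $k$-in-denominator form reproduces published
single-SNP instrument strengths exactly from their $R^2$ and sample size.

# Colocalisation

A nominal MR signal from a single region can reflect genomic confounding:
distinct causal variants for exposure and outcome in LD. Under the
assumption of at most one causal variant per trait in the region, the
Wakefield approximate Bayes factor for each SNP–trait pair is
$\log\mathrm{ABF} = \tfrac12\log(1-r) + z^2 r/2$ with $z=\beta/se$,
$r = W/(V+W)$, $V = se^2$, and prior effect variance $W$
(`prior_sd` 0.15 for quantitative traits, 0.20 for case-control log-odds,
configurable). Five hypotheses are scored — H0 no association, H1/H2 one
trait only, H3 both traits with distinct variants, H4 a shared variant —
with per-SNP priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$
(field-standard defaults; the source method names no numbers). All
hypothesis arithmetic is in log space via log-sum-exp, so no raw Bayes
factor is ever exponentiated unnormalised; posteriors sum to 1 within
$10^{-10}$ by construction and are checked against an exhaustive
enumeration of causal configurations on small regions in the test suite.
A posterior probability of at least 0.80 is the reporting convention for
supporting a hypothesis. Because the one-causal-variant assumption is the
method's weak point, `check_single_causal()` flags secondary peaks (SNPs
within 2 of the lead on the $-\log_{10}p$ scale but $r^2 < 0.1$ with it)
and `run_study()` surfaces them as warnings.

# Study orchestration

`run_study()` executes every (risk factor, endpoint) pair: instrument
selection, harmonisation, then estimator routing — single SNP to the Wald
ratio, weakly-correlated cis set to the correlation-adjusted IVW,
otherwise multiplicative random-effects IVW, with MR-Egger, weighted
median and leave-one-out whenever at least three independent SNPs are
available. The Bonferroni threshold is `alpha` divided by the number of
risk factors, applied across factors separately per endpoint (no
correction across endpoints). Colocalisation runs for any pair at nominal
$p < 0.05$ over ±100 kb around the top instrument SNP. A failure in one
pair is recorded in its `status` and never aborts the others; a JSON-lines
run log records drop reasons and $\varphi$ values so the underdispersion
rule is auditable.

# The synthetic generator

Summary statistics are simulated directly from their asymptotic sampling
distributions rather than from individual-level genotypes: marginal
effect estimates are normal around the LD-projected true effects with
$se = [2f(1-f)\,n\,\phi]^{-1/2}$ ($\phi = v(1-v)$ for a case-control
trait with case fraction $v$, 1 for a unit-variance quantitative trait).
This is orders of magnitude faster and is sufficient for validating
summary-level estimators; it does not emulate genotyping error,
imputation quality, allele-frequency mismatch between samples, or
fine-scale LD, so passing tests speak to estimator correctness, not to
robustness against those artefacts. Regional LD is AR(1) with
$\rho = 0.9$ per 5 kb grid step by default; explicit matrices are
accepted. Directional pleiotropy is applied relative to the
exposure-increasing allele (its mean is carried by the sign of the SNP's
exposure effect), matching the standard MR simulation designs — an
orientation-free mean would cancel in the origin-constrained IVW and no
robustness scenario could bias it. All randomness derives from one master
seed through deterministic per-operation sub-seeds, so every output is
reproducible byte for byte.

`simulate_study()` builds a seven-factor × three-endpoint study whose
defaults are the published study conditions: instrument sizes 8 / 45 / 1
/ 3 / 1 / 3 / 1, instrument $R^2$ from 0.002 to 0.54, exposure GWAS sizes
3,301–204,402, and endpoint case/control counts 122,977/105,974 (overall),
69,501 and 21,468 cases (receptor-stratified). Each factor's exposure
draw is conditioned on instrument discovery (redrawn under deterministic
sub-seeds until one SNP passes $5\times10^{-8}$), because the published
instrument counts are study conditions, not outcomes to be re-randomised.
Two scenarios are planted. One factor has a true causal effect of 0.25
(log-odds per SD) acting through a variant shared with all endpoints, so
its MR signal colocalises (PP(H4) high). One factor is genomically
confounded for a single endpoint: exposure and outcome signals come from
causal variants nine grid steps apart ($r^2 \approx 0.15$), the outcome
variant carrying $z = 14$ — strong enough that the instrument-level
outcome signal ($z \approx 5.4$) is reliably nominal across realisations —
so MR flags the pair but colocalisation favours H3. This is the
confounding signature the pipeline exists to catch.

# Numerical choices and problem sizes

* 95% intervals use $\Phi^{-1}(0.975)$; p-values are floored at the
  smallest positive double; simulated p-values at $10^{-300}$ to stay in
  $(0, 1]$.
* LD files store signed $r$ (so the correlation-adjusted IVW can use
  signs); $r^2$ is derived on demand. Read-time symmetry tolerance is
  $10^{-8}$, after which the matrix is symmetrised and the diagonal set
  to exactly 1.
* Equal clumping p-values are broken by (chromosome, position, SNP id).
* The validation suites run at the sizes their guarantees need: 2,000
  replicates for IVW recovery/coverage, 1,000 for the Egger intercept
  size, 500 for the weighted-median robustness race, 200 per
  colocalisation scenario over 81-SNP regions, and 25–30 random fixtures
  per oracle-equivalence check; the full synthetic study runs in about a
  second.

# Limitations

Unit conversion between source GWAS scales is the user's responsibility
(`unit_note` is free text). No proxy-SNP lookup, no multi-signal
colocalisation (SuSiE-style), no MR-PRESSO/mode-based/multivariable MR,
no Steiger filtering, and no reference-panel LD estimation from
genotypes: LD is always supplied. The generator does not attempt to mimic
any real locus architecture or consortium allele frequencies.
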