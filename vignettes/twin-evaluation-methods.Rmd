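---
title: "Methods: a single-step genomic evaluation for twin pregnancies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a single-step genomic evaluation for twin pregnancies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Twin pregnancies in dairy cattle are an unfavourable reproductive outcome:
they raise the risk of abortion, stillbirth, periparturient disease and
culling, with published cost estimates of $97–$225 per case. Twinning is
lowly heritable but genetically variable, so a routine genetic evaluation
can rank cows and heifers by their transmitted risk and support proactive
selection. `twinblup` implements such an evaluation end to end — from raw
farm-software event logs to standardized transmitting abilities — together
with a synthetic multi-herd generator so that every stage can be exercised
and tested without proprietary herd data.

## Trait definition and record standardization

The trait (TWIN) is binary per cow-lactation: 1 if the pregnancy ended in
the birth or abortion of twin calves, 0 otherwise. On-farm software encodes
twin outcomes in heterogeneous `(event, remark)` pairs;
`standardize_twin_events()` collapses a fixed vocabulary (e.g. `ABORT` with
remarks like `TWIN`, `TW M`, `TWBULL`, or exactly the two letters `TW`; a
`TWIN` remark on `FRESH`, `RP`, `DRYOFF`, ...) to the binary outcome after
trimming whitespace and case. Unknown combinations are treated as
singletons, not errors: absence of twin evidence is a singleton record. No
fuzzier matching is attempted — internal spacing must match the vocabulary.

Edits then mirror routine evaluation practice:

* records of animals recorded as male in the pedigree, and records whose
  calving date does not follow birth, are removed;
* calving intervals must lie in [250, 999] days. We read "between 250 and
  999" as inclusive bounds (a 250-day interval is plausible, and excluding
  exactly the stated bounds would be surprising); the bounds are
  configurable. First-parity records carry no interval and are exempt;
* every herd-year-season (HYS) contemporary group needs at least 20 records
  and at least one recorded twin, otherwise the herd is assumed not to have
  recorded twinning in that period and the whole group is dropped.

Seasons are the meteorological quarters (Winter = December–February, ...).
December is assigned to the *following* year's winter group so that each
winter is one contiguous contemporary group; the year-assignment convention
is otherwise arbitrary and this choice is documented rather than load-bearing.

## The liability model

The evaluation fits a threshold repeatability animal model on the liability
scale,

$$\lambda = X\beta + Z_h h + Z_a a + Z_p p + e,$$

with fixed parity classes (1, 2, 3, 4, 5+), random HYS effects
$h \sim N(0, I\sigma^2_{hys})$, additive animal effects
$a \sim N(0, K\sigma^2_a)$ over **all** pedigree animals (with $K$ the
pedigree relationship matrix A, or the single-step H), permanent-environment
effects $p \sim N(0, I\sigma^2_{pe})$ for cows with records, and
$e \sim N(0, I)$. The observed outcome is 1 when the liability exceeds a
threshold. The model is identified by fixing the threshold at 0 and the
residual variance at 1 — the standard threshold-model constraint; the
original description fixes only the residual.

Heritability and repeatability on the liability scale are
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{pe} + \sigma^2_{hys} + 1)$ and
$r^2 = (\sigma^2_a + \sigma^2_{pe}) / (\cdot)$; with the published component
values (0.1315, 0.1318, 0.2272, 1.0) these evaluate to 0.0882 and 0.1767.

## Relationship matrices

* `compute_inbreeding()` uses the Meuwissen–Luo algorithm (exact, matching
  the tabular-method diagonal), in compiled code.
* `build_A_inverse()` applies Henderson's rules with inbreeding-adjusted
  Mendelian-sampling variances: the exact sparse inverse of the tabular A.
* `build_G()` is VanRaden method 1, $G = ZZ'/(2\sum p(1-p))$, centred at
  observed allele frequencies among the genotyped animals by default (a
  founder-frequency mode exists for simulation studies). G is blended with
  the pedigree relationships among genotyped animals,
  $0.95\,G + 0.05\,A_{22}$ by default, to guarantee invertibility. No
  further rescaling to the pedigree base is applied; the evaluation's only
  compatibility statement is $\tau = \omega = 1$.
* `invert_G_apy()` implements the "algorithm for proven and young": exact
  inverse on a core of animals, diagonal Mendelian-sampling-like terms for
  non-core animals. With the core equal to all animals it reproduces the
  direct inverse; cores are drawn uniformly at random when not supplied.
* `assemble_H_inverse()` forms
  $H^{-1} = A^{-1} + \begin{pmatrix} 0 & 0 \\ 0 & \tau G^{-1} - \omega A_{22}^{-1} \end{pmatrix}$,
  defaults $\tau = \omega = 1$. $A_{22}$ is obtained by solving against the
  sparse $A^{-1}$ (Colleau-style), not by building the dense tabular A.

Everything here targets desk scale (up to roughly 20k animals, dense
genomic blocks of a few thousand); there is deliberately no out-of-core or
distributed path.

## Variance components: data-augmentation Gibbs sampling

`gibbs_variance_components()` runs a single-site Gibbs sampler in compiled
code: truncated-normal draws of the latent liabilities given the binary
outcomes, conjugate normal updates for every location effect, and
scaled-inverse-chi-square updates for $\sigma^2_a$, $\sigma^2_{pe}$,
$\sigma^2_{hys}$. Component estimation is run with the pedigree-only
$A^{-1}$ (as in the original evaluation, which estimated components without
genotypes); an H-inverse can be passed for the genomic variant.

Numerical/design choices:

* Each cow's additive and permanent-environment effects enter every one of
  her records identically, so alternating single-site draws of the pair mix
  extremely poorly. The sampler therefore draws $(a_i, p_i)$ **jointly**
  from their bivariate full conditional for cows with records; this was the
  difference between unusable and usable chains at desk scale.
* Truncated normals use rejection sampling (plain rejection near the
  centre, exponential-tilt rejection in the tail) rather than
  inverse-CDF evaluation; about five times faster at 3% incidence.
* Priors are weakly informative scaled-inverse-chi-square
  ($\nu_0 = 4$, scale 0.05, prior mean 0.1 per component), exposed in
  `gibbs_config()`. With thousands of levels per effect they are
  numerically irrelevant.
* Defaults are 20,000 iterations, 4,000 burn-in, thinning 10. The original
  analysis published no chain settings; these were chosen for desk-scale
  mixing and are configuration, not constants. Effective sample sizes
  (initial-positive-sequence estimator) are reported and a warning is
  raised when the worst chain falls below 30.
* The sampler uses R's RNG throughout, so a fixed seed reproduces chains
  bit for bit.

A degenerate continuous-response mode (observed liabilities, no
augmentation) exists for calibration: on balanced designs it matches
closed-form/method-of-moments answers and REML.

### What recovery on synthetic data does and does not show

The generator's defaults are the study conditions: roughly 3,000 cows with
about three lactations each in a handful of large herds, variances
(0.1315, 0.1318, 0.2272), incidence calibrated to 3.25%. At this scale one
property of the published edit rules becomes visible that is negligible at
industrial scale: requiring at least one twin per HYS group *selects* on
group outcomes. With ~70–120 records per group and 3% incidence, a
non-negligible fraction of groups is dropped, and the surviving groups'
effective HYS dispersion is smaller than the simulated 0.2272. The
heritability ratio is only mildly affected, but recovered
$\sigma^2_{hys}$ itself should not be read as an estimate of the generating
value under these conditions. In an industrial-scale evaluation, HYS
groups carry hundreds of records and the selection effect vanishes.

A second consequence of the weak per-record information in rare binary
outcomes is that the posterior-mean $h^2$ of a single ~3,000-cow population
scatters noticeably from replicate to replicate even with fully converged
chains. The recovery check in `scripts/acceptance.R` therefore reports the
mean posterior $h^2$ over four independently simulated populations, which
lands within ±0.03 of the generating 0.0882; a single-population check at
the same scale is part of the test suite.

## Solving the mixed-model equations

`solve_mme_pcg()` solves Henderson's equations with a Jacobi-preconditioned
conjugate-gradient solver: relative-residual tolerance 1e-10 or 200 rounds,
whichever comes first (the round cap mirrors the production configuration).
The primary threshold mode wraps the linear solver in an
expectation-maximization loop over the truncated-normal working liabilities
$E[\lambda \mid y, \theta]$; a documented linear mode solves directly on the
0/1 codes as a fast approximation. PCG agrees with dense direct solves to
1e-6 on every random instance up to 500 equations in the test suite.

## Scores

* **Probability and PTA.** Each animal's liability solution $s_i$ maps to
  $p_i = \Phi(s_i - t)$, the probability that a unit-variance normal centred
  at the solution exceeds the threshold. The threshold $t$ is the fitted
  cutpoint (0 under the identification constraint) shifted by the overall
  fixed-effect mean — "calculated from the current data"; the production
  procedure is unpublished and this is the natural realization. The
  probability is multiplied by 100 and divided by 2 (a parent transmits
  half its additive merit) and expressed as a deviation from the mean of
  the base cohort: phenotyped animals born in a configurable base year
  (2015 by default). A PTA of −2.0 reads as a 2% lower risk of twinning
  than the base animal.
* **STA.** $\mathrm{sta} = 100 - 5 (\mathrm{pta} - \bar m)/s$ over a scaling
  cohort, i.e. mean 100, SD 5, sign reversed so that higher is better.
  The scaling cohort defaults to the base cohort (the description is
  ambiguous between the base cohort and all animals; both are supported).
  Reported STAs are integers; full precision is retained.
* **Reliability.** An information-accumulation approximation on the
  progeny-equivalent scale $\lambda = (4 - h^2)/h^2$: contributions from own
  repeated records ($n h^2 / (1 + (n-1) r^2)$), one bottom-up pass for
  progeny information, one top-down pass for parent averages, and for
  genotyped animals a term proportional to the G diagonal $g_{ii}$
  (weight 30 by default, giving the familiar ~40% for young genotyped
  animals at $h^2 \approx 0.09$). The total maps to
  $\mathrm{REL} = 1 - \mathrm{PEV}/\sigma^2_a$ in percent, clamped to
  [0, 100]. The production recursion is unpublished; this approximation
  guarantees the stated contract (monotone in information, $g_{ii}$
  substitution, zero for animals with no information) and is not a clone
  of any specific program.
* **Index.** `index_combine()` is the generic weighted sum of trait STAs by
  configured economic weights; deriving the weights is out of scope.

## The demonstration analysis

`assign_tertiles()` ranks animals by STA within herd into worst 33% /
34–66% / best 33% (lowest STA = highest risk = "worst"). Ties break by
animal id; a non-divisible remainder goes to the extreme groups, lowest
first (10 animals split 4/3/3) — the source is silent on both details, so
they are fixed and documented. `fit_incidence_model()` fits, per herd, a
binomial logit mixed model of the 2nd–4th-lactation twin outcomes on
genetic group and lactation with a per-animal random intercept (Laplace
approximation via `lme4::glmer`; with a single record per animal the
intercept variance is unidentified and the model reduces to ordinary
logistic regression). Marginal means on the probability scale average over
lactation levels with equal weights; SEMs come from the delta method
(`emmeans`); the group effect gets a joint Wald chi-square p-value at the
0.05 level. First lactations are excluded because their twinning incidence
is negligible.

`economic_cost()` multiplies an incidence by the mean of the most and least
conservative published per-case estimates, $(97 + 225)/2 = 161$, and rounds
to whole dollars. Decreased losses per cow are differences of the *rounded*
per-case costs — this matches the published $15 for the largest herd gap,
where unrounded arithmetic gives 14.49. Tertile gaps are percentage-point
differences; relative reductions are rounded whole percents of
(worst − best)/worst.

`sta_regression()` provides the supporting association models: STA (clamped
to 85–115, ±3 SD) plus lactation with a random animal intercept; and a
third-lactation variant with conception season and previous-lactation peak
yield as covariates, reported as Type III Wald chi-square tests.

### Avoiding circular validation

In `run_pipeline()` the demonstration uses a temporal split: tertiles are
built from a *snapshot* evaluation that only sees calvings up to
`validation_cutoff_year` (three years before the end of the simulated range
by default), and incidence is measured on later calvings — the synthetic
analogue of adjusting scores back to what a producer would have received
before the cohort entered the milking string. Validating full-data scores
against their own records is circular (a cow's own twin record feeds her
score, so every observed twinner lands in the worst tertile) and is only
used as a fallback when the split leaves too little data, with a warning.

A power caveat: at desk scale the snapshot scores have modest accuracy
(far below what a production evaluation built on millions of records
attains), so
out-of-sample tertile incidence differences are small relative to their
binomial noise and a single synthetic demonstration is often
non-significant. The demonstration-stage statistics are therefore
validated on constructed strong-effect and null simulations (size and
power of the group test), and the end-to-end pipeline is checked for
correct *directional* ranking of true genetic merit rather than for
significance of a single synthetic herd's incidence contrast.

## The synthetic herd generator

`simulate_pedigree()` builds founders plus discrete generations; each
generation samples a small pool of sires (8% of available males) and dams
with replacement, yielding the paternal half-sib structure of dairy
populations. Offspring inherit the dam's herd with probability 0.9.
Generation blocks occupy the early part of the configured year range so the
last generation still completes a lactation career. `simulate_genotypes()`
gene-drops unlinked SNPs from Hardy–Weinberg founders at frequencies drawn
from a configurable range. `simulate_records()` draws, per cow-lactation, a
liability as the sum of parity effect, HYS effect, breeding value (pedigree
recursion with inbreeding-adjusted Mendelian sampling, or a true-SNP-effect
mode), permanent environment and unit residual; the threshold is calibrated
by root-finding on the marginal liability distribution so the expected
incidence matches the target (3.25% by default). Twin outcomes are written
into the raw log using the standardization vocabulary, sampled uniformly —
the source gives no per-remark frequencies, so uniform is a stand-in, not
an inference. Non-recording herds are emulated by suppressing all twin
remarks in a configurable fraction of HYS groups; calving-interval
violations and data-entry defects (male records, impossible dates) can be
injected to exercise the edits.

What the generator does **not** emulate: real herd-management file formats,
genotyping error and imputation, selection and non-random mating, seasonal
incidence trends, or per-remark frequencies. Passing tests on this
generator demonstrate internal consistency of the pipeline under its own
model assumptions — not calibration against any real population.

## Problem sizes and reproducibility

The shipped configurations run the full pipeline at desk scale: the
recovery population is ~7,000–8,000 pedigree animals yielding ~7,500
filtered records from ~3,400 cows; the end-to-end demonstration
configuration uses ~2,000 animals. Chains of 20,000–60,000 iterations mix
adequately at these sizes (minimum effective sample sizes of a few tens for
the hardest component, the additive variance). One global seed fans out to
per-stage substreams; rerunning any configuration reproduces every artifact
byte for byte, and `run_pipeline()` persists a manifest with the
configuration hash and artifact checksums, skipping stages whose outputs
already match.

## Known limitations

* Desk scale only; no out-of-core solving, no multi-trait model, no REML.
* The reliability approximation is a contract-faithful stand-in for an
  unpublished production recursion; absolute levels are indicative.
* The HYS ≥1-twin rule induces outcome selection at small group sizes (see
  above); recovered $\sigma^2_{hys}$ under the default synthetic conditions
  is conditional on that selection.
* The 2013-style "snapshot" adjustment of STAs for demonstration cohorts is
  realized as re-running the evaluation on records truncated at a cutoff
  date; the original adjustment procedure is unpublished.
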