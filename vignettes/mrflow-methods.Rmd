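---
title: "Two-sample Mendelian randomization with mrflow: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrflow)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental variables
to estimate the causal effect of an exposure (here, typically the relative
abundance of a gut-microbial taxon) on an outcome (typically a serum lipid
level), from GWAS summary statistics alone. In the two-sample design the
variant–exposure associations $\hat\gamma_j \pm \sigma_{\gamma j}$ and
variant–outcome associations $\hat\Gamma_j \pm \sigma_{\Gamma j}$ come from
independent studies. A variant is a valid instrument if it is (1) associated
with the exposure (relevance), (2) independent of confounders
(independence), and (3) affects the outcome only through the exposure
(exclusion / no horizontal pleiotropy). Under these assumptions each
variant's Wald ratio $\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ estimates
the same causal effect $\beta$, and the art of summary-level MR is combining
the ratios while remaining honest about instruments that violate (2) or (3).

mrflow implements the complete analysis chain: instrument selection, allele
harmonization, five causal estimators, a sensitivity suite, family-wise FDR
calling, and bidirectional and replication passes — together with a seeded
generator of synthetic summary statistics with known truth, so that every
stage is testable without external downloads.

## Instrument selection

Candidate instruments are screened at a deliberately loose exposure p-value
threshold (default $p < 10^{-5}$, strict inequality; microbiome GWAS rarely
yield genome-wide-significant hits in numbers sufficient for MR). Greedy LD
clumping (`ld_clump()`) then enforces approximate independence: the
smallest-p unprocessed variant becomes an index SNP and removes every
variant on the same chromosome within the window (default 500 kb, boundary
counts as inside) whose $r^2$ with it reaches the threshold (default 0.01).
Ties in p are broken by chromosome, position, then variant id, so the result
does not depend on input row order.

Instrument strength is quantified by the proportion of exposure variance
explained,
$$\mathrm{PVE}_j=\frac{2\hat\gamma_j^2 m_j(1-m_j)}
{2\hat\gamma_j^2 m_j(1-m_j)+2\sigma_{\gamma j}^2 n\, m_j(1-m_j)}
=\frac{\hat\gamma_j^2}{\hat\gamma_j^2+n\sigma_{\gamma j}^2},$$
with $m_j$ the minor allele frequency — the common factor cancels, so the
cancelled form is used and PVE is computable when allele frequency is
missing. The F-statistic for $k$ instruments explaining PVE jointly is
$F = \frac{\mathrm{PVE}}{1-\mathrm{PVE}}\cdot\frac{n-k-1}{k}$ by default; a
`form = "literal"` switch omits the $1/k$ divisor for compatibility with
formulations that write the numerator degrees of freedom into the
denominator term only. The two coincide at $k=1$, the per-variant case used
by the weak-instrument filter (default $F \ge 10$). Per-variant sample size
is used when present, else the study total.

## Harmonization

The exposure study defines the reference orientation. An outcome record with
the same allele pair in the same order is kept; in swapped order its beta is
negated and its effect-allele frequency complemented; alleles matching only
after base complementation are treated as a strand flip. Palindromic
variants (A/T, C/G) cannot be resolved from alleles: they are kept only when
both allele frequencies are available and both lie outside
$0.5 \pm w$ (default $w = 0.08$, the de-facto ambiguity zone 0.42–0.58 of
the reference two-sample MR ecosystem), with frequency concordance deciding
the flip; otherwise they are dropped. When either frequency is missing,
palindromic variants are dropped unconditionally — conservative and
deterministic. Instruments are ordered by (chromosome, position, id) so all
downstream output is reproducible.

## The five estimators

All estimators operate on the Wald ratios with first-order delta-method
standard errors $\sigma_{\beta j} = \sigma_{\Gamma j}/|\hat\gamma_j|$ and
inverse-variance weights $w_j = \sigma_{\beta j}^{-2}$ (outcome error only —
the "NO Measurement Error" convention; a second-order correction was judged
out of scope since the weighting convention, not the SE itself, drives the
estimators).

**IVW.** $\hat\beta = \sum w_j\hat\beta_j / \sum w_j$, identically the
weighted least-squares slope of $\hat\Gamma$ on $\hat\gamma$ through the
origin with weights $\sigma_{\Gamma j}^{-2}$ (the package asserts this
equivalence to $10^{-10}$ relative in its tests). Fixed-effects SE
$(\sum w_j)^{-1/2}$; the random-effects model scales it by
$\max\{1, \sqrt{Q/(J-1)}\}$ (multiplicative overdispersion rather than an
additive $\tau^2$, matching the convention of the reference toolchain).
The choice between them is driven by Cochran's
$Q=\sum w_j(\hat\beta_j-\hat\beta)^2$: random effects iff its
$\chi^2_{J-1}$ p-value is below 0.05 (`choose_ivw_model()`).

**Maximum likelihood.** The joint Gaussian model
$\hat\gamma_j \sim N(\gamma_j, \sigma_{\gamma j}^2)$,
$\hat\Gamma_j \sim N(\beta\gamma_j, \sigma_{\Gamma j}^2)$ with the true
$\gamma_j$ profiled out analytically, leaving the one-dimensional objective
$\sum_j (\hat\Gamma_j-\beta\hat\gamma_j)^2 /
(\sigma_{\Gamma j}^2+\beta^2\sigma_{\gamma j}^2)$, minimized to $10^{-10}$
from the IVW start with one bracket-widening retry; the SE comes from the
profile curvature (central second difference). Unlike IVW it accounts for
exposure-side sampling error; the two agree as
$\sigma_{\gamma j} \to 0$, which the tests assert.

**MR-Egger.** Instruments are oriented so every $\hat\gamma_j > 0$, then
$\hat\Gamma = \alpha + \beta\hat\gamma$ is fitted by weighted least squares
(weights $\sigma_{\Gamma j}^{-2}$). The slope estimates $\beta$ under the
InSIDE assumption; the intercept $\alpha$ estimates the average directional
pleiotropic effect, and feeds the intercept rule (pass iff
$|\hat\alpha| < 0.1$ and $p_\alpha > 0.05$). Residual dispersion is
estimated and inference uses $t_{J-2}$: we deliberately do not floor the
dispersion at 1 (a convention some implementations apply), because the
unfloored test is exactly calibrated under the model and the floor only
makes it conservative.

**Weighted median.** Ratios sorted, normalized weights $p_j$ accumulated as
$s_j = \sum_{i\le j}p_i - p_j/2$, estimate interpolated at $s = 1/2$;
consistent when at least half the weight comes from valid instruments.

**Weighted mode.** Weighted Gaussian kernel density over the ratios with
Silverman-type bandwidth $0.9\,\min(\mathrm{sd},\mathrm{mad})J^{-1/5}$
(scaled by `bandwidth_factor`, default 1; if the robust spread is zero the
sd term is used, and identical ratios return the common value exactly), the
argmax located on a fixed 10,000-point grid spanning the ratio range
$\pm 3$ bandwidths; consistent when the largest cluster is valid.

Median and mode SEs come from a parametric bootstrap (default 1000
replicates) that redraws $\hat\gamma_j^*, \hat\Gamma_j^*$ from their
sampling normals and recomputes ratios, weights and the point estimate.
Instruments are put into canonical orientation ($\hat\gamma_j>0$) before
resampling so bootstrap SEs are exactly invariant to which allele each study
reported as "effect"; given a seed they are reproducible bit for bit.
IVW/ML/median/mode p-values use the standard normal reference, Egger uses
$t_{J-2}$ (with few instruments its heavier tail matters), and 95% CIs use
the fixed critical value 1.959964 so tabular output is digit-reproducible.

## Sensitivity suite

`mr_presso()` implements the simulation-based residual test: for each
variant the IVW slope is refitted without it, the observed weighted residual
$w_j(\hat\Gamma_j-\hat\beta_{(-j)}\hat\gamma_j)^2$ recorded (regression
weights $\sigma_{\Gamma j}^{-2}$), and a parametric null built by redrawing
the summary statistics about the leave-one-out fits. The global test
compares the total residual sum to its null; the outlier test compares each
variant's residual with Bonferroni correction; the distortion test compares
the estimate change after outlier removal against random removals of the
same count. The distortion p is reported but never gates the pipeline: only
the global and outlier tests drive the single corrective pass (outliers
removed, estimation and sensitivity rerun exactly once).

`leave_one_out()` refits IVW with each variant removed; a row is flagged
influential when its CI excludes the sign of the all-instrument estimate —
a flag only, nothing is removed automatically.

`bh_fdr()` performs Benjamini–Hochberg step-up with an explicit family size
`m` that may exceed the number of supplied p-values (unsupplied tests act as
rank fillers with $p = 1$); it delegates to `stats::p.adjust(..., n = m)`
and is cross-checked in the tests against an independently coded step-up.
In matrix runs the family is per outcome with `m` = the number of exposures
tested, the reading consistent with back-calculating published adjusted
values of this design (e.g. $3.01\times10^{-6}\times 196/1 =
5.90\times10^{-4}$ at rank 1). FDR in $[0.05, 0.1)$ is surfaced as a
`promising` flag in reports and gates nothing.

## Classification and the pipeline

For a testable pair (at least `min_ivs = 3` instruments after screening,
clumping, harmonization and the weak filter — below the gate the call is
`not_testable`): `suggestive` iff the IVW p is below 0.05; a
`causal_candidate` additionally needs at least 3 of the 5 estimators
nominally significant; `significant` additionally needs FDR < 0.05.
Boundary conventions are strict and documented: the p-screen and the
heterogeneity rule use strict `<`, so a value exactly at a threshold takes
the conservative branch. The bidirectional driver reruns the identical
procedure with the roles swapped; the replication driver calls a result
concordant iff the replication IVW p is nominally significant *and* the
sign matches the primary call.

## The synthetic generator

`simulate_pair()` draws, per instrument: MAF uniform on `maf_range`
(default 0.05–0.5); true effect $\gamma_j \sim N(0, \texttt{gamma\_sd}^2)$
resampled away from zero ($|\gamma_j| > 0.1\,\texttt{gamma\_sd}$); optional
pleiotropic direct effects $\alpha_j$ on the outcome for a fraction
`invalid_fraction` of instruments — balanced (mean zero) or directional
(mean `alpha_mean`), with an optional correlation `inside_violation` to
$|\gamma_j|$ that violates InSIDE; true outcome effect
$\beta\gamma_j + \alpha_j$; standard errors from the standardized-trait
closed form $[2n\,\mathrm{MAF}(1-\mathrm{MAF})]^{-1/2}$ (no
residual-variance term, for analytic transparency); observed effects equal
truth plus normal noise. Pleiotropy is defined **in the oriented frame**:
the direct effect is tied to the exposure-increasing allele
($\Gamma_j = \beta\gamma_j + \mathrm{sign}(\gamma_j)\alpha_j$), because
"directional" pleiotropy is a statement about variants as the estimators
orient them — applied in the arbitrary reported-allele frame the mean would
cancel and no estimator could (or should) recover it.

Defaults — 10 instruments, both samples 50,000, `gamma_sd = 0.1` — describe
a well-powered clean design with per-variant F-statistics in the hundreds,
typical of clumped lead mbQTL variants; they are the package's reference
conditions for calibration claims. All randomness flows from one master
seed through derived substreams (per taxon, per bootstrap, per PRESSO run),
so any component is independently reproducible and whole-pipeline output is
byte-identical under a fixed seed.

What the generator does *not* emulate: real LD beyond the geometric-decay
block panels of `simulate_ld_blocks()`; winner's-curse correlation between
instrument selection and effect estimates across overlapping samples;
non-normal effect distributions; compositional constraints among taxa.
Passing tests therefore demonstrate correctness of the statistical
machinery under its stated model, not robustness to everything real
microbiome GWAS data can do.

## Numerical and test-design choices

* Monte-Carlo checks in the test-suite use 1000 replicates for null
  calibration and 500 for recovery/robustness means, with bootstrap SEs at
  100 replicates and the mode density on a 512-point grid; these sizes give
  Monte-Carlo SEs comfortably inside the asserted bands while keeping the
  suite quick. Family-wise FDR control is exercised on three independent
  196-taxon all-null families.
* The clean-causal pipeline check uses the asymmetric design its field
  actually runs — a modest exposure GWAS (n = 18,340) screened for
  instruments against a very large outcome GWAS (n = 1,320,000) — because
  with equal 50k samples roughly half the candidate calls sit on the
  nominal-significance boundary, which tests the classifier's luck rather
  than its logic.
* The bidirectional asymmetry check instead uses equal 50k samples: the
  synthetic outcome study contains only the exposure's instruments, and
  with a realistically huge outcome sample the *mediated* variant–outcome
  signals pass the instrument screen, so reverse MR would "detect" the
  forward effect's shadow. That behaviour is a known artifact of
  shared-variant reverse MR, not a defect of the driver; real reverse
  analyses select instruments genome-wide from the outcome trait's own
  loci.

## Known limitations

* **Weighted median under one-sided contamination.** With 40% of
  instruments carrying same-direction pleiotropy, the weighted median
  targets the 0.5/0.6 quantile of the valid-ratio distribution, an upward
  shift of about $\Phi^{-1}(0.833) \approx 0.97$ per-ratio standard errors.
  The estimator is consistent as GWAS sample sizes grow (the shift scales
  with the ratio SE), but the shift also scales exactly like the
  Monte-Carlo SE of a replication mean, so a "mean within 3 MC SEs of
  truth" check at 500 replicates fails under these conditions at *any*
  sample size — the corresponding acceptance test documents this
  finite-precision bias rather than an attainable calibration. The median's
  practical value (its bias here is an order of magnitude below IVW's under
  the same contamination) is unaffected.
* Multivariable MR, Steiger filtering, proxy-variant lookup, robust IVW
  variants and COJO-style conditional selection are out of scope.
* The maximum-likelihood SE uses the profile curvature; with fewer than
  about 5 instruments and very weak effects the quadratic approximation can
  understate uncertainty.
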