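---
title: "Two-sample Mendelian randomization with mrscreen: models, assumptions and validation"
author: "mrscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The problem

Observational associations between an exposure (a plasma lipid level, a
circulating protein, a cytokine) and a disease are confounded by diet,
lifestyle, medication and reverse causation.  Mendelian randomization (MR)
sidesteps this by using genetic variants as instrumental variables: alleles
are assigned at conception, essentially at random with respect to later
environment, so a variant that robustly raises the exposure provides a
natural experiment for the exposure's effect on the outcome.  In the
*two-sample* design the variant–exposure and variant–outcome associations
come from two non-overlapping GWAS cohorts and only summary statistics are
needed.

`mrscreen` implements the complete pipeline: reading and harmonizing GWAS
summary statistics, selecting instruments, estimating the causal effect
(`mr_fit()`), sensitivity diagnostics, and batch screening of hundreds or
thousands of exposures (a proteome or a cytokine panel) against one outcome
with per-panel false-discovery-rate control — plus a synthetic
summary-statistics generator with known ground truth so that every stage is
validated by parameter recovery, without any external downloads.

## Model and estimators

For variant $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its per-allele
effect on the exposure and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) its effect on
the outcome (log-odds for a binary outcome), both expressed for the same
effect allele.  Under the instrumental-variable assumptions each variant
yields a Wald ratio

$$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}, \qquad
  \mathrm{se}(\hat\theta_j) = \left| \sigma_{Yj} / \hat\beta_{Xj} \right|,$$

the first-order standard error that treats the exposure effect as fixed.
The primary multi-instrument estimator is the fixed-effect
inverse-variance-weighted (IVW) combination

$$\hat\theta_{IVW}
  = \frac{\sum_j \hat\beta_{Yj}\hat\beta_{Xj}\sigma_{Yj}^{-2}}
         {\sum_j \hat\beta_{Xj}^2 \sigma_{Yj}^{-2}}, \qquad
  \mathrm{se}(\hat\theta_{IVW})
  = \Big(\sum_j \hat\beta_{Xj}^2 \sigma_{Yj}^{-2}\Big)^{-1/2},$$

algebraically a weighted least-squares regression of outcome on exposure
effects through the origin.  With a single instrument the Wald ratio is
used; `estimate_auto()` encodes this 1-IV/multi-IV rule, which also governs
screening.  Two complementary estimators guard against pleiotropy:

* **Weighted median** — consistent when instruments carrying at least half
  of the inverse-variance weight are valid.  We use the percentile
  convention (cumulative weight minus half the variant's own weight crosses
  0.5, linear interpolation between bracketing ratios).  Its SE comes from
  a parametric bootstrap (betas resampled from normal distributions at
  their SEs; `n_boot = 1000` by default, seed mandatory).
* **MR-Egger** — weighted least squares of $\hat\beta_{Yj}$ on
  $\hat\beta_{Xj}$ with an unconstrained intercept after orienting each
  instrument to $\hat\beta_{Xj} \ge 0$.  Under the InSIDE assumption the
  slope estimates the causal effect and the intercept the average
  directional pleiotropy.  Because the regression typically has few points,
  inference uses the $t$ distribution with $J-2$ degrees of freedom; Wald
  and IVW p-values are two-sided normal.

Confidence intervals are 95% throughout and estimates are reported both on
the log-odds scale and as odds ratios.

## Instrument selection

`select_instruments()` applies, in order:

1. **Significance**: exposure $p < 5\times10^{-8}$ (file p-values are
   authoritative; recomputed from beta/SE only when absent).
2. **Cis window** (optional): variants within 1 Mb of the encoding gene's
   start, for cis-pQTL analyses; `cis_and_trans` applies no positional
   filter, as appropriate for cytokine panels.
3. **Exclusion list**: user-supplied variant identifiers (e.g. variants
   associated with confounders identified in external catalogues); an
   offline file replaces any live annotation-service query.
4. **LD clumping**: greedy — repeatedly keep the unprocessed variant with
   the smallest p-value (ties by identifier for determinism) and discard
   variants within 10,000 kb on the same chromosome with pairwise
   $r^2 > 0.001$.  Pairs absent from the LD table count as independent;
   10,000 kb is interpreted as the pairwise distance limit.
5. **Harmonization** (below).
6. **Instrument strength**: per-variant
   $F = (N-2)\,R^2/(1-R^2)$ with $R^2 = 2\hat\beta_{Xj}^2\,\mathrm{MAF}(1-\mathrm{MAF})$,
   dropping $F < 10$.  The per-SNP form ($K=1$, the variant's own $R^2$) is
   the only reading consistent with excluding individual SNPs.
7. **Steiger directionality**: a variant is kept only if it explains more
   variance in the exposure than in the outcome
   ($R^2_{exp} > R^2_{out}$) with $p < 0.05$ from a Fisher
   $z$-transformation test comparing $r=\sqrt{R^2}$ at the two sample
   sizes.  For binary outcomes $R^2$ is computed on the log-odds beta — an
   approximation (no liability-scale correction), stated as such.
   `steiger_alpha >= 1` disables the filter.

Each stage only removes variants; the returned report counts survivors per
stage.

### Harmonization

Alleles are matched exactly or as an exact swap; a swap negates the outcome
beta and mirrors its allele frequency.  For non-palindromic variants that
match neither way, complementary-base (strand-flip) matching is attempted
before dropping (`infer_strand = TRUE` by default).  Palindromic variants
(A/T, C/G) cannot be strand-resolved from alleles alone; the default policy
`drop_intermediate_af` drops them when either allele frequency lies within
0.08 of 0.5 (or is missing), the conservative standard in two-sample MR —
the choice and window are package defaults, not values taken from any one
study.  Every input variant receives exactly one audit disposition, and
harmonization is idempotent.

## Sensitivity diagnostics

* **Cochran's Q** at the fixed-effect IVW estimate over Wald ratios with
  weights $\mathrm{se}(\hat\theta_j)^{-2}$; $p$ from $\chi^2_{J-1}$.  The
  first-order ratio SE makes this the classic ratio-based Q; it is
  well-calibrated when outcome-side noise dominates (the case-control
  regime below), and anti-conservative when exposure noise is comparable.
* **Egger intercept test**: $t$-based, $J-2$ df; $p > 0.05$ read as no
  evidence of directional pleiotropy.
* **Steiger directionality** for the instrument set: per-variant $R^2$
  summed per trait, harmonic-mean sample sizes in the Fisher-$z$ test.  The
  aggregate convention is ours; the per-variant test does not define one.
* **Leave-one-out**: IVW refitted dropping each variant in turn.

## Screening and candidate criteria

`screen_exposures()` runs the full pipeline per exposure, applies
Benjamini–Hochberg FDR *within the panel* across exposures with at least
one valid instrument (exposures with none are reported as `no_valid_iv`
and excluded from the FDR family — separate panels are separate families,
never merged), and flags candidates by strict inequalities:

* FDR-adjusted $p < 0.05$;
* Egger intercept $p > 0.05$ (not applicable below 3 instruments);
* correct Steiger causal direction with Steiger $p < 0.05$;
* Q $p > 0.05$ (not applicable below 2 instruments).

Not-applicable criteria are reported as `NA` and do not veto candidacy:
single-instrument Wald-ratio findings are legitimate candidates, as is
standard in proteome-wide screens.

## The synthetic generator and what it emulates

`simulate_two_sample()` draws, per variant,
$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj})$ and
$\hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, \sigma_{Yj})$ with
independent noise (non-overlapping cohorts) and the standard
summary-statistic variance approximation
$\sigma^2 = 1/\{2n\,\mathrm{eaf}(1-\mathrm{eaf})\}$, divided by
$\phi(1-\phi)$ (case fraction $\phi$) for a case-control outcome.  This
makes the simulated SEs, $R^2$, $F$ and Steiger statistics interlock with
the configured sample sizes, so the filters are exercised realistically.

Default scenario (chosen once as the study-like conditions): 50 variants;
exposure cohort $n = 35{,}559$ (the scale of a large proteogenomic cohort);
outcome a rare binary phenotype with 228 cases among 344,912 (the scale of
a biobank skin-phenotype GWAS), log-odds effects; $\theta = 0.5$;
$\gamma_j \sim N(0.15, 0.05)$ (per-SNP $F$ in the hundreds); allele
frequencies uniform on $(0.05, 0.45)$; 10% palindromic variants.
Options add balanced, directional ($\alpha_j \sim N(a, a/2)$ on the invalid
fraction) or InSIDE-violating pleiotropy; LD blocks with a shared $r^2$;
and reverse-causal contaminants, generated with a large direct outcome
effect $\delta_j \sim N(0.3, 0.05)$ and an induced exposure effect
$\kappa\delta_j$ ($\kappa = 0.3$), so $R^2_{exp} \approx 0.09\,R^2_{out}$ —
genome-wide significant on the exposure yet detectably reverse-causal.

`simulate_screen_panel()` emulates a cis-pQTL screen: each exposure carries
one strong cis-like instrument ($\gamma = 0.35$) plus clearly
sub-significant background variants ($\gamma = 0.002$), against a
well-powered quantitative outcome, so exposures contribute a single
Wald-ratio instrument — the situation of most proteins in proteome-wide
screens.  The background variants are kept far from the significance
boundary by design: borderline background effects would occasionally clear
$5\times10^{-8}$ by winner's curse and attach a spurious, heterogeneous
second instrument, which is not the structure this generator is documented
to produce.

What the generator does **not** emulate: realistic genome-wide LD,
liability-scale binary traits, sample overlap between cohorts,
population stratification, or allele-frequency differences between
cohorts.  Passing tests therefore demonstrate internal statistical
correctness and calibration under the stated generative model, not
robustness to those artefacts of real data.

## Validation scenarios and numerical choices

The test suite and `scripts/acceptance.R` validate by parameter recovery:

* **Oracle equivalence** — IVW against an independent through-origin
  weighted-least-squares solve, MR-Egger against a generic WLS solve, BH
  against a hand step-up, greedy clumping against a brute-force restatement
  on all small instances.
* **Calibration** — with the binary default outcome, outcome-side noise
  dominates ($\sigma_Y \gg \theta\sigma_X$), the regime in which the
  fixed-effect IVW SE is exact: type-I error at $\theta=0$ and 95% CI
  coverage at $\theta=0.5$ are checked over 1,000 and 500 seeded
  replicates (50 variants each).  With a well-powered quantitative outcome
  and strong instruments this regime would *not* hold — the ratio SE's
  ignored exposure-noise term becomes material — which is itself visible
  in the generator if configured that way.
* **Robustness** — 30% invalid instruments with directional pleiotropy
  ($\alpha \sim N(0.3, 0.15)$), 200 instruments with strengths fixed on a
  uniform grid $[0.05, 0.5]$, quantitative outcome.  The wide, all-positive
  strength spread is deliberate: the Egger intercept is identified by
  extrapolation to zero instrument strength, and with narrow or
  sign-mixed strengths its non-centrality is bounded regardless of the
  pleiotropy magnitude (oriented near-zero instruments carry high
  intercept leverage with sign-flipped pleiotropy).  In this scenario the
  weighted median stays nearly unbiased while IVW inherits the pleiotropy,
  and the intercept test detects it with high power.
* **Filters** — Steiger removes the constructed reverse-causal
  contaminants; the F filter removes variants engineered to $F < 10$
  exactly at the boundary formula.
* **Screening** — a 100-exposure panel with 5 causal exposures recovers
  all 5 as candidates with a false-candidate proportion among nulls
  within the FDR level.
* **Determinism** — one top-level seed is expanded deterministically per
  task (weighted-median bootstrap, per-exposure screening); identical
  seeds give byte-identical result bundles.  `simulate_two_sample()`
  restores the caller's RNG state on exit.

Numerical conventions: degenerate inputs error early with informative
messages (zero exposure effect for a ratio, fewer instruments than a
method needs, degenerate Egger regression); p-values are floored at the
smallest positive double rather than returning 0; clumping ties break
lexicographically; problem sizes above were chosen so the full suite runs
in well under a minute of compute per scenario.

## Known limitations

* The Wald/IVW SE is first-order; no NOME/I² weak-instrument correction
  for MR-Egger is applied.
* When the outcome GWAS is very noisy (few cases), per-variant Steiger
  filtering conditions on the *estimated* outcome effect being small and
  therefore attenuates downstream causal estimates toward zero — visible
  in the simulated default scenario, where the truth is known.  This
  affects any pipeline that Steiger-filters against an underpowered
  outcome; consider reporting estimates with and without the filter.
* Binary-trait $R^2$ for Steiger filtering is the log-odds approximation.
* No proxy-variant lookup, liftover, VCF ingestion, multivariable MR,
  MR-PRESSO or colocalization — out of scope by design.
* LD handling is table-driven; the package never computes LD from
  genotype panels.
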