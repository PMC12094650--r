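---
title: "Modelling joint genetic and environmental risk with geiprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling joint genetic and environmental risk with geiprs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geiprs)
```

## The problem

Psychotic disorders arise from both inherited liability and environmental
exposure, and the two can interact: the same adversity may carry a larger
risk for individuals with a higher polygenic load. Quantifying this
requires a full chain of machinery — a polygenic risk score (PRS) built
from GWAS summary statistics against a linkage-disequilibrium (LD)
reference, an aggregate environmental risk score, a family of case–control
regressions, interaction statistics on two different scales, accuracy
metrics that transfer across study designs, and a power analysis that
respects the rarity of the outcome. `geiprs` implements that chain as
composable, seed-reproducible R functions, together with a synthetic-cohort
generator under known ground truth so that every stage has a testable
oracle.

## The generative model

The generator is the package's specification of the world in which its
statistics are exact, and the conditions under which its tests run.

**Genotypes.** Variants live in fixed-size LD blocks (default 50). Within a
block, each of an individual's two haplotypes follows a latent first-order
autoregressive Gaussian with adjacent correlation `rho` (default 0.6); an
allele is carried when the latent value falls below `qnorm(maf)`, with MAFs
drawn uniformly from `maf_range` (default 0.05–0.5). This yields
Hardy–Weinberg genotypes, banded invertible within-block LD whose implied
dosage correlation is checkable by brute-force Monte Carlo, and exact
independence across blocks — the property the per-block solvers rely on.

**Architecture and summary statistics.** True standardized effects follow
the point-normal prior: zero with probability `1 - p_causal`, otherwise
Normal with variance `h2 / (M * p_causal)` (defaults `h2 = 0.3`,
`p_causal = 0.03`, `M` the variant count). Marginal GWAS estimates are
sampled analytically per block as `N(D beta, D / N_gwas)` with the block LD
matrix `D` estimated from the panel — the sampling distribution a raw
training GWAS of size `N_gwas` (default 50 000) would induce, at a tiny
fraction of the cost. A raw-cohort simulation would add nothing
downstream, so it is not implemented.

**Exposures.** Six binary exposure domains (paternal age, parental SES,
obstetric complications, urbanicity, childhood adversity, recent life
events) are drawn at configurable prevalences, independently of genotype —
so the case-only gene–environment correlation screen has a true null.
The published instruments this mirrors do not report their domain
prevalences or weights in accessible form; the shipped defaults
(prevalences 0.10–0.50, log-RR weights 0.25–0.80 with childhood adversity
heaviest) are plausible configuration chosen once, not estimates, and the
weight table is deliberately data (`load_weight_table()`), with the
packaged YAML labelled synthetic. Four trauma-inventory subdomain counts
are generated with item probabilities tied to the childhood-adversity
indicator, so the trauma-total analysis path carries a weaker, correlated
signal; the positively framed subdomains are reverse-scored (`max - raw`)
on totalling.

**Disease and ascertainment.** Status follows either a logistic model
`P(case) = expit(b0 + bG*zG + bE*zE + bGE*zG*zE)` on the standardized
genetic and environmental scores, or an equivalent liability-threshold
model. The intercept `b0` is calibrated by bisection so the *population*
prevalence equals the lifetime risk `K` (default 0.01); calibration
averages over Monte-Carlo draws in which the genetic score is treated as
standard normal (justified by the CLT over hundreds of variants) and the
environmental score keeps its actual discrete distribution. Cases and
controls are then ascertained by rejection sampling to exact counts
(defaults 717 and 356), emulating a clinical sample rather than a
population cohort; candidates' genotypes are generated chunk-wise so only
retained individuals are kept. The default coefficients
`(bG, bE, bGE) = (0.7, 1.0, 0.3)` put the per-SD odds ratios in the 2–3
range typical of this literature.

What the generator does *not* emulate: realistic human LD maps, ancestry
structure or stratification, imputation artifacts, questionnaire
psychometrics, missing-data mechanisms, or gene–environment correlation.
Passing tests therefore certify the statistical machinery under a clean,
correctly specified world — not robustness to those real-data
complications.

## PRS construction

`ldpred_inf_weights()` solves `(D + (M/(N h2)) I) w = beta_hat` per block —
deterministic, and unit-tested against a dense whole-genome solve to
1e-10. `ldpred_gibbs_weights()` implements the point-normal Gibbs sweep:
for each variant the residualized marginal effect
`r_j = beta_hat_j - sum_{k != j} D_jk w_k` drives an inclusion draw (from
the point-normal posterior odds) and, if included, a normal draw with mean
`r_j s2/(s2 + se_j^2)`, `s2 = h2/(M p)`. The reported weight is the
Rao-Blackwellized posterior mean (inclusion probability × conditional
mean), which has lower Monte-Carlo noise than averaging raw draws and, for
a single-variant block, is *exactly* the closed-form posterior mean — the
quadrature oracle in the tests. The sweep is compiled (C++) but consumes
R's RNG in the same order as the pure-R reference engine also shipped, so
the two produce bit-identical chains for a seed; that equality is itself a
test. Defaults: 100 burn-in + 400 kept sweeps for stand-alone use (the
pipeline uses 50 + 100, which the p = 1 limit check shows is already well
mixed at demo scale); a divergence guard errors if any sampled weight
exceeds `w_bound` (default 5 on the standardized scale, orders of
magnitude above any legitimate value).

The causal fraction is chosen by scoring each candidate on the analysis
cohort and maximizing AUC over the standard grid
`c(1e-3, 3e-3, 0.01, 0.03, 0.1, 0.3, 1)`, ties broken toward smaller `p`.
This replicates the field's common in-sample selection; it is mildly
optimistic, and `select_p_by_auc()` can equally be pointed at a held-out
panel, which is the recommendation for accuracy claims. Scores are
standardized (so any positive rescaling of weights is irrelevant) and
age/sex-adjusted by least-squares residualization.

`ldsc_h2()` estimates heritability from `E[chi2_j] = 1 + N h2 l_j / M`
with iteratively reweighted least squares (weights
`1/(max(l,1) (1 + N h2 l/M)^2)`, 3 iterations) and a 20-block delete-one
jackknife SE. The intercept is fixed at 1 by default: the analytic
generator produces no confounding inflation, and with the modest LD-score
spread of block-structured data a free intercept trades off against the
slope so strongly that single-draw estimates become uninformative (the
free mode remains available via `intercept = "free"` for data where
inflation is plausible). LD scores are computed from the same block
matrices that defined the sampling model, so no finite-panel r² bias
correction is applied by default; `ld_scores(adjust = TRUE)` provides the
usual `r2 - (1-r2)/(n-2)` correction for external reference panels.

## Association and interaction

The four logistic model types (genetic; environmental; independent;
interaction) are fit by IRLS (`glm.fit`, tolerance 1e-8, max 100
iterations) behind `fit_logistic()`, which also assembles the coefficient
covariance (inverse Fisher information — equal to the observed information
under the canonical logit link), both log-likelihoods, and a per-term
OR/CI/p table. Quasi-complete separation is flagged by an explicit error
when any non-intercept coefficient exceeds 15 on the standardized-predictor
scale — a simple, testable rule chosen over a perfect-classification scan.
Continuous G and E terms are standardized over the analyzed complete cases
*before* the product term is formed, so all reported ORs are per SD; the
source instruments' OR units are not stated precisely enough to prefer a
raw-unit convention, and per-SD makes models comparable across measures.

Additive interaction uses `RERI = OR11 - OR10 - OR01 + 1` evaluated by
default at +1 SD increments of both scores (the contrast is recorded in
the output and configurable). The delta-method variance propagates the
coefficient covariance through the gradient
`(dG (OR11 - OR10), dE (OR11 - OR01), dG dE OR11)`; the unit tests verify
it against numerical gradient propagation. The primary significance rule
is CI-excludes-zero. Because RERI is right-skewed, the symmetric delta
interval differs from the percentile bootstrap at the endpoints even when
the two agree closely on width; `reri_bootstrap()` (stratified
case/control resampling, failed refits counted and capped at 10%) is the
asymmetric alternative, and the acceptance suite compares the two on
interval half-width. One consequence of per-sample standardization worth
knowing: in an ascertained sample the SDs of G and E are inflated relative
to the population, so per-SD RERI values from case–control fits are larger
than population-scale ones — comparisons should hold the scale convention
fixed.

Subgroup analyses dichotomize at the control-group quantile (linear
interpolation, type 7; strictly-greater comparison so boundary values fall
"low"), default 75% with 50%/25% sensitivity settings, and fit one
covariate-adjusted model with three indicator terms against the low/low
reference. Degenerate thresholds (fewer than two distinct control values)
and empty cells are explicit errors, with cell counts in the message.

## Accuracy conversion

`liability_r2_to_auc()` is the truncated-normal forward map: a score
explaining liability fraction `rho2` has case mean `rho2 * i` and control
mean `rho2 * v` (`i = dnorm(t)/K`, `v = -iK/(1-K)`, `t = qnorm(1-K)`) with
the corresponding truncation-reduced variances, giving an expected AUC;
`auc_to_liability_r2()` inverts it by bisection on `[0, 1)` to absolute
tolerance 1e-8, with AUC 0.5 mapping to exactly 0 and AUC < 0.5 an error
(fix the score direction upstream). `nagelkerke_to_liability_r2()` is the
standard case–control-to-liability transformation with ascertainment
correction, which at `P = K` reduces exactly to the classical
`R2 K(1-K)/z^2` rescaling — the limit the tests pin. The published
headline accuracy figures of the motivating literature depend on the exact
conversion variant and on whether AUC was covariate-adjusted, neither of
which is recoverable; the two routes here are cross-checks of each other,
not reproductions.

## Power analysis

`estimate_power()` simulates standardized G and E as independent normals,
generates status from the calibrated logistic (or liability) model,
ascertains at the configured case:control ratio, refits the interaction
model and counts successes: Wald p < alpha on the product term
(multiplicative) or delta RERI CI excluding zero (additive — chosen over
the bootstrap criterion for speed; the bootstrap remains available for
final reporting). Monte-Carlo SE is `sqrt(p(1-p)/n_reps)`; replicate refit
failures are counted and error above 10%. Note that with non-zero main
effects the additive criterion has a non-null population value
`(OR10-1)(OR01-1)` even at `bGE = 0`, so its "null" rejection rate is
legitimately far above alpha — the acceptance suite reports it alongside
the calibrated multiplicative rate rather than asserting alpha.
`min_n_for_power()` brackets by doubling and bisects on a user grid,
assuming monotonicity in n up to MC error, and returns the full evaluated
curve.

## Pipeline and reproducibility

`run_pipeline()` orchestrates simulate → prs → env-score → associate →
interact → subgroup → metrics → power from a validated YAML config
(unknown keys rejected with their path; defaults injected). A single
master seed is expanded into named substreams (panel / sumstats /
exposures / cohort / per-p Gibbs chains / power), so stages are
order-independent and an identical config yields a byte-identical
`report.json` — asserted by checksum in the tests. Timestamps go to
stderr logs only, never into the report.

## Problem sizes and test design

The suite exercises: oracle equivalence of the per-block and dense
LDpred-inf solves at M = 2000; the Gibbs p = 1 limit against the
infinitesimal solution (correlation > 0.99); 95% Wald-CI coverage of the
interaction coefficient in [0.91, 0.98] over 200 cohorts of n = 5000;
delta-vs-bootstrap RERI agreement (B = 2000) at n = 2000; type-I
calibration of the multiplicative test over 1000 null replicates;
LDSC recovery of h² = 0.3 within ±0.05 at M = 5000, N = 50 000 (run at
`p_causal = 1`, where the realized heritability of a single draw
concentrates tightly; at sparse architectures the draw-to-draw spread of
the true signal would dominate the band); prevalence calibration within
±0.002 of K = 0.01 over 2×10⁵ draws; and the high-G/high-E subgroup
carrying the largest OR in ≥95 of 100 cohorts (run at `p_causal = 0.2`,
M = 150, so the genetic score is effectively continuous — sparser draws
can leave it too discrete for quantile thresholding, an artifact of score
granularity rather than of the subgroup method). These sizes keep the
default suite to a few minutes on one CPU while leaving each check's
Monte-Carlo error well inside its tolerance.

## Known limitations

- LD is block-diagonal by construction; windowed estimation for external
  data is provided (`estimate_ld(window = ...)`) but cross-block leakage
  of real genomes is not modelled.
- In-sample AUC selection of `p` is optimistic; use a held-out panel for
  reported accuracy.
- The delta-method RERI interval is symmetric by construction and known to
  be strained for strongly skewed estimates; prefer the bootstrap when the
  point estimate is large relative to its SE.
- The shipped environmental weight table is a synthetic placeholder; all
  substantive use requires instrument-specific weights supplied as data.
- Liability-scale conversions assume the threshold model with a single
  normal liability; they are comparability devices, not causal variance
  decompositions.
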