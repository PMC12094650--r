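# geiprs

Joint genetic–environmental modelling of psychiatric case–control risk:
polygenic risk scores (PRS) from GWAS summary statistics, aggregate
polyenvironmental risk scores, and gene–environment interaction (G×E)
inference on both the multiplicative and the additive scale.

## Who this is for

Psychiatric-genetics and epidemiology analysts who want a single, tested R
toolchain for the standard design "ascertained case–control sample + PRS +
environmental risk score": score construction, the four-model logistic
family, interaction statistics with honest uncertainty, liability-scale
accuracy conversion, and simulation-based power analysis. Because the
matching clinical datasets are rarely shareable, the package ships a
synthetic-cohort generator with known ground truth so every stage can be
exercised — and unit-tested — end to end without any external data.

## What it computes

**PRS construction.** Marginal GWAS effects $\hat\beta$ are reweighted
against an LD reference panel $D$ under two priors:

- *infinitesimal* (LDpred-inf): per LD block
  $w = \left(D + \frac{M}{N h^2} I\right)^{-1} \hat\beta$;
- *point-normal* (spike-and-slab): $\beta_j \sim N(0, h^2/(Mp))$ with
  probability $p$, else $\beta_j = 0$, sampled by a per-variant Gibbs
  sweep (compiled, seed-reproducible); the posterior-mean weights over the
  grid $p \in \{10^{-3}, 3\times10^{-3}, 0.01, 0.03, 0.1, 0.3, 1\}$ are
  scored and the $p$ with maximal AUC is selected.

A compact LD-score-regression estimator supplies $h^2$
($E[\chi^2_j] = 1 + N h^2 \ell_j / M$, block-jackknife SE).

**Environmental scores.** A weighted six-domain aggregate (paternal age,
parental SES, obstetric complications, urbanicity, childhood adversity,
recent life events; weights are user-supplied data — the shipped table is a
labelled synthetic placeholder) and a trauma-inventory total with
reverse-scored positive subdomains.

**Association and interaction.** Four logistic model types (genetic,
environmental, independent, interaction) with age/sex/education adjustment,
Nagelkerke $R^2$, AIC/BIC, BH-FDR; multiplicative interaction as the
product-term OR; additive interaction as the relative excess risk due to
interaction, $\mathrm{RERI} = OR_{11} - OR_{10} - OR_{01} + 1$, with a
delta-method CI (gradient $h = (OR_{11}-OR_{10},\, OR_{11}-OR_{01},\,
OR_{11})$, variance $h^\top \Sigma h$) and a stratified bootstrap
alternative; high/low subgroup ORs at control-quantile cutoffs (75%, with
50%/25% sensitivity); a case-only gene–environment correlation screen.

**Accuracy and power.** AUC (Mann–Whitney, midranks), conversion of AUC or
Nagelkerke $R^2$ to liability-scale $R^2$ under the threshold model at
population lifetime risk $K$ (default 0.01), and Monte-Carlo power /
minimum-sample-size estimation for both interaction tests from standardized
coefficients.

## Worked example

```r
library(geiprs)
cfg <- sim_config(master_seed = 7, M = 500, n_ref = 300, block_size = 25,
                  n_case = 300, n_control = 200, K = 0.01)
panel      <- simulate_panel(cfg)             # LD reference
gwas       <- simulate_sumstats(panel, cfg)   # summary statistics + truth
cohort_sim <- simulate_cohort(panel, gwas, cfg)

ld      <- estimate_ld(panel)
aligned <- align_alleles(gwas$sumstats, panel)
h2_hat  <- ldsc_h2(aligned$sumstats, ld)
h2_hat
#> LD score regression: h2 = 0.2954 (SE 0.1258), intercept = 1.000 (fixed), mean chi2 = 42.171

analysis <- structure(list(dosage = cohort_sim$dosage,
                           variants = panel$variants),
                      class = "genotype_panel")
candidates <- lapply(default_p_grid(), function(p)
  ldpred_gibbs_weights(aligned$sumstats, ld, h2 = h2_hat$h2, p = p,
                       n_iter = 150, burn_in = 50, seed = 11))
sel <- select_p_by_auc(candidates, analysis, cohort_sim$cohort$status)

cohort <- cohort_sim$cohort
cohort$prs_adj    <- residualize_covariates(sel$scores$standardized,
                                            cohort[, c("age", "sex")])
cohort$pers_total <- pers_total(cohort, default_weight_table())$total

fit <- fit_model_spec(cohort, model_spec("interaction", g_term = "prs_adj",
                                         e_term = "pers_total"))
reri_delta(fit)
#> RERI = 8.461, 95% CI [0.063, 16.860], p = 0.0483 (delta method)
#>   OR10 = 2.709, OR01 = 4.405, OR11 = 14.576 at contrast (dG=1, dE=1)

lp <- liability_params(K = 0.01, P = mean(cohort$status))
auc(cohort$prs_adj, cohort$status)                    # 0.734
auc_to_liability_r2(0.734, lp)                        # 0.102
```

Reading the output: the point-normal PRS discriminates cases from controls
with AUC 0.734, equivalent to explaining ~10% of liability variance at 1%
lifetime risk; the joint effect of a +1 SD genetic and +1 SD environmental
increment exceeds the sum of the separate effects by RERI ≈ 8.5 excess odds
units, with a CI excluding zero — a positive departure from additivity, as
expected since the cohort was generated with a positive G×E coefficient.

The whole chain can also be driven from a YAML file:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "geiprs"))
```

which writes per-stage TSV/CSV/JSON artifacts plus a deterministic
`report.json` (identical config ⇒ byte-identical report).

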