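# speciationRI

Tools for studying how components of reproductive isolation (RI) accumulate
with genomic differentiation across a speciation continuum — a set of
population pairs ranging from weakly differentiated host ecotypes to
well-separated species. The package is aimed at evolutionary biologists with
trial-level behavioral data (host-preference assays, no-choice mating
trials) and per-pair genetic distances for the same taxa.

## What it computes

**Isolation indices.** For each taxon pair:

- habitat isolation `|p1 − p2|`, the absolute difference between the pair's
  two taxa in the proportion of trials resting on a reference host
  (no-choice trials excluded; invariant to reference labeling and taxon
  order);
- sexual isolation `1 − f_het / f_homo` from the four male-by-female mating
  combinations, with mating counts pooled within the homotypic and
  heterotypic categories (0 = random mating, 1 = complete assortment), plus
  an optional Beta-binomial posterior that propagates finite-trial
  uncertainty.

**Genetic distances.** OLS calibration of genome-wide F_ST against nuclear
sequence divergence for pairs with both measurements, prediction of F_ST for
pairs with sequence data only (raw linear predictor, unclipped), mean
patristic distances from a supplied tree, and per-fit standardization.

**The core model.** A Bayesian linear mixed model for pairwise data,

    RI_ij = b0 + b_gen * x_gen + b_taxon * x_taxon
          + b_int * x_gen * x_taxon + lambda_i + lambda_j + eps_ij

with `x_gen` standardized genetic distance, `x_taxon` a 0/1 heterospecific
indicator, and crossed species random effects `lambda` absorbing the
non-independence of pairs sharing a species. `b_gen` is the within-species
slope; `b_gen + b_int` the between-species slope. Conjugate priors
(normal(0, prec 0.001) on coefficients; gamma(1, 0.01) on both precisions)
admit an exact blocked Gibbs sampler, implemented in compiled code, with
DIC model comparison over the five-model suite (full, no interaction,
distance only, status only, null) and Gelman–Rubin PSRF diagnostics.

**Breakpoint regression.** A status-free alternative: single-breakpoint
piecewise OLS over all admissible splits (each segment ≥ 15% of the data),
compared to the single line by BIC.

**Synthetic data.** `generate_dataset()` emulates the study design (9
species, 36 pairs, binomial trial sampling around model-generated truth)
and records the generating truth for recovery experiments.

## Worked example

```r
library(speciationRI)

g   <- generate_dataset(synth_config(seed = 42))  # study-scale synthetic data
est <- add_final_fst(estimate_all_pairs(g$dataset))
fit <- fit_model_suite(est, "habitat", mm_spec(seed = 7))
fit
#> Model suite for habitat isolation (n = 36 pairs), ranked by DIC:
#>            model    dic     pD mean_deviance mpsrf rank
#> 1           full -57.84 11.381        -69.22 1.004    1
#> 2 no_interaction -57.77 10.661        -68.43 1.008    2
#> 3   genetic_only -54.35  9.499        -63.85 1.006    3
#> 4     taxon_only -40.70  9.133        -49.83 1.012    4
#> 5           null -32.77  8.059        -40.83 1.013    5

fit$fits$full
#> Bayesian pairwise mixed model (habitat isolation, n = 36 pairs)
#>   DIC = -57.84 (pD = 11.38), multivariate PSRF = 1.004
#>   intercept    median   0.430  95% ETPI [0.113, 0.729]  P(>0) = 0.994
#>   beta_gen     median   0.033  95% ETPI [-0.155, 0.213]  P(>0) = 0.641
#>   beta_taxon   median  -0.004  95% ETPI [-0.282, 0.286]  P(>0) = 0.486
#>   beta_int     median   0.150  95% ETPI [-0.058, 0.363]  P(>0) = 0.921
```

The DIC table ranks the five candidate models: here the full model (with
the distance-by-status interaction) fits this realization best, i.e. the
within- and between-species slopes differ. In the full-model summary,
`beta_gen` is the within-species slope (flat here: the interval spans 0)
and `beta_int` the extra between-species slope; all chains mix well
(PSRF ≈ 1). The same estimates feed the status-free check:

```r
ok <- !is.na(est$habitat_isolation) & !is.na(est$fst_final)
fit_breakpoint_models(est$fst_final[ok], est$habitat_isolation[ok])
#> Breakpoint regression (n = 36):
#>   breakpoint at x = 0.6123 (after sorted obs 13)
#>   BIC without breakpoint = -18.91, with breakpoint = -22.43 -> breakpoint favored
#>   left: y = 0.478 + -0.411 x;  right: y = 0.376 + 0.254 x
```

A breakpoint near F_ST ≈ 0.6 — inside the generated gap between the
within-species and between-species F_ST ranges — is favored by BIC,
echoing the mixed-model interaction without using species labels.

`run_pipeline()` chains all stages (estimation → calibration → model suite
→ breakpoint → associations) and writes per-pair estimates as CSV and all
results as JSON with seeds and settings recorded;
`inst/scripts/run_pipeline.R` exposes the same pipeline from the shell.

See the vignette in `vignettes/speciation-continuum-models.Rmd` for the
model, priors, numerical conventions and the generator's assumptions.

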