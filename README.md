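# allomix

Hierarchical Bayesian estimation of lake consumer **allochthony** — the
share of a consumer's assimilated biomass ultimately derived from
terrestrial (catchment) organic matter — from hydrogen and nitrogen stable
isotopes.

## The problem and who this is for

Boreal lakes receive large terrestrial organic-matter subsidies, and δ²H
separates terrestrial from within-lake (algal) production by roughly 100‰,
far more cleanly than carbon or nitrogen isotopes. Turning raw consumer
δ²H into an allochthony estimate, however, requires a chain of corrections
and a mixing model that respects hierarchical structure across lakes and
taxa. `allomix` packages that chain for food-web ecologists:

- **Trophic levels** from δ¹⁵N via the single end-member model
  `TL = 2.1 + (δ¹⁵N_consumer − δ¹⁵N_baseline)/3.4`, with per-lake baselines
  (cladocerans; littoral *Asellus* for littoral zoobenthos), regression
  imputation for missing baselines, and fixing of methane-influenced
  zoobenthos (δ¹³C ≤ −40‰) to the baseline level.
- **Hydrogen-exchange correction**: the water contribution compounds over
  trophic transfers as `ω_compound = 1 − (1 − ω)^(TL−1)` (ω = 0.23 by
  default), and measured values are corrected as
  `δ²H_corr = (δ²H_c − ω_compound·δ²H_water)/(1 − ω_compound)`.
- **Sources**: per-lake terrestrial (inlet DOM δ²H, SD 11.2‰) and aquatic
  (water δ²H − 110‰ photosynthetic discrimination, SD 23.6‰), with
  bacterial-step and benthic-algae scenario variants and a ±k·SD envelope
  screen.
- **Mixing model**: with two sources the composition has a 1-D isometric
  log-ratio (ILR) coordinate `φ = √½·ln(p_aq/(1−p_aq))`; the model is
  `allochthony ~ 1 + x + (1 + x | taxon) + (1 | lake)` in ILR space with
  likelihood `y ~ N((1−p)T + pA, ξ[(1−p)²σ_T² + p²σ_A²] + σ_extra²)` —
  multiplicative process×residual error ξ plus an additive ±13‰
  preprocessing variance. Sampling is adaptive Metropolis in C++ with
  split rank-normalized R̂ and Geweke convergence checks; DIC, Akaike
  weights and approximate R² compare fits.
- **Synthetic-data generator** reproducing the whole study design (35
  lakes, 8 taxa, known ILR slope 0.84, 12% global allochthony at covariate
  zero) so every stage is testable with no field data.

See `vignettes/allochthony-methods.Rmd` for the full model description,
design choices and limitations.

## Worked example

Simulate a 12-lake study, run the full pipeline (PCA covariate →
preprocessing → sources → mixing model), and summarise:

```r
library(allomix)
cfg <- run_config(
  simulate = sim_config(n_lakes = 12, samples_per_taxon_lake = 2, seed = 42),
  mixing   = mix_config(iterations = 30000, burn_in = 15000, thinning = 15, seed = 1),
  out      = "demo_out")
res <- run_pipeline(cfg)
print(res$fit)
```

```
[load] 192 consumer samples, 12 lakes
[pca] 18 variables; PC1 explains 51.7% of variance
[prep] 192 samples; 0 imputed baselines; 0 methane-fixed; 0 TL-clamped
[screen] 7 of 192 corrected values outside +/-2 SD envelope
Hierarchical two-source ILR mixing model
  192 observations, 8 taxa, 12 lakes; covariate: pc1
  3 chains x 30000 iterations (burn-in 15000, thinning 15): 3000 draws
  convergence: passed (max R-hat 1.018)
  global intercept allochthony: 0.17 (95% CI 0.03-0.42)
  global ILR slope: 0.43 (95% CI 0.11-0.84)
```

The global intercept allochthony is the average consumer's terrestrial
share at the gradient midpoint (covariate 0); the positive ILR slope whose
credible interval excludes zero means allochthony declines significantly
along the gradient (toward more agricultural/eutrophic catchments). Per
taxon:

```r
summary(res$fit)$intercepts[, c("taxon", "allochthony", "lo", "hi")]
```

```
                  taxon allochthony    lo   hi
1               asellus        0.25 0.051 0.54
2             chaoborus        0.15 0.026 0.38
3  chironomids_littoral        0.16 0.030 0.39
4 chironomids_profundal        0.25 0.054 0.56
...
```

`plot(res$fit)` draws the fitted allochthony curves along the gradient;
`run_scenarios(cfg)` refits over an ω × source-scenario grid and reports
rank-consistency of taxon intercepts across scenarios.

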