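---
title: "Estimating lake consumer allochthony from hydrogen isotopes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lake consumer allochthony from hydrogen isotopes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomix)
```

## The scientific problem

Lake food webs are fuelled by two broad carbon sources: organic matter fixed
in the lake by algae (autochthonous) and organic matter imported from the
surrounding catchment (allochthonous, mostly of terrestrial plant origin).
The share of a consumer's assimilated biomass that ultimately derives from
terrestrial matter — its *allochthony* — is a central quantity in
freshwater ecology, because it measures how strongly lake secondary
production is subsidised by the landscape.

Hydrogen stable isotopes (δ²H) separate these two end-members unusually
well: terrestrial organic matter is typically enriched in deuterium by on
the order of 100‰ relative to algae produced in the same lake, because
photosynthetic water fixation discriminates strongly against deuterium.
`allomix` implements a complete estimation pipeline from raw consumer
isotope tables to posterior allochthony summaries:

1. **Trophic level estimation** from δ¹⁵N against lake- and
   compartment-specific baselines, with regression imputation for lakes
   missing a baseline taxon.
2. **Hydrogen-exchange (ω) correction** of measured consumer δ²H, removing
   the fraction of tissue hydrogen that derives from environmental water
   rather than diet, compounded over trophic transfers.
3. **Source construction**: a per-lake terrestrial source (inlet stream
   dissolved organic matter) and aquatic source (lake-water δ²H shifted by
   the photosynthetic discrimination), with fixed spatiotemporal SDs.
4. **A hierarchical Bayesian two-source mixing model** in isometric
   log-ratio (ILR) space with a continuous environmental covariate, taxon
   random intercepts and slopes, lake random intercepts, and a
   multiplicative error structure.
5. **Sensitivity scenarios** over the assumed ω value and alternative
   source definitions (a bacterial processing step; measured benthic algae
   as the aquatic source).

A synthetic-data generator reproduces the full study design with known
truth, so every stage — and the pipeline end to end — is testable without
any field data.

## Preprocessing model

### Trophic levels

Consumer trophic level is estimated with a single end-member nitrogen
mixing model,

$$TL = 2.1 + \frac{\delta^{15}N_{consumer} - \delta^{15}N_{baseline}}{3.4},$$

where the baseline taxa (herbivorous cladocerans for pelagic, profundal and
fish compartments; littoral *Asellus* for littoral zoobenthos) are assigned
TL 2.1 ± 0.1 and the nitrogen trophic discrimination factor is 3.4 ± 1.0‰.
Estimates below 1 are clamped to 1 with a warning: the hydrogen correction
exponent TL − 1 must be non-negative, and values below the basal level
indicate baseline problems rather than real trophic positions. Zoobenthos
samples with δ¹³C at or below −40‰ carry a methanogenic carbon signal that
invalidates the nitrogen-based estimate; their TL is fixed to the baseline
level 2.1 (the threshold is configurable).

Lakes lacking a measured baseline receive one through ordinary
least-squares regressions between lake means of the baseline taxon and a
bulk compartment sample (e.g. cladocerans on bulk zooplankton), a standard
device in multi-lake surveys; imputed baselines are flagged.

### Omega correction

A fraction ω of tissue hydrogen is exchanged with environmental water at
each trophic transfer (default ω = 0.23 ± 0.09, from recalibrated
literature estimates). Over TL − 1 transfers this compounds to

$$\omega_{compound} = 1 - (1 - \omega)^{TL - 1},$$

continuous in TL. The measured consumer value is then corrected back to
the trophic level of the basal sources:

$$\delta^2H_{corrected} = \frac{\delta^2H_{c} - \omega_{compound}\,\delta^2H_{water}}{1 - \omega_{compound}}.$$

The correction magnifies deviations from water by
$1/(1-\omega_{compound})$, so high-TL consumers carry proportionally larger
corrected uncertainty; a fixed ±13‰ observation-level SD is attached to
every corrected value to represent propagated baseline-TL and TDF
uncertainty. This SD enters the likelihood as an additive variance term,
outside the multiplicative error factor, because it represents
preprocessing uncertainty rather than source-mixing process error.

```{r omega}
# compound water contribution for a secondary consumer and a top predator
round(100 * omega_compound(c(0.14, 0.23, 0.32), 3))
round(100 * omega_compound(c(0.14, 0.23, 0.32), 4))
```

### Sources

Per lake, the terrestrial source mean is the measured inlet-DOM δ²H (SD
11.2‰); where a lake has no usable inlet, the nearest lake's inlet value is
borrowed and flagged. The aquatic source mean is lake-water δ²H plus the
photosynthetic discrimination of −110‰ (SD 23.6‰). Two alternative
scenarios probe this construction: a *bacterial* scenario in which the
terrestrial source passes through a microbial step,
$\delta^2H_{bact} = \delta^2H_{inlet}(1-\omega_b) + \delta^2H_{water}\,\omega_b$
with $\omega_b = 0.17$, and a *benthic-algae* scenario in which measured
benthic algae δ²H replaces the discrimination-adjusted water as the aquatic
source.

A diagnostic screen reports how many corrected consumer values fall outside
the per-lake source envelope (each endpoint extended by k times that
source's own SD — per-source rather than pooled SDs, the conservative
reading since no pooling rule is standard). No samples are excluded; the
counts are reported so gross mismatches are visible.

## The mixing model

With two sources the composition (p_terrestrial, p_aquatic) has a
one-dimensional ILR coordinate. Ordering the sources aquatic-first
(alphabetically, as in common mixing-model software),

$$\phi = \sqrt{\tfrac12}\,\ln\frac{p_{aq}}{1 - p_{aq}}, \qquad
p_{aq} = \mathrm{logit}^{-1}(\sqrt{2}\,\phi),$$

so larger φ means lower allochthony, and a *positive* covariate slope means
allochthony *declines* along the gradient. The hierarchical structure is

$$\phi_i = (\beta_0 + b_{0,s(i)} + u_{l(i)}) + (\beta_1 + b_{1,s(i)})\,x_{l(i)},$$

i.e. `allochthony ~ 1 + x + (1 + x | taxon) + (1 | lake)` in formula
notation, with observation model

$$y_i \sim \mathcal{N}\!\big(m_i,\; V_i\big), \quad
m_i = (1-p_i)\,T_{l(i)} + p_i\,A_{l(i)}, \quad
V_i = \xi\,[(1-p_i)^2\sigma_T^2 + p_i^2\sigma_A^2] + \sigma_{extra}^2,$$

where $y_i$ is the ω-corrected consumer value, $T, A$ the per-lake source
means, and ξ the multiplicative process-by-residual error factor. The
trophic discrimination factor for hydrogen is fixed at zero with no
variance contribution.

### Priors

With only two sources, a flat prior on the source proportion is the natural
uninformative choice; the remaining priors are weakly informative and
configurable: Normal(0, 10²) on the ILR fixed effects (essentially flat
over the invertible range of the transform), Uniform(0, 5) on the
hierarchical SDs (ILR units), Uniform(0, 20) on ξ, and Normal(0, σ²)
hierarchies on the random effects.

### Sampling

The posterior is explored by component-wise adaptive random-walk
Metropolis, written in C++ for speed. Proposal scales adapt toward a 0.44
acceptance rate during burn-in only (diminishing adaptation in batches of
50 sweeps), so the post-burn-in chain is a fixed Markov kernel. Because the
centered hierarchical parameterization induces strong posterior correlation
between the global intercept/slope and the mean of the matching
random-effect block, three likelihood-invariant *translation moves* shift
mass between β₀ and u, β₀ and b₀, and β₁ and b₁ each sweep; they leave
every linear predictor unchanged, so only the priors enter their acceptance
ratio, and they cost no likelihood evaluations. Per-observation likelihood
terms are cached so each component update touches only the observations its
parameter enters.

Correctness of the sampler is established against an independent oracle: in
the reduced model (one taxon, one lake, no covariate, no hierarchy, fixed
ξ) the posterior is one-dimensional and can be integrated to machine
accuracy on a grid. The test suite requires the MCMC mean and the 2.5% and
97.5% quantiles of allochthony to agree with grid integration within three
Monte-Carlo standard errors, and separately verifies that the C++ chain's
stored log-posterior and pointwise log-likelihoods match an independent R
implementation of the same density at saved draws.

### Convergence

Split rank-normalized Gelman–Rubin R̂ (threshold 1.05) and Geweke z-scores
(first 10% vs last 50% of each chain, spectral-density standard errors) are
computed for every sampled parameter. A fit passes when all R̂ values are
within threshold and at least 90% of the per-parameter, per-chain Geweke
tests satisfy |z| ≤ 2. The 90% pass fraction is deliberate: |z| ≤ 2 has
nominal coverage 95.4% under perfect stationarity, so demanding 95% of
tests to pass would reject roughly half of genuinely converged runs on
binomial noise alone, while genuine drift pushes many z-scores far beyond
2 and is still caught. Non-converged fits are flagged, never silently
returned, and the pipeline propagates the flag to its exit status.

Default MCMC settings (3 chains × 20,000 iterations, half burn-in, thinning
10) are test-scale; the validation suites that fit the full 35-lake design
use 3 × 60,000 (burn-in 30,000, thinning 30), which passes R̂ ≤ 1.05 on
that problem in about 25 seconds. Study-scale settings (3 × 10⁶, burn-in
5 × 10⁵, thinning 500) are available through `mix_config()`.

### Model comparison

`compare_models()` reports DIC ($\bar D + p_D$, $p_D = \bar D - D(\bar\theta)$),
Akaike weights from ΔDIC, and an approximate R² (squared Pearson
correlation between observations and posterior-mean fitted mixture means).
Pointwise log-likelihood matrices are retained on every fit so external
leave-one-out machinery can consume them; PSIS smoothing is intentionally
out of scope.

## The synthetic-data generator

`sim_config()` defaults encode the study design the package targets:
35 lakes spanning an environmental gradient, 8 consumer taxa spanning
trophic levels 2.1–4.0 (including both baseline taxa, so baselines are
always available), 3 samples per taxon and lake, a global ILR slope of
0.84, and a global intercept of `ilr_transform(0.88)` ≈ 1.41, i.e. 12%
allochthony at covariate zero. Source geometry: water δ²H −60 ± 10‰,
inlet DOM offset −10‰ from water, photosynthetic discrimination −110‰ —
a 100‰ separation between the terrestrial source and the
photosynthesis-adjusted aquatic source. Spatiotemporal source SDs default to
11.2‰ (terrestrial) and 23.6‰ (aquatic): each lake's *realized*
source means are drawn once per lake around the nominal values with those
SDs, mirroring how spatiotemporal source variance actually enters field
data (shared within a lake, not independent per sample). Residual noise on
measured δ²H is 10‰; δ¹⁵N noise is 0.3‰. Covariate values are evenly
spaced over [−3, 3] by default so the slope is identifiable even at small
lake counts (uniform random placement is available).

The generator emulates: the two-source geometry, trophic-level-dependent
water incorporation, a linear allochthony gradient in ILR space with taxon
and lake heterogeneity, and an 18-variable environmental table driven by a
single latent factor (so correlation PCA recovers the gradient on PC1,
with forest cover loading negatively). It does **not** emulate seasonal
turnover, growth dilution, food-web topology, methanogenesis (beyond an
optional flagged δ¹³C signature), or realistic joint distributions of the
environmental variables — the environmental table is a one-factor
construction and claims no realism beyond that. Passing recovery tests
therefore demonstrate the estimator works when its structural assumptions
hold approximately; they cannot certify performance on field data with
unmodelled seasonal or spatial structure.

## Validation design choices

**Parameter recovery** is tested at the full design (35 lakes × 8 taxa × 3
samples, slope 0.84) over 20 simulated replicates at the reduced MCMC
length above. Intercept allochthony medians recover truth to about 0.05
mean absolute error. Slope credible intervals cover the generating value
in most but not all replicates (15/20 in the frozen suite): under the
generator's study-faithful conditions the per-lake *shared* realized source
deviations violate the likelihood's per-observation independence, and the
gradient's upper half sits in the saturated low-allochthony region where
the ILR coordinate is weakly identified, attenuating the slope. Fitting
data generated exactly under the model's own assumptions (independent
source noise per observation, Normal random effects) yields nominal
coverage (15/15 in the calibration experiment), so the shortfall reflects
the deliberate generator–model mismatch, not an estimation defect. The
corresponding acceptance test asserts the stricter 18/20 bound and is
expected to flag this.

**Model comparison** is validated on a design where the covariate genuinely
matters in a way the null model cannot absorb: because the lake random
intercept can soak up any lake-level trend, the information separating the
covariate model is the taxon × covariate interaction, so the comparison
suite simulates heterogeneous taxon slopes (offsets ±0.4 and ±0.15 around
0.84, mirroring the empirical contrast between steeply declining and flat
consumer groups) at 20 lakes × 4 taxa × 3 samples. With homogeneous taxon
slopes DIC separates only weakly — a property of the model structure worth
knowing when interpreting comparisons on real data.

**Omega sensitivity** uses one dataset whose taxon intercept allochthonies
span roughly 10–85%, the kind of spread real consumer groups exhibit; with
the package's default (deliberately tighter) taxon spread, intercepts
compress toward zero under ω = 0.32 and rank order among near-ties becomes
meaningless. Higher assumed ω yields lower absolute allochthony,
especially at high trophic levels: the corrected value moves away from
water by $1/(1-\omega_{compound})$, and with water sitting above both
sources this shifts corrected values toward the aquatic end. Rank order of
taxon intercepts is preserved (Spearman ρ > 0.9 against the base ω = 0.23
fit).

## Numerical choices and degenerate inputs

- ILR boundary compositions (p ∈ {0, 1}) raise errors on the forward
  transform; the inverse saturates smoothly.
- Zero-SD sources are rejected at model-frame assembly; zero spectral
  slopes, nonpositive absorbances in a slope window, constant PCA
  variables, and missing environmental values all raise named errors
  rather than propagating NaN.
- The TL clamp at 1, the methane δ¹³C threshold (−40‰), and the baseline
  resolution order (measured → regression imputation → error, no
  cross-compartment fallback) are fixed, documented behaviours.
- PC1's sign is fixed by forcing the forest-cover loading negative, making
  the gradient run forested → agricultural; orientation is deterministic
  and idempotent. The PCA accepts any ≥ 15 complete numeric columns and
  records the count, rather than hard-coding an 18-variable table.
- Seeds: the generator seeds R's RNG once per simulation; each MCMC chain
  is seeded `seed + chain`, so runs are bit-reproducible and chains are
  independent given distinct seeds.

## Known limitations

- DIC separates nested models weakly when taxon trends are homogeneous
  (see above); LOO-based comparison on the exported pointwise
  log-likelihoods may be preferable.
- The ±13‰ corrected-value uncertainty is treated as a constant
  observation SD, though the true propagated uncertainty grows with
  trophic level; the multiplicative ξ factor absorbs the difference on
  average but not per-taxon.
- Slope estimates attenuate when much of the gradient sits at near-zero
  allochthony (ILR saturation); credible intervals there lean on the
  fixed-effect prior.
- The terrestrial DOM and POM pathways are not separated (their δ²H
  signatures are too similar); no concentration dependence, no informative
  source priors, and no more-than-two-source mixing.
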