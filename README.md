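# critwin

Critical-window analysis of gestational ambient-ozone exposure and term
low birth weight.

## What problem this solves

Epidemiologic studies of air pollution and birth weight usually enter
*trimester-average* exposures as covariates, which can detect that a
trimester matters but not *which weeks*. Entering every weekly exposure
jointly fails for a different reason: weekly ambient ozone averages are
strongly autocorrelated, so the weekly coefficients are multicollinear,
their uncertainty explodes, and signs can flip.

`critwin` implements the Bayesian temporal probit regression that resolves
this. For birth $i$ with binary outcome $Y_i$ (1 = birth weight < 2,500 g
among term births of 37–44 completed weeks), covariates $x_i$ and
standardized weekly ozone averages $z_{ij}$,

$$Y_i \sim \text{Bernoulli}(p_i), \qquad
\Phi^{-1}(p_i) = x_i^T\beta + \sum_{j=1}^{ga_i} z_{ij}\theta_j,
\qquad \theta \sim \text{MVN}\!\left(0,\ \sigma_\theta^2\,\Sigma(\phi)\right),$$

with $\Sigma(\phi)_{jk} = \exp\{-\phi|j-k|\}$,
$\phi \sim \text{U}(0.0001, 3)$, $\sigma_\theta^2 \sim \text{IG}(3, 2)$.
The exponentially correlated prior on the weekly effects $\theta$ borrows
strength across adjacent weeks and tames the multicollinearity; a
*critical window* is a maximal run of consecutive weeks whose 95% credible
intervals exclude zero. Fitting uses truncated-normal data augmentation
with Gibbs updates for $\beta$, $\theta$, $\sigma_\theta^2$ and a
Metropolis step for $\phi$.

Around the model, the package provides:

* **Exposure assignment** from three pollution-metric regimes — a sparse
  monitor network, a complete 12-km grid, and a dense point product —
  using the nearest active source per pregnancy day, an 8.49-km
  eligibility radius (the half-diagonal of a 12-km grid cell), weekly and
  trimester averaging, and pooled standardization.
* **Model comparison**: the structured weekly model vs the conventional
  trimester model vs the naive independent-weekly model, via DIC and the
  effective number of parameters $p_D$, plus cross-metric comparison
  tables (average interval widths, Jaccard overlap of significant weeks).
* A **synthetic-data generator** (cohort, co-registered source layouts,
  spatially correlated AR(1) daily ozone fields, probit outcomes with a
  true elevated window at weeks 20–23 and ~2.3% prevalence) so the whole
  pipeline is testable without confidential birth records.

The methods vignette (`vignettes/critical-windows.Rmd`) documents the
model, the numerical choices and the generator in detail.

## Worked example

Simulate a 10,000-birth cohort, assign dense-metric weekly exposures, and
fit the structured weekly model (test profile: 2,000 burn-in + 2,000 kept
draws, ~30 s total):

```r
library(critwin)
cfg <- generator_config(n_births = 10000, seed = 11)
src <- gen_sources(cfg)
pan <- gen_ozone_panel(src, cfg)
co  <- gen_cohort(cfg)
ex  <- compute_exposure(co, src, pan, "dense")
des <- build_design(co)
co  <- gen_outcomes(co, ex$exposure, des, cfg)
mean(co$outcome)
#> [1] 0.0216
blk <- build_exposure_block(ex$exposure, "weekly_structured")
fit <- run_mcmc(co$outcome, des$matrix, blk$block,
                config = mcmc_config(seed = 5), weeks = blk$weeks)
fit
#> Temporal probit posterior (model 1: weekly_structured)
#>   n = 10000, p = 29, exposure effects = 43
#>   kept draws = 2000, phi acceptance = 0.352
sm <- summarize_windows(fit)
sm[20:23, ]
#>         week median lower95 upper95 significant interval_width
#> week_20   20 0.0745  0.0285   0.138        TRUE          0.110
#> week_21   21 0.0953  0.0446   0.172        TRUE          0.127
#> week_22   22 0.1019  0.0502   0.177        TRUE          0.127
#> week_23   23 0.0909  0.0439   0.162        TRUE          0.118
identify_windows(sm)
#>   start_week end_week sign
#> 1         20       23    1
compute_dic(fit, co$outcome, des$matrix, blk$block)
#> DIC = 1818.65 (p_D = 40.69, Dbar = 1777.96, Dhat = 1737.26)
```

The cohort's outcome prevalence lands at the 2.3% target (2.16% here);
the fit recovers the true susceptible window exactly: weeks 20–23, each
with a positive posterior median around +0.07 to +0.10 per standard
deviation of weekly ozone and a 95% interval excluding zero.

## Analysis workflow

The `analysis/` scripts run the full study on the synthetic data (each
takes an optional seed argument, default 1):

| script | what it does |
| --- | --- |
| `01_simulate.R` | generate cohort, source layouts, ozone fields, outcomes |
| `02_metric_comparison.R` | fit the weekly model under monitor/grid/dense metrics on the common eligible subset and compare |
| `03_extended_fit.R` | full-cohort fit with the dense metric; window plot |
| `04_model_comparison.R` | DIC / $p_D$ for models 1–3 |

Outputs (CSV tables, JSON metrics, a manifest with config hash and
timings) land under `results/`. Everything is also available
programmatically through `run_pipeline()`.

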