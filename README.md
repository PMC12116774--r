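# divscale

Scale-dependent plant-diversity change in standardized nutrient-addition
experiments.

## The problem

Nutrient enrichment usually reduces grassland plant richness inside a single
plot, but what happens *between* plots is less obvious: treated communities
can converge on the same nitrophilic winners (biotic homogenization) or
drift apart as different species drop out in different places (biotic
differentiation). Distinguishing these outcomes requires looking at
diversity at more than one spatial scale at once. `divscale` implements that
analysis for blocked, paired-plot experiments of the NutNet type: each site
has three or more blocks, each block one Control and one fertilized (NPK)
1 m × 1 m subplot, with visually estimated percent cover per species.

## The method

Diversity is measured as Hill numbers
D_q = (Σᵢ pᵢ^q)^{1/(1−q)} (q = 0 richness, q = 1 exponential Shannon,
q = 2 inverse Simpson). For each site and treatment:

- **α** — diversity of each subplot;
- **γ** — diversity of the three subplots pooled;
- **β = γ / mean(α)** — Whittaker's multiplicative partition, the effective
  number of distinct communities: 1 if all subplots share the same species,
  3 if all are completely distinct.

Treatment effects are natural-log response ratios:
Δα = ln(α_NPK/α_Control) paired within block, Δᾱ their mean,
Δγ = ln(γ_NPK/γ_Control), and **Δβ = Δγ − Δᾱ**. Δβ < 0 is homogenization,
Δβ > 0 differentiation, and the signs of (Δᾱ, Δγ, Δβ) classify each site
into one of six scenarios driven by gains and losses of spatially
restricted versus widespread species (sites with any exact zero are
uncounted). Overall and site-level effects come from the hierarchical model
`change ~ 1 + (1 | site)` with weakly informative data-scaled t priors,
fitted by a built-in marginalized Gibbs sampler with split-R̂ convergence
checks (bound 1.03). Site covariates (drought intensity PET/precipitation,
grazing index, species pool, productivity, mean block distance) enter
separate linear regressions, and Moran's I with a permutation test checks
spatial autocorrelation of the site-level changes.

A calibrated synthetic-data generator reproduces the study design (blocks,
paired subplots, restricted/widespread species pools, log-normal covers,
species-group labels) with known true effects, so the whole pipeline is
testable end to end without any field data. See
`vignette("scale-dependent-diversity")` for the full model description and
design choices.

## Worked example

```r
library(divscale)

study <- study_sim_config(n_sites = 24, mu = -0.05, tau = 0.04)
st <- generate_study(study, seed = 2024)

cfg <- analysis_config(q_orders = 0, groups = "all",
                       model = model_spec(n_chains = 4, n_iter = 2000,
                                          n_warmup = 500),
                       seed = 7)
bundle <- run_pipeline(st$table, cfg, site_env = st$site_env,
                       herbivores = st$herbivores)
bundle
#> <result_bundle> groups: all; q: 0; all models converged: TRUE
#> # A tibble: 1 × 9
#>   group     q response      mean  ci_low ci_high max_rhat converged n_sites
#>   <chr> <dbl> <chr>        <dbl>   <dbl>   <dbl>    <dbl> <lgl>       <int>
#> 1 all       0 delta_beta -0.0466 -0.0606 -0.0328     1.00 TRUE           24

bundle$scenario_counts$all$q0$scenario
#>         I        II       III        IV         V        VI uncounted
#>         0         0        21         0         0         1         2

bundle$moran$delta_beta
#> Moran's I = -0.06785 (expected -0.04348 under no autocorrelation),
#> permutation p = 0.67 [two.sided, 999 permutations, n = 24]
```

The simulated truth was a homogenizing overall effect of μ = −0.05 across
24 sites: the fitted overall Δβ is −0.047 with a 95% credible interval
(−0.061, −0.033) that covers the truth and excludes zero, 21 of 24 sites
classify as scenario III (loss of spatially restricted species), and
Moran's I finds no spatial structure in the site-level changes — exactly
what the generating process implies.

A command-line wrapper over the same functions ships in
`inst/scripts/divscale.R` (`simulate`, `run`, `sensitivity` subcommands,
YAML configs; non-zero exit if any model misses the R̂ < 1.03 bound).

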