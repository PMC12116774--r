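---
title: "Scale-dependent diversity change: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-dependent diversity change: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscale)
```

`divscale` analyses how nutrient addition changes plant diversity across
spatial scales in blocked grassland experiments. This vignette documents
the statistical machinery, the defaults and why they were chosen, what the
synthetic-data generator does and does not emulate, and the design
decisions that were genuinely open.

## Data model

The unit of observation is a species-cover record in one 1 m × 1 m subplot:
site × block × treatment (Control or NPK) × treatment-year × taxon, with
visually estimated percent cover. Absence is encoded by absence of a
record, so stored covers are strictly positive, and per-subplot totals may
exceed 100% (multilayer canopies) — the reader never rejects them. Records
violating key uniqueness are an error; records with cover ≤ 0 are dropped
with a warning because they contradict the absence convention.

Sampling effort is standardized by analysing a fixed number of blocks per
site (default 3), taking the lowest block numbers. Block labels are ordered
numerically when all labels parse as numbers and lexicographically
otherwise, with ties kept in first-appearance order — the labels are
assigned by site PIs and the convention simply mirrors "the first blocks".
Sites with fewer blocks than requested are dropped and reported, as are
sites missing a treatment in the analysis year. The default analysis year
is `year_trt = 4`, the earliest year at which all qualifying experiments
have been fertilized for at least four seasons.

Species-group analyses (native/non-native; forb, graminoid, legume, woody)
filter records by their labels and then apply the log(0) guard: any site
where any analysis subplot — either treatment, any selected block — holds
zero matching species is excluded from that group's analysis, because its
log response ratio would be undefined. A subplot with no matching rows at
all counts as empty. Records with `unknown` status belong to the whole
community (`all`) but to no specific group.

## Diversity across scales

Diversity is the Hill number
$D_q = \left(\sum_i p_i^q\right)^{1/(1-q)}$ with $p_i$ the relative cover.
$q=0$ is richness, $q=2$ inverse Simpson; $q=1$ is computed by its analytic
limit $\exp(-\sum_i p_i \ln p_i)$ rather than by numerical limiting, which
keeps the $q \to 1$ continuity property exact to floating-point rather than
approximation error.

Per site and treatment, α is the subplot-level Hill number and γ the Hill
number of the three subplots pooled. For $q = 0$ pooling is the species
union. For $q > 0$ per-species covers are summed across subplots and
renormalized — the standard convention for the multiplicative partition
when subplots are equally weighted sampling units. An incidence-based
pooling would be the one defensible alternative; summed covers were chosen
because they reduce to the union at $q = 0$ and use the abundance
information the covers carry.

β is γ divided by a mean of the α values — the effective number of
distinct communities. Both means are computed:

- **arithmetic** — for richness this is bounded in $[1, n_\text{blocks}]$:
  1 when all subplots share the same species, $n$ when all are distinct.
  This is the interpretable "effective number of communities".
- **geometric** — the variant whose logarithm the log-ratio partition
  decomposes exactly (below).

For $q > 0$ with summed-cover pooling the pooled effective number can fall
below the largest subplot α (pooling can reduce evenness), so the
consistency check γ ≥ max(α) — an invariant, and enforced, at $q = 0$ — is
disabled for higher orders.

## The log-ratio partition and the six scenarios

Treatment effects are natural-log response ratios: per block
$\Delta\alpha = \ln(\alpha_{NPK}/\alpha_{Control})$, their arithmetic mean
$\overline{\Delta\alpha}$, $\Delta\gamma$ analogously at the pooled scale,
and $\Delta\beta = \Delta\gamma - \overline{\Delta\alpha}$. Natural logs
are used throughout; the partition identity is base-invariant, so this is
pure convention. The identity

$$\Delta\beta \;=\; \ln \beta^{geom}_{NPK} - \ln \beta^{geom}_{Control}$$

holds algebraically (both sides equal
$\ln\gamma_{N} - \ln\gamma_{C} - \tfrac1n\sum_b(\ln\alpha_{N,b} -
\ln\alpha_{C,b})$) and is asserted numerically to $10^{-12}$ in the tests.

The sign pattern of $(\overline{\Delta\alpha}, \Delta\gamma, \Delta\beta)$
classifies each site: homogenization ($\Delta\beta < 0$) as scenario I
(both ratios positive), II ($\Delta\gamma < 0 < \overline{\Delta\alpha}$:
restricted species replaced by widespread ones) or III (both negative);
differentiation ($\Delta\beta > 0$) as IV (both negative), V
($\overline{\Delta\alpha} < 0 < \Delta\gamma$) or VI (both positive). A
site with any delta exactly zero lies on a boundary (the 1:1 diagonal for
$\Delta\beta = 0$) and is counted in none of the six. Zero comparisons are
exact floating-point equality, no tolerance band: richness ratios are
ratios of small integers, so a site is on the diagonal precisely when the
ratios are equal, and `log(x) - log(x)` is exactly zero in IEEE
arithmetic. A tolerance would silently reclassify near-boundary sites.
Directional site counts (homogenizing / differentiating / no change) use
the sign of the raw site-level $\Delta\beta$; model-based credible
intervals are a separate, shrunken summary.

## The hierarchical model

Overall and site-level effects come from the random-intercept model

$$y_i = \mu + u_{site(i)} + \varepsilon_i,\qquad
u_s \sim N(0, \tau^2),\quad \varepsilon_i \sim N(0, \sigma^2),$$

fitted separately for each response and each group × order combination:
per-block $\Delta\alpha$ (three observations per site), and per-site
$\Delta\gamma$ and $\Delta\beta$ (one observation per site). Fitting the
per-block α response, rather than collapsing to $\overline{\Delta\alpha}$,
uses the within-site replication to separate $\tau$ from $\sigma$; the
collapsed model is a strict special case and can be had by passing the
site means.

Priors are weakly informative and data-scaled, in the style of modern
mixed-model defaults: $\mu \sim t_3(\mathrm{median}(y),\, 2.5\,
\mathrm{mad}(y))$ and half-$t_3$ priors with the same scale on τ and σ.
When $\mathrm{mad}(y) = 0$ (degenerate all-equal data) the scale falls
back to 2.5 so the prior stays proper. Degrees of freedom, location and
scale are all overridable in `model_spec()`.

The sampler is written in the package. Conjugate Gibbs updates handle μ
(through the latent scale-mixture representation of its t prior) and the
site effects; τ and σ are updated by Metropolis steps on the marginal
posterior with the site effects integrated out, using the exact half-t
densities. Marginalization matters: with one observation per site only
$\tau^2 + \sigma^2$ is well identified, and conditional conjugate updates
crawl along that flat ridge. Two move types fix this — a log-scale random
walk (step 0.3) for the overall level, and an independence proposal on the
variance share at fixed total, which traverses the ridge in one jump. This
weak identification is a property of the model, not the sampler; the
priors do the regularizing, and it is why the β- and γ-scale fits report
wider τ intervals than the α-scale fits.

Defaults are 6 chains × 3000 iterations with 1000 warmup; each chain
initializes μ randomly at a quarter of the prior scale around the prior
centre and derives its own RNG stream from the fit seed, so fits are
exactly reproducible. Convergence is monitored by split-R̂ (each chain halved,
between/within variance ratio) with the acceptance bound R̂ < 1.03
surfaced as a warning and a `converged` flag; the statistic is reported as
`NA` when within-chain variance is zero everywhere (constant draws).
Summaries are posterior means with equal-tailed 95% credible intervals
(2.5/97.5 percentiles), not HPD intervals — equal-tailed intervals are
invariant under monotone transforms of the reporting scale and match
common practice. Site-level estimates summarize $\mu + u_s$ (the site's
expected change), not the deviation $u_s$ alone; the deviation is
recoverable from the draws.

## Site covariates and spatial checks

- **Drought intensity** — mean over experiment years 0–4 of annual
  potential evapotranspiration / precipitation (unitless). The per-year
  ratio is averaged, rather than taking the ratio of sums: the index is
  then the mean annual water-balance stress, invariant to relabeling
  years, and an anomalously wet single year cannot dominate the total.
- **Grazing index** — sum of per-herbivore importance values (1–5, large
  vertebrates only); empty list = 0.
- **Species pool** — distinct taxa in the control plots of the selected
  blocks, years 0–4.
- **Productivity** — mean control aboveground biomass over years 0–4,
  scaled from the 0.2 m² harvest strips to g m⁻² (×5; the factor is a
  visible argument).
- **Mean block distance** — mean of the pairwise great-circle (haversine)
  distances between block coordinates, in meters. Haversine is used even
  though block extents are small enough for planar geometry; it avoids a
  projection choice and differs negligibly at ≤ 12.5 km. Sites lacking
  block coordinates are simply omitted from distance regressions.
  Identical coordinates give 0 and are flagged as degenerate.

Each covariate is regressed separately (ordinary least squares, two-sided
t test on the slope) against $\overline{\Delta\alpha}$, $\Delta\gamma$ and
$\Delta\beta$; no multiple regression and no multiple-testing correction
across the battery, which is reported as is.

Moran's I uses row-standardized inverse-haversine-distance weights with a
zero diagonal — the statistic itself does not fix a weight choice, and
inverse distance is the least-committal continuous option for irregularly
scattered sites. Significance comes from a permutation test (default 999
relabelings, two-sided around the null expectation $-1/(n-1)$), not the
normal approximation, because site counts are modest and the weight matrix
is far from regular. Constant values make I undefined and raise a
degenerate-input error.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the study design so
every downstream stage can be exercised with known truth.

Each site draws a species pool of two occupancy classes: *widespread*
species present in every block and *spatially restricted* species unique
to one block. Control subplots contain their full complement; NPK
subplots are derived by Bernoulli losses (site-wide for widespread
species, independent per block for restricted ones) and by gains from
treatment-only candidate pools (site-wide or block-unique). This two-class
loss/gain mechanism is exactly what makes all six scenarios reachable:
losing restricted species removes proportionally more from γ than from α
(scenario III), losing widespread species the reverse (IV), gains mirror
losses (I, VI), and mixtures produce II and V. `scenario_preset()` returns
configurations tuned, by these mechanisms alone, to hit each target
scenario in ≥ 80% of draws (verified over 200 seeded draws in the tests).

Covers are log-normal (meanlog 1.5, sdlog 1.0), giving percent covers
mostly between 1 and 30 with occasional dominants — realistic relative
structure, deliberately uncalibrated to any real dataset since only
richness and relative cover matter downstream. Species labels are drawn
with 80% native fraction and lifeform probabilities
(forb 0.5, graminoid 0.3, legume 0.12, woody 0.08), loosely matching
temperate grassland frequencies, so group analyses and their exclusion
paths are exercised.

`generate_study()` (default 72 sites, 3 blocks, 12 widespread + 6
restricted species per block) gives each site a target β-scale effect
drawn from $N(\mu, \tau^2)$ — defaults μ = 0.03, τ = 0.05, the
study-level conditions the package is tested under — and realizes it by
calibrated restricted-species losses (negative targets) or gains
(positive). The calibration inverts the *exact* expectation of the
realized $\Delta\beta$ under the binomial mechanism (enumerating
$E[\ln(\text{base} \pm X)]$ for binomial $X$, solved by `uniroot` to
$10^{-10}$), so realized site effects are unbiased for their targets —
the property the parameter-recovery and coverage tests rest on. Targets
beyond the attainable range (roughly −0.51 to +0.31 at the default pool
sizes, > 5 standard deviations out) are clamped. Per-site seeds derive
from the study seed, so any subset of sites is reproducible in isolation.
Site coordinates, per-block coordinates (~1 km scatter), PET/precipitation,
control biomass and herbivore lists are generated alongside to feed the
covariate analyses.

What the generator does **not** emulate: real species identities and
abundance distributions, temporal autocorrelation beyond independent
year-4/year-14 snapshots, observer error, within-year repeat surveys, or
spatially structured site effects. Passing tests therefore demonstrate
that the machinery is correct under the assumed data-generating process,
not that any particular field dataset satisfies those assumptions.

## Numerical choices and degenerate inputs

- Exact zero comparison in the scenario classifier (see above); non-finite
  inputs are an error, not `uncounted`.
- `hill_number` treats `q = 1` within $10^{-10}$ as the Shannon limit.
- Empty assemblages raise an explicit undefined-diversity error — callers
  must have excluded such sites via the log(0) guard.
- The γ ≥ max(α) consistency check applies at q = 0 only (tolerance
  $10^{-9}$ for float-valued callers).
- Model seeds: every chain, every pipeline fit slot and the permutation
  test derive distinct 32-bit streams from the master seed via a fixed
  linear hash, so adding a fit does not shift another fit's draws.
- Regressions with < 3 complete pairs or a zero-variance covariate, and
  Moran's I on constant values, raise errors rather than returning NaN.

## Problem sizes in the test suite

The suite simulates at the study's design scale where the property under
test needs it (72 sites for parameter recovery and coverage, 200 draws per
scenario preset) and at 6–24 sites for pipeline plumbing; model fits in
tests use 2–4 chains of 600–2000 iterations, which the split-R̂ checks
show is ample for this conjugate-dominated sampler. The acceptance script
runs the full default study (72 sites, 6 chains × 3000 iterations).

## Known limitations

- With one observation per site, τ and σ are identified only through the
  priors; their individual posteriors should be read as regularized
  decompositions of the well-identified total variance.
- The multiplicative partition is the only β concept implemented — no
  pairwise dissimilarity (Jaccard, Bray–Curtis) or coverage-based
  rarefaction.
- The reader handles the documented CSV dialect only; genus-level
  aggregation and within-year collapsing are assumed done upstream (a
  max-cover collapse helper is provided).
- Replicating published field results requires the corresponding deposited
  data; nothing in this package substitutes for them.
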