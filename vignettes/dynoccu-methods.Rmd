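---
title: "Seasonal occupancy dynamics from camera traps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal occupancy dynamics from camera traps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dynoccu` implements, end to end, a Bayesian workflow for studying how a
species' use of space changes across seasons when the only field data are
camera-trap detections: detection-history construction, dynamic
(multi-season) occupancy models with covariates, leave-one-out model
comparison, stacking-based model averaging, and derived seasonal
occupancy trajectories. This vignette documents the models, the
numerical choices, and the design decisions behind the package, and what
the simulation-based tests do and do not establish.

## The observation problem

Camera traps record detections in continuous time, but a species can be
present and go undetected. Occupancy models separate the *state* process
(is the site used in a primary period, "season"?) from the *observation*
process (did we detect the species in a secondary occasion, given use?).
Repeated occasions within a season — assumed closed, i.e. the state does
not change within the season — let detection probability $p$ be estimated
and the occupancy estimate corrected for false absences.

Events are first reduced to *independent events*: within each
site–species series, an event is kept only if at least 30 minutes have
passed since the last **retained** event (a sliding anchor, the common
camera-trap convention; the window is measured from the last retained
event rather than the immediately preceding raw trigger, and a gap of
exactly 30:00 minutes is kept). Continuous monitoring is then discretized
into consecutive 5-day occasions anchored at each season's start date,
with half-open day binning `[start, end)`; each season holds 13
occasions, so the default calendar uses 65-day seasons that the occasions
tile exactly. An occasion's *effort* is the number of its days covered by
a camera deployment, counting a partially covered day as covered when at
least 12 hours of it fall within a deployment; an occasion with less than
1 day of effort is treated as not surveyed (`NA`), never as a
non-detection.

## The dynamic occupancy model

For site $i$ with latent occupancy state $z_{it} \in \{0, 1\}$ in season
$t$:

$$
z_{i1} \sim \mathrm{Bernoulli}(\phi_{i1}), \qquad
z_{i,t+1} \mid z_{it} \sim \mathrm{Bernoulli}\!\big(z_{it}(1 -
\varepsilon_{it}) + (1 - z_{it})\gamma_{it}\big),
$$

with first-season occupancy $\phi_{i1}$, local extinction
$\varepsilon_{it}$ and local colonization $\gamma_{it}$ — in a seasonal
space-use study these "extinctions" and "colonizations" are changes in
use, not population turnover. Detections are
$y_{itk} \sim \mathrm{Bernoulli}(z_{it}\, p_{itk})$: no false positives.
Under the original parameterization only the first season's occupancy is
a free parameter; later seasons follow the recursion
$\phi_{i,t+1} = \phi_{it}(1 - \varepsilon_{it}) +
(1 - \phi_{it})\gamma_{it}$.

All four parameters carry logit-linear covariate models. The likelihood
of a site's history marginalizes the latent states exactly by a forward
recursion over $z$: the emission of season $t$ in state 1 is
$\prod_{k:\,y \ne NA} p^{y}(1-p)^{1-y}$ and in state 0 is the indicator
that no detection occurred; transitions use the matrix
$[[1-\gamma, \gamma], [\varepsilon, 1-\varepsilon]]$. Numerical choices:

* The recursion rescales the forward vector each season and accumulates
  the log of the scales, so the returned value is the exact
  log-likelihood without underflow even for long histories.
* `NA` occasions contribute emission factor 1 — inserting an `NA` is
  *identical* to removing the observation, and a season that is entirely
  `NA` leaves the site in the likelihood through its other seasons.
* Probabilities exactly 0 or 1 follow limit conventions rather than
  clipping; an impossible history returns `-Inf` rather than erroring.

Both properties are enforced by tests against a brute-force
latent-state-enumeration oracle and by a normalization check (the
likelihood sums to 1 over all $2^{TK}$ possible histories).

### Covariates

Covariates come in three kinds: site covariates (constant over seasons;
usable on any parameter), season-site covariates (vary by season; used on
the dynamics and detection) and observation covariates (vary by occasion;
detection only, e.g. effort). Continuous covariates are standardized to
mean 0, SD 1 with the *sample* SD over all values entering the model —
after any season subsetting, so the scaling support matches the fitted
data. Categorical covariates use reference-cell coding with the first
level as reference (first season for the season effect; `none` for the
camera field-of-view feature).

The season-site covariate attached to transition $t \to t+1$ is the value
recorded for the interval preceding season $t+1$ (forestry interventions
are surveyed before each season; grazing pressure accumulates over the
interval leading into it). This alignment is a package decision — the
measurement protocol does not force one — and is localized in
`build_model_matrices()` should a different pairing be needed.

## Priors and posterior computation

Intercepts and slopes get independent Logistic(0, 1) priors, weakly
informative on the probability scale; Gamma(1, 1) is reserved for
random-effect standard deviations, though no default candidate model
includes random effects (`log_prior_sd()` exists for completeness). The
posterior is sampled by componentwise adaptive random-walk Metropolis:

* chains initialize at the posterior mode (BFGS on the exact
  log-posterior) plus N(0, 0.1) jitter;
* per-coordinate proposal scales adapt toward 0.44 acceptance during
  burn-in only (Robbins–Monro on the log scale, every 50 sweeps) and are
  frozen afterwards, so the retained draws come from a fixed kernel;
* no thinning — the full pointwise log-likelihood matrix (draws × sites)
  is retained because leave-one-out comparison needs it;
* the default run configuration is 3 chains × 15,000 iterations with
  5,000 burn-in; tests and the bundled demo use reduced budgets
  (e.g. 3 × 2,000) and are validated against deterministic oracles, not
  against run length.

A gradient-based sampler would mix faster per iteration; the contract
here is *valid draws from the posterior*, which the tests check against
deterministic numeric integration on small models, not a specific kernel.
The sampler's inner loop is compiled (C++), and design matrices are
deduplicated to their unique rows (categorical detection structures
collapse tens of thousands of occasion rows to a handful), which is what
makes simulation studies at 500 sites practical.

Convergence uses the split-chain Gelman–Rubin statistic with the working
rule $\hat R < 1.1$ for every parameter; summaries report the posterior
mean, SD and central 95% credible interval, and an effect is flagged
"significant" when that interval excludes zero.

## Model set, comparison and averaging

The modeling procedure has two stages, reflecting that 60 sites cannot
support rich joint models:

1. **Detection.** Candidates combine a season effect with at most one
   other detection covariate (null, season-only, and season + one of
   shrub cover, field-of-view feature, vegetation clearing, effort — 6
   specs), with constant state parameters. The top-ranking model's
   detection terms are carried forward (a single structure, even when the
   runner-up is within 4 elpd).
2. **State parameters.** With detection fixed, candidates cross a
   first-season-occupancy choice (none or one site covariate) with a
   dynamics choice (none, one extinction covariate, or one colonization
   covariate): 25 specs. Each state parameter carries at most one
   covariate, and extinction and colonization are never covaried in the
   same model. The default set allows one $\phi_1$ covariate *and* one
   dynamics covariate in the same model — averaged coefficient tables
   report effects on multiple parameters, which single-covariate models
   alone cannot produce — but a `strict_univariate` mode (one covariate
   in the whole model, 9 specs) is available.

Predictive accuracy is the expected log pointwise predictive density
(elpd) estimated by PSIS-LOO with the site as the cross-validation unit.
The importance ratios' tail is smoothed by a generalized Pareto
distribution fitted with the Zhang–Stephens empirical-Bayes profile
method to the largest $M = \min(0.2S, 3\sqrt{S})$ ratios; smoothed
weights are capped at $S^{3/4}$ times the mean weight. (The
shrinkage-toward-0.5 prior some implementations add to $\hat k$ is
omitted; with thousands of draws its effect is negligible and the raw
estimator is what the sampling-distribution tests check.) The fitted
shape $\hat k$ is the reliability diagnostic: below 0.5 the pointwise
elpd is accurate; above 0.7 importance sampling fails and the *model* is
discarded from the candidate set — the strict "any site above 0.7" rule,
the conservative reading where an aggregate rule was also defensible.

Survivors are ranked by elpd. When all surviving differences to the top
model are below 4 (differences are taken pairwise against the top model),
predictive performance is considered similar and the survivors are
combined by **stacking of predictive distributions**: weights maximize
$\sum_i \log \sum_m w_m \exp(\mathrm{elpd}_{im})$ over the simplex,
optimized through a softmax reparameterization with BFGS from five fixed
starts; models with identical pointwise elpd share their weight equally
(the tie rule). Stacking can never score worse than the best single
model, which is asserted as a test invariant.

Model-averaged inference mixes posteriors: each mixture draw picks a
model with probability equal to its weight, then a uniform retained draw
from that model; coefficients absent from the selected model contribute
**exactly zero**. This is deliberate — it reproduces the characteristic
averaged credible intervals with an endpoint at exactly 0 (a covariate
carried only by models with total weight $w < 0.95$ has its 2.5%
percentile pinned at 0). Seasonal occupancy trajectories push every
mixture draw through the occupancy recursion, average over sites *within*
each draw, and then summarize across draws — sites first, then posterior
uncertainty; the reverse order would understate the interval width of the
across-site mean.

Fits with any $\hat R \ge 1.1$ are excluded from averaging with a
warning. Unconverged fits in a 25-model sweep at reduced budgets are
expected occasionally; production budgets make them rare.

## The synthetic-data generator

Field data of this kind are typically not publicly releasable, so the
generator emulates the study design the analysis assumes and every
downstream stage is tested against it:

* 60 sites, four seasons (wet 2020, dry 2021, wet 2021, dry 2022), 13
  five-day occasions; the calendar anchors wet seasons on 1 October and
  dry seasons on 1 June, 65-day seasons tiled exactly by the occasions
  (month ranges, not exact dates, are what such protocols report — the
  tiling is a package decision).
* Continuous covariates are Gaussian with the field study's reported
  means/SDs — distance to riparian vegetation 753 (664) m, distance to
  grazing-exclusion plots 230 (303) m, perennial-vegetation productivity
  0.08 (0.03), total productivity 115 (18), grazing pressure 6.27 (13.24)
  LSU/area × days, forestry-intervention ratio 0.14 (0.25), NDVI 0.53
  (0.10), NDVI heterogeneity 0.12 (0.04), shrub cover 39 (31) % —
  truncated to natural ranges (percent to [0, 100], NDVI to [−1, 1],
  distances and rates to ≥ 0), since only moments, not shapes, are
  reported. Camera-site features are categorical (`none`/`trail`/`dirt
  road` at 40/35/25% and intact/cleared vegetation at 70/30% — chosen as
  plausible frequencies; they are not reported quantities).
* Generating coefficients act on the standardized scale (per-SD effects)
  and mirror realistic magnitudes: +0.5 of total vegetation productivity
  on first-season occupancy, +0.25 of grazing pressure on extinction,
  constant colonization, and season plus feature-type effects on
  detection (logit intercept −0.4, i.e. detection per occasion ≈ 0.4 at
  the reference level).
* Missingness mimics camera failure: each occasion is lost entirely with
  probability 0.05 (effort 0 → `NA`), and active occasions lose single
  days with per-day probability 0.028, giving mean effort ≈ 4.86 of 5
  days, matching the reported effort distribution.
* The optional event-stream simulator emits Poisson visit times over each
  occupied site-season and adds a geometric number of extra triggers
  within 30 minutes of each visit (cameras fire bursts per passage), so
  the independence filter has real work to do. Camera false-trigger rates
  and the per-visit trigger distribution are not reported quantities;
  the defaults are stated choices.
* One integer seed drives each generator function with a documented draw
  order, so equal seeds give identical scenarios.

What passing tests on these simulations shows: the likelihood is exact,
the sampler targets the right posterior, credible intervals attain
nominal coverage under the generating model, and the two-stage selection
recovers generating structures at realistic effect sizes. What they do
not show: robustness to spatial autocorrelation between sites, closure
violations within seasons, false positives (misidentification),
covariate measurement error, or shapes of covariate distributions beyond
their first two moments — none of which the generator emulates.

## Problem sizes used by the checks

The packaged checks run at deliberately chosen sizes: the likelihood
oracle on 1,000 random designs ($T \le 4$, $K \le 3$); the posterior
oracle against 2-D quadrature at 100 sites; the coverage study at 500
sites × 4 seasons × 13 occasions with 50 replicates and reduced chains
(3 × 1,200); the exact-LOO comparison on a 10-site, single-season model
against 351² quadrature; and the end-to-end demo at the study's 60 sites
with 3 × 2,000 chains. These sizes give stable Monte-Carlo behaviour
while keeping a full run of the suite inside an ordinary coffee break.

## Known limitations

* No random effects in the default candidate models (the prior machinery
  exists; the model builder does not emit them).
* No false-positive observation model, no multi-species dependence, no
  spatial model between sites.
* The random-walk sampler needs its burn-in adaptation; posteriors with
  strong ridges (e.g. detection-occupancy confounding at very low $p$)
  mix slowly and would benefit from longer chains.
* Stage-1 selection commits to a single detection structure; detection
  model uncertainty is not propagated into stage 2.
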