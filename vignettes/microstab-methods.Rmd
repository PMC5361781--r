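---
title: "Quantifying temporal stability of a microbiota: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying temporal stability of a microbiota: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(microstab)
```

## The problem

A healthy adult gut microbiota is compositionally stable over months, while
perturbations — antibiotics, enteric infection, drastic diet change, travel,
chronic conditions such as IBS — destabilize it. `microstab` turns that
qualitative statement into numbers computed from a longitudinal taxa table:
one subject, tens to hundreds of taxa, relative abundances at three or more
timepoints.

Three complementary layers are implemented:

1. **Fluctuation scaling (Taylor's law).** For each taxon, the temporal
   standard deviation scales with the temporal mean as
   $\sigma_i = V \, \bar x_i^{\beta}$. On a log-log plot of
   $(\bar x_i, \sigma_i)$ the community falls on a line whose slope is the
   scaling index $\beta$ and whose intercept is the variability $V$. $V$ is
   the fluctuation amplitude a hypothetically dominant taxon
   ($\bar x \to 1$) would show, making it a direct stability read-out;
   $\beta = 1/2$ is the Poisson universality class, $\beta = 1$ the
   exponential one.
2. **Stochastic community dynamics.** Relative abundances follow a Langevin
   equation with a fitness drift and multiplicative noise,
   $\dot x_i = F_i x_i^{\alpha} + V x_i^{\beta} \xi_i(t) - \phi(t) x_i$,
   whose stationary Fokker-Planck density either has an interior maximum
   (ordered = stable phase) or loses it to noise (disordered =
   noise-induced unstable phase).
3. **Rank stability.** Rank-over-time matrices of the dominant taxa with
   the rank stability index (RSI), rank variability (RV) and difference
   variability (DV), which reveal "rank stability islands" of
   mid-dominance taxa.

Because per-subject values from published sequencing studies require
external downloads, all claims are exercised on synthetic cohorts whose
statistical structure matches what the analysis assumes (see *What the
generators emulate*).

## Estimating Taylor parameters with errors on the mean

Each taxon contributes a point $(\bar x_i, s_i)$ with a standard error of
the mean $\mathrm{SEM}_i = s_i/\sqrt{n}$ attached to the *x* coordinate.
Because the measurement error sits on the independent variable, an
ordinary weighted regression is not applicable. `fit_taylor_xweighted()`
uses a bootstrap-style scheme: in every replicate the mean axis is
perturbed, $x_i^{*} = \bar x_i + v_i$ with
$v_i \sim \mathcal N(0, \mathrm{SEM}_i)$, an unweighted power law is fit
(OLS on log-transformed data by default, appropriate for multiplicative
scatter; Levenberg-Marquardt nonlinear least squares as an alternative),
and the replicate ensemble furnishes the estimates (means), their
uncertainties (SDs), the mean $R^2$, and the empirical correlation between
$V$ and $\beta$.

Choices worth knowing about:

* **Replication budget.** Up to 1000 replicates, early-stopped when the
  running means of both parameters change by less than `rel_tol = 1e-3`
  (checked every 50 replicates after a floor of 200). At 100 taxa this
  takes well under a second.
* **Resampled means below zero** are clamped to $10^{-12}$ before the log
  transform (a redraw strategy is available via `clamp = "redraw"`).
* **Constant taxa** ($s_i = 0$) cannot enter a log-log fit and are dropped
  there; the nonlinear mode retains them.
* **The deterministic baseline** `fit_taylor_inversion()` (invert the
  variables, weight, fit, invert back) is exact on clean data and degrades
  as $R^2$ drops — precisely the regime the bootstrap handles; it serves
  as a cross-check, not the default.
* **$R^2$** is reported in log space (`r2_log`) and, for the nonlinear
  mode, on the original scale too; log space is the headline because the
  fit itself is performed there.

### Short windows: SD bias and SD noise

A sample SD over $n$ timepoints is biased in log space,
$E[\ln s] - \ln\sigma = \tfrac12\left(\psi(\tfrac{n-1}{2}) -
\ln\tfrac{n-1}{2}\right)$, which is $-0.135$ at $n = 5$ (a $-13\%$ bias on
$V$) but under 1% from $n \gtrsim 50$. The headline fit therefore leaves
the observed SDs untouched, while `sliding_taylor()` — whose windows hold
only five points — enables two corrections in its inner fits:
`debias_sd` removes the log-space bias, and `resample_sd` draws each
replicate's SDs from their own sampling distribution
($s^{*} = s\,\sqrt{\chi^2_{n-1}/(n-1)}\, e^{-2b}$, centred in log space),
so the reported window errors include the SD sampling noise that dominates
at that scale. Without them, windowed $V$ estimates are systematically low
and their error bars unrealistically tight.

## Standardizing against the healthy reference

Cohorts from different studies carry different systematics, so subjects
are never pooled raw. Within one study, the healthy subjects define a
reference through inverse-variance weights
$\omega_i \propto 1/\sigma_{V_i}^2$ (normalized to 1): the weighted mean
$\hat V = \sum_i \omega_i V_i$ and the weighted SD
$\hat\sigma_V = \sqrt{\sum_i \omega_i (V_i - \hat V)^2 / (1 - W_2)}$,
$W_2 = \sum_i \omega_i^2$. Every subject maps to
$z = (\mathrm{value} - \hat V)/\hat\sigma_V$ per parameter; by
construction the healthy cloud has weighted mean 0 and weighted SD 1
exactly, and a single healthy subject is rejected because $1 - W_2 = 0$.
Position in the $(z_V, z_\beta)$ plane is summarized by Euclidean radius:
inside the unit circle (the 68% confidence region of the healthy group, a
1-D convention kept for continuity), inside the 98% circle (default radius
2.8, configurable — the exact radius used for that contour is not pinned
down by theory), or outside. $V$ and $\beta$ are standardized
independently; no covariance rotation is applied. The reference's own
uncertainty is not propagated into the per-subject error bars.

## The Langevin model and its stationary density

With normalization drift
$\phi(t) = \sum_j F_j x_j^{\alpha} + \sum_j V x_j^{\beta} \xi_j(t)$ the
composition stays on the simplex; its stationary value is
$\phi_0 = (\sum_i F_i^{1/(1-\alpha)})^{1-\alpha}$. The stationary
Fokker-Planck solution has two branches:

* generic ($2\beta \ne 1 + \alpha$):
  $P_0(x) \propto x^{-2\beta} \exp\!\left[\frac{2F}{V^2}
  \frac{x^{1+\alpha-2\beta}}{1+\alpha-2\beta} - \frac{\phi_0}{V^2}
  \frac{x^{2-2\beta}}{1-\beta}\right]$
* equal ($2\beta = 1 + \alpha$):
  $P_0(x) \propto x^{2F/V^2 - 2\beta} \exp\!\left[-\frac{\phi_0}{V^2}
  \frac{x^{2-2\beta}}{1-\beta}\right]$

The sign of the $\phi_0$ term in the equal branch is negative: that is
what the stationary limit of the Fokker-Planck operator gives, it is the
continuity limit of the generic branch, and it reproduces the analytic
phase line $F_{\mathrm{crit}} = \beta V^2$ for that branch.

Numerics: the density is evaluated on a log-spaced grid over
$(x_{\min}, 1]$ with $x_{\min} = 10^{-8}$ (the density can be
integrable-divergent at 0, e.g. $x^{-3/2}$ for $\beta = 0.75$, so the
physical cutoff matters), normalized by trapezoidal quadrature after
max-log subtraction. The mode solves
$F x^{\alpha} - \phi_0 x - \beta V^2 x^{2\beta-1} = 0$ (the zero of the
log-density derivative) and is refined by root finding rather than read
off the grid.

**Phase classification.** A taxon is in the ordered phase when $P_0$ has a
local maximum at some interior $0 < x < 1$; the maximum can be lost
through either end of the interval, so the implemented criterion is simply
"no interior local maximum". Closed forms for the critical fitness:
$F^2 = 4\beta\phi_0 V^2$ for $\beta = \alpha \ne 1$ (which becomes
$F = 4\beta V^2$, i.e. $3V^2$ at $\beta = 0.75$, when the focal taxon
dominates $\phi_0$) and $F = \beta V^2$ for $2\beta = 1 + \alpha$.
`critical_fitness(method = "bisection")` instead scans for an ordered
fitness and bisects the lower phase boundary — because the ordered region
is an interval in $F$, not a half-line, a naive doubling search can
overshoot it.

**Simulation.** `simulate_langevin()` integrates the community equation by
Euler-Maruyama with the same noise draws in the diffusion term and in
$\phi(t)$ (which keeps $\sum_i \Delta x_i = 0$ exactly per step), then
floors at $x_{\min}$ and renormalizes. Default
$\mathrm{d}t = 10^{-3}/\max F_i$; a step producing $|\Delta x| > 0.5$
aborts with a suggestion to shrink $\mathrm{d}t$.

**Fitness inference.** Assuming the series samples the stationary regime
(the equilibrium reading of the fluctuation-dissipation relation),
`infer_fitness()` maximizes $\sum_t \ln P_0(x_t; F)$ over $F$ on a log
grid. $\phi_0$ is either supplied (preferred whenever the full fitness
vector is known or estimated) or tied self-consistently to $F$ — the
dominant-taxon approximation, appropriate only for taxa that actually
dominate. For a degenerate (constant) series the likelihood still has a
finite interior optimum — the mode location moves together with $F$, so
the density cannot sharpen indefinitely at a fixed point — and the
estimate is then essentially a prior-free extrapolation; the `boundary`
flag marks optima pinned at the search bracket. A moment alternative
(`method = "autocorrelation"`, $F \approx 1/\tau$ from the lag-1
autocorrelation, the relaxation-rate reading of fitness) is provided but
is not the default. `infer_fitness_community()` iterates per-taxon
estimates with a shared $\phi_0$ until self-consistent.

## Rank stability

Taxa are ordered by accumulated relative abundance (the overall rank), the
`top_n = 50` most dominant are kept, and that fixed set is re-ranked at
every timepoint; ties break by overall rank then taxon ID so results are
reproducible, and a taxon absent at a timepoint simply takes the worst
ranks within the set (every column stays a permutation). Per taxon,
$\mathrm{RSI} = \left(1 - \frac{D}{(N-1)(t-1)}\right)^p$ with $D$ the
cumulative absolute rank displacement between consecutive samples — the
only reading under which the two limit cases are exact: a frozen rank
gives RSI = 1, and oscillation between the extreme ranks attains
$D = (N-1)(t-1)$, RSI = 0. The power $p = 4$ stretches resolution among
stable taxa. RV (deviation from the overall order) and DV (deviation from
the previous sample) are averaged over the taxa shown.
`stability_islands()` flags taxa in the middle of the dominance band
(default overall ranks 11–40) with RSI at least 0.70 that beat at least
one more-dominant taxon's RSI.

## What the generators emulate — and what they do not

* `gen_poisson_community()` / `gen_exponential_community()`: independent
  per-taxon draws realizing the two universal classes; means log-spaced
  over several decades mimic real dominance spectra.
* `gen_exact_taylor()`: truncated-normal series obeying
  $\sigma = V \bar x^{\beta}$ by construction — the fixture for validating
  the fitting machinery. Feasibility requires $V\bar x^\beta < \bar x/2$,
  which for $(V, \beta) = (0.135, 0.692)$ bounds the means above
  $\approx 0.015$: the fixture spans under two decades of abundance, not
  the six decades of real communities. Its law lives on the absolute
  scale, so the table is analysed with `check_relative = FALSE` rather
  than re-closed to proportions (closure would rescale $V$ by
  $T^{\beta-1}$ for column total $T$).
* `gen_langevin_cohort()`: multi-subject cohorts integrated interval by
  interval with per-interval noise amplitude (antibiotic courses are
  intervals with elevated $V$), sampled daily, converted to counts by a
  multinomial draw at 50 000 reads to emulate sequencing depth. The
  default template (a few subjects, tens of taxa, ~30 daily samples)
  mirrors the smaller published designs and keeps test runtimes in
  seconds; the problem sizes used by the test-suite experiments (e.g. 20
  taxa × 15 timepoints × 4 subjects for the detection experiment, 50 taxa
  × 100 timepoints for the universality checks) are stated in the tests
  themselves.

None of the generators produce compositional artifacts of 16S profiling,
chimeras, taxonomic misassignment, or long-range temporal correlations
beyond the Langevin dynamics. Passing tests therefore demonstrate the
estimators' correctness under the model's own assumptions, not robustness
to every bias of real sequencing data; read QC, OTU picking and taxonomy
are upstream of this package by design.

## A worked mini-analysis

```{r example}
cohort <- gen_langevin_cohort(
  n_subjects = 3, n_taxa = 30, n_timepoints = 15,
  V = 0.04, depth = 20000, burn_in = 3, steps_per_day = 100, seed = 1)

st <- compute_stats(to_relative(cohort[[1]]))
fit <- fit_taylor_xweighted(st, seed = 1)
fit
glance(fit)
```

```{r phase}
classify_phase(alpha = 0.75, beta = 0.75, F = 1, V = fit$V)
```

```{r ranks}
rep_ <- rank_report(rank_over_time(to_relative(cohort[[1]]), top_n = 20))
rep_
```

## Known limitations

* The stationary-likelihood fitness estimator treats observations as
  independent draws from $P_0$; strongly autocorrelated (densely sampled)
  series will yield overconfident likelihood surfaces, though the point
  estimate remains consistent.
* The bootstrap errors of the headline Taylor fit propagate SEM noise
  only; cohort-level scatter of $(V, \beta)$ across re-generated data is
  larger (about twice as large in the recovery experiments), so reported
  errors should be read as fit precision, not full sampling uncertainty.
* Standardization requires at least two healthy subjects per study, and
  the healthy-zone radii are conventions, not fitted quantities.
* $\beta = 1$ is outside the steady-state machinery (the exponents'
  normalization integrals change form); the Taylor fit itself has no such
  restriction.
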