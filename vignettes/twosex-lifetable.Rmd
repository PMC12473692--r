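---
title: "Age-stage two-sex life tables: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-stage two-sex life tables: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twosexlt)
```

## The data model

The raw input is one row per individual per day of life:
`individual_id, sex, age, stage, alive, eggs`.  Age is in integer days,
0-based, with age 0 the day the egg was laid; a row represents the
end-of-day census state (rearing studies typically census once daily at
a fixed hour).  Stages follow a configurable order — by default egg,
four larval instars, pupa, adult — and validation enforces consecutive
ages, a non-decreasing stage sequence with no re-entry, eggs only from
live adult females, and `"undetermined"` sex only for individuals that
died before pupation, since sexing is morphological at the pupal stage.
When the configured stage list has no `"pupa"` (instars collapsed into a
single larval stage), only the adult stage forces a determined sex.

Removals and escapes are not modeled; a censoring flag in the format is
reserved but rejected by the default validator.  The only tolerated
`alive = FALSE` row is a single terminal one marking the day an
individual was found dead; it contributes to no count.

## The demographic model

All quantities derive from the age-stage count matrix
$n_{xj}$ (adults split by sex) and the cohort size $N$:

- $s_{xj} = n_{xj}/N$, $\;l_x = \sum_j s_{xj}$,
  $\;m_x = \sum_j s_{xj} f_{xj} / \sum_j s_{xj}$ where $f_{xj}$ is the
  mean daily egg output of an individual in cell $(x,j)$;
- $R_0 = \sum_x l_x m_x$, which in this framework equals, exactly, the
  proportion of eggs that become adult females times the mean lifetime
  fecundity per adult female — the package tests this identity on every
  cohort;
- $r$ solves $\sum_x e^{-r(x+1)} l_x m_x = 1$ with age indexed from 0.
  The $(x+1)$ exponent is the Goodman convention used by the
  TWOSEX-MSChart lineage of analyses: a female counted at the end-of-day
  census at age $x$ has her offspring discounted over $x+1$ days.  Using
  $e^{-rx}$ instead would shift every $r$ by a factor $e^{r}$ in the
  discount and is **not** what this package computes;
- $\lambda = e^r$ and $T = \ln R_0 / r$ hold by construction for point
  estimates.  After bootstrap aggregation they need not hold between
  *summaries* (the mean of $e^{r_b}$ is not $e^{\bar r}$), which is why
  the reported table carries each parameter's own replicate summary.

### Transition machinery, $e_{xj}$ and $v_{xj}$

Daily transitions are tallied empirically per occupied cell: stay in
stage, develop to the next stage (pupae develop into adult females or
males, tracked separately), or die.  Because flows only ever go from a
stage to itself or its successor, propagating occupancy forward through
these frequencies reproduces the cohort's observed cell occupancies
exactly.  Two consequences the test-suite relies on:

- life expectancy $e_{xj}$ (propagated from a unit mass at $(x,j)$,
  counting the current day as one) satisfies
  $e_{0,\text{egg}} = $ mean observed lifespan, exactly;
- reproductive value
  $v_{xj} = \frac{e^{r(x+1)}}{s_{xj}} \sum_{i \ge x} e^{-r(i+1)}
  \sum_y s'_{iy} f_{iy}$, with $s'$ propagated from
  $s'_{xj} = s_{xj}$, satisfies $v_{0,\text{egg}} = \lambda$
  algebraically, because from $(0, \text{egg})$ the propagation
  reproduces $l_x m_x$ and the Euler sum is 1.

The day-counting convention (an individual censused alive contributes
its current day) was chosen precisely so these identities are exact; the
alternative "future days only" convention breaks both by one day.
Unoccupied cells are masked (`NA`), never zero-filled — a zero would be
a claim about a state no individual ever visited and would corrupt
plots and summaries.

### Numerical choices

The Euler left-hand side is strictly decreasing in $r$, so the root is
unique whenever $R_0 > 0$.  It is bracketed in $[-5, 5]$ per day
(expanded geometrically in the pathological case), solved with
`stats::uniroot` at tolerance $10^{-14}$, and polished with Newton steps
until the residual is below $10^{-12}$; the acceptance residual bound is
$10^{-9}$.  Negative $r$ is legitimate for $0 < R_0 < 1$; $R_0 = 0$
leaves $r$, $\lambda$, $T$ undefined (an error for point estimates, a
counted missing value inside bootstrap replicates).  $r = 0$ leaves $T$
undefined with an explicit flag rather than an infinity.

Ages beyond the last observed death are truncated; there is no tail
extrapolation.  Collapsing the four instars into one larval stage leaves
$R_0$, $r$, $\lambda$, $T$ unchanged (they depend only on $l_x$ and
$m_x$); the suite runs both configurations and requires identity.

## Bootstrap inference

The resampling unit is the individual egg with its complete life
history, because every parameter is a functional of individual
histories.  Replicate $b$ draws its indices from a stream sub-seeded by
(seed, $b$), so two cohorts bootstrapped with the same seed expose
aligned replicate streams; the paired test differences replicates by
index.  The reported SE is the standard deviation of the replicates —
the convention of the field's reference software; whether published
"±" values are replicate SDs or SEs of means is usually unstated, so
this choice is documented rather than assumed to match any one table.

The paired two-sided p-value is percentile-based with add-one
smoothing, $p = 2\min(\#\{d \le 0\}+1, \#\{d \ge 0\}+1)/(B+1)$, capped
at 1.  The reference software does not document its internal formula,
so the construction is declared and configurable (a normal-approximation
alternative is provided).  Replicates with $R_0 = 0$ are excluded from
$r/\lambda/T$ summaries and their count reported.  The production-scale
default is $B = 100{,}000$; tests and examples use $B = 1000$, at which
CI widths already stabilize to within a few percent.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` is a forward individual-based simulation: discretized
gamma stage durations (shape from a CV, floored at one day, matching
integer daily censusing), stage-specific daily survival applied to each
day's transition (so realized durations are censoring-consistent), sex
assigned at pupation with probability one half, sex-specific gamma adult
longevity, and a lifetime egg total (negative binomial) scattered
multinomially along a triangular daily profile that rises for a few days
after first oviposition and falls to zero over `fall_days`.

The presets encode the three study conditions: stage-duration means,
adult longevities and mean fecundities equal the treatment means of the
source rearing study (e.g. control: egg 3.89 d, larva 11.60 d in four
instars, pupa 5.94 d, female longevity 18.48 d, 147.82 eggs/female), and
a uniform preadult daily survival is back-calculated so expected
egg-to-adult survival matches the observed 62.67% / 36.00% / 37.14%.
Two generator defaults were chosen, once, where the study reports only
aggregate outcomes: the published SEs are standard errors of means, so
individual-level dispersions are not recoverable — the stage-duration CV
(0.25), adult-longevity CV (0.3) and negative-binomial size (20) are
declared defaults of this package, not facts of the study; and the
oviposition profile (start 1 d after emergence, peak 3 d later, decline
over 8 d) was set so that the control preset's $m_x$ peaks near day
24 at a single-digit daily rate, as in the study's fecundity curves.

What the generator does *not* emulate: infection dynamics (treatment
effects enter only through the demographic parameters), density or
resource feedback, day-to-day correlation of oviposition beyond the
triangular shape, mortality concentrated at molts, or within-stage
heterogeneity in daily survival.  Passing tests therefore show that the
estimators recover the parameters of cohorts with this statistical
structure — not that any biological claim about real rearing data is
reproduced.

## Bioassay models

Two distinct models, on purpose, mirroring standard practice: cumulative
mortality over *time* is fit by the three-parameter logistic
$Y = K/(1+e^{a-bX})$ by least squares (assays routinely plateau below
100%, hence the free asymptote $K \le 100$), while endpoint mortality
across *concentration* is fit by maximum-likelihood probit on
$\log_{10}$ dose.  LT₅₀ has the closed form $(a - \ln(K/50-1))/b$ and is
undefined — reason `"asymptote <= 50%"`, the dash of a published table —
whenever $K \le 50$.  Its CI uses the delta method on the $(K,a,b)$
covariance; published LT₅₀ CIs rarely state their method, so no numeric
agreement with any specific table is claimed.  LC₅₀ CIs use Fieller's
theorem (solving the quadratic directly; limits are reported undefined
when the slope is too poorly determined).  Nonlinear starts come from a
log-linearization of interior points; a start landing exactly on a
zero-residual optimum can make Levenberg–Marquardt's gradient check
fail, so the fitter falls back to a jittered restart and then to direct
bounded least squares.

Percentage comparisons use the arcsine square-root transform (defined at
0 and 100%), one-way ANOVA, all-pairs LSD t-tests on the transformed
scale with the pooled error mean square, Holm correction, and a
compact letter display assigned by the insert-absorb sweep over groups
ordered by decreasing mean.

## Problem sizes

Simulated checks run at the study's cohort scale, $N = 100$ eggs per
treatment, with $B = 1000$ bootstrap replicates; coverage uses 200
simulation repetitions, power and ordering 20 paired seeds, and LC₅₀
recovery 100 simulated assays at 80 insects per dose over five
log-spaced concentrations.

## Known limitations

- No BCa or jackknife intervals; percentile intervals only.
- No parametric or continuous-time survival modeling; the engine is
  strictly the empirical daily-census framework.
- The paired bootstrap aligns replicates by index, which is exactly the
  reference software's behaviour but means results depend (reproducibly)
  on the shared seed.
- Proprietary input formats of the reference software are not parsed;
  the canonical CSV is the only interchange format.
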