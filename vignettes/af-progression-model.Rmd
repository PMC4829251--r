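---
title: "A two-state switching model of AF progression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-state switching model of AF progression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afsim)
```

## The model

`afsim` simulates atrial fibrillation (AF) as a binary process: a patient
is either in sinus rhythm (SR) or in an AF episode, and flips between the
two at random times governed by history-dependent hazards. The process is
piecewise-deterministic: between switching events the hazards evolve by
ordinary differential equations with closed-form solutions, and the only
randomness is in the exponential waiting-time draws.

The activation (episode-initiation) hazard has three additive components:

* a constant genetic predisposition `A0`,
* a sigmoidal age/co-morbidity component `A1 / (1 + exp(-(t - tc)/td))`,
  negligible in youth and plateauing at `A1` beyond the centre age `tc`,
* an episode-induced component `Aepi` capturing acute AF-induced
  remodelling: during AF it saturates towards a ceiling `Amax` at rate
  `alpha`, in SR it relaxes to zero at rate `beta`. `Aepi` is continuous
  across switching events.

The recovery (episode-termination) hazard has two components: an
age-related baseline `R0 * exp(-lam * t)` that declines over life, and an
episode-induced component `Repi`. During AF the *total* recovery rate
decays exponentially at rate `mu`; the model assumes `mu > lam`, so
episodes actively erode the ability to terminate. In SR, `Repi` relaxes to
zero at rate `nu`. When an episode ends with `Repi < 0` (the usual case
after a long episode), the component is reflected, `Repi <- -B * Repi`, so
the total recovery rate overshoots its baseline — this is what makes a long
episode be followed by a cluster of short ones.

### The episode-recovery component during AF

The AF-phase dynamics are stated for the *total* recovery rate, not for
`Repi` itself. `evolve_af()` therefore decays the total and recovers the
episode component by subtraction, `Repi = R_total - Rage(t + tau)`. `Repi`
routinely turns negative during an episode; only the total has a biological
meaning and it is kept strictly positive (entering AF with `Repi >= 0`
guarantees positivity throughout, since the total decays continuously from
a positive value and termination happens before it is exhausted or never).
This subtraction convention is the only reading consistent with the boost
rule, which is defined in terms of the sign of `Repi` at termination.

## Parameters

The baseline set, `af_params()`, in internal units (1/yr, 365-day year):

| parameter | value | meaning |
|---|---|---|
| `A0` | 1e-5 | genetic activation; arbitrarily small so age and episode effects dominate |
| `A1` | 2920 | age-related plateau: 8 episodes/day reported in paroxysmal cohorts, times 365 |
| `Amax` | 5840 | episode-induced ceiling: chronic AF roughly doubles tissue vulnerability, so 2 x `A1` |
| `tc` | 70 yr | centre of the incidence sigmoid |
| `td` | 3 yr | sigmoid width (transition over ~±10 yr) |
| `alpha` | 52 | episode activation saturates over ~1 week |
| `beta` | 182.5 | and relaxes over ~2 days |
| `R0` | 6.3072e7 (2 s⁻¹) | newborn peak recovery: shortest possible episode 0.5 s |
| `lam` | 1.2·ln(840)/50 ≈ 0.1616 | age-related recovery decline |
| `mu` | = `alpha` | total recovery degradation in AF tracks `alpha` |
| `nu` | = `beta` | recovery relaxation in SR tracks `beta` |
| `B` | 1 | full reflection of the episode-induced recovery deficit |

Two reading decisions deserve a note. First, the `lam` formula uses the
natural logarithm: the derivation fixes `lam` by requiring a mean episode
duration of 14.4 minutes (864 s) at age 50 starting from 2 s⁻¹ at birth,
which gives `ln(864 x 2)/50 ≈ 0.1491`; the baseline value `1.2·ln(840)/50 ≈
0.1616` is described as slightly larger than this, which is true only under
the natural log. The derived value is exposed as `lambda_derived()` and can
be swapped in via `af_params(lam = lambda_derived())`; the default follows
the baseline table. Second, `R0` is converted from 1/s with a 365-day year
(31,536,000 s), consistent with `A1 = 365 x 8` and with the paroxysmal
threshold being "1% of a day" = 14.4 min.

`mu` and `nu` default to the *current* `alpha` and `beta` arguments, so
`af_params(alpha = 26)` keeps the coupling unless `mu` is set explicitly.
One-at-a-time variants built with `param_variant()` change exactly one
stored field.

## Exact event sampling

The simulator is a modified-Gillespie scheme for time-dependent rates:
waiting times are sampled by drawing `E ~ Exp(1)` and solving
`Lambda(tau) = E`, where `Lambda` is the cumulative hazard from the current
state.

* **SR.** The activation hazard integrates in closed form; the sigmoid term
  integrates to a difference of softplus functions, evaluated as
  `x + log1p(exp(-x))` for positive `x` to avoid overflow (the argument
  reaches `(100 - 70)/3 = 10` within the horizon and far beyond it in
  variant scans). `Lambda` is strictly increasing and unbounded (for
  `A0 > 0`), so the root is unique; it is found by geometric bracket
  expansion from the constant-rate guess `E/A(t)` followed by
  Newton-with-bisection safeguards, to a residual below `1e-9·max(1, E)`.
* **AF.** The total recovery rate decays exponentially, so the cumulative
  termination hazard is *bounded* by `R_enter/mu`. A draw at or beyond the
  bound means the episode never self-terminates; this is returned as an
  explicit `Inf` ("never") sentinel, not an error — it is the modelled
  route into permanent AF, and the simulator records a censored episode
  ending at the horizon. Below the bound the inversion is exact:
  `-log1p(-mu*E/R_enter)/mu`.
* A waiting-time floor of 1e-12 yr (~32 µs) guards against zero-length
  waits from floating-point underflow; at baseline the shortest physical
  episodes are ~0.5 s, four orders of magnitude above the floor.
* An episode whose sampled termination falls beyond the horizon is
  likewise recorded as censored at the horizon: by the stage definitions an
  episode that continues to the end of the simulation is permanent AF,
  whether or not it would eventually have terminated.

The event loop is compiled (Rcpp) because baseline lives hold ~10⁴
episodes and variant scans up to ~10⁵ per patient. It draws its
exponentials from R's RNG, so `set.seed()` semantics apply unchanged; the
test suite replays the compiled loop event-for-event through the exported R
functions (`evolve_sr()`, `invert_sr_hazard()`, …) on a shared seed, and
checks it distributionally against an independent Lewis–Shedler thinning
simulator (`thinning_oracle()`), which is kept in pure R and is not part of
the production path.

Initial conditions are `S = 0`, `Aepi = 0`, `Repi = 0` at birth: the
simulation starts before any AF history exists, and nothing else would be
consistent with the components' definitions.

## What the generator emulates — and what it does not

Ensembles emulate the study conditions of the source analyses: identical
parameters for every patient (no parameter heterogeneity — differences
between lives are purely stochastic), no mortality before age 100, no
interventions, cardioversion or drugs, and *complete observability*: every
episode, however short, is recorded. Real clinical data differ on each
point, most importantly detection — short asymptomatic episodes are
routinely missed, so simulated onset ages are systematically earlier than
diagnosis ages. Passing tests therefore validate the mathematical model
and its sampling scheme, not clinical calibration.

## Classification and metrics conventions

* Stage onsets are timed at `episode start + threshold` — the earliest
  moment the criterion is knowable. The alternative (episode end) differs
  by at most the episode duration; at the annual resolution of the
  population summaries the choice is invisible for the 14.4-min threshold.
  A censored episode at least as long as a threshold also qualifies for it.
* Persistent AF (7-day threshold) is computed by `classify()` but not used
  in the headline population summaries, mirroring the source study's focus
  on paroxysmal and permanent AF; it is available in `tidy(ensemble)`.
* In principle a patient whose *first* 14.4-min episode is the final
  censored one would get a paroxysmal onset 14.4 min *after* their
  permanent onset; this cannot happen at baseline (short episodes always
  precede the permanent one) and `classify()` reports the rule-derived
  values without clamping.
* Burden attributes AF time to windows by exact interval overlap; episode
  counts attribute each episode to the window containing its start. A
  "month" window is 30 days; a year is 365 days.
* Curves aligned to paroxysmal onset use whole annual windows forward from
  each patient's own anchor, then average per relative-time bin over the
  patients that have that bin. Curves aligned to permanent onset use a
  sliding 12-month window stepped monthly, labelled by years before the
  anchor (window `[anchor - s, anchor - s + 1)` for `s = 1, 13/12, …`).
  Standard-deviation bands are population sds, not standard errors.

## Problem sizes and reproducibility

Desk-scale runs use 500 patients for baseline cohort statistics and 100
sample paths per variant for the parameter experiments (the package's
default choice balancing Monte-Carlo error against runtime; onset-age means
at n = 500 are stable to ~0.3 yr across master seeds). Per-patient seeds
are spawned from the master seed by one `sample.int()` call, so ensembles
are reproducible, order-independent, and identical across parameter
variants — variant comparisons in `oat_scan()` and `fig7_experiment()` are
paired by construction, and any single patient can be re-simulated in
isolation from their recorded seed.

## Known limitations

* No mortality, interventions, detection model, or per-patient parameter
  heterogeneity (see above).
* The dispersion of episodes within a window ("AF density"-style measures)
  is not implemented; burden and counts do not distinguish clustered from
  evenly spread episodes within a window.
* `validate_params()` enforces the structural constraints (`mu > lam`,
  `Amax >= A1`, positivity); deliberate constraint-breaking variants are
  allowed with a warning (or `quiet`/`check = FALSE`), since the
  sensitivity scans intentionally cross these boundaries (e.g. `Amax` x
  0.1).
* Extreme variants (e.g. recovery rates scaled far down) can generate
  ~10⁵–10⁶ episodes per patient; `max_episodes` caps runaway runs with an
  informative error rather than exhausting memory.
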