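---
title: "Modelling persistent conduct disorder and the economics of parenting programmes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling persistent conduct disorder and the economics of parenting programmes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdsavings)
```

## The question

Clinical conduct disorder in a 5-year-old often persists: roughly half
of affected children still show clinical-level problems in adulthood,
at great cost to health services, social care, education, the criminal
justice system and crime victims. Parenting programmes are a
comparatively cheap, evidence-based intervention. This package
implements a deterministic Markov cohort model that asks: if one family
receives a programme when the child is 5, how much less likely is
persistence at each later age, and what is that worth, sector by
sector, in discounted pounds?

It is a cohort-probability model, not a microsimulation: the state of
the model at each age is a single number, the probability that the
child is still in the clinical range.

## Natural course

The backbone is a persistence curve for a reference cohort clinical at
age 3, anchored at published points — all clinical at 3, 60% at 8, 50%
continuing into adulthood — with straight lines between anchors and a
constant level beyond the last:

```{r}
course <- natural_course()   # anchors (3, 1.00), (8, 0.60), (16, 0.50)
proportion_at(course, c(5, 8, 16, 25))
```

Two placement choices deserve comment.

* **The adulthood anchor sits at age 16.** "Adulthood" is not a single
  age; 16 is the choice under which the published untreated figure —
  about 59% persistence beyond 16 for a child clinical at 5 — follows
  exactly from the anchors (0.50/0.84 = 0.595). It is also the last age
  before the adult cost band applies, so the curve and the cost table
  change regime together.
* **Constant beyond the last anchor.** Persistent conduct disorder is
  treated as absorbed into adulthood: no further resolution after 16.
  This matches the flat adult (17+) cost assignment.

A trajectory for a child clinical at age 5 is the conditional slice of
this curve; conditioning on age 5 (rather than 3) restricts the cohort
to children whose problems have not already resolved:

```{r}
ctrl <- natural_trajectory(course, start_age = 5, horizon = 25)
truncate_pct(persistence_beyond(ctrl))   # 59
```

Headline percentages are **truncated** (floored), not rounded: the
computed endpoints 59.5%, 54.5% and 57.4% are reported as 59, 54 and
57, and truncation is the only convention that reproduces all three.

## The intervention mechanism

Three parameters define a scenario (`scenario_params()`), all
dimensionless fractions:

| parameter | base | best | worst | meaning |
|---|---|---|---|---|
| drop-out *d* | 0.44 | 0.06 | 0.60 | families starting but not completing; they receive no effect and are not replaced |
| effectiveness *e* | 0.34 | 0.68 | 0.20 | relative reduction in the age-5→6 conditional persistence among completers |
| recidivism *ρ* | 0.50 | 0.00 | 0.50 | fraction of intervention-attributable improvers reverting one year after the effect year |

With *p₁* the natural age-5→6 conditional persistence and *q* the
natural age-6→7 step:

1. year 1: clinical share *c₁* = *p₁*(1 − (1 − *d*)*e*);
2. year 2: improvers *x* = *p₁* − *c₁*; share
   *c₂* = min(*c₁q* + *ρx*, *p₁q*);
3. later ages: *c₂* times the natural conditional persistence from age
   7 onward — children who remain clinical keep their natural chance of
   spontaneous resolution.

Effectiveness is applied **multiplicatively** to the single first
transition, i.e. as a relative ("over and above the control group")
reduction. That is the natural reading of an effect expressed as a
percentage reduction in the probability of persisting to the next
period, and the only one that reproduces the published endpoints.

The min(·, *p₁q*) cap is a deliberate repair of a corner case: without
it, full recidivism (*ρ* = 1) would overshoot the natural course,
because reverters would rejoin the clinical pool without having been
exposed to the natural chance of resolution at the second step. With
the cap, two exact identities hold: *ρ* = 1 restores the natural
trajectory from age 7 onward, and the intervention trajectory never
exceeds the natural one anywhere in parameter space. The cap is
inactive for every scenario in the sensitivity set, so it changes no
reported figure.

Two further structural notes:

* **Monotonicity.** Trajectories are non-increasing in age *except*
  possibly at the single recidivism step: the base case itself rises
  slightly from 0.7325 (age 6) to 0.7415 (age 7) as reverters rejoin.
  This bump is intrinsic to the mechanism, so the package's property
  tests assert monotonicity away from that one step, plus dominance by
  the natural course everywhere.
* **Exact no-effect identities.** When no completer benefits (*e* = 0
  or *d* = 1) the function returns the natural trajectory object
  itself, so downstream savings are identically zero rather than
  zero-up-to-rounding.

```{r}
base <- intervention_trajectory(course, scenario_set()$base)
truncate_pct(persistence_beyond(base))   # 54
```

The best-case scenario (*d* = 0.06, *e* = 0.68, *ρ* = 0) yields an
endpoint near 21% under this mechanism. The published best-case figure
is 17%, and no reading of the mechanism we attempted reproduces it; the
best case is therefore excluded from exact checks and reported as
computed. Base and worst cases reproduce the published 54% and 57%
exactly.

## Effectiveness from trial summary statistics

The effectiveness parameter originates from parallel-arm trials
reporting post-treatment Eyberg Child Behaviour Inventory intensity
(ECBI-I) means and SDs. The estimator assumes scores in each arm are
**Normal** with the reported moments — the minimal defensible
distributional assumption, and one that gives a closed form: the
fraction of an arm above the clinical cut-off (126; strictly above,
ties having measure zero under a continuous model) is a Normal
upper-tail probability. A seeded Monte Carlo route (default 100,000
draws) is provided and converges to the closed form, which serves as
its oracle in tests.

Trials enter only if the control arm's mean stays above the cut-off
post-treatment and the total sample is at least 20. The per-trial
effect is the difference in clinical fractions; the model consumes the
**relative** reduction (absolute reduction over the control fraction),
which is also what the generator in the next section holds fixed. The
published pooled values (34%, range 20–68%) rest on an unpublished
per-trial dataset and are consumed here as scenario parameters; the
estimator itself is exercised on synthetic trials.

## Synthetic inputs

Two generators make every stage testable without restricted data. Both
are deterministic given their seed.

**Crime-cost schedule.** Annual crime-related costs given clinical
conduct disorder, ages 10–25, in four components (criminal justice,
victim, lost output, other). The per-age source data are not
redistributable, so the generator emulates their structure: a
discretised gamma-shaped age profile with its mode at 18 (offending
peaks in the late teens), multiplicative log-normal noise (SD 0.1) on
the profile, component shares proportional to the published base-case
present-value rows, and a nominal £60,000 total ahead of calibration.
`calibrate_to_pv()` then rescales each component by a single factor so
that its discounted present-value saving under a given trajectory pair
equals a target — exact, because PV is linear in costs. The default
pipeline calibrates to the published base-case crime rows (£2,842
criminal justice, £7,468 victim, £2,197 lost output, £906 other).
Calibration, not the shape, carries the quantitative burden; the shape
only affects *timing*-sensitive outputs (break-even years, below).

**Trial tables.** Control-arm moments are drawn uniformly (means
135–160, SDs 20–35, arm sizes 15–60 — typical of clinical-range
parent-training trials), and the intervention mean is solved so the
closed-form relative reduction equals the requested true value exactly
before noise. Sampling noise is added at the summary-statistic level
(mean ∼ Normal(μ, σ²/n); SD from a scaled chi distribution); control
arms are redrawn in the rare case the observed mean falls at or below
the cut-off, so every generated trial passes the eligibility filter.
Parameter-recovery tests pool 50 such trials and recover the generating
reduction within three standard errors.

What the generators do **not** emulate: real trial-set heterogeneity
(non-Normal score distributions, correlated arms, publication
selection) and the true age profile of offending costs. Passing tests
therefore demonstrate that the estimator and the costing machinery are
correct and internally consistent, not that the published parameter
values are right.

## Economics

Costs accrue while clinical: expected annual cost in a sector is
P(clinical at that age) × the sector's annual cost, so savings are the
control-minus-intervention probability gap times cost. The service cost
table (2008/09 GBP, inclusive age bands 5–10 / 11–16 / 17+) and the
crime schedule together give eight saving streams; NHS, social
services, education and criminal justice form the public-sector
perspective, the rest accrue to wider society.

Discounting is annual at 3.5%, with the intervention year as period 0,
undiscounted; the first savings year is period 1 (age 6). This timing
is what makes the first-year net public position negative — a small
first-year saving against the full up-front cost. Programme costs are
group £952 / individual £2,078 per participant, mixed 80/20 to £1,177;
`mixed_cost()` returns whole pounds, the convention used by every
published net figure. Reports round pounds at formatting only; totals
are exact sums of unrounded PVs, and ratios are shown to one decimal.

`break_even_year()` returns the first year in which cumulative
discounted public-sector savings reach the programme cost (year 0 for a
zero cost; NA if never within the horizon).

### What is and is not reproducible

The published per-sector present values cannot be derived from the
published inputs alone: the service rows rest on per-age cost schedules
(for ages 11–30 especially) that are summarised only coarsely in the
age-band table, and the crime rows on the restricted schedule. The
package therefore reproduces, by direct computation:

* the persistence endpoints (59/54/57, exactly);
* the provision-mix cost (£1,177) and all NPV/return arithmetic on the
  published totals (savings report identities);
* the crime-component PVs, by calibration (within 0.5%, in practice to
  numerical precision).

Computed from the published age-band table, the service-sector PVs come
out substantially smaller than the published rows (e.g. NHS £489 vs
£2,195), so computed public totals are conservative. One consequence is
visible in break-even years under the default calibrated schedule:
group provision breaks even in year 7 and the 80/20 mix in year 8 —
inside the published 5–8-year window — while individual-only provision
takes 12 years against its £2,078 cost, outside it. This is a data
limitation, not a mechanism difference, and the corresponding check is
left failing rather than papered over: matching it would require either
inflating service costs beyond the published table or front-loading the
crime schedule against the known age profile of offending.

## Numerical and design choices

* Ages are integers, periods annual; defaults start age 5, horizon 25
  (ages 5–30). These are also the problem sizes used throughout the
  test suite; every deterministic check runs in well under a second.
* Probabilities are clamped to [0, 1] after each arithmetic step to
  guard degenerate parameter combinations.
* Truncation (floor) for headline percentages, with a 10⁻⁹ epsilon
  against floating-point representation of exact percents.
* The worst-case recidivism rate is 50%, following the sensitivity
  table over conflicting prose; only that value reproduces the
  published worst-case endpoint.
* Calibration is per-component linear rescaling against the base-case
  trajectory pair; the same calibrated schedule is reused for every
  scenario so cross-scenario comparisons share inputs.
* Configuration is a single YAML document (`default_config()`,
  `read_config()`, `write_config()`); all published defaults are
  packaged so `run_scenario(default_config(), "base")` needs no
  arguments, and identical configurations produce byte-identical CSV
  outputs.

## Limitations

Beyond the reproducibility gaps above: the model excludes cost domains
with insufficient evidence of programme impact (adult earnings and
unemployment, social security, parental and sibling spillovers, excess
mortality), so savings are conservative in scope; sub-clinical conduct
problems are out of scope; effectiveness is a single first-transition
multiplier with no decay structure beyond one recidivism step; and the
sensitivity analysis is deterministic (scenario grids), not
probabilistic.
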