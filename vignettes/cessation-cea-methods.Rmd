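---
title: "Methods: a Markov cohort model for smoking-cessation economics in cancer care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model for smoking-cessation economics in cancer care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cessim)
```

## The decision problem

Roughly one in five newly diagnosed cancer patients smokes, and continued
smoking after diagnosis worsens treatment response, raises the risk of
recurrence and second primaries, and shortens survival. Cancer programs
therefore face a concrete budgeting question: is it worth upgrading a
*basic* cessation service (screening for tobacco use, brief advice,
referral) to a *best-practice* program that adds pharmacotherapy
(varenicline, 12 weeks), weekly nurse counseling, and follow-up?

`cessim` answers this with a cohort-level decision model. Two identical
cohorts of 65-year-old current smokers with cancer are pushed through the
same disease/behaviour process, differing only in the cessation program
applied in the first year(s); the difference in their discounted lifetime
costs and quality-adjusted life-years (QALYs) yields the incremental
cost-effectiveness ratio (ICER),

$$\mathrm{ICER} \;=\; \frac{\Delta C}{\Delta E}
  \;=\; \frac{C_{\text{best}} - C_{\text{basic}}}
             {E_{\text{best}} - E_{\text{basic}}},$$

reported per QALY and per (unweighted) life-year, from a single
healthcare-payer perspective in 2015 Canadian dollars.

## Model structure

The model is a Markov cohort simulation with yearly cycles from age 65 to
age 100 (35 cycles). Clinically there are three states — current smoker,
former smoker, dead — but the annual probability of relapse depends on
how long ago a former smoker quit (0.24/yr in years 1–2 down to 0.005/yr
beyond year 10). Duration-dependence is incompatible with a memoryless
state, so the former-smoker state is expanded into one-year *tunnel*
compartments grouped into the five published relapse bands (1–2, 3–4,
5–8, 9–10, 10+ years since quitting). Relapsers re-enter smoking through
a separate compartment (`S_rel`) that behaves exactly like the smoker
state for mortality, costs and utilities but is only ever eligible for
background self-quitting: the program is a one-time offer. With the
absorbing dead state this gives the 14-state space of `state_space()`.

Within a cycle, events are ordered deterministically: death is applied
first from every living state, then quitting or relapse among survivors.
Any fixed order conserves probability; fixing one makes every transition
probability an explicit product and every test reproducible.

The quit schedule per arm:

| cycle | basic | best practice |
|---|---|---|
| 1 | 0.04 (12-month abstinence) | 0.24 (12-month abstinence) |
| 2 | 0.015 (self-quit) | 0.02 (program effect, year 2) |
| 3+ | 0.015 | 0.015 |

A switch (`year2_program_quit_both_arms`) extends the year-2 program
effect to the basic arm for scenario exploration; it is off by default.

## Mortality: from a life table to status-specific death probabilities

Published all-cause life tables do not distinguish cancer patients or
smoking status, so `derive_adjusted_mortality()` builds the needed
surface in steps:

1. take the sex-specific annual death probability $q(a)$;
2. take the fraction of deaths at each age attributable to cancer,
   $f(a)$;
3. convert to hazards, $m(a) = -\ln(1-q(a))$, and split:
   $m_{\text{ca}} = m f$, $m_{\text{other}} = m (1-f)$;
4. form the never-smoker *cancer-patient* baseline by scaling the cancer
   component with a multiplier $k \ge 1$ (default 1.25), standing in for
   the excess cancer mortality of a diagnosed cohort over the general
   population;
5. apply the smoking-status hazard ratio (current vs never 1.50, former
   vs never 1.30) on the hazard scale;
6. convert back, $p = 1 - e^{-h}$.

Two points deserve emphasis. First, hazard ratios act on hazards, never
on probabilities: $1 - e^{-\mathrm{HR}\,m}$ cannot exceed 1 and matches
the proportional-hazards meaning of a published HR, whereas multiplying
probabilities can. Second, the *scope* of the HR is a genuine modelling
choice. The packaged default (`hr_scope = "non_cancer"`) applies the HR
to the non-cancer hazard only,

$$p(a, s) = 1 - \exp\!\big(-\mathrm{HR}_s\, m_{\text{other}}(a)
  - k\, m_{\text{ca}}(a)\big),$$

on the reading that a smoking-status HR estimated within a cancer cohort
captures excess tobacco-related (largely non-cancer) mortality, while
the cancer-death component is shared by both statuses. The alternative
(`hr_scope = "all_cause"`) scales the whole baseline. The non-cancer
scope is the default because the all-cause scope roughly doubles the
incremental life-year gain, which drags a proportionally large
annual-cancer-care cost into $\Delta C$ and pushes the base-case ICER
well above the $2{,}000$–$10{,}000$ \$/QALY region that this class of
intervention occupies; the non-cancer scope keeps the incremental
surface in that region. The two scopes coincide when $f \equiv 0$,
which is how the closed-form unit tests pin both.

Mortality depends on attained age but not on time since diagnosis: a
single lifetime HR per status drives the adjustment, which extrapolates
a 12-month estimate over the horizon and is a recognised limitation.

## Synthetic life tables

`make_life_table()` generates the two mortality inputs from a Gompertz
law, $h(a) = \alpha e^{\beta a}$, $q = 1 - e^{-h}$, with a closure row
$q(110) = 1$ so the cohort is always absorbed even if the horizon is
extended. `make_cause_split()` interpolates the cancer share of deaths
linearly from age 65 to 110, reflecting the shift of extreme-old-age
mortality toward non-cancer causes. Optional seeded lognormal noise
(σ = 0.03) mimics the year-to-year roughness of real tables, with
monotonicity restored by a cumulative maximum.

The defaults — male $\alpha = 3\times10^{-5}$, $\beta = 0.085$; female
$\alpha = 1.3\times10^{-5}$, $\beta = 0.095$; cancer share 0.45→0.15
(male) and 0.40→0.12 (female); $k = 1.25$ — were chosen once, jointly,
so that three conditions hold simultaneously: undiscounted life
expectancy at 65 sits in a plausible human band (24.7 years both
sexes), the basic-arm *discounted* life expectancy of the adjusted
cancer-smoker cohort lands near published cancer-cohort values (12.0
male, 12.2 female), and the female table has lower early-age mortality
than the male. They are calibration conveniences, not estimates of any
national population.

What the generator does *not* emulate: period-vs-cohort life-table
methodology, graduation/smoothing artefacts of official tables,
cancer-type and stage structure, and any correlation between the cause
split and the life table. Consequently the package's *absolute* totals
(expected lifetime cost near \$306k, 7.4–7.5 QALYs) are properties of
the synthetic inputs; results that survive replacement of the life
table — incremental signs, orders of magnitude, engine identities,
probabilistic conclusions — are what the test suite asserts.
`read_life_table()` accepts real agency exports reshaped to `age,q` for
users who want absolute numbers under official mortality.

## Costs, utilities, discounting

Per cycle, survivors accrue: the annual cancer-patient healthcare cost
(\$25,058, both arms, switchable off via `include_cancer_cost`), the
smoking-attributable annual cost (\$403, current smokers only — former
smokers drop it immediately, an assumption discussed below), and at
cycle 1 the one-time program cost charged to the whole entering cohort
(basic \$16; best practice \$47 administration + \$105 nurse counseling
+ \$150 varenicline = \$302, i.e. every participant is assumed to fill
the prescription and attend follow-up). QALYs weight the alive fraction
by sex/age-band/status EQ-5D utilities (e.g. male current smoker 65–74:
0.7551) minus a 0.12 cancer decrement.

Costs and outcomes are discounted at 5%/yr; cycle $t$'s payoffs are
discounted by $(1+r)^{-t}$, and the one-time program cost is charged
undiscounted at entry. No half-cycle correction is applied by default
(`half_cycle_correction = TRUE` averages each cycle's start and end
occupancy instead); with yearly cycles and a differenced two-arm
comparison the correction largely cancels.

## Incremental analysis

`compute_icer()` classifies dominance before reporting any ratio and
reports ICERs only for genuine trade-offs (both incrementals positive,
or both negative). Cost-effectiveness at a willingness-to-pay threshold
$\lambda$ is decided by the sign of net monetary benefit,
$\mathrm{NMB} = \lambda\,\Delta E - \Delta C$, not by comparing a ratio
to $\lambda$ — the NMB rule remains correct for cost-saving
(southeast-quadrant) draws where the ratio misleads. Reported ICERs are
rounded to the dollar; unrounded values are retained in `glance()`.

## Deterministic sensitivity analysis

`one_way_tornado()` re-runs the full male base case twice per parameter
(at its lower and upper bound, all else at base) and sorts by the
absolute ICER swing. The time-horizon row truncates the run to 2 and 4
cycles. An endpoint at which the comparison stops being a trade-off
(e.g. the former-smoker HR at its upper bound 1.81 exceeds the
current-smoker HR 1.50, so quitting loses QALYs) is flagged as
dominant/dominated rather than forced into a number. Whether the
base-case ICER is bracketed by the endpoints is checked per parameter
and reported (`brackets_base`), not assumed.

## Probabilistic sensitivity analysis

Each parameter with a published range is given a distribution fitted by
moment matching with $\mathrm{SE} = (\text{upper}-\text{lower})/(2
\times 1.96)$ — i.e. ranges are read as 95% confidence intervals:

* **gamma** for costs (skewed, non-negative): shape
  $= \text{base}^2/\mathrm{SE}^2$, scale $= \mathrm{SE}^2/\text{base}$,
  so the mean equals the base value;
* **beta** for probabilities and the cancer utility decrement, matched
  to the same mean/variance, with a point-mass fallback (and warning)
  if the implied variance is infeasible;
* **lognormal** for the two hazard ratios, $\mu = \ln(\text{base})$,
  $\sigma = (\ln \text{upper} - \ln \text{lower})/(2\times 1.96)$ — the
  base value is the *median*, the standard reading of an HR with a CI;
  the test suite checks the empirical mean against
  $e^{\mu + \sigma^2/2}$, not against the base.

The age/sex/status utilities have no published ranges and stay fixed.
Parameters are sampled independently, with one deliberate exception:
the two hazard ratios are driven by a single uniform quantile
(`couple_hrs = TRUE`, the default). Sampled independently, about one
draw in eight inverts the HR ordering (former above current), scattering
points into the west quadrants; rank-coupled, inversion is confined to
the far upper tail (the former-smoker lognormal has the larger σ, so
the two quantile curves cross near $z \approx 1.8$) and the incremental
cloud reproduces the expected northeast/southeast picture. 10,000 draws
run both arms through a draw-vectorised engine (the same recurrences as
`run_cohort()`, applied to draw-long vectors) in a few seconds; a
degenerate all-fixed draw is tested to match the scalar engine exactly.
Draws that would produce an invalid parameter are rejected and redrawn
with a logged count; with these families the count is structurally zero,
and the guard exists to keep the contract explicit.

## Numerical choices and degenerate inputs

* Row-stochasticity of every transition matrix is asserted to 1e-12;
  the engine-vs-matrix-power identity to 1e-10.
* The closure row $q = 1$ is handled by capping the hazard at
  $-\ln(10^{-12})$ rather than propagating infinity.
* A zero Gompertz slope is allowed (constant mortality, useful in
  tests); negative slopes and non-positive baselines are rejected.
* A zero discount rate collapses the discounted and undiscounted
  ledgers exactly; a frozen cohort (no deaths, no transitions)
  reproduces the 35-term geometric series
  $\sum_{t=1}^{35} 1.05^{-t} = 16.374$ to 1e-9.
* Problem sizes: 35-cycle runs, 14 states, 10,000 PSA draws, 100,000
  draws per sampler-mean check — small enough that the full suite runs
  in well under a minute, large enough that Monte-Carlo assertions use
  2% tolerances.

## Known limitations

* Absolute cost/QALY totals depend on the synthetic mortality inputs
  and on unstated timing conventions (half-cycle, cost timing), and are
  not comparable to any official-statistics run without real tables.
* The smoking-attributable cost rule (current smokers only, instant
  drop on quitting) makes quitting save \$403/yr immediately. A
  consequence worth knowing: with the cancer-care stream excluded
  (`include_cancer_cost = FALSE`), those savings exceed the \$286
  incremental program cost and the best-practice arm becomes
  *cost-saving* (dominant) rather than "more costly and more
  effective". The published base-case incrementals imply the same sign
  once their cancer-cost component is removed, so this appears to be
  inherent to the parameter set rather than to this implementation; the
  alternative rule (ex-smokers keep paying the attributable cost)
  restores the sign but roughly doubles the base-case ICER. The default
  keeps the standard rule and documents the behaviour.
* No smoking-related comorbidity states (COPD, cardiovascular disease):
  their inclusion would make the intensive program look better, so the
  packaged results are conservative in that respect.
* One cancer "in general": no type or stage structure.
* A single 12-month HR per status is extrapolated over the lifetime.

## Reproducing the headline numbers

```{r, eval = FALSE}
library(cessim)

res <- run_base_case()            # both sexes, packaged inputs
tidy(res$male$cea)                # cost / QALY / LY table + ICER rows

tor <- one_way_tornado()          # male tornado, all ranged parameters
plot_tornado(tor)

psa <- run_psa(n_draws = 10000, seed = 1)
glance(psa)                       # P(cost-effective at $50k) = 1.00
plot_ceac(psa)
autoplot(psa)                     # CE plane
```

`scripts/acceptance.R` (repository root) re-runs the PSA from scratch
against the installed package and writes the percentage of draws
cost-effective at \$50,000/QALY as JSON.
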