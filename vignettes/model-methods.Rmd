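---
title: "Model and methods: Markov cost-effectiveness analysis of one-time esophageal cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecscreen)
```

## The decision problem

`ecscreen` implements a cohort state-transition (Markov) model of one-time
endoscopic screening with Lugol's iodine staining for esophageal squamous
cell carcinoma (ESCC) in a high-incidence Chinese population. Three
policies are compared for each of six starting cohorts aged 40--44 through
65--69: no screening (`NON_SCR`), one-time screening with annual
endoscopic follow-up of detected low-grade intraepithelial neoplasia
(`SCR_FOL`), and one-time screening without follow-up (`SCR_NFOL`). Each
cohort of 100,000 people is simulated in 1-year cycles until attained age
79, and strategies are ranked by discounted cost per discounted
quality-adjusted life-year (QALY) with standard dominance analysis.

## Health states and transitions

The natural history uses 11 states: `NORMAL`, `LGIN` (low-grade
intraepithelial neoplasia, detectable only by endoscopy), four cancer
stages at diagnosis -- `IC` (intraductal carcinoma including high-grade
neoplasia), `SM` (submucosal), `MOD` (stages IB--III), `ADV` (stage IV) --
four post-treatment survivor states (`DFS_IC`, `DFS_SM`, `DFS_MOD`,
`PFS_ADV`) and absorbing `DEATH`. `IC` and `SM` together form "early"
cancer; `MOD` and `ADV` are "invasive".

Transitions are parameterized by:

* **Incidence.** The annual probability of leaving `NORMAL` for a cancer
  state is the age-band incidence (per 100,000, converted to a per-person
  probability only inside the engine) times the passive-diagnosis stage
  distribution -- in both scenarios, because post-baseline incident cases
  are symptomatic in every arm. In the screened arms the hazard is
  deflated by the screening risk ratio RR = 0.70, derived by converting
  10-year cumulative incidences (4.17% screened vs 5.92% unscreened) to
  one-year probabilities through $r = -\ln(1-p)/t$ and $p = 1-e^{-rt}$
  and taking their ratio (`annual_prob_ratio()`).
* **LGIN dynamics.** LGIN is occupied only in the screened arms (it is
  never diagnosed without endoscopy). With follow-up, LGIN regresses to
  `NORMAL` at 0.1427/year and its incident cancers are detected early
  (screening stage distribution); without follow-up there is no
  regression and incident cancers surface late (passive distribution).
  The LGIN-specific incidence column of the rate table is used directly;
  the generic risk-ratio product (3.66 times population incidence) is
  available for synthetic inputs, and the two deliberately differ
  slightly in the packaged base case.
* **Treatment and survivor states.** Published one-year transition
  scalars govern movement into the survivor states and onward
  progression; gross entries into survivor states are printed net of the
  background death probability `d_nor` (all-cause minus cancer-specific
  mortality for the attained-age band). `SM`, `MOD`, `ADV` and their
  survivor states additionally carry state-specific cancer death
  probabilities, multiplied above age 65 by stage-class risk ratios
  (1.30 / 1.20 / 1.16) and capped at 1.

### Row composition (death-first)

For some states the printed gross masses exceed 1 once death is added
(e.g. `SM`: 0.9051 + 0.1386 + 0.0994 > 1). Rows are therefore composed
death-first: the state's total death probability (cancer-specific plus
background where applicable) is allocated first, and the remaining
transition masses are scaled proportionally whenever they would exceed
the residual $1 - p_{death}$; any shortfall stays in-state. This
guarantees exact row-stochasticity at every age, including above 75 where
`d_nor` is large. It is the single largest modelling convention this
package had to fix on its own, and the main fidelity risk relative to the
original implementation, whose internal handling is not recoverable from
its published description.

### Tunnel semantics and counters

Newly incident patients spend exactly one cycle in their treatment state
before the survivor-state transitions apply; treatment states are
re-enterable from the survivor states (recurrence). The trace counts as
*incident* only transitions from `NORMAL` or `LGIN` into a cancer state,
and attributes a death to cancer in proportion to the cancer-specific
share of the state's composed death probability.

Cycle-0 prevalent/detected cases are **excluded** from the cumulative
incidence tally by default (`include_baseline_cases = FALSE`). The
published cumulative-incidence table behaves this way -- in the oldest
screened cohort it reports a screening-arm cumulative incidence far below
the baseline detection rate alone, which is only possible if baseline
detections are not counted -- and with this convention the package
reproduces the published 29.88% incidence reduction (screening with
follow-up vs none, ages 40--44) to two decimals. The flag restores the
like-for-like tally if wanted.

### Attained age

A cohort starting in band $[a, a+4]$ is aged from the band midpoint
$a+2$; cycle $k$ uses the rates of the band containing $a + 2 + k$, and
the simulation stops after the cycle lived at age 79 (38 transitions for
the 40--44 cohort). The alternative lower-bound convention is available
via `attained_age_convention = "lower"`. Both reproduce the published
follow-up vs no-follow-up ICERs within a few percent; the midpoint is the
default because it centres the band's exposure on its rates.

## Economics

Costs (2017 USD) and utilities accrue on start-of-cycle occupancy over
lived cycles, with no half-cycle correction (the source analysis
describes none). Per cycle $t$:

$$\text{cost}_t = \sum_s occ_{t,s}\, c_s \,(1+\pi)^t (1+d)^{-t}, \qquad
  \text{QALY}_t = \sum_s occ_{t,s}\, u_s \,(1+d)^{-t},$$

with discount $d = 5\%$ on both, and inflation $\pi = 4.7\%$ on costs
only -- an intentional reproduction of the stated method (net cost
discounting is therefore only about 0.29%/year). The one-time endoscopy
cost (60.3 USD) accrues at cycle 0 to every member of a screened cohort.
Treatment-state costs accrue per cycle spent in the state; the LGIN
follow-up cost (149.5 USD/year, the annual surveillance endoscopy)
accrues every cycle in `SCR_FOL` but only at the diagnosis cycle in
`SCR_NFOL`. Disease-free follow-up costs are carried directly in the cost
profile; `dfs_annual_cost()` implements the underlying visits-times-items
formula $C = N \sum_i i\, p_i$ for synthetic schedules, since the item
prices behind the packaged values are not published.

`dominance_analysis()` performs the standard incremental analysis: sort
by cost, remove absolutely dominated strategies, then iteratively remove
extended-dominated ones until frontier ICERs increase strictly.
Undefined ICERs (equal QALYs) are reported as `NA`, never as infinities.

## Sensitivity analysis

* **One-way.** Every registry parameter moves to the ends of its
  plausible range (probabilities, utilities, rates and risk ratios
  +/-20% unless a table prints a range; costs +/-30%; discount 0--8%;
  inflation 3.2--6.2%) and the comparison ICER is recomputed; spans are
  reported tornado-style. Stage-simplex components are perturbed one at a
  time with proportional renormalization of the rest.
* **Probabilistic.** Parameters are drawn jointly: beta for
  probabilities and utilities (method-of-moments from the printed SD, or
  from the range treated as a central 95% interval when no SD is
  printed, i.e. $\sigma = (hi-lo)/(2 \times 1.96)$), gamma for costs,
  Dirichlet for stage simplexes and progression splits (concentration =
  proportions x 100, a moderate effective sample size chosen once;
  configurable), lognormal for risk ratios (median anchored at the point
  estimate, range spanning the central 95%) and triangular for the
  discount and inflation rates. Draws are clamped to their domains
  (probabilities and utilities to [0,1], elderly risk ratios to >= 1)
  and re-validated; invalid draws are resampled with a bounded retry.
  The headline analysis uses 100,000 iterations; 2,000 is the documented
  fast setting, and the test suite uses a handful per run because the
  pipeline is deterministic given the seed.
* **Outputs.** Acceptability curves use net monetary benefit
  $\lambda E - C$ with ties split equally (a measure-zero event that must
  still be deterministic); the cost-effectiveness plane reports
  per-person incremental pairs with a bivariate-normal confidence
  ellipse (mean + covariance scaled by $\chi^2_2$ quantile) and quadrant
  shares.

## Synthetic data

`generate_parameters()` builds fully validated parameter sets with known
ground truth: exponential incidence and background-mortality age trends
discretized to 5-year bands, a configurable screening risk ratio and
stage-shift strength, LGIN prevalence scaling, and jittered cost/utility
profiles. It emulates the *structure* of the real inputs (schedules,
simplexes, scalars), not their empirical correlations: real incidence
need not be log-linear in age, detection rates need not be proportional
to incidence, and costs are not independent of stage mix. Passing tests
on synthetic sets therefore demonstrate internal correctness
(conservation, calibration recovery, null-effect equivalence), not
external validity. A null configuration (RR = 1, no stage shift, no
LGIN, detection equal to incidence) makes screening and nonscreening
traces coincide exactly, which the suite asserts.

## Numerical choices

* Stage simplexes off by at most 1e-6 are renormalized with a warning;
  worse sums are rejected.
* Transition-matrix rows must sum to 1 within 1e-12 (asserted at build
  time); cohort conservation holds to 1e-6 persons over the horizon.
* Death probabilities are capped at 1 after elderly multiplication; the
  cap never binds in the base case but can for extreme PSA draws.
* The engine is a deterministic expected-value cohort: the only random
  numbers in the package are PSA parameter draws, controlled by a single
  seed.

## Known limitations

* Only ESCC natural history is modelled; adenocarcinoma is out of scope.
* The published base-case cost table is a per-state summary; the
  original analysis drew on more detailed stage- and state-specific cost
  breakdowns that are not publicly printed. Our absolute discounted cost
  totals for the no-screening arm consequently sit 20--30% below the
  published ones in every cohort, while cumulative incidence, mortality
  and QALYs land within a few percent. Comparisons dominated by the
  within-screening cost structure (follow-up vs no follow-up) reproduce
  well; the screening-vs-nonscreening cost-saving magnitudes do not, and
  the package reports them as computed rather than tuning toward the
  published figures.
* The row-composition rule above is a reconstruction; other choices
  (e.g. renormalizing death together with transitions) would change
  older-age dynamics.
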