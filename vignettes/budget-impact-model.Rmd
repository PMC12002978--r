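---
title: "The bansim budget-impact model: structure, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bansim budget-impact model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bansim)
```

## The question the model answers

Breath-actuated nebulizers (BAN) release aerosol only during inspiration.
Compared with the continuous nebulizers (CN) that are today's emergency
department (ED) standard of care for asthma and COPD exacerbations, single-site
studies report that BAN shortens pediatric ED stays, modestly lengthens adult
asthma stays, and reduces the probability of hospital admission in all three
patient groups — at a higher per-device price. `bansim` asks what a universal
(or partial) BAN-first policy would cost and save per year, nationally and for
a single ED of a given annual visit volume.

The model is a static annual cohort model with parameter uncertainty
propagated by Monte Carlo simulation. There is no patient-level dynamics, no
queueing, and no time structure: each outcome is a product (or sum of
products) of cohort sizes, shares, rates, and unit costs.

## Cohort structure and outcome arithmetic

Three subgroups are modeled. With the single-letter parameter labels used
throughout the package (the packaged table skips the letter I so that labels
stay alignable with the published input table):

* pediatric asthma visits: $B \cdot C$, of which a fraction $F$ receive
  nebulizer therapy;
* adult asthma visits: $A \cdot D$, nebulizer fraction $G$;
* adult COPD/emphysema visits: $A \cdot E$, nebulizer fraction $H$.

One nebulizer unit is consumed per nebulizer-treated visit, so annual BAN
units are the sum of the three nebulizer-visit counts. The remaining outcomes
are:

* **Marginal supply cost** — units times the BAN/CN per-unit price gap
  $(M - N)$. Two variants are first-class: the Monte Carlo variant differences
  *independently sampled* prices each iteration, and
  `supply_cost_mode_difference()` differences the *most-likely* (mode) prices
  deterministically. Both are reported because they answer slightly different
  questions (expected spending under price uncertainty vs. spending at list
  prices), and reports label which is which.
* **Averted admissions** — per subgroup, nebulizer visits × baseline
  admission rate ($J, K, L$) × percent reduction in admission after
  converting to BAN ($Q, R, S$).
* **Admission savings** — averted admissions × cost per admission
  ($U, V, W$); the total is the exact sum of the three subgroup components.
  "Total cost savings" in all reports means admission savings only; bed-hour
  dollars are reported separately as additional savings.
* **Net bed-hours** — the pediatric length-of-stay (LOS) reduction $O$ net of
  the adult asthma LOS increase $P$ (row P's description says *increase*, so
  it enters negatively), converted from minutes to hours. COPD contributes no
  LOS term.
* **LOS dollar savings** — net bed-hours × the per-bed-hour cost $T$; a
  negative value passes through as a cost.

### The discharged-only LOS rule

A design decision with visible consequences: LOS effects are applied only to
the nebulizer visits *not admitted at the baseline admission rate*, i.e.

$$\text{net bed-hours} = \frac{n_{ped}(1-J)\,O - n_{adult}(1-K)\,P}{60}.$$

The rationale is clinical — an admitted patient's ED stay ends with boarding,
not with symptom resolution, so a faster treatment response does not shorten
it by the same mechanism — and the rule uses the *baseline* rates $J, K$, not
post-BAN rates, because the LOS effect sizes were measured against
standard-of-care admission behavior. At the default table this yields
177,972 bed-hours. The alternative rule (apply the effects to every
nebulizer visit) yields 195,316 and is retained in the API as
`los_rule = "all_visits"` with a regression test pinning both values, so the
choice stays visible and deliberate rather than buried.

## Parameter distributions

Each of the 22 parameters carries one of four families:

* **normal**, for every input published as mean ± SD. The printed SD column
  is used verbatim even where it is not exactly 10% of the mean (the COPD
  admission-reduction SD is 4.6 points on a 45.6% mean; the pediatric LOS SD
  is 50% of its mean): the specific printed number beats a general rule.
  Draws are clipped by *resampling* — proportions into $[0,1]$, volumes,
  costs, and durations into $[0,\infty)$ — so no probability mass piles up at
  the bounds. At the default coefficients of variation the clipping is nearly
  inert (well under $10^{-6}$ of mass for most rows); it exists to guarantee
  physically valid draws for user-supplied tables too. A resampling cap
  (1000 rounds) makes pathological tables fail loudly instead of looping.
* **BetaPERT**, for the two device prices published as a most-likely value
  with a range. The classical PERT with shape constant $\lambda = 4$ is used
  (the conventional meaning of "BetaPERT" when no $\lambda$ is stated):
  $x = \min + (\max-\min)\,\mathrm{Beta}(\alpha,\beta)$ with
  $\alpha = 1 + 4\frac{\text{mode}-\min}{\max-\min}$,
  $\beta = 1 + 4\frac{\max-\text{mode}}{\max-\min}$, and mean
  $(\min + 4\,\text{mode} + \max)/6$.
* **lognormal**, for the two LOS effects, capturing the right skew of ED
  stay durations. The published columns print an *arithmetic* mean and SD
  (59 minutes is plainly an arithmetic effect size), so the underlying
  normal parameters are moment-matched:
  $\sigma^2 = \ln(1 + sd^2/\text{mean}^2)$,
  $\mu = \ln(\text{mean}) - \sigma^2/2$. Whether the original analysis
  software read its lognormal inputs this way is unknowable; this reading is
  recorded as the package's choice, not asserted as the authors' intent. One
  visible consequence: the pediatric LOS parameter (CV 0.5) dominates the
  Monte Carlo spread of net bed-hours, so the bed-hour SD is sensitive to
  this interpretation even though the mean is not.
* **point**, a degenerate value, used by the synthetic zero-variance tables.

Parameters are sampled independently; the model has no correlation
structure.

## The Monte Carlo engine and its oracle

`run_simulation()` defaults to 1000 iterations, the published run size. One
master seed deterministically spawns one sub-seed per iteration; within an
iteration, parameters are sampled in alphabetical label order. Results are
therefore invariant to table serialization order and to any batching of
iterations, and identical `(table, n, seed, scenario)` inputs give
bit-identical summaries. Summaries report the sample mean, sample SD
($n-1$ denominator), and 2.5/50/97.5% quantiles (R's default type-7
interpolation); a single-iteration summary reports SD 0 with a degenerate
flag.

Because every outcome is a multilinear polynomial in independently sampled
parameters, the expectation of each outcome equals the outcome evaluated at
the per-parameter means (PERT mean for BetaPERT rows). `analytic_expectation()`
implements exactly that and serves as a closed-form oracle: the test suite
checks Monte Carlo means against it within four standard errors at 10,000
iterations — a run size chosen to make the 4-SE band tight, while the
package default stays at the published 1000.

## Scenarios

* **Per-ED scaling.** An ED with $V$ annual visits and the national case mix
  receives the fraction $V/(A+B)$ of national volume. The factor uses each
  iteration's *realized* $A$ and $B$, so per-ED SDs inherit national volume
  uncertainty; the closed-form oracle plugs in the mean volumes, and the
  Jensen gap of the ratio at ~10% CV is far below every tolerance used in
  the tests. The published ED sizes are 30,000 / 80,000 / 130,000 visits per
  year; 80,000 is the medium size used throughout the report tables.
* **Partial adoption.** BAN effects accrue only to adopting visits, so every
  cohort-total outcome scales exactly linearly with the adoption rate,
  applied as a post-hoc multiplier (mathematically identical to re-running a
  reduced cohort for this multilinear model). The per-unit price gap is not
  an annual total and never scales.
* **COPD admission-reduction sensitivity.** `apply_copd_reduction()` replaces
  row S's mean (base 0.456; published sensitivity values 0.228 and 0.137)
  and rescales its SD to preserve the SD/mean ratio. COPD-attributable
  savings then scale exactly linearly with the target; the asthma components
  are untouched.

`standard_report_suite()` runs the full published grid: base case, three
COPD targets, and three partial-adoption rates, each at national scope and
the three ED sizes (28 cells).

## Synthetic tables

The generator module makes the pipeline testable away from the packaged
defaults. `zero_variance_table()` collapses every distribution to its mean,
making the whole model deterministic (any draw equals the closed-form
expectation — the strongest available end-to-end identity).
`perturbed_table()` jitters central values multiplicatively by
$\mathrm{Normal}(1, cv)$ with validity repaired (proportions clipped to
$[0,1]$, one common multiplier per BetaPERT row so the min/mode/max ordering
survives, SDs reset to 10% of the new means), and is fuzzed over 100 seeds in
the tests. `tiny_worked_example()` is a pencil-auditable economy (500
nebulizer visits, every outcome a one-line product) used in the
documentation and as a smoke test. These emulate parameter-table *structure*
only; none of them emulates survey microdata, so passing tests say nothing
about the field accuracy of the packaged input values themselves — those
carry their own source citations in the table.

## Known limitations

* Static cohort arithmetic: no ED occupancy dynamics, revisits, readmissions,
  metered-dose-inhaler comparator, inflation, or discounting.
* Independence of all inputs; correlated uncertainty (e.g. between admission
  rates and LOS effects) is not representable.
* The per-ED scaling assumes the national case mix at every ED size.
* Published per-ED pediatric admission cells and one published intermediate
  COPD sensitivity cell are not proportional to the national figures under
  any scaling consistent with the rest of the published tables; the package
  documents them as irreproducible rather than adjusting the model toward
  them, and a test pins the discrepancy.
* Reported SDs (not means) of the bed-hour outcomes depend on the
  arithmetic-moment reading of the lognormal LOS inputs discussed above.
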