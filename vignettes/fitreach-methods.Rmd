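---
title: "Modeling mailed FIT outreach: methods and design choices"
author: "fitreach"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Safety-net clinics (FQHCs) serve large populations of age-eligible patients
who are not up to date with colorectal cancer (CRC) screening. Mailing a
fecal immunochemical test (FIT) directly to those patients, with reminders,
results letters and patient navigation to follow-up colonoscopy after a
positive result, is an effective outreach model. `fitreach` projects, over a
five-year horizon, the process volumes, program costs, and patient outcomes
of scaling such a program to a statewide eligible population of roughly
215,000 unscreened patients, and compares nine ways of running it: three
*outreach strategies* (who gets a kit after year 1) crossed with three
*organizational configurations* (how mailing and navigation operations are
organized).

## The cohort model

The engine is a deterministic difference-equation model, not a Markov chain:
transition probabilities depend on each patient's full participation
history, so they are not time homogeneous. The population is partitioned
into strata indexed by entry year and a history string (`R`/`N` per year,
returned / did not return). Counts are expected values (real numbers, not
integers) — the model propagates means, and the companion microsimulation
(below) carries the stochasticity.

Each year, for each stratum:

1. **Mailing rule.** New entrants are always mailed. Otherwise
   `everyone` mails every stratum still in the pool; `at_least_once`
   requires one prior `R`; `previous_year` requires the last letter to be
   `R`. Patients who opted out or tested positive have left the pool
   entirely.
2. **Return.** An empty history returns with the first-year rate (19%).
   Otherwise the probability is looked up by the pair (returned last year,
   number of prior returns); an exact-history override table takes
   precedence when configured.
3. **Cascade.** Returned kits spoil at the organizational rate
   (processed screens = returns × unspoiled rate); positivity applies to
   processed screens (6% in year 1, 5% in years 2–5 by default); navigation
   converts positives to colonoscopies; detection rates convert
   colonoscopies to cancers and adenomas found. All identities hold exactly
   by construction, and the test suite asserts them every year.
4. **Exits.** Patients with a positive result leave the mailing pool
   permanently (they enter colonoscopy surveillance, which is out of
   scope), whether or not the colonoscopy is completed. Opt-outs are drawn
   from mailed non-returners (the records-update postcard travels with the
   mailing) and are likewise absorbing. The base-case opt-out and postcard
   return rates are 0: they are not published for this program, so they
   ship as configuration knobs rather than invented behavior.

With a five-year horizon the exact history enumeration is tiny (at most
31 strata per entry cohort), so no aggregation approximation is used.

**Cohort growth.** The eligible population grows 5%/year. Entrants in year
t are `initial × g × (1+g)^(t-2)`: the stated growth is read as growth of
the whole eligible cohort, so entrant cohorts compound. A non-compounding
option (`growth_compounding = FALSE`) is provided because the flat reading
("5% of the initial cohort per year") is also defensible; at 5% over five
years the two differ by under 1% of total mailings.

**Positivity timing.** The default (`by_program_year`) applies 6% in
program year 1 and 5% in years 2–5 to all screens, including those of
later entrants, matching how the source rates are indexed. The alternative
(`by_screen_round`) applies 6% to each patient's first-ever screen. The
choice moves total colonoscopies by about 1%.

## Costing

Costs are 2022 US dollars from the perspective of a third-party payer that
funds the program and covers colonoscopy for uninsured patients (39% of the
cohort). Four layers:

* **Direct**: per-mailer ($6.73), reminder letters ($1.15 × 83% of
  mailings), results letters ($1.15 per processed screen), laboratory fee
  per returned kit ($20; $23 regional) — charged for spoiled kits too,
  since the laboratory handles every returned kit (a documented switch),
  EHR updates ($0.97 per processed screen), positive-result calls
  ($3.96 = $39.59/h × 6 min), navigator time per positive
  ($39.59/h × 15 or 18 min) — navigation is priced per attempted
  navigation (per positive), not per completed colonoscopy, because the
  navigator's time is spent either way — plus fixed fees per mailing site:
  one-time text-message set-up ($78.95) in year 1 and the annual
  business-reply permit ($275/year). Regional operations carry seven
  mailing sites; centralized and hybrid carry one.
* **Indirect**: a configuration-specific fraction (15/20/24%) of each
  year's direct cost, colonoscopies excluded.
* **Start-up**: a one-time fraction (5/7.5/10%) of year-1 *ongoing* cost.
  "Ongoing" is read as direct plus indirect (all non-colonoscopy year-1
  cost); applying it to direct cost alone would change totals by well
  under 1%.
* **Colonoscopy (payer)**: completed colonoscopies × 39% uninsured ×
  $1,800.

The base case is undiscounted; a discount rate, applied to both cost and
outcome flows, exists as a sensitivity knob (0–3%/year grid).

## Reconstructed calibration artifacts

Two parameter groups are not published directly and ship as clearly
labelled reconstructions:

* **History-conditional return probabilities.** Four free values — repeat
  return after a first return, repeat return for established returners,
  return after never returning (bounded above by the published "< 3%"),
  and lapsed-returner re-entry — are fitted with
  `calibrate_return_probabilities()` by least squares on relative errors so
  the engine reproduces the published nine-scenario cost, screen and
  colonoscopy totals (`reference_estimates()`). The unconstrained optimum
  is behaviorally implausible (oscillating retention) for a negligible
  gain in fit, so the shipped fit enforces the ordering
  repeat ≥ lapsed ≥ never (`monotone = TRUE`). The frozen values are
  0.552 (repeat), 0.361 (lapsed), 0.019 (never); the fit matches the
  published totals to within about 3% everywhere (asserted in the tests).
* **Prevention coefficients.** Cancers prevented and deaths averted are
  modeled as linear in completed colonoscopies; the natural-history models
  behind those outcomes are out of scope, so only their linear footprint is
  reproduced. `calibrate_prevention()` fits the ratio through the origin;
  the shipped defaults use the minimax (Chebyshev) criterion rather than
  least squares because minimax bounds the worst-case reproduction error —
  it keeps all nine published (prevented, deaths) pairs within 2 cases,
  which the least-squares fit misses at one scenario.

### Known reproduction limits

The published parameter tables give centralized and hybrid configurations
identical mailing, return and spoilage behavior; they differ only in
overhead rates, navigation success (65% vs 70%), navigation minutes and
the uninsured colonoscopy volume. That pins the centralized:hybrid ratio of
detected cancers at exactly 65/70 and the cost ratio near 0.944, whereas
the published result tables imply ratios near 0.933 and 0.930. The
difference sits in unpublished model internals. Consequently two
second-order published quantities that depend on the centralized–hybrid
efficiency gap — the navigation-success threshold at which centralized
matches hybrid efficiency (published 65.15%; this model: 66.5%) and the
centralized cost per detected cancer under regional-grade navigation
(published $52,005; this model: $53,136) — reproduce only to about 2.2%.
The corresponding expectations in the acceptance tests are deliberately
left failing at the 2% tolerance used for the rest of that block, as an
honest record of the gap. All first-order quantities (scenario costs,
screens, detections, budget-scaled outcomes, dominance structure) reproduce
within 2–3%.

## Cost-effectiveness analysis

`dominance_frontier()` sorts options by cost (ties: higher effect first;
exact duplicates collapsed with a warning), marks strict dominance, then
removes extended-dominance violations by repeated ICER-monotonicity sweeps
until the surviving ICERs increase strictly with cost — equivalent to
keeping the lower convex hull of the (effect, cost) cloud, and verified in
the tests against an independent brute-force convex-combination oracle on
1,000 random instances. ICERs are computed per outcome column
independently, each frontier anchored at the zero-cost, zero-effect
no-program option.

Budget-constrained comparison uses average cost-effectiveness ratios:
ACER = total cost / total outcome, and the outcome achievable within a
fixed budget ($5 million by default) is budget / ACER — purely linear
scaling with no integer constraints, which is how the published
fixed-budget table relates to the published totals. The minimum-ACER
scenario is invariant to the budget.

## Sensitivity analysis

One-way analysis re-runs all nine scenarios over a grid spanning at least
±20% of a shared parameter (5 points by default; the resolution is a
package choice, only the range is sourced) and flags whether the ACER
ranking or the ordered frontier changes anywhere on the grid. Because
several scenarios are near-ties (centralized vs hybrid ACERs differ by
under 2%), mid-rank swaps can occur for some parameters; the tests assert
the stability that matters for conclusions — frontier membership and the
most efficient scenario — across all registered shared parameters.

Threshold analysis bisects one organizational parameter of scenario A until
its ACER equals scenario B's (`stats::uniroot` on the ACER gap; default
bracket 0.5–1.5× the base value clipped to the admissible range; relative
gap tolerance 1e-6, with a polishing pass if the root's x-tolerance leaves
a larger residual). A bracket without a sign change reports "no threshold
in range" rather than an error.

## The microsimulation oracle

`simulate_roster()` is a patient-level Bernoulli twin of the engine: every
rate the engine multiplies by becomes an individual draw (return, spoilage,
positivity, navigation, detection, opt-out, reminders, postcards), with
absorbing exits. It serves two purposes: generating synthetic rosters with
the assumed behavioral structure (written/read as a documented CSV schema),
and cross-checking the engine — for every scenario and volume metric the
replicate mean must sit within 3 Monte Carlo standard errors of the
deterministic value (10 replicates of 50,000 patients in the tests).

Determinism: one seeded random stream with a fixed vectorized draw order
per year, so a seed reproduces a roster exactly. Entrant counts are scaled
to the simulated population and rounded to whole patients (a bias of at
most half a patient per year, far below Monte Carlo noise at the tested
sizes).

What the generator does *not* emulate: demographic covariates (the model is
covariate-free by design), within-year timing, correlation between a
patient's return behavior and their positivity risk, and colonoscopy
adverse events or surveillance. Agreement between the engine and the
simulator therefore validates the bookkeeping, not the realism of those
simplifications.

## Problem sizes and numerical notes

The shipped tests run the full 215,000-patient deterministic pipeline (it
is effectively instant: at most ~80 strata regardless of population size),
90 microsimulation runs of 50,000 patients, 1,200 random frontier
instances, and calibration-recovery exercises on a 1,000-patient,
three-year configuration — sizes chosen to make Monte Carlo bounds tight
while keeping the default suite around a minute. Expected-value counts are
kept in double precision throughout; published-style rounding (costs to
$0.1M, outcomes to cases, volumes to 0.1K) happens only in the
`paper_style` rendering of the report tables, never in computation.

## Limitations

Beyond the reproduction limits above: patient time and travel costs are
excluded; treatment costs and downstream savings are excluded (so the
program cost is an implementation cost, not a net cost); no QALYs or
life-years; no geographic heterogeneity across regions; prevention outcomes
inherit whatever bias the linear-footprint approximation carries. The
reconstructed return probabilities are one plausible table consistent with
the published totals, not recovered ground truth; analyses that hinge on
fine history structure (e.g., the exact split between lapsed and
established returners) should treat them as a calibration artifact and use
`history_overrides` to explore alternatives.
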