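# fitreach

Decision-analytic cohort model of a statewide **mailed FIT colorectal
cancer screening program** for unscreened safety-net (FQHC) patients, with
program costing, outcome projection, incremental and budget-constrained
cost-effectiveness analysis, sensitivity analysis, and a patient-level
microsimulation oracle.

## Who this is for

Analysts and program planners comparing ways to scale mailed
fecal-immunochemical-test (FIT) outreach: which patients to re-mail each
year, and whether to run mailing and patient-navigation operations
centrally, regionally, or as a hybrid. The package models nine scenarios —
three outreach strategies × three organizational configurations — over a
five-year horizon for an eligible cohort of ~215,000 unscreened patients
growing 5%/year.

## The model

**Cohort engine.** A difference-equation model over strata indexed by entry
year and exact participation history *h* ∈ {R, N}\*. Counts are expected
values. For a mailed stratum with count *n(h)* and history-conditional
return probability *p(h)*:

    returns        = n(h) · p(h)                      p(∅) = 0.19
    screens        = returns · u                      u = unspoiled rate
    positives      = screens · π_t                    π₁ = 6%, π₂₋₅ = 5%
    colonoscopies  = positives · ν                    ν = navigation success
    CRC detected   = colonoscopies · 4.5%

Positive patients and opt-outs exit the mailing pool permanently. Outreach
strategies decide which strata are mailed after year 1: `everyone`,
`at_least_once` (≥1 prior return), or `previous_year` (last year returned).

**Costing** (2022 US$, third-party payer): direct unit costs (mailers
$6.73, reminder/results letters $1.15, lab fee $20–23 per returned kit,
wage-priced calls and navigation, per-site fixed fees), indirect overhead
(15/20/24% of direct, by configuration), one-time start-up (5/7.5/10% of
year-1 non-colonoscopy cost), and payer colonoscopy cost
(colonoscopies × 39% uninsured × $1,800). Undiscounted by default.

**Cost-effectiveness.** `dominance_frontier()` eliminates strictly and
weakly (extended) dominated scenarios against a zero-cost "no program"
anchor and reports ICERs = Δcost/Δeffect along the frontier.
`acer_fixed_budget()` compares scenarios by average cost-effectiveness
ratio (ACER = cost/outcome) and scales outcomes linearly to a fixed budget
(default $5M).

**Sensitivity.** `one_way()` re-runs the pipeline over ±20% grids of shared
parameters; `threshold_search()` bisects an organizational parameter until
two scenarios' ACERs are equal (relative gap ≤ 1e-6).

**Microsimulation.** `simulate_roster()` is a seeded Bernoulli twin of the
engine used to generate synthetic patient rosters and to cross-check every
deterministic volume against Monte Carlo replicates.

Two parameter groups are shipped as *reconstructed calibration artifacts*
(the source program's full tables are unpublished): history-conditional
return probabilities, fitted so the engine reproduces published
nine-scenario totals (`calibrate_return_probabilities()`), and linear
cancers-prevented / deaths-averted coefficients per colonoscopy
(`calibrate_prevention()`). See the methods vignette
(`vignettes/fitreach-methods.Rmd`) for the fitting criteria and known
reproduction limits.

## Worked example

```r
library(fitreach)

res <- evaluate_scenario(model_config("at_least_once", "hybrid"))
res
#> <fitreach_result> at_least_once_hybrid
#>   cost $10.6M | screens 114.4K | colonoscopies 4.26K
#>   CRC detected 192 | prevented 97 | deaths averted 49
```

Re-mailing only prior participants under a hybrid organization (central
mailing, regional navigation) costs $10.6M over five years, completes
~114K screens and detects ~192 cancers. Across all nine scenarios:

```r
s <- scenario_summary(run_scenarios())
cea_table(s, outcomes = "crc_detected", paper_style = TRUE)
#>                        label cost crc_detected icer_crc_detected
#>                   no_program  0.0            0                 -
#>    previous_year_centralized  7.9          137                WD
#>         previous_year_hybrid  8.3          148                WD
#>       previous_year_regional  9.1          156                WD
#>    at_least_once_centralized 10.0          178                WD
#>         at_least_once_hybrid 10.6          192              55.1
#>       at_least_once_regional 11.6          202              98.5
#>         everyone_centralized 17.7          209                WD
#>              everyone_hybrid 18.6          225                WD
#>            everyone_regional 20.0          237             240.8
```

Six scenarios are weakly dominated (`WD`); the frontier runs from no
program through at-least-once/hybrid ($55.1K per additional cancer
detected) and at-least-once/regional to everyone/regional. Under a fixed
$5M budget, at-least-once/hybrid detects the most cancers (90.8, ACER
$55.1K), with centralized a close second:

```r
acer_table(run_scenarios(), budget = 5e6, paper_style = TRUE)
```

Scenario YAML files (overrides over package defaults) live in
`inst/extdata/scenarios/`; `load_config()`/`save_config()` read and write
them. A thin CLI (`inst/cli/fitreach.R`) exposes `run`, `cea`,
`sensitivity`, `threshold` and `simulate` subcommands.

## Configuration schema

Every field is optional; omitted fields take the defaults below (all
sourced from the published program's cost and assumption tables, shipped
in `reference_estimates()`).

| Block | Field | Unit | Default |
|---|---|---|---|
| (top) | `strategy` | `everyone` \| `at_least_once` \| `previous_year` | `at_least_once` |
| (top) | `discount_rate` | fraction/year | 0 |
| `cohort` | `initial_unscreened` | patients | 215000 |
| | `annual_growth` | fraction/year | 0.05 |
| | `horizon` | years | 5 |
| | `uninsured_fraction` | fraction | 0.39 |
| | `growth_compounding` | logical | true |
| `behavior` | `first_return_rate` | fraction | 0.19 |
| | `conditional_return` | map `yes_k`/`no_k` → fraction | reconstructed calibration |
| | `history_overrides` | map history → fraction | (none) |
| | `reminder_fraction` | fraction of mailed | 0.83 |
| | `optout_rate` | fraction of non-returners/year | 0 |
| | `postcard_return_rate` | fraction of mailed | 0 |
| | `positivity_initial` / `positivity_later` | fraction | 0.06 / 0.05 |
| | `positivity_mode` | `by_program_year` \| `by_screen_round` | `by_program_year` |
| | `crc_detection_rate` | fraction of colonoscopies | 0.045 |
| | `adenoma_detection_rate` | fraction of colonoscopies | 0.39 |
| `costs` | `mailer`, `reminder_letter`, `results_letter` | $ | 6.73, 1.15, 1.15 |
| | `text_setup` | $ one-time/site | 78.95 |
| | `postcard_processing`, `update_result`, `positive_call` | $ | 3.96, 0.97, 3.96 |
| | `reply_mail_annual` | $/year/site | 275 |
| | `fit_processing` | $/returned kit | 20 (org override) |
| | `navigator_wage`, `clerical_wage` | $/hour | 39.59, 29.22 |
| | `colonoscopy` | $/procedure | 1800 |
| `org` | `name` | `centralized` \| `hybrid` \| `regional` \| `custom` | `hybrid` |
| | `indirect_rate`, `startup_rate` | fraction | 0.15/0.20/0.24, 0.05/0.075/0.10 |
| | `unspoiled_rate`, `navigation_success` | fraction | 0.90/0.90/0.95, 0.65/0.70/0.70 |
| | `fit_fee` | $/returned kit | 20/20/23 |
| | `navigation_minutes` | min/positive | 18/15/15 |
| | `n_mailing_sites`, `n_navigation_sites` | count | 1/1, 1/7, 7/7 |
| `prevention` | `prevented_per_unit`, `deaths_per_unit` | cases per basis unit | reconstructed calibration |
| | `basis` | `per_colonoscopy` \| `per_detected` | `per_colonoscopy` |

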