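---
title: "Generalized cost-effectiveness analysis of cancer control: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized cost-effectiveness analysis of cancer control: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcea)
```

## The analytic framework

`gcea` implements generalized cost-effectiveness analysis (GCEA) in the
WHO-CHOICE tradition for breast, cervical and colorectal cancer control.
Every intervention scenario is compared against a hypothetical *null* in
which the effects of all currently implemented interventions are removed,
so that whole packages — not only marginal additions to the status quo —
can be ranked. Health gains are healthy life years (HLYs): person-time
summed over all non-dead states, down-weighted by state-specific
disability weights (DWs). Costs follow an ingredients approach in 2010
international dollars (I$). Programmes run for 100 years at coverage
levels of 50, 80 and 95%; costs are discounted at 3% per year and HLYs
are reported both undiscounted and discounted. All totals are
standardized to a population of 10 million alive at baseline.

The package has three layers:

1. **Natural history and simulation** — validated state graphs per
   cancer, a deterministic annual-cycle open-population cohort engine,
   and a dynamic two-sex HPV transmission sub-model for cervical disease.
2. **Interventions, outcomes and costs** — the fourteen-intervention
   catalog, scenario application (rate, DW and resource modifications),
   HLY accounting and ingredients-based costing.
3. **Decision layer** — ACER/ICER arithmetic, dominance filtering, the
   coverage-locked expansion path, league tables and budget allocations.

## Natural-history models

Each cancer is an exhaustive, mutually exclusive set of health states
with directed transitions (onset, progression, regression, diagnosis,
mortality, clearance, waning immunity). Preclinical (undiagnosed) and
clinical (diagnosed) disease are separate states per stage CIS, I, II,
III, IV, so diagnosis is itself a modelled transition driven by symptoms
or screening. Regression is modelled only for pre-cancerous states.

* **Cervical**: healthy women acquire one of three HPV subtype groups
  (16/18, other high-risk, low-risk; co-infection is not modelled)
  through sexual contact; infection can progress to CIN1 and CIN2-3, then
  to preclinical CIS and onwards to stage IV. CIN can regress to HPV
  (naturally or upon screen-detected treatment), HPV clears into a
  short-term immune state, and immunity wanes back to healthy. Men carry
  only infection, clearance, waning and mortality: they contribute to
  transmission, never to cancer incidence. Structurally the engine runs
  both sexes on the shared graph with male progression rates fixed at
  zero, which is numerically identical to the reduced male graph
  (`build_male_hpv_graph()`).
* **Breast**: cancer initiates directly as carcinoma in situ; no
  precancer states.
* **Colorectal**: onset rate mass splits 77%/23% between an adenoma
  route through three polyp-size classes (≤ 5 mm, 6–9 mm, ≥ 10 mm) and a
  de-novo route straight to preclinical CIS.

`validate_graph()` enforces the invariants (absorbing dead state,
mortality edge everywhere, stage-matched diagnosis edges, no regression
out of cancer states, one-step stage progression, reachability) and
returns violations as messages rather than failing, so defective inputs
can be inspected.

Stage IV doubles as the terminal phase for disability-weight purposes;
no separate terminal state exists. Clinical stages may still progress,
but slowly (0.05/year by default) relative to preclinical progression
(0.30–0.60/year): once diagnosed, the stage largely sticks and prognosis
is carried by stage-specific excess mortality. This choice was made
deliberately after experimentation: if diagnosed patients progress at
full natural rates, stage at diagnosis carries almost no prognostic
information and neither early-stage treatment nor screening can show the
stage-shift benefits these interventions exist to deliver.

## The cohort engine

`simulate_cohort()` advances an open population in annual cycles over
single-year ages 0–100. Intensities convert to per-cycle probabilities by
`1 - exp(-rate)`, with competing risks within a cycle resolved
proportionally to intensities; there is no half-cycle correction, and
person-years for a cycle equal the occupancy at its start. Each year,
occupants transition, everyone ages one year (survivors past age 100
exit and are counted as deaths), and a new birth cohort enters healthy.
Background (all-cause, non-modelled) mortality applies in every state.
The engine contains no randomness: identical inputs give bit-identical
trajectories, and entrants equal occupants plus cumulative deaths to
numerical rounding (`conservation_error()`).

Rates live in `rate_schedule()` objects — dense edge × sex × age
intensity arrays with banded constructors — never on graph edges, so one
graph serves every region and the null.

## HPV transmission

The transmission sub-model is a frequency-dependent, age-structured,
two-sex SIS formulation with short-term immunity: the hazard on
susceptibles of one sex is `partner_rate(sex, age) × Σ mixing(age, a') ×
beta_g × prevalence(other sex, a', g)`. Default mixing is proportionate
(partner ages weighted by opposite-sex partner supply). When transmission
is active the healthy→HPV intensities are recomputed every cycle from
current prevalence, so prevalence and incidence co-evolve; vaccination
enters as a susceptibility multiplier `1 - coverage × efficacy` on the
16/18 hazard of cohorts vaccinated at age 12 from programme start (a
take-type effect, chosen over all-or-nothing so that coverage scaling
stays linear; protection is assumed lifelong; no catch-up cohorts; girls
only by default, so herd effects reach men only through reduced female
prevalence). Immunity wanes at 1/year (mean one year), a configurable
default since the duration of short-term natural immunity is not well
established.

Two numerical properties of this system shaped the package's design and
are worth stating plainly:

* With annual cycles the epidemic threshold sits where the per-cycle
  infection gain `c·beta` balances the per-cycle clearance *probability*
  `1 - exp(-gamma)`, slightly below the continuous-time criterion
  `c·beta = gamma`. The test suite verifies this by bisection against
  long-run simulation.
* A low-prevalence endemic equilibrium is *intrinsically* near the
  threshold (for an SIS process, low prevalence and near-criticality are
  the same thing), where the equilibrium is hypersensitive to `beta` and
  transients span decades. Tuning `beta` so that the endemic force of
  infection matches a small calibrated onset hazard is therefore
  ill-posed. The package instead fixes the transmission parameters at a
  comfortably supercritical operating point shared across regions
  (`default_cervical_transmission()`: partner change concentrated in ages
  15–49, endemic group prevalences of a few percent to ~15% among active
  ages) and calibrates *region-specific cervical incidence through the
  HPV→CIN1 progression intensities* with the dynamic model in the loop.
  Conceptually, once infection is governed by a shared behavioural
  contact process, the population-specific "onset" of the cancer process
  is the HPV→CIN transition.

A corollary of the shared susceptible pool is weak competition between
subtype groups: vaccinating 16/18 away frees susceptibles for the other
groups. The effect is small at the chosen operating point (the other
groups are well above threshold, so their equilibria barely move), and
the invariant "other groups unchanged under 16/18 vaccination" is tested
where it holds cleanly — when the vaccinated group's prevalence is small.

## Calibration

`calibrate_onset_rates()` is a deliberately simple proportional-fitting
routine standing in for full population-specific rate estimation (out of
scope here): it rescales the onset-kind intensities (or any designated
edge set) age band by age band until simulated clinical incidence
(diagnosis-edge flows per 100,000 per year over a quasi-stationary
window) matches targets within 1%, erroring with residuals on
non-convergence. An `onset_lag` maps a diagnosis band to the onset ages
that drive it (≈ the precancer + preclinical sojourn; 12 years for the
cervical HPV→CIN calibration). For cervical disease a second calibration
pass is run from the settled state with its measurement window aligned
to the state stored as the bundle's initial occupancy, so the stationary
incidence seen by downstream scenario runs is the calibrated one; the
closure achieved is better than 1% and is re-verified in the tests at
the 2% level. Breast and colorectal bundles likewise store their
calibrated equilibrium as the initial state, so every scenario starts
from the standing epidemiology rather than a disease-free population.

## Interventions

`build_catalog()` encodes the fourteen interventions (nine cervical,
three breast, two colorectal): HPV vaccination of 9–13-year-old girls
(implemented as routine vaccination of the age-12 cohort), cervical
screening of women 30–49 by VIA, Pap smear or HPV test linked with
treatment of pre-cancerous lesions, the three vaccination-plus-screening
combinations (unions of their components' effects), stage I–II treatment
for each cancer, biennial mammography for women 50–69 linked with
diagnosis and treatment, and basic palliative care. Coverage scales
linearly: the covered fraction experiences the full per-protocol effect.

* Screening frequencies become annual screen probabilities
  `coverage / interval`: VIA every 10 years (the schedule is not pinned
  down in guidance, so the interval is an explicit config default), Pap
  every 4 years (midpoint of the quoted 3–5), HPV test every 5,
  mammography every 2. Screening raises preclinical→clinical diagnosis
  intensities by `σ × sensitivity` in the eligible band and adds a
  screen-detect-and-treat regression intensity from CIN back to HPV
  (returning women to the infected, not the healthy, state — which
  matters because it re-exposes them through the CIN pathway rather than
  through reinfection). Test specificity affects costing only (false
  positives), never state dynamics.
* Treatment multiplies the excess mortality of clinical stages I–II by
  0.25 (I) and 0.45 (II) for the treated fraction; stage III/IV
  treatment is not in the catalog, so late stages are reached only by
  palliative care. Mammography's "linked treatment" carries the
  treatment technology in its technology set, which is what lets it
  supersede stand-alone treatment on the expansion path.
* Palliative care switches the terminal-phase DW from "without
  medication" to "with medication" for the covered fraction.

## Disability weights and HLYs

`derive_dw()` derives per-state weights from six published GBD-2010-style
estimates. Untreated pre-terminal stages inflate the "diagnosis and
primary therapy" weight by the ratio of the terminal-phase weights
without/with medication (the only reading of that rule yielding a ratio
≥ 1), capped at 1. The terminal stage uses the published estimates
directly. Treated weights are cancer-specific: cervical CIS–II
first-year-corrected, stage III uncorrected; breast CIS–II an equal
weighted average of diagnosis and mastectomy weights (the exact weights
are not published, so the mix is a config default), first-year-corrected;
colorectal adds the stoma weight for the 5% of patients with a stoma,
first-year-corrected except stage III. Treated weights are additionally
capped at the untreated derivation, since the stoma add-on can nominally
exceed it when the terminal ratio is near 1 and treatment should never
worsen disability. The metastatic estimate is carried and validated but
unused by the default mapping, because stage IV doubles as the terminal
phase. The first-year-of-treatment fraction is operationalized as a
prevalence-weighted average weight (bundle default 0.3, reflecting long
survivorship after treated early-stage disease).

`healthy_life_years()` returns undiscounted and discounted HLYs;
discounting multiplies year-*t* person-time by `1.03^-(t-1)` and a
discount rate of zero makes both totals identical. ACERs and ICERs use
*undiscounted* HLYs — the convention under which the published
programme-level ratio equals total discounted cost over total
undiscounted HLY — while discounted HLYs are always computed alongside.

## Costing

`scenario_cost()` values the resource plan (vaccine doses, screens,
false-positive follow-ups, screen-positive work-ups, stage-specific
treatment courses, surveillance years, palliative-care years) at unit
costs in 2010 I$, scaled by a regional price level. Screening programmes
add a programme-level component (administration, quality assurance,
monitoring) sized to 20% of the screening programme's total cost;
vaccination and treatment carry their own itemized costs without that
rule. All flows discount from programme start; the breakdown sums to the
total to numerical precision. League tables carry costs in million I$.

## The decision layer

`dominance_filter()` removes strictly dominated and extended-dominated
points, leaving a frontier with non-decreasing ICERs (verified against a
brute-force chord-definition oracle in the tests). `expansion_path()`
walks the menu of evaluated (intervention, coverage) points under the
programmatic lock-in constraint: once a technology is adopted at some
coverage, every later point on its arm must retain it at the same or
higher coverage. Arms are connected groups of interventions sharing a
technology (vaccination and screening connect through their
combinations; treatment and palliative care stand alone); they affect
disjoint states and budgets, so the path interleaves arms purely by ICER
order. Within an arm the walk greedily adopts the feasible point with
the lowest ICER versus the current point, breaking near-ties (within
0.1%) towards the larger health gain so that effectively linear
interventions enter at full coverage directly, and prunes steps made
extended-dominated by their successors so ICERs are non-decreasing along
each arm. League-table ratios round half-up to integers; programme-level
ACERs to two decimals.

`budget_allocation()` reports integer percent shares of total discounted
cost by cancer at the end of the path, and accepts either a computed
path or a named vector of published totals, which is how the package's
arithmetic layer reproduces the published budget shares exactly.

## Synthetic data and what it does (not) show

The regional parameter sets behind the published analysis live in
supplementary materials that are not reproduced here, so
`generate_region_params()` builds complete, internally consistent
synthetic bundles: GLOBOCAN-like age-band incidence targets, a
Gompertz-Makeham demography with an infant bump standardized to 10
million alive, shared natural-history constants, synthetic
GBD-plausible DW inputs (seeded jitter — the only randomness anywhere;
the simulations are deterministic), ingredients-style unit costs, and
the calibrations described above. `make_two_region_demo()` provides a
Southeast-Asia-like profile (moderate cervical incidence, price level
1.0) and an eastern-sub-Saharan-Africa-like profile (about 2.5× the
cervical incidence, price level 0.85).

Passing tests on these bundles demonstrate that the machinery is
correct and that the qualitative decision structure — prevention before
screening, treatment before mammography, cervical programmes cheaper
per HLY where incidence is higher, palliative care cheap to add but far
from the frontier's origin — emerges from the mechanisms the models
encode. They do not validate region-specific magnitudes: the synthetic
effect sizes, unit costs and natural-history constants are plausible
but not estimated from data, molecular subtypes are not distinguished,
and screening-induced overdiagnosis, treatment capacity constraints and
HPV genotype resolution beyond three groups are not modelled.

## Problem sizes and numerical conventions

The shipped configuration simulates both regions at the full 100-year
horizon with single-year ages 0–100 and annual cycles; a full two-region
pipeline (null plus 42 scenario evaluations per region, including
calibration and transmission burn-in) completes in well under a minute.
Calibration tolerance is 1% per band with a cap of 100 iterations and
per-iteration scale factors clipped to [0.1, 10]; the cervical
transmission burn-in runs 150 years from a 2% seeded prevalence.
Coverage values outside {0, 0.5, 0.8, 0.95} are rejected unless
explicitly overridden. Zero-coverage scenarios are bit-for-bit identical
to the null by construction, which the tests assert literally.
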