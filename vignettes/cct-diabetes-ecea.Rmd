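---
title: "Methods: an extended cost-effectiveness microsimulation of cash transfers for diabetes care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an extended cost-effectiveness microsimulation of cash transfers for diabetes care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`eceasim` implements an individual-level annual-cycle Markov model of the
diabetes care cascade in South Africa, used to evaluate conditional cash
transfer (CCT) strategies that subsidise attendance at diabetes services for
the poorest income quintiles. A cohort of adults aged 25–69 in the eligible
quintiles is simulated over a 45-year horizon with one-year cycles. Each
person occupies one state per cycle:

* **Cascade states** — Healthy; undiagnosed diabetes; diagnosed, not on
  pharmacological treatment; and three therapy states (oral, insulin,
  combination).
* **Complication states** — nephropathy, retinopathy, neuropathy, angina,
  peripheral vascular disease, myocardial infarction, stroke, heart failure,
  severe hyperglycaemia, severe hypoglycaemia. These are transient: an event
  drawn in one cycle is occupied for exactly the following cycle, after which
  the person returns to their prior cascade position. Complication risk
  applies to everyone with diabetes; being on any pharmacological therapy
  multiplies each risk by its therapy-effect ratio (e.g. 0.30 for
  nephropathy; 1 for severe hyperglycaemia, encoded as published although it
  reads as counterintuitive).
* **Absorbing states** — diabetes-related death and other-cause death.

Within a cycle, events resolve in a fixed hierarchical order — other-cause
death, diabetes death, diabetes onset, diagnosis, treatment initiation (or
re-initiation), non-adherence, then a single complication draw (first drawn
in the fixed order wins). Earlier events pre-empt later ones, so the realised
per-cycle event distribution is a proper categorical distribution. The order
is a modelling choice; it is documented here because no canonical order
exists for annual-cycle competing risks.

Care-seeking is governed by three utilisation probabilities: `p_dx` (annual
probability an undiagnosed person is diagnosed), `p_dt` (probability a newly
diagnosed person initiates therapy that year, with later re-initiation at
`p_reinit` per year), and `p_tna` (annual probability a treated person leaves
treatment). A CCT covering diagnosis services multiplies the *odds* of
`p_dx` (and of the healthy population's screening attendance `p_screen`) by
the intervention odds ratio, 1.31 (95% CI 1.12–1.54). A CCT covering
treatment services multiplies the odds of adherence (`1 - p_tna`) and — by
default, since the transfer pays for attending treatment services — the odds
of initiation (`p_dt`, `p_reinit`); set `treatment_boosts_initiation = FALSE`
for the adherence-only reading. The same odds ratio is used for every
service type, as in the source estimate.

## Accounting

Costs and health outcomes accrue per person per cycle and are discounted at
5% per year:

* **Health-system costs**: the occupied state's annual direct medical cost,
  plus all transfer outlays ($13 per screening/diagnosis visit, $51 per full
  adherent treatment-year paid as four quarterly transfers), plus an optional
  administrative loading (`admin_cost_fraction`, 0 by default, 0.5 in the
  one-way scenario).
* **Out-of-pocket (OOP) costs**: the occupied state's annual OOP amount
  (transport plus wage loss, as a single figure).
* **DALYs**: the occupied state's disability weight for the cycle; a death
  contributes weight 1 for the death cycle and every remaining horizon cycle
  (discounted years of life lost, truncated at the horizon rather than at
  life expectancy, matching the simulation frame). DALYs are discounted like
  costs by default (`discount_dalys = FALSE` switches this off).

Incremental analysis uses the health-system perspective only: the ICER and
the incremental net monetary benefit, INMB = threshold × ΔDALYs per person −
Δcost per person, at South Africa's supply-side threshold of $3015 per DALY
averted. OOP costs enter only the financial-risk-protection outcomes.

Catastrophic health expenditure (CHE) is assessed per person-year: annual
OOP spending against 10%, 25% and 40% of capacity to pay (income minus the
food poverty line, floored at $1). Spending is **net of transfers received
that year** (floored at zero): the CCT is designed to offset exactly the
transport and wage-loss costs it conditions on, and without netting a
programme that adds treatment person-years would mechanically *increase*
CHE, contradicting the design intent. `net_cct_from_oop = FALSE` restores
gross accounting; on gross OOP, a null intervention (odds ratio 1) averts
exactly zero CHE cases. "Cases" are person-years in CHE, the natural unit of
an annual-cycle model.

All strategy arms for a given cohort are simulated under common random
numbers: every (cycle, decision) pair has its own deterministic random
stream derived from one seed, aligned to cohort row order, with dead
individuals still consuming their positions. Incremental contrasts therefore
difference out first-order Monte Carlo noise, and a null intervention
reproduces the comparator exactly.

## Synthetic inputs and calibration

The published analysis drew its stratum rates (diabetes incidence and
mortality by age, sex and income quintile; background mortality), income
parameters and baseline utilisation from national surveys and
burden-of-disease sources that it did not print. This package therefore
synthesises those inputs, with every choice documented and overridable in
the YAML config:

* **Baseline prevalence and cascade position.** Generated cohorts hit the
  published validation prevalences (17.5% in quintile 1, 18.4% in quintile
  2) by construction: the synthetic incidence curves are scaled per quintile
  (bounded root search on a cumulative-hazard mapping) so a uniform 25–69
  age pyramid implies those prevalences, and the population generator draws
  baseline diabetes from the same mapping. Baseline diabetics are split
  across cascade states by the published proportions (0.600 undiagnosed,
  0.007 diagnosed-untreated, 0.196 oral, 0.036 insulin, 0.160 combination,
  renormalised from their printed sum of 0.999), so ~40% of diabetics start
  diagnosed.
* **Incomes.** Per-quintile gamma distributions (shape 2, scale set so the
  untruncated mean sits at the band midpoint) truncated to documented
  placeholder band boundaries; the food poverty line defaults to $510 per
  person-year, the national food poverty line (~R561/month in 2019) converted
  to 2020 USD. Against the placeholder income bands this leaves much of
  quintile 1 at the capacity floor and the lower part of quintile 2
  financially vulnerable, which is what gives both eligible quintiles
  meaningful financial-risk-protection outcomes. Incomes are held constant in
  real terms over the horizon.
* **Sex structure.** A 50/50 sex split with a 1.3:1 female:male diabetes
  incidence ratio, reproducing the published qualitative finding of a higher
  female burden (and hence larger female INMB and FRP benefits).
* **Ageing.** Uniform ages 25–69 at entry; people age past 69 during the
  horizon and reuse the top rate band beyond the table.
* **Utilisation and mortality defaults.** `p_dx = 0.08`, `p_screen = 0.09`,
  `p_dt = 0.30`, `p_reinit = 0.20`, `p_tna = 0.35`; diabetes-related excess
  mortality grows exponentially with age from a base of 0.035 with a
  quintile gradient, multiplied by 0.40 on pharmacological therapy. These
  were calibrated *once*, by a grid exploration against the published
  anchors — the ~40% diagnosed baseline, and the published orderings
  INMB(diagnosis+treatment) ≥ INMB(treatment) > 0 > INMB(diagnosis-only)
  with positive CHE aversion in treatment-covering arms — and then frozen.
  Two consequences are worth stating plainly. First, the treated share of
  diagnosed people drifts below the published baseline occupancy as the
  cohort evolves: a parameterization that both preserves that occupancy
  (near-universal treatment uptake) and reproduces the published economic
  orderings does not exist in this model family, because with near-universal
  uptake the $51/year transfer to the standing treated stock dominates
  incremental cost. Second, the mortality level is a calibration artefact
  chosen for the economic structure, not an estimate of South African
  diabetes mortality; neither it nor any other synthetic default should be
  quoted as an epidemiological quantity.
* **Screening transfers.** In diagnosis-covering arms, healthy eligible
  people attend an annual screening visit with (odds-boosted) probability
  `p_screen` and receive the $13 transfer regardless of test result. This is
  what makes the diagnosis-only arm expensive per person relative to its
  small health gain, as in the published results; switch
  `screening_transfers = FALSE` to pay only for true diagnosis visits.

What passing tests on these synthetic inputs do **not** show: agreement with
the published absolute totals (they depend on the unprinted supplementary
tables), realistic South African rate levels, or household-level income
dynamics. What they do show: the accounting identities, the competing-risk
semantics, the distributional machinery and the published qualitative
structure are implemented correctly.

## Sensitivity machinery

* **PSA.** Gamma-distributed costs (mean at the point estimate, CV 0.2),
  a log-normal odds ratio matched to the 95% CI (implied median 1.313,
  consistent with the reported 1.31 at printed precision), and
  beta-distributed probabilities (method of moments, CV 0.2). These families
  are asserted as standard practice — the supplement that specified the
  originals is unavailable — and are fully configurable. Each draw re-runs
  every arm on a common cohort, isolating parameter uncertainty;
  population-replicate machinery reports sampling variability separately.
* **CEAC.** The probability each arm has the highest net monetary benefit at
  each willingness-to-pay value. The no-programme comparator is included as
  a zero-net-benefit arm by default; without it the cheapest CCT arm would
  mechanically "win" at low willingness-to-pay.
* **One-way analyses.** The built-in scenarios vary the odds ratio across
  its 95% CI (applied to both channels, diagnosis only, or treatment only)
  and administrative cost between 0 and 50% of outlays. Because
  administration affects nothing but the payer's ledger, its INMB effect has
  a closed form — admin fraction × discounted transfer outlay per person —
  which the tests verify exactly.

## Numerical choices and problem sizes

Random streams are derived on the MINSTD lattice with all intermediates
exact in doubles; every public entry point is deterministic given its seed.
Ties in the therapy-assignment draw are broken by the renormalised published
therapy split (oral 0.50, insulin 0.092, combination 0.408 among initiators).
The packaged test suite exercises the model at the sizes the package's own
validation uses: cohorts of 50,000 (strategy orderings, averaged over
simulation-seed replicates of one cohort to remove residual Monte Carlo
noise from the between-arm contrasts), 100,000 (agreement of state
occupancies with the deterministic expected-value recursion within three
standard errors), and PSA at 200 draws × 10,000 people. The study-scale
configuration (12 million represented people, 100 PSA draws, 1000 population
replicates) is reached by raising `--n`, `--draws` and `--pops` in the
command-line interface; per-person results are stable well below that scale.

## Limitations

Beyond the synthetic-input caveats above: no secular trends in incidence or
mortality over the 45-year horizon; no half-cycle correction (annual event
resolution); complication states carry no excess mortality beyond the
stratum diabetes mortality; one complication at most per person-year;
non-adherent mid-year exits still receive the full $51 treatment-year
transfer (annual resolution cannot see quarters); and diagnosed people never
revert to undiagnosed.
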