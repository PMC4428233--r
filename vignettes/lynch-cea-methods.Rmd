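---
title: "Methods: a cost-utility model of reflex testing for Lynch syndrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cost-utility model of reflex testing for Lynch syndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lynchcea)
```

## The decision problem

Lynch syndrome (LS) is an autosomal-dominant cancer predisposition caused
by mismatch-repair gene mutations (*MLH1*, *MSH2*, *MSH6*, *PMS2*).
Carriers face substantially elevated lifetime risks of colorectal cancer
(CRC) and, in women, endometrial cancer (EC).  Identifying LS in newly
diagnosed early-onset CRC patients ("probands") allows biennial
colonoscopic surveillance and prophylactic hysterectomy with bilateral
salpingo-oophorectomy (H-BSO), and — through cascade predictive testing —
extends those benefits to relatives.  The question the package answers is
economic: which of nine diagnostic strategies (combinations of
microsatellite-instability testing, mismatch-repair immunohistochemistry,
*BRAF* V600E or *MLH1*-hypermethylation triage, diagnostic mutation
testing and Amsterdam II family-history criteria) buys health most
efficiently for an annual national cohort, at a willingness-to-pay of
£20,000 per quality-adjusted life year (QALY)?

## Model structure

The model has two components, combined linearly.

**Diagnostic submodel** (`build_strategy()`, `evaluate_probands()`,
`cascade_relatives()`).  A decision tree evaluated in expectation: the
proband cohort is split into carrier strata (by mutated gene, because IHC
routing in strategy 3 depends on *which* protein is lost) and a sporadic
stratum; each test node applies its sensitivity to carriers and its
false-positive rate to non-carriers.  *BRAF* and methylation testing carry
distinct accuracies depending on whether MSI or IHC preceded them; where
no conditional estimate exists, test independence is assumed.  Probands
referred for genetic testing may decline counselling or testing and are
then classified *LS assumed* or *LS negative* on family history, as is a
proband whose mutation test is negative.  Confirmed mutations trigger
predictive testing of five first-degree relatives (Mendelian carriage
probability 0.5), and confirmed carrier relatives seed one further cascade
generation.  The relative population is held fixed across strategies so
that incremental comparisons never change the cohort — relatives of
negative probands simply remain untested.

**Management submodel** (`simulate_individual()`, `simulate_cohort()`,
`accrue()`).  A continuous-time individual patient simulation over
(role × sex × carrier status × accepted surveillance × accepted H-BSO)
cells, to age 100 or death.  Event times (CRC, metachronous CRC, EC,
general mortality from a life table, stage-specific excess cancer
mortality) are drawn by inversion from piecewise-constant hazards — no
model cycles and no half-cycle correction, so closed forms exist for every
check.  Under surveillance the index-CRC hazard is multiplied by 0.387 and
the metachronous hazard by 0.533 while the individual is in the
surveillance window (ages 25–75, biennial colonoscopies; late entrants
start at entry age).  At most two CRCs occur per lifetime; probands enter
having had the first.  Surveillance-detected cancers are shifted toward
earlier Dukes' stages via a configured stage distribution.  H-BSO is
offered at age 40 (or entry, if later) to accepting women diagnosed with
LS and removes subsequent EC risk, with a small procedural mortality.

Costs are booked at event times and discounted at 3.5% per annum;
colonoscopy unit costs carry a 2/3 multiplier (the effectiveness evidence
comes from 3-yearly surveillance, so biennial colonoscopy costs are
deflated to avoid biasing against the intervention).  QALYs integrate an
age/sex quadratic population-norm utility with continuous discounting,
minus disutilities: 0.13 from metastatic (Dukes' D) CRC diagnosis until
death, and a four-month genetic-testing disutility booked to *short-term*
QALYs at the diagnostic phase.  Base-case disutilities for colonoscopy,
EC and H-BSO are zero; the H-BSO value is the pivotal sensitivity
parameter (see below).

**Cost-utility engine** (`combine_submodels()`, `icer()`, `inhb()`,
`find_frontier()`).  Strategy totals are diagnostic counts × per-cell mean
outcomes plus diagnostic costs.  The frontier algorithm removes strictly
dominated strategies (no more effective, no less costly; equal QALYs at
higher cost count as dominated), then iteratively removes
extended-dominated strategies until the incremental cost-effectiveness
ratio (ICER) ladder is strictly increasing.  Incremental net health
benefit (INHB) is `ΔQALY − ΔCost/λ` at λ = £20,000/QALY.  ICERs are
reported rounded half-away-from-zero to the nearest pound; QALYs and INHB
to 0.1 — internal computation is full precision.

## Randomness, pairing and reproducibility

Each simulation replicate consumes a fixed block of uniform draws (one
per event channel, plus one complication and one procedural-death draw per
potential colonoscopy).  The block matrix is generated once per seed and
shared across *all* profile cells, strategies, scenario arms and
sensitivity runs: common random numbers make between-arm increments
paired, so e.g. varying a pure cost parameter moves no QALYs at all, and
the surveillance arm's CRC incidence is pathwise delayed relative to the
no-surveillance arm (inversion sampling shares the uniform).  Identical
seeds give bit-identical result bundles, and every output directory
carries a manifest (seed, replicates, parameter hash) from which a rerun
reproduces all tables exactly.

## Tunable parameters that matter

| Parameter | Default | Units / source |
|---|---|---|
| Discount rate (costs and QALYs) | 0.035 | per annum, reference case |
| Willingness-to-pay | 20,000 | £/QALY |
| Surveillance hazard ratio, index CRC | 0.387 | Finnish cohort estimate |
| Surveillance hazard ratio, metachronous CRC | 0.533 | Italian cohort estimate |
| Carrier cumulative risk to 70: CRC (M/F), EC | 0.38 / 0.31 / 0.33 | published penetrance (PMS2 carriers excluded) |
| Metastatic CRC disutility | 0.13 | until death |
| Genetic-testing disutility | 0.01 for 4 months | magnitude synthetic (see below) |
| H-BSO disutility | 0 (0.1 in sensitivity) | pivotal parameter |
| Cohort: probands/year, LS prevalence | 1,699, 8.4% | under-50 inclusion |
| Relatives per confirmed proband | 5 FDRs (+3 per carrier, one generation) | |
| Surveillance policy | ages 25–75, 2-yearly | colonoscopy cost ×2/3 |
| Horizon | age 100, max 2 CRCs | |

All other inputs (test accuracies, unit costs, uptakes, stage
distributions, excess mortality, the life table) are synthetic stand-ins
for an unavailable supplementary parameter set.  Every value carries a
provenance tag; `provenance_summary()` counts anchored versus synthetic
entries.

## What the synthetic generator emulates — and what a green test shows

`generate_parameter_set("anchored")` fixes every main-text value exactly
and fills gaps with plausible defaults; `"random"` mode draws from stated
ranges for property tests.  Three synthetic magnitudes were deliberately
*calibrated to the published qualitative findings* rather than estimated:
the Amsterdam II specificity (0.998 — the criteria demand three affected
relatives over two generations and are rarely met by chance in sporadic
families), the mutation-test unit cost (£500) and the genetic-testing
disutility (0.01).  With these, the stated qualitative anchors hold: every
testing strategy is cost-effective versus no testing; MSI → BRAF →
mutation testing maximises INHB; direct mutation testing joins the
frontier below £20,000/QALY only when mutation-test costs are halved; and
an H-BSO disutility of 0.1 makes every testing strategy's INHB negative.
This is a tuning, not a reproduction: a green qualitative test establishes
that the model mechanics produce the published *pattern* under a stated
world, not that the published *numbers* are recovered.  The exact printed
tables are reproduced only by the replay surface (`replay_cea()` on
`generate_table2_fixture()`), which bypasses simulation entirely.

Known divergences of the synthetic world: (i) life expectancies and
absolute cost/QALY totals do not match the published secondary-outcome
table (its parameters are unavailable, and our continuous-time clock
differs from whatever cycle structure the original used); (ii) in our
parameterisation the proband-only ("no relatives identified") ICER is
*lower* than the full-cascade ICER — the opposite ordering to the
published prose — because young relatives incur surveillance costs decades
before their heavily discounted benefits; the stated acceptance property
(no-relatives ICER below £20,000) holds regardless.

## Numerical choices

* **Hazard calibration** is exact interval-wise inversion of
  `F = 1 − exp(−H)` (no optimiser); the calibration-inverse property is
  tested to 1e−9, and simulated incidence recovers the age-70 penetrance
  targets within three Monte-Carlo standard errors at n = 200,000.
* **Discount integrals** use the closed form of
  `∫ poly(age) · e^{−δt} dt` with `δ = log(1+r)`; `δ = 0` is handled
  exactly.  Note the continuous integral of a unit utility over two years
  at 3.5% is 1.9328, slightly below the discrete annual sum 1.9662.
* **Event ordering** with at most three incidences (two CRCs, one EC) is
  resolved chronologically so a cancer death can censor later incidences;
  ties at a death age leave the earlier-booked cause in place.
* **Dual accrual routes**: the vectorised cohort engine and the
  event-list `accrue()` path compute the same quantities independently and
  are cross-checked to 1e−9.
* **Degenerate inputs**: zero hazards give death exactly at the horizon;
  zero QALY differences make the ICER undefined (dominance logic applies,
  never division); empty confusion-matrix denominators return `NaN`.
* **Schedule conventions**: biennial colonoscopies at 25, 27, …, 75 (26
  for a full-span participant); probands not under LS surveillance receive
  routine post-CRC follow-up colonoscopies at +1, +4 and +7 years, which
  is why the no-testing baseline still counts colonoscopies.

## Design choices where the design was open

* The genetic-testing disutility magnitude is unstated in the main text
  (only its four-month duration); relatives testing *negative* also incur
  it (they were tested), configurable.
* Relatives of LS-assumed probands accept surveillance at the same uptake
  as confirmed carriers (configurable; the source is silent).
* Cascade depth beyond first-degree relatives is one extra generation
  with three second-degree relatives per confirmed carrier.
* IHC gene-level routing uses a mutation-spectrum distribution
  (MLH1/MSH2/MSH6/PMS2 = 0.40/0.35/0.18/0.07), a 0.95 probability that an
  abnormal panel flags the truly mutated gene, and a 0.92 probability that
  sporadic loss presents as MLH1.
* Variants of uncertain significance are absorbed into mutation-test
  sensitivity rather than modelled as an outcome.
* Mutation-test false positives in sporadic families are treated as a
  benign familial variant inherited with Mendelian arithmetic but
  conferring no cancer risk.
* Penetrance excludes PMS2 carriers (as in the source estimates) while
  the mutation spectrum includes them; the inconsistency is recorded in
  the provenance notes and is conservative (slightly overstates carrier
  risk for PMS2 families).

## Limitations

Ovarian and other extracolonic cancers, gynaecological surveillance,
chemoprevention and probabilistic sensitivity analysis are out of scope by
design.  The service-demand projection attrites cohorts by general
mortality only (not excess cancer mortality), which slightly overstates
steady-state colonoscopy demand.  Exact reproduction of the published
life-expectancy table is not attempted: the required supplementary
parameters are unavailable, and the continuous-time engine would not match
a cycle-based original to printed precision even with them.
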