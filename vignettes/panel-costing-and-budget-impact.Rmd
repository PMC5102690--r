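---
title: "Costing NGS panels and the budget impact of molecular diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing NGS panels and the budget impact of molecular diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcost)
```

## The problem

Molecular diagnostics for stage-IV non-small-cell lung cancer (NSCLC) and
melanoma has been moving from sequential single-gene tests towards
next-generation sequencing (NGS): first targeted gene panels (TGPs), and, in
specialised centres, whole-genome sequencing (WGS). Health-care payers and
laboratories need two numbers before committing: what one panel test really
costs under realistic laboratory throughput, and what the switch does to the
yearly diagnostic budget. `panelcost` implements both calculations as a
deterministic, configuration-driven model, plus the surrounding apparatus: a
one-way sensitivity layer, a before/after institutional case-study pipeline,
and a seeded synthetic cohort generator that makes the patient-level pipeline
testable without patient-level data.

## Activity-based costing of a panel test

Each panel x platform combination is described by an *activity schedule*:
every resource-consuming step of the workflow with its personnel minutes,
material costs and annualised equipment costs. Aggregation yields a
three-layer decomposition:

* fixed yearly costs \(F_y\) (equipment depreciation and service),
* fixed costs per run \(F_r\) (personnel and material a run consumes
  regardless of occupancy),
* variable costs per sample \(v\).

Given a run plan — \(k\) patient samples booked per run, \(r\) runs per week,
fill fraction \(\phi \in (0,1]\), \(w\) operating weeks per year and overhead
fraction \(h\) — the cost per patient sample is

\[
C(k, r, \phi) \;=\; (1 + h)\,
\frac{F_y/(w r) + F_r + (n_p + c)\,v}{n_p},
\qquad n_p = \phi k,
\]

where \(c\) is the number of quality-control samples: one for runs of at most
eight booked samples, two otherwise. Controls consume variable costs only;
their cost is spread over the patient samples. Overhead (default 30%) is
applied multiplicatively to the full per-sample cost, with VAT treated as
embedded in material purchase prices; this convention reproduces the
published per-sample totals of all four panel x platform combinations within
2% (three of them within 1%). Fixed costs make \(C\) strictly decreasing in
\(k\), \(\phi\) and \(r\); the minimum quoted cost of a panel is the value at
a completely full 48-sample run.

Defaults that matter:

| parameter | default | why |
|---|---|---|
| `samples_per_run` | 24 | routine operating point at which per-sample costs are quoted |
| `runs_per_week` | 1 | weekly diagnostic batch |
| `fill_fraction` | 0.85 | average observed occupancy of booked runs |
| `weeks_per_year` | 52 | equipment annualisation spread uniformly over runs |
| `overhead_fraction` | 0.30 | institutional overhead on the full per-sample cost |

The run capacity is 48 samples, except the medium (capture) panel on the
benchtop sequencer, which coverage requirements restrict to four samples per
run.

### Calibrated personnel rates

Per-role hourly employer costs are not public. The packaged rates
(`load_personnel_rates()`) are therefore *calibrated constants*: the
schedules print per-step minutes, and the per-role euro-per-minute rates were
solved once so that both panels' schedules aggregate exactly to the published
fixed-per-run and variable-per-sample personnel totals. Two consequences are
worth knowing. First, the split of sample-level vs run-level work is a
modelling choice: run execution, data synchronisation/run check and (for the
medium panel) capture batching are treated as run-level, with minutes scaled
from the per-sample timings at the 48-sample batch size. Second, the
board-member rate prices the whole multi-member tumour sequencing board per
meeting minute, which is why it is an order of magnitude above the individual
rates. The rates are fixtures, not estimates of any person's salary.

Two published figures are deliberately not reproduced: the
four-sample-run cost of the medium panel on the benchtop sequencer and the
upper endpoint of the current-cost sensitivity range; neither can be
decomposed from printed information under any fill convention we could
justify, so the package exposes the fill convention as a parameter instead of
guessing (the minimum-cost figure uses a complete run, the maximum-cost
figure an 85%-filled run; both reproduce their published counterparts).

## Budget impact analysis

The BIA follows the ISPOR good-practice structure. For each time frame
(old/2012, current/2015, future/2020) and indication, patients split into a
peripheral and a specialised hospital stratum (NSCLC 70/30, melanoma 30/70),
each stratum receiving a test bundle priced from a unit-cost catalog.
Fractional applicability (a confirmatory test for half of the patients) is an
expected cost, not patient-level sampling; molecular diagnostics is costed
once per newly diagnosed patient. Then

\[
\text{cost/patient}(t) = \sum_{s} \pi_{s}(t)\, B_{s}(t), \qquad
\text{population}(t) = N(t) \cdot \text{cost/patient}(t),
\]

and budget impacts are differences between frames on unrounded values
(positive = cost increase). Future populations (4,474 NSCLC / 887 melanoma)
are taken as printed configuration rather than recomputed from the stated
11% growth, whose own rounding differs.

Two source inconsistencies forced explicit choices, both encoded in the
configuration rather than in code. (1) The scenario table prints bundle
costs that drift from the catalog sums by up to one euro (its tables round
independently); each scenario therefore carries the printed cost, preferred
by default (`use_printed = TRUE`), while `bundle_cost()` always prices from
the catalog. (2) The NSCLC current-peripheral cell is 559 in the scenario
table but 590 (two single-gene tests at 295) in the running text; 590 is
canonical because it is consistent with the published per-patient summary
cells and deltas, and the 559 variant ships as
`default_bia_config("alt559")`. Reconstructed population totals agree with
the published ones within 0.1%; the published population *deltas* embed the
source's own intermediate rounding (one of them differs from its own
operands by one euro), so agreement there is 0.05–0.11%.

The projected WGS price is a first-class computation:
`wgs_price_projection(1250, 4, 0.75, 0.88)` — four genomes per patient
(tumour in triplicate plus germline), a 75% five-year cost reduction, dollars
to euros — gives the 1,100-euro catalog entry.

## Sensitivity analysis

`one_way()` evaluates an outcome model at the low and high end of one
parameter, everything else at base; `tornado()` stacks entries sorted by
descending range width (stable under ties). Two model builders are packaged:

* `future_bia_model()` — population budget impact of the future frame
  relative to the current frame, with the future panel price, future WGS
  price and specialised-care share perturbable. Perturbations apply to the
  future frame only (the current frame keeps its base costs); this is the
  only reading consistent with the published NSCLC swing. The share
  perturbation is relative (70% becomes 56%/84%) with the peripheral share
  renormalised. The conventional symmetric range is 20%.
* `current_cost_sensitivity()` — per-patient test cost in the current
  specialised setting: panel cost per sample under the run plan plus 0–3
  additional single-gene tests. Published bar ranges other than the
  additional-test count are not printed, so the default ranges (run size
  4–48, 0.5–2 runs/week, fill 0.5–1) are the package's own realistic
  operating ranges and explicit `sensitivity_param()`s override them.

## Institutional case study and synthetic cohorts

The case-study pipeline summarises per-patient testing records by period
(tests, costs, cost per test, mutation counts, twelve binary
treatment/mutation categories), compares periods variable by variable, and
annualises a 3.5-month observation window to a yearly institutional budget
impact. Test choice follows a fixed rule: continuous and normal in both
groups (Shapiro–Wilk at 0.05 per group — the conventional default, the
source names no procedure) gives a Welch t-test; continuous otherwise gives
a two-sided Mann–Whitney U (exact for small untied samples, normal
approximation with tie correction otherwise — appropriate at the case
study's group sizes of 36–53); binary variables give a two-sided Fisher
exact test (point-probability method). Zero-variance variables are reported
as degenerate with the p-value omitted. No multiplicity correction is
applied across variables, matching the source analysis.

Patient-level records were never published, so the pipeline is exercised on
synthetic cohorts. A cohort profile fixes the arm size, the test-count
distribution (mean and range), a test mix, the mutation-count distribution
and category prevalences. Test counts follow a truncated shifted Poisson on
\(\{min,\dots,max\}\) whose rate is calibrated (by root finding) so the
truncated mean equals the profile mean; mutation counts use the same
construction without the shift. Calibrating after truncation — rather than
truncating a Poisson at the target rate — keeps cohort-level estimates
convergent to the profile values even where the range binds (the
melanoma-before arm has mean 0.75 on \(\{0,1\}\)). Tests are drawn without
replacement by weight until the distinct entries of the mix are exhausted,
then with replacement (repeats stand for the same assay class applied to
different genes). Category flags are independent Bernoulli draws; some
categories are logically exclusive in reality, so prevalences are matched
but joint structure is not. The generator reproduces marginal structure
only: no correlation between test count and mutation count, no cost-driven
test selection, no temporal ordering. Passing tests therefore validate the
pipeline's arithmetic and calibration, not clinical realism of any single
synthetic patient.

Checked properties (the suite's larger simulations): parameter recovery at
n = 10,000 within three standard errors; empirical size of the null
mean-tests comparison within three standard errors of 0.05 over 1,000 seeded
cohort pairs; power above one half at the published before/after separation
(mean 2.04 vs 3.00 tests at n = 47/53 — empirically about 0.98).

## Numerical conventions and limitations

* All composition is done on unrounded values; `round_euro()` (half away
  from zero) is applied only at the reporting layer. The published tables
  show their own one-euro rounding drift, which is why "exact" checks are
  exact only after rounding and population-level checks carry a 0.1% band.
* Determinism: every stochastic function takes an explicit seed; identical
  (profile, seed) yields byte-identical CSV output, and `render_tables()`
  writes no timestamps so repeated runs are byte-identical.
* Simulation sizes in the test suite (10,000-patient recovery cohorts,
  1,000-seed null replicates, 100-seed power estimates) are chosen so each
  standard-error band is a small multiple of the effect being measured while
  the whole suite stays around a minute.
* Out of scope by design: treatment-cost consequences and
  cost-effectiveness; the RNA part of the medium panel; repeat testing over
  disease progression; probabilistic (multi-way) sensitivity analysis;
  liquid-biopsy and centralised-testing scenarios.
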