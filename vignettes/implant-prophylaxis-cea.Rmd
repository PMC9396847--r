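---
title: "Decision-tree cost-effectiveness analysis of antibiotic prophylaxis at implant placement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-tree cost-effectiveness analysis of antibiotic prophylaxis at implant placement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceatree)
```

## The decision problem and the model

A patient in good general health needs a single posterior implant. The
decision is whether to give a prophylactic antibiotic course (amoxicillin)
around placement. The model is a decision tree with a one-year horizon and
two strategies:

- each strategy leads to a chance node: the implant **survives** the year
  (probability `pantsurv` = 0.9878 with antibiotics, `pnoantsurv` = 0.9567
  without) or fails;
- on failure, a second chance node: the implant is **replaced** within the
  year (probability `preplac` = 0.85) or not;
- a replaced implant **survives** with probability `psurvsecond` = 0.89;
  there is no second replacement.

Failure branches carry the complements `1 - p` of the survival
probabilities, so probability mass is conserved at every chance node by
construction. Terminal payoffs:

- **effect**: an oral-health utility on a 0–1 scale (a rescaled General Oral
  Health Assessment Index): `effImplant` = 0.88 on any path ending with a
  functioning implant, `effNoImplant` = 0.71 after implant loss. The horizon
  is one year and no discounting is applied; these are utilities, not QALYs.
- **cost** (2021 EUR): the placement cost `cImplantPlacement` = 1002 on every
  path; `cImplantReplacement` = 1102 on replacement paths; and on every
  terminal of the antibiotic arm the course cost `cAntibiotics` = 10.20, the
  expected adverse-event cost `pAE × ae_unit_cost`, and — under the
  healthcare perspective — the antibiotic-resistance cost
  `cAntibioticResistance`.

Rolling back the tree gives each strategy's expected cost and effect; the
incremental comparison is summarised as ICER = ΔC/ΔE and net monetary
benefit NMB = λE − C at willingness to pay λ = 3000 EUR per utility unit.

```{r base-case}
base_case_report(wtp = 3000)
```

## Perspectives

The **patient** perspective covers what an Italian private-practice patient
pays: placement, the course, and over-the-counter medication for a mild
adverse event (10 EUR). The **healthcare** perspective additionally bears
what antibiotic externalities cost the public system: severe adverse events
costed at the hospital DRG tariff (`cAE` = 705 EUR) and a per-course
antibiotic-resistance cost. The untreated arm is identical across
perspectives.

Two modelling choices here were genuinely open:

- **Adverse events as a cost adder, not a chance branch.** The adverse-event
  probability (`pAE` = 0.000023 per course) enters as an expected-cost term
  `pAE × unit cost` on every antibiotic-arm terminal rather than as a branch,
  because no effect decrement for an adverse event is available. At the base
  probability the contribution is under 0.02 EUR either way, far below
  reporting precision; the unit cost is an argument of `perspective()`.
- **The resistance-cost value.** The source estimates average 11.15 USD per
  course, 9.47 EUR at the 2021 exchange rate of 0.85 EUR/USD
  (`convert_usd_eur()`). The case study's healthcare results are, however,
  internally consistent only with an effective adder of 13.97 EUR, which is
  what `implant_parameters()` uses as the base value;
  `implant_parameters(resistance_cost = 9.47)` selects the unadjusted
  estimate. Both values sit inside the sensitivity range 2.9–32.16 EUR, and
  the threshold analysis below shows how much the conclusion can bear.

## Parameters and tested ranges

```{r params}
as_tibble_params(implant_parameters())
```

Base values are treated as final (already inflation-adjusted);
`adjust_inflation()` is provided for deriving new cost inputs but is not
re-applied to the table.

## Deterministic sensitivity analysis

One-way sweeps re-roll the tree across a parameter's tested range with
everything else at base values. Thresholds — the parameter value at which
the two strategies' NMBs are equal — are found with a bracketing root solver
(`stats::uniroot`, relative tolerance 1e-8, 200 iterations cap); the NMB
difference is continuous and monotone in each single parameter of this tree,
so a sign change across the bracket guarantees a unique root. A range over
which the NMB difference never changes sign is reported as an error
("no threshold in range"): dominance holds across the whole tested range.

```{r thresholds}
tree <- build_implant_model("healthcare")
strat <- c("Antibiotics", "No Antibiotics")
find_threshold(tree, "cAntibiotics", wtp = 3000, strategies = strat)
find_threshold(tree, "cImplantReplacement", wtp = 3000, strategies = strat)
find_threshold(tree, "pAE", wtp = 3000, strategies = strat)
find_threshold(tree, "cAntibioticResistance", wtp = 3000, strategies = strat)
```

Direction of each relation: antibiotic-arm costs (`cAntibiotics`, `pAE`,
`cAntibioticResistance`) erode the antibiotic strategy's advantage as they
rise (inverse relation), while a higher replacement cost
`cImplantReplacement` strengthens it (direct relation), since prophylaxis
exists to avoid replacements.

The tornado ranking evaluates a chosen output at each parameter's range
endpoints. The default output is the incremental NMB at λ = 3000: an ICER
span is unstable when ΔE passes near zero inside a range, while NMB is
linear in both cost and effect. Note two consequences of ranking by raw
span over the *tested* ranges: the survival probabilities, swept over wide
ranges (0.6 up to their base), dominate the ranking, and `cImplantPlacement`
has exactly zero influence because both arms pay it identically.

```{r tornado}
tornado(tree, wtp = 3000)
```

## Probabilistic sensitivity analysis

The published parameter table states distribution *families* only — normal
for costs, beta for effectiveness — and no hyperparameters. The rules used
here, both configurable in `build_distributions()`:

- **costs**: normal with mean at the base value and sd = (high − low)/3.92,
  i.e. the tested range read as a central 95% interval, truncated at zero by
  rejection (resampling, not clipping, so the retained shape is the
  conditional distribution);
- **utilities**: beta with the mean matched to the base value and
  concentration κ = α + β = 100 (sd ≈ 0.03 at a mean of 0.88), a
  conventional moderate-information choice;
- the seven cost/utility parameters are sampled; the branch probabilities
  are held fixed.

This is the largest gap between the published analysis and anything
reconstructible from it: with ranges this asymmetric (e.g. `cAntibiotics`
base 10.20, range 5–100) the truncated normal is strongly right-skewed and
its mean sits well above the base value, so published Monte Carlo counts
can only be matched as a band, not a point. The PSA here is run from the
patient perspective — the case study's primary one — under which the
antibiotic strategy stays preferred at every willingness to pay; under the
healthcare perspective the same rules push the mean sampled course-plus-
resistance cost high enough that preference at low WTP becomes marginal.

Draws are seeded and bit-reproducible; a draw that would break tree validity
is rejected and resampled from a deterministically seeded stream (none occur
under the default rules, where support constraints are enforced at draw
time). Ties at the maximal NMB are split fractionally across tied
strategies, so acceptability-curve probabilities sum to one exactly at every
WTP.

```{r psa}
tree_pat <- build_implant_model("patient")
specs <- build_distributions(tree_pat$parameters)
psa <- run_psa(tree_pat, sample_draws(specs, 1000, seed = 1), specs)
ice_summary(psa, wtp = 3000, "Antibiotics", "No Antibiotics")
cc <- ceac(psa, seq(0, 10000, by = 100))
min(cc$probability[cc$strategy == "Antibiotics"])
```

## Numerical choices

- Chance-node probability conservation is checked to 1e-9 absolute (inputs
  are exact decimals); all internal arithmetic is full double precision, and
  rounding happens only in reports.
- An effectiveness difference below 1e-12 makes the ICER undefined (`NA`),
  never an infinity.
- Rollback and brute-force path enumeration agree to 1e-9 on randomly
  generated trees (the `random_tree()` generator draws branch probabilities
  from a normalised-uniform simplex with the last weight set to the exact
  complement — a fixture choice, not a statistical claim).
- Default grids: 101 points for one-way sweeps; WTP 0–10,000 in steps of 100
  and n = 1000 draws for the PSA. The test suite uses smaller grids and draw
  counts (200–1000) where the property under test does not need more.

## What the synthetic generator does and does not show

`random_tree()` produces structurally valid trees with literal probabilities
and payoffs: it exercises conservation, rollback-vs-enumeration equivalence,
convexity bounds and seeding, independently of the case study. It does not
emulate clinical structure — no parameter sharing across strategies, no
complement-linked branches, no cost/effect correlation — so passing those
properties says nothing about the realism of any particular model's inputs,
only about the engine's arithmetic.

## Known limitations

- Effectiveness is a one-year oral-health utility, not a QALY; results are
  not comparable across disease areas.
- Thresholds published for this case study are internally inconsistent
  (two printed values differ by ~2 EUR for the course cost and ~16 EUR for
  the replacement cost); the values computed here (19.01, 768.83, 22.78,
  0.0125 at λ = 3000, healthcare perspective) fall between or near the
  printed pairs and are reproducible from the stated model, which is the
  property the engine guarantees.
- The PSA hyperparameter rules are reconstructions; conclusions that depend
  on the exact spread of the cost distributions (quadrant counts, CEAC
  levels at low WTP) should be read as bands.
- Single decision node, finite acyclic trees, time-independent payoffs: no
  Markov/state-transition structure, no multi-stage decisions, no
  discounting.
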