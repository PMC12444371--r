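---
title: "Strategic menu optimization: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strategic menu optimization: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menuswap)
```

## The problem

Many catered settings — hospitals, schools, workplace canteens — offer a
fixed weekly menu of, say, three main dishes per day over five weekdays
(15 dishes in all). Each diner picks one dish per day, so the weekly
environmental and nutritional outcome of the menu depends not just on which
dishes are offered but on *which dishes compete with which* on the same day.
Swapping dishes between days changes that competition structure without
adding or removing any dish, and can therefore steer choices toward
lower-carbon or lower-saturated-fat options while every diner still gets to
pick their favourite among the day's offer.

`menuswap` implements this strategic-swap analysis end to end:

1. **Preference measurement.** Each participant completes a complete
   round-robin two-alternative forced-choice (2AFC) task: every pair of the
   15 dishes is shown once, `choose(15, 2) = 105` trials. Dishes are ranked
   per participant by *win count* — the number of trials in which the dish
   was chosen.
2. **Menu enumeration.** A weekly menu is a partition of the 15 dishes into
   5 unordered days of 3. There are
   `15! / (3!^5 * 5!) = 1,401,400` such partitions; requiring at least one
   vegetarian dish per day reduces this to 113,400 (5 vegetarian + 10 meat
   dishes) or 340,200 (6 + 9).
3. **Choice prediction.** For every menu, every participant is assumed to
   select the best-ranked of the three dishes offered each day.
4. **Optimization.** Cohort mean weekly carbon footprint (CF, g CO2e per
   person) and saturated-fat intake (SFA, g per person) are computed for
   every feasible menu and compared with a baseline menu as percent changes;
   the menus minimizing CF alone, SFA alone, or an equal-weight combination
   of both percent changes are reported.

## The choice model and its assumptions

The prediction step is deliberately minimal: a participant's daily choice
is the offered dish with the numerically smallest rank. This makes
selections purely rank-driven and deterministic, with three consequences
worth stating explicitly:

* **No within-week variety seeking.** A participant may be predicted to
  choose similar dishes on consecutive days; day choices are independent.
* **No stochastic choice at prediction time.** All stochasticity lives in
  the data (or the synthetic generator); prediction is a pure function of
  the rankings.
* **Linearity and scale invariance.** Selections depend only on ranks, so
  multiplying all CF (or SFA) values by any positive constant scales the
  weekly means by the same constant and leaves every percent change and
  every optimal-menu identity untouched. Percent reductions are therefore
  robust to *systematic* over- or under-estimation of the attribute values
  (e.g. recipe-matching error that inflates all footprints alike) — an
  invariance the test suite checks at scale factors 0.1, 3 and 10.

Cohort outcomes average the per-participant weekly sums across the cohort,
which is how heterogeneity in preference enters the optimization: the menu
is chosen once for the whole cohort, not per individual.

## The joint objective

For a menu `m` with cohort means `CF(m)` and `SFA(m)` and a baseline `b`,

```
pct_cf(m)  = 100 * (CF(m)  - CF(b))  / CF(b)
pct_sfa(m) = 100 * (SFA(m) - SFA(b)) / SFA(b)
joint(m)   = 0.5 * pct_cf(m) + 0.5 * pct_sfa(m)
```

"Equal weights" is interpreted as the unweighted mean of the two
*baseline-normalized percent changes*. The alternative — weighting raw
grams — is unit-dependent (g CO2e and g SFA are incommensurate) and would
make the weights meaningless; normalizing by the baseline first makes a
50/50 weighting well-defined. The weights are configurable
(`objective_spec("joint", weights = ...)`) and the definition is recorded in
every run manifest.

Two sign properties matter when reading results. The baseline is itself a
feasible menu, so the single-target optima and the joint *score* can never
be worse than 0. The *componentwise* percent changes at the joint optimum,
however, are only guaranteed non-positive when the two attributes do not
trade off too strongly: under a strong negative CF–SFA correlation the
equal-weight optimum can worsen one variable while improving the other
more. With the weak positive correlation typical of real dish data (and the
generator's default), both components come out as reductions.

## The synthetic-cohort generator

Published menu studies of this kind rest on participant-level choice data
that is not generally redistributable, so the package ships a generator
that emulates the study design and makes every stage testable:

* **Dishes.** `n_dishes = 15`, of which `n_vegetarian = 5` (or 6 for the
  menu variant with a two-vegetarian day). Log CF and log SFA are drawn
  from a bivariate normal and exponentiated, guaranteeing positivity;
  `attribute_correlation` (default 0.2) is the latent log-scale
  correlation, reflecting that footprint and saturated fat are only weakly
  related at the dish level. Defaults `cf_log_mean = log(2200)`,
  `cf_log_sd = 0.45` give per-serving footprints of roughly 1–6 kg CO2e,
  and `sfa_log_mean = log(12)`, `sfa_log_sd = 0.5` give roughly 5–30 g SFA
  per serving — magnitudes consistent with hot main dishes, yielding
  baseline weekly means near 11–13 kg CO2e and 55–80 g SFA per person.
  Vegetarian dishes receive no systematic CF offset by default: real menus
  likely do have lower-footprint vegetarian dishes, but no per-class
  distribution is assumed.
* **Preferences.** Participant utilities follow
  `u[p, i] = m[i] + e[p, i]` with `m[i] ~ N(0, utility_population_spread²)`
  shared across the cohort and `e[p, i] ~ N(0, utility_heterogeneity²)`
  per participant (defaults 1 and 1: population taste and idiosyncrasy
  equally strong).
* **Responses.** The 2AFC responder is Bradley–Terry/logistic on utility
  differences: dish `a` beats `b` with probability
  `plogis((u_a - u_b) / choice_temperature)`. This is the standard
  generative model for pairwise choice data; at `choice_temperature = 0` it
  degenerates to a perfectly transitive responder whose win counts are
  exactly `14, 13, ..., 0` and whose ranking equals the latent utility
  order — the regime in which the win-count ranking provably recovers the
  truth, used heavily in tests. Exact utility ties at temperature 0 break
  toward the lower dish id, keeping the degenerate path deterministic.

What the generator does **not** emulate: regional differences between sites
(every synthetic site is an independent draw), demographic covariates,
response errors correlated across trials, and any dependence of preference
on the attributes themselves (taste is independent of CF/SFA by default).
Passing tests on synthetic sites therefore validate the *machinery* —
combinatorics, prediction, optimization, reproducibility — not the
real-world magnitude of achievable reductions, which depends entirely on
the real preference and attribute data supplied.

## Numerical and algorithmic choices

* **Enumeration.** Menus are enumerated anchor-first: the day containing
  the smallest unused dish is completed by every pair of larger remaining
  dishes, recursively. Each partition is visited exactly once, already in
  canonical form (days sorted by smallest member, ids ascending within a
  day), in strictly increasing lexicographic order — which both makes the
  stream deterministic and proves it duplicate-free. The implementation is
  level-wise vectorized; the full 1,401,400-partition space enumerates in a
  few seconds and the constrained spaces in well under one.
* **Counting.** `count_menus()` is an independent closed form: labelled-day
  assignments are summed over per-day vegetarian-count compositions
  (products of multinomial coefficients) and divided by `5!`. For example
  `113,400 = [10!/(2!^5)] / 5! × 5!` from the single composition
  `(1,1,1,1,1)`. Enumeration and closed form are cross-checked in the tests
  and in the acceptance script.
* **Ties in win counts.** Cyclic choices make ties possible (three dishes
  beating each other circularly all earn one win). Default policy: a
  two-way tie is resolved by the tied pair's head-to-head trial; larger tie
  groups fall back to ascending dish id. The policy is deterministic,
  auditable, pluggable (`tie_rule`), and coincides with plain win-count
  ranking whenever counts are distinct — which is always the case for a
  transitive responder.
* **Ties among optimal menus.** All menus within a relative tolerance of
  1e-9 of the optimum are reported as co-optimal, with the canonically
  first designated representative. The tolerance exists because menus
  inducing identical selections are mathematically tied yet accumulate
  their attribute sums in different orders, so exact floating-point
  equality would split genuine ties arbitrarily.
* **Degenerate inputs.** Zero attribute variance gives constant dishes
  (all reductions exactly 0); constraint infeasibility (e.g. one vegetarian
  dish but five days needing one each) raises an error naming the deficit
  in `enumerate_menus()` and returns 0 in `count_menus()`; non-partition or
  constraint-violating baselines are rejected before any computation.
* **Reproducibility.** Every random draw flows from one integer seed;
  stage-specific offsets derive independent streams for dishes, utilities,
  trial order and baseline sampling, and the caller's RNG state is restored
  afterwards. Identical configuration + seed reproduces a run bundle
  byte-for-byte.

## Problem sizes used in the test suite

Unit tests run on toy sites (6 or 9 dishes, 2 or 3 days) where a monolithic
brute-force re-implementation — labelled-day recursion, canonical-key
deduplication, plain-loop evaluation — is feasible and serves as the
oracle; the pipeline is required to agree exactly over 20+ randomized
sites. Property suites use 50 random 15-dish sites at full 113,400-menu
scale for the dominance and sign invariants, and the end-to-end check runs
the complete 11-site replica (50 participants per site) twice to verify
byte-identical output. These sizes keep the whole suite within a few
minutes on a single core while still exercising the full study-scale menu
space.

## Limitations

Beyond the generator's idealizations listed above, the package scope
matches the analysis it implements: menus with repeated dishes across the
week are rejected (the partition combinatorics do not apply), no
Pareto-front analysis beyond the three stated objectives is offered, and
portion sizes, side dishes and special diets are outside the model.
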