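---
title: "Acceptability-weighted diet optimization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acceptability-weighted diet optimization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietshift)
```

## The problem

Diet optimization asks how an observed population diet should change to meet
nutritional recommendations, or to cut its greenhouse-gas emissions (GHGE),
while staying *acceptable* — close to what people already eat. dietshift
implements a quadratic goal-programming model built for studying the
introduction of a *novel food* (the motivating case is mycoprotein, a fungal
meat alternative) into an observed diet. The novel food has zero baseline
intake, so models built on relative deviations from baseline break down, and
treating it as a perfect substitute for meat overstates its uptake. The model
here addresses both problems.

## The model

The diet is a vector of daily intakes $q_i$ (g/day) over $n$ food categories,
each belonging to exactly one of $m$ food groups with totals
$Q_j = \sum_{i \in S_j} q_i$. Given observed baselines $q_i^0, Q_j^0$ and
observed population SDs $\sigma_i, \sigma_j$, the objective minimized is

$$
\sum_{i=1}^{n} w_i \left(\frac{q_i - q_i^0}{\sigma_i}\right)^2 +
\sum_{j=1}^{m} z_j \left(\frac{Q_j - Q_j^0}{\sigma_j}\right)^2,
$$

with the direction-dependent category weight $w_i$ equal to $w_i^+$ for
increases and $w_i^-$ for decreases. Deviations are SD-standardized: a change
is measured against the typical variation of that food's intake in the
population, so widely varying foods are penalized less per gram. Group-level
terms penalize substitution *between* groups more than substitution *within*
a group, which is what lets a meat alternative absorb meat-group mass without
the whole diet reshuffling.

Implementation uses the split-variable formulation: each category carries an
above-baseline level $q_i^+ \ge q_i^0$ and a below-baseline level
$0 \le q_i^- \le q_i^0$ with $q_i = q_i^+ + q_i^- - q_i^0$ (and likewise per
group), so increases and decreases can carry different weights while the
problem stays a convex quadratic program. Because the objective is strictly
convex with positive weights, deviations at the optimum are one-sided; the
independent audit (`audit_solution()`) *asserts* this complementarity rather
than assuming it.

### Penalty weights

Within each group, baseline intake is min–max normalized to $p \in [0,1]$ as
a popularity proxy, and

$$ w_i^+ = 2 - p_i, \qquad w_i^- = 1 + p_i. $$

Both lie in $[1, 2]$ and sum to 3. Increasing an unpopular food is maximally
penalized ($w^+ = 2$), decreasing it minimally ($w^- = 1$); the group's most
popular food gets the mirror image. A zero-baseline novel food is its group's
minimum by construction and therefore receives $w^+ = 2, w^- = 1$: the model
is *reluctant* to adopt it. Group weights default to $z_j = 2$.

Two cases the normalization formula does not cover are decided here: a
degenerate group whose members all share one baseline gets the neutral value
$p = 0.5$ (weights 1.5/1.5, inside the admissible range), and ties at the
group minimum or maximum all receive the extreme weight, which is what the
formula itself produces. The "no penalty weights" sensitivity variant sets
every $w^\pm$ to 1 but leaves $z_j$ untouched, since the weights being
removed are the category-level ones.

One open modelling point: the normalization set is the full group $S_j$, even
though popularity comparisons are most meaningful among foods consumed in
similar quantities. Users who want a narrower comparison set can reorganize
groups accordingly.

### Constraints

`build_constraints()` assembles, per options:

* **nutrition** — lower/upper bounds on daily nutrient intake. Bounds can be
  absolute per day, or percent-of-energy for macronutrients; the latter are
  converted to absolute grams using the fixed energy target and a
  kJ-per-gram factor supplied per nutrient (e.g. 37 for fat, 17 for protein
  and carbohydrate). The conversion is exact because energy is an equality.
* **energy** — dietary energy pinned at its observed level.
* **feasible-range** — each category boxed between the 5th and 95th
  percentile of observed consumption. A zero 95th percentile (rarely eaten
  foods with positive mean) is replaced by the mean observed intake.
* **group-cap** — the novel food carries no category box; instead its host
  group's total is capped at the group-level 95th percentile. When the group
  file supplies no group percentile, the sum of member 95th percentiles is
  used as a (looser) surrogate.
* **fixed** — categories like water pinned at baseline.
* **mass** — total food mass within ±20% of baseline (`mass_band = 0.2`).
* **ghge** — optional cap on dietary GHGE (kg CO2e/day).
* **group-total** — optional pinned group totals (the scenario ladder).
* **nonneg** — $q \ge 0$, kept even where a positive 5th percentile makes it
  redundant (exact duplicates of a zero 5th-percentile box row are omitted).

All constraint rows live in $q$-space tagged with a family label; the QP and
LP engines translate them into their own variable spaces, and the audit
re-checks them in $q$-space independently of either solver.

### Scenario strategy

`run_nutr()` solves under everything except a GHGE cap, giving the
nutritionally adequate **NUTR** diet. `run_ghge_ladder()` then re-solves with
the cap set to $(1-x)$ times the NUTR diet's GHGE for an increasing ladder of
reduction fractions $x$ (default 5%–60% in 5% steps), while pinning the novel
food's host-group total at its NUTR value — so emission cuts must come partly
from *within-group* substitution toward low-emission members, including the
novel food. The ladder stops at the first infeasible step and reports
statuses; `max_feasible_reduction()` bisects on $x$. Objective values are
non-decreasing and diet GHGE non-increasing along the ladder (nested feasible
sets); the test suite asserts both. Population strata (male/female) are pure
data changes; no code path inspects the stratum label.

### The piecewise-linear comparator

The comparator model replaces the quadratic objective with relative
deviations $|q_i - q_i^0| / q_i^0$, linearized through non-negative up/down
deviation variables. Design choices, since relative deviation is undefined at
a zero baseline: zero-baseline categories use their imputed intake SD as the
denominator (configurable), which keeps the term dimensionless and on a
scale comparable to the SD-standardized quadratic model. The directional
category weights are applied to the linear terms by default, and group terms
(weight $z_j$, denominator $Q_j^0$) are included symmetrically to the
quadratic objective; both are toggleable in `build_lp()`. Alternative optima
are a real possibility for an LP; the solver reports its vertex and sets a
`degenerate` flag from zero reduced costs, with no lexicographic refinement
attempted.

## Solvers and numerical choices

The QP is solved with `quadprog::solve.QP` (dual active-set). Three
numerical measures keep the solve robust at survey scale:

* the problem is preconditioned by a change of variables into SD units with
  unit-norm constraint rows, which bounds the Hessian's conditioning;
* coincident bound pairs are emitted as single equality rows — a nutrient
  with equal lower and upper bound, and the novel food's $q^-$ interval
  $[0, 0]$ — because opposing inequality pairs at the same hyperplane are
  exactly the degenerate geometry active-set methods handle worst;
* rows that duplicate another row exactly are omitted (non-negativity under
  a zero 5th-percentile box; the host-group cap when that group's total is
  pinned at or below the cap).

None of these change the feasible set. Feasibility is audited at
`1e-6` absolute on g/day rows scaled by the row norm, and the recomputed
objective must agree with the solver objective to `1e-6` relative.

No robust LP package being available in the package's dependency set, the
LP engine ships its own dense two-phase primal simplex: Dantzig pricing with
an automatic switch to Bland's rule after a stretch of degenerate pivots
(guaranteeing termination), phase-1 artificial variables for feasibility,
and reduced costs exposed for the degeneracy flag. It is written for the
moderate dense problems this package generates (a few hundred rows and
columns) and is tested against exhaustive vertex enumeration on small
instances.

In the test suite, solver correctness is established by dual-route checks:
the QP against a generic nonlinear minimizer (`nloptr::slsqp`) run on the
piecewise-quadratic objective directly in $q$-space, and the LP against
brute-force enumeration of arrangement vertices (constraint rows plus the
kink planes $q_i = q_i^0$). Closed-form toy cases (a forced group shift
split equally between two identical categories) pin the arithmetic.

## The synthetic survey generator

`generate_survey()` produces the survey structure the model expects with no
external data: by default 79 categories in 13 groups, right-skewed positive
baselines (log-normal within group-specific scales), SDs proportional to
baselines (CV 0.9, floored at 1 g), percentile bounds bracketing the mean, a
fixed high-intake water category, and exactly one zero-baseline novel food
in a designated host group, its SD imputed as the mean SD of the five
largest host-group members. A small fraction of categories (5%) get a zero
95th percentile to exercise the mean-replacement rule.

Scales are chosen for realism of magnitude, not to imitate any country's
data: default surveys total roughly 3–4 kg and 13 MJ per day. The host
group is deliberately meat-like — about six times the emission intensity of
the rest of the diet — and the novel food sits at half its host group's mean
GHGE with a price near the group maximum. That qualitative economics
(high-emission host group, low-emission expensive alternative) is what makes
substitution-direction regressions on fixtures meaningful at all; with a
generic host group the novel food never becomes a GHGE lever and direction
tests degenerate to noise-level ties.

What the generator does *not* emulate: correlations between nutrients and
food groups (a synthetic "meat" group is not systematically protein-rich),
item-level aggregation, survey measurement error, or realistic nutrient
units. Passing tests therefore demonstrate the optimization machinery and
its invariants, not nutritional conclusions about any real population.

`make_feasible_spec()` builds nutrient bounds at $(1 \pm s)$ times baseline
intakes so the observed diet is always feasible; `make_binding_spec()`
raises one nutrient's lower bound above its baseline so it must bind,
forcing non-trivial substitutions in solver tests.

## Problem sizes and runtimes

The test suite runs full-scale fixtures (79 × 13) for scenario, sensitivity
and reporting tests, 100+ random 4–6-category instances for the QP oracle
comparison, and 3-category instances for exhaustive LP enumeration; the
whole suite completes in well under a minute on a single CPU. Scenario
ladders in tests use 5–10 percentage-point grids over the 5%–50% range.

## Limitations

* The spec registry ships an illustrative nutrient-constraint example, not
  any country's official recommendation set; real analyses must supply
  their own bounds (the full Finnish-style set runs to dozens of rows).
* Penalty weights proxy acceptability by observed intake popularity;
  elicited preferences are out of scope.
* The group-level 95th percentile falls back to the sum of member
  percentiles when absent from the data, which is looser than a measured
  group percentile.
* Prices are static; no demand or supply response is modelled.
* The packaged market-product profile for the novel food is synthetic and
  illustrative (see `inst/extdata/`), intended to be replaced by measured
  product data.
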