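# dietshift

Acceptability-weighted diet optimization with novel foods.

## What this package is for

How much of a meat alternative such as mycoprotein would a population
actually adopt if its diet had to become nutritionally adequate and much
lower in greenhouse-gas emissions (GHGE) — without straying far from what
people already eat? dietshift answers this class of question with a convex
quadratic goal-programming model for researchers in nutrition and
sustainable-diet modelling. It is built specifically for *novel* foods: a
food with zero baseline intake breaks relative-deviation objectives and, if
treated as a perfect meat substitute, produces wildly optimistic uptake.

## The model

Over $n$ food categories nested in $m$ food groups, the model minimizes

$$
\sum_{i=1}^{n} w_i \Big(\tfrac{q_i - q_i^0}{\sigma_i}\Big)^2 +
\sum_{j=1}^{m} z_j \Big(\tfrac{Q_j - Q_j^0}{\sigma_j}\Big)^2
$$

where $q_i$ is the optimized and $q_i^0$ the observed intake (g/day),
$Q_j = \sum_{i \in S_j} q_i$ are group totals, and deviations are
standardized by the observed intake SDs $\sigma_i$, $\sigma_j$. The weight
$w_i$ is directional — $w_i^+ = 2 - p_i$ for increases, $w_i^- = 1 + p_i$
for decreases, with $p_i$ the within-group min–max normalized baseline
intake (a popularity proxy) — so increasing an unpopular food costs the most
and a zero-baseline novel food enters reluctantly with $w^+ = 2$,
$w^- = 1$. Group weights default to $z_j = 2$. Increases and decreases are
separated by split deviation variables, making the problem a strictly
convex QP.

Constraints: nutrient bounds (absolute or percent-of-energy), energy pinned
at its observed level, per-category 5th–95th percentile consumption boxes,
a group-level cap for the novel food's host group, fixed categories
(water), total mass within ±20% of baseline, and an optional GHGE cap. The
scenario engine first solves the nutritionally adequate **NUTR** diet, then
a ladder of **NUTR+GHGE-X%** scenarios capping GHGE at $(1-x)$ of the NUTR
level while holding the host-group total fixed — forcing within-group
substitution toward low-emission members. A piecewise-linear comparator
model, four sensitivity-analysis variants, reporting tables and a synthetic
survey generator round out the toolkit. See
`vignettes/dietshift-methods.Rmd` for the full account.

## Worked example

```r
library(dietshift)

survey <- generate_survey(seed = 7)      # synthetic 79 x 13 survey
spec   <- make_binding_spec(survey, "protein", push = 0.08)

nutr   <- run_nutr(survey, spec)
ladder <- run_ghge_ladder(survey, spec, nutr, reductions = seq(0.1, 0.4, 0.1))
print(nutr)
```

```
Scenario 'NUTR' [qp]: optimal
  objective 1.05305 | energy 13398.8 kJ | mass 4221.0 g | GHGE 8.416 kg CO2e | cost 14.61 EUR
  binding constraints: 4
```

The NUTR diet meets the raised protein bound by deviating from the baseline
diet at an acceptability cost of 1.05 (in squared SD units), leaving energy
at its observed 13,399 kJ/day. Walking down the GHGE ladder (each step caps
emissions relative to NUTR's 8.416 kg CO2e/day and pins the host-group
total), the novel food is progressively adopted:

```
new-food intake (g/day) along the ladder:
         NUTR NUTR+GHGE-10% NUTR+GHGE-20% NUTR+GHGE-30% NUTR+GHGE-40%
         0.00          0.95          1.95          2.30          2.08
```

At the 40% reduction step the diet's GHGE is 5.050 kg CO2e/day, the novel
food holds 3.1% of its host group's mass
(`category_breakdown(...)$new_food_share`), and the host group contributes
21.6% of dietary GHGE (`group_shares(..., "ghge")`). Objective values rise
(1.93 → 4.64 → 10.13 → 23.35) as the cap tightens: acceptability is traded
for emissions.

Sensitivity variants re-run the whole grid with one declared change:

```r
config <- diet_config(survey, spec, reductions = seq(0.1, 0.4, 0.1))
run_variant(config, "ghge_scale", list(scale = 0.5))   # -50% new-food GHGE
run_variant(config, "no_category_weights")             # drop w+/w- weights
run_variant(config, "engine_swap")                     # piecewise-linear LP
```

A command-line wrapper lives at `inst/cli/dietshift`
(`fixtures generate`, `optimize nutr`, `optimize ladder`,
`sensitivity run`, `report`).

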