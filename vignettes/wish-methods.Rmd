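---
title: "Scoring diets with the WISH: model, conventions and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring diets with the WISH: model, conventions and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wishindex)
library(dplyr)
```

## The index

The World Index for Sustainability and Health (WISH) scores a diet on 13
EAT-Lancet food groups, each on a 0–10 adherence scale, so the total ranges
from 0 to 130. Each component combines a health classification (protective,
neutral, or limit) with an environmental impact classification (low, medium,
high), and its score is a piecewise-linear function of the daily intake in
g/day. Because the total dilutes opposing signals — a diet heavy in both
protective and limiting foods can score the same as a uniformly moderate one
— four sub-scores are reported alongside it: *healthy* (the 10 protective
and neutral groups, max 100), *less healthy* (the 3 limiting groups, max
30), *low environmental impact* (6 groups, max 60) and *high environmental
impact* (7 groups, max 70). Each pair partitions the components, so
`healthy + less_healthy` and `low_env + high_env` both equal the total;
the package derives every maximum as 10 × membership size rather than
hard-coding it, so locally adapted registries aggregate correctly.

The registry ships with the published thresholds:

```{r}
tidy(wish_index())
```

## Scoring shapes and boundary conventions

Five shapes cover the 13 groups:

* **ramp_up_open** (whole grains, vegetables, fruits, legumes): 0 below the
  lower bound, then `10 (x - lower) / (recommended - lower)`, and 10 from
  the recommended intake upward with no upper restriction.
* **ramp_up_capped** (unsaturated oils): the same rising ramp, but intakes
  strictly above the upper bound (80 g/day) score 0, since surplus fat
  intake raises energy intake.
* **optimum_band** (dairy, fish, nuts): `10 x / recommended` up to the
  recommended intake, a plateau of 10 across the tolerated band, and 0
  strictly above the upper bound — these groups carry a medium/high
  environmental burden, so over-consumption forfeits the whole score.
* **ramp_down** (red meat, eggs, poultry): 10 at or below the recommended
  intake, then `10 ((upper - recommended) - (x - recommended)) /
  (upper - recommended)` down to 0 at the upper bound, 0 beyond it.
* **bivariate_limit** (saturated oils, added sugars): 10 at or below the
  single cut-off, 0 above it.

Boundary inclusivity follows the verbal definitions: plateau edges are
inclusive (saturated oils at exactly 11.8 g/day → 10; dairy at exactly
500 g/day → 10), while "below"/"above" bounds are strict (whole grains at
99.99 g/day → 0; dairy at 500.01 g/day → 0). At the foot of a rising ramp
the formula itself yields 0 (whole grains at exactly 100 g/day → 0). The
jumps at the optimum-band and capped-ramp upper bounds and at the bivariate
cut-offs are intentional features of the index; no smoothing is offered.
Two interpretive choices are worth flagging: the "scored as a ratio" phrase
for the 0-to-recommended stretch of dairy/fish/nuts is implemented as a
straight line through the origin, and unsaturated-oil intakes between 40
and 80 g/day score 10 under the generic plateau rule, the only reading
consistent with the 80 g/day cap.

Intakes must be non-negative and finite; negative or NaN values are hard
errors rather than being clamped, to surface data-cleaning problems early.
Scores keep full floating precision internally; summaries are conventionally
reported to one decimal.

```{r}
score_component(c(99, 100, 112.5, 125), "whole_grains")
score_component(c(10, 14, 21, 28, 30), "red_meat")
```

## From recalls to scores

24-hour-recall data arrive as one record per subject per recall day.
`read_intakes()` accepts wide (one column per food group, the canonical
layout) and long CSV dialects; `map_food_items()` collapses item-level
records through a user-supplied item→group mapping, with an `EXCLUDED`
sentinel for foods the index deliberately omits (refined grains, tubers,
fruit juice, pickled vegetables). No default mapping is shipped — food
lists are context-specific — but a documented template with the group
definitions is installed under `extdata/`. `average_recalls()` takes the
unweighted arithmetic mean across recall days and, by default, drops
subjects with fewer than two recalls, mirroring the duplicate-recall
design; both choices are parameters. Energy-based outlier cleaning is out
of scope by design: the index needs no food composition table, and an
exclusion list hook covers ad-hoc cleaning.

Missing component columns follow an explicit policy: `"zero"` (default)
treats the component as not consumed and warns, `"strict"` errors.
Non-consumers are legitimate in recall data, but an absent column more
often signals a broken mapping.

## Population summaries

`summarize_wish()` reports, per component, the percentage of non-consumers
(recall-averaged intake exactly 0 — the subject-level definition used in
survey tables; a per-day variant of consumer status exists in the
simulator), mean (SD) intake over all subjects, mean (SD) score, and a
direction-of-change label: for protective/neutral groups *Increase* /
*Decrease* / *Good* as the population mean intake is below / above / at the
recommended amount; for limiting groups *Good* at or below the cut-off,
*Decrease* above. The comparison is against the point recommendation, not
the tolerated range — the one rule that reproduces the published advice
column for all 13 groups, including fish, whose mean sits inside its
10-point band yet is labelled *Decrease*. We flag this as a reporting
convention rather than the original authors' confirmed procedure. SDs use
the sample (n−1) convention; a single-subject population reports SD 0 with
a warning.

## Correlation analysis

`correlate_wish()` computes the Spearman rank correlation matrix across the
13 component scores, the four sub-scores and the total, with average-rank
tie handling. Components are left inside the total when correlated with it;
the part–whole correlation is the analysis as published, and a
`leave_one_out` flag removes each component from the total for users who
want the purged variant. Scores constant across the population (common when
nearly everyone scores 0 or 10) admit no rank correlation and are excluded
with reason `"constant score"`; exact equality is the right default test
because scores sit exactly on the breakpoint values, and a tolerance flag
covers noisy inputs. Two-sided p-values use the t approximation
`t = rho sqrt((n-2)/(1-rho^2))`; for n ≤ 10 without ties an `exact` flag
switches to the exact null distribution of the rank statistic (delegated to
the standard reference routine rather than re-enumerated). No
multiple-testing correction is applied by default, matching how such
heatmaps are conventionally reported with raw p-values crossed at 0.05;
Benjamini–Hochberg is available behind a flag.

## The intake simulator

The reference dataset behind the index's first application (396 urban
Vietnamese adults, duplicate recalls) is access-restricted, so the package
ships a generator that emulates its published structure instead:
per-component zero inflation (non-consumers) and right skew (consumer
intakes). Each component is a mixture of a point mass at zero and a
lognormal — the standard choice for dietary intake skew; the true consumer
distribution is unreported, so the lognormal is a documented modelling
stand-in. Calibration is by closed-form moment matching: with consumer
probability $p$ and all-subject mean $\mu$ and SD $\sigma$ (the simulator
reads the published table's "all participants" column as including zeros;
were it consumer-only, the calibration would change), the consumer-level
moments are $m = \mu/p$ and $v = (\sigma^2 - p(1-p)m^2)/p$, and the
log-scale parameters follow from the usual lognormal inversion. When zero
inflation alone exceeds the target variance, the consumer intake collapses
to a point mass at $m$ with a warning.

Consumer status is drawn once per subject (matching the subject-level
non-consumer definition; `consumer_per_day = TRUE` gives the day-level
variant), and a consumer's day-level intakes share a one-factor Gaussian
copula on the log scale with across-day correlation 0.3 by default — a
plausible degree of habitual day-to-day stability, chosen once and exposed
in the configuration since replicate-recall correlations were not
published. Components are simulated independently: the between-food-group
dependence of the real diet is unknown and deliberately not invented.
Consequently, passing calibration tests shows the generator reproduces each
group's marginal non-consumer share and moments — not the joint structure
of real diets, so simulated correlation matrices characterise the scoring
pipeline, not the reference population's dietary pattern.

```{r}
sim <- simulate_intakes(n_subjects = 396, n_recalls = 2, seed = 42)
subjects <- average_recalls(sim)
scores <- score_wish(subjects)
glance(scores)
```

## Numerical and testing choices

Scoring is exact piecewise arithmetic; the test suite checks it against an
independent literal transcription of each group's rule on ~1000-point
grids per component (breakpoints ± 1e-9 included) at 1e-12, and checks the
Spearman engine against a hand-rolled average-rank-then-Pearson oracle at
the same tolerance. Sub-score conservation is verified on 10,000 random
score vectors. Simulation-calibration recovery is tested at 5,000 subjects
against 3 Monte-Carlo standard errors per component, and the
scoring-integration echo (the two bivariate limiting components averaging
≈10 in a 396-subject population) over several fixed seeds; these problem
sizes keep the default suite comfortably fast while leaving the stochastic
checks well-powered. All randomness flows from a single integer seed
recorded in the simulator output.

## Known limitations

* The index is WISH-specific; other diet-quality indices are out of scope,
  though thresholds, shapes and memberships can be overridden via YAML
  (all 13 canonical components must remain present).
* The simulator reproduces marginal distributions only, and its lognormal
  consumer model is an assumption, not an estimate.
* The vegetable and legume upper-range values (600 and 100 g/day) are
  stored for completeness but unused by their open-ended ramps, following
  the published scoring prose rather than the tabulated ranges; the same
  applies to the whole-grain 150 g/day value.
* No inferential statistics accompany the population summaries; the
  published analysis is descriptive, and so is ours.
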