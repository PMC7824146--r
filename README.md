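# wishindex

Scores dietary intake data against the **World Index for Sustainability and
Health (WISH)** — a diet-quality index that measures, in one scoring
system, how closely a population's diet tracks the EAT-Lancet reference
diet for both healthiness and environmental sustainability. It needs only
food-group amounts in g/day: no food composition table, no life-cycle
assessment data, which is what makes it usable in low- and middle-income
settings where those resources are missing.

The package is for nutrition and food-systems researchers working with
24-hour-recall (or food-record / FFQ) data who want per-subject WISH
scores, population summary tables, and the correlation analysis that
identifies which food groups drive a population's score.

## The score

Thirteen food groups (whole grains, vegetables, fruits, dairy, red meat,
fish, eggs, poultry, legumes, nuts, unsaturated oils, saturated oils,
added sugars) are each scored 0–10 by a piecewise-linear function of the
daily intake *x* (g/day) built from a lower bound *l*, recommended intake
*r*, and upper bound *u*:

* rising ramp (protective groups): score = 10 (x − l)/(r − l) for
  l ≤ x < r, then 10, with no upper restriction for whole grains,
  vegetables, fruits and legumes, a cap (score 0 above *u*) for
  unsaturated oils;
* optimum band (dairy, fish, nuts): 10 x/r below *r*, 10 on [r, u],
  0 above *u*;
* falling ramp (red meat, eggs, poultry): 10 up to *r*, then
  10 ((u − r) − (x − r))/(u − r), 0 above *u*;
* single cut-off (saturated oils ≤ 11.8 g/day, added sugars ≤ 31 g/day):
  10 at or below, else 0.

The 13 scores sum to a total out of 130 and to four sub-scores — healthy
(/100), less healthy (/30), low environmental impact (/60), high
environmental impact (/70) — each pair of which partitions the total.
Thresholds, shapes and memberships live in a YAML-overridable registry
(`wish_index()`), so the index can be locally adapted.

## Worked example

Component scores at documented breakpoints — whole grains below, inside
and above its 100–125 g/day ramp:

```r
library(wishindex)
score_component(c(99, 112.5, 125, 300), "whole_grains")
#> [1]  0  5 10 10
```

A full pipeline on a simulated population (the restricted reference
dataset's published structure: 396 subjects, duplicate recalls,
zero-inflated right-skewed intakes):

```r
sim      <- simulate_intakes(n_subjects = 396, n_recalls = 2, seed = 42)
subjects <- average_recalls(sim)           # mean over the two recall days
scores   <- score_wish(subjects)           # 13 components + total + sub-scores
glance(scores)
#>       n mean_total sd_total mean_healthy sd_healthy mean_less_healthy ...
#> 1   396       46.3     11.3         25.9       11.4              20.3
```

A mean total of 46.3 (SD 11.3) out of 130 says this simulated population
adheres to about a third of the recommendations; the healthy sub-score of
25.9/100 versus the less-healthy sub-score of 20.3/30 locates the problem
in under-consumption of protective foods rather than over-consumption of
limiting ones.

```r
summarize_wish(subjects, scores)
#>    component    pct_nonconsumers mean_intake mean_score direction
#>  1 whole_grains            98.0        0.821     0      Increase
#>  2 vegetables               0        225.        3.32   Increase
#>  5 red_meat                 3.28     125.        0.335  Decrease
#> 12 sat_oils                91.2        0.186    10      Good
#> ...
```

Per component: share of non-consumers, mean intake, mean score, and the
direction intake would have to move to raise the score (red meat's 125
g/day is nine times the 14 g/day recommendation, hence `Decrease`;
saturated oils are already under their cut-off, hence `Good`).

```r
corr <- correlate_wish(scores)
corr$excluded
#>   label        reason
#> 1 whole_grains constant score
#> 2 sat_oils     constant score
#> 3 added_sugars constant score
round(corr$rho["legumes", "total"], 2)
#> [1] 0.4
```

Spearman correlations among component, sub- and total scores flag which
components drive the index; components on which everyone scores alike
(here: nobody reaches the whole-grain ramp, everyone clears the two
cut-offs) admit no rank correlation and are excluded, as in the published
heatmap. `autoplot()` methods draw the score bar charts and the
correlation heatmap; `tidy()`/`glance()` give long and one-row views of
every result object.

A command-line wrapper covers the same pipeline:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","wish.R",package="wishindex"))')" \
  simulate --n 396 --recalls 2 --seed 7 --out out/
```

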