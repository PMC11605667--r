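# segsuggest

Effort-aware active learning for suggestive segmentation of 2D image
stacks (serial histological sections, sparse coronal slices).

Building segmentation ground truth for a stack means tracing dozens of
structures on dozens of sections; tracing time, not model fitting, is
the bottleneck. `segsuggest` runs the annotation loop so that each
suggested query — one structure on one section — buys the most
segmentation accuracy per minute of tracing:

* **Learning from partial labels.** A pixel classifier is trained with a
  *mixed cross-entropy*: labelled pixels contribute `-log f_l(x)`,
  unlabelled pixels contribute `-log Σ_{c∈Cn} f_c(x)` over their
  *compatible set* `Cn` — the classes allowed by weak per-structure
  section bounds `[n_c1, n_c2]` (two clicks per structure, no tracing)
  and by the annotations made so far. On fully labelled sections the
  loss is exactly the classical cross-entropy. Predictions are combined
  with the constraints by Bayes' rule: annotated pixels are one-hot,
  the rest renormalised over `Cn`.
* **Predicting annotation effort.** Boundary length (in crack edges of
  the 4-adjacency grid) is the proxy for tracing time. A running C×C
  matrix `B` averages each structure's boundary length and each pair's
  *shared* boundary length; the predicted remaining effort of querying
  `(n, c)` is `R_nc = max(0, B_cc − Σ_c' A_nc' B_cc')` — neighbours
  already traced are credited, because a shared boundary is traced once.
* **The query criterion.** With `D̃_c(T) = α·D_c(T−1) + (1−α)·D_c(T−2)`
  a smoothed prediction of each class's Dice (α = 0.5), the loop queries
  `argmax_{n,c} (1 − D̃_c) / R_nc`: room for improvement per unit of
  predicted effort.

Baselines (`rand`, slice-wise `uniform`, entropy `H`, Monte Carlo
dropout entropy `H_dropout`) and ablations (`Dalpha`, `BDalpha_CE`,
`HBDalpha`, `HDalpha`, `HB`) share the same loop. A synthetic-stack
generator (deformed multi-class blob sections with per-class section
supports and intensity noise) and a simulated annotator that answers
queries with ground-truth masks make every component testable with no
external data, and Dice-versus-effort curves are the evaluation.

## Worked example

```r
library(segsuggest)

# a synthetic stack: 12 sections, 64x64, 6 classes with staggered
# section supports, plus exact ground truth and weak bounds
fx <- generate_synthetic_stack(synthetic_config(seed = 7))

# run the proposed strategy to a 50% tracing budget
run <- run_active_learning(
  fx$stack, fx$gt,
  experiment_config(strategy = "BDalpha", budget_frac = 0.5, seed = 1),
  bounds = fx$bounds)

glance(run)
#> # A tibble: 1 x 7
#>   strategy n_queries bootstrap_cost total_cost cum_cost_frac mean_dice exhausted
#>   <chr>        <int>          <int>      <int>         <dbl>     <dbl> <lgl>
#> 1 BDalpha         27            945       7174         0.511     1.000 FALSE

head(tidy(run), 3)
#> # A tibble: 3 x 6
#>       t section class  cost cumulative_cost mean_dice
#>   <int>   <int> <int> <int>           <int>     <dbl>
#> 1     1       1     1    96            1041     0.764
#> 2     2       2     1   156            1197     0.801
#> 3     3       3     1    10            1207     0.810
```

Reading the output: the bootstrap (one traced instance of each of the 6
classes) cost 945 of the stack's 7174 total crack edges (13.2%); after
27 suggested queries and 51.1% of the total tracing effort the mean
foreground Dice against ground truth is 1.000 to three decimals. Each
`tidy()` row is one query: the strategy opens by chasing class 1 — the
smallest structure, with the most room for improvement per crack edge —
and at t = 3 its instance on section 3 cost only 10 edges because most
of its boundary was already traced as part of neighbouring annotations.
`autoplot(run)` draws the Dice-versus-effort curve, and

```r
cmp <- compare_strategies(fx$stack, fx$gt, c("BDalpha", "rand", "H"),
                          seeds = 1:5,
                          config = experiment_config(budget_frac = 0.5),
                          bounds = fx$bounds)
glance(cmp)   # per-strategy medians; autoplot(cmp) overlays the curves
```

reproduces the strategy comparison. A thin CLI over the same functions
lives in `inst/cli/segsuggest.R` (`simulate`, `run`, `compare`,
`report` subcommands).

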