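# mobcate

Heterogeneous treatment-effect discovery by model-based recursive
partitioning of pooled clinical-trial data.

## What problem this solves

Internet-based depression interventions for patients with chronic back pain
work *on average*, but the average effect hides large differences between
patient subgroups. Given pooled individual-participant data from two
randomized trials — treatment arm, twenty putative baseline moderators, and
PHQ-9 depression severity at post-test with dropout — `mobcate` answers:
*for whom* does the intervention work, how strongly, and does the answer
survive honest validation?

The workflow it implements, end to end:

1. **Multilevel multiple imputation** of missing outcomes: chained
   equations per arm, two-level normal draws with a trial random intercept,
   predictive mean matching for categorical columns, Rubin's-rules pooling
   (m = 50 by default).
2. **Average treatment effect** by one-stage meta-analysis: a maximum
   penalized likelihood (MPL) linear mixed model — the Gaussian likelihood
   plus a Wishart(ν = 4, 0.05·I) log-prior on the relative random-effects
   covariance — with random trial intercepts and trial-specific treatment
   slopes, reported as Cohen's *d*, alongside reliable-change rates
   (Jacobson–Truax index).
3. **Univariate moderation**: per-moderator treatment-interaction mixed
   models, with trial-stratified OLS + CR2 cluster-robust variance
   (Bell–McCaffrey Satterthwaite df) as sensitivity engine, and a
   percentile change-score analysis.
4. **Model-based random forest** (300 MOB trees, mtry = 1/3) for
   out-of-bag permutation importance; moderators with positive importance
   and/or univariate significance are preselected.
5. **Model-based recursive partitioning (MOB)**: score-based parameter
   instability tests (supLM for ordered, χ² for categorical moderators),
   Bonferroni pre-pruning at α = 0.05, exhaustive SSE cutpoint search,
   minimum node size 20, trial random effects handled by an alternating
   global-deviation scheme; terminal nodes report subgroup CATEs as
   *d*ᵢ with CIs and reliable-improvement rates.
6. **Validation**: bootstrap optimism correction of R² (B = 1000) and
   transport to an external pilot trial (n = 76) without refitting.
7. A **LASSO**-penalized multivariable interaction model (BIC-selected λ)
   as a robustness companion.

No patient data are shipped. A tested synthetic-data generator reproduces
the pooled study conditions (N = 504, 253/251 arm split, baseline PHQ-9
10.06 ± 4.55, published subgroup effect structure, between-trial
heterogeneity τ² = 0.48, 20% MAR dropout), so the entire pipeline runs and
is validated offline. See the vignette
(`vignettes/heterogeneous-treatment-effects.Rmd`) for models, assumptions,
and design decisions.

## Worked example

```r
library(mobcate)

cfg   <- synthetic_config(seed = 23)          # two-trial study conditions
d     <- apply_mar_missingness(generate_trial_pair(cfg), cfg)
stack <- impute(d, imputation_config(m = 10, seed = 24))

ate <- estimate_ate(stack)
ate$pooled
#> Pooled estimate (m = 10): -3.2324 (SE 0.5283, df 376.5, t -6.118, p 2.378e-09)
#>   95% CI [-4.2713, -2.1935]; W = 0.2360, B = 0.0392, T = 0.2791
ate$effect_size
#> d = -0.75 (95% CI -0.99 to -0.51); beta = -3.23, SD = 4.32

reliable_change(stack)$by_arm
#>            arm   n improved percent
#> 1      control 251       66      26
#> 2 intervention 253      130      51

agg  <- aggregate_stack(stack)
tree <- grow_mob_tree(agg, c("phq9_baseline", "pseq", "aqol"),
                      mob_control(node_baseline = TRUE))
tree
#> Model-based tree: 2 terminal node(s), n = 504 (random-effects alternation, 2 cycle(s))
#> [1] split pseq <= 38 (adj. p = 0.011)
#>   [2] yes: * n = 312 (61.9%), d = -0.97 [-1.18, -0.77]
#>   [3] no:  * n = 192 (38.1%), d = -0.42 [-0.67, -0.17]

external_validate(tree, generate_external_trial(cfg))
#> [1] 0.181
```

Reading the output: the pooled treatment coefficient is −3.23 PHQ-9 points
(d = −0.75 favoring the intervention; this synthetic realization planted
the published subgroup structure, whose marginal effect is stronger than
d = −0.43 and varies between datasets through the trial-level heterogeneity).
The tree finds one reliable split: patients with low-to-moderate pain
self-efficacy (PSEQ ≤ 38) show a subgroup effect of d = −0.97 versus
−0.42 above the cut — the published moderate-severity pattern. The frozen
tree transports to the unseen external trial with R² = 0.18.

`run_pipeline(pipeline_config(seed = 1))` chains all stages and
`write_report()` serializes CSV/JSON/DOT outputs. A thin command-line
front end lives at `inst/cli/mobcate.R`
(`Rscript inst/cli/mobcate.R run --input data.csv --seed 1 --out results/`).

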