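# condplan

Evidence-based planning of sham-controlled randomized trials: sequential
meta-analysis of the accumulating evidence and conditional-power sample-size
calculation for the next trial.

## The problem

Trials whose control arm receives a sham (placebo) procedure are typically
small — the sham exposes patients to real risk, so investigators enroll as
few as they can justify. That pressure leads to "reverse-engineered" power
calculations: an optimistic anticipated effect is chosen to make the
affordable sample size look adequate. Each trial is then underpowered on its
own, while collectively the evidence may settle the question long before the
last trial is run.

`condplan` implements the alternative workflow for a sequence of two-arm
trials reported as mean differences (MD) with standard errors:

1. **Power replication** — redo each trial's own calculation from its stated
   anticipated difference δ, common per-arm SD σ, and power, using the exact
   noncentral-t two-sample test: the smallest n per arm with
   `P(|T| ≥ t_{1−α/2,2n−2})` ≥ target, where T has df `2n−2` and
   noncentrality `δ/(σ√(2/n))`.
2. **Meta-analysis** — inverse-variance fixed-effect pooling
   (`w_i = 1/SE_i²`, pooled MD `Σw_iθ̂_i/Σw_i`, SE `1/√Σw`), the
   DerSimonian–Laird between-study variance
   `τ² = max(0, (Q − df)/(Σw − Σw²/Σw))`, and the cumulative meta-analysis in
   publication order.
3. **Sequential monitoring** — an α-spending analysis of the cumulative
   z-statistics: looks at information fractions `t_j` (randomized
   participants over the required information size
   `N = ⌈4σ²(z_{1−α/2}+z_{1−β})²/δ²⌉`), boundaries `b_j` solving
   `P(first crossing at look j) = f(t_j) − f(t_{j−1})` under
   `Cov(Z_i,Z_j) = √(t_i/t_j)` by recursive numerical integration, with the
   O'Brien–Fleming-type spending function
   `f(t) = 2 − 2Φ(z_{1−α/2}/√t)` by default. The first look whose |z|
   crosses its boundary is the *final timepoint*; participants randomized in
   later trials are the *unnecessary sample size*.
4. **Conditional planning** — the per-arm size a next trial needs so that
   the *updated* meta-analysis rejects the null with target probability: the
   new trial adds weight `w_new = n/(2σ²)` and the updated statistic is
   `Z = (W·θ̂_old + w_new·θ̂_new)/√(W + w_new)` with
   `θ̂_new ~ N(θ_assumed, 1/w_new)`, where `θ_assumed` defaults to the current
   pooled MD. Analytic (normal closed form) and seeded Monte-Carlo
   evaluation; an iterative prospective walk replays the planning after each
   published trial.

A synthetic-data generator (`synthetic_config()` / `generate_trials()`)
produces trial sequences with a configurable baseline effect, a
per-publication-step drift (the "learning curve" that violates the
constant-effect assumption of conditional planning), and between-trial
heterogeneity, so every stage can be exercised by simulation.

The package ships the summary data of the six sham-controlled renal
sympathetic denervation trials for resistant hypertension (981 participants;
outcome: mean change in 24-h ambulatory systolic blood pressure, mmHg) as
`rdn_trials()`.

## Worked example

```r
library(condplan)
rdn <- rdn_trials()

pool_fixed(rdn[1:4, ])
#> Meta-analysis of 4 trials
#>   pooled MD -2.76 mmHg (95% CI -4.93 to -0.59), z = -2.49, p = 0.01279
#>   Q = 1.37 (df = 3), tau^2 = 0, I^2 = 0.0%

monitor(rdn, sequential_design(delta_plan = -2, sd_plan = 10))
#> Sequential monitoring (obrien_fleming_type spending, RIS = 1051)
#>   upto_order        trial_id cumulative_n information_fraction boundary         z crossed
#> 1          1 symplicity_htn3          535            0.5090390 2.747088 -1.272727   FALSE
#> 2          2      desch_2015          606            0.5765937 2.656454 -1.799021   FALSE
#> 3          3           reset          675            0.6422455 2.548487 -1.794354   FALSE
#> 4          4  spyral_off_med          755            0.7183635 2.429558 -2.489453    TRUE
#> 5          5   spyral_on_med          835            0.7944814 2.334550 -3.386619    TRUE
#> 6          6   radiance_solo          981            0.9333968 2.156473 -3.379471    TRUE
#> Final timepoint: look 4; 226 participants randomized afterwards (114 sham) were unnecessary.
```

After four trials (755 participants) the pooled mean difference is −2.76
mmHg favoring the active intervention, and the cumulative z (−2.49) crosses
the error-spending boundary (2.43): the evidence was already conclusive, and
the 226 participants of the two later trials (114 of them randomized to
sham) added exposure without changing the answer. The prospective planning
walk (`prospective_walk()`) shows the same from the planning side — once the
synthesis of the first four trials rejects the null, the planned size of any
further trial is zero.

`run_pipeline(rdn_trials())` executes all four stages in order and returns
one report object; `write_report()` serializes it to per-stage CSV files and
a combined JSON.

## Scope

Summary-level (aggregate) data only; mean-difference outcomes; efficacy
boundaries only (no futility/beta-spending); DerSimonian–Laird as the sole
τ² estimator. See the methods vignette (`vignettes/conditional-planning.Rmd`)
for the model, assumptions, numerical choices, and limitations.
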