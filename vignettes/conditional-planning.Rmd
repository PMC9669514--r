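---
title: "Sequential meta-analysis and conditional planning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential meta-analysis and conditional planning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condplan)
```

This vignette is the package's account of its statistical machinery: the
models, the assumptions they rest on, the parameters that matter, the
numerical choices, and what the shipped simulations do and do not
demonstrate.

## The setting

A sequence of two-arm randomized trials compares an active procedure to a
sham control on a continuous outcome (in the shipped example, mean change in
24-h ambulatory systolic blood pressure, in mmHg; negative differences favor
the active arm). Each trial reports a mean difference $\hat\theta_i$ with
standard error $SE_i$. The package operates entirely on these summaries —
no patient-level data are modeled — and asks three questions: was each
trial's own sample-size calculation internally consistent; when did the
accumulating evidence become conclusive; and how large would the next trial
have needed to be if it had been planned from the evidence rather than from
a stand-alone power calculation.

## Power replication

`sample_size_two_means()` implements the conventional two-sample
difference-in-means calculation. The default method is the exact
noncentral-t computation: the smallest integer $n$ per control arm (active
arm $\lceil k n \rceil$ for allocation ratio $k$) such that

$$P\left(|T| \ge t_{1-\alpha/2,\,\nu}\right) \ge 1-\beta, \qquad
T \sim t_{\nu}\!\left(\text{ncp} = \frac{\delta - m}{\sigma\sqrt{1/n_a + 1/n_c}}\right),
\quad \nu = n_a + n_c - 2,$$

with anticipated difference $\delta$, common per-arm SD $\sigma$, and
superiority margin $m$ (default 0). The exact method is the default because
the calculations printed in trial reports come from t-based software
(nQuery, Stata), and the normal approximation
$n/\text{arm} = (1+1/k)\,\sigma^2 (z_{1-\alpha/2}+z_{1-\beta})^2/(\delta-m)^2$
systematically returns one participant per arm fewer at these sizes (28
vs 29 for $\delta=6,\sigma=8$). Where a trial record omits them, a
two-sided test at $\alpha=0.05$ and 80% power are assumed. Dropout
inflation (e.g. "+20%") is presentation, not part of the calculation.

Rounding policy for unequal allocation: the control-arm real solution is
rounded up, and the active arm is the ceiling of $k$ times the rounded
control size. The shipped 2:1 trial is therefore recomputed as 976 vs 488
from its tabulated assumptions ($\delta=5$, $\sigma=25$, 95% power); its
published planning figures (316 vs 158) are not recoverable from those
inputs under any rounding convention, and `replicate_reported()`
accordingly flags it as not replicated. This is why the fixture needs no
separate "replicable" column: non-replicability is computed, not asserted.

## Meta-analysis

`pool_fixed()` is inverse-variance fixed-effect pooling,
$w_i = 1/SE_i^2$, $\hat\theta = \sum w_i\hat\theta_i/\sum w_i$,
$SE = 1/\sqrt{\sum w_i}$, with standard-normal confidence intervals and
p-values — the convention of aggregate-data meta-analysis software, kept
here so that the cumulative z-statistics feed the sequential machinery
directly. Heterogeneity uses Cochran's $Q$ and the DerSimonian–Laird moment
estimator truncated at zero,
$\hat\tau^2 = \max\{0, (Q - df)/(\sum w - \sum w^2/\sum w)\}$. In the
shipped data $Q < df$, so $\hat\tau^2 = 0$ and the random-effects fit
(`pool_random()`) coincides exactly with the fixed-effect one; the
random-effects route is retained for synthetic data with genuine
heterogeneity. No other $\tau^2$ estimator is offered.

`cumulative_meta()` re-pools the first $j$ trials for $j = 1..K$ in
publication order (ties in year are resolved by the `order` field, fixed by
the data). A note on printed precision: the shipped fixture stores mean
differences and standard errors to two decimals, as published. Re-pooling
those rounded inputs reproduces the published cumulative trajectory to
within ±0.01 at every step, but can differ in the second decimal from
values the original analysts obtained with unrounded data (e.g. step 6:
−3.086 here, −3.08 published; one downstream sample-size recalculation
lands at 473 instead of the published 474 for the same reason). The package
reports full-precision values and leaves rounding to presentation columns.

## Sequential monitoring

`monitor()` treats each trial's publication as an interim look at a
prospectively monitored meta-analysis. Looks are placed at the observed
information fractions $t_j$ — cumulative randomized participants divided by
the required information size
$N_{RIS} = \lceil 4\sigma_{plan}^2 (z_{1-\alpha/2}+z_{1-\beta})^2 / \delta_{plan}^2 \rceil$ —
capped at 1, where any remaining error is spent (subsequent looks reuse
that final boundary). The participants scale is the default because it is
what sequential-meta-analysis software draws; cumulative statistical
information $\sum w / I_{max}$ is available via
`information_metric = "statistical_information"`.

Boundaries solve, look by look, the first-crossing equation

$$P_0\!\left(|Z_j| \ge b_j,\ |Z_i| < b_i \ \forall i<j\right) = f(t_j) - f(t_{j-1})$$

under the canonical joint law of sequential z-statistics
($\mathrm{Cov}(Z_i, Z_j) = \sqrt{t_i/t_j}$), with the continuous
O'Brien–Fleming-type spending function
$f(t) = 2 - 2\Phi(z_{1-\alpha/2}/\sqrt{t})$ by default (conservative early,
near-nominal late — the standard choice for retrospective sequential
meta-analysis) and a Pocock-type function
$f(t) = \alpha\ln(1 + (e-1)t)$ for sensitivity. `spending = "none"` gives
the naive comparator that tests every look at $z_{1-\alpha/2}$ without
error control.

Numerics: the recursion propagates the sub-density of the non-crossed score
path $S_j = Z_j\sqrt{t_j}$ on a trapezoidal grid of 512 nodes per look
(256 minimum enforced), the first boundary uses its closed form
$\Phi^{-1}(1 - f(t_1)/2)$, later boundaries are found by `uniroot` to
1e−6 in $z$, and a spending increment below 1e−12 yields an infinite
boundary at that look (the grid support is capped at $|z| = 12$). The test
suite checks the schedule against Monte-Carlo first-crossing probabilities
(10^6 replicates at three looks; two-look and four-look designs for both
spending families at 5×10^5) within three MC standard errors, and the
empirical type-I error of the whole monitoring procedure on 10^4 null
synthetic sequences.

**The design anchor.** $N_{RIS}$ needs a planning effect and SD. The
package default — used throughout the shipped example — is
$\delta_{plan} = 2$ mmHg, $\sigma_{plan} = 10$ mmHg, $\alpha = 0.05$, power
0.90. The rationale: 2 mmHg is the smallest systolic reduction the trial
protocols themselves describe as clinically meaningful (pharmacologic
reductions of 2–5 mmHg are credited with measurable cardiovascular benefit),
and 10 mmHg is the smallest per-arm SD observed in any included arm, the
same convention the conditional-planning defaults use. This yields
$N_{RIS} = 1051$, so the six looks sit at information fractions 0.51–0.93:
the monitoring question is live at every publication. Under this anchor the
fourth study is the first to cross (|z| = 2.49 vs boundary 2.43), the same
conclusion as the naive fixed-sample rule — the qualitative finding is not
an artifact of the anchor, and materially different anchors (e.g.
$\delta_{plan} = 3$) would put the very first look past full information,
degenerating the sequential design.

The first crossing is the *final timepoint*; `monitor()` reports the total
and sham-arm participants of all trials published after it as the
*unnecessary sample size* (226 and 114 in the shipped data). Futility
(beta-spending) boundaries are not implemented: only efficacy monitoring is
in scope.

## Conditional planning

`conditional_power()` evaluates the probability that the meta-analysis,
updated with a planned trial of $n$ per arm and per-arm SD $\sigma_{new}$,
rejects the null. The new trial contributes weight
$w_{new} = n/(2\sigma_{new}^2)$ and estimate
$\hat\theta_{new} \sim N(\theta, 1/w_{new})$; the updated statistic is
$Z = (W\hat\theta_{old} + w_{new}\hat\theta_{new})/\sqrt{W + w_{new}}$.
Two conditioning conventions are first-class:

* `conditional_on_estimate` (default): the observed $\hat\theta_{old}$
  enters as a fixed quantity — the literal reading of "conditional power",
  and the planning stance of an investigator who takes the current pooled
  estimate at face value;
* `unconditional`: the updated pooled estimate is drawn around $\theta$
  with the full updated precision, i.e. the old evidence is also treated as
  random under the assumed effect.

Both are exposed because published applications of the method rarely state
which convention their simulation code used, and the two give materially
different sizes (the conditional version needs fewer patients when the
observed estimate already points the right way). $\theta$ defaults to the
current pooled MD — the evidence-based choice — and the planning defaults
$\sigma_{new} = 10$, 80% power mirror the shipped example's conventions.

`plan_next_trial()` returns the smallest $n$ per arm reaching the target
(bisection on the monotone analytic power; minimality is tested), or 0 with
an `already_rejected` flag when the existing synthesis alone rejects under
the chosen rule — which is how zeros in a planning table are to be read.
The rejection rule is fixed-sample ($|Z| \ge z_{1-\alpha/2}$) by default; a
sequential-boundary rule can be selected by passing a boundary schedule,
whose boundary at the first not-yet-reached look serves as the critical
value. The Monte-Carlo method (default 1000 replicates, seeded with
per-candidate substreams so that searches are reproducible) exists to
validate the closed form and to support rejection rules with no analytic
expression; analytic and simulated power are required to agree within three
binomial standard errors across a scenario grid in the test suite.

`prospective_walk()` chains the planner along the publication sequence:
after trial $j$, pool trials $1..j$, set $\theta$ to the pooled MD, plan
trial $j+1$. For the shipped data the walk's assumed effects are the
cumulative MDs (−1.96, −2.37, −2.22, …) and the planned sizes drop to zero
from the step after the fourth trial onward. The published analysis of
these data also prints conditional-planning sizes (1050/260/250 per arm)
from a simulation whose configuration (conditioning convention, rejection
rule, possibly a 90% target) is not reported; those exact figures are not
reproduced by any documented combination of the stated assumptions, so the
package asserts the structural behavior (zeros after rejection, minimality,
analytic–Monte-Carlo agreement) rather than those numbers.
`recalc_with_meta_effect()` implements the simpler published comparator —
each trial's conventional calculation redone with the previous pooled MD
and the trial's own SD — which *is* reproduced (263 and 190 per arm for the
second and sixth trials; 473 vs the published 474 for the third, a printed-
precision artifact noted above).

## The synthetic-data generator

`generate_trials()` draws trial sequences from
$\theta_j = \theta_0 + \gamma (j-1) + \tau u_j$, $u_j \sim N(0,1)$, and
$\hat\theta_j \sim N(\theta_j, se_j^2)$ with
$se_j^2 = \sigma_a^2/n_{a,j} + \sigma_s^2/n_{s,j}$; the true $se_j$ is
recorded as the reported standard error. This is exactly the statistical
structure the downstream pipeline assumes, plus the two controlled
violations that matter for planning: a linear-in-publication-step drift
$\gamma$ (the simplest encoding of a learning curve, under which early
pooled estimates systematically misstate late-trial effects — the test
suite verifies the sign of that bias matches the sign of $\gamma$) and
between-trial heterogeneity $\tau$. Defaults: per-arm SD 15 mmHg (a typical
ambulatory SBP-change SD), 40 per arm (the scale of the shipped trials),
one seed driving a single generator stream.

What passing simulations do *not* show about real data: the generator
emits exact normal summaries with known standard errors — no
reporting/rounding error, no small-sample t-distributed estimates, no
publication bias, no dropout, no outcome-measurement differences between
trials. Coverage and type-I results transfer to real trial sequences only
insofar as those features are negligible.

Simulation sizes used by the shipped tests (chosen to make Monte-Carlo
error a small fraction of the tolerances): 10^4 null sequences for the
monitoring type-I error, 10^6 replicates for the boundary oracle, 2000
replicate datasets for parameter recovery, 4000 for CI coverage, 2×10^4 to
10^5 draws per cell for analytic-vs-simulation power agreement.

## Degenerate inputs and edge policies

* Zero anticipated effect (or effect equal to the margin) is rejected at
  spec construction; an unreachable target errors with the power at the cap.
* A single trial: pooling returns the trial itself; $\tau^2$ requires two.
* One look at $t=1$ reduces the monitor exactly to the fixed-sample z-test.
* Looks at or past $N_{RIS}$ are capped at $t = 1$; repeated full-
  information looks reuse the final boundary.
* Missing planning fields are missing (never zero), must be jointly absent,
  and exclude a trial from power replication but not from meta-analysis.

## Limitations

Aggregate mean differences only (no binary or survival endpoints, no
crossover/cluster designs); DerSimonian–Laird only; no
heterogeneity-adjusted required information size; no futility boundaries;
no Bayesian predictive power. Conditional planning inherits the
constant-effect assumption — under a learning curve its sizes are planned
for the wrong effect, which is precisely the failure mode the drift
parameter of the generator exists to demonstrate.
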