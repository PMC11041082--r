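---
title: "Optimal allocation in platform trials with shared controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal allocation in platform trials with shared controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platalloc)
```

## The design problem

A platform trial compares two experimental arms ($i = 1, 2$) against a
shared control ($i = 0$).  Arm 2 enters after the trial has started and
arm 1 may stop recruiting before the end, which partitions the trial into
three *periods*: period 1 recruits to arm 1 and control, period 2 to all
three arms, period 3 to arm 2 and control.  With total sample size $N$,
period fractions $r_s = N_s/N$, and within-period allocation
probabilities $p_{i,s}$, the design question is how to choose the
$p_{i,s}$ (and, when they are free, the $r_s$) so that both
treatment–control comparisons are as precise as possible.

Responses are modelled as $y_j \sim N(\mu_i, \sigma^2)$, and the effects
of interest are $\theta_i = \mu_i - \mu_0$, tested one-sided at level
$\alpha = 0.025$.  Because allocation ratios change across periods, naive
pooled mean differences are biased whenever the mean response drifts over
time.  All estimators in this package therefore stratify by period: the
arm-$i$ effect is the inverse-variance-weighted combination of the two
period-wise mean differences,

$$\hat\theta_i = \sum_{s = i, i+1} w_{i,s}\,(\bar y_{i,s} - \bar y_{0,s}),
\qquad
w_{i,s} \propto \sigma_{i,s}^{-2},
\quad
\sigma^2_{i,s} = \frac{\sigma_i^2}{n_{i,s}} + \frac{\sigma_0^2}{n_{0,s}},$$

which is identical to the treatment coefficient of a linear regression of
the response on treatment indicators plus a period factor.  Under
additive time trends that affect all arms equally, the period factor
absorbs the drift and the estimator stays unbiased; this is the analysis
model the optimization assumes.

With a common $\sigma$ and continuous cell sizes $n_{i,s} = N r_s
p_{i,s}$, the estimator variance has the closed form implemented in
`var_stratified_cc()`:

$$\operatorname{Var}(\hat\theta_i)
  = \frac{\sigma^2}{N}\Big(r_i\, g(p_{i,i}, p_{0,i})
  + r_{i+1}\, g(p_{i,i+1}, p_{0,i+1})\Big)^{-1},
  \qquad g(a, b) = \frac{ab}{a + b},$$

with the convention $g(a, 0) = g(0, b) = 0$ (an empty group contributes
no information), so degenerate one- and two-period designs need no
special-casing.  The test suite verifies this closed form, for a thousand
random designs, against the corresponding diagonal entry of the inverse
information matrix of the regression model built on expected cell counts.

## Non-concurrent controls

For the late-entering arm 2, the control patients recruited in period 1
are *non-concurrent*.  Fitting the period-adjusted regression to all
three periods pools them into the arm-2 comparison; `var_ncc()`
implements the resulting variance,

$$\operatorname{Var}(\tilde\theta_2)
  = \frac{\sigma^2}{N}\Big(r_3 q_{2,3} + r_2 q_{2,2}
  - \frac{r_2^2\, p_{1,2}^2\, p_{2,2}^2}{r_1 q_{1,1} + r_2 q_{1,2}}
  \Big)^{-1},
  \qquad q_{i,s} = p_{i,s}(1 - p_{i,s}),$$

which in a two-period trial ($r_3 = 0$) is equivalent to the explicit
correction
$\tilde\theta_2 = \hat\theta_{2,2} + \rho(\hat\theta_{1,1} - \hat\theta_{1,2})$
with the harmonic coefficient computed by `rho_coefficient()`.  Because
published renderings of such display formulas are easy to mis-transcribe,
the package treats the regression information matrix as the ground truth:
the closed form is only accepted because it reproduces the model-based
variance to $10^{-10}$ over randomized designs, and it strictly improves
on the concurrent-only variance whenever $r_1 > 0$ and arm 1 recruits in
period 2.  Arm 1 itself is always analyzed with concurrent controls only,
since its efficacy is evaluated when the arm closes.  The closed form is
derived for a common $\sigma$; `var_ncc()` refuses unequal per-arm SDs
rather than extrapolate.

## The minmax criterion and the three cases

The design objective is to minimize
$\max\{\operatorname{Var}(\hat\theta_1), \operatorname{Var}(\hat\theta_2)\}$;
among allocations achieving the same maximum, the one with the smaller
minimum variance is preferred.  If both experimental arms receive
patients in period 2 at the optimum, the two variances must be equal —
otherwise a small shift of allocation from the better arm to the worse
one would improve the objective.

Three cases differ in what is fixed:

* **Case 1** (`optimize_case1()`), nothing fixed: the optimum is the
  one-period multi-arm trial with the square-root-of-$k$ rule
  $p_{0} = 1/(1+\sqrt2) \approx 0.4142$, identical with or without
  non-concurrent controls (none exist).
* **Case 2** (`optimize_case2()`), entry time of arm 2 fixed ($r_1$
  given): for $r_1 \ge 1/2$ the optimum degenerates into two separate
  consecutive trials ($r_2 = 0$, equal splits); for $r_1 < 1/2$ the
  optimum always sets $r_2 = 1 - r_1$ (both arms finish together) and
  reduces to Case 3.
* **Case 3** (`optimize_case3()`), both $r_1$ and $r_2$ fixed: boundary
  scenarios $r_1 \ge 1/2$ (all later patients to arm 2 and control) and
  $r_1 + r_2 < 1/2$ (period 2 to arm 1 and control) sandwich the interior
  scenario in which both arms share period 2 and the variances are
  equalized.

Equal allocation in periods 1 and 3 is optimal in every case because the
period-1 split affects only $\operatorname{Var}(\hat\theta_1)$ through
$g(p_{1,1}, 1 - p_{1,1})$, maximized at $1/2$ (with unequal variances
this generalizes to the Neyman split $p_{i,s} : p_{0,s} = \sigma_i :
\sigma_0$).

### Interior solutions, numerically

For the concurrent-only interior scenario the Lagrange conditions of the
constrained problem collapse onto a one-dimensional *stationarity curve*

$$p_{0,2}^2 = p_{1,2}^2 + p_{2,2}^2
\quad\Longleftrightarrow\quad
p_{0,2} = \frac{(1 - p_{2,2})^2 + p_{2,2}^2}{2(1 - p_{2,2})},$$

parametrized by $p_{2,2} \in (0, 1/2)$.  Its endpoints are exactly the
two boundary designs, and along it the equal-variance constraint
$r_1/4 + r_2\,g(p_{1,2}, p_{0,2}) = r_3/4 + r_2\,g(p_{2,2}, p_{0,2})$ is
strictly decreasing, so the solver is a bracketed root-find
(`uniroot`, tolerance $10^{-14}$) — fast, deterministic, and accurate to
machine precision.  At $r_1 = r_3$ it reproduces the
$1/(1+\sqrt2)$ anchor analytically.  We use this derived relation rather
than the published closed-form display (whose radicals do not survive
text extraction) and validate it two ways: the equivalent polynomial
constraint $r_2/(1-2r_1) = 1/(1 + 4\Delta)$ with
$\Delta = g(p_{1,2},p_{0,2}) - g(p_{2,2},p_{0,2})$ holds to $10^{-10}$,
and a three-stage dense grid enumeration of the raw minmax objective
(steps 0.002, $2\times10^{-4}$, $2\times10^{-5}$) agrees with the solver
to better than $10^{-3}$ per coordinate across a grid of $(r_1, r_2)$
values.

With non-concurrent controls no such reduction is available.  The
interior solver minimizes $\operatorname{Var}(\hat\theta_1)$ along the
equal-variance curve: for each candidate $p_{2,2}$, the constraint
$\operatorname{Var}(\hat\theta_1) = \operatorname{Var}(\tilde\theta_2)$
is solved for $p_{1,2}$ by bracketed root-finds over every sign change on
a deterministic 201-point scan, and the outer one-dimensional problem is
scanned on a 0.005 grid and refined with Brent's method (tolerance
$10^{-10}$).  The procedure is seedless and deterministic; the
equal-variance gap of a returned interior solution is below $10^{-8}$
relative by construction.  Non-convergence (no sign change anywhere)
signals a non-interior scenario and raises an error with the scan trace.

The sum-of-variances variant (`optimize_sum_of_variances()`) has a
smooth objective and uses Nelder–Mead from five deterministic starts
followed by a Newton polish on numerical derivatives; solutions satisfy
a projected-gradient norm below $10^{-6}$ (typically $10^{-9}$).

### A qualitative claim that does not survive enumeration

At $r_1 = r_3$ the sum-of-variances and minmax optima coincide (both give
the square-root-of-$k$ rule).  Away from symmetry it is sometimes stated
that the sum criterion allocates *more* patients to the control.  Our
brute-force enumeration of both objectives finds the opposite, by a small
margin, at asymmetric splits such as $(r_1, r_2) = (0.15, 0.5)$ (control
share 0.420 under the sum vs 0.438 under minmax) and $(0.45, 0.3)$
(0.424 vs 0.462).  The directional claims for the experimental arms do
verify (for $r_1 < r_2$ the sum criterion moves patients from arm 1 to
arm 2), and the test suite asserts exactly what the enumeration supports.

```{r solvers}
optimize_case3(1 / 3, 1 / 3)       # symmetric: sqrt(k) rule
optimize_case2(0.25)               # two-period optimum at r1 = 1/4
optimize_case3(0.3, 0.5, "ncc")    # pooling non-concurrent controls
```

## Estimation and testing on patient-level data

`estimate_stratified_cc()` computes the stratified estimate from
realized cell counts and takes its standard error, residual variance and
degrees of freedom from the matching period-adjusted regression;
`estimate_ncc()` fits the all-periods regression for arm 2.  Both drop
inestimable terms (e.g. the period effect of an empty period) and record
them.  `test_and_ci()` completes either estimate with the one-sided
p-value and a two-sided 95% interval.  The default analysis estimates
$\sigma^2$ from the residuals and uses the $t$ reference — this is what
reproduces the case-study powers — while `sigma =` switches to the
known-variance normal analysis used for exactness checks against the
design formulas.  Dummy coding uses the control arm and the first period
of each model as reference levels.

## The simulator and what it does (not) emulate

`generate_trial()` draws permuted-block trials: within each period the
arm labels are a random permutation of exactly the nominal cell counts,
so realized counts always match the design tables (independent
per-patient randomization would scatter them).  Time trends are additive
and equal across arms — `"stepwise"` jumps by $\lambda$ at each period
boundary, `"linear"` drifts by $\lambda$ in total over the trial.  These
are the conditions under which the period-adjusted analysis is provably
unbiased; the generator deliberately does not emulate arm-specific
trends, non-normal responses, covariates, staggered entry within
periods, or informative dropout, so passing tests say nothing about
those complications.

`operating_characteristics()` vectorizes the whole pipeline: with fixed
counts, every per-replicate estimate, residual sum of squares and test
statistic is a linear-algebra functional of the response matrix, so
100,000 replicates of the case study run in a few seconds.  Within-period
randomization enters only through the trend term and is realized by
permuting trend contributions within periods (equivalent under
exchangeable errors); for stepwise trends the period factor makes the
permutation irrelevant.  Engine results are tested to agree with the
patient-level estimators replicate by replicate.

## Reproducing the case study

The running example is a phase II hypercholesterolemia trial re-imagined
as a platform trial: $N = 92$, control mean 4.94, both treatment means
5.66, unit variance — calibrated to 80% power under the
square-root-of-$k$ multi-arm design.  `reproduce_case_study()` simulates
the ten design-by-allocation rows (one-period; two-period with
$r_1 = 1/4$; three-period symmetric and non-symmetric) under 1:1,
square-root-of-$k$ and minmax-optimal allocation.

```{r table2, eval = FALSE}
tab <- reproduce_case_study(nsim = 100000, seed = 1)
```

Conventions worth making explicit:

* **Rounding.**  Cell counts come from largest-remainder apportionment,
  periods first, then arms within periods.  Remainder ties are broken to
  keep the experimental arms interchangeable: across periods in the
  order 1, 3, 2 (so $N = 92$ in equal thirds gives $31/30/31$), within a
  period in the order arm 1, arm 2, control (so the one-period 1:1:1
  design gives the arms 31 each and the control 30, which is what makes
  the two simulated powers equal).
* **Printed tables.**  The three-period rows use the case study's
  printed per-cell sample-size tables verbatim even though their totals
  (94 and 93) are not exactly 92.  For the non-symmetric
  square-root-of-$k$ row the printed counts simulate to an arm-2 power
  about 0.015 above the published table (the published simulation
  evidently rounded that scenario differently); all other rows agree to
  within Monte-Carlo error.  The test suite checks all ten rows at
  `nsim = 10000` within ±0.02.
* **CI widths.**  Mean 95% CI widths are computed per arm from the
  fitted model.  The published table prints identical widths for both
  arms in designs where the arms' standard errors differ and our per-arm
  widths are accordingly not identical; the defining computation there
  is ambiguous, and we report the model-based quantity.

Problem sizes used by the test suite — 10,000 replicates for the power
table and trend-robustness checks, 1,000 random designs for the
information-matrix equivalence, a 12-point $(r_1, r_2)$ grid for the
solver-vs-enumeration comparison — keep the default run around half a
minute; the acceptance script re-runs the power scenarios at the full
100,000 replicates.

## Known limitations

Two experimental arms and three periods only; continuous endpoints with
normal errors; no interim analyses or early stopping; no multiplicity
adjustment across the two hypotheses (the case study tests marginally);
non-concurrent-control formulas (and hence the ncc solvers) require a
common response variance; entry and exit times are treated as fixed
design parameters, not random.
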