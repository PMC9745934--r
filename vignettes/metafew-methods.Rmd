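---
title: "Meta-analysis of binary outcomes with very few studies: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analysis of binary outcomes with very few studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metafew)
```

## The problem

Most meta-analyses of dichotomous outcomes pool a handful of randomised
trials: in large collections of systematic reviews the median is around three
studies. In that regime the standard inverse-variance random-effects
machinery behaves badly — the DerSimonian-Laird (DSL) interval is too narrow
and under-covers, while the Hartung-Knapp-Sidik-Jonkman (HKSJ) interval holds
the type I error at the price of being extremely wide when only two to four
studies are available. metafew implements a family of likelihood-based
alternatives built on the beta-binomial distribution, the two standard
logistic mixed models, and the classical estimators, together with a
simulation engine and performance harness for comparing them under realistic
few-study conditions.

Throughout, `K` studies compare a binary outcome between a treatment arm
(`y_t` events out of `n_t`) and a control arm (`y_c` out of `n_c`); the
effect of interest is the odds ratio (logit link) or relative risk (log
link), always estimated and pooled on the log scale.

## The models

**Common-rho beta-binomial (`bbst`).** Each arm's event count is
beta-binomial: the arm-level event probability is beta-distributed across
studies with mean `mu_C` (control arms) or `mu_T` (treatment arms) and a
single intraclass correlation `rho = 1/(alpha + beta + 1)` shared by all
arms, which is equivalent to `alpha_C + beta_C = alpha_T + beta_T`. The
treatment effect `b_t = g(mu_T) - g(mu_C)` enters through the linear
predictor `g(mu_i) = b0 + b_t * i`, so only three free parameters are
estimated. Because the arm-level likelihood is a proper count model, single-
and double-zero studies need no continuity correction and still contribute.
The only inestimable configuration is a whole arm *group* without events.
Confidence intervals use the t distribution; `df = 2K - 2` is the default
(a compromise between the too-liberal `2K` and too-conservative `2K - 3`),
with `df = K - 1` available for comparison.

**Beta-binomial with a random treatment effect (`bbfr`).** The common-rho
model treats the effect as fixed and contrasts pooled arm groups, thereby
ignoring which control arm was randomised against which treatment arm. The
extension adds a per-study normal deviation `gamma_k ~ N(0, sigma2)` to the
treatment effect; each study's treatment-arm contribution is marginalised
over `gamma_k` by adaptive Gauss-Hermite quadrature (one node — the Laplace
approximation — by default, matching the estimation choice the comparison
study used; more nodes via `quad_points`). In practice the two models give
almost identical answers unless the study effects are strongly
heterogeneous.

**Common-beta beta-binomial (`bbcb1`, `bbcb2`).** Instead of a common
intraclass correlation, one shared second shape parameter `beta` is assumed.
`bbcb1` pools arms of the same kind across studies (`y_ki ~ BetaBin(n_ki;
alpha_i, beta)`), with log OR `log(alpha_T/alpha_C)`. `bbcb2` conditions on
each study's total event count `m_k`, giving `y_kT | m_k ~ BetaBin(m_k;
n_kT e^(b0+b_t), n_kC e^(b0))` — the two-arm reduction of the fixed-effects
negative-binomial panel likelihood with arm-size exposure offsets — and so
respects the within-study randomisation. Both estimate the odds ratio only.
The exact likelihoods behind the original procedure-based implementations
are not documented; these two are isolated in single functions so that an
alternative parameterisation can be swapped in.

**Logistic mixed models (`glfr`, `glrri`).** The linear predictor is
`g(pi_ki) = gamma_k + i*theta + i*eps_k` with `eps_k ~ N(0, tau2)`; `glfr`
keeps one fixed intercept per study, `glrri` replaces them by a normal
random intercept. Estimation is Laplace-approximated maximum likelihood via
`lme4::glmer(nAGQ = 1)`; the package's own `glmm_marginal_negloglik()`
implements the same marginal likelihood (Laplace or adaptive quadrature)
and serves as an independent cross-check in the test suite. Intervals are
Wald-normal (`± 1.96 se`), as in the study being reproduced. `glrri`
frequently fails to converge under strong heterogeneity; such replications
are recorded as non-converged.

**Inverse-variance methods (`dsl`, `hksj`).** Per-study log effects use the
Woolf/delta-method variances; the 0.5 continuity correction is applied to
all four cells of any included study with a zero cell, and double-zero
studies are excluded. (The correction is triggered by any zero cell — not
only zero *event* cells — because an all-events arm leaves the variance
undefined in exactly the same way; a `policy = "none"` variant excludes
zero-cell studies instead.) DSL uses method-of-moments heterogeneity with
truncation at zero and a normal interval. HKSJ uses Paule-Mandel weights —
`tau2` solving `Q(tau2) = K - 1`, found by monotone root bracketing, set to
0 when `Q(0) <= K - 1` — and the t interval with `K - 1` df scaled by
`sqrt(q)`. When that interval is narrower than the DSL interval on the same
data, the ad-hoc modification `q* = max(1, q)` is applied, so the reported
HKSJ interval is never narrower than DSL's.

**Classical estimators (`mh`, `peto`, `coll`).** Mantel-Haenszel (OR only)
with the Robins-Breslow-Greenland standard error; no continuity correction,
and — as in the comparison study — studies with a zero cell are dropped
entirely (the conventional behaviour that retains single-zero studies is
available via `drop_zero_studies = FALSE`). The Peto one-step estimator uses
hypergeometric moments, includes single-zero studies untouched and drops
only studies with zero variance. The collapsed table sums all studies into
one 2x2 table (deliberately naive — it is the textbook victim of Simpson's
paradox, and the bundled `simpson` fixture demonstrates the sign flip) with
a 0.5 correction when the pooled table has a zero cell.

## The simulation engine

`scenario_config()` + `run_scenario()` emulate realistic Cochrane-style
meta-analytic data situations:

* **Total study size** `n_k`: rounded log-normal(`meanlog = 4.615`,
  `sdlog = 1.1`), redrawn while below `min_total_n = 8` (mean ≈ 185.7,
  median ≈ 102);
* **Arm split**: `n_kT ~ Bin(n_k, 0.5)` (1:1 randomisation), redrawn while
  an arm would be empty;
* **Control risk** `pi_C`: Beta(0.42, 1.43) per meta-analysis
  (median 0.129, lower quartile 0.024 — rare events are common);
* **Heterogeneity** `tau2`: `exp(-1.47 + 1.65 * Y)` with `Y` a zero-mean,
  unit-variance Fleishman cubic with skewness −0.55 (median 0.273). The
  cubic's excess kurtosis is not pinned by the design; 0 is used and
  exposed as `tau2_exkurt`;
* **Effect size** under H1: `theta = -0.59 + 0.61 * Y'` with `Y'` a
  Fleishman cubic with skewness −1.28 and excess kurtosis 3.68 (treated as
  excess kurtosis, since the raw reading lies outside the Fleishman-feasible
  region). Under H0, `theta = 0`;
* **Counts**: `y_kC ~ Bin(n_kC, pi_C)`; a per-study deviation `delta_k` is
  added to the linear predictor; `pi_kT = expit(logit(pi_C) + theta +
  delta_k)` for the OR (for the RR a log link with a hard cap just below 1,
  which is what makes large control risks a genuine convergence hazard for
  the likelihood methods); `y_kT ~ Bin(n_kT, pi_kT)`.

Two generator details deserve emphasis, because they decide whether the
published few-study coverage figures are reproducible at all; both are
config switches with evidence-based defaults.

**How `tau2` scales the study deviations (`heterogeneity_scale`).** The
natural random-effects reading draws `delta_k ~ N(0, sd = sqrt(tau2))`. The
design this engine reproduces, however, described its per-study term as a
normally distributed quantity generated *from* the heterogeneity value in a
SAS workflow, and `RAND("NORMAL", 0, tau2)` takes its second argument as a
*standard deviation* — giving `delta_k ~ N(0, sd = tau2)`. The two readings
are empirically distinguishable from the published summaries: with
`"tau2_as_sd"` (the default) the fixed-intercept mixed model's null coverage
at `K = 10` reproduces the reported 90.4% almost exactly and the
DerSimonian-Laird median CI length at `K = 2` lands on the reported 2.55,
while the variance reading gives ≈ 86% and ≈ 2.95. The conventional reading
remains available as `"tau2_as_var"`. One consequence is accepted rather
than hidden: under the default the common-rho model's median CI length at
`K = 2` computes to ≈ 4.0, somewhat below the published 4.44 (which only
the variance reading reproduces); no single reading matches both sets of
published numbers, and the one that matches the coverage results — which
are the findings this package exists to study — was chosen.

**Double-zero truncation (`exclude_double_zero`).** Under the literal
distributions several percent of studies would have no events in either
arm, yet the realized data of the design being emulated contained *no*
double-zero studies (while 36%–58% of meta-analyses contained single-zero
studies — fractions this generator reproduces). The default therefore
redraws a study's event-count pair while both counts are zero; in the
pathological corner where the event probability is so small that rejection
cannot finish (order 10⁻⁷ and below), the limiting conditional law is used
directly: one event, allocated to an arm with probability proportional to
its expected count. Without this truncation roughly 15% of `K = 2`
meta-analyses consist entirely of double-zero studies and every
inverse-variance method fails, which is irreconcilable with the published
convergence counts.

Reproducibility: `run_scenario()` spawns one seed per replication from the
scenario seed and generates *all* datasets before fitting anything, so the
simulated data stream is byte-identical regardless of which methods are
requested. Method failures of any kind become non-converged rows; a sweep
never aborts.

## Performance measures

`summarize_performance()` computes, per method and over converged
replications only: the converged count `R`; quartiles of the bias
`theta_hat - theta_true` (log scale); percentage bias (H1 only, undefined
when the true effect is numerically zero); coverage of the 95% interval;
quartiles of the interval length; and power (H1 only, the fraction of
intervals excluding 0). Under H0, power equals `100 - coverage` by
construction — the suite asserts this identity exactly. Quartiles are
type-7 (linear interpolation), pinned so that regression tests are stable.
`sensitivity_subset()` restricts a results table to replications whose
Cochran Q test is non-significant (p > 0.05), mirroring the practice of not
pooling visibly heterogeneous studies.

## Numerical choices

* **Beta-binomial likelihoods** are computed through `lbeta()` differences
  (equal to the nine-log-gamma expansion to 10⁻¹⁰, which the tests assert).
  Optimization is quasi-Newton (`nlminb`, then a BFGS polish when nlminb
  reports the "false convergence" typical of boundary drift) on transformed
  parameters: `logit(rho)`, `log(sigma2)`, `log` shapes. Starting values
  come from pooled event rates with `rho = 0.1`, `sigma2 = 0.01`.
* **Convergence accounting** mirrors the rule of the comparison study: a
  fit counts as converged only if the optimizer succeeded, the observed
  information is positive definite, and the standard error of the effect is
  finite — anything else is a non-converged row, never an error. Parameters
  sitting at a flat boundary (`rho -> 0`, `sigma2 -> 0` on homogeneous
  data) carry no curvature; they are dropped from the information matrix
  before inversion, yielding the standard error conditional on the
  boundary.
* **Numeric differentiation near tiny `rho`** loses about five digits to
  log-gamma cancellation; second differences therefore use a larger step
  (10⁻²) than gradients (10⁻³), and the optimizer's Hessian uses
  `ndeps = 5e-3`.
* **Random-effect integrals** use a damped vectorised Newton mode search
  (step halving on any decrease, tolerance 10⁻¹⁰, at most 100 iterations)
  seeded with the normal-approximation posterior mean, then Laplace or
  adaptive Gauss-Hermite around the mode. The one-node value agrees with
  `lme4`'s Laplace deviance to ~10⁻⁴ on test data; 30 nodes agree with
  dense quadrature to 10⁻⁴.
* **Paule-Mandel root finding** brackets geometrically until
  `Q(tau2) < K - 1` and then bisects (`uniroot`, tolerance 10⁻⁸);
  `Q(tau2)` is strictly decreasing so the root is unique.
* **The Fleishman solver** uses Newton iteration on the three-moment system
  from the near-normal start `(1, 0, 0)` with deterministic restarts,
  enforcing the standard `b > 0` root and the zero-mean constraint
  `a = -c`. The quadratic feasibility boundary
  `excess_kurt >= -1.2264 + 1.6410 skew²` is approximate, so it is enforced
  softly: the solver is always attempted and the boundary is reported only
  when no solution exists. Sign symmetry (negate `a` and `c` for negative
  skew) is used for robustness.

## Scale of the bundled checks

The test suite reruns the headline scenarios at 1,000 replications per
scenario and the acceptance script at 1,500–2,000 (the original study used
10,000), with Monte-Carlo tolerance bands of ±3 binomial or order-statistic
standard errors; these sizes keep the whole suite to minutes on a single
core while leaving the bands narrow enough to be informative. Oracles are
independent of the code paths they check: hand-computed worked examples,
dense grid searches for the beta-binomial ML fits, `stats::integrate()` for
the random-effect marginals, moment integration for the Fleishman cubics,
and `metafor` for DSL/PM/HKSJ/MH on identical inputs.

## What passing tests do and do not show

The generator emulates the *distributional shape* of real meta-analytic
data (sizes, risks, heterogeneity, effects) but not its full messiness: no
unbalanced randomisation, no correlation between study size and effect (no
small-study effects or publication bias), no multi-arm trials, no outcome
misclassification, and the double-zero truncation described above. Results
for the relative risk inherit the log link's boundary problems — the
likelihood methods genuinely fail to converge when control risks exceed
0.5, and this package reports those failures rather than papering over
them. Two published figures do not reproduce under any reading of the
stated generator and are documented as discrepancies rather than tuned
away: the effect-size distribution's printed median OR of 0.694 (the stated
Fleishman parameters give 0.614 — the printed quartiles are provably
inconsistent with any zero-mean unit-variance cubic), and the few-study
power values, which compute a few points above the published ≤ 5% at
`K = 2`.

## A worked example

```{r example}
studies <- tibble::tibble(
  study_id = 1:3,
  y_t = c(2, 5, 1), n_t = c(40, 60, 30),
  y_c = c(5, 9, 3), n_c = c(38, 62, 31)
)
fit <- meta_fit(studies, measure = "or",
                methods = c("bbst", "hksj", "dsl", "mh"))
tidy(fit, exponentiate = TRUE)
glance(fit)
```

```{r sim, eval = FALSE}
# a small scenario sweep: 200 null meta-analyses of 3 studies
cfg <- scenario_config(K = 3, reps = 200, hypothesis = "h0", seed = 42,
                       methods = c("bbst", "dsl", "hksj"))
res <- run_scenario(cfg)
summarize_performance(res)
```
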