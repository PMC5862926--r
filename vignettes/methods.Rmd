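---
title: "Methods: default Bayes factors for t-tests, correlations and ANOVA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: default Bayes factors for t-tests, correlations and ANOVA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defaultBF)
```

This vignette records the statistical model behind each analysis in
`defaultBF`, the default prior choices and why they are defaults, and the
numerical decisions that determine the exact digits the package prints.
It is written for a reader who wants to audit the implementation, not only
use it.

## 1. The two-sample JZS t-test

### Model

Two groups with a common unknown variance:

$$y_{1i} \sim N(\mu + \tfrac{\sigma\delta}{2},\ \sigma^2), \qquad
  y_{2j} \sim N(\mu - \tfrac{\sigma\delta}{2},\ \sigma^2),$$

where $\delta = (\mu_1 - \mu_2)/\sigma$ is the standardized effect size.
The null hypothesis fixes $\delta = 0$; the alternative assigns $\delta$ a
Cauchy prior with scale $r$ (the Jeffreys--Zellner--Siow setup, with the
standard Jeffreys priors on the common nuisance parameters $\mu$ and
$\sigma^2$). With those nuisance priors the Bayes factor depends on the data
only through the classical $t$ statistic and the group sizes:

$$\mathrm{BF}_{10}
  = \frac{\int f_{t;\nu}\!\left(t \mid \delta\sqrt{N_\mathrm{eff}}\right)
      \pi(\delta)\, d\delta}{f_{t;\nu}(t \mid 0)},$$

with $\nu = n_1 + n_2 - 2$, effective size
$N_\mathrm{eff} = n_1 n_2 / (n_1 + n_2)$, and $f_{t;\nu}(\cdot \mid a)$ the
noncentral-$t$ density. `jzs_ttest()` computes the pooled-variance $t$ from a
data table; `jzs_ttest_bf()` accepts the sufficient statistics directly.

### Prior and defaults

The default scale is $r = \sqrt{2}/2 \approx 0.707$, the conventional
"medium" default: it puts half the prior mass on $|\delta| < 0.707$, matching
the range of effect sizes common in behavioural research while remaining
heavy-tailed enough that large observed effects are not penalized (the
Cauchy tails give the test its information-consistency property). One-sided
hypotheses use the same Cauchy folded onto one half-line (density doubled,
renormalized), which yields the mixture identity
$\mathrm{BF}_{10} = \tfrac12(\mathrm{BF}_{+0} + \mathrm{BF}_{-0})$ that the
test suite checks on random inputs.

Sign convention: $\delta > 0$ means the *first-appearing* group in the table
scores higher. `descriptives()` reports groups in order of first appearance
so the direction of a one-sided test can be read off the same output.

### Posterior summaries

`posterior_delta()` evaluates the unnormalized log posterior on an adaptive
grid (expanded until the log density has fallen 40 nats below its peak on
both sides), normalizes by the trapezoid rule, and inverts the cumulative
distribution for the median and central 95% interval. The density at
$\delta = 0$ feeds `savage_dickey_bf()`: the ratio of prior to posterior
ordinate at zero equals the Bayes factor, and the package cross-checks this
identity against the integral route in its tests.

## 2. The Pearson correlation test

### Model and likelihood

For a bivariate normal sample the Bayes factor for $\rho \ne 0$ versus
$\rho = 0$ depends only on $(n, r)$. The package integrates the *exact*
reduced likelihood

$$p(r \mid \rho, n) \propto
  (1-\rho^2)^{(n-1)/2}\,(1-\rho r)^{(3-2n)/2}\;
  {}_2F_1\!\left(\tfrac12, \tfrac12;\, n - \tfrac12;\,
  \tfrac{1+\rho r}{2}\right),$$

where ${}_2F_1$ is the Gauss hypergeometric function. An asymptotic
(Jeffreys) approximation is available via `likelihood = "asymptotic"`; the
exact kernel is the default because it is equally cheap at the sample sizes
the package targets and removes one avoidable source of disagreement with
other implementations. At $|r| = 1$ the Bayes factor is reported as infinite
(information consistency).

### Prior

$\rho$ receives a *stretched beta* prior: $\rho = 2x - 1$ with
$x \sim \mathrm{Beta}(1/\kappa, 1/\kappa)$, $\kappa \in (0, 2]$. Width
$\kappa = 1$ is the default and makes the prior uniform on $(-1, 1)$;
smaller $\kappa$ concentrates mass near zero (more sceptical), and
$\kappa = 2$ is the widest prior that remains proper and unimodal-or-flat
in this family, which is why the package rejects larger values. As
$\kappa \to 0$ the prior collapses onto the null and the Bayes factor tends
to 1. One-sided priors fold the density as in the t-test.

### Recovering inputs from published summaries

Published analyses often print a rounded $r$ together with a Fisher-$z$
confidence interval. The interval is more informative than the rounded
point estimate: its midpoint on the $z = \operatorname{atanh}(\rho)$ scale
is $\operatorname{atanh}(r)$ and its half-width is $z_{0.975}/\sqrt{n-3}$,
so both the unrounded $r$ and $n$ can be recovered by inversion.
`cor_stats_from_ci()` implements this. For example, a printed interval of
$[.116, .613]$ yields $n = 46$ and $r = 0.3928$ (which prints as $.39$);
reproducing published Bayes factors to within rounding generally requires
this unrounded value, and the package's acceptance checks use it.

```{r}
cor_stats_from_ci(c(0.116, 0.613))$stats
```

## 3. ANOVA-type linear models with g-priors

### Model

For a model $\mathcal{M}$ with term set $T$ (main effects and interactions),

$$y = \mu \mathbf{1} + \textstyle\sum_{t \in T} X_t \beta_t + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma^2 I),$$

with Jeffreys priors on $\mu, \sigma^2$ and, per term, a $g$-prior
$\beta_t \mid g_t \sim N(0, g_t \sigma^2 I)$ with
$g_t \sim \text{Inv-Gamma}(\tfrac12, r_t^2/2)$ — the mixture-of-$g$
formulation whose single-column special case reduces exactly to the JZS
t-test. Defaults are $r_t = 0.5$ for fixed effects and $r_t = 1.0$ for
random (participant) factors: effects of individual participants are
typically larger and less interesting than the treatment effects, so their
prior is set wider. The balanced two-group case with $r_\text{fixed}=0.5$
equals the JZS t-test with Cauchy scale $\sqrt2 \times 0.5 \approx 0.707$,
and the test suite verifies this equivalence to $10^{-3}$ on the log scale.

### Design coding

Each $k$-level factor contributes $k-1$ columns of an orthonormal
sum-to-zero contrast basis (eigenvectors of the centring matrix
$I - J/k$, sign-normalized so results do not depend on eigen-solver
arbitrariness); interaction blocks are row-wise products of the component
bases. Effects therefore measure distance from the grand mean, and Bayes
factors are invariant to affine rescaling of the response — a property the
tests check numerically. Designs with empty factorial cells are rejected
with an error naming the missing cells.

### Integration over g

Conditional on $g = (g_t)$, the marginal likelihood relative to the null
model is available in closed form from the centred cross-products. What
remains is a $p$-dimensional integral over $\log g$ ($p$ = number of terms):

* $p = 1$: deterministic adaptive quadrature (reported
  `mc_error_pct = 0`);
* $p > 1$: importance sampling with a log-normal proposal centred at the
  Laplace mode of the integrand, `mc_samples` draws (default 10000), and a
  per-model seed derived from `g_prior_settings(seed=)`. The Monte Carlo
  coefficient of variation of the weights is reported as `mc_error_pct`,
  and errors of two model estimates combine in quadrature when Bayes
  factors are formed. Estimates with `mc_error_pct` above 15% are flagged.

All Monte Carlo work runs with the caller's RNG state saved and restored,
so analyses are bit-reproducible under a fixed seed without disturbing the
session.

### Model space, marginality and averaging

`enumerate_models()` generates every submodel of the full factorial model
that respects the principle of marginality (an interaction never appears
without all of its sub-terms); nuisance and random terms appear in every
model including the "Null model". Counts grow quickly — 2, 5, 19, 167
models for 1--4 factors — which is why enumeration is capped by
`max_order` for larger designs. `comparison_table()` converts per-model
Bayes factors to posterior model probabilities in log space (uniform model
prior by default), and `effects_table()` averages over models to give
per-term prior and posterior inclusion probabilities and the inclusion
Bayes factor (change from prior to posterior inclusion odds). Bayes factors
can be re-expressed against any base model with `rebase_bayes_factors()`.

## 4. Monitoring, stopping and evidence categories

`sequential_bf()` recomputes the Bayes factor on each prefix of the data in
collection order (both one- and two-sided, at one or more prior scales), so
the evidential trajectory can be inspected for stability.
`robustness_curve()` sweeps the prior scale over a grid; at scale 0 the
prior collapses onto the null and the Bayes factor is exactly 1, which is
used as an anchor in the tests. `stopping_rule()` and `evaluate_stopping()`
encode the common preregistered design "collect at least $n_\min$ per
group, stop when BF exceeds a threshold in either direction, stop regardless
at $n_\max$"; the evaluation reports which criterion fired and when.

`classify_bf()` maps a Bayes factor to the conventional discrete evidence
bands with cut points 1, 3, 10, 30, 100 (and their reciprocals), labelled
anecdotal / moderate / strong / very strong / extreme for either hypothesis;
a boundary value belongs to the stronger band and BF = 1 is its own
"No evidence" point. `wheel_proportion()` returns the proportion
$\mathrm{BF}/(\mathrm{BF}+1)$ visualized by a two-sector wheel, computed so
that the proportions for BF and 1/BF sum to 1 exactly in floating point.

## 5. Synthetic data and reconstructed inputs

`sim_spec()` / `generate_data()` draw seeded datasets for two-group,
bivariate-normal, one-way, factorial and within-subject designs. The
generators emulate the *designs* of the worked analyses (group sizes,
factor structure, a Gaussian random subject intercept for within-subject
data), not their empirical distributions: residuals are always Gaussian,
whereas real rating data are discrete and often skewed. They are intended
for demonstrations, power exploration and tests — parameter-recovery checks
in the test suite use them with known $\delta$ and $\rho$.

`fixture()` returns sufficient statistics for two published analyses used
throughout the documentation. One of them could not be obtained exactly:
only summary statistics were published, so the $t$ statistic is
*reconstructed* by inverting the published two-sided Bayes factor
($\mathrm{BF}_{01} = 3.71$ at scale $0.707$, $n_1 = 48$, $n_2 = 54$) —
a deterministic root-finding problem with a unique negative solution given
the published group means. Every other published quantity for that analysis
(one-sided and robustness Bayes factors, posterior median and interval)
then follows to within 0.3%, which validates the reconstruction. The
per-participant data in collection order cannot be reconstructed this way,
so sequential results for that example require the original data file.

## 6. Numerical choices

* **One-dimensional integrals** (`log_integral`, internal) use a tangent
  substitution $x = c + s\tan u$ mapping the real line to
  $(-\pi/2, \pi/2)$, with the centre $c$ and width $s$ found by probing the
  log-integrand at exponentially spaced offsets ($10^{-12}$ to $10^2$)
  around candidate peaks; $s$ is the half-width at a log-drop of 2. The
  maximum is factored out before exponentiation. `stats::integrate` then
  runs at `rel.tol = 1e-8`. Deep tails of the noncentral-$t$ density bottom
  out at an absolute noise floor around $10^{-12}$; when that noise defeats
  adaptive refinement (very large $|t|$ with a one-sided prior on the wrong
  side), the routine falls back to a fixed composite Simpson grid, whose
  error is bounded by comparing two resolutions and reported in the result.
* **The Gauss hypergeometric function** is evaluated by its power series,
  switching to the $z \mapsto 1-z$ linear transformation for $z > 0.75$
  (valid here because $c - a - b$ is half-integer for all parameter sets
  the correlation test uses).
* **Log-space throughout**: model comparison tables, posterior model
  probabilities and inclusion Bayes factors are computed with
  log-sum-exp, so quantities like $8.2\times10^{39}$ never overflow.
* **Measurement levels** are inferred when not declared: numeric columns
  with more than ten distinct values are continuous, with ten or fewer
  ordinal, everything else nominal. This is a heuristic for convenience;
  every analysis entry point accepts explicit levels, and small simulated
  numeric tables in the package's own tests declare them explicitly.
* **Problem sizes** exercised by the test suite — up to four factors
  (167 models), $n$ in the tens to hundreds, `mc_samples` up to $10^4$ —
  reflect the designs the package targets; they are package choices, not
  hard limits.

## Limitations

Random effects are limited to a single random intercept factor
(participants); random slopes and crossed random factors are out of scope.
The correlation module covers the Pearson test only. ANOVA models assume
equal residual variance across cells. Sequential analyses recompute each
prefix from scratch, which is quadratic in $n$ but negligible at the sample
sizes involved.
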