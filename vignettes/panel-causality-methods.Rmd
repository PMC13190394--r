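---
title: "Heterogeneous panel Granger causality: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneous panel Granger causality: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcausal)
```

`panelcausal` analyses balanced country-by-year panels — the motivating
application is the EU-27 nexus of CO₂ emissions per capita, current
health expenditure per capita and net migration over 2000–2020 (N = 27,
T = 21) — and answers one question per ordered variable pair: does the
past of one series help predict the other, country by country and at
the panel level? This vignette explains each stage's model and
assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic generator does and does not emulate, and
the numerical conventions the implementation commits to.

## Why second-generation panel methods

Macro panels of neighbouring economies violate the two assumptions that
first-generation panel tests lean on: errors are correlated across
countries (common shocks, shared policy), and slopes differ across
countries. The pipeline therefore opens with diagnostics that decide
the rest of the analysis:

* **Cross-sectional dependence.** Four statistics built on the pairwise
  correlations $\hat\rho_{ij}$ of unit-wise residual series: the
  Breusch–Pagan LM statistic $T\sum_{i<j}\hat\rho_{ij}^2$
  (χ² with $N(N-1)/2$ df; reliable only when T dominates N), its scaled
  normal version, the CD statistic
  $\sqrt{2T/(N(N-1))}\,\sum_{i<j}\hat\rho_{ij}$ (two-sided normal;
  robust across N/T configurations because signed correlations cancel),
  and a bias-adjusted LM that centres and scales each
  $(T-k)\hat\rho_{ij}^2$ by its exact finite-sample moments computed
  from the annihilator matrices of the unit regressions. The scaled LM
  carries a mean distortion of order $\sqrt{P}/T$ ($P$ = number of
  pairs), so it is only trustworthy when T dominates N — which is
  precisely the gap the bias-adjusted variant closes; with N close to
  or above T (as in the motivating panel), CD and the bias-adjusted LM
  are the statistics to read.

  The statistics need residuals, and the source analysis does not state
  the filtering regression behind its per-variable table. The package
  default `residual_model = "adf1"` regresses each unit's level on an
  intercept and its own first lag; raw levels of trending series would
  produce degenerate, near-unit correlations. The alternative
  `"level_demeaned"` is kept selectable, and the choice is recorded in
  the report so either variant can be reproduced.

* **Slope homogeneity.** The dispersion $\tilde S$ of unit-wise OLS
  slopes around the variance-weighted pooled (fixed-effects) slope gives
  $\tilde\Delta = \sqrt N\,(N^{-1}\tilde S - k)/\sqrt{2k}$ and the
  small-sample adjusted $\tilde\Delta_{adj}$ with variance
  $2k(T-k-1)/(T+1)$, both upper-tail normal. Rejection licenses the
  heterogeneous (per-country) causality machinery that follows.

* **Unit roots (CADF/CIPS).** Each unit's ADF regression is augmented
  with the cross-sectional averages of the lagged level and the first
  difference, absorbing one common factor. The CIPS statistic is the
  plain average of the (truncated) unit CADF t-ratios; truncation bounds
  are −6.19/2.61 for the constant case and −6.42/1.70 with a trend.
  The integration order of each variable (0 or 1) is decided at 5%,
  and their maximum becomes `dmax`, the augmentation depth of the
  causality stage.

### CIPS critical values

Critical values for CIPS have no closed form; they are quantiles of a
simulated null distribution. The package embeds a grid of 1/5/10%
quantiles over N ∈ {10, 15, 20, 27, 30, 50} and T ∈ {15, 21, 30, 50}
for both deterministic cases, each node simulated with 100,000
replicates of independent random walks with the cross-averages included
in every CADF regression (`scratch` generator frozen as R source).
Queries between nodes are bilinearly interpolated; queries outside the
grid are clamped to its edge. `simulate_cips_cv()` is the seeded
fallback for configurations far from the grid, and the test suite
checks that a fresh simulation at (N = 27, T = 21) reproduces the
embedded 5% value to within ±0.05. The CADF augmentation order is not
dictated by the data source; the default `p = 1` reflects that T = 21
cannot support deep augmentation, and the report records `p`.

## The causality test

For each country $i$ and ordered pair (x → y) the package estimates a
bivariate VAR in *levels* of order $k_i + d_{max}$ with intercept,

$$y_t = \alpha + \sum_{j=1}^{k_i + d_{max}} \phi_j\, y_{t-j} +
        \sum_{j=1}^{k_i + d_{max}} \beta_j\, x_{t-j} + \varepsilon_t,$$

and tests $H_0: \beta_1 = \dots = \beta_{k_i} = 0$ by a Wald statistic.
The $d_{max}$ extra lags are never restricted: this deliberate
overfitting (the lag-augmented VAR idea) is what keeps the Wald
statistic χ²($k_i$) under the null whatever the integration or
cointegration properties of the pair, so no prior cointegration step is
needed and variables stay untransformed — important for net migration,
which is sign-unrestricted and cannot be logged.

Choices the implementation commits to:

* **Lag selection.** $k_i$ is chosen per country and per pair by AIC
  over orders 1..`k_max` (default 3), with both candidate VARs fitted
  on the common effective sample $t = k_{max} + d_{max} + 1, \dots, T$
  so the criterion compares like with like; ties break toward the
  smaller order. The selected $k_i$ is shared by both directions of a
  pair, keeping the two tests on one estimated system.
* **Common effective sample.** The panel routine estimates observed
  statistics, null-restricted models and all bootstrap re-estimations
  on that same common sample. This costs a few observations for
  countries with small $k_i$ but makes the bootstrap null distribution
  exactly comparable with the observed statistic.
* **Panel combination.** Country p-values $\pi_i$ (asymptotic
  χ²($k_i$)) are combined into Fisher's
  $\lambda = -2\sum_i \ln \pi_i$, χ²(2N) under independence. P-values
  below `p_floor = 1e-16` are floored before the log — printed tables
  legitimately contain "0.000" entries, and an unfloored zero makes λ
  infinite. Reported country p-values keep full precision; only
  printing rounds to 3 decimals.
* **Bootstrap.** Cross-sectional dependence invalidates the χ²(2N)
  reference, so panel inference uses a residual bootstrap: residuals of
  the null-restricted fits are centred, whole cross-sectional residual
  *vectors* (all countries, same time index) are resampled i.i.d. with
  replacement — preserving the contemporaneous correlation structure —
  pseudo target series are rebuilt recursively from the restricted
  estimates and the observed initial conditions (the source series stays
  at its observed values under the null), and λ* is recomputed with the
  same $k_i$. The bootstrap p-value is
  $(1 + \#\{\lambda^* \ge \lambda\})/(B+1)$, which cannot be zero.
  Failed replicates (singular pseudo designs) are redrawn, counted, and
  capped at 10% of B. Everything is driven by one integer seed;
  identical seeds give bit-identical results.
* **N ≥ T caveat.** When N is not small relative to T the asymptotic
  χ²(2N) combination over-rejects; the report carries a note and the
  bootstrap p-value is the one to use. The package's simulation suite
  reproduces exactly this contrast (bootstrap at nominal size,
  asymptotic above it) under a one-factor null.

## CS-ARDL long-run estimation

The causality stage says nothing about sign or magnitude. For that the
package fits, per unit, an ARDL(1,1,…) in levels augmented with lags
0..$p_T$ of the cross-sectional averages of all model variables
(absorbing common factors), with $p_T = \lfloor T^{1/3}\rfloor$ by
default — 2 at T = 21. From the level coefficients it derives the
long-run coefficients $\theta_i = (\beta_0 + \beta_1)/(1-\phi)$, the
error-correction coefficient $\lambda_i = -(1-\phi)$ and the
differenced-form short-run coefficients ($\beta_0$), then averages
across units (mean group) with the nonparametric variance
$\sum_i (b_i-\bar b)^2 / (N(N-1))$. The published table's short-run
rows are differenced ("Δ …") while the specification is in levels; the
package resolves this by also estimating the exact error-correction
re-parameterization (same column space, same fit) and verifying the two
routes agree to machine precision — the reported short-run Δ
coefficients are the ECM-form ones. Units whose design matrix is
singular are dropped with a warning; the mean group requires at least
80% of units retained. A note flags T < 30, where the estimator
operates below its comfort zone, and a mean-group ECT outside (−2, 0).
`ect_interpretation()` turns a stable (negative) ECT into the share of
disequilibrium corrected per period and the implied periods to
equilibrium, e.g.

```{r}
ect_interpretation(-0.340)
```

## Typology

Country-level results are condensed by an inclusive threshold rule
(p ≤ α, default α = 0.10 — inclusive so that entries printed exactly at
a conventional level, e.g. 0.050, count as significant) into one of
four labels per pair (None, A→B, B→A, Bidirectional), then into three
classes: *bidirectional* (at least one feedback pair), *unidirectional*
(significant links, no feedback pair), *none*. Distinct label triples
are enumerated as profiles. Dominant-source groups follow mechanical
rules: one active source variable ⇒ that variable is dominant; several
sources all pointing at the migration variable and nothing else ⇒
*recipient*; any other multi-source pattern ⇒ *multi-linkage*;
countries with a feedback pair form the *feedback* group. An optional
regime name (integrated nexus, environment-sensitive,
demographic-pressure, decoupled) is attached only where a group maps
one-to-one onto it and is explicitly flagged interpretive — it is
narrative shorthand, not a statistical output. Countries that the rules
place in `multi-linkage` are reported as such rather than forced into a
narrative category.

The packaged fixture `fixture_printed_tables()` ships the published
27-country p-value tables for all six directions (transcribed,
3-decimal printed values) so this stage is testable without any data
download:

```{r}
fx <- fixture_printed_tables()
ty <- classify_countries(label_directions(fx$countries, alpha = 0.10))
ty
```

## The synthetic generator

`dgp_config()` / `generate_panel()` produce panels with exactly the
structure the pipeline assumes: per-variable processes (random walk,
AR(1), trend-stationary), cross-sectional dependence through one common
factor per variable with unit loadings drawn U(0.5, 1.5), optional
directional links, and a sign-unrestricted migration-like variable with
an optional block-interpolation artifact (five-year totals assigned to
individual years), which raises lag-1 persistence the way interpolated
demographic series do. The default configuration is the study shape:
N = 27, T = 21, all variables integrated of order one, one factor.
Two conventions matter:

* Causal links inject the *lagged innovation-scale movement* of the
  source (its first difference when the source is integrated) into the
  target's innovations. Planting a link therefore creates genuine
  Granger causality without changing either series' integration order;
  feeding in the source's level would make the target I(2).
* Draws are taken from per-(unit, variable) seeded streams, so
  enlarging N appends units without perturbing existing ones, and
  identical configs are bit-identical across runs.

What the generator does **not** emulate: actual WDI moments (scales,
growth rates), structural breaks (enlargements, 2008, COVID-19),
multi-factor dependence, or measurement error. Passing tests on these
panels show the procedures are correct and calibrated under the model's
own assumptions; they cannot show that the assumptions hold for any
real panel.

## Simulation study sizes

The test suite's Monte-Carlo checks use sizes chosen to make each
property sharply testable on a single CPU: the χ²(1) null of the
lag-augmented Wald statistic at T = 100 with 5,000 replicates
(Kolmogorov–Smirnov check plus 5% rejection within three binomial
standard errors); bootstrap-versus-asymptotic size under a one-factor
null at N = 10, T = 50, B = 200 over 300 outer replicates with
k_max = 1; directional power with links of coefficient 0.5 planted in
half the units over 100 replicates; 2,000-replicate size checks for
CD (N = 10, T = 100), the scaled LM (N = 30, T = 1000 — its intended
T ≫ N regime, see above), the bias-adjusted LM (N = 10, T = 30, the
moderate-T case it was built for) and the adjusted slope-homogeneity
statistic (N = 20, T = 40); a 10,000-replicate re-simulation of the
CIPS 5% critical value at (27, 21); and 200 replicates of long-run
recovery at N = 27, T = 100 (θ = 0.6, ECT = −0.5) under a factor-free
DGP, fitted without the cross-average terms — with them, the extra
regressors add the familiar dynamic-panel small-T bias to the ECT
(about −0.06 at these dimensions), a property of the estimator worth
knowing at T = 21. All simulations are seeded and deterministic.

## Known limitations

* Country-level p-values are asymptotic χ²($k_i$) from regressions with
  roughly 17 effective observations at the study dimensions; treat 10%
  significance as suggestive, which is also why the typology's
  threshold sensitivity is worth sweeping (`label_directions()` takes
  any α).
* The bootstrap corrects panel-level size under contemporaneous
  dependence but not the interpolation-induced serial smoothness of
  five-year migration estimates; the generator can reproduce the
  artifact so its effect can be studied, not removed.
* The CS-ARDL stage estimates one equation (the emissions equation in
  the motivating application); the API accepts any dependent variable,
  but a full three-equation system is out of scope.
* Pairwise bivariate VARs give unconditional predictive relationships;
  each equation omits the third variable by design (degrees of freedom
  at T = 21), so no conditional or trivariate claims are supported.
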