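---
title: "Models and methods for missing item responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for missing item responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irtmiss)
```

## The problem

In educational large-scale assessments a sizeable share of administered
items receives no response: students omit items inside the test or never
reach the final ones. How these cells are treated — scored as wrong,
ignored, modeled jointly with a response propensity, or imputed — changes
the estimated ability distributions, and therefore group (country) means
and standard deviations. `irtmiss` implements the full family of
treatments around the two-parameter logistic (2PL) measurement model

$$P(X_{pi}=1 \mid \theta_p) = \Psi\!\big(a_i(\theta_p - b_i)\big),$$

with $\Psi$ the logistic distribution function, together with a
shared-parameter model in which the response indicator $R_{pi}$ (1 =
observed) depends on a latent response propensity $\xi_p$ and on the
(possibly unobserved) response itself:

$$P(R_{pi}=1 \mid X_{pi}, \theta_p, \xi_p) =
  \Psi\!\big(\xi_p - \beta_i - \delta_i X_{pi}\big),
  \qquad (\theta_p, \xi_p) \sim \mathcal{N}_2.$$

This is the Mislevy–Wu model. Its $\delta_i$ parameter indexes how strongly
missingness depends on the response itself: $\delta_i = 0$ gives latent
ignorability (missingness depends on the person only through $\xi_p$),
while $\delta_i \to -\infty$ (operationally $-10$) means a correct response
is always delivered, so a missing response must hide an incorrect one —
the model-based counterpart of scoring omissions as wrong.

## Treatments

The registry (`model_registry()`) maps the treatment labels to pipelines:

* **U...** (response indicators unmodeled): `UW` scores all missing as 0;
  `UP` scores missing multiple-choice items as the guessing value $1/K_i$
  and missing constructed-response items as 0 (a fractional pseudo-response
  handled by pseudo-likelihood EM); `UN1` ignores not-reached items but
  scores omissions as wrong; `UO1` ignores all missing responses; `UO2` and
  `UN2` additionally put the person's missing (or not-reached) proportion
  $Z_p$ into a latent background model
  $\theta_p \mid Z_p \sim N(\gamma_0 + \gamma_1 Z_p, \sigma_e^2)$.
* **M...** (model-based): joint models for $(X, R)$ over a bivariate
  $(\theta, \xi)$ quadrature — `MO1` ($\delta=0$, $\mathrm{Cor}=0$), `MO2`
  ($\delta=0$), `MW` ($\delta=-10$ fixed), `MM1` (one common free
  $\delta$), `MM2` (one $\delta$ per item format).
* **I...** (imputation-based): five completed datasets are drawn and
  stacked, then scaled with the 2PL. Sources are a joint fit (`IW`, `IO1`,
  `IO2`, `IM1`, `IM2`; Bernoulli draws at the Bayes-rule probability
  $P(X=1 \mid R=0, \theta^\ast, \xi^\ast)$ after sampling person latents
  from their posterior), random guessing (`IP`), or fully conditional
  specification with partial least squares dimension reduction and
  predictive mean matching (`IF1` without, `IF2` with response-indicator
  predictors).

Not-reached detection (`classify_not_reached()`) labels the maximal
trailing run of missing cells in a person's administered item sequence;
everything else missing is an omission. The booklet item order is taken
from the metadata when available, otherwise column order is assumed.

## Estimation

`fit_2pl()` maximizes the marginal likelihood by EM on a fixed grid of 21
equally spaced points on $[-5, 5]$ with renormalized standard normal prior
weights; the ability metric is identified by $\theta \sim N(0,1)$. Item
updates are Newton steps on the expected-count logistic likelihood with
step halving, so every accepted step increases the EM minorant and the
observed log-likelihood trace is non-decreasing. Fractional responses
enter the expected counts directly, which makes partially correct scoring
a pseudo-likelihood rather than a separate algorithm. Missing entries
contribute nothing.

`fit_joint()` works on the three-category recoding $V_{pi} \in$ {observed
wrong, observed correct, missing} over the 21×21 product grid. Two
implementation details matter:

* For $\delta = 0$ the category probabilities separate into a
  $\theta$-part and a $\xi$-part, so the E-step reduces to small
  matrix products. Only the free-$\delta$ and fixed-$\delta$ models need
  the full 441-node coupling, which is accumulated sparsely over the
  missing cells.
* The E-step treats the unobserved response behind each missing cell as
  additional missing data, imputing it with its conditional probability
  $P(X=1 \mid V=2, \theta_t, \xi_u)$; all M-steps are then weighted
  logistic regressions (vectorized Newton with step halving).
  $SD(\xi)$ and $\mathrm{Cor}(\theta,\xi)$ are updated from the
  posterior-weighted node moments and the prior grid weights are rebuilt
  from the implied bivariate normal density each iteration.

Plain EM is slow here (several hundred iterations at realistic sizes), so
the default loop uses SQUAREM-type extrapolation: two EM steps define a
secant direction, an extrapolated point is tried, and it is kept only if
its likelihood beats the unaccelerated update — acceleration never
sacrifices monotonicity. Convergence is declared when the per-cycle
parameter movement falls below `3 * conv_par` (default `conv_par = 1e-4`)
or the log-likelihood change falls below a relative `1e-9`. An absolute
parameter criterion is used deliberately: a relative log-likelihood
criterion degrades with the sample size.

With strong nonignorability and high missingness (around $\delta = -10$
with 30% missing) the free-$\delta$ likelihood can be bimodal, with a
spurious positive-$\delta$ mode that plain EM reaches from the default
start. `fit_joint()` therefore probes two starting points for free-$\delta$
models ($\delta = 0$ and $\delta = -4$) for a few cycles and continues from
the better mode. In replicated simulations `run_cell()` warm-starts each
replication from the previous solution; starting values affect the
optimization path, never the maximum being sought.

Bounds contain boundary items: $a_i \in [0.05, 8]$, $b_i \in [-8, 8]$,
$\beta_i \in [-12, 12]$, $\delta \in [-10, 3]$, $SD(\xi) \in [0.05, 10]$,
$\mathrm{Cor} \in [-0.99, 0.99]$. An item that is never missing pushes
$\beta_i$ to its lower bound, which is the correct degenerate limit.
Persons with no observed responses are retained; they contribute through
the prior (or the latent background model) only.

The latent background model is estimated freely and then standardized so
the implied marginal ability distribution has mean 0 and SD 1, with item
parameters and regression coefficients rescaled accordingly. This keeps
all treatments on a single identification convention; the choice is ours,
as the convention is not dictated by the models themselves.

## Linking and the reporting metric

Group-specific 2PL scalings are aligned with Haberman linking
(`haberman_link()`): least squares on log discriminations gives the scale
$\nu_{1c}$, then least squares on difficulties gives the location
$\nu_{0c}$, under a reference-group constraint (first group fixed to the
identity). Unweighted least squares is used in both stages. Because each
group's ability was standardized during scaling, $(\nu_{0c}, \nu_{1c})$
are the group's mean and SD on the common metric; for two groups the
solution equals log-mean-mean linking, which the tests verify against a
closed form. `link_to_truth()` links an estimated item table to the
generating parameters, so a simulation can read off the implied population
mean and SD directly. `to_reporting_metric()` applies one affine map to
all groups so the weighted pooled distribution (between- plus
within-group variance) has mean 500 and SD 100.

## The synthetic-data generator

`generate_dataset()` draws $(\theta, \xi)$ bivariate normal with
$\mathrm{Var}(\theta) = 1$, $SD(\xi) = 1$ and correlation 0.5, simulates
2PL responses for 20 items with unit discriminations and difficulties
equidistant on $[-2, 2]$, and generates response indicators from the
Mislevy–Wu mechanism with a common $\beta$ and a common $\delta \in
\{-10, -3, -2, -1, 0\}$. The common $\beta$ is calibrated by bisection so
the expected missing proportion — computed by 41-point-per-dimension
Gauss–Hermite quadrature — hits the target rate ($5$–$30\%$) within
$10^{-4}$; the rate is strictly increasing in $\beta$. One master seed per
dataset is split into deterministic sub-streams for the latent draws, the
responses and the indicators, so each component is individually
reproducible.

$SD(\xi) = 1$ is a deliberate normalization: the indicator model is a
1PL in $\xi$, so only the ratio of $\xi$-spread to the logistic scale is
identified in the generator, and unit scale is the conventional choice.
The default design is a linear fixed test (administered mask all ones);
multi-matrix booklet masks are supported structurally by `response_data()`
but no booklet sampler is provided, and items are dichotomous only.

What the generator does **not** emulate: item-format-dependent
missingness (it can be configured via item-specific `delta`, but the
default design uses a common value), position and booklet effects,
polytomous items, response times, and any dependence of omission behavior
on test-taking strategies beyond $(\theta, \xi)$. Tests passing on these
synthetic conditions therefore validate the estimators under the stated
missingness mechanisms, not the realism of any particular assessment.

## The simulation engine

`run_cell()` crosses one missing rate with one $\delta$, generates
replicated datasets, applies the requested treatments, links every fit to
the generating item parameters, and records linked means and SDs (and, for
joint models, $\hat\delta$, $\widehat{\mathrm{Cor}}$, $\widehat{SD}(\xi)$).
`summarize_cell()` reports bias and RMSE against the generating values
(mean 0, SD 1) with delete-one-zone jackknife Monte Carlo standard errors
over 20 zones. Failed fits are excluded with a logged count — with the
multi-start and the bounds above we have not observed failures in the
shipped conditions. `run_design()` stacks cells into a single results
table and optionally writes it as CSV.

Under this generator the qualitative pattern is the expected one, and the
package's acceptance script recomputes it end to end: scoring as wrong is
unbiased when missingness can arise only from incorrect responses
($\delta=-10$) and increasingly biased downward as $\delta \to 0$;
ignoring missingness or assuming latent ignorability is biased upward at
strongly negative $\delta$ and approximately unbiased at $\delta = 0$
(`MO2`) ; the correctly specified Mislevy–Wu model tracks the truth except
in the most extreme corner (30% missing, $\delta=-10$), where the common
$\delta$ sits near its bound and weak identification inflates both bias
and variance.

## Model fit and survey machinery

`information_criteria()` and `ghp()` provide AIC, BIC and the
Gilula–Haberman penalty $\mathrm{GHP} = \mathrm{AIC} / (2\sum_p I_p)$,
where $I_p$ counts person-attributed parameters — 2 per administered item
for the 2PL; for joint models we default to the same per-item convention
with `params_per_item` configurable (3 counts $a$, $b$, $\beta$), since
the literature defines $I_p$ only for the 2PL. GHP differences above
0.001 are conventionally notable; BIC uses the number of persons as $n$.
Information criteria are meaningful for the model-based fits, not for
stacked-imputation fits. `brr_se()` implements balanced repeated
replication standard errors ($A = 0.05$, 80 replicates in the PISA
design), and `weighted_posterior_mean()` computes the weighted
posterior-mean ability on a transformed metric — the quantity whose
replicate-weight version feeds `brr_se()`; it coincides with averaging
many plausible values.

## Numerical choices and limitations

* Quadrature: 21 points on $[-5, 5]$ per dimension. This covers
  $SD(\xi)$ up to roughly 2 comfortably; for much more dispersed
  propensities widen the grid via `quadrature_grid()`.
* PMM uses the 5 nearest donors with a uniform random pick; FCS runs 10
  cycles per stored imputation after a marginal-draw initial fill; PLS is
  NIPALS on centered predictors with components capped at the predictor
  rank (degenerate components are dropped).
* Imputation counts default to $m = 5$; stacking is used instead of
  combining rules, so no imputation-based standard errors are produced —
  resampling (e.g. BRR) is the intended route for uncertainty.
* The linked SD of a group is $\nu_{1c}$, a ratio of discrimination
  geometries; with few items it inherits small-sample bias of order a few
  thousandths, visible in complete-data simulations.
* Test-suite problem sizes are kept at desk scale on purpose: the
  replicated checks use 40–500 replications at $N = 1500$, $I = 20$, and
  the unit tests use smaller synthetic sets; the acceptance script runs
  the full 500-replication cells for the one-dimensional treatments and
  100-replication cells for the two-dimensional ones.
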