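---
title: "Estimating network temperature from longitudinal binary symptom panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating network temperature from longitudinal binary symptom panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nettemp)
```

## The model

`nettemp` models a vector of binarized symptoms
$x = (x_1, \dots, x_p)$ with the Ising distribution

$$P(X = x) = \frac{e^{-\beta H(x)}}{Z}, \qquad
  H(x) = -\left(\tau^\top x + \tfrac{1}{2} x^\top \Omega x\right),$$

where $\Omega$ is a symmetric edge-weight matrix with zero diagonal,
$\tau$ a vector of thresholds (external fields), $\beta$ the inverse
temperature, and $Z = \sum_x e^{-\beta H(x)}$ sums over all $2^p$
configurations. The sign convention makes positive thresholds favour
endorsement and positive edges favour alignment of connected symptoms,
so "cooling" (rising $\beta$) concentrates probability on aligned,
low-energy configurations. The Boltzmann constant that appears in the
thermodynamic definition $\beta = 1/(k_B T)$ is a unit carrier with no
statistical content; it is set to 1 throughout, so $T = 1/\beta$
exactly.

Everything is computed by exact enumeration. The instruments this
package targets have 5–13 items, for which $2^p \le 8192$ states are
trivial to enumerate; the hard cap is $p = 20$, beyond which the
package refuses rather than approximate. `logZ` uses log-sum-exp so it
stays finite up to $|\beta H| \approx 700$. No pseudo-likelihood or
mean-field approximation is implemented, deliberately: at these scales
exact computation removes an entire class of approximation-error
questions.

$\beta$ multiplies the whole potential, so $(\beta, \Omega, \tau)$ and
$(1, \beta\Omega, \beta\tau)$ define the same distribution. A single
cross-section therefore cannot identify $\beta$. Identification comes
from the multigroup scheme: panels from $G$ measurement occasions are
fitted jointly, $\beta_1 \equiv 1$ anchors the scale at the first
occasion (after ordering waves by ascending age), and with parameters
tied across occasions the later $\beta_g$ — and hence the *relative*
temperature trajectory $T_g = 1/\beta_g$ — become identified. All
temperatures reported by this package are relative to the first
occasion; trajectories from independently identified fits (for example
different strata) can be compared only as rates of change, never as
absolute levels, and the stratified output carries that disclaimer in
its metadata.

## Constraint levels and model selection

Four nested constraint levels are crossed with two structures:

| level | $\Omega$ | $\tau$ | $\beta$ | free parameters (dense) |
|---|---|---|---|---|
| saturated | per wave | per wave | all $\equiv 1$ | $G(p + E)$ |
| equal_edges | shared | per wave | $\beta_1 = 1$, rest free | $E + Gp + (G-1)$ |
| equal_edges_thresholds | shared | shared | $\beta_1 = 1$, rest free | $E + p + (G-1)$ |
| equal_all | shared | shared | all $\equiv 1$ | $E + p$ |

with $E = p(p-1)/2$ dense edges. In the saturated model $\beta$ is
unidentified (it would only rescale each wave's free parameters), and in
`equal_all` it is tied; both fix $\beta_g \equiv 1$. Structure is
`dense` (all edges) or `sparse`: backward-stepwise Wald pruning that
repeatedly removes the retained edge with the largest two-sided $p$
above `sparse_alpha` and refits, until all retained edges are
significant. The pruned edge set is shared across waves. Two open points
were settled as package policy: `sparse_alpha` defaults to 0.01 (exposed
in the spec object, since no canonical value exists for this step), and
under the saturated level — where each wave has its own edge estimates
but the mask must still be shared — an edge's $p$-value is the minimum
across waves, so an edge survives if it is clearly nonzero anywhere.
Ties in $p$ during pruning are broken toward the lexicographically
smallest $(i, j)$ pair, making runs deterministic.

`select_model()` fits all $4 \times 2 = 8$ combinations (2 with a single
wave, where only the saturated level is estimable) and computes, against
the dense saturated reference (0 degrees of freedom, as in structural
equation modelling): AIC $= -2\ell + 2k$; BIC $= -2\ell + k\log N$ with
$N$ the pooled individuals across waves; $\chi^2 = 2(\ell_{sat} -
\ell)$ on $df = k_{sat} - k$; and RMSEA
$= \sqrt{\max(\chi^2 - df, 0)/(df\,(N-1))}$, defined as 0 at $df = 0$.
The selection literature lists several admissibility criteria without a
tie-break, so the package operationalizes one rule and reports
everything: **lowest BIC among converged models with RMSEA < 0.05**;
if nothing passes the RMSEA screen, the lowest-BIC model overall is
returned with `rmsea_pass = FALSE`. The RMSEA uses the single-population
formula with pooled $N$; multigroup $\sqrt{G}$ variants exist, and the
choice is declared here and in the output rather than hidden. The full
table is always returned so users can apply their own rule.

## Estimation

The log-likelihood of a complete panel is computed through sufficient
statistics — per-item sums and the pairwise cross-product matrix — so
one pass over the data makes the per-iteration cost independent of $n$:
$\ell = \beta(\tau^\top s + \sum_{i<j}\omega_{ij}c_{ij}) - n\log Z$.
Model expectations (means, cross-moments, mean energy) come from the
exact enumeration, giving analytic gradients for every free parameter.
Free $\beta_g$ are parameterized as $\log\beta_g$, which enforces
positivity without constrained optimization and makes the delta-method
interval below natural.

Starting values are deterministic: thresholds from the independent-item
logistic closed form ($\tau_i = \tfrac12\,\mathrm{logit}\,\hat p_i$
under the −1/+1 encoding, $\mathrm{logit}\,\hat p_i$ under 0/1, with
$\hat p$ clamped away from 0 and 1), $\Omega = 0$, $\log\beta = 0$. The
optimizer is BFGS with analytic gradients (relative tolerance $10^{-10}$,
up to 500 iterations per round), followed by damped Newton steps using
the numerical Hessian whenever the gradient criterion — scaled max-norm
$\max_j |\partial \ell / \partial \theta_j| / N < 10^{-5}$ by default —
asks for more precision than BFGS delivers. The Newton polish converges
quadratically near the optimum and routinely reaches gradient norms near
machine precision when a tighter `gtol` is requested (the
encoding-equivalence checks use $10^{-11}$). Standard errors come from
the inverse numerical Hessian of the negative log-likelihood at the
optimum, with a pseudo-inverse fallback if it is numerically singular.
Non-convergence is reported, not hidden: the fit is returned with
`converged = FALSE` and a warning. If no edge weight is significantly
nonzero in a free-$\beta$ fit, a warning flags that the temperature is
weakly identified ($\beta$ only scales the interactions it multiplies).

Uncertainty for the temperature trajectory comes from two routes that
should — and in the tests do — agree to within a factor of two in width:
(1) the delta method on $\log\beta$, transformed monotonically to the
$T$ scale, which respects positivity and yields nearly symmetric
intervals; and (2) a case bootstrap that resamples individuals with
replacement within each wave, refits the same specification (retained
edge mask fixed, warm-started from the point estimate), and takes
2.5/97.5 percentiles of $\hat\beta$ and $\hat T$. Replicate $b$ draws
its indices from seed `seed + b`, so runs are reproducible and
parallel-stream independent. Non-converged replicates are dropped and
counted, with a warning above 10%. The production default is $B = 1000$;
the package's own simulations use $B = 200$, which is ample for 95%
percentile endpoints at the precision those checks assert.

## Encodings

The classical encoding is $x_i \in \{-1, +1\}$ (the package default);
network psychometrics often prefers $\{0, 1\}$. The two are statistically
equivalent under the affine substitution $x = 2y - 1$, which maps
PM1 parameters to ZO as $\omega' = 4\omega$,
$\tau_i' = 2\tau_i - 2\sum_{j\ne i}\omega_{ij}$ (a constant is absorbed
into $Z$), with $\beta$ unchanged; the transform is linear in
$(\Omega, \tau)$, so it commutes with $\beta$-scaling and the whole
multigroup family — including the constraint levels — maps onto itself.
`encode_params()` implements the transform exactly (round-trip to
machine precision), and fitting the same data under either encoding
yields the same $\hat\beta$ and the same fitted distributions; the
acceptance suite verifies this to $10^{-4}$ and $10^{-8}$ respectively.
The dynamical *interpretation* of parameters still differs between
encodings (under 0/1 only co-presence, not co-absence, is rewarded by a
positive edge), which is why both are first-class rather than one being
emulated.

## Derived trajectory quantities

For a fitted free-$\beta$ model, `temperature_trajectory()` reports per
wave: $T_g = 1/\hat\beta_g$ with both CI routes; the Gibbs entropy
$S_g = -\sum_x P_g(x)\ln P_g(x)$ of that wave's fitted distribution
(nats; bits are a display conversion), computed by the same
`gibbs_entropy()` used everywhere else — a single source of truth that a
regression test enforces; the $\beta$-scaled global strength
$\sum_{i<j}|\beta_g\,\omega_{ij}|$; and the observed sum-score mean and
variance. Sum scores are counted on the 0/1 scale regardless of the
internal encoding, so they match questionnaire conventions. Entropy is
non-increasing in $\beta$ at fixed $(\Omega, \tau)$ — $dS/d\beta =
-\beta\,\mathrm{Var}(H)$ — so a cooling trajectory with stable
thresholds implies declining entropy; with wave-varying thresholds the
two can decouple, which is precisely the package's reason to report
both. Under a shared $\Omega$ the scaled strength is exactly
proportional to $\beta_g$ (positive homogeneity of the absolute sum), so
the ratio to wave-1 strength recovers $\hat\beta_g$ to machine
precision; with per-wave edges the table is still produced but the
identity no longer holds.

`stratified_fit()` runs the whole pipeline independently per stratum,
each with its own wave-1 anchor. The age × stratum interaction on
temperature is tested with a linear mixed model — temperature as
outcome, age, stratum and their interaction as fixed effects, and a
random intercept for age *level*. Random intercepts for a variable that
is also a fixed effect, with few grouping levels, is an unusual
specification; it is implemented literally rather than reinterpreted,
and because the random-intercept variance is then frequently estimated
at zero, the degenerate case reduces to ordinary least squares (the
package falls back to `lm()` whenever the mixed fit fails, and labels
the route in the output). Stratum temperature estimates enter as points,
unweighted — the two-stage convention — and when a comparison is exactly
saturated (zero residual variance) the $t$ statistic is 0/0; the package
reports $p = 1$ for a numerically zero coefficient in that case, since
the data provide no evidence of a difference.

## The synthetic cohort generator

`cohort_design()` describes the generating process the estimator is
built for: a shared $\Omega$, wave-specific $\tau_g$, a $\beta$
trajectory with $\beta_1 = 1$ (the generator mirrors the estimator's
identification convention by construction), and per-wave sample sizes.
Sampling is exact — inverse CDF over the enumerated state distribution —
so there are no burn-in or mixing questions, and identical
`(params, n, seed)` always reproduce the same panel. Waves are sampled
independently: the estimator fits independent cross-sections tied by
equality constraints, not a within-person process, and the generator
deliberately matches that model class.

The built-in `abcd_like_design()` (6 items, 8 waves at ages 10–17,
n = 1500/wave, $T$ declining linearly 1 → 0.6) is sized after the
smallest instrument the method targets, a six-item emotional-symptom
questionnaire; `recovery_design()` is its compact 4-wave variant
($\beta$ = 1, 0.85, 0.70, 0.60, n = 5000/wave) used in the recovery
simulations. Both use a dense positive edge structure (a 0.3 chain over
a 0.12 background — all-positive, neighbour-dominant, as estimated
emotional-symptom networks tend to be), mildly negative thresholds
(symptoms endorsed by a minority), and thresholds that drift upward by
0.25 across waves so that external fields genuinely vary over time —
the model class the selection step is supposed to single out. These
values were fixed once, as plausible for the target instruments, and are
part of the study conditions rather than tuning knobs.

What the generator does **not** emulate: within-person autocorrelation
and attrition, item-level measurement error beyond the Ising likelihood
itself, informative (MNAR) missingness, and cohort-specific demographic
structure. `inject_mcar()` produces only completely-at-random masks, and
only to exercise the readers' missing-data policies — the estimator
itself requires complete panels, with listwise deletion per wave (the
complete-cases route) as the only built-in remedy; imputation is out of
scope. Passing tests on generated data therefore demonstrate correctness
of the estimation machinery under the fitted model class, not robustness
to the many ways real cohort data violate it.

## Numerical choices and degenerate inputs

- Exact enumeration cap $p \le 20$, hard refusal beyond, no approximate
  $Z$ anywhere.
- Missing cells abort estimation with a pointer to the listwise option;
  a wave left empty after listwise deletion is an error.
- A single wave admits only the saturated and equal_all levels; free-
  $\beta$ specifications raise an error naming the valid ones.
- If every edge is pruned, the independence structure is returned with a
  warning.
- All randomness (sampling, masks, bootstrap, CLI) flows from explicit
  integer seeds; bootstrap replicate $b$ uses `seed + b`.
- Numeric CSV output is written at 10 significant digits so identical
  seeds give byte-identical files.

## Problem sizes used by the test suite

The package's simulation-based checks run at desk scale, chosen to keep
the full suite in the tens of minutes while leaving comfortable Monte
Carlo margins: parameter recovery and bootstrap coverage use 50
simulations of the 4-wave, n = 5000 fixture with $B = 200$; selection
recovery uses 50 runs at n = 2000/wave; likelihood-ratio calibration
uses 200 null simulations at n = 2000/wave; moment-matching checks use
n = 40{,}000 draws. The acceptance script runs the 8-wave default
cohort (N = 12{,}000) end to end.

## Known limitations

- No regularized (eLasso-type) estimation and no EM for missing data;
  complete cases only.
- No within-person dynamic modelling; "trajectory" means a sequence of
  cross-sectional states.
- Cross-stratum and cross-cohort temperatures are relative to each
  fit's own first occasion; the package never reports absolute
  temperatures.
- The mixed-model interaction test inherits the weaknesses of two-stage
  summaries: estimation uncertainty in the stage-one temperatures is
  ignored (a weighted variant is deliberately not the default, to match
  the two-stage convention).
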