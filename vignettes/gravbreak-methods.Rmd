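---
title: "Change-point gravity models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Change-point gravity models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

The classical gravity model says that the interaction intensity
$G_{ij}$ between a source location $i$ and a destination $j$ scales
with their population sizes and decays as a power of the distance
between them:

$$G_{ij} = K \frac{m_i^{\alpha} n_j^{\beta}}{d_{ij}^{\gamma}},
\qquad
\log G_{ij} = \log K + \alpha \log m_i + \beta \log n_j
  - \gamma \log d_{ij}.$$

A single decay exponent $\gamma$ at all distances is a strong
assumption, and in dyadic communication data (e.g. county-to-county
call counts) the decay often steepens or flattens beyond some
distance. `gravbreak` relaxes it with a per-source broken-stick decay:

$$Y_{ij} = \mu + \beta_1 \log n_i + \beta_2 \log n_j
  + \beta_{3,i}\,\log d_{ij}
  + \beta_{4,i}\,(\log d_{ij} - \theta_i)_+ + \varepsilon_{ij},
\qquad \varepsilon_{ij} \overset{iid}{\sim} N(0,\sigma^2),$$

where $Y_{ij} = \log G_{ij}$ is the natural-log count, $\theta_i$ is
the break (change point) for source $i$ on the log-distance scale, and
$(x)_+ = x\,I(x > 0)$ is the hinge basis, which keeps the mean
continuous in distance at $d_{ij} = e^{\theta_i}$. $\beta_{3,i}$ is
the decay slope before the break and $\beta_{3,i}+\beta_{4,i}$ the
slope after; $\beta_{4,i} = 0$ means no break for source $i$ (the
*reduced* model for that source). All logarithms in the package are
natural logarithms.

Two variants are fitted:

* **Case I** assumes the intercept and the two population effects are
  shared by all sources.
* **Case II** lets the sources with a break ($\eta_i = 1$, where
  $\eta_i$ is the inclusion indicator of $\beta_{4,i}$) carry their
  own intercept and population-effect *offsets*
  ($\mu_{cp}, \beta_{1,cp}, \beta_{2,cp}$). The offset
  parameterization (baseline plus group offset, rather than two
  disjoint intercepts) is what makes the covariate matrix exactly
  $S(S-1) \times (5 + 2S - b)$ wide; the three group columns flip
  with $\eta$ between iterations. Whether the group effects should be
  offsets or wholly separate parameters is not determined by the
  column count alone; the offset form was chosen because it nests
  Case I at zero offsets.

## Inference: two Gibbs blocks

Conditionally on the breaks $\theta$, estimating the coefficient
vector is a variable-selection regression; conditionally on the
coefficients, updating $\theta$ is a plain Metropolis step. The
sampler alternates the two blocks, which is valid as a two-component
Gibbs scheme. The test suite checks this decomposition literally:
with the $\theta$ block frozen the pipeline reproduces, draw for
draw, the standalone Bayesian LASSO sampler; with the coefficients
frozen the $\theta$ chain reproduces the exhaustive grid posterior.

### The Metropolis block

Each $\theta_i$ receives a random-walk proposal
$\theta_i' \sim N(\theta_i, \sigma^2_\theta)$. The prior on
$\theta_i$ is uniform over the *observed* log-distance range of
source $i$ (open interval), which is the truncation implied by an
indicator term in the posterior: any out-of-range proposal has
posterior ratio zero and is rejected. The proposal is symmetric, so
in-range proposals are accepted with the Gaussian likelihood ratio of
source $i$'s rows only. When $\beta_{4,i} = 0$ the likelihood does
not involve $\theta_i$ and the break location diffuses freely over
its range — which is why credible intervals for $\theta_i$ are
reported *conditionally on inclusion* (draws with $\eta_i = 1$), with
the inclusion frequency reported separately.

The default tuning value is $\sigma^2_\theta = 0.2$; on data of the
scale the package targets it keeps the mean acceptance rate in the
commonly recommended 20–25% band, and acceptance decreases strictly
in $\sigma^2_\theta$ (a property the acceptance suite verifies over a
16-point grid from 0.015 to 0.6).

### The boundary rule

A break proposed so close to the edge of a source's distance range
that strictly fewer than 5% of that source's pairs lie on one side is
not estimable; such sources are flagged, their $\beta_{4,i}$ forced
to zero and their hinge column removed from the next estimation step.
The count of flagged sources is the $b$ in the matrix widths
$2 + 2S - b$ (Case I) and $5 + 2S - b$ (Case II). The rule is strict
("fewer than"): exactly 5% on one side does not flag. Points at
exactly $\theta_i$ count as the pre-break side, matching the hinge,
which is zero there. Flagged coefficients re-enter as zeros after the
inner block, and a flagged source whose break moves back into the
interior simply rejoins the model at the next iteration.

### The Bayesian LASSO block

The coefficient block is a from-scratch Gibbs sampler for the
hierarchical form of the double-exponential (Laplace) prior:

$$\mathbf{Y} \mid \mu, \boldsymbol\beta, \sigma^2
  \sim N(\mu \mathbf{1} + X\boldsymbol\beta, \sigma^2 I), \quad
\boldsymbol\beta \mid \tau^2_{1..p}, \sigma^2
  \sim N(\mathbf{0}, \sigma^2 D_\tau), \quad
\tau^2_j \sim \mathrm{Exp}(\lambda^2/2),$$

with $D_\tau = \mathrm{diag}(\tau_1^2,\dots,\tau_p^2)$. Full
conditionals: $\boldsymbol\beta \sim N(A^{-1}X^\top\tilde{Y},
\sigma^2 A^{-1})$ with $A = X^\top X + D_\tau^{-1}$ and
$\tilde{Y} = Y - \mu\mathbf{1}$; $1/\tau_j^2$ inverse-Gaussian with
mean $\sqrt{\lambda^2\sigma^2/\beta_j^2}$ and shape $\lambda^2$
(sampled by the Michael–Schucany–Haas transformation);
$\sigma^2$ scaled inverse-gamma; $\lambda^2$ gamma. The intercept
$\mu$ is unpenalized, has a flat prior, and is drawn from
$N(\overline{Y - X\beta}, \sigma^2/n)$.

Default priors: $\pi(\sigma^2) \propto 1/\sigma^2$ and
$\lambda^2 \sim \mathrm{Gamma}(r = 2,\ \delta = 0.1)$ — conventional
weakly-informative choices for this hierarchy; both are configurable
through `blasso_priors()` (the improper $\sigma^2$ prior is replaced
by a proper inverse-gamma in the suite's prior-recovery test, which
needs to draw from the prior).

The sweep's correctness is established three ways in the tests: a
Geweke-style successive-conditional simulation (prior marginals of
$\beta,\sigma^2,\lambda^2$ preserved under repeated data
regeneration and sweeps), agreement of posterior means with exact
two-dimensional quadrature on a small problem, and the closed-form
ridge/OLS limits of the $\beta$ conditional.

### Reversible jump (Case II)

Case II updates the model label — the pattern of zeros in
$\beta_4$ — with reversible-jump moves inside the inner block. One
candidate column (a $\beta_4$ column or one of the three group-offset
columns) is picked uniformly and toggled: a *birth* draws the new
coefficient from its Gaussian full conditional (a centering proposal
with unit Jacobian), a *death* zeroes it. With this proposal the
acceptance probability reduces to the marginal-likelihood ratio of
the two models, the coefficient integrated against its
$N(0, \sigma^2\tau_j^2)$ prior; candidate models carry equal prior
weight (an independent Bernoulli(1/2) on each candidate's
inclusion). The toggle kernel is self-inverse, so detailed balance
holds on the model chain; the tests verify it by matching long-run
inclusion frequencies against exact marginal-likelihood enumeration
on a two-model problem. $\eta_i$ is then set to
$I(\beta_{4,i} \neq 0)$ — deliberately sign-agnostic, since a break
may either steepen or flatten the decay.

The inner block runs at least $h = 2$ sweeps per outer iteration
without reversible jump and $h = 3$ with it, so a coefficient zeroed
on entry cannot merely be carried through the block. The penalty
$\lambda$, the error variance $\sigma^2$ and the latent scales are
carried across outer iterations; a column re-entering after a
boundary episode restarts at $\tau_j^2 = 1$, which its first sweep
immediately overwrites.

### Degenerate group splits

The group-offset columns are kept in the covariate matrix even when
the change-point group is momentarily empty (they are then zero
columns, which the shrinkage prior tolerates and for which the RJ
ratio is exactly 1), so the printed width $5 + 2S - b$ always holds.
The unpenalized OLS *initializer* has no such protection: when the
group is empty, is everything, or consists of a single source (whose
log-population offset is then proportional to the group indicator),
the offsets are unidentified and the affected columns are dropped
from the crude fit with coefficient zero. Genuine rank deficiency
anywhere else raises an error naming the collinear columns.

## Initialization

Crude starting values keep the chain away from distant local modes:

1. **Grid search.** For each source, profile the per-source
   broken-stick regression (`y ~ 1 + log n_j + log d + hinge`) over
   100 equally spaced candidate breaks, excluding the outer 5% of the
   log-distance range on each side (mirroring the boundary rule; the
   grid resolution is a package default, exposed as `n_grid`). Ties
   break toward the smallest $\theta$. The profile is per-source:
   given $\theta$, the sources are separable, so the per-source RSS
   argmin coincides with the joint-likelihood argmax.
2. **OLS / BIC.** Case I: ordinary least squares on the full design
   at the profiled breaks. Case II: per-source comparison of the
   break model against the no-break model by
   $\mathrm{BIC} = -2\,\ell_{max} + k \log n$, with $n$ the number of
   that source's pairs (the package's convention; $k$ counts the
   regression coefficients plus the variance, and only the
   difference $\Delta k = 1$ matters); $\eta^{(0)}_i = 1$ iff the
   break model wins, then OLS with the losing sources' hinge columns
   removed.

## Convergence diagnostics

For transdimensional chains the usual potential scale reduction
factor is split in two. With $C$ chains of length $T$ visiting $M$
distinct models, four variations are computed — total $\hat V$
(normalizer $1/(CT-1)$), within-chain $W_c$ ($1/(C(T-1))$),
within-model $W_m$ ($1/(CT-M)$) and within-model-and-chain $W_mW_c$
($1/(C(T-M))$), each centering at the corresponding mean — and

$$\mathrm{PSRF}_1 = \hat V / W_c, \qquad
  \mathrm{PSRF}_2 = W_m / W_mW_c.$$

Both tend to 1 as chains mix. The monitored scalar defaults to
$\sigma^2$, whose meaning is the same in every model; the intercept
or any other global column is selectable. Chains are divided into
disjoint batches (default 500 iterations; computing each batch in
isolation rather than cumulatively is a package choice — either
reading is defensible and the batching is configurable) and the pair
is reported per batch. Convergence is declared when
$\mathrm{PSRF}_1 < 1.5$ (an accepted bound for a fluctuating
transdimensional factor) and $\mathrm{PSRF}_2 < 1.1$ over the final
three batches.

One practical caveat: with many sources the model space
$\{0,1\}^S$ is enormous, and a rapidly mixing reversible-jump chain
can visit more distinct inclusion patterns within a batch than the
batch has iterations, making $W_mW_c$'s normalizer non-positive. For
such runs the diagnostic is computed with the coarser *model-size*
label (the number of included break terms), selected by
`chains_from_draws(..., label = "size")`.

## The synthetic-data generator

`sim_generate()` emulates the structure of a county-level mobile-call
dyad dataset: $S$ locations (default 65) with user populations drawn
log-uniformly over $[7.9\times10^3, 3.6\times10^5]$, centroid
coordinates uniform in a box spanning a few hundred kilometres, all
$S(S-1)$ directed pairs with haversine distances (sphere radius
6371 km), and log counts normal around the broken-stick mean with
$\sigma^2 \in \{0.30, 0.38, 0.45\}$ (medium 0.38 by default) — the
low/medium/high error-variance scenarios used by the study harness.
Latent log intensities are converted to integer counts by
$\max(1, \mathrm{round}(e^{Y}))$, so the stored outcome
$\log(\mathrm{count})$ equals the latent value only up to count
rounding; the default parameters put nearly all counts well above 10,
where the rounding perturbation (at most $\approx 0.7/\mathrm{count}$
on the log scale) is negligible against the noise.

Default true parameters are plausible magnitudes for the roles the
parameters play, fixed once: $\mu = 0.5$,
$\beta_1 = \beta_2 = 0.6$, pre-break slopes spread evenly over
$[-1.7, -0.7]$ across sources — decay heterogeneity is the model's
reason to exist; identical slopes would collapse it to the plain
gravity form — and breaks in the first half of the sources with
slope differences alternating between $-1.0$ and $+0.7$. Breaks are
placed uniformly in the middle 40–60% stretch of each break source's
realized log-distance range; explicitly supplied breaks must fall
inside the realized range, with coordinates resampled a bounded
number of times otherwise.

What the generator does *not* emulate: real county geography
(restricted source data; coordinates are generated, so the study
harness reproduces qualitative orderings, not any particular
published table), zero-count dyads, overdispersion beyond Gaussian
log-noise, and spatial correlation of residuals. Passing tests
therefore demonstrate correctness of the algorithm under its own
assumptions, not robustness to their violation.

## The study harness

`run_study()` crosses error-variance levels with Metropolis tuning
values; in each cell it fits the plain gravity model by OLS, the
crude grid-search/BIC model, and the full sampler, then scores all
three by mean squared prediction error
$\mathrm{PE} = \frac{1}{M}\sum (y_{new} - \hat y_{new})^2$ on fresh
outcome sets drawn on the *same* covariates and true parameters (the
natural reading of a same-covariates test design), and records the
mean $\theta$ acceptance rate and the coverage of 95% break-location
credible intervals against the truth. Predictions from the sampler
are model-averaged: each retained draw's mean model is evaluated and
averaged, so models are weighted by their posterior visit
frequencies.

The acceptance suite runs the harness at $S = 10$ with two simulated
training sets per variance scenario, 20 test sets per fit, and
2,000–4,000 outer iterations (burn-in one third, thinning 1) — sizes
at which the qualitative conclusions are stable: the change-point
fit beats the gravity model by a wide margin at every noise level,
tracks the crude BIC fit within 10%, and the true model's PE sits at
the irreducible $\sigma^2$.

## Numerical choices and edge cases

* Pairs with a zero count are dropped at load (with a warning):
  the log outcome is undefined and adding a small constant biases
  the fit.
* Row order is fixed (source index, then destination index), and the
  column order of the design matrix is fixed and documented, so
  matrices are bit-reproducible.
* Grid-search ties break toward the smallest break location.
* $1/\tau_j^2$ draws guard against $\beta_j$ numerically at zero by
  capping the inverse-Gaussian mean; excluded candidates' scales are
  refreshed from their exponential prior so a later birth finds a
  coherent $\tau_j^2$.
* All randomness flows through R's global RNG; every top-level entry
  point (`sim_generate`, `run_case1/2`, `run_study`, the CLI and the
  acceptance script) takes a seed, and fixed seeds reproduce runs
  bit-for-bit.
* `summarize_draws` reports equal-tailed empirical quantile
  intervals; a source never included has no conditional break
  interval and is reported as `NA`.

## Known limitations

* The shared intercept/population effects are nearly collinear with
  the per-source slope columns when within-source log-distance
  variation is small relative to its mean, so $\mu$ and $\beta_1$
  are only weakly identified individually; predictions and the
  per-source slope/break summaries are unaffected.
* One break per source; no spatially correlated errors; Gaussian
  log-count likelihood only (a count model such as the negative
  binomial would suit very small counts better but is out of scope).
* With few destinations per source the break posterior is wide and
  inclusion probabilities are moderate; that is honest uncertainty,
  not a convergence failure.
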