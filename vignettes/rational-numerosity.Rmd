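---
title: "A rational categorization account of numerosity estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A rational categorization account of numerosity estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numbayes)
```

## The task and the model

In the estimation tasks this package models, a participant briefly sees
a scatter of same-colored circles, types a two-digit estimate of how
many there are, and then receives feedback with the true count. Within
a block, counts come from one of two Gaussian distributions ("baseline"
and "alternative"), each tagged by its own circle color; counts are
rounded to integers and truncated to [10, 100]. Because there is no
time to count, estimates lean on learned expectations — and the
interesting question is *which* expectations: one per color, or a
single merged category spanning both colors when their count
distributions overlap?

The observer model is a Chinese restaurant process (CRP) mixture. Each
trial belongs to a latent category $z_t$; a category $k$ emits counts
$x_t \sim \mathcal{N}(\mu_k, \sigma_k^2)$ and colors
$c_t \sim \mathrm{Multinomial}(\theta_k)$, the observer receives a
noisy sensory signal $y_t \sim \mathcal{N}(x_t, \sigma_y^2)$, and the
partition prior is the CRP with concentration $\alpha$: an occupied
category of size $M_k$ attracts the next trial with probability
$M_k/(t-1+\alpha)$ and a new category opens with probability
$\alpha/(t-1+\alpha)$. Small $\alpha$ encodes a simplicity bias —
categories are multiplied only when the data demand it.

Category parameters are never represented explicitly. A
normal-inverse-gamma prior on $(\mu_k, \sigma_k^2)$ (parameters
$\mu_0, \eta_0, a_0, b_0$) and a symmetric Dirichlet prior (parameter
$\lambda$) on $\theta_k$ are conjugate, so each category is summarized
by sufficient statistics (member count $M_k$, color counts $N_{ck}$,
running mean $\bar{x}_k$ and sum of squared deviations). The posterior
predictive for a new count is Student-t with $2a_k$ degrees of freedom,
location $\hat\mu_k$ and squared scale
$\beta_k = b_k(1+\eta_k)/(a_k\eta_k)$, where

$$\hat\mu_k = \frac{\eta_0\mu_0 + M_k\bar{x}_k}{\eta_k},\qquad
\eta_k = M_k + \eta_0,\qquad
a_k = \frac{M_k + a_0}{2},$$
$$b_k = b_0 + \tfrac12\textstyle\sum_{i} \delta[z_i,k](x_i-\bar x_k)^2
 + \frac{M_k \eta_0 (\mu_0 - \bar x_k)^2}{2\eta_k},$$

and the color predictive is
$(\lambda + N_{ck})/(C\lambda + M_k)$ with $C = 3$ colors. Two
conventions here deserve a note. First, $\beta_k$ is the *squared*
scale of the predictive t — `count_predictive_logpdf()` divides by
$\sqrt{\beta_k}$ — which is what exact marginalization of
$(\mu, \sigma^2)$ under the prior yields; the test suite verifies this
against direct numerical quadrature of the marginal. Second,
$a_k = (M_k + a_0)/2$ means the prior inverse-gamma shape is
effectively $a_0/2$ and an empty category's predictive has $a_0$
degrees of freedom; the implementation follows this parameterization
literally throughout.

## Inference

The exact posterior over partitions is a sum over all set partitions of
the trials so far — feasible only for a handful of trials.
`enumerate_posterior()` and `enumerate_predictions()` compute it
explicitly (guarded at 12 trials); they exist to serve as the oracle
against which everything else is validated.

`run_session()` runs the practical algorithm: a Rao-Blackwellized
sequential importance resampling particle filter. Each particle carries
one assignment history as per-category sufficient statistics. On every
trial the filter first forms the pre-feedback estimate (below); after
feedback each particle samples $z_t$ from its conditional posterior
$\propto \mathrm{CRP} \times \text{color predictive} \times
\text{count predictive}$ and is reweighted by the marginal likelihood
of $(x_t, c_t)$, with systematic resampling when the effective sample
size drops below half the particle count. Beliefs reset at block
boundaries by default (each block is a fresh context; the flag
`reset_per_block` exposes the alternative). A compiled implementation
(the default engine) and a pure-R reference implementation
(`particle_filter_step()`) share the identical kernel and are both
checked against the enumeration oracle.

The trial-wise estimate is the posterior mean of $x_t$ given the signal
$y_t$, the color, and history: for every candidate category the
component mean is a precision-weighted combination of the category's
predictive mean and $y_t$, and component weights multiply the CRP
prior, the color predictive, and the marginal density of $y_t$. That
marginal requires convolving a Student-t predictive with Gaussian
sensory noise, which has no closed form; the implementation
moment-matches the t to a Gaussian (variance
$\beta_k \cdot \mathrm{dof}/(\mathrm{dof}-2)$, falling back to
$\beta_k$ when $\mathrm{dof} \le 2$), making the estimate an exact
mixture-of-Gaussians computation. The concentration limits bound the
impact of this choice: at $\alpha \to 0$ the filter reproduces the
analytic single-category conjugate estimator, and at
$\alpha \to \infty$ the forced all-singletons (exemplar) model, both
verified numerically.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| $\alpha$ | simplicity bias (expected number of categories) | 0.5 | modest preference for few categories; fitted freely per subject |
| $a_0$ | inverse-gamma shape (category variance prior strength) | 4 | weak; empty-category predictive has 4 dof |
| $b_0$ | inverse-gamma scale | 10 (fixed) | sets the $\sigma_k^2$ scale; held fixed during fitting |
| $\eta_0$ | pseudo-count on the category mean | 0.05 | weak prior: fresh-category predictive SD ≈ 14 recentered counts |
| $\mu_0$ | prior category mean | 0 | data are recentered per subject, so 0 is the subject's mean count |
| $\lambda$ | Dirichlet color smoothing | 1 (fixed) | uniform color prior |
| $\sigma_y$ | sensory noise SD (counts) | 5 | moderate noise at these magnitudes; fitted freely per subject |

Counts and responses are always recentered by the subject's mean true
count before fitting (`recenter_trials()`), which is why $\mu_0 = 0$.

## Simulated experiments

`make_design()` hard-codes the three two-condition designs (8 blocks
per condition, 20 trials per block, 10 baseline + 10 alternative
randomly interleaved, counts truncated to [10, 100]):
baseline (65, 10) against alternatives (55, 10) and (35, 10); baseline
(65, 20) against (35, 20) and (35, 10); and baseline (50, 10) against
(60, 10) and (80, 10). Where the procedural record is silent the
generator makes a documented choice, switchable via arguments:
truncation clamps Gaussian draws to the bounds after rounding
(`method = "resample"` redraws instead); each block's two colors are
drawn without replacement from the three available; simulated
responders clamp responses to the two-digit range [10, 99]
(`clamp = FALSE` disables); block order and within-block trial order
are uniform random permutations.

Simulated responders (`responder_ideal()`, `responder_exemplar()`,
`responder_prototype()`, `responder_global_mean()`) answer block by
block using only feedback from earlier trials, with additive Gaussian
response noise (SD 2 by default for the observer-based responders).
What the generator deliberately does not emulate: timeouts (human data
has them; the loader tolerates missing responses), display geometry
(circle density and occupied area are uncontrolled in the task),
response times, and any within-block drift in attention — so passing
tests say the pipeline recovers the statistics of *this* generative
story, not that human data would fit it equally well.

## Fitting and model comparison

`fit_observer()` fits one subject by minimizing the mean-squared error
between the filter's trial-wise predictions (with $y_t = x_t$, the
standard expedient since the experimenter cannot observe the
participant's sensory signal) and the subject's responses — the
Gaussian maximum-likelihood objective. Free parameters:
$(\alpha, a_0, \eta_0, \sigma_y)$ for the rational model,
$(a_0, \eta_0, \sigma_y)$ for the exemplar model (the all-singletons
limit; its $\alpha$ is pinned at $10^8$). Response-noise variance is
not a separate parameter — the MSE objective absorbs it.

The optimizer is Nelder-Mead on logit-transformed coordinates within
bounds ($\alpha \in [10^{-3}, 10^3]$ and $\eta_0 \in [10^{-2}, 10^2]$
log-scaled; $a_0 \in [0.5, 50]$, $\sigma_y \in [0.5, 30]$ linear),
restarted from a canonical mid-range point, from a prior-dominated
corner that approximates the constant-mean predictor (so the fitted MSE
cannot end up worse than that baseline), and from random points — 3
starts by default. Every objective evaluation runs the filter with the
same seed (common random numbers), so the objective is deterministic
and two fits with identical seeds are identical. The default 200
particles per evaluation keep the objective's Monte-Carlo jitter well
below the response-noise floor while fitting a 320-trial session in
tens of milliseconds; `fit_control()` exposes the particle count,
bounds, restarts and iteration budget.

Model comparison uses the BIC approximation to the Bayes factor with
the Gaussian plug-in likelihood, shared constants dropped:
$\mathrm{BIC} = n\ln(\mathrm{MSE}) + p\ln n$ with $p = 4$ (rational)
or $3$ (exemplar), and
$\log \mathrm{BF} = (\mathrm{BIC_{ex}} - \mathrm{BIC_{rat}})/2$,
positive favoring the rational model. `count_categories()` summarizes
the representation a fit posits as the modal number of occupied
categories across particles at each block's end (the expected count is
available from the per-trial output); an exemplar fit always stores one
category per trial — 20 per block.

## Numerical choices and degenerate inputs

Likelihood computations run in log space inside the filter; an
all-underflow trial falls back to opening a new category with a floored
marginal. A zero-variance stimulus stream is well-posed (the
sufficient-statistics update keeps `sse = 0`). The Welford update and
downdate are exact inverses, so removing the last observation restores
a category bit-for-bit. Ties in category sampling need no special
rule — weights are continuous and the seeded sampler resolves exact
ties. The t-to-Gaussian moment match is undefined for dof ≤ 2, where
the squared scale is used instead; with the default $a_0 = 4$ a fresh
category starts at exactly 4 dof.

Problem sizes used by the test-suite and the acceptance script — 6
trials for enumeration cross-checks (5,000 particles), 150 single-session
replicates for direction properties, cohorts of 10 subjects for
recovery — were chosen so each check resolves its effect cleanly at
desk scale.

## Design choices that were genuinely open

* **Exclusion rule scope.** Subjects are excluded when their mean
  absolute error on alternative trials exceeds the across-subject mean
  by two SDs, pooling all experiments; with zero spread nobody is
  excluded.
* **Sequential-correlation pairing.** Each target trial pairs with the
  most recent preceding other-type trial *within the same block*;
  blocks are independent contexts, so pairs never cross boundaries, and
  block-initial targets with no preceding other-type trial are skipped.
* **Cohen's d for paired contrasts** is
  $\bar{d}/\mathrm{SD}(d) = t/\sqrt{n}$, consistent with the reported
  effect sizes in this literature.
* **Per-subject pooling.** All of a subject's blocks are fitted
  jointly with per-block belief resets, one parameter set per subject.

## Known limitations

The differential regularization the behavioral experiments found is
weak in the *unfitted* ideal observer. At the default parameters the
mean-manipulation designs show the expected direction (baseline
estimates pulled further toward the alternative mean in the
higher-overlap condition) at about 0.1–0.2 counts — an order of
magnitude smaller than the behavioral effects, so 10-subject cohorts
resolve the sign only marginally. For the variance-manipulation design
the unfitted observer's differential is reliably *opposite* in sign at
every parameter regime we scanned: the tight low-variance alternative
category attracts the broad baseline's lower tail (a per-trial
attribution effect) more strongly than the extra category merging in
the high-variance condition pushes estimates down. Reproducing that
design's observed direction appears to require parameters fitted to
behavioral data, which these simulations do not have. The package
reports what the model actually does; tests assert the directions the
simulations support and the acceptance checks print the measured
contrasts.

The model also assumes exchangeable trials within a block — it cannot
produce the sequential (trial-to-trial) correlations the statistics
battery measures; on model-simulated data those correlations hover
near zero, and the battery's positive-coupling test uses an explicitly
drifting synthetic responder instead.
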