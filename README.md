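# numbayes

Bayesian nonparametric ideal-observer models of perceptual number
estimation.

When people estimate how many items they briefly saw, their guesses are
pulled toward learned expectations. If items of two kinds (say, two
circle colors) have overlapping count distributions, an observer with a
simplicity bias should *merge* them into one perceptual category and be
biased toward the joint mean; if the distributions are well separated,
the observer should keep one category per kind and estimates should
track each kind's own mean. `numbayes` is for computational cognitive
scientists who want to simulate, fit, and analyze this account end to
end.

The core is a Chinese restaurant process (CRP) mixture ideal observer.
Trial $t$ has a latent category $z_t$ with CRP prior
$P(z_t = k) \propto M_k$ for occupied categories and $\propto \alpha$
for a new one. Category $k$ emits counts
$x_t \sim \mathcal{N}(\mu_k, \sigma_k^2)$ under a normal-inverse-gamma
prior (so its posterior predictive is Student-t with $2a_k$ dof,
location $\hat\mu_k$, squared scale $b_k(1+\eta_k)/(a_k \eta_k)$) and
colors from a Dirichlet-multinomial. The observer sees a noisy signal
$y_t \sim \mathcal{N}(x_t, \sigma_y^2)$ and reports the posterior mean
of $x_t$, computed by a Rao-Blackwellized particle filter (exact
partition enumeration is available as an oracle for short sequences).
The package provides:

* `make_design()` / `generate_session()` / `simulate_responses()` —
  the three two-condition estimation experiments (interleaved blocks,
  truncated rounded Gaussian counts) and simulated responders (ideal
  observer, exemplar, color prototype, global mean);
* `run_session()`, `particle_filter_step()`, `estimate_count()`,
  `enumerate_posterior()` — inference;
* `fit_observer()` — per-subject maximum-likelihood fits of the
  rational observer and its exemplar (all-singletons) limit, with
  `compare_models()` / `compare_group()` BIC Bayes-factor comparison
  and `count_categories()` representation summaries; standard S3
  methods (`print`, `summary`, `coef`, `predict`, `fitted`,
  `residuals`, `simulate`, `plot`);
* `analyze_experiment()` and friends — the behavioral statistics
  battery (subject exclusion, condition means, paired t with Cohen's
  d, Fisher-z sequential correlations, Wilcoxon signed-rank);
* CSV/JSON/YAML round-trip IO (`write_trials()`, `write_fit_json()`,
  `read_config()`).

## Worked example

Simulate a small cohort of ideal observers on the first design and fit
one subject with both models:

```r
library(numbayes)
trials <- simulate_experiment("exp1", n_subjects = 4,
                              responder = responder_ideal(), seed = 42)
fit <- fit_observer(trials[trials$subject_id == "s01", ], "rational",
                    seed = 1)
print(fit)
#> rational observer fit: 320 trials, MSE = 5.180, BIC = 549.42
#> Parameters:
#>   alpha      a0    eta0 sigma_y
#>  1.4076  4.0489  0.0833  5.1220
ex <- fit_observer(trials[trials$subject_id == "s01", ], "exemplar",
                   seed = 1)
compare_models(fit, ex)
#> log Bayes factor (rational vs exemplar): 94.702
#>   BIC rational 549.42 (MSE 5.180) | BIC exemplar 738.82 (MSE 9.533), n = 320
count_categories(fit)
#> $per_block
#>  [1] 4 4 4 4 4 5 4 5 5 2 5 5 4 4 5 5
#> $median
#> [1] 4
```

Reading the numbers: the subject was simulated with response-noise SD 2
on top of an observer with $\sigma_y = 5$, and the fit recovers
$\sigma_y \approx 5.1$ with an MSE near the response-noise floor. The
log Bayes factor of ~95 (positive favors the rational model) says the
all-singletons exemplar model — which must store 20 categories per
20-trial block — explains this subject far worse than the rational
observer, which prefers a handful of categories per block (median 4
here). `analyze_experiment(trials)` then prints the condition means,
paired tests and sequential correlations for the cohort.

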