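---
title: "Methods: dynamic multistate occupancy with Gibbs variable selection"
author: "dmsocc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic multistate occupancy with Gibbs variable selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model the package fits, the sampler that fits
it, the choices made where the design was genuinely open, and what the
synthetic-data generator does and does not emulate.

## The ecological model

Each of $N$ sites is surveyed in $T = 2$ years and is, within a year, in
one latent state $z_{it} \in \{1, 2, 3\}$: unoccupied, occupied without
nesting, occupied with nesting. The state is assumed static within a year;
repeat surveys inform the observation process only. Year-1 states follow
the conditional-binomial simplex
$\phi_{i1} = (1-\psi_{i1},\, \psi_{i1}(1-R_{i1}),\, \psi_{i1} R_{i1})$,
which is preferred over a raw multinomial because occupancy $\psi$ and
nesting-given-occupancy $R$ are the quantities managers reason about.
Year-2 states follow a $3\times3$ transition matrix whose row $m$ applies
the same split with parameters $\psi_2[m]$, $R_2[m]$ conditional on the
year-1 state; $R_2[3]$ is *nest persistence*.

Observations can understate but never overstate the state. We use the
conditional-binomial cascade for the observation model:
$\Pr(y\,|\,z{=}2) = (1-p_2,\, p_2,\, 0)$ and
$\Pr(y\,|\,z{=}3) = (1-p_3,\, p_3(1-\delta),\, p_3\delta)$, i.e. at a
nesting site the adult is detected with probability $p_3$ and the nest is
then confirmed with probability $\delta$. A direct specification
$p_3 = \Pr(y{=}2\,|\,z{=}3)$, $\delta = \Pr(y{=}3\,|\,z{=}3)$ with
independent logit links cannot guarantee $p_3 + \delta \le 1$; the cascade
yields a valid simplex for any logit values, which is why it is the form
implemented (and documented here as a deliberate choice). An observed nest
therefore pins $z = 3$ exactly, and a truly unoccupied site is always
recorded as unoccupied.

Covariates enter through logit links with selection gates
$\gamma_k \beta_k$: standardized ordinal date on $p_2, p_3, \delta$
($\beta_1, \beta_2, \beta_3$; date varies per visit) and standardized log
snag density on $R_1$ and $R_2[3]$ ($\beta_4, \beta_5$; constant per
site). The $\psi$ parameters and the remaining transition entries are
intercept-only: the two-year design carries too few transitions out of
states 1 and 2 to support covariates there, so inference about habitat is
deliberately restricted to the nesting probabilities. Detection parameters
are shared across years, which is what lets a single-survey pilot year
borrow the observation model estimated from the repeat-visit year.

## Data semantics

* Observed states are coded 1/2/3; `NA` marks surveys not conducted. The
  removal design means every entry after the first nest detection within a
  site-year is `NA`, as is every year-1 survey after the first.
  `apply_removal_mask()` reproduces this pattern and is idempotent.
* The stopping rule is ignorable given $z$: conditional on the static
  within-year state, skipped visits carry no information, so masked cells
  simply contribute a factor of one to the likelihood.
* Snag density (stems/ha, >25 cm diameter) is log-transformed and then
  standardized across sites. Standardization uses the sample ($n-1$) SD —
  the `sd()` convention — and the constants are stored with the data so
  predictions can be mapped back to raw scales; results are invariant to
  the convention once constants are stored. The log offset defaults to 0
  and switches to $\log(x+1)$ automatically when zero densities are
  present (configurable via `log_offset`).
* Ordinal dates have 8 days subtracted in year 2 (a phenology delay
  correction) *before* pooled standardization over all surveyed cells.
  Pooling rather than within-year standardization keeps a single date
  scale for the shared detection model; this is a modelling choice, and a
  degenerate date covariate (all dates equal) falls back to centring only.

## Priors and Gibbs variable selection

All 11 logit-scale intercepts have uniform(0,1) priors on the probability
scale — equivalently, standard logistic densities on the logit scale,
which is how the sampler evaluates them.

Each coefficient carries an indicator $\gamma_k \sim \text{Bernoulli}(0.5)$
and the mixture prior: $\beta_k \sim N(0, \Sigma_k)$ when included,
$\beta_k \sim N(\mu_{\beta k}, S_{\beta k})$ (the pseudo-prior) when
excluded. The pseudo-prior moments are taken from a *global* fit with all
indicators fixed at 1 and a vague fixed slab (default variance 10,
logit² scale); they affect only mixing, never the posterior, a property
the test suite checks empirically by refitting under two different
pseudo-priors.

The slab variance is either fixed (`mode = "fixed_sigma"`, used by the
sensitivity sweep over $\Sigma_k = 10^{-1}, 10^{-0.75}, \dots, 10^4$) or
adaptive (`mode = "link_barker"`): $\Sigma_k = V/(\sum_k \gamma_k + 11)$,
the total linear-predictor variance divided by the number of active terms,
with $1/V \sim \Gamma(3.2890, 7.8014)$ — the hyperparameters under which a
logit-scale normal with that variance is closest to producing uniform
probability-scale marginals. Only the included coefficients contribute to
the variance budget; the intercepts have their own uniform priors and are
counted in the divisor but not in the conjugate update.

## The sampler

One iteration sweeps, in order:

1. **Latent states** — $(z_{i1}, z_{i2})$ drawn per site from the exact
   joint full conditional over all nine pairs (observation-inconsistent
   pairs get zero weight automatically through the structural zeros).
2. **Intercepts** — Gaussian random-walk Metropolis on the logit scale
   against the logistic prior density.
3. **Each $(\gamma_k, \beta_k)$ pair** — $\gamma_k$ from its exact
   Bernoulli full conditional. Under the Link–Barker prior a flip of
   $\gamma_k$ changes $\Sigma_k$ for *every* included coefficient, so
   their normal prior terms enter the odds alongside the likelihood
   ratio and the slab/pseudo-prior densities of $\beta_k$ itself. Then
   $\beta_k$: random-walk Metropolis under the slab when included, a
   direct pseudo-prior draw when excluded.
4. **$V$** — conjugate update: with $c = \sum\gamma_k + 11$ and $n_a$
   included coefficients, $1/V \sim \Gamma(3.2890 + n_a/2,\;
   7.8014 + c\sum_{\text{inc}}\beta_k^2/2)$, which reduces to the prior
   when nothing is included.

Proposal SDs adapt during burn-in only (Robbins–Monro on the log scale
toward 0.44 acceptance, step $t^{-0.6}$) and are frozen afterwards, so
detailed balance holds for every retained draw. Initialization: $z$ at the
maximum observed state per site-year (1 where all missing), intercepts
drawn from their priors, coefficients from the pseudo-priors, all
indicators at 1, $V$ from its prior — a configuration with finite
posterior density by construction; a non-finite initial likelihood raises
an error rather than starting a broken chain.

Likelihood evaluations inside the chain use cached per-site tables
(observation log-probabilities per latent state, state simplices), each
Metropolis proposal refreshing only the slice it touches; at every stored
draw the cached value is audited against a from-scratch evaluation and the
run aborts on disagreement. All probability arithmetic is in log space via
`log1pexp`, so extreme logits degrade gracefully rather than producing
NaNs, and the nine-term marginal uses log-sum-exp.

**Chains and storage.** The reference configuration is 3 chains × 55,000
iterations with a 5,000-iteration burn-in and 10,000 stored draws, giving
a thinning interval of $(55000-5000)\times3 / 10000 = 15$. Because 10,000
does not divide evenly by three chains, the total is split as
3,334/3,333/3,333, each chain storing its final quota at spacing 15 —
the only integer-thinning scheme consistent with both the interval and
the total. Each chain's RNG stream derives from the master seed by a
fixed offset, making every fit bit-reproducible given (seed, control,
data). Convergence is flagged with the potential scale reduction factor
$\sqrt{((n-1)W/n + B/n)/W}$ against the conventional 1.1 threshold.

## Posterior summaries

Intercepts, latent states and derived quantities are model-averaged over
the visited structures; coefficient summaries are *conditional on
inclusion* ($\gamma_k = 1$ draws only), the standard GVS reporting
convention, with a warning below 100 included draws and an error at zero.
Credible intervals are equal-tailed quantile intervals. Model
probabilities tabulate the index $M = 1 + \sum_k \gamma_k 2^{k-1}$, a
bijection onto $1..32$; the display rule reports structures in decreasing
probability until the cumulative mass reaches 0.95. The finite-sample
nesting proportion $\hat{x}_t = N^{-1}\sum_i I(z_{it}=3)$ is computed per
draw from the sampled latent states of the actual sites — a realization,
not a population probability, and accordingly more precise. Prediction
curves evaluate $\text{logit}^{-1}(\mu + \beta\,\mathrm{std}(x))$ per
included draw on a raw-scale grid through the stored transform constants.

## The synthetic-data generator

`simulate_dataset()` runs the generative process forward under a
`default_truth()` whose intercepts and coefficients are the study-scale
posterior means (e.g. $\mu_{\psi 1} = 3.27$, $\mu_\delta = 1.73$,
$\beta_3 = 1.96$, $\beta_5 = 1.74$) and whose design is 66 sites, one
survey in year 1, up to four in year 2, visits 7–10 days apart inside a
60-day season window with the year-2 window shifted 8 days later. The
covariate distributions are *fixture choices*, not estimates: snag
densities are log-normal(meanlog 0.7, sdlog 0.8) stems/ha, and survey
start dates uniform in the window — the study reports neither empirical
distribution, so these are configurable defaults chosen to look like a
managed-forest snag tally, fixed once and not tuned.

Two deliberate simplifications: scheduled survey dates are retained at
removal-masked cells (so the date standardization constants are identical
between generation and fitting; a real removal dataset would simply lack
those dates), and there is no spatial structure among sites, no snag
decay, no between-year change in snag density, and no within-year state
change. Passing tests on these data therefore demonstrates correctness of
the estimator under the model's own assumptions — not robustness to the
violations (nest failure mid-season, observer heterogeneity, spatial
autocorrelation) a field dataset might carry.

## Verification strategy and problem sizes

The test suite anchors every layer to an independent oracle: the marginal
likelihood to brute-force enumeration over all nine latent pairs (1,000+
random parameter/data draws at $10^{-12}$); the latent-state Gibbs step to
the enumerated conditional (20,000 draws, binomial error bounds); the
indicator full conditional to a direct evaluation of both marginal terms
($10^{-10}$); the $V$ step to a dense-grid normalization (total variation
< 0.01); and the joint sampler to two-dimensional quadrature on a reduced
model with fixed latents (posterior mean and SD within 0.02). Parameter
recovery uses 10 replicate fits at 500 sites with selection disabled
(3 chains × 5,000 iterations), checking pooled 95%-interval coverage of
all 16 generating values at the 90% level with a per-parameter floor —
the binomial tolerance appropriate to 10 replicates. Selection behaviour
is checked on 500-site data with $\beta_3, \beta_5$ at study scale and
the rest null: the real effects must out-rank every null effect in each
of 5 replicates, and the null-effect inclusion probability must decline
across fixed slab variances $10, 10^{2.5}, 10^4$ (the Lindley–Bartlett
penalty). These sizes were chosen to keep the full suite in a few
minutes while leaving Monte-Carlo error well inside each tolerance.

## Known limitations

* Two years only; the transition structure does not generalize to $T > 2$
  without extending the state model.
* No covariates on $\psi$ and no upward misclassification, by design.
* Metropolis proposals are scalar; heavily correlated posteriors (e.g.
  intercept/slope pairs under extreme covariate imbalance) mix more
  slowly than a blocked or gradient-based sampler would.
* The sensitivity sweep refits the model per slab value; at the reference
  chain length that is deliberately expensive, and the shortened-chain
  mode is the intended default for exploration.
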