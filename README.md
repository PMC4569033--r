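# dmsocc

Dynamic multistate occupancy modelling with Gibbs variable selection, for
two-season detection/non-detection studies in which each site can be
**unoccupied (1)**, **occupied without nesting (2)** or **occupied with
nesting (3)**, and the recorded state can understate — but never overstate —
the truth. The package was built around the design of a short-term
white-headed woodpecker study in recently harvested conifer stands: a
single-survey pilot year followed by a year of up to four repeat visits run
as a removal design (visits stop once a nest is found), with per-site snag
density and per-visit ordinal date as covariates.

## The model

Latent states are static within a year. In year 1 the state simplex for
site *i* is the conditional-binomial split

> φ*ᵢ*₁ = (1 − ψ*ᵢ*₁, ψ*ᵢ*₁(1 − R*ᵢ*₁), ψ*ᵢ*₁R*ᵢ*₁),

where ψ is occupancy and R nesting-given-occupancy. Year-2 states follow a
3 × 3 row-stochastic transition matrix φ*ᵢ*₂ whose row *m* applies the same
split with ψ₂[*m*], R₂[*m*] conditional on the year-1 state *m*.
Observations given the true state use the conditional-binomial cascade

> Pr(y | z = 2) = (1 − p₂, p₂, 0),  Pr(y | z = 3) = (1 − p₃, p₃(1 − δ), p₃δ),

so observing a state above the truth is a structural zero and an observed
nest pins the latent state. Logit-linear covariate effects enter as
γₖβₖ·x: ordinal date on p₂, p₃, δ (β₁–β₃) and standardized log snag
density on R₁ and on nest persistence R₂[3] (β₄, β₅).

Model selection uses Gibbs variable selection: each coefficient carries a
Bernoulli(0.5) inclusion indicator γₖ; included coefficients have a
N(0, Σₖ) slab prior and excluded ones are refreshed from a normal
pseudo-prior fitted from a global model, which provably leaves the
posterior untouched. The slab variance is either fixed (for sensitivity
sweeps) or given the Link–Barker adaptive form Σₖ = V/(Σγₖ + 11) with
1/V ~ Gamma(3.2890, 7.8014), the choice under which the 11 intercepts have
uniform(0,1) marginal priors on the probability scale. Estimation is a
native Metropolis-within-Gibbs sampler (exact latent-state and indicator
full conditionals, random-walk updates for intercepts and included
coefficients, conjugate inverse-gamma update for V), with Gelman–Rubin
diagnostics and finite-sample derived estimates such as the proportion of
the study's own sites with nesting in each year.

## Worked example

```r
library(dmsocc)

sim <- simulate_dataset(default_truth(), seed = 42)   # 66-site study design
fit <- dmsocc(sim$data,
              prior   = mso_prior(mode = "link_barker"),
              control = mso_control(n_chains = 2, n_iter = 2000,
                                    n_burn = 500, n_keep_total = 1000,
                                    seed = 7))
fit
```

```
Dynamic multistate occupancy model fit
  66 sites, 2 chains x 2000 iterations, 1000 stored draws
  prior: link_barker; GVS on
  inclusion probabilities:
beta1 beta2 beta3 beta4 beta5
0.217 0.336 1.000 0.452 0.984
  max Rhat: 1.016 (threshold 1.10)
```

The date effect on nest detection (β₃) is selected in every stored draw
and the snag effect on nest persistence (β₅) in 98% of them, while the
three weak effects hover near their prior inclusion odds — the same
qualitative ranking the generating parameters encode. `summary(fit)` adds
the Table-style posterior summaries; the finite-sample block

```
Finite-sample nesting proportion:
      mean lower upper
x1   0.938 0.848 0.985
x2   0.717 0.682 0.758
diff 0.221 0.121 0.288
```

estimates the realized fraction of these 66 sites with nesting per year
and the between-year decline. `model_probabilities(fit)` tabulates the
visited model structures (here M = 21, the β₃+β₅ model, leads at 0.28),
`predict(fit, "persistence_vs_snag")` returns the posterior mean curve and
95% band of nest persistence against raw snag density, and
`sensitivity_sweep()` traces inclusion probabilities across fixed slab
variances.

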