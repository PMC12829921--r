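# frailtynet

Deep survival prediction for **clustered** right-censored outcomes.

Patients treated at the same facility, members of the same family, or
subjects of the same trial site share unmeasured conditions, so their
times-to-event are correlated.  The standard tool is the shared-frailty Cox
model: conditional on a cluster-level random intercept `b_i ~ N(0, θ)`, the
hazard of subject *j* in cluster *i* is

    λ_ij(t | b_i) = λ0(t) · exp( r_ij + b_i ),

with a linear risk function `r_ij = X'β`.  When covariate effects are
nonlinear or interactive, the linear predictor leaves discrimination on the
table.  `frailtynet` replaces it with a feed-forward neural network and
moves the random intercept into the network's final layer: the risk score
is

    g_ij = η_x · α_ij^(L)  +  η_b[i],

where `α^(L)` is the network output and `η_b` holds one trainable weight
per cluster.  Everything — weights, biases, output scale and the
per-cluster random-effect weights — is trained jointly by mini-batch Adam
on the negative penalized approximated partial log-likelihood

    − Σ_ij Δ_ij [ g_ij − log Σ_{dq ∈ R(t_ij)} exp(g_dq) ]
    + (1/2θ) Σ_i η_b[i]²  +  n·γ·(ω'ω + δ'δ),

the partial-likelihood core with a Laplace-derived quadratic anchor on the
random effects and an L2 penalty on the network parameters.  The frailty
variance θ is refreshed by a moment update during training, the baseline
cumulative hazard is recovered with a Breslow-type estimator, and survival
curves follow `S(t|X,i) = exp(−Λ̂0(t)·exp(g))`.

The package also ships

* a clustered-survival **simulation engine** (two covariate scenarios:
  squared effects, and complex nonlinear/interactive effects) with
  within-cluster train/test splitting,
* the classical **comparison arms**: linear Cox, Cox with all two-way
  interactions, Gaussian-frailty Cox (linear / interactions, fitted by the
  same penalized machinery with empty hidden layers), Cox with fixed
  cluster effects, a no-frailty deep model (Deepsurv-style twin), and the
  true-risk oracle,
* **metrics**: Harrell's C-index and the IPCW time-dependent Brier score,
* a replicated **benchmark runner** and a command-line interface.

## Worked example

Simulate 200 clusters of 20–100 subjects with strong cluster heterogeneity
(θ = 3.5) and squared covariate effects, split every cluster 50/50, train
the frailty network at the benchmark protocol, and evaluate on the held-out
halves:

```r
library(frailtynet)

cfg <- scenario_config(1, theta = 3.5, seed = 1)
d   <- simulate_clusters(cfg)
sprintf("censoring: %.1f%%", 100 * censoring_rate(d))
#> censoring: 72.5%

sp  <- split_within_cluster(d, train_fraction = 0.5, seed = 2)
fit <- fit_frailty_net(sp$train,
                       net_config = network_config(5, c(64, 64)),
                       tr_config  = train_config(seed = 3))
fit
#> Neural-network frailty Cox model
#>   architecture: 5-64-64-1 (relu)
#>   clusters: 200, frailty: yes, theta = 0.1706

evaluate_method(fit, sp$test, times = c(0.05, 0.1, 0.2))
#> C-index: 0.8614 (7138597 usable pairs)
#> IPCW Brier score:
#>  time      score
#>  0.05 0.07499961
#>  0.10 0.09562309
#>  0.20 0.12033393
```

The C-index of 0.86 says that in 86% of usable pairs the subject predicted
to be at higher risk indeed failed earlier; Brier scores near 0.1 indicate
well-calibrated survival probabilities at those horizons.  Context from the
comparison arms on the same split: the linear Cox fit is blind to the
squared effects (C-index 0.51, a coin flip), while ranking by the
generator's true risk score — the ceiling no fitted model can beat — gives
0.90.  The network with its per-cluster weights recovers most of that gap.
The small fitted θ reflects the heavy shrinkage of penalized
partial-likelihood random effects under ~70% censoring; their *ranking*,
which is what prediction uses, is accurate.

The same workflow runs from a shell:

```sh
Rscript inst/cli/frailtynet.R simulate --config scenario.yml --out data.csv
Rscript inst/cli/frailtynet.R fit --data data.csv --method proposed --out model.rds
Rscript inst/cli/frailtynet.R benchmark --scenario 1 --theta 3.5 \
    --replicates 5 --methods cox,cox_fixed,deepsurv,proposed,true_model \
    --seed 1 --out report.csv
```

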