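# bvssl — Bayesian variable selection with graphical structure learning

`bvssl` finds the covariates that drive a continuous outcome when the
covariates are correlated, lie on a network, and arrive on mixed scales
(continuous alongside ordinal or binary). The motivating setting is
integrative genomics: expression and methylation (continuous) and copy
number (ordered categories) measured on the same samples, with prior
pathway knowledge about which genes interact, and a clinical outcome to
explain. The same machinery applies to any regression with heterogeneous,
graph-structured predictors.

The analysis has two stages:

1. **Structure learning** (`bvssl_graph()`). Ordinal covariates are
   modelled as thresholded latent Gaussians, so that jointly with the
   continuous covariates a precision matrix Ω captures all conditional
   dependence. Ω gets an element-wise graphical-lasso prior whose
   shrinkage rates λᵢⱼ follow a two-component Gamma mixture steered by a
   prior graph G₀ through per-edge *belief* parameters κᵢⱼ:

       π(λᵢⱼ) = (1 − pᵢⱼ) Ga(κᵢⱼ + a_λ, b_λ) + pᵢⱼ Ga(a_λ, b_λ),
       pᵢⱼ ~ Be(a₀ᵢⱼ κᵢⱼ + a_p, (1 − a₀ᵢⱼ) κᵢⱼ + b_p),

   so E(pᵢⱼ) = (a₀ᵢⱼκᵢⱼ + a_p)/(κᵢⱼ + a_p + b_p): κ = 0 ignores the
   prior graph, large κ forces strong shrinkage exactly where G₀ says
   "no edge". A Gibbs sampler (latent values, cutpoints, column-wise
   block updates of Ω, collapsed mixture updates) yields posterior
   partial correlations, and edge (i, j) enters the graph estimate iff
   ρ̂ᵢⱼ / E_W(ρᵢⱼ | X) > 0.5 against a Wishart(3, I) reference.

2. **Structured selection** (`bvssl()`). The maximal cliques C₁…C_q of
   the estimated graph define groups that enter or leave the linear model
   together:

       y = α1 + X_γ β_γ + ε,  εᵢ ~ N(0, η⁻¹),  βⱼ ~ DE(η₁),
       P(γ_Ck = 1) = π ~ Be(a_π, b_π).

   Selection uses the median-probability rule on clique inclusion
   probabilities, followed by dropping candidates whose 95% credible
   interval spans zero; `bayesian_fdr_threshold()` gives an
   FDR-controlling cutoff for marginal inclusion probabilities. With no
   graph (q = p singleton cliques) the sampler is exactly SSVS with
   Laplace priors.

The package also ships the simulation designs used to validate the
method (`sim_case_structure()`, `sim_mixed_data()`, `sim_binary_data()`,
`sim_two_block_structure()`), the evaluation metrics (`roc_prc_auc()`,
`power_at_fdr()`, `predictive_metrics()`, `graph_metrics()`), and a
replicate orchestrator (`run_replicates()`). The samplers are written in
C++ (RcppArmadillo) and all randomness flows through R's RNG, so fits are
bit-reproducible given a seed.

## Worked example

Simulate one dataset from the "Ia" design (three precision blocks, nine
ordinal columns, true support 1–8, 23, 24), learn the graph with the true
graph as prior knowledge at belief 20, and select variables:

```r
library(bvssl)

spec <- sim_case_structure("Ia", p = 40)
dat  <- sim_mixed_data(spec, n_train = 100, n_test = 100, seed = 3)

gfit <- bvssl_graph(dat$X_train, dat$col_kind, dat$n_levels,
                    prior_adj = dat$G_true, belief = 20,
                    n_iter = 3000, burn_in = 1000, seed = 3)
gfit
#> Mixed-data graphical model fit ( 40 nodes, 100 samples )
#>   kept samples: 2000
#>   estimated edges at ratio threshold 0.5 : 18

vfit <- bvssl(dat$y_train, dat$X_train, graph = gfit,
              n_iter = 4000, burn_in = 1000, seed = 3)
vfit
#> Clique-structured Bayesian variable selection fit
#>   n = 100 , p = 40 , q = 31 cliques
#>   kept draws: 3000
#>   selected cliques: 4 ; selected variables: 1, 2, 3, 5, 7, 8, 23, 24

pred <- predict(vfit, dat$X_test)
predictive_metrics(pred$fit, pred$lwr, pred$upr, dat$y_test)
#> $mspe
#> [1] 1.269028
#>
#> $coverage95
#> [1] 0.94
```

The graph estimate recovered exactly the 18 true edges (the three blocks),
so the cliques are the three 4-variable blocks plus singletons. All ten
true covariates have marginal inclusion probability 1.0 and the final
model keeps the eight whose credible intervals exclude zero — the weak
coefficients (±0.05–0.2) are deliberately dropped by the interval rule.
Out-of-sample prediction error 1.27 sits near the σ² = 1 noise floor and
the 95% predictive intervals cover 94% of the held-out responses.

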