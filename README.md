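# tcarmix

Model-based clustering of time-course gene-expression profiles with
mixtures of linear mixed models carrying **AR(1) gene-specific random
effects** and **cluster-shared random effects**.

## The problem

Periodically expressed genes — yeast cell-cycle transcripts are the
canonical example — are clustered by the shape of their expression
trajectory. Two correlations undermine a plain normal-mixture treatment
of the gene-by-time matrix: measurements of one gene at nearby time
points are serially dependent, and genes in the same regulatory module
covary with each other because they respond to shared signals.
`tcarmix` is for analysts who want both correlations in the model rather
than in the error term.

Conditional on membership of component *h*, gene *j*'s profile over *m*
time points is

```
y_j = X_h beta_h + u_jh + v_h + eps_jh
```

* `X_h beta_h` — a periodic mean: first-order Fourier basis
  `[1, cos(2 pi t / omega_h), sin(2 pi t / omega_h)]` with coefficients
  `(a0, a1, b1)` and component-specific period `omega_h` (a cubic
  B-spline basis replaces it for non-periodic profiles);
* `u_jh ~ N(0, theta2_h * A(rho_h))` — a gene-level AR(1) random effect,
  `A(rho)` having entries `rho^|i-j| / (1 - rho^2)` (serial dependence);
* `v_h ~ N(0, d2_h * I)` — one draw per cluster shared by all its genes
  (coregulation; `d2` measures its strength);
* `eps_jh ~ N(0, sigma2_h * I)` — measurement noise.

Marginally each component is normal with covariance
`theta2 * A(rho) + (d2 + sigma2) * I`. Fitting is by an EM algorithm with
closed-form E- and M-steps; membership posteriors condition on the
estimated shared effects, which is what lets the fitter exploit the
separation that coregulation creates. An AR(1)-residual mixture baseline
(covariance `theta2 * A(rho)` only) and a k-means adapter are included
for comparison, along with the misclassification error rate, Rand and
adjusted Rand indices, BIC selection of the number of clusters, and a
global grid search over candidate periods.

## Worked example

Simulate a 400-gene dataset from the full generative model (three
clusters with periods 6, 10, 16; `theta2 = 0.5`, `rho = 0.6`,
`sigma2 = 1`, `d2 = (0.4, 0.2, 0.3)`), then fit from a k-means start:

```r
library(tcarmix)
cfg    <- sim_preset("t1", n_genes = 400, seed = 42)
sim    <- sim_generate(cfg)
design <- design_spec("fourier", cfg$times, periods = cfg$periods)
fit    <- fit_emmix_ar1(sim$data, g = 3, design, init = "kmeans", seed = 1)
fit
#> Fitted 3-component full mixture
#>   logLik -17216.4787  BIC 34570.7611  iterations 555 (converged)
#>   cluster sizes: 233, 51, 116
error_rate(sim$true_labels, fit$labels)
#> [1] 0.04
adjusted_rand_index(sim$true_labels, fit$labels)
#> [1] 0.8806
fit$model
#> 3-component full mixture (fourier design)
#>   [1] p=0.586 theta2=0.642 rho=0.528 sigma2=0.902 d2=0.411 omega=6
#>   [2] p=0.125 theta2=0.315 rho=0.729 sigma2=1.138 d2=0.135 omega=10
#>   [3] p=0.289 theta2=0.613 rho=0.564 sigma2=0.934 d2=0.293 omega=16
```

Four percent of genes are misclassified, and the estimates sit near the
generating values (`p = (0.585, 0.1, 0.315)`, `theta2 = 0.5`,
`rho = 0.6`, `sigma2 = 1`): the fitter recovers both the partition and
the variance decomposition. `replicate_study()` repeats this over many
simulated datasets and tabulates mean error rates, Rand indices,
parameter bias/RMSE and how often the proposed model beats the
AR(1)-residual baseline. A thin command-line wrapper with subcommands
`simulate`, `fit`, `evaluate`, `replicate-study` and `select` is
installed at `inst/scripts/tcarmix`.

The methods vignette (`vignettes/time-course-clustering.Rmd`) documents
the model, the EM derivation and its objectives, the generator's
regimes, and the package's numerical conventions.

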