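# stochmom

Parameter inference for discrete-state stochastic reaction networks from
**population snapshot data**, using the **generalized method of moments
(GMM)**.

## The problem

Single-cell techniques such as flow cytometry measure thousands of cells at
a few time points, yielding sample moments (means, variances, higher and
mixed moments) of molecular counts — but no per-cell trajectories.  For a
reaction network modeled as a continuous-time Markov chain with mass-action
propensities $\alpha_j(x) = c_j \cdot \#\{\text{reactant combinations}\}$,
the rate constants $c_j$ must be recovered from those moments.  Likelihood
computation through the chemical master equation is infeasible for large
copy numbers, but the *moments* of the distribution obey small ODE systems
that can be derived symbolically and integrated in milliseconds.

`stochmom` matches sample moments $\hat m_r = N^{-1}\sum_\ell Y_\ell^r$
against theoretical moments $m_r(\theta)$ by minimizing the GMM objective

$$\hat\theta = \arg\min_\theta \sum_t g^{(t)}(\theta)'\, W^{(t)}\, g^{(t)}(\theta),
\qquad g_r(\theta) = \hat m_r - m_r(\theta),$$

over box bounds, where the weight matrix $W$ is the identity (least
squares), the inverse outer-product covariance of the conditions at a
first-step estimate (two-step GMM), or the inverse *demeaned* sample
covariance of the condition monomials (demean GMM, robust to moment-closure
error).  Iterated and continuously-updating variants are included.

Theoretical moments come from one of two engines:

* **standard moment closure** — raw-moment ODEs up to order *k* with all
  central moments above *k* set to zero;
* **hybrid conditional moments** — low-copy species (promoter states) keep
  a discrete mode distribution while high-copy species carry per-mode
  partial moments; fewer equations and markedly better accuracy for
  multimodal networks.

An exact Gillespie simulator (compiled, counter-based reproducible streams)
generates snapshot datasets, and a replication harness reruns whole
simulate-then-estimate grids (estimator x moment order x engine x sample
size).

Two case-study models are built in: a telegraph-type gene expression model
(linear, moments exact) and the bimodal exclusive switch (two proteins
competing for one promoter).

## Worked example

```r
library(stochmom)

net <- builtin_model("gene_expression")      # DNA_ON <-> DNA_OFF -> mRNA
theta0 <- c(a = 0.3, b = 0.2, c = 0.4)       # generating truth, within bounds

# 10,000 simulated cells observed at t = 100 (mRNA counts only)
ds <- sample_snapshots(net, theta0, times = 100, "mRNA",
                       n_samples = 10000, seed = 7)

# moment conditions: E[Y], E[Y^2], E[Y^3] at t = 100
spec <- moment_condition_spec(net, "mRNA", max_order = 3, times = 100)

fit <- estimate_parameters(ds, net, spec, estimator = "demean",
                           engine = "hybrid",
                           optimizer_config = list(n_starts = 8,
                                                   init = c(0, 0.5, 0)),
                           seed = 3)
fit
#> gmm_result (demean, hybrid engine)
#>       b       a       c
#> 0.22512 0.30965 0.41417
#> objective: 1.06011e-07  steps: 1
```

The demean-weighted fit recovers the switching rates `a`, `b` and the
transcription rate `c` within a few percent to ~13% of the truth from a
single observation time — even though the optimizer was started at the
corner `(0, 0.5, 0)` of the parameter box, far from the truth.  The tiny
objective value says the three sample moments are matched to well within
their sampling noise; with identity weights (`estimator = "identity"`) the
same data give visibly worse, higher-variance estimates, which is the
point of the weighting.

The same machinery drives a grid replication:

```r
grid <- experiment_grid("gene_expression", theta0,
                        observed_species = "mRNA", times = 100,
                        estimators = c("demean", "identity"), orders = 3,
                        n_samples = 10000, repetitions = 10, master_seed = 1)
run_recovery_experiment(grid)$summary
```

## Command line

An installed script wires the modules together:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "stochmom", package = "stochmom"))')
Rscript "$CLI" simulate --model gene_expression \
    --theta a=0.3,b=0.2,c=0.4 --times 100 --species mRNA \
    --n-samples 10000 --seed 7 --out snap.tsv
Rscript "$CLI" derive-moments --model exclusive_switch \
    --engine hybrid --order 4 --out odes.txt      # 45 equations
Rscript "$CLI" estimate --model gene_expression --data snap.tsv \
    --estimator demean --order 3 --seed 3 --out fit.txt
```

## Documentation

`vignette("stochmom-methods")` describes the moment derivations, the
closure, the hybrid construction, every estimator variant, and all
numerical choices (tolerances, multistart policy, RNG streams), along with
what the synthetic data do and do not emulate.
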