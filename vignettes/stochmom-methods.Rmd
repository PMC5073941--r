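---
title: "Moment-based GMM inference for stochastic reaction networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-based GMM inference for stochastic reaction networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochmom)
```

## The model class

`stochmom` works with discrete-state stochastic reaction networks: a
continuous-time Markov chain $\{X(t)\}$ over molecule-count vectors
$x \in \mathbb{Z}_{\ge 0}^n$, where reaction $j$ moves the state by a change
vector $v_j = v_j^- + v_j^+$ (consumed plus produced stoichiometry) with
mass-action propensity $\alpha_j(x) = c_j \cdot \#\{\text{distinct reactant
combinations}\}$ — $c_j x_i$ for one reactant, $c_j x_i x_k$ for two distinct
reactants, $c_j x_i (x_i - 1)/2$ for a homodimer pair.  Only mass-action
kinetics up to bimolecular order are accepted, and propensities are derived
from $v_j^-$ rather than taken as user expressions: the entire moment
machinery rests on the propensities being polynomials of degree at most two.
The distribution $p_t(x)$ obeys the chemical master equation (CME), which is
never solved directly; only its moment consequences are used.

Two case-study networks ship with the package
(`builtin_model()`): a telegraph-type **gene expression** model
(DNA\_ON/DNA\_OFF switching plus transcription; all propensities linear, so
every moment equation is exact) and the bimodal **exclusive switch** (two
proteins competing for one promoter; bimolecular binding makes moment
closure genuinely approximate and the hybrid treatment worthwhile).

## Moment equations and the zero closure

For a polynomial test function $T$,
$\frac{d}{dt}E[T(X)] = \sum_j E\!\left[\alpha_j(X)\,(T(X+v_j) - T(X))\right]$.
Taking $T(x) = x^\alpha$ for all multi-indices $1 \le |\alpha| \le k$ yields
ODEs for the raw moments.  Because the propensities are polynomials, the
right-hand sides are *exact* finite polynomials in raw moments; the package
expands them symbolically (`derive_moment_odes()`) instead of manipulating a
truncated Taylor series — for polynomials the Taylor sum about the mean is
finite and exact, so the two formulations coincide and the expansion route
avoids derivative bookkeeping.  Truncation happens only in the closure step.

Bimolecular reactions insert moments of order $k+1$ into the order-$k$
equations.  `apply_zero_closure()` rewrites each such moment through the
central-moment expansion about the mean and sets every central moment of
order $> k$ to zero.  No alternative closure (log-normal, derivative
matching, ...) is implemented.  For networks with at most monomolecular
reactions the closure is a no-op and the integrated moments are exact.

## The hybrid method of conditional moments

Multimodality usually stems from species with tiny copy numbers (promoter
occupancy).  Each species is annotated `low` or `high`; the reachable
low-copy subvectors $\hat x$ ("modes") are enumerated by breadth-first
search, and the integrated state consists of the mode probabilities
$p_t(\hat x)$ and the *partial moments*
$M_{\hat x, \alpha} = E[\tilde X^\alpha \mid \hat x]\, p_t(\hat x)$ of the
high-copy species.  Integrating partial rather than conditional moments
keeps the system an ODE system even where a mode probability vanishes:
every right-hand-side term scales with the source mode's probability.
Conditional closure terms formally divide by $p_t(\hat x)$; these are the
only negative powers in the compiled system and are dropped once the mode
probability falls below the truncation threshold (default `1e-12`, no
renormalization — both bundled models keep all of their modes well above
it).  Conditional moments are only ever formed at output time, and are
reported as `NA` for modes below the threshold.  Unconditional moments
follow from the law of total expectation,
$E[\hat X^\beta \tilde X^\alpha] = \sum_{\hat x} \hat x^\beta M_{\hat x,\alpha}$,
which also defines mixed low/high moments (the package's reconstruction
convention).

For the exclusive switch at order 4 this gives $3 \times (14 + 1) = 45$
equations versus 125 (plus the constant) for the standard closure, and —
more importantly — distinctly more accurate moments, which the test suite
verifies against stochastic-simulation references.

## The estimators

Observations are population snapshots: $N$ independent single-cell count
vectors $Y_\ell$ per observation time (flow-cytometry style; no cell is
tracked through time, and samples at different times come from independent
cells).  With $\hat m_r = N^{-1}\sum_\ell Y_\ell^r$ the sample moments and
$m_r(\theta)$ the engine's theoretical moments, the cost vector stacks
$g_r(\theta) = \hat m_r - m_r(\theta)$ over all (mixed) moment indices up to
order $r_{\max}$ and over the observation times, and the estimate minimizes
$\sum_t g^{(t)}(\theta)' W^{(t)} g^{(t)}(\theta)$ subject to the declared
box bounds.  Identification at minimum requires no more free parameters
than conditions; the package enforces this and only relaxes it behind an
explicit `allow_underidentified` flag used for method comparisons.

Weight choices (`estimate_parameters()`): identity (least squares, "2-Step
I"); two-step ("2-Step II"), with $W = \hat F_1(\tilde\theta)^{+}$, the
pseudo-inverse of the outer-product covariance of the conditions at the
first-step estimate; demean, with $W = \hat F_2^{+}$ where $\hat F_2$ is
the $\theta$-free demeaned covariance of the condition monomials (consistent
under model misspecification, i.e. under closure error); demean-diagonal
(inverse variances only — deliberately discards the mixed-condition
information); iterated two-step (default stops after the second weight
update, where accuracy gains cease); and continuously-updating GMM, which
recomputes $\hat F_1(\theta)^{+}$ inside the objective (documented as slow).
The identity $\hat F_1(\tilde\theta) = \hat F_2 + g(\tilde\theta)
g(\tilde\theta)'$ is checked to machine precision in the tests.

When several observation times are used, the single identity-weight step-1
fit feeds every per-time weight matrix in step 2.

## Numerical choices

* **Closure order.** Inference with conditions up to order $r$ derives and
  closes the engine at $k = r + 1$ and exposes only orders $\le r$: the
  highest closed order is the least accurate and is carried but never
  matched against data.
* **Integration.** A Dormand–Prince 5(4) adaptive Runge–Kutta integrator
  (compiled, shared by both engines) with defaults `rtol = 1e-8`,
  `atol = 1e-10`.  Inside the optimizer the engine runs at `rtol = 1e-6`,
  `atol = 1e-8` with a divergence bail-out (any state beyond `1e12` fails
  the evaluation immediately): the objective is evaluated thousands of
  times, closed bimolecular systems can explode at pathological parameter
  points, and finite-difference gradient steps dominate the residual
  integration error.  Step-size collapse is reported as an error, never
  silently ignored; inside the objective a failed integration scores a
  large penalty.
* **Weight-matrix inversion.** Symmetric pseudo-inverse with relative
  eigenvalue cutoff `1e-12`; near-singular covariance matrices (badly
  conditioned high-order monomials) are flagged, not fatal.
* **Optimization.** Bounded multistart: seeded Latin-hypercube starting
  points (default 50) plus one mandatory user-supplied start; the
  replication harness uses the corner of the parameter box farthest from
  the generating truth as that deliberately bad start.  The local solver is
  L-BFGS-B with numerical gradients (relative finite-difference steps of
  `1e-3` of each box width).  Ties among equal objectives break to the
  lexicographically smallest parameter vector, for determinism.
* **Random numbers.** The simulator uses counter-based splitmix64
  substreams keyed by (seed, time index, trajectory index): datasets are
  bit-reproducible, independent of R's RNG state, and enlarging $N$ or
  adding time points never reshuffles existing trajectories.

## What the synthetic data does (and does not) emulate

All test data come from the exact Gillespie simulator at documented
generating truths inside the declared bounds: gene expression
$(a, b, c) = (0.3, 0.2, 0.4)$ with initial state DNA\_OFF $= 1$ and 10 mRNA
molecules, observed as mRNA at $t = 100$; exclusive switch
$(p_i, d_i, b_i, u_i) = (1.0, 0.02, 0.05, 0.05)$ from one free promoter,
observed as $(P_1, P_2)$ at $t = 100$ and $t = 200$, with the degradation
rates held fixed during estimation so that the production rates are
identifiable from a small number of conditions.  Sample sizes follow the
flow-cytometry regime (default $N = 10{,}000$ per time point).  The
generator produces ideal snapshots: no measurement error, no cell-to-cell
extrinsic variability, no correlated longitudinal observations, perfectly
known observation times.  A green recovery test therefore establishes that
the estimator works under the model's own assumptions — not that those
assumptions hold for any particular instrument.

Replicate counts in the test suite are scaled down from 50 repetitions to
10 (gene expression) and 5 (exclusive switch), and multistart counts from
~500 candidate starts to 4–8, so the whole suite runs on one CPU in
minutes; the harness accepts paper-scale settings unchanged.

## Design decisions that were genuinely open

* The exclusive switch's initial state is taken as one free promoter and no
  proteins (the natural unexcited state); it is not fixed by the model's
  published description.
* Generating truths are the package's own documented choices inside the
  published bounds — the original studies do not print theirs, so numeric
  point targets cannot be reproduced, only the structural and comparative
  properties (weight signs, estimator orderings, error trends), which is
  what the acceptance tests assert.
* Reaction distinctness is enforced on the $(v_j^-, v_j^+)$ pair rather
  than the net change vector: the exclusive switch itself contains two
  reactions with identical net effect but different mechanism.
* The order-2 exclusive-switch comparison uses two observation times; with
  a single time point, five conditions cannot identify six free parameters
  and the identification check (correctly) refuses to run.
* Under-identified cells (order-1 conditions, three free rates) can be run
  only behind an explicit flag and are interpreted as "rough estimates" in
  method comparisons, never as recoveries.

## Known limitations

Mass action only (no Hill/time-varying propensities), zero closure only,
point-mass initial conditions, no measurement-error model, no asymptotic
standard errors or over-identification (Hansen) tests, no SBML import, no
adaptive re-partitioning of species between the low- and high-copy classes.

## A minimal session

```{r example, eval = FALSE}
net <- builtin_model("gene_expression")
theta0 <- c(a = 0.3, b = 0.2, c = 0.4)
ds <- sample_snapshots(net, theta0, times = 100, "mRNA",
                       n_samples = 10000, seed = 1)
spec <- moment_condition_spec(net, "mRNA", max_order = 3, times = 100)
fit <- estimate_parameters(ds, net, spec, estimator = "demean",
                           optimizer_config = list(n_starts = 8), seed = 1)
fit$theta_hat
```
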