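---
title: "Methods: stochastic surrogate modelling and actionable path planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic surrogate modelling and actionable path planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
model, the numerical choices, the places where the design was genuinely open
and what was decided, and what the tests do and do not demonstrate.

## The framework in one paragraph

Given a tabular dataset with continuous and discrete explanatory variables
and one response, the package (1) fits a predictive model, (2) fits a
hierarchical Bayesian mixture — the *stochastic surrogate* — to the
explanatory variables together with the predictive model's outputs, and (3)
discretizes the intervenable variables around a chosen instance into a grid
graph and searches for the cost-minimal path to the node with the best
predicted response, where a node's cost is the negative log of its joint
probability under the surrogate. The product of nodal probabilities along a
path is its *actionability*; maximizing it steers plans through combinations
of variable values that actually occur in the population rather than through
statistical no-man's-land.

## Preprocessing

Continuous explanatory variables are standardized by training-set mean and
standard deviation; the response is never standardized (the surrogate's
response head works on the prediction scale, with prior constants `y_mean`
and `y_std` absorbing the scale). Missing cells are carried in an explicit
mask and filled by training medians (continuous) or modal categories
(discrete, ties broken by schema category order) — deliberately simple and
deterministic; chained multiple imputation is out of scope. Before surrogate
fitting, rows with any continuous explanatory value more than three training
standard deviations from the training mean are dropped for sampling
stability. The filter looks only at continuous explanatory variables:
response values and discrete categories never remove a row. Train/test
splitting assigns `floor(n * fraction)` rows (or groups, when repeated
measurements of one participant must stay together) to training — flooring
is arbitrary but deterministic.

## The surrogate model

Per mixture component `k = 1..K`:

* `x_cont ~ Normal(m_k, Σ_k)` with **diagonal** `Σ_k`;
* `x_disc,j ~ Categorical(φ_jk)` per discrete variable;
* regression: `y ~ Normal(μ_k, σ)` with
  `μ_k = β_1k + η_2kᵀ x_cont + η_3kᵀ onehot(x_disc)` and the response noise
  **fixed** at `σ = RMSE_test / 2`, half the predictive model's held-out
  RMSE. Fixing σ ties the surrogate's tolerance on the response to the
  predictive model's demonstrated accuracy instead of letting the sampler
  trade response fit against covariate fit;
* classification: `y ~ Bernoulli(logistic(μ_k))`.

`y` is the *predictive model's output*, not the observed response: the
surrogate approximates the model, so states are scored jointly for "does
this combination of covariates occur" and "does the model's prediction sit
where the surrogate expects it". Both the training target and the planner's
node probabilities use in-sample predictions; cross-fitted predictions would
also be defensible but add a fold structure the rest of the pipeline never
needs.

Priors: `π ~ Dirichlet(1)`, `m_k ~ Normal(0, 5)` per coordinate
(standardized units), per-coordinate standard deviations
`half-Cauchy(0, 2.5)`, `φ ~ Dirichlet(1)`, coefficients
`η ~ DoubleExponential(0, 1)` (sparsifying: most components need few active
response coefficients), intercepts `β_1k ~ Normal(y_mean, 5 y_std)` on the
prediction scale (classification: `Normal(0, 5)`). These are the standard
weakly-informative choices for mixture models on standardized data. Two
conventions deserve note because the notation `Σ_k ~ diag(Cauchy(0, 2.5))`
underdetermines them: the half-Cauchy is placed on the *standard deviations*
(the usual weakly-informative idiom), and `Normal(0, 5)` means standard
deviation 5, not variance 5.

### Sampling

The component label is marginalized analytically, leaving a fully continuous
posterior that is sampled by component-wise slice sampling (Neal 2003,
stepping-out and shrinkage) in an unconstrained parameterization:
stick-breaking transforms for simplexes, log transforms for scales, with the
transform Jacobians in the target. The log posterior is evaluated in C++;
the sampler needs no step-size tuning beyond an initial bracket width of 1,
adapted once mid-warm-up from the warm-up draw spread. Chains are
initialized from a k-means clustering of the continuous variables (centers,
within-cluster spreads, cluster proportions, per-cluster response means)
plus small jitter, which starts every chain near a sensible labeling of the
components. Defaults are 1500 iterations per chain with 500 warm-up, run
over 4 chains so that split-chain scale reduction
(reported as `model$rhat`) is available; the chain count is a package choice,
as is the sampler itself, which satisfies the draw contract any backend
must provide. Slice chains essentially never hop component-labeling modes,
so density evaluations (which are label-invariant) are unaffected by label
switching; the only label-sensitive summary, `posterior_component_means()`,
aligns chains by best permutation before pooling.

### Densities and WBIC

`log_state_probability()` is the posterior-predictive density: the *mean
over draws of the mixture density*, computed in the log domain with an
online log-sum-exp. Averaging densities rather than parameters is essential
— parameter averages are meaningless across permutation modes. The response
term can be excluded (`include_response = FALSE`); by default the planner
includes it, scoring the predicted response (classification: the predicted
class label at threshold 0.5; a probability-weighted Bernoulli variant is
available via `class_target = "probability"`).

WBIC is computed as the expectation, under the posterior tempered at inverse
temperature `β = 1 / log n`, of the total negative log-likelihood. Because
the sampler works directly on the marginalized likelihood, tempering is a
single multiplier in the target — this is the reason the package samples the
marginal posterior rather than using data-augmented Gibbs, for which exact
tempering of the marginal likelihood is awkward. `select_k_by_wbic()` scans
a K range (default 1–8) and returns the argmin with the full curve.

## Path planning

The grid over the intervenable variables uses a unit cell of 0.2 training
standard deviations per variable (0.2 in standardized units), origin at the
instance. Bounds default to the training data's observed range per variable,
clamped to ±4 sd: the surrogate is a density model and is not trusted under
extrapolation; both are configurable.

The search initializes every node cost to infinity and the start node to its
own negative log probability (so actionability is a true product over *all*
path nodes; the constant does not affect the argmin), then repeatedly
finalizes the cheapest unfinalized reached node and relaxes its neighbours —
uniform-cost (Dijkstra) search, under which every finalized node's recorded
cost is provably the minimum over all lattice paths (the test suite checks
this against exhaustive path enumeration and Bellman-Ford). The iteration
cap `L` (default 20000) counts node finalizations — the only reading under
which "the optimal path within the iteration count" is well-defined. A
first-in-first-out expansion order is retained behind
`expansion = "fifo"` as a fidelity variant of the breadth-first phrasing of
the original description; it is implemented label-correcting (nodes re-queue
when their cost improves) so that, uncapped, it converges to the same
optimal costs. After the cap, the destination is the finalized node with
the best predicted response; ties break by minimal cost, then by
lexicographically smallest offsets (the last rule is an arbitrary but
deterministic tiebreaker). Re-finalization is forbidden, which is optimal
for nonnegative costs. If the start node is already optimal the path has a
single node. Node probabilities and predictions are computed lazily, in
neighbour batches, and memoized per offset vector — the density average over
MCMC draws is the planning hotspot.

## Scoring

The actionability score compares the planned path against random
Manhattan-shortest connections of its endpoints:
`score = log A(optimal) − mean(log A(baseline))` over `n_baseline = 10`
baselines (the log of their geometric-mean actionability). "Shortest
procedure in a random manner" is interpreted as a uniformly random
interleaving of the per-variable unit moves — the only family of shortest,
per-variable-monotone lattice paths between two nodes — sampled by shuffling
the move multiset. Both endpoints' probabilities are included in every
path's actionability, consistent with the product-over-nodes definition.
When the optimal path is longer than the Manhattan distance, baselines have
fewer nodes and the score is reported exactly as defined, with no per-node
normalization. A baseline node of zero probability makes the score `+Inf`
with a `degenerate` flag rather than an error ("infinitely better") — rare,
but possible under aggressive grids. When the optimal path moves a single
variable monotonically, every baseline is node-identical to it and the score
is exactly zero.

Comparator paths for clinician-style assessments move a uniformly random
intervenable variable per step in its guideline-declared direction
(variables at their bound are resampled), with the step count matched to the
planned path and nine paths per instance by default; predicted-response
changes of planned versus comparator paths are compared with a two-sided
Welch test (`stats::t.test` under the hood).

## The synthetic benchmark

`generate_synthetic3d()` draws 200 points from each of three trivariate
normal components and sets `y = x1 + x2 + x3 + Normal(0, noise_sd = 2)`.
The component geometry is a package choice made once, with two design goals:
(a) two of the three generating components overlap into a single elongated
density mode — offset along one axis only, so a diagonal-covariance
component can absorb the merged blob and the surrogate's WBIC-selected K is
two, matching the qualitative behaviour the framework is meant to exhibit
on this kind of data; and (b) the third component sits well apart, so the
straight line between typical high- and low-response points crosses a
low-density valley and the planner has something to gain. The defaults are
means (3,3,3), (0,0,0.75), (0,0,−0.75) with unit covariances, fully
configurable through `mixture_spec()`, which also drives
`generate_mixture_table()` for mixed continuous/discrete tables with planted
missingness (fixed per-component counts, so empirical proportions are exact;
missingness planted over explanatory cells only, since a missing response
row would simply be dropped by any downstream stage).

What the generator does *not* emulate: real checkup data's heavy tails,
measurement artefacts, informative missingness, repeated measurements of
the same participant, and correlations between discrete and continuous
variables within a component. Passing tests therefore demonstrate the
machinery — recovery of a known mixture, correct density normalization,
provably optimal search, scoring identities — not clinical validity on any
real cohort.

## Problem sizes and numerical choices

The test suite and the acceptance script run reduced problem sizes chosen as
package defaults for a single CPU: WBIC selection over K = 1..4 with one
chain of 400 iterations (200 warm-up), surrogate fits of 300–800 iterations
with 1–2 chains, planning caps of L ≤ 2000 on the benchmark, and 1000-draw
Monte-Carlo checks of scoring laws. The WBIC margin between K = 2 and K = 3
on the benchmark is genuinely small (a few nats — the third component is
designed to be nearly redundant), so component selection is asserted as a
majority over five seeds rather than per-seed. Other numerics: densities and
their sums are computed in the log domain throughout; the slice sampler
falls back to the current point if bracket shrinkage degenerates (the
current point is always in the slice); standardization refuses
zero-variance columns; and `wbic()` refuses `n < 3`, where the tempering
exponent would reach or exceed one.

## Limitations

Interventions are modelled on continuous variables only, one unit step at a
time; discrete-variable interventions, clinical constraints on intermediate
nodes, goal-directed (A*-style) search, and any causal reading of the
planned paths are out of scope — the surrogate models a joint density of
observational data, so a path is a sequence of plausible states, not a
guaranteed effect of treatment. Non-diagonal component covariances are not
supported; strongly correlated continuous variables are represented only
through the mixture's ability to tile the correlation with several
components.
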