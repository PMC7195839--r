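---
title: "Methods and design notes for nlgrn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for nlgrn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the model, the statistical machinery, the numerical
choices, and the limitations of `nlgrn` — in particular the places where a
published description left the design open and this package had to commit
to something concrete.

## The model

For `m` genes with expression levels `x_i(t)`, the dynamics are

$$\frac{dx_i}{dt} \;=\; \sum_{j \to i} \alpha_{ij}\, x_j
\;+\; \sum_{(j,k) \to i} \beta_{ijk}\, x_j x_k \;-\; k_i x_i,$$

a second-order truncation of a saturating regulation function. The
product terms ("non-linear terms", NLTs) stand in for protein heterodimers
— assuming fast binding equilibrium, the dimer level is proportional to
the product of the component levels, with the equilibrium constant
absorbed into $\beta$ — or for synergistic co-regulation. Structural
assumptions: regulations are additive; no auto-regulation
($\alpha_{ii} = 0$, it would be confounded with degradation); no squared
terms ($\beta_{ijj} = 0$, the series $x_j^2$ is nearly collinear with
$x_j$); the sign of a coefficient is the sign of the regulation.

Sparsity comes first, from data: a fully connected 11-gene model has
$11 \times (11 + 55) = 726$ coefficients, hopeless against 30 time points.
The structure search below cuts this to about a hundred.

## Structure search

All variables — `m` genes and `n = m(m-1)/2` NLT product rows — enter an
`N`-dimensional Gaussian graphical model with blocked covariance
`[[A, B], [B', C]]`. An edge means conditional dependence; absence means
the partial correlation given all other variables is zero, i.e. a zero in
the precision matrix.

**Edge test.** For a graph `g`, the constrained MLE $\hat\Sigma_g$ matches
the sample covariance on the diagonal and on every edge, and has zeros in
the inverse elsewhere. Adding one candidate edge changes the deviance by
$n_{obs}\,(\log\det\hat\Sigma_g - \log\det\hat\Sigma_{g+e})$, which is
asymptotically $\chi^2(1)$ under the null that the edge is absent. The
forward search tests every remaining candidate each round, adds the
smallest p-value below the cutoff (default 0.1; ties broken by larger
deviance, then lexicographic edge order), and stops otherwise.

**Two stages.** Gene–gene candidates are searched first; the selected
skeleton is oriented into a DAG. NLT→gene candidates are searched second,
starting from the stage-1 graph and capped at the stage-1 edge count, so
the (much more numerous) product terms cannot dominate the network.
NLT–NLT edges are never candidates; running the selection over the whole
covariance without this restriction lets product-product edges crowd out
the gene regulations, and replacing the NLT block by an identity is known
to make the constrained fits singular — both are why the two-stage design
exists. Isolated NLTs (never selected) are reported separately.

**Treating time points as samples.** The covariance treats the 30 time
points as independent observations, which time-course data violate
(consecutive points are strongly autocorrelated). This follows the method
as published; p-values are therefore selection scores, not calibrated
inferential statements about these data. The type-I calibration test in
the acceptance suite uses genuinely i.i.d. data, where the 0.1 cutoff
rejects at frequency 0.10 ± 0.03.

**Standardization.** Rows are standardized (mean 0, variance 1) before
covariance assembly. NLT rows are products with wildly different scales;
deviance differences are invariant to per-variable scaling, so this is
purely a conditioning improvement. Whether the original analysis did the
same is unstated.

**Orientation.** Published rule sets for orienting a skeleton are not
reproducible from the text, so the package uses a deterministic surrogate:
each edge points from the endpoint appearing earlier in the forward-search
provenance log to the later one (never-logged nodes rank last, ties by
input gene order). Orientation along any total order yields a DAG, and
identical inputs give identical networks. Individual edges may be oriented
differently than in the original analysis.

## Computing the constrained MLE

`ips_fit()` starts with proportional-scaling sweeps over the *maximal
cliques* of the graph (Bron–Kerbosch enumeration): each update replaces
the precision submatrix on a clique so the fitted margin matches the
sample covariance there. One sweep is exact for decomposable graphs. On
standardized time-course data, however, gene/NLT correlations reach
0.9999 and interlocking cliques make plain IPS converge at a linear rate
approaching 1. After a bounded number of sweeps the iterate is handed to
a damped Newton ascent of the concave objective
$\log\det K - \mathrm{tr}(S K)$ over the free precision entries, whose
gradient *is* the margin residual; this meets the default `1e-8`
constraint tolerance regardless of conditioning. The acceptance suite
checks the result against a brute-force `optim()` maximization of the
same likelihood on all graphs over up to four variables.

## Simulation

The integrator is an adaptive Dormand–Prince RK45 (compiled via Rcpp;
no ODE solver package is assumed), `rtol = 1e-6`, `atol = 1e-8`. Two
honesty notes:

* *Accuracy floor.* Below the absolute tolerance no solver bounds
  relative error — a pure decay at `k = 0.5` reaches `e^{-84}` by 168 h.
  The oracle tests assert absolute error `< 1e-6` (measured ~`8e-8`)
  everywhere and relative error where the signal exceeds `1e-3`.
* *Failure semantics.* A state exceeding the divergence bound (default
  `1e6 ×` the data scale) gives status `"diverged"`; step-size underflow
  gives `"solver_failure"`. Neither throws: robustness sweeps must
  traverse unstable parameter sets and count them. No stiff fallback is
  implemented — the polynomial right-hand sides at the scales used here
  are non-stiff, and a clean failure status is preferable to a silent
  method switch.
* States are not clipped to non-negative values; the model has no
  positivity guarantee.

The simulation error is the *unnormalized* root total sum of squares over
all genes and time points. Before GA fitting the data are normalized
per-gene by their maximum (`per_gene_max`, default; options `none`,
`zscore`): the magnitude of the published errors (≈1 over 330 residuals)
implies per-point residuals of a few percent, i.e. normalized data,
though the exact scheme is unstated.

## Genetic algorithm

Real-coded, elitist: size-2 tournament selection, arithmetic or uniform
crossover (rate 0.7), per-coordinate Gaussian mutation with a log-uniform
scale between 0.1% and 10% of the box width (so the search both escapes
basins and converges finely), elite fraction 0.1. The published protocol's
sizes are kept as defaults: 1000 generations × population 300, bounds
`(−3, −3, 0)`–`(3, 3, 1)` for `(α, β, k)` (erythroid run; `±2.5` for the
neutrophil run), 200 restarts keeping the 10 best. The binary encoding of
the original MATLAB toolbox is deliberately not reproduced — the protocol
mandates settings, not an encoding.

Each run ends with a deterministic Nelder–Mead polish of the best
individual, kept only when it improves the error (the analogue of a GA
toolbox "hybrid function"). Without it, the desk-scale GA
(pop 60 × 200 generations × 10 restarts) reliably reaches small error but
does not localize coefficient signs even on identifiable problems.

A sampled degradation rate of exactly 0 is admitted during search; a
*final* rate of 0 is nudged to `1e-9` with a warning, preserving the
strict positivity invariant of accepted parameter sets.

## Robustness

Each perturbed parameter set is `θ · (1 + μ ε)` elementwise, with
independent `ε ~ N(0,1)` draws (or uniform on `[−1, 1]`),
`μ = 0.4`, `N = 5000` by default. The displacement
$E^{(k)} = \sqrt{\sum_{ij} (x^{(k)}_{ij}(p) - x_{ij}^{(k)})^2}$ is
measured against the *unperturbed simulation*, not the data; `RA` is the
mean, `RSTD` the sample sd (divisor `N−1`). Perturbed values are not
clipped — a negative perturbed `k` typically diverges and is excluded
with a reported failure count. By default *all* parameters are perturbed
(`targets = "all_parameters"`): the published text speaks of perturbing
"model parameters" while its formula is written for `k_i`; both modes are
available and the choice matters, as the degradation-only mode is far
gentler.

A caveat the acceptance suite respects: at `μ = 0.4` the *expectation* of
`E` can be dominated by rare near-zero-degradation draws that `N = 5000`
samples will never see, so Monte-Carlo-vs-quadrature comparisons are run
at `μ = 0.1`, where `E(ε)` is uniformly bounded.

## Greedy pruning

Phase 1 iterates over NLT→gene edges, phase 2 over gene→gene edges. Each
iteration zeroes one candidate's coefficient (no refit — observed inert
single removals imply the published procedure zeroed rather than refitted;
`--refit` style behaviour can be emulated by refitting between calls),
scores `SE` and robustness (screening `N` default 500, accepted steps
rescored at the full `N`), and permanently removes the candidate with the
smallest error change (ties: smaller `RA`). When *no* single removal
changes `SE` by more than `δ = 1e-4`, up to `batch_max = 3` inert edges
are removed as one step — the published first deletion removed three
product-term regulations at once for exactly this reason. The loop stops
when the best candidate would push `SE` above `(1+τ)·SE_OES` *and* `RA`
above `(1+τ)·RA_OES`; "much worse" is not quantified in the source, so
`τ = 0.10` is an explicit, documented knob.

## Synthetic worlds

`paper_time_grid()` is the 30-point schedule: 0 h, every 2 h to 24 h,
every 3 h to 48 h, every 4 h to 72 h, then 96, 120, 168 h.
`generate_network()` samples a random DAG with exactly `m1` gene edges,
`n1 ≤ m1` NLT edges, uniform coefficients (defaults: fitting bounds `±3`
scaled by the 168-h span, so dynamics stay bounded in raw hours;
`k ∈ [0.01, 0.3] h⁻¹`; initial levels in `[0.5, 2]` normalized units),
rejection-sampling until the noise-free trajectory is finite and does not
go materially negative (dips below 1% of the signal range are tolerated
and clamped — dense networks almost surely graze zero late in the course;
if no stable world is found the coupling ranges shrink automatically).
Noise is multiplicative log-normal (`σ = 0.05`, 3 replicates averaged):
intensities are positive and noise scales with signal, the natural model
for normalized microarray data; the true noise level of the motivating
dataset is unknowable from its description, so `σ` is a benchmark knob.

What a green synthetic test does establish: the machinery — augmentation,
selection, integration, estimation, perturbation, pruning — computes what
it claims on data whose generating process is known. What it does not:
probe-level artifacts, batch effects, non-multiplicative noise, or any
statement about the real FDCPmix biology.

### The recovery benchmark

The sign-recovery acceptance test uses a *hand-constructed* 5-gene world
(`helper-benchmark.R`) rather than a random draw: uniform coefficient
draws routinely produce near-zero couplings whose signs are not
identifiable from noise-free data (verified — local refinement from the
GA optimum reaches equally small error with flipped signs). The benchmark
has couplings bounded away from zero, compensated negative regulations so
trajectories stay positive, and well-separated degradation rates; its
identifiability was verified by checking that local refinement from GA
solutions converges to the true parameters. The acceptance thresholds
(error `< 0.05·‖data‖`, all coupling signs, GA at pop 60 / 200
generations / 10 restarts) are asserted as stated.

## Known limitations

* **Selection saturates on smooth time courses.** At cutoff 0.1 the
  forward search keeps most gene pairs (typically ~11 of 15 on 6-gene
  synthetic data; the published analysis likewise kept 46 of 55), so
  precision against ground truth is close to the density of a random set
  of the same size. Recall of true edges is the informative recovery
  metric (≈0.7–0.8 on the synthetic worlds); the pruning stage, not the
  selection cutoff, is what removes excess edges.
* Gene-edge orientation is a documented surrogate, not the original rule
  set.
* p-values inherit the independence assumption over time points.
* The GA explores a box; coefficients on the bound are not flagged.
* The deletion stop rule requires *both* criteria to worsen; a removal
  catastrophic in error but neutral in robustness would, by the stated
  rule, still be taken. Inspect the trace.
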