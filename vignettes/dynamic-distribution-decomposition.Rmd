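---
title: "Dynamic Distribution Decomposition: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic Distribution Decomposition: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Destructive single-cell technologies (mass cytometry, scRNA-seq) measure
*different* cells at every time point: a time course is a sequence of
snapshots of the cell-state distribution, with no lineage link between
them.  `ddd` infers a single continuous-time linear map — a finite
approximation of the Perron–Frobenius operator — that carries the state
distribution from the first time point across all later ones.  The result is
a continuous-time Markov rate matrix over a small set of interpretable
"metastates" (Gaussian mixture components), whose eigenfunctions expose
steady states, slow transitions and fate-decision states, and whose fitting
error doubles as an *a posteriori* diagnostic of the core modelling
assumption: that the process is autonomous (memoryless in experimental
time).

## Model

Let $\varrho(t,x)$ be the cell-state density and write
$\partial_t \varrho = \mathcal{P}\varrho$ for its (unknown) generator.  We
expand $\varrho$ on $N$ Gaussian probability densities
$\psi_1,\dots,\psi_N$,
$$\tilde\varrho(t,x) = \sum_j c_j(t)\,\psi_j(x), \qquad
  c(t) \in \Lambda = \{c \ge 0,\ \textstyle\sum_j c_j = 1\},$$
and model the coefficients as a linear autonomous system
$c(t) = e^{tP}c_*$.  Conservation of probability and positivity are
guaranteed by constraining $P$ to the rate-matrix cone
$\mathcal{P} = \{P : P_{ij}\ge 0\ (i \ne j),\ \sum_i P_{ij} = 0\}$ and
$c_*$ to the simplex.  The basis inner products form the mass matrix
$M_{ij} = \langle\psi_i,\psi_j\rangle$, available in closed form for
Gaussians ($\langle\psi_i,\psi_j\rangle = N(\mu_i;\mu_j,\Sigma_i+\Sigma_j)$),
and the fit minimises the mean squared relative prediction error
$$\varepsilon^2(P, c_*) = \frac1R \sum_{r=1}^R
  \frac{\|e^{\tau_r P}c_* - c_r\|_M^2}{\|c_r\|_M^2},$$
with observation times rescaled to $\tau \in [0,1]$ so that matrix
exponentials stay well conditioned.  The reported "percentage error" per
time point is $100\,\varepsilon_r$; it measures the relative $L^2$ distance
between the predicted and observed mixture densities.  The initial
condition $c_*$ is a free parameter rather than being pinned to $c_1$,
allowing for mis-specification of the first snapshot; the $r=1$ term keeps
$c_*$ anchored near $c_1$.

An optional Lasso term $\beta\sum_{ij}|M_{ij}P_{ij}|$ sparsifies the rate
matrix for display and topology extraction; weighting by $M$ preferentially
removes edges between distant components.  The penalty can be given
absolutely or as $\beta = 1/(k\cdot\mathrm{mean}(M))$ (`beta_divisor = k`),
the form used for the benchmark graphs ($k = 100$) and recommended for
cytometry-scale problems ($k = 800$).

## Fitting: parameterisation, gradients, convergence

The equality constraints are eliminated rather than penalised: the
$N(N-1)$ off-diagonal rates are optimised directly under box constraints
$q_{ij}\ge 0$ (with the diagonal defined as the negative column sum) and
$c_*$ through $N-1$ softmax logits — $(N-1)(N+1)$ free parameters, handled
by `optim(method = "L-BFGS-B")`.  We chose box constraints over a
softplus/exponential reparameterisation because the Lasso solution lives
*on* the boundary ($P_{ij} = 0$ exactly), which a smooth transform can only
approach asymptotically, and because bound-constrained quasi-Newton steps
avoid the saturation plateaus such transforms introduce.

Gradients are analytic.  $\partial\varepsilon_r^2/\partial c_*$ is a single
matrix-exponential expression; $\partial\varepsilon_r^2/\partial P$ is the
power series $\frac{2}{\|c_r\|_M^2}\sum_k \frac{\tau^{k+1}}{(k+1)!} S_k$
with the recursion
$S_k = P^\top S_{k-1} + S_{k-1}P^\top - P^\top S_{k-2}P^\top$,
$S_0 = M(e^{\tau P}c_* - c_r)c_*^\top$.  Two numerical points matter:

* the recursion is evaluated in *factorial-scaled* form
  ($T_k = \tau^{k+1}S_k/(k+1)!$), so no intermediate overflows even when
  $\|P\|$ is large;
* the series alternates in sign through $P^\top$ products, so for
  $\tau\|P\|_1 \gtrsim 12$ cancellation erodes the mantissa.  There the
  implementation switches to an algebraically identical form: the sum equals
  $\tau$ times the Fréchet derivative of the matrix exponential at
  $\tau P^\top$ in direction $S_0$, computed from the upper-right block of
  one augmented $2N\times 2N$ exponential, which scaling-and-squaring
  evaluates stably.  Both code paths are cross-validated against each other
  and against central finite differences in the test suite; fitted
  benchmark models reach $\|P\| \sim 10$–$15$ per rescaled time, so both
  regimes are exercised in practice.

Propagation itself always uses Padé scaling-and-squaring
(`Matrix::expm`).  The optimiser runs to a relative-change tolerance
(`factr = 1e4`) under an iteration cap of $10^4$; on the benchmark
($N = 30$, 899 free parameters) the cap binds after roughly two minutes on
one core and the objective is flat to several digits by then.  Runs that
stop at the cap are flagged (`hit_iteration_cap`) but are not treated as
failures; a genuine optimiser failure is always surfaced.

Initialisation is deterministic: all off-diagonal rates at $10^{-3}$ and
$c_* = c_1$, a feasible near-stationary point.  Given the seed (which fixes
the basis) the whole fit is reproducible bit-for-bit.

## Basis construction

Each time point is fitted by its own Gaussian mixture (EM with k-means++
initialisation and restarts keeping the best non-degenerate likelihood),
then all components are concatenated in time order.  Three tunable
parameters control the payoff between expressiveness and conditioning:

* **components per time point `k`** — fixed (3 for the benchmark, giving
  $N = 30$) or chosen per time point by AIC: the scan stops at the smallest
  $k$ whose relative AIC improvement to $k+1$ falls below 1% ("the AIC
  curve flattens").  The 1% threshold is our quantification of flatness;
  it is exposed in `basis_config(aic_threshold=)`.
* **covariance regularisation** — a hard floor on the diagonal entries of
  every component covariance, applied inside each M-step.  For
  arcsinh/z-scored cytometry data a floor of 1/2 (half a pooled standard
  deviation) is the recommended default; sharper peaks need smaller floors
  but more components.  The floor also guards EM against singular
  components, which is why we wrote the EM loop ourselves rather than using
  an off-the-shelf fitter (the test suite cross-checks our EM against
  `mclust` on floor-free problems).
* **drop rate `alpha`** — after hard-assigning each cell to its
  maximum-responsibility component, components holding less than
  $\alpha$ of a time point's cells are discarded.  This bounds $N$ without
  an explicit model-selection step; decreasing $\alpha$ buys small error
  reductions at rapidly growing $N$.

Coefficients are encoded by the density-sum rule
$c_{r,j}\propto\sum_i \psi_j(x_{r,i})$, normalised to the simplex.  All
densities are computed in log space and combined by log-sum-exp, so an
18-marker cytometry basis does not underflow.

## The synthetic benchmark

`run_bistable_benchmark()` reproduces the package's validation study: a
two-dimensional overdamped Langevin system in a bistable potential whose
squared polynomial term vanishes on the rays $y = 2x$ and $y = x/2$
(because $2\|x\|^2 - 5x_1x_2 = (2x_1-x_2)(2x_2-x_1)$), with Gaussian wells
at the initial state $(1,1)^\top/2$ and the two terminal states
$(2,4)^\top$ and $(4,2)^\top$.  Particles drift out of the initial basin,
commit stochastically to one ray, and settle in a terminal well — a minimal
cartoon of a binary fate decision.  The study conditions are fixed:
diffusion $D = 1/4$, Euler–Maruyama step $\delta t = 2^{-9}$, reflecting
boundaries on both axes (applied as coordinate-wise absolute value after
every step, and to the initial draw), 2000 fresh trajectories per
observation time $t \in \{0,1,2,3,5,8,13,21,34,55\}$ (destructive
sampling), and 3 mixture components per time point.  Each observation time
consumes its own deterministically derived RNG stream, so removing a time
point does not reshuffle the others.

Four data conditions are fitted: the clean series; the series with the
$t = 8$ snapshot perturbed by $N(0, I_2/4)$ noise (basis rebuilt from the
perturbed data); the perturbed series with $t = 8$ dropped; and all
snapshots perturbed.  On our runs the clean fit reaches a mean percentage
error around 0.9%, removing the corrupted point restores ~0.8%, and
perturbing everything *lowers* the error to ~0.4–0.6% (the rebuilt
components are wider, shrinking relative $L^2$ distances) — all consistent
with the reference study's 0.9%/0.8%/0.5%.  The single-point perturbation
raises the error to ~1.3–1.6% on our runs, concentrated at $t = 8$ and its
neighbours.
The reference implementation reports 3.1% under this condition: the
qualitative signature (a localised error spike, restored by removing the
point) is identical, but our tightly converged fit absorbs more of the
single-point inconsistency than the reference optimiser did, so the spike
is smaller.  We report the number our pipeline computes rather than tuning
the optimiser down to match.

What the benchmark does *not* emulate about real cytometry data: high
dimension (d = 2 here), heavy-tailed marker noise, batch effects, uneven
cell counts per time point, and genuinely non-autonomous dynamics.  Passing
it shows the estimator recovers an autonomous diffusion's distribution flow
from destructive snapshots at realistic sample sizes — not that any
particular biological system satisfies the autonomy assumption; that is
what the split-window diagnostic is for.

## Spectral analysis and graphs

Eigenpairs of $P$ are sorted by descending real part (ties by ascending
$|\Im\lambda|$) and normalised in the $M$-weighted norm; complex pairs are
normalised through the Hermitian form and reported as conjugates, and the
$M^{1/2}$ used for eigenfunction graphs
($G_\lambda = (M^{1/2}v)(M^{1/2}v)^\top$) is the symmetric PSD square root,
not a Cholesky factor, matching the symmetric role it plays in
$G_\lambda$.  A valid rate matrix always has eigenvalue 0 (the steady
state); since times are rescaled to $[0,1]$, no other mode with
$\Re\lambda > -1$ is observable within the experiment's window.

On the benchmark the leading eigenfunctions' extremal coefficients land in
the terminal basins around $(2,4)$ and $(4,2)$; the initial basin, which
empties within the first one or two observation intervals, shows up in
faster modes further down the spectrum rather than in the top three.  Rate
graphs draw $P_{ij}$ as a directed edge $j \to i$; under the benchmark's
Lasso setting ($\beta = 1/[100\,\mathrm{mean}(M)]$) the surviving skeleton
is a minimal branching from a component at the initial condition directly
into both terminal basins, the sparsified counterpart of the dense fit's
committed two-branch structure.  Force-directed layouts weight attraction
by $1/M_{ij}$ (well-separated components repel) and are seeded for
reproducibility.  `prune_to_branching()` iteratively removes sub-threshold
edges and unannotated leaves to reduce a dense graph to its branching
structure; the operation is idempotent and warns (never silently drops)
when pruning disconnects annotated states.

## Autonomy diagnostics

`autonomy_report()` refits the model on user-chosen windows of time points
with *one shared basis*, so errors are comparable across windows.  For an
autonomous process, sub-window errors resemble the full-window error; a
window that stays poorly fitted even in isolation indicates that the
observed state no longer determines the future — e.g. an unobserved driver
changed mid-course.  The test suite exercises both directions with
synthetic coefficient series: a single generator fits all windows
comparably, while a mid-course generator switch concentrates full-window
error at and after the switch and is relieved by splitting.

## Numerical choices and edge cases

* Gaussian overlaps, mass matrices and coefficient encodings are evaluated
  via log-density Cholesky forms; a singular covariance sum is rejected
  with a diagnostic rather than propagated as `NaN`.
* A basis that nowhere covers a snapshot (all log densities below the
  smallest representable double) is reported as an error naming the time
  point.
* `relative_error` rejects observations with zero $M$-norm; `steady_state`
  flags multiple zero eigenvalues (reducible chains) and returns all null
  vectors instead of picking one silently.
* Observation times need not be multiples of $\delta t$; the integrator
  takes a shortened final step, preserving first-order accuracy.
* Near-duplicate basis components make $M$ numerically semidefinite; this
  is warned about, and downstream code adds jitter of at most $10^{-10}$
  before Cholesky factorisations.

## Problem sizes

The shipped tests and the reproduction script run the full benchmark
(10 time points × 2000 trajectories, $N = 30$, four or five fits of 899
parameters each); a complete pass takes on the order of 15 minutes on a
single core, of which each fit contributes about two minutes.  Property
tests (gradient oracles, Monte-Carlo quadrature of overlaps, grid
quadrature of the relative error) use $N \le 6$ bases where closed-form or
brute-force oracles are cheap and exact.

## Known limitations

* $P$ is identifiable only up to dynamics visible at the sampled times;
  two rate matrices agreeing on $e^{\tau_r P}c_*$ at every $\tau_r$ are
  indistinguishable.  Trajectory-level quantities (propagated
  coefficients, errors) are stable across optimiser paths; individual
  entries of $P$, and hence eigenfunction fine structure, are not.
* The basis is data-dependent: perturbing the data moves the basis as well
  as the coefficients, which is why the robustness study rebuilds both.
* Non-autonomous systems are *diagnosed*, not modelled; time-varying
  generators are out of scope.
* No binary FCS ingestion, bead normalisation, debarcoding or batch
  correction: inputs are delimited text tables, optionally already reduced
  (PCA, diffusion maps) upstream.
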