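# ddd — Dynamic Distribution Decomposition

`ddd` reconstructs continuous-time dynamics from *snapshot time series*:
single-cell measurements (mass cytometry, scRNA-seq) where every time point
destroys the cells it measures, so no cell is ever tracked across time.
Instead of linking individual cells, the package infers one linear map — a
finite-dimensional approximation of the Perron–Frobenius operator — that
carries the whole cell-state *distribution* from the first time point
across all later ones.  It is aimed at computational biologists who want
interpretable, dynamics-level structure (steady states, slow transitions,
fate-decision states) out of a time course, together with an honest
per-time-point fitting error that doubles as a diagnostic of the
autonomous-dynamics assumption.

## Method in brief

Each snapshot is encoded on a basis of Gaussian probability densities
ψ₁,…,ψ_N (a Gaussian mixture fitted per time point, pruned by a drop rate
α), giving simplex coefficient vectors c₁,…,c_R with
c_{r,j} ∝ Σᵢ ψⱼ(x_{r,i}).  The dynamics are modelled as c(t) = e^{tP} c⋆
with a rate matrix P (non-negative off-diagonals, zero column sums — so
probability is conserved) and free initial condition c⋆ on the simplex.
With mass matrix M_{ij} = ⟨ψᵢ, ψⱼ⟩ (closed-form for Gaussians), the fit
solves

  min_{P ∈ 𝒫, c⋆ ∈ Λ}  (1/R) Σ_r ‖e^{τ_r P} c⋆ − c_r‖²_M / ‖c_r‖²_M
                        [+ β‖vec(M∘P)‖₁],

by L-BFGS-B with analytic matrix-exponential gradients; the optional Lasso
term sparsifies the transition topology.  Eigenfunctions of P (normalised
in the M-norm) expose the steady state and slow modes; rate and
eigenfunction graphs visualise them in high dimension.  The per-time
percentage error 100·ε_r localises where the data stop being explainable
by any autonomous linear map — a split-window refit (`autonomy_report()`)
separates "one bad snapshot" from "the dynamics changed".

## Worked example

The built-in benchmark simulates particles in a bistable potential well —
a two-dimensional Langevin system whose valleys along y = 2x and y = x/2
caricature a binary fate decision — and fits the full pipeline:

```r
library(ddd)

series <- simulate_snapshots(simulation_config(seed = 1))  # 10 snapshots, 2000 cells each
basis  <- build_basis(series, basis_config(k = 3, seed = 1))
coefs  <- basis_coefficients(series, basis)
fit    <- fit_pf(coefs, basis)
fit
#> Perron-Frobenius model: N = 30 basis functions, R = 10 time points
#>   mean squared relative error: 9.32e-05
#>   mean percentage error: 0.91%
#>   note: optimiser stopped at the iteration cap

round(fit$pct_errors, 2)
#>  [1] 0.37 0.59 0.69 0.93 1.37 1.33 1.22 1.03 0.92 0.68
```

A mean error under 1% means the fitted rate matrix propagates the t = 0
distribution through all ten snapshots to within ~1% relative L² density
error — the simulated system is autonomous, and the model finds that out.
The spectrum and steady state:

```r
sp <- pf_eigen(fit)
round(Re(sp$values[1:3]), 3)
#> [1]  0.000 -1.194 -1.194
```

Eigenvalue 0 is the steady state (mass in the terminal wells); the next
modes (here a conjugate pair) are the slow exchange between the two wells
and the relaxation of the remaining transient.  The Lasso refit collapses
the dense 30-node rate graph to its branching skeleton:

```r
lasso <- fit_pf(coefs, basis, fit_config(beta_divisor = 100))
count_edges(lasso)   # 4, down from ~320 — initial state feeding both wells
g <- rate_graph(lasso)
export_graph(g, "benchmark.graphml")
```

For real data, replace the simulator with
`load_snapshots()` + `preprocess_snapshots()` (arcsinh, cofactor 5, pooled
z-scoring) and consider `basis_config(k = "auto", regularisation = 0.5,
alpha = 0.005)`.  A thin command-line front end for the whole pipeline is
installed at `inst/cli/ddd.R`.

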