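---
title: "Models and methods behind emuflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind emuflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
labelling model, the estimator, the surrogate shortcut, and the design
choices made where several defensible options existed. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The labelling model

A cell at metabolic steady state carries constant fluxes `v` and pool sizes
`c`, yet after a switch to an isotopically labelled nutrient its metabolite
pools relabel over time. For a pool `i` fed at rates `w_j` by sources with
labelling state `x_j`, mass balance on the label gives

    c_i dx_i/dt = sum_j w_j (x_j - x_i),

because at steady state total influx equals total outflux. The labelling
state we track is the mass isotopomer distribution (MID): the vector of
fractions of molecules carrying 0..n heavy atoms, which lives on the
probability simplex.

Tracking all `2^n` isotopomers per metabolite is unnecessary: the elementary
metabolic unit (EMU) reduction identifies the minimal atom subsets whose
MIDs form a closed system under the network's atom transitions. `decompose()`
traces backwards from the measured EMUs through every directed reaction
producing their metabolite; when a target EMU's atoms originate in two or
more substrate molecules its input MID is the *convolution* of the source
EMU MIDs. Because convolution sources are strictly smaller, the system is
block-triangular in EMU size, which is what makes it solvable.

Conventions worth knowing:

* **Directed expansion.** Reversible reactions are split into non-negative
  forward/backward sub-fluxes (label flows both ways even at zero net flux);
  the reported net flux is forward minus backward. Sampling, EMU balances
  and estimation all operate on the directed system.
* **Sources vs sinks.** An EMU is a *source* (known, constant MID) only if
  its metabolite has no producing reaction — an external feed — or is the
  tracer itself. Boundary *sinks* are traced through to their producers;
  they are exempt from the steady-state constraint but not from the atom
  trace. Simulating the accumulated MID of a pure sink is not supported
  (it has no washout pool); sinks are therefore not default measurement
  targets.
* **Symmetry.** A reaction with several equiprobable atom routings lists one
  transition record per routing; records are averaged (weight `1/k`) in the
  EMU balances.
* **Tracer.** The feed's atoms are labelled independently with per-atom
  fractions (default 1.0, the 13CO2 / 15NO3- situation); the initial state
  at the switch time is fully unlabelled. Natural isotope abundance is not
  simulated — measurements are assumed corrected.

## Solving the ODEs

The assembled system per size level is `c ⊙ dX/dt = A(v) X + B(v) Y`, rows
of `[A | B]` summing to zero (label conservation). Two solution paths:

* **Linear fast path.** When no balance term couples two *state* EMUs
  multiplicatively (every convolution involves at most one state EMU — true
  whenever no condensation joins two internal pools), the stacked system is
  linear time-invariant with constant input, and
  `X(t) = X_ss + expm(G t) (X0 - X_ss)` is exact (`Matrix::expm`). The toy
  network is in this class, which is what makes training-set simulation at
  5000 samples cheap.
* **Stiff integrator.** Otherwise `deSolve::ode` (lsoda) at `rtol 1e-8`,
  `atol 1e-10`, with a BDF retry at 100-fold tighter tolerance on failure.
  EMU systems are stiff whenever pool sizes span orders of magnitude.

The two paths agree to `1e-7` on the fixtures (tested), and both are checked
against an independent brute-force isotopomer simulator
(`simulate_isotopomers_bruteforce()`, capped at 4096 states) that knows
nothing about EMUs: marginalising its `2^n` isotopomer fractions must
reproduce every EMU MID to `1e-6`. Solver output is clipped at zero and
renormalised before anything downstream sees it (raw values retained under
`solver_opts$raw`), so chi-square always sees simplex-valid vectors.

## Sampling the solution space

Training inputs are drawn from the flux polytope
`{v : S v = 0, lb <= v <= ub}` by hit-and-run on the null-space
parameterisation `v = v0 + K u` (orthonormal `K` from the SVD; interior
point `v0` by penalty minimisation plus max-min-slack centring). Warm-up is
`100 * dim` steps with thinning `dim`, the standard regime for polytope
samplers; uniformity is tested against the analytic centroid of a triangular
polytope. A cheaper non-uniform `corner_mix` sampler (Dirichlet mixtures of
boundary points) is available for stress tests. Pool sizes are drawn
log-uniformly within bounds — pool sizes span orders of magnitude and the
choice is deliberately uninformative. Fluxes and pools are sampled
independently.

## Surrogates

One fully connected regressor per (EMU, time point) — input: the directed
flux vector concatenated with (by default, log) pool sizes, standardised per
column; output: the MID, standardised per component with zero-variance
components left untouched; hidden layers 216, 36 and 6 with ReLU. Training
is Adam (learning rate 1e-3, batch 32, 200 epochs, validation fraction 0.2)
in compiled single-threaded code with a private RNG, so a seed fixes the
weights bit-for-bit. The output head is linear with post-hoc clipping and
renormalisation onto the simplex — the simplest faithful head; a constrained
alternative would be the obvious extension.

Each model records its held-out error (`holdout_sd`, the standard deviation
of predicted minus simulated MID components) and its training input bounding
box; predictions outside that box raise an out-of-domain flag, because an
ensemble only knows the solution space it was trained on. The package's
working standard, checked by the test suite at the 5000-sample
training size, is that the median `holdout_sd` across (EMU, time point)
cells sits below the 0.01 MID units of a typical measurement sd — the
precondition for swapping the ensemble in for the solver. The exact
simulator and a trained ensemble expose the same `predict_mids()` contract,
so estimation can run in *oracle mode* (exact simulator), which separates
estimation error from surrogate error in every validation experiment.

## Estimation

The fit minimises the weighted SSR `sum ((pred - meas) / sd)^2` over the
null-space flux coordinates `u` and, by default, log pool sizes.
Parameterising by `u` keeps `S v = 0` exact at every iterate — steady state
is a constraint, not a penalty. Physical flux box bounds, which are linear
images of `u`, are enforced by penalty residuals with weight ramping
(1e3, x10 per ramp, up to 4 ramps) and verified at the solution; log-pool
bounds are native box bounds of the optimiser. The optimiser is
Levenberg-Marquardt (`minpack.lm::nls.lm`, max 400 iterations, ftol/ptol
1e-10, gtol 1e-8) from 10 starts (default) drawn by the sampling module.
Records with `sd = 0` are rejected rather than infinitely weighted; missing
predictions are hard errors naming the record.

`L = ssr / dof` with `dof = n_measurements - n_free_parameters` (refusing
`dof <= 0`), and `goodness_of_fit()` accepts when `L` falls inside
`[χ²(α/2, dof), χ²(1-α/2, dof)] / dof` — the lower cut flags over-fitting.

Two concentration modes exist because the underlying question differs:
`estimate` (default) co-estimates log pools; `fixed` takes them as known
inputs. The recoverability experiments use `fixed`: with only MID data,
`v` and `c` enter the dynamics through rates `v/c`, so on small networks
absolute fluxes are structurally identifiable only when pools are pinned —
fixing them is what makes "is this flux recoverable?" a well-posed question.

A note on the synthetic measurement generator: its default post-processing
(clip to [0, 1], renormalise per MID) mimics what a measurement pipeline
reports, but near simplex vertices it shrinks the effective noise below the
nominal sd and the resulting `L` runs low. Calibration studies therefore use
`post_process = "none"`, which keeps the injected noise exactly Gaussian at
the stated sd (redrawing the rare >4σ cells that would break measurement
validity); with it, the mean `L` over replicate fits is statistically
compatible with 1 (tested).

## Profile confidence intervals

For one reaction at level 0.99: pin its *net* flux at `w` by appending the
row `a^T v = w` to the stoichiometric system and re-deriving the null-space
basis — an exact constraint, not a penalty — then re-optimise all remaining
parameters and record `ssr(w)`. The interval is where
`ssr(w) <= ssr_min + Δ` with `Δ = χ²(1 dof, 0.99) = 6.634897`, the
established one-parameter threshold on the SSR scale. The walk doubles an
initial step of 2% of `|v_hat|` (floored at 1% of the bound range) until it
brackets the crossing, then bisects to `1e-4` of the bound range. Endpoints
at the flux bounds are reported censored; profiles dipping below the
optimum beyond numerical slack trigger a local-minimum warning. Profiling
net rather than forward/backward sub-fluxes is a deliberate choice: net
fluxes are the scientifically reported quantity, and sub-flux (exchange)
profiles are routinely flat.

## Recoverability evaluation

Many true `(v, c)` pairs are sampled, measurements simulated from each, and
fluxes re-estimated (pools fixed, see above). Per reaction, the Pearson
correlation between estimated and true values across distributions is
classified as low (`r < 0.3`), mid, or high (`r > 0.85`) — exact threshold
values fall to the middle group; zero-variance columns yield an undefined
marker, never a number. Significance against "random fluxes" is a
row-permutation null: permuting the estimated matrix's rows breaks the
pairing while preserving the marginals, giving an exactly calibrated
one-sided p-value with +1 smoothing (`p >= 1/(B+1)`), Benjamini-Hochberg
adjusted alongside. A fresh-polytope-sample null would also be defensible;
permutation was chosen for its exact calibration (verified by a
Kolmogorov-Smirnov uniformity test under an independent-estimates null).

## Problem sizes and what the fixtures do not show

The package's study conditions are desk-scale by design: a 4-metabolite /
3-reaction linear toy (1-D flux space) and an 8-metabolite rich network
with a reversible exchange, a cleavage, a condensation (the convolution
case) and a branch across two compartments (3-D directed flux space); five
measurement time points at `0.25, 0.5, 1, 2, 4` time units for pools of
order 1 and fluxes of order 0.1–10; measurement sd 0.01 MID units;
surrogate training sets of 5000 samples; recovery studies over 5–10
distributions with 2–3 optimiser starts; CI coverage over 20–50 noisy
replicates. These sizes make every claim recomputable in minutes.

What passing these tests shows: the EMU machinery, solver, estimator and
interval construction are correct and statistically calibrated on networks
where ground truth is known exactly. What it does not show: behaviour at
genome scale (hundreds of reactions, strong non-identifiability, surrogate
extrapolation error, optimiser multimodality at high dimension), real
measurement error structure (correlated, non-Gaussian, natural-abundance
corrected), or compartment-mixed measurements. The synthetic generator
draws fluxes uniformly from the polytope and pools log-uniformly — real
flux distributions are far more structured.

## Degenerate inputs and numerical conventions

Atoms are 1-based; matrices are documented row = metabolite, column =
reaction. An EMU with zero influx and zero pool is an error (undefined
state); zero influx with a positive pool stays unlabelled. Infeasible
bounds fail at network validation. `n = 0` sampling returns empty lists.
Hit-and-run degenerate directions are skipped; if thinning starves the
chain a warning is issued and the current point padded. Ties in the
recoverability classification go to the middle group. All seeds are plain
integers; every stochastic stage (sampling, noise, training, multi-start,
permutation) takes one and is bit-reproducible given it.
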