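---
title: "Persistence energy of brain states: model, synthetic world, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistence energy of brain states: model, synthetic world, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`persistenergy` analyzes task-evoked brain activation through the lens of
linear network control. Brain regions (parcels) are nodes of a weighted
structural connectome $W$ (symmetric, non-negative, zero diagonal; weights on
the scale of quantitative anisotropy from diffusion imaging). Activity evolves
as the controlled linear system

$$\dot{x}(t) = A\,x(t) + B\,u(t),$$

where $x$ is the vector of parcel activations (GLM beta weights), $u$ the
control input, $B$ the actuator matrix, and

$$A = \frac{W}{\lambda_{\max}(W) + c} - I, \qquad c > 0.$$

This normalization places every eigenvalue of $A$ in the negative half-line
(the largest is exactly $-c/(\lambda_{\max}+c)$), so uncontrolled activity
decays: holding any nonzero activation pattern requires continuous input. The
minimum input energy to drive the state from $x_0$ to $x_f$ over horizon $T$
is

$$E = v^\top W_c(T)^{-1} v, \qquad
  v = x_f - e^{AT}x_0, \qquad
  W_c(T) = \int_0^T e^{At} B B^\top e^{A^\top t}\,dt,$$

with the optimal input $u^*(t) = B^\top e^{A^\top (T-t)} W_c(T)^{-1} v$. The
**persistence energy** $P_e$ is the self-transition $x_0 = x_f = x$: the cost
of maintaining the observed activation state. It is a quadratic form in the
state, so $P_e(\alpha x) = \alpha^2 P_e(x)$ — amplitude matters, by design.
Two derived quantities complete the picture:

* **node input** $e_i = \int_0^T u_i^*(t)^2\,dt$, which sums to $E$ when $B$
  is the identity, and whose drug-minus-placebo difference per parcel gives
  the control-input difference maps used in receptor alignment;
* **control impact**, the relative change in $P_e$ when one node is removed
  from the network (weights reduced, dynamics re-normalized on the reduced
  $\lambda_{\max}$, state truncated).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `T` (horizon) | 1.0 | model time | canonical choice in the linear-control literature for connectome dynamics; the package's analytic and oracle properties hold for any `T` |
| `c` (stabilization) | 1.0 | – | guarantees stability for non-negative `W`; exposed because the underlying convention varies across studies |
| `B` | identity | – | every parcel actuated with unit weight; no principled basis for a sparser actuator set here |
| `n_steps` | 1001 | – | trajectory grid; endpoint error of the second-order integrator is $O(\mathrm{d}t^2) \approx 10^{-6}$ relative |
| condition guard | $10^{12}$ | – | Gramian inversion refuses condition numbers above this, reporting the number rather than returning noise |

Gramians are computed three ways: `block_expm` (one matrix exponential of the
$2n \times 2n$ Van Loan block matrix — exact), `quadrature` (composite
Simpson — independent cross-check), and `spectral` (eigendecomposition,
exact, valid for symmetric $A$ with identity $B$; the fast path that makes
cohort-scale energy tables cheap). The first two must agree to $10^{-8}$
relative Frobenius error; the third agrees with the first to $10^{-10}$.
Minimum energies are additionally checked against an independent brute-force
oracle: exact zero-order-hold discretization at 2000 steps with a
minimum-norm input via the discrete reachability Gramian, which matches the
closed form to $10^{-5}$ relative.

## The synthetic cohort: what it emulates, and what it does not

The study design this package targets deposits no raw imaging data, so the
pipeline runs end-to-end on a synthetic cohort whose statistical structure
mirrors the design: a two-group (healthy controls, unaffected first-degree
relatives), two-session (placebo, 1 mg alprazolam) within-subject crossover;
two tasks (emotion identification, emotion memory) by three emotion
conditions (threat, non-threat, neutral); 233 parcels of which 60% lie inside
the functional imaging slab (out-of-slab parcels are zeroed while the full
network is retained, preserving indirect structural pathways — the `drop`
policy is available for sensitivity analysis).

States are built as
$x_{s,d,\mathrm{task},\mathrm{cond}} = m_\mathrm{cond}\, g_d\, h + a_s + \varepsilon$:

* $m_\mathrm{cond}$ — a condition-specific spatial template, white noise
  diffused over the network (3 steps of half-self/half-neighbor averaging) so
  templates are spatially autocorrelated like real activation maps, scaled to
  unit SD over in-slab parcels;
* $g_d$ — drug amplitude factor, default 1 (the emulated study found no drug
  main effect on energy);
* $h = 1 + \delta$ **only** for relatives' alprazolam-session threat-memory
  states — the injected group-by-drug interaction. It is multiplicative on
  amplitude so it propagates through the genuine energy computation
  ($P_e$ ratio $(1+\delta)^2$) rather than being painted onto the energies;
* $a_s$ — subject random offset, SD 0.2 beta units;
* $\varepsilon$ — per-parcel session noise, SD 0.3 beta units. With the unit
  template this gives between-session state correlations around 0.9,
  on the optimistic end of task-fMRI beta reliability; lower reliability
  would require a larger calibrated $\delta$.

**Calibration of $\delta$.** The default $\delta = 0.06$ was fixed by a power
simulation at the evaluation scale (20+20 subjects, 100 nodes, threat-memory
cell, random-intercept model): power 0.63 at $\delta=0.04$, 0.79 at 0.05,
0.97 at 0.06 (100 replicates each). 0.06 was chosen so that the "at least
80% recovery" property holds with Monte-Carlo margin rather than as a coin
flip; the type-I rate of the same model under $\delta = 0$ measures 0.05.
This calibration was run once, before the tests were frozen, and not
revisited.

Behavior is generated downstream of the energies: target efficiency
(accuracy/median RT) is
$0.6 + 0.05\,z(P_e) - 0.05\,[\text{drug}] + \mathcal{N}(0, 0.05)$, with the
$P_e$ coupling applied only to threat-identification records (the association
the emulated study reports). Accuracy is held near 0.9 and reaction time
absorbs the variation, since the accuracy/RT split is under-determined by
efficiency alone. Receptor-like maps are rescaled to $[0,100]$; the first is
rank-blended with a reference map (normal scores mixed at weight $\rho$) to a
target Spearman correlation, the rest are independent.

What the generator does **not** emulate: hemodynamics and trial-level
dynamics, geometry-aware spatial autocorrelation (diffusion is over the
graph, not cortical distance), subject-specific connectomes, and any
receptor-map relationship to the *noise* that drives session-to-session
input differences. The last point matters for interpretation: with
$g_d = 1$, per-subject control-input difference maps are driven by session
noise, so the pipeline's receptor-alignment stage is expected to be null on
the default synthetic world — a green alignment-machinery test establishes
calibration (exact permutation floor $1/(n_\mathrm{perm}+1)$, type-I rate at
the nominal level), not the presence of a planted alignment signal.

## Inference

Energy models: one `lme` fit per task-by-condition cell,
`energy ~ drug * group` with a random intercept per subject, REML, with the
conventional coefficient names $\gamma_{00}$ (intercept), $\gamma_{01}$
(group), $\beta_{1i}$ (drug), $\gamma_{11}$ (interaction); outcomes are
z-scored within the cell by default, which changes no t-statistic or p-value
but makes coefficients comparable across cells. Degrees of freedom are the
fitting engine's (inner–outer) convention and are reported rather than
matched to any external value; random slopes are deliberately omitted — with
two sessions per subject they are not identifiable separately from the
residual. Benjamini–Hochberg FDR is applied across the three emotion
conditions within task (energy models), across all six cells for the
efficiency model's energy slope, and across receptor maps (alignment).

The alignment permutation test permutes the receptor map's parcel labels
within the slab — one shared permutation per iteration across subjects — so
the between-subject correlation of the statistic (mean subject-level
Spearman $\rho$) is preserved under the null. Two-sided p-values use the
add-one convention, making $1/(n_\mathrm{perm}+1)$ the attainable floor.

Demographic comparisons follow the conventional recipe: Fisher's exact test
with the cross-product odds ratio for categorical variables (orientation:
odds of the stated event in group 1 over group 2; a zero cell leaves the OR
undefined unless a Haldane correction is explicitly requested),
pooled-variance t-tests or Wilcoxon rank-sum z for continuous variables, and
pooled-SD Cohen's d (group 2 minus group 1).

## Null models

* **Structural**: degree-preserving double-edge swaps on the binary topology
  (default 10 attempted swaps per edge) followed by reassignment of the
  original weight multiset — uniformly shuffled by default, or greedily
  rank-matched to endpoint strengths for an approximately
  strength-preserving variant. Disconnected nulls are allowed with a warning
  (the Gramian stays invertible under identity actuation).
* **Spatial**: uniform permutation of each state's in-slab values,
  out-of-slab entries untouched. A geometry-respecting (spin-type)
  permutation is not implemented because the synthetic world has no surface
  geometry.

On the synthetic cohort, energies recomputed on rewired connectomes stay
strongly rank-correlated with the originals (Spearman ≈ 0.9–0.98), echoing
the expectation that this class of result is only weakly structure-bound.
Spatially permuting the states erodes the recovered interaction — the
coefficient shrinks and its significance degrades — but only partially
(roughly 20% attenuation of $|\gamma_{11}|$ at default settings). This is a
structural property of the synthetic world, not a bug: the injected effect is
an amplitude scaling, and a value permutation preserves each state's value
multiset and hence its amplitude, so the $(1+\delta)^2$ energy contrast
largely survives; sensitivity analysis shows the attenuation never reaches
50% even at implausibly low noise. An effect tied to the spatial *pattern*
(rather than amplitude) of activation would be destroyed by this null, as in
real data; emulating that would require injecting the interaction as a
pattern rotation rather than a scaling, which would in turn bypass the
amplitude-quadratic energy law the generator is built to exercise.

## Numerical choices and degenerate inputs

* Gramian inversion is by symmetric eigendecomposition with an explicit
  condition-number guard ($10^{12}$); failures carry the condition number.
* All time quadrature is composite trapezoid on the uniform trajectory grid;
  the Gramian quadrature cross-check uses composite Simpson (501 points).
* Asymmetry up to $10^{-10}$ is tolerated and symmetrized on construction;
  larger asymmetry is an error naming the offending entry.
* A constant outcome short-circuits the mixed models (intercept = constant,
  slopes 0) rather than failing inside the optimizer; non-convergence is
  flagged on the result, never silent.
* A zero baseline energy makes relative control impact undefined and errors
  with a pointer toward an absolute measure; per-node Gramian singularities
  during impact computation yield `NA` with a warning, not a global failure.
* Seeds: every stochastic routine takes an explicit seed (or derives one
  from the master seed) and restores the caller's RNG state; identical
  config and seed reproduce every table byte-for-byte.

## Known limitations

The dynamics are linear and time-invariant, with no state-excursion penalty
(pure input energy). The group-averaged connectome ignores individual
structural variation. The synthetic world validates the machinery —
recovery, calibration, determinism, oracle agreement — but its green tests
do not certify any empirical claim about real pharmaco-fMRI data; the
headline statistics of the study this design emulates are not reproducible
without the undeposited imaging data, and this package does not attempt to
match them numerically.
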