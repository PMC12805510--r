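---
title: "Methods: enhanced-sampling force matching on analytic toy systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhanced-sampling force matching on analytic toy systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the statistical identities the package
relies on, and the numerical decisions baked into the defaults. It is a
methods reference, not a tutorial; the README contains a worked example.

## 1. Setting

An "atomistic" configuration `x` in `d` dimensions evolves by overdamped
Langevin dynamics at inverse temperature `β`, discretized with
Euler–Maruyama:

```
x'  =  x + dt · f(x)  +  sqrt(2 dt / β) · η,     η ~ N(0, I)
```

A linear orthonormal mapping `ξ(x) = Ξx` (rows orthonormal; here one CG
coordinate) defines the CG description. The potential of mean force `A(R)`
is minus the log of the marginal density of `R = ξ(x)`, and the mean force
is its negative derivative:

```
-A'(R)  =  E[ Ξ f(x) | ξ(x) = R ]
```

Force matching trains a CG potential `U_φ` by minimizing
`mean | Ξf(x_i) + U_φ'(R_i) |²` over sampled frames. The minimizer of the
population loss is the mean force; the loss at the optimum equals the pooled
conditional variance of the projected force (the irreducible "noise floor"),
which the package estimates independently with `estimate_noise()`.

## 2. The invariance identity and reweighting

Let the simulation run under `f(x) − ∇W(ξ(x))` for any bias `W` along the CG
coordinate. After subtracting the bias force from each frame
(`recompute_unbiased_forces()`), the conditional distribution of the
recomputed projected force given `R` is identical to the unbiased one — the
bias cancels from the conditional density. Only the marginal over `R`
changes, by a factor `exp(−βW(R))`. Consequences:

- binned mean-force estimates on recomputed, CG-biased data need **no
  reweighting** (their per-bin estimand is the bias-*tilted* within-bin
  average of the mean force, see §5);
- force matching on such data converges to the same PMF with coverage where
  the bias put it;
- a bias along any *other* coordinate changes the conditional density, and
  plain averages become inconsistent. Self-normalized importance weights
  `ω ∝ exp(+βW_frame)` (`compute_importance_weights()`) restore consistency;
  `reweighted_expectation()` reports the Kish effective sample size
  `ESS = (Σω)²/Σω²` and flags degenerate weight sets.

For well-tempered metadynamics the final bias state evaluated at each
frame's CV defines the weights (the standard quasi-static approximation);
heights decay as `h·exp(−V(s)/((γ−1) kBT))`, and the long-run sampled
density approaches `exp(−βA/γ)` — the slope diagnostic regresses the
log-histogram on `−βA` and should give `1/γ`.

## 3. Toy systems

| system | dim | CG coordinate | notes |
|---|---|---|---|
| `harmonic_1d` | 1 | identity | closed forms for every estimator |
| `gaussian_2d` | 2 | axis | separable; zero conditional force variance |
| `double_well_1d` | 1 | identity | `u = a(x²−1)²`, `a = 8`, `β = 1` |
| `muller_brown` | 2 | first axis | rotated; `β = 0.125`, `dt = 2e-5` |
| `dihedral_chain_4bead` | 12 | dihedral angle | curvilinear CV |

The Müller–Brown surface is stored **rotated** so that the line connecting
the outer minima is horizontal: the canonical four-Gaussian parameters are
conjugated with the rotation whose first row is the unit vector between the
canonical outer minima, `(0.641352665885, −0.767246217300)`. This makes a
single linear coordinate (the first axis) a meaningful reaction coordinate.
`β = 0.125` puts the saddle ≈ 8–9 kBT above the deep basin, so unbiased
dynamics essentially never crosses — the regime enhanced sampling is for.
The canonical flattening bias used throughout is a negative Gaussian
restraint, height −110, width 0.6, centered at −0.6 on the CG coordinate,
chosen during design to approximately level the marginal over the 99.9%
support interval.

The four-bead chain has stiff bonds (`kb = 100`, `r0 = 1`), stiff angles
(`ka = 50`, `θ0 = 1.910633`) and a cosine dihedral term
`v(θ) = kd (1 + cos θ)`, `kd = 2`. By rigid-rotation symmetry the marginal
density of the dihedral is exactly `∝ exp(−β kd (1+cos θ))`, which provides
the analytic reference for the torque estimator.

## 4. Oracles

`compute_oracle()` computes, on a 2001-point CG grid (trapezoidal quadrature
with 2001 orthogonal nodes in 2D):

1. the marginal density and `A(R) = −log p(R)/β`;
2. the mean force by **two independent routes** — the conditional average of
   the projected force, and the numerical derivative of the quadrature PMF.
   `oracle_route_discrepancy()` reports their relative L2 difference; the two
   routes agreeing is a precondition for using either as ground truth.

Quadrature refuses CG values whose conditional density has significant mass
at the integration boundary (`boundary_tol`), rather than returning silently
truncated expectations.

## 5. Binned comparisons: what the estimator actually estimates

A binned mean-force estimate over bin `b` converges to the *density-weighted
within-bin average* of the mean force — weighted by the **sampled** CG
density, i.e. including any CG-aligned bias tilt. Comparing a binned
estimate to the oracle therefore requires the matching binned oracle
expectation (`oracle_binned_mean_force()`, optionally bias-tilted), not the
mean force at the bin center. Two numerical consequences shaped the
defaults:

- In steep-force regions, wide bins make the within-bin weighting term large
  enough that even sub-percent density errors (the `O(dt)` Euler–Maruyama
  bias) show up against tight standard errors. Equal-count (quantile) bins
  with trimmed tails equalize statistical power and keep bins narrow where
  data concentrate; the invariance demonstrations use 12 equal-count bins
  between the 2% and 98% sample quantiles.
- Bins with coverage gaps (a bin spanning a region the biased run never
  visits) estimate a different average than the oracle integrates; tail
  trimming removes them.

Standard errors are within-bin sample standard errors (reweighted analogues
for weighted estimates); frames are decorrelated by construction — stride
times `dt` is chosen beyond the relevant relaxation time in every shipped
protocol.

## 6. The CG model and training

`cg_potential_model()` is a radial-basis feature layer (fixed centers and
width = center spacing) followed by a small tanh network, producing a scalar
energy; the force is the exact analytic negative gradient, so the model is
conservative by construction and `fm_loss` differentiates cleanly.

One numerical decision matters more than the architecture: the network
carries a **fixed, non-trainable output scale**. Projected forces on
Müller–Brown are O(±500); with unit scale a standard initialization needs
thousands of epochs just to reach the target magnitude. `cg_forcematch()`
sets `out_scale = sd(projected forces) × RBF width` (raw RBF-feature forces
are O(1/width)), trains against rescaled targets, and reports losses in
physical units. Training is full-batch Adam with early stopping on a
validation split; everything is deterministically seeded.

`predict_mean_force()` warns outside the trained support: the RBF features
vanish there and the model force decays to zero, which is an artifact of the
representation, not a prediction.

## 7. Curvilinear CG coordinates: the dihedral

For a curvilinear coordinate `θ(x)` the instantaneous conjugate force is the
generalized torque `Q = f · b`, with `b = ∇θ/|∇θ|²`. Its conditional mean is
**not** `−dA/dθ`: the exact identity is

```
−dA/dθ  =  ⟨ f·b + kBT ∇·b ⟩_θ
```

and the divergence term does not vanish for this `b`. `generalized_torque()`
returns both the bare torque and `div_tangent` (central finite differences
of the analytic dihedral gradient, step 1e-5); estimators must add
`div_tangent/β`. On ideal-geometry frames (bonds at `r0`, angles at `θ0`)
the bond and angle forces vanish and `Q = kd sin θ` holds frame for frame,
which the tests exploit; on thermal frames only the conditional-mean
identity holds. Frames whose first three beads are nearly collinear have an
ill-defined dihedral and are flagged invalid rather than silently included.

## 8. Evaluation and stability

`mean_force_rmse()` compares the model force to the oracle on the central
99.9% oracle mass interval — errors outside the thermally relevant region
are meaningless. `evaluate_model()` simulates CG chains with the learned
potential, Boltzmann-inverts the sampled histogram and reports KL and PMF
mean-squared divergences against the exact profile. Stability counting
treats two events as instability: a chain exceeding an energy threshold, and
a chain *asked to start outside the model's trained support* (counted
unstable at step 0) — a model that cannot represent the starting state is
unstable there by definition. This makes models trained on different data
coverage comparable by launching chains across a common physical region.

## 9. Reproducibility

All artifacts are plain text. Numeric table and checkpoint entries are
written at 17 significant digits (`%.17g`), which round-trips IEEE doubles
exactly; datasets carry a JSON sidecar with an md5 of the table, and
checkpoints embed a parameter hash, so corruption is detected on read.
Manifests contain no timestamps; running the same configuration and seed
twice produces byte-identical artifacts. Stage seeds derive from the master
seed (`+1` sampling, `+2` training, `+3` evaluation) unless overridden.

## 10. Limitations

- Euler–Maruyama has an `O(dt)` equilibrium-density bias; shipped protocols
  choose `dt` so it is below statistical resolution for the quantities
  compared, but very tight bin-level comparisons will see it first.
- Quadrature oracles are limited to ambient dimension ≤ 2 plus the analytic
  dihedral marginal; there is no generic high-dimensional oracle.
- The importance-weight ESS degrades exponentially with bias magnitude off
  the CG coordinate; `reweighted_expectation()` warns, but no automatic
  bridging/stratification is provided.
- Metadynamics reweighting uses the final-bias quasi-static approximation;
  early-run transients are handled by discarding, not by time-dependent
  reweighting.
- The model's force representation decays to zero outside the trained
  support; extrapolation is explicitly unsupported.
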