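# esfm — enhanced-sampling force matching for coarse-grained potentials

Machine-learned coarse-grained (CG) potentials are usually trained by *force
matching*: minimize the mean squared difference between the CG model force
and the projected atomistic forces. The quality of the result is limited less
by the model class than by where the training data lives — unbiased dynamics
rarely visits barriers and transition regions, so the fitted potential of
mean force (PMF) is unconstrained exactly where it matters.

This package is built around one exploitable fact: **the conditional mean
force is invariant under any bias applied along the CG coordinates.** If a
simulation is run with bias energy `W(ξ(x))` and the bias force is subtracted
from the sampled forces afterwards (`recompute_unbiased_forces()`), the
conditional expectation of the projected force given the CG value `R` is
unchanged — only the *distribution over R* shifts, which is precisely what
enhanced sampling is for. Force matching on such recomputed data therefore
converges to the same PMF derivative, with far better coverage per frame.
Biases along *other* coordinates break this invariance; the package provides
self-normalized importance reweighting (`compute_importance_weights()`,
weights `exp(βW)`) to repair it, and estimators that expose the difference.

Everything runs on analytic toy systems with exact quadrature references:

- `muller_brown` — the Müller–Brown surface (rotated so the reaction
  coordinate is the first coordinate), CG-mapped to one dimension;
- `double_well_1d` — a quartic double well;
- `dihedral_chain_4bead` — a four-bead chain whose CG coordinate is the
  dihedral angle, exercising curvilinear coordinates: the conjugate force is
  the generalized torque plus a geometric divergence term
  (`generalized_torque()`).

`compute_oracle()` evaluates the exact marginal density, PMF and mean force
by quadrature (two independent routes, which are required to agree), so every
estimator and every trained model can be checked against ground truth rather
than against another simulation.

Biasing schemes: static harmonic umbrellas (`bias_umbrella()`), Gaussian
restraints (`bias_gaussian_restraint()`), and well-tempered metadynamics
(`bias_wt_metadynamics()`), all usable along a linear CG coordinate or the
dihedral. Sampling is overdamped Langevin (Euler–Maruyama) with deterministic
seeding; identical configuration and seed reproduce trajectory files and
manifests bit for bit.

The trained model (`cg_forcematch()`) is a radial-basis-feature network whose
force is the exact negative gradient of its energy (conservative by
construction). The returned `cgfm` object supports `print`, `summary`,
`coef`, `predict`, `residuals`, `plot` and `simulate` (CG Langevin dynamics
with the learned potential).

## Worked example

Train matched-budget CG potentials on biased and unbiased Müller–Brown data
and compare them against the exact mean force:

```r
library(esfm)
sys  <- make_builtin_system("muller_brown")
xmap <- axis_mapping(1, 2)                       # CG coordinate: first axis of 2
bias <- bias_gaussian_restraint(-110, 0.6, -0.6, xmap)  # flattens the x-marginal

dsb <- simulate_trajectory(sys, bias, n_steps = 2e7, seed = 1, stride = 100)
dsb <- recompute_unbiased_forces(dsb, sys)       # exact unbiased forces
dsu <- simulate_trajectory(sys, n_steps = 2e7, seed = 2, stride = 100)

fitb <- cg_forcematch(dsb, xmap, sys, n_frames = 5000, epochs = 60, seed = 1)
fitu <- cg_forcematch(dsu, xmap, sys, n_frames = 5000, epochs = 60, seed = 1)
print(fitb)
#> Coarse-grained potential fit by force matching
#>   data: 5000 frames from system 'muller_brown' (bias: gaussian_restraint)
#>   model: 64 RBF centers on [-1.6, 0.345], hidden layers 64x64
#>   final training loss: 2977.91 (initial 20337.5)

orc <- compute_oracle(sys, xmap)                 # exact quadrature reference
mean_force_rmse(fitb, orc)$rmse                  # 127.0
mean_force_rmse(fitu, orc)$rmse                  # 226.2
```

The biased-data model roughly halves the mean-force error at identical
training-set size, because the restraint makes the sampler cover the whole
reaction coordinate instead of sitting in the deep basin. The difference is
starker in simulation: launching 20 CG chains spread across the oracle's
99.9% support interval,

```r
iv <- oracle_support_interval(orc)
x0 <- seq(iv[1], iv[2], length.out = 20)
run_cg_simulation(fitb$model, n_traj = 20, n_steps = 5000, dt = 2e-5,
                  beta = sys$beta, x0 = x0, seed = 3)$n_unstable   # 10
run_cg_simulation(fitu$model, n_traj = 20, n_steps = 5000, dt = 2e-5,
                  beta = sys$beta, x0 = x0, seed = 3)$n_unstable   # 18
```

the unbiased-data model cannot even represent most of the region (18 of 20
chains unstable, most at step 0 for lack of support) while the biased-data
model simulates half of them stably at this training budget.

## Command-line interface

A thin CLI wraps the same functions (`inst/cli/esfm`, installed under
`system.file("cli", "esfm", package = "esfm")`):

```sh
Rscript <path>/esfm run-experiment --config config.yaml --seed 7 --out outdir
```

Commands: `simulate`, `train`, `evaluate`, `cgsim`, `oracle`,
`run-experiment`; every command exits nonzero on error with a
machine-readable JSON error record on stderr. Experiment directories contain
plain-text artifacts (TSV tables with JSON sidecars, JSON checkpoints at 17
significant digits for bit-exact round trips) and a manifest with md5 hashes
of every output.
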