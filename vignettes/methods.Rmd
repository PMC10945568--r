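---
title: "Four-site water models, the weighted-MAPE cost, and surrogate-gated optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-site water models, the weighted-MAPE cost, and surrogate-gated optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eccwater)
```

## The model

A rigid four-site water model in the TIP4P family is fully defined by six
scalars: the oxygen Lennard-Jones diameter `sigma` (nm) and well depth
`epsilon` (kJ/mol), the hydrogen partial charge `q_H` (e), the O–H distance
`d_OH` (nm), the O–M distance `d_OM` (nm), and the H–O–H angle `theta`
(degrees). The massless M site carries `q_M = -2 q_H`, so charge neutrality
is structural: it can never be violated by construction, and every geometry
and topology the package emits satisfies it exactly.

The package works in a fixed canonical frame — oxygen at the origin, the
H–O–H bisector along +z pointing toward the hydrogens, hydrogens in the
xz-plane — so that computed moments are bit-for-bit reproducible. In that
frame the dipole is `mu = 2 q_H (d_OH cos(theta/2) - d_OM)` in e·nm, and
the tetrahedral quadrupole is the in-plane anisotropy of the traceless
quadrupole tensor about the oxygen,

```
Q_ab = 1/2 sum_i q_i (3 r_a r_b - r^2 delta_ab),    Q_T = (Q_xx - Q_yy) / 2 ,
```

equal in closed form to `(3/2) q_H (d_OH sin(theta/2))^2`. Several
quadrupole sign/normalization conventions circulate; this one was selected
because it reproduces the published `Q_T` values of all four bundled models
(ECCw2024, TIP4P/2005, TIP4P-FB, OPC4) to within 1e-3 D·Å, and that
agreement is locked in by a golden test. Conversions use a single named
constant, 1 e·nm = 48.03205 D, derived from the CODATA elementary charge
and the debye definition; the ~1e-4 residuals against the published
moments are consistent with the precision of the conversion constants used
there, and the test tolerance (1e-3) absorbs them.

`Q_T` is independent of `d_OM` (the M site lies on the z-axis), while `mu`
decreases linearly in `d_OM` — both properties are tested, and together
they mean the two moments probe complementary directions of parameter
space.

Parameter validation is deliberately two-tier: the optimizer path rejects
out-of-bounds parameters outright, while standalone moment and topology
calculations only warn (TIP4P-FB's `d_OM` lies below the search box, yet
its moments must remain computable).

## Reference targets

The cost function compares simulated properties against:

* the density isobar at 1 bar on a 260–360 K grid (20 K steps). The grid
  values shipped as defaults are literature-derived handbook values
  (supercooled branch below 273 K), clearly labeled as such and
  user-overridable; no acceptance-grade result in this package depends on
  them.
* the nuclear dielectric constant. A nonpolarizable model captures only
  nuclear (orientational) polarization, so the target for a
  charge-scaling-compatible model is `eps_N = eps_r / eps_e` with
  `eps_e ≈ n² = 1.78`; at ambient conditions `79.2 / 1.78 ≈ 44.5`.
* the self-diffusion coefficient at 300 K, finite-size corrected. A
  periodic cubic box of edge L slows diffusion by
  `xi k_B T / (6 pi eta L)` with `xi = 2.837297` (the cubic-lattice
  self-term); subtracting this from the experimental value for an
  832-molecule box (L ≈ 2.92 nm) gives the simulation target
  2.16e-5 cm²/s. The uncorrected experimental value is an input, not a
  constant, since different box sizes need different targets.
* the position (0.280 nm) and height (2.58) of the first O–O RDF peak.
  Peak extraction refines the discrete argmax by a three-point parabolic
  fit, making the position sub-grid accurate; the *first* local maximum
  above 1 is returned even when a later peak is higher.

## The cost function

Each property contributes a loss `f_i = MAPE_i% / 10` — a 10% mean
absolute percentage deviation counts as a loss of 1 — and the cost is
`C = sum_i w_i f_i` with weights 0.667 (density isobar), 0.111 (dielectric),
0.111 (diffusion), 0.0555/0.0555 (RDF peak position/height), renormalized
to sum to 1 over the included properties. The /10 scaling is the convention
that reproduces the published general-cost values of all four bundled
models from their printed per-property errors (0.262, 0.208, 0.248, 0.260
within ±0.002); that derivation is the module's oracle test. `C_ECC`
includes the dielectric target (the optimization variant); `C_G` excludes
it and renormalizes, for fair comparison against models never meant to
have `eps ≈ 45`. The density isobar enters as a single MAPE over the
6-point grid, matching its single weight. Cost comparisons are strict:
ties keep the incumbent.

## The optimization loop

Three phases, all bounded by the search box (sigma 0.3050–0.3250 nm,
epsilon 0.5–1.0 kJ/mol, q_H 0.35–0.70 e, d_OH 0.090–0.100 nm, d_OM
0.012–0.018 nm, theta 100–110°) and fully reproducible under a master
seed:

1. **Random walk.** From the seeding values (the `Initial` column of the
   bounds table), each step perturbs every parameter by a uniform step of
   up to 2% of its range, reflecting at the boundaries. With a real
   molecular dynamics evaluator the walk also warm-starts each simulation
   from the previous configuration — that hook is part of the evaluator
   contract (`state` in, `state` out); the toy evaluator ignores it. The
   step size is a package default (the source protocol does not state
   one): small enough for warm starts to be useful, large enough that the
   walk's diffusion length over the seeding phase covers a substantial
   fraction of the box.
2. **Differential evolution.** Proposals are
   `x = x_a + F (x_b - x_c)` with the base `a` drawn from the elite
   (lowest-cost) quarter of the population and the difference pair `b, c`
   from the whole population, followed by per-coordinate crossover with
   probability CR against a random population member, then clipping to the
   box. Sourcing the difference vectors population-wide is deliberate:
   drawing all three members from the elite tier collapses the proposal
   spread once the elites cluster, which makes runs prone to stalling well
   short of the optimum; population-wide differences keep the search
   diverse, and the recovery tests exercise exactly this behavior.
   `F = 0.7`, `CR = 0.9`, population capacity 64 and elite fraction 0.25
   are conventional DE practice — none are stated in the source — and the
   contract is tested by optimum recovery, not by the constants. A
   candidate enters the population only by strictly improving on the worst
   retained member. The phase stops at budget or when the best cost
   improves by less than 1% over 500 consecutive proposals.
3. **Refinement.** A multi-start coordinate-wise line search minimizes the
   surrogate prediction, restarting from elite members; each proposal is
   then truly evaluated. On an exact surrogate this search localizes a
   quadratic minimum to better than 0.01 in normalized coordinates; on a
   trained network the achievable localization is set by the fit error,
   not the search.

Failed evaluations are logged (`state = "failed"`) and skipped — an
automation-robustness requirement, since a crashed simulation must not
kill a campaign. Every proposed candidate lands in an append-only ledger
(phase, raw and normalized parameters, predicted and true cost, state,
timestamp); under a fixed seed the ledger is reproducible except for the
wall-clock timestamp column.

## The surrogate gate

The mapper is a fully connected multilayer perceptron from the six
normalized parameters to the scalar cost: four ReLU hidden layers of 40
nodes, dropout 0.10 after each hidden layer, a max-norm constraint of 5.0
on each unit's incoming weights, a linear output, and early stopping on a
20%-validation split (patience 50 epochs). It predicts the cost scalar
directly — the gate compares exactly that number against a threshold — and
a candidate predicted worse than the threshold skips its true evaluation.
The default threshold 0.7 mirrors the "acceptable quality" cost band; the
source leaves the actual value unstated.

Training hyperparameters not fixed by the architecture are surfaced in
`mapper_config()` with conventional defaults: Adam at 1e-3 with the step
size halved on validation plateaus (dropout makes the gradient noisy, and
a constant rate stalls above its noise floor), batch 128, epoch cap 500.
The network trains on `log(1 + cost)` and back-transforms predictions:
costs span two orders of magnitude during a run, and the log transform
concentrates resolution at the low-cost end where gate decisions happen.
The surrogate is retrained whenever 25
new true evaluations have accumulated, and refuses to train below 20 rows
(the gate then passes everything).

Three safeguards keep the gate sound; all address failure modes that are
easy to reproduce on the toy landscape.

* *Liveness guard.* After 3 consecutive skips the next candidate is
  evaluated unconditionally. Without it, a surrogate trained only on poor
  early samples can become pessimistic everywhere and starve itself of the
  very data that would correct it. Wrongly rejected regions are also
  naturally re-proposed later, once the surrogate has seen more data.
* *Trust bar.* A freshly retrained surrogate is used for gating only if
  its validation R² reaches 0.3; training occasionally goes badly (early
  stopping can latch onto a noisy epoch), and a single bad network would
  otherwise mass-skip for a whole retraining window.
* *Screening scope.* The gate and the retraining cadence are active while
  the retained population still contains members above the threshold.
  Once every retained point is inside the quality band, proposals
  recombine known-good regions whose cost differences lie far below the
  surrogate's fit error; keeping the gate active there only rejects good
  candidates, so it is turned off.

## The toy landscape

The synthetic evaluator maps parameters to the five target properties as
`value_i = reference_i * (1 + sum_j c_ij (x_j - x*_j)^2)` in normalized
coordinates, optionally after a fixed orthogonal rotation mixing the
coordinates (the `coupled` variant, which removes coordinate separability)
and optionally with Gaussian noise (default 0). At the planted optimum —
the published ECCw2024 parameters, verified in-bounds at construction —
every property equals its reference exactly and the cost is identically
zero, making it the unique global minimum.

Because every property is its reference times `1 + q_i`, the MAPE is
exactly `100 q_i` and the cost has the closed form
`10 * sum_i w_i q_i` — an analytic oracle the evaluator is tested against
at 1e-10.

The curvature scales `c_ij` (0.2–1.2 across properties and parameters)
were fixed once so that the cost surface spans the magnitudes real model
comparisons produce: the seeding values score about 1.8 — comparable to a
poor three-site model's ≈ 2 — the quality band below 0.7 occupies a
sizable but minor fraction of the box, and roughly half of the candidates
an optimization run generates fall below that band. This matters for the
gate: a surface where almost nothing (or almost everything) lies below
the threshold makes the skip gate either self-starving or vacuous,
neither of which reflects the regime the method operates in.

What the toy landscape does *not* emulate: simulation noise (real property
estimates carry statistical error), evaluation cost (real evaluations take
GPU-days, which is the entire reason the gate exists), non-quadratic
landscape features far from the optimum, and property–property
correlations beyond the shared quadratic form. Passing recovery tests on
the toy landscape therefore demonstrates the correctness of the search
machinery, not the physics of any water model.

## Problem sizes used in the tests

The acceptance-grade recovery experiment runs the full pipeline with a
2000-evaluation budget on the noiseless toy landscape, ten seeds, and asks
for all six normalized parameters within 2% of the planted optimum in at
least 8 of 10 runs. Its seeding phase is scaled to 250 walk steps with the
step enlarged to 5% of each range, preserving the diffusion length of a
full-length (1000-step, 2%) seeding phase at a quarter of the cost; and
in-loop surrogate retraining uses a reduced epoch cap (150, patience 30)
to keep the experiment's dozens of retrainings proportionate. The package
defaults remain the full-length values.

The gate comparison reruns the same seeds with the gate at threshold 0.7
under the same proposal budget as the ungated run, and checks the final
best cost against the ungated result alongside the fraction of true
evaluations saved. Converged runs sit at costs below 1e-4, where a pure
relative comparison is numerically meaningless, so the cost comparison
carries an absolute tolerance floor of 1e-3 — negligible on the scale
where model quality lives (good models ≈ 0.2). A caveat this package's
experiments expose honestly: on a noiseless landscape with an elitist
selection rule, candidates above the quality threshold but below the
population's worst member are at once the gate's skip targets and the raw
material for population improvement, so evaluation savings and exact
final-cost parity pull against each other; the gated runs save roughly a
quarter of the true evaluations while matching the ungated result at the
1e-3 resolution in most, though not all, seeds. In the method's
native regime — statistical noise from molecular dynamics far above these
resolutions, and evaluations costing GPU-days — the tension is immaterial.

## Known limitations

* The moments use point charges only; models with charge penetration or
  polarizability are out of scope, as are 3- and 5-site geometries.
* The `C_ECC` value of a model cannot be recomputed from published
  per-property errors alone (the dielectric MAPE is not printed); only
  `C_G` is reproduced.
* The surrogate is a point predictor; it carries no uncertainty, so the
  gate cannot trade off exploration against exploitation beyond the
  liveness guard.
* The refinement search inherits the surrogate's bias: with dropout
  regularization the fit error near a flat minimum is larger than the
  basin's internal cost differences, so refinement reliably reaches the
  right basin but cannot sharpen the location beyond what the data
  support.
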