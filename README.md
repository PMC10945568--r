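# eccwater

Tools for building and parameterizing rigid four-site (TIP4P-family) water
models that are compatible with charge-scaling force fields.

## The problem

Nonpolarizable force fields can account for electronic polarization in a
mean-field way by immersing the system in an electronic dielectric
continuum — in practice, by scaling ionic charges by `1/sqrt(eps_e)` with
`eps_e ≈ n² = 1.78` for water (the electronic continuum correction, ECC).
This is only consistent if the water model itself exhibits the *nuclear*
part of the dielectric constant, `eps_N = eps_r / eps_e ≈ 45`, rather than
the full experimental `eps_r ≈ 78`; common models with `eps > 50`
"overscale" ion–ion interactions. Finding four-site models that satisfy
this dielectric constraint while staying accurate on other properties is a
six-dimensional search problem that `eccwater` implements end to end:

- **Model construction.** A four-site model is fully defined by six
  parameters: the oxygen Lennard-Jones `sigma` and `epsilon`, the hydrogen
  charge `q_H` (the massless M site carries `-2 q_H`), the distances
  `d_OH`, `d_OM`, and the H–O–H angle `theta`. The package builds the
  canonical-frame geometry, computes the molecular dipole
  `mu = 2 q_H (d_OH cos(theta/2) − d_OM)` and the tetrahedral quadrupole
  `Q_T = (Q_xx − Q_yy)/2` of the traceless quadrupole tensor, and exports
  GROMACS topologies.
- **Targets and cost.** Experimental targets (density isobar, `eps_N`,
  finite-size-corrected self-diffusion via the Yeh–Hummer correction
  `ΔD = ξ k_B T / (6 π η L)`, first O–O RDF peak) enter a weighted
  mean-absolute-percentage-error cost `C = Σ w_i f_i` with `f_i = MAPE_i%/10`
  and weights renormalized to sum to 1. `C_ECC` includes the dielectric
  constant; `C_G` excludes it.
- **Optimization.** A three-phase loop: bounded random-walk seeding,
  differential evolution over the best points, and refinement — with a
  multilayer-perceptron surrogate (4 × 40 ReLU, dropout 0.10, max-norm 5,
  early stopping) that predicts a candidate's cost and skips the expensive
  property evaluation when the prediction exceeds a threshold.
- **Toy evaluator.** A smooth synthetic parameters→properties map with a
  planted optimum stands in for the molecular dynamics engine, so the whole
  loop runs in seconds and its recovery behavior is testable.

## Worked example

```r
library(eccwater)

# A published charge-scaling-compatible model and a classic reference model
ecc <- water_model_preset("eccw2024")
m <- molecular_moments(ecc)
sprintf("mu = %.6f D, Q_T = %.6f D*A", m$mu, m$q_t)
#> [1] "mu = 2.167735 D, Q_T = 2.444550 D*A"
molecular_moments(water_model_preset("tip4p2005"))$mu
#> [1] 2.305206

# General cost C_G of ECCw2024 from its per-property errors (%)
res <- list(rho_1bar = as_mape(0.072), D_OW = as_mape(7.0),
            rdf_1p = as_mape(1.429), rdf_1h = as_mape(25.6))
model_cost(res, variant = "general")$cost
#> [1] 0.2615448

# Optimize against the toy evaluator (optimum planted at ECCw2024)
land <- toy_landscape()
fit <- run_optimization(toy_evaluator(land), budget = 2000,
                        config = optimizer_config(rw_steps = 250, seed = 1))
fit$best_cost
#> [1] 7.286114e-05
```

The dipole (2.17 D, between the gas-phase 1.85 D and typical liquid-phase
estimates) and the quadrupole (2.44 D·Å) characterize the model's
electrostatics; `C_G ≈ 0.26` says the model's weighted mean deviation from
experiment is about 2.6% — comparable to the best four-site models
(TIP4P/2005 evaluates to 0.208 from its own error row). The optimization
run recovers the planted optimum to a cost of ~7e-5 — a weighted mean
deviation from the targets below a thousandth of a percent.

A thin command-line wrapper is installed with the package
(`inst/exec/eccwater`):

```sh
Rscript inst/exec/eccwater moments --params eccw2024
Rscript inst/exec/eccwater topology --params tip4p2005 --out tip4p2005.itp --mdp npt.mdp
```

## Scope

The package never runs a molecular dynamics engine: topologies and
run-settings templates are exchange artifacts for an external evaluator,
and trajectory-derived properties (dielectric constant, diffusion,
viscosity, surface tension, melting point) are inputs, not outputs. The
methods vignette (`vignettes/methods.Rmd`) documents the model, the cost
convention, the optimizer and surrogate design choices, and the limits of
what the toy landscape can demonstrate.
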