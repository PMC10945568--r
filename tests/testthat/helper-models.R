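# Published moments of the four reference models (debye, debye*angstrom).
published_moments <- list(
  eccw2024  = c(mu = 2.167631, q_t = 2.444435),
  tip4p2005 = c(mu = 2.305097, q_t = 2.296802),
  tip4pfb   = c(mu = 2.427804, q_t = 2.170775),
  opc4      = c(mu = 2.479542, q_t = 2.299607))

# Per-property MAPE rows (%) from the published model-performance comparison.
published_mapes <- list(
  eccw2024  = c(rho_1bar = 0.072, D_OW = 7.0, rdf_1p = 1.429, rdf_1h = 25.6),
  tip4p2005 = c(rho_1bar = 0.118, D_OW = 3.1, rdf_1p = 1.429, rdf_1h = 24.2),
  opc4      = c(rho_1bar = 0.233, D_OW = 7.3, rdf_1p = 0.714, rdf_1h = 21.5),
  tip4pfb   = c(rho_1bar = 0.085, D_OW = 6.6, rdf_1p = 1.486, rdf_1h = 25.8))

published_cg <- c(eccw2024 = 0.262, tip4p2005 = 0.208, opc4 = 0.248,
                  tip4pfb = 0.260)

# A random in-bounds parameter set (uses the session RNG).
random_params <- function(bounds = parameter_bounds()) {
  denormalize_params(runif(6), bounds)
}

# Random 3-D rotation matrix.
random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}

cg_from_mapes <- function(mapes) {
  res <- lapply(mapes, as_mape)
  model_cost(res, weights = cost_weights(), variant = "general")$cost
}
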