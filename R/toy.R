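# A synthetic, instantaneous stand-in for the molecular dynamics property
# evaluator: a smooth map from parameters to the five target properties with
# a planted optimum at which every property equals its reference exactly.
# It lets the cost function, the surrogate gate and the whole optimization
# loop be exercised and tested at desk scale.

TOY_PROPERTIES <- c("rho_1bar", "eps_r", "D_OW", "rdf_1p", "rdf_1h")

# Fixed per-property curvature scales over the six normalized coordinates.
TOY_DEFAULT_CURVATURE <- matrix(
  c(0.9, 0.3, 0.5, 0.7, 0.2, 0.4,
    0.4, 0.8, 1.2, 0.3, 0.6, 0.5,
    0.6, 0.5, 0.9, 0.4, 0.8, 0.3,
    0.3, 0.6, 0.4, 1.0, 0.5, 0.7,
    0.5, 0.4, 0.7, 0.6, 1.1, 0.9),
  nrow = 5, byrow = TRUE,
  dimnames = list(TOY_PROPERTIES, PARAM_NAMES))

#' Synthetic property landscape with a planted optimum
#'
#' Defines a smooth parameters-to-properties map: in normalized coordinates
#' `x`, each property equals its reference value times
#' `1 + sum_j c_j (x_j - x*_j)^2` (optionally after a fixed rotation mixing
#' the coordinates, to stress the optimizer beyond coordinate separability),
#' plus optional Gaussian noise. At the planted optimum `x*` with zero noise
#' every property matches its reference exactly, so the cost is zero there
#' and the optimum is the unique global minimum.
#'
#' @param optimum Planted optimum (`water_model_params`); defaults to the
#'   ECCw2024 model, which is verified to lie inside the search bounds at
#'   construction.
#' @param curvature 5 x 6 matrix of positive per-property curvature scales
#'   (rows: rho_1bar, eps_r, D_OW, rdf_1p, rdf_1h).
#' @param noise_sd Relative Gaussian noise amplitude (default 0,
#'   deterministic).
#' @param coupled If `TRUE`, the quadratic form acts on rotated coordinates.
#' @param reference The `reference_set` supplying the property values at the
#'   optimum.
#' @param bounds A `parameter_bounds`.
#' @return An object of class `toy_landscape`.
#' @export
toy_landscape <- function(optimum = water_model_preset("eccw2024"),
                          curvature = TOY_DEFAULT_CURVATURE,
                          noise_sd = 0, coupled = FALSE,
                          reference = reference_set(),
                          bounds = parameter_bounds()) {
  check_bounds(optimum, bounds, action = "error")
  curvature <- as.matrix(curvature)
  if (!all(dim(curvature) == c(5L, 6L)) || any(curvature <= 0) ||
      any(!is.finite(curvature)))
    stop("'curvature' must be a positive finite 5 x 6 matrix", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  rotation <- NULL
  if (coupled) {
    # fixed orthogonal mixing matrix, identical across sessions
    rotation <- with_local_seed(20240307L, qr.Q(qr(matrix(rnorm(36), 6, 6))))
  }
  structure(list(optimum = optimum,
                 x_star = normalize_params(optimum, bounds),
                 curvature = curvature, noise_sd = noise_sd,
                 rotation = rotation, reference = reference, bounds = bounds),
            class = "toy_landscape")
}

#' Evaluate the synthetic property map
#'
#' @param params In-bounds `water_model_params`.
#' @param landscape A [toy_landscape()].
#' @return Named list of property results (the `rho_1bar` entry is a vector
#'   over the reference temperature grid), suitable for [model_cost()].
#' @examples
#' land <- toy_landscape()
#' res <- evaluate_toy(land$optimum, land)
#' model_cost(res, land$reference)$cost # 0 at the planted optimum
#' @export
evaluate_toy <- function(params, landscape) {
  stopifnot(inherits(landscape, "toy_landscape"))
  x <- normalize_params(params, landscape$bounds) # errors if out of bounds
  q <- toy_quadratic(x, landscape)
  factors <- 1 + q
  if (landscape$noise_sd > 0)
    factors <- factors + rnorm(length(factors), 0, landscape$noise_sd)
  out <- lapply(TOY_PROPERTIES, function(nm)
    landscape$reference$targets[[nm]]$value * factors[[nm]])
  names(out) <- TOY_PROPERTIES
  out
}

# Quadratic inflation factor per property (named vector).
toy_quadratic <- function(x, landscape) {
  d <- x - landscape$x_star
  if (!is.null(landscape$rotation)) d <- as.numeric(landscape$rotation %*% d)
  q <- as.numeric(landscape$curvature %*% d^2)
  names(q) <- TOY_PROPERTIES
  q
}

#' Closed-form cost of the noiseless toy landscape
#'
#' Independent of the property-evaluation route: because every property is
#' its reference times `1 + q_i`, its MAPE is exactly `100 q_i` percent and
#' the cost reduces to `sum_i w_i (100 q_i / 10)` with renormalized weights.
#' Used as the analytic oracle for the evaluator.
#'
#' @param params In-bounds `water_model_params`.
#' @param landscape A [toy_landscape()].
#' @param weights A `cost_weights` object.
#' @param variant `"ecc"` or `"general"`.
#' @return The cost as a plain numeric scalar.
#' @export
toy_true_cost <- function(params, landscape, weights = cost_weights(),
                          variant = c("ecc", "general")) {
  variant <- match.arg(variant)
  x <- normalize_params(params, landscape$bounds)
  q <- toy_quadratic(x, landscape)
  w <- renormalize_weights(weights,
                           exclude = if (variant == "general") "eps_r"
                                     else character())
  sum(w$weights[names(w$weights)] * 100 * q[names(w$weights)]) /
    MAPE_LOSS_SCALE
}

#' Wrap a toy landscape as an optimizer evaluator
#'
#' @param landscape A [toy_landscape()].
#' @return A function `(params, state)` conforming to the
#'   [run_optimization()] evaluator contract (the warm-start state is
#'   ignored: the toy evaluation is instantaneous).
#' @export
toy_evaluator <- function(landscape) {
  stopifnot(inherits(landscape, "toy_landscape"))
  function(params, state = NULL) evaluate_toy(params, landscape)
}

#' Generate a synthetic oxygen-oxygen RDF curve
#'
#' Builds a water-like g(r): zero inside an excluded-volume core, a Gaussian
#' first peak at the requested position and height, damped oscillations
#' beyond it, decaying to 1 at large r. Used as a fixture for
#' [rdf_first_peak()].
#'
#' @param peak_position First-peak position (nm), `> 0`.
#' @param peak_height First-peak height, `> 1`.
#' @param spacing Grid spacing (nm), `> 0`.
#' @param r_max Largest distance on the grid (nm).
#' @param noise_sd Optional Gaussian noise on g(r) (default 0).
#' @return An `rdf_curve` object.
#' @examples
#' rdf_first_peak(generate_rdf_fixture(0.280, 2.58, 0.002))
#' @export
generate_rdf_fixture <- function(peak_position = 0.280, peak_height = 2.58,
                                 spacing = 0.002, r_max = 0.9,
                                 noise_sd = 0) {
  if (peak_position <= 0) stop("'peak_position' must be > 0", call. = FALSE)
  if (peak_height <= 1) stop("'peak_height' must be > 1", call. = FALSE)
  if (spacing <= 0) stop("'spacing' must be > 0", call. = FALSE)
  r <- seq(spacing, r_max, by = spacing)
  width <- 0.012
  r_on <- peak_position - 0.035 # excluded-volume onset
  switch_on <- 1 / (1 + exp(-(r - r_on) / 0.003))
  peak <- (peak_height - 1) * exp(-(r - peak_position)^2 / (2 * width^2))
  dr <- r - peak_position
  # oscillation amplitude scales with the peak contrast so its slope at the
  # peak never displaces the maximum by more than a fraction of a grid step
  osc <- ifelse(dr > 0,
                0.12 * (peak_height - 1) * exp(-dr / 0.12) *
                  sin(2 * pi * dr / 0.21),
                0)
  g <- switch_on * (1 + peak + osc)
  if (noise_sd > 0) g <- pmax(g + rnorm(length(g), 0, noise_sd), 0)
  rdf_curve(r, g)
}
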