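# The weighted-MAPE cost function. Each property contributes a loss
# f_i = MAPE_i(%) / 10 (a 10% mean deviation counts as a loss of 1), and the
# cost is the weighted average sum(w_i f_i) with the weights renormalized to
# sum to 1 over the included properties. Two variants: C_ECC includes the
# nuclear dielectric constant; C_G drops it, for comparing against models
# that were never meant to reproduce it.

MAPE_LOSS_SCALE <- 10 # percent of MAPE corresponding to a loss of 1

#' Mean absolute percentage error
#'
#' `100 * mean(|sim - ref| / |ref|)`, the per-property loss underlying the
#' cost function. Scale-independent, so properties on very different scales
#' (densities vs diffusion coefficients) are comparable.
#'
#' @param simulated,reference Numeric vectors of equal length; `reference`
#'   entries must be nonzero.
#' @return MAPE in percent.
#' @examples
#' mape(c(100, 110), c(100, 100)) # 5
#' @export
mape <- function(simulated, reference) {
  if (length(simulated) != length(reference))
    stop("'simulated' and 'reference' must have equal length", call. = FALSE)
  if (any(!is.finite(simulated)) || any(!is.finite(reference)))
    stop("MAPE inputs must be finite", call. = FALSE)
  if (any(reference == 0))
    stop("reference values must be nonzero for a percentage error", call. = FALSE)
  100 * mean(abs(simulated - reference) / abs(reference))
}

#' Per-property cost weights
#'
#' The default weights are those used during optimization (the C_ECC
#' weighting): density isobar 0.667, nuclear dielectric constant 0.111,
#' self-diffusion 0.111, RDF first-peak position 0.0555 and height 0.0555;
#' they sum to 1.
#'
#' @param weights Named positive numeric vector of weights.
#' @return An object of class `cost_weights`.
#' @export
cost_weights <- function(weights = c(rho_1bar = 0.667, eps_r = 0.111,
                                     D_OW = 0.111, rdf_1p = 0.0555,
                                     rdf_1h = 0.0555)) {
  if (is.null(names(weights)) || any(names(weights) == ""))
    stop("weights must be named by property", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  structure(list(weights = weights), class = "cost_weights")
}

#' Renormalize weights after excluding properties
#'
#' Drops the excluded properties and divides the remaining weights by their
#' sum so they again sum to 1. Used to derive the C_G weighting (dielectric
#' constant excluded) from the optimization weights.
#'
#' @param weights A `cost_weights` object.
#' @param exclude Character vector of property names to drop.
#' @return A `cost_weights` object whose weights sum to 1.
#' @examples
#' renormalize_weights(cost_weights(), exclude = "eps_r")
#' @export
renormalize_weights <- function(weights, exclude = character()) {
  stopifnot(inherits(weights, "cost_weights"))
  w <- weights$weights
  keep <- setdiff(names(w), exclude)
  if (!length(keep))
    stop("cannot exclude every property from the cost", call. = FALSE)
  w <- w[keep]
  cost_weights(w / sum(w))
}

#' Mark a property result as a precomputed MAPE
#'
#' Property results passed to [model_cost()] are either raw simulated
#' values (compared against the reference targets) or, via this wrapper, an
#' already-computed MAPE in percent (as printed in model performance
#' tables).
#'
#' @param x MAPE in percent (`>= 0`).
#' @return The value tagged with class `mape_pct`.
#' @export
as_mape <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop("a precomputed MAPE must be a single finite value >= 0", call. = FALSE)
  structure(x, class = "mape_pct")
}

#' Evaluate the weighted-MAPE cost of a property-result set
#'
#' For every included property, computes the MAPE of the simulated values
#' against the reference target (or takes the precomputed MAPE, see
#' [as_mape()]), converts it to a loss `MAPE% / 10`, and returns the
#' weighted sum with weights renormalized over the included properties.
#' Variant `"ecc"` includes the nuclear dielectric constant `eps_r`;
#' variant `"general"` excludes it.
#'
#' @param results Named list of property results: numeric vectors of
#'   simulated values, or `as_mape()` scalars.
#' @param reference A `reference_set` with targets for every included
#'   property (ignored for precomputed MAPEs).
#' @param weights A `cost_weights` object (pre-renormalization).
#' @param variant `"ecc"` or `"general"`.
#' @return An object of class `cost_value`: list with `cost`, `variant` and
#'   a per-property `breakdown` data frame.
#' @examples
#' ref <- reference_set()
#' res <- list(rho_1bar = ref$targets$rho_1bar$value, eps_r = 44.0,
#'             D_OW = 2.2e-5, rdf_1p = 0.281, rdf_1h = 3.1)
#' model_cost(res, ref, variant = "ecc")
#' @export
model_cost <- function(results, reference = reference_set(),
                       weights = cost_weights(),
                       variant = c("ecc", "general")) {
  variant <- match.arg(variant)
  w <- renormalize_weights(weights,
                           exclude = if (variant == "general") "eps_r"
                                     else character())
  included <- names(w$weights)
  missing <- setdiff(included, names(results))
  if (length(missing))
    stop("missing property result(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  mapes <- vapply(included, function(nm) {
    res <- results[[nm]]
    if (inherits(res, "mape_pct")) return(as.numeric(res))
    tgt <- reference$targets[[nm]]
    if (is.null(tgt))
      stop("no reference target for property '", nm, "'", call. = FALSE)
    mape(res, tgt$value)
  }, numeric(1))
  losses <- mapes / MAPE_LOSS_SCALE
  contrib <- w$weights[included] * losses
  structure(list(cost = sum(contrib),
                 variant = variant,
                 breakdown = data.frame(property = included,
                                        mape_pct = unname(mapes),
                                        weight = unname(w$weights[included]),
                                        loss = unname(losses),
                                        contribution = unname(contrib),
                                        row.names = NULL)),
            class = "cost_value")
}

#' @export
print.cost_value <- function(x, ...) {
  tag <- if (x$variant == "ecc") "C_ECC" else "C_G"
  cat(sprintf("%s = %.4f\n", tag, x$cost))
  print(x$breakdown, digits = 4)
  invisible(x)
}

#' Compare two cost values
#'
#' A candidate is better than an incumbent when it strictly lowers the cost;
#' ties keep the incumbent. Costs of different variants are not comparable.
#'
#' @param candidate,incumbent `cost_value` objects of the same variant.
#' @return `TRUE` iff `candidate$cost < incumbent$cost`.
#' @export
is_better <- function(candidate, incumbent) {
  stopifnot(inherits(candidate, "cost_value"), inherits(incumbent, "cost_value"))
  if (candidate$variant != incumbent$variant)
    stop("cannot compare costs of different variants (",
         candidate$variant, " vs ", incumbent$variant, ")", call. = FALSE)
  candidate$cost < incumbent$cost
}
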