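#' @importFrom stats optimize predict rnorm runif sd setNames
#' @importFrom utils modifyList write.csv
NULL

PARAM_NAMES <- c("sigma", "epsilon", "q_H", "d_OH", "d_OM", "theta")

#' Define a four-site rigid water model
#'
#' A TIP4P-family water model is fully defined by six scalars: the
#' Lennard-Jones parameters on the oxygen (`sigma`, `epsilon`), the hydrogen
#' partial charge `q_H` (the massless M site carries `q_M = -2 * q_H`, so the
#' molecule is neutral by construction), the O-H and O-M distances and the
#' H-O-H angle. The M site sits on the H-O-H bisector on the hydrogen side.
#'
#' @param sigma Lennard-Jones diameter on oxygen (nm).
#' @param epsilon Lennard-Jones well depth on oxygen (kJ/mol).
#' @param q_H Hydrogen partial charge (e).
#' @param d_OH Oxygen-hydrogen distance (nm).
#' @param d_OM Oxygen-virtual-site distance (nm).
#' @param theta H-O-H angle (degrees).
#' @return An object of class `water_model_params`.
#' @examples
#' water_model_params(0.3155, 0.761, 0.606, 0.0921, 0.0164, 108.74)
#' @export
water_model_params <- function(sigma, epsilon, q_H, d_OH, d_OM, theta) {
  p <- c(sigma = sigma, epsilon = epsilon, q_H = q_H,
         d_OH = d_OH, d_OM = d_OM, theta = theta)
  for (nm in PARAM_NAMES) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar", call. = FALSE)
    if (v <= 0)
      stop("parameter '", nm, "' must be strictly positive (got ", v, ")",
           call. = FALSE)
  }
  structure(as.list(p), class = "water_model_params")
}

#' @export
print.water_model_params <- function(x, ...) {
  cat("Four-site water model parameters\n")
  cat(sprintf("  sigma   %10.6f nm\n", x$sigma))
  cat(sprintf("  epsilon %10.6f kJ/mol\n", x$epsilon))
  cat(sprintf("  q_H     %10.6f e   (q_M = %.6f e)\n", x$q_H, -2 * x$q_H))
  cat(sprintf("  d_OH    %10.6f nm\n", x$d_OH))
  cat(sprintf("  d_OM    %10.6f nm\n", x$d_OM))
  cat(sprintf("  theta   %10.4f deg\n", x$theta))
  invisible(x)
}

#' Coerce model parameters to a named numeric vector
#' @param params A `water_model_params` object.
#' @return Named numeric vector in canonical order
#'   (sigma, epsilon, q_H, d_OH, d_OM, theta).
#' @export
params_as_vector <- function(params) {
  stopifnot(inherits(params, "water_model_params"))
  unlist(params[PARAM_NAMES])
}

#' Parameter-space box constraints
#'
#' Lower/upper bounds per parameter, in the same units as
#' [water_model_params()]. The defaults are the search boundaries used for
#' optimization: sigma 0.3050-0.3250 nm, epsilon 0.5-1.0 kJ/mol,
#' q_H 0.35-0.70 e, d_OH 0.090-0.100 nm, d_OM 0.012-0.018 nm,
#' theta 100-110 degrees.
#'
#' @param lower,upper Named numeric vectors over the six parameters. Missing
#'   entries take the default values.
#' @return An object of class `parameter_bounds`: a 2 x 6 matrix with rows
#'   `lower` and `upper`.
#' @export
parameter_bounds <- function(lower = NULL, upper = NULL) {
  lo <- c(sigma = 0.3050, epsilon = 0.5000, q_H = 0.3500,
          d_OH = 0.0900, d_OM = 0.0120, theta = 100.00)
  hi <- c(sigma = 0.3250, epsilon = 1.0000, q_H = 0.7000,
          d_OH = 0.1000, d_OM = 0.0180, theta = 110.00)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  lo <- lo[PARAM_NAMES]; hi <- hi[PARAM_NAMES]
  if (any(!is.finite(lo)) || any(!is.finite(hi)))
    stop("bounds must be finite", call. = FALSE)
  bad <- PARAM_NAMES[lo >= hi]
  if (length(bad))
    stop("lower bound must be below upper bound for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(rbind(lower = lo, upper = hi), class = "parameter_bounds")
}

#' Seeding parameter set for the optimization
#'
#' The midpoint-like starting values used to launch the random-walk phase.
#' @return A `water_model_params` object.
#' @export
initial_params <- function() {
  water_model_params(sigma = 0.3150, epsilon = 0.7500, q_H = 0.5500,
                     d_OH = 0.0960, d_OM = 0.0150, theta = 105.00)
}

#' Published four-site water models
#'
#' Parameter sets of ECCw2024 (a charge-scaling-compatible model with
#' dielectric constant near 45) and three reference models, TIP4P/2005,
#' TIP4P-FB and OPC (four-site variant).
#'
#' @param name One of `"eccw2024"`, `"tip4p2005"`, `"tip4pfb"`, `"opc4"`.
#' @return A `water_model_params` object.
#' @export
water_model_preset <- function(name = c("eccw2024", "tip4p2005", "tip4pfb", "opc4")) {
  name <- match.arg(tolower(name), c("eccw2024", "tip4p2005", "tip4pfb", "opc4"))
  switch(name,
    eccw2024 = water_model_params(sigma = 0.315480, epsilon = 0.761154,
                                  q_H = 0.605689, d_OH = 0.092084,
                                  d_OM = 0.016388, theta = 108.7392),
    tip4p2005 = water_model_params(sigma = 0.31589, epsilon = 0.7749,
                                   q_H = 0.5564, d_OH = 0.09572,
                                   d_OM = 0.01546, theta = 104.52),
    tip4pfb = water_model_params(sigma = 0.31655, epsilon = 0.74928,
                                 q_H = 0.52587, d_OH = 0.09572,
                                 d_OM = 0.010527, theta = 104.52),
    opc4 = water_model_params(sigma = 0.316655, epsilon = 0.89036,
                              q_H = 0.6791, d_OH = 0.08724,
                              d_OM = 0.01594, theta = 103.60))
}

#' Check model parameters against box bounds
#'
#' The optimizer rejects out-of-bounds parameters outright; standalone moment
#' or topology calculations only warn, so published models whose geometry
#' falls outside the search box (e.g. TIP4P-FB's short d_OM) remain
#' computable.
#'
#' @param params A `water_model_params` object.
#' @param bounds A `parameter_bounds` object.
#' @param action `"error"`, `"warn"` or `"none"` on violation.
#' @return Logical: `TRUE` if all parameters lie inside the bounds
#'   (invisibly when violations trigger an error).
#' @export
check_bounds <- function(params, bounds = parameter_bounds(),
                         action = c("error", "warn", "none")) {
  action <- match.arg(action)
  v <- params_as_vector(params)
  bad <- PARAM_NAMES[v < bounds["lower", ] | v > bounds["upper", ]]
  if (length(bad)) {
    msg <- paste0("parameters outside bounds: ", paste(bad, collapse = ", "))
    if (action == "error") stop(msg, call. = FALSE)
    if (action == "warn") warning(msg, call. = FALSE)
    return(FALSE)
  }
  TRUE
}

#' Map parameters to the unit hypercube and back
#'
#' The surrogate network and the differential-evolution proposals operate on
#' parameters normalized component-wise to `[0, 1]` over the search bounds:
#' `x = (p - lower) / (upper - lower)`.
#'
#' @param params A `water_model_params` object within `bounds`.
#' @param bounds A `parameter_bounds` object.
#' @return `normalize_params()`: a named numeric 6-vector in `[0, 1]`.
#' @export
normalize_params <- function(params, bounds = parameter_bounds()) {
  v <- params_as_vector(params)
  lo <- bounds["lower", ]; hi <- bounds["upper", ]
  bad <- PARAM_NAMES[v < lo | v > hi]
  if (length(bad))
    stop("cannot normalize out-of-bounds parameters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  (v - lo) / (hi - lo)
}

#' @rdname normalize_params
#' @param x A numeric 6-vector in `[0, 1]` (canonical parameter order).
#' @return `denormalize_params()`: the corresponding `water_model_params`.
#' @export
denormalize_params <- function(x, bounds = parameter_bounds()) {
  if (length(x) != 6L || any(!is.finite(x)))
    stop("normalized vector must be 6 finite values", call. = FALSE)
  if (any(x < -1e-12 | x > 1 + 1e-12))
    stop("normalized components outside [0, 1]: ",
         paste(PARAM_NAMES[x < -1e-12 | x > 1 + 1e-12], collapse = ", "),
         call. = FALSE)
  x <- pmin(pmax(x, 0), 1)
  lo <- bounds["lower", ]; hi <- bounds["upper", ]
  v <- lo + x * (hi - lo)
  do.call(water_model_params, as.list(v))
}

#' Read and write water-model parameter files
#'
#' YAML files with explicit unit-suffixed keys: `sigma_nm`, `epsilon_kjmol`,
#' `q_H_e`, `d_OH_nm`, `d_OM_nm`, `theta_deg`.
#'
#' @param path File path.
#' @return `read_params_yaml()` returns a `water_model_params` object;
#'   `write_params_yaml()` returns `path` invisibly.
#' @export
read_params_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  keys <- c("sigma_nm", "epsilon_kjmol", "q_H_e", "d_OH_nm", "d_OM_nm", "theta_deg")
  missing <- setdiff(keys, names(y))
  if (length(missing))
    stop("parameter file missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  water_model_params(sigma = y$sigma_nm, epsilon = y$epsilon_kjmol,
                     q_H = y$q_H_e, d_OH = y$d_OH_nm, d_OM = y$d_OM_nm,
                     theta = y$theta_deg)
}

#' @rdname read_params_yaml
#' @param params A `water_model_params` object.
#' @export
write_params_yaml <- function(params, path) {
  stopifnot(inherits(params, "water_model_params"))
  yaml::write_yaml(list(sigma_nm = params$sigma, epsilon_kjmol = params$epsilon,
                        q_H_e = params$q_H, d_OH_nm = params$d_OH,
                        d_OM_nm = params$d_OM, theta_deg = params$theta),
                   path)
  invisible(path)
}
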