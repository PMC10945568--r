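#' Construct the four-site geometry in the canonical molecular frame
#'
#' Places the oxygen at the origin, the H-O-H bisector along +z (pointing
#' toward the hydrogens), and the hydrogens in the xz-plane at distance
#' `d_OH` from the oxygen. The massless M site carries the negative charge
#' `-2 * q_H` and sits on the bisector at distance `d_OM` from the oxygen, on
#' the hydrogen side. The frame is fixed so that computed moments are
#' reproducible bit-for-bit.
#'
#' @param params A `water_model_params` object.
#' @return An object of class `site_geometry`: list with `labels`
#'   (O, H1, H2, M), `xyz` (4 x 3 matrix, nm), `charge` (e) and `frame`.
#' @examples
#' geom <- build_geometry(water_model_preset("tip4p2005"))
#' sqrt(sum(geom$xyz["H1", ]^2)) # = d_OH
#' @export
build_geometry <- function(params) {
  stopifnot(inherits(params, "water_model_params"))
  half <- params$theta / 2 * pi / 180
  s <- sin(half); c <- cos(half)
  xyz <- rbind(O  = c(0, 0, 0),
               H1 = c( params$d_OH * s, 0, params$d_OH * c),
               H2 = c(-params$d_OH * s, 0, params$d_OH * c),
               M  = c(0, 0, params$d_OM))
  colnames(xyz) <- c("x", "y", "z")
  structure(list(labels = rownames(xyz),
                 xyz = xyz,
                 charge = c(O = 0, H1 = params$q_H, H2 = params$q_H,
                            M = -2 * params$q_H),
                 frame = "O-origin; bisector +z; H in xz-plane"),
            class = "site_geometry")
}

#' @export
print.site_geometry <- function(x, ...) {
  cat("Four-site water geometry (", x$frame, ")\n", sep = "")
  for (i in seq_along(x$labels))
    cat(sprintf("  %-2s  (%9.6f, %9.6f, %9.6f) nm   q = %9.6f e\n",
                x$labels[i], x$xyz[i, 1], x$xyz[i, 2], x$xyz[i, 3],
                x$charge[i]))
  invisible(x)
}

#' Molecular dipole moment of a charge-neutral site set
#'
#' Computes `|sum_i q_i r_i|` and converts from e*nm to debye. For the
#' canonical four-site geometry this equals the closed form
#' `2 q_H (d_OH cos(theta/2) - d_OM)` in e*nm. The geometry must be neutral:
#' for a charged system the dipole would depend on the choice of origin.
#'
#' @param geom A `site_geometry` object.
#' @return Dipole magnitude in debye.
#' @examples
#' dipole_moment(build_geometry(water_model_preset("eccw2024"))) # ~2.168 D
#' @export
dipole_moment <- function(geom) {
  stopifnot(inherits(geom, "site_geometry"))
  if (abs(sum(geom$charge)) > 1e-12)
    stop("geometry is not charge-neutral; dipole would be origin-dependent",
         call. = FALSE)
  d <- colSums(geom$charge * geom$xyz)
  sqrt(sum(d^2)) * E_NM_TO_DEBYE
}

#' Tetrahedral quadrupole moment Q_T
#'
#' Evaluates the traceless quadrupole tensor about the oxygen,
#' `Q_ab = 1/2 sum_i q_i (3 r_a r_b - r^2 delta_ab)`, and returns the
#' in-plane anisotropy `Q_T = (Q_xx - Q_yy) / 2` with the hydrogens in the
#' xz-plane, converted to debye*angstrom. For the four-site geometry this
#' equals the closed form `(3/2) q_H (d_OH sin(theta/2))^2` (see
#' [quadrupole_qt_closed_form()]), which is independent of `d_OM` because
#' the M site lies on the z-axis.
#'
#' @param geom A `site_geometry` object in the canonical frame.
#' @return Q_T in debye*angstrom.
#' @export
quadrupole_qt <- function(geom) {
  Q <- quadrupole_tensor(geom)
  (Q["x", "x"] - Q["y", "y"]) / 2 * E_NM2_TO_DEBYE_ANGSTROM
}

#' Full traceless quadrupole tensor (e*nm^2)
#'
#' @param geom A `site_geometry` object.
#' @return 3 x 3 traceless quadrupole tensor about the origin, in e*nm^2.
#' @export
quadrupole_tensor <- function(geom) {
  stopifnot(inherits(geom, "site_geometry"))
  Q <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  for (i in seq_along(geom$charge)) {
    r <- geom$xyz[i, ]
    Q <- Q + 0.5 * geom$charge[i] * (3 * tcrossprod(r) - sum(r^2) * diag(3))
  }
  Q
}

#' @rdname quadrupole_qt
#' @param params A `water_model_params` object.
#' @export
quadrupole_qt_closed_form <- function(params) {
  stopifnot(inherits(params, "water_model_params"))
  s <- sin(params$theta / 2 * pi / 180)
  1.5 * params$q_H * (params$d_OH * s)^2 * E_NM2_TO_DEBYE_ANGSTROM
}

#' Molecular dipole and tetrahedral quadrupole of a model
#'
#' @param params A `water_model_params` object.
#' @return List with `mu` (debye) and `q_t` (debye*angstrom).
#' @examples
#' molecular_moments(water_model_preset("tip4p2005"))
#' @export
molecular_moments <- function(params) {
  geom <- build_geometry(params)
  list(mu = dipole_moment(geom), q_t = quadrupole_qt(geom))
}

#' Apply a rigid motion to a site geometry
#'
#' Rotates and translates all sites; charges are unchanged. Used to verify
#' frame-independence of the dipole magnitude. The `frame` tag is dropped
#' because the result is generally no longer canonical.
#'
#' @param geom A `site_geometry` object.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 numeric vector (nm).
#' @return A transformed `site_geometry`.
#' @export
transform_geometry <- function(geom, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(geom, "site_geometry"))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("'rotation' must be orthogonal", call. = FALSE)
  out <- geom
  out$xyz <- geom$xyz %*% t(rotation) +
    matrix(translation, nrow(geom$xyz), 3, byrow = TRUE)
  out$frame <- "transformed"
  out
}

#' Electronic continuum correction (ECC) charge scaling
#'
#' Immersing a force field in an electronic dielectric continuum of
#' permittivity `eps_e` is equivalent to scaling ionic charges by
#' `1 / sqrt(eps_e)`. For water, `eps_e` is approximated by the squared
#' refractive index, about 1.78, giving a scaling factor of about 0.75.
#'
#' @param q Charge (e).
#' @param eps_e Electronic (high-frequency) dielectric constant, `>= 1`.
#' @return Scaled charge `q / sqrt(eps_e)`.
#' @examples
#' scale_charge(1.0, 1.78)
#' @export
scale_charge <- function(q, eps_e = 1.78) {
  if (!is.numeric(eps_e) || length(eps_e) != 1L || !is.finite(eps_e) || eps_e < 1)
    stop("'eps_e' must be a finite scalar >= 1", call. = FALSE)
  q / sqrt(eps_e)
}
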