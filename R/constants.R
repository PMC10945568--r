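# Physical constants (CODATA 2018) and unit conversions used throughout.
# Internal unit system: nm, e, degrees, kJ/mol; moments reported in D, D*A.

ELEMENTARY_CHARGE_C <- 1.602176634e-19 # C
DEBYE_CM <- 1e-21 / 299792458 # C*m, definition of the debye
BOLTZMANN_J_K <- 1.380649e-23 # J/K

#' Unit conversion: 1 e*nm in debye
#'
#' Single named constant used for every dipole conversion, so that reported
#' moments are reproducible bit-for-bit.
#' @keywords internal
E_NM_TO_DEBYE <- ELEMENTARY_CHARGE_C * 1e-9 / DEBYE_CM

# 1 e*nm^2 in debye*angstrom (quadrupole conversion)
E_NM2_TO_DEBYE_ANGSTROM <- E_NM_TO_DEBYE * 10

# Self-interaction term of a point particle with its periodic images in a
# cubic lattice; enters the Yeh-Hummer finite-size diffusion correction.
XI_CUBIC <- 2.837297
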