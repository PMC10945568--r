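# GROMACS export: a rigid four-site water .itp (SETTLE constraints + a
# type-1 three-body virtual site for M) and a run-settings template carrying
# the NpT protocol the models are meant to be simulated with.

#' Write a GROMACS topology for a four-site water model
#'
#' Emits an `.itp` molecule-type file: oxygen Lennard-Jones atom type,
#' hydrogen charges `q_H`, a massless M site with charge `-2 q_H`, SETTLE
#' rigid constraints (d_OH and the H-H distance `2 d_OH sin(theta/2)`), and a
#' type-1 three-body virtual site placing M on the H-O-H bisector at `d_OM`
#' from the oxygen: `r_M = r_O + a (r_H1 - r_O) + a (r_H2 - r_O)` with
#' `a = d_OM / (2 d_OH cos(theta/2))`.
#'
#' @param params A `water_model_params` object.
#' @param path Output `.itp` path.
#' @param molecule_name Molecule type name (default `"SOL"`).
#' @return `path`, invisibly.
#' @seealso [read_topology()] for the inverse, [write_mdp_template()] for the
#'   matching run settings.
#' @export
write_topology <- function(params, path, molecule_name = "SOL") {
  stopifnot(inherits(params, "water_model_params"))
  half <- params$theta / 2 * pi / 180
  d_HH <- 2 * params$d_OH * sin(half)
  a <- params$d_OM / (2 * params$d_OH * cos(half))
  q_H <- params$q_H
  lines <- c(
    "; Four-site rigid water model topology",
    sprintf("; d_OH = %.8f nm, d_OM = %.8f nm, theta = %.6f deg", params$d_OH, params$d_OM, params$theta),
    "",
    "[ atomtypes ]",
    ";name  at.num   mass      charge   ptype    sigma(nm)      epsilon(kJ/mol)",
    sprintf("OW_m    8      15.99940   0.0000   A    %.8f   %.8f", params$sigma, params$epsilon),
    "HW_m    1       1.00800   0.0000   A    0.00000000   0.00000000",
    "MW_m    0       0.00000   0.0000   D    0.00000000   0.00000000",
    "",
    "[ moleculetype ]",
    "; name   nrexcl",
    sprintf("%s      2", molecule_name),
    "",
    "[ atoms ]",
    ";nr  type    resnr  res   atom  cgnr   charge       mass",
    sprintf("1    OW_m    1      %s   OW    1    %11.8f   15.99940", molecule_name, 0),
    sprintf("2    HW_m    1      %s   HW1   1    %11.8f    1.00800", molecule_name, q_H),
    sprintf("3    HW_m    1      %s   HW2   1    %11.8f    1.00800", molecule_name, q_H),
    sprintf("4    MW_m    1      %s   MW    1    %11.8f    0.00000", molecule_name, -2 * q_H),
    "",
    "[ settles ]",
    "; i  funct  doh          dhh",
    sprintf("1    1    %.8f   %.8f", params$d_OH, d_HH),
    "",
    "[ virtual_sites3 ]",
    "; site  from               funct   a            b",
    sprintf("4       1     2     3      1    %.8f   %.8f", a, a),
    "",
    "[ exclusions ]",
    "1  2  3  4",
    "2  1  3  4",
    "3  1  2  4",
    "4  1  2  3",
    "")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing: ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Re-parse a topology written by [write_topology()]
#'
#' Recovers the six defining parameters from the emitted `.itp` sections:
#' `sigma`/`epsilon` from `[ atomtypes ]`, `q_H` from `[ atoms ]`, `d_OH` and
#' the H-H distance (hence `theta`) from `[ settles ]`, and `d_OM` from the
#' virtual-site coefficient.
#'
#' @param path An `.itp` file produced by [write_topology()].
#' @return A `water_model_params` object.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  section <- ""
  sigma <- epsilon <- q_H <- d_OH <- d_HH <- a <- NA_real_
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      section <- gsub("[][ ]", "", ln)
      next
    }
    tok <- strsplit(ln, "\\s+")[[1]]
    if (section == "atomtypes" && tok[1] == "OW_m") {
      sigma <- as.numeric(tok[6]); epsilon <- as.numeric(tok[7])
    } else if (section == "atoms" && tok[5] == "HW1") {
      q_H <- as.numeric(tok[7])
    } else if (section == "settles") {
      d_OH <- as.numeric(tok[3]); d_HH <- as.numeric(tok[4])
    } else if (section == "virtual_sites3") {
      a <- as.numeric(tok[6])
    }
  }
  if (anyNA(c(sigma, epsilon, q_H, d_OH, d_HH, a)))
    stop("file does not look like a topology written by write_topology()",
         call. = FALSE)
  theta <- 2 * asin(d_HH / (2 * d_OH)) * 180 / pi
  d_OM <- a * 2 * d_OH * cos(theta / 2 * pi / 180)
  water_model_params(sigma = sigma, epsilon = epsilon, q_H = q_H,
                     d_OH = d_OH, d_OM = d_OM, theta = theta)
}

#' Write the NpT run-settings template
#'
#' A GROMACS `.mdp` file recording the simulation protocol the property
#' targets assume: 832 water molecules in a cubic box, PME electrostatics and
#' Lennard-Jones with a 1.2 nm cutoff, 2 fs leapfrog integration, the
#' Nose-Hoover thermostat (relaxation 1.0 ps) and the Parrinello-Rahman
#' barostat (relaxation 5.0 ps, compressibility 5e-5 1/bar). This package
#' never runs a molecular dynamics engine; the template is an exchange
#' artifact for external evaluation.
#'
#' @param path Output `.mdp` path.
#' @param temperature_K Reference temperature (default 300 K).
#' @param pressure_bar Reference pressure (default 1 bar).
#' @param nsteps Number of integration steps (default 10,500,000 = 21 ns).
#' @return `path`, invisibly.
#' @export
write_mdp_template <- function(path, temperature_K = 300, pressure_bar = 1,
                               nsteps = 10500000) {
  lines <- c(
    "; NpT production protocol for four-site water property evaluation",
    "; system: 832 water molecules, cubic box",
    "integrator               = md",
    "dt                       = 0.002",
    sprintf("nsteps                   = %d", as.integer(nsteps)),
    "cutoff-scheme            = Verlet",
    "coulombtype              = PME",
    "rcoulomb                 = 1.2",
    "vdwtype                  = PME",
    "rvdw                     = 1.2",
    "tcoupl                   = nose-hoover",
    "tc-grps                  = System",
    "tau-t                    = 1.0",
    sprintf("ref-t                    = %g", temperature_K),
    "pcoupl                   = parrinello-rahman",
    "tau-p                    = 5.0",
    "compressibility          = 5e-05",
    sprintf("ref-p                    = %g", pressure_bar),
    "constraints              = none",
    "")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing: ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
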