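# Physical constants and element data. All calculations run in Hartree atomic
# units; coordinates cross the user boundary in Angstrom and are converted to
# bohr exactly once, in basis_shells()/as_bohr().

#: CODATA 2018 where not stated otherwise.
.const <- list(
  bohr_A     = 0.529177210903,    # Angstrom per bohr
  mu0        = 1.25663706212e-06, # vacuum permeability, N A^-2
  mu_B       = 9.2740100783e-24,  # Bohr magneton, J/T
  mu_N       = 5.0507837461e-27,  # nuclear magneton, J/T
  h_planck   = 6.62607015e-34,    # J s
  g_e        = 2.0022319          # free-electron g-factor as used here
)

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"
)

# Standard atomic weights (amu), for centres of mass.
.element_masses <- c(
  1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.948
)

# Bragg-Slater-like atomic radii (Angstrom) for Becke grid mapping.
.element_radii <- c(
  0.35, 0.31, 1.45, 1.05, 0.85, 0.70, 0.65, 0.60, 0.50, 0.38,
  1.80, 1.50, 1.25, 1.10, 1.00, 1.00, 1.00, 0.71
)

element_number <- function(symbol) {
  z <- match(symbol, .element_symbols)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(z)]), collapse = ", "))
  }
  z
}

element_mass <- function(symbol) .element_masses[element_number(symbol)]

#' Convert Angstrom coordinates to bohr
#'
#' The single documented unit boundary of the package: all user-facing
#' geometry is in Angstrom, everything internal is in Hartree atomic units.
#'
#' @param x numeric vector or matrix of coordinates in Angstrom.
#' @return The same object in bohr.
#' @export
as_bohr <- function(x) x / .const$bohr_A

#' @rdname as_bohr
#' @export
as_angstrom <- function(x) x * .const$bohr_A
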