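# Fermi-contact hyperfine couplings: spin density at the nuclei and
# isotropic coupling constants in Gauss.
#
# Unit chain (documented step by step): the spin density rho^{alpha-beta} at
# the nucleus is computed in atomic units (bohr^-3) and converted to SI
# (m^-3) with a0. The Fermi-contact energy prefactor is
#   A = (2 mu0 / 3) * g_e mu_B * g_X mu_N * rho / (2<S_z>)   [J]
# (equivalently the (8 pi / 3) form with the 1/(4 pi) of SI electrostatics
# absorbed into mu0), and the conventional EPR value in field units divides
# by g_e mu_B per Gauss:
#   A[G] = A[J] / (g_e * mu_B * 1e-4).
# The hydrogen-atom closed form pins this convention: an exact 1s density
# 1/pi a0^-3 gives 507.7 G.

isotope_table <- function() {
  read_param_csv("isotopes.csv")
}

default_isotope <- function(element) {
  tab <- isotope_table()
  i <- match(element, tab$element)
  if (anyNA(i)) {
    stop("no default isotope for element(s) ",
         paste(unique(element[is.na(i)]), collapse = ", "),
         "; available: ", paste(tab$isotope, collapse = ", "))
  }
  tab$isotope[i]
}

#' Spin density at nuclear positions
#'
#' Evaluates rho(R_X) = sum_{mu nu} (D^alpha - D^beta)_{mu nu}
#' chi_mu(R_X) chi_nu(R_X) at the requested nuclei, using the TOTAL spin
#' density (active plus inactive blocks).
#'
#' @param D_alpha,D_beta AO density matrices of the whole system.
#' @param system the [atomic_system()].
#' @param nuclei integer atom indices; default all atoms.
#' @param engine optional [scf_engine()] for its shell list.
#' @return Numeric vector of spin densities (bohr^-3), named by atom index.
#' @export
spin_density_at_nuclei <- function(D_alpha, D_beta, system, nuclei = NULL,
                                   engine = NULL) {
  nat <- nrow(system$atoms)
  if (is.null(nuclei)) nuclei <- seq_len(nat)
  if (any(nuclei < 1L | nuclei > nat)) stop("nucleus index out of range")
  shells <- if (!is.null(engine)) engine$shells else basis_shells(system)
  pts <- as_bohr(coords_of(system))[nuclei, , drop = FALSE]
  X <- cpp_ao_values(shells, pts, FALSE)$val
  Dspin <- D_alpha - D_beta
  setNames(rowSums((X %*% Dspin) * X), nuclei)
}

#' Isotropic hyperfine coupling constant from a spin density
#'
#' Fermi-contact coupling in Gauss for one nucleus. The free-electron
#' g-factor is fixed at 2.0022319; nuclear g-factors come from the shipped
#' isotope table.
#'
#' @param rho_X spin density at the nucleus (bohr^-3).
#' @param isotope isotope label, e.g. `"14N"`, `"1H"`.
#' @param spin_expectation <S_z> of the total system, (n_alpha - n_beta)/2.
#' @return A_X in Gauss, with attribute `constants_used`.
#' @export
hyperfine_constant <- function(rho_X, isotope, spin_expectation) {
  tab <- isotope_table()
  i <- match(isotope, tab$isotope)
  if (is.na(i)) {
    stop("unknown isotope '", isotope, "'; available: ",
         paste(tab$isotope, collapse = ", "))
  }
  if (spin_expectation == 0) stop("spin_expectation must be non-zero")
  gX <- tab$g_factor[i]
  k <- .const
  rho_SI <- rho_X / (k$bohr_A * 1e-10)^3
  A_J <- (2 * k$mu0 / 3) * (k$g_e * k$mu_B) * (gX * k$mu_N) * rho_SI /
    (2 * spin_expectation)
  A_G <- A_J / (k$g_e * k$mu_B * 1e-4)
  structure(A_G, constants_used = list(
    g_e = k$g_e, mu_B_J_per_T = k$mu_B, mu_N_J_per_T = k$mu_N,
    g_X = gX, isotope = isotope, mu0 = k$mu0,
    source = "CODATA 2018 constants; g_e as adopted here; nuclear g from shipped table"))
}

#' Hyperfine couplings of a converged calculation
#'
#' Computes per-nucleus spin densities and isotropic couplings from any
#' converged result carrying `D_alpha`/`D_beta` (a full [full_scf()] result
#' or a multilevel [uml_scf()] result). By convention couplings are
#' reported for active atoms; requesting an inactive nucleus is legitimate
#' (the quantity is defined) but warns, since the frozen block is not
#' variationally relaxed there.
#'
#' The traceless dipolar tensor, which averages to zero in isotropic media,
#' is reported as an explicit zero placeholder per nucleus.
#'
#' @param result an object with `D_alpha`, `D_beta`, and `system`.
#' @param nuclei atom indices; defaults to the active atoms for multilevel
#'   results, all atoms otherwise.
#' @param isotopes isotope label per nucleus; defaults per element.
#' @param engine optional [scf_engine()].
#' @return Object of class `hyperfine_result`: a data.frame with element,
#'   position, spin density and `A_iso` (Gauss).
#' @export
hyperfine <- function(result, nuclei = NULL, isotopes = NULL, engine = NULL) {
  system <- result$system
  if (is.null(nuclei)) {
    nuclei <- if (!is.null(result$partition)) result$partition$active_atoms
              else seq_len(nrow(system$atoms))
  }
  if (!is.null(result$partition) &&
      length(setdiff(nuclei, result$partition$active_atoms)) > 0) {
    warning("hyperfine coupling requested for inactive nuclei; ",
            "values are defined but the inactive block is frozen")
  }
  el <- system$atoms$element[nuclei]
  if (is.null(isotopes)) isotopes <- default_isotope(el)
  Sz <- (result$system$n_alpha - result$system$n_beta) / 2
  rho <- spin_density_at_nuclei(result$D_alpha, result$D_beta, system,
                                nuclei = nuclei, engine = engine)
  A <- vapply(seq_along(nuclei), function(i) {
    # a vanishing spin density carries a vanishing contact coupling, also in
    # the closed-shell case where <S_z> = 0
    if (rho[[i]] == 0) 0 else
      as.numeric(hyperfine_constant(rho[i], isotopes[i], Sz))
  }, numeric(1))
  out <- data.frame(
    atom = nuclei, element = el, isotope = isotopes,
    x = system$atoms$x[nuclei], y = system$atoms$y[nuclei],
    z = system$atoms$z[nuclei],
    rho_spin = as.numeric(rho), A_iso = A
  )
  structure(list(table = out, spin_expectation = Sz,
                 A_dip = replicate(length(nuclei), matrix(0, 3, 3),
                                   simplify = FALSE)),
            class = "hyperfine_result")
}

#' @export
print.hyperfine_result <- function(x, ...) {
  cat("<hyperfine_result> (A_iso in Gauss, rho in bohr^-3)\n")
  print(x$table[, c("atom", "element", "isotope", "rho_spin", "A_iso")],
        row.names = FALSE)
  invisible(x)
}
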