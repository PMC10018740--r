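# Classical embedding layers: nonpolarizable point charges and the
# polarizable fluctuating-charge (FQ) model with per-fragment total-charge
# constraints.

read_param_csv <- function(file) {
  read.csv(system.file("extdata", file, package = "mlscf"),
           comment.char = "#", stringsAsFactors = FALSE)
}

#' Classical embedding layers
#'
#' `fixed_charge_layer()` builds a nonpolarizable layer; charges come either
#' from `charges` or from a named preset (`"tip3p-charges"`) looked up by
#' element. `fq_layer()` builds a polarizable fluctuating-charge layer where
#' each site carries an electronegativity chi and hardness eta (atomic
#' units) and each fragment (e.g. each water molecule) conserves its total
#' charge `Q` (default 0).
#'
#' @param positions n x 3 matrix of site positions in Angstrom.
#' @param elements element symbol per site (needed for parameter lookup).
#' @param charges explicit fixed charges (e) per site.
#' @param preset named fixed-charge set shipped with the package.
#' @param fragment integer fragment id per site.
#' @param params named FQ parameter set shipped with the package
#'   (`"water-radical"`), or a data.frame with columns element, chi, eta.
#' @param chi,eta explicit per-site values (override `params`).
#' @param Q per-fragment total charge; scalar or named by fragment id.
#' @return Object of class `embedding_layer`.
#' @export
fixed_charge_layer <- function(positions, elements = NULL, charges = NULL,
                               preset = "tip3p-charges", fragment = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- nrow(positions)
  if (is.null(charges)) {
    if (is.null(elements)) stop("need elements for preset charge lookup")
    tab <- read_param_csv("fixed-charges.csv")
    tab <- tab[tab$set == preset, ]
    if (nrow(tab) == 0L) stop("unknown fixed-charge preset '", preset, "'")
    charges <- tab$charge[match(elements, tab$element)]
    if (anyNA(charges)) stop("preset '", preset, "' lacks an element present in the layer")
  }
  if (length(charges) != n) stop("one charge per site required")
  if (is.null(fragment)) fragment <- rep(1L, n)
  structure(list(
    sites = data.frame(x = positions[, 1], y = positions[, 2],
                       z = positions[, 3],
                       element = elements %||% rep(NA_character_, n),
                       kind = "fixed", q = charges,
                       chi = NA_real_, eta = NA_real_,
                       fragment = as.integer(fragment)),
    fragment_Q = NULL, polarizable = FALSE
  ), class = "embedding_layer")
}

#' @rdname fixed_charge_layer
#' @export
fq_layer <- function(positions, elements, fragment, params = "water-radical",
                     chi = NULL, eta = NULL, Q = 0) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- nrow(positions)
  if (length(elements) != n || length(fragment) != n) {
    stop("elements and fragment must have one entry per site")
  }
  if (is.null(chi) || is.null(eta)) {
    tab <- if (is.data.frame(params)) params else {
      t0 <- read_param_csv("fq-params.csv")
      t0 <- t0[t0$set == params, ]
      if (nrow(t0) == 0L) stop("unknown FQ parameter set '", params, "'")
      t0
    }
    m <- match(elements, tab$element)
    if (anyNA(m)) stop("FQ parameters missing for some elements")
    if (is.null(chi)) chi <- tab$chi[m]
    if (is.null(eta)) eta <- tab$eta[m]
  }
  if (any(eta <= 0)) stop("chemical hardness eta must be positive")
  frag_ids <- sort(unique(as.integer(fragment)))
  Qv <- if (length(Q) == 1L) setNames(rep(Q, length(frag_ids)), frag_ids)
        else setNames(Q[as.character(frag_ids)], frag_ids)
  structure(list(
    sites = data.frame(x = positions[, 1], y = positions[, 2],
                       z = positions[, 3], element = elements,
                       kind = "fq", q = NA_real_,
                       chi = chi, eta = eta, fragment = as.integer(fragment)),
    fragment_Q = Qv, polarizable = TRUE
  ), class = "embedding_layer")
}

#' @export
print.embedding_layer <- function(x, ...) {
  cat(sprintf("<embedding_layer: %d sites (%s), %d fragment(s)>\n",
              nrow(x$sites), if (x$polarizable) "fluctuating charges" else "fixed charges",
              length(unique(x$sites$fragment))))
  invisible(x)
}

site_positions_bohr <- function(layer) {
  as_bohr(as.matrix(layer$sites[, c("x", "y", "z")]))
}

#' Electrostatic potential of the QM system at classical sites
#'
#' Total potential (atomic units) generated by the QM nuclei and the full
#' electron density (active plus inactive blocks) at each site. The nuclear
#' term can be switched off (`include_nuclear = FALSE`) for a strict
#' density-only potential.
#'
#' @param density a [spin_density()] (or any list with `D_alpha`, `D_beta`).
#' @param system the [atomic_system()] the density belongs to.
#' @param sites n x 3 matrix of positions in Angstrom, or an
#'   [fq_layer()] or [fixed_charge_layer()].
#' @param include_nuclear include the nuclear Coulomb term (default TRUE).
#' @param engine optional [scf_engine()] (for its shell list).
#' @return Numeric vector of potentials, one per site (Hartree/e).
#' @export
qm_potential_at_sites <- function(density, system, sites,
                                  include_nuclear = TRUE, engine = NULL) {
  pts <- if (inherits(sites, "embedding_layer")) site_positions_bohr(sites)
         else as_bohr(matrix(as.numeric(sites), ncol = 3))
  shells <- if (!is.null(engine)) engine$shells else basis_shells(system)
  nuc <- as_bohr(coords_of(system))
  for (k in seq_len(nrow(pts))) {
    d2 <- rowSums((nuc - matrix(pts[k, ], nrow(nuc), 3, byrow = TRUE))^2)
    if (any(d2 < 1e-12)) {
      stop("site ", k, " coincides with a nucleus")
    }
  }
  V <- -cpp_esp_electronic(shells, density$D_alpha + density$D_beta, pts)
  if (include_nuclear) {
    for (k in seq_len(nrow(pts))) {
      r <- sqrt(rowSums((nuc - matrix(pts[k, ], nrow(nuc), 3, byrow = TRUE))^2))
      V[k] <- V[k] + sum(system$atoms$Z / r)
    }
  }
  V
}

# Ohno-damped Coulomb kernel between FQ sites (a.u.): diagonal eta_i,
# off-diagonal etabar / sqrt(1 + etabar^2 r^2) with etabar the geometric
# mean of the two hardnesses. Swappable: pass a different `kernel` to
# solve_fq for other conventions.
fq_kernel_ohno <- function(layer) {
  pts <- site_positions_bohr(layer)
  eta <- layer$sites$eta
  r <- as.matrix(dist(pts))
  eb <- sqrt(outer(eta, eta))
  J <- eb / sqrt(1 + (eb * r)^2)
  diag(J) <- eta
  J
}

#' Solve the fluctuating-charge equations
#'
#' Minimizes the FQ energy functional
#' \deqn{E(q) = \chi^T q + \tfrac12 q^T J q + q^T V}
#' subject to one total-charge constraint per fragment, by direct solution
#' of the symmetric saddle-point system (charges + one Lagrange multiplier
#' per fragment).
#'
#' @param layer an [fq_layer()].
#' @param external_potential per-site potential from the QM region (a.u.);
#'   defaults to zero.
#' @param kernel function(layer) returning the site-site interaction matrix;
#'   defaults to the Ohno form.
#' @return Object of class `fq_solution`: charges `q`, multipliers `lambda`
#'   (one per fragment), polarization energy `E_pol` (the minimized
#'   functional value, Hartree), and the stationarity `residual`.
#' @export
solve_fq <- function(layer, external_potential = NULL,
                     kernel = fq_kernel_ohno) {
  if (!layer$polarizable) stop("solve_fq needs a fluctuating-charge layer")
  n <- nrow(layer$sites)
  V <- external_potential %||% rep(0, n)
  if (length(V) != n) stop("external_potential length mismatch")
  J <- kernel(layer)
  frag <- layer$sites$fragment
  frag_ids <- sort(unique(frag))
  nf <- length(frag_ids)
  C <- matrix(0, nf, n)
  for (i in seq_len(nf)) C[i, frag == frag_ids[i]] <- 1
  M <- rbind(cbind(J, t(C)), cbind(C, matrix(0, nf, nf)))
  rhs <- c(-(layer$sites$chi + V), unname(layer$fragment_Q[as.character(frag_ids)]))
  sol <- tryCatch(solve(M, rhs), error = function(e) {
    stop("FQ kernel is singular (fragments ",
         paste(frag_ids, collapse = ", "), "): ", conditionMessage(e))
  })
  q <- unname(sol[seq_len(n)])
  lambda <- unname(sol[n + seq_len(nf)])
  resid <- max(abs(J %*% q + layer$sites$chi + V + as.vector(t(C) %*% lambda)))
  E_pol <- sum(layer$sites$chi * q) + 0.5 * sum(q * (J %*% q)) + sum(V * q)
  structure(list(q = q, lambda = setNames(lambda, frag_ids),
                 E_pol = E_pol, residual = resid),
            class = "fq_solution")
}

#' Electrostatic coupling energy between potential and charges
#'
#' @param V per-site potentials (a.u.).
#' @param q per-site charges (e).
#' @return `sum(V * q)` in Hartree.
#' @export
embedding_interaction_energy <- function(V, q) {
  if (length(V) != length(q)) stop("V and q length mismatch")
  sum(V * q)
}

#' One-electron Fock contribution of the classical charges
#'
#' The charge-field operator added identically to the alpha and beta Fock
#' matrices. For a fixed layer this is built once per geometry; for an FQ
#' layer it is rebuilt every SCF cycle with the re-equilibrated charges.
#'
#' @param layer an [fq_layer()] or [fixed_charge_layer()].
#' @param q charges to use; defaults to the fixed charges stored in `layer`.
#' @param system an [atomic_system()] (or pass `engine`).
#' @param engine optional [scf_engine()].
#' @return AO matrix (same for both spins).
#' @export
embedding_fock <- function(layer, q = NULL, system = NULL, engine = NULL) {
  shells <- if (!is.null(engine)) engine$shells else basis_shells(system)
  q <- q %||% layer$sites$q
  if (anyNA(q)) stop("no charges available; solve the FQ layer first")
  cpp_charge_operator(shells, site_positions_bohr(layer), q)
}

# ---- embedding bookkeeping used by the SCF drivers -------------------------
# state: list(layer, H (AO operator), E (energy contribution), q, V)

embedding_state <- function(layer, engine) {
  if (is.null(layer)) return(list(layer = NULL, H = NULL, E = 0, q = NULL))
  list(layer = layer, H = NULL, E = 0, q = NULL, engine = engine)
}

embedding_update <- function(state, engine, D_total) {
  if (is.null(state$layer)) return(state)
  layer <- state$layer
  dens <- list(D_alpha = D_total / 2, D_beta = D_total / 2)
  V <- qm_potential_at_sites(dens, engine$system, layer, engine = engine)
  if (layer$polarizable) {
    fq <- solve_fq(layer, external_potential = V)
    q <- fq$q
    # full FQ functional: coupling + internal chi/J terms
    state$E <- fq$E_pol
    state$q <- q
    state$H <- embedding_fock(layer, q = q, engine = engine)
  } else {
    q <- layer$sites$q
    state$E <- embedding_interaction_energy(V, q)
    state$q <- q
    if (is.null(state$H)) state$H <- embedding_fock(layer, engine = engine)
  }
  state$V <- V
  state
}
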