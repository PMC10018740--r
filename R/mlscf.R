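# The multilevel SCF itself: frozen inactive contributions, the multilevel
# Fock and energy decomposition, and self-consistent optimization of the
# active block in the frozen field of the inactive block.

#' Precompute frozen contributions of the inactive density
#'
#' The inactive block never changes during the multilevel SCF, so its
#' Coulomb and (scaled) exact-exchange Fock contributions and its energy
#' are computed once. The inactive densities themselves are stored for the
#' nonadditive exchange-correlation terms evaluated on the shared grid.
#'
#' @param engine an [scf_engine()].
#' @param partitioned a `partitioned_density` from [partition_densities()].
#' @param functional a [functional_spec()].
#' @return Object of class `frozen_inactive`: per-spin `twoe_B` matrices,
#'   constant energy `E_B_const` (inactive electronic energy + nuclear
#'   repulsion), the inactive xc energy, the stored inactive densities, and
#'   an md5 `hash` of the frozen matrices.
#' @export
frozen_inactive_terms <- function(engine, partitioned, functional) {
  chk <- check_partition(partitioned)
  if (chk$max_violation > 1e-7) {
    stop("partitioned density violates its invariants")
  }
  DBa <- partitioned$D_B_alpha; DBb <- partitioned$D_B_beta
  DBt <- DBa + DBb
  JB <- coulomb_matrix(engine, DBt)
  KBa <- exchange_matrix(engine, DBa)
  KBb <- exchange_matrix(engine, DBb)
  twoe_B_alpha <- JB - functional$c_x * KBa
  twoe_B_beta <- JB - functional$c_x * KBb
  xcB <- xc_contrib(engine, functional, DBa, DBb)
  E_B <- sum(DBt * engine$h) + 0.5 * sum(DBt * JB) -
    0.5 * functional$c_x * (sum(DBa * KBa) + sum(DBb * KBb)) + xcB$E
  structure(list(
    twoe_B_alpha = twoe_B_alpha, twoe_B_beta = twoe_B_beta,
    E_B = E_B, E_B_const = E_B + engine$E_nn, E_xc_B = xcB$E,
    D_B_alpha = DBa, D_B_beta = DBb,
    hash = object_hash(list(twoe_B_alpha, twoe_B_beta))
  ), class = "frozen_inactive")
}

#' Multilevel Fock matrices
#'
#' Differentiating the multilevel energy with respect to the active density
#' gives, per spin, F = h + 2e_A(D_A) + 2e_B + 2e_nonadd: the active
#' Coulomb/exchange terms, the frozen inactive contribution, and the
#' nonadditive xc potential. Grouping the xc pieces, the xc potential that
#' enters is v_xc evaluated at the total density; the nonadditive operator
#' (and hence the distinction from plain embedding) vanishes for pure HF.
#'
#' @param engine an [scf_engine()].
#' @param D_A_alpha,D_A_beta active density blocks.
#' @param frozen a [frozen_inactive_terms()] result.
#' @param functional a [functional_spec()].
#' @return List with `F_alpha`, `F_beta` and an `energy_breakdown`
#'   (named numeric: E_A, E_B, E_int, E_nonadd, E_nn, E_total).
#' @export
build_ml_fock <- function(engine, D_A_alpha, D_A_beta, frozen, functional) {
  ml_fock_energy(engine, D_A_alpha, D_A_beta, frozen, functional)[
    c("F_alpha", "F_beta")]
}

# Fock build plus the running total energy, sharing intermediates. The xc
# energy of the active density alone cancels between E_A and E_nonadd, so
# one grid pass (total density) per cycle suffices:
#   E_total = E_A0 + E_B0 + E_int + E_xc[rho_tot] + E_nn
# with E_X0 the xc-free block energies.
ml_fock_energy <- function(engine, D_A_alpha, D_A_beta, frozen, functional) {
  DAt <- D_A_alpha + D_A_beta
  cx <- functional$c_x
  JA <- coulomb_matrix(engine, DAt)
  KAa <- exchange_matrix(engine, D_A_alpha)
  KAb <- exchange_matrix(engine, D_A_beta)
  Fa <- engine$h + JA - cx * KAa + frozen$twoe_B_alpha
  Fb <- engine$h + JA - cx * KAb + frozen$twoe_B_beta
  E_xc_tot <- 0
  if (functional$is_dft) {
    xcT <- xc_contrib(engine, functional,
                      D_A_alpha + frozen$D_B_alpha,
                      D_A_beta + frozen$D_B_beta)
    Fa <- Fa + xcT$Va
    Fb <- Fb + xcT$Vb
    E_xc_tot <- xcT$E
  }
  E_A0 <- sum(DAt * engine$h) + 0.5 * sum(DAt * JA) -
    0.5 * cx * (sum(D_A_alpha * KAa) + sum(D_A_beta * KAb))
  E_int <- sum(D_A_alpha * frozen$twoe_B_alpha) +
    sum(D_A_beta * frozen$twoe_B_beta)
  E <- E_A0 + (frozen$E_B - frozen$E_xc_B) + E_int + E_xc_tot + engine$E_nn
  list(F_alpha = sym(Fa), F_beta = sym(Fb), E_total = E)
}

#' Multilevel energy decomposition
#'
#' Total energy split into an active term E_A, an inactive term E_B, the
#' Coulomb/exact-exchange interaction E_int (evaluated once via the trace
#' symmetry Tr D_A G(D_B) = Tr D_B G(D_A)), the nonadditive xc coupling
#' `E_nonadd = E_xc[rho_A + rho_B] - E_xc[rho_A] - E_xc[rho_B]`, and nuclear
#' repulsion. One-electron (kinetic + full nuclear attraction) energies of
#' each block are booked inside E_A and E_B respectively; the split of
#' nuclear terms between E_B and E_int is a bookkeeping convention -- the
#' total is exact and is the tested contract. E_nonadd is identically zero
#' for pure Hartree-Fock.
#'
#' @param engine an [scf_engine()].
#' @param partitioned a `partitioned_density`.
#' @param functional a [functional_spec()].
#' @param frozen optional [frozen_inactive_terms()] (reused when given).
#' @return Named numeric vector with components E_A, E_B, E_int, E_nonadd,
#'   E_nn, E_total.
#' @export
ml_energy <- function(engine, partitioned, functional, frozen = NULL) {
  DAa <- partitioned$D_A_alpha; DAb <- partitioned$D_A_beta
  DBa <- partitioned$D_B_alpha; DBb <- partitioned$D_B_beta
  DAt <- DAa + DAb; DBt <- DBa + DBb
  cx <- functional$c_x
  JA <- coulomb_matrix(engine, DAt)
  KAa <- exchange_matrix(engine, DAa)
  KAb <- exchange_matrix(engine, DAb)
  xcA <- xc_contrib(engine, functional, DAa, DAb)
  E_A <- sum(DAt * engine$h) + 0.5 * sum(DAt * JA) -
    0.5 * cx * (sum(DAa * KAa) + sum(DAb * KAb)) + xcA$E
  if (is.null(frozen)) {
    JB <- coulomb_matrix(engine, DBt)
    KBa <- exchange_matrix(engine, DBa)
    KBb <- exchange_matrix(engine, DBb)
    xcB_E <- xc_contrib(engine, functional, DBa, DBb)$E
    E_B <- sum(DBt * engine$h) + 0.5 * sum(DBt * JB) -
      0.5 * cx * (sum(DBa * KBa) + sum(DBb * KBb)) + xcB_E
    twoe_Ba <- JB - cx * KBa
    twoe_Bb <- JB - cx * KBb
  } else {
    E_B <- frozen$E_B
    xcB_E <- frozen$E_xc_B
    twoe_Ba <- frozen$twoe_B_alpha
    twoe_Bb <- frozen$twoe_B_beta
  }
  # interaction: Tr D_A G(D_B), the trace symmetry used exactly once
  E_int <- sum(DAa * twoe_Ba) + sum(DAb * twoe_Bb)
  E_nonadd <- if (functional$is_dft) {
    xc_contrib(engine, functional, DAa + DBa, DAb + DBb)$E - xcA$E - xcB_E
  } else 0
  tot <- E_A + E_B + E_int + E_nonadd + engine$E_nn
  c(E_A = E_A, E_B = E_B, E_int = E_int, E_nonadd = E_nonadd,
    E_nn = engine$E_nn, E_total = tot)
}

#' Converge the multilevel SCF in the active MO basis
#'
#' Roothaan iterations with DIIS carried out entirely in the orthonormal
#' active orbital basis (Cholesky occupied + PAO virtuals): the Fock matrix
#' is projected into that basis, diagonalized, and the lowest orbitals are
#' re-occupied, so the inactive block is untouched by construction.
#' Convergence requires the max occupied-virtual gradient below `conv_grad`
#' and an energy change below `conv_energy`.
#'
#' @param system the [atomic_system()].
#' @param partition the [define_partition()] result (bookkeeping/reporting).
#' @param functional a [functional_spec()].
#' @param orbital_space an `active_space` from [partition_densities()].
#' @param frozen a [frozen_inactive_terms()] result.
#' @param embedding optional [fq_layer()] or [fixed_charge_layer()].
#' @param partitioned the `partitioned_density` providing the starting
#'   active blocks.
#' @param engine optional prebuilt [scf_engine()].
#' @param max_iter,conv_grad,conv_energy convergence controls; `max_iter = 0`
#'   evaluates the starting energy and returns without touching anything.
#' @return Object of class `uml_result`.
#' @export
run_uml_scf <- function(system, partition, functional, orbital_space, frozen,
                        embedding = NULL, partitioned, engine = NULL,
                        max_iter = 100L, conv_grad = 1e-6,
                        conv_energy = 1e-9) {
  if (is.null(engine)) engine <- scf_engine(system)
  sp <- orbital_space
  Ca <- cbind(sp$C_occ_alpha, sp$C_virt_alpha)
  Cb <- cbind(sp$C_occ_beta, sp$C_virt_beta)
  na <- ncol(sp$C_occ_alpha); nb <- ncol(sp$C_occ_beta)
  ma <- ncol(Ca); mb <- ncol(Cb)
  # occupied orbitals tracked in the fixed orthonormal active basis
  Ua <- diag(ma)[, seq_len(na), drop = FALSE]
  Ub <- diag(mb)[, seq_len(nb), drop = FALSE]
  n <- engine$n_ao
  pd <- partitioned
  emb <- embedding_state(embedding, engine)
  diis <- diis_new()
  E_old <- Inf; trace <- numeric(0); conv <- FALSE; gmax <- NA_real_
  it <- 0L
  repeat {
    Coa <- Ca %*% Ua; Cob <- Cb %*% Ub
    DAa <- if (na > 0) tcrossprod(Coa) else matrix(0, n, n)
    DAb <- if (nb > 0) tcrossprod(Cob) else matrix(0, n, n)
    pd$D_A_alpha <- sym(DAa); pd$D_A_beta <- sym(DAb)
    emb <- embedding_update(emb, engine,
                            DAa + DAb + frozen$D_B_alpha + frozen$D_B_beta)
    fk <- ml_fock_energy(engine, pd$D_A_alpha, pd$D_A_beta, frozen, functional)
    Fa <- fk$F_alpha; Fb <- fk$F_beta
    if (!is.null(emb$H)) { Fa <- Fa + emb$H; Fb <- Fb + emb$H }
    E <- fk$E_total + emb$E
    trace <- c(trace, E)
    Fta <- sym(crossprod(Ca, Fa %*% Ca))
    Ftb <- sym(crossprod(Cb, Fb %*% Cb))
    # gradient: commutator of the projected Fock with the current occupied
    # projector in the orthonormal active basis
    Pa <- tcrossprod(Ua); Pb <- tcrossprod(Ub)
    err_a <- Fta %*% Pa - Pa %*% Fta
    err_b <- Ftb %*% Pb - Pb %*% Ftb
    gmax <- max(max_abs(err_a), max_abs(err_b))
    if (gmax < conv_grad && abs(E - E_old) < conv_energy) { conv <- TRUE; break }
    if (it >= max_iter) break
    it <- it + 1L
    E_old <- E
    Fvec <- diis_extrapolate(diis, c(Fta, Ftb), c(err_a, err_b))
    Fta_x <- matrix(Fvec[seq_len(length(Fta))], ma, ma)
    Ftb_x <- matrix(Fvec[length(Fta) + seq_len(length(Ftb))], mb, mb)
    if (na > 0) {
      ev <- eigen(sym(Fta_x), symmetric = TRUE)
      Ua <- ev$vectors[, order(ev$values)[seq_len(na)], drop = FALSE]
    }
    if (nb > 0) {
      ev <- eigen(sym(Ftb_x), symmetric = TRUE)
      Ub <- ev$vectors[, order(ev$values)[seq_len(nb)], drop = FALSE]
    }
  }
  Coa <- Ca %*% Ua; Cob <- Cb %*% Ub
  bd <- ml_energy(engine, pd, functional, frozen = frozen)
  if (!conv && max_iter > 0) {
    cond <- structure(
      class = c("mlscf_scf_not_converged", "error", "condition"),
      list(message = sprintf("multilevel SCF not converged in %d iterations (gradient %.2e)",
                             max_iter, gmax),
           call = sys.call(), trace = trace))
    stop(cond)
  }
  structure(list(
    E_total = E, breakdown = c(bd, E_embedding = emb$E),
    partitioned = pd, orbital_space = sp,
    C_occ_alpha = Coa, C_occ_beta = Cob,
    D_alpha = pd$D_A_alpha + frozen$D_B_alpha,
    D_beta = pd$D_A_beta + frozen$D_B_beta,
    frozen = frozen, partition = partition,
    fq_charges = emb$q, n_iter = it, gradient = gmax,
    energy_trace = trace, converged = conv || max_iter == 0,
    functional = functional, system = system, engine_n_ao = n
  ), class = "uml_result")
}

#' @export
print.uml_result <- function(x, ...) {
  cat(sprintf("<uml_result: E = %.10f Eh in %d iteration(s); active %d a / %d b electrons>\n",
              x$E_total, x$n_iter,
              x$partitioned$n_A_alpha, x$partitioned$n_A_beta))
  bd <- x$breakdown
  cat(sprintf("  E_A = %.8f  E_B = %.8f  E_int = %.8f  E_nonadd = %.8f  E_emb = %.8f\n",
              bd["E_A"], bd["E_B"], bd["E_int"], bd["E_nonadd"],
              bd["E_embedding"]))
  invisible(x)
}

#' Full multilevel calculation (five-step protocol)
#'
#' Convenience driver running the whole pipeline: SAD guess, one
#' full-system Fock diagonalization, density partitioning, frozen-term
#' precomputation, and the active-space SCF.
#'
#' @param system the [atomic_system()].
#' @param partition a [define_partition()] result or an active-atom specification
#'   accepted by [define_partition()].
#' @param functional a [functional_spec()] or preset name.
#' @param embedding optional [fq_layer()] or [fixed_charge_layer()].
#' @param tau,lindep_tol partitioning thresholds.
#' @param virtual virtual-space construction, `"pao"` or `"cholesky"`.
#' @param include_embedding_in_guess include the embedding potential in the
#'   initial full Fock (default TRUE).
#' @param engine optional prebuilt [scf_engine()].
#' @param ... passed to [run_uml_scf()].
#' @return A `uml_result`.
#' @export
uml_scf <- function(system, partition, functional = functional_spec("uhf"),
                    embedding = NULL, tau = 1e-2, lindep_tol = 1e-8,
                    virtual = "pao", include_embedding_in_guess = TRUE,
                    engine = NULL, ...) {
  if (is.character(functional)) functional <- functional_spec(functional)
  if (!inherits(partition, "region_partition")) {
    partition <- define_partition(system, partition)
  }
  if (is.null(engine)) engine <- scf_engine(system)
  guess <- sad_guess(system, engine = engine)
  initial <- purify_guess(system, guess, functional, embedding = embedding,
                          include_embedding = include_embedding_in_guess,
                          engine = engine)
  parts <- partition_densities(system, initial, partition, tau = tau,
                               lindep_tol = lindep_tol, virtual = virtual)
  frozen <- frozen_inactive_terms(engine, parts$partitioned, functional)
  run_uml_scf(system, partition, functional, parts$space, frozen,
              embedding = embedding, partitioned = parts$partitioned,
              engine = engine, ...)
}
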