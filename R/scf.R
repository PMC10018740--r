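# Reference (full-system) unrestricted SCF and shared SCF machinery:
# Fock builds, aufbau occupation, and DIIS.

# Aufbau density from orthogonalized Fock. Returns density, coefficients and
# eigenvalues. Degenerate frontier orbitals are occupied lowest-index first
# with a warning (no level shifting).
aufbau_density <- function(F, X, nocc, warn_degenerate = TRUE) {
  Fp <- crossprod(X, F %*% X)
  ev <- eigen(sym(Fp), symmetric = TRUE)
  ord <- order(ev$values)
  C <- X %*% ev$vectors[, ord, drop = FALSE]
  eps <- ev$values[ord]
  if (warn_degenerate && nocc >= 1 && nocc < length(eps) &&
      abs(eps[nocc + 1] - eps[nocc]) < 1e-8) {
    warning("degenerate frontier orbitals at the Fermi level; ",
            "occupying the lowest-index eigenvectors")
  }
  Co <- C[, seq_len(nocc), drop = FALSE]
  D <- if (nocc > 0) tcrossprod(Co) else matrix(0, nrow(F), nrow(F))
  list(D = D, C = C, eps = eps)
}

# Pulay DIIS over an arbitrary flattened error/Fock pair history.
diis_new <- function(max_vec = 8L) {
  env <- new.env(parent = emptyenv())
  env$F <- list(); env$e <- list(); env$max_vec <- max_vec
  env
}

diis_extrapolate <- function(st, Fvec, evec) {
  st$F[[length(st$F) + 1L]] <- Fvec
  st$e[[length(st$e) + 1L]] <- evec
  if (length(st$F) > st$max_vec) {
    st$F <- st$F[-1L]; st$e <- st$e[-1L]
  }
  m <- length(st$F)
  if (m < 2L) return(Fvec)
  B <- matrix(-1, m + 1L, m + 1L)
  B[m + 1L, m + 1L] <- 0
  for (i in seq_len(m)) for (j in i:m) {
    B[i, j] <- B[j, i] <- sum(st$e[[i]] * st$e[[j]])
  }
  rhs <- c(rep(0, m), -1)
  c_coef <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
  if (is.null(c_coef) || any(!is.finite(c_coef))) {
    st$F <- st$F[m]; st$e <- st$e[m]
    return(Fvec)
  }
  out <- 0
  for (i in seq_len(m)) out <- out + c_coef[i] * st$F[[i]]
  out
}

# Unrestricted Fock matrices and energy for full densities, including the
# embedding one-electron operator when supplied.
fock_full <- function(engine, fun, Da, Db, H_emb = NULL) {
  J <- coulomb_matrix(engine, Da + Db)
  Ka <- exchange_matrix(engine, Da)
  Kb <- exchange_matrix(engine, Db)
  xc <- xc_contrib(engine, fun, Da, Db)
  Fa <- engine$h + J - fun$c_x * Ka + xc$Va
  Fb <- engine$h + J - fun$c_x * Kb + xc$Vb
  if (!is.null(H_emb)) { Fa <- Fa + H_emb; Fb <- Fb + H_emb }
  E1 <- sum((Da + Db) * engine$h)
  E2 <- 0.5 * sum((Da + Db) * J) -
    0.5 * fun$c_x * (sum(Da * Ka) + sum(Db * Kb))
  E <- E1 + E2 + xc$E + engine$E_nn
  list(Fa = Fa, Fb = Fb, E = E,
       breakdown = c(E_one = E1, E_coulomb_exchange = E2, E_xc = xc$E,
                     E_nn = engine$E_nn))
}

#' Full-system unrestricted SCF (reference route)
#'
#' Conventional UHF/UKS with DIIS over the whole system: every occupied
#' orbital is optimized. This is the package's reference against which the
#' multilevel solver is checked in its full-active limit, and it also
#' provides the single initial diagonalization of the multilevel protocol.
#'
#' @param system an [atomic_system()].
#' @param functional a [functional_spec()].
#' @param embedding optional [fq_layer()] or [fixed_charge_layer()]; fixed charges enter the
#'   core Hamiltonian once, fluctuating charges are re-equilibrated against
#'   the evolving density every cycle.
#' @param engine optional prebuilt [scf_engine()].
#' @param guess optional `spin_density` starting guess (default SAD).
#' @param max_iter,conv_grad,conv_energy convergence controls: max abs of
#'   the occupied-virtual gradient (`FDS - SDF` in orthonormal basis) and
#'   the energy change between cycles.
#' @return Object of class `scf_result`.
#' @export
full_scf <- function(system, functional = functional_spec("uhf"),
                     embedding = NULL, engine = NULL, guess = NULL,
                     max_iter = 100L, conv_grad = 1e-6, conv_energy = 1e-9) {
  if (is.null(engine)) engine <- scf_engine(system)
  if (is.null(guess)) guess <- sad_guess(system, engine = engine)
  X <- s_power(engine$S, -0.5)
  Da <- guess$D_alpha; Db <- guess$D_beta
  na <- system$n_alpha; nb <- system$n_beta
  diis <- diis_new()
  E_old <- Inf; trace <- numeric(0)
  emb <- embedding_state(embedding, engine)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    emb <- embedding_update(emb, engine, Da + Db)
    fk <- fock_full(engine, functional, Da, Db, emb$H)
    E <- fk$E + emb$E
    erra <- X %*% (fk$Fa %*% Da %*% engine$S - engine$S %*% Da %*% fk$Fa) %*% X
    errb <- X %*% (fk$Fb %*% Db %*% engine$S - engine$S %*% Db %*% fk$Fb) %*% X
    gmax <- max(max_abs(erra), max_abs(errb))
    trace <- c(trace, E)
    if (gmax < conv_grad && abs(E - E_old) < conv_energy) { conv <- TRUE; break }
    E_old <- E
    Fvec <- diis_extrapolate(diis, c(fk$Fa, fk$Fb), c(erra, errb))
    n <- engine$n_ao
    Fa_x <- matrix(Fvec[seq_len(n * n)], n, n)
    Fb_x <- matrix(Fvec[n * n + seq_len(n * n)], n, n)
    Da <- aufbau_density(Fa_x, X, na, warn_degenerate = FALSE)$D
    Db <- aufbau_density(Fb_x, X, nb, warn_degenerate = FALSE)$D
  }
  if (!conv) {
    cond <- structure(
      class = c("mlscf_scf_not_converged", "error", "condition"),
      list(message = sprintf("SCF not converged in %d iterations", max_iter),
           call = sys.call(), trace = trace))
    stop(cond)
  }
  sol_a <- aufbau_density(fk$Fa, X, na, warn_degenerate = FALSE)
  sol_b <- aufbau_density(fk$Fb, X, nb, warn_degenerate = FALSE)
  structure(list(
    E_total = E, breakdown = c(fk$breakdown, E_embedding = emb$E),
    D_alpha = Da, D_beta = Db, S = engine$S,
    C_alpha = sol_a$C, C_beta = sol_b$C,
    eps_alpha = sol_a$eps, eps_beta = sol_b$eps,
    n_alpha = na, n_beta = nb,
    fq_charges = emb$q, n_iter = it, energy_trace = trace,
    converged = conv, functional = functional, system = system
  ), class = "scf_result")
}

#' @export
print.scf_result <- function(x, ...) {
  cat(sprintf("<scf_result: E = %.10f Eh, %d iterations, converged: %s>\n",
              x$E_total, x$n_iter, x$converged))
  invisible(x)
}
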