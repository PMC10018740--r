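# Initial densities: superposition of atomic densities (SAD) and the single
# initial full-system diagonalization that seeds the partitioning.

#' Spin-resolved density container
#'
#' @param D_alpha,D_beta symmetric AO density matrices.
#' @param S AO overlap matrix.
#' @param n_alpha,n_beta electron counts.
#' @return Object of class `spin_density`.
#' @export
spin_density <- function(D_alpha, D_beta, S, n_alpha, n_beta) {
  stopifnot(max_abs(D_alpha - t(D_alpha)) < 1e-10,
            max_abs(D_beta - t(D_beta)) < 1e-10)
  structure(list(D_alpha = sym(D_alpha), D_beta = sym(D_beta), S = S,
                 n_alpha = n_alpha, n_beta = n_beta),
            class = "spin_density")
}

#' @export
print.spin_density <- function(x, ...) {
  cat(sprintf("<spin_density: %d AOs, Tr(Da S) = %.6f, Tr(Db S) = %.6f>\n",
              nrow(x$D_alpha), sum(x$D_alpha * x$S), sum(x$D_beta * x$S)))
  invisible(x)
}

# S-metric idempotency residual max|D S D - D|.
idempotency_residual <- function(D, S) max_abs(D %*% S %*% D - D)

# Hund ground-state (n_alpha, n_beta) for neutral atoms we ship bases for.
.atom_spins <- list(H = c(1, 0), He = c(1, 1), Li = c(2, 1), Be = c(2, 2),
                    B = c(3, 2), C = c(4, 2), N = c(5, 2), O = c(5, 3),
                    F = c(5, 4), Ne = c(5, 5))

# Spherically averaged unrestricted atomic density, cached per
# (element, basis). Fractional occupations are spread uniformly over
# degenerate eigenvalue groups so the density is rotationally invariant.
atomic_density <- function(element, basis) {
  key <- paste0("sad:", element, ":", tolower(basis))
  if (!is.null(.mlscf_cache[[key]])) return(.mlscf_cache[[key]])
  occ <- .atom_spins[[element]]
  if (is.null(occ)) stop("no SAD reference configuration for element ", element)
  sys1 <- atomic_system(element, matrix(0, 1, 3), charge = 0L,
                        multiplicity = occ[1] - occ[2] + 1L, basis = basis)
  eng <- scf_engine(sys1)
  X <- s_power(eng$S, -0.5)
  fun <- functional_spec("uhf")
  n <- eng$n_ao
  Da <- Db <- matrix(0, n, n)
  frac_density <- function(F, nel) {
    ev <- eigen(sym(crossprod(X, F %*% X)), symmetric = TRUE)
    ord <- order(ev$values)
    C <- X %*% ev$vectors[, ord, drop = FALSE]
    eps <- ev$values[ord]
    f <- numeric(n)
    remaining <- nel
    i <- 1L
    while (remaining > 1e-12 && i <= n) {
      grp <- which(abs(eps - eps[i]) < 1e-6 & seq_len(n) >= i)
      take <- min(remaining, length(grp))
      f[grp] <- take / length(grp)
      remaining <- remaining - take
      i <- max(grp) + 1L
    }
    C %*% (f * t(C))
  }
  for (it in 1:300) {
    fk <- fock_full(eng, fun, Da, Db)
    Da_new <- frac_density(fk$Fa, occ[1])
    Db_new <- frac_density(fk$Fb, occ[2])
    delta <- max(max_abs(Da_new - Da), max_abs(Db_new - Db))
    Da <- 0.5 * Da + 0.5 * Da_new
    Db <- 0.5 * Db + 0.5 * Db_new
    if (delta < 1e-7) break
  }
  out <- list(D_total = Da + Db, S = eng$S, n_ao = n)
  .mlscf_cache[[key]] <- out
  out
}

#' SAD guess densities
#'
#' Superposition of spherically averaged unrestricted atomic densities,
#' block-diagonal over atoms. The summed atomic density is split between the
#' spin channels in proportion to the molecular electron counts, so the
#' guess traces match `n_alpha`/`n_beta` (exactly for neutral systems,
#' rescaled for ions). The guess is not idempotent.
#'
#' @param system an [atomic_system()].
#' @param engine optional [scf_engine()] (used for its overlap matrix; a
#'   cheap one-electron pass is done otherwise).
#' @return A [spin_density()].
#' @export
sad_guess <- function(system, engine = NULL) {
  shells <- basis_shells(system)
  n <- attr(shells, "n_ao")
  S <- if (!is.null(engine)) engine$S else
    cpp_one_electron(shells, as_bohr(coords_of(system)),
                     as.numeric(system$atoms$Z))$S
  D <- matrix(0, n, n)
  off <- 0L
  ao_atom <- attr(shells, "ao_atom")
  for (i in seq_len(nrow(system$atoms))) {
    at <- system$atoms[i, ]
    ad <- atomic_density(at$element, at$basis)
    idx <- off + seq_len(ad$n_ao)
    stopifnot(all(ao_atom[idx] == i))
    D[idx, idx] <- ad$D_total
    off <- off + ad$n_ao
  }
  Ntot <- sum(D * S)
  Da <- D * system$n_alpha / Ntot
  Db <- D * system$n_beta / Ntot
  spin_density(Da, Db, S, system$n_alpha, system$n_beta)
}

#' One Fock build and diagonalization of the guess
#'
#' The second step of the multilevel protocol: a single Fock construction
#' from the (non-idempotent) SAD density followed by one diagonalization and
#' aufbau filling per spin. The result is S-idempotent with exact integer
#' traces; it is deliberately not iterated to convergence -- the full-system
#' relaxation the multilevel method avoids. When an embedding layer is
#' given it contributes to this initial Fock by default (`include_embedding`),
#' since the classical layer exists before the partitioning.
#'
#' @param system an [atomic_system()].
#' @param guess a [spin_density()] (typically from [sad_guess()]).
#' @param functional a [functional_spec()].
#' @param embedding optional [fq_layer()] or [fixed_charge_layer()].
#' @param include_embedding include the embedding potential in this initial
#'   Fock (default TRUE).
#' @param engine optional [scf_engine()].
#' @return An S-idempotent [spin_density()].
#' @export
purify_guess <- function(system, guess, functional = functional_spec("uhf"),
                         embedding = NULL, include_embedding = TRUE,
                         engine = NULL) {
  if (is.null(engine)) engine <- scf_engine(system)
  if (nrow(guess$D_alpha) != engine$n_ao) {
    stop("guess dimension does not match the AO basis")
  }
  X <- s_power(engine$S, -0.5)  # errors on singular overlap
  H_emb <- NULL
  if (!is.null(embedding) && include_embedding) {
    st <- embedding_update(embedding_state(embedding, engine), engine,
                           guess$D_alpha + guess$D_beta)
    H_emb <- st$H
  }
  fk <- fock_full(engine, functional, guess$D_alpha, guess$D_beta, H_emb)
  Da <- aufbau_density(fk$Fa, X, system$n_alpha)$D
  Db <- aufbau_density(fk$Fb, X, system$n_beta)$D
  spin_density(Da, Db, engine$S, system$n_alpha, system$n_beta)
}
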