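# Density partitioning: partial pivoted Cholesky of the spin densities with
# pivots restricted to active-atom AOs, projected-atomic-orbital virtuals,
# and assembly of the partitioned density + active orbital space.
#
# Convention: the decomposition acts on the metric-folded density
# D' = S^{1/2} D S^{1/2}, for which S-idempotency becomes ordinary matrix
# idempotency; coefficient columns are back-transformed with S^{-1/2}.

#' Partial pivoted Cholesky of an idempotent density
#'
#' Factorizes the S-idempotent density `D` as `L L^T = D_A` where pivoting
#' is restricted to the given active AO indices. Pivots are chosen as the
#' largest remaining diagonal among active AOs (exact ties break to the
#' lowest AO index) and the decomposition stops when that diagonal drops
#' below `tau`; the number of columns returned is the active occupation.
#' The columns are automatically S-orthonormal because `D` is a projector
#' in the S metric.
#'
#' @param D density matrix for one spin (AO basis).
#' @param S overlap matrix.
#' @param active_aos integer AO indices eligible as pivots.
#' @param tau positive decay threshold on the Cholesky diagonal.
#' @return AO x k coefficient matrix `L` (k = active occupation).
#' @export
partial_cholesky_occupied <- function(D, S, active_aos, tau = 1e-2) {
  if (tau <= 0) stop("tau must be positive")
  if (length(active_aos) == 0L) stop("active_aos must be non-empty")
  n <- nrow(D)
  if (any(active_aos < 1L | active_aos > n)) stop("active AO index out of range")
  if (idempotency_residual(D, S) > 1e-6) {
    stop("density is not S-idempotent (residual ",
         format(idempotency_residual(D, S)), ")")
  }
  Sh <- s_power(S, 0.5)
  Shm <- s_power(S, -0.5)
  M <- Sh %*% D %*% Sh
  M <- sym(M)
  L <- matrix(0, n, 0)
  repeat {
    dvals <- diag(M)[active_aos]
    j_rel <- which.max(dvals)          # first maximum = lowest AO index tie-break
    if (dvals[j_rel] < tau) break
    j <- active_aos[j_rel]
    l <- M[, j] / sqrt(M[j, j])
    L <- cbind(L, l)
    M <- M - tcrossprod(l)
    if (ncol(L) >= n) break
  }
  unname(Shm %*% L)
}

#' Projected atomic orbital (PAO) virtual space
#'
#' Projects all occupied components out of the AOs centred on the active
#' atoms and removes linear dependencies by symmetric (Lowdin)
#' orthonormalization, dropping eigenvalues of the projected overlap below
#' `lindep_tol`. The returned columns are S-orthonormal and S-orthogonal to
#' every occupied orbital (active and inactive).
#'
#' @param S overlap matrix.
#' @param occupied_coeffs AO x n_occ matrix of ALL occupied orbitals for the
#'   spin channel (must be S-orthonormal).
#' @param active_aos AO indices of the active atoms.
#' @param lindep_tol eigenvalue threshold of the Lowdin step.
#' @return AO x n_virt coefficient matrix.
#' @export
pao_virtuals <- function(S, occupied_coeffs, active_aos, lindep_tol = 1e-8) {
  n <- nrow(S)
  C <- occupied_coeffs
  if (ncol(C) > 0) {
    orth <- max_abs(crossprod(C, S %*% C) - diag(ncol(C)))
    if (orth > 1e-8) stop("occupied coefficients are not S-orthonormal")
  }
  P <- diag(n) - tcrossprod(C) %*% S   # projector onto the virtual space
  V0 <- P[, active_aos, drop = FALSE]
  Sv <- sym(crossprod(V0, S %*% V0))
  e <- eigen(Sv, symmetric = TRUE)
  keep <- e$values > lindep_tol
  if (!any(keep)) stop("no active virtual space: all projected AOs below lindep_tol")
  unname(V0 %*% e$vectors[, keep, drop = FALSE] %*%
           diag(1 / sqrt(e$values[keep]), sum(keep)))
}

#' Partition spin densities into active and inactive blocks
#'
#' The third step of the multilevel protocol, run once per spin channel:
#' partial limited Cholesky over active-atom AOs for the occupied active
#' space, the complement for the inactive block, and PAO (or Cholesky)
#' virtuals. The resulting active and inactive orbitals are mutually
#' S-orthogonal by construction; invariants are asserted numerically.
#'
#' @param system the [atomic_system()].
#' @param full an idempotent [spin_density()] (e.g. from [purify_guess()]).
#' @param partition a [define_partition()] result.
#' @param tau Cholesky decay threshold.
#' @param lindep_tol Lowdin threshold of the PAO step.
#' @param virtual `"pao"` (default) or `"cholesky"` (decompose the virtual
#'   density with active pivots instead).
#' @return List with `partitioned` (class `partitioned_density`) and
#'   `space` (class `active_space`).
#' @export
partition_densities <- function(system, full, partition, tau = 1e-2,
                                lindep_tol = 1e-8,
                                virtual = c("pao", "cholesky")) {
  virtual <- match.arg(virtual)
  S <- full$S
  n <- nrow(S)
  active_aos <- aos_on_atoms(system, partition$active_atoms)
  one_spin <- function(D) {
    LA <- partial_cholesky_occupied(D, S, active_aos, tau)
    DA <- if (ncol(LA) > 0) tcrossprod(LA) else matrix(0, n, n)
    DB <- D - DA
    LB <- if (max_abs(DB) > 1e-12) {
      partial_cholesky_occupied(DB, S, seq_len(n), tau)
    } else matrix(0, n, 0)
    Cv <- if (virtual == "pao") {
      # a minimal-basis active region can have no virtual space at all
      # (every active AO already spanned by occupied orbitals); that is a
      # legitimate partition with nothing to optimize
      tryCatch(pao_virtuals(S, cbind(LA, LB), active_aos, lindep_tol),
               error = function(e) {
                 if (grepl("no active virtual space", conditionMessage(e)))
                   matrix(0, n, 0) else stop(e)
               })
    } else {
      Dv <- s_power(S, -1) - D        # virtual "density" projector in S metric
      partial_cholesky_occupied(Dv, S, active_aos, tau = lindep_tol)
    }
    list(LA = LA, DA = sym(DA), DB = sym(DB), LB = LB, Cv = Cv)
  }
  a <- one_spin(full$D_alpha)
  b <- one_spin(full$D_beta)
  pd <- structure(list(
    D_A_alpha = a$DA, D_A_beta = b$DA,
    D_B_alpha = a$DB, D_B_beta = b$DB,
    S = S,
    n_A_alpha = ncol(a$LA), n_A_beta = ncol(b$LA),
    n_B_alpha = full$n_alpha - ncol(a$LA),
    n_B_beta = full$n_beta - ncol(b$LA)
  ), class = "partitioned_density")
  sp <- structure(list(
    C_occ_alpha = a$LA, C_occ_beta = b$LA,
    C_virt_alpha = a$Cv, C_virt_beta = b$Cv,
    C_occ_B_alpha = a$LB, C_occ_B_beta = b$LB,
    active_aos = active_aos
  ), class = "active_space")
  chk <- check_partition(pd)
  if (chk$max_violation > 1e-7) {
    stop("partition invariants violated (max residual ",
         format(chk$max_violation), ")")
  }
  list(partitioned = pd, space = sp)
}

#' Numerical check of partitioned-density invariants
#'
#' Reports the reconstruction residual (active + inactive = total is implied
#' by construction, so the inactive block is checked for S-idempotency),
#' per-block S-idempotency, mutual orthogonality Tr(D_A S D_B S), and the
#' integer character of the block traces.
#'
#' @param pd a `partitioned_density`.
#' @return List of residuals and `max_violation`.
#' @export
check_partition <- function(pd) {
  S <- pd$S
  res <- c(
    idem_A_alpha = idempotency_residual(pd$D_A_alpha, S),
    idem_A_beta = idempotency_residual(pd$D_A_beta, S),
    idem_B_alpha = idempotency_residual(pd$D_B_alpha, S),
    idem_B_beta = idempotency_residual(pd$D_B_beta, S),
    ortho_alpha = abs(sum(diag(pd$D_A_alpha %*% S %*% pd$D_B_alpha %*% S))),
    ortho_beta = abs(sum(diag(pd$D_A_beta %*% S %*% pd$D_B_beta %*% S))),
    trace_A_alpha = abs(sum(pd$D_A_alpha * S) - pd$n_A_alpha),
    trace_A_beta = abs(sum(pd$D_A_beta * S) - pd$n_A_beta),
    trace_B_alpha = abs(sum(pd$D_B_alpha * S) - pd$n_B_alpha),
    trace_B_beta = abs(sum(pd$D_B_beta * S) - pd$n_B_beta)
  )
  list(residuals = res, max_violation = max(res))
}

#' @export
print.partitioned_density <- function(x, ...) {
  cat(sprintf("<partitioned_density: active (%d a / %d b), inactive (%d a / %d b) electrons>\n",
              x$n_A_alpha, x$n_A_beta, x$n_B_alpha, x$n_B_beta))
  invisible(x)
}

#' @export
print.active_space <- function(x, ...) {
  cat(sprintf("<active_space: occ %d a / %d b, virt %d a / %d b>\n",
              ncol(x$C_occ_alpha), ncol(x$C_occ_beta),
              ncol(x$C_virt_alpha), ncol(x$C_virt_beta)))
  invisible(x)
}
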