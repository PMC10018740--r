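# Integral engine cache: one-electron matrices, in-core ERI tensor reshaped
# for fast Coulomb/exchange builds, nuclear repulsion, and lazily built
# quadrature grids with cached AO values.

#' Build (and cache) the integral engine for a system
#'
#' Computes overlap, kinetic and nuclear-attraction matrices and the full
#' two-electron integral tensor in core, reshaped so that Coulomb and
#' exchange builds are single matrix-vector products. Intended to be built
#' once per geometry and passed to the SCF drivers; all high-level functions
#' build it on demand when not supplied.
#'
#' @param system an [atomic_system()].
#' @param screen_tol Schwarz screening threshold for two-electron integrals.
#' @return Object of class `scf_engine`.
#' @export
scf_engine <- function(system, screen_tol = 1e-12) {
  shells <- basis_shells(system)
  nucxyz <- as_bohr(coords_of(system))
  Z <- system$atoms$Z
  one <- cpp_one_electron(shells, nucxyz, as.numeric(Z))
  n <- attr(shells, "n_ao")
  eri <- cpp_eri(shells, screen_tol)
  MJ <- matrix(eri, n * n, n * n)
  MK <- matrix(aperm(eri, c(1L, 3L, 2L, 4L)), n * n, n * n)
  rm(eri)
  rij <- as.matrix(dist(nucxyz))
  E_nn <- if (nrow(nucxyz) > 1) {
    sum((outer(Z, Z) / (rij + diag(Inf, length(Z))))[upper.tri(rij)])
  } else 0
  env <- new.env(parent = emptyenv())
  env$grids <- list()
  structure(list(
    system = system, shells = shells, n_ao = n,
    ao_atom = attr(shells, "ao_atom"),
    S = one$S, T = one$T, Vne = one$V, h = one$T + one$V,
    MJ = MJ, MK = MK, E_nn = E_nn, cache = env
  ), class = "scf_engine")
}

#' @export
print.scf_engine <- function(x, ...) {
  cat(sprintf("<scf_engine: %d AOs, %d shells, E_nn = %.8f Eh>\n",
              x$n_ao, length(x$shells), x$E_nn))
  invisible(x)
}

# Coulomb and exchange matrices of a (symmetric) density matrix.
coulomb_matrix <- function(engine, D) {
  matrix(engine$MJ %*% as.vector(D), engine$n_ao, engine$n_ao)
}

exchange_matrix <- function(engine, D) {
  matrix(engine$MK %*% as.vector(D), engine$n_ao, engine$n_ao)
}

# Symmetric orthogonalization helpers in the S metric.
s_power <- function(S, p, lindep_tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < lindep_tol) {
    stop("overlap matrix is singular beyond the linear-dependence threshold (",
         format(min(e$values)), " < ", format(lindep_tol), ")")
  }
  e$vectors %*% (e$values^p * t(e$vectors))
}

sym <- function(M) (M + t(M)) / 2
max_abs <- function(M) max(abs(M))

# md5 of the serialized object -- used for frozen-term constancy checks and
# config provenance. Streams through a temp file to stay dependency-free.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # version 2 serialization is stable across R sessions for numeric payloads
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
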