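# Basis-set bookkeeping: reading basis data files, normalizing contractions,
# and mapping atoms to shells and AO index ranges.

double_factorial <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))

#' Load a Gaussian basis set definition
#'
#' Basis sets ship as JSON data files under `inst/extdata/basis/` (STO-3G and
#' 6-31G for first-row elements and hydrogen). A filesystem path to a file in
#' the same format may be given instead of a name, so users can add sets
#' without touching the package.
#'
#' @param name basis-set name (case-insensitive, e.g. `"sto-3g"`) or a path
#'   to a JSON basis file.
#' @return A list with `name` and `elements` (per-element shell lists).
#' @export
load_basis_set <- function(name) {
  key <- paste0("basis:", tolower(name))
  if (!is.null(.mlscf_cache[[key]])) return(.mlscf_cache[[key]])
  path <- if (file.exists(name)) name else
    system.file("extdata", "basis", paste0(tolower(name), ".json"),
                package = "mlscf")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown basis set '", name, "'")
  }
  bs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  .mlscf_cache[[key]] <- bs
  bs
}

# Normalized contraction coefficients for one shell: primitive norms folded
# in, then the contracted self-overlap of the (l,0,0) component scaled to 1.
# Only s and p shells are accepted (all Cartesian p components share a norm).
normalize_contraction <- function(l, expo, coef) {
  if (l > 1L) stop("only s and p shells are supported")
  np <- (2 * expo / pi)^0.75 * (4 * expo)^(l / 2) / sqrt(double_factorial(2 * l - 1))
  cn <- coef * np
  p <- outer(expo, expo, "+")
  s <- (pi / p)^1.5 * double_factorial(2 * l - 1) / (2 * p)^l
  cn / sqrt(sum(outer(cn, cn) * s))
}

#' Build the shell list for a system
#'
#' Expands each atom's basis label into contracted shells centred on the atom
#' (coordinates converted to bohr here), with normalized coefficients. The
#' result carries the AO index map as attributes.
#'
#' @param system an [atomic_system()].
#' @return List of shells; attributes `ao_atom` (owning atom per AO, 1-based),
#'   `n_ao`, and `shell_atom`.
#' @export
basis_shells <- function(system) {
  stopifnot(inherits(system, "atomic_system"))
  shells <- list()
  ao_atom <- integer(0)
  shell_atom <- integer(0)
  for (i in seq_len(nrow(system$atoms))) {
    at <- system$atoms[i, ]
    bs <- load_basis_set(at$basis)
    el <- bs$elements[[at$element]]
    if (is.null(el)) {
      stop("basis '", at$basis, "' has no functions for element '",
           at$element, "' (atom ", i, ")")
    }
    for (shl in el) {
      l <- as.integer(shl$l)
      expo <- as.numeric(unlist(shl$exp))
      coef <- normalize_contraction(l, expo, as.numeric(unlist(shl$coef)))
      shells[[length(shells) + 1L]] <- list(
        l = l,
        center = as_bohr(c(at$x, at$y, at$z)),
        exp = expo,
        coef = coef
      )
      nc <- (l + 1) * (l + 2) / 2
      ao_atom <- c(ao_atom, rep.int(i, nc))
      shell_atom <- c(shell_atom, i)
    }
  }
  attr(shells, "ao_atom") <- ao_atom
  attr(shells, "n_ao") <- length(ao_atom)
  attr(shells, "shell_atom") <- shell_atom
  shells
}

#' AO indices centred on given atoms
#'
#' @param system an [atomic_system()].
#' @param atoms integer atom indices (1-based).
#' @return Integer vector of AO indices (1-based).
#' @export
aos_on_atoms <- function(system, atoms) {
  ao_atom <- attr(basis_shells(system), "ao_atom")
  which(ao_atom %in% atoms)
}
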