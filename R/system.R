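# Molecular system model: geometry, charge/multiplicity, per-atom basis
# labels, fragment/role tags, and active/inactive partitions.

#' Construct an atomic system
#'
#' The central geometry container. Coordinates are in Angstrom. Each atom
#' carries a basis-set label so mixed-basis calculations (different sets for
#' solute and solvent) are expressed per atom, not globally.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix (n x 3) of positions in Angstrom.
#' @param charge integer net charge.
#' @param multiplicity positive integer spin multiplicity 2S+1. Default: 1
#'   for an even electron count, 2 for odd.
#' @param basis single basis label applied to all atoms, or one label per atom.
#' @param fragment optional integer fragment id per atom (solvent molecules);
#'   used by the solvation pipeline.
#' @param role optional character per atom, `"solute"` or `"solvent"`.
#' @return An object of class `atomic_system`.
#' @export
atomic_system <- function(elements, coords, charge = 0L, multiplicity = NULL,
                          basis = "sto-3g", fragment = NULL, role = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- length(elements)
  if (n < 1L) stop("an atomic system needs at least one atom")
  if (nrow(coords) != n) stop("coords must have one row per atom")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  Z <- element_number(elements)
  n_elec <- sum(Z) - charge
  if (n_elec < 1L) stop("system has no electrons")
  if (is.null(multiplicity)) multiplicity <- if (n_elec %% 2L == 0L) 1L else 2L
  multiplicity <- as.integer(multiplicity)
  if (multiplicity < 1L) stop("multiplicity must be a positive integer")
  if ((multiplicity - 1L) %% 2L != n_elec %% 2L) {
    stop("multiplicity ", multiplicity, " is inconsistent with ",
         n_elec, " electrons")
  }
  if (length(basis) == 1L) basis <- rep(basis, n)
  if (length(basis) != n) stop("basis must be one label or one per atom")
  if (is.null(fragment)) fragment <- rep(NA_integer_, n)
  if (is.null(role)) role <- rep(NA_character_, n)
  n_alpha <- (n_elec + multiplicity - 1L) %/% 2L
  n_beta <- n_elec - n_alpha
  structure(list(
    atoms = data.frame(
      element = elements, Z = Z,
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      basis = basis, fragment = as.integer(fragment), role = role,
      stringsAsFactors = FALSE
    ),
    net_charge = as.integer(charge),
    multiplicity = multiplicity,
    n_electrons = n_elec, n_alpha = n_alpha, n_beta = n_beta
  ), class = "atomic_system")
}

#' @export
print.atomic_system <- function(x, ...) {
  cat(sprintf("<atomic_system: %d atoms, charge %+d, multiplicity %d, %d electrons (%d alpha / %d beta)>\n",
              nrow(x$atoms), x$net_charge, x$multiplicity,
              x$n_electrons, x$n_alpha, x$n_beta))
  invisible(x)
}

coords_of <- function(system) {
  as.matrix(system$atoms[, c("x", "y", "z")])
}

#' Mass-weighted centre of a system or atom subset
#'
#' @param system an [atomic_system()].
#' @param atoms optional atom indices; default all.
#' @return Length-3 numeric, Angstrom.
#' @export
center_of_mass <- function(system, atoms = NULL) {
  if (is.null(atoms)) atoms <- seq_len(nrow(system$atoms))
  m <- element_mass(system$atoms$element[atoms])
  xyz <- coords_of(system)[atoms, , drop = FALSE]
  colSums(xyz * m) / sum(m)
}

#' Read a molecular geometry from a file
#'
#' XYZ files use the standard dialect (atom count, comment line, then
#' `element x y z` in Angstrom). PDB files are parsed through ATOM/HETATM
#' records; residues become fragment ids, with
#' water residues tagged as solvent and everything else as solute.
#'
#' @param path file path.
#' @param format `"xyz"` or `"pdb"`; guessed from the extension by default.
#' @param charge,multiplicity,basis passed to [atomic_system()].
#' @param frame which frame/MODEL to return for multi-frame files.
#' @return An [atomic_system()].
#' @export
load_geometry <- function(path, format = c("auto", "xyz", "pdb"),
                          charge = 0L, multiplicity = NULL,
                          basis = "sto-3g", frame = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "xyz") {
    frames <- read_xyz_frames(path)
    if (frame > length(frames)) stop("file has only ", length(frames), " frame(s)")
    f <- frames[[frame]]
    atomic_system(f$element, f$xyz, charge = charge,
                  multiplicity = multiplicity, basis = basis)
  } else {
    read_pdb_system(path, charge = charge, multiplicity = multiplicity,
                    basis = basis, frame = frame)
  }
}

# Minimal multi-frame XYZ reader (2 header lines per frame).
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) < 3L) stop("XYZ parse error: file too short")
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L) stop("XYZ parse error at line ", i)
    if (i + 1L + nat > length(lines)) stop("XYZ parse error: truncated frame")
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + nat)]), "\\s+")
    el <- vapply(rows, `[[`, "", 1L)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("XYZ parse error: non-numeric coordinates")
    element_number(el)  # errors on unknown symbols
    frames[[length(frames) + 1L]] <- list(element = el, xyz = xyz,
                                          comment = lines[i + 1L])
    i <- i + 2L + nat
  }
  frames
}

read_pdb_system <- function(path, charge, multiplicity, basis, frame = 1L) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  if (length(starts) >= 1L) {
    ends <- grep("^ENDMDL", lines)
    if (frame > length(starts)) stop("PDB has only ", length(starts), " MODEL(s)")
    lines <- lines[(starts[frame] + 1L):(ends[frame] - 1L)]
  }
  rec <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  if (length(rec) == 0L) stop("PDB parse error: no ATOM/HETATM records")
  el <- trimws(substr(rec, 77, 78))
  fallback <- !nzchar(el)
  if (any(fallback)) {
    nm <- trimws(substr(rec[fallback], 13, 16))
    el[fallback] <- sub("^([A-Za-z]).*", "\\1", nm)
  }
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
  xyz <- cbind(as.numeric(substr(rec, 31, 38)),
               as.numeric(substr(rec, 39, 46)),
               as.numeric(substr(rec, 47, 54)))
  if (anyNA(xyz)) stop("PDB parse error: bad coordinates")
  resname <- trimws(substr(rec, 18, 20))
  resid <- as.integer(substr(rec, 23, 26))
  chain <- substr(rec, 22, 22)
  frag <- as.integer(factor(paste(chain, resid)))
  role <- ifelse(resname %in% c("HOH", "WAT", "SOL", "TIP", "T3P"),
                 "solvent", "solute")
  atomic_system(el, xyz, charge = charge, multiplicity = multiplicity,
                basis = basis, fragment = frag, role = role)
}

#' Define an active/inactive partition of the QM atoms
#'
#' The active selection is either an explicit vector of atom indices or a
#' distance rule selecting whole solvent molecules closest to a reference
#' point. The reference point is the solute centre of mass (`ref = "cm"`),
#' the midpoint of two reference atoms such as the N-O group
#' (`ref = "no"`), or an explicit point. A solvent molecule's distance is
#' measured from its oxygen atom by default (`measure = "oxygen"`); this is
#' a documented convention, configurable to `"cm"` or `"closest"`. Exact
#' distance ties are broken toward the lower atom index.
#'
#' @param system an [atomic_system()].
#' @param active integer atom indices (1-based), or a list rule
#'   `list(n_closest =, ref =, ref_atoms =, measure =)`.
#' @return Object of class `region_partition` with `active_atoms`,
#'   `inactive_atoms` and `classical_sites` (empty here; filled by
#'   [select_layers()]).
#' @export
define_partition <- function(system, active) {
  n <- nrow(system$atoms)
  if (is.list(active) && !is.null(active$n_closest)) {
    active <- closest_solvent_selection(system, active)
  }
  active <- sort(unique(as.integer(active)))
  if (length(active) == 0L) stop("active set must not be empty")
  if (any(active < 1L | active > n)) stop("active atom index out of range")
  if (anyDuplicated(c(active, setdiff(seq_len(n), active)))) {
    stop("active and inactive sets overlap")
  }
  structure(list(
    active_atoms = active,
    inactive_atoms = setdiff(seq_len(n), active),
    classical_sites = integer(0)
  ), class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition: %d active / %d inactive atoms>\n",
              length(x$active_atoms), length(x$inactive_atoms)))
  invisible(x)
}

# Distance rule: solute (role == "solute" or fragment of atom 1) is always
# active; the n_closest whole solvent fragments are added.
closest_solvent_selection <- function(system, rule) {
  measure <- rule$measure %||% "oxygen"
  ref <- rule$ref %||% "cm"
  role <- system$atoms$role
  frag <- system$atoms$fragment
  if (all(is.na(role))) stop("distance rule needs solute/solvent role tags")
  solute <- which(role == "solute")
  if (length(solute) == 0L) stop("no solute atoms tagged")
  refpt <- if (is.numeric(ref)) {
    ref
  } else if (identical(ref, "cm")) {
    center_of_mass(system, solute)
  } else if (identical(ref, "no")) {
    ra <- rule$ref_atoms
    if (is.null(ra) || length(ra) != 2L) {
      stop("ref = \"no\" needs ref_atoms = c(i, j)")
    }
    colMeans(coords_of(system)[ra, , drop = FALSE])
  } else stop("unknown reference '", ref, "'")
  solv_frags <- sort(unique(frag[role == "solvent"]))
  if (rule$n_closest > length(solv_frags)) {
    stop("n_closest exceeds the number of solvent molecules (",
         length(solv_frags), ")")
  }
  d <- vapply(solv_frags, function(f) {
    idx <- which(frag == f & role == "solvent")
    solvent_distance(system, idx, refpt, measure)
  }, numeric(1))
  # stable sort: ties go to the fragment containing the lower atom index
  keep <- solv_frags[order(d, solv_frags)][seq_len(rule$n_closest)]
  sort(c(solute, which(frag %in% keep & role == "solvent")))
}

solvent_distance <- function(system, idx, refpt, measure) {
  xyz <- coords_of(system)[idx, , drop = FALSE]
  if (measure == "oxygen") {
    o <- idx[system$atoms$element[idx] == "O"]
    if (length(o) == 0L) stop("solvent fragment without oxygen; use measure = \"cm\"")
    p <- coords_of(system)[min(o), ]
    sqrt(sum((p - refpt)^2))
  } else if (measure == "cm") {
    sqrt(sum((center_of_mass(system, idx) - refpt)^2))
  } else if (measure == "closest") {
    min(sqrt(rowSums((xyz - matrix(refpt, nrow(xyz), 3, byrow = TRUE))^2)))
  } else stop("unknown distance measure '", measure, "'")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Subset a system by atom indices, keeping tags; electron bookkeeping is
# recomputed from charge/multiplicity supplied by the caller.
subset_system <- function(system, atoms, charge = 0L, multiplicity = NULL) {
  a <- system$atoms[atoms, , drop = FALSE]
  atomic_system(a$element, as.matrix(a[, c("x", "y", "z")]),
                charge = charge, multiplicity = multiplicity,
                basis = a$basis, fragment = a$fragment, role = a$role)
}
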