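# Solvation-snapshot machinery: droplet carving, QM-shell and active-water
# selection, out-of-plane angles, ensemble statistics, and the synthetic
# snapshot generator that stands in for molecular-dynamics sampling.

#' Built-in aminoxyl radical solute
#'
#' A small planar H2N-O radical (doublet) used as the default solute of the
#' synthetic snapshot generator; the out-of-plane reference quadruple
#' (analogous to the C-C-N-O quadruple of cyclic nitroxides) is
#' H, H, N, O = atoms 3, 4, 1, 2.
#'
#' @param basis basis label for the solute atoms.
#' @return An [atomic_system()] tagged as solute (fragment 0).
#' @export
h2no_radical <- function(basis = "sto-3g") {
  # N at origin, N-O 1.28 A along +z; N-H 1.01 A, H-N-H ~ 115 deg, planar
  hx <- 1.01 * sin(57.5 * pi / 180)
  hz <- -1.01 * cos(57.5 * pi / 180)
  atomic_system(
    c("N", "O", "H", "H"),
    rbind(c(0, 0, 0), c(0, 0, 1.28), c(hx, 0, hz), c(-hx, 0, hz)),
    charge = 0L, multiplicity = 2L, basis = basis,
    fragment = rep(0L, 4), role = rep("solute", 4)
  )
}

# Rigid water geometry (O at origin, bisector along +z), Angstrom.
water_template <- function() {
  r <- 0.9572; a <- 104.52 * pi / 180
  rbind(O = c(0, 0, 0),
        H1 = c(r * sin(a / 2), 0, r * cos(a / 2)),
        H2 = c(-r * sin(a / 2), 0, r * cos(a / 2)))
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

rotation_about_axis <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  ct * diag(3) + st * rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]),
                            c(-u[2], u[1], 0)) + (1 - ct) * outer(u, u)
}

#' Generate synthetic solvation snapshots
#'
#' Stands in for molecular-dynamics sampling: each frame is the rigid
#' solute, distorted by a small random out-of-plane rotation of its N-O
#' bond to emulate the pyramidalization spread seen in sampled
#' trajectories, surrounded by rigid water molecules packed into a sphere
#' by rejection sampling (minimum intermolecular O-O / O-heavy-atom
#' distance `min_dist`) with uniformly random orientations. Deterministic
#' for a given seed.
#'
#' @param seed integer RNG seed (mandatory, reproducibility).
#' @param n_frames number of frames.
#' @param solute an [atomic_system()] tagged as solute; default
#'   [h2no_radical()].
#' @param n_waters waters per frame.
#' @param box_radius sphere radius (Angstrom) the water oxygens are drawn in.
#' @param min_dist minimum O-O and O-solute-heavy-atom distance (Angstrom).
#' @param oop_sd standard deviation (degrees) of the solute out-of-plane
#'   distortion; 0 disables it.
#' @param oop_atoms the four atoms (plane a, b, c and apex d) defining the
#'   distortion; default the solute's H, H, N, O quadruple.
#' @param water_basis basis label for the solvent atoms.
#' @return List of [atomic_system()] frames (class `snapshot_set`).
#' @export
generate_synthetic_snapshots <- function(seed, n_frames, solute = NULL,
                                         n_waters = 20L, box_radius = 8,
                                         min_dist = 2.4, oop_sd = 10,
                                         oop_atoms = c(3L, 4L, 1L, 2L),
                                         water_basis = "sto-3g") {
  if (n_waters < 0) stop("n_waters must be >= 0")
  set.seed(as.integer(seed))
  if (is.null(solute)) solute <- h2no_radical()
  sxyz0 <- coords_of(solute)
  heavy <- solute$atoms$element != "H"
  wt <- water_template()
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    sxyz <- sxyz0
    if (oop_sd > 0) {
      # rotate the apex atom (O) about the axis through c parallel to a-b
      a <- sxyz[oop_atoms[1], ]; b <- sxyz[oop_atoms[2], ]
      cc <- sxyz[oop_atoms[3], ]; d <- oop_atoms[4]
      theta <- rnorm(1, 0, oop_sd) * pi / 180
      R <- rotation_about_axis(b - a, theta)
      sxyz[d, ] <- as.vector(R %*% (sxyz[d, ] - cc)) + cc
    }
    centers <- matrix(numeric(0), 0, 3)
    placed <- list()
    attempts <- 0L
    while (nrow(centers) < n_waters) {
      attempts <- attempts + 1L
      if (attempts > 500L * max(1L, n_waters)) {
        stop("failed to pack ", n_waters, " waters into radius ",
             box_radius, " A; increase box_radius")
      }
      p <- runif(3, -1, 1)
      if (sum(p^2) > 1) next
      p <- p * box_radius
      if (nrow(centers) > 0 &&
          min(sqrt(rowSums((centers - matrix(p, nrow(centers), 3,
                                             byrow = TRUE))^2))) < min_dist) next
      dsol <- sqrt(rowSums((sxyz[heavy, , drop = FALSE] -
                              matrix(p, sum(heavy), 3, byrow = TRUE))^2))
      if (min(dsol) < min_dist) next
      xyz <- t(random_rotation() %*% t(wt)) +
        matrix(p, 3, 3, byrow = TRUE)
      centers <- rbind(centers, p)
      placed[[length(placed) + 1L]] <- xyz
    }
    el <- c(solute$atoms$element, rep(c("O", "H", "H"), length(placed)))
    xyz <- rbind(sxyz, do.call(rbind, placed))
    frag <- c(solute$atoms$fragment,
              rep(seq_along(placed), each = 3))
    role <- c(solute$atoms$role, rep("solvent", 3 * length(placed)))
    basis <- c(solute$atoms$basis, rep(water_basis, 3 * length(placed)))
    frames[[f]] <- atomic_system(el, xyz, charge = solute$net_charge,
                                 multiplicity = solute$multiplicity,
                                 basis = basis, fragment = frag, role = role)
  }
  structure(frames, class = "snapshot_set",
            seed = seed, oop_atoms = oop_atoms)
}

#' Carve a spherical droplet around the solute
#'
#' Keeps the solute whole and every solvent molecule whose reference atom
#' (oxygen by default) lies within `radius` of the solute centre of mass.
#'
#' @param frame an [atomic_system()] with solute/solvent role tags.
#' @param radius droplet radius in Angstrom (the sampled protocol uses 13).
#' @param measure how a solvent molecule's distance is defined: `"oxygen"`
#'   (default convention), `"cm"` or `"closest"`.
#' @return The carved [atomic_system()].
#' @export
carve_droplet <- function(frame, radius = 13, measure = "oxygen") {
  role <- frame$atoms$role
  if (anyNA(role)) stop("frame has untagged atoms; solute/solvent roles required")
  solute <- which(role == "solute")
  cm <- center_of_mass(frame, solute)
  frag <- frame$atoms$fragment
  keep <- solute
  for (f in sort(unique(frag[role == "solvent"]))) {
    idx <- which(frag == f & role == "solvent")
    if (solvent_distance(frame, idx, cm, measure) <= radius) {
      keep <- c(keep, idx)
    }
  }
  subset_system(frame, sort(keep), charge = frame$net_charge,
                multiplicity = frame$multiplicity)
}

#' Split a droplet into QM (active/inactive) and classical layers
#'
#' Waters whose reference atom lies within `qm_radius` of the solute centre
#' of mass form the QM shell; of those, the `n_active` closest to the
#' reference point of the chosen scheme (`"NO"`: midpoint of the N-O group;
#' `"CM"`: solute centre of mass) join the solute in the active region and
#' the rest are inactive. Waters outside the shell become classical sites.
#'
#' @param droplet an [atomic_system()] from [carve_droplet()].
#' @param qm_radius QM shell radius in Angstrom (the sampled protocol
#'   uses 3.5).
#' @param n_active number of active waters (0 for a solute-only active
#'   region).
#' @param scheme `"NO"` or `"CM"`.
#' @param no_atoms indices of the N and O atoms for scheme `"NO"`; guessed
#'   from the solute's first N and first O when omitted.
#' @param measure distance convention for the shell cut (see
#'   [carve_droplet()]).
#' @param embedding `"fq"`, `"fixed"` or `"none"`: type of classical layer
#'   returned.
#' @param fq_params,charge_preset parameter-set names for the layer.
#' @return List: `system` (QM droplet subset), `partition`
#'   ([define_partition()] result on it), `layer` (an [fq_layer()] or [fixed_charge_layer()] or NULL)
#'   and `counts`.
#' @export
select_layers <- function(droplet, qm_radius = 3.5, n_active = 0L,
                          scheme = c("NO", "CM"), no_atoms = NULL,
                          measure = "oxygen", embedding = "fq",
                          fq_params = "water-radical",
                          charge_preset = "tip3p-charges") {
  scheme <- match.arg(scheme)
  role <- droplet$atoms$role
  frag <- droplet$atoms$fragment
  solute <- which(role == "solute")
  cm <- center_of_mass(droplet, solute)
  solv_frags <- sort(unique(frag[role == "solvent"]))
  d_shell <- vapply(solv_frags, function(f) {
    solvent_distance(droplet, which(frag == f & role == "solvent"), cm, measure)
  }, numeric(1))
  qm_frags <- solv_frags[d_shell <= qm_radius]
  cl_frags <- setdiff(solv_frags, qm_frags)
  if (n_active > length(qm_frags)) {
    stop("n_active (", n_active, ") exceeds the QM-shell water count (",
         length(qm_frags), ")")
  }
  qm_atoms <- sort(c(solute, which(frag %in% qm_frags & role == "solvent")))
  qm_sys <- subset_system(droplet, qm_atoms, charge = droplet$net_charge,
                          multiplicity = droplet$multiplicity)
  # active selection on the QM subsystem
  sel <- if (n_active > 0) {
    ref_atoms <- NULL
    if (scheme == "NO") {
      if (is.null(no_atoms)) {
        no_atoms <- c(which(qm_sys$atoms$element == "N" &
                              qm_sys$atoms$role == "solute")[1],
                      which(qm_sys$atoms$element == "O" &
                              qm_sys$atoms$role == "solute")[1])
      }
      if (anyNA(no_atoms)) stop("scheme 'NO' needs identifiable N and O atoms")
      list(n_closest = n_active, ref = "no", ref_atoms = no_atoms,
           measure = measure)
    } else {
      list(n_closest = n_active, ref = "cm", measure = measure)
    }
  } else {
    which(qm_sys$atoms$role == "solute")
  }
  part <- define_partition(qm_sys, sel)
  layer <- NULL
  if (length(cl_frags) > 0 && embedding != "none") {
    cl_atoms <- which(frag %in% cl_frags & role == "solvent")
    pos <- coords_of(droplet)[cl_atoms, , drop = FALSE]
    el <- droplet$atoms$element[cl_atoms]
    fr <- match(frag[cl_atoms], cl_frags)
    layer <- if (embedding == "fq") {
      fq_layer(pos, el, fr, params = fq_params, Q = 0)
    } else {
      fixed_charge_layer(pos, elements = el, preset = charge_preset,
                         fragment = fr)
    }
  }
  list(system = qm_sys, partition = part, layer = layer,
       counts = c(n_droplet_waters = length(solv_frags),
                  n_qm_waters = length(qm_frags),
                  n_active_waters = n_active,
                  n_inactive_waters = length(qm_frags) - n_active,
                  n_classical_waters = length(cl_frags)))
}

#' Out-of-plane (pyramidalization) angle
#'
#' Improper angle of the apex atom `d` with respect to the plane through
#' atoms `a`, `b`, `c`: the angle between the bond c->d and the a-b-c
#' plane, in (-90, 90] degrees. The sign follows the side of the plane
#' normal `(a - c) x (b - c)` the apex lies on; a planar arrangement gives
#' exactly 0 and mirror images flip the sign.
#'
#' @param frame an [atomic_system()].
#' @param atoms integer vector of the four distinct atom indices
#'   `c(a, b, c, d)` (for nitroxides: C, C, N, O).
#' @return Angle in degrees.
#' @export
out_of_plane_angle <- function(frame, atoms) {
  if (length(unique(atoms)) != 4L) stop("four distinct atom indices required")
  xyz <- coords_of(frame)[atoms, ]
  a <- xyz[1, ]; b <- xyz[2, ]; cc <- xyz[3, ]; d <- xyz[4, ]
  nrm <- pracma_cross(a - cc, b - cc)
  nn <- sqrt(sum(nrm^2))
  v <- d - cc
  vv <- sqrt(sum(v^2))
  if (nn < 1e-10 * max(1, vv)) stop("plane atoms are (near-)collinear")
  asin(pmin(1, pmax(-1, sum(nrm * v) / (nn * vv)))) * 180 / pi
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Ensemble statistics over snapshot values
#'
#' Mean, unbiased standard deviation and the standard error
#' se = sigma / sqrt(N) (67% confidence) over per-snapshot values.
#'
#' @param values numeric vector (N >= 2) of per-snapshot quantities.
#' @return List with `n`, `mean`, `sigma`, `se`.
#' @export
ensemble_stats <- function(values) {
  n <- length(values)
  if (n < 2L) stop("ensemble statistics need at least 2 values")
  s <- sd(values)
  list(n = n, mean = mean(values), sigma = s, se = s / sqrt(n))
}

#' Per-snapshot hyperfine pipeline
#'
#' For every frame: carve the droplet, split the layers, run the multilevel
#' SCF with the chosen functional and classical embedding, and evaluate the
#' hyperfine coupling at the requested solute nucleus, recording the
#' out-of-plane angle alongside. Deterministic given frames and settings.
#'
#' @param frames list of tagged [atomic_system()] frames.
#' @param functional a [functional_spec()] or preset name.
#' @param droplet_radius,qm_radius,n_active,scheme,measure,embedding layer
#'   construction settings (see [carve_droplet()] and [select_layers()]).
#' @param nucleus_element element of the reported nucleus within the solute
#'   (default `"N"`).
#' @param oop_atoms four solute atom indices for the out-of-plane angle.
#' @param ... passed to [uml_scf()].
#' @return Object of class `snapshot_ensemble`: per-snapshot `ledger`
#'   data.frame (frame, scheme, n_active, hcc in Gauss, oop in degrees,
#'   layer counts) and `stats` from [ensemble_stats()] (NULL when fewer
#'   than 2 frames).
#' @export
snapshot_hcc <- function(frames, functional = "uhf", droplet_radius = 13,
                         qm_radius = 3.5, n_active = 0L, scheme = "NO",
                         measure = "oxygen", embedding = "fq",
                         nucleus_element = "N",
                         oop_atoms = c(3L, 4L, 1L, 2L), ...) {
  rows <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    drop_ <- carve_droplet(fr, radius = droplet_radius, measure = measure)
    lay <- select_layers(drop_, qm_radius = qm_radius, n_active = n_active,
                         scheme = scheme, measure = measure,
                         embedding = embedding)
    res <- uml_scf(lay$system, lay$partition, functional = functional,
                   embedding = lay$layer, ...)
    nuc <- which(lay$system$atoms$element == nucleus_element &
                   lay$system$atoms$role == "solute")[1]
    if (is.na(nuc)) stop("nucleus element not found in the solute")
    hf <- hyperfine(res, nuclei = nuc)
    oop <- tryCatch(out_of_plane_angle(fr, oop_atoms), error = function(e) NA_real_)
    data.frame(frame = i, scheme = scheme, n_active = n_active,
               embedding = embedding,
               hcc = hf$table$A_iso[1], oop = oop,
               n_qm_waters = lay$counts[["n_qm_waters"]],
               n_classical_waters = lay$counts[["n_classical_waters"]],
               E_total = res$E_total)
  })
  ledger <- do.call(rbind, rows)
  structure(list(
    ledger = ledger,
    stats = if (nrow(ledger) >= 2) ensemble_stats(ledger$hcc) else NULL
  ), class = "snapshot_ensemble")
}

#' @export
print.snapshot_ensemble <- function(x, ...) {
  cat(sprintf("<snapshot_ensemble: %d snapshot(s)>\n", nrow(x$ledger)))
  if (!is.null(x$stats)) {
    cat(sprintf("  hcc = %.4f +/- %.4f G (sigma %.4f, N = %d)\n",
                x$stats$mean, x$stats$se, x$stats$sigma, x$stats$n))
  }
  invisible(x)
}
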