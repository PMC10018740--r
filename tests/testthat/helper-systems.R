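# Shared fixtures, built in code. Engines are memoized across test files --
# the ERI build is the expensive step and every fixture is reused.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

water_geom <- function(shift = c(0, 0, 0)) {
  rbind(c(0, 0, 0.1173), c(0, 0.7572, -0.4692), c(0, -0.7572, -0.4692)) +
    matrix(shift, 3, 3, byrow = TRUE)
}

fix_water <- function() memo("water", {
  atomic_system(c("O", "H", "H"), water_geom())
})

fix_water_cation <- function() memo("water+", {
  atomic_system(c("O", "H", "H"), water_geom(), charge = 1L, multiplicity = 2L)
})

# asymmetric water-dimer radical cation (open shell, 14 AOs)
fix_dimer_cation <- function() memo("dimer+", {
  atomic_system(rep(c("O", "H", "H"), 2),
                rbind(water_geom(), water_geom(c(2.9, 0.4, 0.2))),
                charge = 1L, multiplicity = 2L)
})

# aminoxyl radical + one hydrogen-bonded water (neutral doublet)
fix_radical_water <- function() memo("h2no+w", {
  rad <- h2no_radical()
  w <- water_geom(c(0, 2.8, 1.0))
  atomic_system(c(rad$atoms$element, "O", "H", "H"),
                rbind(as.matrix(rad$atoms[, c("x", "y", "z")]), w),
                charge = 0L, multiplicity = 2L,
                fragment = c(rad$atoms$fragment, 1L, 1L, 1L),
                role = c(rad$atoms$role, rep("solvent", 3)))
})

fix_engine <- function(system, key) memo(paste0("eng:", key), {
  scf_engine(system)
})

fix_uhf <- function(system, key, functional = functional_spec("uhf")) {
  memo(paste0("scf:", key, ":", functional$name), {
    full_scf(system, functional, engine = fix_engine(system, key))
  })
}

# purified initial densities for partition tests
fix_initial <- function(system, key, functional = functional_spec("uhf")) {
  memo(paste0("init:", key), {
    eng <- fix_engine(system, key)
    purify_guess(system, sad_guess(system, engine = eng), functional,
                 engine = eng)
  })
}

# tagged multi-water frame with waters at controlled oxygen distances (A)
# along +x from the solute centre of mass
frame_with_waters_at <- function(dists) {
  rad <- h2no_radical()
  cm <- center_of_mass(rad)
  wt <- rbind(c(0, 0, 0), c(0.9572, 0, 0), c(-0.2399, 0.9266, 0))
  xyz <- as.matrix(rad$atoms[, c("x", "y", "z")])
  el <- rad$atoms$element; frag <- rad$atoms$fragment; role <- rad$atoms$role
  for (i in seq_along(dists)) {
    w <- wt + matrix(cm + c(dists[i], 0, 0), 3, 3, byrow = TRUE)
    xyz <- rbind(xyz, w)
    el <- c(el, "O", "H", "H")
    frag <- c(frag, rep(i, 3))
    role <- c(role, rep("solvent", 3))
  }
  atomic_system(el, xyz, charge = 0L, multiplicity = 2L,
                fragment = frag, role = role)
}

# independent numerical-quadrature overlap of two s-type contracted shells
# on a dense radial/angular product grid (used as an integral oracle)
quad_overlap_s <- function(e1, c1, R1, e2, c2, R2, n = 80) {
  # integrate on a cube grid centred between the shells
  h <- 12 / n
  g <- seq(-6 + h / 2, 6 - h / 2, length.out = n)
  mid <- (R1 + R2) / 2
  tot <- 0
  for (x in g) {
    yz <- expand.grid(y = g, z = g)
    p <- cbind(x, yz$y, yz$z) + matrix(mid, nrow(yz), 3, byrow = TRUE)
    r1 <- rowSums((p - matrix(R1, nrow(p), 3, byrow = TRUE))^2)
    r2 <- rowSums((p - matrix(R2, nrow(p), 3, byrow = TRUE))^2)
    f1 <- colSums(c1 * exp(-outer(e1, r1)))
    f2 <- colSums(c2 * exp(-outer(e2, r2)))
    tot <- tot + sum(f1 * f2) * h^3
  }
  tot
}
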