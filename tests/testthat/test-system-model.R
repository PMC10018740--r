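# Geometry, parsing, partitions and AO bookkeeping.

test_that("XYZ files parse with correct atoms and coordinates", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "a water molecule",
               "O  0.0 0.0 0.1173",
               "H  0.0 0.7572 -0.4692",
               "H  0.0 -0.7572 -0.4692"), f)
  sys <- load_geometry(f)
  expect_equal(nrow(sys$atoms), 3)
  expect_equal(sys$atoms$Z, c(8, 1, 1))
  expect_equal(sys$atoms$y[2], 0.7572)
  expect_equal(sys$multiplicity, 1L)
})

test_that("a single H atom with supplied multiplicity is a valid doublet", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "hydrogen", "H 0 0 0"), f)
  sys <- load_geometry(f, multiplicity = 2)
  expect_equal(sys$n_alpha, 1L)
  expect_equal(sys$n_beta, 0L)
})

test_that("bad XYZ input raises parse errors", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "mystery element", "Xx 0 0 0"), f)
  expect_error(load_geometry(f), "unknown element")
  writeLines(character(0), f)
  expect_error(load_geometry(f), "parse error|too short")
})

test_that("PDB atom count matches an independent record count", {
  f <- withr::local_tempfile(fileext = ".pdb")
  rec <- function(i, el, res, resid, x, y, z) {
    sprintf("%-6s%5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            if (res == "HOH") "HETATM" else "ATOM", i, el, res, resid,
            x, y, z, el)
  }
  lines <- c(rec(1, "N", "LIG", 1, 0, 0, 0), rec(2, "O", "LIG", 1, 0, 0, 1.3),
             rec(3, "O", "HOH", 2, 3, 0, 0), rec(4, "H", "HOH", 2, 3.9, 0, 0),
             rec(5, "H", "HOH", 2, 2.8, 0.9, 0), "END")
  writeLines(lines, f)
  sys <- load_geometry(f, format = "pdb", multiplicity = 2)
  n_records <- sum(grepl("^(ATOM  |HETATM)", lines))   # line-count oracle
  expect_equal(nrow(sys$atoms), n_records)
  expect_equal(sys$atoms$role, c("solute", "solute", rep("solvent", 3)))
  expect_equal(length(unique(sys$atoms$fragment)), 2)
})

test_that("multiplicity parity is enforced", {
  expect_error(atomic_system("O", matrix(0, 1, 3), multiplicity = 2),
               "inconsistent")
  expect_silent(atomic_system("O", matrix(0, 1, 3), multiplicity = 3))
})

test_that("AO index map covers the basis without gaps or overlaps", {
  sys <- atomic_system(c("O", "H", "N"),
                       rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0)),
                       multiplicity = 1,
                       basis = c("sto-3g", "6-31g", "sto-3g"))
  shells <- basis_shells(sys)
  ao_atom <- attr(shells, "ao_atom")
  n_ao <- attr(shells, "n_ao")
  expect_equal(n_ao, 5 + 2 + 5)   # O/sto-3g + H/6-31g + N/sto-3g
  per_atom <- lapply(1:3, function(i) which(ao_atom == i))
  expect_equal(sort(unlist(per_atom)), seq_len(n_ao))
  expect_true(all(diff(unlist(per_atom)) == 1))
})

test_that("explicit partitions validate their invariants", {
  sys <- fix_radical_water()
  p <- define_partition(sys, 1:7)
  expect_equal(p$inactive_atoms, integer(0))
  expect_error(define_partition(sys, integer(0)), "empty")
  expect_error(define_partition(sys, c(1, 99)), "out of range")
  p2 <- define_partition(sys, 1:4)
  expect_equal(sort(c(p2$active_atoms, p2$inactive_atoms)), 1:7)
})

test_that("distance-rule selection matches a brute-force sort", {
  fr <- frame_with_waters_at(c(4.2, 3.1, 5.8))
  p <- define_partition(fr, list(n_closest = 2, ref = "cm"))
  # brute force: waters sorted by oxygen distance to the solute CM
  cm <- center_of_mass(fr, which(fr$atoms$role == "solute"))
  o_idx <- which(fr$atoms$element == "O" & fr$atoms$role == "solvent")
  d <- sqrt(rowSums((as.matrix(fr$atoms[o_idx, c("x", "y", "z")]) -
                       matrix(cm, length(o_idx), 3, byrow = TRUE))^2))
  want_frags <- fr$atoms$fragment[o_idx][order(d)[1:2]]
  got_waters <- setdiff(p$active_atoms, which(fr$atoms$role == "solute"))
  expect_setequal(unique(fr$atoms$fragment[got_waters]), want_frags)
  expect_error(define_partition(fr, list(n_closest = 5, ref = "cm")),
               "exceeds")
})

test_that("exactly equidistant waters break ties to the lower atom index", {
  # single-atom solute at the origin so the mirrored oxygens are at exactly
  # the same distance in floating point
  w1 <- rbind(c(4, 0, 0), c(4.9572, 0, 0), c(3.76, 0.93, 0))
  w2 <- w1 %*% diag(c(-1, 1, 1))
  sys <- atomic_system(c("N", rep(c("O", "H", "H"), 2)),
                       rbind(c(0, 0, 0), w1, w2),
                       multiplicity = 2,
                       fragment = c(0L, rep(1:2, each = 3)),
                       role = c("solute", rep("solvent", 6)))
  p <- define_partition(sys, list(n_closest = 1, ref = "cm"))
  got <- setdiff(p$active_atoms, 1L)
  expect_equal(unique(sys$atoms$fragment[got]), 1L)  # lower index wins
})
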