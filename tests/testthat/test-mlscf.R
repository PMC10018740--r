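# Frozen inactive terms, the multilevel Fock/energy, and the active-space SCF.

ml_setup <- function(sys, key, active, functional = functional_spec("uhf")) {
  eng <- fix_engine(sys, key)
  init <- fix_initial(sys, key)
  part <- define_partition(sys, active)
  parts <- partition_densities(sys, init, part)
  frozen <- frozen_inactive_terms(eng, parts$partitioned, functional)
  list(eng = eng, init = init, part = part, parts = parts, frozen = frozen,
       fun = functional)
}

test_that("an empty inactive block freezes to zero with nuclear-only constant", {
  st <- ml_setup(fix_water(), "water", 1:3)
  expect_equal(max(abs(st$frozen$twoe_B_alpha)), 0)
  expect_equal(st$frozen$E_B_const, st$eng$E_nn)
})

test_that("frozen 2e_B matches an independent full-Fock difference", {
  st <- ml_setup(fix_radical_water(), "h2no+w", 1:4)
  pd <- st$parts$partitioned
  # oracle: two full UHF Fock builds; the two-electron parts differ by the
  # inactive contribution
  fk_full <- mlscf:::fock_full(st$eng, st$fun,
                               pd$D_A_alpha + pd$D_B_alpha,
                               pd$D_A_beta + pd$D_B_beta)
  fk_A <- mlscf:::fock_full(st$eng, st$fun, pd$D_A_alpha, pd$D_A_beta)
  expect_equal(fk_full$Fa - fk_A$Fa, st$frozen$twoe_B_alpha,
               tolerance = 1e-10)
  expect_equal(fk_full$Fb - fk_A$Fb, st$frozen$twoe_B_beta,
               tolerance = 1e-10)
})

test_that("recomputing frozen terms is bitwise deterministic", {
  st <- ml_setup(fix_radical_water(), "h2no+w", 1:4)
  again <- frozen_inactive_terms(st$eng, st$parts$partitioned, st$fun)
  expect_identical(again$twoe_B_alpha, st$frozen$twoe_B_alpha)
  expect_identical(again$hash, st$frozen$hash)
})

test_that("with no inactive block the multilevel Fock is the plain UHF Fock", {
  st <- ml_setup(fix_water_cation(), "water+", 1:3)
  pd <- st$parts$partitioned
  fk_ml <- build_ml_fock(st$eng, pd$D_A_alpha, pd$D_A_beta, st$frozen, st$fun)
  fk_ref <- mlscf:::fock_full(st$eng, st$fun, pd$D_A_alpha, pd$D_A_beta)
  expect_equal(fk_ml$F_alpha, fk_ref$Fa, tolerance = 1e-10)
  expect_equal(fk_ml$F_beta, fk_ref$Fb, tolerance = 1e-10)
})

test_that("multilevel Fock is the derivative of the multilevel energy", {
  for (fn in c("uhf", "pbe0")) {
    st <- ml_setup(fix_radical_water(), "h2no+w", 1:4,
                   functional = functional_spec(fn, grid_level = 2))
    pd <- st$parts$partitioned
    fk <- build_ml_fock(st$eng, pd$D_A_alpha, pd$D_A_beta, st$frozen, st$fun)
    d <- 1e-6
    set.seed(11)
    for (k in 1:3) {
      i <- sample(nrow(pd$S), 1); j <- sample(nrow(pd$S), 1)
      perturb <- function(sgn) {
        p <- pd
        p$D_A_alpha[i, j] <- p$D_A_alpha[i, j] + sgn * d
        if (i != j) p$D_A_alpha[j, i] <- p$D_A_alpha[j, i] + sgn * d
        ml_energy(st$eng, p, st$fun, frozen = st$frozen)[["E_total"]]
      }
      fd <- (perturb(1) - perturb(-1)) / (2 * d) / (1 + (i != j))
      expect_equal(fd, fk$F_alpha[i, j], tolerance = 1e-5)
    }
  }
})

test_that("alpha/beta swap symmetry of the multilevel Fock", {
  st <- ml_setup(fix_water(), "water", 1:2)
  pd <- st$parts$partitioned
  fk <- build_ml_fock(st$eng, pd$D_A_alpha, pd$D_A_beta, st$frozen, st$fun)
  pd_swap <- pd
  pd_swap$D_B_alpha <- pd$D_B_beta; pd_swap$D_B_beta <- pd$D_B_alpha
  pd_swap$D_A_alpha <- pd$D_A_beta; pd_swap$D_A_beta <- pd$D_A_alpha
  pd_swap$n_A_alpha <- pd$n_A_beta; pd_swap$n_A_beta <- pd$n_A_alpha
  pd_swap$n_B_alpha <- pd$n_B_beta; pd_swap$n_B_beta <- pd$n_B_alpha
  fk_swap <- build_ml_fock(st$eng, pd_swap$D_A_alpha, pd_swap$D_A_beta,
                           frozen_inactive_terms(st$eng, pd_swap, st$fun),
                           st$fun)
  expect_equal(fk_swap$F_alpha, fk$F_beta, tolerance = 1e-12)
  expect_equal(fk_swap$F_beta, fk$F_alpha, tolerance = 1e-12)
})

test_that("the multilevel energy reduces to the plain energy when B is empty", {
  st <- ml_setup(fix_water_cation(), "water+", 1:3)
  pd <- st$parts$partitioned
  bd <- ml_energy(st$eng, pd, st$fun)
  ref <- mlscf:::fock_full(st$eng, st$fun, pd$D_A_alpha, pd$D_A_beta)$E
  expect_equal(bd[["E_total"]], ref, tolerance = 1e-10)
})

test_that("nonadditive energy vanishes identically for pure Hartree-Fock", {
  st <- ml_setup(fix_radical_water(), "h2no+w", 1:4)
  bd <- ml_energy(st$eng, st$parts$partitioned, st$fun, frozen = st$frozen)
  expect_identical(bd[["E_nonadd"]], 0)
})

test_that("nonadditive xc is nonzero for DFT and the breakdown sums exactly", {
  fun <- functional_spec("pbe0", grid_level = 2)
  st <- ml_setup(fix_radical_water(), "h2no+w", 1:4, functional = fun)
  bd <- ml_energy(st$eng, st$parts$partitioned, fun, frozen = st$frozen)
  expect_gt(abs(bd[["E_nonadd"]]), 1e-8)
  expect_equal(sum(bd[c("E_A", "E_B", "E_int", "E_nonadd", "E_nn")]),
               bd[["E_total"]], tolerance = 1e-12)
})

test_that("zero-iteration runs return the partitioned state unchanged", {
  st <- ml_setup(fix_radical_water(), "h2no+w", 1:4)
  res <- run_uml_scf(fix_radical_water(), st$part, st$fun, st$parts$space,
                     st$frozen, partitioned = st$parts$partitioned,
                     engine = st$eng, max_iter = 0)
  expect_identical(res$partitioned$D_A_alpha, st$parts$partitioned$D_A_alpha)
  bd0 <- ml_energy(st$eng, st$parts$partitioned, st$fun, frozen = st$frozen)
  expect_equal(res$E_total, bd0[["E_total"]])
  expect_equal(res$n_iter, 0L)
})

test_that("frozen matrices and the inactive block survive the SCF untouched", {
  st <- ml_setup(fix_radical_water(), "h2no+w", 1:4)
  hash_before <- st$frozen$hash
  res <- run_uml_scf(fix_radical_water(), st$part, st$fun, st$parts$space,
                     st$frozen, partitioned = st$parts$partitioned,
                     engine = st$eng)
  expect_identical(res$frozen$hash, hash_before)
  expect_identical(res$partitioned$D_B_alpha, st$parts$partitioned$D_B_alpha)
  expect_identical(res$partitioned$D_B_beta, st$parts$partitioned$D_B_beta)
  # recomputing from the preserved inactive block gives identical matrices
  re <- frozen_inactive_terms(st$eng, res$partitioned, st$fun)
  expect_identical(re$twoe_B_alpha, res$frozen$twoe_B_alpha)
  # and the updated active block still satisfies every invariant
  expect_lt(check_partition(res$partitioned)$max_violation, 1e-7)
})

test_that("a distant inactive partner leaves the active atom at its isolated energy", {
  sys <- atomic_system(c("He", "He"), rbind(c(0, 0, 0), c(0, 0, 50)))
  res <- uml_scf(sys, 1L, functional = "uhf")
  he <- atomic_system("He", matrix(0, 1, 3))
  ref <- full_scf(he, functional_spec("uhf"))
  # E_A books the active block against all nuclei; at 50 A the cross terms
  # cancel against E_int and E_nn to the isolated-atom energy
  active_E <- res$E_total - ref$E_total   # total = 2 x isolated He
  expect_equal(active_E, ref$E_total, tolerance = 1e-6)
})

test_that("enlarging the active region is variationally monotone", {
  sys <- fix_radical_water()
  e_small <- uml_scf(sys, 1:4, functional = "uhf",
                     engine = fix_engine(sys, "h2no+w"))$E_total
  e_big <- uml_scf(sys, 1:7, functional = "uhf",
                   engine = fix_engine(sys, "h2no+w"))$E_total
  expect_lte(e_big, e_small + 1e-10)
})

test_that("energies decrease monotonically once DIIS settles", {
  sys <- fix_radical_water()
  res <- uml_scf(sys, 1:4, functional = "uhf",
                 engine = fix_engine(sys, "h2no+w"))
  tr <- res$energy_trace
  tail_tr <- tr[max(1, length(tr) - 3):length(tr)]
  expect_true(all(diff(tail_tr) < 1e-7))
})

test_that("inactive-space rotations leave energy and Fock invariant", {
  st <- ml_setup(fix_radical_water(), "h2no+w", 1:4)
  sp <- st$parts$space
  nB <- ncol(sp$C_occ_B_alpha)
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(nB * nB), nB)))
  LB_rot <- sp$C_occ_B_alpha %*% Q
  pd_rot <- st$parts$partitioned
  pd_rot$D_B_alpha <- mlscf:::sym(tcrossprod(LB_rot))
  frozen_rot <- frozen_inactive_terms(st$eng, pd_rot, st$fun)
  expect_equal(frozen_rot$twoe_B_alpha, st$frozen$twoe_B_alpha,
               tolerance = 1e-10)
  bd1 <- ml_energy(st$eng, st$parts$partitioned, st$fun)
  bd2 <- ml_energy(st$eng, pd_rot, st$fun)
  expect_equal(bd2[["E_total"]], bd1[["E_total"]], tolerance = 1e-10)
})

test_that("non-convergence raises a structured error carrying the trace", {
  sys <- fix_radical_water()
  err <- tryCatch(
    uml_scf(sys, 1:4, functional = "uhf", engine = fix_engine(sys, "h2no+w"),
            max_iter = 2, conv_grad = 1e-14, conv_energy = 0),
    mlscf_scf_not_converged = function(e) e)
  expect_s3_class(err, "mlscf_scf_not_converged")
  expect_true(length(err$trace) >= 1)
})
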