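# Partial Cholesky, PAO virtuals and assembled partitions.

test_that("partial Cholesky handles the textbook rank-1 and zero cases", {
  S <- diag(2)
  D <- diag(c(1, 0))
  L <- partial_cholesky_occupied(D, S, active_aos = 1L)
  expect_equal(ncol(L), 1)
  expect_equal(as.vector(L), c(1, 0))
  L0 <- partial_cholesky_occupied(matrix(0, 2, 2), S, active_aos = 1:2)
  expect_equal(ncol(L0), 0)
  expect_error(partial_cholesky_occupied(D, S, 1L, tau = 0), "positive")
  expect_error(partial_cholesky_occupied(D + 0.1, S, 1L), "idempotent")
})

test_that("all-AO pivots with tight tau recover the full density", {
  res <- fix_initial(fix_water(), "water")
  L <- partial_cholesky_occupied(res$D_alpha, res$S,
                                 active_aos = seq_len(nrow(res$S)),
                                 tau = 1e-10)
  expect_lt(max(abs(tcrossprod(L) - res$D_alpha)), 1e-8)
  expect_equal(ncol(L), 5)
})

test_that("restricted-pivot factor matches a dense partial-projection oracle", {
  # independent oracle: for an S-idempotent density and pivot set P, the
  # extracted block is the projection D(:,P) D(P,P)^-1 D(P,:) in the folded
  # metric -- computed here without any Cholesky factorization
  sys <- atomic_system(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  eng <- scf_engine(sys)
  res <- full_scf(sys, engine = eng)
  S <- eng$S
  Sh <- mlscf:::s_power(S, 0.5); Shm <- mlscf:::s_power(S, -0.5)
  Dp <- Sh %*% res$D_alpha %*% Sh
  P <- 1L
  DA_oracle <- Dp[, P, drop = FALSE] %*%
    solve(Dp[P, P, drop = FALSE]) %*% Dp[P, , drop = FALSE]
  DA_oracle <- Shm %*% DA_oracle %*% Shm
  L <- partial_cholesky_occupied(res$D_alpha, S, active_aos = P, tau = 1e-8)
  expect_equal(ncol(L), 1)
  expect_equal(tcrossprod(L), DA_oracle, tolerance = 1e-10)
})

test_that("PAO construction spans and orthogonalizes as specified", {
  eng <- fix_engine(fix_water(), "water")
  S <- eng$S
  n <- nrow(S)
  # no occupied orbitals, all AOs active: a Lowdin-orthonormal AO set
  V <- pao_virtuals(S, matrix(0, n, 0), seq_len(n))
  expect_equal(ncol(V), n)
  expect_equal(crossprod(V, S %*% V), diag(n), tolerance = 1e-10)
  # occupied spanning the whole space: no virtuals remain
  e <- eigen(S, symmetric = TRUE)
  C_full <- e$vectors %*% diag(1 / sqrt(e$values))
  expect_error(pao_virtuals(S, C_full, seq_len(n)), "no active virtual")
  # H2O occupied + PAOs on one H: orthogonality to ALL occupied
  res <- fix_initial(fix_water(), "water")
  Locc <- partial_cholesky_occupied(res$D_alpha, S, seq_len(n), tau = 1e-10)
  h_aos <- aos_on_atoms(fix_water(), 2L)
  Vh <- pao_virtuals(S, Locc, h_aos)
  expect_lt(max(abs(crossprod(Locc, S %*% Vh))), 1e-10)
  expect_equal(crossprod(Vh, S %*% Vh), diag(ncol(Vh)), tolerance = 1e-10)
})

test_that("partition invariants hold on open- and closed-shell fixtures", {
  fixtures <- list(
    list(sys = fix_water(), key = "water", active = 1:2),
    list(sys = fix_dimer_cation(), key = "dimer+", active = 1:3),
    list(sys = fix_radical_water(), key = "h2no+w", active = 1:4)
  )
  for (fx in fixtures) {
    init <- fix_initial(fx$sys, fx$key)
    parts <- partition_densities(fx$sys, init,
                                 define_partition(fx$sys, fx$active))
    chk <- check_partition(parts$partitioned)
    expect_lt(chk$residuals[["idem_A_alpha"]], 1e-8)
    expect_lt(chk$residuals[["idem_B_beta"]], 1e-8)
    expect_lt(chk$residuals[["ortho_alpha"]], 1e-10)
    expect_lt(chk$residuals[["ortho_beta"]], 1e-10)
    expect_lt(max(chk$residuals[c("trace_A_alpha", "trace_A_beta",
                                  "trace_B_alpha", "trace_B_beta")]), 1e-9)
    # reconstruction: D_A + D_B = D
    expect_lt(max(abs(parts$partitioned$D_A_alpha +
                        parts$partitioned$D_B_alpha - init$D_alpha)), 1e-10)
    # orbital space orthonormality (occ + virt per spin)
    sp <- parts$space
    C <- cbind(sp$C_occ_alpha, sp$C_virt_alpha)
    expect_equal(crossprod(C, init$S %*% C), diag(ncol(C)),
                 tolerance = 1e-9)
  }
})

test_that("an all-active partition leaves nothing inactive", {
  init <- fix_initial(fix_water(), "water")
  parts <- partition_densities(fix_water(), init,
                               define_partition(fix_water(), 1:3))
  expect_equal(max(abs(parts$partitioned$D_B_alpha)), 0, tolerance = 1e-12)
  expect_equal(parts$partitioned$n_A_alpha, 5)
})

test_that("closed-shell symmetric partitions give identical spin blocks", {
  init <- fix_initial(fix_water(), "water")
  parts <- partition_densities(fix_water(), init,
                               define_partition(fix_water(), 1L))
  expect_lt(max(abs(parts$partitioned$D_A_alpha -
                      parts$partitioned$D_A_beta)), 1e-10)
})

test_that("the unpaired electron localizes on the active radical", {
  sys <- fix_radical_water()
  init <- fix_initial(sys, "h2no+w")
  parts <- partition_densities(sys, init, define_partition(sys, 1:4))
  expect_equal(parts$partitioned$n_A_alpha - parts$partitioned$n_A_beta, 1)
})

test_that("repartitioning the reassembled density is bit-for-bit stable", {
  sys <- fix_radical_water()
  init <- fix_initial(sys, "h2no+w")
  part <- define_partition(sys, 1:4)
  p1 <- partition_densities(sys, init, part)
  # determinism: the same density and pivot rule reproduce the blocks
  # bit-for-bit
  p2 <- partition_densities(sys, init, part)
  expect_identical(p2$partitioned$D_A_alpha, p1$partitioned$D_A_alpha)
  expect_identical(p2$partitioned$D_A_beta, p1$partitioned$D_A_beta)
  # reassembling D_A + D_B and repartitioning reproduces the same blocks to
  # round-off
  D <- spin_density(p1$partitioned$D_A_alpha + p1$partitioned$D_B_alpha,
                    p1$partitioned$D_A_beta + p1$partitioned$D_B_beta,
                    init$S, init$n_alpha, init$n_beta)
  p3 <- partition_densities(sys, D, part)
  expect_equal(p3$partitioned$D_A_alpha, p1$partitioned$D_A_alpha,
               tolerance = 1e-12)
})

test_that("Cholesky virtuals are a valid alternative to PAOs", {
  sys <- fix_radical_water()
  init <- fix_initial(sys, "h2no+w")
  parts <- partition_densities(sys, init, define_partition(sys, 1:4),
                               virtual = "cholesky")
  sp <- parts$space
  C <- cbind(sp$C_occ_alpha, sp$C_virt_alpha)
  expect_equal(crossprod(C, init$S %*% C), diag(ncol(C)), tolerance = 1e-8)
})
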