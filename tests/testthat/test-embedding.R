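# Point-charge and fluctuating-charge embedding layers.

test_that("QM potential reduces to Coulomb's law for a bare nucleus", {
  sys <- atomic_system("H", matrix(0, 1, 3), multiplicity = 2)
  eng <- scf_engine(sys)
  zero <- spin_density(matrix(0, 1, 1), matrix(0, 1, 1), eng$S, 1, 0)
  V <- qm_potential_at_sites(zero, sys, matrix(c(0, 0, as_angstrom(1)), 1, 3),
                             engine = eng)
  expect_equal(V, 1, tolerance = 1e-12)
})

test_that("the potential of a neutral molecule decays to nothing far away", {
  sys <- fix_water()
  res <- fix_uhf(sys, "water")
  V <- qm_potential_at_sites(res, sys,
                             matrix(c(as_angstrom(1e4), 0, 0), 1, 3),
                             engine = fix_engine(sys, "water"))
  expect_lt(abs(V), 1e-7)
})

test_that("sites on top of nuclei are rejected", {
  sys <- fix_water()
  res <- fix_uhf(sys, "water")
  expect_error(qm_potential_at_sites(res, sys,
                                     matrix(unlist(sys$atoms[1, c("x", "y", "z")]), 1, 3)),
               "coincides")
})

test_that("electronic potential matches dense-grid integration of the density", {
  sys <- atomic_system("H", matrix(0, 1, 3), multiplicity = 2)
  eng <- scf_engine(sys)
  res <- full_scf(sys, engine = eng)
  site_bohr <- 5
  V <- qm_potential_at_sites(res, sys,
                             matrix(c(0, 0, as_angstrom(site_bohr)), 1, 3),
                             include_nuclear = FALSE, engine = eng)
  # oracle: quadrature of rho(r)/|r - site| on the package-independent
  # atom-centred grid
  g <- molecular_grid(sys, 5)
  ao <- mlscf:::cpp_ao_values(eng$shells, g$points, FALSE)$val
  rho <- rowSums((ao %*% (res$D_alpha + res$D_beta)) * ao)
  r <- sqrt(rowSums((g$points - matrix(c(0, 0, site_bohr), nrow(g$points), 3,
                                       byrow = TRUE))^2))
  expect_lt(abs(as.numeric(V) - (-sum(g$w * rho / r))), 1e-6)
})

test_that("one constrained site carries exactly the fragment charge", {
  lay <- fq_layer(matrix(c(0, 0, 0), 1, 3), "O", 1L, chi = 0.4, eta = 0.7,
                  Q = -0.25)
  s <- solve_fq(lay)
  expect_equal(s$q, -0.25)
})

test_that("two identical neutral sites stay uncharged by symmetry", {
  lay <- fq_layer(rbind(c(0, 0, 0), c(0, 0, 2)), c("O", "O"), c(1, 1),
                  chi = c(0.2, 0.2), eta = c(0.6, 0.6))
  s <- solve_fq(lay)
  expect_equal(s$q, c(0, 0))
})

test_that("the two-site electronegativity difference solves in closed form", {
  # zero off-diagonal coupling, equal eta: q = +/- (chi2 - chi1)/(2 eta)
  chi <- c(0.10, 0.30); eta <- 0.52
  lay <- fq_layer(rbind(c(0, 0, 0), c(0, 0, 3)), c("O", "O"), c(1, 1),
                  chi = chi, eta = c(eta, eta))
  s <- solve_fq(lay, kernel = function(l) diag(l$sites$eta))
  expect_equal(s$q, c((chi[2] - chi[1]) / (2 * eta),
                      (chi[1] - chi[2]) / (2 * eta)))
  expect_lt(s$residual, 1e-12)
})

test_that("random FQ instances agree with a null-space quadratic minimizer", {
  set.seed(19)
  for (k in 1:10) {
    pos <- matrix(rnorm(18, sd = 3), 6, 3)
    lay <- fq_layer(pos, rep(c("O", "H", "H"), 2), rep(1:2, each = 3),
                    Q = 0)
    V <- rnorm(6, sd = 0.05)
    s <- solve_fq(lay, V)
    # oracle: eliminate the constraints with an explicit null-space basis
    J <- mlscf:::fq_kernel_ohno(lay)
    N <- cbind(c(1, -1, 0, 0, 0, 0), c(0, 1, -1, 0, 0, 0),
               c(0, 0, 0, 1, -1, 0), c(0, 0, 0, 0, 1, -1))
    z <- solve(t(N) %*% J %*% N, -t(N) %*% (lay$sites$chi + V))
    q_oracle <- as.vector(N %*% z)
    expect_lt(max(abs(s$q - q_oracle)), 1e-10)
    expect_lt(max(abs(tapply(s$q, lay$sites$fragment, sum))), 1e-12)
  }
})

test_that("interaction energy is the plain charge-potential contraction", {
  expect_equal(embedding_interaction_energy(c(1, -1), c(0.5, 0.5)), 0)
  expect_equal(embedding_interaction_energy(numeric(0), numeric(0)), 0)
  expect_error(embedding_interaction_energy(1:3, 1:2), "mismatch")
  V <- c(0.2, -0.1); q <- c(0.3, 0.4)
  expect_equal(embedding_interaction_energy(V, -q),
               -embedding_interaction_energy(V, q))
})

test_that("the charge-field operator obeys the trace identity", {
  sys <- fix_water()
  eng <- fix_engine(sys, "water")
  res <- fix_uhf(sys, "water")
  lay <- fixed_charge_layer(rbind(c(4, 0, 0), c(0, 5, 1)),
                            charges = c(-0.5, 0.25))
  H <- embedding_fock(lay, engine = eng)
  Vel <- qm_potential_at_sites(res, sys, lay, include_nuclear = FALSE,
                               engine = eng)
  D <- res$D_alpha + res$D_beta
  expect_equal(sum(D * H), sum(Vel * lay$sites$q), tolerance = 1e-10)
  # zero charges give a zero operator
  H0 <- embedding_fock(fixed_charge_layer(rbind(c(4, 0, 0)), charges = 0),
                       engine = eng)
  expect_equal(max(abs(H0)), 0)
})

test_that("an infinitely hard FQ layer reproduces fixed charges", {
  pos <- rbind(water_geom(c(4, 0, 0)))
  q_fix <- c(-0.834, 0.417, 0.417)
  eta0 <- 1e8
  lay_fq <- fq_layer(pos, c("O", "H", "H"), rep(1L, 3),
                     chi = -eta0 * q_fix, eta = rep(eta0, 3))
  lay_fixed <- fixed_charge_layer(pos, elements = c("O", "H", "H"))
  sys <- fix_water()
  eng <- fix_engine(sys, "water")
  res <- fix_uhf(sys, "water")
  V <- qm_potential_at_sites(res, sys, lay_fq, engine = eng)
  s <- solve_fq(lay_fq, V)
  expect_equal(s$q, q_fix, tolerance = 1e-6)
  expect_equal(embedding_interaction_energy(V, s$q),
               embedding_interaction_energy(V, lay_fixed$sites$q),
               tolerance = 1e-6)
})

test_that("FQ charges are self-consistent at SCF convergence", {
  sys <- fix_water()
  eng <- fix_engine(sys, "water")
  pos <- rbind(water_geom(c(3.5, 0, 0)), water_geom(c(-3.5, 1, 0)))
  lay <- fq_layer(pos, rep(c("O", "H", "H"), 2), rep(1:2, each = 3))
  res <- full_scf(sys, embedding = lay, engine = eng)
  V <- qm_potential_at_sites(res, sys, lay, engine = eng)
  s <- solve_fq(lay, V)
  expect_lt(max(abs(s$q - res$fq_charges)), 1e-8)
})
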