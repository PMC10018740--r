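# Integral engine checks against independent closed forms and quadrature.

test_that("Boys function matches the incomplete-gamma closed form", {
  Tv <- c(1e-14, 1e-6, 0.05, 0.7, 3, 12, 28, 34.9, 35.1, 60, 150)
  for (m in c(0L, 1L, 3L, 6L)) {
    ref <- ifelse(Tv < 1e-12, 1 / (2 * m + 1),
                  gamma(m + 0.5) * pgamma(Tv, m + 0.5) / (2 * Tv^(m + 0.5)))
    expect_equal(mlscf:::cpp_boys(m, Tv), ref, tolerance = 1e-13)
  }
})

test_that("overlap of contracted s shells matches dense-grid quadrature", {
  sys <- atomic_system(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  eng <- scf_engine(sys)
  sh <- eng$shells
  q <- quad_overlap_s(sh[[1]]$exp, sh[[1]]$coef, sh[[1]]$center,
                      sh[[2]]$exp, sh[[2]]$coef, sh[[2]]$center)
  expect_equal(eng$S[1, 2], q, tolerance = 1e-5)
  expect_equal(diag(eng$S), c(1, 1), tolerance = 1e-10)
})

test_that("s-type Coulomb repulsion matches the erf closed form", {
  # (11|22) over normalized s AOs is the interaction of two Gaussian charge
  # distributions with exponents 2p and 2q: erf(sqrt(2pq/(p+q)) R) / R
  p <- 0.8; q <- 1.7; R <- 2.3
  sh <- list(list(l = 0L, center = c(0, 0, 0), exp = p,
                  coef = (2 * p / pi)^0.75),
             list(l = 0L, center = c(0, 0, R), exp = q,
                  coef = (2 * q / pi)^0.75))
  eri <- mlscf:::cpp_eri(sh, 0)
  erf_ <- 2 * pnorm(sqrt(2) * sqrt(2 * p * q / (p + q)) * R) - 1
  expect_equal(eri[1, 1, 2, 2], erf_ / R, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("ERI tensor has 8-fold permutational symmetry", {
  eng <- fix_engine(fix_water(), "water")
  sh <- eng$shells
  eri <- mlscf:::cpp_eri(sh, 1e-12)
  set.seed(5)
  for (k in 1:25) {
    i <- sample(eng$n_ao, 4, replace = TRUE)
    v <- eri[i[1], i[2], i[3], i[4]]
    expect_equal(eri[i[2], i[1], i[3], i[4]], v, tolerance = 1e-12)
    expect_equal(eri[i[3], i[4], i[1], i[2]], v, tolerance = 1e-12)
    expect_equal(eri[i[4], i[3], i[2], i[1]], v, tolerance = 1e-12)
  }
})

test_that("restricted SCF on H2 reproduces the textbook STO-3G minimum", {
  # classic closed-shell model problem: E(R = 1.4 bohr) = -1.1167 Eh
  sys <- atomic_system(c("H", "H"),
                       rbind(c(0, 0, 0), c(0, 0, as_angstrom(1.4))))
  res <- full_scf(sys, functional_spec("uhf"))
  expect_equal(res$E_total, -1.11671, tolerance = 2e-5)
  expect_equal(max_dab <- max(abs(res$D_alpha - res$D_beta)), 0,
               tolerance = 1e-10)
})

test_that("AO values and gradients on points match direct evaluation", {
  eng <- fix_engine(fix_water(), "water")
  pts <- rbind(c(0.3, -0.2, 0.5), c(1.1, 0.4, -0.7))
  ao <- mlscf:::cpp_ao_values(eng$shells, pts, TRUE)
  # direct R evaluation of shell 1 (oxygen 1s) at the first point
  sh <- eng$shells[[1]]
  r2 <- sum((pts[1, ] - sh$center)^2)
  expect_equal(ao$val[1, 1], sum(sh$coef * exp(-sh$exp * r2)),
               tolerance = 1e-12)
  # gradient vs central difference
  h <- 1e-6
  for (d in 1:3) {
    pp <- pts; pp[1, d] <- pp[1, d] + h
    pm <- pts; pm[1, d] <- pm[1, d] - h
    fd <- (mlscf:::cpp_ao_values(eng$shells, pp, FALSE)$val[1, ] -
             mlscf:::cpp_ao_values(eng$shells, pm, FALSE)$val[1, ]) / (2 * h)
    g <- list(ao$gx, ao$gy, ao$gz)[[d]][1, ]
    expect_equal(g, fd, tolerance = 1e-6)
  }
})

test_that("xc energy-density derivatives match finite differences", {
  set.seed(3)
  ra <- runif(6, 0.01, 2); rb <- runif(6, 0.001, 1.5)
  gaa <- runif(6, 0, 4); gbb <- runif(6, 0, 4)
  gab <- runif(6, -0.5, 0.5)
  for (fn in c("lsda", "pbe")) {
    fun <- functional_spec(fn)
    d <- mlscf:::xc_eval(fun, ra, rb, gaa, gab, gbb)
    h <- 1e-6
    fd <- (Re(mlscf:::xc_energy_density(fun, ra + h, rb, gaa, gab, gbb)) -
             Re(mlscf:::xc_energy_density(fun, ra - h, rb, gaa, gab, gbb))) / (2 * h)
    expect_equal(d$vra, fd, tolerance = 1e-5)
    fd <- (Re(mlscf:::xc_energy_density(fun, ra, rb, gaa + h, gab, gbb)) -
             Re(mlscf:::xc_energy_density(fun, ra, rb, gaa - h, gab, gbb))) / (2 * h)
    expect_equal(d$vgaa, fd, tolerance = 1e-5)
  }
})

test_that("the molecular grid integrates the electron density exactly enough", {
  eng <- fix_engine(fix_water(), "water")
  res <- fix_uhf(fix_water(), "water")
  g <- molecular_grid(fix_water(), 3)
  ao <- mlscf:::cpp_ao_values(eng$shells, g$points, FALSE)$val
  ne <- sum(g$w * rowSums((ao %*% (res$D_alpha + res$D_beta)) * ao))
  expect_equal(ne, 10, tolerance = 1e-5)
})
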