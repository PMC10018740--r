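# Exchange-correlation machinery: functional specifications, energy
# densities (LSDA and PBE families), Becke molecular quadrature, and
# potential-matrix assembly.
#
# Functional derivatives of the energy density with respect to the density
# and gradient invariants are obtained by complex-step differentiation of
# the (holomorphic) energy-density expressions: f'(x) = Im f(x + ih)/h with
# h = 1e-20. This is exact to machine precision and keeps the energy and the
# potential strictly consistent -- the same expression defines both.

#' Specify the exchange-correlation treatment
#'
#' Follows the convention that the exchange energy density enters scaled by
#' (1 - c_x) while c_x is the fraction of exact (Hartree-Fock) exchange
#' built from the exchange matrices. `c_x = 1` with no named exchange or
#' correlation is plain UHF.
#'
#' Presets: `"uhf"`, `"lsda"` (Slater + PW92), `"pbe"`, and `"pbe0"`
#' (PBE exchange and correlation with `c_x = 0.25`).
#'
#' @param name preset name, or `NULL` to give the pieces explicitly.
#' @param c_x fraction of exact exchange in `[0, 1]`.
#' @param exchange,correlation names of the density-functional pieces
#'   (`""` for none).
#' @param grid_level integer 1-5 quadrature level (see [molecular_grid()]).
#' @return Object of class `functional_spec`.
#' @export
functional_spec <- function(name = NULL, c_x = NULL, exchange = NULL,
                            correlation = NULL, grid_level = 3L) {
  presets <- list(
    uhf  = list(c_x = 1,    exchange = "",       correlation = ""),
    lsda = list(c_x = 0,    exchange = "slater", correlation = "pw92"),
    pbe  = list(c_x = 0,    exchange = "pbe",    correlation = "pbe"),
    pbe0 = list(c_x = 0.25, exchange = "pbe",    correlation = "pbe")
  )
  spec <- if (!is.null(name)) {
    if (is.null(presets[[tolower(name)]])) {
      stop("unknown functional preset '", name, "'")
    }
    presets[[tolower(name)]]
  } else list(c_x = 1, exchange = "", correlation = "")
  if (!is.null(c_x)) spec$c_x <- c_x
  if (!is.null(exchange)) spec$exchange <- exchange
  if (!is.null(correlation)) spec$correlation <- correlation
  if (spec$c_x < 0 || spec$c_x > 1) stop("c_x must lie in [0, 1]")
  spec$grid_level <- as.integer(grid_level)
  spec$is_dft <- nzchar(spec$exchange) || nzchar(spec$correlation)
  spec$name <- name %||% "custom"
  structure(spec, class = "functional_spec")
}

#' @export
print.functional_spec <- function(x, ...) {
  cat(sprintf("<functional_spec '%s': c_x = %g, exchange = '%s', correlation = '%s', grid %d>\n",
              x$name, x$c_x, x$exchange, x$correlation, x$grid_level))
  invisible(x)
}

# ---- energy densities (complex-capable, per unit volume) -------------------

.rho_floor <- 1e-12

# Slater exchange for one spin channel, via the spin-scaling identity
# E_x[ra, rb] = (E_x[2 ra] + E_x[2 rb]) / 2 applied by the caller.
e_x_slater_full <- function(rho) {
  -(3 / 4) * (3 / pi)^(1 / 3) * rho^(4 / 3)
}

# PBE exchange enhancement over the full (single-channel) density; g2 is
# |grad rho|^2 of that channel.
e_x_pbe_full <- function(rho, g2) {
  kappa <- 0.804
  mu <- 0.2195149727645171
  s2 <- g2 / (4 * (3 * pi^2)^(2 / 3) * rho^(8 / 3))
  Fx <- 1 + kappa - kappa / (1 + mu * s2 / kappa)
  e_x_slater_full(rho) * Fx
}

pw92_G <- function(rs, A, a1, b1, b2, b3, b4) {
  q <- 2 * A * (b1 * sqrt(rs) + b2 * rs + b3 * rs^1.5 + b4 * rs^2)
  -2 * A * (1 + a1 * rs) * log(1 + 1 / q)
}

# PW92 correlation energy per particle eps_c(rs, zeta).
pw92_eps <- function(rs, zeta) {
  ec0 <- pw92_G(rs, 0.031091, 0.21370, 7.5957, 3.5876, 1.6382, 0.49294)
  ec1 <- pw92_G(rs, 0.015545, 0.20548, 14.1189, 6.1977, 3.3662, 0.62517)
  mac <- pw92_G(rs, 0.016887, 0.11125, 10.357, 3.6231, 0.88026, 0.49671)
  fz <- ((1 + zeta)^(4 / 3) + (1 - zeta)^(4 / 3) - 2) / (2^(4 / 3) - 2)
  fpp0 <- 1.709920934161365
  z4 <- zeta^4
  ec0 + mac * (fz / fpp0) * (1 - z4) + (ec1 - ec0) * fz * z4
}

# PBE correlation; g2 is |grad rho_total|^2.
e_c_pbe <- function(ra, rb, g2) {
  rho <- ra + rb
  zeta <- (ra - rb) / rho
  rs <- (3 / (4 * pi * rho))^(1 / 3)
  eps <- pw92_eps(rs, zeta)
  phi <- ((1 + zeta)^(2 / 3) + (1 - zeta)^(2 / 3)) / 2
  gamma <- (1 - log(2)) / pi^2
  beta <- 0.06672455060314922
  kF <- (3 * pi^2 * rho)^(1 / 3)
  ks2 <- 4 * kF / pi
  t2 <- g2 / (4 * phi^2 * ks2 * rho^2)
  A <- (beta / gamma) / (exp(-eps / (gamma * phi^3)) - 1)
  At2 <- A * t2
  H <- gamma * phi^3 *
    log(1 + (beta / gamma) * t2 * (1 + At2) / (1 + At2 + At2^2))
  rho * (eps + H)
}

# Total xc energy density per volume for a functional spec. Inputs may be
# complex (complex-step differentiation); masking uses the real parts only.
xc_energy_density <- function(fun, ra, rb, gaa, gab, gbb) {
  e <- rep(0 + 0i, length(ra)) * 0  # numeric or complex zero of right type
  e <- ra * 0
  fx <- 1 - fun$c_x
  ma <- Re(ra) > .rho_floor
  mb <- Re(rb) > .rho_floor
  if (fun$exchange == "slater") {
    if (any(ma)) e[ma] <- e[ma] + fx * e_x_slater_full(2 * ra[ma]) / 2
    if (any(mb)) e[mb] <- e[mb] + fx * e_x_slater_full(2 * rb[mb]) / 2
  } else if (fun$exchange == "pbe") {
    if (any(ma)) e[ma] <- e[ma] + fx * e_x_pbe_full(2 * ra[ma], 4 * gaa[ma]) / 2
    if (any(mb)) e[mb] <- e[mb] + fx * e_x_pbe_full(2 * rb[mb], 4 * gbb[mb]) / 2
  } else if (nzchar(fun$exchange)) {
    stop("unknown exchange functional '", fun$exchange, "'")
  }
  mt <- Re(ra + rb) > .rho_floor
  if (fun$correlation == "pw92") {
    if (any(mt)) {
      rho <- ra[mt] + rb[mt]
      rs <- (3 / (4 * pi * rho))^(1 / 3)
      e[mt] <- e[mt] + rho * pw92_eps(rs, (ra[mt] - rb[mt]) / rho)
    }
  } else if (fun$correlation == "pbe") {
    if (any(mt)) {
      g2 <- gaa[mt] + 2 * gab[mt] + gbb[mt]
      e[mt] <- e[mt] + e_c_pbe(ra[mt], rb[mt], g2)
    }
  } else if (nzchar(fun$correlation)) {
    stop("unknown correlation functional '", fun$correlation, "'")
  }
  e
}

# Energy density and all first derivatives by complex step.
xc_eval <- function(fun, ra, rb, gaa, gab, gbb) {
  h <- 1e-20
  f0 <- Re(xc_energy_density(fun, ra, rb, gaa, gab, gbb))
  dstep <- function(wa, wb, wga, wgb, wgc) {
    Im(xc_energy_density(fun,
                         ra + (1i * h) * wa, rb + (1i * h) * wb,
                         gaa + (1i * h) * wga, gab + (1i * h) * wgb,
                         gbb + (1i * h) * wgc)) / h
  }
  list(e = f0,
       vra = dstep(1, 0, 0, 0, 0), vrb = dstep(0, 1, 0, 0, 0),
       vgaa = dstep(0, 0, 1, 0, 0), vgab = dstep(0, 0, 0, 1, 0),
       vgbb = dstep(0, 0, 0, 0, 1))
}

# ---- molecular quadrature ---------------------------------------------------

.grid_levels <- list(c(20L, 6L), c(30L, 8L), c(45L, 12L), c(65L, 16L),
                     c(85L, 20L))

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch via symmetric
# tridiagonal eigenproblem; exact for polynomials to degree 2n-1).
gauss_legendre <- function(n) {
  if (n == 1L) return(list(x = 0, w = 2))
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  Jm <- matrix(0, n, n)
  Jm[cbind(k, k + 1)] <- b
  Jm[cbind(k + 1, k)] <- b
  e <- eigen(Jm, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
}

#' Becke molecular quadrature grid
#'
#' Per-atom product grids (Gauss-Chebyshev radial with the Becke map,
#' Gauss-Legendre in cos(theta) times a uniform phi ring) glued with Becke's
#' fuzzy-cell weights (three smoothing passes, no atomic size adjustment).
#'
#' @param system an [atomic_system()].
#' @param level integer 1-5; radial x angular sizes per atom are
#'   20x72, 30x128, 45x288, 65x512, 85x800.
#' @return List with `points` (n x 3, bohr) and `w` (quadrature weights
#'   including the volume element).
#' @export
molecular_grid <- function(system, level = 3L) {
  spec <- .grid_levels[[max(1L, min(length(.grid_levels), level))]]
  nrad <- spec[1]; nth <- spec[2]; nph <- 2L * nth
  nuc <- as_bohr(coords_of(system))
  nat <- nrow(nuc)
  rm_b <- as_bohr(.element_radii[system$atoms$Z])

  i <- seq_len(nrad)
  xi <- cos(i * pi / (nrad + 1))
  wch <- pi / (nrad + 1) * sin(i * pi / (nrad + 1))
  gl <- gauss_legendre(nth)
  phi <- 2 * pi * (seq_len(nph) - 1) / nph
  ct <- gl$x; st <- sqrt(pmax(0, 1 - ct^2))
  # unit sphere points and weights (sum of weights = 4 pi)
  sp <- cbind(
    as.vector(outer(st, cos(phi))),
    as.vector(outer(st, sin(phi))),
    rep(ct, times = nph)
  )
  sw <- rep(gl$w, times = nph) * (2 * pi / nph)

  pts <- NULL; w0 <- NULL; patom <- NULL
  for (a in seq_len(nat)) {
    rm <- rm_b[a]
    r <- rm * (1 + xi) / (1 - xi)
    drdx <- 2 * rm / (1 - xi)^2
    wr <- wch * drdx * r^2
    P <- kronecker(sp, matrix(1, nrad, 1)) *
      rep(r, times = nrow(sp))  # (nrad fast) x 3
    P <- sweep(P, 2, nuc[a, ], "+")
    W <- rep(sw, each = nrad) * rep(wr, times = nrow(sp))
    pts <- rbind(pts, P); w0 <- c(w0, W)
    patom <- c(patom, rep.int(a, length(W)))
  }

  if (nat > 1) {
    dAt <- matrix(0, nrow(pts), nat)
    for (a in seq_len(nat)) {
      dAt[, a] <- sqrt((pts[, 1] - nuc[a, 1])^2 + (pts[, 2] - nuc[a, 2])^2 +
                         (pts[, 3] - nuc[a, 3])^2)
    }
    Pc <- matrix(1, nrow(pts), nat)
    for (a in seq_len(nat - 1)) {
      for (b in (a + 1):nat) {
        Rab <- sqrt(sum((nuc[a, ] - nuc[b, ])^2))
        mu <- (dAt[, a] - dAt[, b]) / Rab
        f <- mu
        for (k in 1:3) f <- 1.5 * f - 0.5 * f^3
        Pc[, a] <- Pc[, a] * 0.5 * (1 - f)
        Pc[, b] <- Pc[, b] * 0.5 * (1 + f)
      }
    }
    tot <- rowSums(Pc)
    wb <- Pc[cbind(seq_len(nrow(pts)), patom)] / tot
    w0 <- w0 * wb
  }
  keep <- w0 > 1e-14
  list(points = pts[keep, , drop = FALSE], w = w0[keep])
}

# Cached grid + AO values/gradients for an engine, blocked to bound memory.
engine_grid <- function(engine, level) {
  key <- paste0("grid", level)
  g <- engine$cache$grids[[key]]
  if (!is.null(g)) return(g)
  grid <- molecular_grid(engine$system, level)
  npt <- nrow(grid$points)
  blk_size <- max(2000L, as.integer(3e7 / max(1, engine$n_ao)))
  starts <- seq(1L, npt, by = blk_size)
  blocks <- lapply(starts, function(s) {
    idx <- s:min(npt, s + blk_size - 1L)
    ao <- cpp_ao_values(engine$shells, grid$points[idx, , drop = FALSE], TRUE)
    list(w = grid$w[idx], X = ao$val, Gx = ao$gx, Gy = ao$gy, Gz = ao$gz)
  })
  g <- list(blocks = blocks, n_points = npt)
  engine$cache$grids[[key]] <- g
  g
}

# XC energy and potential matrices for a spin-resolved density pair.
xc_contrib <- function(engine, fun, Da, Db, level = fun$grid_level) {
  if (!fun$is_dft) {
    z <- matrix(0, engine$n_ao, engine$n_ao)
    return(list(E = 0, Va = z, Vb = z))
  }
  g <- engine_grid(engine, level)
  n <- engine$n_ao
  E <- 0
  Va <- matrix(0, n, n); Vb <- matrix(0, n, n)
  for (b in g$blocks) {
    XDa <- b$X %*% Da; XDb <- b$X %*% Db
    ra <- rowSums(XDa * b$X); rb <- rowSums(XDb * b$X)
    rax <- 2 * rowSums(XDa * b$Gx); ray <- 2 * rowSums(XDa * b$Gy)
    raz <- 2 * rowSums(XDa * b$Gz)
    rbx <- 2 * rowSums(XDb * b$Gx); rby <- 2 * rowSums(XDb * b$Gy)
    rbz <- 2 * rowSums(XDb * b$Gz)
    gaa <- rax^2 + ray^2 + raz^2
    gbb <- rbx^2 + rby^2 + rbz^2
    gab <- rax * rbx + ray * rby + raz * rbz
    d <- xc_eval(fun, pmax(ra, 0), pmax(rb, 0), gaa, gab, gbb)
    E <- E + sum(b$w * d$e)
    Va <- Va + crossprod(b$X, (b$w * d$vra) * b$X)
    Vb <- Vb + crossprod(b$X, (b$w * d$vrb) * b$X)
    wax <- b$w * (2 * d$vgaa * rax + d$vgab * rbx)
    way <- b$w * (2 * d$vgaa * ray + d$vgab * rby)
    waz <- b$w * (2 * d$vgaa * raz + d$vgab * rbz)
    Ba <- crossprod(b$X, wax * b$Gx + way * b$Gy + waz * b$Gz)
    Va <- Va + Ba + t(Ba)
    wbx <- b$w * (2 * d$vgbb * rbx + d$vgab * rax)
    wby <- b$w * (2 * d$vgbb * rby + d$vgab * ray)
    wbz <- b$w * (2 * d$vgbb * rbz + d$vgab * raz)
    Bb <- crossprod(b$X, wbx * b$Gx + wby * b$Gy + wbz * b$Gz)
    Vb <- Vb + Bb + t(Bb)
  }
  list(E = E, Va = sym(Va), Vb = sym(Vb))
}
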