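// Gaussian integral engine: McMurchie-Davidson Hermite expansion.
//
// Shells are contracted Cartesian Gaussians (s and p in the shipped basis
// sets; the recursions are general in angular momentum). Coefficients arrive
// fully normalized from R (primitive norms folded in, contracted self-overlap
// of the (l,0,0) component scaled to 1). All lengths are in bohr.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Shell {
  int l;
  double x, y, z;
  std::vector<double> e;  // primitive exponents
  std::vector<double> c;  // normalized contraction coefficients
  int off;                // first AO index
  int ncart;
};

int ncart_of(int l) { return (l + 1) * (l + 2) / 2; }

// Cartesian component powers in fixed order: lx descending, then ly.
void components(int l, std::vector<std::array<int, 3> >& comp) {
  comp.clear();
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly) comp.push_back({lx, ly, l - lx - ly});
}

std::vector<Shell> parse_shells(const List& shells) {
  std::vector<Shell> out;
  int off = 0;
  for (int i = 0; i < shells.size(); ++i) {
    List s = shells[i];
    Shell sh;
    sh.l = as<int>(s["l"]);
    NumericVector ctr = s["center"];
    sh.x = ctr[0]; sh.y = ctr[1]; sh.z = ctr[2];
    sh.e = as<std::vector<double> >(s["exp"]);
    sh.c = as<std::vector<double> >(s["coef"]);
    sh.off = off;
    sh.ncart = ncart_of(sh.l);
    off += sh.ncart;
    out.push_back(sh);
  }
  return out;
}

int nao_total(const std::vector<Shell>& sh) {
  return sh.empty() ? 0 : sh.back().off + sh.back().ncart;
}

// Boys function F_m(T), m = 0..mmax.
void boys(int mmax, double T, double* F) {
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2 * m + 1);
    return;
  }
  if (T > 35.0) {
    F[0] = 0.5 * std::sqrt(M_PI / T);
    double eT = (T > 700.0) ? 0.0 : std::exp(-T);
    for (int m = 1; m <= mmax; ++m)
      F[m] = ((2 * m - 1) * F[m - 1] - eT) / (2.0 * T);
    return;
  }
  double eT = std::exp(-T);
  double term = 1.0 / (2 * mmax + 1), sum = term;
  for (int k = 1; k < 300; ++k) {
    term *= 2.0 * T / (2 * mmax + 2 * k + 1);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  F[mmax] = eT * sum;
  for (int m = mmax; m >= 1; --m)
    F[m - 1] = (2.0 * T * F[m] + eT) / (2 * m - 1);
}

// Hermite expansion coefficients E_t^{ij} along one dimension, for all
// i <= imax, j <= jmax, t <= i + j. Index: E[(i*(jmax+1)+j)*(imax+jmax+1)+t].
struct ETab {
  int imax, jmax, tdim;
  std::vector<double> v;
  double at(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(i * (jmax + 1) + j) * tdim + t];
  }
};

void ecoef(int imax, int jmax, double a, double b, double AB, ETab& E) {
  E.imax = imax; E.jmax = jmax; E.tdim = imax + jmax + 1;
  E.v.assign((imax + 1) * (jmax + 1) * E.tdim, 0.0);
  double p = a + b, mu = a * b / p;
  double XPA = -(b / p) * AB, XPB = (a / p) * AB;
  double inv2p = 0.5 / p;
  E.v[0] = std::exp(-mu * AB * AB);
  for (int i = 0; i < imax; ++i)
    for (int t = 0; t <= i + 1; ++t) {
      double val = inv2p * E.at(i, 0, t - 1) + XPA * E.at(i, 0, t) +
                   (t + 1) * E.at(i, 0, t + 1);
      E.v[((i + 1) * (jmax + 1)) * E.tdim + t] = val;
    }
  for (int i = 0; i <= imax; ++i)
    for (int j = 0; j < jmax; ++j)
      for (int t = 0; t <= i + j + 1; ++t) {
        double val = inv2p * E.at(i, j, t - 1) + XPB * E.at(i, j, t) +
                     (t + 1) * E.at(i, j, t + 1);
        E.v[(i * (jmax + 1) + (j + 1)) * E.tdim + t] = val;
      }
}

// Hermite Coulomb integrals R^0_{tuv} for t+u+v <= tmax at PC, exponent p.
// R stored dense over (t,u,v).
struct RTab {
  int tmax;
  std::vector<double> v;
  double& at(int t, int u, int w) {
    return v[(t * (tmax + 1) + u) * (tmax + 1) + w];
  }
};

void hermite_coulomb(int tmax, double p, double PCx, double PCy, double PCz,
                     RTab& R) {
  R.tmax = tmax;
  R.v.assign((tmax + 1) * (tmax + 1) * (tmax + 1), 0.0);
  double T = p * (PCx * PCx + PCy * PCy + PCz * PCz);
  std::vector<double> F(tmax + 1);
  boys(tmax, T, F.data());
  // R^n_{000} = (-2p)^n F_n; build up by recursion over total order.
  // tmp[n] holds R^n_{tuv} for the current working set; use full 4-d table.
  int d = tmax + 1;
  std::vector<double> Rn((size_t)d * d * d * d, 0.0);
  auto idx = [d](int t, int u, int w, int n) {
    return (((size_t)t * d + u) * d + w) * d + n;
  };
  double m2p = 1.0;
  for (int n = 0; n <= tmax; ++n) { Rn[idx(0, 0, 0, n)] = m2p * F[n]; m2p *= -2.0 * p; }
  for (int tot = 1; tot <= tmax; ++tot)
    for (int t = tot; t >= 0; --t)
      for (int u = tot - t; u >= 0; --u) {
        int w = tot - t - u;
        for (int n = 0; n <= tmax - tot; ++n) {
          double val;
          if (t > 0) {
            val = PCx * Rn[idx(t - 1, u, w, n + 1)];
            if (t > 1) val += (t - 1) * Rn[idx(t - 2, u, w, n + 1)];
          } else if (u > 0) {
            val = PCy * Rn[idx(t, u - 1, w, n + 1)];
            if (u > 1) val += (u - 1) * Rn[idx(t, u - 2, w, n + 1)];
          } else {
            val = PCz * Rn[idx(t, u, w - 1, n + 1)];
            if (w > 1) val += (w - 1) * Rn[idx(t, u, w - 2, n + 1)];
          }
          Rn[idx(t, u, w, n)] = val;
        }
      }
  for (int t = 0; t <= tmax; ++t)
    for (int u = 0; u + t <= tmax; ++u)
      for (int w = 0; w + t + u <= tmax; ++w) R.at(t, u, w) = Rn[idx(t, u, w, 0)];
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_boys(int m, NumericVector T) {
  NumericVector out(T.size());
  std::vector<double> F(m + 1);
  for (int i = 0; i < T.size(); ++i) {
    boys(m, T[i], F.data());
    out[i] = F[m];
  }
  return out;
}

// Overlap, kinetic and nuclear-attraction matrices.
// nucxyz: nnuc x 3 (bohr); nucZ: charges. V includes the -Z sign.
// [[Rcpp::export]]
List cpp_one_electron(List shells, NumericMatrix nucxyz, NumericVector nucZ) {
  std::vector<Shell> sh = parse_shells(shells);
  int nao = nao_total(sh);
  NumericMatrix S(nao, nao), Tm(nao, nao), V(nao, nao);
  std::vector<std::array<int, 3> > ca, cb;
  for (size_t A = 0; A < sh.size(); ++A)
    for (size_t B = A; B < sh.size(); ++B) {
      const Shell &s1 = sh[A], &s2 = sh[B];
      components(s1.l, ca); components(s2.l, cb);
      double ABx = s1.x - s2.x, ABy = s1.y - s2.y, ABz = s1.z - s2.z;
      int na = s1.ncart, nb = s2.ncart;
      std::vector<double> Sblk(na * nb, 0.0), Tblk(na * nb, 0.0),
          Vblk(na * nb, 0.0);
      for (size_t ip = 0; ip < s1.e.size(); ++ip)
        for (size_t jp = 0; jp < s2.e.size(); ++jp) {
          double a = s1.e[ip], b = s2.e[jp], p = a + b;
          double cc = s1.c[ip] * s2.c[jp];
          ETab Ex, Ey, Ez;
          // need +2 on second index for kinetic
          ecoef(s1.l, s2.l + 2, a, b, ABx, Ex);
          ecoef(s1.l, s2.l + 2, a, b, ABy, Ey);
          ecoef(s1.l, s2.l + 2, a, b, ABz, Ez);
          double pref = std::pow(M_PI / p, 1.5);
          double Px = (a * s1.x + b * s2.x) / p;
          double Py = (a * s1.y + b * s2.y) / p;
          double Pz = (a * s1.z + b * s2.z) / p;
          int tmax = s1.l + s2.l;
          // nuclear attraction Hermite tables per nucleus reused below
          for (int ia = 0; ia < na; ++ia)
            for (int ib = 0; ib < nb; ++ib) {
              int l1 = ca[ia][0], m1 = ca[ia][1], n1 = ca[ia][2];
              int l2 = cb[ib][0], m2 = cb[ib][1], n2 = cb[ib][2];
              double sx = Ex.at(l1, l2, 0), sy = Ey.at(m1, m2, 0),
                     sz = Ez.at(n1, n2, 0);
              Sblk[ia * nb + ib] += cc * pref * sx * sy * sz;
              // 1D kinetic pieces: K_ij = -1/2 d2_ij
              auto d2 = [&](const ETab& E, int i, int j) {
                double t = 0.0;
                if (j >= 2) t += j * (j - 1) * E.at(i, j - 2, 0);
                t += -2.0 * b * (2 * j + 1) * E.at(i, j, 0);
                t += 4.0 * b * b * E.at(i, j + 2, 0);
                return t;
              };
              double kx = -0.5 * d2(Ex, l1, l2), ky = -0.5 * d2(Ey, m1, m2),
                     kz = -0.5 * d2(Ez, n1, n2);
              Tblk[ia * nb + ib] +=
                  cc * pref * (kx * sy * sz + sx * ky * sz + sx * sy * kz);
            }
          for (int K = 0; K < nucxyz.nrow(); ++K) {
            RTab R;
            hermite_coulomb(tmax, p, Px - nucxyz(K, 0), Py - nucxyz(K, 1),
                            Pz - nucxyz(K, 2), R);
            double zfac = -nucZ[K] * cc * 2.0 * M_PI / p;
            for (int ia = 0; ia < na; ++ia)
              for (int ib = 0; ib < nb; ++ib) {
                int l1 = ca[ia][0], m1 = ca[ia][1], n1 = ca[ia][2];
                int l2 = cb[ib][0], m2 = cb[ib][1], n2 = cb[ib][2];
                double acc = 0.0;
                for (int t = 0; t <= l1 + l2; ++t)
                  for (int u = 0; u <= m1 + m2; ++u)
                    for (int w = 0; w <= n1 + n2; ++w)
                      acc += Ex.at(l1, l2, t) * Ey.at(m1, m2, u) *
                             Ez.at(n1, n2, w) * R.at(t, u, w);
                Vblk[ia * nb + ib] += zfac * acc;
              }
          }
        }
      for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib) {
          int mu = s1.off + ia, nu = s2.off + ib;
          S(mu, nu) = Sblk[ia * nb + ib]; S(nu, mu) = S(mu, nu);
          Tm(mu, nu) = Tblk[ia * nb + ib]; Tm(nu, mu) = Tm(mu, nu);
          V(mu, nu) = Vblk[ia * nb + ib]; V(nu, mu) = V(mu, nu);
        }
    }
  return List::create(_["S"] = S, _["T"] = Tm, _["V"] = V);
}

// One-electron operator of external point charges q_i at pts (bohr):
// H_{mu nu} = -sum_i q_i * (mu | 1/|r - r_i| | nu)   (electron charge -1).
// [[Rcpp::export]]
NumericMatrix cpp_charge_operator(List shells, NumericMatrix pts,
                                  NumericVector q) {
  std::vector<Shell> sh = parse_shells(shells);
  int nao = nao_total(sh);
  NumericMatrix H(nao, nao);
  std::vector<std::array<int, 3> > ca, cb;
  for (size_t A = 0; A < sh.size(); ++A)
    for (size_t B = A; B < sh.size(); ++B) {
      const Shell &s1 = sh[A], &s2 = sh[B];
      components(s1.l, ca); components(s2.l, cb);
      int na = s1.ncart, nb = s2.ncart;
      std::vector<double> blk(na * nb, 0.0);
      for (size_t ip = 0; ip < s1.e.size(); ++ip)
        for (size_t jp = 0; jp < s2.e.size(); ++jp) {
          double a = s1.e[ip], b = s2.e[jp], p = a + b;
          double cc = s1.c[ip] * s2.c[jp];
          ETab Ex, Ey, Ez;
          ecoef(s1.l, s2.l, a, b, s1.x - s2.x, Ex);
          ecoef(s1.l, s2.l, a, b, s1.y - s2.y, Ey);
          ecoef(s1.l, s2.l, a, b, s1.z - s2.z, Ez);
          double Px = (a * s1.x + b * s2.x) / p;
          double Py = (a * s1.y + b * s2.y) / p;
          double Pz = (a * s1.z + b * s2.z) / p;
          int tmax = s1.l + s2.l;
          for (int K = 0; K < pts.nrow(); ++K) {
            if (q[K] == 0.0) continue;
            RTab R;
            hermite_coulomb(tmax, p, Px - pts(K, 0), Py - pts(K, 1),
                            Pz - pts(K, 2), R);
            double fac = -q[K] * cc * 2.0 * M_PI / p;
            for (int ia = 0; ia < na; ++ia)
              for (int ib = 0; ib < nb; ++ib) {
                int l1 = ca[ia][0], m1 = ca[ia][1], n1 = ca[ia][2];
                int l2 = cb[ib][0], m2 = cb[ib][1], n2 = cb[ib][2];
                double acc = 0.0;
                for (int t = 0; t <= l1 + l2; ++t)
                  for (int u = 0; u <= m1 + m2; ++u)
                    for (int w = 0; w <= n1 + n2; ++w)
                      acc += Ex.at(l1, l2, t) * Ey.at(m1, m2, u) *
                             Ez.at(n1, n2, w) * R.at(t, u, w);
                blk[ia * nb + ib] += fac * acc;
              }
          }
        }
      for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib) {
          int mu = s1.off + ia, nu = s2.off + ib;
          H(mu, nu) += blk[ia * nb + ib];
          // A == B blocks already cover both orders in the (ia, ib) loop
          if (A != B) H(nu, mu) += blk[ia * nb + ib];
        }
    }
  return H;
}

// Electronic Coulomb integral of density D at each point:
// out_i = sum_{mu nu} D_{mu nu} (mu | 1/|r - r_i| | nu)   (positive kernel).
// [[Rcpp::export]]
NumericVector cpp_esp_electronic(List shells, NumericMatrix D,
                                 NumericMatrix pts) {
  std::vector<Shell> sh = parse_shells(shells);
  int npt = pts.nrow();
  NumericVector out(npt);
  std::vector<std::array<int, 3> > ca, cb;
  for (size_t A = 0; A < sh.size(); ++A)
    for (size_t B = A; B < sh.size(); ++B) {
      const Shell &s1 = sh[A], &s2 = sh[B];
      components(s1.l, ca); components(s2.l, cb);
      int na = s1.ncart, nb = s2.ncart;
      double sym = (A == B) ? 1.0 : 2.0;  // D symmetric
      for (size_t ip = 0; ip < s1.e.size(); ++ip)
        for (size_t jp = 0; jp < s2.e.size(); ++jp) {
          double a = s1.e[ip], b = s2.e[jp], p = a + b;
          double cc = s1.c[ip] * s2.c[jp];
          ETab Ex, Ey, Ez;
          ecoef(s1.l, s2.l, a, b, s1.x - s2.x, Ex);
          ecoef(s1.l, s2.l, a, b, s1.y - s2.y, Ey);
          ecoef(s1.l, s2.l, a, b, s1.z - s2.z, Ez);
          double Px = (a * s1.x + b * s2.x) / p;
          double Py = (a * s1.y + b * s2.y) / p;
          double Pz = (a * s1.z + b * s2.z) / p;
          int tmax = s1.l + s2.l;
          for (int K = 0; K < npt; ++K) {
            RTab R;
            hermite_coulomb(tmax, p, Px - pts(K, 0), Py - pts(K, 1),
                            Pz - pts(K, 2), R);
            double fac = cc * 2.0 * M_PI / p;
            double acc2 = 0.0;
            for (int ia = 0; ia < na; ++ia)
              for (int ib = 0; ib < nb; ++ib) {
                int l1 = ca[ia][0], m1 = ca[ia][1], n1 = ca[ia][2];
                int l2 = cb[ib][0], m2 = cb[ib][1], n2 = cb[ib][2];
                double acc = 0.0;
                for (int t = 0; t <= l1 + l2; ++t)
                  for (int u = 0; u <= m1 + m2; ++u)
                    for (int w = 0; w <= n1 + n2; ++w)
                      acc += Ex.at(l1, l2, t) * Ey.at(m1, m2, u) *
                             Ez.at(n1, n2, w) * R.at(t, u, w);
                acc2 += acc * D(s1.off + ia, s2.off + ib);
              }
            out[K] += sym * fac * acc2;
          }
        }
    }
  return out;
}

// Full two-electron integral tensor (chemists' notation (mu nu | la si)),
// returned as an nao^4 array. Schwarz screening with threshold screen_tol.
// [[Rcpp::export]]
NumericVector cpp_eri(List shells, double screen_tol) {
  std::vector<Shell> sh = parse_shells(shells);
  int nsh = sh.size();
  int nao = nao_total(sh);
  if ((double)nao * nao * nao * nao * 8.0 > 6e9)
    stop("AO basis too large for an in-core ERI tensor");
  NumericVector out((R_xlen_t)nao * nao * nao * nao);
  std::vector<std::array<int, 3> > ca, cb, cc_, cd;
  R_xlen_t n1 = nao, n2 = (R_xlen_t)nao * nao, n3 = n2 * nao;

  // Precompute primitive-pair data per shell pair.
  struct PairPrim {
    double p, Px, Py, Pz, cc;
    ETab Ex, Ey, Ez;
  };
  struct Pair {
    int A, B;
    std::vector<PairPrim> pp;
    double qmax;  // sqrt((ab|ab)) Schwarz bound (filled later)
  };
  std::vector<Pair> pairs;
  for (int A = 0; A < nsh; ++A)
    for (int B = A; B < nsh; ++B) {
      Pair pr; pr.A = A; pr.B = B; pr.qmax = 0.0;
      const Shell &s1 = sh[A], &s2 = sh[B];
      for (size_t ip = 0; ip < s1.e.size(); ++ip)
        for (size_t jp = 0; jp < s2.e.size(); ++jp) {
          PairPrim q;
          double a = s1.e[ip], b = s2.e[jp];
          q.p = a + b;
          q.cc = s1.c[ip] * s2.c[jp];
          q.Px = (a * s1.x + b * s2.x) / q.p;
          q.Py = (a * s1.y + b * s2.y) / q.p;
          q.Pz = (a * s1.z + b * s2.z) / q.p;
          ecoef(s1.l, s2.l, a, b, s1.x - s2.x, q.Ex);
          ecoef(s1.l, s2.l, a, b, s1.y - s2.y, q.Ey);
          ecoef(s1.l, s2.l, a, b, s1.z - s2.z, q.Ez);
          pr.pp.push_back(q);
        }
      pairs.push_back(pr);
    }

  // Shell-quartet worker: contracted block (ab|cd).
  auto quartet = [&](const Pair& pab, const Pair& pcd,
                     std::vector<double>& blk) {
    const Shell &s1 = sh[pab.A], &s2 = sh[pab.B], &s3 = sh[pcd.A],
                &s4 = sh[pcd.B];
    components(s1.l, ca); components(s2.l, cb);
    components(s3.l, cc_); components(s4.l, cd);
    int na = s1.ncart, nb = s2.ncart, nc = s3.ncart, nd = s4.ncart;
    blk.assign((size_t)na * nb * nc * nd, 0.0);
    int lab = s1.l + s2.l, lcd = s3.l + s4.l, tmax = lab + lcd;
    for (const PairPrim& q1 : pab.pp)
      for (const PairPrim& q2 : pcd.pp) {
        double p = q1.p, qq = q2.p;
        double alpha = p * qq / (p + qq);
        double pref = q1.cc * q2.cc * 2.0 * std::pow(M_PI, 2.5) /
                      (p * qq * std::sqrt(p + qq));
        RTab R;
        hermite_coulomb(tmax, alpha, q1.Px - q2.Px, q1.Py - q2.Py,
                        q1.Pz - q2.Pz, R);
        size_t idx = 0;
        for (int ia = 0; ia < na; ++ia)
          for (int ib = 0; ib < nb; ++ib) {
            int l1 = ca[ia][0], m1 = ca[ia][1], nn1 = ca[ia][2];
            int l2 = cb[ib][0], m2 = cb[ib][1], nn2 = cb[ib][2];
            for (int ic = 0; ic < nc; ++ic)
              for (int id = 0; id < nd; ++id, ++idx) {
                int l3 = cc_[ic][0], m3 = cc_[ic][1], nn3 = cc_[ic][2];
                int l4 = cd[id][0], m4 = cd[id][1], nn4 = cd[id][2];
                double acc = 0.0;
                for (int t = 0; t <= l1 + l2; ++t) {
                  double ex1 = q1.Ex.at(l1, l2, t);
                  if (ex1 == 0.0) continue;
                  for (int u = 0; u <= m1 + m2; ++u) {
                    double ey1 = q1.Ey.at(m1, m2, u);
                    if (ey1 == 0.0) continue;
                    for (int w = 0; w <= nn1 + nn2; ++w) {
                      double ez1 = q1.Ez.at(nn1, nn2, w);
                      if (ez1 == 0.0) continue;
                      double e1 = ex1 * ey1 * ez1;
                      for (int tp = 0; tp <= l3 + l4; ++tp) {
                        double ex2 = q2.Ex.at(l3, l4, tp);
                        if (ex2 == 0.0) continue;
                        for (int up = 0; up <= m3 + m4; ++up) {
                          double ey2 = q2.Ey.at(m3, m4, up);
                          if (ey2 == 0.0) continue;
                          for (int wp = 0; wp <= nn3 + nn4; ++wp) {
                            double ez2 = q2.Ez.at(nn3, nn4, wp);
                            if (ez2 == 0.0) continue;
                            double sgn =
                                ((tp + up + wp) % 2 == 0) ? 1.0 : -1.0;
                            acc += e1 * ex2 * ey2 * ez2 * sgn *
                                   R.at(t + tp, u + up, w + wp);
                          }
                        }
                      }
                    }
                  }
                }
                blk[idx] += pref * acc;
              }
          }
      }
  };

  // Schwarz bounds.
  std::vector<double> blk;
  for (Pair& pr : pairs) {
    quartet(pr, pr, blk);
    const Shell &s1 = sh[pr.A], &s2 = sh[pr.B];
    int na = s1.ncart, nb = s2.ncart;
    double mx = 0.0;
    for (int ia = 0; ia < na; ++ia)
      for (int ib = 0; ib < nb; ++ib) {
        double v = blk[((size_t)(ia * nb + ib)) * (na * nb) + (ia * nb + ib)];
        if (v > mx) mx = v;
      }
    pr.qmax = std::sqrt(mx);
  }

  for (size_t P = 0; P < pairs.size(); ++P)
    for (size_t Q = P; Q < pairs.size(); ++Q) {
      if (pairs[P].qmax * pairs[Q].qmax < screen_tol) continue;
      quartet(pairs[P], pairs[Q], blk);
      const Shell &s1 = sh[pairs[P].A], &s2 = sh[pairs[P].B],
                  &s3 = sh[pairs[Q].A], &s4 = sh[pairs[Q].B];
      int na = s1.ncart, nb = s2.ncart, nc = s3.ncart, nd = s4.ncart;
      size_t idx = 0;
      for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib)
          for (int ic = 0; ic < nc; ++ic)
            for (int id = 0; id < nd; ++id, ++idx) {
              double v = blk[idx];
              R_xlen_t mu = s1.off + ia, nu = s2.off + ib, la = s3.off + ic,
                       si = s4.off + id;
              out[mu + nu * n1 + la * n2 + si * n3] = v;
              out[nu + mu * n1 + la * n2 + si * n3] = v;
              out[mu + nu * n1 + si * n2 + la * n3] = v;
              out[nu + mu * n1 + si * n2 + la * n3] = v;
              out[la + si * n1 + mu * n2 + nu * n3] = v;
              out[si + la * n1 + mu * n2 + nu * n3] = v;
              out[la + si * n1 + nu * n2 + mu * n3] = v;
              out[si + la * n1 + nu * n2 + mu * n3] = v;
            }
    }
  out.attr("dim") = IntegerVector::create(nao, nao, nao, nao);
  return out;
}

// AO values (and optionally gradients) at arbitrary points (bohr).
// [[Rcpp::export]]
List cpp_ao_values(List shells, NumericMatrix pts, bool grad) {
  std::vector<Shell> sh = parse_shells(shells);
  int nao = nao_total(sh);
  int npt = pts.nrow();
  NumericMatrix val(npt, nao);
  NumericMatrix gx, gy, gz;
  if (grad) { gx = NumericMatrix(npt, nao); gy = NumericMatrix(npt, nao);
              gz = NumericMatrix(npt, nao); }
  std::vector<std::array<int, 3> > comp;
  for (const Shell& s : sh) {
    components(s.l, comp);
    for (int k = 0; k < npt; ++k) {
      double dx = pts(k, 0) - s.x, dy = pts(k, 1) - s.y, dz = pts(k, 2) - s.z;
      double r2 = dx * dx + dy * dy + dz * dz;
      double rad = 0.0, drad = 0.0;  // radial part and d(rad)/d(r2)
      for (size_t ip = 0; ip < s.e.size(); ++ip) {
        double g = s.c[ip] * std::exp(-s.e[ip] * r2);
        rad += g;
        drad += -s.e[ip] * g;
      }
      for (int ic = 0; ic < s.ncart; ++ic) {
        int lx = comp[ic][0], ly = comp[ic][1], lz = comp[ic][2];
        double px = 1.0, py = 1.0, pz = 1.0;
        for (int t = 0; t < lx; ++t) px *= dx;
        for (int t = 0; t < ly; ++t) py *= dy;
        for (int t = 0; t < lz; ++t) pz *= dz;
        double poly = px * py * pz;
        val(k, s.off + ic) = poly * rad;
        if (grad) {
          double dpx = (lx > 0) ? lx * (lx > 1 ? std::pow(dx, lx - 1) : 1.0)
                                : 0.0;
          double dpy = (ly > 0) ? ly * (ly > 1 ? std::pow(dy, ly - 1) : 1.0)
                                : 0.0;
          double dpz = (lz > 0) ? lz * (lz > 1 ? std::pow(dz, lz - 1) : 1.0)
                                : 0.0;
          gx(k, s.off + ic) = dpx * py * pz * rad + poly * 2.0 * dx * drad;
          gy(k, s.off + ic) = px * dpy * pz * rad + poly * 2.0 * dy * drad;
          gz(k, s.off + ic) = px * py * dpz * rad + poly * 2.0 * dz * drad;
        }
      }
    }
  }
  if (grad)
    return List::create(_["val"] = val, _["gx"] = gx, _["gy"] = gy,
                        _["gz"] = gz);
  return List::create(_["val"] = val);
}
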