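// Conservative explicit-Euler integration of the non-ideal
// activator-inhibitor dynamics on periodic 1D/2D grids.
//
// Fields are stored column-major (x fastest, length nx*ny; ny == 1 for
// one dimension).  Chemical-potential gradients are evaluated on cell
// faces (staggered grid) with the mobility D_i*phi_i averaged
// arithmetically onto the face, so the divergence of the face fluxes
// telescopes and material is conserved to roundoff under periodic
// boundaries.  All differential operators are second-order central
// stencils.  Loops are fused and boundary-peeled: this is the hot path
// of every simulation, so per-cell work is kept to two logarithms
// (log(phi_i/phi_S)) plus one exponential when reactions are on.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

inline int wrap_next(int i, int n) { return (i + 1 == n) ? 0 : i + 1; }
inline int wrap_prev(int i, int n) { return (i == 0) ? n - 1 : i - 1; }

struct Params {
  double phi0, chi, h, k, DA, DI, w2;
};

Params make_params(List par) {
  Params p;
  p.phi0 = as<double>(par["phi0"]);
  p.chi = as<double>(par["chi"]);
  p.h = as<double>(par["h"]);
  p.k = as<double>(par["k"]);
  p.DA = as<double>(par["D_A"]);
  p.DI = as<double>(par["D_I"]);
  double w = as<double>(par["w"]);
  p.w2 = w * w;
  return p;
}

std::vector<double> to_vec(const NumericVector& v) {
  return std::vector<double>(v.begin(), v.end());
}

// local chemical potentials (and Hill production if REACT); no
// gradient term yet.  mu_i = log(phi_i / phi_S) + chi * phi_j.
template <bool REACT>
inline void local_mu(const double* A, const double* B, double* muA,
                     double* muB, double* prod, int n, const Params& p) {
  for (int i = 0; i < n; ++i) {
    const double a = A[i], b = B[i];
    const double rs = 1.0 / (1.0 - a - b);
    const double lar = std::log(a * rs), lbr = std::log(b * rs);
    muA[i] = lar + p.chi * b;
    muB[i] = lbr + p.chi * a;
    if (REACT) {
      // (phiI/phiA)^h = exp(h*(log phiI - log phiA)); underflow and
      // overflow of the exp saturate the production term gracefully
      prod[i] = 2.0 * p.phi0 / (1.0 + std::exp(p.h * (lbr - lar)));
    }
  }
}

// subtract c * (periodic 3-point Laplacian of phi) from mu, 1D row
inline void sub_lap_row(const double* phi, double* mu, int n, double c) {
  mu[0] -= c * (phi[1] + phi[n - 1] - 2.0 * phi[0]);
  for (int i = 1; i < n - 1; ++i)
    mu[i] -= c * (phi[i + 1] + phi[i - 1] - 2.0 * phi[i]);
  mu[n - 1] -= c * (phi[0] + phi[n - 2] - 2.0 * phi[n - 1]);
}

// face fluxes along x for one row: f[i] sits between cells i and i+1
inline void face_flux_row(const double* phi, const double* mu, double* f,
                          int n, double half_D_inv_dx) {
  for (int i = 0; i < n - 1; ++i)
    f[i] = half_D_inv_dx * (phi[i] + phi[i + 1]) * (mu[i + 1] - mu[i]);
  f[n - 1] = half_D_inv_dx * (phi[n - 1] + phi[0]) * (mu[0] - mu[n - 1]);
}

struct BlowUp {
  bool hit = false;
  int cell = 0;
  double a = 0, b = 0;
};

// divergence of face fluxes + reaction, Euler update, simplex check
template <bool REACT>
inline void update_row(double* A, double* B, const double* fA,
                       const double* fB, const double* prod, int n,
                       double dt, double inv_dx, double k, BlowUp& bu) {
  double prevA = fA[n - 1], prevB = fB[n - 1];
  for (int i = 0; i < n; ++i) {
    double ra = (fA[i] - prevA) * inv_dx;
    double rb = (fB[i] - prevB) * inv_dx;
    prevA = fA[i]; prevB = fB[i];
    if (REACT) {
      ra += k * (prod[i] - A[i]);
      rb += k * (prod[i] - B[i]);
    }
    const double a = A[i] + dt * ra;
    const double b = B[i] + dt * rb;
    A[i] = a; B[i] = b;
    if (!(a > 0.0) || !(b > 0.0) || !(a + b < 1.0)) {
      bu.hit = true; bu.cell = i; bu.a = a; bu.b = b;
      return;
    }
  }
}

struct Work {
  std::vector<double> muA, muB, prod, fA, fB, fyA, fyB;
  void resize(int n, bool twoD) {
    muA.resize(n); muB.resize(n); prod.resize(n);
    fA.resize(n); fB.resize(n);
    if (twoD) { fyA.resize(n); fyB.resize(n); }
  }
};

template <bool REACT>
void step_1d(std::vector<double>& A, std::vector<double>& B, int n,
             double dx, double dt, const Params& p, Work& wk, BlowUp& bu) {
  local_mu<REACT>(A.data(), B.data(), wk.muA.data(), wk.muB.data(),
                  wk.prod.data(), n, p);
  const double c = p.w2 / (dx * dx);
  sub_lap_row(A.data(), wk.muA.data(), n, c);
  sub_lap_row(B.data(), wk.muB.data(), n, c);
  const double inv_dx = 1.0 / dx;
  face_flux_row(A.data(), wk.muA.data(), wk.fA.data(), n,
                0.5 * p.DA * inv_dx);
  face_flux_row(B.data(), wk.muB.data(), wk.fB.data(), n,
                0.5 * p.DI * inv_dx);
  update_row<REACT>(A.data(), B.data(), wk.fA.data(), wk.fB.data(),
                    wk.prod.data(), n, dt, inv_dx, p.k, bu);
}

template <bool REACT>
void step_2d(std::vector<double>& A, std::vector<double>& B, int nx,
             int ny, double dx, double dt, const Params& p, Work& wk,
             BlowUp& bu) {
  const int n = nx * ny;
  double* muA = wk.muA.data();
  double* muB = wk.muB.data();
  local_mu<REACT>(A.data(), B.data(), muA, muB, wk.prod.data(), n, p);
  const double c = p.w2 / (dx * dx);
  // x part of the Laplacian, row by row; then y part (contiguous strides)
  for (int j = 0; j < ny; ++j) {
    sub_lap_row(A.data() + j * nx, muA + j * nx, nx, c);
    sub_lap_row(B.data() + j * nx, muB + j * nx, nx, c);
  }
  for (int j = 0; j < ny; ++j) {
    const double* Aj = A.data() + j * nx;
    const double* Bj = B.data() + j * nx;
    const double* Au = A.data() + wrap_next(j, ny) * nx;
    const double* Ad = A.data() + wrap_prev(j, ny) * nx;
    const double* Bu = B.data() + wrap_next(j, ny) * nx;
    const double* Bd = B.data() + wrap_prev(j, ny) * nx;
    double* mAj = muA + j * nx;
    double* mBj = muB + j * nx;
    for (int i = 0; i < nx; ++i) {
      mAj[i] -= c * (Au[i] + Ad[i] - 2.0 * Aj[i]);
      mBj[i] -= c * (Bu[i] + Bd[i] - 2.0 * Bj[i]);
    }
  }
  const double inv_dx = 1.0 / dx;
  const double hA = 0.5 * p.DA * inv_dx, hI = 0.5 * p.DI * inv_dx;
  // x faces per row
  for (int j = 0; j < ny; ++j) {
    face_flux_row(A.data() + j * nx, muA + j * nx, wk.fA.data() + j * nx,
                  nx, hA);
    face_flux_row(B.data() + j * nx, muB + j * nx, wk.fB.data() + j * nx,
                  nx, hI);
  }
  // y faces: fy[c] between (i,j) and (i,j+1)
  for (int j = 0; j < ny; ++j) {
    const int ju = wrap_next(j, ny) * nx;
    const double* Aj = A.data() + j * nx;
    const double* Bj = B.data() + j * nx;
    double* fyA = wk.fyA.data() + j * nx;
    double* fyB = wk.fyB.data() + j * nx;
    for (int i = 0; i < nx; ++i) {
      fyA[i] = hA * (Aj[i] + A[ju + i]) * (muA[ju + i] - muA[j * nx + i]);
      fyB[i] = hI * (Bj[i] + B[ju + i]) * (muB[ju + i] - muB[j * nx + i]);
    }
  }
  // divergence + update
  for (int j = 0; j < ny; ++j) {
    const int jo = j * nx;
    const int jd = wrap_prev(j, ny) * nx;
    double* Aj = A.data() + jo;
    double* Bj = B.data() + jo;
    const double* fxA = wk.fA.data() + jo;
    const double* fxB = wk.fB.data() + jo;
    for (int i = 0; i < nx; ++i) {
      const int il = (i == 0) ? nx - 1 : i - 1;
      double ra = (fxA[i] - fxA[il]) * inv_dx +
                  (wk.fyA[jo + i] - wk.fyA[jd + i]) * inv_dx;
      double rb = (fxB[i] - fxB[il]) * inv_dx +
                  (wk.fyB[jo + i] - wk.fyB[jd + i]) * inv_dx;
      if (REACT) {
        ra += p.k * (wk.prod[jo + i] - Aj[i]);
        rb += p.k * (wk.prod[jo + i] - Bj[i]);
      }
      const double a = Aj[i] + dt * ra;
      const double b = Bj[i] + dt * rb;
      Aj[i] = a; Bj[i] = b;
      if (!(a > 0.0) || !(b > 0.0) || !(a + b < 1.0)) {
        bu.hit = true; bu.cell = jo + i; bu.a = a; bu.b = b;
        return;
      }
    }
  }
}

double total_energy(const std::vector<double>& A,
                    const std::vector<double>& B, int nx, int ny,
                    double dx, const Params& p) {
  const double inv_dx2 = 1.0 / (dx * dx);
  const double dV = (ny > 1) ? dx * dx : dx;
  double e_local = 0.0, e_grad = 0.0;
  for (int j = 0; j < ny; ++j) {
    const int jo = j * nx;
    const int ju = wrap_next(j, ny) * nx;
    for (int i = 0; i < nx; ++i) {
      const int c = i + jo;
      const double a = A[c], b = B[c], s = 1.0 - a - b;
      e_local += a * std::log(a) + b * std::log(b) + s * std::log(s) +
                 p.chi * a * b;
      const int cr = wrap_next(i, nx) + jo;
      double da = A[cr] - a, db = B[cr] - b;
      e_grad += (da * da + db * db) * inv_dx2;
      if (ny > 1) {
        const int cu = i + ju;
        da = A[cu] - a; db = B[cu] - b;
        e_grad += (da * da + db * db) * inv_dx2;
      }
    }
  }
  return (e_local + 0.5 * p.w2 * e_grad) * dV;
}

} // namespace

// [[Rcpp::export]]
List cpp_full_mu(NumericVector phiA, NumericVector phiI, int nx, int ny,
                 double dx, List par) {
  Params p = make_params(par);
  std::vector<double> A = to_vec(phiA), B = to_vec(phiI);
  const int n = nx * ny;
  std::vector<double> muA(n), muB(n);
  local_mu<false>(A.data(), B.data(), muA.data(), muB.data(), nullptr,
                  n, p);
  const double c = p.w2 / (dx * dx);
  if (ny == 1) {
    sub_lap_row(A.data(), muA.data(), n, c);
    sub_lap_row(B.data(), muB.data(), n, c);
  } else {
    for (int j = 0; j < ny; ++j) {
      sub_lap_row(A.data() + j * nx, muA.data() + j * nx, nx, c);
      sub_lap_row(B.data() + j * nx, muB.data() + j * nx, nx, c);
    }
    for (int j = 0; j < ny; ++j) {
      const int jo = j * nx, ju = wrap_next(j, ny) * nx,
                jd = wrap_prev(j, ny) * nx;
      for (int i = 0; i < nx; ++i) {
        muA[jo + i] -= c * (A[ju + i] + A[jd + i] - 2.0 * A[jo + i]);
        muB[jo + i] -= c * (B[ju + i] + B[jd + i] - 2.0 * B[jo + i]);
      }
    }
  }
  return List::create(_["mu_A"] = NumericVector(muA.begin(), muA.end()),
                      _["mu_I"] = NumericVector(muB.begin(), muB.end()));
}

// [[Rcpp::export]]
List cpp_flux_div(NumericVector phiA, NumericVector phiI,
                  NumericVector muA, NumericVector muI, int nx, int ny,
                  double dx, List par) {
  Params p = make_params(par);
  const int n = nx * ny;
  std::vector<double> A = to_vec(phiA), B = to_vec(phiI);
  std::vector<double> mA = to_vec(muA), mB = to_vec(muI);
  std::vector<double> divA(n), divB(n);
  const double inv_dx = 1.0 / dx;
  for (int sp = 0; sp < 2; ++sp) {
    const std::vector<double>& phi = sp == 0 ? A : B;
    const std::vector<double>& mu = sp == 0 ? mA : mB;
    std::vector<double>& div = sp == 0 ? divA : divB;
    const double hD = 0.5 * (sp == 0 ? p.DA : p.DI) * inv_dx;
    std::vector<double> fx(n), fy(ny > 1 ? n : 0);
    for (int j = 0; j < ny; ++j)
      face_flux_row(phi.data() + j * nx, mu.data() + j * nx,
                    fx.data() + j * nx, nx, hD);
    if (ny > 1) {
      for (int j = 0; j < ny; ++j) {
        const int jo = j * nx, ju = wrap_next(j, ny) * nx;
        for (int i = 0; i < nx; ++i)
          fy[jo + i] = hD * (phi[jo + i] + phi[ju + i]) *
                       (mu[ju + i] - mu[jo + i]);
      }
    }
    for (int j = 0; j < ny; ++j) {
      const int jo = j * nx, jd = wrap_prev(j, ny) * nx;
      for (int i = 0; i < nx; ++i) {
        const int il = (i == 0) ? nx - 1 : i - 1;
        double d = (fx[jo + i] - fx[jo + il]) * inv_dx;
        if (ny > 1) d += (fy[jo + i] - fy[jd + i]) * inv_dx;
        div[jo + i] = d;
      }
    }
  }
  return List::create(_["div_A"] = NumericVector(divA.begin(), divA.end()),
                      _["div_I"] = NumericVector(divB.begin(), divB.end()));
}

// [[Rcpp::export]]
double cpp_energy(NumericVector phiA, NumericVector phiI, int nx, int ny,
                  double dx, List par) {
  Params p = make_params(par);
  std::vector<double> A = to_vec(phiA), B = to_vec(phiI);
  return total_energy(A, B, nx, ny, dx, p);
}

// Advance nsteps explicit-Euler steps.  Raises an R error with time and
// location information if a field leaves the open composition simplex
// (a blow-up of the explicit scheme; the caller should reduce dt).
// [[Rcpp::export]]
List cpp_run(NumericVector phiA, NumericVector phiI, int nx, int ny,
             double dx, List par, double dt, int nsteps, double t0,
             bool record_energy) {
  Params p = make_params(par);
  std::vector<double> A = to_vec(phiA), B = to_vec(phiI);
  Work wk;
  wk.resize(nx * ny, ny > 1);
  const bool react = p.k > 0.0;
  NumericVector energy;
  if (record_energy) {
    energy = NumericVector(nsteps + 1);
    energy[0] = total_energy(A, B, nx, ny, dx, p);
  }
  BlowUp bu;
  for (int step = 0; step < nsteps; ++step) {
    if (ny == 1) {
      if (react) step_1d<true>(A, B, nx, dx, dt, p, wk, bu);
      else step_1d<false>(A, B, nx, dx, dt, p, wk, bu);
    } else {
      if (react) step_2d<true>(A, B, nx, ny, dx, dt, p, wk, bu);
      else step_2d<false>(A, B, nx, ny, dx, dt, p, wk, bu);
    }
    if (bu.hit) {
      stop("integration blow-up at t = %g (step %d, cell %d): "
           "phiA = %g, phiI = %g left the composition simplex; "
           "reduce dt (current dt = %g)",
           t0 + (step + 1) * dt, step + 1, bu.cell + 1, bu.a, bu.b, dt);
    }
    if (record_energy)
      energy[step + 1] = total_energy(A, B, nx, ny, dx, p);
    if ((step & 0xFFF) == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(
      _["phiA"] = NumericVector(A.begin(), A.end()),
      _["phiI"] = NumericVector(B.begin(), B.end()),
      _["t"] = t0 + dt * nsteps);
  if (record_energy) out["energy"] = energy;
  return out;
}

// Ideal-diffusion counterpart: d phi/dt = Dmat %*% lap(phi) + reactions,
// with a constant 2x2 diffusivity matrix (e.g. the first-order
// effective matrix of the weak-interaction expansion).
// [[Rcpp::export]]
List cpp_run_ideal(NumericVector phiA, NumericVector phiI, int nx, int ny,
                   double dx, List par, NumericMatrix Dmat, double dt,
                   int nsteps, double t0) {
  Params p = make_params(par);
  std::vector<double> A = to_vec(phiA), B = to_vec(phiI);
  const int n = nx * ny;
  std::vector<double> lapA(n), lapB(n);
  const double d11 = Dmat(0, 0), d12 = Dmat(0, 1),
               d21 = Dmat(1, 0), d22 = Dmat(1, 1);
  const double inv_dx2 = 1.0 / (dx * dx);
  const bool react = p.k > 0.0;
  for (int step = 0; step < nsteps; ++step) {
    for (int j = 0; j < ny; ++j) {
      const int jo = j * nx;
      const int jp = wrap_next(j, ny) * nx;
      const int jm = wrap_prev(j, ny) * nx;
      for (int i = 0; i < nx; ++i) {
        const int c = i + jo;
        const int ip = wrap_next(i, nx), im = wrap_prev(i, nx);
        double la = A[ip + jo] + A[im + jo] - 2.0 * A[c];
        double lb = B[ip + jo] + B[im + jo] - 2.0 * B[c];
        if (ny > 1) {
          la += A[i + jp] + A[i + jm] - 2.0 * A[c];
          lb += B[i + jp] + B[i + jm] - 2.0 * B[c];
        }
        lapA[c] = la * inv_dx2;
        lapB[c] = lb * inv_dx2;
      }
    }
    for (int c = 0; c < n; ++c) {
      double ra = d11 * lapA[c] + d12 * lapB[c];
      double rb = d21 * lapA[c] + d22 * lapB[c];
      if (react) {
        const double r = std::exp(p.h * (std::log(B[c]) - std::log(A[c])));
        ra += p.k * (2.0 * p.phi0 / (1.0 + r) - A[c]);
        rb += p.k * (2.0 * p.phi0 / (1.0 + r) - B[c]);
      }
      A[c] += dt * ra;
      B[c] += dt * rb;
      if (!(A[c] > 0.0) || !(B[c] > 0.0) || !(A[c] + B[c] < 1.0)) {
        stop("integration blow-up (ideal model) at t = %g (cell %d); "
             "reduce dt (current dt = %g)",
             t0 + (step + 1) * dt, c + 1, dt);
      }
    }
    if ((step & 0xFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["phiA"] = NumericVector(A.begin(), A.end()),
                      _["phiI"] = NumericVector(B.begin(), B.end()),
                      _["t"] = t0 + dt * nsteps);
}
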