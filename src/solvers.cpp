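// Finite-volume kernels for variably saturated flow (Richards equation,
// mixed-form modified Picard) and advection-dispersion-reaction nitrogen
// transport on structured quadrilateral meshes.
//
// Conventions: z positive downward (gravity drives flux towards larger j),
// cells indexed k = i*nz + j (z fastest, matching an R matrix(nz, nx)).
// Units: cm, days, mg N per litre of pore water.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct VGCell {
  std::vector<double> tr, ts, al, nn, mm, ll, Ks;
  int n;
  void init(const List& mats) {
    NumericVector a = mats["theta_r"], b = mats["theta_s"],
                  c = mats["alpha"], d = mats["n"], e = mats["l"],
                  f = mats["Ks"];
    n = a.size();
    tr.assign(a.begin(), a.end()); ts.assign(b.begin(), b.end());
    al.assign(c.begin(), c.end()); nn.assign(d.begin(), d.end());
    ll.assign(e.begin(), e.end()); Ks.assign(f.begin(), f.end());
    mm.resize(n);
    for (int k = 0; k < n; ++k) mm[k] = 1.0 - 1.0 / nn[k];
  }
  // water content (without the saturated compressibility store)
  double theta(double h, int k) const {
    if (h >= 0) return ts[k];
    double ah = std::pow(std::fabs(al[k] * h), nn[k]);
    return tr[k] + (ts[k] - tr[k]) / std::pow(1.0 + ah, mm[k]);
  }
  double capacity(double h, int k, double Ss) const {
    if (h >= 0) return Ss;
    double a = al[k], nv = nn[k], m = mm[k];
    double ah = std::pow(std::fabs(a * h), nv);
    double c = (ts[k] - tr[k]) * m * nv * a *
               std::pow(std::fabs(a * h), nv - 1.0) /
               std::pow(1.0 + ah, m + 1.0);
    return c + 1e-12;
  }
  double cond(double h, int k) const {
    if (h >= 0) return Ks[k];
    double Se = (theta(h, k) - tr[k]) / (ts[k] - tr[k]);
    const double eps = 1e-12;
    Se = std::min(std::max(Se, eps), 1.0 - eps);
    double m = mm[k];
    double t = 1.0 - std::pow(1.0 - std::pow(Se, 1.0 / m), m);
    return Ks[k] * std::pow(Se, ll[k]) * t * t;
  }
  // combined state evaluation: theta, capacity, conductivity in one pass
  // (Se^(1/m) = 1/(1+ahn) under the Mualem constraint, so the wet-end
  // bracket needs no extra pow; l = 0.5 uses sqrt directly)
  inline void state(double h, int k, double Ss, double& th, double& C,
                    double& K) const {
    if (h >= 0) {
      th = ts[k]; C = Ss; K = Ks[k];
      return;
    }
    double a = al[k], nv = nn[k], m = mm[k];
    double ah = std::fabs(a * h);
    double ahn = std::pow(ah, nv);
    double br = 1.0 + ahn;
    double brm = std::pow(br, m);          // (1+ahn)^m
    double dth = ts[k] - tr[k];
    th = tr[k] + dth / brm;
    C = dth * m * nv * a * (ahn / ah) / (brm * br) + 1e-12;
    double Se = 1.0 / brm;                  // (1+ahn)^-m
    double t = 1.0 - std::pow(ahn / br, m); // 1-(1-Se^{1/m})^m
    double sel = (ll[k] == 0.5) ? std::sqrt(Se) : std::pow(Se, ll[k]);
    K = Ks[k] * sel * t * t;
  }
};

inline double face_w(double Ka, double Kb, double drive, int mode) {
  switch (mode) {
    case 1: return 0.5 * (Ka + Kb);            // arithmetic
    case 2: return drive > 0 ? Ka : Kb;        // upstream
    default: return std::sqrt(Ka * Kb);        // geometric
  }
}

// Direct banded Cholesky on the 5-point stencil, rows ordered x fastest
// so the half-bandwidth equals nx (the meshes are tall and narrow).
// Lower band storage: band[r*(bw+1) + d] = A(r, r-d), d = 0..bw.
struct BandChol {
  int n, bw, nx, nz;
  std::vector<double> band, L, y;
  void init(int nx_, int nz_) {
    nx = nx_; nz = nz_; n = nx * nz; bw = nx;
    band.assign((size_t)n * (bw + 1), 0.0);
    L.assign((size_t)n * (bw + 1), 0.0);
    y.resize(n);
  }
  inline int perm(int k) const {  // z-fastest cell id -> x-fastest row
    int i = k / nz, j = k % nz;
    return j * nx + i;
  }
  void reset() { std::fill(band.begin(), band.end(), 0.0); }
  inline void add(int ka, int kb, double v) {  // ka >= kb in row order
    int ra = perm(ka), rb = perm(kb);
    if (ra < rb) std::swap(ra, rb);
    band[(size_t)ra * (bw + 1) + (ra - rb)] += v;
  }
  bool factor() {
    const int w = bw + 1;
    L = band;
    for (int i = 0; i < n; ++i) {
      int k0 = std::max(0, i - bw);
      for (int k = k0; k < i; ++k) {
        double s = L[(size_t)i * w + (i - k)];
        int m0 = std::max(k0, k - bw);
        for (int m = m0; m < k; ++m)
          s -= L[(size_t)i * w + (i - m)] * L[(size_t)k * w + (k - m)];
        L[(size_t)i * w + (i - k)] = s / L[(size_t)k * w];
      }
      double s = L[(size_t)i * w];
      for (int m = k0; m < i; ++m) {
        double lim = L[(size_t)i * w + (i - m)];
        s -= lim * lim;
      }
      if (s <= 0) return false;
      L[(size_t)i * w] = std::sqrt(s);
    }
    return true;
  }
  // solves A x = b (vectors in z-fastest cell order)
  void solve(const std::vector<double>& b, std::vector<double>& x) {
    const int w = bw + 1;
    for (int k = 0; k < n; ++k) y[perm(k)] = b[k];
    for (int i = 0; i < n; ++i) {
      double s = y[i];
      int k0 = std::max(0, i - bw);
      for (int m = k0; m < i; ++m)
        s -= L[(size_t)i * w + (i - m)] * y[m];
      y[i] = s / L[(size_t)i * w];
    }
    for (int i = n - 1; i >= 0; --i) {
      double s = y[i];
      int k1 = std::min(n - 1, i + bw);
      for (int m = i + 1; m <= k1; ++m)
        s -= L[(size_t)m * w + (m - i)] * y[m];
      y[i] = s / L[(size_t)i * w];
    }
    for (int k = 0; k < n; ++k) x[k] = y[perm(k)];
  }
};


// Unpivoted banded LU for the nonsymmetric upwinded transport stencil
// (diagonally dominant), same x-fastest ordering as BandChol.
struct BandLU {
  int n, bw, nx, nz, w;
  std::vector<double> A;  // n x (2*bw+1), A[r*w + bw + (c - r)]
  std::vector<double> y;
  void init(int nx_, int nz_) {
    nx = nx_; nz = nz_; n = nx * nz; bw = nx; w = 2 * bw + 1;
    A.assign((size_t)n * w, 0.0);
    y.resize(n);
  }
  inline int perm(int k) const {
    int i = k / nz, j = k % nz;
    return j * nx + i;
  }
  void reset() { std::fill(A.begin(), A.end(), 0.0); }
  inline void add(int krow, int kcol, double v) {
    int r = perm(krow), c = perm(kcol);
    A[(size_t)r * w + bw + (c - r)] += v;
  }
  bool factor() {
    for (int i = 0; i < n; ++i) {
      double piv = A[(size_t)i * w + bw];
      if (std::fabs(piv) < 1e-300) return false;
      int rmax = std::min(n - 1, i + bw);
      for (int r = i + 1; r <= rmax; ++r) {
        double f = A[(size_t)r * w + bw + (i - r)] / piv;
        A[(size_t)r * w + bw + (i - r)] = f;
        if (f != 0.0) {
          int cmax = std::min(n - 1, i + bw);
          for (int c = i + 1; c <= cmax; ++c)
            A[(size_t)r * w + bw + (c - r)] -=
                f * A[(size_t)i * w + bw + (c - i)];
        }
      }
    }
    return true;
  }
  void solve(const std::vector<double>& b, std::vector<double>& x) {
    for (int k = 0; k < n; ++k) y[perm(k)] = b[k];
    for (int i = 0; i < n; ++i) {
      int k0 = std::max(0, i - bw);
      double s = y[i];
      for (int m = k0; m < i; ++m)
        s -= A[(size_t)i * w + bw + (m - i)] * y[m];
      y[i] = s;
    }
    for (int i = n - 1; i >= 0; --i) {
      int k1 = std::min(n - 1, i + bw);
      double s = y[i];
      for (int m = i + 1; m <= k1; ++m)
        s -= A[(size_t)i * w + bw + (m - i)] * y[m];
      y[i] = s / A[(size_t)i * w + bw];
    }
    for (int k = 0; k < n; ++k) x[k] = y[perm(k)];
  }
};

}  // namespace

// [[Rcpp::export]]
List richards_solve_cpp(List geom, List mats, List bc, List ctrl) {
  const int nx = as<int>(geom["nx"]), nz = as<int>(geom["nz"]);
  const int ncell = nx * nz;
  NumericVector dxv = geom["dx"], dzv = geom["dz"], Vv = geom["V"];
  NumericVector xc = geom["xc"], zc = geom["zc"];
  NumericVector afx = geom["Afx"];  // interior x faces (nx-1)*nz
  NumericVector afz = geom["Afz"];  // interior z faces nx*(nz-1)

  VGCell vg;
  vg.init(mats);

  IntegerVector src_cells = bc["src_cells"];
  NumericVector src_frac = bc["src_frac"];
  NumericVector sched_t = bc["sched_t"];  // breakpoints, first = 0
  NumericVector sched_q = bc["sched_q"];  // plane rate cm^3/d per segment
  IntegerVector seep_cells = bc["seep_cells"];
  NumericVector h0 = bc["h_init"];

  const double t_end = as<double>(ctrl["t_end"]);
  const double tol_h = as<double>(ctrl["tol_h"]);
  const double tol_th = as<double>(ctrl["tol_theta"]);
  const int max_picard = as<int>(ctrl["max_picard"]);
  const double Ss = as<double>(ctrl["Ss"]);
  const double h_crit_min = as<double>(ctrl["h_crit_min"]);
  const int wmode = as<int>(ctrl["face_weight"]);
  const double store_dt = as<double>(ctrl["store_dt"]);
  const double avg_start = as<double>(ctrl["avg_start"]);
  IntegerVector obs_cells = ctrl["obs_cells"];
  const bool store_fluxes = as<bool>(ctrl["store_fluxes"]);
  double dt = as<double>(ctrl["dt_init"]);
  const double dt_min = as<double>(ctrl["dt_min"]);
  const double dt_max = as<double>(ctrl["dt_max"]);
  const double PEN = 1e12;

  // total water per unit volume incl. saturated compressibility store
  auto thtot = [&](double h, int k) {
    return vg.theta(h, k) + (h > 0 ? Ss * h : 0.0);
  };

  std::vector<double> h(h0.begin(), h0.end());
  std::vector<double> hn = h, hm = h;
  std::vector<double> thn(ncell), thm(ncell), Kc(ncell), Cc(ncell);
  std::vector<double> h_state(ncell, 1e300);  // head at last state eval
  for (int k = 0; k < ncell; ++k) thn[k] = thtot(h[k], k);

  std::vector<double> diag(ncell), bvec(ncell), gx((nx - 1) * nz),
      gz(nx * (nz - 1)), grav(ncell);
  BandChol chol;
  chol.init(nx, nz);

  const int nseep = seep_cells.size();
  std::vector<int> seep_active(nseep, 0);
  std::vector<double> seep_out(nseep, 0.0);

  // storage grid
  const int nint = (int)std::ceil(t_end / store_dt - 1e-9);
  std::vector<double> store_edges(nint + 1);
  for (int s = 0; s <= nint; ++s)
    store_edges[s] = std::min(s * store_dt, t_end);
  const int nobs = obs_cells.size();
  NumericMatrix obs_h(nint + 1, nobs), obs_th(nint + 1, nobs);
  NumericVector seep_series(nint), src_series(nint);
  NumericMatrix th_edges, qx_int, qz_int, src_int, seep_int;
  if (store_fluxes) {
    th_edges = NumericMatrix(ncell, nint + 1);
    qx_int = NumericMatrix((nx - 1) * nz, nint);
    qz_int = NumericMatrix(nx * (nz - 1), nint);
    src_int = NumericMatrix(ncell, nint);
    seep_int = NumericMatrix(nseep, nint);
  }
  for (int o = 0; o < nobs; ++o) {
    obs_h(0, o) = h[obs_cells[o]];
    obs_th(0, o) = vg.theta(h[obs_cells[o]], obs_cells[o]);
  }
  if (store_fluxes)
    for (int k = 0; k < ncell; ++k) th_edges(k, 0) = thn[k];

  std::vector<double> th_avg(ncell, 0.0), h_avg(ncell, 0.0);
  double avg_w = 0.0;

  double storage0 = 0;
  for (int k = 0; k < ncell; ++k) storage0 += thn[k] * Vv[k];
  double cum_in = 0, cum_out = 0, cum_clamp = 0, max_step_err = 0;

  double t = 0.0;
  int seg = 0, sint = 0;
  long n_steps = 0, n_picard = 0;
  const int nseg = sched_q.size();

  while (t < t_end - 1e-12) {
    // current dose segment
    while (seg + 1 < nseg && t >= sched_t[seg + 1] - 1e-12) ++seg;
    double q_now = sched_q[seg];
    // clip dt to the next schedule break / store edge / end
    double dtc = std::min(dt, dt_max);
    double t_next_ev = (seg + 1 < (int)sched_t.size()) ? sched_t[seg + 1]
                                                       : t_end;
    dtc = std::min(dtc, t_next_ev - t);
    dtc = std::min(dtc, store_edges[sint + 1] - t);
    if (avg_start > t && avg_start < t + dtc) dtc = avg_start - t;
    dtc = std::max(dtc, dt_min);

    bool ok = false;
    int iters = 0;
    bool was_cut = false;
    for (int attempt = 0; attempt < 40 && !ok; ++attempt) {
      hm = h;
      std::vector<int> act = seep_active;
      double dh_prev = 1e30;
      for (int m = 0; m < max_picard; ++m) {
        ++iters;
        for (int k = 0; k < ncell; ++k) {
          // re-evaluate the constitutive state only where the iterate moved
          if (std::fabs(hm[k] - h_state[k]) >
              1e-7 * (std::fabs(h_state[k]) + 1e-3)) {
            vg.state(hm[k], k, Ss, thm[k], Cc[k], Kc[k]);
            if (hm[k] > 0) thm[k] += Ss * hm[k];
            h_state[k] = hm[k];
          }
        }
        // seepage activation check on current iterate
        for (int s = 0; s < nseep; ++s) {
          int k = seep_cells[s];
          if (!act[s] && hm[k] > 0) act[s] = 1;
        }
        std::fill(grav.begin(), grav.end(), 0.0);
        for (int i = 0; i + 1 < nx; ++i)
          for (int j = 0; j < nz; ++j) {
            int f = i * nz + j, a = i * nz + j, b = (i + 1) * nz + j;
            double Kf = face_w(Kc[a], Kc[b], hm[a] - hm[b], wmode);
            gx[f] = afx[f] * Kf / (xc[i + 1] - xc[i]);
          }
        for (int i = 0; i < nx; ++i)
          for (int j = 0; j + 1 < nz; ++j) {
            int f = i * (nz - 1) + j, a = i * nz + j, b = i * nz + j + 1;
            double Kf = face_w(Kc[a], Kc[b],
                               hm[a] - hm[b] + (zc[j + 1] - zc[j]), wmode);
            double af = afz[f];
            gz[f] = af * Kf / (zc[j + 1] - zc[j]);
            // gravity drives water from a (upper) to b (lower)
            grav[a] -= af * Kf;
            grav[b] += af * Kf;
          }
        for (int k = 0; k < ncell; ++k) {
          double sc = Vv[k] * Cc[k] / dtc;
          diag[k] = sc;
          bvec[k] = sc * hm[k] - Vv[k] * (thm[k] - thn[k]) / dtc + grav[k];
        }
        // face conductance contributions to the diagonal
        for (int i = 0; i + 1 < nx; ++i)
          for (int j = 0; j < nz; ++j) {
            int f = i * nz + j;
            diag[i * nz + j] += gx[f];
            diag[(i + 1) * nz + j] += gx[f];
          }
        for (int i = 0; i < nx; ++i)
          for (int j = 0; j + 1 < nz; ++j) {
            int f = i * (nz - 1) + j;
            diag[i * nz + j] += gz[f];
            diag[i * nz + j + 1] += gz[f];
          }
        for (int s = 0; s < (int)src_cells.size(); ++s)
          bvec[src_cells[s]] += q_now * src_frac[s];
        for (int s = 0; s < nseep; ++s)
          if (act[s]) diag[seep_cells[s]] += PEN;

        chol.reset();
        for (int k = 0; k < ncell; ++k) chol.add(k, k, diag[k]);
        for (int i = 0; i + 1 < nx; ++i)
          for (int j = 0; j < nz; ++j) {
            int f = i * nz + j;
            chol.add(i * nz + j, (i + 1) * nz + j, -gx[f]);
          }
        for (int i = 0; i < nx; ++i)
          for (int j = 0; j + 1 < nz; ++j) {
            int f = i * (nz - 1) + j;
            chol.add(i * nz + j, i * nz + j + 1, -gz[f]);
          }
        if (!chol.factor()) { iters = max_picard + 1; break; }
        std::vector<double> hnew(ncell);
        chol.solve(bvec, hnew);
        for (int k = 0; k < ncell; ++k)
          if (hnew[k] < h_crit_min) hnew[k] = h_crit_min;
        // seepage outflow from the solved state; deactivate on inflow
        bool switched = false;
        for (int s = 0; s < nseep; ++s) {
          if (!act[s]) { seep_out[s] = 0; continue; }
          int k = seep_cells[s];
          int i = k / nz, j = k % nz;
          double infl = 0;
          if (i > 0) infl += gx[(i - 1) * nz + j] * (hnew[k - nz] - hnew[k]);
          if (i + 1 < nx) infl += gx[i * nz + j] * (hnew[k + nz] - hnew[k]);
          if (j > 0)
            infl += gz[i * (nz - 1) + j - 1] * (hnew[k - 1] - hnew[k]);
          if (j + 1 < nz)
            infl += gz[i * (nz - 1) + j] * (hnew[k + 1] - hnew[k]);
          infl += grav[k];
          for (int ss = 0; ss < (int)src_cells.size(); ++ss)
            if (src_cells[ss] == k) infl += q_now * src_frac[ss];
          double stor = Vv[k] * (thm[k] - thn[k] +
                                 Cc[k] * (hnew[k] - hm[k])) / dtc;
          seep_out[s] = infl - stor;
          if (seep_out[s] < 0) { act[s] = 0; switched = true; }
        }
        double dh = 0, dth = 0;
        for (int k = 0; k < ncell; ++k) {
          dh = std::max(dh, std::fabs(hnew[k] - hm[k]));
          dth = std::max(dth, std::fabs(thtot(hnew[k], k) - thm[k]));
        }
        if (dh > dh_prev && dh > 10 * tol_h) {
          // oscillating iterate: damp towards the previous one
          for (int k = 0; k < ncell; ++k)
            hm[k] = 0.5 * (hnew[k] + hm[k]);
        } else {
          hm = hnew;
        }
        dh_prev = dh;
        if (!switched && m >= 1 && (dh < tol_h || dth < tol_th)) {
          ok = true;
          break;
        }
      }
      if (!ok) {
        dtc *= 0.3;
        was_cut = true;
        if (dtc < dt_min) {
          stop("flow solver: no convergence at t=%g d with dt=%g d", t, dtc);
        }
      } else {
        seep_active = act;
      }
    }
    n_picard += iters;
    ++n_steps;

    // accept the step
    double in_step = 0;
    for (int s = 0; s < (int)src_cells.size(); ++s)
      in_step += q_now * src_frac[s];
    in_step *= dtc;
    double out_step = 0;
    for (int s = 0; s < nseep; ++s) out_step += seep_out[s] * dtc;

    double stor_pre = 0, stor_post = 0, clamp_mass = 0;
    for (int k = 0; k < ncell; ++k) {
      stor_pre += thn[k] * Vv[k];
      // exact state refresh keeps the cached constitutive state consistent
      // with the stored water content (no spurious equilibrium drift)
      vg.state(hm[k], k, Ss, thm[k], Cc[k], Kc[k]);
      if (hm[k] > 0) thm[k] += Ss * hm[k];
      h_state[k] = hm[k];
      double th_new = thm[k];
      stor_post += th_new * Vv[k];
      thn[k] = th_new;
    }
    (void)clamp_mass;
    double err = (stor_post - stor_pre) - (in_step - out_step);
    cum_clamp += err;  // residual linearization/clamp error, tracked
    if (in_step > 0)
      max_step_err = std::max(max_step_err, std::fabs(err) / in_step);
    h = hm;
    cum_in += in_step;
    cum_out += out_step;
    double t_new = t + dtc;

    // averaging (end-of-step fields weighted by dt)
    if (t_new > avg_start - 1e-12) {
      for (int k = 0; k < ncell; ++k) {
        th_avg[k] += vg.theta(h[k], k) * dtc;
        h_avg[k] += h[k] * dtc;
      }
      avg_w += dtc;
    }
    if (store_fluxes) {
      for (int i = 0; i + 1 < nx; ++i)
        for (int j = 0; j < nz; ++j) {
          int f = i * nz + j;
          qx_int(f, sint) += gx[f] * (h[f % nz + (f / nz) * nz] -
                                      h[(f / nz + 1) * nz + f % nz]) * dtc;
        }
      for (int i = 0; i < nx; ++i)
        for (int j = 0; j + 1 < nz; ++j) {
          int f = i * (nz - 1) + j;
          int a = i * nz + j, b = a + 1;
          double Kf = gz[f] * (zc[j + 1] - zc[j]) / afz[f];
          qz_int(f, sint) += (gz[f] * (h[a] - h[b]) + afz[f] * Kf) * dtc;
        }
      for (int s = 0; s < (int)src_cells.size(); ++s)
        src_int(src_cells[s], sint) += q_now * src_frac[s] * dtc;
      for (int s = 0; s < nseep; ++s)
        seep_int(s, sint) += seep_out[s] * dtc;
    }
    seep_series[sint] += out_step;
    src_series[sint] += in_step;

    t = t_new;
    // adapt from the proposal unless the step had to be cut; clipping to
    // event/store edges must not throttle the next step
    double base = was_cut ? dtc : std::max(dtc, dt);
    if (iters <= 7) dt = std::min(base * 2.0, dt_max);
    else if (iters >= max_picard - 2) dt = base * 0.7;
    else dt = base;

    // store-edge bookkeeping
    if (t >= store_edges[sint + 1] - 1e-12) {
      double len = store_edges[sint + 1] - store_edges[sint];
      seep_series[sint] /= len;
      src_series[sint] /= len;
      if (store_fluxes) {
        for (int f = 0; f < (nx - 1) * nz; ++f) qx_int(f, sint) /= len;
        for (int f = 0; f < nx * (nz - 1); ++f) qz_int(f, sint) /= len;
        for (int k = 0; k < ncell; ++k) src_int(k, sint) /= len;
        for (int s = 0; s < nseep; ++s) seep_int(s, sint) /= len;
        for (int k = 0; k < ncell; ++k) th_edges(k, sint + 1) = thn[k];
      }
      for (int o = 0; o < nobs; ++o) {
        obs_h(sint + 1, o) = h[obs_cells[o]];
        obs_th(sint + 1, o) = vg.theta(h[obs_cells[o]], obs_cells[o]);
      }
      ++sint;
      Rcpp::checkUserInterrupt();
    }
  }

  double storage1 = 0;
  for (int k = 0; k < ncell; ++k) storage1 += thn[k] * Vv[k];
  if (avg_w > 0)
    for (int k = 0; k < ncell; ++k) {
      th_avg[k] /= avg_w;
      h_avg[k] /= avg_w;
    }

  double denom = std::max(cum_in, 1e-12);
  List wb = List::create(
      _["storage0"] = storage0, _["storage1"] = storage1,
      _["inflow"] = cum_in, _["outflow"] = cum_out,
      _["closure_err"] = (storage1 - storage0) - (cum_in - cum_out),
      _["closure_rel"] = std::fabs((storage1 - storage0) -
                                   (cum_in - cum_out)) / denom,
      _["max_step_err"] = max_step_err);

  List out = List::create(
      _["store_edges"] = store_edges, _["obs_h"] = obs_h,
      _["obs_theta"] = obs_th, _["seep_series"] = seep_series,
      _["src_series"] = src_series,
      _["h"] = NumericVector(h.begin(), h.end()),
      _["theta_avg"] = NumericVector(th_avg.begin(), th_avg.end()),
      _["h_avg"] = NumericVector(h_avg.begin(), h_avg.end()),
      _["water_balance"] = wb, _["n_steps"] = (double)n_steps,
      _["n_picard"] = (double)n_picard,
      _["seep_active"] = IntegerVector(seep_active.begin(),
                                       seep_active.end()));
  NumericVector th_fin(ncell);
  for (int k = 0; k < ncell; ++k) th_fin[k] = vg.theta(h[k], k);
  out["theta"] = th_fin;
  if (store_fluxes) {
    out["th_edges"] = th_edges;
    out["qx"] = qx_int;
    out["qz"] = qz_int;
    out["src"] = src_int;
    out["seep"] = seep_int;
  }
  return out;
}

// ---------------------------------------------------------------------------
// transport

namespace {

// BiCGSTAB with Jacobi preconditioning on the (nonsymmetric, upwinded)
// 5-point transport stencil. Off-diagonals stored per directed face.
struct Stencil {
  int nx, nz, ncell;
  std::vector<double> diag;
  // cab: coefficient of x[b] in row a for face (a,b); cba: of x[a] in row b
  std::vector<double> cx_ab, cx_ba, cz_ab, cz_ba;
  void init(int nx_, int nz_) {
    nx = nx_; nz = nz_; ncell = nx * nz;
    diag.assign(ncell, 0.0);
    cx_ab.assign((nx - 1) * nz, 0.0);
    cx_ba.assign((nx - 1) * nz, 0.0);
    cz_ab.assign(nx * (nz - 1), 0.0);
    cz_ba.assign(nx * (nz - 1), 0.0);
  }
  void reset() {
    std::fill(diag.begin(), diag.end(), 0.0);
    std::fill(cx_ab.begin(), cx_ab.end(), 0.0);
    std::fill(cx_ba.begin(), cx_ba.end(), 0.0);
    std::fill(cz_ab.begin(), cz_ab.end(), 0.0);
    std::fill(cz_ba.begin(), cz_ba.end(), 0.0);
  }
  inline void amul(const std::vector<double>& x,
                   std::vector<double>& y) const {
    for (int k = 0; k < ncell; ++k) y[k] = diag[k] * x[k];
    for (int i = 0; i + 1 < nx; ++i)
      for (int j = 0; j < nz; ++j) {
        int f = i * nz + j, a = i * nz + j, b = (i + 1) * nz + j;
        y[a] += cx_ab[f] * x[b];
        y[b] += cx_ba[f] * x[a];
      }
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j + 1 < nz; ++j) {
        int f = i * (nz - 1) + j, a = i * nz + j, b = a + 1;
        y[a] += cz_ab[f] * x[b];
        y[b] += cz_ba[f] * x[a];
      }
  }
};

struct Kin {
  std::vector<double> muN, KmN, fs, fwp, swp, sl, sh, e1, e2;
  std::vector<double> muD, KmD, sdn, fexp, alc, Topt, beta;
  void init(const List& kin) {
    auto grab = [&](const char* nm, std::vector<double>& v) {
      NumericVector a = kin[nm];
      v.assign(a.begin(), a.end());
    };
    grab("mu_nit", muN); grab("Km_nit", KmN); grab("fs", fs);
    grab("fwp", fwp); grab("swp", swp); grab("sl", sl); grab("sh", sh);
    grab("e1", e1); grab("e2", e2);
    grab("mu_den", muD); grab("Km_den", KmD); grab("sdn", sdn);
    grab("f_exp", fexp); grab("alpha_c", alc); grab("Topt", Topt);
    grab("beta", beta);
  }
  double fswN(double S, int k) const {
    if (S <= swp[k]) return fwp[k];
    if (S <= sl[k])
      return fwp[k] + (1 - fwp[k]) *
             std::pow((S - swp[k]) / (sl[k] - swp[k]), e2[k]);
    if (S <= sh[k]) return 1.0;
    return fs[k] + (1 - fs[k]) * std::pow((1 - S) / (1 - sh[k]), e1[k]);
  }
  double fswD(double S, int k) const {
    if (S < sdn[k]) return 0.0;
    if (S >= 1) return 1.0;
    return std::pow((S - sdn[k]) / (1 - sdn[k]), fexp[k]);
  }
  double ftemp(double T, int k) const {
    return std::exp(-0.5 * beta[k] * Topt[k] +
                    beta[k] * T * (1 - 0.5 * T / Topt[k]));
  }
};

}  // namespace

// [[Rcpp::export]]
List transport_solve_cpp(List geom, List props, List replay, List kin_list,
                         List run) {
  const int nx = as<int>(geom["nx"]), nz = as<int>(geom["nz"]);
  const int ncell = nx * nz;
  NumericVector Vv = geom["V"], xc = geom["xc"], zc = geom["zc"];
  NumericVector afx = geom["Afx"], afz = geom["Afz"];

  NumericVector rho = props["rho_b"], Kd = props["Kd"],
                lamL = props["lambda_L"], lamT = props["lambda_T"],
                DfN = props["D_nh4"], DfO = props["D_no3"],
                ths = props["theta_s"], zis = props["z_below_is"];
  IntegerVector matid = props["mat"];
  const int nmat = as<int>(props["n_mat"]);

  NumericMatrix th_edges = replay["th_edges"], qx = replay["qx"],
                qz = replay["qz"], srcw = replay["src"],
                seepw = replay["seep"];
  IntegerVector seep_cells = replay["seep_cells"];
  NumericVector edges = replay["store_edges"];
  const int nint = qx.ncol();

  const bool react = as<bool>(run["react"]);
  Kin kin;
  if (react) kin.init(kin_list);
  const double T_C = as<double>(run["T_C"]);
  NumericMatrix Cin = run["Cin"];  // nint x 2 (NH4, NO3)
  const double cfl_target = as<double>(run["cfl_target"]);
  const int max_sub = as<int>(run["max_sub"]);
  IntegerVector obs_cells = run["obs_cells"];
  const bool disp_on = as<bool>(run["dispersion"]);

  std::vector<double> C[2];
  NumericVector c0n = run["c0_nh4"], c0o = run["c0_no3"];
  C[0].assign(c0n.begin(), c0n.end());
  C[1].assign(c0o.begin(), c0o.end());
  std::vector<double> KdS[2];
  KdS[0].assign(Kd.begin(), Kd.end());      // NH4 sorbs
  KdS[1].assign(ncell, 0.0);                // NO3 conservative

  Stencil st;
  st.init(nx, nz);
  BandLU lu;
  lu.init(nx, nz);
  std::vector<double> bvec(ncell), n2cell(ncell, 0.0);

  double cum_in[2] = {0, 0}, cum_out[2] = {0, 0};
  double nitrified = 0, denitrified = 0, n2_total = 0;
  double out_water = 0;
  std::vector<double> nit_mass(nmat, 0.0), den_mass(nmat, 0.0),
      wat_time(nmat, 0.0);
  const int nobs = obs_cells.size();
  NumericMatrix obs_c_nh4(nint + 1, nobs), obs_c_no3(nint + 1, nobs);
  NumericMatrix effl(nint, 3);  // NH4, NO3 conc; water rate

  double storage0[2];
  for (int sp = 0; sp < 2; ++sp) {
    storage0[sp] = 0;
    for (int k = 0; k < ncell; ++k)
      storage0[sp] += (th_edges(k, 0) + rho[k] * KdS[sp][k]) * Vv[k] *
                      C[sp][k] / 1000.0;
  }
  for (int o = 0; o < nobs; ++o) {
    obs_c_nh4(0, o) = C[0][obs_cells[o]];
    obs_c_no3(0, o) = C[1][obs_cells[o]];
  }

  std::vector<double> vxc(ncell), vzc(ncell);  // cell-centred velocities

  for (int it = 0; it < nint; ++it) {
    double Dt = edges[it + 1] - edges[it];
    if (Dt <= 0) continue;
    // CFL -> number of sub-steps
    double cfl = 0;
    for (int k = 0; k < ncell; ++k) {
      int i = k / nz, j = k % nz;
      double out = 0;
      if (i > 0) out += std::max(-qx((i - 1) * nz + j, it), 0.0);
      if (i + 1 < nx) out += std::max(qx(i * nz + j, it), 0.0);
      if (j > 0) out += std::max(-qz(i * (nz - 1) + j - 1, it), 0.0);
      if (j + 1 < nz) out += std::max(qz(i * (nz - 1) + j, it), 0.0);
      double thmin = std::min(th_edges(k, it), th_edges(k, it + 1));
      cfl = std::max(cfl, out * Dt / (std::max(thmin, 1e-4) * Vv[k]));
    }
    int nsub = std::min(std::max((int)std::ceil(cfl / cfl_target), 1),
                        max_sub);
    double dts = Dt / nsub;

    // cell-centred velocity components for the dispersion tensor
    for (int k = 0; k < ncell; ++k) {
      int i = k / nz, j = k % nz;
      double thmid = 0.5 * (th_edges(k, it) + th_edges(k, it + 1));
      double qxl = (i > 0) ? qx((i - 1) * nz + j, it) / afx[(i - 1) * nz + j]
                           : 0.0;
      double qxr = (i + 1 < nx) ? qx(i * nz + j, it) / afx[i * nz + j] : 0.0;
      double qzu = (j > 0) ? qz(i * (nz - 1) + j - 1, it) /
                             afz[i * (nz - 1) + j - 1] : 0.0;
      double qzd = (j + 1 < nz) ? qz(i * (nz - 1) + j, it) /
                                  afz[i * (nz - 1) + j] : 0.0;
      vxc[k] = 0.5 * (qxl + qxr) / std::max(thmid, 1e-4);
      vzc[k] = 0.5 * (qzu + qzd) / std::max(thmid, 1e-4);
    }

    for (int s = 0; s < nsub; ++s) {
      double fa = (double)s / nsub, fb = (double)(s + 1) / nsub;
      for (int sp = 0; sp < 2; ++sp) {
        st.reset();
        for (int k = 0; k < ncell; ++k) {
          double tha = th_edges(k, it) * (1 - fa) +
                       th_edges(k, it + 1) * fa;
          double thb = th_edges(k, it) * (1 - fb) +
                       th_edges(k, it + 1) * fb;
          double stor_new = (thb + rho[k] * KdS[sp][k]) * Vv[k] / dts;
          double stor_old = (tha + rho[k] * KdS[sp][k]) * Vv[k] / dts;
          st.diag[k] += stor_new;
          bvec[k] = stor_old * C[sp][k] + srcw(k, it) * Cin(it, sp);
        }
        // advection (upwind) + dispersion on faces
        for (int i = 0; i + 1 < nx; ++i)
          for (int j = 0; j < nz; ++j) {
            int f = i * nz + j, a = i * nz + j, b = (i + 1) * nz + j;
            double F = qx(f, it);
            st.diag[a] += std::max(F, 0.0);
            st.cx_ab[f] += std::min(F, 0.0);
            st.cx_ba[f] -= std::max(F, 0.0);
            st.diag[b] += std::max(-F, 0.0);
            if (disp_on) {
              double thf = 0.25 * (th_edges(a, it) + th_edges(a, it + 1) +
                                   th_edges(b, it) + th_edges(b, it + 1));
              double vx = 0.5 * (vxc[a] + vxc[b]),
                     vz = 0.5 * (vzc[a] + vzc[b]);
              double vm = std::sqrt(vx * vx + vz * vz) + 1e-30;
              double lL = 0.5 * (lamL[a] + lamL[b]),
                     lT = 0.5 * (lamT[a] + lamT[b]);
              double Dmol = 0.5 * ((sp == 0 ? DfN[a] : DfO[a]) +
                                   (sp == 0 ? DfN[b] : DfO[b]));
              double ts2 = 0.5 * (ths[a] + ths[b]);
              double tau = std::pow(thf, 7.0 / 3.0) / (ts2 * ts2);
              double Dxx = lL * vx * vx / vm + lT * vz * vz / vm +
                           Dmol * tau;
              double G = thf * Dxx * afx[f] / (xc[i + 1] - xc[i]);
              st.diag[a] += G; st.cx_ab[f] -= G;
              st.diag[b] += G; st.cx_ba[f] -= G;
            }
          }
        for (int i = 0; i < nx; ++i)
          for (int j = 0; j + 1 < nz; ++j) {
            int f = i * (nz - 1) + j, a = i * nz + j, b = a + 1;
            double F = qz(f, it);
            st.diag[a] += std::max(F, 0.0);
            st.cz_ab[f] += std::min(F, 0.0);
            st.cz_ba[f] -= std::max(F, 0.0);
            st.diag[b] += std::max(-F, 0.0);
            if (disp_on) {
              double thf = 0.25 * (th_edges(a, it) + th_edges(a, it + 1) +
                                   th_edges(b, it) + th_edges(b, it + 1));
              double vx = 0.5 * (vxc[a] + vxc[b]),
                     vz = 0.5 * (vzc[a] + vzc[b]);
              double vm = std::sqrt(vx * vx + vz * vz) + 1e-30;
              double lL = 0.5 * (lamL[a] + lamL[b]),
                     lT = 0.5 * (lamT[a] + lamT[b]);
              double Dmol = 0.5 * ((sp == 0 ? DfN[a] : DfO[a]) +
                                   (sp == 0 ? DfN[b] : DfO[b]));
              double ts2 = 0.5 * (ths[a] + ths[b]);
              double tau = std::pow(thf, 7.0 / 3.0) / (ts2 * ts2);
              double Dzz = lL * vz * vz / vm + lT * vx * vx / vm +
                           Dmol * tau;
              double G = thf * Dzz * afz[f] / (zc[j + 1] - zc[j]);
              st.diag[a] += G; st.cz_ab[f] -= G;
              st.diag[b] += G; st.cz_ba[f] -= G;
            }
          }
        for (int sc = 0; sc < seep_cells.size(); ++sc)
          st.diag[seep_cells[sc]] += seepw(sc, it);

        lu.reset();
        for (int k = 0; k < ncell; ++k) lu.add(k, k, st.diag[k]);
        for (int i = 0; i + 1 < nx; ++i)
          for (int j = 0; j < nz; ++j) {
            int f = i * nz + j, a = i * nz + j, b = (i + 1) * nz + j;
            lu.add(a, b, st.cx_ab[f]);
            lu.add(b, a, st.cx_ba[f]);
          }
        for (int i = 0; i < nx; ++i)
          for (int j = 0; j + 1 < nz; ++j) {
            int f = i * (nz - 1) + j, a = i * nz + j, b = a + 1;
            lu.add(a, b, st.cz_ab[f]);
            lu.add(b, a, st.cz_ba[f]);
          }
        if (!lu.factor())
          stop("transport solver: singular system at t=%g d", edges[it]);
        std::vector<double> x(ncell);
        lu.solve(bvec, x);
        for (int k = 0; k < ncell; ++k)
          if (x[k] < 0 && x[k] > -1e-9) x[k] = 0;
        C[sp] = x;
        for (int k = 0; k < ncell; ++k)
          cum_in[sp] += srcw(k, it) * Cin(it, sp) * dts / 1000.0;
        for (int sc = 0; sc < seep_cells.size(); ++sc)
          cum_out[sp] += seepw(sc, it) * C[sp][seep_cells[sc]] * dts /
                         1000.0;
      }
      out_water += dts * [&] {
        double w = 0;
        for (int sc = 0; sc < seep_cells.size(); ++sc) w += seepw(sc, it);
        return w;
      }();

      if (react) {
        for (int k = 0; k < ncell; ++k) {
          double thb = th_edges(k, it) * (1 - fb) +
                       th_edges(k, it + 1) * fb;
          double S = std::min(thb / ths[k], 1.0);
          double z = std::max(zis[k], 0.0);
          double ft = kin.ftemp(T_C, k);
          double fN = kin.fswN(S, k) * ft;
          double fD = kin.fswD(S, k) * ft *
                      std::exp(-kin.alc[k] * z);
          double rnmax = kin.muN[k] * fN, rdmax = kin.muD[k] * fD;
          if (rnmax <= 0 && rdmax <= 0) {
            wat_time[matid[k]] += thb * Vv[k] / 1000.0 * dts;
            continue;
          }
          double cn = C[0][k], co = C[1][k];
          double relr = std::max(rnmax * dts / (cn + 1e-12),
                                 rdmax * dts / (co + 1e-12));
          int msub = std::min(std::max((int)std::ceil(relr / 0.1), 1), 50);
          double dtm = dts / msub, dn_tot = 0, dd_tot = 0;
          for (int m = 0; m < msub; ++m) {
            double dn = rnmax * cn / (kin.KmN[k] + cn) * dtm;
            if (dn > cn) dn = cn;
            cn -= dn; co += dn; dn_tot += dn;
            double dd = rdmax * co / (kin.KmD[k] + co) * dtm;
            if (dd > co) dd = co;
            co -= dd; dd_tot += dd;
          }
          C[0][k] = cn;
          C[1][k] = co;
          double wvol = thb * Vv[k] / 1000.0;  // litres of pore water
          nitrified += dn_tot * wvol;
          denitrified += dd_tot * wvol;
          n2_total += dd_tot * wvol;
          n2cell[k] += dd_tot * wvol;
          nit_mass[matid[k]] += dn_tot * wvol;
          den_mass[matid[k]] += dd_tot * wvol;
          wat_time[matid[k]] += wvol * dts;
        }
      } else {
        for (int k = 0; k < ncell; ++k) {
          double thb = th_edges(k, it) * (1 - fb) +
                       th_edges(k, it + 1) * fb;
          wat_time[matid[k]] += thb * Vv[k] / 1000.0 * dts;
        }
      }
    }
    // effluent record for the interval
    double wrate = 0, m0 = 0, m1 = 0;
    for (int sc = 0; sc < seep_cells.size(); ++sc) {
      wrate += seepw(sc, it);
      m0 += seepw(sc, it) * C[0][seep_cells[sc]];
      m1 += seepw(sc, it) * C[1][seep_cells[sc]];
    }
    effl(it, 0) = wrate > 0 ? m0 / wrate : NA_REAL;
    effl(it, 1) = wrate > 0 ? m1 / wrate : NA_REAL;
    effl(it, 2) = wrate;
    for (int o = 0; o < nobs; ++o) {
      obs_c_nh4(it + 1, o) = C[0][obs_cells[o]];
      obs_c_no3(it + 1, o) = C[1][obs_cells[o]];
    }
    Rcpp::checkUserInterrupt();
  }

  double storage1[2];
  for (int sp = 0; sp < 2; ++sp) {
    storage1[sp] = 0;
    for (int k = 0; k < ncell; ++k)
      storage1[sp] += (th_edges(k, nint) + rho[k] * KdS[sp][k]) * Vv[k] *
                      C[sp][k] / 1000.0;
  }
  NumericVector mean_nit(nmat), mean_den(nmat);
  for (int m = 0; m < nmat; ++m) {
    mean_nit[m] = wat_time[m] > 0 ? nit_mass[m] / wat_time[m] : 0.0;
    mean_den[m] = wat_time[m] > 0 ? den_mass[m] / wat_time[m] : 0.0;
  }

  return List::create(
      _["cum_in"] = NumericVector::create(cum_in[0], cum_in[1]),
      _["cum_out"] = NumericVector::create(cum_out[0], cum_out[1]),
      _["storage0"] = NumericVector::create(storage0[0], storage0[1]),
      _["storage1"] = NumericVector::create(storage1[0], storage1[1]),
      _["nitrified"] = nitrified, _["denitrified"] = denitrified,
      _["n2_total"] = n2_total,
      _["n2_cell"] = NumericVector(n2cell.begin(), n2cell.end()),
      _["C_nh4"] = NumericVector(C[0].begin(), C[0].end()),
      _["C_no3"] = NumericVector(C[1].begin(), C[1].end()),
      _["effluent"] = effl, _["obs_c_nh4"] = obs_c_nh4,
      _["obs_c_no3"] = obs_c_no3, _["out_water"] = out_water,
      _["mean_rate_nit"] = mean_nit, _["mean_rate_den"] = mean_den);
}
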