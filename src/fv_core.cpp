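// Finite-volume core: incompressible flow with Darcy clot feedback,
// implicit-upwind scalar transport, and per-cell implicit (backward Euler)
// coagulation chemistry with the mature-gel cap.
//
// Mesh arrays arrive from R 1-based; converted on unpack.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct FvMesh {
  int nx, ny, ncell, nf, nb;
  std::vector<double> area, cx, cy;
  std::vector<int> own, nbr;                 // interior faces, 0-based
  std::vector<double> Sx, Sy, E, tvx, tvy, w;
  std::vector<int> b_own, b_patch;           // 1 in, 2 out, 3 up, 4 low
  std::vector<double> b_Sx, b_Sy, b_fcx, b_fcy, b_E, b_tvx, b_tvy, b_len, b_dn;
};

static FvMesh unpack_mesh(const List& m) {
  FvMesh M;
  M.nx = as<int>(m["nx"]); M.ny = as<int>(m["ny"]); M.ncell = as<int>(m["ncell"]);
  NumericVector area = m["area"], cx = m["cx"], cy = m["cy"];
  M.area.assign(area.begin(), area.end());
  M.cx.assign(cx.begin(), cx.end());
  M.cy.assign(cy.begin(), cy.end());
  IntegerVector own = m["own"], nbr = m["nbr"];
  M.nf = own.size();
  M.own.resize(M.nf); M.nbr.resize(M.nf);
  for (int f = 0; f < M.nf; ++f) { M.own[f] = own[f] - 1; M.nbr[f] = nbr[f] - 1; }
  NumericVector Sx = m["Sx"], Sy = m["Sy"], E = m["E"], tvx = m["tvx"],
    tvy = m["tvy"], w = m["w"];
  M.Sx.assign(Sx.begin(), Sx.end()); M.Sy.assign(Sy.begin(), Sy.end());
  M.E.assign(E.begin(), E.end());
  M.tvx.assign(tvx.begin(), tvx.end()); M.tvy.assign(tvy.begin(), tvy.end());
  M.w.assign(w.begin(), w.end());
  IntegerVector bo = m["b_own"], bp = m["b_patch"];
  M.nb = bo.size();
  M.b_own.resize(M.nb); M.b_patch.assign(bp.begin(), bp.end());
  for (int f = 0; f < M.nb; ++f) M.b_own[f] = bo[f] - 1;
  NumericVector bSx = m["b_Sx"], bSy = m["b_Sy"], bfcx = m["b_fcx"],
    bfcy = m["b_fcy"], bE = m["b_E"], btvx = m["b_tvx"], btvy = m["b_tvy"],
    blen = m["b_len"], bdn = m["b_dn"];
  M.b_Sx.assign(bSx.begin(), bSx.end()); M.b_Sy.assign(bSy.begin(), bSy.end());
  M.b_fcx.assign(bfcx.begin(), bfcx.end()); M.b_fcy.assign(bfcy.begin(), bfcy.end());
  M.b_E.assign(bE.begin(), bE.end());
  M.b_tvx.assign(btvx.begin(), btvx.end()); M.b_tvy.assign(btvy.begin(), btvy.end());
  M.b_len.assign(blen.begin(), blen.end()); M.b_dn.assign(bdn.begin(), bdn.end());
  return M;
}

// Green-Gauss cell gradient given boundary face values.
static void green_gauss(const FvMesh& M, const std::vector<double>& phi,
                        const std::vector<double>& phib,
                        std::vector<double>& gx, std::vector<double>& gy) {
  std::fill(gx.begin(), gx.end(), 0.0);
  std::fill(gy.begin(), gy.end(), 0.0);
  for (int f = 0; f < M.nf; ++f) {
    int o = M.own[f], n = M.nbr[f];
    double pf = M.w[f] * phi[o] + (1.0 - M.w[f]) * phi[n];
    gx[o] += pf * M.Sx[f]; gy[o] += pf * M.Sy[f];
    gx[n] -= pf * M.Sx[f]; gy[n] -= pf * M.Sy[f];
  }
  for (int f = 0; f < M.nb; ++f) {
    int o = M.b_own[f];
    gx[o] += phib[f] * M.b_Sx[f]; gy[o] += phib[f] * M.b_Sy[f];
  }
  for (int c = 0; c < M.ncell; ++c) { gx[c] /= M.area[c]; gy[c] /= M.area[c]; }
}

// Preconditioned (Jacobi) conjugate gradients for the compact pressure
// Laplacian: diag[c] p[c] - sum_f g_f p[nbr] = rhs. Dirichlet p = 0 on the
// outlet enters through diag. Convergence on the inf-norm of the residual
// scaled by cell area against div_tol.
static int cg_solve(const FvMesh& M, const std::vector<double>& g,
                    const std::vector<double>& gb_out,
                    const std::vector<double>& rhs, std::vector<double>& p,
                    double div_tol_abs, int maxit) {
  int n = M.ncell;
  std::vector<double> diag(n, 0.0), r(n), z(n), q(n), s(n);
  for (int f = 0; f < M.nf; ++f) { diag[M.own[f]] += g[f]; diag[M.nbr[f]] += g[f]; }
  for (int f = 0; f < M.nb; ++f) if (M.b_patch[f] == 2) diag[M.b_own[f]] += gb_out[f];
  // r = rhs - A p
  for (int c = 0; c < n; ++c) r[c] = rhs[c] - diag[c] * p[c];
  for (int f = 0; f < M.nf; ++f) {
    int o = M.own[f], nb = M.nbr[f];
    r[o] += g[f] * p[nb]; r[nb] += g[f] * p[o];
  }
  auto max_scaled = [&](const std::vector<double>& v) {
    double m = 0.0;
    for (int c = 0; c < n; ++c) m = std::max(m, std::fabs(v[c]) / M.area[c]);
    return m;
  };
  if (max_scaled(r) < div_tol_abs) return 0;
  double rz = 0.0;
  for (int c = 0; c < n; ++c) { z[c] = r[c] / diag[c]; rz += r[c] * z[c]; s[c] = z[c]; }
  int it = 0;
  for (; it < maxit; ++it) {
    // q = A s
    for (int c = 0; c < n; ++c) q[c] = diag[c] * s[c];
    for (int f = 0; f < M.nf; ++f) {
      int o = M.own[f], nb = M.nbr[f];
      q[o] -= g[f] * s[nb]; q[nb] -= g[f] * s[o];
    }
    double sq = 0.0;
    for (int c = 0; c < n; ++c) sq += s[c] * q[c];
    if (sq <= 0.0) break;
    double alpha = rz / sq;
    for (int c = 0; c < n; ++c) { p[c] += alpha * s[c]; r[c] -= alpha * q[c]; }
    if (max_scaled(r) < div_tol_abs) { ++it; break; }
    double rz_new = 0.0;
    for (int c = 0; c < n; ++c) { z[c] = r[c] / diag[c]; rz_new += r[c] * z[c]; }
    double beta = rz_new / rz; rz = rz_new;
    for (int c = 0; c < n; ++c) s[c] = z[c] + beta * s[c];
  }
  return it;
}

// Incompressible flow with Darcy sink: explicit upwind convection and
// deferred-correction viscous fluxes, implicit Darcy drag, and a pressure
// projection whose compact part guarantees the face-flux divergence
// contract. steady=true uses local pseudo-time stepping.
// [[Rcpp::export]]
List cpp_flow_solve(List meshL, NumericVector u_in, NumericVector v_in,
                    NumericVector p_in, NumericVector alpha_p,
                    double V0, double Ly, double nu,
                    double cfl, double tol, int max_steps, int n_nonorth,
                    double div_tol, int cg_max, bool steady, double dt_fixed,
                    int check_every) {
  FvMesh M = unpack_mesh(meshL);
  int n = M.ncell;
  std::vector<double> u(u_in.begin(), u_in.end()), v(v_in.begin(), v_in.end()),
    p(p_in.begin(), p_in.end()), ap(alpha_p.begin(), alpha_p.end());
  std::vector<double> F(M.nf, 0.0), Fb(M.nb, 0.0);
  std::vector<double> ub(M.nb), vb(M.nb), pbv(M.nb);
  std::vector<double> gux(n), guy(n), gvx(n), gvy(n), gpx(n), gpy(n);
  std::vector<double> rhsu(n), rhsv(n), us(n), vs(n), coef(n), dtc(n);
  std::vector<double> Fs(M.nf), Fsb(M.nb), g(M.nf), gb(M.nb), divv(n), cross(M.nf),
    crossb(M.nb);
  std::vector<double> inlet_u(M.nb, 0.0), inlet_F(M.nb, 0.0);

  const double div_tol_abs = div_tol * V0 / Ly;   // per-cell divergence bound
  for (int f = 0; f < M.nb; ++f) {
    if (M.b_patch[f] == 1) {
      double y = M.b_fcy[f];
      inlet_u[f] = 4.0 * V0 * y * (Ly - y) / (Ly * Ly);
      inlet_F[f] = inlet_u[f] * M.b_Sx[f];       // b_Sx < 0: inflow negative
    }
  }
  // initial face fluxes from the supplied velocity
  for (int f = 0; f < M.nf; ++f) {
    int o = M.own[f], nb = M.nbr[f];
    F[f] = (M.w[f] * u[o] + (1 - M.w[f]) * u[nb]) * M.Sx[f] +
           (M.w[f] * v[o] + (1 - M.w[f]) * v[nb]) * M.Sy[f];
  }
  for (int f = 0; f < M.nb; ++f) {
    int pa = M.b_patch[f], o = M.b_own[f];
    if (pa == 1) Fb[f] = inlet_F[f];
    else if (pa == 2) Fb[f] = u[o] * M.b_Sx[f] + v[o] * M.b_Sy[f];
    else Fb[f] = 0.0;
  }

  std::vector<double> resid_hist;
  bool converged = false;
  int step = 0;
  double resid = NA_REAL;
  double aref = V0 * V0 / Ly + nu * V0 / (Ly * Ly);   // acceleration scale

  auto compute_dt = [&]() {
    for (int c = 0; c < n; ++c) { rhsu[c] = 0.0; rhsv[c] = 0.0; } // reuse as sums
    for (int f = 0; f < M.nf; ++f) {
      double af = std::fabs(F[f]);
      rhsu[M.own[f]] += af; rhsu[M.nbr[f]] += af;
      rhsv[M.own[f]] += nu * M.E[f]; rhsv[M.nbr[f]] += nu * M.E[f];
    }
    for (int f = 0; f < M.nb; ++f) {
      rhsu[M.b_own[f]] += std::fabs(Fb[f]);
      if (M.b_patch[f] != 2) rhsv[M.b_own[f]] += nu * M.b_E[f];
    }
    double dt_glob = 1e30;
    for (int c = 0; c < n; ++c) {
      double dconv = M.area[c] / (rhsu[c] + 1e-300);
      double dvisc = 0.5 * M.area[c] / (rhsv[c] + 1e-300);
      double d = cfl * std::min(dconv, dvisc);
      dtc[c] = d;
      dt_glob = std::min(dt_glob, d);
    }
    if (!steady) for (int c = 0; c < n; ++c) dtc[c] = dt_glob;
    return dt_glob;
  };

  double dt_glob = compute_dt();
  if (!steady) {
    if (dt_fixed > dt_glob * (1.0 + 1e-9))
      return List::create(_["error"] = "dt exceeds the advective/viscous stability bound",
                          _["dt_max"] = dt_glob);
    for (int c = 0; c < n; ++c) dtc[c] = dt_fixed;
  }

  for (step = 0; step < max_steps; ++step) {
    if (steady && step % 25 == 0 && step > 0) compute_dt();
    // boundary velocity values
    for (int f = 0; f < M.nb; ++f) {
      int pa = M.b_patch[f], o = M.b_own[f];
      if (pa == 1) { ub[f] = inlet_u[f]; vb[f] = 0.0; }
      else if (pa == 2) { ub[f] = u[o]; vb[f] = v[o]; }
      else { ub[f] = 0.0; vb[f] = 0.0; }
    }
    green_gauss(M, u, ub, gux, guy);
    green_gauss(M, v, vb, gvx, gvy);
    std::fill(rhsu.begin(), rhsu.end(), 0.0);
    std::fill(rhsv.begin(), rhsv.end(), 0.0);
    for (int f = 0; f < M.nf; ++f) {
      int o = M.own[f], nb = M.nbr[f];
      int up = (F[f] >= 0.0) ? o : nb;
      double cu = F[f] * u[up], cv = F[f] * v[up];
      double gxf = 0.5 * (gux[o] + gux[nb]), gyf = 0.5 * (guy[o] + guy[nb]);
      double du = nu * (M.E[f] * (u[nb] - u[o]) + gxf * M.tvx[f] + gyf * M.tvy[f]);
      gxf = 0.5 * (gvx[o] + gvx[nb]); gyf = 0.5 * (gvy[o] + gvy[nb]);
      double dv = nu * (M.E[f] * (v[nb] - v[o]) + gxf * M.tvx[f] + gyf * M.tvy[f]);
      rhsu[o] += -cu + du; rhsu[nb] += cu - du;
      rhsv[o] += -cv + dv; rhsv[nb] += cv - dv;
    }
    for (int f = 0; f < M.nb; ++f) {
      int pa = M.b_patch[f], o = M.b_own[f];
      double cu = Fb[f] * ub[f], cv = Fb[f] * vb[f];
      double du = 0.0, dv = 0.0;
      if (pa != 2) {   // Dirichlet patches get a one-sided viscous flux
        du = nu * (M.b_E[f] * (ub[f] - u[o]) + gux[o] * M.b_tvx[f] + guy[o] * M.b_tvy[f]);
        dv = nu * (M.b_E[f] * (vb[f] - v[o]) + gvx[o] * M.b_tvx[f] + gvy[o] * M.b_tvy[f]);
      }
      rhsu[o] += -cu + du; rhsv[o] += -cv + dv;
    }
    for (int c = 0; c < n; ++c) {
      double den = 1.0 + dtc[c] * nu * ap[c];
      us[c] = (u[c] + dtc[c] * rhsu[c] / M.area[c]) / den;
      vs[c] = (v[c] + dtc[c] * rhsv[c] / M.area[c]) / den;
      coef[c] = dtc[c] / den;
    }
    // predictor fluxes and conductances
    for (int f = 0; f < M.nf; ++f) {
      int o = M.own[f], nb = M.nbr[f];
      Fs[f] = (M.w[f] * us[o] + (1 - M.w[f]) * us[nb]) * M.Sx[f] +
              (M.w[f] * vs[o] + (1 - M.w[f]) * vs[nb]) * M.Sy[f];
      double ch = 2.0 * coef[o] * coef[nb] / (coef[o] + coef[nb]);
      g[f] = ch * M.E[f];
      cross[f] = 0.0;
    }
    for (int f = 0; f < M.nb; ++f) {
      int pa = M.b_patch[f], o = M.b_own[f];
      if (pa == 1) Fsb[f] = inlet_F[f];
      else if (pa == 2) { Fsb[f] = us[o] * M.b_Sx[f] + vs[o] * M.b_Sy[f]; gb[f] = coef[o] * M.b_E[f]; }
      else Fsb[f] = 0.0;
      if (pa != 2) gb[f] = 0.0;
      crossb[f] = 0.0;
    }
    // pressure solve with deferred non-orthogonal correction
    for (int k = 0; k <= n_nonorth; ++k) {
      if (k > 0) {
        for (int f = 0; f < M.nb; ++f)
          pbv[f] = (M.b_patch[f] == 2) ? 0.0 : p[M.b_own[f]];
        green_gauss(M, p, pbv, gpx, gpy);
        for (int f = 0; f < M.nf; ++f) {
          int o = M.own[f], nb = M.nbr[f];
          double ch = 2.0 * coef[o] * coef[nb] / (coef[o] + coef[nb]);
          cross[f] = ch * (0.5 * (gpx[o] + gpx[nb]) * M.tvx[f] +
                           0.5 * (gpy[o] + gpy[nb]) * M.tvy[f]);
        }
        for (int f = 0; f < M.nb; ++f)
          crossb[f] = (M.b_patch[f] == 2)
            ? coef[M.b_own[f]] * (gpx[M.b_own[f]] * M.b_tvx[f] + gpy[M.b_own[f]] * M.b_tvy[f])
            : 0.0;
      }
      std::fill(divv.begin(), divv.end(), 0.0);
      for (int f = 0; f < M.nf; ++f) {
        double q = Fs[f] - cross[f];
        divv[M.own[f]] -= q; divv[M.nbr[f]] += q;   // rhs = -div(F*)
      }
      for (int f = 0; f < M.nb; ++f) divv[M.b_own[f]] -= Fsb[f] - crossb[f];
      cg_solve(M, g, gb, divv, p, 0.5 * div_tol_abs, cg_max);
    }
    // corrected fluxes (compact part consistent with the last solve)
    for (int f = 0; f < M.nf; ++f)
      F[f] = Fs[f] - cross[f] - g[f] * (p[M.nbr[f]] - p[M.own[f]]);
    for (int f = 0; f < M.nb; ++f) {
      int pa = M.b_patch[f], o = M.b_own[f];
      if (pa == 2) Fb[f] = Fsb[f] - crossb[f] - gb[f] * (0.0 - p[o]);
      else Fb[f] = Fsb[f];
    }
    // velocity correction from the cell pressure gradient
    for (int f = 0; f < M.nb; ++f)
      pbv[f] = (M.b_patch[f] == 2) ? 0.0 : p[M.b_own[f]];
    green_gauss(M, p, pbv, gpx, gpy);
    resid = 0.0;
    for (int c = 0; c < n; ++c) {
      double un = us[c] - coef[c] * gpx[c];
      double vn = vs[c] - coef[c] * gpy[c];
      double r = std::max(std::fabs(un - u[c]), std::fabs(vn - v[c])) / dtc[c];
      resid = std::max(resid, r / aref);
      u[c] = un; v[c] = vn;
    }
    if (step % check_every == 0) resid_hist.push_back(resid);
    if (!std::isfinite(resid)) { converged = false; ++step; break; }
    if (steady && resid < tol && step > 10) { converged = true; ++step; break; }
  }
  // divergence diagnostic
  std::fill(divv.begin(), divv.end(), 0.0);
  for (int f = 0; f < M.nf; ++f) { divv[M.own[f]] += F[f]; divv[M.nbr[f]] -= F[f]; }
  for (int f = 0; f < M.nb; ++f) divv[M.b_own[f]] += Fb[f];
  double div_max = 0.0;
  for (int c = 0; c < n; ++c) div_max = std::max(div_max, std::fabs(divv[c]) / M.area[c]);

  return List::create(
    _["u"] = NumericVector(u.begin(), u.end()),
    _["v"] = NumericVector(v.begin(), v.end()),
    _["p"] = NumericVector(p.begin(), p.end()),
    _["flux"] = NumericVector(F.begin(), F.end()),
    _["b_flux"] = NumericVector(Fb.begin(), Fb.end()),
    _["resid"] = resid, _["resid_hist"] = NumericVector(resid_hist.begin(), resid_hist.end()),
    _["converged"] = converged, _["steps"] = step,
    _["div_max"] = div_max, _["div_tol_abs"] = div_tol_abs,
    _["dt_min"] = *std::min_element(dtc.begin(), dtc.end()));
}

// ---------------- chemistry ----------------

struct ChemPars {
  double alpha, theta0, chi1, gamma, beta, cc, eps_g, phi0, chi2,
    kg, kp, kb, kr, kd, ku, Fg0, Nws, Ne, alpha0, eps_floor, cap_mult;
};

static ChemPars unpack_pars(const List& p) {
  ChemPars q;
  q.alpha = as<double>(p["alpha"]); q.theta0 = as<double>(p["theta0"]);
  q.chi1 = as<double>(p["chi1"]); q.gamma = as<double>(p["gamma"]);
  q.beta = as<double>(p["beta"]); q.cc = as<double>(p["c"]);
  q.eps_g = as<double>(p["eps_g"]); q.phi0 = as<double>(p["phi0"]);
  q.chi2 = as<double>(p["chi2"]); q.kg = as<double>(p["k_g"]);
  q.kp = as<double>(p["k_p"]); q.kb = as<double>(p["k_b"]);
  q.kr = as<double>(p["k_r"]); q.kd = as<double>(p["k_d"]);
  q.ku = as<double>(p["k_u"]); q.Fg0 = as<double>(p["Fg0"]);
  q.Nws = as<double>(p["Nws"]); q.Ne = as<double>(p["Ne"]);
  q.alpha0 = as<double>(p["alpha0"]); q.eps_floor = as<double>(p["eps_floor"]);
  q.cap_mult = as<double>(p["cap_mult"]);
  return q;
}

// One backward-Euler step of the local kinetics. The system is solved
// exactly in dependency order: u (linear), (theta, phi) by 2x2 Newton,
// Fg and M1 (linear given theta), M2 (scalar quadratic, continuous root).
// Returns false when the step must be subdivided (Newton failure or the
// M2 discriminant turning negative, i.e. blow-up inside the step).
static bool chem_be_step(double s[6], double dt, const ChemPars& q) {
  double un = s[0], thn = s[1], phn = s[2], fgn = s[3], m1n = s[4], m2n = s[5];
  double u1 = un / (1.0 + dt * q.kd);
  // (theta, phi) Newton
  double th = thn, ph = phn;
  bool ok = false;
  for (int it = 0; it < 60; ++it) {
    double den = th + q.theta0;
    double auto_t = q.alpha * th * th / den;
    double f1 = th - thn - dt * (q.ku * u1 + auto_t - q.chi1 * th - q.gamma * th * ph);
    double pacc = 1.0 + (ph / q.phi0) * (ph / q.phi0);
    double f2 = ph - phn - dt * (q.beta * th * (1.0 - ph / q.cc) * pacc - q.chi2 * ph);
    double dauto = q.alpha * th * (th + 2.0 * q.theta0) / (den * den);
    double j11 = 1.0 - dt * (dauto - q.chi1 - q.gamma * ph);
    double j12 = dt * q.gamma * th;
    double j21 = -dt * q.beta * (1.0 - ph / q.cc) * pacc;
    double j22 = 1.0 - dt * (q.beta * th * (-pacc / q.cc +
                   (1.0 - ph / q.cc) * 2.0 * ph / (q.phi0 * q.phi0)) - q.chi2);
    double det = j11 * j22 - j12 * j21;
    if (det == 0.0 || !std::isfinite(det)) return false;
    double dth = (-f1 * j22 + f2 * j12) / det;
    double dph = (-f2 * j11 + f1 * j21) / det;
    th += dth; ph += dph;
    if (th < 0.0) th = 0.0;
    if (ph < 0.0) ph = 0.0;
    double sc = std::fabs(th) + std::fabs(thn) + 1e-12;
    double sc2 = std::fabs(ph) + std::fabs(phn) + 1e-12;
    if (std::fabs(dth) < 1e-13 * sc && std::fabs(dph) < 1e-13 * sc2) { ok = true; break; }
  }
  if (!ok) return false;
  double fg1 = (fgn + dt * q.eps_g * q.Fg0) / (1.0 + dt * (q.kg * th + q.eps_g));
  double S = q.kg * fg1 * th;
  double m1 = (m1n + dt * S) / (1.0 + dt * q.kr);
  double m1f = std::max(m1, q.eps_floor);
  double A2, B2, C2;
  if (m1 <= q.eps_floor) {      // breakage term -> 0 in the vanishing-pool limit
    A2 = dt * 4.0 * q.kp;
    B2 = -1.0 + dt * (8.0 * q.kp * m1 - q.kr);
    C2 = m2n + dt * (S + 4.0 * q.kp * m1 * m1);
  } else {
    A2 = dt * (4.0 * q.kp - q.kb / (3.0 * m1f));
    B2 = -1.0 + dt * (8.0 * q.kp * m1 - q.kr);
    C2 = m2n + dt * (S + 4.0 * q.kp * m1 * m1 + q.kb * m1 / 3.0);
  }
  double m2;
  if (std::fabs(A2) < 1e-300) {
    m2 = -C2 / B2;
  } else {
    double disc = B2 * B2 - 4.0 * A2 * C2;
    if (disc < 0.0) return false;             // blow-up within dt: subdivide
    double sq = std::sqrt(disc);
    double qq = -0.5 * (B2 + (B2 >= 0 ? sq : -sq));
    double r1 = qq / A2, r2 = (qq != 0.0) ? C2 / qq : r1;
    // continuous branch: the root nearest the explicit predictor
    double pred = m2n + dt * (S + 4.0 * q.kp * (m2n + m1) * (m2n + m1) - q.kr * m2n);
    m2 = (std::fabs(r1 - pred) < std::fabs(r2 - pred)) ? r1 : r2;
    if (m2 < 0.0) m2 = std::max(r1, r2);
    if (m2 < 0.0) return false;
  }
  if (!std::isfinite(m2)) return false;
  if (m2 < m1) m2 = m1;                       // second moment dominates the first
  s[0] = u1; s[1] = th; s[2] = ph; s[3] = fg1; s[4] = m1; s[5] = m2;
  return true;
}

static inline void gel_cap(double& m1, double& m2, const ChemPars& q) {
  double cap = q.cap_mult * q.Nws * m1;
  if (m2 > cap) m2 = cap;
}

// Adaptive time marching over dt: halve the sub-step on failure (Newton
// breakdown or M2 blow-up inside the step), grow it back on success; the
// mature-gel cap is projected after every accepted sub-step. Work is
// linear in the number of sub-steps.
static bool chem_be_adaptive(double s[6], double dt, const ChemPars& q, int /*unused*/) {
  double t = 0.0, h = dt;
  const double h_min = dt * 1e-12;
  int accepted = 0;
  while (t < dt * (1.0 - 1e-15)) {
    if (t + h > dt) h = dt - t;
    double trial[6];
    for (int k = 0; k < 6; ++k) trial[k] = s[k];
    if (chem_be_step(trial, h, q)) {
      gel_cap(trial[4], trial[5], q);
      for (int k = 0; k < 6; ++k) s[k] = trial[k];
      t += h;
      if (++accepted % 2 == 0 && h < dt) h = std::min(2.0 * h, dt - t + 1e-300);
      if (accepted > 2000000) return false;
    } else {
      h *= 0.5;
      if (h < h_min) {
        // sub-step underflow: the second moment is blowing up faster than
        // resolvable -- project straight onto the mature-gel cap
        s[5] = std::max(s[5], q.cap_mult * q.Nws * std::max(s[4], q.eps_floor));
        t += h * 2.0;
        h = std::max(h, dt * 1e-9);
      }
    }
  }
  return true;
}

// [[Rcpp::export]]
List cpp_integrate_chemistry(NumericVector u, NumericVector theta,
                             NumericVector phi, NumericVector Fg,
                             NumericVector M1, NumericVector M2,
                             double dt, List pars, int nsub) {
  ChemPars q = unpack_pars(pars);
  int n = u.size();
  NumericVector uo = clone(u), to = clone(theta), po = clone(phi),
    fo = clone(Fg), m1o = clone(M1), m2o = clone(M2);
  double h = dt / nsub;
  for (int c = 0; c < n; ++c) {
    double s[6] = { uo[c], to[c], po[c], fo[c], m1o[c], m2o[c] };
    for (int k = 0; k < nsub; ++k) {
      if (!chem_be_adaptive(s, h, q, 0)) stop("chemistry Newton failed in cell %d", c + 1);
      gel_cap(s[4], s[5], q);
    }
    uo[c] = s[0]; to[c] = s[1]; po[c] = s[2]; fo[c] = s[3]; m1o[c] = s[4]; m2o[c] = s[5];
  }
  return List::create(_["u"] = uo, _["theta"] = to, _["phi"] = po,
                      _["Fg"] = fo, _["M1"] = m1o, _["M2"] = m2o);
}

// ---------------- scalar transport ----------------

// cell -> incident interior faces, with +1 when the cell is the owner
static void build_adjacency(const FvMesh& M, std::vector<int>& adj_start,
                            std::vector<int>& adj_face, std::vector<int>& adj_sign) {
  adj_start.assign(M.ncell + 1, 0);
  for (int f = 0; f < M.nf; ++f) { adj_start[M.own[f] + 1]++; adj_start[M.nbr[f] + 1]++; }
  for (int c = 0; c < M.ncell; ++c) adj_start[c + 1] += adj_start[c];
  adj_face.resize(2 * M.nf); adj_sign.resize(2 * M.nf);
  std::vector<int> pos(adj_start.begin(), adj_start.end() - 1);
  for (int f = 0; f < M.nf; ++f) {
    adj_face[pos[M.own[f]]] = f; adj_sign[pos[M.own[f]]++] = 1;
    adj_face[pos[M.nbr[f]]] = f; adj_sign[pos[M.nbr[f]]++] = -1;
  }
}

// Implicit first-order upwind convection (Gauss-Seidel, alternating sweep
// direction) + explicit diffusion + linearized Robin wall exchange.
// b_cell multiplies the advected flux (polymer transport coefficient).
static void transport_species(const FvMesh& M,
                              const std::vector<double>& F,
                              const std::vector<double>& Fb,
                              std::vector<double>& phi,
                              const std::vector<double>& Dcell,
                              const std::vector<double>& bcell,
                              double inlet_val,
                              const std::vector<double>& mu_b,
                              const std::vector<double>& u0_b,
                              double Dwall,
                              double dt, double gs_tol, int gs_max,
                              // adjacency (cell -> faces)
                              const std::vector<int>& adj_start,
                              const std::vector<int>& adj_face,
                              const std::vector<int>& adj_sign,
                              double* boundary_flux_out,
                              double scale_hint,
                              int scheme) {   // 0: upwind, 1: van Leer TVD
  int n = M.ncell;
  std::vector<double> phi_old(phi);          // diffusion is explicit
  std::vector<double> aP(n), b(n), diff(n, 0.0);
  // explicit diffusion
  for (int f = 0; f < M.nf; ++f) {
    int o = M.own[f], nb = M.nbr[f];
    double Dh = (Dcell[o] > 0 && Dcell[nb] > 0)
      ? 2.0 * Dcell[o] * Dcell[nb] / (Dcell[o] + Dcell[nb]) : 0.0;
    double q = Dh * M.E[f] * (phi[nb] - phi[o]);
    diff[o] += q; diff[nb] -= q;
  }
  // deferred TVD correction (van Leer limiter) against the old field:
  // sharpens the first-order upwind faces toward second order, which
  // suppresses the artificial eddy-core/main-flow exchange
  if (scheme == 1) {
    std::vector<double> gx(n), gy(n), pb(M.nb);
    std::vector<double> qf(M.nf, 0.0), Pout(n, 0.0);
    for (int f = 0; f < M.nb; ++f)
      pb[f] = (M.b_patch[f] == 1) ? inlet_val : phi_old[M.b_own[f]];
    green_gauss(M, phi_old, pb, gx, gy);
    for (int f = 0; f < M.nf; ++f) {
      int o = M.own[f], nb = M.nbr[f];
      int U = (F[f] >= 0.0) ? o : nb;
      int D = (F[f] >= 0.0) ? nb : o;
      double dphi = phi_old[D] - phi_old[U];
      if (dphi == 0.0) continue;
      double dx_ = M.cx[D] - M.cx[U], dy_ = M.cy[D] - M.cy[U];
      double r = 2.0 * (gx[U] * dx_ + gy[U] * dy_) / dphi - 1.0;
      double psi = (r + std::fabs(r)) / (1.0 + std::fabs(r));
      // correction to the owner->neighbour convective flux F b phi_face
      double q = F[f] * bcell[U] * 0.5 * psi * dphi;
      qf[f] = q;
      // donor cell of the correction mass (the cell it depletes)
      int donor = (q >= 0.0) ? o : nb;
      Pout[donor] += std::fabs(q);
    }
    // flux-corrected-transport style clip: the explicit corrections may
    // not remove more than half a donor cell's content per step
    for (int f = 0; f < M.nf; ++f) {
      double q = qf[f];
      if (q == 0.0) continue;
      int donor = (q >= 0.0) ? M.own[f] : M.nbr[f];
      double cap = 0.5 * phi_old[donor] * M.area[donor] / dt;
      double sc = (Pout[donor] > cap) ? cap / Pout[donor] : 1.0;
      q *= sc;
      diff[M.own[f]] -= q; diff[M.nbr[f]] += q;
    }
  }
  for (int c = 0; c < n; ++c) {
    aP[c] = M.area[c] / dt;
    b[c] = M.area[c] / dt * phi[c] + diff[c];
  }
  for (int f = 0; f < M.nb; ++f) {
    int pa = M.b_patch[f], o = M.b_own[f];
    if (pa == 1) {                           // inlet: Dirichlet
      double Fin = Fb[f];                    // negative on inflow
      if (Fin < 0) b[o] += -Fin * bcell[o] * inlet_val;
      else aP[o] += Fin * bcell[o];
      b[o] += Dcell[o] * M.b_E[f] * (inlet_val - phi_old[o]);   // diffusive
    } else if (pa == 2) {                    // outlet: zero gradient
      aP[o] += std::max(Fb[f], 0.0) * bcell[o];
      // (backflow would re-enter at the cell value; same coefficient)
      aP[o] += std::min(Fb[f], 0.0) * bcell[o];
    } else {                                 // walls: Robin exchange (or sealed)
      double mu = mu_b[f];
      if (mu > 0.0 && Dwall > 0.0) {
        double kd = Dwall / M.b_dn[f];
        double kk = M.b_len[f] * mu * kd / (mu + kd);
        aP[o] += kk;
        b[o] += kk * u0_b[f];
      }
    }
  }
  // Gauss-Seidel with alternating sweeps
  double scale = scale_hint + std::fabs(inlet_val);
  for (int c = 0; c < n; ++c) scale = std::max(scale, std::fabs(phi[c]));
  for (int sweep = 0; sweep < gs_max; ++sweep) {
    double dmax = 0.0;
    bool fwd = (sweep % 2 == 0);
    for (int ci = 0; ci < n; ++ci) {
      int c = fwd ? ci : (n - 1 - ci);
      double acc = b[c], ap = aP[c];
      for (int k = adj_start[c]; k < adj_start[c + 1]; ++k) {
        int f = adj_face[k];
        double Ff = F[f] * adj_sign[k];      // outward of c
        int other = (adj_sign[k] > 0) ? M.nbr[f] : M.own[f];
        if (Ff >= 0) ap += Ff * bcell[c];
        else acc += -Ff * bcell[other] * phi[other];
      }
      double nv = acc / ap;
      dmax = std::max(dmax, std::fabs(nv - phi[c]));
      phi[c] = nv;
    }
    if (dmax < gs_tol * (scale + 1e-300)) break;
  }
  if (boundary_flux_out) {
    // realized boundary fluxes, evaluated with the same field values the
    // update used (convection & Robin implicit: new phi; diffusion: old phi)
    double tot = 0.0;
    for (int f = 0; f < M.nb; ++f) {
      int pa = M.b_patch[f], o = M.b_own[f];
      if (pa == 1) {
        double Fin = Fb[f];
        tot += -std::min(Fin, 0.0) * bcell[o] * inlet_val
             - std::max(Fin, 0.0) * bcell[o] * phi[o]
             + Dcell[o] * M.b_E[f] * (inlet_val - phi_old[o]);
      } else if (pa == 2) {
        tot += -Fb[f] * bcell[o] * phi[o];
      } else {
        double mu = mu_b[f];
        if (mu > 0.0 && Dwall > 0.0) {
          double kd = Dwall / M.b_dn[f];
          double kk = M.b_len[f] * mu * kd / (mu + kd);
          tot += kk * (u0_b[f] - phi[o]);
        }
      }
    }
    *boundary_flux_out = tot;
  }
}

// [[Rcpp::export]]
NumericVector cpp_advect_diffuse(List meshL, NumericVector flux, NumericVector bflux,
                                 NumericVector field, NumericVector Dcell,
                                 NumericVector bcell, double inlet_value,
                                 NumericVector mu_b, NumericVector u0_b,
                                 double Dwall, double dt, double gs_tol, int gs_max,
                                 int nsteps, int scheme) {
  FvMesh M = unpack_mesh(meshL);
  std::vector<double> F(flux.begin(), flux.end()), Fb(bflux.begin(), bflux.end());
  std::vector<double> phi(field.begin(), field.end());
  std::vector<double> Dc(Dcell.begin(), Dcell.end()), bc(bcell.begin(), bcell.end());
  std::vector<double> mb(mu_b.begin(), mu_b.end()), ub(u0_b.begin(), u0_b.end());
  std::vector<int> adj_start, adj_face, adj_sign;
  build_adjacency(M, adj_start, adj_face, adj_sign);
  for (int k = 0; k < nsteps; ++k)
    transport_species(M, F, Fb, phi, Dc, bc, inlet_value, mb, ub, Dwall,
                      dt, gs_tol, gs_max, adj_start, adj_face, adj_sign,
                      nullptr, 0.0, scheme);
  return NumericVector(phi.begin(), phi.end());
}

// Full coupled chunk: for each step, transport all six species on frozen
// face fluxes, integrate the local chemistry implicitly, apply the
// mature-gel cap, and refresh the polymer closures (Nw, bp, Df, alpha_p).
// Stops early when max Nw crosses nws_stop (gel nucleation).
// [[Rcpp::export]]
List cpp_transport_chunk(List meshL, NumericVector flux, NumericVector bflux,
                         NumericVector u_, NumericVector theta_,
                         NumericVector phi_, NumericVector Fg_,
                         NumericVector M1_, NumericVector M2_,
                         NumericVector mu_b_, NumericVector u0_b_,
                         List pars, NumericVector Dcoef,
                         double dt, int nsteps, int chem_sub, bool chem_on,
                         double nws_stop, double gs_tol, int gs_max,
                         bool audit, int scheme) {
  FvMesh M = unpack_mesh(meshL);
  ChemPars q = unpack_pars(pars);
  int n = M.ncell;
  double D_u = Dcoef[0], D_theta = Dcoef[1], D_phi = Dcoef[2],
    D_g = Dcoef[3], D_mono = Dcoef[4];
  std::vector<double> F(flux.begin(), flux.end()), Fb(bflux.begin(), bflux.end());
  std::vector<double> mu_b(mu_b_.begin(), mu_b_.end()), u0_b(u0_b_.begin(), u0_b_.end());
  std::vector<std::vector<double>> S(6);
  S[0].assign(u_.begin(), u_.end()); S[1].assign(theta_.begin(), theta_.end());
  S[2].assign(phi_.begin(), phi_.end()); S[3].assign(Fg_.begin(), Fg_.end());
  S[4].assign(M1_.begin(), M1_.end()); S[5].assign(M2_.begin(), M2_.end());
  std::vector<int> adj_start, adj_face, adj_sign;
  build_adjacency(M, adj_start, adj_face, adj_sign);

  std::vector<double> ones(n, 1.0), Dconst(n), bp(n), Df(n), Nw(n), apv(n);
  std::vector<double> mu_zero(M.nb, 0.0), u0_zero(M.nb, 0.0);
  auto closures = [&]() {
    for (int c = 0; c < n; ++c) {
      double nw = 1.0;
      if (S[4][c] > q.eps_floor) {
        nw = S[5][c] / S[4][c];
        if (nw < 1.0) nw = 1.0;
        double cap = q.cap_mult * q.Nws;
        if (nw > cap) nw = cap;
      }
      Nw[c] = nw;
      bp[c] = 1.0 / (1.0 + nw / q.Ne);
      Df[c] = D_mono / (nw * (1.0 + nw / q.Ne));
      double m1_mol = S[4][c] * 1e-12;      // nM -> mol/cm^3
      apv[c] = q.alpha0 * m1_mol * m1_mol * (1.0 - bp[c]);
    }
  };
  closures();

  NumericVector max_nw(nsteps);
  std::vector<double> scales = { q.Fg0 * 0.01, q.theta0, q.phi0 * 10, q.Fg0, q.Fg0, q.Fg0 };
  double inlet_vals[6] = { 0.0, 0.0, 0.0, q.Fg0, 0.0, 0.0 };
  double clip_count = 0.0, audit_max = 0.0, influx_u = 0.0;
  int steps_done = 0, cross_cell = -1;
  bool crossed = false;
  double cross_frac = NA_REAL, prev_max_nw = 0.0;
  for (int c = 0; c < n; ++c) prev_max_nw = std::max(prev_max_nw, Nw[c]);

  for (int step = 0; step < nsteps; ++step) {
    for (int sp = 0; sp < 6; ++sp) {
      double mass0 = 0.0;
      if (audit) for (int c = 0; c < n; ++c) mass0 += M.area[c] * S[sp][c];
      double Dw = 0.0;
      const std::vector<double>* Dcell = &Dconst;
      const std::vector<double>* bc = &ones;
      const std::vector<double>* mu = &mu_zero;
      const std::vector<double>* u0b = &u0_zero;
      double Dval = D_theta;
      switch (sp) {
        case 0: Dval = D_u; Dw = D_u; mu = &mu_b; u0b = &u0_b; break;
        case 1: Dval = D_theta; break;
        case 2: Dval = D_phi; break;
        case 3: Dval = D_g; break;
        case 4: case 5: Dcell = &Df; bc = &bp; break;
      }
      if (Dcell == &Dconst) std::fill(Dconst.begin(), Dconst.end(), Dval);
      double bfl = 0.0;
      transport_species(M, F, Fb, S[sp], *Dcell, *bc, inlet_vals[sp],
                        *mu, *u0b, Dw, dt, gs_tol, gs_max,
                        adj_start, adj_face, adj_sign,
                        audit ? &bfl : nullptr, scales[sp], scheme);
      if (sp == 0 && audit) influx_u += bfl * dt;
      if (audit) {
        double mass1 = 0.0;
        for (int c = 0; c < n; ++c) mass1 += M.area[c] * S[sp][c];
        double denom = std::max(std::fabs(mass1), scales[sp] * 1e-6);
        audit_max = std::max(audit_max, std::fabs(mass1 - mass0 - dt * bfl) / denom);
      }
      // positivity policy: clip tiny negatives, abort on large ones
      double floor_bad = -1e-9 * (scales[sp] + 1.0);
      for (int c = 0; c < n; ++c) {
        if (S[sp][c] < 0.0) {
          if (S[sp][c] < floor_bad)
            stop("transport produced a significant negative value (species %d)", sp + 1);
          S[sp][c] = 0.0; clip_count += 1.0;
        }
      }
      // fibrinogen ceiling: the deferred TVD correction may overshoot the
      // inlet maximum by a small amount on rough fields; project back
      if (sp == 3) {
        double cap_bad = q.Fg0 * (1.0 + 0.02);
        for (int c = 0; c < n; ++c) {
          if (S[3][c] > q.Fg0) {
            if (S[3][c] > cap_bad)
              stop("transport overshot the fibrinogen ceiling significantly");
            S[3][c] = q.Fg0; clip_count += 1.0;
          }
        }
      }
    }
    if (chem_on) {
      double h = dt / chem_sub;
      for (int c = 0; c < n; ++c) {
        double s6[6] = { S[0][c], S[1][c], S[2][c], S[3][c], S[4][c], S[5][c] };
        for (int k = 0; k < chem_sub; ++k) {
          if (!chem_be_adaptive(s6, h, q, 0))
            stop("chemistry integration failed in cell %d", c + 1);
          gel_cap(s6[4], s6[5], q);
        }
        S[0][c] = s6[0]; S[1][c] = s6[1]; S[2][c] = s6[2];
        S[3][c] = s6[3]; S[4][c] = s6[4]; S[5][c] = s6[5];
      }
    }
    closures();
    double mx = 0.0; int amx = 0;
    for (int c = 0; c < n; ++c) if (Nw[c] > mx) { mx = Nw[c]; amx = c; }
    max_nw[step] = mx;
    ++steps_done;
    if (!crossed && mx >= nws_stop) {
      crossed = true; cross_cell = amx + 1;
      double denom = mx - prev_max_nw;
      cross_frac = (denom > 0) ? std::min(1.0, std::max(0.0, (nws_stop - prev_max_nw) / denom)) : 1.0;
      break;
    }
    prev_max_nw = mx;
  }

  return List::create(
    _["u"] = NumericVector(S[0].begin(), S[0].end()),
    _["theta"] = NumericVector(S[1].begin(), S[1].end()),
    _["phi"] = NumericVector(S[2].begin(), S[2].end()),
    _["Fg"] = NumericVector(S[3].begin(), S[3].end()),
    _["M1"] = NumericVector(S[4].begin(), S[4].end()),
    _["M2"] = NumericVector(S[5].begin(), S[5].end()),
    _["Nw"] = NumericVector(Nw.begin(), Nw.end()),
    _["bp"] = NumericVector(bp.begin(), bp.end()),
    _["Df"] = NumericVector(Df.begin(), Df.end()),
    _["alpha_p"] = NumericVector(apv.begin(), apv.end()),
    _["max_nw"] = max_nw[Range(0, std::max(steps_done - 1, 0))],
    _["steps_done"] = steps_done,
    _["crossed"] = crossed, _["cross_frac"] = cross_frac,
    _["cross_cell"] = cross_cell,
    _["clip_count"] = clip_count, _["audit_max"] = audit_max,
    _["influx_u"] = influx_u);
}
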