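// Fused time-stepping core for the coupled Beris-Edwards / D2Q9 lattice
// Boltzmann model, plus a window-counting kernel for number-variance
// statistics. The math mirrors the R-level operators exactly (same
// stencils, same update ordering); an equivalence test in the package
// asserts one compiled step == the R composition.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int    CX[9] = {0, 1, 0, -1, 0, 1, -1, -1, 1};
static const int    CY[9] = {0, 0, 1, 0, -1, 1, 1, -1, -1};
static const double W9[9] = {4.0 / 9,  1.0 / 9,  1.0 / 9,  1.0 / 9, 1.0 / 9,
                             1.0 / 36, 1.0 / 36, 1.0 / 36, 1.0 / 36};

// Advance the coupled system n_steps. Per step:
//   (1) hydrodynamic moments of f with the previous body force ->
//       velocity (half-force corrected);
//   (2) polarity from (Q, v) with sign persistence at ties;
//   (3) explicit Beris-Edwards update of Q (upwind self-advection,
//       central differences elsewhere), q_substeps sub-cycles;
//   (4) molecular field and passive+active stress from the updated Q,
//       body force = divergence of that stress;
//   (5) BGK collision with Guo forcing using the new force, periodic
//       streaming.
// Aborts with an R error on NaN or max |v| > 0.3.
// [[Rcpp::export]]
List cpp_run_steps(arma::mat Qxx, arma::mat Qxy, arma::cube f,
                   arma::mat px, arma::mat py,
                   arma::mat Fx, arma::mat Fy,
                   List params, int n_steps, int q_substeps,
                   int step_offset) {
  const int L = Qxx.n_rows;
  const double rho0 = params["rho"], eta = params["eta"],
               lam = params["lam"], Gam = params["Gamma"],
               K = params["K"], A = params["A"], zeta = params["zeta"],
               V0 = params["V0"], dt = params["dt"];
  const double tau = 3.0 * eta / rho0 + 0.5;
  const double pref = 1.0 - 1.0 / (2.0 * tau);
  const double sub_dt = dt / q_substeps;

  std::vector<int> ipv(L), imv(L);
  for (int i = 0; i < L; ++i) {
    ipv[i] = (i + 1) % L;
    imv[i] = (i + L - 1) % L;
  }

  arma::mat rho(L, L), mx(L, L), my(L, L), vx(L, L), vy(L, L);
  arma::mat Exx(L, L), Eyy(L, L), Exy(L, L), Wxy(L, L), trg(L, L);
  arma::mat Qxx_n(L, L), Qxy_n(L, L);
  arma::mat sxx(L, L), sxy(L, L), syx(L, L), syy(L, L);
  arma::cube fpost(L, L, 9);
  // columns: max|v|, mean q, kinetic energy, mean Qxy^2, mean omega^2
  arma::mat diag_out(n_steps, 5);

  for (int step = 0; step < n_steps; ++step) {
    // (1) moments and velocity from the previous force
    double maxv2 = 0.0, ke = 0.0;
    for (int j = 0; j < L; ++j) {
      for (int i = 0; i < L; ++i) {
        double r = 0.0, sx = 0.0, sy = 0.0;
        for (int k = 0; k < 9; ++k) {
          const double fk = f(i, j, k);
          r += fk;
          sx += CX[k] * fk;
          sy += CY[k] * fk;
        }
        rho(i, j) = r;
        mx(i, j) = sx;
        my(i, j) = sy;
        const double ux = (sx + 0.5 * Fx(i, j)) / r;
        const double uy = (sy + 0.5 * Fy(i, j)) / r;
        vx(i, j) = ux;
        vy(i, j) = uy;
        const double v2 = ux * ux + uy * uy;
        ke += 0.5 * v2;
        if (v2 > maxv2) maxv2 = v2;
      }
    }
    if (!std::isfinite(maxv2) || maxv2 > 0.09 || rho.min() <= 0.0) {
      stop("blow-up at step %d: max|v| = %g (limit 0.3) or bad density",
           step_offset + step + 1, std::sqrt(maxv2));
    }

    // (2) polarity: director sign closest to the flow, persistent at ties.
    // Director via half-angle identities on theta = atan2(Qxy, Qxx)/2 in
    // (-pi/2, pi/2]: cos(theta) = sqrt((1 + Qxx/q)/2) >= 0 and
    // sin(theta) = Qxy / (2 q cos(theta)).
    double mean_q = 0.0;
    for (int j = 0; j < L; ++j) {
      for (int i = 0; i < L; ++i) {
        const double qxx = Qxx(i, j), qxy = Qxy(i, j);
        const double qmag = std::sqrt(qxx * qxx + qxy * qxy);
        mean_q += qmag;
        double nx = 1.0, ny = 0.0;
        if (qmag > 0.0) {
          nx = std::sqrt(0.5 * (1.0 + qxx / qmag));
          ny = (nx > 1e-154) ? qxy / (2.0 * qmag * nx) : 1.0;
        }
        const double vn = vx(i, j) * nx + vy(i, j) * ny;
        const double vm = std::sqrt(vx(i, j) * vx(i, j) +
                                    vy(i, j) * vy(i, j));
        double s;
        if (vm < 1e-12 || std::fabs(vn) < 1e-12 * vm) {
          s = (px(i, j) * nx + py(i, j) * ny >= 0.0) ? 1.0 : -1.0;
        } else {
          s = (vn > 0.0) ? 1.0 : -1.0;
        }
        px(i, j) = s * nx;
        py(i, j) = s * ny;
      }
    }

    // velocity gradients (central), fixed during the Q sub-cycle
    double om2 = 0.0;
    for (int j = 0; j < L; ++j) {
      const int jp = ipv[j], jm = imv[j];
      for (int i = 0; i < L; ++i) {
        const int ip = ipv[i], im = imv[i];
        const double dxvx = 0.5 * (vx(ip, j) - vx(im, j));
        const double dyvx = 0.5 * (vx(i, jp) - vx(i, jm));
        const double dxvy = 0.5 * (vy(ip, j) - vy(im, j));
        const double dyvy = 0.5 * (vy(i, jp) - vy(i, jm));
        Exx(i, j) = dxvx;
        Eyy(i, j) = dyvy;
        Exy(i, j) = 0.5 * (dxvy + dyvx);
        Wxy(i, j) = 0.5 * (dyvx - dxvy);   // omega = -2 Wxy
        trg(i, j) = dxvx - dyvy;          // times Qxx; plus (dxvy+dyvx)*Qxy
        const double om = -2.0 * Wxy(i, j);
        om2 += om * om;
      }
    }

    // (3) Beris-Edwards sub-cycled update
    for (int sub = 0; sub < q_substeps; ++sub) {
      for (int j = 0; j < L; ++j) {
        const int jp = ipv[j], jm = imv[j];
        for (int i = 0; i < L; ++i) {
          const int ip = ipv[i], im = imv[i];
          const double qxx = Qxx(i, j), qxy = Qxy(i, j);
          const double lapxx = Qxx(ip, j) + Qxx(im, j) + Qxx(i, jp) +
                               Qxx(i, jm) - 4.0 * qxx;
          const double lapxy = Qxy(ip, j) + Qxy(im, j) + Qxy(i, jp) +
                               Qxy(i, jm) - 4.0 * qxy;
          const double bulk = 4.0 * A * (1.0 - 2.0 * (qxx * qxx + qxy * qxy));
          const double hxx = K * lapxx + bulk * qxx;
          const double hxy = K * lapxy + bulk * qxy;

          // co-rotation: S = M Qh + Qh M^T - 2 lam Qh tr(Q grad v),
          // M = lam E + W; traceless-symmetric projection stored
          const double Qhxx = qxx + 0.5, Qhyy = 0.5 - qxx;
          const double Mxx = lam * Exx(i, j), Myy = lam * Eyy(i, j);
          const double Mxy = lam * Exy(i, j) + Wxy(i, j);
          const double Myx = lam * Exy(i, j) - Wxy(i, j);
          double Sxx = 2.0 * (Mxx * Qhxx + Mxy * qxy);
          double Syy = 2.0 * (Myx * qxy + Myy * Qhyy);
          double Sxy = Mxx * qxy + Mxy * Qhyy + Qhxx * Myx + qxy * Myy;
          double Syx = Myx * Qhxx + Myy * qxy + qxy * Mxx + Qhyy * Mxy;
          const double tr = qxx * trg(i, j) +
                            qxy * 2.0 * Exy(i, j);
          Sxx -= 2.0 * lam * Qhxx * tr;
          Syy -= 2.0 * lam * Qhyy * tr;
          Sxy -= 2.0 * lam * qxy * tr;
          Syx -= 2.0 * lam * qxy * tr;
          const double Sxx_p = 0.5 * (Sxx - Syy);
          const double Sxy_p = 0.5 * (Sxy + Syx);

          // upwind advection on v + V0 p
          const double wx = vx(i, j) + V0 * px(i, j);
          const double wy = vy(i, j) + V0 * py(i, j);
          const double dxQxx = (wx > 0.0) ? (qxx - Qxx(im, j))
                                          : (Qxx(ip, j) - qxx);
          const double dyQxx = (wy > 0.0) ? (qxx - Qxx(i, jm))
                                          : (Qxx(i, jp) - qxx);
          const double dxQxy = (wx > 0.0) ? (qxy - Qxy(im, j))
                                          : (Qxy(ip, j) - qxy);
          const double dyQxy = (wy > 0.0) ? (qxy - Qxy(i, jm))
                                          : (Qxy(i, jp) - qxy);

          Qxx_n(i, j) = qxx + sub_dt * (-(wx * dxQxx + wy * dyQxx) +
                                        Gam * hxx + Sxx_p);
          Qxy_n(i, j) = qxy + sub_dt * (-(wx * dxQxy + wy * dyQxy) +
                                        Gam * hxy + Sxy_p);
        }
      }
      Qxx.swap(Qxx_n);
      Qxy.swap(Qxy_n);
    }
    if (!Qxx.is_finite() || !Qxy.is_finite()) {
      stop("blow-up at step %d: non-finite order parameter",
           step_offset + step + 1);
    }

    // (4) molecular field and stress from the updated Q (one pass: the
    // stress needs H only at the site itself)
    double qxy2 = 0.0;
    for (int j = 0; j < L; ++j) {
      const int jp = ipv[j], jm = imv[j];
      for (int i = 0; i < L; ++i) {
        const int ip = ipv[i], im = imv[i];
        const double qxx = Qxx(i, j), qxy = Qxy(i, j);
        qxy2 += qxy * qxy;
        const double lapxx = Qxx(ip, j) + Qxx(im, j) + Qxx(i, jp) +
                             Qxx(i, jm) - 4.0 * qxx;
        const double lapxy = Qxy(ip, j) + Qxy(im, j) + Qxy(i, jp) +
                             Qxy(i, jm) - 4.0 * qxy;
        const double bulk = 4.0 * A * (1.0 - 2.0 * (qxx * qxx + qxy * qxy));
        const double hxx = K * lapxx + bulk * qxx;
        const double hxy = K * lapxy + bulk * qxy;
        const double Qhxx = qxx + 0.5, Qhyy = 0.5 - qxx;
        const double QH2 = 2.0 * (qxx * hxx + qxy * hxy);
        const double HQh_xx = hxx * Qhxx + hxy * qxy;
        const double HQh_xy = hxx * qxy + hxy * Qhyy;
        const double HQh_yx = hxy * Qhxx - hxx * qxy;
        const double HQh_yy = hxy * qxy - hxx * Qhyy;
        const double anti = 2.0 * (qxx * hxy - hxx * qxy);
        const double dxQxx = 0.5 * (Qxx(ip, j) - Qxx(im, j));
        const double dyQxx = 0.5 * (Qxx(i, jp) - Qxx(i, jm));
        const double dxQxy = 0.5 * (Qxy(ip, j) - Qxy(im, j));
        const double dyQxy = 0.5 * (Qxy(i, jp) - Qxy(i, jm));
        const double er_xx = -2.0 * K * (dxQxx * dxQxx + dxQxy * dxQxy);
        const double er_yy = -2.0 * K * (dyQxx * dyQxx + dyQxy * dyQxy);
        const double er_xy = -2.0 * K * (dxQxx * dyQxx + dxQxy * dyQxy);
        const double mixed = -lam * (HQh_xy + HQh_yx);
        sxx(i, j) = 2.0 * lam * Qhxx * QH2 - 2.0 * lam * HQh_xx + er_xx -
                    zeta * qxx;
        sxy(i, j) = 2.0 * lam * qxy * QH2 + mixed + anti + er_xy -
                    zeta * qxy;
        syx(i, j) = 2.0 * lam * qxy * QH2 + mixed - anti + er_xy -
                    zeta * qxy;
        syy(i, j) = 2.0 * lam * Qhyy * QH2 - 2.0 * lam * HQh_yy + er_yy +
                    zeta * qxx;
      }
    }
    for (int j = 0; j < L; ++j) {
      const int jp = ipv[j], jm = imv[j];
      for (int i = 0; i < L; ++i) {
        const int ip = ipv[i], im = imv[i];
        Fx(i, j) = 0.5 * (sxx(ip, j) - sxx(im, j)) +
                   0.5 * (sxy(i, jp) - sxy(i, jm));
        Fy(i, j) = 0.5 * (syx(ip, j) - syx(im, j)) +
                   0.5 * (syy(i, jp) - syy(i, jm));
      }
    }

    // (5) BGK collision + Guo forcing (new force), streamed directly into
    // the target cube, then swapped back
    for (int j = 0; j < L; ++j) {
      const int jp = ipv[j], jm = imv[j];
      for (int i = 0; i < L; ++i) {
        const int ip = ipv[i], im = imv[i];
        const double r = rho(i, j);
        const double fx = Fx(i, j), fy = Fy(i, j);
        const double ux = (mx(i, j) + 0.5 * fx) / r;
        const double uy = (my(i, j) + 0.5 * fy) / r;
        const double u2 = ux * ux + uy * uy;
        const double uF = ux * fx + uy * fy;
        const int it[9] = {i, ip, i, im, i, ip, im, im, ip};
        const int jt[9] = {j, j, jp, j, jm, jp, jp, jm, jm};
        for (int k = 0; k < 9; ++k) {
          const double cu = CX[k] * ux + CY[k] * uy;
          const double cF = CX[k] * fx + CY[k] * fy;
          const double feq = W9[k] * r *
            (1.0 + 3.0 * cu + 4.5 * cu * cu - 1.5 * u2);
          const double src = pref * W9[k] * (3.0 * (cF - uF) + 9.0 * cu * cF);
          fpost(it[k], jt[k], k) = f(i, j, k) - (f(i, j, k) - feq) / tau + src;
        }
      }
    }
    f.swap(fpost);

    // diagnostics: velocity/KE/enstrophy are the pre-update ones of this
    // step, mean q pre-update (polarity loop), Qxy^2 post-update
    const double n2 = double(L) * double(L);
    diag_out(step, 0) = std::sqrt(maxv2);
    diag_out(step, 1) = mean_q / n2;
    diag_out(step, 2) = ke / n2;
    diag_out(step, 3) = qxy2 / n2;
    diag_out(step, 4) = om2 / n2;
  }

  return List::create(_["Qxx"] = Qxx, _["Qxy"] = Qxy, _["f"] = f,
                      _["px"] = px, _["py"] = py,
                      _["Fx"] = Fx, _["Fy"] = Fy,
                      _["diagnostics"] = diag_out);
}

// Counts of points inside circular windows of several radii around random
// centers, with periodic minimum-image distances. Returns an
// n_centers x n_radii integer matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_count_in_windows(NumericVector x, NumericVector y,
                                   NumericVector cx, NumericVector cy,
                                   double L, NumericVector radii) {
  const int np = x.size(), nc = cx.size(), nr = radii.size();
  std::vector<double> r2(nr);
  for (int k = 0; k < nr; ++k) r2[k] = radii[k] * radii[k];
  IntegerMatrix out(nc, nr);
  const double half = 0.5 * L;
  for (int c = 0; c < nc; ++c) {
    const double xc = cx[c], yc = cy[c];
    for (int p = 0; p < np; ++p) {
      double dx = std::fabs(x[p] - xc);
      if (dx > half) dx = L - dx;
      double dy = std::fabs(y[p] - yc);
      if (dy > half) dy = L - dy;
      const double d2 = dx * dx + dy * dy;
      for (int k = nr - 1; k >= 0; --k) {
        if (d2 <= r2[k]) out(c, k) += 1; else break;
      }
    }
  }
  return out;
}
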