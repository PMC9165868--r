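// Compiled core: right-hand side of the non-dimensionalised 21-state system,
// a numerical Jacobian, an L-stable adaptive Rosenbrock 2(3) stepper
// (Shampine-Reichelt scheme) with cubic-Hermite dense output, and a
// fixed-step classical RK4 used as an independent integration route.
//
// Parameter vector layout (must match hl_par_names() on the R side):
//  0 J        1 W        2 P        3 f
//  4 mu_mh_star  5 mu_mr_star  6 mu_mp_star
//  7 delta_mh    8 delta_mr    9 delta_mp
// 10 kappa_mh   11 kappa_mr   12 kappa_mp
// 13 kc  14 xc  15 xh  16 xr  17 xp
// 18 mu_h 19 mu_r 20 mu_p
// 21 delta_h 22 delta_p 23 delta_c
// 24 gamma_r 25 gamma_p 26 gamma_l 27 gamma_v
// 28 beta_0 29 beta_l 30 beta_v 31 beta_p
// 32 alpha_l 33 alpha_minus_l 34 alpha_v 35 alpha_minus_v
// 36 alpha_p 37 alpha_minus_p
// 38 M_l 39 M_v 40 M_p
// 41 chi_v 42 omega_v
// 43 R_l_chol 44 R_v_chol 45 mu_c
// 46 sigma_l 47 sigma_v 48 nu_l 49 nu_v 50 nu_p 51 rho_v
// 52 CL_S 53 eps_S 54 eps_minus_S 55 zeta_S
// 56 eps_p 57 eps_minus_p
//
// State order (canonical, must match hl_state_names()):
//  0 m_h  1 m_r  2 m_p  3 h  4 p_I  5 r_I  6 r_f
//  7 l_E  8 l_RB  9 l_I  10 v_E  11 v_RB  12 v_I  13 c
// 14 p_E 15 p_RB 16 A_E 17 p_AB 18 S_E 19 S_i 20 S_ih
//
// Sources vector (dimensionless rates): 0 l_E, 1 v_E, 2 p_E, 3 A_E, 4 S_E.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int NSTATE = 21;
static const double OCC_GUARD = 1.0 - 1e-10;

enum par_idx {
  iJ = 0, iW, iP, if_, imu_mh, imu_mr, imu_mp,
  idelta_mh, idelta_mr, idelta_mp,
  ikappa_mh, ikappa_mr, ikappa_mp,
  ikc, ixc, ixh, ixr, ixp,
  imu_h, imu_r, imu_p,
  idelta_h, idelta_p, idelta_c,
  igamma_r, igamma_p, igamma_l, igamma_v,
  ibeta_0, ibeta_l, ibeta_v, ibeta_p,
  ialpha_l, ialpha_ml, ialpha_v, ialpha_mv,
  ialpha_p, ialpha_mp,
  iM_l, iM_v, iM_p,
  ichi_v, iomega_v,
  iR_l, iR_v, imu_c,
  isigma_l, isigma_v, inu_l, inu_v, inu_p, irho_v,
  iCL_S, ieps_S, ieps_mS, izeta_S,
  ieps_p, ieps_mp,
  NPAR
};

// transcriptional activation: mu_star / (1 + (kappa * (1 + (c/kc)^xc))^x_gene)
static inline double transcription(double mu_star, double kappa, double c,
                                   double kc, double xc, double xg) {
  const double occ = kappa * (1.0 + std::pow(c / kc, xc));
  return mu_star / (1.0 + std::pow(occ, xg));
}

static void rhs_core(const double *y, const double *p, const double *src,
                     double *dy) {
  const double J = p[iJ], W = p[iW], Ppit = p[iP], f = p[if_];
  const double c = y[13], r_f = y[6];

  const double occ_free = 1.0 - r_f;
  if (occ_free < 1.0 - OCC_GUARD)
    stop("receptor occupancy singularity: r_f = %g has reached the surface "
         "capacity (dimensionless r_f >= 1)", r_f);

  const double T_h = transcription(p[imu_mh], p[ikappa_mh], c, p[ikc], p[ixc], p[ixh]);
  const double T_r = transcription(p[imu_mr], p[ikappa_mr], c, p[ikc], p[ixc], p[ixr]);
  const double T_p = transcription(p[imu_mp], p[ikappa_mp], c, p[ikc], p[ixc], p[ixp]);

  // co-internalisation rates of surface material with bound-particle vesicles;
  // each internalised particle carries its M bound receptors plus
  // M * r_f/(1 - r_f) co-captured free receptors, total M * x_RB/(1 - r_f)
  const double rec_l = p[ibeta_l] * y[8]  / occ_free;
  const double rec_v = p[ibeta_v] * y[11] / occ_free;
  const double rec_p = p[ibeta_p] * y[15] / occ_free;

  dy[0] = (T_h - p[idelta_mh] * y[0]) / J;
  dy[1] = (T_r - p[idelta_mr] * y[1]) / J;
  dy[2] = (T_p - p[idelta_mp] * y[2]) / J;

  dy[3] = p[imu_h] * y[0] - p[idelta_h] * y[3]
        - p[ieps_S] * p[izeta_S] * y[19] * y[3]
        + p[ieps_mS] * p[izeta_S] * y[20];

  dy[4] = p[imu_p] * y[2] - (p[igamma_p] + p[idelta_p]) * y[4];

  dy[5] = p[imu_r] * y[1] - p[igamma_r] * y[5]
        + f * p[ibeta_0] * r_f / Ppit
        + f * p[iM_l] * p[inu_l] * rec_l
        + f * p[iM_v] * p[inu_v] * rec_v;

  dy[6] = p[igamma_r] * y[5] - p[ibeta_0] * r_f / Ppit
        + p[iM_l] * p[inu_l] * (-rec_l * r_f - p[ialpha_l] * r_f * y[7]  + p[ialpha_ml] * y[8])
        + p[iM_v] * p[inu_v] * (-rec_v * r_f - p[ialpha_v] * r_f * y[10] + p[ialpha_mv] * y[11])
        + p[iM_p] * p[inu_p] * (-rec_p * r_f - p[ialpha_p] * r_f * y[14] + p[ialpha_mp] * y[15]);

  dy[7] = (-p[ialpha_l] * r_f * y[7] + p[ialpha_ml] * y[8]) / W
        + p[ichi_v] * p[irho_v] * y[10] + src[0];
  dy[8] = p[ialpha_l] * r_f * y[7] - p[ialpha_ml] * y[8] - p[ibeta_l] * y[8];
  dy[9] = p[ibeta_l] * y[8] - p[igamma_l] * y[9];

  dy[10] = (-p[ialpha_v] * r_f * y[10] + p[ialpha_mv] * y[11]) / W
         - p[ichi_v] * y[10] + p[iomega_v] + src[1];
  dy[11] = p[ialpha_v] * r_f * y[10] - p[ialpha_mv] * y[11] - p[ibeta_v] * y[11];
  dy[12] = p[ibeta_v] * y[11] - p[igamma_v] * y[12];

  dy[13] = p[iR_l] * p[isigma_l] * p[igamma_l] * y[9]
         + p[iR_v] * p[isigma_v] * p[igamma_v] * y[12]
         + p[imu_c] * y[3] - p[idelta_c] * c;

  dy[14] = (-p[ialpha_p] * r_f * y[14] + p[ialpha_mp] * y[15]
            + p[igamma_p] * y[4]
            - p[ieps_p] * y[16] * y[14] + p[ieps_mp] * y[17]) / W + src[2];
  dy[15] = p[ialpha_p] * r_f * y[14] - p[ialpha_mp] * y[15] - p[ibeta_p] * y[15];

  dy[16] = (-p[ieps_p] * y[16] * y[14] + p[ieps_mp] * y[17]) / W + src[3];
  dy[17] = p[ieps_p] * y[16] * y[14] - p[ieps_mp] * y[17];

  dy[18] = -p[iCL_S] * y[18] / W + src[4];
  dy[19] = p[iCL_S] * y[18] - p[ieps_S] * y[19] * y[3] + p[ieps_mS] * y[20];
  dy[20] = p[ieps_S] * y[19] * y[3] - p[ieps_mS] * y[20];
}

static void check_inputs(const arma::vec &y, const arma::vec &par,
                         const arma::vec &src) {
  if ((int)y.n_elem != NSTATE)
    stop("state vector must have %d components, got %d", NSTATE, (int)y.n_elem);
  if ((int)par.n_elem != NPAR)
    stop("parameter vector must have %d components, got %d", NPAR, (int)par.n_elem);
  if (src.n_elem != 5) stop("source vector must have 5 components");
  if (!y.is_finite()) stop("non-finite value in state vector");
  if (!par.is_finite()) stop("non-finite value in parameter vector");
}

// [[Rcpp::export(name = ".hl_rhs_cpp")]]
arma::vec hl_rhs_cpp(double t, arma::vec y, arma::vec par, arma::vec src,
                     bool check_negative = true) {
  check_inputs(y, par, src);
  if (check_negative && y.min() < 0)
    stop("negative value in state vector (component %d = %g)",
         (int)y.index_min() + 1, y.min());
  arma::vec dy(NSTATE);
  rhs_core(y.memptr(), par.memptr(), src.memptr(), dy.memptr());
  return dy;
}

// forward-difference Jacobian of the compiled RHS
static arma::mat num_jac(const arma::vec &y, const arma::vec &par,
                         const arma::vec &src) {
  arma::mat Jm(NSTATE, NSTATE);
  arma::vec f0(NSTATE), f1(NSTATE), yp = y;
  rhs_core(y.memptr(), par.memptr(), src.memptr(), f0.memptr());
  const double sqeps = std::sqrt(std::numeric_limits<double>::epsilon());
  for (int j = 0; j < NSTATE; ++j) {
    double dj = sqeps * std::max(std::abs(y[j]), 1e-6);
    yp[j] = y[j] + dj;
    dj = yp[j] - y[j];  // exact representable increment
    rhs_core(yp.memptr(), par.memptr(), src.memptr(), f1.memptr());
    Jm.col(j) = (f1 - f0) / dj;
    yp[j] = y[j];
  }
  return Jm;
}

// [[Rcpp::export(name = ".hl_jac_cpp")]]
arma::mat hl_jac_cpp(arma::vec y, arma::vec par, arma::vec src) {
  check_inputs(y, par, src);
  return num_jac(y, par, src);
}

struct step_stats {
  long n_steps = 0, n_rejected = 0, n_rhs = 0, n_jac = 0;
};

// weighted rms/max error norm
static double err_norm(const arma::vec &err, const arma::vec &y0,
                       const arma::vec &y1, double rtol, double atol) {
  double m = 0.0;
  for (int i = 0; i < NSTATE; ++i) {
    double sc = atol + rtol * std::max(std::abs(y0[i]), std::abs(y1[i]));
    m = std::max(m, std::abs(err[i]) / sc);
  }
  return m;
}

// clip small integration undershoots below zero; hard error beyond neg_tol
static void enforce_nonneg(arma::vec &y, double neg_tol, double t) {
  for (int i = 0; i < NSTATE; ++i) {
    if (y[i] < 0) {
      if (y[i] < -neg_tol)
        stop("negative excursion beyond tolerance at t = %g: component %d = %g",
             t, i + 1, y[i]);
      y[i] = 0.0;
    }
  }
}

// Rosenbrock 2(3) (ode23s scheme) over [times.front(), times.back()] with a
// constant source vector; dense output at `times` by cubic Hermite
// interpolation over accepted steps.
// [[Rcpp::export(name = ".hl_ros23_cpp")]]
List hl_ros23_cpp(arma::vec y0, arma::vec times, arma::vec par, arma::vec src,
                  double rtol = 1e-8, double atol = 1e-12,
                  double hmax = 1e300, double neg_tol = 1e-9,
                  long max_steps = 5000000) {
  check_inputs(y0, par, src);
  if (times.n_elem < 2) stop("need at least two output times");
  for (arma::uword i = 1; i < times.n_elem; ++i)
    if (times[i] <= times[i - 1]) stop("output times must be strictly increasing");
  enforce_nonneg(y0, neg_tol, times[0]);

  const double d = 1.0 / (2.0 + std::sqrt(2.0));
  const double e32 = 6.0 + std::sqrt(2.0);
  const double t_end = times[times.n_elem - 1];

  arma::mat out(times.n_elem, NSTATE);
  out.row(0) = y0.t();
  arma::uword next_out = 1;

  step_stats st;
  arma::vec y = y0, f0(NSTATE), f1(NSTATE), f2(NSTATE);
  double t = times[0];
  rhs_core(y.memptr(), par.memptr(), src.memptr(), f0.memptr());
  st.n_rhs++;

  // initial step: conservative fraction of the span, limited by the RHS scale
  double span = t_end - t;
  double h = std::min(span / 100.0, hmax);
  {
    double fm = arma::abs(f0).max();
    if (fm > 0) h = std::min(h, 0.01 * (atol / rtol + arma::abs(y).max() + 1.0) / fm);
    h = std::max(h, span * 1e-12);
  }

  arma::mat I_n = arma::eye(NSTATE, NSTATE);

  while (t < t_end) {
    if (st.n_steps + st.n_rejected > max_steps)
      stop("ros23: step limit exceeded at t = %g (possible step underflow)", t);
    h = std::min(h, t_end - t);
    if (h <= std::abs(t) * 1e-14 && t + h == t)
      stop("ros23: step size underflow at t = %g", t);

    arma::mat Jm = num_jac(y, par, src);
    st.n_jac++; st.n_rhs += NSTATE + 1;

    bool accepted = false;
    arma::vec ynew(NSTATE);
    double enorm = 0.0;
    while (!accepted) {
      arma::mat Wm = I_n - (h * d) * Jm;
      arma::vec k1, k2, k3;
      bool ok = arma::solve(k1, Wm, f0, arma::solve_opts::fast);
      if (!ok) stop("ros23: singular stage matrix at t = %g", t);
      arma::vec ymid = y + 0.5 * h * k1;
      rhs_core(ymid.memptr(), par.memptr(), src.memptr(), f1.memptr());
      st.n_rhs++;
      arma::solve(k2, Wm, f1 - k1, arma::solve_opts::fast);
      k2 += k1;
      ynew = y + h * k2;
      rhs_core(ynew.memptr(), par.memptr(), src.memptr(), f2.memptr());
      st.n_rhs++;
      arma::solve(k3, Wm, f2 - e32 * (k2 - f1) - 2.0 * (k1 - f0), arma::solve_opts::fast);
      arma::vec err = (h / 6.0) * (k1 - 2.0 * k2 + k3);
      enorm = err_norm(err, y, ynew, rtol, atol);
      if (enorm <= 1.0 || h <= std::abs(t) * 4e-15) {
        accepted = true;
      } else {
        st.n_rejected++;
        h *= std::max(0.2, 0.9 * std::pow(enorm, -1.0 / 3.0));
        if (st.n_steps + st.n_rejected > max_steps)
          stop("ros23: step limit exceeded at t = %g", t);
      }
    }

    double tnew = t + h;
    enforce_nonneg(ynew, neg_tol, tnew);

    // dense output on (t, tnew]
    while (next_out < times.n_elem && times[next_out] <= tnew * (1 + 4e-16)) {
      double to = std::min(times[next_out], tnew);
      double s = (to - t) / h;
      double s2 = s * s, s3 = s2 * s;
      arma::vec yi = (2 * s3 - 3 * s2 + 1) * y + (s3 - 2 * s2 + s) * h * f0 +
                     (-2 * s3 + 3 * s2) * ynew + (s3 - s2) * h * f2;
      enforce_nonneg(yi, neg_tol, to);
      out.row(next_out) = yi.t();
      next_out++;
    }

    t = tnew;
    y = ynew;
    f0 = f2;
    st.n_steps++;
    double fac = 0.9 * std::pow(std::max(enorm, 1e-10), -1.0 / 3.0);
    h *= std::min(5.0, std::max(0.2, fac));
    h = std::min(h, hmax);
  }
  if (next_out < times.n_elem) out.row(times.n_elem - 1) = y.t();

  return List::create(_["y"] = out,
                      _["n_steps"] = (double)st.n_steps,
                      _["n_rejected"] = (double)st.n_rejected,
                      _["n_rhs"] = (double)st.n_rhs,
                      _["n_jac"] = (double)st.n_jac,
                      _["final_state"] = y);
}

// fixed-step classical RK4 on the compiled RHS; independent of the
// Rosenbrock route (no Jacobian, no adaptivity, no interpolation)
// [[Rcpp::export(name = ".hl_rk4_cpp")]]
arma::mat hl_rk4_cpp(arma::vec y0, arma::vec times, arma::vec par,
                     arma::vec src, double h) {
  check_inputs(y0, par, src);
  if (h <= 0) stop("rk4: step must be positive");
  arma::mat out(times.n_elem, NSTATE);
  out.row(0) = y0.t();
  arma::vec y = y0, k1(NSTATE), k2(NSTATE), k3(NSTATE), k4(NSTATE), tmp(NSTATE);
  double t = times[0];
  for (arma::uword i = 1; i < times.n_elem; ++i) {
    double target = times[i];
    while (t < target) {
      double hs = std::min(h, target - t);
      rhs_core(y.memptr(), par.memptr(), src.memptr(), k1.memptr());
      tmp = y + 0.5 * hs * k1;
      rhs_core(tmp.memptr(), par.memptr(), src.memptr(), k2.memptr());
      tmp = y + 0.5 * hs * k2;
      rhs_core(tmp.memptr(), par.memptr(), src.memptr(), k3.memptr());
      tmp = y + hs * k3;
      rhs_core(tmp.memptr(), par.memptr(), src.memptr(), k4.memptr());
      y += (hs / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      t += hs;
      for (int j = 0; j < NSTATE; ++j) if (y[j] < 0 && y[j] > -1e-9) y[j] = 0;
    }
    out.row(i) = y.t();
  }
  return out;
}
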