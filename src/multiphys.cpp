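// Element-level kernels for the coupled artery model:
// finite-strain kinematics with multiplicative volumetric growth,
// degraded neo-Hookean energy/stress, nutrient diffusion-reaction,
// Allen-Cahn inflammation/hematoma and damage phase fields, follower
// pressure loads, and global residual/tangent assembly.
//
// The element tangent is obtained by central-difference perturbation of
// the element residual; the local growth variable alpha is re-solved
// inside every residual evaluation, so the perturbation tangent carries
// the full local sensitivity d(alpha)/d(nodal dofs).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

namespace art {

struct MatPar {
  double mu, nu, k_g, R_c, D_max, D_min, R_s, M, eps, l, eta_d, d_min,
      G_f, c_th, K_c, K_phi, K_d, c_cut;
  int phi_source;  // 0 none, 1 hematoma R_s*c*d, 2 inflammation ramp
};

static MatPar unpack_params(const NumericVector& p) {
  if (p.size() == 0 || Rf_isNull(p.names()))
    stop("material parameter vector must be named");
  CharacterVector nm = p.names();
  std::map<std::string, double> m;
  for (int i = 0; i < p.size(); ++i) m[std::string(nm[i])] = p[i];
  auto get = [&](const char* k) -> double {
    std::map<std::string, double>::iterator it = m.find(k);
    if (it == m.end()) stop(std::string("missing material parameter '") + k + "'");
    return it->second;
  };
  MatPar mp;
  mp.mu = get("mu");       mp.nu = get("nu");       mp.k_g = get("k_g");
  mp.R_c = get("R_c");     mp.D_max = get("D_max"); mp.D_min = get("D_min");
  mp.R_s = get("R_s");     mp.M = get("M");         mp.eps = get("eps");
  mp.l = get("l");         mp.eta_d = get("eta_d"); mp.d_min = get("d_min");
  mp.G_f = get("G_f");     mp.c_th = get("c_th");   mp.K_c = get("K_c");
  mp.K_phi = get("K_phi"); mp.K_d = get("K_d");
  mp.c_cut = m.count("c_cut") ? m["c_cut"] : 0.05;
  mp.phi_source = m.count("phi_source") ? (int)m["phi_source"] : 0;
  return mp;
}

static inline double clamp01(double x) { return x < 0 ? 0 : (x > 1 ? 1 : x); }

// smooth cutoff on the constant consumption sink: 0 for c<=0, 1 for c>=w
static inline double sink_cut(double c, double w) {
  if (c <= 0) return 0.0;
  if (c >= w) return 1.0;
  double t = c / w;
  return t * t * (3.0 - 2.0 * t);
}

// derivative of the double-well barrier f = 16 M phi^2 (1-phi)^2
static inline double barrier_dfdphi(double phi, double M) {
  return 32.0 * M * phi * (1.0 - phi) * (1.0 - 2.0 * phi);
}

struct SE {
  double psi_iso, psi_vol, psi_deg, psi_drive, g_d;
  int H_J;
  mat sigma;  // Cauchy, 3x3
};

// Degraded neo-Hookean energy and Cauchy stress.
//   psi_iso  = mu/2 (I1_iso - 3)
//   psi_vol  = nu*mu/(1-2nu) (Je-1)^2 + mu (Je - 1 - log Je)
//   psi_deg  = g(d) psi_iso + [(1-H_J) g(d) + H_J] psi_vol
//   psi_drive = psi_iso + (1-H_J) psi_vol     (undegraded tensile part)
//   sigma    = (1/Je) dpsi_deg/dFe Fe^T       (analytic derivative)
// The mu(Je-1) term makes the unloaded reference state stress-free when
// the isochoric invariant is used for psi_iso; the logarithmic barrier
// keeps the compressive branch singular as Je -> 0.
static SE energy_stress(const mat& Fe, double d, double mu, double nu,
                        double d_min) {
  double Je = arma::det(Fe);
  if (!(Je > 0.0))
    throw std::runtime_error("degenerate elastic deformation (det F_e <= 0)");
  double trC = arma::accu(Fe % Fe);  // tr(Fe^T Fe)
  double Jm23 = std::pow(Je, -2.0 / 3.0);
  double I1iso = Jm23 * trC;
  double psi_iso = 0.5 * mu * (I1iso - 3.0);
  double kap = nu * mu / (1.0 - 2.0 * nu);
  double psi_vol =
      kap * (Je - 1.0) * (Je - 1.0) + mu * (Je - 1.0 - std::log(Je));
  int HJ = (Je <= 1.0) ? 1 : 0;
  double dc = clamp01(d);
  double gd = (1.0 - dc) * (1.0 - dc) + dc * d_min;
  double wvol = (1 - HJ) * gd + HJ;  // volumetric degradation weight
  SE out;
  out.psi_iso = psi_iso;
  out.psi_vol = psi_vol;
  out.psi_deg = gd * psi_iso + wvol * psi_vol;
  out.psi_drive = psi_iso + (1 - HJ) * psi_vol;
  out.g_d = gd;
  out.H_J = HJ;
  mat FeinvT = arma::inv(Fe).t();
  mat dIso = mu * Jm23 * (Fe - (trC / 3.0) * FeinvT);
  double dVdJ = 2.0 * kap * (Je - 1.0) + mu * (1.0 - 1.0 / Je);
  mat P = gd * dIso + wvol * (dVdJ * Je) * FeinvT;
  mat sig = (P * Fe.t()) / Je;
  out.sigma = 0.5 * (sig + sig.t());
  return out;
}

// isoparametric bases -------------------------------------------------------

static const double GP = 0.57735026918962576451;  // 1/sqrt(3)

static void shape_quad4(const double* xi, vec& N, mat& dN) {
  static const double sg[4][2] = {{-1, -1}, {1, -1}, {1, 1}, {-1, 1}};
  for (int i = 0; i < 4; ++i) {
    double a = sg[i][0], b = sg[i][1];
    N(i) = 0.25 * (1 + a * xi[0]) * (1 + b * xi[1]);
    dN(i, 0) = 0.25 * a * (1 + b * xi[1]);
    dN(i, 1) = 0.25 * b * (1 + a * xi[0]);
  }
}

static void shape_hex8(const double* xi, vec& N, mat& dN) {
  static const double sg[8][3] = {{-1, -1, -1}, {1, -1, -1}, {1, 1, -1},
                                  {-1, 1, -1},  {-1, -1, 1}, {1, -1, 1},
                                  {1, 1, 1},    {-1, 1, 1}};
  for (int i = 0; i < 8; ++i) {
    double a = sg[i][0], b = sg[i][1], c = sg[i][2];
    N(i) = 0.125 * (1 + a * xi[0]) * (1 + b * xi[1]) * (1 + c * xi[2]);
    dN(i, 0) = 0.125 * a * (1 + b * xi[1]) * (1 + c * xi[2]);
    dN(i, 1) = 0.125 * b * (1 + a * xi[0]) * (1 + c * xi[2]);
    dN(i, 2) = 0.125 * c * (1 + a * xi[0]) * (1 + b * xi[1]);
  }
}

static void gauss_point(int dim, int q, double* xi) {
  if (dim == 2) {
    static const double pts[4][2] = {{-GP, -GP}, {GP, -GP}, {GP, GP}, {-GP, GP}};
    xi[0] = pts[q][0]; xi[1] = pts[q][1]; xi[2] = 0.0;
  } else {
    static const double pts[8][3] = {{-GP, -GP, -GP}, {GP, -GP, -GP},
                                     {GP, GP, -GP},   {-GP, GP, -GP},
                                     {-GP, -GP, GP},  {GP, -GP, GP},
                                     {GP, GP, GP},    {-GP, GP, GP}};
    xi[0] = pts[q][0]; xi[1] = pts[q][1]; xi[2] = pts[q][2];
  }
}

// element kernel ------------------------------------------------------------

struct ElemWork {
  int dim, nn, ndofn, ngp;
  mat X;                    // dim x nn reference coordinates
  vec dofs;                 // nn*ndofn, node-major (u..., c, phi, d)
  vec phi_prev, d_prev;     // nn, previous time step nodal values
  vec alpha_n, psimax_n;    // ngp, committed Gauss state
  MatPar mp;
  double dt;
};

static void elem_residual(const ElemWork& w, vec& R, vec* alpha_out,
                          vec* psimax_out, mat* sig_out, vec* vol_out,
                          mat* xgp_out) {
  const int dim = w.dim, nn = w.nn, ndofn = w.ndofn, ngp = w.ngp;
  R.zeros(nn * ndofn);
  mat u(dim, nn);
  vec cn(nn), pn(nn), dn(nn);
  for (int I = 0; I < nn; ++I) {
    for (int k = 0; k < dim; ++k) u(k, I) = w.dofs(I * ndofn + k);
    cn(I) = w.dofs(I * ndofn + dim);
    pn(I) = w.dofs(I * ndofn + dim + 1);
    dn(I) = w.dofs(I * ndofn + dim + 2);
  }
  vec N(nn);
  mat dNdxi(nn, dim);
  double xi[3];
  for (int q = 0; q < ngp; ++q) {
    gauss_point(dim, q, xi);
    if (dim == 2) shape_quad4(xi, N, dNdxi); else shape_hex8(xi, N, dNdxi);
    mat Jref = w.X * dNdxi;  // dim x dim
    double detJ0 = arma::det(Jref);
    if (!(detJ0 > 0.0))
      throw std::runtime_error("non-positive reference Jacobian");
    mat dNdX = dNdxi * arma::inv(Jref);  // nn x dim, material gradients
    mat H = u * dNdX;                    // displacement gradient dU/dX
    mat F3 = arma::eye(3, 3);
    F3.submat(0, 0, dim - 1, dim - 1) += H;
    double J = arma::det(F3);
    if (!(J > 0.0))
      throw std::runtime_error("degenerate deformation (det F <= 0)");
    double phi_gp = arma::dot(N, pn);
    double phiprev_gp = arma::dot(N, w.phi_prev);
    double c_gp = arma::dot(N, cn);
    double d_gp = arma::dot(N, dn);
    double dprev_gp = arma::dot(N, w.d_prev);

    // local growth update (closed form of the scalar residual)
    double k = w.mp.k_g * (phi_gp - phiprev_gp);
    if (k >= 1.0)
      throw std::runtime_error("growth increment k_g*dphi >= 1; cut time step");
    double alpha = (w.alpha_n(q) + k) / (1.0 - k);
    if (alpha <= -1.0)
      throw std::runtime_error("growth scalar alpha <= -1");

    mat Fe = F3 / (1.0 + alpha);
    SE se = energy_stress(Fe, d_gp, w.mp.mu, w.mp.nu, w.mp.d_min);
    double psimax = std::max(se.psi_drive, w.psimax_n(q));

    mat Finv = arma::inv(F3);
    mat dNdx = dNdX * Finv.submat(0, 0, dim - 1, dim - 1);  // spatial grads
    vec gc = dNdx.t() * cn;
    vec gphi = dNdx.t() * pn;
    vec gdm = dNdX.t() * dn;  // damage gradient in reference configuration
    double dv = detJ0 * J;    // gauss weight 1; dv = J dV

    double cc = clamp01(c_gp), dcl = clamp01(d_gp), pcl = clamp01(phi_gp);
    double Deff = pcl * w.mp.D_min + (1.0 - pcl) * w.mp.D_max;
    double Sphi = 0.0;
    if (w.mp.phi_source == 1) Sphi = w.mp.R_s * cc * dcl;
    else if (w.mp.phi_source == 2)
      Sphi = w.mp.R_s * std::max(w.mp.c_th - cc, 0.0) / w.mp.c_th;
    double Sd = (2.0 * (1.0 - dcl) - w.mp.d_min) * psimax / w.mp.G_f;
    double dfdp = barrier_dfdphi(phi_gp, w.mp.M);
    double sink = w.mp.R_c * sink_cut(c_gp, w.mp.c_cut);
    double phidot = (w.dt == R_PosInf) ? 0.0 : (phi_gp - phiprev_gp) / w.dt;
    double ddot = (w.dt == R_PosInf) ? 0.0 : (d_gp - dprev_gp) / w.dt;

    for (int I = 0; I < nn; ++I) {
      for (int j = 0; j < dim; ++j) {
        double rj = 0.0;
        for (int kk = 0; kk < dim; ++kk) rj += se.sigma(j, kk) * dNdx(I, kk);
        R(I * ndofn + j) += rj * dv;
      }
      double rc = Deff * arma::dot(gc, dNdx.row(I).t()) + sink * N(I);
      R(I * ndofn + dim) += w.mp.K_c * rc * dv;
      double rp = w.mp.eps * w.mp.eps * arma::dot(gphi, dNdx.row(I).t()) +
                  w.mp.M * dfdp * N(I) + phidot * N(I) - Sphi * N(I);
      R(I * ndofn + dim + 1) += w.mp.K_phi * rp * dv;
      double rd = d_gp * N(I) + w.mp.l * w.mp.l * arma::dot(gdm, dNdX.row(I).t()) +
                  w.mp.eta_d * ddot * N(I) - Sd * N(I);
      R(I * ndofn + dim + 2) += w.mp.K_d * rd * dv;
    }
    if (alpha_out) (*alpha_out)(q) = alpha;
    if (psimax_out) (*psimax_out)(q) = psimax;
    if (sig_out) {
      (*sig_out)(0, q) = se.sigma(0, 0);
      (*sig_out)(1, q) = se.sigma(1, 1);
      (*sig_out)(2, q) = se.sigma(2, 2);
      (*sig_out)(3, q) = se.sigma(0, 1);
      (*sig_out)(4, q) = se.sigma(1, 2);
      (*sig_out)(5, q) = se.sigma(0, 2);
    }
    if (vol_out) (*vol_out)(q) = dv;
    if (xgp_out) xgp_out->col(q) = w.X * N;
  }
}

static void elem_tangent(const ElemWork& w, mat& K, double fd_eps) {
  const int nd = w.nn * w.ndofn;
  K.set_size(nd, nd);
  vec Rp(nd), Rm(nd);
  ElemWork wp = w;
  for (int j = 0; j < nd; ++j) {
    double h = fd_eps * std::max(1.0, std::abs(w.dofs(j)));
    wp.dofs = w.dofs;
    wp.dofs(j) = w.dofs(j) + h;
    elem_residual(wp, Rp, 0, 0, 0, 0, 0);
    wp.dofs(j) = w.dofs(j) - h;
    elem_residual(wp, Rm, 0, 0, 0, 0, 0);
    K.col(j) = (Rp - Rm) / (2.0 * h);
  }
}

// follower pressure ---------------------------------------------------------
// Facet node ordering follows the lumen traversal (counter-clockwise in 2D;
// in 3D extruded as (n1, n2, n2+top, n1+top)), for which the in-surface
// tangent cross product points radially outward into the solid; the external
// nodal force is then f_I = p * int N_I (x_xi x x_eta) and the residual is
// reduced by f_I.

static void facet_residual_2d(const mat& X, const vec& uf, double p, vec& R) {
  double x1 = X(0, 0) + uf(0), y1 = X(1, 0) + uf(1);
  double x2 = X(0, 1) + uf(2), y2 = X(1, 1) + uf(3);
  double ex = x2 - x1, ey = y2 - y1;
  if (ex == 0.0 && ey == 0.0)
    throw std::runtime_error("zero-length pressure facet");
  R.set_size(4);
  R(0) = -p * 0.5 * ey;
  R(1) = p * 0.5 * ex;
  R(2) = -p * 0.5 * ey;
  R(3) = p * 0.5 * ex;
}

static void facet_residual_3d(const mat& X, const vec& uf, double p, vec& R) {
  mat x(3, 4);
  for (int I = 0; I < 4; ++I)
    for (int k = 0; k < 3; ++k) x(k, I) = X(k, I) + uf(3 * I + k);
  R.zeros(12);
  static const double sg[4][2] = {{-1, -1}, {1, -1}, {1, 1}, {-1, 1}};
  static const double pts[4][2] = {{-GP, -GP}, {GP, -GP}, {GP, GP}, {-GP, GP}};
  for (int q = 0; q < 4; ++q) {
    double xi = pts[q][0], eta = pts[q][1];
    vec N(4), dxi(4), deta(4);
    for (int i = 0; i < 4; ++i) {
      N(i) = 0.25 * (1 + sg[i][0] * xi) * (1 + sg[i][1] * eta);
      dxi(i) = 0.25 * sg[i][0] * (1 + sg[i][1] * eta);
      deta(i) = 0.25 * sg[i][1] * (1 + sg[i][0] * xi);
    }
    vec txi = x * dxi, teta = x * deta;
    vec nvec = arma::cross(txi, teta);
    if (arma::norm(nvec) == 0.0)
      throw std::runtime_error("degenerate pressure facet");
    for (int I = 0; I < 4; ++I)
      for (int k = 0; k < 3; ++k) R(3 * I + k) -= p * N(I) * nvec(k);
  }
}

static void facet_residual(int dim, const mat& X, const vec& uf, double p,
                           vec& R) {
  if (dim == 2) facet_residual_2d(X, uf, p, R);
  else facet_residual_3d(X, uf, p, R);
}

static void facet_tangent(int dim, const mat& X, const vec& uf, double p,
                          mat& K, double fd_eps) {
  int nd = (dim == 2) ? 4 : 12;
  K.set_size(nd, nd);
  vec Rp(nd), Rm(nd), u2 = uf;
  for (int j = 0; j < nd; ++j) {
    double h = fd_eps * std::max(1.0, std::abs(uf(j)));
    u2 = uf; u2(j) = uf(j) + h;
    facet_residual(dim, X, u2, p, Rp);
    u2(j) = uf(j) - h;
    facet_residual(dim, X, u2, p, Rm);
    K.col(j) = (Rp - Rm) / (2.0 * h);
  }
}

}  // namespace art

// exported constitutive point functions -------------------------------------

// [[Rcpp::export]]
List cpp_kinematics(NumericMatrix grad_u, double alpha) {
  mat gu(grad_u.begin(), 3, 3);
  mat A = arma::eye(3, 3) - gu;
  double dA = arma::det(A);
  if (!(dA > 0.0)) stop("degenerate deformation: det(I - grad_u) <= 0");
  mat F = arma::inv(A);
  mat Fg = (1.0 + alpha) * arma::eye(3, 3);
  mat Fe = F / (1.0 + alpha);
  double Je = arma::det(Fe);
  if (!(Je > 0.0)) stop("degenerate elastic deformation (det F_e <= 0)");
  mat Ce_iso = std::pow(Je, -2.0 / 3.0) * (Fe.t() * Fe);
  return List::create(_["F"] = wrap(F), _["F_g"] = wrap(Fg), _["F_e"] = wrap(Fe),
                      _["J_e"] = Je, _["C_e_iso"] = wrap(Ce_iso),
                      _["I1_iso"] = arma::trace(Ce_iso), _["alpha"] = alpha);
}

// [[Rcpp::export]]
List cpp_update_alpha(double alpha_n, double dphi, double k_g) {
  double k = k_g * dphi;
  if (k >= 1.0) stop("growth increment k_g*dphi >= 1; reduce the time step");
  double a = (alpha_n + k) / (1.0 - k);
  double dadphi = k_g * (1.0 + alpha_n) / ((1.0 - k) * (1.0 - k));
  return List::create(_["alpha"] = a, _["dalpha_dphi"] = dadphi);
}

// [[Rcpp::export]]
List cpp_energy_stress(NumericMatrix Fe_, double d, double mu, double nu,
                       double d_min) {
  mat Fe(Fe_.begin(), 3, 3);
  art::SE se = art::energy_stress(Fe, d, mu, nu, d_min);
  return List::create(
      _["psi_iso"] = se.psi_iso, _["psi_vol"] = se.psi_vol,
      _["psi_deg"] = se.psi_deg, _["psi_drive"] = se.psi_drive,
      _["g_d"] = se.g_d, _["H_J"] = se.H_J, _["sigma"] = wrap(se.sigma),
      _["J_e"] = arma::det(Fe));
}

// [[Rcpp::export]]
List cpp_shape_quadrature(std::string element_type) {
  int dim, nn;
  if (element_type == "quad4") { dim = 2; nn = 4; }
  else if (element_type == "hex8") { dim = 3; nn = 8; }
  else stop("unknown element type '" + element_type + "'");
  int ngp = (dim == 2) ? 4 : 8;
  NumericMatrix pts(ngp, dim), Nmat(ngp, nn);
  NumericVector wts(ngp);
  List dNlist(ngp);
  vec N(nn);
  mat dN(nn, dim);
  double xi[3];
  for (int q = 0; q < ngp; ++q) {
    art::gauss_point(dim, q, xi);
    for (int k = 0; k < dim; ++k) pts(q, k) = xi[k];
    wts[q] = 1.0;
    if (dim == 2) art::shape_quad4(xi, N, dN); else art::shape_hex8(xi, N, dN);
    for (int i = 0; i < nn; ++i) Nmat(q, i) = N(i);
    dNlist[q] = wrap(dN);
  }
  return List::create(_["points"] = pts, _["weights"] = wts, _["N"] = Nmat,
                      _["dN"] = dNlist);
}

static art::ElemWork make_work(NumericMatrix X_, NumericVector dofs_,
                               NumericVector phi_prev_, NumericVector d_prev_,
                               NumericVector alpha_n_, NumericVector psimax_n_,
                               NumericVector params_, double dt) {
  art::ElemWork w;
  w.dim = X_.nrow();
  w.nn = X_.ncol();
  if (!((w.dim == 2 && w.nn == 4) || (w.dim == 3 && w.nn == 8)))
    stop("element coordinates must be 2x4 (quad4) or 3x8 (hex8)");
  w.ndofn = w.dim + 3;
  w.ngp = (w.dim == 2) ? 4 : 8;
  if (dofs_.size() != w.nn * w.ndofn) stop("dof vector has wrong length");
  if (alpha_n_.size() != w.ngp || psimax_n_.size() != w.ngp)
    stop("gauss state has wrong length");
  w.X = mat(X_.begin(), w.dim, w.nn);
  w.dofs = vec(dofs_.begin(), dofs_.size());
  w.phi_prev = vec(phi_prev_.begin(), w.nn);
  w.d_prev = vec(d_prev_.begin(), w.nn);
  w.alpha_n = vec(alpha_n_.begin(), w.ngp);
  w.psimax_n = vec(psimax_n_.begin(), w.ngp);
  w.mp = art::unpack_params(params_);
  w.dt = dt;
  return w;
}

// [[Rcpp::export]]
List cpp_element_residual(NumericMatrix X, NumericVector dofs,
                          NumericVector phi_prev, NumericVector d_prev,
                          NumericVector alpha_n, NumericVector psimax_n,
                          NumericVector params, double dt) {
  art::ElemWork w = make_work(X, dofs, phi_prev, d_prev, alpha_n, psimax_n,
                              params, dt);
  vec R, al(w.ngp), pm(w.ngp), vol(w.ngp);
  mat sig(6, w.ngp), xg(w.dim, w.ngp);
  art::elem_residual(w, R, &al, &pm, &sig, &vol, &xg);
  return List::create(_["residual"] = wrap(R), _["alpha"] = wrap(al),
                      _["psi_max"] = wrap(pm), _["sigma_gp"] = wrap(sig),
                      _["vol_gp"] = wrap(vol), _["x_gp"] = wrap(xg));
}

// [[Rcpp::export]]
NumericMatrix cpp_element_tangent(NumericMatrix X, NumericVector dofs,
                                  NumericVector phi_prev, NumericVector d_prev,
                                  NumericVector alpha_n, NumericVector psimax_n,
                                  NumericVector params, double dt,
                                  double fd_eps = 3e-6) {
  art::ElemWork w = make_work(X, dofs, phi_prev, d_prev, alpha_n, psimax_n,
                              params, dt);
  mat K;
  art::elem_tangent(w, K, fd_eps);
  return wrap(K);
}

// [[Rcpp::export]]
NumericVector cpp_facet_pressure(NumericMatrix X, NumericVector u, double p) {
  int dim = X.nrow();
  int nfn = X.ncol();
  if (!((dim == 2 && nfn == 2) || (dim == 3 && nfn == 4)))
    stop("facet coordinates must be 2x2 (edge) or 3x4 (quad)");
  mat Xm(X.begin(), dim, nfn);
  vec uf(u.begin(), u.size());
  if ((int)uf.size() != dim * nfn) stop("facet displacement has wrong length");
  vec R;
  art::facet_residual(dim, Xm, uf, p, R);
  return wrap(R);
}

// global assembly ------------------------------------------------------------

// [[Rcpp::export]]
List cpp_assemble(NumericMatrix nodes, IntegerMatrix elems, NumericVector D,
                  NumericVector phi_prev, NumericVector d_prev,
                  NumericMatrix alpha_n, NumericMatrix psimax_n,
                  NumericVector params, double dt, double pressure,
                  Nullable<IntegerMatrix> lumen_facets = R_NilValue,
                  bool want_tangent = true, bool want_stress = false,
                  double fd_eps = 3e-6) {
  const int nnode = nodes.nrow();
  const int dim = nodes.ncol();
  if (dim != 2 && dim != 3) stop("nodes must have 2 or 3 columns");
  const int nn = elems.ncol();
  const int nelem = elems.nrow();
  const int ndofn = dim + 3;
  const int ngp = (dim == 2) ? 4 : 8;
  const int nde = nn * ndofn;
  if ((int)D.size() != nnode * ndofn) stop("global dof vector has wrong length");
  if (alpha_n.nrow() != ngp || alpha_n.ncol() != nelem)
    stop("alpha state must be ngp x nelem");
  if (psimax_n.nrow() != ngp || psimax_n.ncol() != nelem)
    stop("psi_max state must be ngp x nelem");

  art::MatPar mp = art::unpack_params(params);
  NumericVector Rglob(nnode * ndofn);
  NumericMatrix alpha_new(ngp, nelem), psimax_new(ngp, nelem);
  NumericMatrix sig_all, xgp_all;
  NumericVector vol_all;
  if (want_stress) {
    sig_all = NumericMatrix(6, ngp * nelem);
    xgp_all = NumericMatrix(dim, ngp * nelem);
    vol_all = NumericVector(ngp * nelem);
  }
  std::vector<int> Ti, Tj;
  std::vector<double> Tx;
  if (want_tangent) {
    Ti.reserve((size_t)nelem * nde * nde);
    Tj.reserve((size_t)nelem * nde * nde);
    Tx.reserve((size_t)nelem * nde * nde);
  }

  art::ElemWork w;
  w.dim = dim; w.nn = nn; w.ndofn = ndofn; w.ngp = ngp;
  w.mp = mp; w.dt = dt;
  w.X.set_size(dim, nn);
  w.dofs.set_size(nde);
  w.phi_prev.set_size(nn);
  w.d_prev.set_size(nn);
  w.alpha_n.set_size(ngp);
  w.psimax_n.set_size(ngp);
  vec Re;
  mat Ke;
  std::vector<int> gdof(nde);

  for (int e = 0; e < nelem; ++e) {
    for (int I = 0; I < nn; ++I) {
      int nd = elems(e, I) - 1;
      if (nd < 0 || nd >= nnode) stop("element connectivity out of range");
      for (int k = 0; k < dim; ++k) w.X(k, I) = nodes(nd, k);
      for (int k = 0; k < ndofn; ++k) {
        w.dofs(I * ndofn + k) = D[nd * ndofn + k];
        gdof[I * ndofn + k] = nd * ndofn + k;
      }
      w.phi_prev(I) = phi_prev[nd];
      w.d_prev(I) = d_prev[nd];
    }
    for (int q = 0; q < ngp; ++q) {
      w.alpha_n(q) = alpha_n(q, e);
      w.psimax_n(q) = psimax_n(q, e);
    }
    vec al(ngp), pm(ngp), vol(ngp);
    mat sig(6, ngp), xg(dim, ngp);
    try {
      art::elem_residual(w, Re, &al, &pm, want_stress ? &sig : 0,
                         want_stress ? &vol : 0, want_stress ? &xg : 0);
      if (want_tangent) art::elem_tangent(w, Ke, fd_eps);
    } catch (std::exception& ex) {
      stop("element " + std::to_string(e + 1) + ": " + ex.what());
    }
    for (int a = 0; a < nde; ++a) Rglob[gdof[a]] += Re(a);
    if (want_tangent)
      for (int b = 0; b < nde; ++b)
        for (int a = 0; a < nde; ++a) {
          Ti.push_back(gdof[a] + 1);
          Tj.push_back(gdof[b] + 1);
          Tx.push_back(Ke(a, b));
        }
    for (int q = 0; q < ngp; ++q) {
      alpha_new(q, e) = al(q);
      psimax_new(q, e) = pm(q);
    }
    if (want_stress)
      for (int q = 0; q < ngp; ++q) {
        for (int k = 0; k < 6; ++k) sig_all(k, e * ngp + q) = sig(k, q);
        for (int k = 0; k < dim; ++k) xgp_all(k, e * ngp + q) = xg(k, q);
        vol_all[e * ngp + q] = vol(q);
      }
  }

  // follower pressure on lumen facets (current configuration)
  if (lumen_facets.isNotNull() && pressure != 0.0) {
    IntegerMatrix fac(lumen_facets);
    int nfn = fac.ncol();
    if ((dim == 2 && nfn != 2) || (dim == 3 && nfn != 4))
      stop("lumen facets must have 2 nodes in 2D, 4 in 3D");
    int nfd = dim * nfn;
    mat Xf(dim, nfn);
    vec uf(nfd), Rf;
    mat Kf;
    std::vector<int> fdof(nfd);
    for (int f = 0; f < fac.nrow(); ++f) {
      for (int I = 0; I < nfn; ++I) {
        int nd = fac(f, I) - 1;
        if (nd < 0 || nd >= nnode) stop("facet node out of range");
        for (int k = 0; k < dim; ++k) {
          Xf(k, I) = nodes(nd, k);
          uf(I * dim + k) = D[nd * ndofn + k];
          fdof[I * dim + k] = nd * ndofn + k;
        }
      }
      try {
        art::facet_residual(dim, Xf, uf, pressure, Rf);
        if (want_tangent) art::facet_tangent(dim, Xf, uf, pressure, Kf, fd_eps);
      } catch (std::exception& ex) {
        stop("lumen facet " + std::to_string(f + 1) + ": " + ex.what());
      }
      for (int a = 0; a < nfd; ++a) Rglob[fdof[a]] += Rf(a);
      if (want_tangent)
        for (int b = 0; b < nfd; ++b)
          for (int a = 0; a < nfd; ++a) {
            Ti.push_back(fdof[a] + 1);
            Tj.push_back(fdof[b] + 1);
            Tx.push_back(Kf(a, b));
          }
    }
  }

  List out = List::create(_["R"] = Rglob, _["alpha"] = alpha_new,
                          _["psi_max"] = psimax_new);
  if (want_tangent) {
    out["Ki"] = IntegerVector(Ti.begin(), Ti.end());
    out["Kj"] = IntegerVector(Tj.begin(), Tj.end());
    out["Kx"] = NumericVector(Tx.begin(), Tx.end());
  }
  if (want_stress) {
    out["sigma_gp"] = sig_all;
    out["x_gp"] = xgp_all;
    out["vol_gp"] = vol_all;
  }
  return out;
}
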