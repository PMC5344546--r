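// Finite-element kernel: hyperelastic point evaluation, F-bar hexahedral
// elements, global assembly (internal force + finite-difference stiffness)
// and an explicit dynamic-relaxation integrator.
//
// Units: mm, N, MPa. Material types: 0 = anisotropic hyperelastic
// (Holzapfel-Gasser-Ogden with dispersion; params c10, D, k1, k2, kappa),
// 1 = Neo-Hookean (c10, D), 2 = Saint Venant-Kirchhoff (lambda, mu).
// Swelling enters as an isotropic eigenstretch: F_e = F / s, energy per
// reference volume s^3 * psi(F_e), first Piola P_R = s^2 * P_e.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

static const double GP = 0.5773502691896258; // 1/sqrt(3)

// exp with linear continuation above 60: overflow guard far outside the
// physical range (converged states have arguments of order 1).
static inline double exp_guard(double x) {
  if (x <= 60.0) return std::exp(x);
  return std::exp(60.0) * (1.0 + (x - 60.0));
}
static inline double dexp_guard(double x) {
  if (x <= 60.0) return std::exp(x);
  return std::exp(60.0);
}

static inline double det3(const double* F) {
  return F[0]*(F[4]*F[8]-F[5]*F[7])
       - F[1]*(F[3]*F[8]-F[5]*F[6])
       + F[2]*(F[3]*F[7]-F[4]*F[6]);
}

static inline void invT3(const double* F, double J, double* FinvT) {
  // transpose of inverse
  double iJ = 1.0 / J;
  FinvT[0] = (F[4]*F[8]-F[5]*F[7])*iJ;
  FinvT[3] = -(F[1]*F[8]-F[2]*F[7])*iJ;
  FinvT[6] = (F[1]*F[5]-F[2]*F[4])*iJ;
  FinvT[1] = -(F[3]*F[8]-F[5]*F[6])*iJ;
  FinvT[4] = (F[0]*F[8]-F[2]*F[6])*iJ;
  FinvT[7] = -(F[0]*F[5]-F[2]*F[3])*iJ;
  FinvT[2] = (F[3]*F[7]-F[4]*F[6])*iJ;
  FinvT[5] = -(F[0]*F[7]-F[1]*F[6])*iJ;
  FinvT[8] = (F[0]*F[4]-F[1]*F[3])*iJ;
}

struct PointOut {
  double psi;      // energy per unit reference volume (incl. swelling factor)
  double P[9];     // first Piola-Kirchhoff w.r.t. reference (incl. swelling)
  double sig[9];   // true Cauchy stress
  double modest;   // stiffness-modulus estimate for explicit stability
  bool ok;
};

// F: total deformation gradient (row-major 3x3), swell: eigenstretch.
static void point_eval(const double* F, int type, const double* pr,
                       const double* a1, const double* a2, double swell,
                       PointOut& out, bool want_stress) {
  double Fe[9];
  double isw = 1.0 / swell;
  for (int i = 0; i < 9; i++) Fe[i] = F[i] * isw;
  double Je = det3(Fe);
  if (!(Je > 0.0) || !std::isfinite(Je)) { out.ok = false; return; }
  out.ok = true;
  double s3 = swell * swell * swell, s2 = swell * swell;

  double tau[9];   // Kirchhoff stress of the elastic part
  double psi = 0.0, modest = 0.0;

  if (type == 2) {
    // "linear elastic" layers: compressible Neo-Hookean with Lame constants
    // psi = mu/2 (I1 - 3) - mu ln J + lam/2 (ln J)^2
    // (exactly Hooke in the small-strain limit; monotone -lnJ resistance in
    // compression, unlike Saint Venant-Kirchhoff which collapses there)
    double lam = pr[0], mu = pr[1];
    double b[9];
    for (int i = 0; i < 3; i++)
      for (int j = 0; j < 3; j++) {
        double s = 0;
        for (int k = 0; k < 3; k++) s += Fe[3*i+k]*Fe[3*j+k];
        b[3*i+j] = s;
      }
    double lnJ = std::log(Je);
    double I1 = b[0]+b[4]+b[8];
    psi = 0.5*mu*(I1 - 3.0) - mu*lnJ + 0.5*lam*lnJ*lnJ;
    for (int i = 0; i < 9; i++) tau[i] = mu*b[i];
    tau[0] += lam*lnJ - mu; tau[4] += lam*lnJ - mu; tau[8] += lam*lnJ - mu;
    modest = lam + 2.0*mu + 2.0*std::fabs(lam*lnJ)/Je;
  } else { // decoupled isochoric/volumetric hyperelastic
    double c10 = pr[0], D = pr[1];
    double Jm23 = std::pow(Je, -2.0/3.0);
    double bbar[9];
    for (int i = 0; i < 3; i++)
      for (int j = 0; j < 3; j++) {
        double s = 0;
        for (int k = 0; k < 3; k++) s += Fe[3*i+k]*Fe[3*j+k];
        bbar[3*i+j] = Jm23 * s;
      }
    double I1b = bbar[0]+bbar[4]+bbar[8];
    double psi1 = c10;
    psi = c10 * (I1b - 3.0);
    modest = 2.0*c10 + 2.0/D;

    double taubar[9];
    for (int i = 0; i < 9; i++) taubar[i] = 2.0*c10*bbar[i];

    if (type == 0) { // add dispersed fiber families
      double k1 = pr[2], k2 = pr[3], kap = pr[4];
      const double* as[2] = { a1, a2 };
      double Jm13 = std::sqrt(Jm23);
      for (int f = 0; f < 2; f++) {
        const double* a = as[f];
        double h[3];
        for (int i = 0; i < 3; i++)
          h[i] = Jm13 * (Fe[3*i]*a[0] + Fe[3*i+1]*a[1] + Fe[3*i+2]*a[2]);
        double I4b = h[0]*h[0]+h[1]*h[1]+h[2]*h[2];
        double Eb = kap*(I1b-3.0) + (1.0-3.0*kap)*(I4b-1.0);
        if (Eb > 0.0) {
          double arg = k2*Eb*Eb;
          double ex = exp_guard(arg);
          psi += 0.5*(k1/k2)*(ex - 1.0);
          double fE = k1 * Eb * dexp_guard(arg); // d psi_f / d Ebar
          // d psi / d I1b and d psi / d I4b contributions
          double p1 = fE * kap;
          double p4 = fE * (1.0-3.0*kap);
          for (int i = 0; i < 9; i++) taubar[i] += 2.0*p1*bbar[i];
          for (int i = 0; i < 3; i++)
            for (int j = 0; j < 3; j++)
              taubar[3*i+j] += 2.0*p4*h[i]*h[j];
          double g = k1 * (1.0 + 2.0*k2*Eb*Eb) * dexp_guard(arg);
          modest += 4.0 * g * I4b;
        } else {
          modest += k1;
        }
      }
      psi1 = psi1; // psi1 folded into taubar above
    }

    double trt = (taubar[0]+taubar[4]+taubar[8]) / 3.0;
    double p = (Je - 1.0/Je) / D;
    psi += ((Je*Je - 1.0)/2.0 - std::log(Je)) / D;
    for (int i = 0; i < 9; i++) tau[i] = taubar[i];
    tau[0] += Je*p - trt; tau[4] += Je*p - trt; tau[8] += Je*p - trt;
  }

  out.psi = s3 * psi;
  out.modest = modest;
  double FeinvT[9];
  invT3(Fe, Je, FeinvT);
  // P_e = tau * Fe^{-T}; P_R = s^2 * P_e
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) {
      double s = 0;
      for (int k = 0; k < 3; k++) s += tau[3*i+k]*FeinvT[3*k+j];
      out.P[3*i+j] = s2 * s;
    }
  if (want_stress) {
    double iJe = 1.0/Je;
    for (int i = 0; i < 9; i++) out.sig[i] = tau[i]*iJe;
  }
}

// ---------------------------------------------------------------------------
// Element preprocessing: shape-function gradients w.r.t. reference coords and
// reference Jacobian determinants at the 8 Gauss points of a trilinear hex.

struct ElemPrep {
  double gradN[8][24]; // [gp][a*3+k]
  double detJ0[8];
  double V;            // reference volume
  double hmin;         // shortest edge (reference)
};

static const int HEXE[12][2] = {
  {0,1},{1,2},{2,3},{3,0},{4,5},{5,6},{6,7},{7,4},{0,4},{1,5},{2,6},{3,7}
};

static bool prep_elem(const double* X /*8x3 row-major*/, ElemPrep& ep) {
  static const double sg[8][3] = {
    {-1,-1,-1},{1,-1,-1},{1,1,-1},{-1,1,-1},
    {-1,-1,1},{1,-1,1},{1,1,1},{-1,1,1}
  };
  ep.V = 0.0;
  for (int g = 0; g < 8; g++) {
    double xi = GP*sg[g][0], eta = GP*sg[g][1], zeta = GP*sg[g][2];
    double dN[8][3];
    for (int a = 0; a < 8; a++) {
      double sx = sg[a][0], sy = sg[a][1], sz = sg[a][2];
      dN[a][0] = 0.125*sx*(1+sy*eta)*(1+sz*zeta);
      dN[a][1] = 0.125*sy*(1+sx*xi)*(1+sz*zeta);
      dN[a][2] = 0.125*sz*(1+sx*xi)*(1+sy*eta);
    }
    double Jm[9] = {0,0,0,0,0,0,0,0,0}; // dX/dxi
    for (int a = 0; a < 8; a++)
      for (int i = 0; i < 3; i++)
        for (int k = 0; k < 3; k++)
          Jm[3*k+i] += dN[a][k]*X[3*a+i]; // J[k][i] = dX_i/dxi_k
    double dj = det3(Jm);
    if (!(dj > 0.0)) return false;
    ep.detJ0[g] = dj;
    ep.V += dj;
    double JinvT[9];
    invT3(Jm, dj, JinvT); // (J^{-1})^T ; J^{-1}[i][k] = JinvT[k][i]... careful
    // grad_X N_a = J^{-T} * dN (since dN/dX_i = dN/dxi_k * dxi_k/dX_i)
    // J[k][i] = dX_i/dxi_k -> dxi_k/dX_i = (J^{-1})[i][k] of the matrix J[k][i]
    // With Jm stored as M[3*k+i] = J[k][i], inv of M gives Minv[3*i+k];
    // invT3 returns transpose of inverse: invT[3*k+i] = Minv[3*i+k].
    for (int a = 0; a < 8; a++) {
      for (int i = 0; i < 3; i++) {
        double s = 0;
        for (int k = 0; k < 3; k++) s += JinvT[3*k+i]*dN[a][k];
        ep.gradN[g][3*a+i] = s;
      }
    }
  }
  ep.hmin = 1e30;
  for (int e = 0; e < 12; e++) {
    const double* p = X + 3*HEXE[e][0];
    const double* q = X + 3*HEXE[e][1];
    double d = std::sqrt((p[0]-q[0])*(p[0]-q[0])+(p[1]-q[1])*(p[1]-q[1])+
                         (p[2]-q[2])*(p[2]-q[2]));
    if (d < ep.hmin) ep.hmin = d;
  }
  return true;
}

// Internal force of one element with F-bar volumetric treatment.
// The force is the exact gradient of the element energy
//   E = sum_g w detJ0 psi(Fhat_g),  Fhat = (Jbar/J)^(1/3) F,  Jbar = v/V,
// including the Jbar-coupling terms (variationally consistent F-bar), so
// dynamic relaxation dissipates monotonically and the FD stiffness is
// symmetric. Returns false on inverted deformation.
static bool elem_force(const ElemPrep& ep, const double* u /*24*/,
                       int type, const double* pr,
                       const double* a1, const double* a2, double swell,
                       double* f /*24*/, double& psi, double* sig6 /*or null*/,
                       double& modest, double& minJ) {
  double Fgp[8][9], Jgp[8], FiT[8][9];
  double v = 0.0;
  for (int g = 0; g < 8; g++) {
    double F[9] = {1,0,0, 0,1,0, 0,0,1};
    const double* gn = ep.gradN[g];
    for (int a = 0; a < 8; a++)
      for (int i = 0; i < 3; i++)
        for (int k = 0; k < 3; k++)
          F[3*i+k] += u[3*a+i]*gn[3*a+k];
    double J = det3(F);
    if (!(J > 0.0) || !std::isfinite(J)) return false;
    Jgp[g] = J;
    std::memcpy(Fgp[g], F, sizeof(F));
    invT3(F, J, FiT[g]);
    v += J * ep.detJ0[g];
  }
  double Jbar = v / ep.V;
  if (!(Jbar > 0.0)) return false;

  for (int i = 0; i < 24; i++) f[i] = 0.0;
  double dv[24]; // d v / d u
  for (int i = 0; i < 24; i++) dv[i] = 0.0;
  psi = 0.0; modest = 0.0; minJ = 1e30;
  double Tbar = 0.0; // sum_g w detJ0 (Phat : Fhat)
  double sacc[9] = {0,0,0,0,0,0,0,0,0};
  double wacc = 0.0;
  PointOut po;
  for (int g = 0; g < 8; g++) {
    double scale = std::cbrt(Jbar / Jgp[g]);
    double Fh[9];
    for (int i = 0; i < 9; i++) Fh[i] = scale * Fgp[g][i];
    point_eval(Fh, type, pr, a1, a2, swell, po, sig6 != nullptr);
    if (!po.ok) return false;
    double w = ep.detJ0[g];
    psi += w * po.psi;
    if (po.modest > modest) modest = po.modest;
    if (Jbar < minJ) minJ = Jbar;
    double tauh = 0.0; // Phat : Fhat
    for (int i = 0; i < 9; i++) tauh += po.P[i]*Fh[i];
    Tbar += w * tauh;
    const double* gn = ep.gradN[g];
    for (int a = 0; a < 8; a++)
      for (int i = 0; i < 3; i++) {
        double s = 0, fi = 0;
        for (int k = 0; k < 3; k++) {
          s  += po.P[3*i+k]*gn[3*a+k];
          fi += FiT[g][3*i+k]*gn[3*a+k];
        }
        f[3*a+i] += w * (scale * s - (tauh/3.0) * fi);
        dv[3*a+i] += w * Jgp[g] * fi;
      }
    if (sig6) {
      double wc = w * Jbar;
      for (int i = 0; i < 9; i++) sacc[i] += wc * po.sig[i];
      wacc += wc;
    }
  }
  double cfac = Tbar / (3.0 * v);
  for (int i = 0; i < 24; i++) f[i] += cfac * dv[i];
  if (sig6) {
    for (int i = 0; i < 9; i++) sacc[i] /= wacc;
    sig6[0] = sacc[0]; sig6[1] = sacc[4]; sig6[2] = sacc[8];
    sig6[3] = 0.5*(sacc[1]+sacc[3]);
    sig6[4] = 0.5*(sacc[5]+sacc[7]);
    sig6[5] = 0.5*(sacc[2]+sacc[6]);
  }
  return true;
}

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_point_eval(NumericMatrix F, int type, NumericVector params,
                    NumericVector a1, NumericVector a2, double swell) {
  double Fv[9];
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) Fv[3*i+j] = F(i, j);
  double A1[3] = {0,0,0}, A2[3] = {0,0,0};
  if (a1.size() == 3) { A1[0]=a1[0]; A1[1]=a1[1]; A1[2]=a1[2]; }
  if (a2.size() == 3) { A2[0]=a2[0]; A2[1]=a2[1]; A2[2]=a2[2]; }
  PointOut po;
  point_eval(Fv, type, params.begin(), A1, A2, swell, po, true);
  if (!po.ok) stop("non-positive Jacobian in point evaluation");
  NumericMatrix P(3,3), S(3,3);
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) { P(i,j)=po.P[3*i+j]; S(i,j)=po.sig[3*i+j]; }
  return List::create(_["psi"]=po.psi, _["P"]=P, _["sigma"]=S,
                      _["modulus_estimate"]=po.modest);
}

struct MeshData {
  int nn, ne;
  std::vector<double> X;       // 3*nn
  std::vector<int> conn;       // 8*ne (0-based)
  std::vector<int> mtype;      // ne
  std::vector<double> mpar;    // 5*ne
  std::vector<double> fib;     // 6*ne (a1,a2)
  std::vector<double> swell;   // ne
  std::vector<ElemPrep> prep;  // ne
};

static void build_meshdata(const NumericMatrix& nodes, const IntegerMatrix& hexes,
                           const IntegerVector& mtype, const NumericMatrix& mpar,
                           const NumericMatrix& fib1, const NumericMatrix& fib2,
                           const NumericVector& swell, MeshData& md) {
  md.nn = nodes.nrow(); md.ne = hexes.nrow();
  md.X.resize(3*md.nn);
  for (int i = 0; i < md.nn; i++)
    for (int k = 0; k < 3; k++) md.X[3*i+k] = nodes(i,k);
  md.conn.resize(8*md.ne);
  md.mtype.resize(md.ne); md.mpar.assign(5*md.ne, 0.0);
  md.fib.assign(6*md.ne, 0.0); md.swell.resize(md.ne);
  md.prep.resize(md.ne);
  int npar = mpar.ncol();
  for (int e = 0; e < md.ne; e++) {
    for (int a = 0; a < 8; a++) md.conn[8*e+a] = hexes(e,a) - 1;
    md.mtype[e] = mtype[e];
    for (int k = 0; k < npar && k < 5; k++) md.mpar[5*e+k] = mpar(e,k);
    for (int k = 0; k < 3; k++) {
      md.fib[6*e+k]   = fib1(e,k);
      md.fib[6*e+3+k] = fib2(e,k);
    }
    md.swell[e] = swell[e];
    double Xe[24];
    for (int a = 0; a < 8; a++)
      for (int k = 0; k < 3; k++) Xe[3*a+k] = md.X[3*md.conn[8*e+a]+k];
    if (!prep_elem(Xe, md.prep[e]))
      stop("element %d has non-positive reference Jacobian", e+1);
  }
}

// Assemble internal force (and optionally the finite-difference stiffness)
// for the whole mesh at displacement U.
// [[Rcpp::export]]
List cpp_assemble(NumericMatrix nodes, IntegerMatrix hexes,
                  IntegerVector mtype, NumericMatrix mpar,
                  NumericMatrix fib1, NumericMatrix fib2,
                  NumericVector swell, NumericVector U,
                  bool want_K, bool want_stress, double fd_h) {
  MeshData md;
  build_meshdata(nodes, hexes, mtype, mpar, fib1, fib2, swell, md);
  int ndof = 3*md.nn;
  if (U.size() != ndof) stop("displacement vector has wrong length");

  NumericVector fint(ndof);
  NumericMatrix sig(want_stress ? md.ne : 1, 6);
  std::vector<int> Ki, Kj; std::vector<double> Kx;
  if (want_K) { Ki.reserve(md.ne*576); Kj.reserve(md.ne*576); Kx.reserve(md.ne*576); }
  double energy = 0.0, minJ = 1e30;
  bool ok = true; int bad_elem = -1;

  for (int e = 0; e < md.ne && ok; e++) {
    double ue[24];
    const int* cn = &md.conn[8*e];
    for (int a = 0; a < 8; a++)
      for (int k = 0; k < 3; k++) ue[3*a+k] = U[3*cn[a]+k];
    double fe[24], psi, s6[6], modest, mJ;
    if (!elem_force(md.prep[e], ue, md.mtype[e], &md.mpar[5*e],
                    &md.fib[6*e], &md.fib[6*e+3], md.swell[e],
                    fe, psi, want_stress ? s6 : nullptr, modest, mJ)) {
      ok = false; bad_elem = e; break;
    }
    energy += psi;
    if (mJ < minJ) minJ = mJ;
    for (int a = 0; a < 8; a++)
      for (int k = 0; k < 3; k++) fint[3*cn[a]+k] += fe[3*a+k];
    if (want_stress) for (int k = 0; k < 6; k++) sig(e,k) = s6[k];
    if (want_K) {
      double h = fd_h;
      double fp[24], psid, mo, mj2, u2[24];
      for (int c = 0; c < 24; c++) {
        std::memcpy(u2, ue, sizeof(u2));
        u2[c] += h;
        if (!elem_force(md.prep[e], u2, md.mtype[e], &md.mpar[5*e],
                        &md.fib[6*e], &md.fib[6*e+3], md.swell[e],
                        fp, psid, nullptr, mo, mj2)) { ok=false; bad_elem=e; break; }
        int gc = 3*cn[c/3] + (c%3);
        for (int r = 0; r < 24; r++) {
          double kx = (fp[r]-fe[r])/h;
          if (kx != 0.0) {
            Ki.push_back(3*cn[r/3] + (r%3));
            Kj.push_back(gc);
            Kx.push_back(kx);
          }
        }
      }
    }
  }

  List out = List::create(
    _["ok"] = ok, _["bad_elem"] = bad_elem + 1,
    _["fint"] = fint, _["energy"] = energy, _["minJ"] = minJ);
  if (want_stress) out["sigma"] = sig;
  if (want_K) {
    out["Ki"] = IntegerVector(Ki.begin(), Ki.end());
    out["Kj"] = IntegerVector(Kj.begin(), Kj.end());
    out["Kx"] = NumericVector(Kx.begin(), Kx.end());
  }
  return out;
}

// Reference volumes per element.
// [[Rcpp::export]]
NumericVector cpp_elem_volumes(NumericMatrix nodes, IntegerMatrix hexes) {
  int ne = hexes.nrow();
  NumericVector V(ne);
  for (int e = 0; e < ne; e++) {
    double Xe[24];
    for (int a = 0; a < 8; a++)
      for (int k = 0; k < 3; k++) Xe[3*a+k] = nodes(hexes(e,a)-1, k);
    ElemPrep ep;
    if (!prep_elem(Xe, ep)) stop("element %d has non-positive reference Jacobian", e+1);
    V[e] = ep.V;
  }
  return V;
}

// Minimum scaled Jacobian over Gauss points, per element (mesh quality scan).
// [[Rcpp::export]]
NumericVector cpp_scaled_jacobians(NumericMatrix nodes, IntegerMatrix hexes) {
  int ne = hexes.nrow();
  NumericVector q(ne);
  for (int e = 0; e < ne; e++) {
    double Xe[24];
    for (int a = 0; a < 8; a++)
      for (int k = 0; k < 3; k++) Xe[3*a+k] = nodes(hexes(e,a)-1, k);
    ElemPrep ep;
    if (!prep_elem(Xe, ep)) { q[e] = -1.0; continue; }
    double mn = 1e30;
    for (int g = 0; g < 8; g++) if (ep.detJ0[g] < mn) mn = ep.detJ0[g];
    // normalize by (hmin-based) characteristic volume of one octant
    double ref = ep.V / 8.0;
    q[e] = mn / ref;
  }
  return q;
}

static void rodrigues(const double* w, double R[9]) {
  double th = std::sqrt(w[0]*w[0]+w[1]*w[1]+w[2]*w[2]);
  if (th < 1e-14) {
    R[0]=1;R[1]=0;R[2]=0;R[3]=0;R[4]=1;R[5]=0;R[6]=0;R[7]=0;R[8]=1;
    return;
  }
  double k[3] = {w[0]/th, w[1]/th, w[2]/th};
  double c = std::cos(th), s = std::sin(th), v = 1.0-c;
  R[0]=c+k[0]*k[0]*v;      R[1]=k[0]*k[1]*v-k[2]*s; R[2]=k[0]*k[2]*v+k[1]*s;
  R[3]=k[1]*k[0]*v+k[2]*s; R[4]=c+k[1]*k[1]*v;      R[5]=k[1]*k[2]*v-k[0]*s;
  R[6]=k[2]*k[0]*v-k[1]*s; R[7]=k[2]*k[1]*v+k[0]*s; R[8]=c+k[2]*k[2]*v;
}

// Explicit dynamic relaxation under a smooth simultaneous ramp of a rigid
// rotation (about a reference point, applied to the coupled node set), an
// axial dead force on the rigid set, and fixed caudal nodes. Mass scaling is
// recomputed periodically from current stiffness estimates; dt = 1.
// [[Rcpp::export]]
List cpp_explicit(NumericMatrix nodes, IntegerMatrix hexes,
                  IntegerVector mtype, NumericMatrix mpar,
                  NumericMatrix fib1, NumericMatrix fib2,
                  NumericVector swell, NumericVector u0,
                  IntegerVector fixed_nodes, IntegerVector coupled_nodes,
                  NumericVector xref, NumericVector rotvec,
                  double axial_force, bool free_tz,
                  int nsteps, int nhold, double damping,
                  int record_every, double mass_safety, int mass_update) {
  MeshData md;
  build_meshdata(nodes, hexes, mtype, mpar, fib1, fib2, swell, md);
  int nn = md.nn, ne = md.ne, ndof = 3*nn;
  std::vector<double> u(ndof), v(ndof, 0.0), fint(ndof), mass(nn, 0.0);
  for (int i = 0; i < ndof; i++) u[i] = u0[i];

  std::vector<char> role(nn, 0); // 0 free, 1 fixed, 2 coupled
  for (int i = 0; i < fixed_nodes.size(); i++) role[fixed_nodes[i]-1] = 1;
  for (int i = 0; i < coupled_nodes.size(); i++) role[coupled_nodes[i]-1] = 2;

  std::vector<double> modest(ne, 0.0);
  double tz = 0.0, vtz = 0.0;
  // initial tz from prestate: mean axial displacement of coupled nodes
  if (coupled_nodes.size() > 0) {
    double s = 0;
    for (int i = 0; i < coupled_nodes.size(); i++)
      s += u[3*(coupled_nodes[i]-1)+2];
    tz = s / coupled_nodes.size();
  }

  int total = nsteps + nhold;
  int nrec = total / record_every + 2;
  NumericVector ke_hist(nrec), ie_hist(nrec), t_hist(nrec), s_hist(nrec),
    tz_hist(nrec), minj_hist(nrec);
  int irec = 0;
  double dt = 1.0;
  bool ok = true; int bad_elem = -1, bad_step = -1;

  std::vector<double> uprev_coup(3*coupled_nodes.size(), 0.0);
  for (int i = 0; i < coupled_nodes.size(); i++)
    for (int k = 0; k < 3; k++)
      uprev_coup[3*i+k] = u[3*(coupled_nodes[i]-1)+k];

  double energy = 0.0;

  for (int step = 0; step <= total && ok; step++) {
    double s = (step >= nsteps) ? 1.0 :
               0.5*(1.0 - std::cos(M_PI * (double)step / (double)nsteps));
    // prescribe coupled nodes: rigid rotation + axial translation tz
    double w[3] = { rotvec[0]*s, rotvec[1]*s, rotvec[2]*s };
    double R[9];
    rodrigues(w, R);
    for (int i = 0; i < coupled_nodes.size(); i++) {
      int n = coupled_nodes[i]-1;
      double r0[3] = { md.X[3*n]-xref[0], md.X[3*n+1]-xref[1], md.X[3*n+2]-xref[2] };
      double rn[3];
      for (int a = 0; a < 3; a++)
        rn[a] = R[3*a]*r0[0]+R[3*a+1]*r0[1]+R[3*a+2]*r0[2];
      u[3*n]   = rn[0]-r0[0];
      u[3*n+1] = rn[1]-r0[1];
      u[3*n+2] = rn[2]-r0[2] + tz;
    }
    // internal force + energy + stiffness estimates
    std::fill(fint.begin(), fint.end(), 0.0);
    energy = 0.0;
    double minJ_now = 1e30;
    for (int e = 0; e < ne; e++) {
      double ue[24], fe[24], psi, mo, mJ;
      const int* cn = &md.conn[8*e];
      for (int a = 0; a < 8; a++)
        for (int k = 0; k < 3; k++) ue[3*a+k] = u[3*cn[a]+k];
      if (!elem_force(md.prep[e], ue, md.mtype[e], &md.mpar[5*e],
                      &md.fib[6*e], &md.fib[6*e+3], md.swell[e],
                      fe, psi, nullptr, mo, mJ)) {
        ok=false; bad_elem=e; bad_step=step; break;
      }
      energy += psi;
      if (mJ < minJ_now) minJ_now = mJ;
      modest[e] = mo;
      for (int a = 0; a < 8; a++)
        for (int k = 0; k < 3; k++) fint[3*cn[a]+k] += fe[3*a+k];
    }
    if (!ok) break;

    if (step % mass_update == 0) {
      std::fill(mass.begin(), mass.end(), 0.0);
      for (int e = 0; e < ne; e++) {
        double h = md.prep[e].hmin;
        double rho = modest[e] * (dt*dt) / (h*h) * mass_safety*mass_safety;
        double mnode = rho * md.prep[e].V / 8.0;
        for (int a = 0; a < 8; a++) mass[md.conn[8*e+a]] += mnode;
      }
    }

    // kinetic energy: free nodes + coupled (prescribed) + rigid axial dof
    double ke = 0.0;
    // integrate free nodes
    double dfac = 1.0 - damping;
    for (int n = 0; n < nn; n++) {
      if (role[n] != 0) continue;
      for (int k = 0; k < 3; k++) {
        double a = -fint[3*n+k] / mass[n];
        v[3*n+k] = dfac*v[3*n+k] + dt*a;
        u[3*n+k] += dt*v[3*n+k];
        ke += 0.5*mass[n]*v[3*n+k]*v[3*n+k];
      }
    }
    // rigid axial dof: same stability margin as the nodes it aggregates,
    // but near-critical damping (the mode is much slower than the element
    // modes, so the global velocity damping alone lets it overshoot and
    // crush thin layers under force-controlled compression)
    if (coupled_nodes.size() > 0) {
      double mref = 0.0, fz = 0.0;
      for (int i = 0; i < coupled_nodes.size(); i++) {
        int n = coupled_nodes[i]-1;
        mref += mass[n];
        fz += fint[3*n+2];
      }
      if (free_tz) {
        double dfac_tz = 1.0 - std::max(damping, 0.25);
        double a = (-axial_force*s - fz) / mref;
        vtz = dfac_tz*vtz + dt*a;
        tz += dt*vtz;
      }
      // prescribed-node kinetic energy from actual motion
      for (int i = 0; i < coupled_nodes.size(); i++) {
        int n = coupled_nodes[i]-1;
        for (int k = 0; k < 3; k++) {
          double vel = (u[3*n+k] - uprev_coup[3*i+k]) / dt;
          ke += 0.5*mass[n]*vel*vel;
          uprev_coup[3*i+k] = u[3*n+k];
        }
      }
    }
    // fixed nodes stay at zero
    for (int n = 0; n < nn; n++)
      if (role[n] == 1) { u[3*n]=0; u[3*n+1]=0; u[3*n+2]=0; }

    if (step % record_every == 0 && irec < nrec) {
      ke_hist[irec] = ke; ie_hist[irec] = energy;
      t_hist[irec] = step; s_hist[irec] = s;
      tz_hist[irec] = tz; minj_hist[irec] = minJ_now;
      irec++;
    }
  }

  // residual on free nodes (static equilibrium quality)
  double res2 = 0.0, reac2 = 0.0;
  for (int n = 0; n < nn; n++) {
    double f2 = fint[3*n]*fint[3*n]+fint[3*n+1]*fint[3*n+1]+fint[3*n+2]*fint[3*n+2];
    if (role[n] == 0) res2 += f2; else reac2 += f2;
  }

  NumericVector uout(ndof);
  for (int i = 0; i < ndof; i++) uout[i] = u[i];
  return List::create(
    _["ok"] = ok, _["bad_elem"] = bad_elem+1, _["bad_step"] = bad_step,
    _["u"] = uout, _["tz"] = tz,
    _["ke"] = ke_hist[Range(0, std::max(irec-1,0))],
    _["ie"] = ie_hist[Range(0, std::max(irec-1,0))],
    _["step"] = t_hist[Range(0, std::max(irec-1,0))],
    _["s"] = s_hist[Range(0, std::max(irec-1,0))],
    _["tz_hist"] = tz_hist[Range(0, std::max(irec-1,0))],
    _["minj_hist"] = minj_hist[Range(0, std::max(irec-1,0))],
    _["residual_free"] = std::sqrt(res2),
    _["reaction_norm"] = std::sqrt(reac2),
    _["final_energy"] = energy);
}
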