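// Articulated multibody core: forward kinematics, recursive Newton-Euler
// inverse dynamics, penetration contact, Hill-type muscle residuals, and the
// direct-collocation residual stack with a 3-colored finite-difference
// Jacobian over the banded node structure.
//
// Conventions: right-handed lab frame, vertical = +Y, ground plane y = 0.
// Angles in radians, lengths in meters, forces in N, moments in N*m.
// State x = [q (nd), qdot (nd), a (nm), s (nm)]; control u = [n_e (nm), m (ntor)].
// Residual f = [qdot - dq/dt (nd); RNEA - tau_applied (nd);
//               da/dt - activation rate (nm); tendon force balance (nm)].

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
};
static inline V3 operator+(const V3& a, const V3& b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator-(const V3& a, const V3& b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator*(double s, const V3& a) { return V3(s * a.x, s * a.y, s * a.z); }
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}

struct M3 {
  double m[9];  // row-major
  M3() { for (int i = 0; i < 9; ++i) m[i] = 0; }
  static M3 eye() { M3 r; r.m[0] = r.m[4] = r.m[8] = 1; return r; }
};
static inline V3 mul(const M3& A, const V3& v) {
  return V3(A.m[0] * v.x + A.m[1] * v.y + A.m[2] * v.z,
            A.m[3] * v.x + A.m[4] * v.y + A.m[5] * v.z,
            A.m[6] * v.x + A.m[7] * v.y + A.m[8] * v.z);
}
static inline M3 mul(const M3& A, const M3& B) {
  M3 C;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += A.m[3 * i + k] * B.m[3 * k + j];
      C.m[3 * i + j] = s;
    }
  return C;
}
static inline M3 transpose(const M3& A) {
  M3 T;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) T.m[3 * i + j] = A.m[3 * j + i];
  return T;
}
// Rotation about unit axis by angle (Rodrigues).
static inline M3 axisRot(const V3& a, double th) {
  double c = std::cos(th), s = std::sin(th), t = 1 - c;
  M3 R;
  R.m[0] = c + a.x * a.x * t;       R.m[1] = a.x * a.y * t - a.z * s; R.m[2] = a.x * a.z * t + a.y * s;
  R.m[3] = a.y * a.x * t + a.z * s; R.m[4] = c + a.y * a.y * t;       R.m[5] = a.y * a.z * t - a.x * s;
  R.m[6] = a.z * a.x * t - a.y * s; R.m[7] = a.z * a.y * t + a.x * s; R.m[8] = c + a.z * a.z * t;
  return R;
}

struct Muscle {
  double fmax, lmopt, ltslack, vmax, tact, tdeact, w, kt;
  bool rigid;
  std::vector<double> coef;          // polynomial terms of the muscle-tendon length
  std::vector<std::vector<int> > expo;  // per term: exponent per dof
};

struct Model {
  int nd, nbody, nmark, ncp, nmus, ntor;
  // dofs
  std::vector<int> parent;   // 0-based, -1 = world
  std::vector<int> jtype;    // 0 translation, 1 rotation
  std::vector<V3> axis, trans;
  // bodies (segments with inertia)
  std::vector<int> bdof;
  std::vector<double> bmass;
  std::vector<V3> bcom;
  std::vector<M3> binert;
  // markers
  std::vector<int> mdof;
  std::vector<V3> mloc;
  // contact points
  std::vector<int> cdof, cfoot;
  std::vector<V3> cloc;
  double ck, cexp, cdamp, cmu, cvs, ceps, coffset;
  // muscles, torque actuators
  std::vector<Muscle> mus;
  std::vector<int> tordof;
  std::vector<double> torgain;  // N*m per unit control
  // passive moments per dof
  std::vector<double> qlo, qhi, kpas, bpas, dpas;
  V3 grav;
};

static Model parseModel(const List& ml) {
  Model M;
  List dof = ml["dof"];
  IntegerVector par = dof["parent"], jt = dof["jtype"];
  NumericMatrix ax = dof["axis"], tr = dof["trans"];
  M.nd = par.size();
  for (int i = 0; i < M.nd; ++i) {
    M.parent.push_back(par[i] - 1);
    M.jtype.push_back(jt[i]);
    M.axis.push_back(V3(ax(i, 0), ax(i, 1), ax(i, 2)));
    M.trans.push_back(V3(tr(i, 0), tr(i, 1), tr(i, 2)));
  }
  List body = ml["body"];
  IntegerVector bd = body["dof"];
  NumericVector bm = body["mass"];
  NumericMatrix bc = body["com"], bi = body["inertia"];  // inertia nb x 9 row-major
  M.nbody = bd.size();
  for (int i = 0; i < M.nbody; ++i) {
    M.bdof.push_back(bd[i] - 1);
    M.bmass.push_back(bm[i]);
    M.bcom.push_back(V3(bc(i, 0), bc(i, 1), bc(i, 2)));
    M3 I;
    for (int k = 0; k < 9; ++k) I.m[k] = bi(i, k);
    M.binert.push_back(I);
  }
  List mk = ml["markers"];
  IntegerVector md = mk["dof"];
  NumericMatrix mlc = mk["local"];
  M.nmark = md.size();
  for (int i = 0; i < M.nmark; ++i) {
    M.mdof.push_back(md[i] - 1);
    M.mloc.push_back(V3(mlc(i, 0), mlc(i, 1), mlc(i, 2)));
  }
  List ct = ml["contacts"];
  IntegerVector cd = ct["dof"], cf = ct["foot"];
  NumericMatrix clc = ct["local"];
  M.ncp = cd.size();
  for (int i = 0; i < M.ncp; ++i) {
    M.cdof.push_back(cd[i] - 1);
    M.cfoot.push_back(cf[i]);
    M.cloc.push_back(V3(clc(i, 0), clc(i, 1), clc(i, 2)));
  }
  M.ck = as<double>(ct["k"]);
  M.cexp = as<double>(ct["expn"]);
  M.cdamp = as<double>(ct["cdamp"]);
  M.cmu = as<double>(ct["mu"]);
  M.cvs = as<double>(ct["vs"]);
  M.ceps = as<double>(ct["eps"]);
  M.coffset = as<double>(ct["offset"]);
  List mus = ml["muscles"];
  NumericVector fmax = mus["fmax"], lmo = mus["lmopt"], lts = mus["ltslack"],
                vmx = mus["vmax"], ta = mus["tact"], td = mus["tdeact"], w = mus["w"],
                kt = mus["kt"];
  IntegerVector rig = mus["rigid"];
  List poly = mus["poly"];
  M.nmus = fmax.size();
  for (int i = 0; i < M.nmus; ++i) {
    Muscle mu;
    mu.fmax = fmax[i]; mu.lmopt = lmo[i]; mu.ltslack = lts[i]; mu.vmax = vmx[i];
    mu.tact = ta[i]; mu.tdeact = td[i]; mu.w = w[i]; mu.kt = kt[i];
    mu.rigid = rig[i] != 0;
    List p = poly[i];
    NumericVector cf2 = p["coef"];
    IntegerMatrix ex = p["expo"];
    for (int t = 0; t < cf2.size(); ++t) {
      mu.coef.push_back(cf2[t]);
      std::vector<int> e(M.nd);
      for (int d = 0; d < M.nd; ++d) e[d] = ex(t, d);
      mu.expo.push_back(e);
    }
    M.mus.push_back(mu);
  }
  IntegerVector tor = ml["tor"];
  NumericVector tg = ml["tor_gain"];
  M.ntor = tor.size();
  for (int i = 0; i < M.ntor; ++i) {
    M.tordof.push_back(tor[i] - 1);
    M.torgain.push_back(tg[i]);
  }
  List pas = ml["passive"];
  NumericVector lo = pas["qlo"], hi = pas["qhi"], kp = pas["k"], bp = pas["b"], dp = pas["d"];
  for (int i = 0; i < M.nd; ++i) {
    M.qlo.push_back(lo[i]); M.qhi.push_back(hi[i]);
    M.kpas.push_back(kp[i]); M.bpas.push_back(bp[i]); M.dpas.push_back(dp[i]);
  }
  NumericVector g = ml["gravity"];
  M.grav = V3(g[0], g[1], g[2]);
  return M;
}

struct Kin {
  std::vector<M3> R;
  std::vector<V3> o, aw, om, vo, al, ao;  // rotation, origin, world axis,
                                          // angular vel, origin vel, angular acc, origin acc
};

static void computeKin(const Model& M, const double* q, const double* qd,
                       const double* qdd, Kin& K) {
  int nd = M.nd;
  K.R.assign(nd, M3::eye());
  K.o.assign(nd, V3()); K.aw.assign(nd, V3()); K.om.assign(nd, V3());
  K.vo.assign(nd, V3()); K.al.assign(nd, V3()); K.ao.assign(nd, V3());
  for (int i = 0; i < nd; ++i) {
    int p = M.parent[i];
    M3 Rp = (p >= 0) ? K.R[p] : M3::eye();
    V3 op = (p >= 0) ? K.o[p] : V3();
    V3 omp = (p >= 0) ? K.om[p] : V3();
    V3 vop = (p >= 0) ? K.vo[p] : V3();
    V3 alp = (p >= 0) ? K.al[p] : V3();
    V3 aop = (p >= 0) ? K.ao[p] : V3();
    V3 aw = mul(Rp, M.axis[i]);
    K.aw[i] = aw;
    double qi = q[i], qdi = qd ? qd[i] : 0.0, qddi = qdd ? qdd[i] : 0.0;
    if (M.jtype[i] == 1) {  // rotation
      K.o[i] = op + mul(Rp, M.trans[i]);
      K.R[i] = mul(Rp, axisRot(M.axis[i], qi));
      V3 r = K.o[i] - op;
      K.om[i] = omp + qdi * aw;
      K.vo[i] = vop + cross(omp, r);
      K.al[i] = alp + qddi * aw + cross(omp, qdi * aw);
      K.ao[i] = aop + cross(alp, r) + cross(omp, cross(omp, r));
    } else {  // translation
      K.o[i] = op + mul(Rp, M.trans[i]) + qi * aw;
      K.R[i] = Rp;
      V3 r = K.o[i] - op;
      K.om[i] = omp;
      K.vo[i] = vop + cross(omp, r) + qdi * aw;
      K.al[i] = alp;
      K.ao[i] = aop + cross(alp, r) + cross(omp, cross(omp, r)) +
                qddi * aw + 2.0 * cross(omp, qdi * aw);
    }
  }
}

static inline double softplus(double x, double w) {
  return 0.5 * (x + std::sqrt(x * x + w * w));
}
static inline double expc(double x) { return std::exp(x > 50 ? 50 : x); }

// Contact forces at each point; also per-foot net GRF (foot 0 then foot 1).
static void contactForces(const Model& M, const Kin& K, std::vector<V3>& P,
                          std::vector<V3>& F, double grf[6]) {
  P.resize(M.ncp); F.resize(M.ncp);
  for (int i = 0; i < 6; ++i) grf[i] = 0;
  for (int c = 0; c < M.ncp; ++c) {
    int d = M.cdof[c];
    V3 loc = mul(K.R[d], M.cloc[c]);
    V3 p = K.o[d] + loc;
    V3 v = K.vo[d] + cross(K.om[d], loc);
    double pen = M.coffset - p.y;
    double sp = softplus(pen, M.ceps);
    double fy = M.ck * std::pow(sp, M.cexp) * (1.0 + M.cdamp * (-v.y));
    double vh = std::sqrt(v.x * v.x + v.z * v.z + M.cvs * M.cvs);
    double fx = -M.cmu * fy * v.x / vh;
    double fz = -M.cmu * fy * v.z / vh;
    P[c] = p;
    F[c] = V3(fx, fy, fz);
    int off = M.cfoot[c] == 0 ? 0 : 3;
    grf[off + 0] += fx; grf[off + 1] += fy; grf[off + 2] += fz;
  }
}

struct ExtWrench { int dof; V3 F, P, N; };

// Recursive Newton-Euler: generalized forces required to realize (q, qd, qdd)
// under gravity and the given external wrenches. Q = RNEA(...) and the
// equations of motion read Q = tau_applied.
static void rnea(const Model& M, const Kin& K, const std::vector<ExtWrench>& ext,
                 double* Q) {
  int nd = M.nd;
  std::vector<V3> f(nd), n(nd);
  for (int b = 0; b < M.nbody; ++b) {
    int d = M.bdof[b];
    V3 rc = mul(K.R[d], M.bcom[b]);
    V3 xc = K.o[d] + rc;
    V3 ac = K.ao[d] + cross(K.al[d], rc) + cross(K.om[d], cross(K.om[d], rc));
    M3 Iw = mul(mul(K.R[d], M.binert[b]), transpose(K.R[d]));
    V3 Fb = M.bmass[b] * ac - M.bmass[b] * M.grav;
    V3 Nb = mul(Iw, K.al[d]) + cross(K.om[d], mul(Iw, K.om[d]));
    f[d] = f[d] + Fb;
    n[d] = n[d] + Nb + cross(xc - K.o[d], Fb);
  }
  for (size_t e = 0; e < ext.size(); ++e) {
    int d = ext[e].dof;
    f[d] = f[d] - ext[e].F;
    n[d] = n[d] - cross(ext[e].P - K.o[d], ext[e].F) - ext[e].N;
  }
  for (int i = nd - 1; i >= 0; --i) {
    Q[i] = (M.jtype[i] == 1) ? dot(K.aw[i], n[i]) : dot(K.aw[i], f[i]);
    int p = M.parent[i];
    if (p >= 0) {
      f[p] = f[p] + f[i];
      n[p] = n[p] + n[i] + cross(K.o[i] - K.o[p], f[i]);
    }
  }
}

// Muscle-tendon length and moment arms (-dL/dq) from the polynomial.
static void lmtMa(const Muscle& mu, const double* q, int nd, double& lmt, double* ma) {
  lmt = 0;
  for (int d = 0; d < nd; ++d) ma[d] = 0;
  for (size_t t = 0; t < mu.coef.size(); ++t) {
    double term = mu.coef[t];
    for (int d = 0; d < nd; ++d) {
      int e = mu.expo[t][d];
      for (int k = 0; k < e; ++k) term *= q[d];
    }
    lmt += term;
    for (int d = 0; d < nd; ++d) {
      int e = mu.expo[t][d];
      if (e == 0) continue;
      double dterm = mu.coef[t] * e;
      for (int dd = 0; dd < nd; ++dd) {
        int ee = mu.expo[t][dd] - (dd == d ? 1 : 0);
        for (int k = 0; k < ee; ++k) dterm *= q[dd];
      }
      ma[d] -= dterm;  // moment arm = -dL/dq
    }
  }
}

static inline double fLcurve(double s) {
  double z = (s - 1.0) / 0.45;
  return std::exp(-z * z);
}
static inline double fVcurve(double vt) { return 1.0 + 0.45 * std::tanh(3.0 * vt); }
static inline double fPEcurve(double s) {
  double z = softplus(s - 1.0, 0.05);
  return 2.0 * z * z;
}
static inline double fTcurve(double lt_tilde, double kt) {
  double z = softplus(lt_tilde - 1.0, 0.01);
  return 0.2 * (expc(kt * z) - 1.0);
}
static inline double actRate(double ne, double a, double tact, double tdeact) {
  double sig = 0.5 + 0.5 * std::tanh((ne - a) / 0.1);
  return (ne - a) * (sig / tact + (1.0 - sig) / tdeact);
}

// Tendon force applied to the skeleton.
static double tendonForce(const Muscle& mu, double lmt, double a, double s, double sdot) {
  if (mu.rigid) {
    double vt = sdot / mu.vmax;
    return mu.fmax * (a * fLcurve(s) * fVcurve(vt) + fPEcurve(s));
  }
  double lt_tilde = (lmt - s * mu.lmopt) / mu.ltslack;
  return mu.fmax * fTcurve(lt_tilde, mu.kt);
}

// Fiber damping keeps the implicit equation solvable for sdot everywhere
// (the sigmoidal force-velocity curve alone is bounded).
static const double kFiberDamping = 0.1;

static double contractionResidual(const Muscle& mu, double lmt, double a,
                                  double s, double sdot) {
  if (mu.rigid) return (lmt - mu.ltslack) / mu.lmopt - s;
  double lt_tilde = (lmt - s * mu.lmopt) / mu.ltslack;
  double vt = sdot / mu.vmax;
  return fTcurve(lt_tilde, mu.kt) -
         (a * fLcurve(s) * fVcurve(vt) + fPEcurve(s) + kFiberDamping * vt);
}

static inline double passiveMoment(const Model& M, int d, double q, double qd) {
  if (M.kpas[d] == 0 && M.dpas[d] == 0) return 0.0;
  return M.kpas[d] * (expc(-M.bpas[d] * (q - M.qlo[d])) - expc(M.bpas[d] * (q - M.qhi[d]))) -
         M.dpas[d] * qd;
}

// Applied generalized forces: muscle moments + passive moments + actuator torques.
static void appliedTau(const Model& M, const double* q, const double* qd,
                       const double* a, const double* s, const double* sdot,
                       const double* u, double* tau) {
  int nd = M.nd;
  std::vector<double> ma(nd);
  for (int d = 0; d < nd; ++d) tau[d] = passiveMoment(M, d, q[d], qd[d]);
  for (int m = 0; m < M.nmus; ++m) {
    double lmt;
    lmtMa(M.mus[m], q, nd, lmt, &ma[0]);
    double ft = tendonForce(M.mus[m], lmt, a[m], s[m], sdot ? sdot[m] : 0.0);
    for (int d = 0; d < nd; ++d)
      if (ma[d] != 0.0) tau[d] += ma[d] * ft;
  }
  for (int t = 0; t < M.ntor; ++t)
    tau[M.tordof[t]] += M.torgain[t] * u[M.nmus + t];
}

// Implicit dynamics residual f(x, xdot, u); length 2*nd + 2*nmus.
static void dynResidual(const Model& M, const double* x, const double* xd,
                        const double* u, double* out) {
  int nd = M.nd, nm = M.nmus;
  const double* q = x;
  const double* qd = x + nd;
  const double* a = x + 2 * nd;
  const double* s = x + 2 * nd + nm;
  const double* dq = xd;
  const double* dqd = xd + nd;
  const double* da = xd + 2 * nd;
  const double* ds = xd + 2 * nd + nm;
  for (int i = 0; i < nd; ++i) out[i] = qd[i] - dq[i];
  Kin K;
  computeKin(M, q, qd, dqd, K);
  std::vector<V3> P, F;
  double grf[6];
  contactForces(M, K, P, F, grf);
  std::vector<ExtWrench> ext(M.ncp);
  for (int c = 0; c < M.ncp; ++c) {
    ext[c].dof = M.cdof[c]; ext[c].F = F[c]; ext[c].P = P[c]; ext[c].N = V3();
  }
  std::vector<double> Q(nd), tau(nd);
  rnea(M, K, ext, &Q[0]);
  appliedTau(M, q, qd, a, s, ds, u, &tau[0]);
  for (int i = 0; i < nd; ++i) out[nd + i] = Q[i] - tau[i];
  for (int m = 0; m < nm; ++m)
    out[2 * nd + m] = da[m] - actRate(u[m], a[m], M.mus[m].tact, M.mus[m].tdeact);
  for (int m = 0; m < nm; ++m) {
    double lmt, dummy;
    std::vector<double> ma(nd);
    lmtMa(M.mus[m], q, nd, lmt, &ma[0]);
    (void)dummy;
    out[2 * nd + nm + m] = contractionResidual(M.mus[m], lmt, a[m], s[m], ds[m]);
  }
}

// ---------------------------------------------------------------- exports

// [[Rcpp::export]]
List cpp_fk(List model, NumericVector q) {
  Model M = parseModel(model);
  Kin K;
  computeKin(M, q.begin(), NULL, NULL, K);
  NumericMatrix orig(M.nd, 3);
  NumericVector rots(Dimension(3, 3, M.nd));
  for (int i = 0; i < M.nd; ++i) {
    orig(i, 0) = K.o[i].x; orig(i, 1) = K.o[i].y; orig(i, 2) = K.o[i].z;
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) rots[9 * i + 3 * c + r] = K.R[i].m[3 * r + c];
  }
  NumericMatrix mk(M.nmark, 3);
  for (int m = 0; m < M.nmark; ++m) {
    V3 p = K.o[M.mdof[m]] + mul(K.R[M.mdof[m]], M.mloc[m]);
    mk(m, 0) = p.x; mk(m, 1) = p.y; mk(m, 2) = p.z;
  }
  return List::create(_["origins"] = orig, _["rotations"] = rots, _["markers"] = mk);
}

// [[Rcpp::export]]
NumericMatrix cpp_markers(List model, NumericVector q) {
  Model M = parseModel(model);
  Kin K;
  computeKin(M, q.begin(), NULL, NULL, K);
  NumericMatrix mk(M.nmark, 3);
  for (int m = 0; m < M.nmark; ++m) {
    V3 p = K.o[M.mdof[m]] + mul(K.R[M.mdof[m]], M.mloc[m]);
    mk(m, 0) = p.x; mk(m, 1) = p.y; mk(m, 2) = p.z;
  }
  return mk;
}

// Jacobian of stacked marker coordinates (x1,y1,z1,x2,...) w.r.t. q, central FD.
// [[Rcpp::export]]
NumericMatrix cpp_marker_jac(List model, NumericVector q) {
  Model M = parseModel(model);
  int nd = M.nd, nm = M.nmark;
  NumericMatrix J(3 * nm, nd);
  std::vector<double> qp(q.begin(), q.end());
  Kin K;
  double del = 1e-6;
  for (int d = 0; d < nd; ++d) {
    double q0 = qp[d];
    std::vector<double> plus(3 * nm), minus(3 * nm);
    qp[d] = q0 + del;
    computeKin(M, &qp[0], NULL, NULL, K);
    for (int m = 0; m < nm; ++m) {
      V3 p = K.o[M.mdof[m]] + mul(K.R[M.mdof[m]], M.mloc[m]);
      plus[3 * m] = p.x; plus[3 * m + 1] = p.y; plus[3 * m + 2] = p.z;
    }
    qp[d] = q0 - del;
    computeKin(M, &qp[0], NULL, NULL, K);
    for (int m = 0; m < nm; ++m) {
      V3 p = K.o[M.mdof[m]] + mul(K.R[M.mdof[m]], M.mloc[m]);
      minus[3 * m] = p.x; minus[3 * m + 1] = p.y; minus[3 * m + 2] = p.z;
    }
    qp[d] = q0;
    for (int r = 0; r < 3 * nm; ++r) J(r, d) = (plus[r] - minus[r]) / (2 * del);
  }
  return J;
}

// [[Rcpp::export]]
List cpp_contact(List model, NumericVector q, NumericVector qdot) {
  Model M = parseModel(model);
  Kin K;
  computeKin(M, q.begin(), qdot.begin(), NULL, K);
  std::vector<V3> P, F;
  double grf[6];
  contactForces(M, K, P, F, grf);
  NumericMatrix pts(M.ncp, 3), frc(M.ncp, 3);
  for (int c = 0; c < M.ncp; ++c) {
    pts(c, 0) = P[c].x; pts(c, 1) = P[c].y; pts(c, 2) = P[c].z;
    frc(c, 0) = F[c].x; frc(c, 1) = F[c].y; frc(c, 2) = F[c].z;
  }
  NumericVector g(6);
  for (int i = 0; i < 6; ++i) g[i] = grf[i];
  return List::create(_["points"] = pts, _["forces"] = frc, _["grf"] = g);
}

// [[Rcpp::export]]
NumericVector cpp_dyn_residual(List model, NumericVector x, NumericVector xdot,
                               NumericVector u) {
  Model M = parseModel(model);
  int nf = 2 * M.nd + 2 * M.nmus;
  NumericVector out(nf);
  dynResidual(M, x.begin(), xdot.begin(), u.begin(), out.begin());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_applied_tau(List model, NumericVector x, NumericVector sdot,
                              NumericVector u) {
  Model M = parseModel(model);
  int nd = M.nd, nm = M.nmus;
  NumericVector tau(nd);
  appliedTau(M, x.begin(), x.begin() + nd, x.begin() + 2 * nd,
             x.begin() + 2 * nd + nm, nm > 0 ? sdot.begin() : NULL, u.begin(),
             tau.begin());
  return tau;
}

// Generalized forces for given accelerations; optional external wrenches and
// optional built-in contact model.
// [[Rcpp::export]]
NumericVector cpp_rnea(List model, NumericVector q, NumericVector qdot,
                       NumericVector qddot, bool with_contact,
                       Nullable<List> external = R_NilValue) {
  Model M = parseModel(model);
  Kin K;
  computeKin(M, q.begin(), qdot.begin(), qddot.begin(), K);
  std::vector<ExtWrench> ext;
  if (with_contact) {
    std::vector<V3> P, F;
    double grf[6];
    contactForces(M, K, P, F, grf);
    for (int c = 0; c < M.ncp; ++c) {
      ExtWrench e; e.dof = M.cdof[c]; e.F = F[c]; e.P = P[c]; e.N = V3();
      ext.push_back(e);
    }
  }
  if (external.isNotNull()) {
    List exl(external);
    for (int i = 0; i < exl.size(); ++i) {
      List w = exl[i];
      NumericVector F = w["force"], P = w["point"], N = w["moment"];
      ExtWrench e;
      e.dof = as<int>(w["dof"]) - 1;
      e.F = V3(F[0], F[1], F[2]); e.P = V3(P[0], P[1], P[2]); e.N = V3(N[0], N[1], N[2]);
      ext.push_back(e);
    }
  }
  NumericVector Q(M.nd);
  rnea(M, K, ext, Q.begin());
  return Q;
}

// [[Rcpp::export]]
List cpp_lmt_ma(List model, NumericVector q) {
  Model M = parseModel(model);
  NumericVector lmt(M.nmus);
  NumericMatrix ma(M.nmus, M.nd);
  std::vector<double> row(M.nd);
  for (int m = 0; m < M.nmus; ++m) {
    double l;
    lmtMa(M.mus[m], q.begin(), M.nd, l, &row[0]);
    lmt[m] = l;
    for (int d = 0; d < M.nd; ++d) ma(m, d) = row[d];
  }
  return List::create(_["lmt"] = lmt, _["moment_arm"] = ma);
}

// [[Rcpp::export]]
List cpp_muscle_residual(List model, NumericVector a, NumericVector adot,
                         NumericVector s, NumericVector sdot, NumericVector ne,
                         NumericVector q) {
  Model M = parseModel(model);
  NumericVector ares(M.nmus), cres(M.nmus), ft(M.nmus);
  std::vector<double> ma(M.nd);
  for (int m = 0; m < M.nmus; ++m) {
    ares[m] = adot[m] - actRate(ne[m], a[m], M.mus[m].tact, M.mus[m].tdeact);
    double lmt;
    lmtMa(M.mus[m], q.begin(), M.nd, lmt, &ma[0]);
    cres[m] = contractionResidual(M.mus[m], lmt, a[m], s[m], sdot[m]);
    ft[m] = tendonForce(M.mus[m], lmt, a[m], s[m], sdot[m]);
  }
  return List::create(_["activation"] = ares, _["contraction"] = cres,
                      _["tendon_force"] = ft);
}

// [[Rcpp::export]]
NumericVector cpp_passive_moment(List model, NumericVector q, NumericVector qdot) {
  Model M = parseModel(model);
  NumericVector out(M.nd);
  for (int d = 0; d < M.nd; ++d) out[d] = passiveMoment(M, d, q[d], qdot[d]);
  return out;
}

// ---- collocation residual stack -------------------------------------------
// Rows: for k = 0..N-2 the backward-Euler block
//   f(x[k+1], (x[k+1]-x[k])/h, u[k+1])        (nf rows each)
// followed by the first-node forward-Euler closure
//   f(x[0], (x[1]-x[0])/h, u[0])              (nf - 6 rows; the kinematic
// identity rows of the 6 global pelvis coordinates are removed).
static void trajResidual(const Model& M, const double* X, const double* U,
                         int N, int nx, int nu, double h, double* out) {
  int nf = 2 * M.nd + 2 * M.nmus;
  std::vector<double> xd(nx), fr(nf);
  for (int k = 0; k < N - 1; ++k) {
    const double* x0 = X + (size_t)k * nx;
    const double* x1 = X + (size_t)(k + 1) * nx;
    const double* u1 = U + (size_t)(k + 1) * nu;
    for (int i = 0; i < nx; ++i) xd[i] = (x1[i] - x0[i]) / h;
    dynResidual(M, x1, &xd[0], u1, out + (size_t)k * nf);
  }
  const double* x0 = X;
  const double* x1 = X + nx;
  for (int i = 0; i < nx; ++i) xd[i] = (x1[i] - x0[i]) / h;
  dynResidual(M, x0, &xd[0], U, &fr[0]);
  double* tail = out + (size_t)(N - 1) * nf;
  for (int i = 6; i < nf; ++i) tail[i - 6] = fr[i];
}

// [[Rcpp::export]]
NumericVector cpp_traj_residual(List model, NumericMatrix X, NumericMatrix U,
                                double h) {
  Model M = parseModel(model);
  int N = X.nrow(), nx = X.ncol(), nu = U.ncol();
  int nf = 2 * M.nd + 2 * M.nmus;
  // transpose to node-major contiguous storage
  std::vector<double> Xv((size_t)N * nx), Uv((size_t)N * nu);
  for (int k = 0; k < N; ++k) {
    for (int i = 0; i < nx; ++i) Xv[(size_t)k * nx + i] = X(k, i);
    for (int i = 0; i < nu; ++i) Uv[(size_t)k * nu + i] = U(k, i);
  }
  NumericVector out((size_t)(N - 1) * nf + nf - 6);
  trajResidual(M, &Xv[0], &Uv[0], N, nx, nu, h, out.begin());
  return out;
}

// Sparse Jacobian of the collocation residual stack w.r.t. the node-major
// variable vector z = (x[0], u[0], x[1], u[1], ...), by central finite
// differences compressed with a 3-coloring over nodes (block k touches only
// nodes k and k+1). Returns 1-based triplets.
// [[Rcpp::export]]
List cpp_traj_jacobian(List model, NumericMatrix X, NumericMatrix U, double h) {
  Model M = parseModel(model);
  int N = X.nrow(), nx = X.ncol(), nu = U.ncol(), nv = nx + nu;
  int nf = 2 * M.nd + 2 * M.nmus;
  size_t nr = (size_t)(N - 1) * nf + nf - 6;
  std::vector<double> Z((size_t)N * nv);
  for (int k = 0; k < N; ++k) {
    for (int i = 0; i < nx; ++i) Z[(size_t)k * nv + i] = X(k, i);
    for (int i = 0; i < nu; ++i) Z[(size_t)k * nv + nx + i] = U(k, i);
  }
  // residual evaluator on Z layout
  std::vector<double> Xv((size_t)N * nx), Uv((size_t)N * nu);
  std::vector<double> rp(nr), rm(nr);
  std::vector<int> ti, tj;
  std::vector<double> tv;
  ti.reserve(nr * 8); tj.reserve(nr * 8); tv.reserve(nr * 8);
  std::vector<double> delk(N);
  for (int color = 0; color < 3; ++color) {
    for (int v = 0; v < nv; ++v) {
      // perturb variable v at all nodes k = color (mod 3)
      for (int sgn = 0; sgn < 2; ++sgn) {
        for (int k = color; k < N; k += 3) {
          double z0 = Z[(size_t)k * nv + v];
          double del = 1e-5 * (std::fabs(z0) > 1 ? std::fabs(z0) : 1.0);
          delk[k] = del;
          Z[(size_t)k * nv + v] = z0 + (sgn == 0 ? del : -del);
        }
        for (int k = 0; k < N; ++k) {
          for (int i = 0; i < nx; ++i) Xv[(size_t)k * nx + i] = Z[(size_t)k * nv + i];
          for (int i = 0; i < nu; ++i) Uv[(size_t)k * nu + i] = Z[(size_t)k * nv + nx + i];
        }
        trajResidual(M, &Xv[0], &Uv[0], N, nx, nu, h, sgn == 0 ? &rp[0] : &rm[0]);
        for (int k = color; k < N; k += 3) {
          // restore
          for (int i = 0; i < nx; ++i) Xv[(size_t)k * nx + i] = X(k, i);
          Z[(size_t)k * nv + v] = (v < nx) ? X(k, v) : U(k, v - nx);
        }
      }
      // attribute compressed differences
      for (int b = 0; b < N - 1; ++b) {
        int n = -1;
        if (v < nx) {
          if (b % 3 == color) n = b;
          else if ((b + 1) % 3 == color) n = b + 1;
        } else {
          if ((b + 1) % 3 == color) n = b + 1;  // block b uses only u[b+1]
        }
        if (n < 0) continue;
        double den = 2.0 * delk[n];
        size_t r0 = (size_t)b * nf;
        int col = n * nv + v + 1;
        for (int r = 0; r < nf; ++r) {
          double val = (rp[r0 + r] - rm[r0 + r]) / den;
          if (val != 0.0) {
            ti.push_back((int)(r0 + r) + 1);
            tj.push_back(col);
            tv.push_back(val);
          }
        }
      }
      // first-node closure block: uses x[0], u[0], x[1]
      int n = -1;
      if (color == 0) n = 0;
      else if (color == 1 && v < nx) n = 1;
      if (n >= 0 && N > n) {
        double den = 2.0 * delk[n];
        size_t r0 = (size_t)(N - 1) * nf;
        int col = n * nv + v + 1;
        for (int r = 0; r < nf - 6; ++r) {
          double val = (rp[r0 + r] - rm[r0 + r]) / den;
          if (val != 0.0) {
            ti.push_back((int)(r0 + r) + 1);
            tj.push_back(col);
            tv.push_back(val);
          }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["v"] = wrap(tv),
                      _["nrow"] = (double)nr, _["ncol"] = (double)(N * nv));
}

// Predicted tracking signals per node: marker coordinates (m) and per-foot
// net GRF (N), plus their Jacobians w.r.t. the node state (central FD).
// [[Rcpp::export]]
List cpp_predicted(List model, NumericMatrix X, bool with_jac) {
  Model M = parseModel(model);
  int N = X.nrow(), nx = X.ncol(), nd = M.nd;
  int nmk = 3 * M.nmark;
  NumericMatrix mk(N, nmk), gr(N, 6);
  NumericVector dmk, dgr;
  if (with_jac) {
    dmk = NumericVector(Dimension(nmk, nd, N));
    dgr = NumericVector(Dimension(6, 2 * nd, N));
  }
  std::vector<double> x(nx);
  Kin K;
  std::vector<V3> P, F;
  double grf[6];
  for (int k = 0; k < N; ++k) {
    for (int i = 0; i < nx; ++i) x[i] = X(k, i);
    computeKin(M, &x[0], &x[nd], NULL, K);
    for (int m = 0; m < M.nmark; ++m) {
      V3 p = K.o[M.mdof[m]] + mul(K.R[M.mdof[m]], M.mloc[m]);
      mk(k, 3 * m) = p.x; mk(k, 3 * m + 1) = p.y; mk(k, 3 * m + 2) = p.z;
    }
    contactForces(M, K, P, F, grf);
    for (int i = 0; i < 6; ++i) gr(k, i) = grf[i];
    if (!with_jac) continue;
    for (int d = 0; d < 2 * nd; ++d) {
      double z0 = x[d];
      double del = 1e-6 * (std::fabs(z0) > 1 ? std::fabs(z0) : 1.0);
      std::vector<double> mp(nmk), mm(nmk), gp(6), gm(6);
      x[d] = z0 + del;
      computeKin(M, &x[0], &x[nd], NULL, K);
      if (d < nd)
        for (int m = 0; m < M.nmark; ++m) {
          V3 p = K.o[M.mdof[m]] + mul(K.R[M.mdof[m]], M.mloc[m]);
          mp[3 * m] = p.x; mp[3 * m + 1] = p.y; mp[3 * m + 2] = p.z;
        }
      contactForces(M, K, P, F, grf);
      for (int i = 0; i < 6; ++i) gp[i] = grf[i];
      x[d] = z0 - del;
      computeKin(M, &x[0], &x[nd], NULL, K);
      if (d < nd)
        for (int m = 0; m < M.nmark; ++m) {
          V3 p = K.o[M.mdof[m]] + mul(K.R[M.mdof[m]], M.mloc[m]);
          mm[3 * m] = p.x; mm[3 * m + 1] = p.y; mm[3 * m + 2] = p.z;
        }
      contactForces(M, K, P, F, grf);
      for (int i = 0; i < 6; ++i) gm[i] = grf[i];
      x[d] = z0;
      if (d < nd)
        for (int r = 0; r < nmk; ++r)
          dmk[(size_t)k * nmk * nd + (size_t)d * nmk + r] = (mp[r] - mm[r]) / (2 * del);
      for (int r = 0; r < 6; ++r)
        dgr[(size_t)k * 12 * nd + (size_t)d * 6 + r] = (gp[r] - gm[r]) / (2 * del);
    }
  }
  if (with_jac)
    return List::create(_["markers"] = mk, _["grf"] = gr, _["dmarkers"] = dmk,
                        _["dgrf"] = dgr);
  return List::create(_["markers"] = mk, _["grf"] = gr);
}

// Inverse dynamics over frames: generalized forces with measured external
// wrenches (no contact model). ext: list per wrench source with fields
// dof (1-based), force/point/moment matrices (N x 3).
// [[Rcpp::export]]
NumericMatrix cpp_inverse_dynamics(List model, NumericMatrix Q, NumericMatrix QD,
                                   NumericMatrix QDD, List ext) {
  Model M = parseModel(model);
  int N = Q.nrow(), nd = M.nd;
  NumericMatrix out(N, nd);
  int nw = ext.size();
  std::vector<int> wdof(nw);
  std::vector<NumericMatrix> WF, WP, WM;
  for (int w = 0; w < nw; ++w) {
    List wl = ext[w];
    wdof[w] = as<int>(wl["dof"]) - 1;
    WF.push_back(as<NumericMatrix>(wl["force"]));
    WP.push_back(as<NumericMatrix>(wl["point"]));
    WM.push_back(as<NumericMatrix>(wl["moment"]));
  }
  std::vector<double> q(nd), qd(nd), qdd(nd), g(nd);
  Kin K;
  for (int k = 0; k < N; ++k) {
    for (int i = 0; i < nd; ++i) { q[i] = Q(k, i); qd[i] = QD(k, i); qdd[i] = QDD(k, i); }
    computeKin(M, &q[0], &qd[0], &qdd[0], K);
    std::vector<ExtWrench> ew(nw);
    for (int w = 0; w < nw; ++w) {
      ew[w].dof = wdof[w];
      ew[w].F = V3(WF[w](k, 0), WF[w](k, 1), WF[w](k, 2));
      ew[w].P = V3(WP[w](k, 0), WP[w](k, 1), WP[w](k, 2));
      ew[w].N = V3(WM[w](k, 0), WM[w](k, 1), WM[w](k, 2));
    }
    rnea(M, K, ew, &g[0]);
    for (int i = 0; i < nd; ++i) out(k, i) = g[i];
  }
  return out;
}

// Net GRF trajectory (N x 6) for states X.
// [[Rcpp::export]]
NumericMatrix cpp_grf_traj(List model, NumericMatrix X) {
  Model M = parseModel(model);
  int N = X.nrow(), nd = M.nd;
  NumericMatrix out(N, 6);
  std::vector<double> x(X.ncol());
  Kin K;
  std::vector<V3> P, F;
  double grf[6];
  for (int k = 0; k < N; ++k) {
    for (int i = 0; i < X.ncol(); ++i) x[i] = X(k, i);
    computeKin(M, &x[0], &x[nd], NULL, K);
    contactForces(M, K, P, F, grf);
    for (int i = 0; i < 6; ++i) out(k, i) = grf[i];
  }
  return out;
}

// Contact point positions and per-point forces over a trajectory, plus
// center of pressure per foot (for synthetic force-plate data).
// [[Rcpp::export]]
List cpp_contact_traj(List model, NumericMatrix X) {
  Model M = parseModel(model);
  int N = X.nrow(), nd = M.nd;
  NumericMatrix grf(N, 6), cop(N, 6), frmom(N, 2);
  std::vector<double> x(X.ncol());
  Kin K;
  std::vector<V3> P, F;
  double g[6];
  for (int k = 0; k < N; ++k) {
    for (int i = 0; i < X.ncol(); ++i) x[i] = X(k, i);
    computeKin(M, &x[0], &x[nd], NULL, K);
    contactForces(M, K, P, F, g);
    for (int i = 0; i < 6; ++i) grf(k, i) = g[i];
    for (int foot = 0; foot < 2; ++foot) {
      double fy = 0, sx = 0, sz = 0, my = 0;
      for (int c = 0; c < M.ncp; ++c) {
        if (M.cfoot[c] != foot) continue;
        fy += F[c].y; sx += F[c].y * P[c].x; sz += F[c].y * P[c].z;
      }
      double cx = fy > 1e-6 ? sx / fy : 0.0, cz = fy > 1e-6 ? sz / fy : 0.0;
      for (int c = 0; c < M.ncp; ++c) {
        if (M.cfoot[c] != foot) continue;
        // vertical free moment about the CoP
        my += (P[c].x - cx) * F[c].z - (P[c].z - cz) * F[c].x;
      }
      cop(k, 3 * foot) = cx; cop(k, 3 * foot + 1) = 0.0; cop(k, 3 * foot + 2) = cz;
      frmom(k, foot) = my;
    }
  }
  return List::create(_["grf"] = grf, _["cop"] = cop, _["free_moment"] = frmom);
}
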