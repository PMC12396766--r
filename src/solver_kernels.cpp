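// Compiled inner loop of the projection solver.
//
// The R layer builds all operators (sparse CSC) and LU factors once per
// grid/time-step; run_phase_block advances the state over the sub-steps of
// one stored phase interval entirely in C++ (Picard-iterated momentum,
// pressure projection, CFL tracking), so the per-step cost is pure linear
// algebra with no interpreter or allocation overhead.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Csc {
  const int *p, *i;
  const double *x;
  int nrow, ncol;
};

Csc unpack(const List &op) {
  Csc m;
  IntegerVector p = op["p"], i = op["i"];
  NumericVector x = op["x"];
  m.p = INTEGER(p); m.i = INTEGER(i); m.x = REAL(x);
  m.nrow = as<int>(op["nrow"]);
  m.ncol = p.size() - 1;
  return m;
}

inline void spmv(const Csc &A, const double *v, double *y) {
  std::fill(y, y + A.nrow, 0.0);
  for (int j = 0; j < A.ncol; ++j) {
    const double vj = v[j];
    if (vj == 0.0) continue;
    for (int k = A.p[j]; k < A.p[j + 1]; ++k) y[A.i[k]] += A.x[k] * vj;
  }
}

inline void spmv_acc(const Csc &A, const double *v, double alpha, double *y) {
  for (int j = 0; j < A.ncol; ++j) {
    const double vj = alpha * v[j];
    if (vj == 0.0) continue;
    for (int k = A.p[j]; k < A.p[j + 1]; ++k) y[A.i[k]] += A.x[k] * vj;
  }
}

struct LuFac {
  Csc L, U;
  const int *pperm, *qperm;   // 1-based permutations from Matrix::expand
  int n;
};

LuFac unpack_lu(const List &f) {
  LuFac F;
  F.L = unpack(as<List>(f["L"]));
  F.U = unpack(as<List>(f["U"]));
  IntegerVector pp = f["pperm"], qp = f["qperm"];
  F.pperm = INTEGER(pp); F.qperm = INTEGER(qp);
  F.n = F.L.nrow;
  return F;
}

// x = Q U^{-1} L^{-1} P b   (A = P' L U Q')
inline void lusolve(const LuFac &F, const double *b, double *x,
                    std::vector<double> &work) {
  double *y = work.data();
  for (int k = 0; k < F.n; ++k) y[k] = b[F.pperm[k] - 1];
  for (int j = 0; j < F.n; ++j) {                    // L: diagonal first
    const int k0 = F.L.p[j], k1 = F.L.p[j + 1];
    y[j] /= F.L.x[k0];
    const double yj = y[j];
    for (int k = k0 + 1; k < k1; ++k) y[F.L.i[k]] -= F.L.x[k] * yj;
  }
  for (int j = F.n - 1; j >= 0; --j) {               // U: diagonal last
    const int k0 = F.U.p[j], k1 = F.U.p[j + 1];
    y[j] /= F.U.x[k1 - 1];
    const double yj = y[j];
    for (int k = k0; k < k1 - 1; ++k) y[F.U.i[k]] -= F.U.x[k] * yj;
  }
  for (int k = 0; k < F.n; ++k) x[F.qperm[k] - 1] = y[k];
}

} // namespace

// [[Rcpp::export]]
List run_phase_block(List ops, List lus, List state, NumericMatrix uin_mat,
                     double dt, double rho, double nu, double tol,
                     int picard_max, double u_ref, double dz,
                     NumericVector deta_u) {
  Csc Lu_E = unpack(as<List>(ops["Eu_L"]));
  Csc Uzm = unpack(as<List>(ops["Uzm"])), Uzp = unpack(as<List>(ops["Uzp"]));
  Csc Euzm = unpack(as<List>(ops["Euzm"])), Euzp = unpack(as<List>(ops["Euzp"]));
  Csc Uem = unpack(as<List>(ops["Uem"])), Uep = unpack(as<List>(ops["Uep"]));
  Csc Vzm = unpack(as<List>(ops["Vzm"])), Vzp = unpack(as<List>(ops["Vzp"]));
  Csc Vem = unpack(as<List>(ops["Vem"])), Vep = unpack(as<List>(ops["Vep"]));
  Csc Ivu = unpack(as<List>(ops["Ivu"])), Iuv = unpack(as<List>(ops["Iuv"]));
  Csc Euv = unpack(as<List>(ops["Euv"]));
  Csc Du = unpack(as<List>(ops["Du"])), Dv = unpack(as<List>(ops["Dv"]));
  Csc Bd = unpack(as<List>(ops["Bd"]));
  Csc Gz = unpack(as<List>(ops["Gz"])), Gr = unpack(as<List>(ops["Gr"]));
  NumericVector a_u = ops["a_u"], Rfu = ops["Rfu"];
  NumericVector a_v = ops["a_v"], Rcv = ops["Rcv"];

  LuFac Mu = unpack_lu(as<List>(lus["Mu"]));
  LuFac Mv = unpack_lu(as<List>(lus["Mv"]));
  LuFac Ap = unpack_lu(as<List>(lus["A"]));

  NumericVector u = clone(as<NumericVector>(state["u"]));
  NumericVector v = clone(as<NumericVector>(state["v"]));
  NumericVector pr = clone(as<NumericVector>(state["p"]));
  NumericVector u_prev = clone(as<NumericVector>(state["u_prev"]));
  NumericVector v_prev = clone(as<NumericVector>(state["v_prev"]));

  const int Nu = u.size(), Nv = v.size(), Np = pr.size();
  const int nsub = uin_mat.ncol();
  const int Nin = uin_mat.nrow();

  std::vector<double> ue(Nu), ve(Nv), us(Nu), vs(Nv);
  std::vector<double> gpz(Nu), gpr(Nv), bu_visc(Nu);
  std::vector<double> v_at_u(Nu), u_at_v(Nv);
  std::vector<double> duz_m(Nu), duz_p(Nu), due_m(Nu), due_p(Nu);
  std::vector<double> dvz_m(Nv), dvz_p(Nv), dve_m(Nv), dve_p(Nv);
  std::vector<double> conv_u(Nu), conv_v(Nv), rhs_u(Nu), rhs_v(Nv);
  std::vector<double> div_star(Np), phi(Np), gphi_u(Nu), gphi_v(Nv);
  std::vector<double> work(std::max(std::max(Nu, Nv), Np));
  std::vector<double> tmp(std::max(std::max(Nu, Nv), Np));

  double cfl_max_blk = 0.0, resid = 0.0;
  int picard_total = 0;
  bool failed = false;
  double t_fail = 0;

  for (int st = 0; st < nsub; ++st) {
    const double *uin1 = &uin_mat(0, st);
    for (int k = 0; k < Nu; ++k) ue[k] = 2 * u[k] - u_prev[k];
    for (int k = 0; k < Nv; ++k) ve[k] = 2 * v[k] - v_prev[k];
    spmv(Gz, REAL(pr), gpz.data());
    for (int k = 0; k < Nu; ++k) gpz[k] /= rho;
    spmv(Gr, REAL(pr), gpr.data());
    for (int k = 0; k < Nv; ++k) gpr[k] /= rho;
    spmv(Lu_E, uin1, bu_visc.data());
    for (int k = 0; k < Nu; ++k) bu_visc[k] *= nu;

    double cfl_here = 0.0;
    resid = R_PosInf;
    int kp = 0;
    for (kp = 0; kp < picard_max; ++kp) {
      // u convection
      spmv(Ivu, ve.data(), v_at_u.data());
      spmv(Uzm, ue.data(), duz_m.data());
      spmv_acc(Euzm, uin1, 1.0, duz_m.data());
      spmv(Uzp, ue.data(), duz_p.data());
      spmv_acc(Euzp, uin1, 1.0, duz_p.data());
      spmv(Uem, ue.data(), due_m.data());
      spmv(Uep, ue.data(), due_p.data());
      double czmax = 0.0, cemax = 0.0;
      for (int k = 0; k < Nu; ++k) {
        const double cz = ue[k];
        const double ce = a_u[k] * ue[k] + v_at_u[k] / Rfu[k];
        conv_u[k] = cz * (cz >= 0 ? duz_m[k] : duz_p[k]) +
                    ce * (ce >= 0 ? due_m[k] : due_p[k]);
        if (std::abs(cz) > czmax) czmax = std::abs(cz);
        const double cscl = std::abs(ce) / deta_u[k];
        if (cscl > cemax) cemax = cscl;
      }
      cfl_here = dt * std::max(czmax / dz, cemax);
      // v convection
      spmv(Iuv, ue.data(), u_at_v.data());
      spmv_acc(Euv, uin1, 1.0, u_at_v.data());
      spmv(Vzm, ve.data(), dvz_m.data());
      spmv(Vzp, ve.data(), dvz_p.data());
      spmv(Vem, ve.data(), dve_m.data());
      spmv(Vep, ve.data(), dve_p.data());
      for (int k = 0; k < Nv; ++k) {
        const double cz = u_at_v[k];
        const double ce = a_v[k] * u_at_v[k] + ve[k] / Rcv[k];
        conv_v[k] = cz * (cz >= 0 ? dvz_m[k] : dvz_p[k]) +
                    ce * (ce >= 0 ? dve_m[k] : dve_p[k]);
      }
      for (int k = 0; k < Nu; ++k)
        rhs_u[k] = u[k] / dt - conv_u[k] - gpz[k] + bu_visc[k];
      for (int k = 0; k < Nv; ++k)
        rhs_v[k] = v[k] / dt - conv_v[k] - gpr[k];
      lusolve(Mu, rhs_u.data(), us.data(), work);
      lusolve(Mv, rhs_v.data(), vs.data(), work);
      double d = 0.0;
      for (int k = 0; k < Nu; ++k) d = std::max(d, std::abs(us[k] - ue[k]));
      for (int k = 0; k < Nv; ++k) d = std::max(d, std::abs(vs[k] - ve[k]));
      resid = d / u_ref;
      std::copy(us.begin(), us.end(), ue.begin());
      std::copy(vs.begin(), vs.end(), ve.begin());
      if (resid < tol) break;
    }
    picard_total += kp + 1;
    if (resid >= tol) { failed = true; t_fail = st; break; }
    // projection
    spmv(Du, ue.data(), div_star.data());
    spmv_acc(Dv, ve.data(), 1.0, div_star.data());
    spmv_acc(Bd, uin1, 1.0, div_star.data());
    for (int k = 0; k < Np; ++k) tmp[k] = div_star[k] * rho / dt;
    lusolve(Ap, tmp.data(), phi.data(), work);
    spmv(Gz, phi.data(), gphi_u.data());
    spmv(Gr, phi.data(), gphi_v.data());
    for (int k = 0; k < Nu; ++k) {
      u_prev[k] = u[k];
      u[k] = ue[k] - (dt / rho) * gphi_u[k];
    }
    for (int k = 0; k < Nv; ++k) {
      v_prev[k] = v[k];
      v[k] = ve[k] - (dt / rho) * gphi_v[k];
    }
    for (int k = 0; k < Np; ++k) pr[k] += phi[k];
    if (cfl_here > cfl_max_blk) cfl_max_blk = cfl_here;
  }

  return List::create(
    _["u"] = u, _["v"] = v, _["p"] = pr,
    _["u_prev"] = u_prev, _["v_prev"] = v_prev,
    _["cfl"] = cfl_max_blk, _["resid"] = resid,
    _["picard_mean"] = double(picard_total) / nsub,
    _["failed"] = failed, _["fail_step"] = t_fail);
}

// standalone kernels used by the R-side wrappers (setup, diagnostics)

// [[Rcpp::export]]
NumericVector spmv_csc(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                       int nrow, NumericVector v) {
  NumericVector y(nrow);
  const int ncol = Ap.size() - 1;
  for (int j = 0; j < ncol; ++j) {
    const double vj = v[j];
    if (vj == 0.0) continue;
    for (int k = Ap[j]; k < Ap[j + 1]; ++k) y[Ai[k]] += Ax[k] * vj;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector trsolve_lower_csc(IntegerVector Lp, IntegerVector Li,
                                NumericVector Lx, NumericVector b) {
  NumericVector y = clone(b);
  const int n = Lp.size() - 1;
  for (int j = 0; j < n; ++j) {
    const int k0 = Lp[j], k1 = Lp[j + 1];
    y[j] /= Lx[k0];
    const double yj = y[j];
    for (int k = k0 + 1; k < k1; ++k) y[Li[k]] -= Lx[k] * yj;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector trsolve_upper_csc(IntegerVector Up, IntegerVector Ui,
                                NumericVector Ux, NumericVector b) {
  NumericVector y = clone(b);
  const int n = Up.size() - 1;
  for (int j = n - 1; j >= 0; --j) {
    const int k0 = Up[j], k1 = Up[j + 1];
    y[j] /= Ux[k1 - 1];
    const double yj = y[j];
    for (int k = k0; k < k1 - 1; ++k) y[Ui[k]] -= Ux[k] * yj;
  }
  return y;
}

// divergence residual helper: max |Du u + Dv v + Bd uin|
// [[Rcpp::export]]
double div_residual(List ops, NumericVector u, NumericVector v,
                    NumericVector uin) {
  Csc Du = unpack(as<List>(ops["Du"])), Dv = unpack(as<List>(ops["Dv"]));
  Csc Bd = unpack(as<List>(ops["Bd"]));
  std::vector<double> d(Du.nrow);
  spmv(Du, REAL(u), d.data());
  spmv_acc(Dv, REAL(v), 1.0, d.data());
  spmv_acc(Bd, REAL(uin), 1.0, d.data());
  double m = 0;
  for (int k = 0; k < Du.nrow; ++k) m = std::max(m, std::abs(d[k]));
  return m;
}
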