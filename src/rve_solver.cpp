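// Core numerical kernels: fiber constitutive law, RVE Newton equilibrium,
// affine-boundary stress/tangent evaluation, and a normalized
// cross-correlation matcher for the bead tracker.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Exponential fiber force F(lambda) = EfAf/B (exp(B*eps) - 1),
// eps = 0.5 (lambda^2 - 1). Small-B branch avoids 0/0.
// exponent clamp keeps trial states finite when a line search probes an
// extreme stretch; any such state is rejected anyway
static inline double clamp_exp(double x) { return x > 200.0 ? 200.0 : x; }

static inline double fib_force(double lam, double EfAf, double B) {
  double eps = 0.5 * (lam * lam - 1.0);
  if (B < 1e-8) return EfAf * eps;
  return EfAf / B * (std::exp(clamp_exp(B * eps)) - 1.0);
}

// dF/dlambda
static inline double fib_dforce(double lam, double EfAf, double B) {
  double eps = 0.5 * (lam * lam - 1.0);
  if (B < 1e-8) return EfAf * lam;
  return EfAf * std::exp(clamp_exp(B * eps)) * lam;
}

// Strain energy of one fiber, relative to lambda = 1:
// W = L0 * int_1^lam F(s) ds, by 8-point Gauss-Legendre.
static const double GL8_X[8] = {
  -0.9602898564975363, -0.7966664774136267, -0.5255324099163290,
  -0.1834346424956498,  0.1834346424956498,  0.5255324099163290,
   0.7966664774136267,  0.9602898564975363 };
static const double GL8_W[8] = {
   0.1012285362903763, 0.2223810344533745, 0.3137066458778873,
   0.3626837833783620, 0.3626837833783620, 0.3137066458778873,
   0.2223810344533745, 0.1012285362903763 };

static inline double fib_energy(double lam, double L0, double EfAf, double B) {
  double a = 1.0, b = lam;
  double mid = 0.5 * (a + b), half = 0.5 * (b - a);
  double s = 0.0;
  for (int k = 0; k < 8; ++k)
    s += GL8_W[k] * fib_force(mid + half * GL8_X[k], EfAf, B);
  return L0 * half * s;
}

struct Network {
  arma::mat pos;        // n x 3, current positions (boundary rows fixed)
  const arma::umat& fib; // m x 2, 0-based
  const arma::vec& L0;
  const arma::uvec& interior; // indices of interior nodes
  arma::ivec int_of;    // node index -> interior slot (or -1)
  Network(arma::mat p, const arma::umat& f, const arma::vec& l,
          const arma::uvec& inter)
    : pos(std::move(p)), fib(f), L0(l), interior(inter) {
    int_of.set_size(pos.n_rows);
    int_of.fill(-1);
    for (arma::uword k = 0; k < interior.n_elem; ++k)
      int_of(interior(k)) = (int)k;
  }
};

// Nodal forces from all fibers; returns total energy.
static double assemble_forces(const Network& net, double EfAf, double B,
                              arma::mat& g) {
  g.zeros(net.pos.n_rows, 3);
  double E = 0.0;
  for (arma::uword f = 0; f < net.fib.n_rows; ++f) {
    arma::uword i = net.fib(f, 0), j = net.fib(f, 1);
    arma::rowvec d = net.pos.row(j) - net.pos.row(i);
    double l = arma::norm(d);
    if (l < 1e-300) continue;
    double lam = l / net.L0(f);
    double F = fib_force(lam, EfAf, B);
    arma::rowvec u = d / l;
    g.row(i) += F * u;
    g.row(j) -= F * u;
    E += fib_energy(lam, net.L0(f), EfAf, B);
  }
  return E;
}

// Tangent stiffness on interior DOF (dense, 3*ni x 3*ni).
static void assemble_tangent(const Network& net, double EfAf, double B,
                             arma::mat& K) {
  arma::uword ni = net.interior.n_elem;
  K.zeros(3 * ni, 3 * ni);
  arma::mat33 kf;
  for (arma::uword f = 0; f < net.fib.n_rows; ++f) {
    arma::uword i = net.fib(f, 0), j = net.fib(f, 1);
    int si = net.int_of(i), sj = net.int_of(j);
    if (si < 0 && sj < 0) continue;
    arma::vec d = (net.pos.row(j) - net.pos.row(i)).t();
    double l = arma::norm(d);
    if (l < 1e-300) continue;
    double lam = l / net.L0(f);
    arma::vec u = d / l;
    double kt = fib_dforce(lam, EfAf, B) / net.L0(f);
    double Fl = fib_force(lam, EfAf, B) / l;
    kf = kt * (u * u.t()) + Fl * (arma::eye(3, 3) - u * u.t());
    if (si >= 0) K.submat(3 * si, 3 * si, 3 * si + 2, 3 * si + 2) += kf;
    if (sj >= 0) K.submat(3 * sj, 3 * sj, 3 * sj + 2, 3 * sj + 2) += kf;
    if (si >= 0 && sj >= 0) {
      K.submat(3 * si, 3 * sj, 3 * si + 2, 3 * sj + 2) -= kf;
      K.submat(3 * sj, 3 * si, 3 * sj + 2, 3 * si + 2) -= kf;
    }
  }
}

static double max_interior_residual(const Network& net, const arma::mat& g) {
  double r = 0.0;
  for (arma::uword k = 0; k < net.interior.n_elem; ++k) {
    double n = arma::norm(g.row(net.interior(k)));
    if (n > r) r = n;
  }
  return r;
}

// Newton with backtracking line search on total fiber energy.
// Returns convergence flag; fills residual history.
static bool rve_newton(Network& net, double EfAf, double B, double tol,
                       int maxit, double& resid, int& iters,
                       std::vector<double>& hist) {
  arma::uword ni = net.interior.n_elem;
  arma::mat g;
  double E = assemble_forces(net, EfAf, B, g);
  resid = max_interior_residual(net, g);
  hist.push_back(resid);
  iters = 0;
  if (ni == 0 || resid <= tol) return true;
  arma::mat K;
  for (int it = 0; it < maxit; ++it) {
    iters = it + 1;
    assemble_tangent(net, EfAf, B, K);
    arma::vec r(3 * ni);
    for (arma::uword k = 0; k < ni; ++k)
      r.subvec(3 * k, 3 * k + 2) = g.row(net.interior(k)).t();
    // pin-jointed networks have mechanism modes at the stress-free state
    // (geometric stiffness vanishes at lambda = 1), so the tangent is
    // always slightly damped; escalate if factorization still fails
    double kscale = arma::abs(K.diag()).max();
    if (!(kscale > 0.0)) kscale = 1.0;
    arma::vec du;
    double mu = 1e-10 * kscale;
    bool ok = false;
    for (int t = 0; t < 10 && !(ok && du.is_finite()); ++t, mu *= 100.0)
      ok = arma::solve(du, K + mu * arma::eye(3 * ni, 3 * ni), r,
                       arma::solve_opts::no_approx);
    if (!ok || !du.is_finite()) return false;
    // cap the largest nodal move per iteration (RVE-local units)
    double mxmove = 0.0;
    for (arma::uword k = 0; k < ni; ++k) {
      double m = arma::norm(du.subvec(3 * k, 3 * k + 2));
      if (m > mxmove) mxmove = m;
    }
    if (mxmove > 0.2) du *= 0.2 / mxmove;
    // line search: accept step that lowers energy or residual
    arma::mat pos_old = net.pos;
    double alpha = 1.0;
    double E_new = E, res_new = resid;
    bool accepted = false;
    for (int ls = 0; ls < 40; ++ls) {
      net.pos = pos_old;
      for (arma::uword k = 0; k < ni; ++k)
        net.pos.row(net.interior(k)) += alpha * du.subvec(3 * k, 3 * k + 2).t();
      E_new = assemble_forces(net, EfAf, B, g);
      res_new = max_interior_residual(net, g);
      if (std::isfinite(E_new) && std::isfinite(res_new) &&
          (E_new <= E + 1e-14 * std::abs(E) || res_new < resid)) {
        accepted = true;
        break;
      }
      alpha *= 0.5;
    }
    if (!accepted) { net.pos = pos_old; assemble_forces(net, EfAf, B, g); return false; }
    E = E_new;
    resid = res_new;
    hist.push_back(resid);
    if (resid <= tol) return true;
  }
  return resid <= tol;
}

static arma::uvec interior_idx(const LogicalVector& is_bnd) {
  std::vector<arma::uword> v;
  for (int i = 0; i < is_bnd.size(); ++i)
    if (!is_bnd[i]) v.push_back((arma::uword)i);
  return arma::uvec(v);
}

static arma::uvec boundary_idx(const LogicalVector& is_bnd) {
  std::vector<arma::uword> v;
  for (int i = 0; i < is_bnd.size(); ++i)
    if (is_bnd[i]) v.push_back((arma::uword)i);
  return arma::uvec(v);
}

// Solve interior equilibrium with prescribed boundary positions.
// fibers are 1-based (R convention). bnd_pos rows follow the order of
// boundary nodes as they appear in node order.
// [[Rcpp::export]]
List cpp_rve_solve(NumericMatrix pos0, IntegerMatrix fibers,
                   NumericVector L0, LogicalVector is_bnd,
                   NumericMatrix bnd_pos, double EfAf, double B,
                   double tol, int maxit,
                   Nullable<NumericMatrix> pos_init = R_NilValue) {
  arma::mat P = as<arma::mat>(pos0);
  arma::umat fib = arma::conv_to<arma::umat>::from(as<arma::imat>(fibers) - 1);
  arma::vec l0 = as<arma::vec>(L0);
  arma::uvec inter = interior_idx(is_bnd);
  arma::uvec bnd = boundary_idx(is_bnd);
  arma::mat start = pos_init.isNotNull() ? as<arma::mat>(pos_init.get()) : P;
  Network net(start, fib, l0, inter);
  arma::mat bp = as<arma::mat>(bnd_pos);
  for (arma::uword k = 0; k < bnd.n_elem; ++k)
    net.pos.row(bnd(k)) = bp.row(k);
  double resid; int iters; std::vector<double> hist;
  bool conv = rve_newton(net, EfAf, B, tol, maxit, resid, iters, hist);
  arma::mat g;
  double E = assemble_forces(net, EfAf, B, g);
  // reaction force on a boundary node = -(net fiber force on it)
  arma::mat bf(bnd.n_elem, 3);
  for (arma::uword k = 0; k < bnd.n_elem; ++k)
    bf.row(k) = -g.row(bnd(k));
  return List::create(_["pos"] = net.pos, _["boundary_forces"] = bf,
                      _["residual"] = resid, _["converged"] = conv,
                      _["iterations"] = iters, _["energy"] = E,
                      _["residual_history"] = hist);
}

// Affine-boundary solve: boundary nodes at c + F (X - c); returns the raw
// Eq-2 sum S_ij = sum_b x_i F_j (local units), per-fiber signed forces,
// and optionally the finite-difference tangent dS/dF (9x9, column-major
// pairing (i,j) -> 3*(j-1)+i as in R's matrix layout).
// [[Rcpp::export]]
List cpp_rve_affine(NumericMatrix pos0, IntegerMatrix fibers,
                    NumericVector L0, LogicalVector is_bnd,
                    NumericMatrix Fmat, NumericVector center,
                    double EfAf, double B, double tol, int maxit,
                    Nullable<NumericMatrix> pos_init = R_NilValue,
                    bool want_tangent = false, double fd_step = 1e-6) {
  arma::mat P0 = as<arma::mat>(pos0);
  arma::umat fib = arma::conv_to<arma::umat>::from(as<arma::imat>(fibers) - 1);
  arma::vec l0 = as<arma::vec>(L0);
  arma::uvec inter = interior_idx(is_bnd);
  arma::uvec bnd = boundary_idx(is_bnd);
  arma::mat33 F = as<arma::mat>(Fmat);
  arma::vec c = as<arma::vec>(center);

  arma::mat start = pos_init.isNotNull() ? as<arma::mat>(pos_init.get()) : P0;

  auto solve_at = [&](const arma::mat33& Fc, const arma::mat& init,
                      arma::mat& pos_out, arma::mat33& S, bool& conv,
                      double& resid, int& iters, std::vector<double>& hist,
                      arma::vec* ff, arma::mat* bf) {
    Network net(init, fib, l0, inter);
    for (arma::uword k = 0; k < bnd.n_elem; ++k)
      net.pos.row(bnd(k)) = c.t() + (Fc * (P0.row(bnd(k)).t() - c)).t();
    conv = rve_newton(net, EfAf, B, tol, maxit, resid, iters, hist);
    arma::mat g;
    assemble_forces(net, EfAf, B, g);
    S.zeros();
    for (arma::uword k = 0; k < bnd.n_elem; ++k) {
      arma::vec x = net.pos.row(bnd(k)).t();
      arma::vec Fb = -g.row(bnd(k)).t();
      S += x * Fb.t();
      if (bf) bf->row(k) = Fb.t();
    }
    if (ff) {
      ff->set_size(fib.n_rows);
      for (arma::uword f = 0; f < fib.n_rows; ++f) {
        double l = arma::norm(net.pos.row(fib(f, 1)) - net.pos.row(fib(f, 0)));
        (*ff)(f) = fib_force(l / l0(f), EfAf, B);
      }
    }
    pos_out = net.pos;
  };

  arma::mat pos_out; arma::mat33 S; bool conv; double resid; int iters;
  std::vector<double> hist;
  arma::vec ff;
  arma::mat bf(bnd.n_elem, 3);
  solve_at(F, start, pos_out, S, conv, resid, iters, hist, &ff, &bf);

  List out = List::create(_["S"] = arma::mat(S), _["pos"] = pos_out,
                          _["converged"] = conv, _["residual"] = resid,
                          _["iterations"] = iters,
                          _["fiber_forces"] = ff,
                          _["boundary_forces"] = bf);
  if (want_tangent) {
    arma::mat A(9, 9);
    for (int jj = 0; jj < 3; ++jj)
      for (int ii = 0; ii < 3; ++ii) {
        arma::mat33 Fp = F;
        Fp(ii, jj) += fd_step;
        arma::mat pos_p; arma::mat33 Sp; bool cv; double rs; int itn;
        std::vector<double> h2;
        solve_at(Fp, pos_out, pos_p, Sp, cv, rs, itn, h2, nullptr, nullptr);
        arma::mat33 dS = (Sp - S) / fd_step;
        A.col(3 * jj + ii) = arma::vectorise(dS);
      }
    out["tangent"] = A;
  }
  return out;
}

// Normalized cross-correlation of a template against every valid placement
// inside a search window. Returns (wr-tr+1) x (wc-tc+1) correlation map.
// [[Rcpp::export]]
NumericMatrix cpp_ncc(NumericMatrix window, NumericMatrix templ) {
  int wr = window.nrow(), wc = window.ncol();
  int tr = templ.nrow(), tc = templ.ncol();
  int orow = wr - tr + 1, ocol = wc - tc + 1;
  if (orow < 1 || ocol < 1) stop("template larger than search window");
  int n = tr * tc;
  double tmean = 0.0;
  for (int j = 0; j < tc; ++j)
    for (int i = 0; i < tr; ++i) tmean += templ(i, j);
  tmean /= n;
  double tss = 0.0;
  std::vector<double> tz(n);
  for (int j = 0; j < tc; ++j)
    for (int i = 0; i < tr; ++i) {
      double v = templ(i, j) - tmean;
      tz[j * tr + i] = v;
      tss += v * v;
    }
  NumericMatrix out(orow, ocol);
  for (int oj = 0; oj < ocol; ++oj)
    for (int oi = 0; oi < orow; ++oi) {
      double wmean = 0.0;
      for (int j = 0; j < tc; ++j)
        for (int i = 0; i < tr; ++i) wmean += window(oi + i, oj + j);
      wmean /= n;
      double num = 0.0, wss = 0.0;
      for (int j = 0; j < tc; ++j)
        for (int i = 0; i < tr; ++i) {
          double wv = window(oi + i, oj + j) - wmean;
          num += wv * tz[j * tr + i];
          wss += wv * wv;
        }
      double den = std::sqrt(wss * tss);
      out(oi, oj) = den > 1e-12 ? num / den : 0.0;
    }
  return out;
}

// Exposed for unit tests of the constitutive law's compiled path.
// [[Rcpp::export]]
NumericVector cpp_fiber_force(NumericVector lambda, double EfAf, double B) {
  NumericVector out(lambda.size());
  for (int i = 0; i < lambda.size(); ++i)
    out[i] = fib_force(lambda[i], EfAf, B);
  return out;
}
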