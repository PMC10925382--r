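#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft(double x, double lambda) {
  if (x > lambda) return x - lambda;
  if (x < -lambda) return x + lambda;
  return 0.0;
}

// One coordinate update; returns |change|. g = C*beta is kept in sync.
static inline double cd_update(const arma::mat& C, const arma::vec& d,
                               double lambda, arma::uword j,
                               arma::vec& beta, arma::vec& g) {
  const double cjj = C(j, j);
  const double resid = d(j) - (g(j) - cjj * beta(j));
  const double bj = soft(resid, lambda) / cjj;
  const double diff = bj - beta(j);
  if (diff != 0.0) {
    beta(j) = bj;
    g += diff * C.col(j);
  }
  return std::abs(diff);
}

// Coordinate descent with active-set cycling: full sweeps establish the
// active set, inner sweeps iterate over it until stable, and convergence
// is declared only when a full sweep moves every coordinate by < tol.
// Returns sweeps used (negative if the sweep budget ran out).
static int cd_solve(const arma::mat& C, const arma::vec& d, double lambda,
                    arma::vec& beta, arma::vec& g, double tol,
                    int max_sweeps) {
  const arma::uword m = d.n_elem;
  std::vector<arma::uword> active;
  int sweeps = 0;
  while (sweeps < max_sweeps) {
    double delta = 0.0;
    active.clear();
    for (arma::uword j = 0; j < m; ++j) {
      const double a = cd_update(C, d, lambda, j, beta, g);
      if (a > delta) delta = a;
      if (beta(j) != 0.0) active.push_back(j);
    }
    ++sweeps;
    if (delta < tol) return sweeps;
    while (sweeps < max_sweeps) {
      double da = 0.0;
      for (arma::uword idx = 0; idx < active.size(); ++idx) {
        const double a = cd_update(C, d, lambda, active[idx], beta, g);
        if (a > da) da = a;
      }
      ++sweeps;
      if (da < tol) break;
    }
  }
  return -sweeps;
}

// Solve  min_beta 0.5 beta' C beta - d' beta + lambda ||beta||_1
// for symmetric C with strictly positive diagonal.
// [[Rcpp::export]]
List gram_lasso_cd(const arma::mat& C, const arma::vec& d, double lambda,
                   arma::vec beta, double tol = 1e-8, int max_sweeps = 10000) {
  arma::vec g = C * beta;
  const int sweeps = cd_solve(C, d, lambda, beta, g, tol, max_sweeps);
  return List::create(_["beta"] = beta,
                      _["sweeps"] = std::abs(sweeps),
                      _["converged"] = sweeps > 0,
                      _["max_change"] = NA_REAL);
}

// Warm-started solution path over a decreasing lambda sequence.
// Returns an m x n_lambda matrix of coefficient vectors.
// [[Rcpp::export]]
arma::mat gram_lasso_path(const arma::mat& C, const arma::vec& d,
                          const arma::vec& lambdas, double tol = 1e-8,
                          int max_sweeps = 10000) {
  const arma::uword m = d.n_elem;
  const arma::uword L = lambdas.n_elem;
  arma::mat out(m, L, arma::fill::zeros);
  arma::vec beta(m, arma::fill::zeros);
  arma::vec g(m, arma::fill::zeros);
  for (arma::uword l = 0; l < L; ++l) {
    cd_solve(C, d, lambdas(l), beta, g, tol, max_sweeps);
    out.col(l) = beta;
  }
  return out;
}

// Cyclic coordinate ascent for the knockoff slack program
//   max sum(s)  s.t.  0 <= s_j <= ub_j,  diag(s) <= target  (PSD order).
// Maintains A = target - diag(s) and its inverse; the coordinate-wise
// maximum is s_j <= s_j + 1/(A^{-1})_jj, approached with a 1e-6 relative
// back-off so A stays positive definite throughout.
// [[Rcpp::export]]
arma::vec solve_s_sdp_cd(const arma::mat& target, const arma::vec& ub,
                         double tol = 1e-5, int max_sweeps = 100) {
  const arma::uword p = ub.n_elem;
  arma::mat A = target;
  // guarantee strict positive definiteness for the initial inverse
  const double ridge = 1e-8 * arma::mean(A.diag());
  A.diag() += ridge;
  arma::mat Ainv;
  if (!arma::inv_sympd(Ainv, A)) {
    Rcpp::stop("initial slack matrix is not invertible");
  }
  arma::vec s(p, arma::fill::zeros);
  const double backoff = 1.0 - 1e-6;
  const double scale = std::max(ub.max(), 1.0);
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    // damped steps early on, so that no coordinate greedily exhausts the
    // joint PSD slack before the others have grown (full steps once the
    // iterate has settled)
    const double step = (sweep < 20) ? 0.5 : backoff;
    double delta = 0.0;
    for (arma::uword j = 0; j < p; ++j) {
      const double a = Ainv(j, j);
      if (!(a > 0.0)) return s;  // at the PSD boundary: stop here
      const double cap = s(j) + step / a;
      const double s_new = std::min(ub(j), cap);
      const double diff = s_new - s(j);
      if (diff > 0.0) {
        s(j) = s_new;
        const arma::vec u = Ainv.col(j);
        Ainv += (diff / (1.0 - diff * a)) * (u * u.t());
        A(j, j) -= diff;
        if (diff > delta) delta = diff;
      }
    }
    // refresh the inverse to curb Sherman-Morrison drift; a failure means
    // a constraint is numerically tight, so keep the feasible iterate
    arma::mat A_reg = A;
    A_reg.diag() += ridge;
    if (!arma::inv_sympd(Ainv, A_reg)) break;
    if (delta < tol * scale) break;
  }
  return s;
}
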