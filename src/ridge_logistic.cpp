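// Penalized logistic regression and recursive feature elimination kernels.
//
// The stability-consensus selection runs RFE hundreds of times per round, so
// the Newton solver and the elimination sweep live here. The objective is
//
//   f(b0, b) = sum_i w_i * [ -y_i * eta_i + log(1 + exp(eta_i)) ]
//              + (lambda / 2) * ||b||^2,        eta_i = b0 + x_i' b
//
// with the intercept unpenalized. Damped Newton iterations; with lambda > 0
// the problem is strictly convex in b, so convergence is guaranteed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

static double logistic_obj(const mat& X, const vec& y, const vec& w,
                           double b0, const vec& beta, double lambda) {
  vec eta = b0 + X * beta;
  // log(1 + exp(eta)) computed stably
  vec lse(eta.n_elem);
  for (arma::uword i = 0; i < eta.n_elem; ++i) {
    double e = eta[i];
    lse[i] = (e > 30.0) ? e : std::log1p(std::exp(e));
  }
  return arma::dot(w, lse - y % eta) + 0.5 * lambda * arma::dot(beta, beta);
}

// Newton fit. Returns b0, beta, converged flag, final gradient inf-norm.
static void newton_fit(const mat& X, const vec& y, const vec& w,
                       double lambda, double tol, int maxit,
                       double& b0, vec& beta, bool& converged, double& gnorm) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  b0 = 0.0;
  beta.zeros(p);
  converged = false;
  double f = logistic_obj(X, y, w, b0, beta, lambda);
  for (int it = 0; it < maxit; ++it) {
    vec eta = b0 + X * beta;
    vec mu = 1.0 / (1.0 + arma::exp(-eta));
    vec r = w % (mu - y);
    vec g = X.t() * r + lambda * beta;       // gradient wrt beta
    double g0 = arma::accu(r);               // gradient wrt intercept
    gnorm = std::max(std::abs(g0), g.is_empty() ? 0.0 : arma::abs(g).max());
    if (gnorm < tol) { converged = true; return; }
    vec wt = w % mu % (1.0 - mu);
    wt.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    // (p+1) x (p+1) Hessian with intercept in slot 0
    mat H(p + 1, p + 1);
    H(0, 0) = arma::accu(wt);
    vec xw = X.t() * wt;
    H(arma::span(1, p), 0) = xw;
    H(0, arma::span(1, p)) = xw.t();
    H(arma::span(1, p), arma::span(1, p)) =
        X.t() * (X.each_col() % wt) + lambda * arma::eye(p, p);
    vec grad(p + 1);
    grad[0] = g0;
    grad.subvec(1, p) = g;
    vec step;
    if (!arma::solve(step, H, grad, arma::solve_opts::likely_sympd)) {
      arma::solve(step, H + 1e-8 * arma::eye(p + 1, p + 1), grad);
    }
    // backtracking on the objective
    double t = 1.0;
    for (int ls = 0; ls < 40; ++ls) {
      double nb0 = b0 - t * step[0];
      vec nbeta = beta - t * step.subvec(1, p);
      double nf = logistic_obj(X, y, w, nb0, nbeta, lambda);
      if (nf <= f + 1e-12 * std::abs(f) || t < 1e-10) {
        b0 = nb0; beta = nbeta; f = nf;
        break;
      }
      t *= 0.5;
    }
    (void)n;
  }
  // final gradient check
  vec eta = b0 + X * beta;
  vec mu = 1.0 / (1.0 + arma::exp(-eta));
  vec r = w % (mu - y);
  vec g = X.t() * r + lambda * beta;
  double g0 = arma::accu(r);
  gnorm = std::max(std::abs(g0), g.is_empty() ? 0.0 : arma::abs(g).max());
  converged = gnorm < tol;
}

static vec balanced_weights(const vec& y) {
  double n = static_cast<double>(y.n_elem);
  double n1 = arma::accu(y), n0 = n - n1;
  vec w(y.n_elem);
  for (arma::uword i = 0; i < y.n_elem; ++i)
    w[i] = (y[i] > 0.5) ? n / (2.0 * n1) : n / (2.0 * n0);
  return w;
}

// [[Rcpp::export(name = ".ridge_logistic_cpp")]]
List ridge_logistic_cpp(const arma::mat& X, const arma::vec& y,
                        double lambda, bool balanced,
                        double tol = 1e-8, int maxit = 100) {
  vec w = balanced ? balanced_weights(y) : vec(y.n_elem, arma::fill::ones);
  double b0, gnorm;
  vec beta;
  bool conv;
  newton_fit(X, y, w, lambda, tol, maxit, b0, beta, conv, gnorm);
  return List::create(_["intercept"] = b0,
                      _["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["converged"] = conv,
                      _["grad_norm"] = gnorm);
}

// Mean held-out accuracy across folds for one lambda, on the given columns.
static double cv_accuracy(const mat& X, const vec& y, const arma::ivec& foldid,
                          double lambda, bool balanced, double tol, int maxit) {
  int nfold = foldid.max() + 1;
  double acc_sum = 0.0;
  for (int k = 0; k < nfold; ++k) {
    uvec tr = arma::find(foldid != k);
    uvec te = arma::find(foldid == k);
    mat Xtr = X.rows(tr);
    vec ytr = y.elem(tr);
    vec w = balanced ? balanced_weights(ytr) : vec(ytr.n_elem, arma::fill::ones);
    double b0, gnorm; vec beta; bool conv;
    newton_fit(Xtr, ytr, w, lambda, tol, maxit, b0, beta, conv, gnorm);
    vec eta = b0 + X.rows(te) * beta;
    vec yte = y.elem(te);
    double correct = 0.0;
    for (arma::uword i = 0; i < te.n_elem; ++i)
      if ((eta[i] > 0.0) == (yte[i] > 0.5)) correct += 1.0;
    acc_sum += correct / static_cast<double>(te.n_elem);
  }
  return acc_sum / static_cast<double>(nfold);
}

// [[Rcpp::export(name = ".cv_accuracy_cpp")]]
NumericVector cv_accuracy_cpp(const arma::mat& X, const arma::vec& y,
                              const arma::ivec& foldid,
                              const arma::vec& lambda_grid, bool balanced,
                              double tol = 1e-8, int maxit = 100) {
  NumericVector out(lambda_grid.n_elem);
  for (arma::uword l = 0; l < lambda_grid.n_elem; ++l)
    out[l] = cv_accuracy(X, y, foldid, lambda_grid[l], balanced, tol, maxit);
  return out;
}

// Recursive feature elimination with internal CV model selection.
//
// Columns of X must already be ordered lexicographically by feature id so the
// tie-break "smallest |weight|, then lexicographic id" is the (|beta|, index)
// sort. foldid (0-based) is drawn once by the caller and reused at every size.
// Returns accuracy per size, the surviving column indices (1-based) at each
// size, and the selected size: the smallest whose accuracy is within 1e-12 of
// the maximum.
// [[Rcpp::export(name = ".rfe_cpp")]]
List rfe_cpp(const arma::mat& X, const arma::vec& y, const arma::ivec& foldid,
             const arma::vec& lambda_grid, double step_fraction, bool balanced,
             double tol = 1e-8, int maxit = 100) {
  uvec active = arma::regspace<uvec>(0, X.n_cols - 1);
  std::vector<int> sizes;
  std::vector<double> accs, lambdas;
  std::vector<std::vector<int>> sets;
  std::vector<int> elim_order;  // eliminated features, first-out first
  while (true) {
    mat Xa = X.cols(active);
    // lambda by internal CV; ties resolved toward the larger lambda
    double best_acc = -1.0, best_lambda = lambda_grid[0];
    for (arma::uword l = 0; l < lambda_grid.n_elem; ++l) {
      double a = cv_accuracy(Xa, y, foldid, lambda_grid[l], balanced, tol, maxit);
      if (a > best_acc + 1e-12 ||
          (std::abs(a - best_acc) <= 1e-12 && lambda_grid[l] > best_lambda)) {
        best_acc = a;
        best_lambda = lambda_grid[l];
      }
    }
    vec w = balanced ? balanced_weights(y) : vec(y.n_elem, arma::fill::ones);
    double b0, gnorm; vec beta; bool conv;
    newton_fit(Xa, y, w, best_lambda, tol, maxit, b0, beta, conv, gnorm);
    sizes.push_back(static_cast<int>(active.n_elem));
    accs.push_back(best_acc);
    lambdas.push_back(best_lambda);
    std::vector<int> cur(active.n_elem);
    for (arma::uword i = 0; i < active.n_elem; ++i)
      cur[i] = static_cast<int>(active[i]) + 1;
    sets.push_back(cur);
    if (active.n_elem == 1) break;
    int drop = static_cast<int>(
        std::ceil(step_fraction * static_cast<double>(active.n_elem)));
    if (drop < 1) drop = 1;
    if (drop >= static_cast<int>(active.n_elem))
      drop = static_cast<int>(active.n_elem) - 1;
    // order by (|beta| asc, column index asc); stable sort keeps index order
    vec ab = arma::abs(beta);
    uvec ord = arma::stable_sort_index(ab, "ascend");
    uvec keep_local = arma::sort(ord.subvec(drop, ord.n_elem - 1));
    for (int d = 0; d < drop; ++d)
      elim_order.push_back(static_cast<int>(active[ord[d]]) + 1);
    active = active.elem(keep_local);
  }
  // smallest size within tolerance of the best accuracy; sizes are descending
  double amax = *std::max_element(accs.begin(), accs.end());
  size_t sel = 0;
  for (size_t i = 0; i < accs.size(); ++i)
    if (accs[i] >= amax - 1e-12) sel = i;  // last qualifying = smallest size
  List set_list(sets.size());
  for (size_t i = 0; i < sets.size(); ++i) set_list[i] = wrap(sets[i]);
  return List::create(_["sizes"] = wrap(sizes),
                      _["accuracy"] = wrap(accs),
                      _["lambda"] = wrap(lambdas),
                      _["feature_sets"] = set_list,
                      _["selected"] = wrap(sets[sel]),
                      _["elimination_order"] = wrap(elim_order));
}
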