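// Multinomial logistic regression by Newton-Raphson, plus greedy forward
// selection under a BIC improvement rule. Reference class is class 0; the
// coefficient matrix has one column per non-reference class.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Class probabilities for design X (n x m, intercept included) and
// coefficients B (m x K-1). Returns n x K, column 0 = reference.
static mat softmax_probs(const mat& X, const mat& B) {
  const uword n = X.n_rows, K1 = B.n_cols;
  mat eta = X * B;                       // n x K-1
  // subtract rowwise max (with implicit 0 for the reference) for stability
  vec mx = max(join_rows(zeros<vec>(n), eta), 1);
  mat P(n, K1 + 1);
  P.col(0) = exp(-mx);
  for (uword j = 0; j < K1; ++j) P.col(j + 1) = exp(eta.col(j) - mx);
  P.each_col() /= sum(P, 1);
  return P;
}

static double loglik(const mat& P, const uvec& y) {
  double ll = 0.0;
  for (uword i = 0; i < y.n_elem; ++i) ll += std::log(std::max(P(i, y(i)), 1e-300));
  return ll;
}

// Core Newton fit. Returns log-likelihood; fills B; sets converged/iters.
static double newton_fit(const mat& X, const uvec& y, const int K,
                         const double ridge, const double tol, const int maxit,
                         mat& B, bool& converged, int& iters) {
  const uword n = X.n_rows, m = X.n_cols, K1 = (uword)K - 1;
  const uword M = m * K1;
  B.zeros(m, K1);
  mat Y(n, K1, fill::zeros);
  for (uword i = 0; i < n; ++i) if (y(i) > 0) Y(i, y(i) - 1) = 1.0;

  mat P = softmax_probs(X, B);
  double ll = loglik(P, y) - 0.5 * ridge * accu(square(B));
  converged = false;
  iters = 0;
  for (int it = 0; it < maxit; ++it) {
    iters = it + 1;
    // gradient and Hessian of the penalized log-likelihood
    vec g(M);
    mat H(M, M);
    for (uword j = 0; j < K1; ++j) {
      vec r = Y.col(j) - P.col(j + 1);
      g.subvec(j * m, (j + 1) * m - 1) = X.t() * r - ridge * B.col(j);
      for (uword l = j; l < K1; ++l) {
        vec w;
        if (j == l) w = P.col(j + 1) % (1.0 - P.col(j + 1));
        else        w = -P.col(j + 1) % P.col(l + 1);
        mat Hb = X.t() * (X.each_col() % w);
        H.submat(j * m, l * m, (j + 1) * m - 1, (l + 1) * m - 1) = Hb;
        if (l != j)
          H.submat(l * m, j * m, (l + 1) * m - 1, (j + 1) * m - 1) = Hb.t();
      }
    }
    H.diag() += ridge + 1e-10;
    vec step;
    bool ok = solve(step, H, g, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) { solve(step, H + 1e-6 * eye(M, M), g); }
    // step-halving line search
    double t = 1.0, llNew = -datum::inf;
    mat Bnew;
    for (int h = 0; h < 30; ++h) {
      Bnew = B + t * reshape(step, m, K1);
      mat Pn = softmax_probs(X, Bnew);
      llNew = loglik(Pn, y) - 0.5 * ridge * accu(square(Bnew));
      if (llNew >= ll - 1e-12) { P = Pn; break; }
      t *= 0.5;
    }
    double rel = std::fabs(llNew - ll) / (std::fabs(ll) + 1.0);
    B = Bnew;
    ll = llNew;
    if (rel < tol) { converged = true; break; }
  }
  return ll;
}

// [[Rcpp::export]]
Rcpp::List cpp_mlr_fit(const arma::mat& X, const arma::uvec& y, const int K,
                       const double ridge, const double tol, const int maxit) {
  mat Xd = join_rows(ones<vec>(X.n_rows), X);
  mat B;
  bool conv;
  int iters;
  double usedRidge = ridge;
  double ll = newton_fit(Xd, y, K, usedRidge, tol, maxit, B, conv, iters);
  bool sep = false;
  if (!conv || abs(B).max() > 100.0) {  // quasi/perfect separation fallback
    sep = true;
    usedRidge = std::max(ridge, 1e-6 * (double)X.n_rows);
    ll = newton_fit(Xd, y, K, usedRidge, tol, maxit, B, conv, iters);
  }
  return Rcpp::List::create(
      Rcpp::Named("coef") = B, Rcpp::Named("logLik") = ll,
      Rcpp::Named("converged") = conv, Rcpp::Named("iterations") = iters,
      Rcpp::Named("separation") = sep, Rcpp::Named("ridge") = usedRidge);
}

// [[Rcpp::export]]
arma::mat cpp_mlr_prob(const arma::mat& X, const arma::mat& B) {
  return softmax_probs(join_rows(ones<vec>(X.n_rows), X), B);
}

static double fit_bic(const mat& Xd, const uvec& y, const int K,
                      const double tol, const int maxit) {
  mat B;
  bool conv;
  int iters;
  double ll = newton_fit(Xd, y, K, 0.0, tol, maxit, B, conv, iters);
  if (!conv || abs(B).max() > 100.0)
    ll = newton_fit(Xd, y, K, 1e-6 * (double)Xd.n_rows, tol, maxit, B, conv, iters);
  const double q = (double)(K - 1) * (double)Xd.n_cols;
  return -2.0 * ll + q * std::log((double)Xd.n_rows);
}

// Greedy forward selection: at each step add the candidate with lowest BIC;
// continue only while the improvement over the current BIC exceeds delta.
// candidates are 0-based column indices into X.
// [[Rcpp::export]]
Rcpp::List cpp_forward_select(const arma::mat& X, const arma::uvec& y,
                              const int K, const arma::uvec& candidates,
                              const double delta, const int maxFeatures,
                              const double tol, const int maxit) {
  const uword n = X.n_rows;
  mat Xcur = ones<mat>(n, 1);  // intercept only
  double bicCur = fit_bic(Xcur, y, K, tol, maxit);
  const double bic0 = bicCur;

  std::vector<uword> pool(candidates.begin(), candidates.end());
  std::vector<uword> order;
  std::vector<double> bics;
  std::string stop = "no_improvement";

  while (!pool.empty() && (int)order.size() < maxFeatures) {
    double best = datum::inf;
    size_t bestIdx = 0;
    for (size_t c = 0; c < pool.size(); ++c) {
      mat Xc = join_rows(Xcur, X.col(pool[c]));
      double b = fit_bic(Xc, y, K, tol, maxit);
      if (b < best) { best = b; bestIdx = c; }
    }
    if (bicCur - best <= delta) break;
    Xcur = join_rows(Xcur, X.col(pool[bestIdx]));
    order.push_back(pool[bestIdx]);
    bics.push_back(best);
    bicCur = best;
    pool.erase(pool.begin() + bestIdx);
  }
  if ((int)order.size() >= maxFeatures) stop = "max_features";
  else if (pool.empty() && !order.empty()) stop = "exhausted";

  return Rcpp::List::create(
      Rcpp::Named("order") = Rcpp::IntegerVector(order.begin(), order.end()),
      Rcpp::Named("bic") = Rcpp::NumericVector(bics.begin(), bics.end()),
      Rcpp::Named("bic0") = bic0, Rcpp::Named("stop") = stop);
}
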