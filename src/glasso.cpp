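// Graphical lasso by block coordinate descent (Friedman-Hastie-Tibshirani),
// plus a full EBIC selection path.  Kept in C++ because the permutation test
// and the bootstrap re-estimate networks thousands of times.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// coordinate descent for  min_b  0.5 b'Vb - s'b + lambda ||b||_1
// with an active-set strategy: full sweeps establish the support, then
// only nonzero coordinates are iterated until stable, and a final full
// sweep verifies optimality.
static void lasso_cd(const mat& V, const vec& s, double lambda, vec& b,
                     double tol, int maxit) {
  const int m = b.n_elem;
  bool active_only = false;
  for (int it = 0; it < maxit; ++it) {
    double maxd = 0.0;
    for (int k = 0; k < m; ++k) {
      if (active_only && b(k) == 0.0) continue;
      double old = b(k);
      double r = s(k) - dot(V.col(k), b) + V(k, k) * old;
      double nb = soft(r, lambda) / V(k, k);
      if (nb != old) {
        b(k) = nb;
        double d = std::fabs(nb - old);
        if (d > maxd) maxd = d;
      }
    }
    if (maxd < tol) {
      if (!active_only) break;      // converged and verified on full sweep
      active_only = false;          // re-verify with one full sweep
    } else {
      active_only = true;
    }
  }
}

struct GlassoResult {
  mat K;
  mat W;
  int iter;
  bool converged;
};

static GlassoResult glasso_core(const mat& S, double lambda, double tol,
                                int maxit, mat& W, mat& B, bool warm) {
  const int p = S.n_rows;
  // off-diagonal penalty only: the diagonal of W stays at diag(S)
  if (!warm) {
    W = S;
    B.zeros(p - 1, p);
  } else {
    W.diag() = S.diag();
  }

  // threshold convention of the reference algorithm: average |offdiag(S)|
  double offavg = 0.0;
  int cnt = 0;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) { offavg += std::fabs(S(i, j)); ++cnt; }
  offavg = (cnt > 0) ? offavg / cnt : 0.0;
  double thr = tol * std::max(offavg, 1e-12);

  uvec all = regspace<uvec>(0, p - 1);
  bool converged = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    double maxd = 0.0;
    for (int j = 0; j < p; ++j) {
      uvec idx = find(all != (unsigned) j);
      mat V = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec b = B.col(j);
      lasso_cd(V, s12, lambda, b, thr, 200);
      B.col(j) = b;
      vec w12 = V * b;
      for (int k = 0; k < p - 1; ++k) {
        double d = std::fabs(W(idx(k), j) - w12(k));
        if (d > maxd) maxd = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
    }
    if (maxd < thr) { converged = true; break; }
  }

  // recover the precision matrix from W and the regression coefficients
  mat K(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    uvec idx = find(all != (unsigned) j);
    vec b = B.col(j);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double kjj = 1.0 / (W(j, j) - dot(w12, b));
    K(j, j) = kjj;
    for (int k = 0; k < p - 1; ++k) K(idx(k), j) = -b(k) * kjj;
  }
  K = 0.5 * (K + K.t());

  GlassoResult res;
  res.K = K;
  res.W = W;
  res.iter = it + 1;
  res.converged = converged;
  return res;
}

static mat partial_from_precision(const mat& K, double zero_tol) {
  const int p = K.n_rows;
  vec d = sqrt(K.diag());
  mat Wp(p, p, fill::zeros);
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) {
        double w = -K(i, j) / (d(i) * d(j));
        Wp(i, j) = (std::fabs(w) < zero_tol) ? 0.0 : w;
      }
  return Wp;
}

// [[Rcpp::export]]
Rcpp::List cpp_glasso(const arma::mat& S, double lambda, double tol,
                      int maxit) {
  mat W, B;
  GlassoResult res = glasso_core(S, lambda, tol, maxit, W, B, false);
  return Rcpp::List::create(
      Rcpp::Named("K") = res.K, Rcpp::Named("W") = res.W,
      Rcpp::Named("iterations") = res.iter,
      Rcpp::Named("converged") = res.converged);
}

// Fits the whole descending-lambda path with warm starts and returns the
// EBIC-selected precision matrix together with the path diagnostics.
// loglik convention: (n/2) * (log det K - tr(S K)), constants omitted.
// [[Rcpp::export]]
Rcpp::List cpp_ebic_glasso_path(const arma::mat& S, double n, double gamma,
                                const arma::vec& lambdas, double tol,
                                int maxit, double zero_tol,
                                int stop_after) {
  const int p = S.n_rows;
  const int L = lambdas.n_elem;
  vec ebic(L), loglik(L);
  ivec edges(L);
  Rcpp::LogicalVector conv(L);

  mat W, B;
  bool warm = false;
  int best = -1;
  double best_ebic = datum::inf;
  mat bestK;
  int computed = 0;

  for (int l = 0; l < L; ++l) {
    GlassoResult res = glasso_core(S, lambdas(l), tol, maxit, W, B, warm);
    warm = true;
    conv[l] = res.converged;

    mat Wp = partial_from_precision(res.K, zero_tol);
    int E = 0;
    for (int i = 0; i < p; ++i)
      for (int j = i + 1; j < p; ++j)
        if (Wp(i, j) != 0.0) ++E;

    double ldet, sign;
    log_det(ldet, sign, res.K);
    double ll = (sign > 0) ? 0.5 * n * (ldet - trace(S * res.K))
                           : -datum::inf;
    loglik(l) = ll;
    edges(l) = E;
    ebic(l) = -2.0 * ll + E * std::log(n) + 4.0 * E * gamma * std::log((double) p);
    if (res.converged && ebic(l) < best_ebic) {
      best_ebic = ebic(l);
      best = l;
      bestK = res.K;
    }
    computed = l + 1;
    // the EBIC along a descending-lambda path is near-unimodal: once it
    // has not improved for stop_after consecutive grid points, stop
    if (stop_after > 0 && best >= 0 && (l - best) >= stop_after) break;
  }

  if (best < 0) Rcpp::stop("graphical lasso failed to converge on every lambda");

  return Rcpp::List::create(
      Rcpp::Named("K") = bestK,
      Rcpp::Named("partial") = partial_from_precision(bestK, zero_tol),
      Rcpp::Named("lambda_selected") = lambdas(best),
      Rcpp::Named("index_selected") = best + 1,
      Rcpp::Named("lambda") = lambdas.head(computed),
      Rcpp::Named("ebic") = ebic.head(computed),
      Rcpp::Named("loglik") = loglik.head(computed),
      Rcpp::Named("edges") = edges.head(computed),
      Rcpp::Named("converged") = conv[Rcpp::Range(0, computed - 1)]);
}
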