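// k-means engine: k-means++ seeding, Lloyd descent, and the restart loop.
// This is the hot path of the gap statistic (the gap machinery runs
// (B+1) * k_max k-means fits per call), so the whole engine lives in
// compiled code.  Data are held point-per-column (column-major friendly).
// All randomness comes from R's RNG, keeping runs seed-deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// squared distances centre x point (k x n)
static arma::mat dist2_t(const arma::mat& Xt, const arma::mat& Ct,
                         const arma::rowvec& xsq) {
  arma::mat d2 = -2.0 * (Ct.t() * Xt);   // k x n
  d2.each_row() += xsq;
  d2.each_col() += arma::sum(arma::square(Ct), 0).t();
  d2.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return d2;
}

struct LloydFit {
  arma::urowvec assign;
  arma::mat Ct;            // r x k
  double inertia;
  std::vector<double> trace;
};

// one Lloyd descent from the given centres
static LloydFit lloyd_run(const arma::mat& Xt, const arma::rowvec& xsq,
                          arma::mat Ct, int max_iter, double tol) {
  const arma::uword n = Xt.n_cols;
  const arma::uword k = Ct.n_cols;
  LloydFit fit;
  fit.inertia = arma::datum::inf;

  arma::urowvec assign(n, arma::fill::zeros);
  for (int it = 0; it < max_iter; ++it) {
    arma::mat d2 = dist2_t(Xt, Ct, xsq);
    assign = arma::index_min(d2, 0);

    // empty-cluster repair: reseed at the point farthest from its centre
    for (arma::uword round = 0; round < k; ++round) {
      arma::uvec sizes(k, arma::fill::zeros);
      for (arma::uword i = 0; i < n; ++i) sizes[assign[i]]++;
      arma::uvec empty = arma::find(sizes == 0);
      if (empty.n_elem == 0) break;
      arma::vec cur(n);
      for (arma::uword i = 0; i < n; ++i) cur[i] = d2(assign[i], i);
      arma::uvec far = arma::sort_index(cur, "descend");
      for (arma::uword j = 0; j < empty.n_elem; ++j) {
        Ct.col(empty[j]) = Xt.col(far[j]);
      }
      d2 = dist2_t(Xt, Ct, xsq);
      assign = arma::index_min(d2, 0);
    }

    // centroid update
    arma::mat newc(Xt.n_rows, k, arma::fill::zeros);
    arma::vec sizes(k, arma::fill::zeros);
    for (arma::uword i = 0; i < n; ++i) {
      newc.col(assign[i]) += Xt.col(i);
      sizes[assign[i]] += 1.0;
    }
    for (arma::uword j = 0; j < k; ++j) newc.col(j) /= sizes[j];
    Ct = newc;

    double new_inertia = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      new_inertia += arma::accu(arma::square(Xt.col(i) - Ct.col(assign[i])));
    }
    fit.trace.push_back(new_inertia);

    bool converged =
        std::isfinite(fit.inertia) &&
        (fit.inertia - new_inertia) <=
            tol * std::max(fit.inertia, std::numeric_limits<double>::epsilon());
    fit.inertia = new_inertia;
    if (converged) break;
  }
  fit.assign = assign;
  fit.Ct = Ct;
  return fit;
}

// k-means++ seeding: first centre uniform, then proportional to squared
// distance from the nearest chosen centre; draws from R's RNG
static arma::mat kmeanspp(const arma::mat& Xt, const arma::rowvec& xsq,
                          arma::uword k) {
  const arma::uword n = Xt.n_cols;
  arma::mat Ct(Xt.n_rows, k);
  arma::uword first = std::min((arma::uword)(unif_rand() * n), n - 1);
  Ct.col(0) = Xt.col(first);
  if (k == 1) return Ct;

  arma::rowvec min_d2 =
      dist2_t(Xt, Ct.cols(0, 0), xsq).row(0);
  for (arma::uword j = 1; j < k; ++j) {
    double total = arma::accu(min_d2);
    arma::uword pick;
    if (total <= 0.0) {
      pick = std::min((arma::uword)(unif_rand() * n), n - 1);
    } else {
      double u = unif_rand() * total, cum = 0.0;
      pick = n - 1;
      for (arma::uword i = 0; i < n; ++i) {
        cum += min_d2[i];
        if (u <= cum) { pick = i; break; }
      }
    }
    Ct.col(j) = Xt.col(pick);
    min_d2 = arma::min(min_d2, dist2_t(Xt, Ct.cols(j, j), xsq).row(0));
  }
  return Ct;
}

static List fit_to_list(const LloydFit& fit) {
  const arma::uword n = fit.assign.n_elem;
  IntegerVector assignments(n);
  for (arma::uword i = 0; i < n; ++i) assignments[i] = (int) fit.assign[i] + 1;
  return List::create(
      _["assignments"] = assignments, _["centers"] = fit.Ct.t(),
      _["inertia"] = fit.inertia, _["n_iter"] = (int) fit.trace.size(),
      _["inertia_trace"] = NumericVector(fit.trace.begin(), fit.trace.end()));
}

// single Lloyd descent from caller-supplied centres (exposed for the
// inertia-trace invariant tests)
// [[Rcpp::export(name = ".lloyd_cpp")]]
List lloyd_cpp(const arma::mat& X, const arma::mat& centers, int max_iter,
               double tol) {
  const arma::mat Xt = X.t();
  const arma::rowvec xsq = arma::sum(arma::square(Xt), 0);
  return fit_to_list(lloyd_run(Xt, xsq, centers.t(), max_iter, tol));
}

// full k-means: n_restarts k-means++ starts, best inertia wins
// [[Rcpp::export(name = ".kmeans_cpp")]]
List kmeans_cpp(const arma::mat& X, int k, int n_restarts, int max_iter,
                double tol) {
  const arma::mat Xt = X.t();
  const arma::rowvec xsq = arma::sum(arma::square(Xt), 0);
  LloydFit best;
  best.inertia = arma::datum::inf;
  for (int r = 0; r < n_restarts; ++r) {
    LloydFit fit = lloyd_run(Xt, xsq, kmeanspp(Xt, xsq, (arma::uword) k),
                             max_iter, tol);
    if (fit.inertia < best.inertia) best = fit;
  }
  return fit_to_list(best);
}
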