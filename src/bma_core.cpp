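// Core numerics: IRLS logistic regression, batch fitting of candidate
// predictor subsets, and branch-and-bound best-subsets search on a weighted
// least-squares surrogate. Masks are integer bitmasks over the candidate
// predictors; forced columns (intercept + center indicators) sit outside the
// mask and appear in every model.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double logit_loglik(const arma::vec& eta, const arma::vec& y) {
  double ll = 0.0;
  for (arma::uword i = 0; i < eta.n_elem; ++i) {
    const double e = eta[i];
    // log(1 + exp(e)) without overflow
    const double lse = (e > 30.0) ? e : std::log1p(std::exp(e));
    ll += y[i] * e - lse;
  }
  return ll;
}

struct IrlsFit {
  arma::vec beta;
  double loglik;
  bool converged;     // max coefficient change < tol
  bool ll_converged;  // log-likelihood stabilized (quasi-separation etc.)
  bool separated;
  bool singular;
  int iter;
};

static IrlsFit irls(const arma::mat& X, const arma::vec& y, int maxit,
                    double tol, arma::vec beta) {
  const arma::uword k = X.n_cols;
  if (beta.n_elem != k) beta = arma::zeros(k);
  IrlsFit out;
  out.converged = false;
  out.ll_converged = false;
  out.separated = false;
  out.singular = false;
  out.iter = 0;

  arma::vec eta = X * beta;
  double ll_cur = logit_loglik(eta, y);
  for (int it = 1; it <= maxit; ++it) {
    out.iter = it;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = arma::clamp(mu % (1.0 - mu), 1e-10, 0.25);
    arma::vec z = eta + (y - mu) / w;
    arma::mat Xw = X.each_col() % w;
    arma::mat XtWX = X.t() * Xw;
    arma::vec XtWz = Xw.t() * z;
    arma::vec bnew;
    const bool ok = arma::solve(bnew, XtWX, XtWz,
                                arma::solve_opts::likely_sympd +
                                arma::solve_opts::no_approx);
    if (!ok || !bnew.is_finite()) {
      out.singular = true;
      break;
    }
    // step-halving: never accept a step that decreases the log-likelihood
    // (guards against divergence from poor starts or extreme weights)
    arma::vec etanew = X * bnew;
    double ll_new = logit_loglik(etanew, y);
    int halvings = 0;
    while ((!std::isfinite(ll_new) || ll_new < ll_cur - 1e-12) &&
           halvings < 20) {
      bnew = 0.5 * (bnew + beta);
      etanew = X * bnew;
      ll_new = logit_loglik(etanew, y);
      ++halvings;
    }
    const double delta = arma::abs(bnew - beta).max();
    const double ll_change = std::fabs(ll_new - ll_cur);
    beta = bnew;
    eta = etanew;
    ll_cur = ll_new;
    if (delta < tol) {
      out.converged = true;
      out.ll_converged = true;
      break;
    }
    if (ll_change < 1e-8 * (std::fabs(ll_new) + 1.0)) {
      out.ll_converged = true;
    } else {
      out.ll_converged = false;
    }
  }
  out.beta = beta;
  out.loglik = logit_loglik(eta, y);
  if (!out.converged) {
    const double emax = eta.is_finite() ? arma::abs(eta).max() : R_PosInf;
    const double bmax = beta.is_finite() ? arma::abs(beta).max() : R_PosInf;
    if (emax > 25.0 || bmax > 100.0) out.separated = true;
  }
  return out;
}

// Single logistic fit. X must already contain the intercept column.
// [[Rcpp::export]]
List cpp_fit_logistic(const arma::mat& X, const arma::vec& y, int maxit,
                      double tol, const arma::vec& start, bool want_cov) {
  IrlsFit f = irls(X, y, maxit, tol, start);
  List out = List::create(
      _["coefficients"] = f.beta, _["loglik"] = f.loglik,
      _["converged"] = f.converged, _["ll_converged"] = f.ll_converged,
      _["separated"] = f.separated, _["singular"] = f.singular,
      _["iter"] = f.iter);
  if (want_cov) {
    arma::vec eta = X * f.beta;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = arma::clamp(mu % (1.0 - mu), 1e-10, 0.25);
    arma::mat XtWX = X.t() * (X.each_col() % w);
    arma::mat cov;
    if (arma::inv_sympd(cov, XtWX)) {
      out["cov"] = cov;
    } else {
      out["cov"] = R_NilValue;
    }
  }
  return out;
}

// Fit one logistic model per candidate bitmask. D holds the forced design
// (intercept + center indicators), X the candidate predictors. full_start is
// the coefficient vector of the full model, used to warm-start each subset.
// Returns per-model loglik/convergence flags plus a padded coefficient
// matrix (rows: forced coefs then all candidates; NA where excluded).
// [[Rcpp::export]]
List cpp_fit_masks(const arma::mat& D, const arma::mat& X, const arma::vec& y,
                   const IntegerVector& masks, int maxit, double tol,
                   const arma::vec& full_start) {
  const arma::uword nf = D.n_cols;
  const arma::uword p = X.n_cols;
  const arma::uword n = D.n_rows;
  const int M = masks.size();

  NumericVector loglik(M);
  IntegerVector nterms(M);
  LogicalVector converged(M), ll_converged(M), separated(M), singular(M);
  NumericMatrix coefs(nf + p, M);
  std::fill(coefs.begin(), coefs.end(), NA_REAL);

  const bool warm = (full_start.n_elem == nf + p);

  for (int m = 0; m < M; ++m) {
    const uint32_t mask = static_cast<uint32_t>(masks[m]);
    std::vector<arma::uword> idx;
    for (arma::uword j = 0; j < p; ++j)
      if (mask & (1u << j)) idx.push_back(j);
    const arma::uword k = idx.size();

    arma::mat Xm(n, nf + k);
    Xm.cols(0, nf - 1) = D;
    arma::vec start = arma::zeros(nf + k);
    if (warm) start.subvec(0, nf - 1) = full_start.subvec(0, nf - 1);
    for (arma::uword j = 0; j < k; ++j) {
      Xm.col(nf + j) = X.col(idx[j]);
      if (warm) start[nf + j] = full_start[nf + idx[j]];
    }

    IrlsFit f = irls(Xm, y, maxit, tol, start);
    loglik[m] = f.loglik;
    nterms[m] = nf + k;
    converged[m] = f.converged;
    ll_converged[m] = f.ll_converged;
    separated[m] = f.separated;
    singular[m] = f.singular;
    for (arma::uword j = 0; j < nf; ++j) coefs(j, m) = f.beta[j];
    for (arma::uword j = 0; j < k; ++j) coefs(nf + idx[j], m) = f.beta[nf + j];
    if (m % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["loglik"] = loglik, _["nterms"] = nterms,
                      _["converged"] = converged,
                      _["ll_converged"] = ll_converged,
                      _["separated"] = separated,
                      _["singular"] = singular, _["coefficients"] = coefs);
}

namespace {

struct BnbState {
  const arma::mat* A;   // (nf+p) x (nf+p) weighted cross-product
  const arma::vec* b;   // (nf+p) weighted X'z
  double zz;            // z'Wz
  int nf;
  int p;
  unsigned int nbest;
  double max_nodes;
  double nodes;
  bool truncated;
  // per model size: max-heap of (rss, mask) pairs, at most nbest entries
  std::vector<std::vector<std::pair<double, uint32_t> > > best;

  double worst(int size) const {
    if (best[size].size() < nbest) return R_PosInf;
    return best[size].front().first;
  }

  void insert(int size, double rss, uint32_t mask) {
    std::vector<std::pair<double, uint32_t> >& h = best[size];
    if (h.size() < nbest) {
      h.push_back(std::make_pair(rss, mask));
      std::push_heap(h.begin(), h.end());
    } else if (rss < h.front().first) {
      std::pop_heap(h.begin(), h.end());
      h.back() = std::make_pair(rss, mask);
      std::push_heap(h.begin(), h.end());
    }
  }

  // RSS of the model containing the forced columns, the candidates flagged
  // in `mask`, and every candidate with index >= from.
  double rss(uint32_t mask, int from) const {
    std::vector<arma::uword> cols;
    cols.reserve(nf + p);
    for (int j = 0; j < nf; ++j) cols.push_back(j);
    for (int j = 0; j < from; ++j)
      if (mask & (1u << j)) cols.push_back(nf + j);
    for (int j = from; j < p; ++j) cols.push_back(nf + j);
    const arma::uvec ci(cols);
    const arma::mat As = (*A)(ci, ci);
    const arma::vec bs = (*b)(ci);
    arma::vec s;
    if (!arma::solve(s, As, bs, arma::solve_opts::likely_sympd +
                                    arma::solve_opts::no_approx)) {
      if (!arma::solve(s, As, bs)) return R_PosInf;
    }
    const double r = zz - arma::dot(bs, s);
    return (r < 0.0) ? 0.0 : r;
  }

  void search(int i, uint32_t mask, int insize, double bound) {
    nodes += 1.0;
    if (truncated) return;
    if (nodes > max_nodes) {
      truncated = true;
      return;
    }
    if (i == p) {
      insert(insize, bound, mask);
      return;
    }
    const int rem = p - i;
    bool viable = false;
    for (int s = insize; s <= insize + rem; ++s) {
      if (bound < worst(s) - 1e-12) {
        viable = true;
        break;
      }
    }
    if (!viable) return;
    // include candidate i: the relaxation (and hence the bound) is unchanged
    search(i + 1, mask | (1u << i), insize + 1, bound);
    // exclude candidate i: recompute the relaxation without it
    const double nb = rss(mask, i + 1);
    search(i + 1, mask, insize, nb);
  }
};

}  // namespace

// Branch-and-bound best-subsets on the weighted least-squares problem
// defined by cross-products A = F'WF, b = F'Wz, zz = z'Wz, where F is the
// design with nf forced columns followed by p candidate columns (already
// ordered by priority). Keeps the nbest lowest-RSS subsets per model size.
// [[Rcpp::export]]
List cpp_bnb_subsets(const arma::mat& A, const arma::vec& b, double zz,
                     int nf, int nbest, double max_nodes) {
  const int p = static_cast<int>(A.n_cols) - nf;
  BnbState st;
  st.A = &A;
  st.b = &b;
  st.zz = zz;
  st.nf = nf;
  st.p = p;
  st.nbest = static_cast<unsigned int>(nbest);
  st.max_nodes = max_nodes;
  st.nodes = 0.0;
  st.truncated = false;
  st.best.resize(p + 1);

  st.search(0, 0u, 0, st.rss(0u, 0));

  std::vector<int> masks;
  std::vector<double> rss;
  std::vector<int> sizes;
  for (int s = 0; s <= p; ++s) {
    for (std::size_t j = 0; j < st.best[s].size(); ++j) {
      masks.push_back(static_cast<int>(st.best[s][j].second));
      rss.push_back(st.best[s][j].first);
      sizes.push_back(s);
    }
  }
  return List::create(_["mask"] = wrap(masks), _["rss"] = wrap(rss),
                      _["size"] = wrap(sizes), _["nodes"] = st.nodes,
                      _["truncated"] = st.truncated);
}
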