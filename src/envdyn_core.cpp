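// Compiled numerical kernels: zero-phase IIR filtering, Gaussian-observation
// HMM (scaled Baum-Welch EM + Viterbi), and Markov-chain sampling using R's RNG.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Direct-form-II-transposed IIR filter; a[0] assumed 1 (normalised in R).
static arma::vec iir_filter(const arma::vec& b, const arma::vec& a,
                            const arma::vec& x) {
  const int n = b.n_elem;  // b and a padded to equal length upstream
  arma::vec z(n > 1 ? n - 1 : 1, arma::fill::zeros);
  arma::vec y(x.n_elem);
  for (arma::uword t = 0; t < x.n_elem; ++t) {
    const double xt = x[t];
    const double yt = b[0] * xt + z[0];
    for (int i = 1; i < n - 1; ++i)
      z[i - 1] = b[i] * xt + z[i] - a[i] * yt;
    if (n > 1) z[n - 2] = b[n - 1] * xt - a[n - 1] * yt;
    y[t] = yt;
  }
  return y;
}

// Zero-phase (forward-backward) filtering of each ROW of x, with odd
// reflection padding of 3*(order) samples at both ends to suppress
// startup transients.
// [[Rcpp::export]]
arma::mat filtfilt_mat(const arma::vec& b, const arma::vec& a,
                       const arma::mat& x) {
  const int order = std::max(b.n_elem, a.n_elem) - 1;
  const arma::uword T = x.n_cols;
  arma::uword npad = 3 * order;
  if (npad >= T) npad = T - 1;
  arma::mat out(x.n_rows, T);
  for (arma::uword r = 0; r < x.n_rows; ++r) {
    arma::vec v = x.row(r).t();
    arma::vec padded(T + 2 * npad);
    for (arma::uword i = 0; i < npad; ++i)
      padded[i] = 2.0 * v[0] - v[npad - i];
    padded.subvec(npad, npad + T - 1) = v;
    for (arma::uword i = 0; i < npad; ++i)
      padded[npad + T + i] = 2.0 * v[T - 1] - v[T - 2 - i];
    arma::vec y = iir_filter(b, a, padded);
    y = arma::reverse(y);
    y = iir_filter(b, a, y);
    y = arma::reverse(y);
    out.row(r) = y.subvec(npad, npad + T - 1).t();
  }
  return out;
}

// Cholesky with diagonal loading fallback; loading amount grows until success.
static bool safe_chol(arma::mat& L, const arma::mat& S, double reg,
                      int& n_loaded) {
  if (arma::chol(L, S, "lower")) return true;
  const double base = reg * (arma::trace(S) / S.n_rows + 1e-12);
  double lambda = base;
  for (int k = 0; k < 40; ++k) {
    arma::mat Sr = S + lambda * arma::eye(S.n_rows, S.n_rows);
    if (arma::chol(L, Sr, "lower")) { ++n_loaded; return true; }
    lambda *= 10.0;
  }
  return false;
}

// T x K matrix of Gaussian log-densities.
static arma::mat log_obs_dens(const arma::mat& X, const arma::mat& means,
                              const arma::cube& covs, double reg,
                              int& n_loaded) {
  const arma::uword T = X.n_rows, d = X.n_cols, K = means.n_rows;
  arma::mat logB(T, K);
  const double c0 = -0.5 * d * std::log(2.0 * M_PI);
  for (arma::uword k = 0; k < K; ++k) {
    arma::mat L;
    if (!safe_chol(L, covs.slice(k), reg, n_loaded))
      stop("state covariance not positive definite even after loading");
    const double logdet = 2.0 * arma::sum(arma::log(L.diag()));
    arma::mat D = X.each_row() - means.row(k);          // T x d
    arma::mat Z = arma::solve(arma::trimatl(L), D.t()); // d x T
    logB.col(k) = (c0 - 0.5 * logdet) - 0.5 * arma::sum(arma::square(Z), 0).t();
  }
  return logB;
}

// Scaled forward-backward. Returns loglik; fills gamma (T x K) and xi_sum (K x K).
static double forward_backward(const arma::mat& logB, const arma::mat& trans,
                               const arma::vec& init, arma::mat& gamma,
                               arma::mat& xi_sum) {
  const arma::uword T = logB.n_rows, K = logB.n_cols;
  arma::vec shift = arma::max(logB, 1);
  arma::mat B = arma::exp(logB.each_col() - shift);  // T x K, rows peak at 1
  arma::mat alpha(T, K), beta(T, K);
  arma::vec c(T);

  arma::rowvec a0 = init.t() % B.row(0);
  c[0] = arma::accu(a0) + 1e-300;
  alpha.row(0) = a0 / c[0];
  for (arma::uword t = 1; t < T; ++t) {
    arma::rowvec at = (alpha.row(t - 1) * trans) % B.row(t);
    c[t] = arma::accu(at) + 1e-300;
    alpha.row(t) = at / c[t];
  }
  beta.row(T - 1).ones();
  for (arma::uword t = T - 1; t >= 1; --t) {
    arma::rowvec bt = (beta.row(t) % B.row(t)) * trans.t();
    beta.row(t - 1) = bt / c[t];
  }
  gamma = alpha % beta;
  gamma.each_col() /= (arma::sum(gamma, 1) + 1e-300);
  xi_sum.zeros(K, K);
  for (arma::uword t = 1; t < T; ++t) {
    arma::mat xi = (alpha.row(t - 1).t() * (B.row(t) % beta.row(t))) % trans;
    xi_sum += xi / c[t];
  }
  return arma::accu(arma::log(c)) + arma::accu(shift);
}

// EM for a Gaussian-observation HMM on one (concatenated) sequence.
// [[Rcpp::export]]
List hmm_em(const arma::mat& X, arma::mat means, arma::cube covs,
            arma::mat trans, arma::vec init, int max_iter, double tol,
            double reg) {
  const arma::uword T = X.n_rows, K = means.n_rows;
  int n_loaded = 0;
  arma::mat gamma, xi_sum;
  double ll_prev = -arma::datum::inf, ll = ll_prev;
  bool converged = false;
  std::vector<double> trace;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    arma::mat logB = log_obs_dens(X, means, covs, reg, n_loaded);
    ll = forward_backward(logB, trans, init, gamma, xi_sum);
    trace.push_back(ll);
    if (iter > 0 && (ll - ll_prev) / T < tol && ll >= ll_prev) {
      converged = true;
      break;
    }
    ll_prev = ll;
    // M step
    init = gamma.row(0).t();
    init /= arma::accu(init);
    arma::vec rows = arma::sum(xi_sum, 1);
    for (arma::uword k = 0; k < K; ++k) {
      if (rows[k] > 0)
        trans.row(k) = xi_sum.row(k) / rows[k];
      else
        trans.row(k).fill(1.0 / K);
    }
    arma::rowvec Nk = arma::sum(gamma, 0) + 1e-300;
    for (arma::uword k = 0; k < K; ++k) {
      arma::vec g = gamma.col(k);
      arma::rowvec mu = (g.t() * X) / Nk[k];
      arma::mat Xw = X.each_col() % arma::sqrt(g);
      arma::mat S = (Xw.t() * Xw) / Nk[k] - mu.t() * mu;
      S = 0.5 * (S + S.t());
      means.row(k) = mu;
      covs.slice(k) = S;
    }
  }
  return List::create(
      _["means"] = means, _["covs"] = covs, _["trans"] = trans,
      _["init"] = init, _["loglik"] = ll,
      _["loglik_trace"] = NumericVector(trace.begin(), trace.end()),
      _["n_iter"] = iter + 1, _["converged"] = converged,
      _["n_regularized"] = n_loaded, _["gamma"] = gamma);
}

// Viterbi decoding (log space); returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(const arma::mat& X, const arma::mat& means,
                          const arma::cube& covs, const arma::mat& trans,
                          const arma::vec& init, double reg) {
  const arma::uword T = X.n_rows, K = means.n_rows;
  int n_loaded = 0;
  arma::mat logB = log_obs_dens(X, means, covs, reg, n_loaded);
  arma::mat logA = arma::log(trans + 1e-300);
  arma::mat delta(T, K);
  arma::umat psi(T, K, arma::fill::zeros);
  delta.row(0) = arma::log(init.t() + 1e-300) + logB.row(0);
  for (arma::uword t = 1; t < T; ++t) {
    for (arma::uword j = 0; j < K; ++j) {
      arma::vec cand = delta.row(t - 1).t() + logA.col(j);
      arma::uword best = cand.index_max();
      psi(t, j) = best;
      delta(t, j) = cand[best] + logB(t, j);
    }
  }
  IntegerVector path(T);
  arma::uword s = delta.row(T - 1).index_max();
  path[T - 1] = s + 1;
  for (arma::uword t = T - 1; t >= 1; --t) {
    s = psi(t, s);
    path[t - 1] = s + 1;
  }
  return path;
}

// Markov chain sampling through R's RNG (deterministic under set.seed()).
// [[Rcpp::export]]
IntegerVector markov_sample_cpp(const arma::mat& trans, const arma::vec& init,
                                int n) {
  const arma::uword K = init.n_elem;
  IntegerVector out(n);
  auto draw = [&](const arma::vec& p) -> arma::uword {
    double u = R::unif_rand(), acc = 0.0;
    for (arma::uword k = 0; k < K; ++k) {
      acc += p[k];
      if (u <= acc) return k;
    }
    return K - 1;
  };
  arma::uword s = draw(init);
  out[0] = s + 1;
  for (int t = 1; t < n; ++t) {
    s = draw(trans.row(s).t());
    out[t] = s + 1;
  }
  return out;
}
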