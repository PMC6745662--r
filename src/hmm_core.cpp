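// Core recursions for the movement HMM: scaled forward log-likelihood,
// Viterbi decoding, one-step-ahead predictive state weights, and an exact
// Euclidean distance transform for raster masks. Kept in C++ because the
// forward/Viterbi loops are inherently sequential over time.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double POS_INF = std::numeric_limits<double>::infinity();

// column of beta for transition i -> j (0-based), row-major over off-diagonal
static inline int beta_col(int i, int j, int N) {
  return i * (N - 1) + (j - (j > i ? 1 : 0));
}

// multinomial-logit transition matrix at covariate row x (length 1+p)
static arma::mat gamma_at(const arma::mat& beta, const arma::rowvec& x, int N) {
  arma::mat G(N, N);
  for (int i = 0; i < N; ++i) {
    arma::vec eta(N, arma::fill::zeros); // eta_ii = 0
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      eta(j) = arma::dot(x, beta.col(beta_col(i, j, N)));
    }
    double m = eta.max();
    arma::vec e = arma::exp(eta - m);
    G.row(i) = (e / arma::accu(e)).t();
  }
  return G;
}

// stationary distribution of a row-stochastic matrix: delta (I - G + U) = 1
static arma::rowvec stationary_of(const arma::mat& G) {
  int N = G.n_rows;
  arma::mat A = arma::eye(N, N) - G + arma::ones(N, N);
  arma::vec d;
  bool ok = arma::solve(d, A.t(), arma::ones(N), arma::solve_opts::no_approx);
  if (!ok) d = arma::ones(N) / N;
  return d.t();
}

// emission likelihood matrix (T x N); missing channels contribute factor 1
static arma::mat emission_matrix(const NumericVector& step,
                                 const NumericVector& angle,
                                 const arma::vec& mu, const arma::vec& sigma,
                                 const arma::vec& zmass,
                                 const arma::vec& amu, const arma::vec& kappa) {
  int T = step.size(), N = mu.n_elem;
  arma::vec shape = arma::square(mu) / arma::square(sigma);
  arma::vec rate = mu / arma::square(sigma);    // 1 / scale
  // per-state log-density constants (von Mises normalizer uses the
  // exponentially scaled Bessel for stability at large kappa)
  arma::vec g_c(N), vm_c(N), cos_amu(N), sin_amu(N), log_zm(N);
  for (int k = 0; k < N; ++k) {
    g_c(k) = std::log1p(-zmass(k)) - std::lgamma(shape(k)) +
      shape(k) * std::log(rate(k));
    vm_c(k) = std::log(2.0 * M_PI) +
      std::log(R::bessel_i(kappa(k), 0.0, 2.0)) + kappa(k);
    cos_amu(k) = std::cos(amu(k));
    sin_amu(k) = std::sin(amu(k));
    log_zm(k) = std::log(zmass(k));
  }
  arma::mat E(T, N, arma::fill::ones);
  for (int t = 0; t < T; ++t) {
    bool s_ok = !NumericVector::is_na(step[t]);
    bool a_ok = !NumericVector::is_na(angle[t]);
    if (!s_ok && !a_ok) continue;
    double logl = (s_ok && step[t] > 0.0) ? std::log(step[t]) : 0.0;
    double ca = 0.0, sa = 0.0;
    if (a_ok) { ca = std::cos(angle[t]); sa = std::sin(angle[t]); }
    for (int k = 0; k < N; ++k) {
      double lp = 0.0;
      if (s_ok) {
        if (step[t] == 0.0) lp += log_zm(k);
        else lp += g_c(k) + (shape(k) - 1.0) * logl - rate(k) * step[t];
      }
      if (a_ok)
        lp += kappa(k) * (ca * cos_amu(k) + sa * sin_amu(k)) - vm_c(k);
      E(t, k) = std::exp(lp);
    }
  }
  return E;
}

// [[Rcpp::export]]
double C_hmm_loglik(NumericVector step, NumericVector angle,
                    arma::mat X, IntegerVector track_start,
                    IntegerVector track_end,
                    arma::vec mu, arma::vec sigma, arma::vec zmass,
                    arma::vec amu, arma::vec kappa, arma::mat beta,
                    bool stationary_delta, arma::vec delta0) {
  int N = mu.n_elem;
  arma::mat E = emission_matrix(step, angle, mu, sigma, zmass, amu, kappa);
  // intercept-only designs have one constant transition matrix
  bool homog = (X.n_cols == 1);
  arma::mat G0;
  arma::rowvec delta_h;
  if (homog) {
    G0 = gamma_at(beta, X.row(0), N);
    delta_h = stationary_of(G0);
  }
  double ll = 0.0;
  for (int tr = 0; tr < track_start.size(); ++tr) {
    int a = track_start[tr] - 1, b = track_end[tr] - 1;
    arma::rowvec delta = stationary_delta
      ? (homog ? delta_h : stationary_of(gamma_at(beta, X.row(a), N)))
      : arma::rowvec(delta0.t());
    arma::rowvec phi = delta % E.row(a);
    double c = arma::accu(phi);
    if (!(c > 0.0)) return NEG_INF;
    ll += std::log(c);
    phi /= c;
    for (int t = a + 1; t <= b; ++t) {
      const arma::mat& G = homog ? G0 : gamma_at(beta, X.row(t - 1), N);
      phi = (phi * G) % E.row(t);
      c = arma::accu(phi);
      if (!(c > 0.0)) return NEG_INF;
      ll += std::log(c);
      phi /= c;
    }
  }
  return ll;
}

// [[Rcpp::export]]
IntegerVector C_viterbi(NumericVector step, NumericVector angle,
                        arma::mat X, IntegerVector track_start,
                        IntegerVector track_end,
                        arma::vec mu, arma::vec sigma, arma::vec zmass,
                        arma::vec amu, arma::vec kappa, arma::mat beta,
                        bool stationary_delta, arma::vec delta0) {
  int N = mu.n_elem, T = step.size();
  arma::mat E = emission_matrix(step, angle, mu, sigma, zmass, amu, kappa);
  arma::mat logE = arma::log(E);
  IntegerVector path(T);
  for (int tr = 0; tr < track_start.size(); ++tr) {
    int a = track_start[tr] - 1, b = track_end[tr] - 1;
    int L = b - a + 1;
    arma::mat lv(L, N);
    arma::imat back(L, N, arma::fill::zeros);
    arma::rowvec delta = stationary_delta
      ? stationary_of(gamma_at(beta, X.row(a), N))
      : arma::rowvec(delta0.t());
    lv.row(0) = arma::log(delta) + logE.row(a);
    for (int t = a + 1; t <= b; ++t) {
      int r = t - a;
      arma::mat logG = arma::log(gamma_at(beta, X.row(t - 1), N));
      for (int j = 0; j < N; ++j) {
        double best = NEG_INF; int arg = 0;
        for (int i = 0; i < N; ++i) {
          double v = lv(r - 1, i) + logG(i, j);
          if (v > best) { best = v; arg = i; } // strict '>' => lowest index wins ties
        }
        lv(r, j) = best + logE(t, j);
        back(r, j) = arg;
      }
    }
    int s = 0; double best = NEG_INF;
    for (int j = 0; j < N; ++j)
      if (lv(L - 1, j) > best) { best = lv(L - 1, j); s = j; }
    path[b] = s + 1;
    for (int r = L - 1; r > 0; --r) {
      s = back(r, s);
      path[a + r - 1] = s + 1;
    }
  }
  return path;
}

// One-step-ahead predictive weights w_t(k) = P(S_t = k | obs_{1:t-1}),
// first slot of each track gets the initial distribution.
// [[Rcpp::export]]
arma::mat C_forward_weights(NumericVector step, NumericVector angle,
                            arma::mat X, IntegerVector track_start,
                            IntegerVector track_end,
                            arma::vec mu, arma::vec sigma, arma::vec zmass,
                            arma::vec amu, arma::vec kappa, arma::mat beta,
                            bool stationary_delta, arma::vec delta0) {
  int N = mu.n_elem, T = step.size();
  arma::mat E = emission_matrix(step, angle, mu, sigma, zmass, amu, kappa);
  arma::mat W(T, N, arma::fill::zeros);
  for (int tr = 0; tr < track_start.size(); ++tr) {
    int a = track_start[tr] - 1, b = track_end[tr] - 1;
    arma::rowvec delta = stationary_delta
      ? stationary_of(gamma_at(beta, X.row(a), N))
      : arma::rowvec(delta0.t());
    W.row(a) = delta;
    arma::rowvec phi = delta % E.row(a);
    double c = arma::accu(phi);
    phi = (c > 0.0) ? arma::rowvec(phi / c) : delta;
    for (int t = a + 1; t <= b; ++t) {
      arma::mat G = gamma_at(beta, X.row(t - 1), N);
      arma::rowvec pred = phi * G;
      W.row(t) = pred;
      phi = pred % E.row(t);
      c = arma::accu(phi);
      phi = (c > 0.0) ? arma::rowvec(phi / c) : pred;
    }
  }
  return W;
}

// [[Rcpp::export]]
arma::mat C_transition_matrix(arma::mat beta, arma::vec x, int N) {
  return gamma_at(beta, arma::rowvec(x.t()), N);
}

// 1-D squared distance transform (lower-envelope-of-parabolas algorithm);
// infinite entries (no feature reachable along this line yet) are skipped
static void dt1d(const arma::vec& f, arma::vec& d) {
  int n = f.n_elem;
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f(q) == POS_INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -POS_INF; z[1] = POS_INF;
      continue;
    }
    double s;
    while (true) {
      s = ((f(q) + (double)q * q) - (f(v[k]) + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = POS_INF;
  }
  if (k < 0) { d.fill(POS_INF); return; }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d(q) = dq * dq + f(v[k]);
  }
}

// exact squared Euclidean distance transform in cell units; mask != 0 are
// the feature (woodland) cells
// [[Rcpp::export]]
arma::mat C_edt_sq(arma::mat mask) {
  int nr = mask.n_rows, nc = mask.n_cols;
  arma::mat g(nr, nc);
  g.fill(POS_INF);
  g.elem(arma::find(mask != 0)).zeros();
  arma::vec d;
  for (int j = 0; j < nc; ++j) {
    arma::vec col = g.col(j);
    if (col.min() == POS_INF) continue;
    d.set_size(nr);
    dt1d(col, d);
    g.col(j) = d;
  }
  for (int i = 0; i < nr; ++i) {
    arma::vec row = g.row(i).t();
    d.set_size(nc);
    dt1d(row, d);
    g.row(i) = d.t();
  }
  return g;
}
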