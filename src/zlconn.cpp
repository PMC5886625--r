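// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Exact-discretization OU recursion x_{t+1} = E x_t + L z_t with standard
// normal z drawn from R's RNG stream (so set.seed() governs the run).
// Returns the n x n_steps sample matrix, first column = x0.
// [[Rcpp::export]]
arma::mat ou_simulate_cpp(const arma::mat& E, const arma::mat& L,
                          const arma::vec& x0, const int n_steps) {
  const int n = E.n_rows;
  mat X(n, n_steps);
  vec x = x0, z(n);
  X.col(0) = x;
  for (int t = 1; t < n_steps; ++t) {
    for (int i = 0; i < n; ++i) z[i] = R::norm_rand();
    x = E * x + L * z;
    X.col(t) = x;
  }
  return X;
}

// Causal FIR filter along rows, output truncated to the input length
// (zero initial history).
// [[Rcpp::export]]
arma::mat fir_filter_cpp(const arma::mat& x, const arma::vec& kernel) {
  const int n = x.n_rows, m = x.n_cols, K = kernel.n_elem;
  mat y(n, m);
  std::vector<double> row(m), out(m);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < m; ++t) row[t] = x(i, t);
    for (int t = 0; t < m; ++t) {
      const int jmax = std::min(t + 1, K);
      double acc = 0.0;
      for (int j = 0; j < jmax; ++j) acc += kernel[j] * row[t - j];
      out[t] = acc;
    }
    for (int t = 0; t < m; ++t) y(i, t) = out[t];
  }
  return y;
}

// Streaming pipeline for long simulations: OU recursion, optional causal
// HRF filtering via a ring buffer, optional observation noise, and running
// first/second moments of the (noisy) observed signal -- without ever
// materializing the full series.  Draw order per step matches the
// composed simulate/filter path when sigma_obs == 0.
// [[Rcpp::export]]
Rcpp::List ou_moments_cpp(const arma::mat& E, const arma::mat& L,
                          const arma::vec& x0, const int n_steps,
                          const arma::vec& kernel, const bool use_hrf,
                          const double sigma_obs, const int block = 1024) {
  const int n = E.n_rows;
  const int K = kernel.n_elem;
  mat hist(n, use_hrf ? K : 1, fill::zeros);
  vec kk(use_hrf ? K : 1);
  mat S(n, n, fill::zeros);
  vec ysum(n, fill::zeros), csum(n, fill::zeros), c2sum(n, fill::zeros);
  mat Y(n, block);
  int bi = 0;
  vec x = x0, z(n), y(n);
  for (int t = 0; t < n_steps; ++t) {
    if (t > 0) {
      for (int i = 0; i < n; ++i) z[i] = R::norm_rand();
      x = E * x + L * z;
    }
    if (use_hrf) {
      const int pos = t % K;
      hist.col(pos) = x;
      for (int c = 0; c < K; ++c) {
        int j = pos - c; if (j < 0) j += K;
        kk[c] = kernel[j];
      }
      y = hist * kk;
      if (t < K - 1) {
        // history slots not yet written are zero-initialized, so the
        // truncated causal convolution is already correct
      }
    } else {
      y = x;
    }
    csum += y;
    c2sum += square(y);
    if (sigma_obs > 0) {
      for (int i = 0; i < n; ++i) y[i] += sigma_obs * R::norm_rand();
    }
    ysum += y;
    Y.col(bi++) = y;
    if (bi == block) {
      S += Y * Y.t();
      bi = 0;
    }
  }
  if (bi > 0) S += Y.cols(0, bi - 1) * Y.cols(0, bi - 1).t();
  return Rcpp::List::create(
      Rcpp::Named("S") = S, Rcpp::Named("sum") = ysum,
      Rcpp::Named("clean_sum") = csum, Rcpp::Named("clean_sq") = c2sum,
      Rcpp::Named("n_steps") = n_steps);
}

// L1 cost, optionally eps-smoothed (sum sqrt(x^2+eps^2)-eps) and
// optionally excluding the diagonal
static double l1s(const mat& M, const double eps, const bool incl_diag) {
  if (eps <= 0.0) {
    double v = accu(abs(M));
    return incl_diag ? v : v - accu(abs(M.diag()));
  }
  const mat S = sqrt(square(M) + eps * eps) - eps;
  return incl_diag ? accu(S) : accu(S) - accu(S.diag());
}

// Geodesic L1 descent over the orthogonal group (real fast path).
// Mirrors the R reference implementation unitary_minimize_ref().
// status: 0 maxiter, 1 gtol, 2 xftol, 3 stall.
// [[Rcpp::export]]
Rcpp::List unitary_descent_cpp(const arma::mat& B0, const double xtol,
                               const double ftol, const double gtol,
                               const double kappa, const int max_iter,
                               const int reorth_every,
                               const int max_halvings,
                               const arma::mat& U0, const double eps = 0.0,
                               const bool incl_diag = true) {
  const int n = B0.n_rows;
  mat U = U0, UB = U0 * B0;
  double gamma = l1s(UB, eps, incl_diag);
  std::vector<double> tr_g, tr_n, tr_d;
  int status = 0;
  mat a_last(n, n, fill::zeros);
  bool have_a = false;
  const cx_double iu(0.0, 1.0);
  for (int it = 1; it <= max_iter; ++it) {
    mat S = eps > 0.0 ? mat(UB / sqrt(square(UB) + eps * eps)) : sign(UB);
    if (!incl_diag) S.diag().zeros();
    mat d = S * B0.t();
    mat a = 0.5 * (d * U.t() - U * d.t());
    double gnorm = 2.0 * norm(a, "fro");
    tr_g.push_back(gamma);
    tr_n.push_back(gnorm);
    if (gnorm < gtol) { tr_d.push_back(0.0); status = 1; break; }
    a_last = a; have_a = true;
    cx_mat H(zeros(n, n), a);  // H = i a, Hermitian
    vec lam; cx_mat V;
    eig_sym(lam, V, H);
    const double lmax = max(abs(lam));
    double delta = 2.0 * M_PI / (lmax * kappa);
    bool accepted = false;
    mat U_new(n, n);
    double g_new = gamma;
    for (int h = 0; h <= max_halvings; ++h) {
      cx_vec ph = exp(iu * delta * conv_to<cx_vec>::from(lam));
      cx_mat Exp = V * diagmat(ph) * V.t();
      U_new = real(Exp) * U;
      g_new = l1s(U_new * B0, eps, incl_diag);
      if (g_new <= gamma) { accepted = true; break; }
      delta /= 2.0;
    }
    tr_d.push_back(delta);
    if (!accepted) { status = 3; break; }
    const bool stalled =
        norm(U_new - U, "fro") / n < xtol &&
        std::abs(gamma - g_new) / (std::abs(gamma) + 1.0) < ftol;
    U = U_new;
    gamma = g_new;
    if (it % reorth_every == 0) {
      mat Us, Vs; vec sv;
      svd(Us, sv, Vs, U);
      U = Us * Vs.t();
    }
    UB = U * B0;
    if (stalled) { status = 2; break; }
  }
  return Rcpp::List::create(
      Rcpp::Named("U") = U, Rcpp::Named("status") = status,
      Rcpp::Named("iterations") = (int)tr_g.size(),
      Rcpp::Named("gamma_trace") = tr_g, Rcpp::Named("grad_trace") = tr_n,
      Rcpp::Named("delta_trace") = tr_d,
      Rcpp::Named("a_last") = have_a ? Rcpp::wrap(a_last) : R_NilValue);
}
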