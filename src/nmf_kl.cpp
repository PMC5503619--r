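// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Multiplicative-update NMF for the (generalized) Kullback-Leibler divergence
//   D(A || WH) = sum_ij [ A_ij log(A_ij / (WH)_ij) - A_ij + (WH)_ij ]
// with the classic updates
//   H_au <- H_au * sum_i W_ia A_iu / (WH)_iu / sum_i W_ia
//   W_ia <- W_ia * sum_u H_au A_iu / (WH)_iu / sum_u H_au
// which never increase the divergence. Convergence is monitored through the
// sample connectivity implied by H (argmax metagene per column): the run
// stops once the connectivity has been unchanged for `conv_window`
// consecutive checks (one check every `check_every` iterations).
//
// W0/H0 are initialized by the caller, so the routine itself is
// deterministic; the divergence is recorded at every connectivity check
// (evaluating it every iteration would double the cost of a run for a
// quantity that is only asserted to be non-increasing).

// [[Rcpp::export]]
Rcpp::List nmf_kl_cpp(const arma::mat& A, arma::mat W, arma::mat H,
                      int max_iter, int check_every, int conv_window) {
  const uword N = A.n_rows, M = A.n_cols;
  const double floor = 1e-16;
  std::vector<double> trace;
  trace.reserve(static_cast<size_t>(max_iter));

  urowvec labels_prev(M, fill::zeros);
  bool have_prev = false;
  int stable = 0, it = 0;
  bool converged = false;

  for (it = 1; it <= max_iter; ++it) {
    mat WH = W * H;
    WH.for_each([&](double& v) { if (v < floor) v = floor; });
    mat R = A / WH;

    // H update
    H %= (W.t() * R);
    vec wsum = sum(W, 0).t();
    wsum.for_each([&](double& v) { if (v < floor) v = floor; });
    H.each_col() /= wsum;

    // W update (recompute residual ratio at the new H)
    WH = W * H;
    WH.for_each([&](double& v) { if (v < floor) v = floor; });
    R = A / WH;
    W %= (R * H.t());
    rowvec hsum = sum(H, 1).t();
    hsum.for_each([&](double& v) { if (v < floor) v = floor; });
    W.each_row() /= hsum;

    if (it % check_every == 0 || it == max_iter) {
      // divergence at the updated factors
      WH = W * H;
      WH.for_each([&](double& v) { if (v < floor) v = floor; });
      double d = 0.0;
      for (uword j = 0; j < M; ++j)
        for (uword i = 0; i < N; ++i) {
          const double a = A(i, j), wh = WH(i, j);
          if (a > 0.0) d += a * std::log(a / wh) - a + wh;
          else d += wh;
        }
      trace.push_back(d);

      urowvec labels(M);
      for (uword j = 0; j < M; ++j) labels(j) = H.col(j).index_max();
      if (have_prev && all(labels == labels_prev)) {
        if (++stable >= conv_window) { converged = true; break; }
      } else {
        stable = 0;
      }
      labels_prev = labels;
      have_prev = true;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("H") = H,
      Rcpp::Named("objective_trace") = trace,
      Rcpp::Named("iterations") = std::min(it, max_iter),
      Rcpp::Named("converged") = converged);
}
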