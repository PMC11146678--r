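// Scaled forward-backward and Baum-Welch for discrete-emission HMMs with
// structural-zero transition masks.  Transitions are iterated over the edge
// list of the mask, so feedforward (Bakis) chains and the block-diagonal
// boosted topology cost O(T * n_edges) rather than O(T * K^2).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct EdgeList {
  std::vector<int> from, to;
};

static EdgeList edges_from_mask(const LogicalMatrix &mask) {
  EdgeList e;
  const int K = mask.nrow();
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j)
      if (mask(i, j)) {
        e.from.push_back(i);
        e.to.push_back(j);
      }
  return e;
}

// Scaled forward-backward on obs[offset .. offset+T-1] (0-based symbols).
// Fills gamma (T x K, row-major in `gamma`) and returns the log-likelihood.
// alpha/beta/c are caller-provided workspaces (resized here).
static double forward_backward_core(
    const double *pi, const NumericMatrix &A, const NumericMatrix &B,
    const int *obs, int T, int K, const EdgeList &e,
    std::vector<double> &alpha, std::vector<double> &beta,
    std::vector<double> &c, std::vector<double> &gamma) {
  const int nE = (int)e.from.size();
  alpha.assign((size_t)T * K, 0.0);
  beta.assign((size_t)T * K, 0.0);
  c.assign(T, 0.0);
  gamma.assign((size_t)T * K, 0.0);

  double s = 0.0;
  for (int j = 0; j < K; ++j) {
    alpha[j] = pi[j] * B(j, obs[0]);
    s += alpha[j];
  }
  if (s <= 0.0) stop("forward pass underflow at t = 1 (zero total probability)");
  c[0] = s;
  for (int j = 0; j < K; ++j) alpha[j] /= s;

  for (int t = 1; t < T; ++t) {
    double *at = &alpha[(size_t)t * K];
    const double *ap = &alpha[(size_t)(t - 1) * K];
    for (int k = 0; k < nE; ++k) at[e.to[k]] += ap[e.from[k]] * A(e.from[k], e.to[k]);
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      at[j] *= B(j, obs[t]);
      s += at[j];
    }
    if (s <= 0.0) stop("forward pass underflow at t = %d (zero total probability)", t + 1);
    c[t] = s;
    for (int j = 0; j < K; ++j) at[j] /= s;
  }

  for (int j = 0; j < K; ++j) beta[(size_t)(T - 1) * K + j] = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    double *bt = &beta[(size_t)t * K];
    const double *bn = &beta[(size_t)(t + 1) * K];
    for (int k = 0; k < nE; ++k)
      bt[e.from[k]] += A(e.from[k], e.to[k]) * B(e.to[k], obs[t + 1]) * bn[e.to[k]];
    const double cs = c[t + 1];
    for (int j = 0; j < K; ++j) bt[j] /= cs;
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    ll += std::log(c[t]);
    double *gt = &gamma[(size_t)t * K];
    const double *at = &alpha[(size_t)t * K];
    const double *bt = &beta[(size_t)t * K];
    double gs = 0.0;
    for (int j = 0; j < K; ++j) {
      gt[j] = at[j] * bt[j];
      gs += gt[j];
    }
    for (int j = 0; j < K; ++j) gt[j] /= gs;
  }
  return ll;
}

// [[Rcpp::export]]
List rs_forward_backward(NumericVector pi, NumericMatrix A, NumericMatrix B,
                         LogicalMatrix mask, IntegerVector obs) {
  const int K = A.nrow(), T = obs.size();
  if (T < 1) stop("empty observation sequence");
  EdgeList e = edges_from_mask(mask);
  std::vector<double> alpha, beta, c, gamma;
  double ll = forward_backward_core(REAL(pi), A, B, obs.begin(), T, K, e,
                                    alpha, beta, c, gamma);
  NumericMatrix G(T, K);
  for (int t = 0; t < T; ++t)
    for (int j = 0; j < K; ++j) G(t, j) = gamma[(size_t)t * K + j];
  return List::create(_["gamma"] = G, _["loglik"] = ll);
}

// Baum-Welch over a list of sequences.  pi is held fixed (the chain always
// starts in its first state); masked transitions stay exactly zero; every
// emission row gets an additive floor and is renormalized after each M-step.
// [[Rcpp::export]]
List rs_baum_welch(NumericVector pi, NumericMatrix A0, NumericMatrix B0,
                   LogicalMatrix mask, List obs_list, int max_iter,
                   double tol, double emission_floor) {
  const int K = A0.nrow(), M = B0.ncol();
  EdgeList e = edges_from_mask(mask);
  const int nE = (int)e.from.size();
  NumericMatrix A = clone(A0), B = clone(B0);

  const int S = obs_list.size();
  std::vector<IntegerVector> seqs;
  seqs.reserve(S);
  for (int s = 0; s < S; ++s) {
    IntegerVector o = obs_list[s];
    if (o.size() < 1) stop("empty observation sequence");
    for (int t = 0; t < o.size(); ++t)
      if (o[t] < 0 || o[t] >= M) stop("symbol out of range [0, M)");
    seqs.push_back(o);
  }

  std::vector<double> alpha, beta, c, gamma;
  std::vector<double> xi_sum(nE), g_trans(K), g_all(K), gB((size_t)K * M);
  std::vector<double> ll_trace;
  double ll_prev = R_NegInf;
  int iter = 0;
  bool converged = false;

  for (iter = 1; iter <= max_iter; ++iter) {
    std::fill(xi_sum.begin(), xi_sum.end(), 0.0);
    std::fill(g_trans.begin(), g_trans.end(), 0.0);
    std::fill(g_all.begin(), g_all.end(), 0.0);
    std::fill(gB.begin(), gB.end(), 0.0);
    double ll = 0.0;

    for (int s = 0; s < S; ++s) {
      const IntegerVector &o = seqs[s];
      const int T = o.size();
      ll += forward_backward_core(REAL(pi), A, B, o.begin(), T, K, e,
                                  alpha, beta, c, gamma);
      for (int t = 0; t < T; ++t) {
        const double *gt = &gamma[(size_t)t * K];
        for (int j = 0; j < K; ++j) {
          g_all[j] += gt[j];
          gB[(size_t)j * M + o[t]] += gt[j];
          if (t < T - 1) g_trans[j] += gt[j];
        }
      }
      for (int t = 0; t < T - 1; ++t) {
        const double *at = &alpha[(size_t)t * K];
        const double *bn = &beta[(size_t)(t + 1) * K];
        const double cs = c[t + 1];
        for (int k = 0; k < nE; ++k) {
          const int i = e.from[k], j = e.to[k];
          xi_sum[k] += at[i] * A(i, j) * B(j, o[t + 1]) * bn[j] / cs;
        }
      }
    }

    ll_trace.push_back(ll);
    if (iter > 1 && ll - ll_prev < tol) {
      converged = true;
      break;
    }
    ll_prev = ll;

    // M-step: transitions (masked entries untouched, i.e. exactly zero)
    for (int i = 0; i < K; ++i) {
      if (g_trans[i] <= 0.0) continue;  // state never occupied: keep row
      double rs = 0.0;
      for (int k = 0; k < nE; ++k)
        if (e.from[k] == i) {
          A(i, e.to[k]) = xi_sum[k] / g_trans[i];
          rs += A(i, e.to[k]);
        }
      if (rs > 0.0)
        for (int k = 0; k < nE; ++k)
          if (e.from[k] == i) A(i, e.to[k]) /= rs;
    }
    // M-step: emissions with additive floor + renormalization
    for (int j = 0; j < K; ++j) {
      if (g_all[j] > 0.0)
        for (int m = 0; m < M; ++m) B(j, m) = gB[(size_t)j * M + m] / g_all[j];
      double rs = 0.0;
      for (int m = 0; m < M; ++m) {
        B(j, m) += emission_floor;
        rs += B(j, m);
      }
      for (int m = 0; m < M; ++m) B(j, m) /= rs;
    }
  }

  return List::create(_["A"] = A, _["B"] = B,
                      _["loglik_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()),
                      _["iterations"] = std::min(iter, max_iter),
                      _["converged"] = converged);
}

// Sliding-window posterior decoding: for each window [starts[w], starts[w] +
// width) of obs (0-based starts), run forward-backward restarting from pi and
// return the bin-averaged posterior (n_windows x K).
// [[Rcpp::export]]
NumericMatrix rs_window_posteriors(NumericVector pi, NumericMatrix A,
                                   NumericMatrix B, LogicalMatrix mask,
                                   IntegerVector obs, IntegerVector starts,
                                   int width) {
  const int K = A.nrow(), nW = starts.size(), T = obs.size();
  EdgeList e = edges_from_mask(mask);
  std::vector<double> alpha, beta, c, gamma;
  NumericMatrix out(nW, K);
  for (int w = 0; w < nW; ++w) {
    const int s0 = starts[w];
    if (s0 < 0 || s0 + width > T) stop("window exceeds sequence bounds");
    forward_backward_core(REAL(pi), A, B, obs.begin() + s0, width, K, e,
                          alpha, beta, c, gamma);
    for (int j = 0; j < K; ++j) {
      double m = 0.0;
      for (int t = 0; t < width; ++t) m += gamma[(size_t)t * K + j];
      out(w, j) = m / width;
    }
  }
  return out;
}
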