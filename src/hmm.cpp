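// Scaled forward-backward, Baum-Welch EM, posterior and Viterbi decoding
// for a hidden Markov model with independent-Bernoulli (multivariate
// binary) emissions. Observations arrive as a list of integer matrices
// (one per sequence/chromosome, rows = bins, cols = marks); there are no
// transitions across sequence boundaries.
//
// Hot loops work on row-major flat buffers (obs[t*M+m], B[t*K+k]) so the
// time-ordered recursions stream through memory.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

typedef std::vector<double> dvec;
typedef std::vector<int> ivec;

// column-major R matrix -> row-major flat vector
static ivec flatten_obs(const IntegerMatrix& obs) {
  const int T = obs.nrow(), M = obs.ncol();
  ivec out((size_t)T * M);
  for (int m = 0; m < M; ++m) {
    for (int t = 0; t < T; ++t) out[(size_t)t * M + m] = obs(t, m);
  }
  return out;
}

static dvec flatten_rowmajor(const NumericMatrix& x) {
  const int R = x.nrow(), C = x.ncol();
  dvec out((size_t)R * C);
  for (int j = 0; j < C; ++j) {
    for (int i = 0; i < R; ++i) out[(size_t)i * C + j] = x(i, j);
  }
  return out;
}

// per-bin emission probabilities: B[t*K+k]
static void emission_matrix(const ivec& obs, int T, int M, const dvec& E,
                            int K, dvec& B) {
  for (int t = 0; t < T; ++t) {
    const int* o = &obs[(size_t)t * M];
    double* b = &B[(size_t)t * K];
    for (int k = 0; k < K; ++k) {
      const double* e = &E[(size_t)k * M];
      double p = 1.0;
      for (int m = 0; m < M; ++m) p *= o[m] ? e[m] : (1.0 - e[m]);
      b[k] = p;
    }
  }
}

// scaled forward pass; returns log-likelihood
static double forward_scaled(const dvec& B, int T, int K, const dvec& pi,
                             const dvec& A, dvec& alpha, dvec& c) {
  double ll = 0.0, s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha[k] = pi[k] * B[k];
    s += alpha[k];
  }
  if (s <= 0.0) return R_NegInf;
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha[k] /= s;
  ll += std::log(s);
  for (int t = 1; t < T; ++t) {
    const double* ap = &alpha[(size_t)(t - 1) * K];
    const double* b = &B[(size_t)t * K];
    double* an = &alpha[(size_t)t * K];
    for (int k = 0; k < K; ++k) an[k] = 0.0;
    for (int j = 0; j < K; ++j) {
      const double aj = ap[j];
      const double* Aj = &A[(size_t)j * K];
      for (int k = 0; k < K; ++k) an[k] += aj * Aj[k];
    }
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      an[k] *= b[k];
      s += an[k];
    }
    if (s <= 0.0) return R_NegInf;
    c[t] = s;
    for (int k = 0; k < K; ++k) an[k] /= s;
    ll += std::log(s);
  }
  return ll;
}

// backward pass with the forward scales
static void backward_scaled(const dvec& B, int T, int K, const dvec& A,
                            const dvec& c, dvec& beta) {
  for (int k = 0; k < K; ++k) beta[(size_t)(T - 1) * K + k] = 1.0 / c[T - 1];
  dvec tmp(K);
  for (int t = T - 2; t >= 0; --t) {
    const double* bn = &B[(size_t)(t + 1) * K];
    const double* be = &beta[(size_t)(t + 1) * K];
    double* bt = &beta[(size_t)t * K];
    for (int j = 0; j < K; ++j) tmp[j] = bn[j] * be[j];
    for (int k = 0; k < K; ++k) {
      const double* Ak = &A[(size_t)k * K];
      double v = 0.0;
      for (int j = 0; j < K; ++j) v += Ak[j] * tmp[j];
      bt[k] = v / c[t];
    }
  }
}

struct FlatModel {
  int K, M;
  dvec pi, A, E;  // A, E row-major
};

static FlatModel flatten_model(const NumericVector& pi,
                               const NumericMatrix& A,
                               const NumericMatrix& E) {
  FlatModel m;
  m.K = E.nrow();
  m.M = E.ncol();
  m.pi = dvec(pi.begin(), pi.end());
  m.A = flatten_rowmajor(A);
  m.E = flatten_rowmajor(E);
  return m;
}

// [[Rcpp::export]]
double cpp_forward_loglik(List obs_list, NumericVector pi, NumericMatrix A,
                          NumericMatrix E) {
  FlatModel m = flatten_model(pi, A, E);
  double ll = 0.0;
  for (int s = 0; s < obs_list.size(); ++s) {
    IntegerMatrix om = obs_list[s];
    const int T = om.nrow();
    if (T == 0) continue;
    ivec obs = flatten_obs(om);
    dvec B((size_t)T * m.K), alpha((size_t)T * m.K), c(T);
    emission_matrix(obs, T, m.M, m.E, m.K, B);
    double l = forward_scaled(B, T, m.K, m.pi, m.A, alpha, c);
    if (!R_FINITE(l)) return R_NegInf;
    ll += l;
  }
  return ll;
}

// [[Rcpp::export]]
List cpp_posterior(List obs_list, NumericVector pi, NumericMatrix A,
                   NumericMatrix E) {
  FlatModel m = flatten_model(pi, A, E);
  const int K = m.K;
  List out(obs_list.size());
  for (int s = 0; s < obs_list.size(); ++s) {
    IntegerMatrix om = obs_list[s];
    const int T = om.nrow();
    NumericMatrix gamma(T, K);
    if (T > 0) {
      ivec obs = flatten_obs(om);
      dvec B((size_t)T * K), alpha((size_t)T * K), beta((size_t)T * K),
          c(T);
      emission_matrix(obs, T, m.M, m.E, K, B);
      double l = forward_scaled(B, T, K, m.pi, m.A, alpha, c);
      if (!R_FINITE(l)) stop("observation sequence has probability zero");
      backward_scaled(B, T, K, m.A, c, beta);
      for (int t = 0; t < T; ++t) {
        double z = 0.0;
        const double* a = &alpha[(size_t)t * K];
        const double* b = &beta[(size_t)t * K];
        for (int k = 0; k < K; ++k) z += a[k] * b[k];
        for (int k = 0; k < K; ++k) gamma(t, k) = a[k] * b[k] / z;
      }
    }
    out[s] = gamma;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_viterbi(List obs_list, NumericVector pi, NumericMatrix A,
                 NumericMatrix E) {
  FlatModel m = flatten_model(pi, A, E);
  const int K = m.K;
  dvec lpi(K), lA((size_t)K * K);
  for (int k = 0; k < K; ++k) lpi[k] = std::log(m.pi[k]);
  for (size_t i = 0; i < lA.size(); ++i) lA[i] = std::log(m.A[i]);
  List out(obs_list.size());
  for (int s = 0; s < obs_list.size(); ++s) {
    IntegerMatrix om = obs_list[s];
    const int T = om.nrow();
    IntegerVector path(T);
    if (T > 0) {
      ivec obs = flatten_obs(om);
      dvec B((size_t)T * K);
      emission_matrix(obs, T, m.M, m.E, K, B);
      dvec delta((size_t)T * K);
      ivec psi((size_t)T * K);
      for (int k = 0; k < K; ++k) delta[k] = lpi[k] + std::log(B[k]);
      for (int t = 1; t < T; ++t) {
        const double* dp = &delta[(size_t)(t - 1) * K];
        double* dn = &delta[(size_t)t * K];
        int* pn = &psi[(size_t)t * K];
        const double* b = &B[(size_t)t * K];
        for (int k = 0; k < K; ++k) {
          double best = R_NegInf;
          int arg = 0;
          for (int j = 0; j < K; ++j) {
            double v = dp[j] + lA[(size_t)j * K + k];
            if (v > best) { best = v; arg = j; }
          }
          dn[k] = best + std::log(b[k]);
          pn[k] = arg;
        }
      }
      int arg = 0;
      double best = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double v = delta[(size_t)(T - 1) * K + k];
        if (v > best) { best = v; arg = k; }
      }
      path[T - 1] = arg + 1;  // states reported 1-based
      for (int t = T - 1; t > 0; --t) {
        arg = psi[(size_t)t * K + arg];
        path[t - 1] = arg + 1;
      }
    }
    out[s] = path;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_baum_welch(List obs_list, NumericVector pi0, NumericMatrix A0,
                    NumericMatrix E0, int max_iter, double rel_tol,
                    double prob_floor) {
  FlatModel m = flatten_model(pi0, A0, E0);
  const int K = m.K, M = m.M;
  const int S = obs_list.size();
  // pre-flatten all sequences once
  std::vector<ivec> seqs;
  std::vector<int> lens;
  for (int s = 0; s < S; ++s) {
    IntegerMatrix om = obs_list[s];
    if (om.nrow() == 0) continue;
    seqs.push_back(flatten_obs(om));
    lens.push_back(om.nrow());
  }
  int Tmax = 0;
  for (size_t i = 0; i < lens.size(); ++i) Tmax = std::max(Tmax, lens[i]);
  dvec B((size_t)Tmax * K), alpha((size_t)Tmax * K), beta((size_t)Tmax * K),
      c(Tmax);
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  double prev_ll = R_NegInf;
  for (int iter = 0; iter < max_iter; ++iter) {
    dvec pi_acc(K, 0.0), xi_acc((size_t)K * K, 0.0),
        emit_num((size_t)K * M, 0.0), gamma_acc(K, 0.0), g(K);
    double ll = 0.0;
    int n_seq = 0;
    for (size_t si = 0; si < seqs.size(); ++si) {
      const ivec& obs = seqs[si];
      const int T = lens[si];
      ++n_seq;
      emission_matrix(obs, T, M, m.E, K, B);
      double l = forward_scaled(B, T, K, m.pi, m.A, alpha, c);
      if (!R_FINITE(l)) stop("zero-probability sequence during EM");
      ll += l;
      backward_scaled(B, T, K, m.A, c, beta);
      for (int t = 0; t < T; ++t) {
        const double* a = &alpha[(size_t)t * K];
        const double* b = &beta[(size_t)t * K];
        const int* o = &obs[(size_t)t * M];
        double z = 0.0;
        for (int k = 0; k < K; ++k) {
          g[k] = a[k] * b[k] * c[t];
          z += g[k];
        }
        for (int k = 0; k < K; ++k) {
          const double gk = g[k] / z;
          gamma_acc[k] += gk;
          if (t == 0) pi_acc[k] += gk;
          double* em = &emit_num[(size_t)k * M];
          for (int mm = 0; mm < M; ++mm) {
            if (o[mm]) em[mm] += gk;
          }
        }
        if (t + 1 < T) {
          const double* bn = &B[(size_t)(t + 1) * K];
          const double* be = &beta[(size_t)(t + 1) * K];
          for (int i = 0; i < K; ++i) {
            const double ai = a[i];
            const double* Ai = &m.A[(size_t)i * K];
            double* xi = &xi_acc[(size_t)i * K];
            for (int j = 0; j < K; ++j) {
              xi[j] += ai * Ai[j] * bn[j] * be[j];
            }
          }
        }
      }
    }
    trace.push_back(ll);
    // M-step
    double pi_sum = 0.0;
    for (int k = 0; k < K; ++k) {
      m.pi[k] = pi_acc[k] / std::max(n_seq, 1);
      if (m.pi[k] < prob_floor) m.pi[k] = prob_floor;
      pi_sum += m.pi[k];
    }
    for (int k = 0; k < K; ++k) m.pi[k] /= pi_sum;
    for (int i = 0; i < K; ++i) {
      double rs = 0.0;
      double* Ai = &m.A[(size_t)i * K];
      const double* xi = &xi_acc[(size_t)i * K];
      for (int j = 0; j < K; ++j) {
        double v = xi[j];
        if (v < prob_floor) v = prob_floor;
        Ai[j] = v;
        rs += v;
      }
      for (int j = 0; j < K; ++j) Ai[j] /= rs;
    }
    for (int k = 0; k < K; ++k) {
      const double denom = gamma_acc[k];
      double* Ek = &m.E[(size_t)k * M];
      const double* em = &emit_num[(size_t)k * M];
      for (int mm = 0; mm < M; ++mm) {
        double e = denom > 0 ? em[mm] / denom : 0.5;
        if (e < prob_floor) e = prob_floor;
        if (e > 1.0 - prob_floor) e = 1.0 - prob_floor;
        Ek[mm] = e;
      }
    }
    if (iter > 0) {
      double rel = std::fabs(ll - prev_ll) / (std::fabs(prev_ll) + 1e-300);
      if (rel < rel_tol) { prev_ll = ll; break; }
    }
    prev_ll = ll;
  }
  // log-likelihood of the final parameters
  double final_ll = 0.0;
  for (size_t si = 0; si < seqs.size(); ++si) {
    emission_matrix(seqs[si], lens[si], M, m.E, K, B);
    double l = forward_scaled(B, lens[si], K, m.pi, m.A, alpha, c);
    final_ll += R_FINITE(l) ? l : R_NegInf;
  }
  trace.push_back(final_ll);
  NumericVector pi_out(m.pi.begin(), m.pi.end());
  NumericMatrix A_out(K, K), E_out(K, M);
  for (int i = 0; i < K; ++i) {
    for (int j = 0; j < K; ++j) A_out(i, j) = m.A[(size_t)i * K + j];
    for (int mm = 0; mm < M; ++mm) E_out(i, mm) = m.E[(size_t)i * M + mm];
  }
  return List::create(_["pi"] = pi_out, _["A"] = A_out, _["E"] = E_out,
                      _["loglik_trace"] = NumericVector(trace.begin(),
                                                        trace.end()),
                      _["loglik"] = final_ll);
}
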