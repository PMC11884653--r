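#include <Rcpp.h>
#define USE_FC_LEN_T
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Piecewise-linear expected-trajectory and stage-likelihood kernels for the
// threshold-event progression model. A sequence is passed as parallel arrays
// bio[k] (1-based biomarker index) and z[k] (threshold reached) for stage
// positions k = 1..N; stage 0 has all biomarkers at 0. Beyond its last
// threshold each biomarker rises linearly to zmax at stage N.

static void fill_expected(const int *bio, const double *z, int N,
                          const double *zmax, int B, double *E /* (N+1)xB */) {
  const int K = N + 1;
  std::fill(E, E + (size_t)K * B, 0.0);
  std::vector<int> prev_k(B, 0);
  std::vector<double> prev_v(B, 0.0);
  for (int k = 1; k <= N; ++k) {
    const int b = bio[k - 1] - 1;
    const double v = z[k - 1];
    const int k0 = prev_k[b];
    const double v0 = prev_v[b];
    for (int s = k0 + 1; s <= k; ++s)
      E[s + (size_t)K * b] = v0 + (v - v0) * double(s - k0) / double(k - k0);
    prev_k[b] = k;
    prev_v[b] = v;
  }
  for (int b = 0; b < B; ++b) {
    const int k0 = prev_k[b];
    const double v0 = prev_v[b];
    if (k0 < N) {
      for (int s = k0 + 1; s <= N; ++s)
        E[s + (size_t)K * b] =
            v0 + (zmax[b] - v0) * double(s - k0) / double(N - k0);
    }
  }
}

// Shared scratch holding the scaled data (x / sigma_b) and per-row constants.
struct ScaledData {
  int n, B;
  std::vector<double> Xs;   // n x B column-major, scaled
  std::vector<double> x2h;  // 0.5 * rowSums(Xs^2)
  double logconst;          // sum_b -0.5 log(2 pi sigma_b^2)
  std::vector<double> smx;  // 1/sigma per biomarker

  ScaledData(const NumericMatrix &X, const NumericVector &sigma) {
    n = X.nrow();
    B = X.ncol();
    Xs.resize((size_t)n * B);
    x2h.assign(n, 0.0);
    smx.resize(B);
    logconst = 0.0;
    for (int b = 0; b < B; ++b) {
      const double s = sigma[b % sigma.size()];
      smx[b] = 1.0 / s;
      logconst += -0.5 * std::log(2.0 * M_PI * s * s);
      for (int i = 0; i < n; ++i) {
        const double v = X(i, b) * smx[b];
        Xs[i + (size_t)n * b] = v;
        x2h[i] += 0.5 * v * v;
      }
    }
  }
};

// Build the scaled expected matrix for a sequence (z and zmax divided by
// sigma_b so squared distances are already in likelihood units).
static void scaled_expected(const ScaledData &D, const int *bio,
                            const double *z, int N, const double *zmax,
                            std::vector<double> &E, std::vector<double> &zbuf,
                            std::vector<double> &zmaxbuf) {
  const int B = D.B;
  zbuf.resize(N);
  zmaxbuf.resize(B);
  for (int k = 0; k < N; ++k) zbuf[k] = z[k] * D.smx[bio[k] - 1];
  for (int b = 0; b < B; ++b) zmaxbuf[b] = zmax[b] * D.smx[b];
  E.assign((size_t)(N + 1) * B, 0.0);
  fill_expected(bio, zbuf.data(), N, zmaxbuf.data(), B, E.data());
}

// ll[i][k] = logconst - x2h[i] - e2h[k] + sum_b Xs[i,b] * E[k,b]
static void stage_ll_into(const ScaledData &D, const std::vector<double> &E,
                          int N, std::vector<double> &G,
                          std::vector<double> &e2h) {
  const int n = D.n, B = D.B, K = N + 1;
  G.assign((size_t)n * K, 0.0);
  e2h.assign(K, 0.0);
  for (int b = 0; b < B; ++b)
    for (int k = 0; k < K; ++k) {
      const double e = E[k + (size_t)K * b];
      e2h[k] += 0.5 * e * e;
    }
  for (int k = 0; k < K; ++k) {
    double *gc = &G[(size_t)n * k];
    for (int b = 0; b < B; ++b) {
      const double e = E[k + (size_t)K * b];
      if (e == 0.0) continue;
      const double *xc = &D.Xs[(size_t)n * b];
      for (int i = 0; i < n; ++i) gc[i] += xc[i] * e;
    }
    const double c = D.logconst - e2h[k];
    for (int i = 0; i < n; ++i) gc[i] += c - D.x2h[i];
  }
}

// Per-subject marginal log-likelihood under a uniform stage prior:
// ls_i = logsumexp_k ll[i,k] - log(K)
static void marginal_from_ll(const std::vector<double> &G, int n, int K,
                             std::vector<double> &ls) {
  ls.assign(n, -std::numeric_limits<double>::infinity());
  for (int k = 0; k < K; ++k) {
    const double *gc = &G[(size_t)n * k];
    for (int i = 0; i < n; ++i)
      if (gc[i] > ls[i]) ls[i] = gc[i];
  }
  std::vector<double> acc(n, 0.0);
  for (int k = 0; k < K; ++k) {
    const double *gc = &G[(size_t)n * k];
    for (int i = 0; i < n; ++i) {
      const double d = gc[i] - ls[i];
      if (d > -37.0) acc[i] += std::exp(d); // exp(-37) < 1e-16: negligible
    }
  }
  const double lk = std::log((double)K);
  for (int i = 0; i < n; ++i) ls[i] += std::log(acc[i]) - lk;
}

// [[Rcpp::export]]
NumericMatrix cpp_expected_matrix(IntegerVector bio, NumericVector z,
                                  NumericVector zmax, int B) {
  const int N = bio.size();
  NumericMatrix E(N + 1, B);
  std::vector<double> buf((size_t)(N + 1) * B);
  fill_expected(bio.begin(), z.begin(), N, zmax.begin(), B, buf.data());
  std::copy(buf.begin(), buf.end(), E.begin());
  return E;
}

// [[Rcpp::export]]
NumericMatrix cpp_stage_loglik(NumericMatrix X, IntegerVector bio,
                               NumericVector z, NumericVector zmax,
                               NumericVector sigma) {
  const int N = bio.size();
  ScaledData D(X, sigma);
  std::vector<double> E, zb, zmb, G, e2h;
  scaled_expected(D, bio.begin(), z.begin(), N, zmax.begin(), E, zb, zmb);
  stage_ll_into(D, E, N, G, e2h);
  NumericMatrix out(D.n, N + 1);
  std::copy(G.begin(), G.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_marginal_loglik(NumericMatrix X, IntegerVector bio,
                                  NumericVector z, NumericVector zmax,
                                  NumericVector sigma) {
  const int N = bio.size();
  ScaledData D(X, sigma);
  std::vector<double> E, zb, zmb, G, e2h, ls;
  scaled_expected(D, bio.begin(), z.begin(), N, zmax.begin(), E, zb, zmb);
  stage_ll_into(D, E, N, G, e2h);
  marginal_from_ll(G, D.n, N + 1, ls);
  return NumericVector(ls.begin(), ls.end());
}

static double weighted_obj(const ScaledData &D, const std::vector<int> &bio,
                           const std::vector<double> &z, const double *zmax,
                           const NumericVector &w, std::vector<double> &E,
                           std::vector<double> &zb, std::vector<double> &zmb,
                           std::vector<double> &G, std::vector<double> &e2h,
                           std::vector<double> &ls) {
  const int N = (int)bio.size();
  scaled_expected(D, bio.data(), z.data(), N, zmax, E, zb, zmb);
  stage_ll_into(D, E, N, G, e2h);
  marginal_from_ll(G, D.n, N + 1, ls);
  double obj = 0.0;
  for (int i = 0; i < D.n; ++i) obj += w[i] * ls[i];
  return obj;
}

// Move element `from` to position `to` (0-based) and restore ascending
// threshold order within the moved event's biomarker.
static void move_and_canon(const std::vector<int> &bio,
                           const std::vector<double> &z, int from, int to,
                           std::vector<int> &bio2, std::vector<double> &z2) {
  const int N = (int)bio.size();
  bio2.resize(N);
  z2.resize(N);
  const int mb = bio[from];
  const double mz = z[from];
  int j = 0;
  for (int k = 0; k < N; ++k) {
    if (k == from) continue;
    if (j == to) ++j;
    bio2[j] = bio[k];
    z2[j] = z[k];
    ++j;
  }
  bio2[to] = mb;
  z2[to] = mz;
  // re-sort the moved biomarker's thresholds by position
  std::vector<double> vals;
  std::vector<int> pos;
  for (int k = 0; k < N; ++k)
    if (bio2[k] == mb) {
      pos.push_back(k);
      vals.push_back(z2[k]);
    }
  std::sort(vals.begin(), vals.end());
  for (size_t q = 0; q < pos.size(); ++q) z2[pos[q]] = vals[q];
}

// Greedy event-relocation ascent on the weighted marginal log-likelihood.
// For each position, the event there is tried at every other position (with
// within-biomarker threshold order restored); the best strictly improving
// relocation is applied. Passes repeat until no improvement or max_passes.
// All candidate targets of one event are evaluated in a single batched
// matrix product (dgemm) over the stacked expected-value matrices.
// [[Rcpp::export]]
List cpp_greedy_opt(NumericMatrix X, IntegerVector bio, NumericVector z,
                    NumericVector zmax, NumericVector sigma, NumericVector w,
                    int max_passes, double tol) {
  const int N = bio.size();
  const int K = N + 1;
  ScaledData D(X, sigma);
  const int n = D.n, B = D.B;
  std::vector<int> cur_b(bio.begin(), bio.end());
  std::vector<double> cur_z(z.begin(), z.end());
  std::vector<double> E, zb, zmb, G, e2h, ls;
  std::vector<int> cand_b, best_b;
  std::vector<double> cand_z, best_z;
  const double *zmx = zmax.begin();

  // batched buffers: up to N candidate targets per sweep
  std::vector<double> Ecat((size_t)B * K * N);  // B x (K*nt), column-major
  std::vector<double> e2cat((size_t)K * N);
  std::vector<double> Gcat((size_t)n * K * N);
  std::vector<std::vector<int> > cands_b(N);
  std::vector<std::vector<double> > cands_z(N);
  const double lK = std::log((double)K);

  double cur = weighted_obj(D, cur_b, cur_z, zmx, w, E, zb, zmb, G, e2h, ls);
  int passes = 0;
  bool improved = true;
  while (improved && passes < max_passes) {
    improved = false;
    ++passes;
    for (int f = 0; f < N; ++f) {
      int nt = 0;
      for (int t = 0; t < N; ++t) {
        if (t == f) continue;
        move_and_canon(cur_b, cur_z, f, t, cand_b, cand_z);
        if (cand_b == cur_b && cand_z == cur_z) continue;
        // stack this candidate's scaled expected matrix (transposed: B x K)
        scaled_expected(D, cand_b.data(), cand_z.data(), N, zmx, E, zb, zmb);
        double *dst = &Ecat[(size_t)B * K * nt];
        for (int k = 0; k < K; ++k) {
          double s2 = 0.0;
          for (int b2 = 0; b2 < B; ++b2) {
            const double e = E[k + (size_t)K * b2];
            dst[b2 + (size_t)B * k] = e;
            s2 += 0.5 * e * e;
          }
          e2cat[(size_t)K * nt + k] = s2;
        }
        cands_b[nt] = cand_b;
        cands_z[nt] = cand_z;
        ++nt;
      }
      if (!nt) continue;
      // Gcat = Xs (n x B) %*% Ecat (B x K*nt)
      {
        const int m_ = n, n_ = K * nt, k_ = B;
        const double one = 1.0, zero = 0.0;
        F77_CALL(dgemm)("N", "N", &m_, &n_, &k_, &one, D.Xs.data(), &m_,
                        Ecat.data(), &k_, &zero, Gcat.data(), &m_
                        FCONE FCONE);
      }
      double best = cur;
      int best_t = -1;
      std::vector<double> mx(n), acc(n);
      for (int t = 0; t < nt; ++t) {
        const double *g = &Gcat[(size_t)n * K * t];
        const double *e2 = &e2cat[(size_t)K * t];
        std::fill(mx.begin(), mx.end(),
                  -std::numeric_limits<double>::infinity());
        for (int k = 0; k < K; ++k) {
          const double *gc = g + (size_t)n * k;
          const double c = e2[k];
          for (int i = 0; i < n; ++i) {
            const double v = gc[i] - c;
            if (v > mx[i]) mx[i] = v;
          }
        }
        std::fill(acc.begin(), acc.end(), 0.0);
        for (int k = 0; k < K; ++k) {
          const double *gc = g + (size_t)n * k;
          const double c = e2[k];
          for (int i = 0; i < n; ++i) {
            const double d = gc[i] - c - mx[i];
            if (d > -37.0) acc[i] += std::exp(d);
          }
        }
        double obj = 0.0;
        for (int i = 0; i < n; ++i)
          obj += w[i] * (mx[i] + std::log(acc[i]) + D.logconst - D.x2h[i] - lK);
        if (obj > best + tol) {
          best = obj;
          best_t = t;
        }
      }
      if (best_t >= 0) {
        cur_b = cands_b[best_t];
        cur_z = cands_z[best_t];
        cur = best;
        improved = true;
      }
    }
  }
  return List::create(_["bio"] = IntegerVector(cur_b.begin(), cur_b.end()),
                      _["z"] = NumericVector(cur_z.begin(), cur_z.end()),
                      _["objective"] = cur, _["passes"] = passes);
}
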