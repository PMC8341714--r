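// Blocked Gibbs sampler for the truncated Dirichlet-process mixture model of
// SNP effect sizes.  Per-block likelihood enters only through the quadratic
// summaries (B_b, v_b, N_b): log L(beta) = N (beta'v - beta'B beta / 2) + c.
//
// Reproducibility contract: one RNG substream per LD block plus one global
// substream, all derived from the master seed via splitmix64.  Blocks are
// updated serially in block order, so results are invariant to the requested
// thread count by construction.  All draws go through inverse-CDF transforms
// of 53-bit uniforms (R's qnorm/qgamma/qbeta), never through std::
// distributions, so output is identical across platforms with the same
// floating-point semantics.

#include <Rcpp.h>
#include <Rmath.h>
#include <cstdint>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Stream {
  std::mt19937_64 gen;
  explicit Stream(uint64_t seed) : gen(seed) {}
  // uniform in the open interval (0, 1), 53-bit resolution
  double unif() {
    double u = ((gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
    return u;
  }
  double norm() { return R::qnorm(unif(), 0.0, 1.0, 1, 0); }
  double gamma(double shape, double rate) {
    return R::qgamma(unif(), shape, 1.0 / rate, 1, 0);
  }
  double beta(double a, double b) { return R::qbeta(unif(), a, b, 1, 0); }
};

// substream seeds: block b in 0..n_blocks-1 gets stream b, global gets
// stream n_blocks
inline uint64_t stream_seed(uint64_t master, uint64_t stream_id) {
  return splitmix64(master ^ splitmix64(stream_id + 1));
}

// sigma^2 | (n_k, S_k) for an occupied cluster, truncated to (0, u^2].
// Density prop. to (s2)^{-(nk+1)/2} exp(-Sk / (2 s2)) on (0, u^2];
// x = 1/s2 is Gamma(shape a = (nk-1)/2, rate b = Sk/2) truncated to x >= L,
// L = 1/u^2.  a > 0: inverse CDF on the gamma.  a == 0 (nk == 1): exact
// rejection sampler for the x^{-1} e^{-bx} tail density on the log scale.
double draw_sigma2_occupied(int nk, double Sk, double u, Stream& rng) {
  const double L = 1.0 / (u * u);
  const double a = 0.5 * (nk - 1);
  const double b = 0.5 * Sk;
  if (Sk <= 0.0) {
    // all gamma_i in the cluster numerically zero: fall back to a base draw
    double s = u * rng.unif();
    return s * s;
  }
  if (a > 0.0) {
    double Flo = R::pgamma(L, a, 1.0 / b, 1, 0);
    double tail = 1.0 - Flo;
    if (tail < 1e-14) return u * u;  // conditional mass piles at the bound
    double x = R::qgamma(Flo + rng.unif() * tail, a, 1.0 / b, 1, 0);
    if (!R_FINITE(x) || x < L) x = L;
    return 1.0 / x;
  }
  // nk == 1: target in w = log(x / L) >= 0 is prop. to exp(-bL e^w).
  // Envelope: height-1 uniform on [0, wstar] plus exp(-1 - (w - wstar)) tail,
  // wstar = max(0, -log(bL)); bound uses e^w >= 1 + w.
  const double bL = b * L;
  const double wstar = (bL < 1.0) ? -std::log(bL) : 0.0;
  const double tail_mass = std::exp(-1.0);
  const double total = wstar + tail_mass;
  for (int tries = 0; tries < 10000; ++tries) {
    double w, log_env;
    if (rng.unif() * total < wstar) {
      w = wstar * rng.unif();
      log_env = 0.0;
    } else {
      w = wstar - std::log(rng.unif());
      log_env = -1.0 - (w - wstar);
    }
    double log_target = -bL * std::exp(w);
    if (std::log(rng.unif()) < log_target - log_env) {
      double x = L * std::exp(w);
      return 1.0 / x;
    }
  }
  return u * u;  // unreachable in practice
}

// log assignment weights for SNP i given residual summaries.
// a = N eta^2 B_ii, bb = N eta rho_i.  k = 0 is the point mass at zero.
void assignment_logw(double a, double bb, const std::vector<double>& logp,
                     const std::vector<double>& inv_s2,
                     const std::vector<double>& log_s2,
                     std::vector<double>& lw) {
  const int K = (int)logp.size();
  lw[0] = logp[0];
  const double bb2 = bb * bb;
  for (int k = 1; k < K; ++k) {
    double lam = a + inv_s2[k];
    lw[k] = logp[k] - 0.5 * (log_s2[k] + std::log(lam)) + 0.5 * bb2 / lam;
  }
}

int sample_categorical(const std::vector<double>& lw, Stream& rng,
                       double* out_total = nullptr) {
  const int K = (int)lw.size();
  double m = R_NegInf;
  for (int k = 0; k < K; ++k)
    if (lw[k] > m) m = lw[k];
  double total = 0.0;
  std::vector<double> w(K);
  for (int k = 0; k < K; ++k) {
    w[k] = std::exp(lw[k] - m);
    total += w[k];
  }
  double target = rng.unif() * total;
  double cum = 0.0;
  int pick = K - 1;
  for (int k = 0; k < K; ++k) {
    cum += w[k];
    if (target <= cum) { pick = k; break; }
  }
  if (out_total) *out_total = total;
  return pick;
}

void stick_break(const std::vector<double>& V, std::vector<double>& p) {
  const int K = (int)V.size();
  double remain = 1.0;
  for (int k = 0; k < K; ++k) {
    p[k] = V[k] * remain;
    remain *= (1.0 - V[k]);
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_sigma2_draws(int nk, double Sk, double u, int n,
                               double seed) {
  Stream rng(stream_seed((uint64_t)seed, 0));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (nk == 0) {
      double s = u * rng.unif();
      out[i] = s * s;
    } else {
      out[i] = draw_sigma2_occupied(nk, Sk, u, rng);
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_sample_sticks(IntegerVector counts, double alpha, double seed) {
  const int K = counts.size();
  Stream rng(stream_seed((uint64_t)seed, 0));
  std::vector<double> V(K), p(K);
  std::vector<long long> tail(K, 0);
  long long acc = 0;
  for (int k = K - 1; k >= 0; --k) {
    tail[k] = acc;  // counts strictly after k
    acc += counts[k];
  }
  for (int k = 0; k < K - 1; ++k)
    V[k] = rng.beta(1.0 + counts[k], alpha + (double)tail[k]);
  V[K - 1] = 1.0;
  stick_break(V, p);
  return List::create(_["V"] = NumericVector(V.begin(), V.end()),
                      _["p"] = NumericVector(p.begin(), p.end()));
}

// [[Rcpp::export]]
NumericVector cpp_alpha_draws(NumericVector V, double shape, double rate,
                              int n, double seed) {
  Stream rng(stream_seed((uint64_t)seed, 0));
  const int K = V.size();
  double s = 0.0;
  for (int k = 0; k < K - 1; ++k) {
    double l1m = std::log(1.0 - V[k]);
    if (l1m < -30.0) l1m = -30.0;
    s += l1m;
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = rng.gamma(shape + K - 1, rate - s);
  return out;
}

// Normalized assignment probabilities for SNP i (1-based) of one block,
// exposing the conditional the sweep uses.
// [[Rcpp::export]]
NumericVector cpp_assignment_weights(int i, NumericMatrix B, NumericVector v,
                                     double N, double eta, NumericVector p,
                                     NumericVector sigma2,
                                     NumericVector gamma) {
  const int m = v.size(), K = p.size();
  const int ii = i - 1;
  double rho = v[ii];
  for (int j = 0; j < m; ++j)
    if (j != ii) rho -= eta * B(ii, j) * gamma[j];
  double a = N * eta * eta * B(ii, ii);
  double bb = N * eta * rho;
  std::vector<double> logp(K), inv_s2(K, 0.0), log_s2(K, 0.0), lw(K);
  for (int k = 0; k < K; ++k)
    logp[k] = (p[k] > 0.0) ? std::log(p[k]) : R_NegInf;
  for (int k = 1; k < K; ++k) {
    inv_s2[k] = 1.0 / sigma2[k];
    log_s2[k] = std::log(sigma2[k]);
  }
  assignment_logw(a, bb, logp, inv_s2, log_s2, lw);
  double mx = R_NegInf;
  for (int k = 0; k < K; ++k)
    if (lw[k] > mx) mx = lw[k];
  NumericVector w(K);
  double tot = 0.0;
  for (int k = 0; k < K; ++k) {
    w[k] = std::exp(lw[k] - mx);
    tot += w[k];
  }
  for (int k = 0; k < K; ++k) w[k] /= tot;
  return w;
}

// Full sampler.  `blocks` is a list of list(B, R, v, N); `init` may carry
// sigma2, V, eta, alpha, gamma, z; `updates` carries logical flags sigma2,
// sticks, alpha, eta.
// [[Rcpp::export]]
List cpp_run_mcmc(List blocks, int K, double u, double alpha_shape,
                  double alpha_rate, double eta_prior_var, int n_iter,
                  int burn_in, int thin, double seed, List init, List updates,
                  double guard, int n_threads, bool save_beta_trace) {
  (void)n_threads;  // serial execution with per-block substreams: results are
                    // thread-count invariant by construction
  const int n_blocks = blocks.size();
  std::vector<NumericMatrix> Bm, Rm;
  std::vector<NumericVector> vv;
  std::vector<double> Nb(n_blocks);
  std::vector<int> bsize(n_blocks), boffset(n_blocks);
  int M = 0;
  for (int b = 0; b < n_blocks; ++b) {
    List blk = blocks[b];
    Bm.push_back(as<NumericMatrix>(blk["B"]));
    Rm.push_back(as<NumericMatrix>(blk["R"]));
    vv.push_back(as<NumericVector>(blk["v"]));
    Nb[b] = as<double>(blk["N"]);
    bsize[b] = vv[b].size();
    boffset[b] = M;
    M += bsize[b];
  }

  const bool upd_sigma2 = as<bool>(updates["sigma2"]);
  const bool upd_sticks = as<bool>(updates["sticks"]);
  const bool upd_alpha = as<bool>(updates["alpha"]);
  const bool upd_eta = as<bool>(updates["eta"]);

  std::vector<Stream> block_rng;
  block_rng.reserve(n_blocks);
  for (int b = 0; b < n_blocks; ++b)
    block_rng.emplace_back(stream_seed((uint64_t)seed, (uint64_t)b));
  Stream grng(stream_seed((uint64_t)seed, (uint64_t)n_blocks));

  // --- state ---
  std::vector<double> sigma2(K, 0.0), V(K, 0.0), p(K, 0.0), logp(K, 0.0);
  std::vector<double> inv_s2(K, 0.0), log_s2(K, 0.0);
  std::vector<double> gamma(M, 0.0), beta(M, 0.0);
  std::vector<int> z(M, 0);
  double eta = 1.0, alpha = 1.0;

  if (init.containsElementNamed("eta") && init["eta"] != R_NilValue)
    eta = as<double>(init["eta"]);
  if (init.containsElementNamed("alpha") && init["alpha"] != R_NilValue)
    alpha = as<double>(init["alpha"]);
  if (init.containsElementNamed("sigma2") && init["sigma2"] != R_NilValue) {
    NumericVector s0 = init["sigma2"];
    for (int k = 0; k < K; ++k) sigma2[k] = s0[k];
  } else {
    for (int k = 1; k < K; ++k) {
      double s = u * grng.unif();
      sigma2[k] = s * s;
    }
  }
  sigma2[0] = 0.0;
  if (init.containsElementNamed("V") && init["V"] != R_NilValue) {
    NumericVector V0 = init["V"];
    for (int k = 0; k < K; ++k) V[k] = V0[k];
  } else {
    for (int k = 0; k < K - 1; ++k) V[k] = grng.beta(1.0, alpha);
    V[K - 1] = 1.0;
  }
  stick_break(V, p);
  if (init.containsElementNamed("gamma") && init["gamma"] != R_NilValue) {
    NumericVector g0 = init["gamma"];
    for (int i = 0; i < M; ++i) gamma[i] = g0[i];
  }
  if (init.containsElementNamed("z") && init["z"] != R_NilValue) {
    IntegerVector z0 = init["z"];
    for (int i = 0; i < M; ++i) z[i] = z0[i];
  }

  // --- accumulators ---
  std::vector<double> beta_sum(M, 0.0);
  std::vector<int> nonzero(M, 0);
  NumericVector tr_h2(n_iter, NA_REAL), tr_eta(n_iter, NA_REAL),
      tr_alpha(n_iter, NA_REAL);
  IntegerVector tr_occ(n_iter, NA_INTEGER);
  int n_retained = 0;
  const int n_keep_max =
      (n_iter > burn_in) ? ((n_iter - burn_in - 1) / thin + 1) : 0;
  NumericMatrix beta_trace(save_beta_trace ? n_keep_max : 0,
                           save_beta_trace ? M : 0);
  bool guard_hit = false;
  int guard_iter = -1;
  double max_p_err = 0.0, max_s2_excess = 0.0;
  bool zg_consistent = true;

  std::vector<double> lw(K);
  std::vector<long long> nk(K, 0), tailcnt(K, 0);
  std::vector<double> Sk(K, 0.0);

  for (int iter = 0; iter < n_iter; ++iter) {
    // per-sweep component caches
    for (int k = 1; k < K; ++k) {
      inv_s2[k] = 1.0 / sigma2[k];
      log_s2[k] = std::log(sigma2[k]);
    }
    for (int k = 0; k < K; ++k)
      logp[k] = (p[k] > 0.0) ? std::log(p[k]) : R_NegInf;

    // --- block updates: assignments and gamma ---
    for (int b = 0; b < n_blocks; ++b) {
      const int m = bsize[b], off = boffset[b];
      const NumericMatrix& B = Bm[b];
      const NumericVector& v = vv[b];
      const double N = Nb[b];
      Stream& rng = block_rng[b];
      // r = B gamma, maintained incrementally within the sweep
      std::vector<double> r(m, 0.0);
      for (int j = 0; j < m; ++j) {
        double gj = gamma[off + j];
        if (gj != 0.0)
          for (int i2 = 0; i2 < m; ++i2) r[i2] += B(i2, j) * gj;
      }
      const double eta2 = eta * eta;
      for (int i = 0; i < m; ++i) {
        double gi = gamma[off + i];
        double rho = v[i] - eta * (r[i] - B(i, i) * gi);
        double a = N * eta2 * B(i, i);
        double bb = N * eta * rho;
        assignment_logw(a, bb, logp, inv_s2, log_s2, lw);
        int k = sample_categorical(lw, rng);
        double gnew;
        if (k == 0) {
          gnew = 0.0;
        } else {
          double lam = a + inv_s2[k];
          double mean = bb / lam;
          gnew = mean + rng.norm() / std::sqrt(lam);
        }
        double delta = gnew - gi;
        if (delta != 0.0)
          for (int j = 0; j < m; ++j) r[j] += B(j, i) * delta;
        gamma[off + i] = gnew;
        z[off + i] = k;
      }
    }

    // --- cluster statistics ---
    std::fill(nk.begin(), nk.end(), 0);
    std::fill(Sk.begin(), Sk.end(), 0.0);
    for (int i = 0; i < M; ++i) {
      nk[z[i]]++;
      Sk[z[i]] += gamma[i] * gamma[i];
    }

    // --- cluster variances ---
    if (upd_sigma2) {
      for (int k = 1; k < K; ++k) {
        if (nk[k] > 0) {
          sigma2[k] = draw_sigma2_occupied((int)nk[k], Sk[k], u, grng);
        } else {
          double s = u * grng.unif();
          sigma2[k] = s * s;
        }
      }
      sigma2[0] = 0.0;
    }

    // --- sticks ---
    if (upd_sticks) {
      long long acc = 0;
      for (int k = K - 1; k >= 0; --k) {
        tailcnt[k] = acc;
        acc += nk[k];
      }
      for (int k = 0; k < K - 1; ++k)
        V[k] = grng.beta(1.0 + (double)nk[k], alpha + (double)tailcnt[k]);
      V[K - 1] = 1.0;
      stick_break(V, p);
    }

    // --- concentration ---
    if (upd_alpha) {
      double s = 0.0;
      for (int k = 0; k < K - 1; ++k) {
        double l1m = std::log(1.0 - V[k]);
        if (l1m < -30.0) l1m = -30.0;
        s += l1m;
      }
      alpha = grng.gamma(alpha_shape + K - 1, alpha_rate - s);
    }

    // --- eta ---
    if (upd_eta) {
      double quad = 0.0, lin = 0.0;
      for (int b = 0; b < n_blocks; ++b) {
        const int m = bsize[b], off = boffset[b];
        const NumericMatrix& B = Bm[b];
        const NumericVector& v = vv[b];
        double q = 0.0, l = 0.0;
        for (int i = 0; i < m; ++i) {
          double gi = gamma[off + i];
          if (gi == 0.0) continue;
          l += gi * v[i];
          double ri = 0.0;
          for (int j = 0; j < m; ++j) ri += B(i, j) * gamma[off + j];
          q += gi * ri;
        }
        quad += Nb[b] * q;
        lin += Nb[b] * l;
      }
      double s2 = 1.0 / (quad + 1.0 / eta_prior_var);
      double mean = s2 * lin;
      eta = mean + grng.norm() * std::sqrt(s2);
    }

    // --- beta, traces, invariants ---
    double maxabs = 0.0, h2 = 0.0;
    for (int i = 0; i < M; ++i) {
      beta[i] = eta * gamma[i];
      double a2 = std::fabs(beta[i]);
      if (a2 > maxabs) maxabs = a2;
    }
    for (int b = 0; b < n_blocks; ++b) {
      const int m = bsize[b], off = boffset[b];
      const NumericMatrix& R = Rm[b];
      for (int i = 0; i < m; ++i) {
        double bi = beta[off + i];
        if (bi == 0.0) continue;
        double ri = 0.0;
        for (int j = 0; j < m; ++j) ri += R(i, j) * beta[off + j];
        h2 += bi * ri;
      }
    }
    int occ = 0;
    for (int k = 1; k < K; ++k)
      if (nk[k] > 0) ++occ;
    tr_h2[iter] = h2;
    tr_eta[iter] = eta;
    tr_alpha[iter] = alpha;
    tr_occ[iter] = occ;

    double psum = 0.0;
    for (int k = 0; k < K; ++k) psum += p[k];
    double perr = std::fabs(psum - 1.0);
    if (perr > max_p_err) max_p_err = perr;
    for (int k = 1; k < K; ++k) {
      double ex = sigma2[k] - u * u;
      if (ex > max_s2_excess) max_s2_excess = ex;
    }
    for (int i = 0; i < M; ++i)
      if ((z[i] == 0) != (gamma[i] == 0.0)) zg_consistent = false;

    if (maxabs > guard) {
      guard_hit = true;
      guard_iter = iter + 1;
      break;
    }

    if (iter >= burn_in && (iter - burn_in) % thin == 0) {
      for (int i = 0; i < M; ++i) {
        beta_sum[i] += beta[i];
        if (z[i] > 0) nonzero[i]++;
      }
      if (save_beta_trace)
        for (int i = 0; i < M; ++i) beta_trace(n_retained, i) = beta[i];
      ++n_retained;
    }
    if (iter % 64 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector beta_mean(M), nz_freq(M);
  for (int i = 0; i < M; ++i) {
    beta_mean[i] = (n_retained > 0) ? beta_sum[i] / n_retained : NA_REAL;
    nz_freq[i] = (n_retained > 0) ? (double)nonzero[i] / n_retained : NA_REAL;
  }

  List final_state = List::create(
      _["z"] = IntegerVector(z.begin(), z.end()),
      _["gamma"] = NumericVector(gamma.begin(), gamma.end()),
      _["beta"] = NumericVector(beta.begin(), beta.end()),
      _["sigma2"] = NumericVector(sigma2.begin(), sigma2.end()),
      _["V"] = NumericVector(V.begin(), V.end()),
      _["p"] = NumericVector(p.begin(), p.end()), _["eta"] = eta,
      _["alpha"] = alpha);

  return List::create(
      _["beta_mean"] = beta_mean, _["nonzero_freq"] = nz_freq,
      _["h2_trace"] = tr_h2, _["eta_trace"] = tr_eta,
      _["alpha_trace"] = tr_alpha, _["occupied_trace"] = tr_occ,
      _["n_retained"] = n_retained, _["guard_triggered"] = guard_hit,
      _["guard_iter"] = guard_iter, _["max_stick_sum_error"] = max_p_err,
      _["max_sigma2_excess"] = max_s2_excess,
      _["z_gamma_consistent"] = zg_consistent, _["final_state"] = final_state,
      _["beta_trace"] = beta_trace);
}
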