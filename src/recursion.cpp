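#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Windowed forward recursion for the multi-state diffusion likelihood.
//
// Hidden positions are integrated out exactly per state sequence (Gaussian
// belief recursion); hidden state sequences are summed with the sliding
// window approximation: sequences sharing their last m (sub-)states are
// merged into a single belief with weights proportional to each branch's
// joint density. All weights are carried in log space.
//
// Bucket codes are base-N integers with the MOST RECENT state in the least
// significant digit; merging drops the oldest digit.

static const double LOG2PI = 1.8378770664093454836;
static const double NEG_INF = -std::numeric_limits<double>::infinity();

// probability that a molecule with per-frame displacement SD delta leaves a
// 1D observable region of length l, its position being uniform in [0, l]
static double leave_prob_1d(double delta, double l) {
  if (!(delta > 0.0) || !R_finite(l)) return 0.0;
  // closed form of 1 - (1/l) int_0^l [Phi((l-x)/d) - Phi(-x/d)] dx
  // via G(t) = t*Phi(t) + phi(t)
  double h = l / delta;
  double G0 = 0.3989422804014327; // phi(0)
  double Gh = h * R::pnorm(h, 0.0, 1.0, 1, 0) + R::dnorm(h, 0.0, 1.0, 0);
  double pl = 1.0 - (2.0 * (Gh - G0) - h) / h;
  if (pl < 0.0) pl = 0.0;
  if (pl > 1.0) pl = 1.0;
  return pl;
}

static double leave_prob_combined(double delta, const NumericVector& fov_len) {
  double keep = 1.0;
  for (int a = 0; a < fov_len.size(); ++a) {
    if (R_finite(fov_len[a]))
      keep *= 1.0 - leave_prob_1d(delta, fov_len[a]);
  }
  return 1.0 - keep;
}

// [[Rcpp::export(name = ".cpp_leave_prob")]]
double cpp_leave_prob(double delta, double l) {
  return leave_prob_1d(delta, l);
}

// pos:        nt x n x na array (observed positions, um)
// d:          per-state diffusion length per frame (um), length N
// sigma:      localization error per axis (um), length na
// logP:       N x N log per-SUB-step transition probabilities
// logF:       length-N log initial fractions
// m:          window length counted in sub-steps
// u:          sub-steps per frame
// sigma_scale:nt x n per-peak localization error scale, or 0 x 0
// fov_len:    per-axis observable length (Inf = unbounded), length na or 0
// pK:         per-frame state-independent termination probability
// use_fov:    apply the track-length factor
// fov_final:  apply the final termination bracket (false when the track was
//             censored by the movie end rather than terminated)
// constrain_frame: 1-based frame whose state is constrained (0 = none)
// constrain_state: 0-based state required at constrain_frame
//
// Returns per-track log density (log f_C, uniform prior constant over the
// first position dropped).
// [[Rcpp::export(name = ".cpp_window_loglik")]]
NumericVector cpp_window_loglik(NumericVector pos, IntegerVector dims,
                                NumericVector d, NumericVector sigma,
                                NumericMatrix logP, NumericVector logF,
                                int m, int u,
                                NumericMatrix sigma_scale,
                                NumericVector fov_len, double pK,
                                bool use_fov, bool fov_final,
                                int constrain_frame, int constrain_state) {
  const int nt = dims[0], n = dims[1], na = dims[2];
  const int N = d.size();
  if (m < 1 || u < 1) stop("window and substeps must be >= 1");
  if (N < 1 || N > 16) stop("between 1 and 16 states supported");
  const bool per_peak = sigma_scale.nrow() == nt && sigma_scale.ncol() == n;

  // bucket capacity: transient N^(m+1), merged N^m (fewer early on)
  double cap_d = 1.0;
  for (int i = 0; i < m + 1; ++i) cap_d *= N;
  if (cap_d > 4194304.0) stop("N^(m+1) too large; reduce the window length");
  const int capB = (int)cap_d;        // transient buffer
  const int capA = capB / N;          // merged buffer

  // both buffer sets sized for the transient N^(m+1) expansion: the A/B
  // roles swap on sub-steps without a merge, so either set can host it
  const size_t ntn = (size_t)nt * na;
  std::vector<double> logwA((size_t)capB * nt), logwB((size_t)capB * nt);
  std::vector<double> muA((size_t)capB * ntn), muB((size_t)capB * ntn);
  std::vector<double> s2A((size_t)capB * ntn), s2B((size_t)capB * ntn);
  std::vector<double> accA(capB), accB(capB);
  std::vector<int> curA(capB), curB(capB);

  // precomputed step SDs^2 between sub-states, scaled to one sub-step's
  // share of the per-frame variance: (d_i^2 + d_j^2) / (2u)
  std::vector<double> pair_d2((size_t)N * N);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      pair_d2[i + (size_t)N * j] = (d[i] * d[i] + d[j] * d[j]) / (2.0 * u);

  const double log_surv = (use_fov && pK < 1.0) ? std::log(1.0 - pK) : 0.0;

  // all axes share sigma -> s2 identical across axes, one log(v) per update
  bool iso = true;
  for (int a = 1; a < na; ++a) if (sigma[a] != sigma[0]) iso = false;

  // position accessor: pos[t + nt*(i + n*a)]
  const double* P = pos.begin();

  // init at frame 1
  int K = N;          // live buckets
  int L = 1;          // suffix length in sub-states
  for (int b = 0; b < N; ++b) {
    curA[b] = b;
    accA[b] = 0.0;
    double w0 = logF[b];
    if (constrain_frame == 1 && b != constrain_state) w0 = NEG_INF;
    for (int t = 0; t < nt; ++t) logwA[(size_t)b * nt + t] = w0;
  }

  for (int i = 1; i <= n - 1; ++i) {       // frame i -> i+1
    for (int k = 1; k <= u; ++k) {         // sub-transitions
      const bool at_obs = (k == u);        // arrive at frame i+1; update obs i
      // lazy merge: drop the oldest sub-state only when the next expansion
      // needs room, so sequences keep m+1 states through their last update
      if (K > capA) {
        const int KA = K / N;
        for (int g = 0; g < KA; ++g) {
          curB[g] = curA[g];
          accB[g] = accA[g];
          double* lwB_ = &logwB[(size_t)g * nt];
          double* muB_ = &muB[(size_t)g * ntn];
          double* s2B_ = &s2B[(size_t)g * ntn];
          for (int t = 0; t < nt; ++t) {
            double M = NEG_INF;
            for (int j = 0; j < N; ++j) {
              const double w = logwA[(size_t)(g + j * KA) * nt + t];
              if (w > M) M = w;
            }
            if (M == NEG_INF) {
              lwB_[t] = NEG_INF;
              for (int a = 0; a < na; ++a) {
                muB_[(size_t)a * nt + t] =
                    muA[(size_t)g * ntn + (size_t)a * nt + t];
                s2B_[(size_t)a * nt + t] =
                    s2A[(size_t)g * ntn + (size_t)a * nt + t];
              }
              continue;
            }
            double den = 0.0;
            double al[16];
            for (int j = 0; j < N; ++j) {
              al[j] = std::exp(logwA[(size_t)(g + j * KA) * nt + t] - M);
              den += al[j];
            }
            lwB_[t] = M + std::log(den);
            for (int j = 0; j < N; ++j) al[j] /= den;
            for (int a = 0; a < na; ++a) {
              double mm = 0.0, ss = 0.0;
              for (int j = 0; j < N; ++j) {
                const size_t src = (size_t)(g + j * KA);
                mm += al[j] * muA[src * ntn + (size_t)a * nt + t];
                ss += al[j] * s2A[src * ntn + (size_t)a * nt + t];
              }
              muB_[(size_t)a * nt + t] = mm;
              s2B_[(size_t)a * nt + t] = ss;
            }
          }
        }
        std::swap(logwA, logwB);
        std::swap(muA, muB);
        std::swap(s2A, s2B);
        std::swap(accA, accB);
        std::swap(curA, curB);
        K = KA;
        L = L - 1;
      }

      const int newK = K * N;
      // bucket metadata for all successors
      for (int b = 0; b < K; ++b) {
        const int cs = curA[b];
        const double acc0 = accA[b];
        for (int s = 0; s < N; ++s) {
          const int nb = s + N * b;        // may exceed capA; B sized capB
          curB[nb] = s;
          accB[nb] = acc0 + pair_d2[cs + (size_t)N * s];
        }
      }
      if (!at_obs) {
        // plain expansion between observations: carry beliefs unchanged
        for (int b = 0; b < K; ++b) {
          const int cs = curA[b];
          for (int s = 0; s < N; ++s) {
            const int nb = s + N * b;
            const double lp = logP(cs, s);
            double* lwB = &logwB[(size_t)nb * nt];
            const double* lwA = &logwA[(size_t)b * nt];
            for (int t = 0; t < nt; ++t) lwB[t] = lwA[t] + lp;
            if (i > 1) {
              std::copy(&muA[(size_t)b * ntn], &muA[(size_t)b * ntn] + ntn,
                        &muB[(size_t)nb * ntn]);
              std::copy(&s2A[(size_t)b * ntn], &s2A[(size_t)b * ntn] + ntn,
                        &s2B[(size_t)nb * ntn]);
            }
          }
        }
      } else {
        // fused expansion + Gaussian update with observation i: read the
        // belief from the source bucket, write the updated belief
        for (int b = 0; b < K; ++b) {
          const int cs = curA[b];
          const double* lwS = &logwA[(size_t)b * nt];
          const double* muS = &muA[(size_t)b * ntn];
          const double* s2S = &s2A[(size_t)b * ntn];
          for (int s = 0; s < N; ++s) {
            const int nb = s + N * b;
            const double lp = logP(cs, s);
            const bool dead =
                (constrain_frame == i + 1 && s != constrain_state);
            const double delta2 = accB[nb];
            accB[nb] = 0.0;
            double* lw = &logwB[(size_t)nb * nt];
            double* mu = &muB[(size_t)nb * ntn];
            double* s2 = &s2B[(size_t)nb * ntn];
            double lterm = 0.0;
            if (use_fov) {
              lterm = log_surv;
              double plc = leave_prob_combined(std::sqrt(delta2), fov_len);
              lterm += (plc < 1.0) ? std::log(1.0 - plc) : NEG_INF;
            }
            if (i == 1) {
              // first-step initialization: s1^2 = sigma1^2 + delta1^2,
              // mu1 = c1
              for (int t = 0; t < nt; ++t) {
                const double sc = per_peak ? sigma_scale(t, 0) : 1.0;
                for (int a = 0; a < na; ++a) {
                  const double sg = sigma[a] * sc;
                  mu[(size_t)a * nt + t] =
                      P[t + (size_t)nt * ((size_t)n * a)];
                  s2[(size_t)a * nt + t] = sg * sg + delta2;
                }
                lw[t] = dead ? NEG_INF : lwS[t] + lp + lterm;
              }
            } else if (iso) {
              for (int t = 0; t < nt; ++t) {
                const double s2o = s2S[t];
                if (dead || lwS[t] == NEG_INF) {
                  lw[t] = NEG_INF;
                  for (int a = 0; a < na; ++a) {
                    const size_t ix = (size_t)a * nt + t;
                    mu[ix] = muS[ix];
                    s2[ix] = s2o;
                  }
                  continue;
                }
                const double sc = per_peak ? sigma_scale(t, i - 1) : 1.0;
                const double sg2 = sigma[0] * sigma[0] * sc * sc;
                const double v = sg2 + s2o;
                const double lv = std::log(v);
                const double news2 =
                    (delta2 * sg2 + delta2 * s2o + sg2 * s2o) / v;
                double acc_lw = 0.0;
                for (int a = 0; a < na; ++a) {
                  const size_t ix = (size_t)a * nt + t;
                  const double c =
                      P[t + (size_t)nt * (i - 1 + (size_t)n * a)];
                  const double dm = c - muS[ix];
                  acc_lw += -dm * dm / (2.0 * v) - 0.5 * (LOG2PI + lv);
                  mu[ix] = (muS[ix] * sg2 + c * s2o) / v;
                  s2[ix] = news2;
                }
                lw[t] = lwS[t] + lp + acc_lw + lterm;
              }
            } else {
              for (int t = 0; t < nt; ++t) {
                if (dead || lwS[t] == NEG_INF) {
                  lw[t] = NEG_INF;
                  for (int a = 0; a < na; ++a) {
                    const size_t ix = (size_t)a * nt + t;
                    mu[ix] = muS[ix];
                    s2[ix] = s2S[ix];
                  }
                  continue;
                }
                const double sc = per_peak ? sigma_scale(t, i - 1) : 1.0;
                double acc_lw = 0.0;
                for (int a = 0; a < na; ++a) {
                  const double sg2 = sigma[a] * sigma[a] * sc * sc;
                  const size_t ix = (size_t)a * nt + t;
                  const double c =
                      P[t + (size_t)nt * (i - 1 + (size_t)n * a)];
                  const double v = sg2 + s2S[ix];
                  const double dm = c - muS[ix];
                  acc_lw +=
                      -dm * dm / (2.0 * v) - 0.5 * (LOG2PI + std::log(v));
                  mu[ix] = (muS[ix] * sg2 + c * s2S[ix]) / v;
                  s2[ix] =
                      (delta2 * sg2 + delta2 * s2S[ix] + sg2 * s2S[ix]) / v;
                }
                lw[t] = lwS[t] + lp + acc_lw + lterm;
              }
            }
          }
        }
      }

      std::swap(logwA, logwB);
      std::swap(muA, muB);
      std::swap(s2A, s2B);
      std::swap(accA, accB);
      std::swap(curA, curB);
      K = newK;
      L = L + 1;
    }
  }

  // final integration over r_n and optional termination factor
  NumericVector out(nt);
  std::vector<double> lterm_fin(N, 0.0);
  if (use_fov && fov_final) {
    for (int s = 0; s < N; ++s) {
      double plc = leave_prob_combined(d[s], fov_len);
      double val = pK + (1.0 - pK) * plc;
      lterm_fin[s] = (val > 0.0) ? std::log(val) : NEG_INF;
    }
  }
  for (int t = 0; t < nt; ++t) {
    double M = NEG_INF;
    std::vector<double> wf(K);
    const double sc = per_peak ? sigma_scale(t, n - 1) : 1.0;
    for (int b = 0; b < K; ++b) {
      double w = logwA[(size_t)b * nt + t];
      if (w != NEG_INF) {
        for (int a = 0; a < na; ++a) {
          const double sg2 = sigma[a] * sigma[a] * sc * sc;
          const size_t ix = (size_t)a * nt + t;
          const double c = P[t + (size_t)nt * (n - 1 + (size_t)n * a)];
          const double v = sg2 + s2A[(size_t)b * ntn + ix];
          const double dm = c - muA[(size_t)b * ntn + ix];
          w += -dm * dm / (2.0 * v) - 0.5 * (LOG2PI + std::log(v));
        }
        if (use_fov && fov_final) w += lterm_fin[curA[b]];
      }
      wf[b] = w;
      if (w > M) M = w;
    }
    if (M == NEG_INF) {
      out[t] = NEG_INF;
      continue;
    }
    double den = 0.0;
    for (int b = 0; b < K; ++b) den += std::exp(wf[b] - M);
    out[t] = M + std::log(den);
  }
  return out;
}
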