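#include <Rcpp.h>
#include <cstdint>
#include <string>
using namespace Rcpp;

// splitmix64: the per-trial generator. Counter-based seeding keeps every
// trial an independent, order-free stream: trial k of sequence `key` under
// master seed m always sees the same draws, whether run alone or in a batch.
static inline uint64_t sm64(uint64_t &s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t mix3(uint64_t a, uint64_t b, uint64_t c) {
  uint64_t s = a;
  uint64_t h = sm64(s);
  s ^= b * 0x9E3779B97F4A7C15ULL;
  h ^= sm64(s);
  s ^= c * 0xC2B2AE3D27D4EB4FULL;
  h ^= sm64(s);
  return h;
}

static inline double unif01(uint64_t &s) {
  return (sm64(s) >> 11) * (1.0 / 9007199254740992.0);
}

// FNV-1a hash of a sequence id, so trial seeds depend on the id, not on
// batch position.
// [[Rcpp::export]]
double fnv1a_hash(std::string id) {
  uint64_t h = 0xCBF29CE484222325ULL;
  for (char ch : id) {
    h ^= (uint64_t)(unsigned char)ch;
    h *= 0x100000001B3ULL;
  }
  // return as double holding the low 53 bits exactly
  return (double)(h & 0x1FFFFFFFFFFFFFULL);
}

// Metropolis trials of the whole-chain hop dynamics on a precomputed
// landscape. acc_up/acc_dn are min(1, exp(-dE)) for the M transient offsets
// x = -5..N (index 0 <-> x = -5); the walker starts at x = 0 (index 5).
// One proposal draw per MCT; the acceptance draw is taken only when the
// move is uphill. Outcomes: 1 translocated (x = N+1), 2 rejected (x = -6),
// 3 trapped (still transient after tw attempts).
// [[Rcpp::export]]
IntegerMatrix mc_trials_cpp(NumericVector acc_up, NumericVector acc_dn,
                            double tw, int trials,
                            double master_seed, double seq_key,
                            int trial_offset = 0) {
  const int M = acc_up.size();
  const int i0 = 5;
  IntegerMatrix out(trials, 3); // outcome, time, final offset x
  const double *up = acc_up.begin();
  const double *dn = acc_dn.begin();
  for (int k = 0; k < trials; ++k) {
    uint64_t s = mix3((uint64_t)master_seed, (uint64_t)seq_key,
                      (uint64_t)(k + trial_offset));
    int x = i0;
    int outcome = 3;
    double t = 0, tend = tw;
    while (t < tend) {
      t += 1;
      if (unif01(s) < 0.5) { // propose +1
        double a = up[x];
        if (a >= 1.0 || unif01(s) < a) {
          if (x == M - 1) { outcome = 1; break; }
          ++x;
        }
      } else {               // propose -1
        double a = dn[x];
        if (a >= 1.0 || unif01(s) < a) {
          if (x == 0) { outcome = 2; break; }
          --x;
        }
      }
    }
    out(k, 0) = outcome;
    out(k, 1) = (int)t;
    out(k, 2) = (outcome == 1) ? (M - 5) : (outcome == 2 ? -6 : x - 5);
  }
  return out;
}

// Exact absorption-time distribution: push a point mass at x = 0 through
// the transient states and record the probability absorbed on each side at
// every step. Early exit once survival falls below `tol` (remaining entries
// stay zero); `steps` reports how far the iteration actually ran.
// [[Rcpp::export]]
List absorb_dist_cpp(NumericVector p_up, NumericVector p_dn,
                     double t_max, double tol = 0.0) {
  const int M = p_up.size();
  const int i0 = 5;
  const double *up = p_up.begin();
  const double *dn = p_dn.begin();
  std::vector<double> occ(M, 0.0), nxt(M, 0.0);
  occ[i0] = 1.0;
  R_xlen_t T = (R_xlen_t)t_max;
  NumericVector ptr(T), prej(T);
  double surv = 1.0;
  R_xlen_t t = 0;
  for (; t < T; ++t) {
    double a_tr = occ[M - 1] * up[M - 1];
    double a_rej = occ[0] * dn[0];
    for (int i = 0; i < M; ++i)
      nxt[i] = occ[i] * (1.0 - up[i] - dn[i]);
    for (int i = 0; i < M - 1; ++i) {
      nxt[i + 1] += occ[i] * up[i];
      nxt[i] += occ[i + 1] * dn[i + 1];
    }
    std::swap(occ, nxt);
    ptr[t] = a_tr;
    prej[t] = a_rej;
    surv -= a_tr + a_rej;
    if (surv < tol) { ++t; break; }
  }
  return List::create(_["p_translocate"] = ptr, _["p_reject"] = prej,
                      _["survival"] = surv, _["steps"] = (double)t,
                      _["occupancy"] = NumericVector(occ.begin(), occ.end()));
}
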