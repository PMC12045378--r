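#include <Rcpp.h>
using namespace Rcpp;

// Group-structured birth-death core. Populations are integer matrices with
// columns (nA, nB); one row per living group. All randomness goes through
// R's RNG so set.seed() at the R level controls every draw.

namespace {

inline int runif_int(int n) {
  // uniform on {0, ..., n}
  int k = (int)(unif_rand() * (n + 1));
  return k > n ? n : k;
}

enum FitnessMode { NEUTRAL = 0, RELATIVE = 1, ABSOLUTE = 2 };

// Conditional selection weights g_j (given that a death event was drawn):
// neutral 1/Ng, relative (1 - a fA_j) / sum_l (1 - a fA_l),
// absolute (1 - a fA_j) / Ng (residual mass = no death).
void death_sel_weights(const std::vector<int>& nA, const std::vector<int>& nB,
                       double a, int mode, std::vector<double>& g) {
  int Ng = (int)nA.size();
  g.resize(Ng);
  if (mode == NEUTRAL) {
    for (int j = 0; j < Ng; ++j) g[j] = 1.0 / Ng;
    return;
  }
  double tot = 0.0;
  for (int j = 0; j < Ng; ++j) {
    double fA = (double)nA[j] / (nA[j] + nB[j]);
    g[j] = 1.0 - a * fA;
    tot += g[j];
  }
  if (mode == RELATIVE) {
    if (tot <= 0.0) {            // all groups all-A with a = 1: 0/0 limit
      for (int j = 0; j < Ng; ++j) g[j] = 1.0 / Ng;
    } else {
      for (int j = 0; j < Ng; ++j) g[j] /= tot;
    }
  } else {                       // ABSOLUTE
    for (int j = 0; j < Ng; ++j) g[j] /= Ng;
  }
}

// One synchronous reproduction pass: each group uses its own pre-step
// composition; groups are independent so in-place update is safe.
void reproduce_all(std::vector<int>& nA, std::vector<int>& nB, int K, double b) {
  int Ng = (int)nA.size();
  for (int j = 0; j < Ng; ++j) {
    int n = nA[j] + nB[j];
    if (n >= K) continue;        // no resources left
    double res = 1.0 - (double)n / K;
    double pA = ((double)nA[j] / K) * res;
    double pB = b * ((double)nB[j] / K) * res;
    double u = unif_rand();
    if (u < pA) nA[j] += 1;
    else if (u < pA + pB) nB[j] += 1;
  }
}

// At most one group death per step, attempted with probability mu.
// Returns index of removed group or -1.
int death_event(std::vector<int>& nA, std::vector<int>& nB,
                double mu, double a, int mode) {
  int Ng = (int)nA.size();
  if (Ng == 0) return -1;
  if (unif_rand() >= mu) return -1;
  std::vector<double> g;
  death_sel_weights(nA, nB, a, mode, g);
  double v = unif_rand(), cum = 0.0;
  for (int j = 0; j < Ng; ++j) {
    cum += g[j];
    if (v < cum) {
      nA.erase(nA.begin() + j);
      nB.erase(nB.begin() + j);
      return j;
    }
  }
  return -1;                     // absolute mode residual: no death
}

// At most one split per step: a group at the threshold K splits into two
// daughters by uniform allocation; an empty daughter is discarded
// (abortive split leaves the full-size survivor in place).
void split_event(std::vector<int>& nA, std::vector<int>& nB, int K, int Kg) {
  int Ng = (int)nA.size();
  if (Ng == 0 || Ng >= Kg) return;
  std::vector<int> full;
  for (int j = 0; j < Ng; ++j)
    if (nA[j] + nB[j] == K) full.push_back(j);
  if (full.empty()) return;
  int j = full[runif_int((int)full.size() - 1)];
  int mA = runif_int(nA[j]);
  int mB = runif_int(nB[j]);
  int d2A = nA[j] - mA, d2B = nB[j] - mB;
  if (mA + mB == 0) return;      // abortive: survivor equals the parent
  if (d2A + d2B == 0) return;    // abortive, mirror case
  nA[j] = mA; nB[j] = mB;
  nA.push_back(d2A); nB.push_back(d2B);
}

void summarize(const std::vector<int>& nA, const std::vector<int>& nB,
               int& Ng, int& NgA, long& totA, long& totB) {
  Ng = (int)nA.size(); NgA = 0; totA = 0; totB = 0;
  for (int j = 0; j < Ng; ++j) {
    if (nB[j] == 0) ++NgA;
    totA += nA[j]; totB += nB[j];
  }
}

void from_matrix(const IntegerMatrix& groups,
                 std::vector<int>& nA, std::vector<int>& nB) {
  int Ng = groups.nrow();
  nA.resize(Ng); nB.resize(Ng);
  for (int j = 0; j < Ng; ++j) { nA[j] = groups(j, 0); nB[j] = groups(j, 1); }
}

IntegerMatrix to_matrix(const std::vector<int>& nA, const std::vector<int>& nB) {
  int Ng = (int)nA.size();
  IntegerMatrix out(Ng, 2);
  for (int j = 0; j < Ng; ++j) { out(j, 0) = nA[j]; out(j, 1) = nB[j]; }
  colnames(out) = CharacterVector::create("nA", "nB");
  return out;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_death_weights(IntegerMatrix groups, double mu, double a,
                                int mode) {
  std::vector<int> nA, nB;
  from_matrix(groups, nA, nB);
  std::vector<double> g;
  death_sel_weights(nA, nB, a, mode, g);
  NumericVector out((int)g.size());
  for (int j = 0; j < (int)g.size(); ++j) out[j] = mu * g[j];
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_reproduction_step(IntegerMatrix groups, int K, double b) {
  std::vector<int> nA, nB;
  from_matrix(groups, nA, nB);
  reproduce_all(nA, nB, K, b);
  return to_matrix(nA, nB);
}

// [[Rcpp::export]]
List cpp_apply_group_death(IntegerMatrix groups, double mu, double a, int mode) {
  std::vector<int> nA, nB;
  from_matrix(groups, nA, nB);
  int removed = death_event(nA, nB, mu, a, mode);
  return List::create(_["groups"] = to_matrix(nA, nB),
                      _["removed"] = removed >= 0 ? removed + 1 : NA_INTEGER);
}

// [[Rcpp::export]]
IntegerMatrix cpp_split_group(IntegerVector group) {
  int pA = group[0], pB = group[1];
  int mA = runif_int(pA), mB = runif_int(pB);
  int d2A = pA - mA, d2B = pB - mB;
  if (mA + mB == 0) {
    IntegerMatrix out(1, 2); out(0, 0) = d2A; out(0, 1) = d2B;
    colnames(out) = CharacterVector::create("nA", "nB");
    return out;
  }
  if (d2A + d2B == 0) {
    IntegerMatrix out(1, 2); out(0, 0) = mA; out(0, 1) = mB;
    colnames(out) = CharacterVector::create("nA", "nB");
    return out;
  }
  IntegerMatrix out(2, 2);
  out(0, 0) = mA; out(0, 1) = mB; out(1, 0) = d2A; out(1, 1) = d2B;
  colnames(out) = CharacterVector::create("nA", "nB");
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_splitting_step(IntegerMatrix groups, int K, int Kg) {
  std::vector<int> nA, nB;
  from_matrix(groups, nA, nB);
  split_event(nA, nB, K, Kg);
  return to_matrix(nA, nB);
}

// [[Rcpp::export]]
IntegerMatrix cpp_step(IntegerMatrix groups, int K, int Kg, double mu,
                       double a, double b, int mode) {
  std::vector<int> nA, nB;
  from_matrix(groups, nA, nB);
  reproduce_all(nA, nB, K, b);
  death_event(nA, nB, mu, a, mode);
  split_event(nA, nB, K, Kg);
  return to_matrix(nA, nB);
}

// Full trajectory driver. stop_absorb: additionally stop when the whole
// population is homogeneous (all-A or all-B) or extinct.
// outcome codes: 0 horizon reached, 1 all-A, 2 all-B, 3 extinct.
// [[Rcpp::export]]
List cpp_run(IntegerMatrix init, int K, int Kg, double mu, double a, double b,
             int mode, int T, bool record, bool stop_absorb) {
  std::vector<int> nA, nB;
  from_matrix(init, nA, nB);

  int Ng, NgA; long totA, totB;
  summarize(nA, nB, Ng, NgA, totA, totB);

  NumericMatrix traj;
  if (record) {
    traj = NumericMatrix(T + 1, 5);
    colnames(traj) = CharacterVector::create("t", "Ng", "Ng_A",
                                             "nA_total", "nB_total");
  }
  if (record) {
    traj(0, 0) = 0; traj(0, 1) = Ng; traj(0, 2) = NgA;
    traj(0, 3) = (double)totA; traj(0, 4) = (double)totB;
  }

  int outcome = 0, t_end = 0;
  if (Ng == 0) outcome = 3;
  else if (stop_absorb && totB == 0) outcome = 1;
  else if (stop_absorb && totA == 0) outcome = 2;

  for (int t = 1; t <= T && outcome == 0; ++t) {
    reproduce_all(nA, nB, K, b);
    death_event(nA, nB, mu, a, mode);
    split_event(nA, nB, K, Kg);
    summarize(nA, nB, Ng, NgA, totA, totB);
    t_end = t;
    if (record) {
      traj(t, 0) = t; traj(t, 1) = Ng; traj(t, 2) = NgA;
      traj(t, 3) = (double)totA; traj(t, 4) = (double)totB;
    }
    if (Ng == 0) outcome = 3;
    else if (stop_absorb && totB == 0) outcome = 1;
    else if (stop_absorb && totA == 0) outcome = 2;
    if ((t & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  if (record && t_end < T) {
    // extinction (or absorption) before the horizon: pad the record; the
    // extinct state is all-zero, an absorbed state is frozen.
    for (int t = t_end + 1; t <= T; ++t) {
      traj(t, 0) = t;
      if (outcome == 3) { traj(t, 1) = 0; traj(t, 2) = 0;
                          traj(t, 3) = 0; traj(t, 4) = 0; }
      else { traj(t, 1) = Ng; traj(t, 2) = NgA;
             traj(t, 3) = (double)totA; traj(t, 4) = (double)totB; }
    }
  }

  return List::create(_["trajectory"] = traj,
                      _["groups"] = to_matrix(nA, nB),
                      _["t_end"] = t_end,
                      _["outcome"] = outcome,
                      _["extinct"] = (outcome == 3),
                      _["Ng"] = Ng, _["Ng_A"] = NgA,
                      _["nA_total"] = (double)totA,
                      _["nB_total"] = (double)totB);
}

// Monte-Carlo hitting probability for a single group held at a fixed
// per-step survival probability delta (group number frozen): used as the
// simulation side of the recursion cross-check at small K.
// [[Rcpp::export]]
int cpp_single_group_hits(int n0, int K, double b, double delta, int M) {
  int hits = 0;
  for (int m = 0; m < M; ++m) {
    int n = n0;
    while (n > 0 && n < K) {
      if (unif_rand() >= delta) { n = 0; break; }  // group death
      double p = b * ((double)n / K) * (1.0 - (double)n / K);
      if (unif_rand() < p) ++n;
    }
    if (n == K) ++hits;
    if ((m & 4095) == 0) Rcpp::checkUserInterrupt();
  }
  return hits;
}
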