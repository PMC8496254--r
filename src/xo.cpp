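// Obligate-crossover counting and the permuted-sliding-window (ripple)
// order search. Doses are coded 0 (A), 1 (H), 2 (B), NA_INTEGER missing.
//
// The obligate crossover count is the minimum number of recombination
// events consistent with an ordered call sequence. It is computed by
// dynamic programming over the four phased genotype states (ordered
// gamete-allele pairs); the transition cost between states is the number
// of gametes that switch. Missing calls are skipped.

#include <Rcpp.h>
using namespace Rcpp;

static const int BIG = 1 << 28;

// allowed phased states per dose: state = 2*a + b with gamete alleles a,b
// in {0,1}. dose 0 -> {00}; 1 -> {01, 10}; 2 -> {11}.
static inline void allowed_states(int dose, bool out[4]) {
  out[0] = (dose == 0);
  out[1] = out[2] = (dose == 1);
  out[3] = (dose == 2);
}

static inline int state_cost(int s, int t) {
  int x = s ^ t;            // bit 1: gamete 1 switched, bit 0: gamete 2
  return (x & 1) + ((x >> 1) & 1);
}

// DP over one individual's calls (already in map order, NA skipped).
static int xo_one(const IntegerMatrix& geno, int ind,
                  const IntegerVector& order0) {
  double best[4];
  bool started = false;
  bool allow[4];
  for (int k = 0; k < order0.size(); ++k) {
    int dose = geno(ind, order0[k]);
    if (dose == NA_INTEGER) continue;
    allowed_states(dose, allow);
    if (!started) {
      for (int s = 0; s < 4; ++s) best[s] = allow[s] ? 0 : BIG;
      started = true;
      continue;
    }
    double next[4];
    for (int t = 0; t < 4; ++t) {
      if (!allow[t]) { next[t] = BIG; continue; }
      double b = BIG;
      for (int s = 0; s < 4; ++s) {
        double c = best[s] + state_cost(s, t);
        if (c < b) b = c;
      }
      next[t] = b;
    }
    for (int s = 0; s < 4; ++s) best[s] = next[s];
  }
  if (!started) return 0;
  double b = BIG;
  for (int s = 0; s < 4; ++s) if (best[s] < b) b = best[s];
  return (int)b;
}

// [[Rcpp::export]]
IntegerVector count_xo_cpp(IntegerMatrix geno, IntegerVector order0) {
  int n = geno.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = xo_one(geno, i, order0);
  return out;
}

// One ripple pass: slide a window over the order; at each position score
// every window permutation by the total obligate crossovers it implies
// (only the window segment and its per-individual flanking anchors can
// change), adopt a minimal one, ties broken uniformly at random using R's
// RNG. Individuals with no missing call in the window are scored in
// aggregate through pairwise dose-difference sums; individuals with
// missing data are walked per permutation.
// [[Rcpp::export]]
List ripple_pass_cpp(IntegerMatrix geno, IntegerVector order0, int window,
                     IntegerMatrix perms0) {
  int m = order0.size();
  int n = geno.nrow();
  std::vector<int> ord(order0.begin(), order0.end());
  int nperm = perms0.nrow();
  bool improved = false;

  std::vector<int> dose(n * window);       // window doses per individual
  std::vector<int> anchorL(n), anchorR(n); // flanking doses, -1 if none
  std::vector<int> clean;                  // individuals w/o NA in window
  std::vector<int> dirty;
  std::vector<double> pairD(window * window);
  std::vector<double> aL(window), aR(window);

  for (int pos = 0; pos + window <= m; ++pos) {
    // collect window doses and anchors
    clean.clear(); dirty.clear();
    for (int i = 0; i < n; ++i) {
      bool has_na = false;
      for (int k = 0; k < window; ++k) {
        int d = geno(i, ord[pos + k]);
        if (d == NA_INTEGER) { d = -1; has_na = true; }
        dose[i * window + k] = d;
      }
      int a = -1;
      for (int j = pos - 1; j >= 0; --j) {
        int d = geno(i, ord[j]);
        if (d != NA_INTEGER) { a = d; break; }
      }
      anchorL[i] = a;
      a = -1;
      for (int j = pos + window; j < m; ++j) {
        int d = geno(i, ord[j]);
        if (d != NA_INTEGER) { a = d; break; }
      }
      anchorR[i] = a;
      if (has_na) dirty.push_back(i); else clean.push_back(i);
    }
    // aggregate tables over clean individuals
    std::fill(pairD.begin(), pairD.end(), 0.0);
    std::fill(aL.begin(), aL.end(), 0.0);
    std::fill(aR.begin(), aR.end(), 0.0);
    for (size_t ci = 0; ci < clean.size(); ++ci) {
      int i = clean[ci];
      const int* d = &dose[i * window];
      for (int a = 0; a < window; ++a) {
        for (int b = a + 1; b < window; ++b) {
          double dd = std::abs(d[a] - d[b]);
          pairD[a * window + b] += dd;
          pairD[b * window + a] += dd;
        }
        if (anchorL[i] >= 0) aL[a] += std::abs(anchorL[i] - d[a]);
        if (anchorR[i] >= 0) aR[a] += std::abs(anchorR[i] - d[a]);
      }
    }
    // score permutations
    double best_cost = R_PosInf;
    double identity_cost = R_PosInf;
    std::vector<int> ties;
    for (int p = 0; p < nperm; ++p) {
      double cost = 0.0;
      int first = perms0(p, 0), last = perms0(p, window - 1);
      cost += aL[first] + aR[last];
      for (int k = 0; k + 1 < window; ++k) {
        cost += pairD[perms0(p, k) * window + perms0(p, k + 1)];
      }
      for (size_t di = 0; di < dirty.size(); ++di) {
        int i = dirty[di];
        const int* d = &dose[i * window];
        int prev = anchorL[i];
        for (int k = 0; k < window; ++k) {
          int dk = d[perms0(p, k)];
          if (dk < 0) continue;
          if (prev >= 0) cost += std::abs(dk - prev);
          prev = dk;
        }
        if (prev >= 0 && anchorR[i] >= 0) cost += std::abs(anchorR[i] - prev);
      }
      if (p == 0) identity_cost = cost;  // perms0 row 0 is the identity
      if (cost < best_cost - 1e-9) {
        best_cost = cost;
        ties.clear();
        ties.push_back(p);
      } else if (cost <= best_cost + 1e-9) {
        ties.push_back(p);
      }
    }
    int chosen = ties[(int)(unif_rand() * ties.size()) % ties.size()];
    if (best_cost < identity_cost - 1e-9) improved = true;
    if (chosen != 0) {
      std::vector<int> neworder(window);
      for (int k = 0; k < window; ++k) neworder[k] = ord[pos + perms0(chosen, k)];
      for (int k = 0; k < window; ++k) ord[pos + k] = neworder[k];
    }
  }
  IntegerVector out(ord.begin(), ord.end());
  IntegerVector xo = count_xo_cpp(geno, out);
  long total = 0;
  for (int i = 0; i < n; ++i) total += xo[i];
  return List::create(_["order"] = out, _["improved"] = improved,
                      _["total_xo"] = (double)total);
}
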