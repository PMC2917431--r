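#include <Rcpp.h>
#include <random>
#include <vector>

using namespace Rcpp;

// One level of greedy local moves for Potts energy minimisation.
//
// The energy is H = -sum_{i != j} (B_ij - lambda * k_i k_j / (2W)) delta(s_i, s_j)
// over ordered pairs of distinct nodes of the *original* network.  On an
// aggregated (weighted) graph the self-pair and self-loop terms are constant
// under any move, so the move gain reduces to the standard Louvain form:
//   gain(i -> c) = w(i, c) - lambda * k_i * K_c / (2W)
// where w(i, c) is the weight from i to community c (self-loops excluded),
// k_i the node strength (self-loops counted twice) and K_c the strength sum
// of c excluding i.  Moves are accepted only on strict improvement; among
// equal best gains the lowest community label wins.  Node visit order is a
// Fisher-Yates shuffle driven by a seeded mt19937 so runs are reproducible.
//
// edges are 0-based (from, to, weight) with each undirected edge once;
// self-loops allowed (from == to).  init is a 0-based starting assignment.
// [[Rcpp::export]]
IntegerVector louvain_one_level(int n,
                                IntegerVector from,
                                IntegerVector to,
                                NumericVector weight,
                                NumericVector strength,
                                double two_w,
                                double lambda,
                                IntegerVector init,
                                int seed,
                                int max_passes = 100) {
  int m = from.size();
  // CSR adjacency (both directions), self-loops skipped: they never enter
  // a move gain (their contribution is community-independent).
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) {
    if (from[e] != to[e]) {
      deg[from[e]]++;
      deg[to[e]]++;
    }
  }
  std::vector<int> ptr(n + 1, 0);
  for (int i = 0; i < n; ++i) ptr[i + 1] = ptr[i] + deg[i];
  std::vector<int> nbr(ptr[n]);
  std::vector<double> nw(ptr[n]);
  std::vector<int> fill(n, 0);
  for (int e = 0; e < m; ++e) {
    int a = from[e], b = to[e];
    if (a == b) continue;
    nbr[ptr[a] + fill[a]] = b;
    nw[ptr[a] + fill[a]] = weight[e];
    fill[a]++;
    nbr[ptr[b] + fill[b]] = a;
    nw[ptr[b] + fill[b]] = weight[e];
    fill[b]++;
  }

  std::vector<int> comm(n);
  std::vector<double> ctot(n, 0.0);  // strength sum per community label
  std::vector<int> csize(n, 0);      // occupancy per community label
  for (int i = 0; i < n; ++i) {
    comm[i] = init[i];
    ctot[comm[i]] += strength[i];
    csize[comm[i]]++;
  }

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::mt19937 rng(static_cast<unsigned int>(seed));
  for (int i = n - 1; i > 0; --i) {
    int j = static_cast<int>(rng() % static_cast<unsigned int>(i + 1));
    std::swap(order[i], order[j]);
  }

  // scratch: weight from current node to each community
  std::vector<double> wcom(n, 0.0);
  std::vector<int> touched;
  touched.reserve(64);
  const double eps = 1e-12;

  bool improved = true;
  int pass = 0;
  while (improved && pass < max_passes) {
    improved = false;
    ++pass;
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      int ci = comm[i];
      touched.clear();
      for (int p = ptr[i]; p < ptr[i + 1]; ++p) {
        int c = comm[nbr[p]];
        if (wcom[c] == 0.0) touched.push_back(c);
        wcom[c] += nw[p];
      }
      // gain of staying put (i removed from its community first)
      double ki = strength[i];
      double gain_stay = wcom[ci] - lambda * ki * (ctot[ci] - ki) / two_w;
      // candidate communities: neighbours, plus a fresh singleton (gain 0)
      double best_gain = 0.0;  // fresh singleton baseline
      int best_comm = -1;      // -1 => fresh singleton
      // visit candidates in increasing label order for a deterministic
      // lowest-label tie-break
      std::sort(touched.begin(), touched.end());
      for (size_t t = 0; t < touched.size(); ++t) {
        int c = touched[t];
        if (c == ci) continue;
        double g = wcom[c] - lambda * ki * ctot[c] / two_w;
        if (g > best_gain + eps) {
          best_gain = g;
          best_comm = c;
        }
      }
      if (best_gain > gain_stay + eps) {
        ctot[ci] -= ki;
        csize[ci]--;
        int target = best_comm;
        if (target < 0) {
          // fresh singleton: reuse i's old label if vacated, else lowest
          // empty label (n labels always suffice)
          if (csize[ci] == 0) {
            target = ci;
          } else {
            for (int c = 0; c < n; ++c)
              if (csize[c] == 0) { target = c; break; }
          }
        }
        comm[i] = target;
        ctot[target] += ki;
        csize[target]++;
        improved = true;
      }
      for (size_t t = 0; t < touched.size(); ++t) wcom[touched[t]] = 0.0;
    }
  }

  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = comm[i];
  return out;
}
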