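// Greedy Louvain community detection with a resolution parameter:
// local moving + graph aggregation repeated to a fixed point, maximizing
// Q(r) = sum_c [ W_in(c)/W - r * (S_c / (2W))^2 ].
// The graph arrives in compressed sparse column form (symmetric, both
// triangles stored, zero diagonal). Node sweep order is shuffled with R's
// RNG so set.seed() upstream makes runs reproducible.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

namespace {

struct Csr {
  std::vector<int> p;     // column pointers, size n + 1
  std::vector<int> idx;   // row indices
  std::vector<double> w;  // weights
  int n;
};

// Fisher-Yates with R's RNG (deterministic under set.seed)
void shuffle_r(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// one Louvain level: local moving on `g`, returns communities (0-based,
// contiguous) and whether any node moved
bool local_moving(const Csr& g, double resolution, double two_w,
                  std::vector<int>& comm, std::vector<double>& self_loop) {
  int n = g.n;
  std::vector<double> strength(n, 0.0);
  for (int v = 0; v < n; ++v) {
    for (int e = g.p[v]; e < g.p[v + 1]; ++e) strength[v] += g.w[e];
    strength[v] += 2.0 * self_loop[v];
  }
  std::vector<double> comm_strength(strength);
  for (int v = 0; v < n; ++v) comm[v] = v;

  std::vector<double> link(n, 0.0);   // weight from v to each community
  std::vector<int> touched;
  touched.reserve(64);
  std::vector<int> order(n);
  for (int v = 0; v < n; ++v) order[v] = v;

  bool any_move = false;
  bool improved = true;
  int sweep = 0;
  while (improved && sweep < 100) {
    improved = false;
    ++sweep;
    shuffle_r(order);
    for (int oi = 0; oi < n; ++oi) {
      int v = order[oi];
      int cv = comm[v];
      touched.clear();
      for (int e = g.p[v]; e < g.p[v + 1]; ++e) {
        int c = comm[g.idx[e]];
        if (link[c] == 0.0) touched.push_back(c);
        link[c] += g.w[e];
      }
      if (link[cv] == 0.0) touched.push_back(cv);  // ensure present
      comm_strength[cv] -= strength[v];
      double best_gain = link[cv] - resolution * comm_strength[cv] *
                                        strength[v] / two_w;
      int best_c = cv;
      for (int t = 0; t < (int)touched.size(); ++t) {
        int c = touched[t];
        if (c == cv) continue;
        double gain = link[c] - resolution * comm_strength[c] *
                                    strength[v] / two_w;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_c = c;
        }
      }
      comm[v] = best_c;
      comm_strength[best_c] += strength[v];
      if (best_c != cv) {
        improved = true;
        any_move = true;
      }
      for (int t = 0; t < (int)touched.size(); ++t) link[touched[t]] = 0.0;
    }
  }
  // relabel contiguous
  std::vector<int> remap(n, -1);
  int k = 0;
  for (int v = 0; v < n; ++v) {
    if (remap[comm[v]] < 0) remap[comm[v]] = k++;
    comm[v] = remap[comm[v]];
  }
  return any_move;
}

// aggregate graph by communities; self-loops accumulate internal weight
void aggregate(const Csr& g, const std::vector<int>& comm,
               const std::vector<double>& self_loop, int k, Csr& out,
               std::vector<double>& out_self) {
  out.n = k;
  out_self.assign(k, 0.0);
  std::vector<std::vector<std::pair<int, double> > > buckets(k);
  for (int v = 0; v < g.n; ++v) {
    int cv = comm[v];
    out_self[cv] += self_loop[v];
    for (int e = g.p[v]; e < g.p[v + 1]; ++e) {
      int cu = comm[g.idx[e]];
      if (cu == cv) {
        if (g.idx[e] > v) out_self[cv] += g.w[e];  // count each edge once
      } else {
        buckets[cv].push_back(std::make_pair(cu, g.w[e]));
      }
    }
  }
  out.p.assign(k + 1, 0);
  out.idx.clear();
  out.w.clear();
  std::vector<double> acc(k, 0.0);
  std::vector<int> seen;
  for (int c = 0; c < k; ++c) {
    seen.clear();
    for (size_t b = 0; b < buckets[c].size(); ++b) {
      int d = buckets[c][b].first;
      if (acc[d] == 0.0) seen.push_back(d);
      acc[d] += buckets[c][b].second;
    }
    for (size_t s = 0; s < seen.size(); ++s) {
      out.idx.push_back(seen[s]);
      out.w.push_back(acc[seen[s]]);
      acc[seen[s]] = 0.0;
    }
    out.p[c + 1] = (int)out.idx.size();
  }
}

}  // namespace

// [[Rcpp::export(name = ".louvain_cpp")]]
IntegerVector louvain_cpp(IntegerVector p, IntegerVector idx,
                          NumericVector w, int n, double resolution) {
  GetRNGstate();
  Csr g;
  g.n = n;
  g.p.assign(p.begin(), p.end());
  g.idx.assign(idx.begin(), idx.end());
  g.w.assign(w.begin(), w.end());
  double two_w = 0.0;
  for (size_t e = 0; e < g.w.size(); ++e) two_w += g.w[e];  // both triangles

  std::vector<int> membership(n);
  for (int v = 0; v < n; ++v) membership[v] = v;
  std::vector<double> self_loop(n, 0.0);

  for (int level = 0; level < 100; ++level) {
    std::vector<int> comm(g.n);
    bool moved = local_moving(g, resolution, two_w, comm, self_loop);
    int k = 0;
    for (int v = 0; v < g.n; ++v) k = std::max(k, comm[v] + 1);
    for (int v = 0; v < n; ++v) membership[v] = comm[membership[v]];
    if (!moved || k == g.n) break;
    Csr next;
    std::vector<double> next_self;
    aggregate(g, comm, self_loop, k, next, next_self);
    g = next;
    self_loop = next_self;
  }
  PutRNGstate();
  return IntegerVector(membership.begin(), membership.end());
}
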