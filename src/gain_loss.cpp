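// Exact maximum-gain / maximum-loss simple-path products from one source.
//
// A node's gain label is the largest positive product of edge weights over
// simple paths from the source; its loss label is the most negative such
// product.  Because |w| <= 1 a walk that revisits a node can only beat a
// simple path by absorbing a cycle whose edge-sign product is negative, so
// plain label-correcting over walks is not sound for the simple-path
// definition.  We therefore run a best-first search over labels that carry
// the visited set as a bitmask, with two sound prunes:
//   * Pareto dominance per (node, sign): a label is dropped when another
//     label at the node with the same sign has magnitude >= and a visited
//     set that is a subset of the new label's.
//   * a bound prune: walk-product upper bounds M+(v,j), M-(v,j) (all-pairs
//     Dijkstra on the signed double cover, computed in R) certify when no
//     extension of a label can strictly improve any unvisited node's
//     current label, in which case the label need not be expanded.
// Termination is guaranteed by the finite number of simple paths.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <queue>
#include <vector>

using namespace Rcpp;

namespace {

struct Label {
  double p;                    // signed running product, never 0
  int node;                    // 0-based
  std::vector<uint64_t> mask;  // visited set incl. source and node
};

struct ByMagnitude {
  bool operator()(const Label& a, const Label& b) const {
    return std::fabs(a.p) < std::fabs(b.p);
  }
};

inline bool in_mask(const std::vector<uint64_t>& m, int v) {
  return (m[v >> 6] >> (v & 63)) & 1ULL;
}

inline void set_mask(std::vector<uint64_t>& m, int v) {
  m[v >> 6] |= 1ULL << (v & 63);
}

// a subset of b?
inline bool subset_of(const std::vector<uint64_t>& a,
                      const std::vector<uint64_t>& b) {
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] & ~b[i]) return false;
  return true;
}

struct Stored {
  double mag;
  std::vector<uint64_t> mask;
};

// Can extending (node v, sign s, magnitude a, visited mask) strictly improve
// gain[] or loss[] at some unvisited node?  Mpos/Mneg rows hold walk-product
// magnitude bounds from v; a positive continuation keeps the sign, a
// negative continuation flips it.
bool improvable(int n, int v, int s, double a,
                const std::vector<uint64_t>& mask,
                const std::vector<double>& gain,
                const std::vector<double>& loss,
                const NumericMatrix& Mpos, const NumericMatrix& Mneg) {
  for (int j = 0; j < n; ++j) {
    if (j == v || in_mask(mask, j)) continue;
    const double up = a * Mpos(v, j);
    const double un = a * Mneg(v, j);
    if (s > 0) {
      if (up > gain[j] || un > -loss[j]) return true;
    } else {
      if (up > -loss[j] || un > gain[j]) return true;
    }
  }
  return false;
}

}  // namespace

// [[Rcpp::export(name = ".gain_loss_cpp")]]
List gain_loss_cpp(int n, IntegerVector from, IntegerVector to,
                   NumericVector weight, int source,
                   NumericMatrix Mpos, NumericMatrix Mneg) {
  std::vector<std::vector<std::pair<int, double>>> adj(n);
  const int m = from.size();
  for (int e = 0; e < m; ++e) {
    adj[from[e]].push_back({to[e], weight[e]});
    adj[to[e]].push_back({from[e], weight[e]});
  }

  std::vector<double> gain(n, 0.0), loss(n, 0.0);
  const size_t words = (n + 63) / 64;

  // Pareto stores, one per (node, sign)
  std::vector<std::vector<Stored>> store_pos(n), store_neg(n);

  std::priority_queue<Label, std::vector<Label>, ByMagnitude> pq;
  Label init;
  init.p = 1.0;
  init.node = source;
  init.mask.assign(words, 0ULL);
  set_mask(init.mask, source);
  pq.push(std::move(init));

  while (!pq.empty()) {
    Label cur = pq.top();
    pq.pop();
    const int s = cur.p > 0 ? 1 : -1;
    const double a = std::fabs(cur.p);
    // labels decay in usefulness as gain/loss tighten; re-check at pop
    if (!improvable(n, cur.node, s, a, cur.mask, gain, loss, Mpos, Mneg))
      continue;

    for (const auto& nb : adj[cur.node]) {
      const int u = nb.first;
      if (in_mask(cur.mask, u)) continue;
      const double p2 = cur.p * nb.second;
      if (p2 > 0) {
        if (p2 > gain[u]) gain[u] = p2;
      } else {
        if (p2 < loss[u]) loss[u] = p2;
      }

      std::vector<uint64_t> mask2 = cur.mask;
      set_mask(mask2, u);
      const double a2 = std::fabs(p2);
      std::vector<Stored>& bucket = (p2 > 0) ? store_pos[u] : store_neg[u];

      bool dominated = false;
      for (const Stored& st : bucket) {
        if (st.mag >= a2 && subset_of(st.mask, mask2)) {
          dominated = true;
          break;
        }
      }
      if (dominated) continue;
      // drop stored labels this one dominates
      for (size_t k = bucket.size(); k-- > 0;) {
        if (a2 >= bucket[k].mag && subset_of(mask2, bucket[k].mask)) {
          bucket[k] = bucket.back();
          bucket.pop_back();
        }
      }
      bucket.push_back({a2, mask2});

      if (!improvable(n, u, p2 > 0 ? 1 : -1, a2, mask2, gain, loss, Mpos,
                      Mneg))
        continue;
      Label nxt;
      nxt.p = p2;
      nxt.node = u;
      nxt.mask = std::move(mask2);
      // keep the stored copy: Stored holds its own mask (copied above via
      // push_back), so moving here is safe only because bucket stored a copy
      pq.push(std::move(nxt));
    }
  }

  return List::create(_["gain"] = NumericVector(gain.begin(), gain.end()),
                      _["loss"] = NumericVector(loss.begin(), loss.end()));
}
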