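// HOSE-code kernel: builds the breadth-first sphere tree around each
// query atom and emits the canonical dialect strings.  The molecule-
// level canonicalization (Morgan-style atom ranks) is computed in R
// and passed in; this kernel owns tree construction, canonical sibling
// ordering and string assembly.  All string comparisons are plain byte
// comparisons, so ordering is locale-independent.

#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

namespace {

const char* kBondSym[] = {"", "=", "%", "*"};

struct Node {
  int atom;          // -1 for ring-closure nodes
  int brank;         // 1..4
  std::string elem;  // element symbol or "&"
  int parent_atom;   // 0-based, -1 for root
  std::vector<int> children;
  std::vector<std::string> levels;
};

}  // namespace

// Cumulative HOSE codes (spheres 1..S) for each query center.
// `nbrs` and `branks` are per-atom adjacency lists (1-based indices,
// bond ranks 1..4); `ranks` are canonical atom ranks; `centers` are
// 1-based query atoms.  Returns a length(centers) x S character matrix.
// [[Rcpp::export(name = ".cpp_hose_codes")]]
Rcpp::CharacterMatrix cpp_hose_codes(Rcpp::CharacterVector elements,
                                     Rcpp::List nbrs, Rcpp::List branks,
                                     Rcpp::IntegerVector ranks,
                                     Rcpp::IntegerVector centers, int S) {
  const int n = elements.size();
  std::vector<std::vector<int>> adj(n), bnd(n);
  for (int i = 0; i < n; ++i) {
    Rcpp::IntegerVector a = nbrs[i], b = branks[i];
    adj[i].assign(a.begin(), a.end());
    for (auto& v : adj[i]) v -= 1;
    bnd[i].assign(b.begin(), b.end());
  }
  std::vector<std::string> elem(n);
  for (int i = 0; i < n; ++i) elem[i] = Rcpp::as<std::string>(elements[i]);

  Rcpp::CharacterMatrix out(centers.size(), S);

  for (int q = 0; q < centers.size(); ++q) {
    const int c0 = centers[q] - 1;
    // breadth-first distances
    std::vector<int> dist(n, -1);
    dist[c0] = 0;
    std::vector<int> queue{c0};
    for (size_t head = 0; head < queue.size(); ++head) {
      int a = queue[head];
      for (int j : adj[a])
        if (dist[j] < 0) {
          dist[j] = dist[a] + 1;
          queue.push_back(j);
        }
    }
    // tree construction, level-synchronous
    std::vector<Node> nodes;
    nodes.push_back({c0, 0, elem[c0], -1, {}, {}});
    std::vector<bool> assigned(n, false);
    assigned[c0] = true;
    std::vector<std::vector<int>> level(S + 1);
    level[0] = {0};
    for (int d = 1; d <= S; ++d) {
      for (int nd : level[d - 1]) {
        const int a = nodes[nd].atom;
        if (a < 0) continue;
        // candidate neighbours, excluding the tree parent
        std::vector<int> cand;
        for (size_t t = 0; t < adj[a].size(); ++t)
          if (adj[a][t] != nodes[nd].parent_atom) cand.push_back((int)t);
        if (cand.empty()) continue;
        std::stable_sort(cand.begin(), cand.end(), [&](int x, int y) {
          const int jx = adj[a][x], jy = adj[a][y];
          const int bx = bnd[a][x], by = bnd[a][y];
          if (bx != by) return bx < by;
          const bool cx = dist[jx] == d && !assigned[jx];
          const bool cy = dist[jy] == d && !assigned[jy];
          const std::string& ex = cx ? elem[jx] : "&";
          const std::string& ey = cy ? elem[jy] : "&";
          if (ex != ey) return ex < ey;
          return ranks[jx] < ranks[jy];
        });
        for (int t : cand) {
          const int j = adj[a][t];
          const bool child = dist[j] == d && !assigned[j];
          Node nw;
          nw.atom = child ? j : -1;
          nw.brank = bnd[a][t];
          nw.elem = child ? elem[j] : "&";
          nw.parent_atom = a;
          nodes.push_back(nw);
          const int id = (int)nodes.size() - 1;
          nodes[nd].children.push_back(id);
          level[d].push_back(id);
          if (child) assigned[j] = true;
        }
      }
    }
    // canonical per-node level strings, bottom-up
    for (int d = S; d >= 0; --d) {
      for (int nd : level[d]) {
        Node& node = nodes[nd];
        const int len = S - d + 1;
        node.levels.assign(len, "");
        // bond symbol lookup: brank 1->"", 2->"=", 3->"%", 4->"*"
        node.levels[0] =
            (node.brank >= 1 ? kBondSym[node.brank - 1] : "") + node.elem;
        if (node.children.empty()) continue;
        std::vector<std::pair<std::string, int>> keyed;
        keyed.reserve(node.children.size());
        for (int cn : node.children) {
          std::string key;
          key += ('0' + nodes[cn].brank);
          key += '\x02';
          key += nodes[cn].elem;
          key += '\x02';
          for (size_t k = 0; k < nodes[cn].levels.size(); ++k) {
            if (k) key += '\x01';
            key += nodes[cn].levels[k];
          }
          keyed.emplace_back(key, cn);
        }
        std::stable_sort(keyed.begin(), keyed.end(),
                         [](const std::pair<std::string, int>& x,
                            const std::pair<std::string, int>& y) {
                           return x.first < y.first;
                         });
        for (size_t k = 0; k < keyed.size(); ++k)
          node.children[k] = keyed[k].second;
        for (int k = 1; k < len; ++k) {
          std::string joined;
          for (size_t t = 0; t < node.children.size(); ++t) {
            if (t) joined += ',';
            joined += nodes[node.children[t]].levels[k - 1];
          }
          node.levels[k] = joined;
        }
      }
    }
    // emit sphere strings in canonical traversal order
    std::string center_tok =
        elem[c0] + "-" + std::to_string(adj[c0].size()) + ";";
    std::vector<int> prev{0};
    std::string code = center_tok;
    for (int d = 1; d <= S; ++d) {
      std::string sphere;
      std::vector<int> nxt;
      for (size_t p = 0; p < prev.size(); ++p) {
        if (p) sphere += ';';
        const Node& pn = nodes[prev[p]];
        for (size_t t = 0; t < pn.children.size(); ++t) {
          if (t) sphere += ',';
          sphere += nodes[pn.children[t]].levels[0];
          nxt.push_back(pn.children[t]);
        }
      }
      if (d > 1) code += '/';
      code += sphere;
      out(q, d - 1) = code;
      prev = nxt;
    }
  }
  return out;
}
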