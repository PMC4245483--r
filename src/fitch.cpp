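#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fitch parsimony length of an unrooted binary tree. The tree arrives as an
// undirected edge list over node ids (tips 1..ntip, internals > ntip); it is
// rooted internally along tip 1's pendant edge, which keeps every internal
// node strictly binary, and scored by the usual intersection/union pass.
// States are nucleotide bitmasks (A=1, C=2, G=4, T=8; missing = 15), one
// column per tip in `states`, one row per site pattern with `weights` counts.

// [[Rcpp::export(name = ".fitch_score_cpp")]]
List fitch_score_cpp(IntegerMatrix edge, int ntip,
                     IntegerMatrix states, IntegerVector weights,
                     bool per_site = false) {
  const int npat = states.nrow();
  if (states.ncol() != ntip) stop("states must have one column per tip");
  int maxnode = 0;
  for (int e = 0; e < edge.nrow(); ++e) {
    maxnode = std::max(maxnode, std::max(edge(e, 0), edge(e, 1)));
  }
  std::vector<std::vector<int> > adj(maxnode + 1);
  for (int e = 0; e < edge.nrow(); ++e) {
    adj[edge(e, 0)].push_back(edge(e, 1));
    adj[edge(e, 1)].push_back(edge(e, 0));
  }
  // anchor on the smallest tip present in the edge list (partial trees
  // built during stepwise addition need not contain tip 1 yet)
  int anchor = 0;
  for (int t = 1; t <= ntip && t <= maxnode; ++t) {
    if (adj[t].size() == 1) { anchor = t; break; }
  }
  if (anchor == 0) stop("no pendant tip found in the edge list");
  if (edge.nrow() == 1) {
    // single edge between two tips
    int other = (edge(0, 0) == anchor) ? edge(0, 1) : edge(0, 0);
    double tot = 0.0;
    IntegerVector ps(per_site ? npat : 0);
    for (int p = 0; p < npat; ++p) {
      int st = states(p, anchor - 1) & states(p, other - 1);
      int s = (st == 0) ? 1 : 0;
      if (per_site) ps[p] = s;
      tot += (double)s * weights[p];
    }
    return List::create(_["steps"] = tot, _["per_site"] = ps);
  }
  int root = adj[anchor][0];

  // iterative postorder from `root`, parent side = tip 1
  std::vector<int> order; order.reserve(maxnode);
  std::vector<int> parent(maxnode + 1, 0);
  std::vector<int> stack_; stack_.push_back(root);
  parent[root] = anchor;
  while (!stack_.empty()) {
    int v = stack_.back(); stack_.pop_back();
    order.push_back(v);
    for (size_t i = 0; i < adj[v].size(); ++i) {
      int w = adj[v][i];
      if (w != parent[v]) { parent[w] = v; stack_.push_back(w); }
    }
  }
  std::reverse(order.begin(), order.end()); // children before parents

  std::vector<std::vector<int> > kids(maxnode + 1);
  for (size_t i = 0; i < order.size(); ++i) {
    int v = order[i];
    if (v != root && parent[v] > 0) kids[parent[v]].push_back(v);
  }
  for (size_t i = 0; i < order.size(); ++i) {
    int v = order[i];
    if (v > ntip && kids[v].size() != 2)
      stop("tree is not binary (internal node %d has %d children)",
           v, (int)kids[v].size());
  }

  std::vector<int> set_((maxnode + 1) * 1, 0);
  std::vector<std::vector<int> > nodeset(maxnode + 1,
                                         std::vector<int>(npat, 0));
  IntegerVector ps(per_site ? npat : 0);
  std::vector<int> steps(npat, 0);

  for (size_t i = 0; i < order.size(); ++i) {
    int v = order[i];
    if (v <= ntip) {
      for (int p = 0; p < npat; ++p) nodeset[v][p] = states(p, v - 1);
    } else {
      const std::vector<int>& a = nodeset[kids[v][0]];
      const std::vector<int>& b = nodeset[kids[v][1]];
      std::vector<int>& out = nodeset[v];
      for (int p = 0; p < npat; ++p) {
        int inter = a[p] & b[p];
        if (inter) out[p] = inter;
        else { out[p] = a[p] | b[p]; ++steps[p]; }
      }
    }
  }
  // close the virtual root edge against the anchor tip
  for (int p = 0; p < npat; ++p) {
    if ((nodeset[root][p] & states(p, anchor - 1)) == 0) ++steps[p];
  }
  double tot = 0.0;
  for (int p = 0; p < npat; ++p) {
    tot += (double)steps[p] * weights[p];
    if (per_site) ps[p] = steps[p];
  }
  return List::create(_["steps"] = tot, _["per_site"] = ps);
}
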