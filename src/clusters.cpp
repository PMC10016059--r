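#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Label connected suprathreshold points on a channel x frequency x time grid.
//
// Connectivity: same channel and adjacent frequency OR time bin (4-neighborhood
// on the spectro-temporal grid, no diagonals), or same frequency-time bin and a
// neighboring channel according to the sensor adjacency graph.
//
// Before labelling, the spatial constraint is applied: a point is kept only if,
// at its frequency-time bin, at least `minnbchan` of its graph-neighbor
// channels are also suprathreshold (single pass).
//
// mask: logical vector in R array order (channel fastest, then freq, then time)
// dims: c(n_channels, n_freqs, n_times)
// adj:  list of integer vectors, 0-based channel neighbor indices
// returns: integer vector of cluster labels (0 = background)
// [[Rcpp::export]]
IntegerVector label_clusters_cpp(LogicalVector mask, IntegerVector dims,
                                 List adj, int minnbchan) {
  const int nc = dims[0], nf = dims[1], nt = dims[2];
  const int n = nc * nf * nt;
  if (mask.size() != n) stop("mask length does not match dims");

  std::vector<std::vector<int>> nb(nc);
  for (int c = 0; c < nc; ++c) {
    IntegerVector v = adj[c];
    nb[c] = std::vector<int>(v.begin(), v.end());
  }

  std::vector<char> on(n);
  for (int i = 0; i < n; ++i) on[i] = mask[i] ? 1 : 0;

  // spatial neighborhood constraint
  if (minnbchan > 0) {
    std::vector<char> keep(on);
    for (int t = 0; t < nt; ++t) {
      for (int f = 0; f < nf; ++f) {
        const int base = f * nc + t * nc * nf;
        for (int c = 0; c < nc; ++c) {
          if (!on[base + c]) continue;
          int cnt = 0;
          for (int c2 : nb[c]) if (on[base + c2]) ++cnt;
          if (cnt < minnbchan) keep[base + c] = 0;
        }
      }
    }
    on.swap(keep);
  }

  IntegerVector labels(n, 0);
  int next_label = 0;
  std::queue<int> q;
  for (int start = 0; start < n; ++start) {
    if (!on[start] || labels[start]) continue;
    ++next_label;
    labels[start] = next_label;
    q.push(start);
    while (!q.empty()) {
      int i = q.front(); q.pop();
      int c = i % nc;
      int f = (i / nc) % nf;
      int t = i / (nc * nf);
      auto visit = [&](int j) {
        if (on[j] && !labels[j]) { labels[j] = next_label; q.push(j); }
      };
      if (f > 0) visit(i - nc);
      if (f < nf - 1) visit(i + nc);
      if (t > 0) visit(i - nc * nf);
      if (t < nt - 1) visit(i + nc * nf);
      for (int c2 : nb[c]) visit(i + (c2 - c));
    }
  }
  return labels;
}
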