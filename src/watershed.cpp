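#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Seeded priority-flood watershed on an altitude map. Seeds carry positive
// integer labels; unlabeled pixels (0) are flooded from the lowest altitude
// outward, each taking the label of the basin that reaches it first.
// Deterministic: ties in altitude resolve by insertion order.
struct Node {
  double alt;
  long long order;
  int idx;
};
struct Cmp {
  bool operator()(const Node& a, const Node& b) const {
    if (a.alt != b.alt) return a.alt > b.alt;
    return a.order > b.order;
  }
};

// [[Rcpp::export(name = ".priority_flood")]]
IntegerMatrix priority_flood(NumericMatrix altitude, IntegerMatrix seeds) {
  const int nr = altitude.nrow(), nc = altitude.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc)
    stop("altitude and seeds must share dimensions");
  IntegerMatrix labels(nr, nc);
  std::vector<bool> queued((size_t)nr * nc, false);
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  long long counter = 0;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int i = c * nr + r;
      if (seeds[i] > 0) {
        labels[i] = seeds[i];
        pq.push({altitude[i], counter++, i});
        queued[i] = true;
      }
    }
  }
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    int r = nd.idx % nr, c = nd.idx / nr;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = cc * nr + rr;
      if (queued[j]) continue;
      labels[j] = labels[nd.idx];
      pq.push({altitude[j], counter++, j});
      queued[j] = true;
    }
  }
  return labels;
}
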