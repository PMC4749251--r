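#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
#include <cstdint>
#include <climits>
using namespace Rcpp;

// Max-flow / min-cut solver for closure (project-selection) graphs:
// every explicit arc has effectively infinite capacity, and each node
// carries a terminal capacity (positive = source excess, negative = sink
// demand).  The minimum s-t cut then yields the minimum-weight closed set.
//
// Tree-growth augmenting scheme in the style of Boykov & Kolmogorov,
// which is fast on the grid-structured graphs produced by optimal-surface
// segmentation.  Capacities are scaled to 64-bit integers internally so
// the search terminates without floating-point residual pathologies.

static const int P_NONE = -1, P_TERM = -2, P_ORPHAN = -3;

// [[Rcpp::export(name = ".closure_mincut")]]
List closure_mincut(int n, IntegerVector arc_from, IntegerVector arc_to,
                    NumericVector trcap) {
  const int m = arc_from.size();
  if (arc_to.size() != m) stop("arc_from/arc_to length mismatch");
  if (trcap.size() != n) stop("trcap must have one entry per node");

  // integer scaling: resolution ~ sum(|trcap|) / 2^60
  long double sumabs = 0;
  for (int i = 0; i < n; i++) {
    if (!R_finite(trcap[i])) stop("non-finite terminal capacity");
    sumabs += fabsl((long double)trcap[i]);
  }
  long double scale = ((long double)(1LL << 60)) / (sumabs + 1.0L);
  if (scale > (long double)(1LL << 40)) scale = (long double)(1LL << 40);

  std::vector<long long> ex(n);
  long long HUGE_ = 1;
  for (int i = 0; i < n; i++) {
    ex[i] = (long long)llroundl((long double)trcap[i] * scale);
    HUGE_ += llabs(ex[i]);
  }

  // adjacency: arc pairs (2i forward INF, 2i+1 reverse 0)
  std::vector<int> first(n, -1), nxt(2 * (size_t)m), head(2 * (size_t)m);
  std::vector<long long> rc(2 * (size_t)m);
  for (int i = 0; i < m; i++) {
    int u = arc_from[i], v = arc_to[i];
    if (u < 0 || u >= n || v < 0 || v >= n) stop("arc endpoint out of range");
    int a = 2 * i, b = 2 * i + 1;
    head[a] = v; nxt[a] = first[u]; first[u] = a; rc[a] = HUGE_;
    head[b] = u; nxt[b] = first[v]; first[v] = b; rc[b] = 0;
  }

  // tree state: 0 free, 1 source tree, 2 sink tree
  // parent convention: S-tree par[x] = arc (parent -> x); T-tree par[x] = arc (x -> parent)
  std::vector<int> par(n, P_NONE);
  std::vector<signed char> tre(n, 0);
  std::vector<int> ts(n, -1), dst(n, 0);  // timestamp/distance marks
  int tick = 0;
  std::deque<int> act;
  std::deque<int> orph;

  // distance from q to its tree's terminal, or -1 if rooted at an orphan;
  // stamps the walked path with the current tick so repeated checks are O(1)
  auto origin_dist = [&](int q, signed char t_o) -> int {
    int d = 0, x = q;
    while (true) {
      if (ts[x] == tick) { d += dst[x]; break; }
      int pa = par[x];
      if (pa == P_TERM) { ts[x] = tick; dst[x] = 1; d += 1; break; }
      if (pa == P_ORPHAN || pa == P_NONE) return -1;
      x = (t_o == 1) ? head[pa ^ 1] : head[pa];
      d++;
    }
    int dd = d; x = q;
    while (ts[x] != tick) {
      ts[x] = tick; dst[x] = dd--;
      int pa = par[x];
      if (pa == P_TERM) break;
      x = (t_o == 1) ? head[pa ^ 1] : head[pa];
    }
    return d;
  };
  for (int v = 0; v < n; v++) {
    if (ex[v] > 0) { tre[v] = 1; par[v] = P_TERM; act.push_back(v); }
    else if (ex[v] < 0) { tre[v] = 2; par[v] = P_TERM; act.push_back(v); }
  }

  long long flow = 0;
  while (!act.empty()) {
    int p = act.front();
    if (tre[p] == 0) { act.pop_front(); continue; }

    // growth from p
    int meet = -1;
    for (int a = first[p]; a != -1; a = nxt[a]) {
      long long res = (tre[p] == 1) ? rc[a] : rc[a ^ 1];
      if (res <= 0) continue;
      int q = head[a];
      if (tre[q] == 0) {
        tre[q] = tre[p];
        par[q] = (tre[p] == 1) ? a : (a ^ 1);
        act.push_back(q);
      } else if (tre[q] != tre[p]) {
        meet = (tre[p] == 1) ? a : (a ^ 1);  // arc from S side into T side
        break;
      }
    }
    if (meet < 0) { act.pop_front(); continue; }

    // augment along the path S-root ... u -> v ... T-root
    int a = meet;
    int u = head[a ^ 1], v = head[a];
    long long bn = rc[a];
    {
      int x = u;
      while (par[x] != P_TERM) { int pa = par[x]; if (rc[pa] < bn) bn = rc[pa]; x = head[pa ^ 1]; }
      if (ex[x] < bn) bn = ex[x];
      int y = v;
      while (par[y] != P_TERM) { int pa = par[y]; if (rc[pa] < bn) bn = rc[pa]; y = head[pa]; }
      if (-ex[y] < bn) bn = -ex[y];
    }
    rc[a] -= bn; rc[a ^ 1] += bn;
    {
      int x = u;
      while (par[x] != P_TERM) {
        int pa = par[x]; rc[pa] -= bn; rc[pa ^ 1] += bn;
        int px = head[pa ^ 1];
        if (rc[pa] == 0) { par[x] = P_ORPHAN; orph.push_back(x); }
        x = px;
      }
      ex[x] -= bn;
      if (ex[x] == 0) { par[x] = P_ORPHAN; orph.push_back(x); }
      int y = v;
      while (par[y] != P_TERM) {
        int pa = par[y]; rc[pa] -= bn; rc[pa ^ 1] += bn;
        int py = head[pa];
        if (rc[pa] == 0) { par[y] = P_ORPHAN; orph.push_back(y); }
        y = py;
      }
      ex[y] += bn;
      if (ex[y] == 0) { par[y] = P_ORPHAN; orph.push_back(y); }
    }
    flow += bn;
    tick++;

    // adoption of orphans: reattach to the closest terminal-rooted neighbour
    while (!orph.empty()) {
      int o = orph.front(); orph.pop_front();
      signed char t_o = tre[o];
      int found = -1, dmin = INT_MAX;
      for (int a2 = first[o]; a2 != -1; a2 = nxt[a2]) {
        int q = head[a2];
        if (tre[q] != t_o) continue;
        long long res = (t_o == 1) ? rc[a2 ^ 1] : rc[a2];
        if (res <= 0) continue;
        int dq = origin_dist(q, t_o);
        if (dq >= 0 && dq < dmin) {
          dmin = dq;
          found = (t_o == 1) ? (a2 ^ 1) : a2;
        }
      }
      if (found >= 0) {
        par[o] = found;
        ts[o] = tick; dst[o] = dmin + 1;
      } else {
        for (int a2 = first[o]; a2 != -1; a2 = nxt[a2]) {
          int q = head[a2];
          if (tre[q] != t_o) continue;
          long long res = (t_o == 1) ? rc[a2 ^ 1] : rc[a2];
          if (res > 0) act.push_back(q);
          if (par[q] >= 0) {
            int pn = (t_o == 1) ? head[par[q] ^ 1] : head[par[q]];
            if (pn == o) { par[q] = P_ORPHAN; orph.push_back(q); }
          }
        }
        tre[o] = 0; par[o] = P_NONE;
      }
    }
  }

  LogicalVector member(n);
  for (int v = 0; v < n; v++) member[v] = (tre[v] == 1);
  return List::create(_["flow"] = (double)(flow / (long double)scale),
                      _["member"] = member);
}
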