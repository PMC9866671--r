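// Binary-image morphology: Guo-Hall thinning and 8-connected labelling.
#include <functional>
#include <Rcpp.h>
using namespace Rcpp;

// Guo-Hall two-subiteration thinning. Unlike Zhang-Suen it does not show
// runaway front erosion on 45-degree ribbons with perpendicular end cuts
// (the geometry a disk cut across a diagonal tube produces).
// Neighbourhood named as in Zhang-Suen: p2=N, p3=NE, p4=E, p5=SE, p6=S,
// p7=SW, p8=W, p9=NW.
// [[Rcpp::export(name = ".thin_guohall")]]
IntegerMatrix thin_guohall(IntegerMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix a = clone(img);
  auto at = [&](int i, int j) -> int {
    return (i < 0 || i >= H || j < 0 || j >= W) ? 0 : a(i, j);
  };
  std::vector<std::pair<int,int> > kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int phase = 0; phase < 2; ++phase) {
      kill.clear();
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          if (!a(i, j)) continue;
          int p2 = at(i - 1, j),     p3 = at(i - 1, j + 1);
          int p4 = at(i, j + 1),     p5 = at(i + 1, j + 1);
          int p6 = at(i + 1, j),     p7 = at(i + 1, j - 1);
          int p8 = at(i, j - 1),     p9 = at(i - 1, j - 1);
          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = std::min(N1, N2);
          if (C != 1 || N < 2 || N > 3) continue;
          int c3 = phase == 0 ? ((p2 | p3 | (!p5)) & p4)
                              : ((p6 | p7 | (!p9)) & p8);
          if (c3 != 0) continue;
          kill.push_back(std::make_pair(i, j));
        }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k)
        a(kill[k].first, kill[k].second) = 0;
    }
  }
  return a;
}

// Sequential minimality pass after thinning: delete any pixel with >= 2
// neighbours whose foreground neighbours form a single 8-connected
// component when viewed as pixels (so deletion cannot disconnect or close
// a hole). Removes the doubled staircase pixels that parallel thinning
// leaves on diagonal runs; endpoints (1 neighbour) are never touched.
// [[Rcpp::export(name = ".thin_minimal")]]
IntegerMatrix thin_minimal(IntegerMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix a = clone(img);
  auto at = [&](int i, int j) -> int {
    return (i < 0 || i >= H || j < 0 || j >= W) ? 0 : a(i, j);
  };
  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        if (!a(i, j)) continue;
        int nb[8], cnt = 0;
        for (int k = 0; k < 8; ++k)
          if (at(i + di[k], j + dj[k])) nb[cnt++] = k;
        if (cnt < 2) continue;
        // union-find over the neighbours, joined when pixel-adjacent
        int parent[8];
        for (int k = 0; k < cnt; ++k) parent[k] = k;
        std::function<int(int)> find = [&](int x) {
          while (parent[x] != x) x = parent[x] = parent[parent[x]];
          return x;
        };
        for (int u = 0; u < cnt; ++u)
          for (int v = u + 1; v < cnt; ++v) {
            int dr = std::abs(di[nb[u]] - di[nb[v]]);
            int dc = std::abs(dj[nb[u]] - dj[nb[v]]);
            if (dr <= 1 && dc <= 1) parent[find(u)] = find(v);
          }
        int comps = 0;
        for (int k = 0; k < cnt; ++k) if (find(k) == k) ++comps;
        if (comps == 1) { a(i, j) = 0; changed = true; }
      }
  }
  return a;
}

// 8-connected component labelling of nonzero pixels (BFS flood fill).
// Returns an integer matrix with labels 1..K (0 = background).
// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8(IntegerMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> qi, qj;
  int next = 0;
  for (int j0 = 0; j0 < W; ++j0)
    for (int i0 = 0; i0 < H; ++i0) {
      if (!img(i0, j0) || lab(i0, j0)) continue;
      ++next;
      qi.clear(); qj.clear();
      qi.push_back(i0); qj.push_back(j0);
      lab(i0, j0) = next;
      size_t head = 0;
      while (head < qi.size()) {
        int i = qi[head], j = qj[head]; ++head;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (img(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              qi.push_back(ii); qj.push_back(jj);
            }
          }
      }
    }
  return lab;
}

// Count of 8-neighbours that are foreground, for each foreground pixel.
// [[Rcpp::export(name = ".neighbor_count8")]]
IntegerMatrix neighbor_count8(IntegerMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!img(i, j)) continue;
      int n = 0;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj) continue;
          int ii = i + di, jj = j + dj;
          if (ii >= 0 && ii < H && jj >= 0 && jj < W && img(ii, jj)) ++n;
        }
      out(i, j) = n;
    }
  return out;
}
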