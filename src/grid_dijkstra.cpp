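#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

int gcd3(int a, int b) {
  a = std::abs(a); b = std::abs(b);
  while (b) { int t = a % b; a = b; b = t; }
  return a;
}

struct Offset {
  int dx, dy, dz;
  double w;
  std::vector<int> mid; // flat relative index of intermediate cells
};

} // namespace

// Shortest obstacle-avoiding grid paths from one source node.
//
// Nodes are the cells of an nx*ny*nz grid (flat index i + nx*(j + ny*k),
// passed 1-based from R for the source). Edges connect cells whose index
// offset is a primitive vector with components in [-radius, radius]; edge
// length is the Euclidean offset norm times the grid spacing. For offsets
// longer than one cell the intermediate cells along the straight segment
// must be allowed too, so paths cannot tunnel through thin obstacles.
// Dijkstra with early stop at maxdist; unreachable cells get +Inf.
// [[Rcpp::export]]
NumericVector grid_dijkstra_cpp(IntegerVector dims, LogicalVector allowed,
                                int source, double spacing, int radius,
                                double maxdist) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (allowed.size() != n) stop("allowed mask does not match grid dims");
  if (source < 1 || source > n) stop("source index out of range");

  std::vector<Offset> offs;
  for (int dz = -radius; dz <= radius; ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx) {
        if (!dx && !dy && !dz) continue;
        if (gcd3(gcd3(dx, dy), dz) != 1) continue; // collinear duplicate
        Offset o;
        o.dx = dx; o.dy = dy; o.dz = dz;
        o.w = spacing * std::sqrt((double)(dx * dx + dy * dy + dz * dz));
        int m = std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz)));
        // every cell the straight segment touches at each intermediate step
        // (floor and ceil per component, symmetric under edge reversal)
        for (int s = 1; s < m; ++s) {
          double fx = (double)dx * s / m;
          double fy = (double)dy * s / m;
          double fz = (double)dz * s / m;
          int xs[2] = {(int)std::floor(fx), (int)std::ceil(fx)};
          int ys[2] = {(int)std::floor(fy), (int)std::ceil(fy)};
          int zs[2] = {(int)std::floor(fz), (int)std::ceil(fz)};
          for (int a = 0; a < (xs[0] == xs[1] ? 1 : 2); ++a)
            for (int b = 0; b < (ys[0] == ys[1] ? 1 : 2); ++b)
              for (int c = 0; c < (zs[0] == zs[1] ? 1 : 2); ++c) {
                int ix = xs[a], iy = ys[b], iz = zs[c];
                if (ix == 0 && iy == 0 && iz == 0) continue;
                if (ix == dx && iy == dy && iz == dz) continue;
                o.mid.push_back(ix + nx * (iy + (R_xlen_t)ny * iz));
              }
        }
        std::sort(o.mid.begin(), o.mid.end());
        o.mid.erase(std::unique(o.mid.begin(), o.mid.end()), o.mid.end());
        offs.push_back(o);
      }

  NumericVector dist(n, R_PosInf);
  std::priority_queue<std::pair<double, R_xlen_t>,
                      std::vector<std::pair<double, R_xlen_t> >,
                      std::greater<std::pair<double, R_xlen_t> > > pq;
  const R_xlen_t src = source - 1;
  dist[src] = 0.0;
  pq.push(std::make_pair(0.0, src));

  while (!pq.empty()) {
    double d = pq.top().first;
    R_xlen_t u = pq.top().second;
    pq.pop();
    if (d > dist[u]) continue;
    if (d > maxdist) break;
    int k = (int)(u / ((R_xlen_t)nx * ny));
    int rem = (int)(u % ((R_xlen_t)nx * ny));
    int j = rem / nx;
    int i = rem % nx;
    for (size_t e = 0; e < offs.size(); ++e) {
      const Offset &o = offs[e];
      int ii = i + o.dx, jj = j + o.dy, kk = k + o.dz;
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      R_xlen_t v = ii + nx * (jj + (R_xlen_t)ny * kk);
      if (!allowed[v]) continue;
      bool clear = true;
      for (size_t s = 0; s < o.mid.size(); ++s) {
        R_xlen_t m = u + o.mid[s];
        // relative flat offsets stay in range because the endpoint is
        // in range and intermediates lie between; still guard the mask
        if (m < 0 || m >= n || !allowed[m]) { clear = false; break; }
      }
      if (!clear) continue;
      double nd = d + o.w;
      if (nd < dist[v]) {
        dist[v] = nd;
        pq.push(std::make_pair(nd, v));
      }
    }
  }
  return dist;
}
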