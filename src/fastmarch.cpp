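#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Best-first wavefront propagation (cost-correct fast marching) on the
// implicit voxel graph.  Edge weight between neighbouring voxels u,v is
// ||u - v|| * (g[u] + g[v]) / 2, where g holds the precomputed intensity
// penalty exp(lambda * (1 - Inorm)^2) per voxel.  Ties on the frontier are
// broken by the lower linear index (x fastest, then y, then z), which is
// ascending (z,y,x) lexicographic order, so results are platform-stable.

static int build_offsets(int connectivity, int dx[26], int dy[26], int dz[26],
                         double dw[26]) {
  int n = 0;
  for (int z = -1; z <= 1; ++z)
    for (int y = -1; y <= 1; ++y)
      for (int x = -1; x <= 1; ++x) {
        int m = std::abs(x) + std::abs(y) + std::abs(z);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dx[n] = x; dy[n] = y; dz[n] = z;
        dw[n] = std::sqrt((double)m);
        ++n;
      }
  return n;
}

typedef std::pair<double, int> QE; // (cost, linear index)

// [[Rcpp::export]]
List fm_march(IntegerVector dims, NumericVector g,
              IntegerMatrix sources, IntegerMatrix sinks,
              int connectivity, LogicalVector mask, bool all_sinks) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const bool use_mask = mask.size() > 0;

  int dx[26], dy[26], dz[26];
  double dw[26];
  const int noff = build_offsets(connectivity, dx, dy, dz, dw);

  std::vector<double> dist(nvox, R_PosInf);
  std::vector<int> parent(nvox, -1);
  std::vector<int> sink_id(nvox, -1);
  for (int i = 0; i < sinks.nrow(); ++i) {
    int idx = sinks(i, 0) + nx * (sinks(i, 1) + (R_xlen_t)ny * sinks(i, 2));
    if (sink_id[idx] < 0) sink_id[idx] = i; // keep first occurrence
  }

  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int i = 0; i < sources.nrow(); ++i) {
    int idx = sources(i, 0) + nx * (sources(i, 1) + (R_xlen_t)ny * sources(i, 2));
    if (use_mask && !mask[idx]) continue;
    if (dist[idx] > 0.0) { dist[idx] = 0.0; pq.push(QE(0.0, idx)); }
  }

  NumericVector sink_costs;
  IntegerVector sink_hit_idx;
  int remaining = 0;
  if (all_sinks) {
    sink_costs = NumericVector(sinks.nrow(), R_PosInf);
    sink_hit_idx = IntegerVector(sinks.nrow(), NA_INTEGER);
    // count distinct sink voxels to know when the search may stop
    for (R_xlen_t i = 0; i < nvox; ++i) if (sink_id[i] >= 0) ++remaining;
  }

  int hit = -1;
  long long settled = 0;
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    const double c = top.first;
    const int idx = top.second;
    if (c > dist[idx]) continue; // stale entry
    ++settled;
    if (sink_id[idx] >= 0) {
      if (!all_sinks) { hit = idx; break; }
      if (!R_finite(sink_costs[sink_id[idx]]) || c < sink_costs[sink_id[idx]]) {
        sink_costs[sink_id[idx]] = c;
        sink_hit_idx[sink_id[idx]] = idx;
      }
      sink_id[idx] = -2; // settled sink; do not count again
      if (--remaining == 0) break;
    }
    const int x = idx % nx, y = (idx / nx) % ny, z = idx / (nx * ny);
    for (int k = 0; k < noff; ++k) {
      const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      const int jdx = xx + nx * (yy + (R_xlen_t)ny * zz);
      if (use_mask && !mask[jdx]) continue;
      const double w = dw[k] * 0.5 * (g[idx] + g[jdx]);
      const double nc = c + w;
      if (nc < dist[jdx]) {
        dist[jdx] = nc;
        parent[jdx] = idx;
        pq.push(QE(nc, jdx));
      }
    }
  }

  if (all_sinks) {
    // duplicate sink voxels: give repeats the settled cost of their voxel
    for (int i = 0; i < sinks.nrow(); ++i) {
      int idx = sinks(i, 0) + nx * (sinks(i, 1) + (R_xlen_t)ny * sinks(i, 2));
      if (!R_finite(sink_costs[i]) && R_finite(dist[idx])) {
        sink_costs[i] = dist[idx];
        sink_hit_idx[i] = idx;
      }
    }
    return List::create(_["found"] = true, _["sink_costs"] = sink_costs,
                        _["visited"] = (double)settled);
  }

  if (hit < 0)
    return List::create(_["found"] = false, _["visited"] = (double)settled);

  std::vector<int> chain;
  for (int cur = hit; cur >= 0; cur = parent[cur]) chain.push_back(cur);
  const int nlen = (int)chain.size();
  IntegerMatrix path(nlen, 3);
  for (int i = 0; i < nlen; ++i) {
    const int idx = chain[nlen - 1 - i]; // source -> sink order
    path(i, 0) = idx % nx;
    path(i, 1) = (idx / nx) % ny;
    path(i, 2) = idx / (nx * ny);
  }
  return List::create(_["found"] = true, _["path"] = path,
                      _["cost"] = dist[hit], _["visited"] = (double)settled);
}
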