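#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// neighbour offsets for 6/18/26-connectivity on a 3D grid
static std::vector<std::array<int, 3>> neighbour_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// [[Rcpp::export]]
IntegerVector label_components_3d(NumericVector vol, int connectivity) {
  IntegerVector dims = vol.attr("dim");
  if (dims.size() != 3) stop("volume must be 3D");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  auto off = neighbour_offsets(connectivity);
  int next = 0;
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (vol[i] == 0.0 || lab[i] != 0) continue;
    lab[i] = ++next;
    q.push(i);
    while (!q.empty()) {
      int cur = q.front();
      q.pop();
      int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
      for (auto &d : off) {
        int x = cx + d[0], y = cy + d[1], z = cz + d[2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
          continue;
        int j = x + nx * (y + ny * z);
        if (vol[j] != 0.0 && lab[j] == 0) {
          lab[j] = next;
          q.push(j);
        }
      }
    }
  }
  return lab;
}

// TFCE for the positive part of a 3D statistic volume: each voxel
// accumulates extent^E * height^H * dh over thresholds h = dh, 2dh, ...
// [[Rcpp::export]]
NumericVector tfce_positive(NumericVector vol, double E, double H,
                            double dh, int connectivity) {
  IntegerVector dims = vol.attr("dim");
  if (dims.size() != 3) stop("volume must be 3D");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  NumericVector out(n, 0.0);
  out.attr("dim") = dims;
  double mx = 0.0;
  for (int i = 0; i < n; ++i) mx = std::max(mx, vol[i]);
  if (mx <= 0.0) return out;
  auto off = neighbour_offsets(connectivity);
  std::vector<int> lab(n);
  std::vector<int> size;
  std::queue<int> q;
  const int n_steps = (int)std::floor(mx / dh + 1e-9);
  for (int step = 1; step <= n_steps; ++step) {
    const double h = step * dh;
    std::fill(lab.begin(), lab.end(), 0);
    size.assign(1, 0);
    int next = 0;
    for (int i = 0; i < n; ++i) {
      if (vol[i] < h || lab[i] != 0) continue;
      lab[i] = ++next;
      size.push_back(1);
      q.push(i);
      while (!q.empty()) {
        int cur = q.front();
        q.pop();
        int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
        for (auto &d : off) {
          int x = cx + d[0], y = cy + d[1], z = cz + d[2];
          if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
            continue;
          int j = x + nx * (y + ny * z);
          if (vol[j] >= h && lab[j] == 0) {
            lab[j] = next;
            size[next]++;
            q.push(j);
          }
        }
      }
    }
    double hh = std::pow(h, H) * dh;
    for (int i = 0; i < n; ++i) {
      if (lab[i] != 0) out[i] += std::pow((double)size[lab[i]], E) * hh;
    }
  }
  return out;
}
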