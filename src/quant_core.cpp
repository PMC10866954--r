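// Low-level voxel-grid primitives shared by the segmentation and proximity
// code: anisotropic Euclidean distance transform, 3D connected components,
// seeded watershed, capsule rasterization, separable convolution, running
// box min/max, and a spatial-hash nearest-neighbour query. All grids are
// column-major arrays with dims (nx, ny, nz); a 2D image is nz = 1.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const double BIG = 1e20; // finite sentinel for "no seed on this line"

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with grid
// spacing w; f holds finite squared distances (BIG as sentinel).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  auto x = [w](int i) { return i * w; };
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + x(q) * x(q)) - (f[v[k]] + x(v[k]) * x(v[k]))) /
          (2 * x(q) - 2 * x(v[k]));
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    if (s <= z[k] && k == 0) { v[0] = q; }
    else { ++k; v[k] = q; z[k] = s; z[k + 1] = INF; }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < x(q)) ++k;
    double dx = x(q) - x(v[k]);
    d[q] = dx * dx + f[v[k]];
  }
}

// Squared anisotropic EDT: distance from every voxel to the nearest TRUE
// voxel of `mask` (0 on the mask itself, Inf if the mask is empty).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : BIG;
  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }
  if (nz > 1) {
    f.resize(nz); d.resize(nz);
    R_xlen_t stepz = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; ++z) f[z] = out[base + (R_xlen_t)z * stepz];
        dt1d(f, d, nz, spacing[2]);
        for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * stepz] = d[z];
      }
  }
  for (R_xlen_t i = 0; i < n; ++i) if (out[i] >= BIG) out[i] = R_PosInf;
  return out;
}

static int neighbor_offsets(int nx, int ny, int nz, int connectivity,
                            std::vector<std::array<int,3>>& off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m > 1) continue;
        if (nz == 1 && dz != 0) continue;
        off.push_back({dx, dy, dz});
      }
  return (int)off.size();
}

// Connected-component labelling (6- or 26-connectivity).
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dims,
                        int connectivity = 6) {
  int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> off;
  neighbor_offsets(nx, ny, nz, connectivity, off);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur; stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int z = (int)(p / ((R_xlen_t)nx * ny));
      int rem = (int)(p % ((R_xlen_t)nx * ny));
      int y = rem / nx, x = rem % nx;
      for (auto& o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t q = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[q] && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Seeded watershed by priority flooding: voxels inside `mask` are flooded
// from labelled seeds in order of increasing `priority` (pass the negated
// distance transform to split at distance ridges). Deterministic: ties are
// broken by insertion order.
// [[Rcpp::export]]
IntegerVector cpp_watershed_seeded(NumericVector priority, IntegerVector seeds,
                                   LogicalVector mask, IntegerVector dims,
                                   int connectivity = 6) {
  int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> off;
  neighbor_offsets(nx, ny, nz, connectivity, off);
  typedef std::tuple<double, std::uint64_t, R_xlen_t, int> Item; // prio, tick, voxel, label
  std::priority_queue<Item, std::vector<Item>, std::greater<Item>> pq;
  std::uint64_t tick = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push(Item(priority[i], tick++, i, seeds[i]));
    }
  while (!pq.empty()) {
    Item it = pq.top(); pq.pop();
    R_xlen_t p = std::get<2>(it);
    int l = std::get<3>(it);
    int z = (int)(p / ((R_xlen_t)nx * ny));
    int rem = (int)(p % ((R_xlen_t)nx * ny));
    int y = rem / nx, x = rem % nx;
    for (auto& o : off) {
      int xx = x + o[0], yy = y + o[1], zz = z + o[2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      R_xlen_t q = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
      if (!mask[q] || lab[q] != 0) continue;
      lab[q] = l;
      pq.push(Item(priority[q], tick++, q, l));
    }
  }
  return lab;
}

// Rasterize capsules (cylinders with spherical caps) onto a voxel grid.
// Segment endpoints p0, p1 are in physical units (µm); voxel centers sit at
// (i + 0.5) * spacing. Returns the union mask.
// [[Rcpp::export]]
LogicalVector cpp_capsule_mask(IntegerVector dims, NumericVector spacing,
                               NumericMatrix p0, NumericMatrix p1,
                               NumericVector radius) {
  int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  double sx = spacing[0], sy = spacing[1], sz = spacing.size() > 2 ? spacing[2] : 1.0;
  for (int e = 0; e < p0.nrow(); ++e) {
    double ax = p0(e,0), ay = p0(e,1), az = nz > 1 ? p0(e,2) : 0.5 * sz;
    double bx = p1(e,0), by = p1(e,1), bz = nz > 1 ? p1(e,2) : 0.5 * sz;
    double r = radius[e], r2 = r * r;
    double vx = bx - ax, vy = by - ay, vz = bz - az;
    double vv = vx*vx + vy*vy + vz*vz;
    int x0 = std::max(0, (int)std::floor((std::min(ax,bx) - r) / sx - 0.5));
    int x1 = std::min(nx - 1, (int)std::ceil((std::max(ax,bx) + r) / sx));
    int y0 = std::max(0, (int)std::floor((std::min(ay,by) - r) / sy - 0.5));
    int y1 = std::min(ny - 1, (int)std::ceil((std::max(ay,by) + r) / sy));
    int z0 = 0, z1 = nz - 1;
    if (nz > 1) {
      z0 = std::max(0, (int)std::floor((std::min(az,bz) - r) / sz - 0.5));
      z1 = std::min(nz - 1, (int)std::ceil((std::max(az,bz) + r) / sz));
    }
    for (int z = z0; z <= z1; ++z) {
      double cz = (z + 0.5) * sz;
      for (int y = y0; y <= y1; ++y) {
        double cy = (y + 0.5) * sy;
        for (int x = x0; x <= x1; ++x) {
          double cx = (x + 0.5) * sx;
          double wx = cx - ax, wy = cy - ay, wz = cz - az;
          double t = vv > 0 ? (wx*vx + wy*vy + wz*vz) / vv : 0.0;
          t = std::min(1.0, std::max(0.0, t));
          double dx = wx - t*vx, dy = wy - t*vy, dz = wz - t*vz;
          if (dx*dx + dy*dy + dz*dz <= r2)
            out[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x] = true;
        }
      }
    }
  }
  return out;
}

// Separable convolution with reflecting boundaries; kernels of odd length.
// Pass a length-1 kernel c(1) to skip an axis.
// [[Rcpp::export]]
NumericVector cpp_sepconv(NumericVector arr, IntegerVector dims,
                          NumericVector kx, NumericVector ky, NumericVector kz) {
  int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(arr.begin(), arr.end()), b(n);
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  auto pass = [&](const NumericVector& k, int axis) {
    int kn = k.size(), h = kn / 2;
    if (kn == 1 && k[0] == 1.0) return;
    int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
    R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? nx : (R_xlen_t)nx * ny);
    int n1 = axis == 0 ? ny : nx;
    int n2 = axis == 2 ? ny : nz;
    for (int j2 = 0; j2 < n2; ++j2)
      for (int j1 = 0; j1 < n1; ++j1) {
        R_xlen_t base;
        if (axis == 0)      base = (R_xlen_t)j2 * nx * ny + (R_xlen_t)j1 * nx;
        else if (axis == 1) base = (R_xlen_t)j2 * nx * ny + j1;
        else                base = (R_xlen_t)j2 * nx + j1;
        for (int i = 0; i < len; ++i) {
          double s = 0;
          for (int t = 0; t < kn; ++t)
            s += k[t] * a[base + (R_xlen_t)reflect(i + t - h, len) * stride];
          b[base + (R_xlen_t)i * stride] = s;
        }
      }
    std::swap(a, b);
  };
  pass(kx, 0); pass(ky, 1); if (nz > 1) pass(kz, 2);
  return NumericVector(a.begin(), a.end());
}

// Running box min (op=0) or max (op=1) over a (2r+1)^2 window, 2D image.
// [[Rcpp::export]]
NumericMatrix cpp_boxminmax2d(NumericMatrix img, int radius, int op) {
  int nx = img.nrow(), ny = img.ncol();
  NumericMatrix tmp(nx, ny), out(nx, ny);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      int lo = std::max(0, x - radius), hi = std::min(nx - 1, x + radius);
      double v = img(lo, y);
      for (int i = lo + 1; i <= hi; ++i)
        v = op ? std::max(v, img(i, y)) : std::min(v, img(i, y));
      tmp(x, y) = v;
    }
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      int lo = std::max(0, y - radius), hi = std::min(ny - 1, y + radius);
      double v = tmp(x, lo);
      for (int j = lo + 1; j <= hi; ++j)
        v = op ? std::max(v, tmp(x, j)) : std::min(v, tmp(x, j));
      out(x, y) = v;
    }
  return out;
}

// For each query point, the distance to the nearest reference point,
// using a uniform spatial hash (expanding-shell search).
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix query, NumericMatrix ref) {
  int nq = query.nrow(), nr = ref.nrow();
  NumericVector out(nq);
  if (nr == 0) { std::fill(out.begin(), out.end(), R_PosInf); return out; }
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = INF; hi[d] = -INF; }
  for (int i = 0; i < nr; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], ref(i,d)); hi[d] = std::max(hi[d], ref(i,d));
    }
  double ext = std::max({hi[0]-lo[0], hi[1]-lo[1], hi[2]-lo[2], 1e-9});
  double cell = std::max(ext / std::cbrt((double)nr) , 1e-9);
  auto key = [&](double x, double y, double z) {
    std::int64_t ix = (std::int64_t)std::floor((x - lo[0]) / cell);
    std::int64_t iy = (std::int64_t)std::floor((y - lo[1]) / cell);
    std::int64_t iz = (std::int64_t)std::floor((z - lo[2]) / cell);
    return std::make_tuple(ix, iy, iz);
  };
  std::unordered_map<std::int64_t, std::vector<int>> bins;
  auto hsh = [](std::int64_t ix, std::int64_t iy, std::int64_t iz) {
    return (ix * 73856093) ^ (iy * 19349663) ^ (iz * 83492791);
  };
  for (int i = 0; i < nr; ++i) {
    auto k = key(ref(i,0), ref(i,1), ref(i,2));
    bins[hsh(std::get<0>(k), std::get<1>(k), std::get<2>(k))].push_back(i);
  }
  for (int q = 0; q < nq; ++q) {
    double qx = query(q,0), qy = query(q,1), qz = query(q,2);
    auto k = key(qx, qy, qz);
    std::int64_t cx = std::get<0>(k), cy = std::get<1>(k), cz = std::get<2>(k);
    double best = INF;
    for (int ring = 0; ; ++ring) {
      bool any = false;
      for (std::int64_t iz = cz - ring; iz <= cz + ring; ++iz)
        for (std::int64_t iy = cy - ring; iy <= cy + ring; ++iy)
          for (std::int64_t ix = cx - ring; ix <= cx + ring; ++ix) {
            if (std::max({std::llabs(ix-cx), std::llabs(iy-cy), std::llabs(iz-cz)}) != ring)
              continue;
            auto it = bins.find(hsh(ix, iy, iz));
            if (it == bins.end()) continue;
            any = true;
            for (int i : it->second) {
              double dx = qx - ref(i,0), dy = qy - ref(i,1), dz = qz - ref(i,2);
              best = std::min(best, dx*dx + dy*dy + dz*dz);
            }
          }
      // safe stop: nearest point can still hide one ring further than the
      // first non-empty ring, so continue until ring*cell exceeds sqrt(best)
      if (best < INF && (double)ring * cell > std::sqrt(best)) break;
      if (ring > 3 && !any && best < INF) break;
      if ((double)ring * cell > 2 * ext + 2 * cell && best == INF) {
        // query far outside the hash extent: brute force
        for (int i = 0; i < nr; ++i) {
          double dx = qx - ref(i,0), dy = qy - ref(i,1), dz = qz - ref(i,2);
          best = std::min(best, dx*dx + dy*dy + dz*dz);
        }
        break;
      }
    }
    out[q] = std::sqrt(best);
  }
  return out;
}
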