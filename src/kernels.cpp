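#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = "median_filter3_cpp")]]
NumericVector median_filter3_cpp(NumericVector arr, IntegerVector dims,
                                 int size) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int r = size / 2;
  NumericVector out(arr.size());
  std::vector<double> buf;
  buf.reserve((size_t)size * size * size);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        buf.clear();
        for (int dk = -r; dk <= r; ++dk) {
          int kk = k + dk;
          if (kk < 0 || kk >= nz) continue;
          for (int dj = -r; dj <= r; ++dj) {
            int jj = j + dj;
            if (jj < 0 || jj >= ny) continue;
            for (int di = -r; di <= r; ++di) {
              int ii = i + di;
              if (ii < 0 || ii >= nx) continue;
              buf.push_back(arr[ii + nx * (jj + (size_t)ny * kk)]);
            }
          }
        }
        size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (buf.size() % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + m - 1, buf.begin() + m);
          med = 0.5 * (med + buf[m - 1]);
        }
        out[i + nx * (j + (size_t)ny * k)] = med;
      }
    }
  }
  return out;
}

static inline double interp3(const double *a, int nx, int ny, int nz,
                             double x, double y, double z, bool &ok) {
  // x, y, z are 0-based fractional voxel coordinates
  if (!(x >= 0 && x <= nx - 1 && y >= 0 && y <= ny - 1 &&
        z >= 0 && z <= nz - 1)) {
    ok = false;
    return 0.0;
  }
  ok = true;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx - 2;
  if (y0 > ny - 2) y0 = ny - 2;
  if (z0 > nz - 2) z0 = nz - 2;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  size_t b = x0 + (size_t)nx * (y0 + (size_t)ny * z0);
  size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  double v000 = a[b], v100 = a[b + sx], v010 = a[b + sy], v110 = a[b + sx + sy];
  double v001 = a[b + sz], v101 = a[b + sx + sz], v011 = a[b + sy + sz],
         v111 = a[b + sx + sy + sz];
  return v000 * (1 - fx) * (1 - fy) * (1 - fz) + v100 * fx * (1 - fy) * (1 - fz) +
         v010 * (1 - fx) * fy * (1 - fz) + v110 * fx * fy * (1 - fz) +
         v001 * (1 - fx) * (1 - fy) * fz + v101 * fx * (1 - fy) * fz +
         v011 * (1 - fx) * fy * fz + v111 * fx * fy * fz;
}

// Streamline region growing: integrate streamlines of the (frame-frozen)
// field from every seed in both directions with RK4 on trilinear
// interpolation, stop on interpolated Q <= 0, mask exit or maxLen steps,
// and mark every voxel whose cell is entered. Seeds are physical positions
// in mm. Returns the marked voxels as 1-based linear indices.
// [[Rcpp::export(name = "grow_region_cpp")]]
IntegerVector grow_region_cpp(NumericVector vfield, NumericVector qfield,
                              LogicalVector mask, IntegerVector dims,
                              NumericVector spacing, NumericVector origin,
                              NumericMatrix seeds, double step, int maxLen) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t V = (size_t)nx * ny * nz;
  const double *vx = &vfield[0];
  const double *vy = &vfield[0] + V;
  const double *vz = &vfield[0] + 2 * V;
  const double *q = &qfield[0];
  std::vector<char> marked(V, 0);

  auto vox2phys_ok = [&](double px, double py, double pz, double &gx,
                         double &gy, double &gz) {
    gx = (px - origin[0]) / spacing[0];
    gy = (py - origin[1]) / spacing[1];
    gz = (pz - origin[2]) / spacing[2];
    return gx >= 0 && gx <= nx - 1 && gy >= 0 && gy <= ny - 1 && gz >= 0 &&
           gz <= nz - 1;
  };
  auto sample = [&](double px, double py, double pz, double *v, double &qv,
                    bool &inside) {
    double gx, gy, gz;
    if (!vox2phys_ok(px, py, pz, gx, gy, gz)) {
      inside = false;
      return;
    }
    bool ok;
    v[0] = interp3(vx, nx, ny, nz, gx, gy, gz, ok);
    v[1] = interp3(vy, nx, ny, nz, gx, gy, gz, ok);
    v[2] = interp3(vz, nx, ny, nz, gx, gy, gz, ok);
    qv = interp3(q, nx, ny, nz, gx, gy, gz, ok);
    inside = true;
  };
  auto mark = [&](double px, double py, double pz) {
    double gx, gy, gz;
    if (!vox2phys_ok(px, py, pz, gx, gy, gz)) return true; // outside
    int i = (int)std::floor(gx + 0.5), j = (int)std::floor(gy + 0.5),
        k = (int)std::floor(gz + 0.5);
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return true;
    size_t lin = i + (size_t)nx * (j + (size_t)ny * k);
    if (!mask[lin]) return true; // left the LV mask
    marked[lin] = 1;
    return false;
  };

  for (int s = 0; s < seeds.nrow(); ++s) {
    for (int dir = -1; dir <= 1; dir += 2) {
      double p[3] = {seeds(s, 0), seeds(s, 1), seeds(s, 2)};
      double v1[3], v2[3], v3[3], v4[3], qv;
      bool inside;
      sample(p[0], p[1], p[2], v1, qv, inside);
      if (!inside || qv <= 0) continue;
      mark(p[0], p[1], p[2]);
      for (int it = 0; it < maxLen; ++it) {
        sample(p[0], p[1], p[2], v1, qv, inside);
        if (!inside || qv <= 0) break;
        double n1 = std::sqrt(v1[0] * v1[0] + v1[1] * v1[1] + v1[2] * v1[2]);
        if (n1 < 1e-12) break; // stagnation
        // velocity is in m/s, positions in mm: pseudo-time h chosen so the
        // step displacement h * 1000 * v has length `step` mm
        double h = dir * step / (n1 * 1000.0);
        double ptmp[3];
        // classical RK4 on dp/dt = v(p), then renormalized step length
        ptmp[0] = p[0] + 0.5 * h * v1[0] * 1000.0;
        ptmp[1] = p[1] + 0.5 * h * v1[1] * 1000.0;
        ptmp[2] = p[2] + 0.5 * h * v1[2] * 1000.0;
        sample(ptmp[0], ptmp[1], ptmp[2], v2, qv, inside);
        if (!inside) break;
        ptmp[0] = p[0] + 0.5 * h * v2[0] * 1000.0;
        ptmp[1] = p[1] + 0.5 * h * v2[1] * 1000.0;
        ptmp[2] = p[2] + 0.5 * h * v2[2] * 1000.0;
        sample(ptmp[0], ptmp[1], ptmp[2], v3, qv, inside);
        if (!inside) break;
        ptmp[0] = p[0] + h * v3[0] * 1000.0;
        ptmp[1] = p[1] + h * v3[1] * 1000.0;
        ptmp[2] = p[2] + h * v3[2] * 1000.0;
        sample(ptmp[0], ptmp[1], ptmp[2], v4, qv, inside);
        if (!inside) break;
        for (int c = 0; c < 3; ++c)
          p[c] += h * 1000.0 *
                  (v1[c] + 2 * v2[c] + 2 * v3[c] + v4[c]) / 6.0;
        sample(p[0], p[1], p[2], v1, qv, inside);
        if (!inside || qv <= 0) break;
        if (mark(p[0], p[1], p[2])) break;
      }
    }
  }
  std::vector<int> res;
  for (size_t i = 0; i < V; ++i)
    if (marked[i]) res.push_back((int)i + 1);
  return IntegerVector(res.begin(), res.end());
}
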