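#ifndef KIDNEYSEG_DT_H
#define KIDNEYSEG_DT_H

#include <vector>

// Exact 1D squared Euclidean distance transform over samples at
// coordinates i*step (Felzenszwalb & Huttenlocher lower envelope).
namespace kidneyseg {

static const double DT_INF = 1e30;

inline void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double step) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  const double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
               (2.0 * s2 * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
          (2.0 * s2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]) * step;
    d[q] = dq * dq + f[v[k]];
  }
}

// 3D squared EDT in place over a double grid initialized to 0 at seeds and
// DT_INF elsewhere.
inline void edt3(std::vector<double>& out, int nx, int ny, int nz,
                 const double* spacing) {
  std::vector<double> f, d;
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      size_t base = (size_t)z * nx * ny + (size_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      size_t base = (size_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (size_t)y * nx];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (size_t)y * nx] = d[y];
    }
  f.resize(nz); d.resize(nz);
  const size_t sz = (size_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      size_t base = (size_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = out[base + (size_t)z * sz];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + (size_t)z * sz] = d[z];
    }
}

}  // namespace kidneyseg

#endif
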