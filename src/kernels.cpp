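#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Axis order throughout: dim = (nz, ny, nx), z fastest (R column-major,
// arrays indexed [z, y, x]). Linear index = z + nz*(y + ny*x), 0-based.

static void neighbor_offsets(int connectivity,
                             std::vector<int> &dz,
                             std::vector<int> &dy,
                             std::vector<int> &dx) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
}

// Breadth-first growth from one or more seeds through voxels whose value
// lies in [lo, hi]. Stops (leaked = TRUE) once more than max_voxels voxels
// have been accepted; max_voxels <= 0 means unlimited.
// [[Rcpp::export]]
List cpp_flood_fill(NumericVector vol, IntegerVector dim, IntegerVector seeds,
                    double lo, double hi, int connectivity,
                    double max_voxels) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector mask(n, false);
  std::vector<int> dz, dy, dx;
  neighbor_offsets(connectivity, dz, dy, dx);
  const int nn = (int)dz.size();

  std::vector<R_xlen_t> queue;
  queue.reserve(1024);
  double count = 0.0;
  bool leaked = false;

  for (R_xlen_t s = 0; s < seeds.size(); ++s) {
    R_xlen_t idx = seeds[s];
    if (idx < 0 || idx >= n) stop("seed index out of bounds");
    double v = vol[idx];
    if (!mask[idx] && v >= lo && v <= hi) {
      mask[idx] = true;
      queue.push_back(idx);
      count += 1.0;
    }
  }

  size_t head = 0;
  while (head < queue.size()) {
    if (max_voxels > 0 && count > max_voxels) { leaked = true; break; }
    R_xlen_t idx = queue[head++];
    int z = (int)(idx % nz);
    int rest = (int)(idx / nz);
    int y = rest % ny;
    int x = rest / ny;
    for (int k = 0; k < nn; ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (mask[j]) continue;
      double v = vol[j];
      if (v >= lo && v <= hi) {
        mask[j] = true;
        queue.push_back(j);
        count += 1.0;
      }
    }
  }

  return List::create(_["mask"] = mask,
                      _["count"] = count,
                      _["leaked"] = leaked);
}

// Connected-component labels of a boolean mask (0 = background).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n, 0);
  std::vector<int> dz, dy, dx;
  neighbor_offsets(connectivity, dz, dy, dx);
  const int nn = (int)dz.size();
  int next = 0;
  std::vector<R_xlen_t> queue;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next;
    labels[start] = next;
    queue.clear();
    queue.push_back(start);
    size_t head = 0;
    while (head < queue.size()) {
      R_xlen_t idx = queue[head++];
      int z = (int)(idx % nz);
      int rest = (int)(idx / nz);
      int y = rest % ny;
      int x = rest / ny;
      for (int k = 0; k < nn; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[j] && labels[j] == 0) {
          labels[j] = next;
          queue.push_back(j);
        }
      }
    }
  }
  labels.attr("n_components") = next;
  return labels;
}

// Separable Gaussian blur; sigma per axis in voxel units. Truncated at
// 3 sigma; the kernel is renormalized near the borders so flat regions
// stay flat (no edge darkening).
// [[Rcpp::export]]
NumericVector cpp_blur3d(NumericVector vol, IntegerVector dim,
                         NumericVector sigma_vox) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  // axis 0 (z): lines indexed by (y, x)
  {
    double s = sigma_vox[0];
    if (s > 0) {
      int radius = (int)std::ceil(3.0 * s);
      std::vector<double> w(2 * radius + 1);
      for (int i = -radius; i <= radius; ++i)
        w[i + radius] = std::exp(-0.5 * (double)i * i / (s * s));
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y) {
          R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
          for (int i = 0; i < nz; ++i) {
            double acc = 0, norm = 0;
            int j0 = std::max(0, i - radius), j1 = std::min(nz - 1, i + radius);
            for (int j = j0; j <= j1; ++j) {
              double wk = w[j - i + radius];
              acc += wk * a[base + j]; norm += wk;
            }
            b[base + i] = acc / norm;
          }
        }
      std::swap(a, b);
    }
  }
  // axis 1 (y): stride nz
  {
    double s = sigma_vox[1];
    if (s > 0) {
      int radius = (int)std::ceil(3.0 * s);
      std::vector<double> w(2 * radius + 1);
      for (int i = -radius; i <= radius; ++i)
        w[i + radius] = std::exp(-0.5 * (double)i * i / (s * s));
      for (int x = 0; x < nx; ++x)
        for (int z = 0; z < nz; ++z) {
          R_xlen_t base = (R_xlen_t)z + (R_xlen_t)nz * ny * (R_xlen_t)x;
          for (int i = 0; i < ny; ++i) {
            double acc = 0, norm = 0;
            int j0 = std::max(0, i - radius), j1 = std::min(ny - 1, i + radius);
            for (int j = j0; j <= j1; ++j) {
              double wk = w[j - i + radius];
              acc += wk * a[base + (R_xlen_t)nz * j]; norm += wk;
            }
            b[base + (R_xlen_t)nz * i] = acc / norm;
          }
        }
      std::swap(a, b);
    }
  }
  // axis 2 (x): stride nz*ny
  {
    double s = sigma_vox[2];
    if (s > 0) {
      int radius = (int)std::ceil(3.0 * s);
      std::vector<double> w(2 * radius + 1);
      for (int i = -radius; i <= radius; ++i)
        w[i + radius] = std::exp(-0.5 * (double)i * i / (s * s));
      R_xlen_t stride = (R_xlen_t)nz * ny;
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          R_xlen_t base = (R_xlen_t)z + (R_xlen_t)nz * y;
          for (int i = 0; i < nx; ++i) {
            double acc = 0, norm = 0;
            int j0 = std::max(0, i - radius), j1 = std::min(nx - 1, i + radius);
            for (int j = j0; j <= j1; ++j) {
              double wk = w[j - i + radius];
              acc += wk * a[base + stride * j]; norm += wk;
            }
            b[base + stride * i] = acc / norm;
          }
        }
      std::swap(a, b);
    }
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// ---- isosurface area by marching tetrahedra -------------------------------
// Each cell (cube of 8 voxel centers) is split into 6 tetrahedra sharing the
// main diagonal; within a tetrahedron the iso-level crossing is triangulated
// by linear interpolation along edges. Returns total area in spacing units^2.

struct P3 { double z, y, x; };

static inline P3 lerp_edge(const double *vz, const double *vy,
                           const double *vx, const double *val,
                           int a, int b, double iso) {
  double t = (iso - val[a]) / (val[b] - val[a]);
  P3 p;
  p.z = vz[a] + t * (vz[b] - vz[a]);
  p.y = vy[a] + t * (vy[b] - vy[a]);
  p.x = vx[a] + t * (vx[b] - vx[a]);
  return p;
}

static inline double tri_area(const P3 &p, const P3 &q, const P3 &r) {
  double uz = q.z - p.z, uy = q.y - p.y, ux = q.x - p.x;
  double vz2 = r.z - p.z, vy2 = r.y - p.y, vx2 = r.x - p.x;
  double cz = uy * vx2 - ux * vy2;
  double cy = ux * vz2 - uz * vx2;
  double cx = uz * vy2 - uy * vz2;
  return 0.5 * std::sqrt(cz * cz + cy * cy + cx * cx);
}

// [[Rcpp::export]]
double cpp_isosurface_area(NumericVector field, IntegerVector dim, double iso,
                           NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  // cube corners: bit 0 -> +z, bit 1 -> +y, bit 2 -> +x
  static const int tets[6][4] = {
    {0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
    {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}
  };
  double total = 0.0;
  std::vector<double> cz(8), cy(8), cx(8), cv(8);
  for (int x = 0; x + 1 < nx; ++x)
    for (int y = 0; y + 1 < ny; ++y) {
      R_xlen_t base_x0 = (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
      R_xlen_t base_x1 = (R_xlen_t)nz * ((R_xlen_t)y + 1 + (R_xlen_t)ny * x);
      R_xlen_t base_x2 = (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (x + 1));
      R_xlen_t base_x3 = (R_xlen_t)nz * ((R_xlen_t)y + 1 + (R_xlen_t)ny * (x + 1));
      for (int z = 0; z + 1 < nz; ++z) {
        double v000 = field[base_x0 + z],     v100 = field[base_x0 + z + 1];
        double v010 = field[base_x1 + z],     v110 = field[base_x1 + z + 1];
        double v001 = field[base_x2 + z],     v101 = field[base_x2 + z + 1];
        double v011 = field[base_x3 + z],     v111 = field[base_x3 + z + 1];
        double lo = v000, hi = v000;
        double vv[8] = {v000, v100, v010, v110, v001, v101, v011, v111};
        for (int k = 1; k < 8; ++k) {
          if (vv[k] < lo) lo = vv[k];
          if (vv[k] > hi) hi = vv[k];
        }
        if (lo >= iso || hi < iso) continue;
        for (int k = 0; k < 8; ++k) {
          cv[k] = vv[k];
          cz[k] = (z + (k & 1)) * sz;
          cy[k] = (y + ((k >> 1) & 1)) * sy;
          cx[k] = (x + ((k >> 2) & 1)) * sx;
        }
        for (int t = 0; t < 6; ++t) {
          int id[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          double tv[4]; double tz[4], ty[4], tx[4];
          int below = 0, nb = 0;
          for (int k = 0; k < 4; ++k) {
            tv[k] = cv[id[k]];
            tz[k] = cz[id[k]]; ty[k] = cy[id[k]]; tx[k] = cx[id[k]];
            if (tv[k] < iso) { below |= (1 << k); ++nb; }
          }
          if (nb == 0 || nb == 4) continue;
          if (nb == 1 || nb == 3) {
            // single separated vertex -> one triangle
            int lone = -1;
            for (int k = 0; k < 4; ++k) {
              bool isBelow = (below >> k) & 1;
              if ((nb == 1 && isBelow) || (nb == 3 && !isBelow)) { lone = k; break; }
            }
            P3 tri[3]; int m = 0;
            for (int k = 0; k < 4; ++k) {
              if (k == lone) continue;
              tri[m++] = lerp_edge(tz, ty, tx, tv, lone, k, iso);
            }
            total += tri_area(tri[0], tri[1], tri[2]);
          } else {
            // 2/2 split -> quad -> two triangles
            int aIdx[2], bIdx[2], na = 0, nbk = 0;
            for (int k = 0; k < 4; ++k) {
              if ((below >> k) & 1) aIdx[na++] = k; else bIdx[nbk++] = k;
            }
            P3 p00 = lerp_edge(tz, ty, tx, tv, aIdx[0], bIdx[0], iso);
            P3 p01 = lerp_edge(tz, ty, tx, tv, aIdx[0], bIdx[1], iso);
            P3 p11 = lerp_edge(tz, ty, tx, tv, aIdx[1], bIdx[1], iso);
            P3 p10 = lerp_edge(tz, ty, tx, tv, aIdx[1], bIdx[0], iso);
            total += tri_area(p00, p01, p11);
            total += tri_area(p00, p11, p10);
          }
        }
      }
    }
  return total;
}
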