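// Low-level 3D grid primitives shared by the segmentation, vessel-metric and
// interactome layers. All volumes are column-major with dim = (n1, n2, n3)
// and per-axis physical spacing in micrometres; a voxel's physical position
// is (0-based index) * spacing (voxel-centre convention).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int idx3(int i, int j, int k, int n1, int n2) {
  return i + n1 * (j + n2 * k);
}

// ---------------------------------------------------------------------------
// Exact anisotropic Euclidean distance transform (squared-distance lower
// envelope of parabolas, one pass per axis). f holds squared distances.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  const double s2 = s * s;
  int k = -1; // infinite sites are skipped: they can never be nearest
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double sval;
    while (true) {
      sval = ((f[q] + s2 * (double)q * q) -
              (f[v[k]] + s2 * (double)v[k] * v[k])) /
             (2.0 * s2 * (q - v[k]));
      if (k > 0 && sval <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sval;
    z[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = s * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector fg, IntegerVector dim, NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] ? 0.0 : INF;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      bool any = false;
      for (int i = 0; i < n1; ++i) { f[i] = out[idx3(i, j, k, n1, n2)]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, n1, spacing[0]);
      for (int i = 0; i < n1; ++i) out[idx3(i, j, k, n1, n2)] = d[i];
    }
  // axis 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      bool any = false;
      for (int j = 0; j < n2; ++j) { f[j] = out[idx3(i, j, k, n1, n2)]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, n2, spacing[1]);
      for (int j = 0; j < n2; ++j) out[idx3(i, j, k, n1, n2)] = d[j];
    }
  // axis 3
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      bool any = false;
      for (int k = 0; k < n3; ++k) { f[k] = out[idx3(i, j, k, n1, n2)]; if (f[k] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, n3, spacing[2]);
      for (int k = 0; k < n3; ++k) out[idx3(i, j, k, n1, n2)] = d[k];
    }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (6- or 26-connectivity), flood fill.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector fg, IntegerVector dim, int connectivity) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n, 0);
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (connectivity == 6 && std::abs(a) + std::abs(b) + std::abs(c) != 1) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  const int noff = (int)di.size();
  std::vector<int> stack;
  int next = 0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int p = idx3(i, j, k, n1, n2);
        if (!fg[p] || lab[p]) continue;
        ++next;
        lab[p] = next;
        stack.clear();
        stack.push_back(p);
        while (!stack.empty()) {
          int q = stack.back(); stack.pop_back();
          int qi = q % n1, qj = (q / n1) % n2, qk = q / (n1 * n2);
          for (int o = 0; o < noff; ++o) {
            int ii = qi + di[o], jj = qj + dj[o], kk = qk + dk[o];
            if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3) continue;
            int r = idx3(ii, jj, kk, n1, n2);
            if (fg[r] && !lab[r]) { lab[r] = next; stack.push_back(r); }
          }
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, sigma given in voxels per axis, reflected edges.
static void blur_axis(std::vector<double> &vol, int n1, int n2, int n3,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int t = -r; t <= r; ++t) { ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma)); s += ker[t + r]; }
  for (double &w : ker) w /= s;
  int len = (axis == 0) ? n1 : (axis == 1 ? n2 : n3);
  std::vector<double> line(len), res(len);
  int outer1, outer2;
  if (axis == 0) { outer1 = n2; outer2 = n3; }
  else if (axis == 1) { outer1 = n1; outer2 = n3; }
  else { outer1 = n1; outer2 = n2; }
  for (int b = 0; b < outer2; ++b)
    for (int a = 0; a < outer1; ++a) {
      for (int t = 0; t < len; ++t) {
        int p = (axis == 0) ? idx3(t, a, b, n1, n2)
              : (axis == 1) ? idx3(a, t, b, n1, n2)
              : idx3(a, b, t, n1, n2);
        line[t] = vol[p];
      }
      for (int t = 0; t < len; ++t) {
        double acc = 0;
        for (int u = -r; u <= r; ++u) {
          int q = t + u;
          if (q < 0) q = -q - 1;          // reflect
          if (q >= len) q = 2 * len - q - 1;
          if (q < 0) q = 0;               // tiny axes
          if (q >= len) q = len - 1;
          acc += ker[u + r] * line[q];
        }
        res[t] = acc;
      }
      for (int t = 0; t < len; ++t) {
        int p = (axis == 0) ? idx3(t, a, b, n1, n2)
              : (axis == 1) ? idx3(a, t, b, n1, n2)
              : idx3(a, b, t, n1, n2);
        vol[p] = res[t];
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dim, NumericVector sigma_vox) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  blur_axis(v, n1, n2, n3, 0, sigma_vox[0]);
  blur_axis(v, n1, n2, n3, 1, sigma_vox[1]);
  blur_axis(v, n1, n2, n3, 2, sigma_vox[2]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Isosurface area by marching tetrahedra (6 tetrahedra per cell sharing the
// main diagonal); vertices placed by linear interpolation along cell edges.
static double tri_area(const double a[3], const double b[3], const double c[3]) {
  double u[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
  double v[3] = { c[0] - a[0], c[1] - a[1], c[2] - a[2] };
  double x = u[1] * v[2] - u[2] * v[1];
  double y = u[2] * v[0] - u[0] * v[2];
  double z = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(x * x + y * y + z * z);
}

static void edge_point(const double p[4][3], const double f[4], int a, int b,
                       double iso, double out[3]) {
  double t = (iso - f[a]) / (f[b] - f[a]);
  for (int d = 0; d < 3; ++d) out[d] = p[a][d] + t * (p[b][d] - p[a][d]);
}

// [[Rcpp::export]]
double cpp_isosurface_area(NumericVector field, IntegerVector dim,
                           NumericVector spacing, double iso) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  // cube corner offsets, v0..v7
  static const int co[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
  };
  static const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}
  };
  double area = 0.0;
  for (int k = 0; k + 1 < n3; ++k)
    for (int j = 0; j + 1 < n2; ++j)
      for (int i = 0; i + 1 < n1; ++i) {
        double cf[8];
        double cp[8][3];
        bool lo = false, hi = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + co[c][0], jj = j + co[c][1], kk = k + co[c][2];
          cf[c] = field[idx3(ii, jj, kk, n1, n2)];
          cp[c][0] = ii * spacing[0];
          cp[c][1] = jj * spacing[1];
          cp[c][2] = kk * spacing[2];
          if (cf[c] < iso) lo = true; else hi = true;
        }
        if (!lo || !hi) continue;
        for (int t = 0; t < 6; ++t) {
          double f[4], p[4][3];
          int nin = 0;
          int in[4], outv[4];
          int nout = 0;
          for (int c = 0; c < 4; ++c) {
            int vc = tets[t][c];
            f[c] = cf[vc];
            for (int d = 0; d < 3; ++d) p[c][d] = cp[vc][d];
            if (f[c] >= iso) in[nin++] = c; else outv[nout++] = c;
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int lone = (nin == 1) ? in[0] : outv[0];
            double e[3][3];
            int m = 0;
            for (int c = 0; c < 4; ++c) {
              if (c == lone) continue;
              edge_point(p, f, lone, c, iso, e[m++]);
            }
            area += tri_area(e[0], e[1], e[2]);
          } else {
            // 2-2: quad from the four crossing edges
            int a1 = in[0], a2 = in[1], b1 = outv[0], b2 = outv[1];
            double q1[3], q2[3], q3[3], q4[3];
            edge_point(p, f, a1, b1, iso, q1);
            edge_point(p, f, a1, b2, iso, q2);
            edge_point(p, f, a2, b2, iso, q3);
            edge_point(p, f, a2, b1, iso, q4);
            area += tri_area(q1, q2, q3) + tri_area(q1, q3, q4);
          }
        }
      }
  return area;
}

// ---------------------------------------------------------------------------
// Local maxima above a threshold (26-neighbourhood). Plateaus are broken by
// linear index: strict > against earlier neighbours, >= against later ones,
// so each flat plateau yields a single detection.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector field, IntegerVector dim, double threshold) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  std::vector<int> hits;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int p = idx3(i, j, k, n1, n2);
        double f = field[p];
        if (!(f > threshold)) continue;
        bool ok = true;
        for (int a = -1; a <= 1 && ok; ++a)
          for (int b = -1; b <= 1 && ok; ++b)
            for (int c = -1; c <= 1 && ok; ++c) {
              if (a == 0 && b == 0 && c == 0) continue;
              int ii = i + a, jj = j + b, kk = k + c;
              if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3) continue;
              int q = idx3(ii, jj, kk, n1, n2);
              if (q < p) { if (!(f > field[q])) ok = false; }
              else { if (!(f >= field[q])) ok = false; }
            }
        if (ok) hits.push_back(p + 1);
      }
  return IntegerVector(hits.begin(), hits.end());
}

// ---------------------------------------------------------------------------
// Seeded region growing. Priority-flood from seed voxels; with a landscape
// (membrane channel) the flood order is the classic watershed immersion
// (priority = max landscape along the path), without one it is the geodesic
// nearest-seed partition. Growth is stopped at max_radius_um (Euclidean from
// the owning seed) and restricted to mask when given.
struct QNode {
  double prio;
  long long order;
  int voxel;
  int label;
  int seed;
  bool operator<(const QNode &o) const {
    if (prio != o.prio) return prio > o.prio; // min-heap
    return order > o.order;
  }
};

// [[Rcpp::export]]
IntegerVector cpp_seeded_grow(NumericVector landscape, IntegerVector seed_idx,
                              LogicalVector mask, IntegerVector dim,
                              NumericVector spacing, double max_radius_um,
                              bool use_landscape) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const bool has_mask = mask.size() == n;
  IntegerVector lab(n, 0);
  std::vector<double> sz(seed_idx.size()), sy(seed_idx.size()), sx(seed_idx.size());
  std::priority_queue<QNode> pq;
  long long order = 0;
  for (int s = 0; s < seed_idx.size(); ++s) {
    int p = seed_idx[s] - 1;
    int i = p % n1, j = (p / n1) % n2, k = p / (n1 * n2);
    sz[s] = i * spacing[0]; sy[s] = j * spacing[1]; sx[s] = k * spacing[2];
    double prio = use_landscape ? landscape[p] : 0.0;
    pq.push({prio, order++, p, s + 1, s});
  }
  while (!pq.empty()) {
    QNode nd = pq.top(); pq.pop();
    if (lab[nd.voxel]) continue;
    lab[nd.voxel] = nd.label;
    int i = nd.voxel % n1, j = (nd.voxel / n1) % n2, k = nd.voxel / (n1 * n2);
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          int ii = i + a, jj = j + b, kk = k + c;
          if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3) continue;
          int q = idx3(ii, jj, kk, n1, n2);
          if (lab[q]) continue;
          if (has_mask && !mask[q]) continue;
          double dz = ii * spacing[0] - sz[nd.seed];
          double dy = jj * spacing[1] - sy[nd.seed];
          double dx = kk * spacing[2] - sx[nd.seed];
          double dist = std::sqrt(dz * dz + dy * dy + dx * dx);
          if (max_radius_um > 0 && dist > max_radius_um) continue;
          double prio;
          if (use_landscape) prio = std::max(nd.prio, landscape[q]);
          else prio = dist;
          pq.push({prio, order++, q, nd.label, nd.seed});
        }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Geodesic diameter of a foreground set (26-connectivity, physical edge
// lengths): double-sweep Dijkstra from an arbitrary start, good for the
// elongated shapes it is used on.
static void dijkstra_mask(const LogicalVector &fg, int n1, int n2, int n3,
                          const NumericVector &spacing, int start,
                          std::vector<double> &dist) {
  const double INF = std::numeric_limits<double>::infinity();
  std::fill(dist.begin(), dist.end(), INF);
  typedef std::pair<double, int> PD;
  std::priority_queue<PD, std::vector<PD>, std::greater<PD> > pq;
  dist[start] = 0;
  pq.push({0.0, start});
  while (!pq.empty()) {
    PD t = pq.top(); pq.pop();
    if (t.first > dist[t.second]) continue;
    int p = t.second;
    int i = p % n1, j = (p / n1) % n2, k = p / (n1 * n2);
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          int ii = i + a, jj = j + b, kk = k + c;
          if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3) continue;
          int q = idx3(ii, jj, kk, n1, n2);
          if (!fg[q]) continue;
          double w = std::sqrt(a * a * spacing[0] * spacing[0] +
                               b * b * spacing[1] * spacing[1] +
                               c * c * spacing[2] * spacing[2]);
          if (dist[p] + w < dist[q]) {
            dist[q] = dist[p] + w;
            pq.push({dist[q], q});
          }
        }
  }
}

// [[Rcpp::export]]
double cpp_geodesic_diameter(LogicalVector fg, IntegerVector dim, NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  int start = -1;
  for (R_xlen_t i = 0; i < n; ++i) if (fg[i]) { start = (int)i; break; }
  if (start < 0) return 0.0;
  std::vector<double> dist(n);
  dijkstra_mask(fg, n1, n2, n3, spacing, start, dist);
  int far1 = start; double best = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (fg[i] && std::isfinite(dist[i]) && dist[i] > best) { best = dist[i]; far1 = (int)i; }
  dijkstra_mask(fg, n1, n2, n3, spacing, far1, dist);
  best = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (fg[i] && std::isfinite(dist[i]) && dist[i] > best) best = dist[i];
  return best;
}

// ---------------------------------------------------------------------------
// Local-maximum mask of a scalar field restricted to fg (26-neighbourhood,
// tolerance tol): used as a medial-ridge detector on the interior distance
// transform.
// [[Rcpp::export]]
LogicalVector cpp_ridge_mask(NumericVector field, LogicalVector fg,
                             IntegerVector dim, double tol) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  LogicalVector out(n, 0);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int p = idx3(i, j, k, n1, n2);
        if (!fg[p]) continue;
        double f = field[p];
        bool ok = true;
        for (int a = -1; a <= 1 && ok; ++a)
          for (int b = -1; b <= 1 && ok; ++b)
            for (int c = -1; c <= 1 && ok; ++c) {
              if (a == 0 && b == 0 && c == 0) continue;
              int ii = i + a, jj = j + b, kk = k + c;
              if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3) continue;
              if (field[idx3(ii, jj, kk, n1, n2)] > f + tol) ok = false;
            }
        if (ok) out[p] = 1;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Rasterise flat-capped cylinders: a voxel centre is foreground when its
// axial projection falls within the segment and its radial distance is <= r,
// so a fully interior tube has analytic volume pi r^2 L exactly.
// segs columns: p1 (3 physical coords, axis order matching dim), p2, radius.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_tubes(IntegerVector dim, NumericVector spacing,
                                  NumericMatrix segs, LogicalVector base) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  LogicalVector out(n, 0);
  if (base.size() == n) for (R_xlen_t i = 0; i < n; ++i) out[i] = base[i];
  for (int s = 0; s < segs.nrow(); ++s) {
    double a1 = segs(s, 0), a2 = segs(s, 1), a3 = segs(s, 2);
    double b1 = segs(s, 3), b2 = segs(s, 4), b3 = segs(s, 5);
    double r = segs(s, 6);
    double lo1 = std::min(a1, b1) - r, hi1 = std::max(a1, b1) + r;
    double lo2 = std::min(a2, b2) - r, hi2 = std::max(a2, b2) + r;
    double lo3 = std::min(a3, b3) - r, hi3 = std::max(a3, b3) + r;
    int i0 = std::max(0, (int)std::floor(lo1 / spacing[0]));
    int i1 = std::min(n1 - 1, (int)std::ceil(hi1 / spacing[0]));
    int j0 = std::max(0, (int)std::floor(lo2 / spacing[1]));
    int j1 = std::min(n2 - 1, (int)std::ceil(hi2 / spacing[1]));
    int k0 = std::max(0, (int)std::floor(lo3 / spacing[2]));
    int k1 = std::min(n3 - 1, (int)std::ceil(hi3 / spacing[2]));
    double d1 = b1 - a1, d2 = b2 - a2, d3 = b3 - a3;
    double len2 = d1 * d1 + d2 * d2 + d3 * d3;
    double r2 = r * r;
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double p1 = i * spacing[0], p2 = j * spacing[1], p3 = k * spacing[2];
          double t = 0;
          if (len2 > 0) {
            t = ((p1 - a1) * d1 + (p2 - a2) * d2 + (p3 - a3) * d3) / len2;
            if (t < 0 || t > 1) continue; // beyond the flat caps
          }
          double q1 = a1 + t * d1 - p1, q2 = a2 + t * d2 - p2, q3 = a3 + t * d3 - p3;
          if (q1 * q1 + q2 * q2 + q3 * q3 <= r2)
            out[idx3(i, j, k, n1, n2)] = 1;
        }
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_rasterize_balls(IntegerVector dim, NumericVector spacing,
                                  NumericMatrix balls, LogicalVector base) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  LogicalVector out(n, 0);
  if (base.size() == n) for (R_xlen_t i = 0; i < n; ++i) out[i] = base[i];
  for (int s = 0; s < balls.nrow(); ++s) {
    double c1 = balls(s, 0), c2 = balls(s, 1), c3 = balls(s, 2), r = balls(s, 3);
    double r2 = r * r;
    int i0 = std::max(0, (int)std::floor((c1 - r) / spacing[0]));
    int i1 = std::min(n1 - 1, (int)std::ceil((c1 + r) / spacing[0]));
    int j0 = std::max(0, (int)std::floor((c2 - r) / spacing[1]));
    int j1 = std::min(n2 - 1, (int)std::ceil((c2 + r) / spacing[1]));
    int k0 = std::max(0, (int)std::floor((c3 - r) / spacing[2]));
    int k1 = std::min(n3 - 1, (int)std::ceil((c3 + r) / spacing[2]));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double d1 = i * spacing[0] - c1, d2 = j * spacing[1] - c2, d3 = k * spacing[2] - c3;
          if (d1 * d1 + d2 * d2 + d3 * d3 <= r2)
            out[idx3(i, j, k, n1, n2)] = 1;
        }
  }
  return out;
}
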