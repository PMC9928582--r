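// Voxel-grid primitives: surface extraction by marching tetrahedra on the
// Freudenthal (Kuhn) cube decomposition, 3D connected-component labelling,
// binary morphology, separable Gaussian smoothing, and multi-Otsu threshold
// search. All grids are R arrays in column-major order, index
// (i, j, k) -> i + nx * (j + ny * k), 0-based here.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// The six tetrahedra of the Kuhn subdivision of the unit cube, as corner
// indices with bit encoding c = x + 2y + 4z. Each tet is a monotone path
// 0 -> 7 adding one coordinate at a time; this tiling of space is globally
// consistent across neighbouring cubes, which makes the extracted surface
// watertight by construction.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

struct MTState {
  std::unordered_map<int64_t, int> edge_vertex; // global edge key -> vertex id
  std::vector<double> vx, vy, vz;               // vertex positions (index space)
  std::vector<int> faces;                       // triples of 0-based vertex ids
  int64_t nvox;
};

static inline int64_t edge_key(int64_t a, int64_t b, int64_t nvox) {
  return (a < b) ? a * nvox + b : b * nvox + a;
}

// vertex on the cut edge between grid vertices a and b (linear interpolation)
static int cut_vertex(MTState &st, int64_t ga, int64_t gb,
                      double fa, double fb, double iso,
                      const double pa[3], const double pb[3]) {
  int64_t key = edge_key(ga, gb, st.nvox);
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double t = (iso - fa) / (fb - fa);
  // keep cut vertices strictly inside the edge so no face degenerates to
  // zero area even when the field equals iso at a grid vertex
  if (t < 1e-6) t = 1e-6;
  if (t > 1.0 - 1e-6) t = 1.0 - 1e-6;
  int id = (int) st.vx.size();
  st.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  st.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  st.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  st.edge_vertex.emplace(key, id);
  return id;
}

// append triangle, optionally with reversed winding
static void emit_tri(MTState &st, int i1, int i2, int i3, bool reverse) {
  if (reverse) { int tmp = i2; i2 = i3; i3 = tmp; }
  st.faces.push_back(i1); st.faces.push_back(i2); st.faces.push_back(i3);
}

// sign of det(b - a, c - a, d - a) on (integer) lattice corner positions;
// exact, so the winding decision is combinatorial, never a float guess
static int orient4(const double a[3], const double b[3],
                   const double c[3], const double d[3]) {
  double m[3][3];
  for (int q = 0; q < 3; ++q) {
    m[0][q] = b[q] - a[q];
    m[1][q] = c[q] - a[q];
    m[2][q] = d[q] - a[q];
  }
  double det =
    m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
    m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
    m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
  return (det > 0) - (det < 0);
}

// [[Rcpp::export]]
List marching_tetrahedra_cpp(NumericVector field, IntegerVector dim, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  MTState st;
  st.nvox = (int64_t) nx * ny * nz;
  const double *f = REAL(field);

  int64_t gcorner[8];
  double fval[8], pos[8][3];
  bool inside[8];

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        // gather the 8 cube corners
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          int64_t g = ci + (int64_t) nx * (cj + (int64_t) ny * ck);
          gcorner[c] = g;
          fval[c] = f[g];
          pos[c][0] = ci; pos[c][1] = cj; pos[c][2] = ck;
          inside[c] = fval[c] > iso;
          if (inside[c]) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          int vin[4], vout[4], nin = 0, nout = 0;
          for (int s = 0; s < 4; ++s) {
            int c = TETS[t][s];
            if (inside[c]) vin[nin++] = c; else vout[nout++] = c;
          }
          if (nin == 0 || nin == 4) continue;

          if (nin == 1) {
            // triangle separating the single inside corner I; for a
            // positively oriented (I, O1, O2, O3) the winding
            // (p_IO1, p_IO2, p_IO3) has its normal away from I (outward)
            int I = vin[0];
            int s = orient4(pos[I], pos[vout[0]], pos[vout[1]], pos[vout[2]]);
            int t1 = cut_vertex(st, gcorner[I], gcorner[vout[0]], fval[I], fval[vout[0]], iso, pos[I], pos[vout[0]]);
            int t2 = cut_vertex(st, gcorner[I], gcorner[vout[1]], fval[I], fval[vout[1]], iso, pos[I], pos[vout[1]]);
            int t3 = cut_vertex(st, gcorner[I], gcorner[vout[2]], fval[I], fval[vout[2]], iso, pos[I], pos[vout[2]]);
            emit_tri(st, t1, t2, t3, s < 0);
          } else if (nin == 3) {
            // single outside corner O: same triangle, opposite convention
            int O = vout[0];
            int s = orient4(pos[O], pos[vin[0]], pos[vin[1]], pos[vin[2]]);
            int t1 = cut_vertex(st, gcorner[O], gcorner[vin[0]], fval[O], fval[vin[0]], iso, pos[O], pos[vin[0]]);
            int t2 = cut_vertex(st, gcorner[O], gcorner[vin[1]], fval[O], fval[vin[1]], iso, pos[O], pos[vin[1]]);
            int t3 = cut_vertex(st, gcorner[O], gcorner[vin[2]], fval[O], fval[vin[2]], iso, pos[O], pos[vin[2]]);
            emit_tri(st, t1, t2, t3, s > 0);
          } else {
            // two inside (a, b), two outside (c, d): quad in cyclic order
            // ac, ad, bd, bc; for positively oriented (a, b, c, d) the
            // windings below are outward
            int a = vin[0], b = vin[1], c = vout[0], d = vout[1];
            int s = orient4(pos[a], pos[b], pos[c], pos[d]);
            int pac = cut_vertex(st, gcorner[a], gcorner[c], fval[a], fval[c], iso, pos[a], pos[c]);
            int pad = cut_vertex(st, gcorner[a], gcorner[d], fval[a], fval[d], iso, pos[a], pos[d]);
            int pbd = cut_vertex(st, gcorner[b], gcorner[d], fval[b], fval[d], iso, pos[b], pos[d]);
            int pbc = cut_vertex(st, gcorner[b], gcorner[c], fval[b], fval[c], iso, pos[b], pos[c]);
            emit_tri(st, pac, pad, pbd, s < 0);
            emit_tri(st, pac, pbd, pbc, s < 0);
          }
        }
      }
    }
  }

  int nv = (int) st.vx.size();
  int nf = (int) st.faces.size() / 3;
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = st.vx[v]; V(v, 1) = st.vy[v]; V(v, 2) = st.vz[v];
  }
  IntegerMatrix F(nf, 3);
  for (int q = 0; q < nf; ++q) {
    F(q, 0) = st.faces[3 * q] + 1;      // 1-based for R
    F(q, 1) = st.faces[3 * q + 1] + 1;
    F(q, 2) = st.faces[3 * q + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Connected components of a logical mask; connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int64_t n = (int64_t) nx * ny * nz;
  IntegerVector labels(n, 0);
  const int *m = LOGICAL(mask);
  int *lab = INTEGER(labels);

  std::vector<int> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        off.push_back(dx); off.push_back(dy); off.push_back(dz);
      }
  int noff = (int) off.size() / 3;

  std::vector<int64_t> stack;
  int next_label = 0;
  for (int64_t s = 0; s < n; ++s) {
    if (m[s] == 0 || lab[s] != 0) continue;
    ++next_label;
    lab[s] = next_label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      int64_t cur = stack.back(); stack.pop_back();
      int ci = (int)(cur % nx);
      int cj = (int)((cur / nx) % ny);
      int ck = (int)(cur / ((int64_t) nx * ny));
      for (int o = 0; o < noff; ++o) {
        int ii = ci + off[3 * o], jj = cj + off[3 * o + 1], kk = ck + off[3 * o + 2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        int64_t q = ii + (int64_t) nx * (jj + (int64_t) ny * kk);
        if (m[q] != 0 && lab[q] == 0) {
          lab[q] = next_label;
          stack.push_back(q);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// 6-neighbourhood binary erosion (iterated); voxels outside the grid count
// as background, so erosion also peels the border.
// [[Rcpp::export]]
LogicalVector binary_erode_cpp(LogicalVector mask, IntegerVector dim, int iterations) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int64_t n = (int64_t) nx * ny * nz;
  std::vector<int> cur(LOGICAL(mask), LOGICAL(mask) + n), nxt(n);
  for (int it = 0; it < iterations; ++it) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int64_t s = i + (int64_t) nx * (j + (int64_t) ny * k);
          bool keep = cur[s] != 0;
          if (keep) {
            keep =
              (i > 0      && cur[s - 1]) && (i < nx - 1 && cur[s + 1]) &&
              (j > 0      && cur[s - nx]) && (j < ny - 1 && cur[s + nx]) &&
              (k > 0      && cur[s - (int64_t) nx * ny]) &&
              (k < nz - 1 && cur[s + (int64_t) nx * ny]);
          }
          nxt[s] = keep ? 1 : 0;
        }
    cur.swap(nxt);
  }
  LogicalVector out(n);
  for (int64_t s = 0; s < n; ++s) out[s] = cur[s];
  out.attr("dim") = dim;
  return out;
}

// 6-neighbourhood binary dilation (iterated)
// [[Rcpp::export]]
LogicalVector binary_dilate_cpp(LogicalVector mask, IntegerVector dim, int iterations) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int64_t n = (int64_t) nx * ny * nz;
  std::vector<int> cur(LOGICAL(mask), LOGICAL(mask) + n), nxt(n);
  for (int it = 0; it < iterations; ++it) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int64_t s = i + (int64_t) nx * (j + (int64_t) ny * k);
          bool on = cur[s] != 0 ||
            (i > 0      && cur[s - 1]) || (i < nx - 1 && cur[s + 1]) ||
            (j > 0      && cur[s - nx]) || (j < ny - 1 && cur[s + nx]) ||
            (k > 0      && cur[s - (int64_t) nx * ny]) ||
            (k < nz - 1 && cur[s + (int64_t) nx * ny]);
          nxt[s] = on ? 1 : 0;
        }
    cur.swap(nxt);
  }
  LogicalVector out(n);
  for (int64_t s = 0; s < n; ++s) out[s] = cur[s];
  out.attr("dim") = dim;
  return out;
}

// Separable Gaussian smoothing, sigma in voxels, replicated borders.
// [[Rcpp::export]]
NumericVector gaussian_smooth3d_cpp(NumericVector field, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int64_t n = (int64_t) nx * ny * nz;
  if (sigma <= 0) {
    NumericVector out = clone(field);
    out.attr("dim") = dim;
    return out;
  }
  int rad = (int) std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double s2 = 2.0 * sigma * sigma, ksum = 0.0;
  for (int t = -rad; t <= rad; ++t) { ker[t + rad] = std::exp(-(double)(t * t) / s2); ksum += ker[t + rad]; }
  for (auto &w : ker) w /= ksum;

  std::vector<double> a(REAL(field), REAL(field) + n), b(n);
  const int dims[3] = {nx, ny, nz};
  const int64_t strides[3] = {1, nx, (int64_t) nx * ny};
  for (int axis = 0; axis < 3; ++axis) {
    int len = dims[axis];
    int64_t stride = strides[axis];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int idx3[3] = {i, j, k};
          int64_t s = i + (int64_t) nx * (j + (int64_t) ny * k);
          double acc = 0.0;
          for (int t = -rad; t <= rad; ++t) {
            int p = idx3[axis] + t;
            if (p < 0) p = 0;
            if (p >= len) p = len - 1;
            acc += ker[t + rad] * a[s + (int64_t)(p - idx3[axis]) * stride];
          }
          b[s] = acc;
        }
    a.swap(b);
  }
  NumericVector out(n);
  for (int64_t s = 0; s < n; ++s) out[s] = a[s];
  out.attr("dim") = dim;
  return out;
}

// Multi-Otsu: exhaustive maximisation of between-class variance over
// (classes - 1) split points of a histogram. Returns 0-based bin indices t
// meaning "class boundary after bin t". classes in {2, 3, 4}.
// [[Rcpp::export]]
IntegerVector multiotsu_cpp(NumericVector counts, NumericVector mids, int classes) {
  int nb = counts.size();
  std::vector<double> w(nb + 1, 0.0), wm(nb + 1, 0.0);
  for (int i = 0; i < nb; ++i) {
    w[i + 1] = w[i] + counts[i];
    wm[i + 1] = wm[i] + counts[i] * mids[i];
  }
  double W = w[nb];
  auto term = [&](int lo, int hi) { // bins [lo, hi), between-class contribution
    double ww = w[hi] - w[lo];
    if (ww <= 0) return 0.0;
    double mu = (wm[hi] - wm[lo]) / ww;
    return ww / W * mu * mu;
  };
  double best = -1.0;
  IntegerVector out(classes - 1);
  if (classes == 2) {
    for (int t1 = 0; t1 < nb - 1; ++t1) {
      double v = term(0, t1 + 1) + term(t1 + 1, nb);
      if (v > best) { best = v; out[0] = t1; }
    }
  } else if (classes == 3) {
    for (int t1 = 0; t1 < nb - 2; ++t1)
      for (int t2 = t1 + 1; t2 < nb - 1; ++t2) {
        double v = term(0, t1 + 1) + term(t1 + 1, t2 + 1) + term(t2 + 1, nb);
        if (v > best) { best = v; out[0] = t1; out[1] = t2; }
      }
  } else if (classes == 4) {
    for (int t1 = 0; t1 < nb - 3; ++t1) {
      double a = term(0, t1 + 1);
      for (int t2 = t1 + 1; t2 < nb - 2; ++t2) {
        double ab = a + term(t1 + 1, t2 + 1);
        for (int t3 = t2 + 1; t3 < nb - 1; ++t3) {
          double v = ab + term(t2 + 1, t3 + 1) + term(t3 + 1, nb);
          if (v > best) { best = v; out[0] = t1; out[1] = t2; out[2] = t3; }
        }
      }
    }
  } else {
    stop("classes must be 2, 3 or 4");
  }
  return out;
}
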