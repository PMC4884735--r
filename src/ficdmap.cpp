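// Compiled kernels for the tensor-field tracker and seed-layer extraction.
// Conventions (fixed package-wide): voxel indices are 0-based, a voxel's
// world position is its center, tensors are stored as the 6 unique
// components (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz) on the 4th array axis.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double fa_from_eigvals(const arma::vec3& l) {
  double m = (l(0) + l(1) + l(2)) / 3.0;
  double num = (l(0) - m) * (l(0) - m) + (l(1) - m) * (l(1) - m) +
               (l(2) - m) * (l(2) - m);
  double den = l(0) * l(0) + l(1) * l(1) + l(2) * l(2);
  if (den <= 0.0) return 0.0;
  double fa = std::sqrt(1.5 * num / den);
  return fa > 1.0 ? 1.0 : fa;
}

// FA and principal eigenvector for each row of an n x 6 tensor matrix.
// [[Rcpp::export]]
List cpp_tensor_principal(const arma::mat& t6) {
  const arma::uword n = t6.n_rows;
  arma::vec fa(n);
  arma::mat v1(n, 3);
  arma::mat33 D;
  arma::vec eigval;
  arma::mat eigvec;
  for (arma::uword i = 0; i < n; ++i) {
    D(0, 0) = t6(i, 0); D(0, 1) = t6(i, 1); D(0, 2) = t6(i, 2);
    D(1, 0) = t6(i, 1); D(1, 1) = t6(i, 3); D(1, 2) = t6(i, 4);
    D(2, 0) = t6(i, 2); D(2, 1) = t6(i, 4); D(2, 2) = t6(i, 5);
    arma::eig_sym(eigval, eigvec, D);
    fa(i) = fa_from_eigvals(eigval);
    v1.row(i) = eigvec.col(2).t();  // eig_sym sorts ascending
  }
  return List::create(_["fa"] = fa, _["v1"] = v1);
}

struct TensorGrid {
  const double* data;
  int nx, ny, nz;
  arma::mat inv_affine;

  TensorGrid(const NumericVector& arr, const IntegerVector& dims,
             const arma::mat& inv_aff)
      : data(arr.begin()), nx(dims[0]), ny(dims[1]), nz(dims[2]),
        inv_affine(inv_aff) {}

  inline double at(int x, int y, int z, int c) const {
    return data[x + (size_t)nx * (y + (size_t)ny * (z + (size_t)nz * c))];
  }

  // world mm -> fractional 0-based voxel coordinates
  inline arma::vec3 to_voxel(const arma::vec3& w) const {
    arma::vec3 v;
    for (int r = 0; r < 3; ++r)
      v(r) = inv_affine(r, 0) * w(0) + inv_affine(r, 1) * w(1) +
             inv_affine(r, 2) * w(2) + inv_affine(r, 3);
    return v;
  }

  // Trilinear interpolation of the 6 tensor components; false if the
  // interpolation support falls outside the grid.
  bool sample(const arma::vec3& w, arma::vec6& out) const {
    arma::vec3 p = to_voxel(w);
    const double eps = 1e-9;
    if (p(0) < -eps || p(1) < -eps || p(2) < -eps ||
        p(0) > nx - 1 + eps || p(1) > ny - 1 + eps || p(2) > nz - 1 + eps)
      return false;
    int i0 = std::min((int)std::floor(p(0)), nx - 2);
    int j0 = std::min((int)std::floor(p(1)), ny - 2);
    int k0 = std::min((int)std::floor(p(2)), nz - 2);
    i0 = std::max(i0, 0); j0 = std::max(j0, 0); k0 = std::max(k0, 0);
    double fx = p(0) - i0, fy = p(1) - j0, fz = p(2) - k0;
    for (int c = 0; c < 6; ++c) {
      double c00 = at(i0, j0, k0, c) * (1 - fx) + at(i0 + 1, j0, k0, c) * fx;
      double c10 = at(i0, j0 + 1, k0, c) * (1 - fx) + at(i0 + 1, j0 + 1, k0, c) * fx;
      double c01 = at(i0, j0, k0 + 1, c) * (1 - fx) + at(i0 + 1, j0, k0 + 1, c) * fx;
      double c11 = at(i0, j0 + 1, k0 + 1, c) * (1 - fx) + at(i0 + 1, j0 + 1, k0 + 1, c) * fx;
      out(c) = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
               (c01 * (1 - fy) + c11 * fy) * fz;
    }
    return true;
  }

  // FA + principal direction at a world point. Returns false out of bounds.
  bool principal(const arma::vec3& w, double& fa, arma::vec3& dir) const {
    arma::vec6 t;
    if (!sample(w, t)) return false;
    arma::mat33 D = {{t(0), t(1), t(2)}, {t(1), t(3), t(4)}, {t(2), t(4), t(5)}};
    arma::vec eigval;
    arma::mat eigvec;
    arma::eig_sym(eigval, eigvec, D);
    fa = fa_from_eigvals(eigval);
    dir = eigvec.col(2);
    return true;
  }
};

// Interpolated FA and principal direction at world points, with the
// eigenvector sign chosen to align with a per-point reference direction.
// Out-of-bounds points get FA = NA.
// [[Rcpp::export]]
List cpp_sample_field(const NumericVector& tensor, const IntegerVector& dims,
                      const arma::mat& inv_affine, const arma::mat& pts,
                      const arma::mat& ref) {
  TensorGrid grid(tensor, dims, inv_affine);
  const arma::uword n = pts.n_rows;
  arma::vec fa(n);
  arma::mat dir(n, 3);
  LogicalVector inside(n);
  for (arma::uword i = 0; i < n; ++i) {
    arma::vec3 w = pts.row(i).t(), d;
    double f;
    if (grid.principal(w, f, d)) {
      arma::vec3 r = ref.row(i).t();
      if (arma::dot(d, r) < 0) d = -d;
      fa(i) = f;
      dir.row(i) = d.t();
      inside(i) = true;
    } else {
      fa(i) = NA_REAL;
      dir.row(i).fill(NA_REAL);
      inside(i) = false;
    }
  }
  return List::create(_["fa"] = fa, _["dir"] = dir, _["inside"] = inside);
}

// One tracking branch. Appends points (excluding the seed) to pts/fas.
static void track_branch(const TensorGrid& grid, const arma::vec3& seed,
                         const arma::vec3& dir0, double fa_thr,
                         double cos_thr, double step, double smooth,
                         double max_len, std::vector<arma::vec3>& pts,
                         std::vector<double>& fas) {
  arma::vec3 pos = seed;
  arma::vec3 d_prev = dir0;
  double len = 0.0;
  int max_steps = (int)(max_len / step) + 4;
  for (int it = 0; it < max_steps; ++it) {
    double fa;
    arma::vec3 v;
    if (!grid.principal(pos, fa, v)) break;       // defensive; pos is sampled
    if (arma::dot(v, d_prev) < 0) v = -v;         // tensor +/- symmetry
    if (arma::dot(v, d_prev) < cos_thr) break;    // turning-angle rule
    arma::vec3 d = (1.0 - smooth) * v + smooth * d_prev;
    double nd = arma::norm(d);
    if (nd <= 0) break;
    d /= nd;
    arma::vec3 nxt = pos + step * d;
    double fa_n;
    arma::vec3 v_n;
    if (!grid.principal(nxt, fa_n, v_n)) break;   // leaves the grid
    if (fa_n < fa_thr) break;                     // FA termination
    pts.push_back(nxt);
    fas.push_back(fa_n);
    pos = nxt;
    d_prev = d;
    len += step;
  }
}

// Deterministic bidirectional streamline tracking from world-mm seed points.
// Returns, per seed, either NULL (seed below FA threshold) or a list with the
// polyline (n x 3, world mm) and per-point FA samples.
// [[Rcpp::export]]
List cpp_track(const NumericVector& tensor, const IntegerVector& dims,
               const arma::mat& inv_affine, const arma::mat& seeds,
               double fa_threshold, double turning_angle_deg, double step_mm,
               double smoothing, double max_len_mm) {
  TensorGrid grid(tensor, dims, inv_affine);
  double cos_thr = std::cos(turning_angle_deg * M_PI / 180.0);
  const arma::uword n = seeds.n_rows;
  List out(n);
  for (arma::uword s = 0; s < n; ++s) {
    arma::vec3 seed = seeds.row(s).t();
    double fa0;
    arma::vec3 v0;
    if (!grid.principal(seed, fa0, v0) || fa0 < fa_threshold) {
      out[s] = R_NilValue;
      continue;
    }
    std::vector<arma::vec3> fwd, bwd;
    std::vector<double> fwd_fa, bwd_fa;
    track_branch(grid, seed, v0, fa_threshold, cos_thr, step_mm, smoothing,
                 max_len_mm, fwd, fwd_fa);
    track_branch(grid, seed, -v0, fa_threshold, cos_thr, step_mm, smoothing,
                 max_len_mm, bwd, bwd_fa);
    const size_t np = bwd.size() + 1 + fwd.size();
    NumericMatrix pts(np, 3);
    NumericVector fa(np);
    size_t r = 0;
    for (size_t i = bwd.size(); i-- > 0; ++r) {
      for (int c = 0; c < 3; ++c) pts(r, c) = bwd[i](c);
      fa[r] = bwd_fa[i];
    }
    for (int c = 0; c < 3; ++c) pts(r, c) = seed(c);
    fa[r] = fa0;
    ++r;
    for (size_t i = 0; i < fwd.size(); ++i, ++r) {
      for (int c = 0; c < 3; ++c) pts(r, c) = fwd[i](c);
      fa[r] = fwd_fa[i];
    }
    out[s] = List::create(_["points"] = pts, _["fa"] = fa);
  }
  return out;
}

// ---- seed-layer extraction --------------------------------------------

// Closest point on triangle abc to p (Ericson, Real-Time Collision Detection).
static arma::vec3 closest_on_triangle(const arma::vec3& p, const arma::vec3& a,
                                      const arma::vec3& b, const arma::vec3& c) {
  arma::vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = arma::dot(ab, ap), d2 = arma::dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return a;
  arma::vec3 bp = p - b;
  double d3 = arma::dot(ab, bp), d4 = arma::dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return a + (d1 / (d1 - d3)) * ab;
  arma::vec3 cp = p - c;
  double d5 = arma::dot(ab, cp), d6 = arma::dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return a + (d2 / (d2 - d6)) * ac;
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return b + ((d4 - d3) / ((d4 - d3) + (d5 - d6))) * (c - b);
  double denom = 1.0 / (va + vb + vc);
  return a + ab * (vb * denom) + ac * (vc * denom);
}

// For every voxel center within `thickness` of the mesh on the inward-normal
// side, find the nearest surface point over all faces and report the owning
// face's label. Returns 0-based voxel ijk triplets, owner labels, and the
// distances. Face orientation: counter-clockwise seen from outside (outward
// normals).
// [[Rcpp::export]]
List cpp_seed_layer(const arma::mat& verts, const IntegerMatrix& faces,
                    const IntegerVector& face_label, const arma::mat& affine,
                    const IntegerVector& dims, double thickness) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const arma::uword nf = faces.nrow();
  const arma::mat& A = affine;

  // face normals (outward) and longest edge
  arma::mat fnorm(nf, 3);
  double max_edge = 0.0;
  for (arma::uword f = 0; f < nf; ++f) {
    arma::vec3 a = verts.row(faces(f, 0) - 1).t();
    arma::vec3 b = verts.row(faces(f, 1) - 1).t();
    arma::vec3 c = verts.row(faces(f, 2) - 1).t();
    arma::vec3 n = arma::cross(b - a, c - a);
    double nn = arma::norm(n);
    if (nn > 0) n /= nn;
    fnorm.row(f) = n.t();
    max_edge = std::max(max_edge, arma::norm(b - a));
    max_edge = std::max(max_edge, arma::norm(c - b));
    max_edge = std::max(max_edge, arma::norm(a - c));
  }

  // hash vertices into a uniform grid of cells
  double cell = std::max(thickness + max_edge, 1e-6);
  arma::vec3 lo = arma::min(verts, 0).t() - 2 * cell;
  arma::vec3 hi = arma::max(verts, 0).t() + 2 * cell;
  int gx = (int)((hi(0) - lo(0)) / cell) + 1;
  int gy = (int)((hi(1) - lo(1)) / cell) + 1;
  int gz = (int)((hi(2) - lo(2)) / cell) + 1;
  std::vector<std::vector<int>> buckets((size_t)gx * gy * gz);
  auto cell_of = [&](const arma::vec3& p) -> long {
    int cx = (int)((p(0) - lo(0)) / cell);
    int cy = (int)((p(1) - lo(1)) / cell);
    int cz = (int)((p(2) - lo(2)) / cell);
    if (cx < 0 || cy < 0 || cz < 0 || cx >= gx || cy >= gy || cz >= gz)
      return -1;
    return cx + (long)gx * (cy + (long)gy * cz);
  };
  for (arma::uword v = 0; v < verts.n_rows; ++v) {
    long c = cell_of(verts.row(v).t());
    if (c >= 0) buckets[c].push_back((int)v);
  }

  // faces incident to each vertex
  std::vector<std::vector<int>> vfaces(verts.n_rows);
  for (arma::uword f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) vfaces[faces(f, k) - 1].push_back((int)f);

  std::vector<int> out_i, out_j, out_k, out_lab;
  std::vector<double> out_d;
  double reach = thickness + max_edge;  // vertices this close can own a face
                                        // whose surface is within thickness
  std::vector<char> fseen(nf, 0);
  std::vector<int> fstack;

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        arma::vec3 p;
        for (int r = 0; r < 3; ++r)
          p(r) = A(r, 0) * i + A(r, 1) * j + A(r, 2) * k + A(r, 3);
        long c0 = cell_of(p);
        if (c0 < 0) continue;
        int cx = (int)((p(0) - lo(0)) / cell);
        int cy = (int)((p(1) - lo(1)) / cell);
        int cz = (int)((p(2) - lo(2)) / cell);
        // collect candidate faces via nearby vertices
        fstack.clear();
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int ex = cx + dx, ey = cy + dy, ez = cz + dz;
              if (ex < 0 || ey < 0 || ez < 0 || ex >= gx || ey >= gy || ez >= gz)
                continue;
              const std::vector<int>& bk =
                  buckets[ex + (long)gx * (ey + (long)gy * ez)];
              for (int v : bk) {
                if (arma::norm(verts.row(v).t() - p) > reach) continue;
                for (int f : vfaces[v])
                  if (!fseen[f]) { fseen[f] = 1; fstack.push_back(f); }
              }
            }
        if (fstack.empty()) continue;
        double best_d2 = std::numeric_limits<double>::infinity();
        int best_f = -1;
        arma::vec3 best_q;
        for (int f : fstack) {
          fseen[f] = 0;  // reset for next voxel
          arma::vec3 a = verts.row(faces(f, 0) - 1).t();
          arma::vec3 b = verts.row(faces(f, 1) - 1).t();
          arma::vec3 cc = verts.row(faces(f, 2) - 1).t();
          arma::vec3 q = closest_on_triangle(p, a, b, cc);
          double d2 = arma::dot(p - q, p - q);
          if (d2 < best_d2) { best_d2 = d2; best_f = f; best_q = q; }
        }
        double d = std::sqrt(best_d2);
        if (d > thickness) continue;
        // inward side: opposite the outward face normal
        arma::vec3 off = p - best_q;
        if (arma::dot(off, fnorm.row(best_f).t()) >= 0 && d > 1e-12) continue;
        out_i.push_back(i); out_j.push_back(j); out_k.push_back(k);
        out_lab.push_back(face_label[best_f]);
        out_d.push_back(d);
      }

  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                      _["k"] = wrap(out_k), _["label"] = wrap(out_lab),
                      _["dist"] = wrap(out_d));
}
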