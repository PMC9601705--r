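#include <Rcpp.h>
#include <map>
#include <queue>
#include <vector>
#include <array>
#include <set>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Exact K nearest neighbours of each query point among the reference
// points, by squared Euclidean distance. Ties are broken by smaller
// reference index. Returns 1-based indices, K columns, distances
// non-decreasing along each row.
// [[Rcpp::export]]
IntegerMatrix cpp_knn_query(NumericMatrix query, NumericMatrix ref, int K) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (K > nr) stop("K (%d) exceeds the number of reference points (%d)", K, nr);
  IntegerMatrix out(nq, K);
  std::vector<std::pair<double, int>> d(nr);
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < nr; ++j) {
      const double dx = ref(j, 0) - qx, dy = ref(j, 1) - qy,
                   dz = ref(j, 2) - qz;
      d[j] = {dx * dx + dy * dy + dz * dz, j};
    }
    std::partial_sort(d.begin(), d.begin() + K, d.end());
    for (int k = 0; k < K; ++k) out(i, k) = d[k].second + 1;
  }
  return out;
}

// ---- quadric edge-collapse decimation ----------------------------------

namespace {

struct Quadric {
  // symmetric 4x4 quadric, stored as upper triangle (10 numbers)
  double q[10];
  Quadric() { std::fill(q, q + 10, 0.0); }
  void add_plane(double a, double b, double c, double d, double w) {
    q[0] += w * a * a; q[1] += w * a * b; q[2] += w * a * c; q[3] += w * a * d;
    q[4] += w * b * b; q[5] += w * b * c; q[6] += w * b * d;
    q[7] += w * c * c; q[8] += w * c * d;
    q[9] += w * d * d;
  }
  void add(const Quadric& o) { for (int i = 0; i < 10; ++i) q[i] += o.q[i]; }
  double eval(double x, double y, double z) const {
    return q[0]*x*x + 2*q[1]*x*y + 2*q[2]*x*z + 2*q[3]*x
         + q[4]*y*y + 2*q[5]*y*z + 2*q[6]*y
         + q[7]*z*z + 2*q[8]*z
         + q[9];
  }
};

struct HeapItem {
  double cost;
  int v1, v2;        // v1 < v2
  int stamp1, stamp2;
  bool operator<(const HeapItem& o) const { return cost > o.cost; }
};

} // namespace

// Decimate a triangular mesh to approximately target_faces faces using
// Garland-Heckbert quadric error metrics with edge collapses. Boundary
// edges receive penalty quadrics so open surfaces keep their rims. The
// collapsed vertex is placed at the endpoint or midpoint with the lowest
// quadric error. Returns the compacted vertex/face arrays plus, for each
// output face, the index of the input face it came from (for attribute
// transfer fallbacks).
// [[Rcpp::export]]
List cpp_decimate_qem(NumericMatrix V, IntegerMatrix F, int target_faces) {
  const int nv = V.nrow(), nf = F.nrow();
  if (target_faces < 4) stop("target_faces must be at least 4");
  if (target_faces >= nf)
    return List::create(_["vertices"] = V, _["faces"] = F,
                        _["kept"] = seq_len(nf));

  std::vector<double> vx(nv), vy(nv), vz(nv);
  for (int i = 0; i < nv; ++i) { vx[i] = V(i,0); vy[i] = V(i,1); vz[i] = V(i,2); }
  std::vector<std::array<int,3>> faces(nf);
  for (int i = 0; i < nf; ++i)
    faces[i] = { F(i,0) - 1, F(i,1) - 1, F(i,2) - 1 };

  std::vector<Quadric> Q(nv);
  std::vector<bool> face_alive(nf, true);
  std::vector<std::vector<int>> vfaces(nv);   // faces incident to a vertex

  // face plane quadrics
  for (int i = 0; i < nf; ++i) {
    const auto& f = faces[i];
    double ax = vx[f[1]] - vx[f[0]], ay = vy[f[1]] - vy[f[0]], az = vz[f[1]] - vz[f[0]];
    double bx = vx[f[2]] - vx[f[0]], by = vy[f[2]] - vy[f[0]], bz = vz[f[2]] - vz[f[0]];
    double nxv = ay * bz - az * by, nyv = az * bx - ax * bz, nzv = ax * by - ay * bx;
    double len = std::sqrt(nxv*nxv + nyv*nyv + nzv*nzv);
    double area = 0.5 * len;
    if (len < 1e-300) continue;
    nxv /= len; nyv /= len; nzv /= len;
    double d = -(nxv * vx[f[0]] + nyv * vy[f[0]] + nzv * vz[f[0]]);
    for (int j = 0; j < 3; ++j) {
      Q[f[j]].add_plane(nxv, nyv, nzv, d, area);
      vfaces[f[j]].push_back(i);
    }
  }

  // boundary edges: count edge occurrences
  std::map<std::pair<int,int>, std::pair<int,int>> edge_count; // edge -> (count, face)
  for (int i = 0; i < nf; ++i) {
    const auto& f = faces[i];
    for (int j = 0; j < 3; ++j) {
      int a = f[j], b = f[(j + 1) % 3];
      if (a > b) std::swap(a, b);
      auto& e = edge_count[{a, b}];
      e.first++; e.second = i;
    }
  }
  for (auto& kv : edge_count) {
    if (kv.second.first != 1) continue;     // interior edge
    int a = kv.first.first, b = kv.first.second, fi = kv.second.second;
    const auto& f = faces[fi];
    // plane through the edge, perpendicular to the face
    double ex = vx[b]-vx[a], ey = vy[b]-vy[a], ez = vz[b]-vz[a];
    double ax2 = vx[f[1]]-vx[f[0]], ay2 = vy[f[1]]-vy[f[0]], az2 = vz[f[1]]-vz[f[0]];
    double bx2 = vx[f[2]]-vx[f[0]], by2 = vy[f[2]]-vy[f[0]], bz2 = vz[f[2]]-vz[f[0]];
    double fnx = ay2*bz2 - az2*by2, fny = az2*bx2 - ax2*bz2, fnz = ax2*by2 - ay2*bx2;
    double px = ey*fnz - ez*fny, py = ez*fnx - ex*fnz, pz = ex*fny - ey*fnx;
    double len = std::sqrt(px*px + py*py + pz*pz);
    if (len < 1e-300) continue;
    px /= len; py /= len; pz /= len;
    double d = -(px*vx[a] + py*vy[a] + pz*vz[a]);
    double w = 1e3 * (ex*ex + ey*ey + ez*ez);  // strong rim preservation
    Q[a].add_plane(px, py, pz, d, w);
    Q[b].add_plane(px, py, pz, d, w);
  }

  std::vector<int> stamp(nv, 0);
  std::vector<bool> v_alive(nv, true);
  std::priority_queue<HeapItem> heap;

  auto best_cost = [&](int a, int b, double& ox, double& oy, double& oz) {
    Quadric s = Q[a]; s.add(Q[b]);
    double c1 = s.eval(vx[a], vy[a], vz[a]);
    double c2 = s.eval(vx[b], vy[b], vz[b]);
    double mx = 0.5*(vx[a]+vx[b]), my = 0.5*(vy[a]+vy[b]), mz = 0.5*(vz[a]+vz[b]);
    double cm = s.eval(mx, my, mz);
    if (c1 <= c2 && c1 <= cm) { ox = vx[a]; oy = vy[a]; oz = vz[a]; return c1; }
    if (c2 <= cm)             { ox = vx[b]; oy = vy[b]; oz = vz[b]; return c2; }
    ox = mx; oy = my; oz = mz; return cm;
  };

  auto push_edge = [&](int a, int b) {
    if (a > b) std::swap(a, b);
    double ox, oy, oz;
    double c = best_cost(a, b, ox, oy, oz);
    heap.push({c, a, b, stamp[a], stamp[b]});
  };

  for (auto& kv : edge_count) push_edge(kv.first.first, kv.first.second);

  int alive_faces = nf;
  auto vertex_of_face = [&](int fi, int j) { return faces[fi][j]; };

  while (alive_faces > target_faces && !heap.empty()) {
    HeapItem it = heap.top(); heap.pop();
    int a = it.v1, b = it.v2;
    if (!v_alive[a] || !v_alive[b]) continue;
    if (it.stamp1 != stamp[a] || it.stamp2 != stamp[b]) continue; // stale

    // link condition: every common neighbour of a and b must be the third
    // vertex of a face containing the edge (a,b), else collapsing pinches
    // the surface into a non-manifold configuration
    std::set<int> na, third;
    for (int fi : vfaces[a]) if (face_alive[fi])
      for (int j = 0; j < 3; ++j) { int v = vertex_of_face(fi, j);
        if (v != a && v != b) na.insert(v); }
    int shared_faces = 0;
    bool pinch = false;
    std::set<int> nb;
    for (int fi : vfaces[b]) if (face_alive[fi]) {
      bool has_a = false;
      for (int j = 0; j < 3; ++j) if (vertex_of_face(fi, j) == a) has_a = true;
      for (int j = 0; j < 3; ++j) { int v = vertex_of_face(fi, j);
        if (v != a && v != b) { if (has_a) third.insert(v); nb.insert(v); } }
      if (has_a) shared_faces++;
    }
    if (shared_faces == 0) continue;       // a,b no longer share a face
    for (int v : nb)
      if (na.count(v) && !third.count(v)) { pinch = true; break; }
    if (pinch) continue;

    double ox, oy, oz;
    best_cost(a, b, ox, oy, oz);

    // collapse b into a, move a to the optimal position
    vx[a] = ox; vy[a] = oy; vz[a] = oz;
    Q[a].add(Q[b]);
    v_alive[b] = false;

    for (int fi : vfaces[b]) {
      if (!face_alive[fi]) continue;
      auto& f = faces[fi];
      bool has_a = false;
      for (int j = 0; j < 3; ++j) if (f[j] == a) has_a = true;
      if (has_a) { face_alive[fi] = false; alive_faces--; continue; }
      for (int j = 0; j < 3; ++j) if (f[j] == b) f[j] = a;
      vfaces[a].push_back(fi);
    }
    vfaces[b].clear();

    stamp[a]++;
    // re-queue edges around a
    std::set<int> nbrs;
    for (int fi : vfaces[a]) if (face_alive[fi])
      for (int j = 0; j < 3; ++j) { int v = vertex_of_face(fi, j);
        if (v != a) nbrs.insert(v); }
    for (int v : nbrs) push_edge(a, v);
  }

  // compact
  std::vector<int> vmap(nv, -1);
  int nv_out = 0;
  for (int i = 0; i < nv; ++i) if (v_alive[i]) vmap[i] = nv_out++;
  int nf_out = 0;
  for (int i = 0; i < nf; ++i) if (face_alive[i]) nf_out++;

  NumericMatrix Vout(nv_out, 3);
  for (int i = 0; i < nv; ++i) if (vmap[i] >= 0) {
    Vout(vmap[i], 0) = vx[i]; Vout(vmap[i], 1) = vy[i]; Vout(vmap[i], 2) = vz[i];
  }
  IntegerMatrix Fout(nf_out, 3);
  IntegerVector kept(nf_out);
  int r = 0;
  for (int i = 0; i < nf; ++i) if (face_alive[i]) {
    for (int j = 0; j < 3; ++j) Fout(r, j) = vmap[faces[i][j]] + 1;
    kept[r] = i + 1;
    ++r;
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout,
                      _["kept"] = kept);
}

// ---- fused elementwise kernels for the network hot path ----------------

// [[Rcpp::export]]
NumericMatrix cpp_relu(NumericMatrix x) {
  const int n = x.nrow() * x.ncol();
  NumericMatrix y(x.nrow(), x.ncol());
  const double* xv = x.begin(); double* yv = y.begin();
  for (int i = 0; i < n; ++i) yv[i] = xv[i] > 0 ? xv[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_relu_backward(NumericMatrix gr, NumericMatrix y) {
  const int n = gr.nrow() * gr.ncol();
  NumericMatrix dx(gr.nrow(), gr.ncol());
  const double* g = gr.begin(); const double* yv = y.begin();
  double* d = dx.begin();
  for (int i = 0; i < n; ++i) d[i] = yv[i] > 0 ? g[i] : 0.0;
  return dx;
}

// column-wise softmax over each contiguous block of K rows
// [[Rcpp::export]]
NumericMatrix cpp_group_softmax(NumericMatrix x, int K) {
  const int n = x.nrow(), c = x.ncol(), ng = n / K;
  NumericMatrix y(n, c);
  for (int j = 0; j < c; ++j) {
    const double* xv = &x(0, j);
    double* yv = &y(0, j);
    for (int gId = 0; gId < ng; ++gId) {
      const int off = gId * K;
      double m = xv[off];
      for (int k = 1; k < K; ++k) if (xv[off + k] > m) m = xv[off + k];
      double s = 0.0;
      for (int k = 0; k < K; ++k) { yv[off + k] = std::exp(xv[off + k] - m); s += yv[off + k]; }
      for (int k = 0; k < K; ++k) yv[off + k] /= s;
    }
  }
  return y;
}

// backward of the grouped softmax: dx = s * (g - sum_k(g*s))
// [[Rcpp::export]]
NumericMatrix cpp_group_softmax_backward(NumericMatrix gr, NumericMatrix soft,
                                         int K) {
  const int n = gr.nrow(), c = gr.ncol(), ng = n / K;
  NumericMatrix dx(n, c);
  for (int j = 0; j < c; ++j) {
    const double* g = &gr(0, j);
    const double* s = &soft(0, j);
    double* d = &dx(0, j);
    for (int gId = 0; gId < ng; ++gId) {
      const int off = gId * K;
      double t = 0.0;
      for (int k = 0; k < K; ++k) t += g[off + k] * s[off + k];
      for (int k = 0; k < K; ++k) d[off + k] = s[off + k] * (g[off + k] - t);
    }
  }
  return dx;
}

// sum of each contiguous block of K rows -> (n/K) x c
// [[Rcpp::export]]
NumericMatrix cpp_group_rowsum(NumericMatrix x, int K) {
  const int n = x.nrow(), c = x.ncol(), ng = n / K;
  NumericMatrix y(ng, c);
  for (int j = 0; j < c; ++j) {
    const double* xv = &x(0, j);
    double* yv = &y(0, j);
    for (int gId = 0; gId < ng; ++gId) {
      const int off = gId * K;
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += xv[off + k];
      yv[gId] = s;
    }
  }
  return y;
}

// expand rows: y[(i-1)*K + k, ] = x[i, ]  (backward of group_rowsum)
// [[Rcpp::export]]
NumericMatrix cpp_group_expand(NumericMatrix x, int K) {
  const int ng = x.nrow(), c = x.ncol();
  NumericMatrix y(ng * K, c);
  for (int j = 0; j < c; ++j) {
    const double* xv = &x(0, j);
    double* yv = &y(0, j);
    for (int gId = 0; gId < ng; ++gId)
      for (int k = 0; k < K; ++k) yv[gId * K + k] = xv[gId];
  }
  return y;
}

// gather rows: y[r, ] = x[idx[r], ] (idx 1-based)
// [[Rcpp::export]]
NumericMatrix cpp_gather_rows(NumericMatrix x, IntegerVector idx) {
  const int m = idx.size(), c = x.ncol();
  NumericMatrix y(m, c);
  for (int j = 0; j < c; ++j) {
    const double* xv = &x(0, j);
    double* yv = &y(0, j);
    for (int r = 0; r < m; ++r) yv[r] = xv[idx[r] - 1];
  }
  return y;
}

// scatter-add rows: out[idx[r], ] += gr[r, ], out has n rows
// [[Rcpp::export]]
NumericMatrix cpp_scatter_add_rows(NumericMatrix gr, IntegerVector idx, int n) {
  const int m = idx.size(), c = gr.ncol();
  NumericMatrix y(n, c);
  for (int j = 0; j < c; ++j) {
    const double* g = &gr(0, j);
    double* yv = &y(0, j);
    for (int r = 0; r < m; ++r) yv[idx[r] - 1] += g[r];
  }
  return y;
}

// fused batch-norm (+ optional ReLU) forward: given the linear output xw and
// the normalization constants, return the activation y and the normalized
// input xhat (kept for the backward pass)
// [[Rcpp::export]]
List cpp_bn_act_forward(NumericMatrix xw, NumericVector mu, NumericVector inv,
                        NumericVector gv, NumericVector bv, bool relu) {
  const int n = xw.nrow(), c = xw.ncol();
  NumericMatrix y(n, c), xhat(n, c);
  for (int j = 0; j < c; ++j) {
    const double m = mu[j], iv = inv[j], gj = gv[j], bj = bv[j];
    const double* x = &xw(0, j);
    double* yj = &y(0, j);
    double* xh = &xhat(0, j);
    for (int i = 0; i < n; ++i) {
      const double h = (x[i] - m) * iv;
      xh[i] = h;
      double v = h * gj + bj;
      if (relu && v < 0) v = 0;
      yj[i] = v;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// fused backward of (optional ReLU) -> batch norm, in one pass
// [[Rcpp::export]]
List cpp_bn_act_backward(NumericMatrix gr, NumericMatrix y, NumericMatrix xhat,
                         NumericVector gv, NumericVector inv,
                         bool batch_stats, bool relu) {
  const int n = gr.nrow(), c = gr.ncol();
  NumericMatrix dx(n, c);
  NumericVector dgamma(c), dbeta(c);
  std::vector<double> gtmp(n);
  for (int j = 0; j < c; ++j) {
    const double* g0 = &gr(0, j);
    const double* yj = &y(0, j);
    const double* xh = &xhat(0, j);
    double sg = 0.0, sgx = 0.0;
    for (int i = 0; i < n; ++i) {
      const double gi = (relu && yj[i] <= 0) ? 0.0 : g0[i];
      gtmp[i] = gi;
      sg += gi; sgx += gi * xh[i];
    }
    dgamma[j] = sgx; dbeta[j] = sg;
    const double a = gv[j] * inv[j];
    double* d = &dx(0, j);
    if (batch_stats) {
      const double m1 = sg / n, m2 = sgx / n;
      for (int i = 0; i < n; ++i) d[i] = (gtmp[i] - m1 - xh[i] * m2) * a;
    } else {
      for (int i = 0; i < n; ++i) d[i] = gtmp[i] * a;
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// column means and (biased) variances in one pass
// [[Rcpp::export]]
List cpp_col_mean_var(NumericMatrix x) {
  const int n = x.nrow(), c = x.ncol();
  NumericVector mu(c), v(c);
  for (int j = 0; j < c; ++j) {
    const double* xj = &x(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i];
    const double m = s / n;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) { const double d = xj[i] - m; ss += d * d; }
    mu[j] = m; v[j] = ss / n;
  }
  return List::create(_["mean"] = mu, _["var"] = v);
}

// fused attention aggregation: column-wise softmax of the scores over each
// contiguous block of K rows, then the softmax-weighted sum of the feature
// slots. Returns the aggregate (n/K x c) and the softmax (kept for backward).
// [[Rcpp::export]]
List cpp_attend_forward(NumericMatrix fhat, NumericMatrix scores, int K) {
  const int n = fhat.nrow(), c = fhat.ncol(), ng = n / K;
  NumericMatrix agg(ng, c), soft(n, c);
  for (int j = 0; j < c; ++j) {
    const double* f = &fhat(0, j);
    const double* sc = &scores(0, j);
    double* s = &soft(0, j);
    double* a = &agg(0, j);
    for (int gId = 0; gId < ng; ++gId) {
      const int off = gId * K;
      double m = sc[off];
      for (int k = 1; k < K; ++k) if (sc[off + k] > m) m = sc[off + k];
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { s[off + k] = std::exp(sc[off + k] - m); tot += s[off + k]; }
      double acc = 0.0;
      for (int k = 0; k < K; ++k) { s[off + k] /= tot; acc += f[off + k] * s[off + k]; }
      a[gId] = acc;
    }
  }
  return List::create(_["agg"] = agg, _["soft"] = soft);
}

// backward of the fused attention aggregation
// [[Rcpp::export]]
List cpp_attend_backward(NumericMatrix gr, NumericMatrix fhat,
                         NumericMatrix soft, int K) {
  const int n = fhat.nrow(), c = fhat.ncol(), ng = n / K;
  NumericMatrix dfhat(n, c), dscores(n, c);
  for (int j = 0; j < c; ++j) {
    const double* g = &gr(0, j);
    const double* f = &fhat(0, j);
    const double* s = &soft(0, j);
    double* df = &dfhat(0, j);
    double* ds = &dscores(0, j);
    for (int gId = 0; gId < ng; ++gId) {
      const int off = gId * K;
      const double gi = g[gId];
      double t = 0.0;
      for (int k = 0; k < K; ++k) {
        df[off + k] = gi * s[off + k];
        ds[off + k] = gi * f[off + k];          // dL/ds before softmax jac
        t += ds[off + k] * s[off + k];
      }
      for (int k = 0; k < K; ++k)
        ds[off + k] = s[off + k] * (ds[off + k] - t);
    }
  }
  return List::create(_["dfhat"] = dfhat, _["dscores"] = dscores);
}

// fused neighbour gather + column concat: y = [ a , b[idx, ] ]
// [[Rcpp::export]]
NumericMatrix cpp_gather_concat(NumericMatrix a, NumericMatrix b,
                                IntegerVector idx) {
  const int n = a.nrow(), ca = a.ncol(), cb = b.ncol();
  NumericMatrix y(n, ca + cb);
  std::copy(a.begin(), a.end(), y.begin());
  for (int j = 0; j < cb; ++j) {
    const double* bj = &b(0, j);
    double* yj = &y(0, ca + j);
    for (int r = 0; r < n; ++r) yj[r] = bj[idx[r] - 1];
  }
  return y;
}
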