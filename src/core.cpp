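// Compiled kernels: 3D connected-component labelling, threshold-free
// cluster enhancement (dense and graph forms), trilinear resampling and
// Hessian principal directions. These are the inner loops of the skeleton
// statistics and registration code.
#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---- neighbourhood offsets -------------------------------------------------

static void neighbour_offsets(int connectivity, int nx, int ny,
                              std::vector<int>& di, std::vector<int>& dj,
                              std::vector<int>& dk) {
  di.clear(); dj.clear(); dk.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  (void)nx; (void)ny;
}

// ---- plain union-find ------------------------------------------------------

struct UF {
  std::vector<int> parent, sz;
  void init(int n) {
    parent.resize(n); sz.assign(n, 1);
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    int r = x;
    while (parent[r] != r) r = parent[r];
    while (parent[x] != r) { int nx_ = parent[x]; parent[x] = r; x = nx_; }
    return r;
  }
  int unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return a;
    if (sz[a] < sz[b]) std::swap(a, b);
    parent[b] = a; sz[a] += sz[b];
    return a;
  }
};

// 26- (or 6-) connected component labels of a logical 3D mask.
// Returns integer labels, 0 outside the mask, components numbered from 1
// in raster order of their first voxel.
// [[Rcpp::export]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims,
                       int connectivity = 26) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  UF uf; uf.init(n);
  std::vector<int> di, dj, dk;
  neighbour_offsets(connectivity, nx, ny, di, dj, dk);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int idx = i + nx * (j + ny * k);
        if (!mask[idx]) continue;
        for (size_t m = 0; m < di.size(); ++m) {
          int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          int nidx = ii + nx * (jj + ny * kk);
          if (mask[nidx]) uf.unite(idx, nidx);
        }
      }
  IntegerVector lab(n, 0);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int idx = 0; idx < n; ++idx) {
    if (!mask[idx]) continue;
    int r = uf.find(idx);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; lab[idx] = next; }
    else lab[idx] = it->second;
  }
  return lab;
}

// Edge list (0-based, a < b as positions within vox) connecting the given
// voxels (0-based linear indices into a dims grid) under the connectivity.
// [[Rcpp::export]]
List build_adjacency(IntegerVector vox, IntegerVector dims,
                     int connectivity = 26) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = vox.size();
  std::unordered_map<int, int> pos;
  pos.reserve(n * 2);
  for (int i = 0; i < n; ++i) pos[vox[i]] = i;
  std::vector<int> di, dj, dk;
  neighbour_offsets(connectivity, nx, ny, di, dj, dk);
  std::vector<int> ea, eb;
  for (int p = 0; p < n; ++p) {
    int idx = vox[p];
    int i = idx % nx, j = (idx / nx) % ny, k = idx / (nx * ny);
    for (size_t m = 0; m < di.size(); ++m) {
      int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      auto it = pos.find(ii + nx * (jj + ny * kk));
      if (it != pos.end() && it->second > p) {
        ea.push_back(p); eb.push_back(it->second);
      }
    }
  }
  return List::create(_["a"] = wrap(ea), _["b"] = wrap(eb));
}

// ---- TFCE on a voxel graph -------------------------------------------------
//
// Weighted union-find: thresholds descend, voxels activate in height order
// and merge; each root carries the enhancement accumulated by its current
// component, and merge-time offsets keep per-voxel totals exact.

struct WUF {
  std::vector<int> parent, sz;
  std::vector<double> delta, acc; // delta: offset to parent; acc: roots only
  void init(int n) {
    parent.resize(n); sz.assign(n, 0);
    delta.assign(n, 0.0); acc.assign(n, 0.0);
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x, double& off) {
    // returns root; off accumulates delta along (compressed) path
    if (parent[x] == x) { off = 0.0; return x; }
    double d;
    int r = find(parent[x], d);
    delta[x] += d;
    parent[x] = r;
    off = delta[x];
    return r;
  }
};

static void tfce_graph_core(const double* stat, int n,
                            const int* ea, const int* eb, int nedge,
                            double E, double H, double dh, int nsteps,
                            double* out) {
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });
  // adjacency lists
  std::vector<int> deg(n, 0);
  for (int e = 0; e < nedge; ++e) { deg[ea[e]]++; deg[eb[e]]++; }
  std::vector<int> start(n + 1, 0);
  for (int i = 0; i < n; ++i) start[i + 1] = start[i] + deg[i];
  std::vector<int> adj(start[n]);
  std::vector<int> fill(start.begin(), start.end() - 1);
  for (int e = 0; e < nedge; ++e) {
    adj[fill[ea[e]]++] = eb[e];
    adj[fill[eb[e]]++] = ea[e];
  }
  WUF uf; uf.init(n);
  std::vector<char> active(n, 0);
  std::vector<int> roots; roots.reserve(256);
  int next = 0; // next voxel (in height order) to activate
  for (int t = nsteps; t >= 1; --t) {
    double h = t * dh;
    while (next < n && stat[order[next]] >= h) {
      int v = order[next++];
      active[v] = 1;
      uf.sz[v] = 1;
      roots.push_back(v);
      for (int m = start[v]; m < start[v + 1]; ++m) {
        int w = adj[m];
        if (!active[w]) continue;
        double offv, offw;
        int rv = uf.find(v, offv), rw = uf.find(w, offw);
        if (rv == rw) continue;
        // larger component survives as root
        int big = rv, small = rw;
        if (uf.sz[big] < uf.sz[small]) std::swap(big, small);
        uf.parent[small] = big;
        uf.delta[small] = uf.acc[small] - uf.acc[big];
        uf.sz[big] += uf.sz[small];
      }
    }
    if (roots.empty()) continue;
    // drop stale roots, accumulate on live ones
    size_t keep = 0;
    double hH = std::pow(h, H) * dh;
    for (size_t r = 0; r < roots.size(); ++r) {
      int x = roots[r];
      if (uf.parent[x] != x) continue;
      uf.acc[x] += std::pow((double)uf.sz[x], E) * hH;
      roots[keep++] = x;
    }
    roots.resize(keep);
  }
  for (int i = 0; i < n; ++i) {
    if (!active[i]) { out[i] = 0.0; continue; }
    double off;
    int r = uf.find(i, off);
    out[i] = uf.acc[r] + (i == r ? 0.0 : off);
  }
}

// TFCE of a stat vector over an explicit voxel graph (0-based edge list).
// Only positive support is enhanced; dh <= 0 means max(stat)/nsteps.
// [[Rcpp::export]]
NumericVector tfce_graph(NumericVector stat, IntegerVector ea,
                         IntegerVector eb, double E, double H,
                         double dh = -1.0, int nsteps = 100) {
  int n = stat.size();
  NumericVector out(n);
  double mx = 0.0;
  for (int i = 0; i < n; ++i) mx = std::max(mx, stat[i]);
  if (mx <= 0.0) return out;
  double step = dh;
  int ns = nsteps;
  if (step <= 0.0) step = mx / nsteps;
  else ns = (int)std::floor(mx / step + 1e-12);
  if (ns < 1) ns = 1;
  std::vector<double> s(n);
  for (int i = 0; i < n; ++i) s[i] = std::max(0.0, (double)stat[i]);
  tfce_graph_core(s.data(), n, ea.begin(), eb.begin(), ea.size(),
                  E, H, step, ns, REAL(out));
  return out;
}

// Max TFCE score per row of a permutation stat matrix (rows = permutations,
// columns = skeleton voxels); enhances the positive tail only. dh is taken
// per row as rowmax/nsteps, the convention of per-image normalised steps.
// [[Rcpp::export]]
NumericVector tfce_graph_max_batch(NumericMatrix stats, IntegerVector ea,
                                   IntegerVector eb, double E, double H,
                                   int nsteps = 100) {
  int nperm = stats.nrow(), n = stats.ncol();
  NumericVector mx(nperm);
  std::vector<double> s(n), out(n);
  for (int p = 0; p < nperm; ++p) {
    double rowmax = 0.0;
    for (int i = 0; i < n; ++i) {
      s[i] = std::max(0.0, stats(p, i));
      rowmax = std::max(rowmax, s[i]);
    }
    if (rowmax <= 0.0) { mx[p] = 0.0; continue; }
    double dh = rowmax / nsteps;
    tfce_graph_core(s.data(), n, ea.begin(), eb.begin(), ea.size(),
                    E, H, dh, nsteps, out.data());
    mx[p] = *std::max_element(out.begin(), out.end());
  }
  return mx;
}

// ---- trilinear resampling --------------------------------------------------

// Resample src (dims sdims) onto a target grid (dims tdims) through M, a
// 4x4 matrix sending 0-based target voxel indices to 0-based fractional
// source indices. Missing-valued corners are excluded from interpolation
// (weights renormalised); an all-missing neighbourhood or out-of-field
// voxel receives `background`.
// [[Rcpp::export]]
NumericVector resample_affine(NumericVector src, IntegerVector sdims,
                              NumericMatrix M, IntegerVector tdims,
                              double background = 0.0,
                              bool has_missing = false,
                              double missing = -1.0,
                              bool nearest = false) {
  int sx = sdims[0], sy = sdims[1], sz = sdims[2];
  int tx = tdims[0], ty = tdims[1], tz = tdims[2];
  NumericVector out((R_xlen_t)tx * ty * tz);
  double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  R_xlen_t o = 0;
  for (int k = 0; k < tz; ++k)
    for (int j = 0; j < ty; ++j)
      for (int i = 0; i < tx; ++i, ++o) {
        double x = m00 * i + m01 * j + m02 * k + m03;
        double y = m10 * i + m11 * j + m12 * k + m13;
        double z = m20 * i + m21 * j + m22 * k + m23;
        if (nearest) {
          int ii = (int)std::lround(x), jj = (int)std::lround(y),
              kk = (int)std::lround(z);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= sx || jj >= sy || kk >= sz)
            { out[o] = background; continue; }
          out[o] = src[ii + (R_xlen_t)sx * (jj + (R_xlen_t)sy * kk)];
          continue;
        }
        if (x < 0 || y < 0 || z < 0 || x > sx - 1 || y > sy - 1 || z > sz - 1)
          { out[o] = background; continue; }
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
        if (x0 == sx - 1) x0--;
        if (y0 == sy - 1) y0--;
        if (z0 == sz - 1) z0--;
        double fx = x - x0, fy = y - y0, fz = z - z0;
        double vsum = 0.0, wsum = 0.0;
        bool any_missing = false;
        for (int c = 0; c < 8; ++c) {
          int dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
          double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                     (dz ? fz : 1 - fz);
          if (w <= 0.0) continue;
          double v = src[(x0 + dx) +
                         (R_xlen_t)sx * ((y0 + dy) + (R_xlen_t)sy * (z0 + dz))];
          if (has_missing && v == missing) { any_missing = true; continue; }
          vsum += w * v; wsum += w;
        }
        if (wsum <= 0.0) out[o] = has_missing && any_missing ? missing
                                                             : background;
        else out[o] = vsum / wsum;
      }
  return out;
}

// ---- Hessian principal directions ------------------------------------------

// For each voxel in `idx` (0-based linear indices), the two
// largest-|eigenvalue| eigenvectors of the local Hessian of `img`
// (central differences, voxel units), plus a tube flag set when the two
// leading |eigenvalues| are comparable (perpendicular direction
// degenerate, as on a tube centerline).
// [[Rcpp::export]]
List hessian_eigensystem(NumericVector img, IntegerVector dims,
                         IntegerVector idx) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = idx.size();
  NumericMatrix dir1(n, 3), dir2(n, 3);
  LogicalVector tube(n);
  arma::mat33 Hm;
  arma::vec eval; arma::mat evec;
  auto at = [&](int i, int j, int k) -> double {
    if (i < 0) i = 0; if (i >= nx) i = nx - 1;
    if (j < 0) j = 0; if (j >= ny) j = ny - 1;
    if (k < 0) k = 0; if (k >= nz) k = nz - 1;
    return img[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
  };
  for (int p = 0; p < n; ++p) {
    int v = idx[p];
    int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
    double c = at(i, j, k);
    Hm(0,0) = at(i+1,j,k) - 2*c + at(i-1,j,k);
    Hm(1,1) = at(i,j+1,k) - 2*c + at(i,j-1,k);
    Hm(2,2) = at(i,j,k+1) - 2*c + at(i,j,k-1);
    Hm(0,1) = Hm(1,0) = (at(i+1,j+1,k) - at(i+1,j-1,k)
                         - at(i-1,j+1,k) + at(i-1,j-1,k)) / 4.0;
    Hm(0,2) = Hm(2,0) = (at(i+1,j,k+1) - at(i+1,j,k-1)
                         - at(i-1,j,k+1) + at(i-1,j,k-1)) / 4.0;
    Hm(1,2) = Hm(2,1) = (at(i,j+1,k+1) - at(i,j+1,k-1)
                         - at(i,j-1,k+1) + at(i,j-1,k-1)) / 4.0;
    arma::eig_sym(eval, evec, Hm);
    // order eigenvalues by |value| descending
    arma::uvec ord = arma::sort_index(arma::abs(eval), "descend");
    for (int d = 0; d < 3; ++d) {
      dir1(p, d) = evec(d, ord(0));
      dir2(p, d) = evec(d, ord(1));
    }
    double a1 = std::abs(eval(ord(0))), a2 = std::abs(eval(ord(1)));
    tube[p] = (a1 > 0) && (a2 / a1 > 0.5);
  }
  return List::create(_["dir1"] = dir1, _["dir2"] = dir2,
                      _["tube_like"] = tube);
}
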