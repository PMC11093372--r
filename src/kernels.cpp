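// Low-level voxel kernels: separable Gaussian filtering, connected
// components, topology-preserving thinning, capsule rasterization.
// All volumes are passed as flat vectors in R array (column-major)
// order with dims = c(nx, ny, nz); linear index = i + nx*(j + ny*k).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur with reflective boundaries. sigma in voxel units,
// one value per axis; sigma <= 0 leaves that axis untouched.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dims,
                          NumericVector sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n[3] = {nx, ny, nz};
  std::vector<double> cur(vol.begin(), vol.end());
  std::vector<double> out(cur.size());

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    if (r < 1) r = 1;
    std::vector<double> ker(2 * r + 1);
    double sum = 0;
    for (int t = -r; t <= r; ++t) {
      ker[t + r] = std::exp(-0.5 * (double)t * t / (s * s));
      sum += ker[t + r];
    }
    for (double &w : ker) w /= sum;

    int len = n[ax];
    // strides
    long sx = 1, sy = nx, sz = (long)nx * ny;
    long stride = (ax == 0) ? sx : (ax == 1) ? sy : sz;
    std::vector<double> line(len);
    // iterate over all lines along axis ax
    int a1 = (ax == 0) ? ny : nx;
    int a2 = (ax == 2) ? ny : nz;
    long st1 = (ax == 0) ? sy : sx;
    long st2 = (ax == 2) ? sy : sz;
    for (int b = 0; b < a2; ++b) {
      for (int a = 0; a < a1; ++a) {
        long base = a * st1 + b * st2;
        for (int t = 0; t < len; ++t) line[t] = cur[base + t * stride];
        for (int t = 0; t < len; ++t) {
          double acc = 0;
          for (int u = -r; u <= r; ++u) {
            int p = t + u;
            if (p < 0) p = -p - 1;            // reflect
            if (p >= len) p = 2 * len - p - 1;
            if (p < 0) p = 0;                 // tiny axes
            if (p >= len) p = len - 1;
            acc += ker[u + r] * line[p];
          }
          out[base + t * stride] = acc;
        }
      }
    }
    std::swap(cur, out);
  }
  NumericVector res(cur.begin(), cur.end());
  res.attr("dim") = dims;
  return res;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (26- or 6-connectivity).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long ntot = (long)nx * ny * nz;
  IntegerVector lab(ntot, 0);
  std::vector<long> stack;
  int next = 0;

  // neighbour offsets
  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && m != 1) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  int nn = dx.size();

  for (long s = 0; s < ntot; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      long v = stack.back(); stack.pop_back();
      int i = v % nx, j = (v / nx) % ny, k = v / ((long)nx * ny);
      for (int t = 0; t < nn; ++t) {
        int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        long w = lin(ii, jj, kk, nx, ny);
        if (mask[w] && lab[w] == 0) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---------------------------------------------------------------------------
// Number of foreground voxels among the 26 neighbours, for every voxel.
// [[Rcpp::export]]
IntegerVector cpp_count_neighbors(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long ntot = (long)nx * ny * nz;
  IntegerVector cnt(ntot, 0);
  for (long s = 0; s < ntot; ++s) {
    int i = s % nx, j = (s / nx) % ny, k = s / ((long)nx * ny);
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (!a && !b && !c) continue;
          int ii = i + a, jj = j + b, kk = k + c;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          if (mask[lin(ii, jj, kk, nx, ny)]) ++cnt[s];
        }
  }
  cnt.attr("dim") = dims;
  return cnt;
}

// ---------------------------------------------------------------------------
// Simple-point test on a 3x3x3 neighbourhood (cube[27], index
// (a+1) + 3*(b+1) + 9*(c+1)); cube[13] is the centre and must be true.
// A voxel is simple iff (i) its 26-neighbourhood foreground (centre
// excluded) has exactly one 26-connected component, and (ii) the
// background restricted to the 18-neighbourhood has exactly one
// 6-connected component that is 6-adjacent to the centre.
static bool is_simple(const bool cube[27]) {
  // condition (i)
  int compFG = 0;
  bool seen[27] = {false};
  int st[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !cube[s] || seen[s]) continue;
    ++compFG;
    if (compFG > 1) return false;
    int top = 0; st[top++] = s; seen[s] = true;
    while (top) {
      int v = st[--top];
      int va = v % 3, vb = (v / 3) % 3, vc = v / 9;
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c) {
            if (!a && !b && !c) continue;
            int wa = va + a, wb = vb + b, wc = vc + c;
            if (wa < 0 || wb < 0 || wc < 0 || wa > 2 || wb > 2 || wc > 2)
              continue;
            int w = wa + 3 * wb + 9 * wc;
            if (w == 13 || !cube[w] || seen[w]) continue;
            seen[w] = true; st[top++] = w;
          }
    }
  }
  if (compFG != 1) return false;

  // condition (ii): background 6-components within N18, 6-adjacent to centre
  bool inN18[27];
  for (int s = 0; s < 27; ++s) {
    int a = s % 3 - 1, b = (s / 3) % 3 - 1, c = s / 9 - 1;
    int m = std::abs(a) + std::abs(b) + std::abs(c);
    inN18[s] = (m == 1 || m == 2);
  }
  bool seenB[27] = {false};
  int compBG = 0;
  for (int s = 0; s < 27; ++s) {
    int a = s % 3 - 1, b = (s / 3) % 3 - 1, c = s / 9 - 1;
    if (std::abs(a) + std::abs(b) + std::abs(c) != 1) continue; // face nbr
    if (cube[s] || seenB[s]) continue;
    ++compBG;
    if (compBG > 1) return false;
    int top = 0; st[top++] = s; seenB[s] = true;
    while (top) {
      int v = st[--top];
      int va = v % 3, vb = (v / 3) % 3, vc = v / 9;
      const int f[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int t = 0; t < 6; ++t) {
        int wa = va + f[t][0], wb = vb + f[t][1], wc = vc + f[t][2];
        if (wa < 0 || wb < 0 || wc < 0 || wa > 2 || wb > 2 || wc > 2) continue;
        int w = wa + 3 * wb + 9 * wc;
        if (w == 13 || !inN18[w] || cube[w] || seenB[w]) continue;
        seenB[w] = true; st[top++] = w;
      }
    }
  }
  return compBG == 1;
}

// ---------------------------------------------------------------------------
// Topology-preserving curve thinning: sequentially delete simple border
// points (six directional sub-iterations per pass), never deleting curve
// end points (exactly one 26-neighbour) or isolated voxels, until stable.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long ntot = (long)nx * ny * nz;
  std::vector<char> v(ntot);
  for (long s = 0; s < ntot; ++s) v[s] = mask[s] ? 1 : 0;

  const int dirs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  bool cube[27];
  std::vector<long> cand;

  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (long s = 0; s < ntot; ++s) {
        if (!v[s]) continue;
        int i = s % nx, j = (s / nx) % ny, k = s / ((long)nx * ny);
        int ii = i + dirs[d][0], jj = j + dirs[d][1], kk = k + dirs[d][2];
        bool bg = (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                   kk >= nz) ? true : !v[lin(ii, jj, kk, nx, ny)];
        if (bg) cand.push_back(s);
      }
      for (long s : cand) {
        if (!v[s]) continue;
        int i = s % nx, j = (s / nx) % ny, k = s / ((long)nx * ny);
        // recheck border in direction d
        int ii = i + dirs[d][0], jj = j + dirs[d][1], kk = k + dirs[d][2];
        bool bg = (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                   kk >= nz) ? true : !v[lin(ii, jj, kk, nx, ny)];
        if (!bg) continue;
        // local cube + neighbour count
        int nnb = 0;
        for (int c = -1; c <= 1; ++c)
          for (int b = -1; b <= 1; ++b)
            for (int a = -1; a <= 1; ++a) {
              int wa = i + a, wb = j + b, wc = k + c;
              int idx = (a + 1) + 3 * (b + 1) + 9 * (c + 1);
              bool fg = !(wa < 0 || wb < 0 || wc < 0 || wa >= nx ||
                          wb >= ny || wc >= nz) &&
                        v[lin(wa, wb, wc, nx, ny)];
              cube[idx] = fg;
              if (idx != 13 && fg) ++nnb;
            }
        if (nnb <= 1) continue;  // endpoint / isolated: keep
        if (is_simple(cube)) { v[s] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(ntot);
  for (long s = 0; s < ntot; ++s) out[s] = v[s] != 0;
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Conditional label dilation: unlabelled voxels inside `allow` take the
// label of any 26-neighbour (double-buffered per iteration).
// [[Rcpp::export]]
IntegerVector cpp_dilate_labels(IntegerVector lab, LogicalVector allow,
                                IntegerVector dims, int iter) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long ntot = (long)nx * ny * nz;
  std::vector<int> cur(lab.begin(), lab.end());
  std::vector<int> nxt;
  for (int it = 0; it < iter; ++it) {
    nxt = cur;
    bool changed = false;
    for (long s = 0; s < ntot; ++s) {
      if (cur[s] != 0 || !allow[s]) continue;
      int i = s % nx, j = (s / nx) % ny, k = s / ((long)nx * ny);
      for (int a = -1; a <= 1; ++a) {
        for (int b = -1; b <= 1; ++b) {
          for (int c = -1; c <= 1; ++c) {
            if (!a && !b && !c) continue;
            int ii = i + a, jj = j + b, kk = k + c;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                kk >= nz) continue;
            int l = cur[lin(ii, jj, kk, nx, ny)];
            if (l > 0) { nxt[s] = l; changed = true; a = b = c = 2; }
          }
        }
      }
    }
    std::swap(cur, nxt);
    if (!changed) break;
  }
  IntegerVector out(cur.begin(), cur.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Rasterize capsules (cylinders with spherical caps) onto a voxel grid:
// voxel centres within `radius` of any segment become TRUE. segs is an
// n x 6 matrix (x1,y1,z1,x2,y2,z2) in physical units; voxel centre of
// voxel (i,j,k) (0-based) is origin + (i+0.5)*voxel_size.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_capsules(NumericMatrix segs, double radius,
                                     NumericVector voxel_size,
                                     NumericVector origin,
                                     IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long ntot = (long)nx * ny * nz;
  std::vector<char> v(ntot, 0);
  double dx = voxel_size[0], dy = voxel_size[1], dz = voxel_size[2];
  double r2 = radius * radius;

  for (int s = 0; s < segs.nrow(); ++s) {
    double ax = segs(s,0), ay = segs(s,1), az = segs(s,2);
    double bx = segs(s,3), by = segs(s,4), bz = segs(s,5);
    double lox = std::min(ax,bx) - radius, hix = std::max(ax,bx) + radius;
    double loy = std::min(ay,by) - radius, hiy = std::max(ay,by) + radius;
    double loz = std::min(az,bz) - radius, hiz = std::max(az,bz) + radius;
    int i0 = std::max(0, (int)std::floor((lox - origin[0]) / dx - 0.5));
    int i1 = std::min(nx - 1, (int)std::ceil((hix - origin[0]) / dx - 0.5));
    int j0 = std::max(0, (int)std::floor((loy - origin[1]) / dy - 0.5));
    int j1 = std::min(ny - 1, (int)std::ceil((hiy - origin[1]) / dy - 0.5));
    int k0 = std::max(0, (int)std::floor((loz - origin[2]) / dz - 0.5));
    int k1 = std::min(nz - 1, (int)std::ceil((hiz - origin[2]) / dz - 0.5));
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double uu = ux*ux + uy*uy + uz*uz;
    for (int k = k0; k <= k1; ++k) {
      double pz = origin[2] + (k + 0.5) * dz;
      for (int j = j0; j <= j1; ++j) {
        double py = origin[1] + (j + 0.5) * dy;
        for (int i = i0; i <= i1; ++i) {
          long idx = lin(i, j, k, nx, ny);
          if (v[idx]) continue;
          double px = origin[0] + (i + 0.5) * dx;
          double wx = px - ax, wy = py - ay, wz = pz - az;
          double t = uu > 0 ? (wx*ux + wy*uy + wz*uz) / uu : 0.0;
          if (t < 0) t = 0; if (t > 1) t = 1;
          double qx = wx - t*ux, qy = wy - t*uy, qz = wz - t*uz;
          if (qx*qx + qy*qy + qz*qz <= r2) v[idx] = 1;
        }
      }
    }
  }
  LogicalVector out(ntot);
  for (long s = 0; s < ntot; ++s) out[s] = v[s] != 0;
  out.attr("dim") = dims;
  return out;
}
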