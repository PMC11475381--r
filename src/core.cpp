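#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Non-local means de-noising of a single 2D slice.
// Weights follow Buades: w = exp(-max(d2 - 2*sigma^2, 0) / h^2) where d2 is
// the mean squared difference between template patches and h the strength.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_nlm_denoise(NumericMatrix img, double h, double sigma,
                              int template_size, int search_size) {
  int nr = img.nrow(), nc = img.ncol();
  int tr = template_size / 2;   // template radius
  int sr = search_size / 2;     // search radius
  NumericMatrix out(nr, nc);
  if (h <= 0) { // nothing to remove
    std::copy(img.begin(), img.end(), out.begin());
    return out;
  }
  double h2 = h * h;
  double s2 = 2.0 * sigma * sigma;
  int tn = (2 * tr + 1) * (2 * tr + 1);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double wsum = 0.0, vsum = 0.0;
      for (int dj = -sr; dj <= sr; ++dj) {
        for (int di = -sr; di <= sr; ++di) {
          int ci = i + di, cj = j + dj;
          if (ci < 0 || ci >= nr || cj < 0 || cj >= nc) continue;
          // mean squared patch difference (clamped borders)
          double d2 = 0.0;
          for (int tj = -tr; tj <= tr; ++tj) {
            for (int ti = -tr; ti <= tr; ++ti) {
              int ai = std::min(std::max(i + ti, 0), nr - 1);
              int aj = std::min(std::max(j + tj, 0), nc - 1);
              int bi = std::min(std::max(ci + ti, 0), nr - 1);
              int bj = std::min(std::max(cj + tj, 0), nc - 1);
              double diff = img(ai, aj) - img(bi, bj);
              d2 += diff * diff;
            }
          }
          d2 /= tn;
          double ex = d2 - s2;
          if (ex < 0) ex = 0;
          double w = std::exp(-ex / h2);
          wsum += w;
          vsum += w * img(ci, cj);
        }
      }
      out(i, j) = vsum / wsum;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Scale-normalised Hessian of a 2D image at Gaussian scale sigma.
// Separable convolution with sampled Gaussian-derivative kernels; returns
// sigma^2-normalised Hxx, Hxy, Hyy ("x" = row direction).
// ---------------------------------------------------------------------------
static std::vector<double> gauss_kernel(double sigma, int order, int &rad) {
  rad = std::max(1, (int)std::ceil(3.0 * sigma));
  int n = 2 * rad + 1;
  std::vector<double> k(n);
  double s2 = sigma * sigma;
  double norm = 0.0;
  for (int i = 0; i < n; ++i) {
    double x = i - rad;
    double g = std::exp(-0.5 * x * x / s2);
    norm += g;
  }
  for (int i = 0; i < n; ++i) {
    double x = i - rad;
    double g = std::exp(-0.5 * x * x / s2) / norm;
    if (order == 0) k[i] = g;
    else if (order == 1) k[i] = -x / s2 * g;
    else k[i] = (x * x / (s2 * s2) - 1.0 / s2) * g;
  }
  if (order == 2) {           // enforce zero DC response exactly
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += k[i];
    for (int i = 0; i < n; ++i) k[i] -= s / n;
  }
  return k;
}

static void conv_rows(const NumericMatrix &in, NumericMatrix &out,
                      const std::vector<double> &k, int rad) {
  int nr = in.nrow(), nc = in.ncol();
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int d = -rad; d <= rad; ++d) {
        int ii = std::min(std::max(i + d, 0), nr - 1);
        s += in(ii, j) * k[rad - d];
      }
      out(i, j) = s;
    }
}

static void conv_cols(const NumericMatrix &in, NumericMatrix &out,
                      const std::vector<double> &k, int rad) {
  int nr = in.nrow(), nc = in.ncol();
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int d = -rad; d <= rad; ++d) {
        int jj = std::min(std::max(j + d, 0), nc - 1);
        s += in(i, jj) * k[rad - d];
      }
      out(i, j) = s;
    }
}

// [[Rcpp::export]]
List cpp_hessian2d(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  int r0, r1, r2;
  std::vector<double> g0 = gauss_kernel(sigma, 0, r0);
  std::vector<double> g1 = gauss_kernel(sigma, 1, r1);
  std::vector<double> g2 = gauss_kernel(sigma, 2, r2);
  NumericMatrix tmp(nr, nc), hxx(nr, nc), hyy(nr, nc), hxy(nr, nc);
  conv_rows(img, tmp, g2, r2); conv_cols(tmp, hxx, g0, r0);
  conv_rows(img, tmp, g0, r0); conv_cols(tmp, hyy, g2, r2);
  conv_rows(img, tmp, g1, r1); conv_cols(tmp, hxy, g1, r1);
  double s2 = sigma * sigma;  // gamma-normalisation (gamma = 2)
  for (int i = 0; i < nr * nc; ++i) {
    hxx[i] *= s2; hyy[i] *= s2; hxy[i] *= s2;
  }
  return List::create(_["hxx"] = hxx, _["hxy"] = hxy, _["hyy"] = hyy);
}

// ---------------------------------------------------------------------------
// DBSCAN on integer voxel coordinates.  Points live on a grid so the
// eps-neighbourhood is a fixed offset stencil; neighbour lookup is O(1)
// through a dense id volume.  minPts counts the point itself.  Cluster
// labels are assigned in lexicographic scan order of the (sorted) input,
// making the partition and border-point assignment deterministic.
// idx: n x 3 1-based (i,j,k); dims: volume dims.  Returns 0 for noise.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_dbscan_grid(IntegerMatrix idx, NumericVector dims, double eps,
                     int min_pts) {
  int n = idx.nrow();
  int nx = (int)dims[0], ny = (int)dims[1], nz = (int)dims[2];
  IntegerVector labels(n, 0);
  LogicalVector core(n, false);
  if (n == 0) return List::create(_["labels"] = labels, _["core"] = core);

  // offset stencil within euclidean distance eps
  int r = (int)std::floor(eps);
  std::vector<int> offs;
  double eps2 = eps * eps;
  for (int dk = -r; dk <= r; ++dk)
    for (int dj = -r; dj <= r; ++dj)
      for (int di = -r; di <= r; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        if (di * di + dj * dj + dk * dk <= eps2) {
          offs.push_back(di); offs.push_back(dj); offs.push_back(dk);
        }
      }
  int noff = offs.size() / 3;

  // dense id volume (-1 = empty)
  std::vector<int> vol((size_t)nx * ny * nz, -1);
  for (int p = 0; p < n; ++p) {
    int i = idx(p, 0) - 1, j = idx(p, 1) - 1, k = idx(p, 2) - 1;
    vol[(size_t)i + (size_t)nx * (j + (size_t)ny * k)] = p;
  }

  std::vector<std::vector<int> > nb(n);
  for (int p = 0; p < n; ++p) {
    int i = idx(p, 0) - 1, j = idx(p, 1) - 1, k = idx(p, 2) - 1;
    for (int o = 0; o < noff; ++o) {
      int ii = i + offs[3 * o], jj = j + offs[3 * o + 1], kk = k + offs[3 * o + 2];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      int q = vol[(size_t)ii + (size_t)nx * (jj + (size_t)ny * kk)];
      if (q >= 0) nb[p].push_back(q);
    }
    if ((int)nb[p].size() + 1 >= min_pts) core[p] = true;
  }

  int next_label = 0;
  for (int p = 0; p < n; ++p) {
    if (labels[p] != 0 || !core[p]) continue;
    ++next_label;
    labels[p] = next_label;
    std::queue<int> q;
    q.push(p);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      if (!core[u]) continue;          // border points do not expand
      for (size_t a = 0; a < nb[u].size(); ++a) {
        int v = nb[u][a];
        if (labels[v] == 0) {
          labels[v] = next_label;
          if (core[v]) q.push(v);
        }
      }
    }
  }
  return List::create(_["labels"] = labels, _["core"] = core);
}

// ---------------------------------------------------------------------------
// 2D connected-component labelling (8-connectivity) of a logical matrix.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cpp_label2d(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int,int> > stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back(); stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(std::make_pair(ii, jj));
            }
          }
      }
    }
  return lab;
}

// ---------------------------------------------------------------------------
// 3D topology-preserving thinning (curve skeleton).
// A border voxel is deleted when it is a simple point (deletion preserves
// both the number of 26-connected foreground components in its 26-
// neighbourhood and the 6-connectivity of background in its 18-
// neighbourhood) and not a curve end point (>= 2 foreground neighbours).
// Six directional sub-iterations with sequential deletion keep the result
// centred and deterministic.
// ---------------------------------------------------------------------------
static inline size_t vidx(int i, int j, int k, int nx, int ny) {
  return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
}

// collect the 3x3x3 neighbourhood (27 flags, centre included)
static void get_nbhd(const std::vector<unsigned char> &vol, int i, int j, int k,
                     int nx, int ny, int nz, int nb[27]) {
  int t = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di, ++t) {
        int ii = i + di, jj = j + dj, kk = k + dk;
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          nb[t] = 0;
        else
          nb[t] = vol[vidx(ii, jj, kk, nx, ny)] ? 1 : 0;
      }
}

// number of 26-connected foreground components among the 26 neighbours
static int n26_components(const int nb[27]) {
  int lab[27]; for (int t = 0; t < 27; ++t) lab[t] = 0;
  int ncomp = 0;
  for (int t = 0; t < 27; ++t) {
    if (t == 13 || !nb[t] || lab[t]) continue;
    ++ncomp;
    int stack[27], sp = 0;
    stack[sp++] = t; lab[t] = ncomp;
    while (sp) {
      int u = stack[--sp];
      int ui = u % 3, uj = (u / 3) % 3, uk = u / 9;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int vi = ui + di, vj = uj + dj, vk = uk + dk;
            if (vi < 0 || vi > 2 || vj < 0 || vj > 2 || vk < 0 || vk > 2) continue;
            int v = vi + 3 * vj + 9 * vk;
            if (v == 13 || !nb[v] || lab[v]) continue;
            lab[v] = ncomp; stack[sp++] = v;
          }
    }
  }
  return ncomp;
}

// number of 6-connected background components in the 18-neighbourhood that
// are 6-adjacent to the centre (6-connectivity restricted to the N18 set)
static int n6_bg_components(const int nb[27]) {
  // N18: positions with manhattan offset distance 1 or 2 (not corners)
  bool in18[27];
  for (int t = 0; t < 27; ++t) {
    int ti = t % 3 - 1, tj = (t / 3) % 3 - 1, tk = t / 9 - 1;
    int m = std::abs(ti) + std::abs(tj) + std::abs(tk);
    in18[t] = (m == 1 || m == 2) && !(std::abs(ti) == 1 && std::abs(tj) == 1 && std::abs(tk) == 1);
  }
  int lab[27]; for (int t = 0; t < 27; ++t) lab[t] = 0;
  int ncomp = 0;
  for (int t = 0; t < 27; ++t) {
    int ti = t % 3 - 1, tj = (t / 3) % 3 - 1, tk = t / 9 - 1;
    bool face = (std::abs(ti) + std::abs(tj) + std::abs(tk)) == 1;
    if (!face || nb[t] || lab[t]) continue;   // seed from background face voxels
    ++ncomp;
    int stack[27], sp = 0;
    stack[sp++] = t; lab[t] = ncomp;
    while (sp) {
      int u = stack[--sp];
      int ui = u % 3, uj = (u / 3) % 3, uk = u / 9;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int a = 0; a < 6; ++a) {
        int vi = ui + d6[a][0], vj = uj + d6[a][1], vk = uk + d6[a][2];
        if (vi < 0 || vi > 2 || vj < 0 || vj > 2 || vk < 0 || vk > 2) continue;
        int v = vi + 3 * vj + 9 * vk;
        if (v == 13 || !in18[v] || nb[v] || lab[v]) continue;
        lab[v] = ncomp; stack[sp++] = v;
      }
    }
  }
  return ncomp;
}

static bool is_simple(const int nb[27]) {
  return n26_components(nb) == 1 && n6_bg_components(nb) == 1;
}

static int count_fg_neighbours(const int nb[27]) {
  int c = 0;
  for (int t = 0; t < 27; ++t) if (t != 13 && nb[t]) ++c;
  return c;
}

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<unsigned char> vol(nvox, 0);
  std::vector<int> fi, fj, fk;
  for (size_t t = 0; t < nvox; ++t) if (mask[t]) vol[t] = 1;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (vol[vidx(i, j, k, nx, ny)]) { fi.push_back(i); fj.push_back(j); fk.push_back(k); }

  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  int nb[27];
  bool changed = true;
  std::vector<size_t> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      // phase 1: freeze the current d-border so one sub-iteration removes
      // at most one boundary layer (parallel-style candidate collection)
      cand.clear();
      for (size_t p = 0; p < fi.size(); ++p) {
        int i = fi[p], j = fj[p], k = fk[p];
        size_t t = vidx(i, j, k, nx, ny);
        if (!vol[t]) continue;
        int bi = i + dirs[d][0], bj = j + dirs[d][1], bk = k + dirs[d][2];
        bool border = (bi < 0 || bi >= nx || bj < 0 || bj >= ny || bk < 0 || bk >= nz) ||
                      !vol[vidx(bi, bj, bk, nx, ny)];
        if (border) cand.push_back(p);
      }
      // phase 2: sequential deletion with simplicity re-checked in the
      // current volume, preserving topology exactly
      for (size_t c = 0; c < cand.size(); ++c) {
        size_t p = cand[c];
        int i = fi[p], j = fj[p], k = fk[p];
        size_t t = vidx(i, j, k, nx, ny);
        if (!vol[t]) continue;
        get_nbhd(vol, i, j, k, nx, ny, nz, nb);
        int nn = count_fg_neighbours(nb);
        if (nn <= 1) continue;               // end point or isolated: keep
        if (!is_simple(nb)) continue;
        vol[t] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(nvox);
  for (size_t t = 0; t < nvox; ++t) out[t] = vol[t] != 0;
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Iso-surface by marching tetrahedra on the Kuhn 6-tet cube decomposition
// (face-consistent across cubes, hence watertight).  Vertices returned in
// world coordinates: origin + (index - 1) * spacing (1-based R convention).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_march_tets(NumericVector vol, IntegerVector dims,
                    NumericVector spacing, NumericVector origin, double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  // cube corner offsets
  const int co[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  const int tets[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};
  double cval[8];
  double cpos[8][3];
  int above[4];

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_above = false, any_below = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + co[c][0], jj = j + co[c][1], kk = k + co[c][2];
          cval[c] = vol[vidx(ii, jj, kk, nx, ny)];
          cpos[c][0] = origin[0] + ii * spacing[0];
          cpos[c][1] = origin[1] + jj * spacing[1];
          cpos[c][2] = origin[2] + kk * spacing[2];
          if (cval[c] > iso) any_above = true; else any_below = true;
        }
        if (!any_above || !any_below) continue;
        for (int tt = 0; tt < 6; ++tt) {
          int na = 0;
          for (int a = 0; a < 4; ++a) {
            above[a] = cval[tets[tt][a]] > iso ? 1 : 0;
            na += above[a];
          }
          if (na == 0 || na == 4) continue;
          // collect crossing edges
          int ea[6], eb[6], ne = 0;
          const int edges[6][2] = {{0,1},{0,2},{0,3},{1,2},{1,3},{2,3}};
          for (int e = 0; e < 6; ++e) {
            int a = edges[e][0], b = edges[e][1];
            if (above[a] != above[b]) { ea[ne] = tets[tt][a]; eb[ne] = tets[tt][b]; ++ne; }
          }
          // interpolated points
          double px[4], py[4], pz[4];
          for (int e = 0; e < ne; ++e) {
            double a = cval[ea[e]], b = cval[eb[e]];
            double t = (iso - a) / (b - a);
            px[e] = cpos[ea[e]][0] + t * (cpos[eb[e]][0] - cpos[ea[e]][0]);
            py[e] = cpos[ea[e]][1] + t * (cpos[eb[e]][1] - cpos[ea[e]][1]);
            pz[e] = cpos[ea[e]][2] + t * (cpos[eb[e]][2] - cpos[ea[e]][2]);
          }
          int base = vx.size();
          if (ne == 3) {
            for (int e = 0; e < 3; ++e) { vx.push_back(px[e]); vy.push_back(py[e]); vz.push_back(pz[e]); }
            tri.push_back(base); tri.push_back(base + 1); tri.push_back(base + 2);
          } else if (ne == 4) {
            // The four cut edges form a cycle; consecutive edges of the cycle
            // share one tet vertex.  Walk the cycle greedily from edge 0.
            int order[4] = {0, -1, -1, -1};
            bool used[4] = {true, false, false, false};
            for (int pos = 1; pos < 4; ++pos) {
              int prev = order[pos - 1];
              for (int e = 0; e < 4; ++e) {
                if (used[e]) continue;
                bool share = ea[e] == ea[prev] || ea[e] == eb[prev] ||
                             eb[e] == ea[prev] || eb[e] == eb[prev];
                if (share) { order[pos] = e; used[e] = true; break; }
              }
              if (order[pos] < 0) { // fallback: take any unused edge
                for (int e = 0; e < 4; ++e)
                  if (!used[e]) { order[pos] = e; used[e] = true; break; }
              }
            }
            for (int e = 0; e < 4; ++e) {
              vx.push_back(px[order[e]]); vy.push_back(py[order[e]]); vz.push_back(pz[order[e]]);
            }
            tri.push_back(base); tri.push_back(base + 1); tri.push_back(base + 2);
            tri.push_back(base); tri.push_back(base + 2); tri.push_back(base + 3);
          }
        }
      }

  int nv = vx.size(), nt = tri.size() / 3;
  NumericMatrix verts(nv, 3);
  for (int v = 0; v < nv; ++v) { verts(v, 0) = vx[v]; verts(v, 1) = vy[v]; verts(v, 2) = vz[v]; }
  IntegerMatrix faces(nt, 3);
  for (int f = 0; f < nt; ++f) {
    faces(f, 0) = tri[3 * f] + 1; faces(f, 1) = tri[3 * f + 1] + 1; faces(f, 2) = tri[3 * f + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// ---------------------------------------------------------------------------
// Minimum Euclidean distance from each query point to any surface vertex.
// Uniform-grid acceleration over the vertex cloud.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_min_dist(NumericMatrix pts, NumericMatrix verts) {
  int np = pts.nrow(), nv = verts.nrow();
  NumericVector out(np);
  if (nv == 0) { std::fill(out.begin(), out.end(), R_PosInf); return out; }
  // bounding box + grid
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int v = 0; v < nv; ++v)
    for (int d = 0; d < 3; ++d) {
      if (verts(v, d) < lo[d]) lo[d] = verts(v, d);
      if (verts(v, d) > hi[d]) hi[d] = verts(v, d);
    }
  double ext = 0.0;
  for (int d = 0; d < 3; ++d) ext = std::max(ext, hi[d] - lo[d]);
  double cell = std::max(ext / 64.0, 1e-9);
  int ng[3];
  for (int d = 0; d < 3; ++d)
    ng[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cell) + 1);
  std::vector<std::vector<int> > bins((size_t)ng[0] * ng[1] * ng[2]);
  for (int v = 0; v < nv; ++v) {
    int c[3];
    for (int d = 0; d < 3; ++d) {
      c[d] = (int)((verts(v, d) - lo[d]) / cell);
      if (c[d] >= ng[d]) c[d] = ng[d] - 1;
    }
    bins[(size_t)c[0] + (size_t)ng[0] * (c[1] + (size_t)ng[1] * c[2])].push_back(v);
  }
  for (int p = 0; p < np; ++p) {
    double qx = pts(p, 0), qy = pts(p, 1), qz = pts(p, 2);
    int c[3];
    for (int d = 0; d < 3; ++d) {
      double val = pts(p, d);
      int ci = (int)((val - lo[d]) / cell);
      c[d] = std::min(std::max(ci, 0), ng[d] - 1);
    }
    double best2 = R_PosInf;
    for (int ring = 0; ring < std::max(std::max(ng[0], ng[1]), ng[2]); ++ring) {
      bool found_any = false;
      int i0 = std::max(c[0] - ring, 0), i1 = std::min(c[0] + ring, ng[0] - 1);
      int j0 = std::max(c[1] - ring, 0), j1 = std::min(c[1] + ring, ng[1] - 1);
      int k0 = std::max(c[2] - ring, 0), k1 = std::min(c[2] + ring, ng[2] - 1);
      for (int kk = k0; kk <= k1; ++kk)
        for (int jj = j0; jj <= j1; ++jj)
          for (int ii = i0; ii <= i1; ++ii) {
            // only the shell of the ring
            if (ring > 0 &&
                ii != i0 && ii != i1 && jj != j0 && jj != j1 && kk != k0 && kk != k1)
              continue;
            const std::vector<int> &b = bins[(size_t)ii + (size_t)ng[0] * (jj + (size_t)ng[1] * kk)];
            for (size_t a = 0; a < b.size(); ++a) {
              int v = b[a];
              double dx = verts(v, 0) - qx, dy = verts(v, 1) - qy, dz = verts(v, 2) - qz;
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best2) { best2 = d2; found_any = true; }
            }
            if (!b.empty()) found_any = true;
          }
      // stop when the closest possible point in the next ring cannot beat best
      if (best2 < R_PosInf) {
        double safe = (double)ring * cell;   // distance covered for sure
        if (safe * safe >= best2) break;
      }
      (void)found_any;
    }
    out[p] = std::sqrt(best2);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fill interior cavities: background voxels not 6-connected to the volume
// border become foreground (a lumen is solid; cavities are segmentation
// noise).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_fill_cavities(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<unsigned char> outside(nvox, 0);
  std::queue<size_t> q;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1)
          continue;
        size_t t = vidx(i, j, k, nx, ny);
        if (!mask[t] && !outside[t]) { outside[t] = 1; q.push(t); }
      }
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty()) {
    size_t t = q.front(); q.pop();
    int i = t % nx, j = (t / nx) % ny, k = t / ((size_t)nx * ny);
    for (int a = 0; a < 6; ++a) {
      int ii = i + d6[a][0], jj = j + d6[a][1], kk = k + d6[a][2];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      size_t u = vidx(ii, jj, kk, nx, ny);
      if (!mask[u] && !outside[u]) { outside[u] = 1; q.push(u); }
    }
  }
  LogicalVector out(nvox);
  for (size_t t = 0; t < nvox; ++t) out[t] = mask[t] || !outside[t];
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Shortest normal distance: minimum distance from each centreline point to
// surface vertices lying within a slab of half-width `slab` around the
// plane normal to the local tangent.  Falls back to the unrestricted
// minimum when the slab is empty (e.g. a point past the surface end).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_min_dist_normal(NumericMatrix pts, NumericMatrix tans,
                                  NumericMatrix verts, double slab) {
  int np = pts.nrow(), nv = verts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double qx = pts(p, 0), qy = pts(p, 1), qz = pts(p, 2);
    double tx = tans(p, 0), ty = tans(p, 1), tz = tans(p, 2);
    double best2 = R_PosInf, best2_any = R_PosInf;
    for (int v = 0; v < nv; ++v) {
      double dx = verts(v, 0) - qx, dy = verts(v, 1) - qy, dz = verts(v, 2) - qz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best2_any) best2_any = d2;
      double axial = std::fabs(dx * tx + dy * ty + dz * tz);
      if (axial <= slab && d2 < best2) best2 = d2;
    }
    out[p] = std::sqrt(R_finite(best2) ? best2 : best2_any);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing of a 3D volume (sigma per axis, in voxels).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_smooth3d(NumericVector vol, IntegerVector dims,
                           NumericVector sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(nvox);
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int rad;
    std::vector<double> k = gauss_kernel(s, 0, rad);
    int n[3] = {nx, ny, nz};
    for (int kk = 0; kk < nz; ++kk)
      for (int jj = 0; jj < ny; ++jj)
        for (int ii = 0; ii < nx; ++ii) {
          double acc = 0.0;
          for (int d = -rad; d <= rad; ++d) {
            int c[3] = {ii, jj, kk};
            c[axis] += d;
            if (c[axis] < 0) c[axis] = 0;
            if (c[axis] >= n[axis]) c[axis] = n[axis] - 1;
            acc += a[vidx(c[0], c[1], c[2], nx, ny)] * k[rad - d];
          }
          b[vidx(ii, jj, kk, nx, ny)] = acc;
        }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}
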