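// Threshold-free cluster enhancement and the max-statistic permutation
// engine. TFCE uses an incremental union-find over voxels sorted by
// descending statistic value, so each threshold step touches only the
// currently suprathreshold voxels.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  std::vector<int> offsets;  // linear-index neighbor offsets
  std::vector<int> dxyz;     // packed (dx,dy,dz) per offset for bounds checks

  Grid(const IntegerVector& dims, int conn) {
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
          if (m == 0) continue;
          if (conn == 6 && m > 1) continue;
          if (conn == 18 && m > 2) continue;
          offsets.push_back(dx + nx * (dy + ny * dz));
          dxyz.push_back(dx); dxyz.push_back(dy); dxyz.push_back(dz);
        }
  }
};

struct UnionFind {
  std::vector<int> parent;
  std::vector<int> size;
  void reset(int n) {
    parent.assign(n, -1);
    size.assign(n, 0);
  }
  int find(int v) {
    int r = v;
    while (parent[r] != r) r = parent[r];
    while (parent[v] != r) { int nxt = parent[v]; parent[v] = r; v = nxt; }
    return r;
  }
  void activate(int v) { parent[v] = v; size[v] = 1; }
  bool active(int v) const { return parent[v] >= 0; }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
  }
};

// One-sided TFCE: values <= 0 are background. Writes into `out` (same
// length), overwriting. Returns the maximum TFCE value.
double tfce_one_sided(const std::vector<double>& stat, const Grid& g,
                      double E, double H, double dh, int n_steps,
                      std::vector<double>& out, UnionFind& uf) {
  const int V = (int)stat.size();
  std::fill(out.begin(), out.end(), 0.0);
  double maxv = 0.0;
  std::vector<int> order;
  order.reserve(256);
  for (int v = 0; v < V; ++v)
    if (stat[v] > 0) { order.push_back(v); if (stat[v] > maxv) maxv = stat[v]; }
  if (order.empty()) return 0.0;
  if (dh <= 0) dh = maxv / n_steps;
  int K = (int)std::floor(maxv / dh + 1e-9);
  if (K < 1) K = 1;
  std::sort(order.begin(), order.end(),
            [&stat](int a, int b) { return stat[a] > stat[b]; });
  uf.reset(V);
  const double eps = 1e-12 * maxv;
  size_t ptr = 0;
  double tfce_max = 0.0;
  for (int k = K; k >= 1; --k) {
    double h = k * dh;
    while (ptr < order.size() && stat[order[ptr]] >= h - eps) {
      int v = order[ptr];
      uf.activate(v);
      int x = v % g.nx, y = (v / g.nx) % g.ny, z = v / (g.nx * g.ny);
      for (size_t o = 0; o < g.offsets.size(); ++o) {
        int xx = x + g.dxyz[3 * o], yy = y + g.dxyz[3 * o + 1],
            zz = z + g.dxyz[3 * o + 2];
        if (xx < 0 || xx >= g.nx || yy < 0 || yy >= g.ny ||
            zz < 0 || zz >= g.nz) continue;
        int u = v + g.offsets[o];
        if (uf.active(u)) uf.unite(v, u);
      }
      ++ptr;
    }
    double hH = std::pow(h, H) * dh;
    for (size_t i = 0; i < ptr; ++i) {
      int v = order[i];
      double add = std::pow((double)uf.size[uf.find(v)], E) * hH;
      out[v] += add;
      if (out[v] > tfce_max) tfce_max = out[v];
    }
  }
  return tfce_max;
}

}  // namespace

// [[Rcpp::export]]
NumericVector tfce_one_sided_cpp(NumericVector stat, IntegerVector dims,
                                 double E, double H, double dh, int n_steps,
                                 int conn) {
  Grid g(dims, conn);
  int V = stat.size();
  std::vector<double> in(stat.begin(), stat.end());
  for (int v = 0; v < V; ++v) if (!(in[v] > 0)) in[v] = 0.0;
  std::vector<double> out(V, 0.0);
  UnionFind uf;
  tfce_one_sided(in, g, E, H, dh, n_steps, out, uf);
  return NumericVector(out.begin(), out.end());
}

// Label connected components of a logical volume (flood fill).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector fg, IntegerVector dims,
                                   int conn) {
  Grid g(dims, conn);
  int V = fg.size();
  IntegerVector lab(V, 0);
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < V; ++s) {
    if (!fg[s] || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int x = v % g.nx, y = (v / g.nx) % g.ny, z = v / (g.nx * g.ny);
      for (size_t o = 0; o < g.offsets.size(); ++o) {
        int xx = x + g.dxyz[3 * o], yy = y + g.dxyz[3 * o + 1],
            zz = z + g.dxyz[3 * o + 2];
        if (xx < 0 || xx >= g.nx || yy < 0 || yy >= g.ny ||
            zz < 0 || zz >= g.nz) continue;
        int u = v + g.offsets[o];
        if (fg[u] && lab[u] == 0) { lab[u] = next; stack.push_back(u); }
      }
    }
  }
  return lab;
}

// Freedman-Lane max-statistic permutation engine.
//
// Y: n x V matrix of masked voxel values (columns follow mask_idx order);
// X: full model; cvec: contrast; Z: reduced (nuisance) model;
// perms: n x B permutation indices (1-based rows of the nuisance
// residuals); mask_idx: 1-based linear grid indices of the masked voxels;
// rois: list of integer vectors of 1-based linear grid indices.
// Returns a B x (2 + 2 * n_roi) matrix: per permutation the maximum
// positive- and negative-tail TFCE over the whole mask, then within each
// ROI. dh > 0 fixes the integration step (shared with the observed map so
// observed and permuted statistics are computed on the same threshold
// grid); dh <= 0 falls back to max(|t|) / n_steps per permuted map.
// [[Rcpp::export]]
NumericMatrix perm_max_tfce_cpp(const arma::mat& Y, const arma::mat& X,
                                const arma::vec& cvec, const arma::mat& Z,
                                const arma::imat& perms,
                                const arma::uvec& mask_idx,
                                IntegerVector dims, double E, double H,
                                double dh, int n_steps, int conn,
                                List rois) {
  const int n = Y.n_rows, V = Y.n_cols, B = perms.n_cols;
  const int nroi = rois.size();
  Grid g(dims, conn);
  const int Vgrid = dims[0] * dims[1] * dims[2];

  arma::mat XtXinv = arma::inv_sympd(X.t() * X);
  arma::mat A = XtXinv * X.t();           // p x n
  double ccc = arma::as_scalar(cvec.t() * XtXinv * cvec);
  double df = n - (double)X.n_cols;
  arma::rowvec cA = (XtXinv * cvec).t() * X.t();  // 1 x n

  arma::mat Hz = Z * arma::solve(Z.t() * Z, Z.t());  // n x n
  arma::mat fitZ = Hz * Y;
  arma::mat resZ = Y - fitZ;

  std::vector<std::vector<int> > roi_idx(nroi);
  for (int r = 0; r < nroi; ++r) {
    IntegerVector rr = rois[r];
    roi_idx[r].assign(rr.begin(), rr.end());
    for (size_t i = 0; i < roi_idx[r].size(); ++i) roi_idx[r][i] -= 1;
  }

  NumericMatrix out(B, 2 + 2 * nroi);
  std::vector<double> grid_stat(Vgrid), tfce(Vgrid);
  UnionFind uf;
  arma::uvec pidx(n);

  // permutation-invariant pieces: column sums of squares, and the fit of
  // the unpermuted nuisance part
  arma::mat XtX = X.t() * X;
  arma::mat AfZ = A * fitZ;                              // p x V
  arma::rowvec sum_fitZ2 = arma::sum(arma::square(fitZ), 0);
  arma::rowvec sum_resZ2 = arma::sum(arma::square(resZ), 0);
  arma::mat Bmat(X.n_cols, V), Cmat(X.n_cols, V);
  arma::rowvec cross(V), num(V), ssq_model(V), tvals(V);

  arma::uvec ipidx(n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) pidx[i] = (arma::uword)(perms(i, b) - 1);
    for (int i = 0; i < n; ++i) ipidx[pidx[i]] = i;
    // Y* = fitZ + P resZ, but Y* itself is never materialized:
    // beta = A Y* = AfZ + sum_i A(:,i) resZ(p(i),:) = AfZ + A.cols(p^-1) resZ
    // sse  = |Y*|^2 - beta' X'X beta (per voxel)
    Bmat = AfZ + A.cols(ipidx) * resZ;
    num = cvec.t() * Bmat;
    cross.zeros();
    for (int i = 0; i < n; ++i)
      cross += fitZ.row(i) % resZ.row(pidx[i]);
    Cmat = XtX * Bmat;
    ssq_model = arma::sum(Bmat % Cmat, 0);
    for (int v = 0; v < V; ++v) {
      double sse = sum_fitZ2[v] + sum_resZ2[v] + 2.0 * cross[v] -
        ssq_model[v];
      if (sse < 0) sse = 0;
      double se = std::sqrt(ccc * sse / df);
      tvals[v] = se > 0 ? num[v] / se : 0.0;
    }
    double dh_b = dh;
    if (dh_b <= 0) {
      double maxabs = 0.0;
      for (int v = 0; v < V; ++v)
        maxabs = std::max(maxabs, std::fabs(tvals[v]));
      dh_b = maxabs > 0 ? maxabs / n_steps : 1.0;
    }
    for (int tail = 0; tail < 2; ++tail) {
      std::fill(grid_stat.begin(), grid_stat.end(), 0.0);
      for (int v = 0; v < V; ++v) {
        double t = tail == 0 ? tvals[v] : -tvals[v];
        if (t > 0) grid_stat[mask_idx[v] - 1] = t;
      }
      double mx = tfce_one_sided(grid_stat, g, E, H, dh_b, n_steps, tfce, uf);
      out(b, tail) = mx;
      for (int r = 0; r < nroi; ++r) {
        double m = 0.0;
        for (size_t i = 0; i < roi_idx[r].size(); ++i)
          m = std::max(m, tfce[roi_idx[r][i]]);
        out(b, 2 + 2 * r + tail) = m;
      }
    }
  }
  return out;
}
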