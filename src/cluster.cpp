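// Connected-component labeling of supra-threshold voxels (26-connectivity)
// and the permutation max-cluster-extent kernel. Compiled because the
// voxelwise calibration suite runs this over hundreds of permutations per
// replicate.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

static void neighbors26(int idx, int nx, int ny, int nz, std::vector<int> &out) {
  out.clear();
  int x = idx % nx;
  int y = (idx / nx) % ny;
  int z = idx / (nx * ny);
  for (int dz = -1; dz <= 1; ++dz) {
    int zz = z + dz;
    if (zz < 0 || zz >= nz) continue;
    for (int dy = -1; dy <= 1; ++dy) {
      int yy = y + dy;
      if (yy < 0 || yy >= ny) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx;
        if (xx < 0 || xx >= nx) continue;
        if (dx == 0 && dy == 0 && dz == 0) continue;
        out.push_back(xx + nx * (yy + ny * zz));
      }
    }
  }
}

static int label_one(const double *stat, double thr, int nx, int ny, int nz,
                     std::vector<int> &labels, std::vector<int> *sizes) {
  int n = nx * ny * nz;
  std::fill(labels.begin(), labels.end(), 0);
  int next = 0;
  std::vector<int> stack;
  std::vector<int> nb;
  nb.reserve(26);
  for (int i = 0; i < n; ++i) {
    if (labels[i] != 0 || !(stat[i] > thr)) continue;
    ++next;
    int count = 0;
    labels[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      ++count;
      neighbors26(cur, nx, ny, nz, nb);
      for (size_t j = 0; j < nb.size(); ++j) {
        int v = nb[j];
        if (labels[v] == 0 && stat[v] > thr) {
          labels[v] = next;
          stack.push_back(v);
        }
      }
    }
    if (sizes) sizes->push_back(count);
  }
  return next;
}

// [[Rcpp::export]]
List label_clusters_3d(NumericVector stat, IntegerVector dims, double thr) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  if (stat.size() != n) stop("stat length does not match dims");
  std::vector<int> labels(n);
  std::vector<int> sizes;
  label_one(REAL(stat), thr, nx, ny, nz, labels, &sizes);
  IntegerVector lab(labels.begin(), labels.end());
  lab.attr("dim") = dims;
  return List::create(_["labels"] = lab,
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}

// [[Rcpp::export]]
IntegerVector max_cluster_extent(NumericMatrix statmat, IntegerVector dims,
                                 double thr) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  if (statmat.nrow() != n) stop("statmat rows do not match dims");
  int p = statmat.ncol();
  IntegerVector out(p);
  std::vector<int> labels(n);
  for (int j = 0; j < p; ++j) {
    std::vector<int> sizes;
    label_one(&statmat(0, j), thr, nx, ny, nz, labels, &sizes);
    int mx = 0;
    for (size_t s = 0; s < sizes.size(); ++s)
      if (sizes[s] > mx) mx = sizes[s];
    out[j] = mx;
  }
  return out;
}
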