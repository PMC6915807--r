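#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// 8-connected component labeling of a binary image stored column-major
// (H rows x W cols). Labels are 1..K in discovery order, 0 = background.
static void label8(const std::vector<char>& img, int H, int W,
                   std::vector<int>& lab, std::vector<int>& sizes) {
  std::fill(lab.begin(), lab.end(), 0);
  sizes.clear();
  std::vector<int> stack;
  int next = 0;
  const int n = H * W;
  for (int s = 0; s < n; ++s) {
    if (!img[s] || lab[s]) continue;
    ++next;
    int sz = 0;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      ++sz;
      int r = cur % H, c = cur / H;
      for (int dc = -1; dc <= 1; ++dc) {
        int cc = c + dc;
        if (cc < 0 || cc >= W) continue;
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = r + dr;
          if (rr < 0 || rr >= H || (dr == 0 && dc == 0)) continue;
          int idx = cc * H + rr;
          if (img[idx] && !lab[idx]) { lab[idx] = next; stack.push_back(idx); }
        }
      }
    }
    sizes.push_back(sz);
  }
}

// [[Rcpp::export(name = ".cc_label8")]]
IntegerMatrix cc_label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol(), n = H * W;
  std::vector<char> img(n);
  for (int i = 0; i < n; ++i) img[i] = mask[i] != 0;
  std::vector<int> lab(n), sizes;
  label8(img, H, W, lab, sizes);
  IntegerMatrix out(H, W);
  for (int i = 0; i < n; ++i) out[i] = lab[i];
  return out;
}

// Exact per-pixel permutation p-values plus the null distribution of the
// maximum 8-connected supra-threshold cluster extent.
//
// Z: (B+1) x P matrix of |z| maps; row 1 is the observed map, rows 2..B+1
// the permuted maps; pixel j of the H x W image is column j in column-major
// order (j = (col-1)*H + row). For map m at pixel j,
//   p_m(j) = #{m' in all B+1 maps : |z_{m'}(j)| >= |z_m(j)|} / (B+1),
// which for the observed map is the add-one estimator
// (1 + #permutations >= observed) / (B + 1). Maps are thresholded
// identically at p < alpha; the returned null_max_extent holds, for each
// permuted map, the size of its largest 8-connected supra-threshold
// component.
// [[Rcpp::export(name = ".perm_pixel_stats")]]
List perm_pixel_stats(NumericMatrix Z, int H, int W, double alpha) {
  const int N = Z.nrow();       // B + 1 maps
  const int P = Z.ncol();       // pixels
  if (P != H * W) stop("pixel count does not match raster dims");
  const int B = N - 1;

  NumericVector p_obs(P);
  // supra[m*P + j]: map m's pixel j exceeds the cluster-forming threshold
  std::vector<char> supra((size_t)N * P, 0);
  std::vector<double> col(N), sorted(N);

  for (int j = 0; j < P; ++j) {
    for (int m = 0; m < N; ++m) col[m] = Z(m, j);
    sorted = col;
    std::sort(sorted.begin(), sorted.end());
    for (int m = 0; m < N; ++m) {
      // #{values >= v} = N - (# values < v)
      int below = std::lower_bound(sorted.begin(), sorted.end(), col[m]) -
                  sorted.begin();
      double p = double(N - below) / double(N);
      if (m == 0) p_obs[j] = p;
      if (p < alpha) supra[(size_t)m * P + j] = 1;
    }
  }

  std::vector<int> lab(P), sizes;
  NumericVector null_max(B);
  std::vector<char> img(P);
  for (int m = 1; m < N; ++m) {
    std::copy(supra.begin() + (size_t)m * P, supra.begin() + (size_t)(m + 1) * P,
              img.begin());
    label8(img, H, W, lab, sizes);
    null_max[m - 1] = sizes.empty() ? 0.0 :
      *std::max_element(sizes.begin(), sizes.end());
  }

  IntegerVector obs_supra(P);
  for (int j = 0; j < P; ++j) obs_supra[j] = supra[j];
  return List::create(_["p_obs"] = p_obs,
                      _["obs_supra"] = obs_supra,
                      _["null_max_extent"] = null_max);
}
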