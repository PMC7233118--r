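#include <Rcpp.h>
using namespace Rcpp;

// Raw directed co-occurrence counts for one offset. `levels` holds discretized
// gray levels in 1..ng inside the ROI and 0 outside; both pixels of a pair
// must be inside. Symmetrization/normalization happen on the R side.
// [[Rcpp::export]]
IntegerMatrix cpp_glcm_counts(const IntegerMatrix& levels, int ng,
                              int dx, int dy) {
  const int nr = levels.nrow(), nc = levels.ncol();
  IntegerMatrix counts(ng, ng);
  for (int j = 0; j < nc; ++j) {
    const int j2 = j + dx;           // dx moves along columns (x), dy along rows (y)
    if (j2 < 0 || j2 >= nc) continue;
    for (int i = 0; i < nr; ++i) {
      const int i2 = i + dy;
      if (i2 < 0 || i2 >= nr) continue;
      const int a = levels(i, j), b = levels(i2, j2);
      if (a > 0 && b > 0) counts(a - 1, b - 1)++;
    }
  }
  return counts;
}

// 8-connected zones of equal gray level restricted to the ROI (levels > 0).
// Returns one row per zone: its gray level and pixel count.
// [[Rcpp::export]]
DataFrame cpp_glszm_zones(const IntegerMatrix& levels) {
  const int nr = levels.nrow(), nc = levels.ncol();
  std::vector<int> lab(static_cast<size_t>(nr) * nc, 0);
  std::vector<int> zlevel, zsize, stack;
  int nzones = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int idx = j * nr + i;
      const int g = levels(i, j);
      if (g <= 0 || lab[idx]) continue;
      ++nzones;
      int size = 0;
      stack.clear();
      stack.push_back(idx);
      lab[idx] = nzones;
      while (!stack.empty()) {
        const int cur = stack.back();
        stack.pop_back();
        ++size;
        const int ci = cur % nr, cj = cur / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            const int nidx = nj * nr + ni;
            if (!lab[nidx] && levels(ni, nj) == g) {
              lab[nidx] = nzones;
              stack.push_back(nidx);
            }
          }
        }
      }
      zlevel.push_back(g);
      zsize.push_back(size);
    }
  }
  return DataFrame::create(_["level"] = zlevel, _["size"] = zsize);
}
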