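#include <Rcpp.h>
using namespace Rcpp;

// Two-pass connected-component labelling (4-connectivity) of a logical mask.
// Returns an integer matrix of labels (0 = background), labels are 1..K.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  int next = 0;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      if (!mask(h, w)) continue;
      int up = (h > 0) ? lab(h - 1, w) : 0;
      int lf = (w > 0) ? lab(h, w - 1) : 0;
      if (up == 0 && lf == 0) {
        parent.push_back(++next);
        lab(h, w) = next;
      } else if (up != 0 && lf != 0) {
        int ru = find(up), rl = find(lf);
        lab(h, w) = std::min(ru, rl);
        if (ru != rl) parent[std::max(ru, rl)] = std::min(ru, rl);
      } else {
        lab(h, w) = up + lf;
      }
    }
  }
  // resolve and compact labels
  std::vector<int> remap(parent.size(), 0);
  int k = 0;
  for (size_t i = 1; i < parent.size(); ++i) {
    int r = find((int)i);
    if (remap[r] == 0) remap[r] = ++k;
    remap[i] = remap[r];
  }
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      if (lab(h, w) != 0) lab(h, w) = remap[lab(h, w)];
  return lab;
}

// Bilinear sampling of an image at fractional (row, col) positions
// (1-based, matching R matrix indexing). Out-of-range positions return
// `fill`.
// [[Rcpp::export(name = ".bilinear_sample")]]
NumericVector bilinear_sample(const NumericMatrix& img,
                              const NumericVector& row,
                              const NumericVector& col,
                              double fill = 0.0) {
  const int H = img.nrow(), W = img.ncol();
  const int n = row.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double r = row[i] - 1.0, c = col[i] - 1.0;
    if (r < 0 || c < 0 || r > H - 1 || c > W - 1) { out[i] = fill; continue; }
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
    double fr = r - r0, fc = c - c0;
    out[i] = (1 - fr) * (1 - fc) * img(r0, c0) + (1 - fr) * fc * img(r0, c1) +
             fr * (1 - fc) * img(r1, c0) + fr * fc * img(r1, c1);
  }
  return out;
}
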