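#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a binary mask.
//
// Foreground connectivity is 8 (diagonally touching blobs merge, as the
// ImageJ-style particle analyzer does). Labels are assigned in raster order
// of each component's first pixel, scanning rows top-to-bottom and, within a
// row, left-to-right, so label k is the k-th component encountered and the
// numbering is deterministic across runs.
//
// `mask` is a logical matrix indexed [row, col] = [y, x].
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      if (mask(y, x) && lab(y, x) == 0) {
        ++next;
        lab(y, x) = next;
        stack.push_back(y + x * h);
        while (!stack.empty()) {
          const int p = stack.back();
          stack.pop_back();
          const int py = p % h, px = p / h;
          for (int dx = -1; dx <= 1; ++dx) {
            const int nx = px + dx;
            if (nx < 0 || nx >= w) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              if (dx == 0 && dy == 0) continue;
              const int ny = py + dy;
              if (ny < 0 || ny >= h) continue;
              if (mask(ny, nx) && lab(ny, nx) == 0) {
                lab(ny, nx) = next;
                stack.push_back(ny + nx * h);
              }
            }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Fill enclosed holes in a binary mask.
//
// Background is flood-filled from the image border under 4-connectivity (the
// standard dual of 8-connected foreground); any background pixel not reached
// is an enclosed hole and becomes foreground. Output is a superset of the
// input; border-connected background is untouched.
// [[Rcpp::export]]
LogicalMatrix fill_holes_cpp(const LogicalMatrix& mask) {
  const int h = mask.nrow(), w = mask.ncol();
  std::vector<char> outside(static_cast<size_t>(h) * w, 0);
  std::vector<int> stack;
  stack.reserve(2 * (h + w));
  auto push_bg = [&](int y, int x) {
    const size_t i = static_cast<size_t>(y) + static_cast<size_t>(x) * h;
    if (!mask(y, x) && !outside[i]) {
      outside[i] = 1;
      stack.push_back(y + x * h);
    }
  };
  for (int x = 0; x < w; ++x) { push_bg(0, x); push_bg(h - 1, x); }
  for (int y = 0; y < h; ++y) { push_bg(y, 0); push_bg(y, w - 1); }
  const int dy4[4] = {-1, 1, 0, 0};
  const int dx4[4] = {0, 0, -1, 1};
  while (!stack.empty()) {
    const int p = stack.back();
    stack.pop_back();
    const int py = p % h, px = p / h;
    for (int k = 0; k < 4; ++k) {
      const int ny = py + dy4[k], nx = px + dx4[k];
      if (ny >= 0 && ny < h && nx >= 0 && nx < w) push_bg(ny, nx);
    }
  }
  LogicalMatrix out(h, w);
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y)
      out(y, x) = mask(y, x) ||
        !outside[static_cast<size_t>(y) + static_cast<size_t>(x) * h];
  return out;
}
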