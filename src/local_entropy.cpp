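#include <Rcpp.h>
using namespace Rcpp;

// Local Shannon entropy (base 2) of quantized gray levels in a circular
// neighborhood around every pixel; border neighborhoods are truncated to
// in-bounds pixels (no padding). `bins` holds 0-based bin indices.
//
// Sliding-window implementation: for every output column the histogram of
// the circular window is maintained incrementally while the center moves
// down one row at a time; the entropy numerator S = sum c*ln(c) is updated
// in O(1) per count change via a lookup table, so the cost per pixel is
// O(window diameter) instead of O(window area).
// [[Rcpp::export(name = ".local_entropy_cpp")]]
NumericMatrix local_entropy_cpp(IntegerMatrix bins, int radius, int n_bins) {
  const int h = bins.nrow(), w = bins.ncol();
  NumericMatrix out(h, w);

  // half-height of the circular window at each column offset dx
  std::vector<int> half(2 * radius + 1);
  for (int dx = -radius; dx <= radius; ++dx) {
    half[dx + radius] = (int) std::floor(std::sqrt(
        (double) radius * radius - (double) dx * dx));
  }

  // xlogx[c] = c * ln(c); window size is at most the full disc area
  int max_cells = 0;
  for (int dx = -radius; dx <= radius; ++dx)
    max_cells += 2 * half[dx + radius] + 1;
  std::vector<double> xlogx(max_cells + 2, 0.0);
  for (int c = 2; c <= max_cells + 1; ++c)
    xlogx[c] = (double) c * std::log((double) c);

  const double inv_ln2 = 1.0 / std::log(2.0);
  std::vector<int> count(n_bins, 0);

  for (int j = 0; j < w; ++j) {
    std::fill(count.begin(), count.end(), 0);
    double S = 0.0;  // sum over bins of c * ln(c)
    int n = 0;

    // initialize the window centered at row 0
    for (int dx = -radius; dx <= radius; ++dx) {
      int jj = j + dx;
      if (jj < 0 || jj >= w) continue;
      int hh = half[dx + radius];
      int top = 0;            // max(0, 0 - hh)
      int bot = std::min(h - 1, hh);
      for (int ii = top; ii <= bot; ++ii) {
        int b = bins(ii, jj);
        S += xlogx[count[b] + 1] - xlogx[count[b]];
        ++count[b];
        ++n;
      }
    }
    out(0, j) = n > 1 ? (std::log((double) n) - S / n) * inv_ln2 : 0.0;

    for (int i = 1; i < h; ++i) {
      for (int dx = -radius; dx <= radius; ++dx) {
        int jj = j + dx;
        if (jj < 0 || jj >= w) continue;
        int hh = half[dx + radius];
        int leave = i - 1 - hh;     // row exiting the window
        int enter = i + hh;         // row entering the window
        if (leave >= 0) {
          int b = bins(leave, jj);
          S += xlogx[count[b] - 1] - xlogx[count[b]];
          --count[b];
          --n;
        }
        if (enter < h) {
          int b = bins(enter, jj);
          S += xlogx[count[b] + 1] - xlogx[count[b]];
          ++count[b];
          ++n;
        }
      }
      out(i, j) = n > 1 ? (std::log((double) n) - S / n) * inv_ln2 : 0.0;
    }
  }
  return out;
}
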