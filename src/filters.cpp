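#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Reflect (symmetric) boundary: ... c b a | a b c ... Edge pixel is repeated.
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Window of size w covers offsets -(w-1)/2 .. w/2 (integer division), so an
// even window puts its extra row/column toward larger indices.
static inline void window_bounds(int w, int &lo, int &hi) {
  lo = -((w - 1) / 2);
  hi = w / 2;
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int wy, int wx) {
  int ny = img.nrow(), nx = img.ncol();
  int ly, hy, lx, hx;
  window_bounds(wy, ly, hy);
  window_bounds(wx, lx, hx);
  NumericMatrix out(ny, nx);
  const double *src = img.begin();
  size_t m_full = (size_t)wy * wx;
  size_t mid = m_full / 2;
  bool even = (m_full % 2 == 0);
  std::vector<double> buf(m_full);
  std::vector<const double *> cols(wx);
  for (int x = 0; x < nx; ++x) {
    for (int dx = lx; dx <= hx; ++dx)
      cols[dx - lx] = src + (size_t)reflect_idx(x + dx, nx) * ny;
    for (int y = 0; y < ny; ++y) {
      double *b = buf.data();
      if (y + ly >= 0 && y + hy < ny) {
        // interior: contiguous copy of each source column segment
        for (int c = 0; c < wx; ++c) {
          std::copy(cols[c] + y + ly, cols[c] + y + hy + 1, b);
          b += wy;
        }
      } else {
        for (int c = 0; c < wx; ++c)
          for (int dy = ly; dy <= hy; ++dy)
            *b++ = cols[c][reflect_idx(y + dy, ny)];
      }
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (even) {
        // lower half's max completes the even-count median
        double lower = *std::max_element(buf.begin(), buf.begin() + mid);
        med = 0.5 * (med + lower);
      }
      out(y, x) = med;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix mean_filter_cpp(NumericMatrix img, int wy, int wx) {
  int ny = img.nrow(), nx = img.ncol();
  int ly, hy, lx, hx;
  window_bounds(wy, ly, hy);
  window_bounds(wx, lx, hx);
  // horizontal pass then vertical pass (separable box filter)
  NumericMatrix tmp(ny, nx), out(ny, nx);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      double s = 0;
      for (int dx = lx; dx <= hx; ++dx) s += img(y, reflect_idx(x + dx, nx));
      tmp(y, x) = s;
    }
  double norm = 1.0 / ((double)wy * wx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double s = 0;
      for (int dy = ly; dy <= hy; ++dy) s += tmp(reflect_idx(y + dy, ny), x);
      out(y, x) = s * norm;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix gaussian_filter_cpp(NumericMatrix img, double sigma) {
  int ny = img.nrow(), nx = img.ncol();
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
  NumericMatrix tmp(ny, nx), out(ny, nx);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      double v = 0;
      for (int i = -r; i <= r; ++i) v += k[i + r] * img(y, reflect_idx(x + i, nx));
      tmp(y, x) = v;
    }
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double v = 0;
      for (int i = -r; i <= r; ++i) v += k[i + r] * tmp(reflect_idx(y + i, ny), x);
      out(y, x) = v;
    }
  return out;
}

// Discrete 5-point Laplacian with reflect boundary.
// [[Rcpp::export]]
NumericMatrix laplacian_cpp(NumericMatrix img) {
  int ny = img.nrow(), nx = img.ncol();
  NumericMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      out(y, x) = img(reflect_idx(y - 1, ny), x) + img(reflect_idx(y + 1, ny), x) +
                  img(y, reflect_idx(x - 1, nx)) + img(y, reflect_idx(x + 1, nx)) -
                  4.0 * img(y, x);
  return out;
}

// Connected-component labelling of a logical mask, connectivity 4 or 8.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  const int dy8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[] = {-1, 1, 0, 0};
  const int dx4[] = {0, 0, -1, 1};
  int nn = (connectivity == 4) ? 4 : 8;
  const int *DY = (connectivity == 4) ? dy4 : dy8;
  const int *DX = (connectivity == 4) ? dx4 : dx8;
  for (int x0 = 0; x0 < nx; ++x0)
    for (int y0 = 0; y0 < ny; ++y0) {
      if (!mask(y0, x0) || lab(y0, x0)) continue;
      ++next;
      stack.push_back(std::make_pair(y0, x0));
      lab(y0, x0) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int i = 0; i < nn; ++i) {
          int y = p.first + DY[i], x = p.second + DX[i];
          if (y < 0 || y >= ny || x < 0 || x >= nx) continue;
          if (mask(y, x) && !lab(y, x)) {
            lab(y, x) = next;
            stack.push_back(std::make_pair(y, x));
          }
        }
      }
    }
  return lab;
}

// Pixels of a label image farther than radius_px (Euclidean) from any pixel
// carrying a different label (or the image edge counts as same label).
// Used to build membrane bands by subtracting this interior from each cell.
// [[Rcpp::export]]
LogicalMatrix label_interior_cpp(IntegerMatrix labels, double radius_px) {
  int ny = labels.nrow(), nx = labels.ncol();
  int r = (int)std::floor(radius_px);
  std::vector<std::pair<int, int> > disc;
  for (int dy = -r - 1; dy <= r + 1; ++dy)
    for (int dx = -r - 1; dx <= r + 1; ++dx)
      if ((double)dy * dy + (double)dx * dx <= radius_px * radius_px)
        disc.push_back(std::make_pair(dy, dx));
  LogicalMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      int l = labels(y, x);
      if (l == 0) { out(y, x) = false; continue; }
      bool interior = true;
      for (size_t i = 0; i < disc.size() && interior; ++i) {
        int yy = y + disc[i].first, xx = x + disc[i].second;
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        if (labels(yy, xx) != l) interior = false;
      }
      out(y, x) = interior;
    }
  return out;
}
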