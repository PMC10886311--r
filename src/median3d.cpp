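#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Reflect an out-of-range index back into [0, n-1] (mirror without repeating
// the border sample beyond once; matches symmetric padding for radius < n).
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
Rcpp::NumericVector median_filter_3d_cpp(Rcpp::NumericVector vol,
                                         Rcpp::IntegerVector dims,
                                         Rcpp::IntegerVector radius) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int rz = radius[0], ry = radius[1], rx = radius[2];
  Rcpp::NumericVector out(vol.size());
  const int wlen = (2 * rz + 1) * (2 * ry + 1) * (2 * rx + 1);
  std::vector<double> win(wlen);
  // column-major layout of an R array dim (nz, ny, nx): idx = z + nz*(y + ny*x)
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        int k = 0;
        for (int dx = -rx; dx <= rx; ++dx) {
          const int xx = reflect(x + dx, nx);
          for (int dy = -ry; dy <= ry; ++dy) {
            const int yy = reflect(y + dy, ny);
            const long base = (long)nz * (yy + (long)ny * xx);
            for (int dz = -rz; dz <= rz; ++dz)
              win[k++] = vol[reflect(z + dz, nz) + base];
          }
        }
        std::nth_element(win.begin(), win.begin() + wlen / 2, win.end());
        double med = win[wlen / 2];
        if (wlen % 2 == 0) {
          // even window: average the two central order statistics
          double lo = *std::max_element(win.begin(), win.begin() + wlen / 2);
          med = 0.5 * (med + lo);
        }
        out[z + (long)nz * (y + (long)ny * x)] = med;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
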