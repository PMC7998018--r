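#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Paint a filled disc onto a size x size frame stored column-major.
static void paint_disc(double *img, int size, double cx, double cy, double r,
                       double val) {
  int x0 = std::max(0, (int)std::floor(cx - r));
  int x1 = std::min(size - 1, (int)std::ceil(cx + r));
  int y0 = std::max(0, (int)std::floor(cy - r));
  int y1 = std::min(size - 1, (int)std::ceil(cy + r));
  double r2 = r * r;
  for (int y = y0; y <= y1; ++y) {
    double dy = y - cy;
    for (int x = x0; x <= x1; ++x) {
      double dx = x - cx;
      if (dx * dx + dy * dy <= r2) img[x + size * y] = val;
    }
  }
}

//' @noRd
// [[Rcpp::export]]
NumericVector render_stack_cpp(int size, IntegerVector stage, LogicalVector pn,
                               LogicalVector degraded, List layouts,
                               NumericMatrix pn_discs, int n_speckles,
                               NumericVector par) {
  // par: bg, well_r, well_val, cyto_val, speckle_r, speckle_val, pn_val,
  //      noise_sd, emb_r, degrade_gain, degrade_offset, degrade_noise
  const double bg = par[0], well_r = par[1] * size, well_val = par[2],
               cyto = par[3], spk_r = par[4] * size, spk_val = par[5],
               pn_val = par[6], noise_sd = par[7], dg = par[8], doff = par[9],
               dnoise = par[10];
  const int n = stage.size();
  const double c0 = (size - 1) / 2.0;
  NumericVector out(Dimension(size, size, n));
  const int npix = size * size;

  for (int f = 0; f < n; ++f) {
    double *img = &out[(R_xlen_t)f * npix];
    for (int i = 0; i < npix; ++i) img[i] = bg;
    paint_disc(img, size, c0, c0, well_r, well_val);
    int k = stage[f];
    if (k < 1) k = 1;
    if (k > 5) k = 5;
    NumericMatrix lay = layouts[k - 1];
    for (int d = 0; d < lay.nrow(); ++d)
      paint_disc(img, size, c0 + lay(d, 0) * size, c0 + lay(d, 1) * size,
                 lay(d, 2) * size, cyto);
    // cytoplasmic fragmentation speckles, confined to the blastomeres so the
    // thresholded cell mask stays connected per cell
    for (int s = 0; s < n_speckles; ++s) {
      int d = (int)(unif_rand() * lay.nrow());
      if (d >= lay.nrow()) d = lay.nrow() - 1;
      double rmax = 0.8 * lay(d, 2) * size;
      double rr = rmax * std::sqrt(unif_rand());
      double th = 2.0 * M_PI * unif_rand();
      paint_disc(img, size, c0 + lay(d, 0) * size + rr * std::cos(th),
                 c0 + lay(d, 1) * size + rr * std::sin(th), spk_r, spk_val);
    }
    if (pn[f]) {
      for (int d = 0; d < pn_discs.nrow(); ++d)
        paint_disc(img, size, c0 + pn_discs(d, 0) * size,
                   c0 + pn_discs(d, 1) * size, pn_discs(d, 2) * size, pn_val);
    }
    if (degraded[f]) {
      for (int i = 0; i < npix; ++i)
        img[i] = doff + dg * img[i] + dnoise * norm_rand();
    }
    for (int i = 0; i < npix; ++i) {
      double v = img[i] + noise_sd * norm_rand();
      img[i] = v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
    }
  }
  return out;
}

// Connected components (8-connectivity) of a binary mask; returns component
// areas sorted descending. Labels buffer is caller-provided scratch.
static void comp_areas(const std::vector<char> &mask, int size,
                       std::vector<int> &areas) {
  areas.clear();
  const int npix = size * size;
  std::vector<int> lab(npix, 0);
  std::vector<int> stack;
  int next = 0;
  for (int p = 0; p < npix; ++p) {
    if (!mask[p] || lab[p]) continue;
    ++next;
    int area = 0;
    stack.push_back(p);
    lab[p] = next;
    while (!stack.empty()) {
      int q = stack.back();
      stack.pop_back();
      ++area;
      int x = q % size, y = q / size;
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy) continue;
          int nx = x + dx, ny = y + dy;
          if (nx < 0 || nx >= size || ny < 0 || ny >= size) continue;
          int np = nx + size * ny;
          if (mask[np] && !lab[np]) {
            lab[np] = next;
            stack.push_back(np);
          }
        }
      }
    }
    areas.push_back(area);
  }
  std::sort(areas.begin(), areas.end(), std::greater<int>());
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix stack_features_cpp(NumericVector arr, double mask_thr,
                                 double bright_thr, int min_area,
                                 int min_bright_area) {
  IntegerVector dim = arr.attr("dim");
  const int size = dim[0];
  const int n = dim[2];
  const int npix = size * size;
  const int nf = 12;
  NumericMatrix out(n, nf);
  std::vector<char> mask(npix), bright(npix);
  std::vector<int> areas;

  for (int f = 0; f < n; ++f) {
    const double *img = &arr[(R_xlen_t)f * npix];
    double s = 0, s2 = 0, ms = 0, ms2 = 0;
    int nm = 0, nb = 0, perim = 0;
    for (int p = 0; p < npix; ++p) {
      double v = img[p];
      s += v;
      s2 += v * v;
      mask[p] = v > mask_thr;
      bright[p] = v > bright_thr;
      if (mask[p]) {
        ++nm;
        ms += v;
        ms2 += v * v;
      }
      if (bright[p]) ++nb;
    }
    // 4-neighbour boundary pixels of the mask
    for (int y = 0; y < size; ++y) {
      for (int x = 0; x < size; ++x) {
        int p = x + size * y;
        if (!mask[p]) continue;
        if (x == 0 || x == size - 1 || y == 0 || y == size - 1 ||
            !mask[p - 1] || !mask[p + 1] || !mask[p - size] || !mask[p + size])
          ++perim;
      }
    }
    comp_areas(mask, size, areas);
    int ncomp = 0;
    double a1 = 0, a2 = 0;
    for (size_t i = 0; i < areas.size(); ++i)
      if (areas[i] >= min_area) ++ncomp;
    if (areas.size() > 0) a1 = areas[0];
    if (areas.size() > 1) a2 = areas[1];
    comp_areas(bright, size, areas);
    int nbright = 0;
    double b1 = 0;
    for (size_t i = 0; i < areas.size(); ++i)
      if (areas[i] >= min_bright_area) ++nbright;
    if (areas.size() > 0) b1 = areas[0];

    double mean = s / npix;
    double var = s2 / npix - mean * mean;
    out(f, 0) = mean;
    out(f, 1) = var > 0 ? std::sqrt(var) : 0.0;
    out(f, 2) = (double)nm / npix;
    out(f, 3) = ncomp;
    out(f, 4) = a1 / npix;
    out(f, 5) = a2 / npix;
    out(f, 6) = (double)perim / npix;
    if (nm > 0) {
      double mm = ms / nm;
      double mv = ms2 / nm - mm * mm;
      out(f, 7) = mm;
      out(f, 8) = mv > 0 ? std::sqrt(mv) : 0.0;
    } else {
      out(f, 7) = 0.0;
      out(f, 8) = 0.0;
    }
    out(f, 9) = (double)nb / npix;
    out(f, 10) = nbright;
    out(f, 11) = b1 / npix;
  }
  colnames(out) = CharacterVector::create(
      "mean", "sd", "mask_frac", "n_comp", "area1", "area2", "perim",
      "mask_mean", "mask_sd", "bright_frac", "n_bright", "bright_area1");
  return out;
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix resize_bilinear_cpp(NumericMatrix img, int out_r, int out_c) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(out_r, out_c);
  for (int j = 0; j < out_c; ++j) {
    double y = (nc == 1 || out_c == 1) ? 0.0
                                       : (double)j * (nc - 1) / (out_c - 1);
    int y0 = (int)std::floor(y);
    int y1 = std::min(y0 + 1, nc - 1);
    double wy = y - y0;
    for (int i = 0; i < out_r; ++i) {
      double x = (nr == 1 || out_r == 1) ? 0.0
                                         : (double)i * (nr - 1) / (out_r - 1);
      int x0 = (int)std::floor(x);
      int x1 = std::min(x0 + 1, nr - 1);
      double wx = x - x0;
      out(i, j) = (1 - wx) * (1 - wy) * img(x0, y0) +
                  wx * (1 - wy) * img(x1, y0) + (1 - wx) * wy * img(x0, y1) +
                  wx * wy * img(x1, y1);
    }
  }
  return out;
}
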