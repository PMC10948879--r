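#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Bilinear sample of img at (continuous) 0-based (row, col); out-of-range -> fill.
static inline double sample_bilinear(const NumericMatrix &img, double r, double c,
                                     double fill) {
  int nr = img.nrow(), nc = img.ncol();
  if (r < 0 || c < 0 || r > nr - 1 || c > nc - 1) return fill;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = std::min(r0 + 1, nr - 1), c1 = std::min(c0 + 1, nc - 1);
  double fr = r - r0, fc = c - c0;
  return (1 - fr) * ((1 - fc) * img(r0, c0) + fc * img(r0, c1)) +
         fr * ((1 - fc) * img(r1, c0) + fc * img(r1, c1));
}

// Translate by (dx cols, dy rows): out(r, c) = in(r - dy, c - dx), bilinear,
// out-of-view filled with `fill`.
// [[Rcpp::export]]
NumericMatrix cpp_warp_translate(const NumericMatrix &img, double dx, double dy,
                                 double fill) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = sample_bilinear(img, r - dy, c - dx, fill);
  return out;
}

// Enhanced-correlation-coefficient maximization restricted to pure translation.
// Estimates (dx, dy) such that mov(r, c) ~ ref(r - dy, c - dx); i.e. the shift of
// `mov` relative to `ref`. Forward-additive Gauss-Newton on the ECC objective:
// at the current (dx, dy) the moving image is sampled back onto the reference
// grid, both images are zero-meaned over the valid overlap, and the translation
// update solves the 2x2 projected normal equations. Termination: correlation
// increment <= eps, or max_iter.
// [[Rcpp::export]]
List cpp_ecc_translation(const NumericMatrix &ref, const NumericMatrix &mov,
                         double dx0, double dy0, int max_iter, double eps) {
  int nr = ref.nrow(), nc = ref.ncol();
  if (mov.nrow() != nr || mov.ncol() != nc)
    stop("reference and moving images must have the same shape");
  double dx = dx0, dy = dy0;
  // central-difference gradients of the moving image
  NumericMatrix gx(nr, nc), gy(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int cm = std::max(c - 1, 0), cp = std::min(c + 1, nc - 1);
      int rm = std::max(r - 1, 0), rp = std::min(r + 1, nr - 1);
      gx(r, c) = (mov(r, cp) - mov(r, cm)) / (cp - cm);
      gy(r, c) = (mov(rp, c) - mov(rm, c)) / (rp - rm);
    }
  double rho = -2.0, last_rho = -2.0;
  int iter = 0;
  bool converged = false;
  std::string status = "max_iter";
  std::vector<double> iw(nr * nc), ir(nr * nc), jx(nr * nc), jy(nr * nc);
  std::vector<char> valid(nr * nc);
  for (iter = 0; iter < max_iter; ++iter) {
    // sample moving (and its gradients) on the reference grid
    long nvalid = 0;
    double sum_w = 0, sum_r = 0;
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        long k = (long)c * nr + r;
        double rr = r + dy, cc = c + dx;
        if (rr < 0 || cc < 0 || rr > nr - 1 || cc > nc - 1) {
          valid[k] = 0;
          continue;
        }
        valid[k] = 1;
        iw[k] = sample_bilinear(mov, rr, cc, 0.0);
        jx[k] = sample_bilinear(gx, rr, cc, 0.0);
        jy[k] = sample_bilinear(gy, rr, cc, 0.0);
        ir[k] = ref(r, c);
        sum_w += iw[k];
        sum_r += ir[k];
        ++nvalid;
      }
    if (nvalid < 64) {
      status = "no_overlap";
      break;
    }
    double mw = sum_w / nvalid, mr = sum_r / nvalid;
    // zero-mean projections and inner products
    double Qxx = 0, Qxy = 0, Qyy = 0, mgx = 0, mgy = 0;
    for (long k = 0; k < (long)nr * nc; ++k)
      if (valid[k]) {
        mgx += jx[k];
        mgy += jy[k];
      }
    mgx /= nvalid;
    mgy /= nvalid;
    double Gw_x = 0, Gw_y = 0, Gr_x = 0, Gr_y = 0;
    double nw2 = 0, nr2 = 0, rw = 0;
    for (long k = 0; k < (long)nr * nc; ++k)
      if (valid[k]) {
        double w = iw[k] - mw, t = ir[k] - mr;
        double ax = jx[k] - mgx, ay = jy[k] - mgy;
        Qxx += ax * ax;
        Qxy += ax * ay;
        Qyy += ay * ay;
        Gw_x += ax * w;
        Gw_y += ay * w;
        Gr_x += ax * t;
        Gr_y += ay * t;
        nw2 += w * w;
        nr2 += t * t;
        rw += w * t;
      }
    double det = Qxx * Qyy - Qxy * Qxy;
    if (det <= 1e-12 || nw2 <= 0 || nr2 <= 0) {
      status = "degenerate";
      break;
    }
    rho = rw / std::sqrt(nw2 * nr2);
    if (iter > 0 && std::fabs(rho - last_rho) <= eps) {
      converged = true;
      status = "eps";
      break;
    }
    last_rho = rho;
    // Qinv * Gw and Qinv * Gr
    double iQxx = Qyy / det, iQxy = -Qxy / det, iQyy = Qxx / det;
    double qw_x = iQxx * Gw_x + iQxy * Gw_y, qw_y = iQxy * Gw_x + iQyy * Gw_y;
    double num = nw2 - (Gw_x * qw_x + Gw_y * qw_y);
    double den = rw - (Gr_x * qw_x + Gr_y * qw_y);
    if (den <= 0) {
      status = "uncorrelated";
      break;
    }
    double lambda = num / den;
    // error = lambda * ir0 - iw0 ; dp = Qinv * G' * error
    double ex = lambda * Gr_x - Gw_x, ey = lambda * Gr_y - Gw_y;
    double ddx = iQxx * ex + iQxy * ey;
    double ddy = iQxy * ex + iQyy * ey;
    dx += ddx;
    dy += ddy;
    if (!std::isfinite(dx) || !std::isfinite(dy)) {
      status = "diverged";
      break;
    }
  }
  return List::create(_["dx"] = dx, _["dy"] = dy, _["rho"] = rho,
                      _["iterations"] = iter + 1, _["converged"] = converged,
                      _["status"] = status);
}

// Connected-component labeling of a binary mask, 8- or 4-connectivity.
// Labels are positive integers assigned in column-major first-encounter order.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix &mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<long> stack;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  int nn = connectivity == 8 ? 8 : 4;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back((long)c * nr + r);
      while (!stack.empty()) {
        long k = stack.back();
        stack.pop_back();
        int cr = (int)(k % nr), cc = (int)(k / nr);
        for (int i = 0; i < nn; ++i) {
          int r2 = cr + dr[i], c2 = cc + dc[i];
          if (r2 < 0 || c2 < 0 || r2 >= nr || c2 >= nc) continue;
          if (mask(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            stack.push_back((long)c2 * nr + r2);
          }
        }
      }
    }
  return lab;
}

struct WsNode {
  double value;
  long order;
  int r, c, label;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.value != b.value) return a.value < b.value;  // higher value first
    return a.order > b.order;                          // FIFO tie-break
  }
};

// Marker-based watershed: flood from labeled markers over the relief `height`
// (flooding from high to low values, i.e. the relief is the probability map and
// regions grow downhill), restricted to `fg`. 4-connected growth; deterministic
// via insertion-order tie-break.
// [[Rcpp::export]]
IntegerMatrix cpp_marker_watershed(const NumericMatrix &height,
                                   const IntegerMatrix &markers,
                                   const LogicalMatrix &fg) {
  int nr = height.nrow(), nc = height.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (markers(r, c) > 0 && fg(r, c)) {
        lab(r, c) = markers(r, c);
        pq.push({height(r, c), order++, r, c, markers(r, c)});
      }
  const int dr[4] = {-1, 0, 0, 1}, dc[4] = {0, -1, 1, 0};
  while (!pq.empty()) {
    WsNode n = pq.top();
    pq.pop();
    for (int i = 0; i < 4; ++i) {
      int r2 = n.r + dr[i], c2 = n.c + dc[i];
      if (r2 < 0 || c2 < 0 || r2 >= nr || c2 >= nc) continue;
      if (!fg(r2, c2) || lab(r2, c2)) continue;
      lab(r2, c2) = n.label;
      pq.push({height(r2, c2), order++, r2, c2, n.label});
    }
  }
  return lab;
}

// Separable convolution with a 1-D kernel applied along rows then columns,
// zero-padded boundary. Kernel length must be odd.
// [[Rcpp::export]]
NumericMatrix cpp_sep_convolve(const NumericMatrix &img,
                               const NumericVector &kernel) {
  int nr = img.nrow(), nc = img.ncol(), kl = kernel.size();
  int h = kl / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // vertical pass: kernel taps outermost, contiguous column runs inside
  for (int c = 0; c < nc; ++c) {
    const double *src = &img(0, c);
    double *dst = &tmp(0, c);
    for (int j = 0; j < kl; ++j) {
      double w = kernel[j];
      int off = j - h;  // dst[r] += w * src[r + off]
      int r0 = std::max(0, -off), r1 = std::min(nr, nr - off);
      for (int r = r0; r < r1; ++r) dst[r] += w * src[r + off];
    }
  }
  // horizontal pass: accumulate whole source columns into each output column
  for (int c = 0; c < nc; ++c) {
    double *dst = &out(0, c);
    int j0 = std::max(0, h - c), j1 = std::min(kl, nc - c + h);
    for (int j = j0; j < j1; ++j) {
      double w = kernel[j];
      const double *src = &tmp(0, c + j - h);
      for (int r = 0; r < nr; ++r) dst[r] += w * src[r];
    }
  }
  return out;
}

// Variance of the 3x3 five-point Laplacian response (center -4, cross +1),
// evaluated on the interior of the frame in double precision. Population
// variance, matching the usual image-processing convention.
// [[Rcpp::export]]
double cpp_laplacian_variance(const NumericMatrix &img) {
  int nr = img.nrow(), nc = img.ncol();
  if (nr < 3 || nc < 3) return 0.0;
  double s = 0, s2 = 0;
  long n = 0;
  for (int c = 1; c < nc - 1; ++c)
    for (int r = 1; r < nr - 1; ++r) {
      double v = img(r - 1, c) + img(r + 1, c) + img(r, c - 1) + img(r, c + 1) -
                 4.0 * img(r, c);
      s += v;
      s2 += v * v;
      ++n;
    }
  double m = s / n;
  return s2 / n - m * m;
}
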