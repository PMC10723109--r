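#include <Rcpp.h>
using namespace Rcpp;

// Area of the intersection of a convex quadrilateral with an axis-aligned
// rectangle, for many quads at once. Quads are given by 4 vertices in order
// (rows of qx/qy, N x 4); rectangles by [rx0,rx1] x [ry0,ry1] (recycled if
// length 1). Sutherland-Hodgman clipping followed by the shoelace formula.
// [[Rcpp::export]]
NumericVector clip_quad_rect_area(NumericMatrix qx, NumericMatrix qy,
                                  NumericVector rx0, NumericVector rx1,
                                  NumericVector ry0, NumericVector ry1) {
  const int n = qx.nrow();
  NumericVector out(n);
  const bool rec = rx0.size() == 1;
  double px[16], py[16], cx[16], cy[16];
  for (int e = 0; e < n; ++e) {
    int np = 4;
    for (int i = 0; i < 4; ++i) { px[i] = qx(e, i); py[i] = qy(e, i); }
    const double b[4] = {rec ? rx0[0] : rx0[e], rec ? rx1[0] : rx1[e],
                         rec ? ry0[0] : ry0[e], rec ? ry1[0] : ry1[e]};
    // clip against x>=b0, x<=b1, y>=b2, y<=b3
    for (int side = 0; side < 4 && np > 0; ++side) {
      int nc = 0;
      for (int i = 0; i < np; ++i) {
        int j = (i + 1) % np;
        double xi = px[i], yi = py[i], xj = px[j], yj = py[j];
        double di, dj;
        switch (side) {
          case 0: di = xi - b[0]; dj = xj - b[0]; break;
          case 1: di = b[1] - xi; dj = b[1] - xj; break;
          case 2: di = yi - b[2]; dj = yj - b[2]; break;
          default: di = b[3] - yi; dj = b[3] - yj; break;
        }
        if (di >= 0) { cx[nc] = xi; cy[nc] = yi; ++nc; }
        if ((di > 0 && dj < 0) || (di < 0 && dj > 0)) {
          double t = di / (di - dj);
          cx[nc] = xi + t * (xj - xi);
          cy[nc] = yi + t * (yj - yi);
          ++nc;
        }
      }
      np = nc;
      for (int i = 0; i < np; ++i) { px[i] = cx[i]; py[i] = cy[i]; }
    }
    double a = 0.0;
    for (int i = 0; i < np; ++i) {
      int j = (i + 1) % np;
      a += px[i] * py[j] - px[j] * py[i];
    }
    out[e] = std::fabs(a) / 2.0;
  }
  return out;
}

// Per-column maximum of a dgCMatrix given its slot vectors (zero-absent
// columns give 0). Used for slice maxima of the Compton response matrix.
// [[Rcpp::export]]
NumericVector col_max_sparse(IntegerVector p, NumericVector x, int ncol) {
  NumericVector out(ncol);
  for (int c = 0; c < ncol; ++c) {
    double m = 0.0;
    for (int k = p[c]; k < p[c + 1]; ++k) if (x[k] > m) m = x[k];
    out[c] = m;
  }
  return out;
}

// Sum, per column, of entries strictly below thr * (column max).
// [[Rcpp::export]]
NumericVector col_mass_below(IntegerVector p, NumericVector x, int ncol,
                             double thr) {
  NumericVector out(ncol);
  for (int c = 0; c < ncol; ++c) {
    double m = 0.0;
    for (int k = p[c]; k < p[c + 1]; ++k) if (x[k] > m) m = x[k];
    double cut = thr * m, s = 0.0;
    for (int k = p[c]; k < p[c + 1]; ++k) if (x[k] < cut) s += x[k];
    out[c] = s;
  }
  return out;
}
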