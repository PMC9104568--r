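#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::vector<double> vd;

// Shoelace area of a (possibly unordered-sign) simple polygon.
static double poly_area(const vd& x, const vd& y) {
  const int n = (int)x.size();
  if (n < 3) return 0.0;
  double a = 0.0;
  for (int i = 0, j = n - 1; i < n; j = i++)
    a += x[j] * y[i] - x[i] * y[j];
  return 0.5 * std::fabs(a);
}

// Sutherland-Hodgman clip of polygon (x, y) by half-plane a*px + b*py <= c.
static void clip_halfplane(vd& x, vd& y, double a, double b, double c) {
  const int n = (int)x.size();
  if (n == 0) return;
  vd nx, ny;
  nx.reserve(n + 4);
  ny.reserve(n + 4);
  for (int i = 0; i < n; ++i) {
    const int j = (i + 1) % n;
    const double di = a * x[i] + b * y[i] - c;
    const double dj = a * x[j] + b * y[j] - c;
    if (di <= 0.0) {
      nx.push_back(x[i]);
      ny.push_back(y[i]);
    }
    if ((di < 0.0 && dj > 0.0) || (di > 0.0 && dj < 0.0)) {
      const double t = di / (di - dj);
      nx.push_back(x[i] + t * (x[j] - x[i]));
      ny.push_back(y[i] + t * (y[j] - y[i]));
    }
  }
  x.swap(nx);
  y.swap(ny);
}

// Sibson weights of one query point against all sites, by direct construction
// of the inserted point's Voronoi cell and its overlaps with each site's cell.
// Returns false (exterior) when the query's cell is unbounded, i.e. touches
// the enclosing box: that happens exactly when the query lies outside the
// sites' convex hull.
static bool sibson_one(const NumericMatrix& S, double qx, double qy,
                       double xlo, double xhi, double ylo, double yhi,
                       vd& w) {
  const int n = S.nrow();
  vd cx, cy;
  cx.assign({xlo, xhi, xhi, xlo});
  cy.assign({ylo, ylo, yhi, yhi});
  for (int j = 0; j < n; ++j) {
    const double ax = S(j, 0) - qx, ay = S(j, 1) - qy;
    const double c = 0.5 * (ax * (qx + S(j, 0)) + ay * (qy + S(j, 1)));
    clip_halfplane(cx, cy, ax, ay, c);
    if (cx.empty()) return false;
  }
  const double tol = 1e-9 * (std::fabs(xhi - xlo) + std::fabs(yhi - ylo));
  for (size_t k = 0; k < cx.size(); ++k) {
    if (cx[k] - xlo < tol || xhi - cx[k] < tol ||
        cy[k] - ylo < tol || yhi - cy[k] < tol)
      return false;
  }
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    vd ox = cx, oy = cy;
    for (int j = 0; j < n && !ox.empty(); ++j) {
      if (j == i) continue;
      const double ax = S(j, 0) - S(i, 0), ay = S(j, 1) - S(i, 1);
      const double c = 0.5 * (ax * (S(i, 0) + S(j, 0)) + ay * (S(i, 1) + S(j, 1)));
      clip_halfplane(ox, oy, ax, ay, c);
    }
    const double a = poly_area(ox, oy);
    w[i] = a;
    tot += a;
  }
  if (!(tot > 0.0)) return false;
  for (int i = 0; i < n; ++i) w[i] /= tot;
  return true;
}

static int nearest_site(const NumericMatrix& S, double qx, double qy,
                        double* d2_out) {
  int best = 0;
  double bd = R_PosInf;
  for (int i = 0; i < S.nrow(); ++i) {
    const double dx = S(i, 0) - qx, dy = S(i, 1) - qy;
    const double d2 = dx * dx + dy * dy;
    if (d2 < bd) {
      bd = d2;
      best = i;
    }
  }
  if (d2_out) *d2_out = bd;
  return best;
}

static void site_bbox(const NumericMatrix& S, double pad_factor,
                      double& xlo, double& xhi, double& ylo, double& yhi) {
  xlo = ylo = R_PosInf;
  xhi = yhi = R_NegInf;
  for (int i = 0; i < S.nrow(); ++i) {
    xlo = std::min(xlo, S(i, 0));
    xhi = std::max(xhi, S(i, 0));
    ylo = std::min(ylo, S(i, 1));
    yhi = std::max(yhi, S(i, 1));
  }
  double span = std::max(xhi - xlo, yhi - ylo);
  if (span <= 0.0) span = 1.0;
  const double pad = pad_factor * span;
  xlo -= pad; xhi += pad; ylo -= pad; yhi += pad;
}

// [[Rcpp::export]]
List cpp_sibson(NumericMatrix sites, NumericVector values,
                NumericMatrix queries) {
  const int n = sites.nrow(), m = queries.nrow();
  NumericVector out(m);
  LogicalVector exterior(m);
  double xlo, xhi, ylo, yhi;
  site_bbox(sites, 10.0, xlo, xhi, ylo, yhi);
  const double span = std::max(xhi - xlo, yhi - ylo);
  const double coincide2 = 1e-18 * span * span;
  vd w((size_t)n);
  for (int q = 0; q < m; ++q) {
    const double qx = queries(q, 0), qy = queries(q, 1);
    double d2;
    const int ns = nearest_site(sites, qx, qy, &d2);
    if (d2 <= coincide2) {
      out[q] = values[ns];
      exterior[q] = false;
      continue;
    }
    if (sibson_one(sites, qx, qy, xlo, xhi, ylo, yhi, w)) {
      double v = 0.0;
      for (int i = 0; i < n; ++i) v += w[i] * values[i];
      out[q] = v;
      exterior[q] = false;
    } else {
      out[q] = values[ns];  // nearest-site fallback outside the hull
      exterior[q] = true;
    }
  }
  return List::create(_["value"] = out, _["exterior"] = exterior);
}

// [[Rcpp::export]]
List cpp_sibson_weights(NumericMatrix sites, NumericMatrix queries) {
  const int n = sites.nrow(), m = queries.nrow();
  NumericMatrix W(m, n);
  LogicalVector exterior(m);
  double xlo, xhi, ylo, yhi;
  site_bbox(sites, 10.0, xlo, xhi, ylo, yhi);
  const double span = std::max(xhi - xlo, yhi - ylo);
  const double coincide2 = 1e-18 * span * span;
  vd w((size_t)n);
  for (int q = 0; q < m; ++q) {
    const double qx = queries(q, 0), qy = queries(q, 1);
    double d2;
    const int ns = nearest_site(sites, qx, qy, &d2);
    if (d2 <= coincide2) {
      for (int i = 0; i < n; ++i) W(q, i) = (i == ns) ? 1.0 : 0.0;
      continue;
    }
    if (sibson_one(sites, qx, qy, xlo, xhi, ylo, yhi, w)) {
      for (int i = 0; i < n; ++i) W(q, i) = w[i];
    } else {
      for (int i = 0; i < n; ++i) W(q, i) = NA_REAL;
      exterior[q] = true;
    }
  }
  return List::create(_["weights"] = W, _["exterior"] = exterior);
}

// 8-connected component labelling of equal nonzero values.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  int next_label = 0;
  std::vector<std::pair<int, int> > stack;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (m(r0, c0) == 0 || m(r0, c0) == NA_INTEGER || lab(r0, c0) != 0)
        continue;
      const int v = m(r0, c0);
      ++next_label;
      stack.clear();
      stack.push_back(std::make_pair(r0, c0));
      lab(r0, c0) = next_label;
      while (!stack.empty()) {
        const int r = stack.back().first, c = stack.back().second;
        stack.pop_back();
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            const int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (lab(rr, cc) == 0 && m(rr, cc) == v) {
              lab(rr, cc) = next_label;
              stack.push_back(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}
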