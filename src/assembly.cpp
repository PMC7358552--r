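#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Abundance-weighted beta mean nearest taxon distance for one pair.
// xi/yi: 0-based taxon indices into D; xf/yf: relative abundances.
static double pair_bmntd(const NumericMatrix& D,
                         const std::vector<int>& xi,
                         const NumericVector& xf,
                         const std::vector<int>& yi,
                         const NumericVector& yf) {
  double s = 0.0;
  const int nx = xi.size(), ny = yi.size();
  for (int a = 0; a < nx; ++a) {
    double m = R_PosInf;
    const int ia = xi[a];
    for (int b = 0; b < ny; ++b) {
      const double d = D(ia, yi[b]);
      if (d < m) m = d;
    }
    s += xf[a] * m;
  }
  for (int b = 0; b < ny; ++b) {
    double m = R_PosInf;
    const int ib = yi[b];
    for (int a = 0; a < nx; ++a) {
      const double d = D(ib, xi[a]);
      if (d < m) m = d;
    }
    s += yf[b] * m;
  }
  return 0.5 * s;
}

// [[Rcpp::export]]
double cpp_bmntd(const NumericMatrix& D, const IntegerVector& xi,
                 const NumericVector& xf, const IntegerVector& yi,
                 const NumericVector& yf) {
  std::vector<int> x(xi.begin(), xi.end()), y(yi.begin(), yi.end());
  return pair_bmntd(D, x, xf, y, yf);
}

// Null betaMNTD distribution: tip labels shuffled uniformly across all
// tips of the tree (regional-pool randomization). Shared taxa map to the
// same shuffled index, so their zero self-distance is preserved.
// [[Rcpp::export]]
NumericVector cpp_bmntd_null(const NumericMatrix& D, const IntegerVector& xi,
                             const NumericVector& xf, const IntegerVector& yi,
                             const NumericVector& yf, int n_null) {
  const int S = D.nrow();
  NumericVector out(n_null);
  std::vector<int> xs(xi.size()), ys(yi.size());
  for (int k = 0; k < n_null; ++k) {
    IntegerVector perm = sample(S, S, false);  // R RNG, 1-based
    for (int a = 0; a < (int)xs.size(); ++a) xs[a] = perm[xi[a]] - 1;
    for (int b = 0; b < (int)ys.size(); ++b) ys[b] = perm[yi[b]] - 1;
    out[k] = pair_bmntd(D, xs, xf, ys, yf);
  }
  return out;
}

// Weighted sampling of r items without replacement, prob proportional to
// w (Efraimidis-Spirakis exponential keys).
static void wsample(int r, const NumericVector& w,
                    std::vector<std::pair<double, int> >& keys,
                    std::vector<int>& out) {
  const int S = w.size();
  for (int i = 0; i < S; ++i) {
    keys[i].first = (w[i] > 0.0) ? R::exp_rand() / w[i] : R_PosInf;
    keys[i].second = i;
  }
  std::partial_sort(keys.begin(), keys.begin() + r, keys.end());
  out.resize(r);
  for (int i = 0; i < r; ++i) out[i] = keys[i].second;
}

// Null Bray-Curtis distribution for the Raup-Crick metric. Each null
// community preserves the observed richness and total count of its
// sample: taxa are drawn without replacement with probability
// proportional to occupancy across the metacommunity, then counts are
// allocated multinomially with probabilities proportional to
// metacommunity-wide relative abundances of the selected taxa.
// [[Rcpp::export]]
NumericVector cpp_rc_null_bc(const NumericVector& occ,
                             const NumericVector& relab,
                             int rx, int nx, int ry, int ny, int n_null) {
  const int S = occ.size();
  NumericVector out(n_null);
  std::vector<std::pair<double, int> > keys(S);
  std::vector<int> ix, iy;
  std::vector<double> px, py;
  std::vector<int> cx(S, 0), cy(S, 0);
  std::vector<char> inX(S, 0);
  std::vector<int> mx, my;
  for (int k = 0; k < n_null; ++k) {
    wsample(rx, occ, keys, ix);
    wsample(ry, occ, keys, iy);
    // multinomial allocation proportional to metacommunity abundance
    px.resize(rx); py.resize(ry);
    double sx = 0.0, sy = 0.0;
    for (int a = 0; a < rx; ++a) { px[a] = relab[ix[a]]; sx += px[a]; }
    for (int b = 0; b < ry; ++b) { py[b] = relab[iy[b]]; sy += py[b]; }
    for (int a = 0; a < rx; ++a) px[a] = (sx > 0) ? px[a] / sx : 1.0 / rx;
    for (int b = 0; b < ry; ++b) py[b] = (sy > 0) ? py[b] / sy : 1.0 / ry;
    mx.assign(rx, 0); my.assign(ry, 0);
    R::rmultinom(nx, px.data(), rx, mx.data());
    R::rmultinom(ny, py.data(), ry, my.data());
    for (int a = 0; a < rx; ++a) { cx[ix[a]] = mx[a]; inX[ix[a]] = 1; }
    for (int b = 0; b < ry; ++b) cy[iy[b]] = my[b];
    double num = 0.0;
    for (int a = 0; a < rx; ++a) num += std::abs(cx[ix[a]] - cy[ix[a]]);
    for (int b = 0; b < ry; ++b)
      if (!inX[iy[b]]) num += std::abs(cy[iy[b]]);  // y-only taxa
    out[k] = num / double(nx + ny);
    for (int a = 0; a < rx; ++a) { cx[ix[a]] = 0; inX[ix[a]] = 0; }
    for (int b = 0; b < ry; ++b) cy[iy[b]] = 0;
  }
  return out;
}
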