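#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Leave-one-out Brownian bridge likelihood machinery.
//
// For an interior fix z_k between its neighbouring anchors z_a (t_a) and
// z_b (t_b), with alpha = (t_k - t_a) / (t_b - t_a), the bridge predicts
//   z_k ~ N2( z_a + alpha (z_b - z_a),
//             alpha (1-alpha) (t_b - t_a) s2 + (1-alpha)^2 e_a^2 + alpha^2 e_b^2 )
// per axis, where s2 is the Brownian motion variance (m^2/s) and e are the
// fix location-error SDs. Each odd-indexed interior fix of a sliding window
// is left out and scored this way; s2 maximizes the summed log density.

struct LooPoint {
  double d2;   // squared deviation from the bridge mean (both axes summed)
  double a;    // alpha (1-alpha) (t_b - t_a): coefficient of s2 in variance
  double e;    // (1-alpha)^2 e_a^2 + alpha^2 e_b^2: error floor of variance
  int fix;     // index of the left-out fix (0-based, within whole track)
};

// negative log-likelihood of a point set at motion variance s2
static double nll_points(const std::vector<LooPoint>& pts, int lo, int hi,
                         double s2) {
  double nll = 0.0;
  for (int i = lo; i < hi; ++i) {
    double v = pts[i].a * s2 + pts[i].e;
    if (v <= 0) v = 1e-300;
    nll += std::log(2.0 * M_PI * v) + pts[i].d2 / (2.0 * v);
  }
  return nll;
}

// golden-section minimization of nll over log(s2) in [log(lo), log(hi)]
static double mle_s2(const std::vector<LooPoint>& pts, int lo, int hi,
                     double s2_lo, double s2_hi, double* nll_out) {
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double a = std::log(s2_lo), b = std::log(s2_hi);
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = nll_points(pts, lo, hi, std::exp(c));
  double fd = nll_points(pts, lo, hi, std::exp(d));
  for (int it = 0; it < 80 && (b - a) > 1e-8; ++it) {
    if (fc < fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a);
      fc = nll_points(pts, lo, hi, std::exp(c));
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a);
      fd = nll_points(pts, lo, hi, std::exp(d));
    }
  }
  double s2 = std::exp(0.5 * (a + b));
  if (nll_out) *nll_out = nll_points(pts, lo, hi, s2);
  return s2;
}

// Build leave-out points for fixes [from, to) of one burst: every odd offset
// interior fix, anchored on its immediate neighbours.
static std::vector<LooPoint> loo_points(const NumericVector& x,
                                        const NumericVector& y,
                                        const NumericVector& t,
                                        const NumericVector& err,
                                        int from, int to) {
  std::vector<LooPoint> pts;
  for (int k = from + 1; k < to - 1; k += 2) {
    int ai = k - 1, bi = k + 1;
    double T = t[bi] - t[ai];
    if (T <= 0) continue;
    double alpha = (t[k] - t[ai]) / T;
    double mx = x[ai] + alpha * (x[bi] - x[ai]);
    double my = y[ai] + alpha * (y[bi] - y[ai]);
    double dx = x[k] - mx, dy = y[k] - my;
    LooPoint p;
    p.d2 = dx * dx + dy * dy;
    p.a = alpha * (1.0 - alpha) * T;
    p.e = (1.0 - alpha) * (1.0 - alpha) * err[ai] * err[ai] +
          alpha * alpha * err[bi] * err[bi];
    p.fix = k;
    pts.push_back(p);
  }
  return pts;
}

// [[Rcpp::export(name = ".cpp_motion_variance")]]
List cpp_motion_variance(NumericVector x, NumericVector y, NumericVector t,
                         NumericVector err, int window, int margin,
                         double max_gap_s, double s2_lo, double s2_hi) {
  int n = x.size();
  int nseg = n - 1;
  NumericVector seg_sum(nseg, 0.0);
  IntegerVector seg_cnt(nseg, 0);
  LogicalVector bridgeable(nseg);
  IntegerVector breaks;  // fix indices (1-based) where a BIC break was accepted

  for (int i = 0; i < nseg; ++i)
    bridgeable[i] = (t[i + 1] - t[i]) <= max_gap_s && (t[i + 1] - t[i]) > 0;

  // burst boundaries: runs of consecutive bridgeable segments
  int b0 = 0;
  std::vector<std::pair<int,int>> bursts;  // fix ranges [from, to)
  for (int i = 0; i <= nseg; ++i) {
    bool cut = (i == nseg) || !bridgeable[i];
    if (cut) {
      if (i + 1 - b0 >= 2) bursts.push_back(std::make_pair(b0, i + 1));
      b0 = i + 1;
    }
  }

  for (size_t bi = 0; bi < bursts.size(); ++bi) {
    int from = bursts[bi].first, to = bursts[bi].second;
    int nb = to - from;
    if (nb < window) {
      // short burst: static MLE over the whole burst (if it has interior points)
      std::vector<LooPoint> pts = loo_points(x, y, t, err, from, to);
      if (!pts.empty()) {
        double s2 = mle_s2(pts, 0, (int)pts.size(), s2_lo, s2_hi, nullptr);
        for (int s = from; s < to - 1; ++s) { seg_sum[s] += s2; seg_cnt[s]++; }
      }
      continue;
    }
    for (int ws = from; ws + window <= to; ++ws) {
      int we = ws + window;  // exclusive
      std::vector<LooPoint> pts = loo_points(x, y, t, err, ws, we);
      int m = (int)pts.size();
      if (m == 0) continue;
      double nll0;
      double s2_all = mle_s2(pts, 0, m, s2_lo, s2_hi, &nll0);
      double bic0 = 2.0 * nll0 + 1.0 * std::log((double)m);

      // single change point at fix offsets >= margin from both window edges
      double best_bic = bic0, best_s1 = s2_all, best_s2v = s2_all;
      int best_cut = -1;
      for (int cut = ws + margin; cut <= we - 1 - margin; ++cut) {
        // points strictly before the cut fix go left, the rest right
        int nl = 0;
        while (nl < m && pts[nl].fix < cut) nl++;
        if (nl == 0 || nl == m) continue;
        double nll1, nll2;
        double s1 = mle_s2(pts, 0, nl, s2_lo, s2_hi, &nll1);
        double s2v = mle_s2(pts, nl, m, s2_lo, s2_hi, &nll2);
        double bic1 = 2.0 * (nll1 + nll2) + 2.0 * std::log((double)m);
        if (bic1 < best_bic) {
          best_bic = bic1; best_cut = cut; best_s1 = s1; best_s2v = s2v;
        }
      }
      if (best_cut < 0) {
        for (int s = ws; s < we - 1; ++s) { seg_sum[s] += s2_all; seg_cnt[s]++; }
      } else {
        breaks.push_back(best_cut + 1);  // 1-based for R
        for (int s = ws; s < we - 1; ++s) {
          double v = (s < best_cut) ? best_s1 : best_s2v;
          seg_sum[s] += v; seg_cnt[s]++;
        }
      }
    }
  }

  NumericVector sigma2(nseg, NA_REAL);
  for (int s = 0; s < nseg; ++s)
    if (seg_cnt[s] > 0) sigma2[s] = seg_sum[s] / seg_cnt[s];

  return List::create(_["sigma2"] = sigma2,
                      _["bridgeable"] = bridgeable,
                      _["breaks"] = breaks);
}

// Accumulate Brownian bridge densities on a grid. Cell-centre evaluation;
// contributions truncated beyond trunc_sd bridge standard deviations.
// [[Rcpp::export(name = ".cpp_accumulate_ud")]]
NumericMatrix cpp_accumulate_ud(NumericVector x, NumericVector y,
                                NumericVector t, NumericVector err,
                                NumericVector sigma2, LogicalVector bridgeable,
                                double x0, double y0, double cell,
                                int nx, int ny, int alpha_steps,
                                double trunc_sd) {
  NumericMatrix dens(ny, nx);  // rows = y (row 0 at y0), cols = x
  int nseg = x.size() - 1;
  for (int i = 0; i < nseg; ++i) {
    if (!bridgeable[i] || NumericVector::is_na(sigma2[i])) continue;
    double T = t[i + 1] - t[i];
    double w = T / alpha_steps;  // time weight per quadrature point
    for (int j = 0; j < alpha_steps; ++j) {
      double alpha = (j + 0.5) / alpha_steps;
      double mx = x[i] + alpha * (x[i + 1] - x[i]);
      double my = y[i] + alpha * (y[i + 1] - y[i]);
      double v = alpha * (1.0 - alpha) * T * sigma2[i] +
                 (1.0 - alpha) * (1.0 - alpha) * err[i] * err[i] +
                 alpha * alpha * err[i + 1] * err[i + 1];
      if (v <= 0) continue;
      double sd = std::sqrt(v);
      double r = trunc_sd * sd;
      int c_lo = (int)std::floor((mx - r - x0) / cell);
      int c_hi = (int)std::floor((mx + r - x0) / cell);
      int r_lo = (int)std::floor((my - r - y0) / cell);
      int r_hi = (int)std::floor((my + r - y0) / cell);
      if (c_lo < 0) c_lo = 0;
      if (r_lo < 0) r_lo = 0;
      if (c_hi >= nx) c_hi = nx - 1;
      if (r_hi >= ny) r_hi = ny - 1;
      double inv2v = 1.0 / (2.0 * v);
      double norm = w / (2.0 * M_PI * v);
      for (int cc = c_lo; cc <= c_hi; ++cc) {
        double cxv = x0 + (cc + 0.5) * cell - mx;
        for (int rr = r_lo; rr <= r_hi; ++rr) {
          double cyv = y0 + (rr + 0.5) * cell - my;
          dens(rr, cc) += norm * std::exp(-(cxv * cxv + cyv * cyv) * inv2v);
        }
      }
    }
  }
  return dens;
}

// Point-in-polygon labelling (ray casting, boundary-inclusive) for a list of
// polygons given as two-column matrices of ring vertices.
// [[Rcpp::export(name = ".cpp_label_points")]]
IntegerVector cpp_label_points(NumericVector px, NumericVector py,
                               List polys) {
  int n = px.size(), np = polys.size();
  std::vector<NumericMatrix> rings;
  std::vector<double> bx0(np), bx1(np), by0(np), by1(np);
  for (int p = 0; p < np; ++p) {
    NumericMatrix m = polys[p];
    rings.push_back(m);
    double xl = R_PosInf, xh = R_NegInf, yl = R_PosInf, yh = R_NegInf;
    for (int i = 0; i < m.nrow(); ++i) {
      if (m(i, 0) < xl) xl = m(i, 0);
      if (m(i, 0) > xh) xh = m(i, 0);
      if (m(i, 1) < yl) yl = m(i, 1);
      if (m(i, 1) > yh) yh = m(i, 1);
    }
    bx0[p] = xl; bx1[p] = xh; by0[p] = yl; by1[p] = yh;
  }
  IntegerVector out(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    double X = px[i], Y = py[i];
    for (int p = 0; p < np; ++p) {
      if (X < bx0[p] || X > bx1[p] || Y < by0[p] || Y > by1[p]) continue;
      const NumericMatrix& m = rings[p];
      int nv = m.nrow();
      bool inside = false, onedge = false;
      for (int a = 0, b = nv - 1; a < nv; b = a++) {
        double xa = m(a, 0), ya = m(a, 1), xb = m(b, 0), yb = m(b, 1);
        // on-segment check
        double cross = (xb - xa) * (Y - ya) - (yb - ya) * (X - xa);
        if (std::fabs(cross) < 1e-9 &&
            X >= std::fmin(xa, xb) - 1e-9 && X <= std::fmax(xa, xb) + 1e-9 &&
            Y >= std::fmin(ya, yb) - 1e-9 && Y <= std::fmax(ya, yb) + 1e-9) {
          onedge = true; break;
        }
        if (((ya > Y) != (yb > Y)) &&
            (X < (xb - xa) * (Y - ya) / (yb - ya) + xa))
          inside = !inside;
      }
      if (inside || onedge) { out[i] = p + 1; break; }
    }
  }
  return out;
}
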