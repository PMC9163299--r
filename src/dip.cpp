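// Exact computation of Hartigan's dip statistic.
//
// The dip of an empirical CDF F_n is the smallest d such that some unimodal
// CDF G (convex on (-infty, m], concave on [m, infty), with a jump permitted
// only at the mode m) satisfies sup_x |F_n(x) - G(x)| <= d.  For a fixed
// modal position the existence of such a G is a feasibility problem over the
// values of G at the data knots: box constraints from the ECDF plateaus,
// monotonicity, and convexity/concavity of the piecewise-linear chain on
// either side of the mode.  Feasibility is decided exactly by propagating,
// knot by knot, the convex polygon of attainable (last slope, value) states;
// the dip is then found by bisection on d, taking the OR over all modal
// positions (every data knot and every inter-knot gap).
//
// Ties are collapsed to unique knots carrying their ECDF step heights, so a
// point mass at the mode is handled by the jump the modal knot is allowed.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Pt {
  double s;  // last-used slope of the chain
  double g;  // value of G at the current knot
};

typedef std::vector<Pt> Poly;

double cross(const Pt &o, const Pt &a, const Pt &b) {
  return (a.s - o.s) * (b.g - o.g) - (a.g - o.g) * (b.s - o.s);
}

// Andrew's monotone chain; keeps degenerate (point / segment) sets intact.
Poly hull(Poly pts) {
  std::sort(pts.begin(), pts.end(), [](const Pt &a, const Pt &b) {
    return a.s < b.s || (a.s == b.s && a.g < b.g);
  });
  pts.erase(std::unique(pts.begin(), pts.end(), [](const Pt &a, const Pt &b) {
              return a.s == b.s && a.g == b.g;
            }),
            pts.end());
  const size_t n = pts.size();
  if (n <= 2) return pts;
  Poly h(2 * n);
  size_t k = 0;
  for (size_t i = 0; i < n; ++i) {  // lower
    while (k >= 2 && cross(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  for (size_t i = n - 1, t = k + 1; i-- > 0;) {  // upper
    while (k >= t && cross(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  h.resize(k - 1);
  return h;
}

// Keep the part of (CCW) polygon with a*s + b*g <= c.  Works for degenerate
// polygons (segments, points) as well.
Poly clipHalf(const Poly &poly, double a, double b, double c) {
  const double tol = 1e-12;
  Poly out;
  const size_t n = poly.size();
  if (n == 0) return out;
  for (size_t i = 0; i < n; ++i) {
    const Pt &P = poly[i];
    const Pt &Q = poly[(i + 1) % n];
    const double fp = a * P.s + b * P.g - c;
    const double fq = a * Q.s + b * Q.g - c;
    if (fp <= tol) out.push_back(P);
    if ((fp < -tol && fq > tol) || (fp > tol && fq < -tol)) {
      const double t = fp / (fp - fq);
      out.push_back({P.s + t * (Q.s - P.s), P.g + t * (Q.g - P.g)});
    }
  }
  if (n == 1) {  // single point: the loop above duplicates it
    double fp = a * poly[0].s + b * poly[0].g - c;
    out.clear();
    if (fp <= tol) out.push_back(poly[0]);
    return out;
  }
  return hull(out);
}

double minG(const Poly &p) {
  double m = R_PosInf;
  for (const Pt &v : p) m = std::min(m, v.g);
  return m;
}

// min over polygon of g + s*w  (w >= 0)
double minLin(const Poly &p, double w) {
  double m = R_PosInf;
  for (const Pt &v : p) m = std::min(m, v.g + v.s * w);
  return m;
}

// One chain transition: previous knot at distance dx behind, new box [lo,hi].
// Region update: allow any new slope >= previous slope, advance the value by
// slope*dx, then intersect with the box.
Poly advance(const Poly &poly, double dx, double lo, double hi) {
  if (poly.empty() || lo > hi + 1e-12) return Poly();
  // slopes larger than needed to reach hi from the lowest value are clipped
  // away by the box anyway; cap so the extended region stays bounded
  double cap = (hi - minG(poly)) / dx + 1.0;
  Poly pts = poly;
  for (const Pt &v : poly)
    if (v.s < cap) pts.push_back({cap, v.g});
  for (Pt &v : pts) v.g += v.s * dx;  // shear
  Poly h = hull(pts);
  h = clipHalf(h, 0.0, -1.0, -lo);  // g >= lo
  h = clipHalf(h, 0.0, 1.0, hi);    // g <= hi
  return h;
}

Poly startChain(double lo, double hi) {
  Poly p;
  if (lo > hi + 1e-12) return p;
  p.push_back({0.0, lo});
  if (hi > lo) p.push_back({0.0, hi});
  return p;
}

struct DipData {
  std::vector<double> z;   // unique sorted values, size m
  std::vector<double> cb;  // ECDF just below z[t]  (c[t]/n)
  std::vector<double> ca;  // ECDF at z[t]          (c[t+1]/n)
  int m;
};

DipData collapse(const std::vector<double> &xs, int n) {
  DipData D;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && xs[j] == xs[i]) ++j;
    D.z.push_back(xs[i]);
    D.cb.push_back((double)i / n);
    D.ca.push_back((double)j / n);
    i = j;
  }
  D.m = (int)D.z.size();
  return D;
}

// Feasibility of sup-distance d, maximising over all modal positions.
// If modeOut is non-null, records the first feasible modal interval.
bool feasible(const DipData &D, double d, double *modeLo, double *modeHi) {
  const int m = D.m;
  const double tol = 1e-12;
  // strong boxes (no jump at knot t): within d of both adjacent plateaus
  std::vector<double> L(m), U(m);
  for (int t = 0; t < m; ++t) {
    L[t] = std::max(D.ca[t] - d, 0.0);
    U[t] = std::min(D.cb[t] + d, 1.0);
  }
  // prefix convex chains over strong boxes: pre[s] = polygon at knot s
  std::vector<Poly> pre(m);
  pre[0] = startChain(L[0], U[0]);
  for (int t = 1; t < m; ++t) {
    if (pre[t - 1].empty()) break;
    pre[t] = advance(pre[t - 1], D.z[t] - D.z[t - 1], L[t], U[t]);
  }
  // suffix concave chains, run on reflected data (x -> -x, g -> 1 - g):
  // suf[s] = polygon at knot s in reflected coordinates
  std::vector<Poly> suf(m);
  {
    double rl = std::max(1.0 - D.cb[m - 1] - d, 0.0);
    double ru = std::min(1.0 - D.ca[m - 1] + d, 1.0);
    suf[m - 1] = startChain(rl, ru);
  }
  for (int t = m - 2; t >= 0; --t) {
    if (suf[t + 1].empty()) break;
    double rl = std::max(1.0 - D.cb[t] - d, 0.0);
    double ru = std::min(1.0 - D.ca[t] + d, 1.0);
    suf[t] = advance(suf[t + 1], D.z[t + 1] - D.z[t], rl, ru);
  }

  // gap modes: convex on knots 0..s-1, mode strictly between z[s-1] and z[s]
  // (s = 0: decreasing-density limit; s = m: increasing).  The concave side
  // must additionally admit a first slope no steeper than the chord across
  // the gap, i.e. exists right state with g_right - s_right*gap >= g_left.
  for (int s = 0; s <= m; ++s) {
    if (s == 0) {
      if (!suf[0].empty()) {
        if (modeLo) { *modeLo = D.z[0]; *modeHi = D.z[0]; }
        return true;
      }
      continue;
    }
    if (s == m) {
      if (!pre[m - 1].empty()) {
        if (modeLo) { *modeLo = D.z[m - 1]; *modeHi = D.z[m - 1]; }
        return true;
      }
      continue;
    }
    if (pre[s - 1].empty() || suf[s].empty()) continue;
    double gap = D.z[s] - D.z[s - 1];
    double aL = minG(pre[s - 1]);
    // max over right polygon of (g - s*gap) = 1 - min over reflected of
    // (g' + s'*gap)
    double best = 1.0 - minLin(suf[s], gap);
    if (aL <= best + tol) {
      if (modeLo) { *modeLo = D.z[s - 1]; *modeHi = D.z[s]; }
      return true;
    }
  }

  // knot modes: mode at z[k]; G may jump there, so the left chain ends in the
  // weak box around the lower plateau and the right chain starts in the weak
  // box around the upper plateau, coupled only by monotonicity g- <= g+.
  for (int k = 0; k < m; ++k) {
    double wlLo = std::max(D.cb[k] - d, 0.0), wlHi = std::min(D.cb[k] + d, 1.0);
    double wrLo = std::max(D.ca[k] - d, 0.0), wrHi = std::min(D.ca[k] + d, 1.0);
    Poly left = (k == 0) ? startChain(wlLo, wlHi)
                         : (pre[k - 1].empty()
                                ? Poly()
                                : advance(pre[k - 1], D.z[k] - D.z[k - 1],
                                          wlLo, wlHi));
    if (left.empty()) continue;
    Poly right;
    if (k == m - 1) {
      right = startChain(std::max(1.0 - wrHi, 0.0), std::min(1.0 - wrLo, 1.0));
    } else if (!suf[k + 1].empty()) {
      right = advance(suf[k + 1], D.z[k + 1] - D.z[k],
                      std::max(1.0 - wrHi, 0.0), std::min(1.0 - wrLo, 1.0));
    }
    if (right.empty()) continue;
    double aL = minG(left);
    double bR = 1.0 - minG(right);
    if (aL <= bR + tol) {
      if (modeLo) { *modeLo = D.z[k]; *modeHi = D.z[k]; }
      return true;
    }
  }
  return false;
}

double dipOf(std::vector<double> xs, double *modeLo, double *modeHi) {
  const int n = (int)xs.size();
  std::sort(xs.begin(), xs.end());
  DipData D = collapse(xs, n);
  if (D.m == 1) {
    if (modeLo) { *modeLo = D.z[0]; *modeHi = D.z[0]; }
    return 0.0;
  }
  double lo = 0.0, hi = 0.2500000001;
  for (int it = 0; it < 64 && (hi - lo) > 1e-14; ++it) {
    double mid = 0.5 * (lo + hi);
    if (feasible(D, mid, nullptr, nullptr))
      hi = mid;
    else
      lo = mid;
  }
  if (modeLo) feasible(D, hi * (1 + 1e-9) + 1e-13, modeLo, modeHi);
  return hi;
}

}  // namespace

// [[Rcpp::export(name = ".dip_stat_cpp")]]
List dip_stat_cpp(NumericVector x) {
  std::vector<double> xs(x.begin(), x.end());
  if (xs.size() < 2) stop("dip statistic requires at least 2 observations");
  double mlo = NA_REAL, mhi = NA_REAL;
  double d = dipOf(xs, &mlo, &mhi);
  return List::create(_["dip"] = d,
                      _["modal_lo"] = mlo,
                      _["modal_hi"] = mhi);
}

// [[Rcpp::export(name = ".dip_boot_cpp")]]
NumericVector dip_boot_cpp(int n, int n_boot) {
  // dip statistics of n_boot uniform(0,1) samples of size n, using R's RNG
  NumericVector out(n_boot);
  for (int b = 0; b < n_boot; ++b) {
    std::vector<double> xs(n);
    for (int i = 0; i < n; ++i) xs[i] = unif_rand();
    out[b] = dipOf(xs, nullptr, nullptr);
  }
  return out;
}
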