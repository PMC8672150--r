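// Core one-dimensional nonparametric machinery:
//  - Hartigan & Hartigan dip statistic of unimodality (exact, via iterative
//    convex-minorant / concave-majorant modal-interval shrinkage)
//  - Monte-Carlo sampler of the dip null distribution (sorted uniforms)
//  - taut-string estimate: shortest path through a fixed-radius tube around
//    the empirical distribution function (funnel algorithm), whose derivative
//    is a piecewise-constant density with the minimal number of modes
//    consistent with the tube.
#include <Rcpp.h>
#include <vector>
#include <random>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------- dip ----

// Hulls of the index staircase (x_i, i+1): y-values are implicit, so no
// per-call allocation. Lower hull = greatest convex minorant; upper hull =
// least concave majorant.
static void hull_lower_stair(const std::vector<double>& x, int lo, int hi,
                             std::vector<int>& out) {
  out.clear();
  for (int i = lo; i <= hi; ++i) {
    while (out.size() >= 2) {
      int a = out[out.size() - 2], b = out[out.size() - 1];
      if ((double)(b - a) * (x[i] - x[a]) >= (double)(i - a) * (x[b] - x[a]))
        out.pop_back();
      else break;
    }
    out.push_back(i);
  }
}
static void hull_upper_stair(const std::vector<double>& x, int lo, int hi,
                             std::vector<int>& out) {
  out.clear();
  for (int i = lo; i <= hi; ++i) {
    while (out.size() >= 2) {
      int a = out[out.size() - 2], b = out[out.size() - 1];
      if ((double)(b - a) * (x[i] - x[a]) <= (double)(i - a) * (x[b] - x[a]))
        out.pop_back();
      else break;
    }
    out.push_back(i);
  }
}

// linear interpolation of a hull chain at x[q] (y = index + 1), queries
// ascending via a persistent segment pointer
struct StairInterp {
  const std::vector<double>& x;
  const std::vector<int>& hull;
  size_t seg;
  explicit StairInterp(const std::vector<double>& x_, const std::vector<int>& h_)
    : x(x_), hull(h_), seg(0) {}
  double at(int q) {
    while (seg + 2 < hull.size() && hull[seg + 1] < q) ++seg;
    int a = hull[seg], b = hull[seg + 1 < hull.size() ? seg + 1 : seg];
    if (q <= a) return a + 1.0;
    if (q >= b) return b + 1.0;
    double w = (x[q] - x[a]) / (x[b] - x[a]);
    return (a + 1.0) + w * (double)(b - a);
  }
};

static double dip_sorted(const std::vector<double>& x) {
  const int n = (int) x.size();
  if (n < 2) return 0.0;
  if (x[n - 1] <= x[0]) return 0.0;  // all ties: degenerate, callers jitter
  int lo = 0, hi = n - 1;
  double dipv = 1.0;  // count units; statistic = dipv / (2n)
  static std::vector<int> gh, lh;
  for (;;) {
    hull_lower_stair(x, lo, hi, gh);   // gcm knots
    hull_upper_stair(x, lo, hi, lh);   // lcm knots
    // modal gap (lcm above gcm, +1 staircase correction) at both knot sets
    double d = -1.0; int argj = lo; bool at_gcm = true;
    {
      StairInterp li(x, lh);
      for (size_t k = 0; k < gh.size(); ++k) {
        int j = gh[k];
        double v = li.at(j) - (j + 1.0) + 1.0;
        if (v > d) { d = v; argj = j; at_gcm = true; }
      }
    }
    {
      StairInterp gi(x, gh);
      for (size_t k = 0; k < lh.size(); ++k) {
        int j = lh[k];
        double v = (j + 1.0) - gi.at(j) + 1.0;
        if (v > d) { d = v; argj = j; at_gcm = false; }
      }
    }
    if (d <= dipv) break;
    int ig, ih;
    if (at_gcm) {
      ig = argj;
      ih = hi;
      for (size_t k = 0; k < lh.size(); ++k) if (lh[k] >= argj) { ih = lh[k]; break; }
    } else {
      ih = argj;
      ig = lo;
      for (size_t k = gh.size(); k-- > 0;) if (gh[k] <= argj) { ig = gh[k]; break; }
    }
    // flank deviations on [lo, ig] (staircase above gcm) and [ih, hi]
    double dl_out = 0.0, du_out = 0.0;
    {
      StairInterp gi(x, gh);
      for (int j = lo; j <= ig; ++j) {
        double v = (j + 1.0) - gi.at(j) + 1.0;
        if (v > dl_out) dl_out = v;
      }
    }
    {
      StairInterp li(x, lh);
      for (int j = ih; j <= hi; ++j) {
        double v = li.at(j) - (j + 1.0) + 1.0;
        if (v > du_out) du_out = v;
      }
    }
    if (dl_out > dipv) dipv = dl_out;
    if (du_out > dipv) dipv = du_out;
    if (ig == lo && ih == hi) break;
    lo = ig; hi = ih;
  }
  return dipv / (2.0 * n);
}

//' @noRd
// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector xs) {
  std::vector<double> x(xs.begin(), xs.end());
  if (!std::is_sorted(x.begin(), x.end())) std::sort(x.begin(), x.end());
  return dip_sorted(x);
}

//' @noRd
// [[Rcpp::export(name = ".dip_null_cpp")]]
NumericVector dip_null_cpp(int n, int reps, int seed) {
  std::mt19937_64 rng((uint64_t) seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  NumericVector out(reps);
  std::vector<double> x((size_t) n);
  for (int r = 0; r < reps; ++r) {
    for (int i = 0; i < n; ++i) x[i] = U(rng);
    std::sort(x.begin(), x.end());
    out[r] = dip_sorted(x);
  }
  return out;
}

// --------------------------------------------------------- taut string ----

// Taut string through vertical gates (t_i, [l_i, u_i]) with degenerate first
// and last gates. Divide & conquer: the chord is the string unless a gate is
// violated; the string then touches the violated bound at the gate of maximal
// violation, splitting the problem. Explicit stack avoids deep recursion.
struct Seg { int i; double vi; int j; double vj; };

static void taut_dc(const std::vector<double>& t, const std::vector<double>& lb,
                    const std::vector<double>& ub,
                    std::vector<int>& kidx, std::vector<double>& kval) {
  const int m = (int) t.size();
  std::vector<char> isknot(m, 0);
  std::vector<double> val(m, 0.0);
  isknot[0] = isknot[m - 1] = 1;
  val[0] = lb[0]; val[m - 1] = lb[m - 1];
  std::vector<Seg> stack;
  stack.push_back(Seg{0, lb[0], m - 1, lb[m - 1]});
  while (!stack.empty()) {
    Seg s = stack.back(); stack.pop_back();
    if (s.j <= s.i + 1) continue;
    const double slope = (s.vj - s.vi) / (t[s.j] - t[s.i]);
    double best = 1e-13; int bk = -1; double bv = 0.0;
    for (int k = s.i + 1; k < s.j; ++k) {
      double line = s.vi + slope * (t[k] - t[s.i]);
      double vup = line - ub[k];   // above ceiling
      double vdn = lb[k] - line;   // below floor
      if (vup > best) { best = vup; bk = k; bv = ub[k]; }
      if (vdn > best) { best = vdn; bk = k; bv = lb[k]; }
    }
    if (bk < 0) continue;
    isknot[bk] = 1; val[bk] = bv;
    stack.push_back(Seg{s.i, s.vi, bk, bv});
    stack.push_back(Seg{bk, bv, s.j, s.vj});
  }
  kidx.clear(); kval.clear();
  for (int i = 0; i < m; ++i) if (isknot[i]) { kidx.push_back(i); kval.push_back(val[i]); }
}

//' @noRd
// [[Rcpp::export(name = ".taut_string_cpp")]]
List taut_string_cpp(NumericVector xs, double radius) {
  const int n = xs.size();
  std::vector<double> x(xs.begin(), xs.end());
  if (!std::is_sorted(x.begin(), x.end())) std::sort(x.begin(), x.end());
  if (n < 2 || x[n - 1] <= x[0]) stop("taut string needs >= 2 distinct values");
  // gates: anchors at (x_1, 0), (x_n, 1); interior tube around (i - 0.5)/n
  std::vector<double> t, lb, ub;
  t.reserve(n); lb.reserve(n); ub.reserve(n);
  t.push_back(x[0]); lb.push_back(0.0); ub.push_back(0.0);
  for (int i = 1; i < n - 1; ++i) {
    double f = (i + 0.5) / n;
    t.push_back(x[i]);
    lb.push_back(std::max(0.0, f - radius));
    ub.push_back(std::min(1.0, f + radius));
  }
  t.push_back(x[n - 1]); lb.push_back(1.0); ub.push_back(1.0);
  std::vector<int> kidx; std::vector<double> kval;
  taut_dc(t, lb, ub, kidx, kval);
  const int k = (int) kidx.size();
  NumericVector px(k), py(k);
  for (int i = 0; i < k; ++i) { px[i] = t[kidx[i]]; py[i] = kval[i]; }
  return List::create(_["x"] = px, _["y"] = py);
}

// ------------------------------------------------------------ node scan ----

// dip p-value by interpolation of the Monte-Carlo null quantile table on the
// sqrt(n)*dip scale in log n (mirrors dip_pvalue on the R side); sample
// sizes beyond the table reuse the last row's sqrt(n) scaling.
static double dip_pval_tab(double stat, int n,
                           const std::vector<double>& tn,
                           const std::vector<double>& tp,
                           const std::vector<std::vector<double> >& tq) {
  const int R = (int) tn.size(), C = (int) tp.size();
  std::vector<double> qs(C);
  if (n <= tn[0]) {
    for (int c = 0; c < C; ++c) qs[c] = tq[0][c];
  } else if (n >= tn[R - 1]) {
    double s = std::sqrt(tn[R - 1]) / std::sqrt((double) n);
    for (int c = 0; c < C; ++c) qs[c] = tq[R - 1][c] * s;
  } else {
    int i = 0;
    while (i + 1 < R && tn[i + 1] < n) ++i;
    if (tn[i] == n) {
      for (int c = 0; c < C; ++c) qs[c] = tq[i][c];
    } else {
      double w = (std::log((double) n) - std::log(tn[i])) /
                 (std::log(tn[i + 1]) - std::log(tn[i]));
      double s0 = std::sqrt(tn[i]), s1 = std::sqrt(tn[i + 1]),
             sn = std::sqrt((double) n);
      for (int c = 0; c < C; ++c)
        qs[c] = ((1 - w) * s0 * tq[i][c] + w * s1 * tq[i + 1][c]) / sn;
    }
  }
  if (stat <= qs[0]) return 1.0 - tp[0];
  if (stat >= qs[C - 1]) return 1.0 - tp[C - 1];
  int c = 0;
  while (c + 1 < C && qs[c + 1] < stat) ++c;
  double cdf;
  if (qs[c + 1] == qs[c]) cdf = tp[c + 1];
  else cdf = tp[c] + (tp[c + 1] - tp[c]) * (stat - qs[c]) / (qs[c + 1] - qs[c]);
  return 1.0 - cdf;
}

// taut-string gates (antimode midpoints) of sorted x with radius scale/sqrt(n)
static void taut_gates(const std::vector<double>& x, double ts_scale,
                       std::vector<double>& gates) {
  gates.clear();
  const int n = (int) x.size();
  double radius = ts_scale / std::sqrt((double) n);
  std::vector<double> t, lb, ub;
  t.reserve(n); lb.reserve(n); ub.reserve(n);
  t.push_back(x[0]); lb.push_back(0.0); ub.push_back(0.0);
  for (int i = 1; i < n - 1; ++i) {
    double f = (i + 0.5) / n;
    t.push_back(x[i]);
    lb.push_back(std::max(0.0, f - radius));
    ub.push_back(std::min(1.0, f + radius));
  }
  t.push_back(x[n - 1]); lb.push_back(1.0); ub.push_back(1.0);
  std::vector<int> kidx; std::vector<double> kval;
  taut_dc(t, lb, ub, kidx, kval);
  const int m = (int) kidx.size();
  // slopes, merged over equal runs; antimode = interior strict local min
  std::vector<double> sx, sl;
  double maxh = 1e-300;
  for (int i = 0; i + 1 < m; ++i) {
    double h = (kval[i + 1] - kval[i]) / (t[kidx[i + 1]] - t[kidx[i]]);
    if (!sl.empty() && std::fabs(h - sl.back()) <= 1e-12 * maxh) {
      sx.back() = t[kidx[i + 1]];
    } else {
      sl.push_back(h);
      sx.push_back(t[kidx[i + 1]]);
    }
    if (h > maxh) maxh = h;
  }
  const int k = (int) sl.size();
  for (int i = 1; i + 1 < k; ++i) {
    if (sl[i] < sl[i - 1] && sl[i] < sl[i + 1])
      gates.push_back((sx[i - 1] + sx[i]) / 2.0);   // antimode midpoint
  }
}

// One discovery/annotation node: for each requested marker column, gather
// events strictly inside the marker bounds, sort, break ties
// deterministically, compute the dip and its table p-value, and - when
// unimodality is rejected - the taut-string gates. In lazy mode markers are
// visited in the caller-supplied order and scanning stops at the first
// marker with a usable gate set (uniform marker choice via a random
// permutation).
//' @noRd
// [[Rcpp::export(name = ".node_scan_cpp")]]
List node_scan_cpp(NumericMatrix vals, IntegerVector idx, IntegerVector cols,
                   NumericVector low, NumericVector high,
                   double dip_threshold, double ts_scale, int max_gates,
                   int min_scan, NumericVector tab_n, NumericVector tab_probs,
                   NumericMatrix tab_q, bool lazy) {
  const int nm = cols.size();
  std::vector<double> tnv(tab_n.begin(), tab_n.end());
  std::vector<double> tpv(tab_probs.begin(), tab_probs.end());
  std::vector<std::vector<double> > tqv(tab_n.size(),
                                        std::vector<double>(tab_probs.size()));
  for (int r = 0; r < tab_n.size(); ++r)
    for (int c = 0; c < tab_probs.size(); ++c) tqv[r][c] = tab_q(r, c);

  IntegerVector n_eff(nm);
  NumericVector pval(nm, NA_REAL);
  LogicalVector scanned(nm, false);
  List gates_out(nm);
  std::vector<double> x; x.reserve(idx.size());
  std::vector<double> g;

  for (int j = 0; j < nm; ++j) {
    int col = cols[j] - 1;
    x.clear();
    for (int r = 0; r < idx.size(); ++r) {
      double v = vals(idx[r] - 1, col);
      if (v > low[j] && v < high[j]) x.push_back(v);
    }
    n_eff[j] = (int) x.size();
    gates_out[j] = NumericVector(0);
    if ((int) x.size() < min_scan) continue;
    std::sort(x.begin(), x.end());
    // deterministic rank-preserving tie spread
    double rng = x.back() - x.front();
    if (rng <= 0) continue;
    bool ties = false;
    for (size_t r = 1; r < x.size(); ++r) if (x[r] == x[r - 1]) { ties = true; break; }
    if (ties) {
      double eps = 1e-9 * rng / x.size();
      for (size_t r = 0; r < x.size(); ++r) x[r] += r * eps;
    }
    scanned[j] = true;
    double stat = dip_sorted(x);
    double p = dip_pval_tab(stat, (int) x.size(), tnv, tpv, tqv);
    pval[j] = p;
    if (p < dip_threshold) {
      taut_gates(x, ts_scale, g);
      if (!g.empty() && (int) g.size() <= max_gates) {
        gates_out[j] = NumericVector(g.begin(), g.end());
        if (lazy) break;
      }
    }
  }
  return List::create(_["n_eff"] = n_eff, _["p"] = pval,
                      _["gates"] = gates_out, _["scanned"] = scanned);
}
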