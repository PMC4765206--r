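// Hartigan-Hartigan dip statistic, computed exactly from its definition:
//   dip = inf over unimodal CDFs G of sup_x |G(x) - Fn(x)|.
//
// A unimodal CDF is convex up to its mode and concave after it; an atom is
// permitted only at the mode.  For a fixed candidate dip value d this turns
// into a band-feasibility problem on the distinct sample values t_1..t_K
// (cumulative counts c_1..c_K, n total):
//
//   full band at t_j:        l_j = c_j/n - d  <=  G(t_j)  <=  u_j = c_{j-1}/n + d
//   mode at t_j (jump ok):   left limit  in [l_{j-1}, u_j]
//                            right value in [l_j, u_{j+1}]
//
// The convex (left) piece is a nondecreasing convex chain through the bands;
// the binding lower bounds on later chain values are the pairwise "forcing
// lines" through (t_i, u_i) and (t_j, l_j) with slope clipped at 0 (steeper
// cascaded bounds are convex combinations of pairwise ones, hence dominated).
// A prefix is feasible iff the running maximum of forcing lines stays below
// the upper band, and the minimum achievable chain value at t_j is that
// running maximum.  The concave (right) piece is the mirror image (reflect
// t -> -t, G -> 1-G).  The sample is unimodal at tolerance d iff some mode
// index j has a feasible left prefix, feasible right suffix, and
// min-left-limit <= max-right-value.  The dip is found by bisection on d.
//
// Forcing-line maxima are queried with a Li Chao tree over the t grid; the
// steepest line per j comes from a tangent query against the lower convex
// hull of the processed (t_i, u_i) points.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double FEAS_TOL = 1e-12;

namespace {

struct Line {
  double m, b;  // value(t) = m * t + b
  double at(double t) const { return m * t + b; }
};

// Li Chao tree for maximum over inserted lines, queried at fixed abscissae.
class LiChao {
public:
  void init(const std::vector<double>& xs) {
    xs_ = &xs;
    n_ = (int)xs.size();
    tree_.assign(4 * std::max(n_, 1), Line{0.0, NEG_INF});
  }
  void insert(Line ln) { if (n_ > 0) insert_(ln, 1, 0, n_ - 1); }
  double query(int idx) const {
    if (n_ == 0) return NEG_INF;
    double best = NEG_INF;
    int node = 1, lo = 0, hi = n_ - 1;
    double t = (*xs_)[idx];
    while (true) {
      const Line& ln = tree_[node];
      if (ln.b != NEG_INF) best = std::max(best, ln.at(t));
      if (lo == hi) break;
      int mid = (lo + hi) / 2;
      if (idx <= mid) { node = 2 * node; hi = mid; }
      else            { node = 2 * node + 1; lo = mid + 1; }
    }
    return best;
  }
private:
  void insert_(Line ln, int node, int lo, int hi) {
    int mid = (lo + hi) / 2;
    bool leftBetter = val(ln, lo) > val(tree_[node], lo);
    bool midBetter  = val(ln, mid) > val(tree_[node], mid);
    if (midBetter) std::swap(ln, tree_[node]);
    if (lo == hi) return;
    if (ln.b == NEG_INF) return;
    if (leftBetter != midBetter) insert_(ln, 2 * node, lo, mid);
    else {
      bool rightBetter = val(ln, hi) > val(tree_[node], hi);
      if (rightBetter != midBetter) insert_(ln, 2 * node + 1, mid + 1, hi);
    }
  }
  double val(const Line& ln, int idx) const {
    return ln.b == NEG_INF ? NEG_INF : ln.at((*xs_)[idx]);
  }
  const std::vector<double>* xs_ = nullptr;
  int n_ = 0;
  std::vector<Line> tree_;
};

// Lower convex hull of (t_i, u_i), points appended with increasing t.
// Supports max-slope tangent queries from a point strictly right of all t_i.
class LowerHull {
public:
  void clear() { tx_.clear(); ty_.clear(); }
  void add(double t, double u) {
    while (tx_.size() >= 2) {
      size_t k = tx_.size();
      double cx1 = tx_[k - 1] - tx_[k - 2], cy1 = ty_[k - 1] - ty_[k - 2];
      double cx2 = t - tx_[k - 1],          cy2 = u - ty_[k - 1];
      // keep hull lower-convex: pop if middle point is not below segment
      if (cy1 * cx2 >= cy2 * cx1) { tx_.pop_back(); ty_.pop_back(); }
      else break;
    }
    tx_.push_back(t); ty_.push_back(u);
  }
  // max over hull vertices of (lq - u_i) / (tq - t_i); tq > all t_i
  double maxSlope(double tq, double lq) const {
    if (tx_.empty()) return NEG_INF;
    int lo = 0, hi = (int)tx_.size() - 1;
    while (hi - lo > 2) {
      int m1 = lo + (hi - lo) / 3, m2 = hi - (hi - lo) / 3;
      if (slope(m1, tq, lq) < slope(m2, tq, lq)) lo = m1 + 1; else hi = m2;
    }
    double best = NEG_INF;
    for (int i = lo; i <= hi; ++i) best = std::max(best, slope(i, tq, lq));
    return best;
  }
private:
  double slope(int i, double tq, double lq) const {
    return (lq - ty_[i]) / (tq - tx_[i]);
  }
  std::vector<double> tx_, ty_;
};

struct PassResult {
  std::vector<double> Atil;   // min achievable value entering mode point j
  std::vector<char>   ok;     // prefix feasible and Atil within mode band
};

// One convex-side pass over points (t_j, bands [l_j, u_j]), j = 0..K-1.
// lm0 is the lower mode-band bound for j = 0 (zero on the original axis).
void leftPass(const std::vector<double>& t, const std::vector<double>& l,
              const std::vector<double>& u, PassResult& out,
              LiChao& env, LowerHull& hull) {
  int K = (int)t.size();
  out.Atil.assign(K, 0.0);
  out.ok.assign(K, 0);
  env.init(t);
  hull.clear();
  bool prefixFeasible = true;  // feasibility of full-band points 0..j-1
  for (int j = 0; j < K; ++j) {
    double envHere = env.query(j);
    double lm = (j == 0) ? 0.0 : l[j - 1];
    double Atil = std::max(std::max(lm, 0.0), envHere);
    out.Atil[j] = Atil;
    out.ok[j] = (prefixFeasible && Atil <= u[j] + FEAS_TOL) ? 1 : 0;
    // now absorb point j with its full band
    double Afull = std::max(std::max(l[j], 0.0), envHere);
    if (Afull > u[j] + FEAS_TOL) prefixFeasible = false;
    double s = hull.maxSlope(t[j], l[j]);
    if (s < 0.0 || s == NEG_INF) s = 0.0;
    env.insert(Line{s, l[j] - s * t[j]});
    hull.add(t[j], u[j]);
  }
}

class DipSolver {
public:
  // x must be sorted ascending, finite, length >= 1
  double dip(const std::vector<double>& x) {
    n_ = (int)x.size();
    t_.clear(); c_.clear();
    for (int i = 0; i < n_; ++i) {
      if (t_.empty() || x[i] > t_.back()) { t_.push_back(x[i]); c_.push_back(i + 1); }
      else c_.back() = i + 1;
    }
    K_ = (int)t_.size();
    if (K_ <= 1) return 0.0;
    // reflected axis for the concave side
    rt_.assign(K_, 0.0);
    for (int p = 0; p < K_; ++p) rt_[p] = -t_[K_ - 1 - p];

    double lo = 0.0, hi = 0.25;
    if (feasible(hi)) {
      if (feasible(lo)) return 0.0;
    } else {
      hi = 0.5;  // defensive; should not trigger
    }
    for (int it = 0; it < 46; ++it) {
      double mid = 0.5 * (lo + hi);
      if (feasible(mid)) hi = mid; else lo = mid;
    }
    return 0.5 * (lo + hi);
  }

private:
  bool feasible(double d) {
    // full bands on the original axis
    l_.assign(K_, 0.0); u_.assign(K_, 0.0);
    for (int j = 0; j < K_; ++j) {
      l_[j] = std::max(0.0, (double)c_[j] / n_ - d);
      double cprev = (j == 0) ? 0.0 : (double)c_[j - 1];
      u_[j] = std::min(1.0, cprev / n_ + d);
    }
    leftPass(t_, l_, u_, left_, env_, hull_);
    // reflected bands: point p corresponds to original j = K-1-p
    rl_.assign(K_, 0.0); ru_.assign(K_, 0.0);
    for (int p = 0; p < K_; ++p) {
      int j = K_ - 1 - p;
      rl_[p] = std::max(0.0, 1.0 - u_[j]);
      ru_[p] = std::min(1.0, 1.0 - l_[j]);
    }
    leftPass(rt_, rl_, ru_, right_, env_, hull_);
    for (int j = 0; j < K_; ++j) {
      int p = K_ - 1 - j;
      if (!left_.ok[j] || !right_.ok[p]) continue;
      double Btil = 1.0 - right_.Atil[p];  // max achievable right value at mode
      if (left_.Atil[j] <= Btil + FEAS_TOL) return true;
    }
    return false;
  }

  int n_ = 0, K_ = 0;
  std::vector<double> t_, rt_, l_, u_, rl_, ru_;
  std::vector<int> c_;
  PassResult left_, right_;
  LiChao env_;
  LowerHull hull_;
};

}  // namespace

// [[Rcpp::export(name = ".dipStatCpp")]]
double dipStatCpp(NumericVector x) {
  int n = x.size();
  if (n < 1) stop("empty input");
  std::vector<double> v(x.begin(), x.end());
  for (double xi : v) if (!std::isfinite(xi)) stop("non-finite values");
  std::sort(v.begin(), v.end());
  DipSolver solver;
  return solver.dip(v);
}

// [[Rcpp::export(name = ".dipNullCpp")]]
NumericVector dipNullCpp(int n, int nSim) {
  if (n < 1 || nSim < 1) stop("invalid null-table dimensions");
  NumericVector out(nSim);
  DipSolver solver;
  std::vector<double> v((size_t)n);
  RNGScope scope;
  for (int s = 0; s < nSim; ++s) {
    for (int i = 0; i < n; ++i) v[i] = unif_rand();
    std::sort(v.begin(), v.end());
    out[s] = solver.dip(v);
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  std::sort(out.begin(), out.end());
  return out;
}
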