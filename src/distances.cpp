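#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// ISI- and SPIKE-distance profiles between two spike trains on a common
// observation interval [a, b]. Edge handling follows the auxiliary-spike
// convention: virtual spikes at both interval boundaries define the
// inter-spike intervals before the first and after the last real spike,
// so both measures are total functions (including empty trains).
//
// The ISI profile is piecewise constant between events; the SPIKE profile
// is piecewise linear between events (events = union of augmented spike
// times of both trains). Scalar distances integrate the profiles exactly,
// segment by segment, and divide by the interval length.

static std::vector<double> augment(const NumericVector& x, double a, double b) {
  std::vector<double> s;
  s.reserve(x.size() + 2);
  s.push_back(a);
  for (double t : x) s.push_back(t);
  s.push_back(b);
  return s;
}

static std::vector<double> event_union(const std::vector<double>& x,
                                       const std::vector<double>& y) {
  std::vector<double> e;
  e.reserve(x.size() + y.size());
  std::merge(x.begin(), x.end(), y.begin(), y.end(), std::back_inserter(e));
  e.erase(std::unique(e.begin(), e.end()), e.end());
  return e;
}

// signed instantaneous ISI ratio: vx/vy - 1 if vx <= vy,
// else -(vy/vx - 1); in (-1, 1), zero for equal ISIs
static inline double isi_ratio(double vx, double vy) {
  if (vx == vy) return 0.0;  // also covers vx == vy == 0
  if (vx <= vy) return vx / vy - 1.0;
  return -(vy / vx - 1.0);
}

// Walk the event segments; cb(t0, t1, value) for the constant ISI value on
// each segment of positive length.
template <typename F>
static void isi_walk(const std::vector<double>& sx, const std::vector<double>& sy,
                     F cb) {
  std::vector<double> ev = event_union(sx, sy);
  size_t ix = 0, iy = 0;
  for (size_t i = 0; i + 1 < ev.size(); ++i) {
    double t0 = ev[i], t1 = ev[i + 1];
    double tm = 0.5 * (t0 + t1);
    while (ix + 1 < sx.size() - 1 && sx[ix + 1] <= tm) ++ix;
    while (iy + 1 < sy.size() - 1 && sy[iy + 1] <= tm) ++iy;
    double vx = sx[ix + 1] - sx[ix];
    double vy = sy[iy + 1] - sy[iy];
    if (t1 > t0) cb(t0, t1, isi_ratio(vx, vy));
  }
}

// [[Rcpp::export]]
double isi_distance_cpp(NumericVector x, NumericVector y, double a, double b) {
  std::vector<double> sx = augment(x, a, b), sy = augment(y, a, b);
  double acc = 0.0;
  isi_walk(sx, sy, [&](double t0, double t1, double v) {
    acc += std::fabs(v) * (t1 - t0);
  });
  return acc / (b - a);
}

// [[Rcpp::export]]
List isi_profile_cpp(NumericVector x, NumericVector y, double a, double b) {
  std::vector<double> sx = augment(x, a, b), sy = augment(y, a, b);
  std::vector<double> times, values;
  isi_walk(sx, sy, [&](double t0, double t1, double v) {
    if (times.empty()) times.push_back(t0);
    times.push_back(t1);
    values.push_back(v);
  });
  return List::create(_["times"] = times, _["values"] = values);
}

// SPIKE profile on one segment: between consecutive events the preceding
// and following spikes of both trains are fixed, so the weighted term is
// linear in t. Evaluate at the segment edges.
struct SpikeSeg {
  double tP1, tP2, tF1, tF2;
  double value(double t) const {
    double dtP = std::fabs(tP1 - tP2);
    double dtF = std::fabs(tF1 - tF2);
    double xF = 0.5 * ((tF1 - t) + (tF2 - t));
    double xP = 0.5 * ((t - tP1) + (t - tP2));
    double mISI = 0.5 * ((tF1 - tP1) + (tF2 - tP2));
    if (mISI <= 0) return 0.0;
    return (dtP * xF + dtF * xP) / (mISI * mISI);
  }
};

template <typename F>
static void spike_walk(const std::vector<double>& sx, const std::vector<double>& sy,
                       F cb) {
  std::vector<double> ev = event_union(sx, sy);
  size_t px = 0, py = 0;   // index of last spike <= segment start
  size_t fx = 0, fy = 0;   // index of first spike >= segment end
  for (size_t i = 0; i + 1 < ev.size(); ++i) {
    double t0 = ev[i], t1 = ev[i + 1];
    if (t1 <= t0) continue;
    while (px + 1 < sx.size() && sx[px + 1] <= t0) ++px;
    while (py + 1 < sy.size() && sy[py + 1] <= t0) ++py;
    while (fx < sx.size() - 1 && sx[fx] < t1) ++fx;
    while (fy < sy.size() - 1 && sy[fy] < t1) ++fy;
    SpikeSeg seg{sx[px], sy[py], sx[fx], sy[fy]};
    cb(t0, t1, seg);
  }
}

// [[Rcpp::export]]
double spike_distance_cpp(NumericVector x, NumericVector y, double a, double b) {
  std::vector<double> sx = augment(x, a, b), sy = augment(y, a, b);
  double acc = 0.0;
  spike_walk(sx, sy, [&](double t0, double t1, const SpikeSeg& s) {
    acc += 0.5 * (s.value(t0) + s.value(t1)) * (t1 - t0);
  });
  return acc / (b - a);
}

// [[Rcpp::export]]
List spike_profile_cpp(NumericVector x, NumericVector y, double a, double b) {
  std::vector<double> sx = augment(x, a, b), sy = augment(y, a, b);
  std::vector<double> times, values;
  spike_walk(sx, sy, [&](double t0, double t1, const SpikeSeg& s) {
    times.push_back(t0); values.push_back(s.value(t0));
    times.push_back(t1); values.push_back(s.value(t1));
  });
  return List::create(_["times"] = times, _["values"] = values);
}

static double scalar_distance(const NumericVector& x, const NumericVector& y,
                              double a, double b, bool spike) {
  return spike ? spike_distance_cpp(x, y, a, b) : isi_distance_cpp(x, y, a, b);
}

// mean over all cross trial pairs (i of a) x (j of b)
// [[Rcpp::export]]
double trial_mean_distance_cpp(List xs, List ys, double a, double b,
                               std::string metric) {
  bool spike = (metric == "spike");
  double acc = 0.0;
  int n = 0;
  for (int i = 0; i < xs.size(); ++i) {
    NumericVector xi = xs[i];
    for (int j = 0; j < ys.size(); ++j) {
      NumericVector yj = ys[j];
      acc += scalar_distance(xi, yj, a, b, spike);
      ++n;
    }
  }
  return acc / n;
}

// full unit-by-unit matrix: trials is a list (units) of lists (trials) of
// numeric spike-time vectors, all on the common interval [a, b]
// [[Rcpp::export]]
NumericMatrix distance_matrix_cpp(List trials, double a, double b,
                                  std::string metric) {
  int n = trials.size();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    List ti = trials[i];
    for (int j = i + 1; j < n; ++j) {
      List tj = trials[j];
      double d = trial_mean_distance_cpp(ti, tj, a, b, metric);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
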