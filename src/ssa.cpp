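#include <Rcpp.h>
#include <cfloat>
#include <cmath>
using namespace Rcpp;

// Direct-method Gillespie simulation of the burst Schlogl scheme.
// Channels: +1 at k1, -1 at k2*x, +r at k3*x^2/r, -1 at k4*x^3.
// Uses R's RNG stream (unif_rand) so set.seed() gives bit-exact
// reproducibility. Time-weighted occupancy after burn_in_time is
// accumulated in place so arbitrarily long runs need no event storage;
// the first max_store events are additionally recorded for trajectory
// output.
// [[Rcpp::export]]
List ssa_run_cpp(double k1, double k2, double k3, double k4, int r,
                 double x0, double t_max, double burn_in_time,
                 int max_store) {
  double t = 0.0, x = x0;
  std::vector<double> ts, xs;
  const bool store = max_store > 0;
  if (store) {
    ts.reserve(std::min(max_store, 1 << 20));
    xs.reserve(std::min(max_store, 1 << 20));
    ts.push_back(0.0);
    xs.push_back(x);
  }
  std::vector<double> occ(256, 0.0);
  bool truncated = false;
  double n_events = 0.0;

  while (t < t_max) {
    const double a1 = k1;
    const double a2 = k2 * x;
    const double a3 = k3 * x * x / r;
    const double a4 = k4 * x * x * x;
    const double a0 = a1 + a2 + a3 + a4;
    if (a0 <= 0.0) {
      // absorbing (only reachable when k1 == 0 and x == 0)
      const double lo = std::max(t, burn_in_time);
      if (t_max > lo) {
        if ((size_t)x >= occ.size()) occ.resize((size_t)x + 64, 0.0);
        occ[(size_t)x] += t_max - lo;
      }
      t = t_max;
      break;
    }
    double u1 = unif_rand();
    if (u1 <= 0.0) u1 = DBL_MIN;
    const double t_next = t - std::log(u1) / a0;

    const double lo = std::max(t, burn_in_time);
    const double hi = std::min(t_next, t_max);
    if (hi > lo) {
      if ((size_t)x >= occ.size()) occ.resize((size_t)x + 64, 0.0);
      occ[(size_t)x] += hi - lo;
    }
    if (t_next >= t_max) {
      t = t_max;
      break;
    }
    t = t_next;

    const double u2 = unif_rand() * a0;
    if (u2 < a1) {
      x += 1.0;
    } else if (u2 < a1 + a2) {
      x -= 1.0;
    } else if (u2 < a1 + a2 + a3) {
      x += r;
    } else {
      x -= 1.0;
    }
    if (x < 0.0) stop("state went negative: propensity bookkeeping error");
    n_events += 1.0;

    if (store) {
      if ((int)ts.size() < max_store) {
        ts.push_back(t);
        xs.push_back(x);
      } else {
        truncated = true;
      }
    }
  }

  // trim trailing zero-weight states
  size_t last = occ.size();
  while (last > 0 && occ[last - 1] == 0.0) --last;
  occ.resize(last);

  return List::create(
    _["t"] = ts, _["x"] = xs,
    _["occ_weight"] = occ,
    _["n_events"] = n_events,
    _["t_end"] = t,
    _["final_state"] = x,
    _["truncated"] = truncated);
}
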