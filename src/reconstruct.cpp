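#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double GRAV = 9.81;

// Gradient energy-cost polynomial for running (J kg^-1 m^-1) as a
// function of the equivalent slope es = a / g.
static inline double gradient_cost_poly(double es) {
  return ((((155.4 * es - 30.4) * es - 43.3) * es + 46.3) * es + 19.5) * es + 3.6;
}

static inline double gradient_cost_poly_d(double es) {
  return (((777.0 * es - 121.6) * es - 129.9) * es + 92.6) * es + 19.5;
}

// Energy cost of accelerated running (J kg^-1 m^-1), excluding air
// resistance. variant 1: gradient polynomial evaluated at the
// equivalent slope, times the equivalent mass sqrt(es^2 + 1), with
// slope-matched linear extrapolation beyond |es| > es_limit (the
// polynomial is only calibrated on moderate gradients). variant 2:
// closed-form cost of accelerated running fitted directly on sprint
// acceleration data.
static double cost_accel_c(double a, int variant, double es_limit) {
  if (variant == 2) {
    return 0.102 * std::sqrt(a * a + 96.2) *
           (4.03 * a + 3.6 * std::exp(-0.408 * a));
  }
  double es = a / GRAV;
  double c;
  if (es > es_limit) {
    c = gradient_cost_poly(es_limit) +
        gradient_cost_poly_d(es_limit) * (es - es_limit);
  } else if (es < -es_limit) {
    c = gradient_cost_poly(-es_limit) +
        gradient_cost_poly_d(-es_limit) * (es + es_limit);
  } else {
    c = gradient_cost_poly(es);
  }
  return c * std::sqrt(es * es + 1.0);
}

// [[Rcpp::export]]
NumericVector cpp_cost_accelerated(NumericVector a, int variant,
                                   double es_limit) {
  int n = a.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = cost_accel_c(a[i], variant, es_limit);
  return out;
}

struct StepPars {
  double dt, air, flat, es_limit, a_max;
  int variant;
  int scheme;  // 1 = endpoint, 2 = midpoint
};

// metabolic power implied by moving from v_prev to v_next over one step
static inline double step_power(double v_next, double v_prev,
                                const StepPars &p) {
  double a = (v_next - v_prev) / p.dt;
  double c = (a > 0.0) ? cost_accel_c(a, p.variant, p.es_limit) : p.flat;
  double v = (p.scheme == 2) ? 0.5 * (v_next + v_prev) : v_next;
  return (c + p.air * v * v) * v;
}

// bisection for step_power(v) == target on [lo, hi]; power is
// monotone increasing in v_next within one cost branch
static double solve_step(double lo, double hi, double v_prev, double target,
                         const StepPars &p) {
  for (int it = 0; it < 80; ++it) {
    double mid = 0.5 * (lo + hi);
    if (step_power(mid, v_prev, p) < target) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// power implied by an acceleration-phase step: the accelerated-running
// cost applies even as a -> 0 (its a = 0 limit, ~3.6, differs from the
// flat running cost used for deceleration steps)
static inline double step_power_accel(double v_next, double v_prev,
                                      const StepPars &p) {
  double a = (v_next - v_prev) / p.dt;
  double c = cost_accel_c(a > 0.0 ? a : 0.0, p.variant, p.es_limit);
  double v = (p.scheme == 2) ? 0.5 * (v_next + v_prev) : v_next;
  return (c + p.air * v * v) * v;
}

static double solve_step_accel(double lo, double hi, double v_prev,
                               double target, const StepPars &p) {
  for (int it = 0; it < 80; ++it) {
    double mid = 0.5 * (lo + hi);
    if (step_power_accel(mid, v_prev, p) < target) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// Stepwise inversion of a metabolic power series into velocity.
// power[0] corresponds to t = 0 where v = 0; steps advance on a
// uniform grid of width dt.
//
// Branch selection: near the acceleration/deceleration transition the
// two cost branches overlap (the accelerated cost tends to ~3.6 as
// a -> 0 while the deceleration cost is the flat 3.8), so one power
// value can be matched by either a low-acceleration step or a
// flat-cost deceleration. When the series carries its cost-switch
// time (n_accel > 0: number of steps in the acceleration phase) the
// inversion mirrors the forward convention exactly: accelerated cost
// up to that step, flat cost beyond. Otherwise (n_accel < 0) the
// deceleration branch is preferred whenever it can match the target
// within |a| <= a_max, and the acceleration branch is used when the
// target exceeds the flat-cost power of holding the current velocity.
// [[Rcpp::export]]
List cpp_reconstruct(NumericVector power, double dt, int variant,
                     double es_limit, double flat_cost, double air_coeff,
                     double a_max, int scheme, int n_accel) {
  int n = power.size();
  NumericVector v(n);
  IntegerVector flagged;
  StepPars p{dt, air_coeff, flat_cost, es_limit, a_max, variant, scheme};
  v[0] = 0.0;
  for (int i = 1; i < n; ++i) {
    double v_prev = v[i - 1];
    bool force_accel = (n_accel >= 0) && (i <= n_accel);
    bool force_decel = (n_accel >= 0) && (i > n_accel);
    // the step that crosses the recorded cost discontinuity must not
    // average the target across the jump: match the endpoint power
    bool at_switch = (n_accel >= 0) && (i == n_accel + 1);
    StepPars ps = p;
    if (at_switch) ps.scheme = 1;
    double target = (ps.scheme == 2) ? 0.5 * (power[i - 1] + power[i])
                                     : power[i];
    double dec_lo = std::max(0.0, v_prev - a_max * dt);
    double acc_hi = v_prev + a_max * dt;

    if (force_accel) {
      double p_lo = step_power_accel(v_prev, v_prev, ps);
      double p_hi = step_power_accel(acc_hi, v_prev, ps);
      if (target <= p_lo) {
        v[i] = v_prev;  // hold; target marginally below the branch floor
      } else if (target > p_hi) {
        v[i] = acc_hi;
        flagged.push_back(i + 1);
      } else {
        v[i] = solve_step_accel(v_prev, acc_hi, v_prev, target, ps);
      }
      continue;
    }

    double p_dec_hi = step_power(v_prev, v_prev, ps);  // a = 0: flat cost
    if (target <= p_dec_hi || force_decel) {
      // deceleration (or hold) step under the flat running cost
      double p_dec_lo = (dec_lo < v_prev) ? step_power(dec_lo, v_prev, ps)
                                          : p_dec_hi;
      if (target < p_dec_lo) {  // would need a < -a_max
        v[i] = dec_lo;
        flagged.push_back(i + 1);
      } else if (target > p_dec_hi) {  // forced decel cannot reach: hold
        v[i] = v_prev;
        flagged.push_back(i + 1);
      } else {
        v[i] = solve_step(dec_lo, v_prev, v_prev, target, ps);
      }
    } else {
      // acceleration step
      double p_acc_hi = step_power(acc_hi, v_prev, ps);
      if (target > p_acc_hi) {  // would need a > a_max
        v[i] = acc_hi;
        flagged.push_back(i + 1);
      } else {
        v[i] = solve_step(v_prev, acc_hi, v_prev, target, ps);
      }
    }
  }
  // trapezoidal distance
  double dist = 0.0;
  for (int i = 1; i < n; ++i) dist += 0.5 * (v[i] + v[i - 1]) * dt;
  return List::create(_["velocity"] = v, _["distance"] = dist,
                      _["flagged_steps"] = flagged);
}
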