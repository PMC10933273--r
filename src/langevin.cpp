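#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Overdamped Langevin integrator for a trapped bead with a tethered motor.
//
// Coordinates: x along the microtubule axis, nm. Sample i is taken at time
// i*dt_out; trap_pos[i] is the commanded trap centre at that time (linearly
// interpolated inside each interval). The motor, when bound, is anchored at
// a lattice site and walks in +x with a linear force-velocity relation; the
// tether is slack below its (projected) rest length and a stiff spring
// beyond it. Euler-Maruyama with two substep sizes: coarse while unbound
// (relaxation time gamma/k_trap), fine while bound (gamma/(k_trap+k_tether)).
//
// Units: nm, pN, s; kT in pN nm; gamma in pN s/nm. Uses R's RNG, so traces
// are reproducible under set.seed().
//
// Scripted mode (scripted_bind non-empty): binding occurs exactly at the
// given times, detachment exactly after the paired duration; the stochastic
// binding/unbinding channels are disabled. Used to validate detectors on
// traces with controlled event durations.

// [[Rcpp::export]]
List langevin_core(NumericVector trap_pos, double dt_out,
                   double k_trap, double gamma, double kT,
                   double k_on, double v0, double f_stall,
                   double k_off0, double f_detach,
                   double tether_slack, double k_tether,
                   double lattice_period,
                   double dt_unbound, double dt_bound,
                   NumericVector scripted_bind,
                   NumericVector scripted_dur,
                   double x0) {
  const int n = trap_pos.size();
  NumericVector bead(n), force(n);
  LogicalVector bound_out(n);
  std::vector<double> bind_times, unbind_times;

  const bool scripted = scripted_bind.size() > 0;
  std::size_t i_script = 0;          // next scripted binding
  double t_unbind_sched = -1.0;      // scheduled scripted detachment

  double x = x0;        // bead position
  double xm = 0.0;      // motor head position (valid while bound)
  bool bound = false;
  double t = 0.0;
  const double eps = 1e-12;
  const double tau_u = gamma / k_trap;  // free-bead relaxation time

  RNGScope scope;

  for (int i = 0; i < n; ++i) {
    bead[i] = x;
    force[i] = k_trap * (x - trap_pos[i]);
    bound_out[i] = bound;
    if (i + 1 == n) break;

    const double xt0 = trap_pos[i], xt1 = trap_pos[i + 1];
    const double t_next = (i + 1) * dt_out;

    while (t < t_next - eps) {
      double dt = bound ? dt_bound : dt_unbound;
      if (t + dt > t_next) dt = t_next - t;

      // snap the step to a scheduled scripted transition
      double t_event = -1.0;
      if (scripted) {
        if (!bound && i_script < (std::size_t)scripted_bind.size())
          t_event = scripted_bind[i_script];
        else if (bound)
          t_event = t_unbind_sched;
        if (t_event >= t - eps && t_event < t + dt)
          dt = std::max(t_event - t, 0.0);
        else
          t_event = -1.0;
      }

      if (dt > 0.0) {
        const double frac = (t - i * dt_out) / dt_out;
        const double xt = xt0 + (xt1 - xt0) * std::min(std::max(frac, 0.0), 1.0);

        if (!bound) {
          // free bead in the trap: exact Ornstein-Uhlenbeck update (trap
          // frozen over the substep), so the sampled statistics are unbiased
          const double a = std::exp(-dt / tau_u);
          const double sd = (kT > 0.0)
              ? std::sqrt(kT / k_trap * (1.0 - a * a)) : 0.0;
          x = xt + (x - xt) * a + (sd > 0.0 ? sd * norm_rand() : 0.0);
          if (!scripted && k_on > 0.0 &&
              unif_rand() < -std::expm1(-k_on * dt)) {
            bound = true;
            xm = std::round(x / lattice_period) * lattice_period;
            bind_times.push_back(t + dt);
          }
        } else {
          // tethered: piecewise-linear force, Euler-Maruyama at fine step
          double ft = 0.0;  // tether force on the bead (+x: motor ahead, taut)
          const double sep = xm - x;
          if (sep > tether_slack)       ft = k_tether * (sep - tether_slack);
          else if (sep < -tether_slack) ft = k_tether * (sep + tether_slack);
          const double noise =
              (kT > 0.0) ? std::sqrt(2.0 * kT * dt / gamma) * norm_rand() : 0.0;
          x += (-k_trap * (x - xt) + ft) / gamma * dt + noise;

          // hindering load slows walking; any tension accelerates detachment
          const double f_hind = (ft > 0.0) ? ft : 0.0;
          double v = v0 * (1.0 - f_hind / f_stall);
          if (v < 0.0) v = 0.0;
          xm += v * dt;
          if (!scripted) {
            const double koff = k_off0 * std::exp(std::fabs(ft) / f_detach);
            if (unif_rand() < -std::expm1(-koff * dt)) {
              bound = false;
              unbind_times.push_back(t + dt);
            }
          }
        }
        t += dt;
      }

      if (scripted && t_event >= 0.0 && t >= t_event - eps) {
        if (!bound) {
          bound = true;
          xm = std::round(x / lattice_period) * lattice_period;
          bind_times.push_back(t_event);
          t_unbind_sched = t_event + scripted_dur[i_script];
          ++i_script;
        } else {
          bound = false;
          unbind_times.push_back(t_event);
          t_unbind_sched = -1.0;
        }
        if (dt <= 0.0) t = t_event + eps;  // avoid re-triggering at dt == 0
      }
    }
    t = t_next;
  }

  // still bound at the end: censor the final event at the trace duration
  if (bound) unbind_times.push_back(n * dt_out);

  return List::create(_["bead"] = bead, _["force"] = force,
                      _["bound"] = bound_out,
                      _["bind_times"] = NumericVector(bind_times.begin(), bind_times.end()),
                      _["unbind_times"] = NumericVector(unbind_times.begin(), unbind_times.end()));
}
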