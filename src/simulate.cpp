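#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 integration of a single passive-stretch movement + hold.
// Angles in degrees, torques in Nm; controller gains are per-radian
// (kp, kd, damping, spastic gain) except hold_gain / contracture stiffness
// which are per-degree, matching how they are specified.

static const double D2R = M_PI / 180.0;
static const double R2D = 180.0 / M_PI;

struct SimCfg {
  double start, target, T;                 // deg, deg, s (nominal duration)
  double kp, kd, hold_gain, tq_lim, i_est; // robot
  double timeout;                          // s, controller persistence
  double inertia, damping;                 // limb
  double sp_gain, sp_onset, sp_tau;        // spastic resistance
  double c_limit, c_stiff;                 // contracture
  bool contracture;
};

// half-cosine commanded profile: zero endpoint velocity, single sine-lobe
// velocity profile
static inline void command(const SimCfg& c, double t,
                           double& th, double& om, double& al) {
  if (t >= c.T) { th = c.target; om = 0.0; al = 0.0; return; }
  double d = c.target - c.start;
  double ph = M_PI * t / c.T;
  th = c.start + d * (1.0 - std::cos(ph)) / 2.0;
  om = d * M_PI / (2.0 * c.T) * std::sin(ph);
  al = d * M_PI * M_PI / (2.0 * c.T * c.T) * std::cos(ph);
}

static inline double clip(double x, double lim) {
  return x > lim ? lim : (x < -lim ? -lim : x);
}

static inline double robot_torque(const SimCfg& c, double t,
                                  double th, double om) {
  if (t > c.timeout) return 0.0;
  if (t <= c.T) {
    double thc, omc, alc;
    command(c, t, thc, omc, alc);
    double tau = c.kp * (thc - th) * D2R + c.kd * (omc - om) * D2R +
                 c.i_est * alc * D2R; // inertial feedforward
    return clip(tau, c.tq_lim);
  }
  // post-stretch hold: proportional pull toward the commanded end angle
  return clip(c.hold_gain * (c.target - th), c.tq_lim);
}

// spastic activation: latched at onset excursion, unity through the
// movement, exponential release afterwards (produces creep)
static inline double gate(const SimCfg& c, bool engaged, double t) {
  if (!engaged) return 0.0;
  if (t <= c.T) return 1.0;
  return std::exp(-(t - c.T) / c.sp_tau);
}

static inline double accel(const SimCfg& c, double t, double th, double om,
                           bool engaged) {
  double tau = robot_torque(c, t, th, om);
  tau -= c.damping * om * D2R;
  tau -= c.sp_gain * gate(c, engaged, t) * om * D2R;
  if (c.contracture && th > c.c_limit) tau -= c.c_stiff * (th - c.c_limit);
  return tau / c.inertia * R2D; // deg/s^2
}

// [[Rcpp::export(name = ".simulate_trial_core")]]
List simulate_trial_core(double start_angle, double target_angle,
                         double duration_ms, double record_ms,
                         double dt_ms, List robot, List limb) {
  SimCfg c;
  c.start = start_angle;
  c.target = target_angle;
  c.T = duration_ms / 1000.0;
  c.kp = as<double>(robot["kp"]);
  c.kd = as<double>(robot["kd"]);
  c.hold_gain = as<double>(robot["hold_gain"]);
  c.tq_lim = as<double>(robot["torque_limit"]);
  c.i_est = as<double>(robot["inertia_estimate"]);
  c.timeout = as<double>(robot["timeout_ms"]) / 1000.0;
  c.inertia = as<double>(limb["inertia"]);
  c.damping = as<double>(limb["passive_damping"]);
  c.sp_gain = as<double>(limb["spastic_gain"]);
  c.sp_onset = as<double>(limb["catch_onset_excursion"]);
  c.sp_tau = as<double>(limb["release_time_constant"]);
  double cl = as<double>(limb["contracture_limit"]);
  c.contracture = R_finite(cl) &&
                  as<double>(limb["contracture_stiffness"]) > 0.0;
  c.c_limit = c.contracture ? cl : 1e9;
  c.c_stiff = as<double>(limb["contracture_stiffness"]);

  int n = (int) std::lround(record_ms / dt_ms);
  double h = dt_ms / 1000.0;
  NumericVector th(n), om(n), tq(n), act(n);
  double x = start_angle, v = 0.0;
  bool engaged = false;

  for (int i = 0; i < n; ++i) {
    double t = i * h;
    if (c.sp_gain > 0.0 && t <= c.T &&
        std::fabs(x - c.start) >= c.sp_onset)
      engaged = true;
    th[i] = x;
    om[i] = v;
    tq[i] = robot_torque(c, t, x, v);
    act[i] = gate(c, engaged, t);

    double k1x = v,            k1v = accel(c, t, x, v, engaged);
    double k2x = v + k1v * h/2,
           k2v = accel(c, t + h/2, x + k1x * h/2, v + k1v * h/2, engaged);
    double k3x = v + k2v * h/2,
           k3v = accel(c, t + h/2, x + k2x * h/2, v + k2v * h/2, engaged);
    double k4x = v + k3v * h,
           k4v = accel(c, t + h, x + k3x * h, v + k3v * h, engaged);
    x += h / 6.0 * (k1x + 2*k2x + 2*k3x + k4x);
    v += h / 6.0 * (k1v + 2*k2v + 2*k3v + k4v);

    if (!std::isfinite(x) || !std::isfinite(v) || std::fabs(v) > 1e5)
      stop("simulation instability at t = %d ms (|velocity| > 1e5 deg/s); "
           "check inertia = %g, kp = %g, kd = %g, spastic_gain = %g",
           (int) std::lround(t * 1000), c.inertia, c.kp, c.kd, c.sp_gain);
  }

  return List::create(_["angle"] = th, _["velocity"] = om,
                      _["torque"] = tq, _["spastic_activation"] = act);
}
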