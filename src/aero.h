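#ifndef STOOPSIM_AERO_H
#define STOOPSIM_AERO_H

#include <cmath>
#include <algorithm>

// Species morphology in SI units (wing mass is the pair of wings).
struct Morph {
  double f;    // wingbeat frequency, Hz
  double b;    // wingspan, m
  double mb;   // body mass, kg
  double mw;   // wing mass (both wings), kg
  double Sw;   // wing area, m^2
  double AR;   // aspect ratio
  double Cdb;  // body drag coefficient
  // cached derived quantities (filled by init_derived; hot path)
  double Sb;   // body frontal area, m^2
  double wb;   // body width, m
  double mfac; // muscle factor m_w^a_mw
  double rfac; // roll-asymmetry factor m_w^a_rm
  double gfac; // thrust factor (f b)^a_u (S_w m_w)^a_G f^a_fG
};

// Global aerodynamic / mechanical constants.  The starred (*) entries are
// the calibration knobs: fitted once against the printed flight anchors of
// the two falcon rows (top level speeds, terminal dive speeds, carry loads)
// and then frozen for every species.
struct AeroPars {
  double rho;       // air density, kg m^-3
  double g;         // gravitational acceleration, m s^-2
  double CL_max;    // maximum lift coefficient (stall limit)
  double Cd_pro0;   // zero-lift profile drag coefficient of the wing
  double k_ind;     // induced drag factor
  double amp;       // wingbeat amplitude, rad
  double Cd_pro2;   // * lift-dependence of profile drag (Cd = Cd0 + Cd2 CL^2)
  double c_q;       // * flap dynamic-pressure augmentation (on u_tip^2)
  double k_G;       // * gross flapping-thrust coefficient
  double a_u;       // flap-speed exponent of the thrust factor
  double a_G;       // * wing size-mass exponent of the thrust factor
  double a_fG;      // * extra wingbeat-frequency exponent of the thrust factor
  double k_musc;    // * muscle normal-force coefficient (N s m^-1 per unit factor)
  double a_mw;      // wing-mass exponent in the muscle factor
  double tau_frac;  // * maximum lift-asymmetry fraction for roll torque
  double k_roll;    // * muscle lift-asymmetry coefficient (roll channel)
  double a_rm;      // wing-mass exponent of the roll-asymmetry cap
  double k_Sb;      // * body frontal area coefficient, S_b = k_Sb * m^0.68
  double k_wb;      // body width coefficient, w_b = k_wb * m^0.35
  double rho_ret;   // span/area reduction at full wing retraction
  double n_elem;    // blade elements per wing (envelope integration)
};

inline AeroPars default_aero() {
  AeroPars p;
  p.rho = 1.225;
  p.g = 9.81;
  p.CL_max = 1.6;
  p.Cd_pro0 = 0.02;
  p.k_ind = 1.1;
  p.amp = 1.05;
  // calibrated values (see calibration protocol in the package docs);
  // kept in sync with R/aero-params.R
  p.Cd_pro2 = 0.047443;
  p.c_q = 0.1666666666666667;
  p.k_G = 0.635725;
  p.a_u = 2.07178;
  p.a_G = 0.36482;
  p.a_fG = -0.10256;
  p.k_musc = 6.215705916;
  p.a_mw = 0.7;
  p.tau_frac = 0.9;
  p.k_roll = 17.92174096;
  p.a_rm = 1.08;
  p.k_Sb = 0.007544302753;
  p.k_wb = 0.07;
  p.rho_ret = 0.6;
  p.n_elem = 20;
  return p;
}

inline double body_frontal_area_(double mb, const AeroPars &p) {
  return p.k_Sb * std::pow(mb, 0.68);
}
inline double body_width_(double mb, const AeroPars &p) {
  return p.k_wb * std::pow(mb, 0.35);
}

inline void init_derived(Morph &m, const AeroPars &p) {
  m.Sb = body_frontal_area_(m.mb, p);
  m.wb = body_width_(m.mb, p);
  m.mfac = std::pow(m.mw, p.a_mw);
  m.rfac = std::pow(m.mw, p.a_rm);
  m.gfac = std::pow(m.f * m.b, p.a_u) * std::pow(m.Sw * m.mw, p.a_G) *
           std::pow(m.f, p.a_fG);
}
inline double eff_span(const Morph &m, double zeta, const AeroPars &p) {
  return m.b * (1.0 - p.rho_ret * zeta);
}
inline double eff_area(const Morph &m, double zeta, const AeroPars &p) {
  return m.Sw * (1.0 - p.rho_ret * zeta);
}

// uniform-rod wings plus cylindrical body
inline double roll_inertia_(const Morph &m, double zeta, const AeroPars &p) {
  double be = eff_span(m, zeta, p);
  return (m.mw / 12.0) * be * be + (m.mb / 8.0) * m.wb * m.wb;
}

// peak flapping tip speed at the current retraction
inline double u_tip(const Morph &m, double zeta, const AeroPars &p) {
  return 2.0 * M_PI * m.f * p.amp * 0.5 * eff_span(m, zeta, p);
}

// Stall-limited lift, blade-element average.  Elementwise dynamic pressure
// q_e = 0.5 rho (v^2 + (w r')^2) integrated over the span equals
// 0.5 rho (v^2 + c_q u_tip^2) S_eff with c_q = 1/6 for a sinusoidal stroke
// of a uniform-chord wing; c_q is kept as an explicit constant.
inline double lift_stall(const Morph &m, double v, double zeta, bool flap,
                         const AeroPars &p) {
  double ut = flap ? u_tip(m, zeta, p) : 0.0;
  double q = 0.5 * p.rho * (v * v + p.c_q * ut * ut);
  return p.CL_max * q * eff_area(m, zeta, p);
}

// Muscle/mechanical cap on the wingbeat-averaged normal force.  The cap
// grows linearly with airspeed (the force coefficient the flight muscles
// can hold is fixed, while the reference dynamic pressure grows with the
// product of airspeed and flap speed), with a per-species scale set by
// the flight-muscle (wing) mass.
inline double lift_muscle(const Morph &m, double v, const AeroPars &p) {
  return p.k_musc * m.mfac * v;
}

inline double max_lift_(const Morph &m, double v, double zeta, bool flap,
                        const AeroPars &p) {
  return std::min(lift_stall(m, v, zeta, flap, p), lift_muscle(m, v, p));
}

// Minimum drag at a given lift: body parasite + wing profile (with its
// lift-dependent part, Cd = Cd_pro0 + Cd_pro2 CL^2) + span-induced.
inline double min_drag_(const Morph &m, double v, double L, double zeta,
                        const AeroPars &p) {
  double q = 0.5 * p.rho * v * v;
  double be = eff_span(m, zeta, p);
  double Se = eff_area(m, zeta, p);
  double Dpar = q * m.Sb * m.Cdb;
  // zero-lift wing drag vanishes at full retraction (folded wings shed
  // no exposed area), while the lift-bearing area shrinks only to the
  // effective area used for lift
  double Dpro = q * m.Sw * (1.0 - zeta) * p.Cd_pro0;
  double Dpro2 = (q > 1e-12) ? p.Cd_pro2 * L * L / (q * Se) : 0.0;
  double Dind = (q > 1e-12) ? p.k_ind * L * L / (q * M_PI * be * be) : 0.0;
  return Dpar + Dpro + Dpro2 + Dind;
}

// Gross wingbeat-averaged flapping thrust.  In a quasi-steady blade
// element with a parabolic profile polar, tilting the elementwise force
// forward on the downstroke and feathering the upstroke yields a nearly
// speed-independent propulsive force whose scale follows the squared
// flap tip speed (f b)^2 acting on an effective propulsive area; the
// drag side of the polar is charged in min_drag_.
inline double thrust_gross(const Morph &m, double v, const AeroPars &p) {
  (void)v;
  return p.k_G * m.gfac;
}

// Net maximum forward force while flapping at lift L (can be negative).
inline double max_thrust_net(const Morph &m, double v, double L,
                             const AeroPars &p) {
  return thrust_gross(m, v, p) - min_drag_(m, v, L, 0.0, p);
}

// maximum level acceleration a(v) with lift = weight
inline double level_accel(const Morph &m, double v, const AeroPars &p) {
  double W = m.mb * p.g;
  if (max_lift_(m, v, 0.0, true, p) < W) return -1e6; // cannot support weight
  return max_thrust_net(m, v, W, p) / m.mb;
}

// top sustained level speed: largest root of level_accel(v) = 0
inline double v_top_level(const Morph &m, const AeroPars &p) {
  double lo = 1.0, hi = 1.0;
  // find a speed where level flight is possible
  double vstart = -1.0;
  for (double v = 1.0; v <= 120.0; v += 0.5) {
    if (level_accel(m, v, p) > 0.0) { vstart = v; break; }
  }
  if (vstart < 0.0) return 0.0;
  lo = vstart;
  hi = vstart;
  while (hi < 200.0 && level_accel(m, hi, p) > 0.0) hi += 0.5;
  for (int i = 0; i < 60; ++i) {
    double mid = 0.5 * (lo + hi);
    if (level_accel(m, mid, p) > 0.0) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// vertical dive, fully retracted wings, wing drag neglected
inline double dive_accel(const Morph &m, double v, const AeroPars &p) {
  double q = 0.5 * p.rho * v * v;
  return p.g - q * m.Sb * m.Cdb / m.mb;
}

inline double v_terminal_(const Morph &m, const AeroPars &p) {
  return std::sqrt(2.0 * m.mb * p.g / (p.rho * m.Sb * m.Cdb));
}

// maximum-range speed: minimises mechanical cost of transport P/v = D(v)
// over level-feasible speeds (golden-section on drag at lift = weight)
inline double v_max_range(const Morph &m, const AeroPars &p) {
  double vtop = v_top_level(m, p);
  if (vtop <= 0.0) return 0.0;
  double lo = 1.0, hi = vtop;
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double W = m.mb * p.g;
  auto cost = [&](double v) {
    if (max_lift_(m, v, 0.0, true, p) < W) return 1e9;
    return min_drag_(m, v, W, 0.0, p);
  };
  double f1 = cost(x1), f2 = cost(x2);
  for (int i = 0; i < 80; ++i) {
    if (f1 < f2) { b = x2; x2 = x1; f2 = f1; x1 = b - gr * (b - a); f1 = cost(x1); }
    else { a = x1; x1 = x2; f1 = f2; x2 = a + gr * (b - a); f2 = cost(x2); }
  }
  double v = 0.5 * (a + b);
  return std::min(v, vtop);
}

inline double max_load_factor_(const Morph &m, double v, const AeroPars &p) {
  return max_lift_(m, v, 0.0, true, p) / (m.mb * p.g);
}

// Maximum roll acceleration from the sustainable lift asymmetry between
// the wings.  The asymmetry the flight muscles can hold has its own
// (steeper) wing-mass allometry than the total normal force, and can
// never exceed the total lift available.
inline double max_roll_accel_(const Morph &m, double v, double zeta,
                              const AeroPars &p) {
  double L = std::min(max_lift_(m, v, zeta, true, p), p.k_roll * m.rfac * v);
  double arm = eff_span(m, zeta, p) / 4.0;
  return p.tau_frac * L * arm / roll_inertia_(m, zeta, p);
}

inline double min_turn_radius_(const Morph &m, double v, const AeroPars &p) {
  double L = max_lift_(m, v, 0.0, true, p);
  return v * v * m.mb / L;
}

// Can the falcon sustain level flight while carrying a prey mass?  The prey
// adds its weight to the required lift and its body parasite drag (frontal
// area from the m^0.68 allometry) to the drag budget.
inline bool can_carry(const Morph &m, double prey_m, double prey_Cdb,
                      const AeroPars &p) {
  double Ltot = (m.mb + prey_m) * p.g;
  double Sbp = body_frontal_area_(prey_m, p);
  for (double v = 1.0; v <= 80.0; v += 0.05) {
    if (max_lift_(m, v, 0.0, true, p) < Ltot) continue;
    double q = 0.5 * p.rho * v * v;
    double T = max_thrust_net(m, v, Ltot, p) - q * Sbp * prey_Cdb;
    if (T >= 0.0) return true;
  }
  return false;
}

inline double max_carry_mass(const Morph &m, double prey_Cdb, const AeroPars &p) {
  if (!can_carry(m, 0.0, prey_Cdb, p)) return 0.0;
  double lo = 0.0, hi = 0.05;
  while (hi < 10.0 && can_carry(m, hi, prey_Cdb, p)) { lo = hi; hi *= 2.0; }
  for (int i = 0; i < 45; ++i) {
    double mid = 0.5 * (lo + hi);
    if (can_carry(m, mid, prey_Cdb, p)) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

#endif
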