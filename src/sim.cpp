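#include <Rcpp.h>
#include <vector>
#include "aero.h"
#include "rng.h"

using namespace Rcpp;

Morph morph_from_list(const List &m);     // aero.cpp
Morph morph_from_list_full(const List &m, const AeroPars &p);
AeroPars aero_from_list(const List &a);   // aero.cpp

// ---------------------------------------------------------------- vectors
struct Vec3 {
  double x, y, z;
};
static inline Vec3 v3(double x, double y, double z) { Vec3 v{x, y, z}; return v; }
static inline Vec3 operator+(Vec3 a, Vec3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline Vec3 operator-(Vec3 a, Vec3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline Vec3 operator*(double s, Vec3 a) { return v3(s * a.x, s * a.y, s * a.z); }
static inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(Vec3 a, Vec3 b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm3(Vec3 a) { return std::sqrt(dot(a, a)); }
static inline Vec3 unit(Vec3 a) {
  double n = norm3(a);
  return (n > 1e-300) ? (1.0 / n) * a : v3(1, 0, 0);
}
static inline Vec3 perp_to(Vec3 a, Vec3 ev) { return a - dot(a, ev) * ev; }

// closest approach between two linearly-interpolated positions over one
// step: min over t in [0,1] of |r0 + t (r1 - r0)|
static inline double seg_min_dist(Vec3 r0, Vec3 r1) {
  Vec3 d = r1 - r0;
  double dd = dot(d, d);
  if (dd < 1e-30) return norm3(r0);
  double t = -dot(r0, d) / dd;
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  return norm3(r0 + t * d);
}

static inline double wrap_pi(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a <= -M_PI) a += 2.0 * M_PI;
  return a;
}

// zero-roll lift direction: projection of world-up onto the plane normal
// to the velocity (coordinated flight, no sideslip)
static inline Vec3 up_perp(Vec3 ev) {
  Vec3 ez = v3(0, 0, 1);
  Vec3 u = perp_to(ez, ev);
  double n = norm3(u);
  if (n < 1e-9) { // flying (almost) straight up/down: any perpendicular
    Vec3 ex = v3(1, 0, 0);
    u = perp_to(ex, ev);
    n = norm3(u);
  }
  return (1.0 / n) * u;
}

// minimum-time double-integrator (bang-bang) torque command toward a
// target angle; returns angular acceleration in [-alpha, alpha]
static inline double bang_bang(double err, double rate, double alpha,
                               double dt) {
  if (alpha <= 0.0) return 0.0;
  // close enough to snap within one step
  if (std::fabs(err) < 0.5 * alpha * dt * dt && std::fabs(rate) < alpha * dt)
    return 0.0;
  double s = (err >= 0.0) ? 1.0 : -1.0;
  double e = s * err, r = s * rate; // normalised so target is ahead
  double u;
  if (r < 0.0) u = 1.0;
  else u = (r * r / (2.0 * alpha) >= e) ? -1.0 : 1.0;
  return s * u * alpha;
}

// --------------------------------------------------------------- agents
struct FullBird {
  Morph m;
  AeroPars p;
  Vec3 pos, vel;
  double roll, roll_rate;
  double zeta;   // wing retraction 0..1
  bool flap;
  // realised per-step diagnostics
  double lf;        // load factor (lift / weight)
  double rollacc;   // available max roll acceleration at current state
  double radius;    // realised turn radius
};

struct CappedBird {
  double speed, n_max, rollacc_max;
  Vec3 pos, vel;
  double psi, psi_rate; // force-direction angle in the normal plane
  double lf, rollacc, radius;
};

// advance a full-physics bird one step under a commanded normal
// acceleration (world frame); implements saturation, bang-bang roll and
// flap/glide selection, then fixed-step RK4 translation
static void step_full(FullBird &b, Vec3 acmd, double dt) {
  double v = norm3(b.vel);
  Vec3 ev = unit(b.vel);
  Vec3 u0 = up_perp(ev);
  Vec3 w0 = cross(ev, u0);
  Vec3 gv = v3(0, 0, -b.p.g);
  Vec3 gperp = perp_to(gv, ev);

  acmd = perp_to(acmd, ev);
  Vec3 Lreq = b.m.mb * (acmd - gperp);
  double Lr = norm3(Lreq);

  // roll toward the required lift direction
  double phi_t = (Lr > 1e-9) ? std::atan2(dot(Lreq, w0), dot(Lreq, u0)) : b.roll;
  double alpha = max_roll_accel_(b.m, v, b.zeta, b.p);
  double err = wrap_pi(phi_t - b.roll);
  double u = bang_bang(err, b.roll_rate, alpha, dt);
  if (u == 0.0 && std::fabs(err) < 0.5 * alpha * dt * dt &&
      std::fabs(b.roll_rate) < alpha * dt) {
    b.roll = phi_t;
    b.roll_rate = 0.0;
  } else {
    b.roll = wrap_pi(b.roll + b.roll_rate * dt + 0.5 * u * dt * dt);
    b.roll_rate += u * dt;
  }

  // While the bang-bang roll is still redirecting the lift vector, the
  // bird pulls only the component of the demanded lift that lies along
  // the currently achievable direction (it unloads while rolling).
  double err2 = wrap_pi(phi_t - b.roll);
  double ce = std::cos(err2);
  if (ce < 0.0) ce = 0.0;
  Lr *= ce;

  // flap-or-glide: compare best forward force at the required lift
  double Lmax_f = max_lift_(b.m, v, 0.0, true, b.p);
  double Lf_app = std::min(Lr, Lmax_f);
  double fwd_flap = max_thrust_net(b.m, v, Lf_app, b.p);
  double best_gl = -1e18, best_zeta = 0.0, Lg_app = 0.0;
  for (int i = 0; i <= 4; ++i) {
    double z = 0.25 * i;
    double Lm = max_lift_(b.m, v, z, false, b.p);
    double La = std::min(Lr, Lm);
    double fwd = -min_drag_(b.m, v, La, z, b.p);
    // prefer configurations that meet the lift demand; among those,
    // maximise forward force (minimise drag)
    double score = (La >= Lr - 1e-9 ? 1e9 : La * 1e3) + fwd;
    if (score > best_gl + 1e-12) { best_gl = score; best_zeta = z; Lg_app = La; }
  }
  double fwd_gl = -min_drag_(b.m, v, Lg_app, best_zeta, b.p);

  double L_app, thrust_mode_zeta;
  bool use_flap;
  bool flap_meets = (Lf_app >= Lr - 1e-9);
  bool glide_meets = (Lg_app >= Lr - 1e-9);
  if (flap_meets && glide_meets) {
    use_flap = fwd_flap > fwd_gl; // ties go to glide
  } else if (flap_meets || glide_meets) {
    use_flap = flap_meets;
  } else { // saturated in every mode: exert the maximum lift available
    use_flap = Lf_app >= Lg_app;
  }
  if (use_flap) { L_app = Lf_app; thrust_mode_zeta = 0.0; }
  else { L_app = Lg_app; thrust_mode_zeta = best_zeta; }
  b.flap = use_flap;
  b.zeta = thrust_mode_zeta;

  // RK4 with frozen roll/mode/lift-magnitude; drag and thrust are
  // re-evaluated from the instantaneous speed inside each stage
  double Lmag = L_app, zz = thrust_mode_zeta;
  bool fl = use_flap;
  const Morph &mm = b.m;
  const AeroPars &pp = b.p;
  double phi = b.roll;
  auto accel = [&](Vec3 vel) -> Vec3 {
    double s = norm3(vel);
    Vec3 e = unit(vel);
    Vec3 uu = up_perp(e);
    Vec3 ww = cross(e, uu);
    Vec3 eL = std::cos(phi) * uu + std::sin(phi) * ww;
    double fwd = fl ? max_thrust_net(mm, s, Lmag, pp)
                    : -min_drag_(mm, s, Lmag, zz, pp);
    return (1.0 / mm.mb) * (Lmag * eL + fwd * e) + v3(0, 0, -pp.g);
  };
  Vec3 k1v = accel(b.vel);
  Vec3 k1x = b.vel;
  Vec3 k2v = accel(b.vel + (0.5 * dt) * k1v);
  Vec3 k2x = b.vel + (0.5 * dt) * k1v;
  Vec3 k3v = accel(b.vel + (0.5 * dt) * k2v);
  Vec3 k3x = b.vel + (0.5 * dt) * k2v;
  Vec3 k4v = accel(b.vel + dt * k3v);
  Vec3 k4x = b.vel + dt * k3v;
  b.pos = b.pos + (dt / 6.0) * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
  b.vel = b.vel + (dt / 6.0) * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);

  double W = b.m.mb * b.p.g;
  b.lf = L_app / W;
  b.rollacc = alpha;
  b.radius = (L_app > 1e-9) ? v * v * b.m.mb / L_app : R_PosInf;
}

// purely kinematic capped agent: constant speed, clipped normal
// acceleration, bang-bang reorientation of the force direction, no gravity
static void step_capped(CappedBird &b, Vec3 acmd, double dt) {
  Vec3 ev = unit(b.vel);
  Vec3 u0 = up_perp(ev);
  Vec3 w0 = cross(ev, u0);
  acmd = perp_to(acmd, ev);
  double amag = norm3(acmd);
  double acap = b.n_max * 9.81;
  if (amag > acap) amag = acap;

  double psi_t = (norm3(acmd) > 1e-12)
                     ? std::atan2(dot(acmd, w0), dot(acmd, u0))
                     : b.psi;
  double err = wrap_pi(psi_t - b.psi);
  double u = bang_bang(err, b.psi_rate, b.rollacc_max, dt);
  if (u == 0.0 && std::fabs(err) < 0.5 * b.rollacc_max * dt * dt &&
      std::fabs(b.psi_rate) < b.rollacc_max * dt) {
    b.psi = psi_t;
    b.psi_rate = 0.0;
  } else {
    b.psi = wrap_pi(b.psi + b.psi_rate * dt + 0.5 * u * dt * dt);
    b.psi_rate += u * dt;
  }
  Vec3 ea = std::cos(b.psi) * u0 + std::sin(b.psi) * w0;
  Vec3 a = amag * ea;
  Vec3 vnew = b.vel + dt * a;
  vnew = b.speed * unit(vnew);
  b.pos = b.pos + (0.5 * dt) * (b.vel + vnew);
  b.vel = vnew;
  b.lf = amag / 9.81;
  b.rollacc = b.rollacc_max;
  b.radius = (amag > 1e-12) ? b.speed * b.speed / amag : R_PosInf;
}

// ------------------------------------------------------------- guidance
struct Erratic {
  double c1, c2, c3, c4;
  int side;
  double t_next;

  void init(Pcg32 &rng) {
    side = rng.runif() < 0.5 ? -1 : 1;
    t_next = 0.0;
  }
  // Commanded normal acceleration for a prey with available cap a_max.
  // The command is a weight-supported coordinated jink: the prey banks
  // its lift (c3 of the available maximum) to alternating sides while
  // keeping the vertical component equal to its weight, so the lateral
  // acceleration is sqrt((c3 a_max)^2 - g^2); the jink plane is tilted
  // out of the horizontal by the bias angle c4.  Capped agents ignore
  // gravity and command the full c3 a_max laterally.
  Vec3 command(double t, Vec3 vel, double a_max, bool with_gravity,
               double g, Pcg32 &rng) {
    if (t >= t_next) {
      side = -side;
      double mean = std::max(c1 - c2, 1e-6);
      t_next = t + c2 + rng.rexp(mean);
    }
    Vec3 ev = unit(vel);
    Vec3 ez = v3(0, 0, 1);
    Vec3 h = cross(ez, ev);
    double n = norm3(h);
    Vec3 hs = (n > 1e-9) ? (1.0 / n) * h : up_perp(ev);
    Vec3 dir = std::cos(c4) * ((double)side * hs) + std::sin(c4) * ez;
    dir = unit(perp_to(dir, ev));
    double mag = c3 * a_max;
    if (with_gravity) {
      double m2 = mag * mag - g * g;
      mag = (m2 > 0.0) ? std::sqrt(m2) : 0.0;
    }
    return mag * dir;
  }
};

struct Ppn {
  double N, sigma_v;
  int delay_steps;
  int every; // guidance update interval, in integration steps
  bool have_prev;
  Vec3 prev_los;
  Vec3 held_cmd;
  Vec3 omega_f; // fading-memory filtered line-of-sight rate

  // apparent (delayed, noisy) line of sight
  Vec3 sense(const std::vector<Vec3> &fhist, const std::vector<Vec3> &phist,
             int k, Pcg32 &rng) {
    int i = k - delay_steps;
    if (i < 0) i = 0;
    Vec3 los = unit(phist[i] - fhist[i]);
    if (sigma_v > 0.0) {
      // rotate by a Gaussian angle about a uniformly random axis
      // perpendicular to the line of sight
      double ang = sigma_v * rng.rnorm();
      double az = rng.runif(0.0, 2.0 * M_PI);
      Vec3 u0 = up_perp(los);
      Vec3 w0 = cross(los, u0);
      Vec3 axis = std::cos(az) * u0 + std::sin(az) * w0;
      // Rodrigues rotation
      los = std::cos(ang) * los + std::sin(ang) * cross(axis, los);
      los = unit(los);
    }
    return los;
  }

  // Line-of-sight rate from the two most recent guidance samples,
  // spaced `every` integration steps apart, passed through a
  // fading-memory filter (gain 0.5) that halves the differentiation
  // noise at the cost of one extra guidance interval of lag.
  Vec3 command(Vec3 los, Vec3 vel, double dt) {
    Vec3 a = v3(0, 0, 0);
    const double beta = 0.5;
    if (have_prev) {
      Vec3 omega = (1.0 / (dt * every)) * cross(prev_los, los);
      omega_f = (1.0 - beta) * omega_f + beta * omega;
      a = N * cross(omega_f, vel);
      a = perp_to(a, unit(vel));
    }
    prev_los = los;
    have_prev = true;
    return a;
  }
};

// ----------------------------------------------------------- engagement
struct EngCfg {
  double dz, dx, dt, r_int, r_near, blind_cos, head_start, timeout;
  double v0_falcon, v0_prey;
  double N, delay, sigma_v, guidance_dt;
  double c1, c2, c3, c4;
};

static EngCfg cfg_from_list(const List &l) {
  EngCfg c;
  c.dz = as<double>(l["dz"]);
  c.dx = as<double>(l["dx"]);
  c.dt = as<double>(l["dt"]);
  c.r_int = as<double>(l["r_intercept"]);
  c.r_near = as<double>(l["r_nearmiss"]);
  c.blind_cos = std::cos(as<double>(l["blind_halfangle"]));
  c.head_start = as<double>(l["head_start"]);
  c.timeout = as<double>(l["timeout"]);
  c.v0_falcon = as<double>(l["v0_falcon"]);
  c.v0_prey = as<double>(l["v0_prey"]);
  c.N = as<double>(l["N"]);
  c.delay = as<double>(l["delay"]);
  c.sigma_v = as<double>(l["sigma_v"]);
  c.guidance_dt = as<double>(l["guidance_dt"]);
  c.c1 = as<double>(l["c1"]);
  c.c2 = as<double>(l["c2"]);
  c.c3 = as<double>(l["c3"]);
  c.c4 = as<double>(l["c4"]);
  return c;
}

// one engagement; falcon and prey may each be full-physics or capped.
// Writes 14 numbers into out:
// category, t_end, min_distance,
// falcon speed/lf/rollacc/radius at end,
// prey speed/lf/rollacc/radius at end,
// prey mean load factor, prey mean speed, n_steps
static void run_one(const Morph *fm, const CappedBird *fc0, const Morph *pm,
                    const CappedBird *pc0, const AeroPars &p, const EngCfg &c,
                    uint64_t master, uint64_t index, double *out) {
  Pcg32 rng = stream_rng(master, index);

  bool falcon_full = fm != nullptr;
  bool prey_full = pm != nullptr;

  FullBird F, P;
  CappedBird Fc, Pc;

  // --- prey initial state: origin, level, random azimuth
  double az = rng.runif(0.0, 2.0 * M_PI);
  Vec3 pv = v3(std::cos(az), std::sin(az), 0.0);
  if (prey_full) {
    P.m = *pm; P.p = p;
    P.pos = v3(0, 0, 0);
    P.vel = c.v0_prey * pv;
    P.roll = 0; P.roll_rate = 0; P.zeta = 0; P.flap = true;
    P.lf = 1; P.rollacc = 0; P.radius = R_PosInf;
  } else {
    Pc = *pc0;
    Pc.pos = v3(0, 0, 0);
    Pc.vel = Pc.speed * pv;
    Pc.psi = 0; Pc.psi_rate = 0;
    Pc.lf = 0; Pc.rollacc = Pc.rollacc_max; Pc.radius = R_PosInf;
  }

  Erratic er;
  er.c1 = c.c1; er.c2 = c.c2; er.c3 = c.c3; er.c4 = c.c4;
  er.init(rng);

  // --- prey head start (flies alone, erratic guidance active)
  int hs_steps = (int)std::lround(c.head_start / c.dt);
  double t = 0.0;
  for (int k = 0; k < hs_steps; ++k) {
    if (prey_full) {
      double v = norm3(P.vel);
      double amax = max_lift_(P.m, v, 0.0, true, p) / P.m.mb;
      Vec3 a = er.command(t, P.vel, amax, true, p.g, rng);
      step_full(P, a, c.dt);
    } else {
      Vec3 a = er.command(t, Pc.vel, Pc.n_max * 9.81, false, p.g, rng);
      step_capped(Pc, a, c.dt);
    }
    t += c.dt;
  }

  // --- falcon initial state: offset position, heading at the prey
  Vec3 ppos = prey_full ? P.pos : Pc.pos;
  Vec3 fpos = v3(c.dx, 0.0, c.dz);
  Vec3 fdir = unit(ppos - fpos);
  if (falcon_full) {
    F.m = *fm; F.p = p;
    F.pos = fpos;
    F.vel = c.v0_falcon * fdir;
    F.roll = 0; F.roll_rate = 0; F.zeta = 0; F.flap = true;
    F.lf = 1; F.rollacc = 0; F.radius = R_PosInf;
  } else {
    Fc = *fc0;
    Fc.pos = fpos;
    Fc.vel = Fc.speed * fdir;
    Fc.psi = 0; Fc.psi_rate = 0;
    Fc.lf = 0; Fc.rollacc = Fc.rollacc_max; Fc.radius = R_PosInf;
  }

  Ppn ppn;
  ppn.N = c.N;
  ppn.sigma_v = c.sigma_v;
  ppn.delay_steps = (int)std::lround(c.delay / c.dt);
  ppn.every = std::max(1, (int)std::lround(c.guidance_dt / c.dt));
  ppn.have_prev = false;
  ppn.held_cmd = v3(0, 0, 0);
  ppn.omega_f = v3(0, 0, 0);

  int max_steps = (int)std::lround(c.timeout / c.dt);
  std::vector<Vec3> fhist, phist;
  fhist.reserve(max_steps + 1);
  phist.reserve(max_steps + 1);

  double min_d = R_PosInf;
  bool armed = false;
  int category = 2; // timeout unless decided otherwise
  double sum_plf = 0.0, sum_pspeed = 0.0;
  int nrec = 0;
  double tc = 0.0;

  for (int k = 0; k < max_steps; ++k) {
    Vec3 fp = falcon_full ? F.pos : Fc.pos;
    Vec3 pp = prey_full ? P.pos : Pc.pos;
    Vec3 fv = falcon_full ? F.vel : Fc.vel;
    fhist.push_back(fp);
    phist.push_back(pp);

    Vec3 rel = pp - fp;
    double d = norm3(rel);
    if (d < min_d) min_d = d;
    if (d < c.r_int) { category = 0; break; }
    if (armed) {
      double cosb = dot(unit(rel), -1.0 * unit(fv));
      if (cosb > c.blind_cos) { category = 1; break; }
    }
    if (d < c.r_near) armed = true;
    Vec3 rel_prev = rel;

    // falcon: sense -> PPN (at the guidance update rate) -> step
    if (k % ppn.every == 0) {
      Vec3 los = ppn.sense(fhist, phist, k, rng);
      ppn.held_cmd = ppn.command(los, fv, c.dt);
    }
    if (falcon_full) step_full(F, ppn.held_cmd, c.dt);
    else step_capped(Fc, ppn.held_cmd, c.dt);

    // prey: erratic -> step
    if (prey_full) {
      double v = norm3(P.vel);
      double amax = max_lift_(P.m, v, 0.0, true, p) / P.m.mb;
      Vec3 a = er.command(t, P.vel, amax, true, p.g, rng);
      step_full(P, a, c.dt);
      sum_plf += P.lf;
      sum_pspeed += norm3(P.vel);
    } else {
      Vec3 a = er.command(t, Pc.vel, Pc.n_max * 9.81, false, p.g, rng);
      step_capped(Pc, a, c.dt);
      sum_plf += Pc.lf;
      sum_pspeed += Pc.speed;
    }
    ++nrec;
    t += c.dt;
    tc += c.dt;

    // continuous collision check: at stoop speeds the falcon covers
    // ~0.5 m per step, so the 0.2 m intercept sphere must be tested
    // against the whole step segment, not just its endpoints
    {
      Vec3 fp2 = falcon_full ? F.pos : Fc.pos;
      Vec3 pp2 = prey_full ? P.pos : Pc.pos;
      double dseg = seg_min_dist(rel_prev, pp2 - fp2);
      if (dseg < min_d) min_d = dseg;
      if (dseg < c.r_int) { category = 0; break; }
      if (dseg < c.r_near) armed = true;
    }

    if (falcon_full && (!std::isfinite(F.pos.x) || !std::isfinite(norm3(F.vel)))) {
      category = 3; // non-finite dynamics
      break;
    }
  }

  out[0] = category;
  out[1] = tc;
  out[2] = min_d;
  if (falcon_full) {
    out[3] = norm3(F.vel); out[4] = F.lf; out[5] = F.rollacc; out[6] = F.radius;
  } else {
    out[3] = Fc.speed; out[4] = Fc.lf; out[5] = Fc.rollacc; out[6] = Fc.radius;
  }
  if (prey_full) {
    out[7] = norm3(P.vel); out[8] = P.lf; out[9] = P.rollacc; out[10] = P.radius;
  } else {
    out[7] = Pc.speed; out[8] = Pc.lf; out[9] = Pc.rollacc; out[10] = Pc.radius;
  }
  out[11] = nrec > 0 ? sum_plf / nrec : NA_REAL;
  out[12] = nrec > 0 ? sum_pspeed / nrec : NA_REAL;
  out[13] = nrec;
}

static CappedBird capped_from_list(const List &l) {
  CappedBird b;
  b.speed = as<double>(l["speed"]);
  b.n_max = as<double>(l["n_max"]);
  b.rollacc_max = as<double>(l["rollacc_max"]);
  b.pos = v3(0, 0, 0);
  b.vel = v3(b.speed, 0, 0);
  b.psi = 0; b.psi_rate = 0; b.lf = 0; b.rollacc = 0; b.radius = R_PosInf;
  return b;
}

static const char *outcome_names[14] = {
    "category", "t_end", "min_distance", "falcon_speed", "falcon_lf",
    "falcon_rollacc", "falcon_radius", "prey_speed", "prey_lf",
    "prey_rollacc", "prey_radius", "prey_mean_lf", "prey_mean_speed",
    "n_steps"};

// [[Rcpp::export(name = ".cpp_run_engagements")]]
NumericMatrix cpp_run_engagements(List falcon, List prey, List aero, List cfg,
                                  int n, double master_seed,
                                  double start_index) {
  AeroPars p = aero_from_list(aero);
  EngCfg c = cfg_from_list(cfg);

  bool falcon_full = as<std::string>(falcon["type"]) == "full";
  bool prey_full = as<std::string>(prey["type"]) == "full";
  Morph fm, pm;
  CappedBird fc, pc;
  if (falcon_full) fm = morph_from_list_full(falcon["morph"], p);
  else fc = capped_from_list(falcon);
  if (prey_full) pm = morph_from_list_full(prey["morph"], p);
  else pc = capped_from_list(prey);

  NumericMatrix out(n, 14);
  double buf[14];
  for (int i = 0; i < n; ++i) {
    run_one(falcon_full ? &fm : nullptr, falcon_full ? nullptr : &fc,
            prey_full ? &pm : nullptr, prey_full ? nullptr : &pc, p, c,
            (uint64_t)master_seed, (uint64_t)(start_index + i), buf);
    for (int j = 0; j < 14; ++j) out(i, j) = buf[j];
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  colnames(out) = CharacterVector(outcome_names, outcome_names + 14);
  return out;
}

// Mean realised centripetal acceleration and mean climb rate of a prey
// flying alone under erratic guidance (the fitness used when evolving the
// evasion parameters; the climb rate enters as a sustainability
// constraint).  Returns an n x 2 matrix (accel, dz/dt).
// [[Rcpp::export(name = ".cpp_prey_solo_accel")]]
NumericMatrix cpp_prey_solo_accel(List prey, List aero, List cfg, int n,
                                  double duration, double master_seed) {
  AeroPars p = aero_from_list(aero);
  EngCfg c = cfg_from_list(cfg);
  bool prey_full = as<std::string>(prey["type"]) == "full";
  Morph pm;
  CappedBird pc;
  if (prey_full) pm = morph_from_list_full(prey["morph"], p);
  else pc = capped_from_list(prey);

  NumericMatrix out(n, 2);
  int steps = (int)std::lround(duration / c.dt);
  for (int i = 0; i < n; ++i) {
    Pcg32 rng = stream_rng((uint64_t)master_seed, (uint64_t)i);
    double az = rng.runif(0.0, 2.0 * M_PI);
    Vec3 pv = v3(std::cos(az), std::sin(az), 0.0);
    FullBird P;
    CappedBird Pc;
    if (prey_full) {
      P.m = pm; P.p = p;
      P.pos = v3(0, 0, 0); P.vel = c.v0_prey * pv;
      P.roll = 0; P.roll_rate = 0; P.zeta = 0; P.flap = true;
    } else {
      Pc = pc; Pc.pos = v3(0, 0, 0); Pc.vel = Pc.speed * pv;
      Pc.psi = 0; Pc.psi_rate = 0;
    }
    Erratic er;
    er.c1 = c.c1; er.c2 = c.c2; er.c3 = c.c3; er.c4 = c.c4;
    er.init(rng);
    double t = 0.0, acc = 0.0;
    double z0 = 0.0;
    for (int k = 0; k < steps; ++k) {
      if (prey_full) {
        Vec3 vold = P.vel;
        double v = norm3(P.vel);
        double amax = max_lift_(P.m, v, 0.0, true, p) / P.m.mb;
        Vec3 a = er.command(t, P.vel, amax, true, p.g, rng);
        step_full(P, a, c.dt);
        Vec3 dv = (1.0 / c.dt) * (P.vel - vold);
        acc += norm3(perp_to(dv, unit(vold)));
      } else {
        Vec3 vold = Pc.vel;
        Vec3 a = er.command(t, Pc.vel, Pc.n_max * 9.81, false, p.g, rng);
        step_capped(Pc, a, c.dt);
        Vec3 dv = (1.0 / c.dt) * (Pc.vel - vold);
        acc += norm3(perp_to(dv, unit(vold)));
      }
      t += c.dt;
    }
    out(i, 0) = acc / steps;
    double z1 = prey_full ? P.pos.z : Pc.pos.z;
    out(i, 1) = (z1 - z0) / duration;
  }
  return out;
}

// single-step exports used by the dynamics-level unit tests -----------

// [[Rcpp::export(name = ".cpp_step_full")]]
List cpp_step_full(List morph, List aero, List state, NumericVector acmd,
                   double dt, int nsteps) {
  FullBird b;
  b.p = aero_from_list(aero);
  b.m = morph_from_list_full(morph, b.p);
  NumericVector pos = state["pos"], vel = state["vel"];
  b.pos = v3(pos[0], pos[1], pos[2]);
  b.vel = v3(vel[0], vel[1], vel[2]);
  b.roll = as<double>(state["roll"]);
  b.roll_rate = as<double>(state["roll_rate"]);
  b.zeta = as<double>(state["retraction"]);
  b.flap = as<std::string>(state["mode"]) == "flap";
  b.lf = 0; b.rollacc = 0; b.radius = R_PosInf;
  Vec3 a = v3(acmd[0], acmd[1], acmd[2]);
  for (int i = 0; i < nsteps; ++i) step_full(b, a, dt);
  return List::create(
      _["pos"] = NumericVector::create(b.pos.x, b.pos.y, b.pos.z),
      _["vel"] = NumericVector::create(b.vel.x, b.vel.y, b.vel.z),
      _["roll"] = b.roll, _["roll_rate"] = b.roll_rate,
      _["retraction"] = b.zeta,
      _["mode"] = b.flap ? "flap" : "glide", _["lf"] = b.lf,
      _["rollacc"] = b.rollacc, _["radius"] = b.radius);
}

// [[Rcpp::export(name = ".cpp_step_capped")]]
List cpp_step_capped(List agent, List state, NumericVector acmd, double dt,
                     int nsteps) {
  CappedBird b = capped_from_list(agent);
  NumericVector pos = state["pos"], vel = state["vel"];
  b.pos = v3(pos[0], pos[1], pos[2]);
  b.vel = v3(vel[0], vel[1], vel[2]);
  b.psi = as<double>(state["psi"]);
  b.psi_rate = as<double>(state["psi_rate"]);
  Vec3 a = v3(acmd[0], acmd[1], acmd[2]);
  for (int i = 0; i < nsteps; ++i) step_capped(b, a, dt);
  return List::create(
      _["pos"] = NumericVector::create(b.pos.x, b.pos.y, b.pos.z),
      _["vel"] = NumericVector::create(b.vel.x, b.vel.y, b.vel.z),
      _["psi"] = b.psi, _["psi_rate"] = b.psi_rate, _["lf"] = b.lf);
}
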