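#include <Rcpp.h>
#include "aero.h"

using namespace Rcpp;

Morph morph_from_list(const List &m) {
  Morph mo;
  mo.f = as<double>(m["f"]);
  mo.b = as<double>(m["b"]);
  mo.mb = as<double>(m["m_b"]);
  mo.mw = as<double>(m["m_w"]);
  mo.Sw = as<double>(m["S_w"]);
  mo.AR = as<double>(m["AR"]);
  mo.Cdb = as<double>(m["C_db"]);
  return mo;
}

Morph morph_from_list_full(const List &m, const AeroPars &p) {
  Morph mo = morph_from_list(m);
  init_derived(mo, p);
  return mo;
}

AeroPars aero_from_list(const List &a) {
  AeroPars p = default_aero();
  if (a.containsElementNamed("rho")) p.rho = as<double>(a["rho"]);
  if (a.containsElementNamed("g")) p.g = as<double>(a["g"]);
  if (a.containsElementNamed("CL_max")) p.CL_max = as<double>(a["CL_max"]);
  if (a.containsElementNamed("Cd_pro0")) p.Cd_pro0 = as<double>(a["Cd_pro0"]);
  if (a.containsElementNamed("k_ind")) p.k_ind = as<double>(a["k_ind"]);
  if (a.containsElementNamed("stroke_amplitude")) p.amp = as<double>(a["stroke_amplitude"]);
  if (a.containsElementNamed("c_q")) p.c_q = as<double>(a["c_q"]);
  if (a.containsElementNamed("Cd_pro2")) p.Cd_pro2 = as<double>(a["Cd_pro2"]);
  if (a.containsElementNamed("k_G")) p.k_G = as<double>(a["k_G"]);
  if (a.containsElementNamed("a_u")) p.a_u = as<double>(a["a_u"]);
  if (a.containsElementNamed("a_G")) p.a_G = as<double>(a["a_G"]);
  if (a.containsElementNamed("a_fG")) p.a_fG = as<double>(a["a_fG"]);
  if (a.containsElementNamed("k_musc")) p.k_musc = as<double>(a["k_musc"]);
  if (a.containsElementNamed("a_mw")) p.a_mw = as<double>(a["a_mw"]);
  if (a.containsElementNamed("tau_frac")) p.tau_frac = as<double>(a["tau_frac"]);
  if (a.containsElementNamed("k_roll")) p.k_roll = as<double>(a["k_roll"]);
  if (a.containsElementNamed("a_rm")) p.a_rm = as<double>(a["a_rm"]);
  if (a.containsElementNamed("k_Sb")) p.k_Sb = as<double>(a["k_Sb"]);
  if (a.containsElementNamed("k_wb")) p.k_wb = as<double>(a["k_wb"]);
  if (a.containsElementNamed("rho_ret")) p.rho_ret = as<double>(a["rho_ret"]);
  if (a.containsElementNamed("n_elements")) p.n_elem = as<double>(a["n_elements"]);
  return p;
}

// [[Rcpp::export(name = ".cpp_max_lift")]]
NumericVector cpp_max_lift(List morph, NumericVector v, double retraction,
                           bool flap, List aero) {
  AeroPars p = aero_from_list(aero);
  Morph m = morph_from_list(morph);
  init_derived(m, p);
  NumericVector out(v.size());
  for (int i = 0; i < v.size(); ++i)
    out[i] = max_lift_(m, v[i], retraction, flap, p);
  return out;
}

// [[Rcpp::export(name = ".cpp_min_drag")]]
NumericVector cpp_min_drag(List morph, NumericVector v, NumericVector L,
                           double retraction, List aero) {
  AeroPars p = aero_from_list(aero);
  Morph m = morph_from_list(morph);
  init_derived(m, p);
  NumericVector out(v.size());
  for (int i = 0; i < v.size(); ++i)
    out[i] = min_drag_(m, v[i], L[i], retraction, p);
  return out;
}

// [[Rcpp::export(name = ".cpp_max_thrust")]]
NumericVector cpp_max_thrust(List morph, NumericVector v, NumericVector L,
                             List aero) {
  AeroPars p = aero_from_list(aero);
  Morph m = morph_from_list(morph);
  init_derived(m, p);
  NumericVector out(v.size());
  for (int i = 0; i < v.size(); ++i)
    out[i] = max_thrust_net(m, v[i], L[i], p);
  return out;
}

// [[Rcpp::export(name = ".cpp_level_accel")]]
NumericVector cpp_level_accel(List morph, NumericVector v, List aero) {
  AeroPars p = aero_from_list(aero);
  Morph m = morph_from_list(morph);
  init_derived(m, p);
  NumericVector out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = level_accel(m, v[i], p);
  return out;
}

// [[Rcpp::export(name = ".cpp_dive_accel")]]
NumericVector cpp_dive_accel(List morph, NumericVector v, List aero) {
  AeroPars p = aero_from_list(aero);
  Morph m = morph_from_list(morph);
  init_derived(m, p);
  NumericVector out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = dive_accel(m, v[i], p);
  return out;
}

// [[Rcpp::export(name = ".cpp_speeds")]]
List cpp_speeds(List morph, List aero) {
  AeroPars p = aero_from_list(aero);
  Morph m = morph_from_list(morph);
  init_derived(m, p);
  return List::create(_["v_top_level"] = v_top_level(m, p),
                      _["v_terminal"] = v_terminal_(m, p),
                      _["v_range"] = v_max_range(m, p));
}

// [[Rcpp::export(name = ".cpp_roll_accel")]]
NumericVector cpp_roll_accel(List morph, NumericVector v, double retraction,
                             List aero) {
  AeroPars p = aero_from_list(aero);
  Morph m = morph_from_list(morph);
  init_derived(m, p);
  NumericVector out(v.size());
  for (int i = 0; i < v.size(); ++i)
    out[i] = max_roll_accel_(m, v[i], retraction, p);
  return out;
}

// [[Rcpp::export(name = ".cpp_roll_inertia")]]
double cpp_roll_inertia(List morph, double retraction, List aero) {
  AeroPars p = aero_from_list(aero);
  Morph m = morph_from_list_full(morph, p);
  return roll_inertia_(m, retraction, p);
}

// [[Rcpp::export(name = ".cpp_max_carry")]]
List cpp_max_carry(List morph, double prey_Cdb, List aero) {
  AeroPars p = aero_from_list(aero);
  Morph m = morph_from_list(morph);
  init_derived(m, p);
  double mm = max_carry_mass(m, prey_Cdb, p);
  return List::create(_["can_carry"] = mm > 0.0, _["max_mass"] = mm);
}
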