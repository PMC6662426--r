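// Daily carbon-cycle engine for a deciduous broadleaf (or annual grass)
// stand: Farquhar photosynthesis coupled to stomatal conductance through
// the supply equation A = g (Ca - Ci), allocation by fixed ratios,
// temperature-threshold phenology, turnover/mortality/fire, a
// labile/cellulose/lignin litter cascade and a bucket water balance.
// The daily step is pure: state' = f(state, met, params, site).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---- state vector layout (kg-C/m2, kg-N/m2, kg-H2O/m2) ----
enum {
  S_LEAFC = 0, S_FROOTC, S_LIVESTEMC, S_DEADSTEMC, S_LIVECROOTC, S_DEADCROOTC,
  S_STORAGEC, S_TRANSFERC, S_LITR_LAB, S_LITR_CEL, S_LITR_LIG, S_CWDC,
  S_SOILC, S_LITRN, S_CWDN, S_SOILN, S_SMINN, S_SOILW, S_CUMFIRE, S_CUMHARV,
  S_N
};

// ---- met row layout ----
enum {
  M_TMAX = 0, M_TMIN, M_TDAY, M_TAVG, M_TSOIL, M_PRCP_CM, M_VPD, M_SRAD,
  M_DAYLEN, M_CO2, M_PHASE, M_DAYSLEFT, M_ONSET,
  M_N
};

// phenophase codes
enum { PH_DORMANT = 0, PH_TRANSFER = 1, PH_GROWTH = 2, PH_SENESCENCE = 3 };

struct Par {
  double frc_lc, sc_lc, crc_sc, live_wood_frac, current_growth_prop;
  double sla, sla_shade_ratio, flnr, gsmax, g_cuticular, g_boundary;
  double lwp_start, lwp_final, vpd_start, vpd_final;
  double cn_leaf, cn_litter, cn_froot, cn_livewood, cn_deadwood;
  double leaf_froot_turnover, livewood_turnover, mortality, fire_mortality;
  double transfer_frac, litterfall_frac;
  double litter_labile, litter_cellulose, litter_lignin;
  double froot_labile, froot_cellulose, froot_lignin;
  double deadwood_cellulose, deadwood_lignin;
  double canopy_intercept, k_ext, lai_allsided_ratio;
  double growth_resp_frac;
  // physiological / decomposition constants (documented defaults)
  double act25, q10_act, rd_frac, jmax_ratio, alpha_j, par_frac, ppfd_per_j;
  double ppfd_half, tmin_lo, tmin_hi;
  double mr_per_n, q10_mr, q10_hr;
  double k_lab, k_cel, k_lig, k_cwd, k_soil;
  double rf_lab, rf_cel, rf_lig;
  double cn_soil, soil_evap_max, sminn_loss_rate;
  bool woody;
  double harvest_frac, fertilization;
};

struct SiteP {
  double elevation, latitude, albedo, soil_depth;
  double first_year_max_leafC, first_year_max_stemC;
  double n_deposition, n_fixation;
  double sand, silt, clay;
  // derived
  double pressure, vwc_sat, psi_sat, b_ch, capacity;
};

struct Flux {
  double gpp, mr, gr, hr, fire, harvest, litterfall;
  double transp, soil_evap, interception, drainage, nloss;
  double psi, lai;
};

static double getd(const List& L, const char* n) {
  if (!L.containsElementNamed(n)) stop(std::string("missing parameter: ") + n);
  return as<double>(L[n]);
}

static Par parse_par(const List& L) {
  Par p;
  p.frc_lc = getd(L, "frc_lc"); p.sc_lc = getd(L, "sc_lc");
  p.crc_sc = getd(L, "crc_sc"); p.live_wood_frac = getd(L, "live_wood_frac");
  p.current_growth_prop = getd(L, "current_growth_prop");
  p.sla = getd(L, "sla"); p.sla_shade_ratio = getd(L, "sla_shade_ratio");
  p.flnr = getd(L, "flnr"); p.gsmax = getd(L, "gsmax");
  p.g_cuticular = getd(L, "g_cuticular"); p.g_boundary = getd(L, "g_boundary");
  p.lwp_start = getd(L, "lwp_start"); p.lwp_final = getd(L, "lwp_final");
  p.vpd_start = getd(L, "vpd_start"); p.vpd_final = getd(L, "vpd_final");
  p.cn_leaf = getd(L, "cn_leaf"); p.cn_litter = getd(L, "cn_litter");
  p.cn_froot = getd(L, "cn_froot"); p.cn_livewood = getd(L, "cn_livewood");
  p.cn_deadwood = getd(L, "cn_deadwood");
  p.leaf_froot_turnover = getd(L, "leaf_froot_turnover");
  p.livewood_turnover = getd(L, "livewood_turnover");
  p.mortality = getd(L, "mortality"); p.fire_mortality = getd(L, "fire_mortality");
  p.transfer_frac = getd(L, "transfer_frac");
  p.litterfall_frac = getd(L, "litterfall_frac");
  p.litter_labile = getd(L, "litter_labile");
  p.litter_cellulose = getd(L, "litter_cellulose");
  p.litter_lignin = getd(L, "litter_lignin");
  p.froot_labile = getd(L, "froot_labile");
  p.froot_cellulose = getd(L, "froot_cellulose");
  p.froot_lignin = getd(L, "froot_lignin");
  p.deadwood_cellulose = getd(L, "deadwood_cellulose");
  p.deadwood_lignin = getd(L, "deadwood_lignin");
  p.canopy_intercept = getd(L, "canopy_intercept");
  p.k_ext = getd(L, "k_ext");
  p.lai_allsided_ratio = getd(L, "lai_allsided_ratio");
  p.growth_resp_frac = getd(L, "growth_resp_frac");
  p.act25 = getd(L, "act25"); p.q10_act = getd(L, "q10_act");
  p.rd_frac = getd(L, "rd_frac"); p.jmax_ratio = getd(L, "jmax_ratio");
  p.alpha_j = getd(L, "alpha_j"); p.par_frac = getd(L, "par_frac");
  p.ppfd_per_j = getd(L, "ppfd_per_j");
  p.ppfd_half = getd(L, "ppfd_half");
  p.tmin_lo = getd(L, "tmin_lo"); p.tmin_hi = getd(L, "tmin_hi");
  p.mr_per_n = getd(L, "mr_per_n"); p.q10_mr = getd(L, "q10_mr");
  p.q10_hr = getd(L, "q10_hr");
  p.k_lab = getd(L, "k_lab"); p.k_cel = getd(L, "k_cel");
  p.k_lig = getd(L, "k_lig"); p.k_cwd = getd(L, "k_cwd");
  p.k_soil = getd(L, "k_soil");
  p.rf_lab = getd(L, "rf_lab"); p.rf_cel = getd(L, "rf_cel");
  p.rf_lig = getd(L, "rf_lig");
  p.cn_soil = getd(L, "cn_soil");
  p.soil_evap_max = getd(L, "soil_evap_max");
  p.sminn_loss_rate = getd(L, "sminn_loss_rate");
  p.woody = as<bool>(L["woody"]);
  p.harvest_frac = getd(L, "harvest_frac");
  p.fertilization = getd(L, "fertilization");
  return p;
}

static SiteP parse_site(const List& L) {
  SiteP s;
  s.elevation = getd(L, "elevation"); s.latitude = getd(L, "latitude");
  s.albedo = getd(L, "albedo"); s.soil_depth = getd(L, "soil_depth");
  s.first_year_max_leafC = getd(L, "first_year_max_leafC");
  s.first_year_max_stemC = getd(L, "first_year_max_stemC");
  s.n_deposition = getd(L, "n_deposition"); s.n_fixation = getd(L, "n_fixation");
  s.sand = getd(L, "sand"); s.silt = getd(L, "silt"); s.clay = getd(L, "clay");
  // barometric pressure from elevation (standard atmosphere)
  s.pressure = 101325.0 * std::pow(1.0 - 2.2569e-5 * s.elevation, 5.2553);
  // Clapp-Hornberger/Cosby texture relations
  s.vwc_sat = 0.489 - 0.00126 * s.sand;
  s.psi_sat = -(std::exp((1.54 - 0.0095 * s.sand + 0.0063 * s.silt) *
                         std::log(10.0)) * 9.8e-5);       // MPa
  s.b_ch = 2.91 + 0.159 * s.clay;
  s.capacity = s.soil_depth * s.vwc_sat * 1000.0;          // kg H2O / m2
  return s;
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// saturation vapour pressure is only needed on the R side (climate module);
// the engine receives VPD ready-made.

// Farquhar limitation rates at a given Ci
static inline void farquhar_rates(double vcmax, double J, double ci,
                                  double gamma, double kc, double ko,
                                  double o2, double rd,
                                  double& ac, double& aj) {
  ac = vcmax * (ci - gamma) / (ci + kc * (1.0 + o2 / ko)) - rd;
  aj = J * (ci - gamma) / (4.5 * ci + 10.5 * gamma) - rd;
}

// [[Rcpp::export(name = ".farquhar_cpp")]]
NumericVector farquhar_cpp(double vcmax, double j, double ci, double gamma,
                           double kc, double ko, double o2, double rd) {
  double ac, aj;
  farquhar_rates(vcmax, j, ci, gamma, kc, ko, o2, rd, ac, aj);
  double a = ac < aj ? ac : aj;
  return NumericVector::create(_["A"] = a, _["Ac"] = ac, _["Aj"] = aj);
}

// stable positive root of a x^2 + b x + c = 0 with a > 0 and c < 0
static inline double pos_root(double a, double b, double c) {
  double disc = b * b - 4.0 * a * c;
  if (disc < 0.0) disc = 0.0;
  double sq = std::sqrt(disc);
  double q = -0.5 * (b + (b >= 0.0 ? sq : -sq));
  double r1 = q / a;
  double r2 = (q != 0.0) ? c / q : 0.0;
  return r1 > r2 ? r1 : r2;
}

// Solve the coupled supply/demand system: A = g (Ca - Ci) intersected with
// each Farquhar limitation; final A is the minimum of the two branch
// solutions (the active branch has the larger Ci).
// g in umol m-2 s-1 Pa-1, pressures in Pa, rates in umol m-2 s-1.
// [[Rcpp::export(name = ".solve_ci_cpp")]]
NumericVector solve_ci_cpp(double g, double ca, double vcmax, double j,
                           double gamma, double kc, double ko, double o2,
                           double rd) {
  double K = kc * (1.0 + o2 / ko);
  if (g <= 0.0 || vcmax <= 0.0) {
    // zero supply: A = 0; Ci floats to where demand is zero
    double ci_c = (vcmax > rd) ? (vcmax * gamma + rd * K) / (vcmax - rd) : ca;
    double ci_j = (j > 4.5 * rd) ? (j * gamma + 10.5 * rd * gamma) / (j - 4.5 * rd)
                                 : ca;
    double ci = ci_c > ci_j ? ci_c : ci_j;
    if (ci > ca || !std::isfinite(ci)) ci = ca;
    return NumericVector::create(_["ci"] = ci, _["A"] = 0.0);
  }
  // carboxylation branch: g ci^2 + (gK + vcmax - rd - g ca) ci
  //                        - (g ca K + vcmax gamma + rd K) = 0
  double ci_c = pos_root(g, g * K + vcmax - rd - g * ca,
                         -(g * ca * K + vcmax * gamma + rd * K));
  double a_c = g * (ca - ci_c);
  // RuBP-regeneration branch: 4.5 g ci^2 +
  //   (10.5 gamma g + j - 4.5 rd - 4.5 g ca) ci -
  //   (10.5 gamma g ca + j gamma + 10.5 rd gamma) = 0
  double ci_j = pos_root(4.5 * g, 10.5 * gamma * g + j - 4.5 * rd - 4.5 * g * ca,
                         -(10.5 * gamma * g * ca + j * gamma +
                           10.5 * rd * gamma));
  double a_j = g * (ca - ci_j);
  double ci, a;
  if (a_c <= a_j) { a = a_c; ci = ci_c; } else { a = a_j; ci = ci_j; }
  return NumericVector::create(_["ci"] = ci, _["A"] = a);
}

// [[Rcpp::export(name = ".stomatal_mult_cpp")]]
NumericVector stomatal_mult_cpp(double ppfd, double psi, double tmin,
                                double vpd, double ppfd_half,
                                double lwp_start, double lwp_final,
                                double tmin_lo, double tmin_hi,
                                double vpd_start, double vpd_final) {
  double m_ppfd = clamp01(ppfd / (ppfd + ppfd_half));
  double m_psi = clamp01((psi - lwp_final) / (lwp_start - lwp_final));
  double m_tmin = clamp01((tmin - tmin_lo) / (tmin_hi - tmin_lo));
  double m_vpd = clamp01((vpd_final - vpd) / (vpd_final - vpd_start));
  return NumericVector::create(_["m_ppfd"] = m_ppfd, _["m_psi"] = m_psi,
                               _["m_tmin"] = m_tmin, _["m_vpd"] = m_vpd);
}

static double soil_psi(const SiteP& site, double soil_water) {
  double vwc = soil_water / (site.soil_depth * 1000.0);
  if (vwc <= 1e-6) return -10.0;
  double rel = vwc / site.vwc_sat;
  if (rel > 1.0) rel = 1.0;
  double psi = site.psi_sat * std::pow(rel, -site.b_ch);
  if (psi < -10.0) psi = -10.0;
  return psi;
}

// one model day; st is modified in place
static void step_core(double* st, const double* met, const Par& p,
                      const SiteP& site, Flux& fx) {
  const double tavg = met[M_TAVG], tday = met[M_TDAY], tmin = met[M_TMIN];
  const double tsoil = met[M_TSOIL], vpd = met[M_VPD], srad = met[M_SRAD];
  const double daylen = met[M_DAYLEN], co2 = met[M_CO2];
  const int phase = (int)met[M_PHASE];
  const double days_left = met[M_DAYSLEFT];
  const bool onset = met[M_ONSET] > 0.5;

  fx = Flux();
  const double tk = tday + 273.15;
  const double psi = soil_psi(site, st[S_SOILW]);
  fx.psi = psi;

  // mineral N inputs
  st[S_SMINN] += (site.n_deposition + site.n_fixation + p.fertilization) / 365.0;

  // season onset: storage becomes the transfer pool
  if (onset) { st[S_TRANSFERC] += st[S_STORAGEC]; st[S_STORAGEC] = 0.0; }

  // ---- transfer growth (stored C -> new tissue over early season) -----
  // built with the same organ ratios as current growth, so stored and
  // current assimilate express the same allometry
  double gr = 0.0;
  if (phase == PH_TRANSFER && st[S_TRANSFERC] > 0.0 && days_left >= 1.0) {
    double t_amt = st[S_TRANSFERC] / days_left;
    double denom = p.woody ? (1.0 + p.frc_lc + p.sc_lc * (1.0 + p.crc_sc))
                           : (1.0 + p.frc_lc);
    double tissue = t_amt / (1.0 + p.growth_resp_frac);
    double leaf_t = tissue / denom;
    double froot_t = p.frc_lc * leaf_t;
    double stem_t = p.woody ? p.sc_lc * leaf_t : 0.0;
    double croot_t = p.woody ? p.crc_sc * stem_t : 0.0;
    double wood_ncoef = p.live_wood_frac / p.cn_livewood +
                        (1.0 - p.live_wood_frac) / p.cn_deadwood;
    double ndem = leaf_t / p.cn_leaf + froot_t / p.cn_froot +
                  (stem_t + croot_t) * wood_ncoef;
    double rho = (ndem > 0.0 && ndem > st[S_SMINN]) ? st[S_SMINN] / ndem : 1.0;
    st[S_LEAFC] += leaf_t * rho;
    st[S_FROOTC] += froot_t * rho;
    st[S_LIVESTEMC] += p.live_wood_frac * stem_t * rho;
    st[S_DEADSTEMC] += (1.0 - p.live_wood_frac) * stem_t * rho;
    st[S_LIVECROOTC] += p.live_wood_frac * croot_t * rho;
    st[S_DEADCROOTC] += (1.0 - p.live_wood_frac) * croot_t * rho;
    st[S_TRANSFERC] -= t_amt * rho;
    st[S_SMINN] -= ndem * rho;
    gr += (t_amt - tissue) * rho;
  }

  // ---- canopy photosynthesis -----------------------------------------
  double gpp = 0.0, transp_dem = 0.0;
  double lai = st[S_LEAFC] > 0.0 ? st[S_LEAFC] * p.sla : 0.0;
  fx.lai = lai;
  if (lai > 0.0 && srad > 0.0 && daylen > 0.0) {
    const double P = site.pressure;
    const double o2 = 0.209 * P;
    const double ca = co2 * 1e-6 * P;
    const double kc = 40.49 * std::pow(2.1, (tday - 25.0) / 10.0);
    const double ko = 27840.0 * std::pow(1.2, (tday - 25.0) / 10.0);
    const double tau = 2600.0 * std::pow(0.57, (tday - 25.0) / 10.0);
    const double gamma = 0.5 * o2 / tau;
    const double act = p.act25 * std::pow(p.q10_act, (tday - 25.0) / 10.0);

    double lai_sun = (1.0 - std::exp(-p.k_ext * lai)) / p.k_ext;
    if (lai_sun > lai) lai_sun = lai;
    double lai_shade = lai - lai_sun;
    double ppfd_top = srad * p.par_frac * p.ppfd_per_j;
    double ppfd_cls[2] = { ppfd_top,
                           ppfd_top * std::exp(-p.k_ext * lai_sun) * 0.5 };
    double lai_cls[2] = { lai_sun, lai_shade };
    double sla_cls[2] = { p.sla, p.sla * p.sla_shade_ratio };

    double m_psi = clamp01((psi - p.lwp_final) / (p.lwp_start - p.lwp_final));
    double m_tmin = clamp01((tmin - p.tmin_lo) / (p.tmin_hi - p.tmin_lo));
    double m_vpd = clamp01((p.vpd_final - vpd) / (p.vpd_final - p.vpd_start));

    for (int c = 0; c < 2; ++c) {
      if (lai_cls[c] <= 0.0) continue;
      double lnc = 1.0 / (sla_cls[c] * p.cn_leaf);     // kg N / m2 leaf
      double vcmax = lnc * p.flnr * 7.16 * act;
      if (vcmax <= 0.0) continue;
      double jmax = p.jmax_ratio * vcmax;
      double ppfd = ppfd_cls[c];
      double jj = jmax * p.alpha_j * ppfd / (p.alpha_j * ppfd + jmax);
      double rd = p.rd_frac * vcmax;
      double m_ppfd = clamp01(ppfd / (ppfd + p.ppfd_half));
      double gs = p.gsmax * m_ppfd * m_psi * m_tmin * m_vpd;
      double g_co2_ms = 1.0 / (1.4 / p.g_boundary +
                               1.6 / (gs + p.g_cuticular));
      double g_mol = g_co2_ms * 1e6 / (8.314 * tk);    // umol m-2 s-1 Pa-1
      NumericVector sol = solve_ci_cpp(g_mol, ca, vcmax, jj, gamma, kc, ko,
                                       o2, rd);
      double a = sol[1];
      if (a > 0.0) gpp += a * lai_cls[c] * daylen * 12.011e-9;
      double g_w_ms = 1.0 / (1.0 / p.g_boundary + 1.0 / (gs + p.g_cuticular));
      transp_dem += g_w_ms * vpd * 0.018 / (8.314 * tk) * lai_cls[c] * daylen;
    }
  }
  fx.gpp = gpp;

  // ---- maintenance respiration (N-based, Q10) ------------------------
  double mr_above = (st[S_LEAFC] / p.cn_leaf + st[S_LIVESTEMC] / p.cn_livewood) *
                    p.mr_per_n * std::pow(p.q10_mr, (tavg - 20.0) / 10.0);
  double mr_below = (st[S_FROOTC] / p.cn_froot +
                     st[S_LIVECROOTC] / p.cn_livewood) *
                    p.mr_per_n * std::pow(p.q10_mr, (tsoil - 20.0) / 10.0);
  double mr_pot = mr_above + mr_below;
  double mr = 0.0;
  double avail = gpp;
  {
    double pay = mr_pot < avail ? mr_pot : avail;
    avail -= pay; mr += pay;
    double deficit = mr_pot - pay;
    if (deficit > 0.0) {                   // draw on storage, then transfer
      double d1 = deficit < st[S_STORAGEC] ? deficit : st[S_STORAGEC];
      st[S_STORAGEC] -= d1; mr += d1; deficit -= d1;
      double d2 = deficit < st[S_TRANSFERC] ? deficit : st[S_TRANSFERC];
      st[S_TRANSFERC] -= d2; mr += d2;
      // any remaining deficit is forgiven (carbon starvation limit)
    }
  }
  fx.mr = mr;

  // ---- allocation of today's net assimilate --------------------------
  if (avail > 0.0) {
    double cur = (phase == PH_DORMANT) ? 0.0 : avail * p.current_growth_prop;
    double to_storage = avail - cur;
    if (cur > 0.0) {
      double denom = p.woody ? (1.0 + p.frc_lc + p.sc_lc * (1.0 + p.crc_sc))
                             : (1.0 + p.frc_lc);
      double tissue = cur / (1.0 + p.growth_resp_frac);
      double leaf_i = tissue / denom;
      double froot_i = p.frc_lc * leaf_i;
      double stem_i = p.woody ? p.sc_lc * leaf_i : 0.0;
      double croot_i = p.woody ? p.crc_sc * stem_i : 0.0;
      double wood_ncoef = p.live_wood_frac / p.cn_livewood +
                          (1.0 - p.live_wood_frac) / p.cn_deadwood;
      double ndem = leaf_i / p.cn_leaf + froot_i / p.cn_froot +
                    (stem_i + croot_i) * wood_ncoef;
      double rho = (ndem > 0.0 && ndem > st[S_SMINN]) ? st[S_SMINN] / ndem : 1.0;
      st[S_LEAFC] += leaf_i * rho;
      st[S_FROOTC] += froot_i * rho;
      st[S_LIVESTEMC] += p.live_wood_frac * stem_i * rho;
      st[S_DEADSTEMC] += (1.0 - p.live_wood_frac) * stem_i * rho;
      st[S_LIVECROOTC] += p.live_wood_frac * croot_i * rho;
      st[S_DEADCROOTC] += (1.0 - p.live_wood_frac) * croot_i * rho;
      gr += (cur - tissue) * rho;
      st[S_SMINN] -= ndem * rho;
      to_storage += cur * (1.0 - rho);     // N-limited carbon is deferred
    }
    st[S_STORAGEC] += to_storage;
  }
  fx.gr = gr;

  // ---- senescence litterfall ------------------------------------------
  double litterfall = 0.0, harvest = 0.0;
  if (phase == PH_SENESCENCE && days_left >= 1.0) {
    double fl = 1.0 / days_left;
    double leaf_fall = st[S_LEAFC] * fl;
    double froot_fall = st[S_FROOTC] * fl;
    st[S_LEAFC] -= leaf_fall; st[S_FROOTC] -= froot_fall;
    double harv = p.harvest_frac * leaf_fall;       // grass management only
    double leaf_lit = leaf_fall - harv;
    harvest += harv;
    st[S_LITR_LAB] += leaf_lit * p.litter_labile +
                      froot_fall * p.froot_labile;
    st[S_LITR_CEL] += leaf_lit * p.litter_cellulose +
                      froot_fall * p.froot_cellulose;
    st[S_LITR_LIG] += leaf_lit * p.litter_lignin +
                      froot_fall * p.froot_lignin;
    // leaf N is retranslocated down to the litter C:N; surplus to mineral N
    double litn = leaf_lit / p.cn_litter + froot_fall / p.cn_froot;
    st[S_LITRN] += litn;
    double resorb = leaf_lit / p.cn_leaf - leaf_lit / p.cn_litter;
    if (resorb > 0.0) st[S_SMINN] += resorb;
    litterfall += leaf_lit + froot_fall;
  }

  // ---- live wood turnover, whole-plant mortality, fire ----------------
  if (p.woody) {
    double r = p.livewood_turnover / 365.0;
    double t1 = st[S_LIVESTEMC] * r, t2 = st[S_LIVECROOTC] * r;
    st[S_LIVESTEMC] -= t1; st[S_DEADSTEMC] += t1;
    st[S_LIVECROOTC] -= t2; st[S_DEADCROOTC] += t2;
    double nfree = (t1 + t2) * (1.0 / p.cn_livewood - 1.0 / p.cn_deadwood);
    if (nfree > 0.0) st[S_SMINN] += nfree;
  }
  if (p.mortality > 0.0) {
    double m = p.mortality / 365.0;
    double leaf_m = st[S_LEAFC] * m, froot_m = st[S_FROOTC] * m;
    double ls_m = st[S_LIVESTEMC] * m, ds_m = st[S_DEADSTEMC] * m;
    double lc_m = st[S_LIVECROOTC] * m, dc_m = st[S_DEADCROOTC] * m;
    double sto_m = st[S_STORAGEC] * m, tra_m = st[S_TRANSFERC] * m;
    st[S_LEAFC] -= leaf_m; st[S_FROOTC] -= froot_m;
    st[S_LIVESTEMC] -= ls_m; st[S_DEADSTEMC] -= ds_m;
    st[S_LIVECROOTC] -= lc_m; st[S_DEADCROOTC] -= dc_m;
    st[S_STORAGEC] -= sto_m; st[S_TRANSFERC] -= tra_m;
    st[S_LITR_LAB] += leaf_m * p.litter_labile + froot_m * p.froot_labile +
                      sto_m + tra_m;
    st[S_LITR_CEL] += leaf_m * p.litter_cellulose +
                      froot_m * p.froot_cellulose;
    st[S_LITR_LIG] += leaf_m * p.litter_lignin + froot_m * p.froot_lignin;
    st[S_CWDC] += ls_m + ds_m + lc_m + dc_m;
    st[S_LITRN] += leaf_m / p.cn_leaf + froot_m / p.cn_froot;
    st[S_CWDN] += (ls_m + lc_m) / p.cn_livewood +
                  (ds_m + dc_m) / p.cn_deadwood;
    litterfall += leaf_m + froot_m + sto_m + tra_m + ls_m + ds_m + lc_m + dc_m;
  }
  if (p.fire_mortality > 0.0) {
    double f = p.fire_mortality / 365.0;
    double burned = 0.0;
    int pools[] = { S_LEAFC, S_FROOTC, S_LIVESTEMC, S_DEADSTEMC, S_LIVECROOTC,
                    S_DEADCROOTC, S_STORAGEC, S_TRANSFERC, S_LITR_LAB,
                    S_LITR_CEL, S_LITR_LIG, S_CWDC };
    for (int k = 0; k < 12; ++k) {
      double b = st[pools[k]] * f; st[pools[k]] -= b; burned += b;
    }
    st[S_LITRN] *= (1.0 - f); st[S_CWDN] *= (1.0 - f);
    st[S_CUMFIRE] += burned;
    fx.fire = burned;
  }

  // ---- decomposition cascade ------------------------------------------
  {
    double tscal = tsoil <= 0.0 ? 0.0
                 : std::pow(p.q10_hr, (tsoil - 20.0) / 10.0);
    if (tscal > 3.0) tscal = 3.0;
    double wscal = clamp01(st[S_SOILW] / site.capacity);
    double s = tscal * wscal;
    double hr = 0.0;
    // coarse woody debris fragments into cellulose/lignin litter
    if (st[S_CWDC] > 0.0) {
      double frag = st[S_CWDC] * p.k_cwd * s;
      st[S_CWDC] -= frag;
      st[S_LITR_CEL] += frag * p.deadwood_cellulose;
      st[S_LITR_LIG] += frag * p.deadwood_lignin;
      double fragn = st[S_CWDN] * p.k_cwd * s;
      st[S_CWDN] -= fragn; st[S_LITRN] += fragn;
    }
    double litC = st[S_LITR_LAB] + st[S_LITR_CEL] + st[S_LITR_LIG];
    if (litC > 0.0) {
      double l_lab = st[S_LITR_LAB] * p.k_lab * s;
      double l_cel = st[S_LITR_CEL] * p.k_cel * s;
      double l_lig = st[S_LITR_LIG] * p.k_lig * s;
      st[S_LITR_LAB] -= l_lab; st[S_LITR_CEL] -= l_cel; st[S_LITR_LIG] -= l_lig;
      double resp = p.rf_lab * l_lab + p.rf_cel * l_cel + p.rf_lig * l_lig;
      double to_soil = (l_lab + l_cel + l_lig) - resp;
      hr += resp;
      st[S_SOILC] += to_soil;
      double nrel = st[S_LITRN] * (l_lab + l_cel + l_lig) / litC;
      st[S_LITRN] -= nrel;
      double ndem = to_soil / p.cn_soil;
      if (nrel >= ndem) {
        st[S_SOILN] += ndem; st[S_SMINN] += nrel - ndem;
      } else {
        double immob = ndem - nrel;
        if (immob > st[S_SMINN]) immob = st[S_SMINN];
        st[S_SMINN] -= immob; st[S_SOILN] += nrel + immob;
      }
    }
    if (st[S_SOILC] > 0.0) {
      double sl = st[S_SOILC] * p.k_soil * s;
      st[S_SOILC] -= sl; hr += sl;
      double snrel = st[S_SOILN] * p.k_soil * s;
      st[S_SOILN] -= snrel; st[S_SMINN] += snrel;
    }
    fx.hr = hr;
  }

  // mineral N bulk loss (leaching/denitrification lump term)
  {
    double nl = st[S_SMINN] * p.sminn_loss_rate;
    st[S_SMINN] -= nl; fx.nloss = nl;
  }

  // ---- bucket water balance -------------------------------------------
  {
    double precip = met[M_PRCP_CM] * 10.0;            // cm -> kg/m2
    double icept = p.canopy_intercept * lai * precip;
    if (icept > precip) icept = precip;
    double infil = precip - icept;
    st[S_SOILW] += infil;
    double transp = transp_dem < st[S_SOILW] ? transp_dem : st[S_SOILW];
    st[S_SOILW] -= transp;
    double wscal_now = clamp01(st[S_SOILW] / site.capacity);
    double sevap = tavg > 0.0
      ? p.soil_evap_max * std::exp(-p.k_ext * lai) * wscal_now : 0.0;
    if (sevap > st[S_SOILW]) sevap = st[S_SOILW];
    st[S_SOILW] -= sevap;
    double drain = st[S_SOILW] > site.capacity ? st[S_SOILW] - site.capacity
                                               : 0.0;
    st[S_SOILW] -= drain;
    fx.interception = icept; fx.transp = transp; fx.soil_evap = sevap;
    fx.drainage = drain;
  }

  fx.litterfall = litterfall;
  fx.harvest = harvest;
  st[S_CUMHARV] += harvest;
}

static NumericVector flux_vector(const Flux& fx) {
  return NumericVector::create(
    _["gpp"] = fx.gpp, _["maint_resp"] = fx.mr, _["growth_resp"] = fx.gr,
    _["npp"] = fx.gpp - fx.mr - fx.gr, _["heterotrophic_resp"] = fx.hr,
    _["fire_loss"] = fx.fire, _["harvest"] = fx.harvest,
    _["litterfall_C"] = fx.litterfall, _["transpiration"] = fx.transp,
    _["soil_evap"] = fx.soil_evap, _["interception"] = fx.interception,
    _["drainage"] = fx.drainage, _["n_loss"] = fx.nloss,
    _["soil_psi"] = fx.psi, _["lai"] = fx.lai);
}

static CharacterVector state_names() {
  return CharacterVector::create(
    "leafC", "frootC", "livestemC", "deadstemC", "livecrootC", "deadcrootC",
    "storageC", "transferC", "litr_lab", "litr_cel", "litr_lig", "cwdC",
    "soilC", "litrN", "cwdN", "soilN", "sminN", "soil_water", "cum_fire",
    "cum_harvest");
}

// [[Rcpp::export(name = ".bgc_step_cpp")]]
List bgc_step_cpp(NumericVector state, NumericVector met, List params,
                  List site) {
  if (state.size() != S_N) stop("state vector must have %d elements", S_N);
  if (met.size() != M_N) stop("met vector must have %d elements", M_N);
  Par p = parse_par(params);
  SiteP s = parse_site(site);
  NumericVector st = clone(state);
  Flux fx;
  step_core(REAL(st), REAL(met), p, s, fx);
  st.attr("names") = state_names();
  return List::create(_["state"] = st, _["fluxes"] = flux_vector(fx));
}

// Run the model for `years` 365-day years, recycling the forcing matrix
// cyclically if it is shorter than the run. Returns annual summaries and
// the final state.
// [[Rcpp::export(name = ".bgc_run_cpp")]]
List bgc_run_cpp(NumericMatrix forcing, List params, List site,
                 NumericVector init, int years) {
  if (forcing.ncol() != M_N) stop("forcing must have %d columns", M_N);
  if (forcing.nrow() % 365 != 0) stop("forcing must cover whole 365-day years");
  if (init.size() != S_N) stop("init state must have %d elements", S_N);
  int n_forc_years = forcing.nrow() / 365;
  if (n_forc_years < 1) stop("forcing must cover at least one year");
  Par p = parse_par(params);
  SiteP s = parse_site(site);

  std::vector<double> st(init.begin(), init.end());
  NumericMatrix ann(years, 12);
  colnames(ann) = CharacterVector::create(
    "year", "AC", "BC", "LC", "soilC", "litterC", "cwdC", "gpp", "npp", "hr",
    "fire", "soil_water");
  Flux fx;
  std::vector<double> met(M_N);
  for (int y = 0; y < years; ++y) {
    int fy = y % n_forc_years;
    double ac_max = 0.0, bc_max = 0.0, lc_max = 0.0;
    double gpp_s = 0.0, npp_s = 0.0, hr_s = 0.0, fire_s = 0.0;
    for (int d = 0; d < 365; ++d) {
      int row = fy * 365 + d;
      for (int c = 0; c < M_N; ++c) met[c] = forcing(row, c);
      step_core(st.data(), met.data(), p, s, fx);
      double ac = st[S_LIVESTEMC] + st[S_DEADSTEMC];
      double bc = st[S_LIVECROOTC] + st[S_DEADCROOTC] + st[S_FROOTC];
      double lc = st[S_LEAFC];
      if (ac > ac_max) ac_max = ac;
      if (bc > bc_max) bc_max = bc;
      if (lc > lc_max) lc_max = lc;
      gpp_s += fx.gpp; npp_s += fx.gpp - fx.mr - fx.gr; hr_s += fx.hr;
      fire_s += fx.fire;
    }
    ann(y, 0) = y + 1; ann(y, 1) = ac_max; ann(y, 2) = bc_max;
    ann(y, 3) = lc_max; ann(y, 4) = st[S_SOILC];
    ann(y, 5) = st[S_LITR_LAB] + st[S_LITR_CEL] + st[S_LITR_LIG];
    ann(y, 6) = st[S_CWDC]; ann(y, 7) = gpp_s; ann(y, 8) = npp_s;
    ann(y, 9) = hr_s; ann(y, 10) = fire_s; ann(y, 11) = st[S_SOILW];
  }
  NumericVector fin(st.begin(), st.end());
  fin.attr("names") = state_names();
  return List::create(_["annual"] = ann, _["final_state"] = fin);
}
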