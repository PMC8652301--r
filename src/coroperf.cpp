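// Compiled inner loops: the linearized-implicit coronary network stepper and
// the per-cycle closed-loop driver.  Formulas mirror the R module functions
// (circulation.R, lv_shell.R, network.R); units are mmHg / ml / ms / cm,
// stresses in kPa converted at the interface.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double MMHG_PER_KPA = 7.50061683;

// ---------------------------------------------------------------------------
// Coronary network: one boundary-frozen interval of the volume-state DAE.
//
// Per sub-step the pressure-diameter law is linearized about the current
// volume, which makes the implicit (backward-Euler) update a linear
// tree-structured system in the mid-node and junction pressures; that system
// is solved exactly in O(n) by leaf-to-root elimination and root-to-leaf
// back-substitution.  Volumes are then updated from the implicit flows, so
// total network volume bookkeeping is exact.
// ---------------------------------------------------------------------------

struct NetworkDef {
  int n;
  const int *parent;        // upstream node of vessel i (0 = inlet)
  const int *elim;          // internal node ids, deepest first
  const int *child_start;   // slices into child_idx, aligned with elim
  const int *child_idx;
  const int *is_term;       // vessel's downstream node is a terminal
  int n_elim;
  const double *L;          // cm
  const double *Ap, *Bp;    // um (radii asymptotes)
  const double *phip, *Cp;  // mmHg
  double mu;                // mmHg.ms
};

// advance Vol over dt with n_sub sub-steps; returns interval-average
// inlet/outlet flows through the pointers
static void network_interval(const NetworkDef &net, double *Vol,
                             double P_in, double P_out, double P_T,
                             double dt, int n_sub,
                             double *q_in_avg, double *q_out_avg) {
  const int n = net.n;
  const double hs = dt / n_sub;
  std::vector<double> R1(n), k0(n), den(n), au(n), bu(n), cu(n),
      ad(n), bd(n), cd(n), alpha(n), beta(n), Pnode(n), Pmid(n);
  double acc_in = 0.0, acc_out = 0.0;

  for (int s = 0; s < n_sub; ++s) {
    // per-vessel coefficients at the current volume
    for (int i = 0; i < n; ++i) {
      const double Dcm = std::sqrt(4.0 * Vol[i] / (M_PI * net.L[i]));
      const double Dum = Dcm * 1e4;
      const double halfspan = net.Ap[i] - net.Bp[i];
      // clamp strictly inside the open diameter interval for the tan()
      double x = (Dum - 2.0 * net.Bp[i]) * M_PI / (2.0 * halfspan) - M_PI_2;
      const double xmax = M_PI_2 * (1.0 - 1e-9);
      if (x > xmax) x = xmax;
      if (x < -xmax) x = -xmax;
      const double Ptrans = net.phip[i] + net.Cp[i] * std::tan(x);
      const double cx = std::cos(x);
      // dP/dD [mmHg/um] and dD/dVol [um/ml]
      const double dPdD = net.Cp[i] / (cx * cx) * M_PI / (2.0 * halfspan);
      const double dDdV = 1e4 * 2.0 / (M_PI * net.L[i] * Dcm);
      const double dPdV = dPdD * dDdV;
      const double C = 1.0 / dPdV;                 // ml/mmHg (dVol/dPmid)
      const double R = 64.0 * net.mu * net.L[i] /
                       (M_PI * Dcm * Dcm * Dcm * Dcm);
      R1[i] = R;
      const double g = 1.0 / R;
      const double M = Ptrans + P_T;               // current mid pressure
      const double cd_dt = C / hs;
      const double dn = cd_dt + 2.0 * g;
      den[i] = dn;
      k0[i] = cd_dt * M;
      const double rd = 1.0 / (R * dn);
      au[i] = (dn - g) * rd;
      bu[i] = -g * rd;
      cu[i] = -k0[i] * rd;
      ad[i] = g * rd;
      bd[i] = (g - dn) * rd;
      cd[i] = k0[i] * rd;
    }

    // leaf-to-root elimination: P_j = alpha_j + beta_j * P_parentnode
    for (int e = 0; e < net.n_elim; ++e) {
      const int j = net.elim[e] - 1;               // 0-based vessel/node id
      double Sa = 0.0, Sc = 0.0;
      for (int c = net.child_start[e]; c < net.child_start[e + 1]; ++c) {
        const int k = net.child_idx[c] - 1;
        if (net.is_term[k]) {
          Sa += au[k];
          Sc += cu[k] + bu[k] * P_out;
        } else {
          Sa += au[k] + bu[k] * beta[k];
          Sc += cu[k] + bu[k] * alpha[k];
        }
      }
      const double denom = bd[j] - Sa;
      beta[j] = -ad[j] / denom;
      alpha[j] = (Sc - cd[j]) / denom;
    }

    // root-to-leaf resolution of junction pressures
    for (int e = net.n_elim - 1; e >= 0; --e) {
      const int j = net.elim[e] - 1;
      const int pn = net.parent[j];                // upstream node of vessel j
      const double Ppu = (pn == 0) ? P_in : Pnode[pn - 1];
      Pnode[j] = alpha[j] + beta[j] * Ppu;
    }
    for (int i = 0; i < n; ++i)
      if (net.is_term[i]) Pnode[i] = P_out;

    // implicit mid pressures, flows, exact volume update
    double qin = 0.0, qout = 0.0;
    for (int i = 0; i < n; ++i) {
      const int pn = net.parent[i];
      const double Pu = (pn == 0) ? P_in : Pnode[pn - 1];
      const double Pd = Pnode[i];
      const double pm = (k0[i] + Pu / R1[i] + Pd / R1[i]) / den[i];
      Pmid[i] = pm;
      const double Qu = (Pu - pm) / R1[i];
      const double Qd = (pm - Pd) / R1[i];
      Vol[i] += hs * (Qu - Qd);
      if (pn == 0) qin += Qu;
      if (net.is_term[i]) qout += Qd;
    }
    acc_in += qin * hs;
    acc_out += qout * hs;
  }
  *q_in_avg = acc_in / dt;
  *q_out_avg = acc_out / dt;
}

static NetworkDef make_def(const IntegerVector &parent,
                           const IntegerVector &elim,
                           const IntegerVector &child_start,
                           const IntegerVector &child_idx,
                           const LogicalVector &is_terminal,
                           const NumericVector &L, const NumericVector &Ap,
                           const NumericVector &Bp, const NumericVector &phip,
                           const NumericVector &Cp, double mu,
                           std::vector<int> &term_buf) {
  NetworkDef d;
  d.n = parent.size();
  d.parent = INTEGER(parent);
  d.elim = elim.size() ? INTEGER(elim) : nullptr;
  d.child_start = INTEGER(child_start);
  d.child_idx = child_idx.size() ? INTEGER(child_idx) : nullptr;
  term_buf.resize(d.n);
  for (int i = 0; i < d.n; ++i) term_buf[i] = is_terminal[i] ? 1 : 0;
  d.is_term = term_buf.data();
  d.n_elim = elim.size();
  d.L = REAL(L); d.Ap = REAL(Ap); d.Bp = REAL(Bp);
  d.phip = REAL(phip); d.Cp = REAL(Cp);
  d.mu = mu;
  return d;
}

// [[Rcpp::export]]
List cpp_advance_network(IntegerVector parent, IntegerVector elim_order,
                         IntegerVector child_start, IntegerVector child_idx,
                         LogicalVector is_terminal,
                         NumericVector L, NumericVector Ap, NumericVector Bp,
                         NumericVector phip, NumericVector Cp, double mu,
                         NumericVector Vol0, double P_in, double P_out,
                         double P_T, double dt, int n_sub) {
  std::vector<int> term_buf;
  NetworkDef net = make_def(parent, elim_order, child_start, child_idx,
                            is_terminal, L, Ap, Bp, phip, Cp, mu, term_buf);
  NumericVector Vol = clone(Vol0);
  double qi, qo;
  network_interval(net, REAL(Vol), P_in, P_out, P_T, dt, n_sub, &qi, &qo);
  return List::create(_["Vol"] = Vol, _["q_in_avg"] = qi,
                      _["q_out_avg"] = qo);
}

// ---------------------------------------------------------------------------
// LV shell backend: (V_LV, t) -> P_LV, boundary IMP profile, shell stresses
// ---------------------------------------------------------------------------

struct ShellDef {
  int n;
  const double *Rb3, *Rm3, *Rm, *Rhat_b;
  double Ri3;
  // constitutive
  double C_f, b_f, T_max, Ca0sq, Ca0max_sq, Bl, l0, l_ref, t0, tau, T_trans;
};

static double activation(double t, const ShellDef &s) {
  const double ct = 0.5 * (1.0 - std::cos(M_PI * t / s.t0));
  if (t <= s.T_trans) return ct;
  const double cT = 0.5 * (1.0 - std::cos(M_PI * s.T_trans / s.t0));
  return cT * std::exp(-(t - s.T_trans) / s.tau);
}

// fills lambda, E_ff, S_ff (length n) and p_b (length n+1, mmHg); returns
// P_LV in mmHg
static double shell_eval(const ShellDef &s, double V_LV, double t,
                         double *lambda, double *E_ff, double *S_ff,
                         double *p_b) {
  if (V_LV <= 0.0) stop("diverged state: LV cavity volume collapsed");
  const double ri3 = 3.0 * V_LV / (4.0 * M_PI);
  const double shift = ri3 - s.Ri3;
  const double Ct = activation(t, s);
  std::vector<double> lnr(s.n);
  double rb_prev = std::cbrt(s.Rb3[0] + shift);
  for (int k = 0; k < s.n; ++k) {
    const double rb = std::cbrt(s.Rb3[k + 1] + shift);
    lnr[k] = std::log(rb / rb_prev);
    rb_prev = rb;
    const double rm = std::cbrt(s.Rm3[k] + shift);
    const double lam = rm / s.Rm[k];
    lambda[k] = lam;
    const double E = 0.5 * (lam * lam - 1.0);
    E_ff[k] = E;
    // tension-only passive fiber law: no compressive fiber stress
    double S = (E > 0.0) ? s.C_f * s.b_f * E * std::exp(s.b_f * E * E) : 0.0;
    const double l = s.l_ref * lam;
    if (l > s.l0) {
      const double ex = std::exp(s.Bl * (l - s.l0)) - 1.0;
      const double eca50sq = s.Ca0max_sq / ex;
      S += s.T_max * s.Ca0sq / (s.Ca0sq + eca50sq) * Ct;
    }
    S_ff[k] = S;
  }
  // IMP at boundaries, cumulated from the epicardium (kPa -> mmHg)
  double acc = 0.0;
  p_b[s.n] = 0.0;
  for (int k = s.n - 1; k >= 0; --k) {
    acc += 2.0 * lambda[k] * lambda[k] * S_ff[k] * lnr[k];
    p_b[k] = acc * MMHG_PER_KPA;
  }
  return p_b[0];
}

static double interp_depth(const double *x, const double *y, int n,
                           double xo) {
  if (xo <= x[0]) return y[0];
  if (xo >= x[n - 1]) return y[n - 1];
  int lo = 0;
  while (lo < n - 2 && x[lo + 1] < xo) ++lo;
  const double w = (xo - x[lo]) / (x[lo + 1] - x[lo]);
  return y[lo] * (1.0 - w) + y[lo + 1] * w;
}

// ---------------------------------------------------------------------------
// One cardiac cycle of the fully coupled model
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_cycle(NumericVector circ, NumericVector lv,
                   NumericVector Rb3, NumericVector Rm3, NumericVector Rm,
                   NumericVector Rhat_b, double Ri3,
                   IntegerVector parent, IntegerVector elim_order,
                   IntegerVector child_start, IntegerVector child_idx,
                   LogicalVector is_terminal,
                   NumericVector L, NumericVector Ap, NumericVector Bp,
                   NumericVector phip, NumericVector Cp, double mu,
                   NumericVector state0, NumericMatrix Vol0,
                   NumericVector depths, double dt, int n_steps, int n_sub) {
  // circulation parameter unpack (order fixed by the R wrapper)
  const double R_ao = circ[0], R_ap = circ[1], R_ad = circ[2],
               R_ven = circ[3], R_mv = circ[4], C_ap = circ[5],
               C_ad = circ[6], C_ven = circ[7], V_ap0 = circ[8],
               V_ad0 = circ[9], V_ven0 = circ[10], E_es_LA = circ[11],
               V_LA0 = circ[12], A_LA = circ[13], B_LA = circ[14],
               T_max_LA = circ[15], tau_LA = circ[16], T_cycle = circ[17];

  ShellDef sh;
  sh.n = Rm3.size();
  sh.Rb3 = REAL(Rb3); sh.Rm3 = REAL(Rm3); sh.Rm = REAL(Rm);
  sh.Rhat_b = REAL(Rhat_b); sh.Ri3 = Ri3;
  sh.C_f = lv[0]; sh.b_f = lv[1]; sh.T_max = lv[2];
  sh.Ca0sq = lv[3] * lv[3]; sh.Ca0max_sq = lv[4] * lv[4];
  sh.Bl = lv[5]; sh.l0 = lv[6]; sh.l_ref = lv[7];
  sh.t0 = lv[8]; sh.tau = lv[9]; sh.T_trans = lv[10];

  const int n_net = Vol0.ncol();
  const int nv = Vol0.nrow();
  std::vector<int> term_buf;
  NetworkDef net = make_def(parent, elim_order, child_start, child_idx,
                            is_terminal, L, Ap, Bp, phip, Cp, mu, term_buf);

  double V_LA = state0[0], V_LV = state0[1], V_ap = state0[2],
         V_ad = state0[3], V_ven = state0[4];
  NumericMatrix Vol(nv, n_net);
  for (int j = 0; j < n_net; ++j)
    for (int i = 0; i < nv; ++i) Vol(i, j) = Vol0(i, j);

  const int NC = 16 + 4 * n_net;
  NumericMatrix series(n_steps, NC);
  NumericMatrix lam_m(sh.n, n_steps), Eff_m(sh.n, n_steps),
      Sff_m(sh.n, n_steps);
  std::vector<double> lambda(sh.n), E_ff(sh.n), S_ff(sh.n), p_b(sh.n + 1);
  const int nd = depths.size();
  if (n_net > 0 && nd != n_net) stop("depths must match the network count");

  for (int k = 0; k < n_steps; ++k) {
    double t = k * dt;
    while (t >= T_cycle) t -= T_cycle;
    // 1. LV backend: V_LV -> P_LV and the transmural IMP profile
    const double P_LV = shell_eval(sh, V_LV, t, lambda.data(), E_ff.data(),
                                   S_ff.data(), p_b.data());
    // 2. compartment pressures
    const double e_la = (t <= 1.5 * T_max_LA)
        ? 0.5 * (std::sin(M_PI * t / T_max_LA - M_PI_2) + 1.0)
        : 0.5 * std::exp(-(t - 1.5 * T_max_LA) / tau_LA);
    const double dVla = V_LA - V_LA0;
    const double P_LA = e_la * E_es_LA * dVla +
        (1.0 - e_la) * A_LA * (std::exp(B_LA * dVla) - 1.0);
    const double P_ap = (V_ap - V_ap0) / C_ap;
    const double P_ad = (V_ad - V_ad0) / C_ad;
    const double P_ven = (V_ven - V_ven0) / C_ven;
    // 3. branch flows (diode valves)
    const double q_ao = std::max(P_LV - P_ap, 0.0) / R_ao;
    const double q_mv = std::max(P_LA - P_LV, 0.0) / R_mv;
    const double q_ap = (P_ap - P_ad) / R_ap;
    const double q_ad = (P_ad - P_ven) / R_ad;
    const double q_ven = (P_ven - P_LA) / R_ven;

    // record state at the start of the step
    series(k, 0) = k * dt;
    series(k, 1) = P_LA; series(k, 2) = P_LV; series(k, 3) = P_ap;
    series(k, 4) = P_ad; series(k, 5) = P_ven;
    series(k, 6) = V_LA; series(k, 7) = V_LV; series(k, 8) = V_ap;
    series(k, 9) = V_ad; series(k, 10) = V_ven;
    series(k, 11) = q_mv; series(k, 12) = q_ao; series(k, 13) = q_ap;
    series(k, 14) = q_ad; series(k, 15) = q_ven;
    for (int s = 0; s < sh.n; ++s) {
      lam_m(s, k) = lambda[s]; Eff_m(s, k) = E_ff[s]; Sff_m(s, k) = S_ff[s];
    }

    // 4. coronary networks over [t, t + dt] with frozen boundaries
    double q_cor_in = 0.0, q_cor_out = 0.0;
    for (int j = 0; j < n_net; ++j) {
      const double imp = interp_depth(sh.Rhat_b, p_b.data(), sh.n + 1,
                                      depths[j]);
      double qi = 0.0, qo = 0.0;
      network_interval(net, &Vol(0, j), P_ap, P_ven, imp, dt, n_sub,
                       &qi, &qo);
      series(k, 16 + j) = qi;
      series(k, 16 + n_net + j) = qo;
      series(k, 16 + 2 * n_net + j) = imp;
      double tv = 0.0;
      for (int i = 0; i < nv; ++i) tv += Vol(i, j);
      series(k, 16 + 3 * n_net + j) = tv;
      q_cor_in += qi;
      q_cor_out += qo;
    }

    // 5. explicit Euler volume update (coronary totals enter the proximal
    //    arterial compartment with negative and the veins with positive sign)
    V_LA += dt * (q_ven - q_mv);
    V_LV += dt * (q_mv - q_ao);
    V_ap += dt * (q_ao - q_ap - q_cor_in);
    V_ad += dt * (q_ap - q_ad);
    V_ven += dt * (q_ad - q_ven + q_cor_out);
    if (V_LA <= 0.0) stop("diverged simulation: compartment volume V_LA became non-positive");
    if (V_LV <= 0.0) stop("diverged simulation: compartment volume V_LV became non-positive");
    if (V_ap <= 0.0) stop("diverged simulation: compartment volume V_ap became non-positive");
    if (V_ad <= 0.0) stop("diverged simulation: compartment volume V_ad became non-positive");
    if (V_ven <= 0.0) stop("diverged simulation: compartment volume V_ven became non-positive");
  }

  return List::create(
      _["series"] = series, _["lambda"] = lam_m, _["E_ff"] = Eff_m,
      _["S_ff"] = Sff_m,
      _["state"] = NumericVector::create(V_LA, V_LV, V_ap, V_ad, V_ven),
      _["Vol"] = Vol);
}
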