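// Implicit (theta-method) integrator for the branched cable equation with
// Hodgkin-Huxley gating, explicit Na+/K+/Cl- concentration pools, Nernst
// reversal potentials, a Na+/K+ pump and longitudinal diffusion.
//
// Units: mV, ms, uF/cm^2, mS/cm^2, uA/cm^2, um, um^2, um^3, mM.
// The voltage solve is a direct Hines elimination on the compartment tree
// (parents precede children in the ordering); gating uses staggered
// exponential-Euler updates, concentrations a first-order split step.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Gate {
  double vhalf, k, tbase, tamp, tvmax, tw1, tw2, sh_inf, sh_tau;
  inline double uinf(double V) const {
    return 1.0 / (1.0 + std::exp(-((V - sh_inf) - vhalf) / k));
  }
  inline double tau(double V) const {
    double v = (V - sh_tau) - tvmax;
    return tbase + tamp / (std::exp(v / tw1) + std::exp(-v / tw2));
  }
  // exponential-Euler update, exact for fixed V
  inline double step(double u, double V, double dt) const {
    double ui = uinf(V);
    return ui + (u - ui) * std::exp(-dt / tau(V));
  }
};

Gate read_gate(const NumericMatrix& gp, int col) {
  Gate g;
  g.vhalf = gp(0, col); g.k = gp(1, col);
  g.tbase = gp(2, col); g.tamp = gp(3, col); g.tvmax = gp(4, col);
  g.tw1 = gp(5, col); g.tw2 = gp(6, col);
  g.sh_inf = gp(7, col); g.sh_tau = gp(8, col);
  return g;
}

} // namespace

// [[Rcpp::export]]
List sim_core(List model, List state, List control) {
  const IntegerVector parent = model["parent"];       // 0-based, -1 root
  const NumericVector area = model["area"];           // cm^2
  const NumericVector cm = model["cm"];               // uF/cm^2
  const NumericVector g_ax = model["g_axial"];        // S to parent (0 root)
  const NumericVector gbar12 = model["gbar12"];       // mS/cm^2
  const NumericVector gbar16 = model["gbar16"];
  const NumericVector gbarkv = model["gbarkv"];
  const NumericVector glna = model["gleak_na"];
  const NumericVector glk = model["gleak_k"];
  const NumericVector glcl = model["gleak_cl"];
  const NumericVector pimax = model["pump_imax"];     // uA/cm^2
  const double km_k = model["km_k"], km_na = model["km_na"];
  const LogicalVector ais12 = model["kin12_ais"];
  const NumericMatrix gp = model["gate_params"];      // 9 x 7
  const int n_exp = model["kv_exp"];
  const NumericVector vol_in = model["vol_in"];       // um^3
  const NumericVector vol_out = model["vol_out"];
  const NumericVector ax_in = model["ax_in"];         // um^2 (to parent)
  const NumericVector ax_out = model["ax_out"];
  const NumericVector ds = model["ds"];               // um
  const double D_na = model["D_na"], D_k = model["D_k"], D_cl = model["D_cl"];
  const double unernst = model["nernst_coef"];        // RT/F in mV
  const double faraday = model["faraday"];
  const double dt = model["dt"], theta = model["theta"];
  const bool ion_on = model["ion_dynamics"];
  const bool diff_on = model["diffusion_on"];

  NumericVector V = clone(as<NumericVector>(state["V"]));
  NumericMatrix gates = clone(as<NumericMatrix>(state["gates"])); // n x 5
  NumericMatrix conc = clone(as<NumericMatrix>(state["conc"]));   // n x 6

  const int nsteps = control["nsteps"];
  const int stim_comp = control["stim_comp"];         // 0-based, -1 none
  const double stim_amp = control["stim_amp"];        // nA
  const double stim_onset = control["stim_onset"];
  const double stim_dur = control["stim_dur"];
  const IntegerVector rec = control["record_idx"];    // 0-based
  const int rec_every = control["record_every"];

  const int n = V.size();
  const int nrec = rec.size();
  const int nsamp = nsteps / rec_every + 1;

  const Gate m16 = read_gate(gp, 0), h16 = read_gate(gp, 1);
  const Gate m12n = read_gate(gp, 2), h12n = read_gate(gp, 3);
  const Gate m12a = read_gate(gp, 4), h12a = read_gate(gp, 5);
  const Gate kvn = read_gate(gp, 6);

  // axial coupling coefficients (uA/cm^2 per mV), row-normalized by area
  std::vector<double> c_to_par(n, 0.0), c_from_child(n, 0.0), csum(n, 0.0);
  for (int j = 0; j < n; ++j) {
    int p = parent[j];
    if (p < 0) continue;
    double cj = 1e3 * g_ax[j] / area[j];  // row j, neighbor p
    double cp = 1e3 * g_ax[j] / area[p];  // row p, neighbor j
    c_to_par[j] = cj;
    c_from_child[j] = cp;
    csum[j] += cj;
    csum[p] += cp;
  }
  std::vector<double> coef_in(n), coef_out(n), area_um2(n);
  for (int j = 0; j < n; ++j) {
    area_um2[j] = area[j] * 1e8;
    coef_in[j] = 10.0 * area_um2[j] / (faraday * vol_in[j]);
    coef_out[j] = 10.0 * area_um2[j] / (faraday * vol_out[j]);
  }

  NumericMatrix Vout(nsamp, nrec);
  NumericVector tout(nsamp);
  NumericVector vmax(nrec, -1e30);
  IntegerVector first_cross(n, -1);  // step of first upward crossing of 0 mV
  for (int r = 0; r < nrec; ++r) {
    Vout(0, r) = V[rec[r]];
    if (V[rec[r]] > vmax[r]) vmax[r] = V[rec[r]];
  }
  tout[0] = 0.0;

  std::vector<double> gtot(n), bterm(n), diag(n), rhs(n), Vnew(n);
  std::vector<double> gna(n), gk(n), gcl(n), ena(n), ek(n), ecl(n), ipv(n);
  std::vector<double> dlap(n);
  double max_dvdt = 0.0;

  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;
    bool stim_on = (stim_comp >= 0) && (t >= stim_onset - 1e-12) &&
                   (t < stim_onset + stim_dur - 1e-12);

    // 1. gating update (staggered, uses V at step start)
    for (int j = 0; j < n; ++j) {
      double v = V[j];
      if (gbar12[j] > 0) {
        const Gate& gm = ais12[j] ? m12a : m12n;
        const Gate& gh = ais12[j] ? h12a : h12n;
        gates(j, 0) = gm.step(gates(j, 0), v, dt);
        gates(j, 1) = gh.step(gates(j, 1), v, dt);
      }
      if (gbar16[j] > 0) {
        gates(j, 2) = m16.step(gates(j, 2), v, dt);
        gates(j, 3) = h16.step(gates(j, 3), v, dt);
      }
      if (gbarkv[j] > 0)
        gates(j, 4) = kvn.step(gates(j, 4), v, dt);
    }

    // 2. conductances, reversal potentials, pump
    for (int j = 0; j < n; ++j) {
      double g12 = 0.0, g16 = 0.0, gkv = 0.0;
      if (gbar12[j] > 0) {
        double m = gates(j, 0);
        g12 = gbar12[j] * m * m * m * gates(j, 1);
      }
      if (gbar16[j] > 0) {
        double m = gates(j, 2);
        g16 = gbar16[j] * m * m * m * gates(j, 3);
      }
      if (gbarkv[j] > 0) {
        double nn = gates(j, 4);
        gkv = gbarkv[j] * (n_exp == 1 ? nn : std::pow(nn, n_exp));
      }
      ena[j] = unernst * std::log(conc(j, 1) / conc(j, 0));
      ek[j] = unernst * std::log(conc(j, 3) / conc(j, 2));
      ecl[j] = -unernst * std::log(conc(j, 5) / conc(j, 4));
      double ip = 0.0;
      if (pimax[j] > 0) {
        double fk = 1.0 + km_k / conc(j, 3);
        double fna = 1.0 + km_na / conc(j, 0);
        ip = pimax[j] / (fk * fk * fna * fna * fna);
      }
      ipv[j] = ip;
      gna[j] = g12 + g16 + glna[j];
      gk[j] = gkv + glk[j];
      gcl[j] = glcl[j];
      gtot[j] = gna[j] + gk[j] + gcl[j];
      double b = gna[j] * ena[j] + gk[j] * ek[j] + gcl[j] * ecl[j] - ip;
      if (stim_on && j == stim_comp)
        b += 1e-3 * stim_amp / area[j];  // nA -> uA, per cm^2
      bterm[j] = b;
    }

    // 3. theta-method voltage solve (Hines elimination on the tree)
    for (int j = 0; j < n; ++j) {
      double cd = cm[j] / dt;
      diag[j] = cd + theta * (gtot[j] + csum[j]);
      // explicit part: -(1-theta) * (gtot V - axial laplacian applied to V)
      double lapv = csum[j] * V[j];
      rhs[j] = cd * V[j] - (1.0 - theta) * gtot[j] * V[j] + bterm[j];
      if (parent[j] >= 0) lapv -= c_to_par[j] * V[parent[j]];
      rhs[j] -= (1.0 - theta) * lapv;
    }
    // children contributions to the explicit laplacian of their parents
    for (int j = n - 1; j >= 1; --j) {
      int p = parent[j];
      rhs[p] += (1.0 - theta) * c_from_child[j] * V[j];
    }
    for (int j = n - 1; j >= 1; --j) {
      int p = parent[j];
      double a = -theta * c_to_par[j];       // row j, col p
      double bcf = -theta * c_from_child[j]; // row p, col j
      double f = bcf / diag[j];
      diag[p] -= f * a;
      rhs[p] -= f * rhs[j];
    }
    Vnew[0] = rhs[0] / diag[0];
    for (int j = 1; j < n; ++j) {
      int p = parent[j];
      Vnew[j] = (rhs[j] + theta * c_to_par[j] * Vnew[p]) / diag[j];
    }

    // 4. per-ion currents at the new voltage, concentration update
    if (ion_on) {
      for (int ion = 0; ion < 3; ++ion) {
        int ci = 2 * ion, co = 2 * ion + 1;
        double D = (ion == 0) ? D_na : (ion == 1) ? D_k : D_cl;
        for (int j = 0; j < n; ++j) {
          double I;
          if (ion == 0)      I = gna[j] * (Vnew[j] - ena[j]) + 3.0 * ipv[j];
          else if (ion == 1) I = gk[j] * (Vnew[j] - ek[j]) - 2.0 * ipv[j];
          else               I = gcl[j] * (Vnew[j] - ecl[j]);
          conc(j, ci) -= dt * coef_in[j] * I;
          conc(j, co) += dt * coef_out[j] * I;
        }
        if (diff_on) {
          // intracellular pool
          std::fill(dlap.begin(), dlap.end(), 0.0);
          for (int j = 1; j < n; ++j) {
            int p = parent[j];
            double f = D * ax_in[j] / ds[j] * (conc(p, ci) - conc(j, ci));
            dlap[j] += f / vol_in[j];
            dlap[p] -= f / vol_in[p];
          }
          for (int j = 0; j < n; ++j) conc(j, ci) += dt * dlap[j];
          // extracellular pool
          std::fill(dlap.begin(), dlap.end(), 0.0);
          for (int j = 1; j < n; ++j) {
            int p = parent[j];
            double f = D * ax_out[j] / ds[j] * (conc(p, co) - conc(j, co));
            dlap[j] += f / vol_out[j];
            dlap[p] -= f / vol_out[p];
          }
          for (int j = 0; j < n; ++j) conc(j, co) += dt * dlap[j];
        }
        for (int j = 0; j < n; ++j)
          if (conc(j, ci) <= 0.0 || conc(j, co) <= 0.0)
            stop("ionic concentration driven non-positive at t = %f ms; "
                 "reduce dt", t);
      }
    }

    // 5. bookkeeping
    max_dvdt = 0.0;
    for (int j = 0; j < n; ++j) {
      double dv = std::abs(Vnew[j] - V[j]) / dt;
      if (dv > max_dvdt) max_dvdt = dv;
      if (first_cross[j] < 0 && V[j] <= 0.0 && Vnew[j] > 0.0)
        first_cross[j] = step + 1;
      V[j] = Vnew[j];
    }
    for (int r = 0; r < nrec; ++r)
      if (V[rec[r]] > vmax[r]) vmax[r] = V[rec[r]];
    if ((step + 1) % rec_every == 0) {
      int srow = (step + 1) / rec_every;
      tout[srow] = (step + 1) * dt;
      for (int r = 0; r < nrec; ++r) Vout(srow, r) = V[rec[r]];
    }
  }

  return List::create(
    _["t"] = tout, _["V"] = Vout, _["vmax"] = vmax,
    _["V_final"] = V, _["gates_final"] = gates, _["conc_final"] = conc,
    _["max_dvdt"] = max_dvdt, _["first_cross_step"] = first_cross);
}
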