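// Core computations for the multi-sign dynamic occupancy model:
//  - per-survey emission probabilities for each sign's true/false process
//  - two-state forward recursion marginalizing the latent occupancy path
//    (probability scale with per-site running products; logs deferred)
//  - adaptive Metropolis-within-Gibbs sampler over coefficients and
//    park / park-year random effects, with conjugate Gibbs draws for the
//    random-effect precisions and forward-filtering backward-sampling of
//    the latent states at retained iterations.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double LOG_ZERO = -1e300;
static const double FLUSH_LO = 1e-250;

static inline double invlogit(double x) {
  if (x > 30.0) x = 30.0;
  if (x < -30.0) x = -30.0;
  return 1.0 / (1.0 + std::exp(-x));
}

struct Model {
  // dimensions
  int nsite, nyear, npark, S, nsurv;
  int KL, Kg, Ke;
  std::vector<int> Kp, Kfp;
  bool perfect;

  // data
  std::vector<int> site_park;          // nsite, 0-based
  std::vector<double> cplx;            // nsite
  NumericMatrix Xlam;                  // nsite x KL
  NumericMatrix Xg, Xe;                // (nsite*nyear) x Kg/Ke
  std::vector<int> sv_site, sv_year;   // nsurv, 0-based
  IntegerMatrix Y, U;                  // nsurv x S
  std::vector<NumericMatrix> Xp, Xfp;  // per sign
  IntegerMatrix pin;                   // nsite x nyear (-1 latent, 0/1 pinned)
  std::vector<std::vector<int>> park_sites;

  // parameter layout offsets into theta
  int off_lam, off_li, off_ls, off_g, off_e;
  int off_reG, off_reE, off_sig, P;
  std::vector<int> off_beta, off_fp;

  // priors
  double coef_sd, gam_shape, gam_rate;

  // state (cur) and proposal buffers (swapped on accept)
  std::vector<double> theta;
  std::vector<std::vector<double>> p1, p0;   // per sign, per survey
  std::vector<double> pscr;                  // scratch for one sign
  std::vector<double> f1, f0, f1p, f0p;      // per survey
  std::vector<double> E1, E0, E1p, E0p;      // nsite*nyear
  std::vector<double> psi1;                  // nsite
  std::vector<double> G, Eps;                // nsite*nyear (col 0 unused)
  std::vector<double> llsite, llp;           // nsite
  double ll_total;
  // forward scratch
  std::vector<double> a1s, a0s, prods;

  void setup(List dat, double coef_sd_, double gs, double gr) {
    coef_sd = coef_sd_; gam_shape = gs; gam_rate = gr;
    nsite = as<int>(dat["nsite"]);
    nyear = as<int>(dat["nyear"]);
    npark = as<int>(dat["npark"]);
    perfect = as<bool>(dat["perfect"]);
    IntegerVector sp = dat["site_park"];
    site_park.assign(sp.begin(), sp.end());
    NumericVector cx = dat["complexity"];
    cplx.assign(cx.begin(), cx.end());
    Xlam = as<NumericMatrix>(dat["Xlam"]);
    KL = Xlam.ncol();
    Xg = as<NumericMatrix>(dat["Xg"]);
    Xe = as<NumericMatrix>(dat["Xe"]);
    Kg = Xg.ncol(); Ke = Xe.ncol();
    IntegerVector svs = dat["sv_site"], svy = dat["sv_year"];
    sv_site.assign(svs.begin(), svs.end());
    sv_year.assign(svy.begin(), svy.end());
    nsurv = sv_site.size();
    Y = as<IntegerMatrix>(dat["Y"]);
    U = as<IntegerMatrix>(dat["U"]);
    List xp = dat["Xp"], xfp = dat["Xfp"];
    S = xp.size();
    for (int s = 0; s < S; s++) {
      Xp.push_back(as<NumericMatrix>(xp[s]));
      Xfp.push_back(as<NumericMatrix>(xfp[s]));
      Kp.push_back(Xp[s].ncol());
      Kfp.push_back(Xfp[s].ncol());
    }
    pin = as<IntegerMatrix>(dat["pin"]);
    park_sites.assign(npark, {});
    for (int i = 0; i < nsite; i++) park_sites[site_park[i]].push_back(i);

    // layout
    int o = 0;
    for (int s = 0; s < S; s++) { off_beta.push_back(o); o += Kp[s]; }
    for (int s = 0; s < S; s++) { off_fp.push_back(o); o += Kfp[s]; }
    off_lam = o; o += KL;
    off_li = o; o += npark;
    off_ls = o; o += npark;
    off_g = o; o += Kg;
    off_e = o; o += Ke;
    off_reG = o; o += npark * (nyear - 1);
    off_reE = o; o += npark * (nyear - 1);
    off_sig = o; o += 4;
    P = o;

    p1.assign(S, std::vector<double>(nsurv));
    p0.assign(S, std::vector<double>(nsurv));
    pscr.assign(nsurv, 0.0);
    f1.assign(nsurv, 1.0); f0.assign(nsurv, 1.0);
    f1p = f1; f0p = f0;
    E1.assign(nsite * nyear, 1.0); E0.assign(nsite * nyear, 1.0);
    E1p = E1; E0p = E0;
    psi1.assign(nsite, 0.5);
    G.assign(nsite * nyear, 0.0); Eps.assign(nsite * nyear, 0.0);
    llsite.assign(nsite, 0.0); llp = llsite;
    a1s.assign(nsite, 0.0); a0s.assign(nsite, 0.0); prods.assign(nsite, 1.0);
  }

  inline double sig(int k) const { return theta[off_sig + k]; }

  void compute_p1(int s, std::vector<double>& out) {
    const NumericMatrix& X = Xp[s];
    const double* b = &theta[off_beta[s]];
    for (int j = 0; j < nsurv; j++) {
      double lin = 0.0;
      for (int k = 0; k < Kp[s]; k++) lin += X(j, k) * b[k];
      out[j] = invlogit(lin);
    }
  }

  void compute_p0(int s, std::vector<double>& out) {
    if (Kfp[s] == 0) { std::fill(out.begin(), out.end(), 0.0); return; }
    const NumericMatrix& X = Xfp[s];
    const double* b = &theta[off_fp[s]];
    for (int j = 0; j < nsurv; j++) {
      if (U(j, s) == 1) { out[j] = 0.0; continue; }
      double lin = 0.0;
      for (int k = 0; k < Kfp[s]; k++) lin += X(j, k) * b[k];
      out[j] = invlogit(lin);
    }
  }

  // survey factors, with sign `schg`'s probabilities taken from `palt`
  // (palt replaces p1[schg] if chg_true, else p0[schg])
  void compute_f_to(std::vector<double>& o1, std::vector<double>& o0,
                    int schg, bool chg_true, const std::vector<double>& palt) {
    for (int j = 0; j < nsurv; j++) {
      double a = 1.0, b = 1.0;
      for (int s = 0; s < S; s++) {
        double q1 = (s == schg && chg_true) ? palt[j] : p1[s][j];
        double q0 = (s == schg && !chg_true) ? palt[j] : p0[s][j];
        if (Y(j, s) == 1) { a *= q1; b *= q0; }
        else             { a *= 1.0 - q1; b *= 1.0 - q0; }
      }
      o1[j] = a; o0[j] = b;
    }
  }

  void compute_E_to(std::vector<double>& o1, std::vector<double>& o0,
                    const std::vector<double>& ff1,
                    const std::vector<double>& ff0) {
    std::fill(o1.begin(), o1.end(), 1.0);
    std::fill(o0.begin(), o0.end(), 1.0);
    if (perfect) {
      for (int t = 0; t < nyear; t++)
        for (int i = 0; i < nsite; i++) {
          int v = pin(i, t);
          if (v == 1) o0[i + nsite * t] = 0.0;
          else if (v == 0) o1[i + nsite * t] = 0.0;
        }
      return;
    }
    for (int j = 0; j < nsurv; j++) {
      int idx = sv_site[j] + nsite * sv_year[j];
      o1[idx] *= ff1[j];
      o0[idx] *= ff0[j];
    }
  }

  void compute_psi1_site(int i) {
    double lin = 0.0;
    for (int k = 0; k < KL; k++) lin += Xlam(i, k) * theta[off_lam + k];
    int p = site_park[i];
    lin += theta[off_li + p] + theta[off_ls + p] * cplx[i];
    psi1[i] = invlogit(lin);
  }

  void compute_G_cell(int i, int t) {
    int idx = i + nsite * t;
    double lin = 0.0;
    for (int k = 0; k < Kg; k++) lin += Xg(idx, k) * theta[off_g + k];
    lin += theta[off_reG + site_park[i] + npark * (t - 1)];
    G[idx] = invlogit(lin);
  }

  void compute_E_cell(int i, int t) {
    int idx = i + nsite * t;
    double lin = 0.0;
    for (int k = 0; k < Ke; k++) lin += Xe(idx, k) * theta[off_e + k];
    lin += theta[off_reE + site_park[i] + npark * (t - 1)];
    Eps[idx] = invlogit(lin);
  }

  // forward recursion over all sites, year-outer and vectorized across
  // sites; logs deferred to one per site (with underflow flushes);
  // emissions read from the supplied buffers, result into `out`.
  double forward_all_to(const std::vector<double>& eo1,
                        const std::vector<double>& eo0,
                        std::vector<double>& out) {
    for (int i = 0; i < nsite; i++) {
      double x1 = psi1[i] * eo1[i];
      double x0 = (1.0 - psi1[i]) * eo0[i];
      double c = x1 + x0;
      if (c <= 0.0) { prods[i] = 0.0; a1s[i] = 0.5; a0s[i] = 0.5; out[i] = LOG_ZERO; continue; }
      prods[i] = c; a1s[i] = x1 / c; a0s[i] = x0 / c; out[i] = 0.0;
    }
    for (int t = 1; t < nyear; t++) {
      const double* g = &G[nsite * t];
      const double* e = &Eps[nsite * t];
      const double* b1 = &eo1[nsite * t];
      const double* b0 = &eo0[nsite * t];
      for (int i = 0; i < nsite; i++) {
        if (prods[i] == 0.0) continue;
        double n1 = (a0s[i] * g[i] + a1s[i] * (1.0 - e[i])) * b1[i];
        double n0 = (a0s[i] * (1.0 - g[i]) + a1s[i] * e[i]) * b0[i];
        double c = n1 + n0;
        if (c <= 0.0) { prods[i] = 0.0; out[i] = LOG_ZERO; continue; }
        prods[i] *= c;
        if (prods[i] < FLUSH_LO) { out[i] += std::log(prods[i]); prods[i] = 1.0; }
        a1s[i] = n1 / c; a0s[i] = n0 / c;
      }
    }
    double tot = 0.0;
    for (int i = 0; i < nsite; i++) {
      if (prods[i] > 0.0) out[i] += std::log(prods[i]);
      tot += out[i];
    }
    return tot;
  }

  // forward for a subset of sites using the current emission buffers;
  // writes into llsite and returns the subset sum
  double forward_subset(const std::vector<int>& sites) {
    double tot = 0.0;
    for (int i : sites) {
      double x1 = psi1[i] * E1[i];
      double x0 = (1.0 - psi1[i]) * E0[i];
      double c = x1 + x0;
      if (c <= 0.0) { llsite[i] = LOG_ZERO; continue; }
      double a1 = x1 / c, a0 = x0 / c;
      double prod = c, ll = 0.0;
      bool dead = false;
      for (int t = 1; t < nyear; t++) {
        int idx = i + nsite * t;
        double n1 = (a0 * G[idx] + a1 * (1.0 - Eps[idx])) * E1[idx];
        double n0 = (a0 * (1.0 - G[idx]) + a1 * Eps[idx]) * E0[idx];
        c = n1 + n0;
        if (c <= 0.0) { llsite[i] = LOG_ZERO; dead = true; break; }
        prod *= c;
        if (prod < FLUSH_LO) { ll += std::log(prod); prod = 1.0; }
        a1 = n1 / c; a0 = n0 / c;
      }
      if (!dead) llsite[i] = ll + std::log(prod);
      tot += llsite[i];
    }
    return tot;
  }

  void refresh_all() {
    for (int s = 0; s < S; s++) { compute_p1(s, p1[s]); compute_p0(s, p0[s]); }
    if (S > 0) compute_f_to(f1, f0, -1, true, pscr);
    compute_E_to(E1, E0, f1, f0);
    for (int i = 0; i < nsite; i++) compute_psi1_site(i);
    for (int t = 1; t < nyear; t++)
      for (int i = 0; i < nsite; i++) { compute_G_cell(i, t); compute_E_cell(i, t); }
    ll_total = forward_all_to(E1, E0, llsite);
  }

  // filtered forward + backward sampling of the latent path for site i
  void ffbs_site(int i, std::vector<double>& filt, int* zout) const {
    double a1 = psi1[i] * E1[i];
    double a0 = (1.0 - psi1[i]) * E0[i];
    double c = a1 + a0;
    filt[0] = (c > 0.0) ? a1 / c : 0.5;
    for (int t = 1; t < nyear; t++) {
      int idx = i + nsite * t;
      double g = G[idx], e = Eps[idx];
      double p1f = filt[t - 1];
      double n1 = ((1.0 - p1f) * g + p1f * (1.0 - e)) * E1[idx];
      double n0 = ((1.0 - p1f) * (1.0 - g) + p1f * e) * E0[idx];
      double ct = n1 + n0;
      filt[t] = (ct > 0.0) ? n1 / ct : 0.5;
    }
    zout[nyear - 1] = (R::unif_rand() < filt[nyear - 1]) ? 1 : 0;
    for (int t = nyear - 2; t >= 0; t--) {
      int idx = i + nsite * (t + 1);
      double g = G[idx], e = Eps[idx];
      double w1, w0;
      if (zout[t + 1] == 1) { w1 = filt[t] * (1.0 - e); w0 = (1.0 - filt[t]) * g; }
      else                  { w1 = filt[t] * e;        w0 = (1.0 - filt[t]) * (1.0 - g); }
      double tot = w1 + w0;
      double pr = (tot > 0.0) ? w1 / tot : filt[t];
      zout[t] = (R::unif_rand() < pr) ? 1 : 0;
    }
  }
};

// ---------------------------------------------------------------------------
// sampler

struct Adapt {
  std::vector<double> lstep;
  std::vector<int> acc, tries;
  int batch = 0;
  void init(int P, double s0) {
    lstep.assign(P, std::log(s0));
    acc.assign(P, 0); tries.assign(P, 0);
  }
  void update() {
    batch++;
    double d = std::min(0.1, 1.0 / std::sqrt((double)batch));
    for (size_t k = 0; k < lstep.size(); k++) {
      if (tries[k] == 0) continue;
      double rate = (double)acc[k] / tries[k];
      lstep[k] += (rate > 0.44 ? d : -d);
      acc[k] = 0; tries[k] = 0;
    }
  }
};

static inline double norm_lprior(double x, double sd) {
  return -0.5 * x * x / (sd * sd);
}

// detection coefficient update (kind 0 true process, 1 false-positive)
static void mh_detection(Model& M, Adapt& A, int pidx, bool is_true, int s) {
  double old = M.theta[pidx];
  double prop = old + std::exp(A.lstep[pidx]) * R::norm_rand();
  double dlp = norm_lprior(prop, M.coef_sd) - norm_lprior(old, M.coef_sd);
  A.tries[pidx]++;
  M.theta[pidx] = prop;
  if (is_true) M.compute_p1(s, M.pscr); else M.compute_p0(s, M.pscr);
  M.compute_f_to(M.f1p, M.f0p, s, is_true, M.pscr);
  M.compute_E_to(M.E1p, M.E0p, M.f1p, M.f0p);
  double tot = M.forward_all_to(M.E1p, M.E0p, M.llp);
  if (std::log(R::unif_rand()) < tot - M.ll_total + dlp) {
    if (is_true) std::swap(M.p1[s], M.pscr); else std::swap(M.p0[s], M.pscr);
    std::swap(M.f1, M.f1p); std::swap(M.f0, M.f0p);
    std::swap(M.E1, M.E1p); std::swap(M.E0, M.E0p);
    std::swap(M.llsite, M.llp);
    M.ll_total = tot;
    A.acc[pidx]++;
  } else {
    M.theta[pidx] = old;
  }
}

// initial-occupancy updates: kind 2 fixed coef (all sites), 3 park
// intercept, 4 park slope
static void mh_lambda(Model& M, Adapt& A, int pidx, int kind, int p,
                      const std::vector<int>& sites) {
  double old = M.theta[pidx];
  double prop = old + std::exp(A.lstep[pidx]) * R::norm_rand();
  double sd = (kind == 2) ? M.coef_sd : (kind == 3) ? M.sig(0) : M.sig(1);
  double dlp = norm_lprior(prop, sd) - norm_lprior(old, sd);
  A.tries[pidx]++;
  M.theta[pidx] = prop;
  std::vector<double> save_psi, save_ll;
  save_psi.reserve(sites.size()); save_ll.reserve(sites.size());
  double old_sum = 0.0;
  for (int i : sites) { save_psi.push_back(M.psi1[i]); save_ll.push_back(M.llsite[i]); old_sum += M.llsite[i]; }
  for (int i : sites) M.compute_psi1_site(i);
  double new_sum = M.forward_subset(sites);
  if (std::log(R::unif_rand()) < new_sum - old_sum + dlp) {
    M.ll_total += new_sum - old_sum;
    A.acc[pidx]++;
  } else {
    M.theta[pidx] = old;
    size_t k = 0;
    for (int i : sites) { M.psi1[i] = save_psi[k]; M.llsite[i] = save_ll[k]; k++; }
  }
}

// colonization/extinction updates: fixed coefficient (all cells) or one
// park-year random effect (one park, one transition year)
static void mh_dynamics(Model& M, Adapt& A, int pidx, bool is_gamma,
                        bool fixed, int p, int t) {
  double old = M.theta[pidx];
  double prop = old + std::exp(A.lstep[pidx]) * R::norm_rand();
  double sd = fixed ? M.coef_sd : (is_gamma ? M.sig(2) : M.sig(3));
  double dlp = norm_lprior(prop, sd) - norm_lprior(old, sd);
  A.tries[pidx]++;
  M.theta[pidx] = prop;

  if (fixed) {
    std::vector<double>& dyn = is_gamma ? M.G : M.Eps;
    std::vector<double> save_dyn = dyn;
    for (int t2 = 1; t2 < M.nyear; t2++)
      for (int i = 0; i < M.nsite; i++)
        is_gamma ? M.compute_G_cell(i, t2) : M.compute_E_cell(i, t2);
    double tot = M.forward_all_to(M.E1, M.E0, M.llp);
    if (std::log(R::unif_rand()) < tot - M.ll_total + dlp) {
      std::swap(M.llsite, M.llp);
      M.ll_total = tot;
      A.acc[pidx]++;
    } else {
      M.theta[pidx] = old;
      dyn = std::move(save_dyn);
    }
  } else {
    const std::vector<int>& sites = M.park_sites[p];
    std::vector<double> save_dyn, save_ll;
    save_dyn.reserve(sites.size()); save_ll.reserve(sites.size());
    double old_sum = 0.0;
    for (int i : sites) {
      int idx = i + M.nsite * t;
      save_dyn.push_back(is_gamma ? M.G[idx] : M.Eps[idx]);
      save_ll.push_back(M.llsite[i]);
      old_sum += M.llsite[i];
    }
    for (int i : sites) is_gamma ? M.compute_G_cell(i, t) : M.compute_E_cell(i, t);
    double new_sum = M.forward_subset(sites);
    if (std::log(R::unif_rand()) < new_sum - old_sum + dlp) {
      M.ll_total += new_sum - old_sum;
      A.acc[pidx]++;
    } else {
      M.theta[pidx] = old;
      size_t k = 0;
      for (int i : sites) {
        int idx = i + M.nsite * t;
        if (is_gamma) M.G[idx] = save_dyn[k]; else M.Eps[idx] = save_dyn[k];
        M.llsite[i] = save_ll[k];
        k++;
      }
    }
  }
}

// conjugate Gibbs draw for a random-effect precision: tau ~ Gamma(a + n/2,
// b + sum(re^2)/2), sigma = tau^{-1/2}
static double gibbs_sigma(const double* re, int n, double a, double b) {
  double ss = 0.0;
  for (int k = 0; k < n; k++) ss += re[k] * re[k];
  double tau = R::rgamma(a + 0.5 * n, 1.0 / (b + 0.5 * ss));
  if (tau < 1e-10) tau = 1e-10;
  return 1.0 / std::sqrt(tau);
}

// [[Rcpp::export]]
List cpp_mcmc_chain(List dat, NumericVector theta0, List cfg) {
  Model M;
  M.setup(dat, as<double>(cfg["coef_sd"]), as<double>(cfg["gamma_shape"]),
          as<double>(cfg["gamma_rate"]));
  if ((int)theta0.size() != M.P) stop("theta0 has wrong length");
  M.theta.assign(theta0.begin(), theta0.end());
  M.refresh_all();

  int n_iter = as<int>(cfg["iterations"]);
  int burn = as<int>(cfg["burn_in"]);
  int thin = as<int>(cfg["thin"]);
  int z_thin = as<int>(cfg["z_thin"]);
  int nkeep = (n_iter - burn + thin - 1) / thin;
  int nzkeep = (nkeep + z_thin - 1) / z_thin;

  NumericMatrix draws(nkeep, M.P);
  NumericVector lls(nkeep);
  IntegerMatrix zdraws(std::max(nzkeep, 1), M.nsite * M.nyear);

  Adapt A;
  A.init(M.P, 0.3);

  std::vector<int> allsites(M.nsite);
  for (int i = 0; i < M.nsite; i++) allsites[i] = i;
  int nT = M.nyear - 1;
  std::vector<double> filt(std::max(M.nyear, 1));
  std::vector<int> zrow(std::max(M.nyear, 1));
  int keep = 0, zkeep = 0;

  for (int iter = 0; iter < n_iter; iter++) {
    bool adapting = iter < burn;
    // detection coefficients
    for (int s = 0; s < M.S; s++) {
      for (int k = 0; k < M.Kp[s]; k++)
        mh_detection(M, A, M.off_beta[s] + k, true, s);
      for (int k = 0; k < M.Kfp[s]; k++)
        mh_detection(M, A, M.off_fp[s] + k, false, s);
    }
    // initial occupancy
    for (int k = 0; k < M.KL; k++)
      mh_lambda(M, A, M.off_lam + k, 2, 0, allsites);
    for (int p = 0; p < M.npark; p++) {
      mh_lambda(M, A, M.off_li + p, 3, p, M.park_sites[p]);
      mh_lambda(M, A, M.off_ls + p, 4, p, M.park_sites[p]);
    }
    // colonization / extinction fixed effects
    for (int k = 0; k < M.Kg; k++)
      mh_dynamics(M, A, M.off_g + k, true, true, 0, 0);
    for (int k = 0; k < M.Ke; k++)
      mh_dynamics(M, A, M.off_e + k, false, true, 0, 0);
    // park-year random effects
    for (int t = 1; t < M.nyear; t++) {
      for (int p = 0; p < M.npark; p++) {
        mh_dynamics(M, A, M.off_reG + p + M.npark * (t - 1), true, false, p, t);
        mh_dynamics(M, A, M.off_reE + p + M.npark * (t - 1), false, false, p, t);
      }
    }
    // random-effect scales (conjugate given the effects)
    M.theta[M.off_sig + 0] = gibbs_sigma(&M.theta[M.off_li], M.npark,
                                         M.gam_shape, M.gam_rate);
    M.theta[M.off_sig + 1] = gibbs_sigma(&M.theta[M.off_ls], M.npark,
                                         M.gam_shape, M.gam_rate);
    if (nT > 0) {
      M.theta[M.off_sig + 2] = gibbs_sigma(&M.theta[M.off_reG], M.npark * nT,
                                           M.gam_shape, M.gam_rate);
      M.theta[M.off_sig + 3] = gibbs_sigma(&M.theta[M.off_reE], M.npark * nT,
                                           M.gam_shape, M.gam_rate);
    }

    if (adapting && (iter + 1) % 50 == 0) A.update();

    if (iter >= burn && (iter - burn) % thin == 0) {
      for (int k = 0; k < M.P; k++) draws(keep, k) = M.theta[k];
      lls[keep] = M.ll_total;
      if (keep % z_thin == 0) {
        for (int i = 0; i < M.nsite; i++) {
          M.ffbs_site(i, filt, &zrow[0]);
          for (int t = 0; t < M.nyear; t++)
            zdraws(zkeep, i + M.nsite * t) = zrow[t];
        }
        zkeep++;
      }
      keep++;
    }
  }

  return List::create(_["draws"] = draws, _["loglik"] = lls,
                      _["zdraws"] = zdraws, _["n_z"] = zkeep,
                      _["steps"] = NumericVector(A.lstep.begin(), A.lstep.end()));
}

// Marginal log-likelihood of the full dataset at a given parameter vector
// (same code path as the sampler); used for cross-checking against the
// reference R implementation.
// [[Rcpp::export]]
double cpp_loglik_total(List dat, NumericVector theta, double coef_sd = 3.16) {
  Model M;
  M.setup(dat, coef_sd, 1.0, 1.0);
  if ((int)theta.size() != M.P) stop("theta has wrong length");
  M.theta.assign(theta.begin(), theta.end());
  M.refresh_all();
  return M.ll_total;
}

// [[Rcpp::export]]
int cpp_n_params(List dat) {
  Model M;
  M.setup(dat, 1.0, 1.0, 1.0);
  return M.P;
}
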