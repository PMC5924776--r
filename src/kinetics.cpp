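// Compiled fast path for the half-sarcomere distribution engine.
// Mirrors the algorithm of the R-level step_half_sarcomere() exactly:
// per macro step, (1) shift the bound distribution for the imposed
// length change, (2) adaptive-RK4 (step-doubling) update of the 21 bin
// equations with the detached pool recomputed in every stage, (3) one
// forward-Euler activation step with the [N_bound, N_overlap] clamp.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct ActivePars {
  double rho, kcb, xps, aon, aoff, kplus, kminus;
  double Ckp, Ckn, kdp, kdn, kdbp, kdbn;
  double kT, sl_floor, knot1, knot2, knot3, knot4;
  double shift_frac;
  bool clamp_neg;
  int coop_form; // 1 inactive, 2 active, 3 unbound
};

ActivePars unpack(const NumericVector& v) {
  ActivePars p;
  p.rho = v[0]; p.kcb = v[1]; p.xps = v[2]; p.aon = v[3]; p.aoff = v[4];
  p.kplus = v[5]; p.kminus = v[6]; p.Ckp = v[7]; p.Ckn = v[8];
  p.kdp = v[9]; p.kdn = v[10]; p.kdbp = v[11]; p.kdbn = v[12];
  p.kT = v[13]; p.sl_floor = v[14];
  p.knot1 = v[15]; p.knot2 = v[16]; p.knot3 = v[17]; p.knot4 = v[18];
  p.shift_frac = v[19];
  p.clamp_neg = v[20] != 0.0;
  p.coop_form = (int)v[21];
  return p;
}

double overlap(const ActivePars& p, double hsl) {
  double up = (hsl - p.knot1) / (p.knot2 - p.knot1);
  double down = (p.knot4 - hsl) / (p.knot4 - p.knot3);
  double f = std::min(up, down);
  return std::max(0.0, std::min(1.0, f));
}

void bin_rates(const ActivePars& p, const NumericVector& bins,
               std::vector<double>& k1, std::vector<double>& km1) {
  int nb = bins.size();
  k1.resize(nb); km1.resize(nb);
  for (int i = 0; i < nb; ++i) {
    double x = bins[i];
    double Ck = (x >= 0) ? p.Ckp : p.Ckn;
    double kd = (x >= 0) ? p.kdp : p.kdn;
    double kdb = (x >= 0) ? p.kdbp : p.kdbn;
    double xm = x * 1e-9;
    k1[i] = Ck * std::exp(-p.kcb * xm * xm / (2.0 * p.kT)); // * 1 nm width
    km1[i] = kd + kdb * x * x * x * x;
  }
}

inline void deriv(const std::vector<double>& k1, const std::vector<double>& km1,
                  double N, const std::vector<double>& A,
                  std::vector<double>& dA) {
  int nb = A.size();
  double Nb = 0.0;
  for (int i = 0; i < nb; ++i) Nb += A[i];
  double D = std::max(N - Nb, 0.0);
  for (int i = 0; i < nb; ++i) dA[i] = k1[i] * D - km1[i] * A[i];
}

void rk4(const std::vector<double>& k1, const std::vector<double>& km1,
         double N, std::vector<double>& A, double h,
         std::vector<double>& f1, std::vector<double>& f2,
         std::vector<double>& f3, std::vector<double>& f4,
         std::vector<double>& tmp) {
  int nb = A.size();
  deriv(k1, km1, N, A, f1);
  for (int i = 0; i < nb; ++i) tmp[i] = A[i] + 0.5 * h * f1[i];
  deriv(k1, km1, N, tmp, f2);
  for (int i = 0; i < nb; ++i) tmp[i] = A[i] + 0.5 * h * f2[i];
  deriv(k1, km1, N, tmp, f3);
  for (int i = 0; i < nb; ++i) tmp[i] = A[i] + h * f3[i];
  deriv(k1, km1, N, tmp, f4);
  for (int i = 0; i < nb; ++i)
    A[i] += h / 6.0 * (f1[i] + 2.0 * f2[i] + 2.0 * f3[i] + f4[i]);
}

// advance A over dt with step-doubling error control
void evolve_bound_cpp(const std::vector<double>& k1,
                      const std::vector<double>& km1,
                      double N, std::vector<double>& A, double dt,
                      double tol, int max_sub) {
  int nb = A.size();
  std::vector<double> f1(nb), f2(nb), f3(nb), f4(nb), tmp(nb);
  std::vector<double> Afull(nb), Ahalf(nb), Astart(nb);
  // start near the RK4 stability limit of the stiffest bin
  double km_max = 0.0;
  for (int i = 0; i < nb; ++i) km_max = std::max(km_max, km1[i]);
  int n_sub = 1;
  while (n_sub < max_sub && dt / n_sub > 2.5 / km_max) n_sub *= 2;
  for (;;) {
    double h = dt / n_sub;
    std::vector<double> A0(A);
    bool ok = true;
    for (int s = 0; s < n_sub; ++s) {
      Afull = A0; rk4(k1, km1, N, Afull, h, f1, f2, f3, f4, tmp);
      Ahalf = A0;
      rk4(k1, km1, N, Ahalf, 0.5 * h, f1, f2, f3, f4, tmp);
      rk4(k1, km1, N, Ahalf, 0.5 * h, f1, f2, f3, f4, tmp);
      double err = 0.0;
      for (int i = 0; i < nb; ++i)
        err = std::max(err, std::fabs(Afull[i] - Ahalf[i]));
      if (!(err <= tol)) { ok = false; break; }  // NaN/Inf also fail
      A0 = Ahalf;
    }
    if (ok) { A = A0; break; }
    if (n_sub >= max_sub)
      stop("kinetics: RK4 error control failed within %d sub-steps", max_sub);
    n_sub *= 2;
  }
  for (int i = 0; i < nb; ++i) if (A[i] < 0.0) A[i] = 0.0;
}

void shift_dist(std::vector<double>& A, const NumericVector& bins,
                double shift) {
  if (shift == 0.0) return;
  int nb = bins.size();
  double lo = bins[0];
  double span = bins[nb - 1] - bins[0];
  if (std::fabs(shift) >= span)
    stop("distribution shift exceeds the bin-grid span");
  std::vector<double> out(nb, 0.0);
  for (int i = 0; i < nb; ++i) {
    double src = bins[i] - shift;       // old strain now mapped to bin i
    double pos = src - lo;              // in units of 1 nm bins
    int i0 = (int)std::floor(pos);
    double w = pos - i0;
    double a0 = (i0 >= 0 && i0 < nb) ? A[i0] : 0.0;
    double a1 = (i0 + 1 >= 0 && i0 + 1 < nb) ? A[i0 + 1] : 0.0;
    out[i] = (1.0 - w) * a0 + w * a1;
    if (out[i] < 0.0) out[i] = 0.0;
  }
  A = out;
}

double tension(const ActivePars& p, const NumericVector& bins,
               const std::vector<double>& A, double hsl) {
  if (2.0 * hsl <= p.sl_floor) return 0.0;
  double s = 0.0;
  for (int i = 0; i < (int)A.size(); ++i)
    s += A[i] * (bins[i] + p.xps) * 1e-9;
  double T = p.rho * p.kcb * s;
  if (p.clamp_neg && T < 0.0) T = 0.0;
  return T;
}

double coop_sink(const ActivePars& p, double N, double Nb, double Nov) {
  switch (p.coop_form) {
    case 2: return p.kminus * N;
    case 3: return p.kminus * (N - Nb);
    default: return p.kminus * (Nov - N);
  }
}

} // namespace

// advance one mechanics time step for a batch of independent
// half-sarcomeres (one per finite element); A is ne x 21 (row per
// element).  The step is divided into n_kin kinetic sub-steps, the
// imposed length change (and hence the distribution shift) being
// apportioned equally among them.
// [[Rcpp::export]]
List xb_step_batch_cpp(NumericVector pars, NumericVector bins, double ca,
                       NumericVector hsl_new, double dt,
                       NumericVector N, NumericMatrix A,
                       NumericVector hsl_old, int n_kin = 4,
                       double tol = 1e-8, int max_sub = 1024) {
  ActivePars p = unpack(pars);
  int ne = N.size(), nb = bins.size();
  std::vector<double> k1, km1;
  bin_rates(p, bins, k1, km1);
  NumericVector Nout(ne), Nbout(ne), Tout(ne);
  NumericMatrix Aout(ne, nb);
  double h = dt / n_kin;
  for (int e = 0; e < ne; ++e) {
    std::vector<double> Ae(nb);
    for (int i = 0; i < nb; ++i) Ae[i] = A(e, i);
    double d_hsl = (hsl_new[e] - hsl_old[e]) / n_kin;
    double Ne = N[e], Nb = 0.0, hsl = hsl_old[e];
    for (int s = 0; s < n_kin; ++s) {
      if (d_hsl != 0.0) {
        shift_dist(Ae, bins, p.shift_frac * d_hsl);
        hsl += d_hsl;
      }
      evolve_bound_cpp(k1, km1, Ne, Ae, h, tol, max_sub);
      Nb = 0.0;
      for (int i = 0; i < nb; ++i) Nb += Ae[i];
      double Nov = overlap(p, hsl);
      double dN = p.aon * ca * (Nov - Ne) - p.aoff * (Ne - Nb) +
        p.kplus * Nb - coop_sink(p, Ne, Nb, Nov);
      Ne += h * dN;
      Ne = std::min(std::max(Ne, std::max(Nb, 0.0)), std::max(Nov, Nb));
    }
    Nout[e] = Ne; Nbout[e] = Nb;
    Tout[e] = tension(p, bins, Ae, hsl_new[e]);
    for (int i = 0; i < nb; ++i) Aout(e, i) = Ae[i];
  }
  return List::create(_["N"] = Nout, _["Nb"] = Nbout, _["T"] = Tout,
                      _["A"] = Aout);
}

// [[Rcpp::export]]
List xb_simulate_cpp(NumericVector pars, NumericVector bins,
                     NumericVector ca, NumericVector hsl, double dt,
                     double N0, NumericVector A0, double hsl0,
                     double tol = 1e-8, int max_sub = 1024) {
  ActivePars p = unpack(pars);
  int n = ca.size(), nb = bins.size();
  if (hsl.size() != n) stop("ca and hsl schedules must have equal length");
  std::vector<double> k1, km1;
  bin_rates(p, bins, k1, km1);

  std::vector<double> A(A0.begin(), A0.end());
  double N = N0, cur_hsl = hsl0;
  NumericVector Nout(n), Nbout(n), Tout(n);

  for (int s = 0; s < n; ++s) {
    double d_hsl = hsl[s] - cur_hsl;
    if (d_hsl != 0.0) {
      shift_dist(A, bins, p.shift_frac * d_hsl);
      cur_hsl = hsl[s];
    }
    evolve_bound_cpp(k1, km1, N, A, dt, tol, max_sub);
    double Nb = 0.0;
    for (int i = 0; i < nb; ++i) Nb += A[i];
    double Nov = overlap(p, cur_hsl);
    double dN = p.aon * ca[s] * (Nov - N) - p.aoff * (N - Nb) +
      p.kplus * Nb - coop_sink(p, N, Nb, Nov);
    N += dt * dN;
    double hi = std::max(Nov, Nb);
    N = std::min(std::max(N, std::max(Nb, 0.0)), hi);
    Nout[s] = N; Nbout[s] = Nb;
    Tout[s] = tension(p, bins, A, cur_hsl);
  }
  return List::create(_["N"] = Nout, _["Nb"] = Nbout, _["T"] = Tout,
                      _["A_final"] = NumericVector(A.begin(), A.end()));
}
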