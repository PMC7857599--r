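#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of the mediator-explicit community model through
// serial growth-dilution cycles.
//
// State: species densities S (cells/ml), mediator concentrations C (fmole/ml),
// optionally a single limiting resource R (fmole/ml).
//
//   dC_i/dt = sum_j [ beta_ij - alpha_ij * C_i/(C_i + K_ji) ] * S_j
//   dS_j/dt = rho_j * [ r0_j + sum_i r_ji * C_i/(C_i + K_ji) ] * S_j
//   dR/dt   = - sum_j alphaR_j * rho_j * [ ... same bracket ... ] * S_j
//
// rho_j = R/(R + KR_j) in the resource variant, 1 otherwise.  K is stored
// species x mediator and shared between uptake and growth influence.
//
// A cycle ends when total density reaches n_dil (or, with a finite
// max_cycle_time, when the cycle clock exceeds it); the culture is then
// diluted back to n_inoc total, mediators are diluted by the same factor,
// the resource is reset to fresh-medium concentration, and species below
// n_ext are set extinct (0, permanently).  Generations accrue per growth
// interval as log2(end/start of total density); the run stops once
// cumulative generations reach target_gen (possibly mid-cycle).

// [[Rcpp::export]]
List euler_cycles_cpp(NumericVector S0, NumericVector C0,
                      NumericVector r0, NumericMatrix rinf,
                      NumericMatrix beta, NumericMatrix alpha,
                      NumericMatrix Ksm,
                      double dt,
                      double n_inoc, double n_dil, double n_ext,
                      double target_gen,
                      bool resource,
                      double R_init, double R_fresh,
                      NumericVector KR, NumericVector alphaR,
                      double max_cycle_time,
                      double stall_time,
                      int max_cycles,
                      double max_steps) {
  const int N = S0.size();   // species
  const int M = C0.size();   // mediators

  if (rinf.nrow() != N || rinf.ncol() != M)
    stop("influence matrix must be n_species x n_mediators");
  if (beta.nrow() != M || beta.ncol() != N)
    stop("production matrix must be n_mediators x n_species");
  if (alpha.nrow() != M || alpha.ncol() != N)
    stop("consumption matrix must be n_mediators x n_species");
  if (Ksm.nrow() != N || Ksm.ncol() != M)
    stop("saturation matrix must be n_species x n_mediators");
  if (resource && ((int) KR.size() != N || (int) alphaR.size() != N))
    stop("resource parameter vectors must have one entry per species");

  std::vector<double> S(S0.begin(), S0.end());
  std::vector<double> C(C0.begin(), C0.end());
  double R = resource ? R_init : NA_REAL;

  // flat row-major (mediator-major) copies for contiguous inner loops
  std::vector<double> betaF((size_t) M * N), alphaF((size_t) M * N),
      kF((size_t) M * N), rinfF((size_t) M * N);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < N; ++j) {
      betaF[(size_t) i * N + j] = beta(i, j);
      alphaF[(size_t) i * N + j] = alpha(i, j);
      kF[(size_t) i * N + j] = Ksm(j, i);
      rinfF[(size_t) i * N + j] = rinf(j, i);
    }

  std::vector<double> dS(N), dC(M), growth(N);

  double t = 0.0, cycle_t = 0.0;
  double gen_completed = 0.0, gen_now = 0.0;
  double start_total = 0.0;
  for (int j = 0; j < N; ++j) start_total += S[j];
  if (start_total <= 0.0) stop("initial total density must be positive");

  long n_clamps = 0;
  double steps = 0.0;
  int n_cycles = 0;
  bool stalled = false, collapsed = false;

  // per-dilution event records
  std::vector<double> dil_time, dil_gen, dil_total, dil_comp, dil_med;
  std::vector<int> ext_species, ext_cycle;

  while (true) {
    // derivatives: one fused pass over mediators, then the species pass
    for (int j = 0; j < N; ++j) growth[j] = r0[j];
    for (int i = 0; i < M; ++i) {
      const double ci = C[i];
      double dci = 0.0;
      const double *bi = &betaF[(size_t) i * N];
      const double *ai = &alphaF[(size_t) i * N];
      const double *ki = &kF[(size_t) i * N];
      const double *ri = &rinfF[(size_t) i * N];
      if (ci > 0.0) {
        for (int j = 0; j < N; ++j) {
          const double s = ci / (ci + ki[j]);
          dci += (bi[j] - ai[j] * s) * S[j];
          growth[j] += ri[j] * s;
        }
      } else {
        for (int j = 0; j < N; ++j) dci += bi[j] * S[j];
      }
      dC[i] = dci;
    }
    double rho_sum = 0.0; // dR accumulator
    for (int j = 0; j < N; ++j) {
      const double g = growth[j];
      double rho = 1.0;
      if (resource) rho = (R > 0.0) ? R / (R + KR[j]) : 0.0;
      dS[j] = rho * g * S[j];
      if (resource) rho_sum += alphaR[j] * rho * g * S[j];
    }

    // Euler step with clamping at zero
    for (int j = 0; j < N; ++j) {
      S[j] += dt * dS[j];
      if (S[j] < 0.0) { S[j] = 0.0; ++n_clamps; }
    }
    for (int i = 0; i < M; ++i) {
      C[i] += dt * dC[i];
      if (C[i] < 0.0) { C[i] = 0.0; ++n_clamps; }
    }
    if (resource) {
      R -= dt * rho_sum;
      if (R < 0.0) { R = 0.0; ++n_clamps; }
    }
    t += dt; cycle_t += dt; steps += 1.0;

    double total = 0.0;
    for (int j = 0; j < N; ++j) total += S[j];

    if (total <= 0.0) { collapsed = true; gen_now = gen_completed; break; }

    gen_now = gen_completed + std::log2(total / start_total);
    if (gen_now >= target_gen) break;

    bool timed_out = R_finite(max_cycle_time) && cycle_t >= max_cycle_time;
    if (total >= n_dil || timed_out) {
      // record the pre-dilution state
      dil_time.push_back(t);
      dil_gen.push_back(gen_now);
      dil_total.push_back(total);
      for (int j = 0; j < N; ++j) dil_comp.push_back(S[j]);
      for (int i = 0; i < M; ++i) dil_med.push_back(C[i]);

      double factor = n_inoc / total;
      for (int j = 0; j < N; ++j) S[j] *= factor;
      for (int i = 0; i < M; ++i) C[i] *= factor;
      if (resource) R = R_fresh;
      ++n_cycles;
      for (int j = 0; j < N; ++j) {
        if (S[j] > 0.0 && S[j] < n_ext) {
          S[j] = 0.0;
          ext_species.push_back(j + 1);
          ext_cycle.push_back(n_cycles);
        }
      }
      gen_completed = gen_now;
      start_total = 0.0;
      for (int j = 0; j < N; ++j) start_total += S[j];
      if (start_total <= 0.0) { collapsed = true; break; }
      cycle_t = 0.0;
      if (n_cycles >= max_cycles) { stalled = true; break; }
    } else if (!R_finite(max_cycle_time) && cycle_t > stall_time) {
      stalled = true; // basic model: community not reaching the threshold
      break;
    }
    if (steps >= max_steps) { stalled = true; break; }
  }

  int ndil = (int) dil_time.size();
  NumericMatrix comp(ndil, N), med(ndil, M);
  for (int k = 0; k < ndil; ++k) {
    for (int j = 0; j < N; ++j)
      comp(k, j) = dil_comp[(size_t) k * N + j];
    for (int i = 0; i < M; ++i)
      med(k, i) = dil_med[(size_t) k * M + i];
  }

  return List::create(
    _["species"] = NumericVector(S.begin(), S.end()),
    _["mediators"] = NumericVector(C.begin(), C.end()),
    _["resource"] = R,
    _["time"] = t,
    _["generations"] = gen_now,
    _["n_cycles"] = n_cycles,
    _["n_steps"] = steps,
    _["n_clamps"] = (double) n_clamps,
    _["stalled"] = stalled,
    _["collapsed"] = collapsed,
    _["dilution_time"] = NumericVector(dil_time.begin(), dil_time.end()),
    _["dilution_generations"] = NumericVector(dil_gen.begin(), dil_gen.end()),
    _["dilution_total"] = NumericVector(dil_total.begin(), dil_total.end()),
    _["dilution_composition"] = comp,
    _["dilution_mediators"] = med,
    _["extinction_species"] = IntegerVector(ext_species.begin(), ext_species.end()),
    _["extinction_cycle"] = IntegerVector(ext_cycle.begin(), ext_cycle.end()));
}
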