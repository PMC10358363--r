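// Direct stochastic (Monte Carlo) simulation of the same network: finite
// ensembles of leaky integrate-and-fire neurons per population, mean-field
// Tsodyks-Markram synapses driven by the instantaneous population rate
// n_fired / (N dt), and external inputs realized as Poisson generators.
//
// Noise: the membrane noise is parameterized so that sigma_m is the
// stationary subthreshold voltage dispersion, dV_noise =
// sigma_m * sqrt(2 dt / tau_M) * xi, which is the scaling assumed by the
// hazard function of the density solver (T = (V_T - V) / (sqrt(2) sigma_m)).
//
// Refractory: for `refr` ms after a spike the neuron integrates its membrane
// equation but cannot fire, matching the density solver where V(t*) evolves
// at all ages while the hazard is masked below the refractory age.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
List mc_forward_cpp(int n_steps, double dt, int n_per_pop,
                    NumericVector Cm, NumericVector gL, NumericVector EL,
                    NumericVector VT, NumericVector Vres,
                    NumericVector sigma, NumericVector refr,
                    NumericVector Iext, IntegerVector pre,
                    IntegerVector post, NumericVector Esyn,
                    NumericVector Uinc, NumericVector tauf,
                    NumericVector taur, NumericVector taud,
                    NumericVector w, NumericVector gmax,
                    NumericMatrix drives, int n_generators,
                    bool heun, bool no_stp, double w_scale,
                    int raster_max) {
  const int K = Cm.size(), M = pre.size(), n_ext = drives.ncol();
  RNGScope rng;

  std::vector<double> V((size_t)K * n_per_pop);
  std::vector<double> rc((size_t)K * n_per_pop); // time since last spike
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < n_per_pop; ++i) {
      V[(size_t)k * n_per_pop + i] = EL[k];
      rc[(size_t)k * n_per_pop + i] = 1e9;
    }
  }
  std::vector<double> u(M, 0.0), x(M, 1.0), y(M, 0.0), g(M, 0.0);
  std::vector<double> nu(K, 0.0), nu_ext(n_ext, 0.0);

  IntegerMatrix counts(n_steps, K);
  NumericMatrix drive_real(n_steps, n_ext);
  std::vector<double> ras_t;
  std::vector<int> ras_id, ras_pop;

  for (int n = 0; n < n_steps; ++n) {
    // realized Poisson drive rates (spikes/ms per generator)
    for (int e = 0; e < n_ext; ++e) {
      double lam = drives(n, e) * dt * n_generators;
      double cnt = (lam > 0.0) ? R::rpois(lam) : 0.0;
      nu_ext[e] = cnt / ((double)n_generators * dt);
      drive_real(n, e) = nu_ext[e];
    }
    // mean-field synapses, one state per pathway
    for (int j = 0; j < M; ++j) {
      double nupre = (pre[j] > 0) ? nu[pre[j] - 1] : nu_ext[-pre[j] - 1];
      double a = w_scale * w[j] * nupre;
      if (no_stp) {
        double y1 = y[j] + dt * (-y[j] / taud[j] + Uinc[j] * a);
        y[j] = (y1 > 0.0) ? y1 : 0.0;
        u[j] = Uinc[j]; x[j] = 1.0;
      } else {
        double uj = u[j], xj = x[j], yj = y[j];
        double uplus = uj + Uinc[j] * (1.0 - uj);
        double u1 = uj + dt * (-uj / tauf[j] + Uinc[j] * (1.0 - uj) * a);
        double x1 = xj + dt * ((1.0 - xj - yj) / taur[j] - uplus * xj * a);
        double y1 = yj + dt * (-yj / taud[j] + uplus * xj * a);
        if (u1 < 0.0) u1 = 0.0; else if (u1 > 1.0) u1 = 1.0;
        if (x1 < 0.0) x1 = 0.0;
        if (y1 < 0.0) y1 = 0.0;
        double s = x1 + y1;
        if (s > 1.0) { x1 /= s; y1 /= s; }
        u[j] = u1; x[j] = x1; y[j] = y1;
      }
      g[j] = gmax[j] * y[j];
    }
    // membrane integration and threshold crossing
    for (int k = 0; k < K; ++k) {
      double gs = 0.0, ge = 0.0;
      for (int j = 0; j < M; ++j) {
        if (post[j] - 1 == k) { gs += g[j]; ge += g[j] * Esyn[j]; }
      }
      double gtot = gL[k] + gs;
      double drive0 = gL[k] * EL[k] + Iext[k] + ge;
      double tauM = Cm[k] / gtot;
      double nstd = sigma[k] * std::sqrt(2.0 * dt / tauM);
      double *Vk = &V[(size_t)k * n_per_pop];
      double *rck = &rc[(size_t)k * n_per_pop];
      int fired = 0;
      for (int i = 0; i < n_per_pop; ++i) {
        double noise = nstd * norm_rand();
        double f0 = (drive0 - gtot * Vk[i]) / Cm[k];
        double Vn;
        if (heun) {
          double Vp = Vk[i] + f0 * dt + noise;
          double f1 = (drive0 - gtot * Vp) / Cm[k];
          Vn = Vk[i] + 0.5 * (f0 + f1) * dt + noise;
        } else {
          Vn = Vk[i] + f0 * dt + noise;
        }
        rck[i] += dt;
        if (Vn > VT[k] && rck[i] >= refr[k]) {
          ++fired;
          Vn = Vres[k];
          rck[i] = 0.0;
          if (i < raster_max) {
            ras_t.push_back((n + 1) * dt);
            ras_id.push_back(i + 1);
            ras_pop.push_back(k + 1);
          }
        }
        Vk[i] = Vn;
      }
      counts(n, k) = fired;
      nu[k] = fired / ((double)n_per_pop * dt);
    }
  }
  return List::create(
      _["counts"] = counts,
      _["drive_rates"] = drive_real,
      _["raster_time"] = NumericVector(ras_t.begin(), ras_t.end()),
      _["raster_id"] = IntegerVector(ras_id.begin(), ras_id.end()),
      _["raster_pop"] = IntegerVector(ras_pop.begin(), ras_pop.end()));
}
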