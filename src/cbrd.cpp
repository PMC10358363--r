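// Conductance-based refractory density (CBRD) network solver.
//
// State per simulated population: density rho(t*) and membrane potential
// V(t*) on an N-point refractory-age grid. State per connection: the
// Tsodyks-Markram triple (u, x, y), rate-driven by the presynaptic
// population rate (mean-field over all synapses of the pathway).
//
// The transport scheme is the flux-limited second-order upwind scheme with a
// monotonized-central limiter. The hazard sink -rho*H removes firing mass,
// which is re-injected exactly at t* = 0; total mass is conserved to
// machine precision because the interior scheme is in flux form and the
// left-boundary inflow equals advective outflow plus the full sink sum.
//
// cbrd_adjoint_cpp computes the gradient of a scalar loss (seeded as
// dL/d nu(t,k)) with respect to all trainable parameters by a hand-derived
// reverse sweep that transposes every assignment of the forward step; the
// forward states are recorded and the nonlinear intermediates are recomputed
// during the backward sweep. Kinked operations (limiter, rectifier, clamps)
// use their a.e. derivative.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif

using namespace Rcpp;

// The advected density tails underflow into subnormals, which are pathologically
// slow; flush them to zero for the duration of a solver call.
struct FlushDenormals {
#ifdef __SSE2__
  unsigned int ftz, daz;
  FlushDenormals() {
    ftz = _MM_GET_FLUSH_ZERO_MODE();
    daz = _MM_GET_DENORMALS_ZERO_MODE();
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~FlushDenormals() {
    _MM_SET_FLUSH_ZERO_MODE(ftz);
    _MM_SET_DENORMALS_ZERO_MODE(daz);
  }
#endif
};

static const double SQRT_2_OVER_PI = 0.7978845608028654;

static inline double limiter(double a, double b) {
  if (a * b <= 0.0) return 0.0;
  double m = std::min(0.5 * std::fabs(a + b),
                      std::min(2.0 * std::fabs(a), 2.0 * std::fabs(b)));
  return (a > 0.0) ? m : -m;
}

// d limiter / d a, d limiter / d b (a.e.; ties resolved in branch order)
static inline void limiter_grad(double a, double b, double &da, double &db) {
  da = 0.0; db = 0.0;
  if (a * b <= 0.0) return;
  double m1 = 0.5 * std::fabs(a + b);
  double m2 = 2.0 * std::fabs(a);
  double m3 = 2.0 * std::fabs(b);
  if (m1 <= m2 && m1 <= m3) { da = 0.5; db = 0.5; }
  else if (m2 <= m3)        { da = 2.0; }
  else                      { db = 2.0; }
}

static inline double hazA(double T) {
  return std::exp(0.0061 - 1.12 * T - 0.257 * T * T - 0.072 * T * T * T -
                  0.0117 * T * T * T * T);
}
static inline double hazA_logderiv(double T) {
  return -1.12 - 0.514 * T - 0.216 * T * T - 0.0468 * T * T * T;
}
// F_T = sqrt(2/pi) exp(-T^2) / (1 + erf(T)). For very negative T the
// denominator underflows; rewriting through the scaled complementary error
// function, F_T = sqrt(2/pi)/erfcx(-T), whose asymptotic series
// erfcx(z) ~ (1 - 1/(2z^2) + 3/(4z^4) - ...)/(z sqrt(pi)) is accurate to
// ~1e-4 at the z = 4 switch and improves rapidly beyond.
static inline double erfcx_S(double z2) {
  // erfcx(z) = S(z) / (z sqrt(pi)) for large z
  double iz2 = 1.0 / z2;
  return 1.0 + iz2 * (-0.5 + iz2 * (0.75 + iz2 * (-1.875 + iz2 * 6.5625)));
}
static inline double erfcx_S_zprime(double z2) {
  // z * dS/dz
  double iz2 = 1.0 / z2;
  return iz2 * (1.0 + iz2 * (-3.0 + iz2 * (11.25 + iz2 * -52.5)));
}
static inline double hazFT(double T) {
  if (T > -4.0) {
    return SQRT_2_OVER_PI * std::exp(-T * T) / (1.0 + std::erf(T));
  }
  return M_SQRT2 * (-T) / erfcx_S(T * T);
}
// In the erf branch, d/dT ln F_T = -2T - sqrt(2) F_T exactly; in the
// asymptotic branch the derivative is that of the implemented
// approximation itself, so adjoint and finite differences see the same
// function.
static inline double hazFT_deriv(double T, double FT) {
  if (T > -4.0) return FT * (-2.0 * T - M_SQRT2 * FT);
  double z2 = T * T;
  double S = erfcx_S(z2);
  return -M_SQRT2 * (S - erfcx_S_zprime(z2)) / (S * S);
}

struct CbrdProblem {
  int n_steps, N, K, M, n_ext;
  double dt, dt_star, cfl;
  std::vector<double> Cm, gL, EL, VT, Vres, sigma, refr, Iext;
  std::vector<int> pre, post;   // pre: >=0 simulated index, <0 external ~(-idx-1)
  std::vector<double> Esyn, Uinc, tauf, taur, taud, w, gmax;
  std::vector<int> nref;        // refractory bins per population
  const double *drives;         // n_steps x n_ext, column-major (R matrix)
  bool no_stp;
};

static CbrdProblem build_problem(
    int n_steps, double dt, int N, double dt_star,
    NumericVector Cm, NumericVector gL, NumericVector EL, NumericVector VT,
    NumericVector Vres, NumericVector sigma, NumericVector refr,
    NumericVector Iext, IntegerVector pre, IntegerVector post,
    NumericVector Esyn, NumericVector Uinc, NumericVector tauf,
    NumericVector taur, NumericVector taud, NumericVector w,
    NumericVector gmax, NumericMatrix drives, bool no_stp) {
  CbrdProblem p;
  p.n_steps = n_steps; p.N = N; p.K = Cm.size(); p.M = pre.size();
  p.n_ext = drives.ncol();
  p.dt = dt; p.dt_star = dt_star; p.cfl = dt / dt_star;
  if (p.cfl > 1.0 + 1e-12) stop("CFL violation: dt/dt_star must be <= 1");
  p.Cm.assign(Cm.begin(), Cm.end());
  p.gL.assign(gL.begin(), gL.end());
  p.EL.assign(EL.begin(), EL.end());
  p.VT.assign(VT.begin(), VT.end());
  p.Vres.assign(Vres.begin(), Vres.end());
  p.sigma.assign(sigma.begin(), sigma.end());
  p.refr.assign(refr.begin(), refr.end());
  p.Iext.assign(Iext.begin(), Iext.end());
  p.Esyn.assign(Esyn.begin(), Esyn.end());
  p.Uinc.assign(Uinc.begin(), Uinc.end());
  p.tauf.assign(tauf.begin(), tauf.end());
  p.taur.assign(taur.begin(), taur.end());
  p.taud.assign(taud.begin(), taud.end());
  p.w.assign(w.begin(), w.end());
  p.gmax.assign(gmax.begin(), gmax.end());
  p.pre.resize(p.M); p.post.resize(p.M);
  for (int j = 0; j < p.M; ++j) {
    // R sends 1-based simulated index or -(1-based external index);
    // keep simulated as 0-based, external as the negative code (column
    // -pre-1 of the drives matrix)
    int pj = pre[j];
    p.pre[j] = (pj > 0) ? pj - 1 : pj;
    p.post[j] = post[j] - 1;
  }
  p.nref.resize(p.K);
  for (int k = 0; k < p.K; ++k) {
    int nr = (int)std::ceil(p.refr[k] / dt_star - 1e-12);
    if (nr < 1) nr = 1; // the age-zero bin is always non-firing
    if (nr > N) nr = N;
    p.nref[k] = nr;
  }
  p.drives = drives.begin();
  p.no_stp = no_stp;
  return p;
}

// One forward step. State arrays are overwritten in place.
// rho, V: K x N (row k contiguous). u, x, y, g: length M. nu: length K.
// scratch holds per-population work arrays.
struct StepScratch {
  std::vector<double> srcR, dVdt, wlR, wlV, znew, vnew, H;
  StepScratch(int N)
      : srcR(N), dVdt(N), wlR(N), wlV(N), znew(N), vnew(N), H(N) {}
};

static void forward_step(const CbrdProblem &p, int n,
                         std::vector<double> &rho, std::vector<double> &V,
                         std::vector<double> &u, std::vector<double> &x,
                         std::vector<double> &y, std::vector<double> &g,
                         std::vector<double> &nu, StepScratch &sc) {
  const int N = p.N, K = p.K, M = p.M;
  const double dt = p.dt, cfl = p.cfl;

  // presynaptic rates and synapse update
  for (int j = 0; j < M; ++j) {
    double nupre = (p.pre[j] >= 0)
        ? nu[p.pre[j]]
        : p.drives[(size_t)n + (size_t)p.n_steps * (-p.pre[j] - 1)];
    double a = p.w[j] * nupre;
    if (p.no_stp) {
      double y1 = y[j] + dt * (-y[j] / p.taud[j] + p.Uinc[j] * a);
      y[j] = (y1 > 0.0) ? y1 : 0.0;
      u[j] = p.Uinc[j]; x[j] = 1.0;
    } else {
      double uj = u[j], xj = x[j], yj = y[j];
      double uplus = uj + p.Uinc[j] * (1.0 - uj);
      double u1 = uj + dt * (-uj / p.tauf[j] + p.Uinc[j] * (1.0 - uj) * a);
      double x1 = xj + dt * ((1.0 - xj - yj) / p.taur[j] - uplus * xj * a);
      double y1 = yj + dt * (-yj / p.taud[j] + uplus * xj * a);
      if (u1 < 0.0) u1 = 0.0; else if (u1 > 1.0) u1 = 1.0;
      if (x1 < 0.0) x1 = 0.0;
      if (y1 < 0.0) y1 = 0.0;
      double s = x1 + y1;
      if (s > 1.0) { x1 /= s; y1 /= s; }
      u[j] = u1; x[j] = x1; y[j] = y1;
    }
    g[j] = p.gmax[j] * y[j];
  }

  for (int k = 0; k < K; ++k) {
    double *rk = &rho[(size_t)k * N];
    double *Vk = &V[(size_t)k * N];
    double gs = 0.0, ge = 0.0;
    for (int j = 0; j < M; ++j) {
      if (p.post[j] == k) { gs += g[j]; ge += g[j] * p.Esyn[j]; }
    }
    double gtot = p.gL[k] + gs;
    double Cm = p.Cm[k];
    double sq2sig = M_SQRT2 * p.sigma[k];
    double drive0 = p.gL[k] * p.EL[k] + p.Iext[k] + ge;
    double sink_sum = 0.0;
    for (int i = 0; i < N; ++i) {
      double dv = (drive0 - gtot * Vk[i]) / Cm;
      sc.dVdt[i] = dv;
      double Hi = 0.0;
      if (i >= p.nref[k]) {
        double T = (p.VT[k] - Vk[i]) / sq2sig;
        double A = hazA(T);
        double FT = hazFT(T);
        double drift = (dv > 0.0) ? dv : 0.0;
        Hi = A * gtot / Cm + 2.0 * drift / sq2sig * FT;
      }
      sc.H[i] = Hi;
      // exponential sink: removes rho (1 - e^{-H dt}) per step, which is the
      // exact single-bin solution and stays stable for arbitrarily large H
      sc.srcR[i] = rk[i] * std::expm1(-Hi * dt) / dt;
      sink_sum += sc.srcR[i];
    }
    // limited slopes
    sc.wlR[0] = 0.0; sc.wlV[0] = 0.0;
    for (int i = 1; i < N - 1; ++i) {
      sc.wlR[i] = limiter(rk[i + 1] - rk[i], rk[i] - rk[i - 1]);
      sc.wlV[i] = limiter(Vk[i + 1] - Vk[i], Vk[i] - Vk[i - 1]);
    }
    // interior + right boundary
    for (int i = 1; i < N - 1; ++i) {
      sc.znew[i] = rk[i] - cfl * (rk[i] - rk[i - 1] +
                   0.5 * (1.0 - cfl) * (sc.wlR[i] - sc.wlR[i - 1])) +
                   dt * sc.srcR[i];
      sc.vnew[i] = Vk[i] - cfl * (Vk[i] - Vk[i - 1] +
                   0.5 * (1.0 - cfl) * (sc.wlV[i] - sc.wlV[i - 1])) +
                   dt * sc.dVdt[i];
    }
    sc.znew[N - 1] = rk[N - 1] +
        cfl * (rk[N - 2] + 0.5 * (1.0 - cfl) * sc.wlR[N - 2]) +
        dt * sc.srcR[N - 1];
    sc.vnew[N - 1] = Vk[N - 1] + dt * sc.dVdt[N - 1];
    // left boundary: re-inject fired mass, reset potential
    sc.znew[0] = rk[0] - cfl * rk[0] - dt * sink_sum;
    sc.vnew[0] = p.Vres[k];
    for (int i = 0; i < N; ++i) { rk[i] = sc.znew[i]; Vk[i] = sc.vnew[i]; }
    nu[k] = rk[0];
  }
}

static void init_state(const CbrdProblem &p, std::vector<double> &rho,
                       std::vector<double> &V, std::vector<double> &u,
                       std::vector<double> &x, std::vector<double> &y,
                       std::vector<double> &nu) {
  rho.assign((size_t)p.K * p.N, 0.0);
  V.assign((size_t)p.K * p.N, 0.0);
  for (int k = 0; k < p.K; ++k) {
    rho[(size_t)k * p.N + p.N - 1] = 1.0 / p.dt_star;
    for (int i = 0; i < p.N; ++i) V[(size_t)k * p.N + i] = p.EL[k];
  }
  u.assign(p.M, 0.0);
  x.assign(p.M, 1.0);
  y.assign(p.M, 0.0);
  nu.assign(p.K, 0.0);
}

// [[Rcpp::export]]
List cbrd_forward_cpp(int n_steps, double dt, int N, double dt_star,
                      NumericVector Cm, NumericVector gL, NumericVector EL,
                      NumericVector VT, NumericVector Vres,
                      NumericVector sigma, NumericVector refr,
                      NumericVector Iext, IntegerVector pre,
                      IntegerVector post, NumericVector Esyn,
                      NumericVector Uinc, NumericVector tauf,
                      NumericVector taur, NumericVector taud,
                      NumericVector w, NumericVector gmax,
                      NumericMatrix drives, bool no_stp, bool record_g) {
  FlushDenormals ftz_guard;
  CbrdProblem p = build_problem(n_steps, dt, N, dt_star, Cm, gL, EL, VT, Vres,
                                sigma, refr, Iext, pre, post, Esyn, Uinc,
                                tauf, taur, taud, w, gmax, drives, no_stp);
  std::vector<double> rho, V, u, x, y, nu;
  init_state(p, rho, V, u, x, y, nu);
  std::vector<double> g(p.M, 0.0);
  StepScratch sc(p.N);

  NumericMatrix nu_out(n_steps, p.K);
  NumericMatrix g_out(record_g ? n_steps : 0, record_g ? p.M : 0);
  NumericMatrix mass_out(n_steps, p.K);

  for (int n = 0; n < n_steps; ++n) {
    forward_step(p, n, rho, V, u, x, y, g, nu, sc);
    for (int k = 0; k < p.K; ++k) {
      nu_out(n, k) = nu[k];
      double mass = 0.0;
      for (int i = 0; i < p.N; ++i) mass += rho[(size_t)k * p.N + i];
      mass_out(n, k) = mass * p.dt_star;
    }
    if (record_g) for (int j = 0; j < p.M; ++j) g_out(n, j) = g[j];
    if ((n & 127) == 0) {
      for (int k = 0; k < p.K; ++k) {
        if (!std::isfinite(nu[k])) {
          stop("CBRD state became non-finite at step %d (population %d)",
               n + 1, k + 1);
        }
      }
    }
  }
  return List::create(_["nu"] = nu_out, _["g"] = g_out,
                      _["mass"] = mass_out);
}

// Forward with state recording + reverse (adjoint) sweep.
// The simulation loss sum_k sum_t (log1p(target) - log1p(rate))^2 (rates in
// spikes/s) is evaluated on the window of steps [win_start, win_start +
// nrow(target)) and seeds the reverse sweep; `target` is that window's
// target-rate matrix (spikes/s).
// [[Rcpp::export]]
List cbrd_adjoint_cpp(int n_steps, double dt, int N, double dt_star,
                      NumericVector Cm, NumericVector gL, NumericVector EL,
                      NumericVector VT, NumericVector Vres,
                      NumericVector sigma, NumericVector refr,
                      NumericVector Iext, IntegerVector pre,
                      IntegerVector post, NumericVector Esyn,
                      NumericVector Uinc, NumericVector tauf,
                      NumericVector taur, NumericVector taud,
                      NumericVector w, NumericVector gmax,
                      NumericMatrix drives, bool no_stp,
                      NumericMatrix target, int win_start) {
  FlushDenormals ftz_guard;
  CbrdProblem p = build_problem(n_steps, dt, N, dt_star, Cm, gL, EL, VT, Vres,
                                sigma, refr, Iext, pre, post, Esyn, Uinc,
                                tauf, taur, taud, w, gmax, drives, no_stp);
  if (win_start < 0 || win_start + target.nrow() > n_steps) {
    stop("loss window out of range");
  }
  const int K = p.K, M = p.M;
  const double cfl = p.cfl;
  std::vector<double> rho, V, u, x, y, nu;
  init_state(p, rho, V, u, x, y, nu);
  std::vector<double> g(M, 0.0);
  StepScratch sc(N);

  // record pre-step states for every step
  size_t frame = (size_t)K * N;
  std::vector<double> rho_h((size_t)n_steps * frame);
  std::vector<double> V_h((size_t)n_steps * frame);
  std::vector<double> u_h((size_t)n_steps * M), x_h((size_t)n_steps * M),
      y_h((size_t)n_steps * M), nu_h((size_t)n_steps * K);

  NumericMatrix nu_out(n_steps, K);
  for (int n = 0; n < n_steps; ++n) {
    std::copy(rho.begin(), rho.end(), rho_h.begin() + (size_t)n * frame);
    std::copy(V.begin(), V.end(), V_h.begin() + (size_t)n * frame);
    std::copy(u.begin(), u.end(), u_h.begin() + (size_t)n * M);
    std::copy(x.begin(), x.end(), x_h.begin() + (size_t)n * M);
    std::copy(y.begin(), y.end(), y_h.begin() + (size_t)n * M);
    std::copy(nu.begin(), nu.end(), nu_h.begin() + (size_t)n * K);
    forward_step(p, n, rho, V, u, x, y, g, nu, sc);
    for (int k = 0; k < K; ++k) {
      nu_out(n, k) = nu[k];
      if ((n & 127) == 0 && !std::isfinite(nu[k])) {
        stop("CBRD state became non-finite at step %d (population %d)",
             n + 1, k + 1);
      }
    }
  }

  // loss on the window and its seed dL/dnu (nu in spikes/ms)
  double L_sim = 0.0;
  std::vector<double> seed((size_t)n_steps * K, 0.0);
  for (int k = 0; k < K; ++k) {
    for (int t = 0; t < target.nrow(); ++t) {
      int n = win_start + t;
      double s = nu_out(n, k) * 1000.0;
      if (s < 0.0) s = 0.0;
      double diff = std::log1p(target(t, k)) - std::log1p(s);
      L_sim += diff * diff;
      if (nu_out(n, k) * 1000.0 >= 0.0) {
        seed[(size_t)n * K + k] = -2.0 * diff / (1.0 + s) * 1000.0;
      }
    }
  }

  // adjoints of the post-step state
  std::vector<double> Ar((size_t)K * N, 0.0), Av((size_t)K * N, 0.0);
  std::vector<double> Au(M, 0.0), Ax(M, 0.0), Ay(M, 0.0);
  // parameter gradients
  std::vector<double> dUinc(M, 0.0), dtauf(M, 0.0), dtaur(M, 0.0),
      dtaud(M, 0.0), dw(M, 0.0), dgmax(M, 0.0), dIext(K, 0.0);

  std::vector<double> rbp(N), vbp(N), srcRb(N), srcVb(N), wlbR(N), wlbV(N);
  std::vector<double> gb(M);
  std::vector<double> u_new(M), x_new(M), y_new(M);
  std::vector<double> nupre_v(M), a_v(M);
  std::vector<double> u1_v(M), x1_v(M), y1_v(M); // pre-clamp Euler results

  for (int n = n_steps - 1; n >= 0; --n) {
    const double *rho0 = &rho_h[(size_t)n * frame];
    const double *V0 = &V_h[(size_t)n * frame];
    const double *u0 = &u_h[(size_t)n * M];
    const double *x0 = &x_h[(size_t)n * M];
    const double *y0 = &y_h[(size_t)n * M];
    const double *nu0 = &nu_h[(size_t)n * K];

    // ---- recompute synapse intermediates of step n ----
    for (int j = 0; j < M; ++j) {
      double nupre = (p.pre[j] >= 0)
          ? nu0[p.pre[j]]
          : p.drives[(size_t)n + (size_t)p.n_steps * (-p.pre[j] - 1)];
      nupre_v[j] = nupre;
      double a = p.w[j] * nupre;
      a_v[j] = a;
      if (p.no_stp) {
        double y1 = y0[j] + dt * (-y0[j] / p.taud[j] + p.Uinc[j] * a);
        y1_v[j] = y1;
        y_new[j] = (y1 > 0.0) ? y1 : 0.0;
        u_new[j] = p.Uinc[j]; x_new[j] = 1.0;
      } else {
        double uj = u0[j], xj = x0[j], yj = y0[j];
        double uplus = uj + p.Uinc[j] * (1.0 - uj);
        double u1 = uj + dt * (-uj / p.tauf[j] + p.Uinc[j] * (1.0 - uj) * a);
        double x1 = xj + dt * ((1.0 - xj - yj) / p.taur[j] - uplus * xj * a);
        double y1 = yj + dt * (-yj / p.taud[j] + uplus * xj * a);
        u1_v[j] = u1; x1_v[j] = x1; y1_v[j] = y1;
        double u2 = (u1 < 0.0) ? 0.0 : ((u1 > 1.0) ? 1.0 : u1);
        double x2 = (x1 < 0.0) ? 0.0 : x1;
        double y2 = (y1 < 0.0) ? 0.0 : y1;
        double s = x2 + y2;
        if (s > 1.0) { x2 /= s; y2 /= s; }
        u_new[j] = u2; x_new[j] = x2; y_new[j] = y2;
      }
      gb[j] = 0.0;
    }

    // ---- per-population transpose of transport + hazard + currents ----
    for (int k = 0; k < K; ++k) {
      const double *rk = rho0 + (size_t)k * N;
      const double *Vk = V0 + (size_t)k * N;
      double *Ark = &Ar[(size_t)k * N];
      double *Avk = &Av[(size_t)k * N];

      // loss seed on nu(n, k) = rho_new[0]
      Ark[0] += seed[(size_t)n * K + k];

      // recompute currents / hazard / slopes of step n for population k
      double gs = 0.0, ge = 0.0;
      for (int j = 0; j < M; ++j) {
        if (p.post[j] == k) {
          double gj = p.gmax[j] * y_new[j];
          gs += gj; ge += gj * p.Esyn[j];
        }
      }
      double gtot = p.gL[k] + gs;
      double Cm = p.Cm[k];
      double sq2sig = M_SQRT2 * p.sigma[k];
      double drive0 = p.gL[k] * p.EL[k] + p.Iext[k] + ge;
      for (int i = 0; i < N; ++i) {
        sc.dVdt[i] = (drive0 - gtot * Vk[i]) / Cm;
        double Hi = 0.0;
        if (i >= p.nref[k]) {
          double T = (p.VT[k] - Vk[i]) / sq2sig;
          double drift = (sc.dVdt[i] > 0.0) ? sc.dVdt[i] : 0.0;
          Hi = hazA(T) * gtot / Cm + 2.0 * drift / sq2sig * hazFT(T);
        }
        sc.H[i] = Hi;
        sc.srcR[i] = rk[i] * std::expm1(-Hi * dt) / dt;
      }
      sc.wlR[0] = 0.0; sc.wlV[0] = 0.0;
      for (int i = 1; i < N - 1; ++i) {
        sc.wlR[i] = limiter(rk[i + 1] - rk[i], rk[i] - rk[i - 1]);
        sc.wlV[i] = limiter(Vk[i + 1] - Vk[i], Vk[i] - Vk[i - 1]);
      }

      std::fill(rbp.begin(), rbp.end(), 0.0);
      std::fill(vbp.begin(), vbp.end(), 0.0);
      std::fill(srcRb.begin(), srcRb.end(), 0.0);
      std::fill(srcVb.begin(), srcVb.end(), 0.0);
      std::fill(wlbR.begin(), wlbR.end(), 0.0);
      std::fill(wlbV.begin(), wlbV.end(), 0.0);

      // left boundary: rho_new[0] = (1-cfl) rho[0] - dt * sum_i srcR[i]
      //                V_new[0] = Vres (kills the V adjoint at i = 0)
      double Ar0 = Ark[0];
      rbp[0] += (1.0 - cfl) * Ar0;
      for (int i = 0; i < N; ++i) srcRb[i] -= dt * Ar0;
      // interior
      for (int i = 1; i < N - 1; ++i) {
        double ari = Ark[i], avi = Avk[i];
        rbp[i] += (1.0 - cfl) * ari;
        rbp[i - 1] += cfl * ari;
        wlbR[i] += -0.5 * cfl * (1.0 - cfl) * ari;
        wlbR[i - 1] += 0.5 * cfl * (1.0 - cfl) * ari;
        srcRb[i] += dt * ari;
        vbp[i] += (1.0 - cfl) * avi;
        vbp[i - 1] += cfl * avi;
        wlbV[i] += -0.5 * cfl * (1.0 - cfl) * avi;
        wlbV[i - 1] += 0.5 * cfl * (1.0 - cfl) * avi;
        srcVb[i] += dt * avi;
      }
      // right boundary
      {
        double arN = Ark[N - 1], avN = Avk[N - 1];
        rbp[N - 1] += arN;
        rbp[N - 2] += cfl * arN;
        wlbR[N - 2] += 0.5 * cfl * (1.0 - cfl) * arN;
        srcRb[N - 1] += dt * arN;
        vbp[N - 1] += avN;
        srcVb[N - 1] += dt * avN;
      }
      // limiter transpose
      for (int i = 1; i < N - 1; ++i) {
        if (wlbR[i] != 0.0) {
          double da, db;
          limiter_grad(rk[i + 1] - rk[i], rk[i] - rk[i - 1], da, db);
          rbp[i + 1] += da * wlbR[i];
          rbp[i] += (db - da) * wlbR[i];
          rbp[i - 1] -= db * wlbR[i];
        }
        if (wlbV[i] != 0.0) {
          double da, db;
          limiter_grad(Vk[i + 1] - Vk[i], Vk[i] - Vk[i - 1], da, db);
          vbp[i + 1] += da * wlbV[i];
          vbp[i] += (db - da) * wlbV[i];
          vbp[i - 1] -= db * wlbV[i];
        }
      }
      // sources and hazard
      double geb = 0.0, gtotb = 0.0;
      for (int i = 0; i < N; ++i) {
        // srcR[i] = rho[i] expm1(-H[i] dt) / dt
        double Hb = -rk[i] * std::exp(-sc.H[i] * dt) * srcRb[i];
        rbp[i] += std::expm1(-sc.H[i] * dt) / dt * srcRb[i];
        double dVdtb = srcVb[i];
        if (i >= p.nref[k]) {
          double T = (p.VT[k] - Vk[i]) / sq2sig;
          double A = hazA(T);
          double FT = hazFT(T);
          double drift = (sc.dVdt[i] > 0.0) ? sc.dVdt[i] : 0.0;
          // H = A gtot / Cm + 2 relu(dVdt) FT / sq2sig
          double Ab = Hb * gtot / Cm;
          gtotb += Hb * A / Cm;
          if (sc.dVdt[i] > 0.0) dVdtb += Hb * 2.0 * FT / sq2sig;
          double FTb = Hb * 2.0 * drift / sq2sig;
          double Tb = Ab * A * hazA_logderiv(T) + FTb * hazFT_deriv(T, FT);
          vbp[i] += -Tb / sq2sig;
        }
        // dVdt = (gL EL + Iext + ge - gtot V[i]) / Cm
        dIext[k] += dVdtb / Cm;
        geb += dVdtb / Cm;
        gtotb += -Vk[i] / Cm * dVdtb;
        vbp[i] += -gtot / Cm * dVdtb;
      }
      for (int j = 0; j < M; ++j) {
        if (p.post[j] == k) gb[j] += gtotb + p.Esyn[j] * geb;
      }
      // commit pre-step adjoints
      for (int i = 0; i < N; ++i) { Ark[i] = rbp[i]; Avk[i] = vbp[i]; }
    }

    // ---- synapse transpose ----
    for (int j = 0; j < M; ++j) {
      double Aynew = Ay[j] + p.gmax[j] * gb[j];
      dgmax[j] += y_new[j] * gb[j];
      double ab = 0.0;
      if (p.no_stp) {
        double Ay1 = (y1_v[j] > 0.0) ? Aynew : 0.0;
        Ay[j] = Ay1 * (1.0 - dt / p.taud[j]);
        dUinc[j] += Ay1 * dt * a_v[j];
        dtaud[j] += Ay1 * dt * y0[j] / (p.taud[j] * p.taud[j]);
        ab = Ay1 * dt * p.Uinc[j];
        // frozen variant: u_new = Uinc (constant), x_new = 1
        dUinc[j] += Au[j];
        Au[j] = 0.0; Ax[j] = 0.0;
      } else {
        double uj = u0[j], xj = x0[j], yj = y0[j];
        double a = a_v[j];
        double uplus = uj + p.Uinc[j] * (1.0 - uj);
        double Aunew = Au[j], Axnew = Ax[j];
        // projection transpose
        double x2 = (x1_v[j] < 0.0) ? 0.0 : x1_v[j];
        double y2 = (y1_v[j] < 0.0) ? 0.0 : y1_v[j];
        double s = x2 + y2;
        double Ax2, Ay2;
        if (s > 1.0) {
          Ax2 = (Axnew - Aynew) * y2 / (s * s);
          Ay2 = (Aynew - Axnew) * x2 / (s * s);
        } else { Ax2 = Axnew; Ay2 = Aynew; }
        // clamp transpose
        double Au1 = (u1_v[j] > 0.0 && u1_v[j] < 1.0) ? Aunew : 0.0;
        double Ax1 = (x1_v[j] > 0.0) ? Ax2 : 0.0;
        double Ay1 = (y1_v[j] > 0.0) ? Ay2 : 0.0;
        // Euler transpose
        double Auplus = Ax1 * (-dt * xj * a) + Ay1 * (dt * xj * a);
        Au[j] = Au1 * (1.0 - dt / p.tauf[j] - dt * p.Uinc[j] * a) +
                Auplus * (1.0 - p.Uinc[j]);
        Ax[j] = Ax1 * (1.0 - dt / p.taur[j] - dt * uplus * a) +
                Ay1 * (dt * uplus * a);
        Ay[j] = Ax1 * (-dt / p.taur[j]) + Ay1 * (1.0 - dt / p.taud[j]);
        dUinc[j] += Au1 * dt * (1.0 - uj) * a + Auplus * (1.0 - uj);
        dtauf[j] += Au1 * dt * uj / (p.tauf[j] * p.tauf[j]);
        dtaur[j] += -Ax1 * dt * (1.0 - xj - yj) / (p.taur[j] * p.taur[j]);
        dtaud[j] += Ay1 * dt * yj / (p.taud[j] * p.taud[j]);
        ab = Au1 * dt * p.Uinc[j] * (1.0 - uj) +
             Ax1 * (-dt * uplus * xj) + Ay1 * (dt * uplus * xj);
      }
      // a = w * nupre
      dw[j] += ab * nupre_v[j];
      if (p.pre[j] >= 0) {
        Ar[(size_t)p.pre[j] * N] += ab * p.w[j];
      }
    }
  }

  return List::create(
      _["nu"] = nu_out,
      _["L_sim"] = L_sim,
      _["dUinc"] = NumericVector(dUinc.begin(), dUinc.end()),
      _["dtauf"] = NumericVector(dtauf.begin(), dtauf.end()),
      _["dtaur"] = NumericVector(dtaur.begin(), dtaur.end()),
      _["dtaud"] = NumericVector(dtaud.begin(), dtaud.end()),
      _["dw"] = NumericVector(dw.begin(), dw.end()),
      _["dgmax"] = NumericVector(dgmax.begin(), dgmax.end()),
      _["dIext"] = NumericVector(dIext.begin(), dIext.end()));
}
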