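#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integrator for 1d overdamped particles driven by
// Ornstein-Uhlenbeck propulsion noise:
//   x' = x + dt * (-grad phi(x) + eta),   eta updated by the exact OU map.
// Pair forms: 0 = none, 1 = inverse-power x^-12 (minimum image, cutoff),
//             2 = harmonic ring (fixed index topology, rest length a0).
// External forms: 0 = none, 1 = x^2, 2 = x^4.
// Uses R's RNG so set.seed() gives bit-reproducible trajectories.

static inline double wrap_pos(double x, double L) {
  double w = x - L * std::floor(x / L);
  if (w >= L) w -= L;  // guard against floor rounding at the boundary
  return w;
}

struct ForceResult {
  double min_gap;
};

// Pair forces for the inverse-power potential using a sorted-order scan:
// in 1d all pairs within the minimum-image cap are contiguous in sorted
// order, so each pair is visited exactly once via forward gaps < L/2.
static ForceResult inv12_forces(const std::vector<double>& x,
                                const std::vector<int>& ord,
                                double L, bool periodic,
                                double eps, double cutoff,
                                std::vector<double>& F) {
  const int N = (int)x.size();
  std::fill(F.begin(), F.end(), 0.0);
  ForceResult res;
  res.min_gap = R_PosInf;
  if (N < 2) return res;
  double cap = cutoff;
  if (periodic) cap = std::min(cap, 0.5 * L * (1.0 - 1e-12));
  for (int a = 0; a < N; ++a) {
    const int i = ord[a];
    const double xa = x[i];
    for (int bb = a + 1; bb < a + N; ++bb) {
      const int b = (bb < N) ? bb : bb - N;
      if (!periodic && bb >= N) break;
      const int j = ord[b];
      double g = x[j] - xa;
      if (periodic && g < 0) g += L;
      if (bb == a + 1 && g < res.min_gap) res.min_gap = g;
      if (g > cap) break;
      if (g < 1e-12)
        stop("degenerate configuration: coincident particles (gap < 1e-12)");
      const double fmag = 12.0 * eps * std::pow(g, -13.0);
      F[i] -= fmag;
      F[j] += fmag;
    }
  }
  return res;
}

static ForceResult ring_forces(const std::vector<double>& x,
                               double L, bool periodic,
                               double k, double a0,
                               std::vector<double>& F) {
  const int N = (int)x.size();
  std::fill(F.begin(), F.end(), 0.0);
  ForceResult res;
  res.min_gap = R_PosInf;
  for (int i = 0; i < N; ++i) {
    const int j = (i + 1 == N) ? 0 : i + 1;
    if (!periodic && j == 0) break;
    double d = x[j] - x[i];
    if (periodic) {
      d -= L * std::floor(d / L);  // forward gap in [0, L)
    }
    if (std::abs(d) < res.min_gap) res.min_gap = std::abs(d);
    const double t = k * (d - a0);
    F[i] += t;
    F[j] -= t;
  }
  return res;
}

static void external_forces(const std::vector<double>& x, int ext_form,
                            std::vector<double>& F) {
  const int N = (int)x.size();
  if (ext_form == 1) {
    for (int i = 0; i < N; ++i) F[i] += -2.0 * x[i];
  } else if (ext_form == 2) {
    for (int i = 0; i < N; ++i) F[i] += -4.0 * x[i] * x[i] * x[i];
  }
}

// Repair a nearly sorted order index by insertion sort (O(N + swaps)).
static void repair_order(const std::vector<double>& x, std::vector<int>& ord) {
  const int N = (int)ord.size();
  for (int a = 1; a < N; ++a) {
    const int key = ord[a];
    const double xv = x[key];
    int b = a - 1;
    while (b >= 0 && x[ord[b]] > xv) {
      ord[b + 1] = ord[b];
      --b;
    }
    ord[b + 1] = key;
  }
}

// [[Rcpp::export]]
List gcn_integrate(NumericVector x0, NumericVector eta0,
                   double L, double dt, double D, double tau,
                   int pair_form, double eps, double cutoff,
                   double spring_k, double rest_length,
                   int ext_form,
                   int n_equil_steps, int n_samples, int sample_interval) {
  const int N = x0.size();
  if (eta0.size() != N) stop("x0 and eta0 must have the same length");
  if (dt <= 0) stop("dt must be positive");
  if (D < 0) stop("D must be non-negative");
  if (tau <= 0) stop("tau must be positive");
  if (n_samples < 1) stop("need at least one sample");
  if (sample_interval < 1) stop("sample_interval must be >= 1");

  const bool periodic = R_finite(L);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> eta(eta0.begin(), eta0.end());
  std::vector<double> F(N), v(N);

  if (periodic)
    for (int i = 0; i < N; ++i) x[i] = wrap_pos(x[i], L);

  std::vector<int> ord(N);
  for (int i = 0; i < N; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&x](int a, int b) { return x[a] < x[b]; });

  // exact OU update coefficients; tau = Inf freezes the noise
  double mu = 1.0, sig = 0.0;
  if (R_finite(tau)) {
    mu = std::exp(-dt / tau);
    sig = std::sqrt(D / tau * (1.0 - mu * mu));
  }

  NumericMatrix pos_out(n_samples, N), eta_out(n_samples, N),
      vel_out(n_samples, N);
  NumericVector t_out(n_samples);

  const long total_steps =
      (long)n_equil_steps + (long)n_samples * sample_interval;
  long rec_next = n_equil_steps;  // record at the start of each interval
  int rec = 0;
  double t = 0.0;

  for (long step = 0; step < total_steps + 1; ++step) {
    ForceResult fr;
    fr.min_gap = R_PosInf;
    if (pair_form == 1)
      fr = inv12_forces(x, ord, L, periodic, eps, cutoff, F);
    else if (pair_form == 2)
      fr = ring_forces(x, L, periodic, spring_k, rest_length, F);
    else
      std::fill(F.begin(), F.end(), 0.0);
    external_forces(x, ext_form, F);

    double vmax = 0.0;
    for (int i = 0; i < N; ++i) {
      v[i] = F[i] + eta[i];
      const double av = std::abs(v[i]);
      if (av > vmax) vmax = av;
    }

    if (rec < n_samples && step == rec_next) {
      for (int i = 0; i < N; ++i) {
        pos_out(rec, i) = x[i];
        eta_out(rec, i) = eta[i];
        vel_out(rec, i) = v[i];
      }
      t_out[rec] = t;
      ++rec;
      rec_next += sample_interval;
    }
    if (rec >= n_samples) break;

    if (pair_form == 1 && dt * vmax > 0.5 * fr.min_gap)
      stop("stiffness: per-step displacement (%g) exceeds half the minimum "
           "interparticle gap (%g); reduce dt", dt * vmax, fr.min_gap);

    for (int i = 0; i < N; ++i) {
      x[i] += dt * v[i];
      if (periodic) x[i] = wrap_pos(x[i], L);
      if (!R_finite(x[i]))
        stop("non-finite coordinate at t = %g; simulation aborted", t);
    }
    if (sig > 0.0 || mu != 1.0) {
      for (int i = 0; i < N; ++i) eta[i] = mu * eta[i] + sig * norm_rand();
    }
    if (pair_form == 1) repair_order(x, ord);
    t += dt;

    if ((step & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["positions"] = pos_out, _["noises"] = eta_out,
                      _["velocities"] = vel_out, _["time"] = t_out);
}
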