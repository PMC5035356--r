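#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Velocity-Verlet MD core over harmonic-tether / elastic-network potentials.
// Units: A, fs, amu, kcal/mol, K.  Accelerations apply the kcal/mol ->
// amu A^2/fs^2 conversion exactly once.  Randomness comes from R's RNG
// (norm_rand) so set.seed() in R fully determines a run.

static const double KB = 0.0019872041;   // kcal/(mol K)
static const double CE = 4.184e-4;       // kcal/mol -> amu A^2/fs^2

// force (kcal/mol/A) into f, returns potential energy (kcal/mol)
static double compute_force(const std::vector<double>& x,
                            std::vector<double>& f,
                            int n, int pot_type, double k,
                            const std::vector<double>& ref,
                            const IntegerMatrix& pairs,
                            const NumericVector& r0) {
  std::fill(f.begin(), f.end(), 0.0);
  double pe = 0.0;
  if (pot_type == 0) {          // harmonic tether to reference
    for (int i = 0; i < 3 * n; ++i) {
      double d = x[i] - ref[i];
      f[i] = -k * d;
      pe += 0.5 * k * d * d;
    }
  } else {                      // elastic network between reference contacts
    int m = pairs.nrow();
    for (int p = 0; p < m; ++p) {
      int i = pairs(p, 0), j = pairs(p, 1);
      double dx = x[3 * j] - x[3 * i];
      double dy = x[3 * j + 1] - x[3 * i + 1];
      double dz = x[3 * j + 2] - x[3 * i + 2];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dev = d - r0[p];
      pe += 0.5 * k * dev * dev;
      double fac = -k * dev / d;   // force on j along r_ij
      f[3 * j]     += fac * dx;  f[3 * i]     -= fac * dx;
      f[3 * j + 1] += fac * dy;  f[3 * i + 1] -= fac * dy;
      f[3 * j + 2] += fac * dz;  f[3 * i + 2] -= fac * dz;
    }
  }
  return pe;
}

// [[Rcpp::export]]
List integrate_cpp(NumericMatrix coords, NumericMatrix vels,
                   NumericVector masses, int pot_type, double k,
                   NumericMatrix ref_coords, IntegerMatrix pairs,
                   NumericVector r0, double dt, int n_steps,
                   int save_interval, int thermostat, double T0,
                   double tau, double gamma, bool heat,
                   double heat_rate_K_fs, double heat_target) {
  const int n = coords.nrow();
  std::vector<double> x(3 * n), v(3 * n), f(3 * n), a(3 * n), ref(3 * n);
  std::vector<double> inv_m(n), sig(n);
  for (int i = 0; i < n; ++i) {
    inv_m[i] = CE / masses[i];
    for (int d = 0; d < 3; ++d) {
      x[3 * i + d] = coords(i, d);
      v[3 * i + d] = vels(i, d);
      ref[3 * i + d] = ref_coords(i, d);
    }
  }

  const int n_save = n_steps / save_interval;
  NumericVector frames(Dimension(n_save, n, 3));
  NumericMatrix log(n_save, 5);   // step, time_fs, kinetic_T, PE, total E

  double pe = compute_force(x, f, n, pot_type, k, ref, pairs, r0);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) a[3 * i + d] = f[3 * i + d] * inv_m[i];

  const double c1 = (thermostat == 2) ? std::exp(-gamma * dt) : 0.0;
  const double c2 = (thermostat == 2) ? std::sqrt(1.0 - c1 * c1) : 0.0;

  int saved = 0;
  for (int step = 1; step <= n_steps; ++step) {
    double t_fs = step * dt;
    double target = T0;
    if (heat) {
      target = heat_rate_K_fs * t_fs;
      if (target > heat_target) target = heat_target;
    }

    if (thermostat == 2) {
      // BAOAB: exact Ornstein-Uhlenbeck substep between half drifts
      double kT = KB * target * CE;
      for (int i = 0; i < n; ++i) sig[i] = std::sqrt(kT / masses[i]);
      for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * a[i];
      for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          v[3 * i + d] = c1 * v[3 * i + d] + c2 * sig[i] * norm_rand();
      for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
      pe = compute_force(x, f, n, pot_type, k, ref, pairs, r0);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) a[3 * i + d] = f[3 * i + d] * inv_m[i];
      for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * a[i];
    } else {
      // velocity Verlet (NVE / Berendsen)
      for (int i = 0; i < 3 * n; ++i) {
        v[i] += 0.5 * dt * a[i];
        x[i] += dt * v[i];
      }
      pe = compute_force(x, f, n, pot_type, k, ref, pairs, r0);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) {
          a[3 * i + d] = f[3 * i + d] * inv_m[i];
          v[3 * i + d] += 0.5 * dt * a[3 * i + d];
        }
      if (thermostat == 1) {
        double ke = 0.0;
        for (int i = 0; i < n; ++i)
          for (int d = 0; d < 3; ++d)
            ke += 0.5 * masses[i] * v[3 * i + d] * v[3 * i + d];
        ke /= CE;
        double Tinst = 2.0 * ke / (3.0 * n * KB);
        if (Tinst > 0) {
          double lam = std::sqrt(1.0 + (dt / tau) * (target / Tinst - 1.0));
          for (int i = 0; i < 3 * n; ++i) v[i] *= lam;
        }
      }
    }

    if (step % save_interval == 0) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          ke += 0.5 * masses[i] * v[3 * i + d] * v[3 * i + d];
      ke /= CE;
      for (int i = 0; i < 3 * n; ++i) {
        if (!std::isfinite(x[i]))
          stop("non-finite coordinate at step %d", step);
      }
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          frames[saved + n_save * (i + n * d)] = x[3 * i + d];
      log(saved, 0) = step;
      log(saved, 1) = t_fs;
      log(saved, 2) = 2.0 * ke / (3.0 * n * KB);
      log(saved, 3) = pe;
      log(saved, 4) = pe + ke;
      ++saved;
    }
  }

  NumericMatrix fin_x(n, 3), fin_v(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      fin_x(i, d) = x[3 * i + d];
      fin_v(i, d) = v[3 * i + d];
    }
  return List::create(_["frames"] = frames, _["log"] = log,
                      _["final_coords"] = fin_x, _["final_vels"] = fin_v);
}
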