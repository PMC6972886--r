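#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Model surfaces are encoded by an integer form code plus a parameter vector
// so the propagator never calls back into R:
//   form 1: double well  V = h[(x/a)^2 - 1]^2 + k y^2 / 2 + tilt * x
//           params = (h, a, k, tilt)
//   form 2: harmonic     V = kx x^2 / 2 + ky y^2 / 2
//           params = (kx, ky)

static inline double surf_value(int form, const double* p, double x, double y) {
  if (form == 1) {
    const double u = (x / p[1]) * (x / p[1]) - 1.0;
    return p[0] * u * u + 0.5 * p[2] * y * y + p[3] * x;
  }
  return 0.5 * p[0] * x * x + 0.5 * p[1] * y * y;
}

static inline void surf_grad(int form, const double* p, double x, double y,
                             double& gx, double& gy) {
  if (form == 1) {
    const double u = x / p[1];
    gx = 4.0 * p[0] * u * (u * u - 1.0) / p[1] + p[3];
    gy = p[2] * y;
  } else {
    gx = p[0] * x;
    gy = p[1] * y;
  }
}

// Bias value and gradient from deposited hills at (x, y).  Hills are rows of
// (center1, center2, sigma1, sigma2, height); evaluation is truncated beyond
// cutoff_sig standard deviations (pass R_PosInf for no truncation).
static inline double bias_at(const double* H, int n_hills, double x, double y,
                             double cutoff_sig, double* gx, double* gy) {
  double v = 0.0;
  if (gx) { *gx = 0.0; *gy = 0.0; }
  const double c2 = cutoff_sig * cutoff_sig;
  for (int k = 0; k < n_hills; ++k) {
    const double dx = (x - H[5 * k]) / H[5 * k + 2];
    const double dy = (y - H[5 * k + 1]) / H[5 * k + 3];
    const double r2 = dx * dx + dy * dy;
    if (r2 > c2) continue;
    const double g = H[5 * k + 4] * std::exp(-0.5 * r2);
    v += g;
    if (gx) {
      *gx += -g * dx / H[5 * k + 2];
      *gy += -g * dy / H[5 * k + 3];
    }
  }
  return v;
}

// Overdamped Langevin propagation on a model surface, optionally under a
// static hill bias.  Uses R's RNG (seed via set.seed on the R side).
// Returns the (n_done+1) x 2 trajectory and a status flag
// (0 = completed, 1 = left the domain box after n_done valid steps).
// [[Rcpp::export]]
List cpp_langevin(int form, NumericVector params, double x0, double y0,
                  double dt, double friction, double kBT, int n_steps,
                  NumericMatrix hills, double cutoff_sig,
                  NumericVector domain) {
  // repack column-major R matrix into row-major quintuples
  const int nh = hills.nrow();
  std::vector<double> Hr(5 * nh);
  for (int k = 0; k < nh; ++k)
    for (int j = 0; j < 5; ++j) Hr[5 * k + j] = hills(k, j);

  NumericMatrix traj(n_steps + 1, 2);
  double x = x0, y = y0;
  traj(0, 0) = x; traj(0, 1) = y;
  const double mob = dt / friction;                 // mobility * dt
  const double noise = std::sqrt(2.0 * kBT * mob);  // fluctuation-dissipation
  // Leimkuhler-Matthews update: average consecutive noises; exact
  // configurational statistics on harmonic potentials, O(dt^2) otherwise
  double rx = norm_rand(), ry = norm_rand();
  int status = 0, n_done = n_steps;
  for (int i = 1; i <= n_steps; ++i) {
    double gx, gy, bgx = 0.0, bgy = 0.0;
    surf_grad(form, params.begin(), x, y, gx, gy);
    if (nh > 0) bias_at(Hr.data(), nh, x, y, cutoff_sig, &bgx, &bgy);
    const double rx1 = norm_rand(), ry1 = norm_rand();
    x += -(gx + bgx) * mob + noise * 0.5 * (rx + rx1);
    y += -(gy + bgy) * mob + noise * 0.5 * (ry + ry1);
    rx = rx1; ry = ry1;
    if (x < domain[0] || x > domain[1] || y < domain[2] || y > domain[3]) {
      status = 1; n_done = i - 1; break;
    }
    traj(i, 0) = x; traj(i, 1) = y;
  }
  return List::create(_["traj"] = traj, _["status"] = status,
                      _["n_done"] = n_done);
}

// Well-tempered metadynamics on a model surface: deposits one Gaussian every
// `pace` steps with height height0 * exp(-V_B(s)/kB_dT) (kB_dT = k_B (gamma-1) T;
// pass R_PosInf for standard, undamped metadynamics).  Returns trajectory,
// the hill list (time fs, center1, center2, sigma1, sigma2, height) and status.
// [[Rcpp::export]]
List cpp_metadynamics(int form, NumericVector params, double x0, double y0,
                      double dt, double friction, double kBT, int n_steps,
                      int pace, double height0, double sigma1, double sigma2,
                      double kB_dT, double cutoff_sig, NumericVector domain,
                      int stop_crossings, double stop_divide,
                      double stop_hyst, int stop_min_steps,
                      NumericVector wall, double wall_k) {
  const int max_hills = n_steps / pace + 1;
  std::vector<double> Hr;           // row-major quintuples, grows as deposited
  Hr.reserve(5 * max_hills);
  std::vector<double> hill_time;
  hill_time.reserve(max_hills);

  NumericMatrix traj(n_steps + 1, 2);
  double x = x0, y = y0;
  traj(0, 0) = x; traj(0, 1) = y;
  const double mob = dt / friction;
  const double noise = std::sqrt(2.0 * kBT * mob);
  double rx = norm_rand(), ry = norm_rand();
  int status = 0, n_done = n_steps;
  // stopping rule: halt once the dividing surface on CV1 has been crossed
  // (with hysteresis) stop_crossings times; 0 disables
  int side = 0, crossings = 0;
  const double lo = stop_divide - stop_hyst / 2;
  const double hi = stop_divide + stop_hyst / 2;

  for (int i = 1; i <= n_steps; ++i) {
    // deposit before the step so a hill lands every `pace` steps from step pace
    if (i % pace == 0) {
      const int nh = (int)hill_time.size();
      double damp = 1.0;
      if (R_finite(kB_dT)) {
        const double vb = bias_at(Hr.data(), nh, x, y, cutoff_sig, 0, 0);
        damp = std::exp(-vb / kB_dT);
      }
      Hr.push_back(x); Hr.push_back(y);
      Hr.push_back(sigma1); Hr.push_back(sigma2);
      Hr.push_back(height0 * damp);
      hill_time.push_back(i * dt);
    }
    double gx, gy, bgx = 0.0, bgy = 0.0;
    surf_grad(form, params.begin(), x, y, gx, gy);
    bias_at(Hr.data(), (int)hill_time.size(), x, y, cutoff_sig, &bgx, &bgy);
    if (wall_k > 0) {  // harmonic restraining walls against bias creep
      if (x < wall[0]) gx += wall_k * (x - wall[0]);
      if (x > wall[1]) gx += wall_k * (x - wall[1]);
      if (y < wall[2]) gy += wall_k * (y - wall[2]);
      if (y > wall[3]) gy += wall_k * (y - wall[3]);
    }
    const double rx1 = norm_rand(), ry1 = norm_rand();
    x += -(gx + bgx) * mob + noise * 0.5 * (rx + rx1);
    y += -(gy + bgy) * mob + noise * 0.5 * (ry + ry1);
    rx = rx1; ry = ry1;
    if (x < domain[0] || x > domain[1] || y < domain[2] || y > domain[3]) {
      status = 1; n_done = i - 1; break;
    }
    traj(i, 0) = x; traj(i, 1) = y;
    if (stop_crossings > 0) {
      const int s2 = x < lo ? -1 : (x > hi ? 1 : 0);
      if (s2 != 0) {
        if (side != 0 && s2 != side) ++crossings;
        side = s2;
      }
      if (crossings >= stop_crossings && i >= stop_min_steps) {
        n_done = i; break;
      }
    }
  }

  const int nh = (int)hill_time.size();
  NumericMatrix hills(nh, 6);
  for (int k = 0; k < nh; ++k) {
    hills(k, 0) = hill_time[k];
    for (int j = 0; j < 5; ++j) hills(k, j + 1) = Hr[5 * k + j];
  }
  return List::create(_["traj"] = traj, _["hills"] = hills,
                      _["status"] = status, _["n_done"] = n_done);
}

// Committor shooting: n_shots overdamped Langevin trajectories from (x0, y0),
// each stopped on first entry into the reactant or product rectangle
// (xmin, xmax, ymin, ymax) or after max_steps.  Outcome codes:
// +1 product, -1 reactant, 0 timeout.
// [[Rcpp::export]]
IntegerVector cpp_committor_shots(int form, NumericVector params,
                                  double x0, double y0, double dt,
                                  double friction, double kBT, int n_shots,
                                  int max_steps, NumericVector reactant,
                                  NumericVector product) {
  IntegerVector out(n_shots);
  const double mob = dt / friction;
  const double noise = std::sqrt(2.0 * kBT * mob);
  for (int s = 0; s < n_shots; ++s) {
    double x = x0, y = y0;
    double rx = norm_rand(), ry = norm_rand();
    int res = 0;
    for (int i = 0; i < max_steps; ++i) {
      double gx, gy;
      surf_grad(form, params.begin(), x, y, gx, gy);
      const double rx1 = norm_rand(), ry1 = norm_rand();
      x += -gx * mob + noise * 0.5 * (rx + rx1);
      y += -gy * mob + noise * 0.5 * (ry + ry1);
      rx = rx1; ry = ry1;
      if (x >= reactant[0] && x <= reactant[1] &&
          y >= reactant[2] && y <= reactant[3]) { res = -1; break; }
      if (x >= product[0] && x <= product[1] &&
          y >= product[2] && y <= product[3]) { res = 1; break; }
    }
    out[s] = res;
  }
  return out;
}

// Hill summation on a rectangular grid (the metadynamics bias potential).
// [[Rcpp::export]]
NumericMatrix cpp_sum_hills(NumericVector xg, NumericVector yg,
                            NumericMatrix hills, double cutoff_sig) {
  const int nx = xg.size(), ny = yg.size(), nh = hills.nrow();
  std::vector<double> Hr(5 * nh);
  for (int k = 0; k < nh; ++k)
    for (int j = 0; j < 5; ++j) Hr[5 * k + j] = hills(k, j);
  NumericMatrix out(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      out(i, j) = bias_at(Hr.data(), nh, xg[i], yg[j], cutoff_sig, 0, 0);
  return out;
}

// [[Rcpp::export]]
double cpp_surface_value(int form, NumericVector params, double x, double y) {
  return surf_value(form, params.begin(), x, y);
}

// [[Rcpp::export]]
NumericVector cpp_surface_gradient(int form, NumericVector params, double x,
                                   double y) {
  double gx, gy;
  surf_grad(form, params.begin(), x, y, gx, gy);
  return NumericVector::create(gx, gy);
}
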