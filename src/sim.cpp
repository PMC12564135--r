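#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation of a gradient tabulated on a uniform grid.
// Values outside the grid are clamped to the edge value; the integrators
// reflect at the domain edges so excursions beyond the grid are transient.
static inline double grad_at(double z, double z0, double dz, const double* g,
                             int n) {
  double u = (z - z0) / dz;
  if (u <= 0.0) return g[0];
  if (u >= n - 1) return g[n - 1];
  int i = (int)u;
  double f = u - i;
  return g[i] * (1.0 - f) + g[i + 1] * f;
}

static inline double reflect(double z, double lo, double hi) {
  // One bounce is enough when the step-size bound holds; a second pass
  // guards pathological steps, anything further is reported by the caller.
  for (int k = 0; k < 2 && (z < lo || z > hi); ++k) {
    if (z < lo) z = 2.0 * lo - z;
    if (z > hi) z = 2.0 * hi - z;
  }
  return z;
}

// Overdamped Euler-Maruyama on a tabulated gradient, reflecting boundaries.
// Returns positions recorded every `stride` steps (initial point included,
// final point always recorded).
// [[Rcpp::export]]
NumericVector langevin_path_cpp(double z0, int n_steps, double dt, double D,
                                double kBT, double zmin, double zmax,
                                double grid_z0, double grid_dz,
                                NumericVector grad, int stride) {
  const double* g = grad.begin();
  int ng = grad.size();
  double drift = -D * dt / kBT;
  double sigma = std::sqrt(2.0 * D * dt);
  int n_rec = n_steps / stride + 1;
  bool extra = (n_steps % stride) != 0;
  NumericVector out(n_rec + (extra ? 1 : 0));
  double z = z0;
  out[0] = z;
  int j = 1;
  for (int i = 1; i <= n_steps; ++i) {
    double gr = grad_at(z, grid_z0, grid_dz, g, ng);
    if (!std::isfinite(gr)) stop("non-finite gradient at z = %f", z);
    z += drift * gr + sigma * norm_rand();
    z = reflect(z, zmin, zmax);
    if (z < zmin || z > zmax)
      stop("position left the domain after reflection at step %d; dt too large",
           i);
    if (i % stride == 0) out[j++] = z;
  }
  if (extra) out[j] = z;
  return out;
}

// Constant-velocity steered pull: particle in U(z) + (k/2)(z - lambda(t))^2,
// lambda moving from lam0 at signed speed v. Work accumulated as the
// trapezoidal integral of f dlambda with f = k (lambda - z).
// Returns a matrix with columns t, lambda, z, f, W at the recorded steps.
// [[Rcpp::export]]
NumericMatrix smd_pull_cpp(double z0, int n_steps, double dt, double D,
                           double kBT, double zmin, double zmax,
                           double grid_z0, double grid_dz, NumericVector grad,
                           double k_spring, double lam0, double v_signed,
                           int stride) {
  const double* g = grad.begin();
  int ng = grad.size();
  double drift = -D * dt / kBT;
  double sigma = std::sqrt(2.0 * D * dt);
  int n_rec = n_steps / stride + 1;
  bool extra = (n_steps % stride) != 0;
  NumericMatrix out(n_rec + (extra ? 1 : 0), 5);
  double z = z0, lam = lam0, W = 0.0;
  double f = k_spring * (lam - z);
  out(0, 0) = 0.0; out(0, 1) = lam; out(0, 2) = z; out(0, 3) = f; out(0, 4) = W;
  int j = 1;
  for (int i = 1; i <= n_steps; ++i) {
    double gr = grad_at(z, grid_z0, grid_dz, g, ng);
    if (!std::isfinite(gr)) stop("non-finite gradient at z = %f", z);
    double f_prev = f;
    z += drift * (gr - f) + sigma * norm_rand();
    z = reflect(z, zmin, zmax);
    if (z < zmin || z > zmax)
      stop("position left the domain after reflection at step %d; dt too large",
           i);
    lam = lam0 + v_signed * (i * dt);
    f = k_spring * (lam - z);
    W += 0.5 * (f_prev + f) * v_signed * dt;
    if (i % stride == 0) {
      out(j, 0) = i * dt; out(j, 1) = lam; out(j, 2) = z; out(j, 3) = f;
      out(j, 4) = W;
      ++j;
    }
  }
  if (extra) {
    out(j, 0) = n_steps * dt; out(j, 1) = lam; out(j, 2) = z; out(j, 3) = f;
    out(j, 4) = W;
  }
  return out;
}
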