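#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One-dimensional overdamped (Brownian) Langevin dynamics over the model
// H-bond landscape U(x, n) = U0(x) - n * c * g(x), with a two-state water
// occupancy n updated once per time step. Uses R's RNG so runs are
// reproducible under set.seed() from the R side.

struct Land {
  double D, x0, a, a_rep, c, xc, w, k_entry, k_exit;
};

static Land unpack(const List& p) {
  Land L;
  L.D = p["D"]; L.x0 = p["x0"]; L.a = p["a"]; L.a_rep = p["a_rep"];
  L.c = p["c"]; L.xc = p["xc"]; L.w = p["w"];
  L.k_entry = p["k_entry"]; L.k_exit = p["k_exit"];
  return L;
}

static inline double du0(const Land& L, double x) {
  double a = (x >= L.x0) ? L.a : L.a_rep;
  double e = std::exp(-a * (x - L.x0));
  return 2.0 * L.D * a * e * (1.0 - e);
}

static inline double dg(const Land& L, double x) {
  double s = 1.0 / (1.0 + std::exp(-(x - L.xc) / L.w));
  return s * (1.0 - s) / L.w;
}

// deterministic force on x (landscape + optional flat-bottom restraint)
static inline double force(const Land& L, double x, int n,
                           bool restrained, double lo, double hi, double kr) {
  double f = -du0(L, x) + n * L.c * dg(L, x);
  if (restrained) {
    if (x < lo) f += -kr * (x - lo);
    else if (x > hi) f += -kr * (x - hi);
  }
  return f;
}

static inline int update_occupancy(const Land& L, int n, double dt) {
  if (n == 0) {
    if (L.k_entry <= 0.0) return 0;
    return (unif_rand() < L.k_entry * dt) ? 1 : 0;
  }
  if (L.k_exit <= 0.0) return 1;
  return (unif_rand() < L.k_exit * dt) ? 0 : 1;
}

// [[Rcpp::export]]
List cpp_equilibrate(List land, double x_init, int n_init,
                     double lo, double hi, double kr,
                     double dt, double duration, int sample_every,
                     double diff_coeff, double kT) {
  Land L = unpack(land);
  const long nsteps = (long)std::llround(duration / dt);
  const int nsamp = (int)(nsteps / sample_every);
  NumericVector xs(nsamp);
  IntegerVector ns(nsamp);
  const double mob = diff_coeff / kT;          // mobility, 1/(friction)
  const double noise = std::sqrt(2.0 * diff_coeff * dt);
  double x = x_init;
  int n = n_init;
  double max_dx = 0.0;
  int isamp = 0;
  for (long s = 1; s <= nsteps; ++s) {
    double f = force(L, x, n, true, lo, hi, kr);
    double dx = mob * f * dt + noise * norm_rand();
    if (std::fabs(dx) > max_dx) max_dx = std::fabs(dx);
    x += dx;
    n = update_occupancy(L, n, dt);
    if (s % sample_every == 0 && isamp < nsamp) {
      xs[isamp] = x;
      ns[isamp] = n;
      ++isamp;
    }
  }
  return List::create(_["x"] = xs, _["n"] = ns,
                      _["x_final"] = x, _["n_final"] = n,
                      _["max_dx"] = max_dx);
}

// Steered pull: guide centre moves lam0 -> lam1 at constant |rate|;
// accumulates work dW = k_spring * (lam - x) * dlam. When record_work is
// true, W is recorded each time the guide crosses a report-grid point
// (grid from lam0 to lam1 spaced report_step). Used both for the stage-2
// approach (record_work = false) and the stage-3 rupture pull.
// [[Rcpp::export]]
List cpp_pull(List land, double x_init, int n_init,
              double lam0, double lam1, double rate, double k_spring,
              double dt, double diff_coeff, double kT,
              double report_step, bool record_work) {
  Land L = unpack(land);
  const double dir = (lam1 >= lam0) ? 1.0 : -1.0;
  const double dlam = dir * rate * dt;
  const long nsteps = (long)std::llround(std::fabs(lam1 - lam0) / (rate * dt));
  int ngrid = 0;
  NumericVector work(0);
  if (record_work) {
    ngrid = (int)std::llround(std::fabs(lam1 - lam0) / report_step) + 1;
    work = NumericVector(ngrid);
  }
  const double mob = diff_coeff / kT;
  const double noise = std::sqrt(2.0 * diff_coeff * dt);
  double x = x_init;
  int n = n_init;
  double lam = lam0;
  double W = 0.0;
  double max_lag = 0.0, sum_lag = 0.0, max_dx = 0.0;
  int igrid = 1;  // grid point 0 is lam0 with W = 0
  if (record_work) work[0] = 0.0;
  for (long s = 1; s <= nsteps; ++s) {
    double f = force(L, x, n, false, 0.0, 0.0, 0.0) - k_spring * (x - lam);
    double dx = mob * f * dt + noise * norm_rand();
    if (std::fabs(dx) > max_dx) max_dx = std::fabs(dx);
    x += dx;
    lam = lam0 + dir * rate * dt * (double)s;
    W += k_spring * (lam - x) * dlam;
    double lag = std::fabs(lam - x);
    if (lag > max_lag) max_lag = lag;
    sum_lag += lag;
    n = update_occupancy(L, n, dt);
    if (record_work) {
      while (igrid < ngrid &&
             dir * (lam - (lam0 + dir * report_step * (double)igrid)) >= -1e-12) {
        work[igrid] = W;
        ++igrid;
      }
    }
  }
  if (record_work) for (; igrid < ngrid; ++igrid) work[igrid] = W;
  return List::create(_["work"] = work,
                      _["x_final"] = x, _["n_final"] = n,
                      _["max_lag"] = max_lag,
                      _["mean_lag"] = (nsteps > 0) ? sum_lag / (double)nsteps : 0.0,
                      _["max_dx"] = max_dx);
}
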