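// Adaptive Dormand-Prince 5(4) integration of the GEF exchange cycle.
//
// Three right-hand sides share one stepper:
//   full     : y = (e, e_gdp, e_gtp, e_g, g_gdp, g_gtp)      6 states
//   protocol : y = (e_gdp, e_gtp, e_g, g_gdp, g_gtp)         5 states,
//              free GEF computed algebraically from the enzyme total
//   clamped  : y = (e, e_gdp, e_gtp, e_g)                    4 states,
//              free G_GDP / G_GTP held at fixed concentrations
//
// No general-purpose solver is available in the deployment image, so the
// stepper is implemented here. The system is small and at most mildly stiff
// for realistic rate magnitudes; the error controller plus a step-count
// guard keeps worst cases bounded.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Pars {
  double k[8];       // k1..k8
  double gdp, gtp;   // buffered nucleotide pools (uM)
  int    mode;       // 0 none, 1 intrinsic, 2 gap
  double kase, km, f0;
  double e0;         // enzyme total for the protocol model
  bool   removal;    // protocol removal-phase semantics
  double gd_c, gt_c; // clamped substrate concentrations
};

static inline double fGTPase(double gt, const Pars &p) {
  if (p.mode == 1) return p.kase * gt;
  if (p.mode == 2) return p.kase * gt * p.f0 / (p.km + gt);
  return 0.0;
}

// Free enzyme under the protocol semantics: e = e0 - bound, clamped at zero
// while excess bound complexes dissociate during a removal phase.
static inline double free_enzyme(const double *y, const Pars &p) {
  double bound = y[0] + y[1] + y[2];
  double e = p.e0 - bound;
  if (p.removal && e < 0.0) e = 0.0;
  return e;
}

static void rhs_full(const double *y, double *dy, const Pars &p) {
  const double e = y[0], egd = y[1], egt = y[2], eg = y[3],
               gd = y[4], gt = y[5];
  const double f = fGTPase(gt, p);
  dy[0] = -e * (p.k[0] * gd + p.k[4] * gt) + p.k[1] * egd + p.k[5] * egt;
  dy[1] = -(p.k[1] + p.k[2]) * egd + p.k[0] * gd * e + p.k[3] * eg * p.gdp;
  dy[2] = -(p.k[5] + p.k[6]) * egt + p.k[4] * gt * e + p.k[7] * eg * p.gtp;
  dy[3] = -(p.k[3] * p.gdp + p.k[7] * p.gtp) * eg + p.k[2] * egd + p.k[6] * egt;
  dy[4] = -p.k[0] * e * gd + p.k[1] * egd + f;
  dy[5] = -p.k[4] * e * gt + p.k[5] * egt - f;
}

static void rhs_protocol(const double *y, double *dy, const Pars &p) {
  const double egd = y[0], egt = y[1], eg = y[2], gd = y[3], gt = y[4];
  const double e = free_enzyme(y, p);
  const double f = fGTPase(gt, p);
  dy[0] = -(p.k[1] + p.k[2]) * egd + p.k[0] * gd * e + p.k[3] * eg * p.gdp;
  dy[1] = -(p.k[5] + p.k[6]) * egt + p.k[4] * gt * e + p.k[7] * eg * p.gtp;
  dy[2] = -(p.k[3] * p.gdp + p.k[7] * p.gtp) * eg + p.k[2] * egd + p.k[6] * egt;
  dy[3] = -p.k[0] * e * gd + p.k[1] * egd + f;
  dy[4] = -p.k[4] * e * gt + p.k[5] * egt - f;
}

static void rhs_clamped(const double *y, double *dy, const Pars &p) {
  const double e = y[0], egd = y[1], egt = y[2], eg = y[3];
  const double gd = p.gd_c, gt = p.gt_c;
  dy[0] = -e * (p.k[0] * gd + p.k[4] * gt) + p.k[1] * egd + p.k[5] * egt;
  dy[1] = -(p.k[1] + p.k[2]) * egd + p.k[0] * gd * e + p.k[3] * eg * p.gdp;
  dy[2] = -(p.k[5] + p.k[6]) * egt + p.k[4] * gt * e + p.k[7] * eg * p.gtp;
  dy[3] = -(p.k[3] * p.gdp + p.k[7] * p.gtp) * eg + p.k[2] * egd + p.k[6] * egt;
}

typedef void (*RhsFn)(const double *, double *, const Pars &);

// Dormand-Prince tableau
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// Integrate from times[0] to times.back(), writing the state at each
// requested time into `out` (row-major, n_times x dim).
static void dopri5(RhsFn f, int dim, const double *y0, const NumericVector &times,
                   const Pars &p, double rtol, double atol, double maxsteps,
                   NumericMatrix &out) {
  const int nt = times.size();
  double y[6], ynew[6], k1v[6], k2v[6], k3v[6], k4v[6], k5v[6], k6v[6],
      k7v[6], ytmp[6], err[6];
  for (int i = 0; i < dim; ++i) y[i] = y0[i];

  double t = times[0];
  for (int i = 0; i < dim; ++i) out(0, i) = y[i];
  int next = 1;
  if (nt == 1) return;

  f(y, k1v, p);
  // initial step heuristic
  double sc = 0.0, sd = 0.0;
  for (int i = 0; i < dim; ++i) {
    sc = std::max(sc, std::fabs(y[i]));
    sd = std::max(sd, std::fabs(k1v[i]));
  }
  double h = (sd > 0) ? 0.01 * std::max(sc, atol) / sd : 1e-6;
  double tend = times[nt - 1];
  h = std::min(h, tend - t);
  if (h <= 0) h = 1e-6;

  double steps = 0;
  bool first_same_as_last_valid = true; // k1v holds f(y)
  while (t < tend) {
    if (++steps > maxsteps)
      stop("dopri5: maximum number of steps (%g) exceeded at t = %g", maxsteps, t);
    bool hit_output = false;
    if (t + h >= times[next] - 1e-14 * std::max(1.0, std::fabs(times[next]))) {
      h = times[next] - t;
      hit_output = true;
    }
    if (!first_same_as_last_valid) f(y, k1v, p);

    for (int i = 0; i < dim; ++i) ytmp[i] = y[i] + h * a21 * k1v[i];
    f(ytmp, k2v, p);
    for (int i = 0; i < dim; ++i)
      ytmp[i] = y[i] + h * (a31 * k1v[i] + a32 * k2v[i]);
    f(ytmp, k3v, p);
    for (int i = 0; i < dim; ++i)
      ytmp[i] = y[i] + h * (a41 * k1v[i] + a42 * k2v[i] + a43 * k3v[i]);
    f(ytmp, k4v, p);
    for (int i = 0; i < dim; ++i)
      ytmp[i] = y[i] + h * (a51 * k1v[i] + a52 * k2v[i] + a53 * k3v[i] +
                            a54 * k4v[i]);
    f(ytmp, k5v, p);
    for (int i = 0; i < dim; ++i)
      ytmp[i] = y[i] + h * (a61 * k1v[i] + a62 * k2v[i] + a63 * k3v[i] +
                            a64 * k4v[i] + a65 * k5v[i]);
    f(ytmp, k6v, p);
    for (int i = 0; i < dim; ++i)
      ynew[i] = y[i] + h * (b1 * k1v[i] + b3 * k3v[i] + b4 * k4v[i] +
                            b5 * k5v[i] + b6 * k6v[i]);
    f(ynew, k7v, p);
    double errnorm = 0.0;
    for (int i = 0; i < dim; ++i) {
      err[i] = h * (e1 * k1v[i] + e3 * k3v[i] + e4 * k4v[i] + e5 * k5v[i] +
                    e6 * k6v[i] + e7 * k7v[i]);
      double scale = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = err[i] / scale;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / dim);

    if (errnorm <= 1.0) { // accept
      t += h;
      for (int i = 0; i < dim; ++i) {
        y[i] = ynew[i];
        k1v[i] = k7v[i]; // FSAL
      }
      first_same_as_last_valid = true;
      if (hit_output) {
        for (int i = 0; i < dim; ++i) out(next, i) = y[i];
        ++next;
        if (next >= nt) break;
      }
      double fac = (errnorm > 0) ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else { // reject
      double fac = 0.9 * std::pow(errnorm, -0.2);
      h *= std::max(0.1, fac);
      first_same_as_last_valid = true; // k1v unchanged, still f(y)
    }
    if (!(h > 0) || t + h == t)
      stop("dopri5: step size underflow at t = %g", t);
  }
}

// ---------------------------------------------------------------------------
// Rosenbrock 2(3) (Shampine-Reichelt ode23s): L-stable, for stiff parameter
// regimes where the explicit stepper is stability-limited. Analytic Jacobians.

static inline double dfGTPase(double gt, const Pars &p) {
  if (p.mode == 1) return p.kase;
  if (p.mode == 2) {
    double d = p.km + gt;
    return p.kase * p.f0 * p.km / (d * d);
  }
  return 0.0;
}

typedef void (*JacFn)(const double *, double *, const Pars &);

static void jac_full(const double *y, double *J, const Pars &p) {
  const double e = y[0], gd = y[4], gt = y[5];
  const double fp = dfGTPase(gt, p);
  const double *k = p.k;
  double M[36] = {
      -(k[0] * gd + k[4] * gt), k[1], k[5], 0, -k[0] * e, -k[4] * e,
      k[0] * gd, -(k[1] + k[2]), 0, k[3] * p.gdp, k[0] * e, 0,
      k[4] * gt, 0, -(k[5] + k[6]), k[7] * p.gtp, 0, k[4] * e,
      0, k[2], k[6], -(k[3] * p.gdp + k[7] * p.gtp), 0, 0,
      -k[0] * gd, k[1], 0, 0, -k[0] * e, fp,
      -k[4] * gt, 0, k[5], 0, 0, -k[4] * e - fp};
  for (int i = 0; i < 36; ++i) J[i] = M[i];
}

static void jac_protocol(const double *y, double *J, const Pars &p) {
  const double gd = y[3], gt = y[4];
  const double e = free_enzyme(y, p);
  const double fp = dfGTPase(gt, p);
  const double *k = p.k;
  // de/d(complex): -1, except 0 while clamped at zero during removal
  const double de = (p.removal && p.e0 - (y[0] + y[1] + y[2]) < 0.0) ? 0.0 : -1.0;
  double M[25] = {
      -(k[1] + k[2]), 0, k[3] * p.gdp, k[0] * e, 0,
      0, -(k[5] + k[6]), k[7] * p.gtp, 0, k[4] * e,
      k[2], k[6], -(k[3] * p.gdp + k[7] * p.gtp), 0, 0,
      k[1], 0, 0, -k[0] * e, fp,
      0, k[5], 0, 0, -k[4] * e - fp};
  const double dfde[5] = {k[0] * gd, k[4] * gt, 0, -k[0] * gd, -k[4] * gt};
  for (int i = 0; i < 5; ++i)
    for (int j = 0; j < 3; ++j) M[i * 5 + j] += dfde[i] * de;
  for (int i = 0; i < 25; ++i) J[i] = M[i];
}

static void jac_clamped(const double *y, double *J, const Pars &p) {
  const double gd = p.gd_c, gt = p.gt_c;
  const double *k = p.k;
  (void)y;
  double M[16] = {
      -(k[0] * gd + k[4] * gt), k[1], k[5], 0,
      k[0] * gd, -(k[1] + k[2]), 0, k[3] * p.gdp,
      k[4] * gt, 0, -(k[5] + k[6]), k[7] * p.gtp,
      0, k[2], k[6], -(k[3] * p.gdp + k[7] * p.gtp)};
  for (int i = 0; i < 16; ++i) J[i] = M[i];
}

// Solve A x = b in place (A row-major dim x dim), partial pivoting.
static bool lu_solve(double *A, double *b, int dim) {
  int piv[6];
  for (int i = 0; i < dim; ++i) piv[i] = i;
  for (int c = 0; c < dim; ++c) {
    int pr = c;
    double best = std::fabs(A[piv[c] * dim + c]);
    for (int r = c + 1; r < dim; ++r) {
      double v = std::fabs(A[piv[r] * dim + c]);
      if (v > best) { best = v; pr = r; }
    }
    if (best == 0.0) return false;
    std::swap(piv[c], piv[pr]);
    const double d = A[piv[c] * dim + c];
    for (int r = c + 1; r < dim; ++r) {
      double m = A[piv[r] * dim + c] / d;
      A[piv[r] * dim + c] = 0.0;
      for (int j = c + 1; j < dim; ++j) A[piv[r] * dim + j] -= m * A[piv[c] * dim + j];
      b[piv[r]] -= m * b[piv[c]];
    }
  }
  double x[6];
  for (int c = dim - 1; c >= 0; --c) {
    double s = b[piv[c]];
    for (int j = c + 1; j < dim; ++j) s -= A[piv[c] * dim + j] * x[j];
    x[c] = s / A[piv[c] * dim + c];
  }
  for (int i = 0; i < dim; ++i) b[i] = x[i];
  return true;
}

static void ros23(RhsFn f, JacFn jac, int dim, const double *y0,
                  const NumericVector &times, const Pars &p, double rtol,
                  double atol, double maxsteps, NumericMatrix &out) {
  const double d = 1.0 / (2.0 + std::sqrt(2.0));
  const double e32 = 6.0 + std::sqrt(2.0);
  const int nt = times.size();
  double y[6], ynew[6], F0[6], F1[6], F2[6], k1[6], k2[6], k3[6], ytmp[6];
  double J[36], W[36], rhsbuf[6];
  for (int i = 0; i < dim; ++i) y[i] = y0[i];
  double t = times[0];
  for (int i = 0; i < dim; ++i) out(0, i) = y[i];
  int next = 1;
  if (nt == 1) return;
  const double tend = times[nt - 1];

  f(y, F0, p);
  double sc = 0.0, sd = 0.0;
  for (int i = 0; i < dim; ++i) {
    sc = std::max(sc, std::fabs(y[i]));
    sd = std::max(sd, std::fabs(F0[i]));
  }
  double h = (sd > 0) ? 0.01 * std::max(sc, atol) / sd : 1e-6;
  h = std::min(h, tend - t);
  if (h <= 0) h = 1e-6;

  double steps = 0;
  while (t < tend) {
    if (++steps > maxsteps)
      stop("ros23: maximum number of steps (%g) exceeded at t = %g", maxsteps, t);
    bool hit_output = false;
    if (t + h >= times[next] - 1e-14 * std::max(1.0, std::fabs(times[next]))) {
      h = times[next] - t;
      hit_output = true;
    }
    f(y, F0, p);
    jac(y, J, p);
    // W = I - h d J
    for (int i = 0; i < dim * dim; ++i) W[i] = -h * d * J[i];
    for (int i = 0; i < dim; ++i) W[i * dim + i] += 1.0;
    double Wk[36];
    // k1
    std::copy(W, W + dim * dim, Wk);
    for (int i = 0; i < dim; ++i) rhsbuf[i] = F0[i];
    if (!lu_solve(Wk, rhsbuf, dim)) stop("ros23: singular W matrix");
    for (int i = 0; i < dim; ++i) k1[i] = rhsbuf[i];
    // k2
    for (int i = 0; i < dim; ++i) ytmp[i] = y[i] + 0.5 * h * k1[i];
    f(ytmp, F1, p);
    std::copy(W, W + dim * dim, Wk);
    for (int i = 0; i < dim; ++i) rhsbuf[i] = F1[i] - k1[i];
    if (!lu_solve(Wk, rhsbuf, dim)) stop("ros23: singular W matrix");
    for (int i = 0; i < dim; ++i) k2[i] = rhsbuf[i] + k1[i];
    // proposed step
    for (int i = 0; i < dim; ++i) ynew[i] = y[i] + h * k2[i];
    f(ynew, F2, p);
    // k3 and error estimate
    std::copy(W, W + dim * dim, Wk);
    for (int i = 0; i < dim; ++i)
      rhsbuf[i] = F2[i] - e32 * (k2[i] - F1[i]) - 2.0 * (k1[i] - F0[i]);
    if (!lu_solve(Wk, rhsbuf, dim)) stop("ros23: singular W matrix");
    for (int i = 0; i < dim; ++i) k3[i] = rhsbuf[i];
    double errnorm = 0.0;
    for (int i = 0; i < dim; ++i) {
      double err = h / 6.0 * (k1[i] - 2.0 * k2[i] + k3[i]);
      double scale = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = err / scale;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / dim);
    if (errnorm <= 1.0) {
      t += h;
      for (int i = 0; i < dim; ++i) y[i] = ynew[i];
      if (hit_output) {
        for (int i = 0; i < dim; ++i) out(next, i) = y[i];
        ++next;
        if (next >= nt) break;
      }
      double fac = (errnorm > 0) ? 0.9 * std::pow(errnorm, -1.0 / 3.0) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.1, 0.9 * std::pow(errnorm, -1.0 / 3.0));
    }
    if (!(h > 0) || t + h == t)
      stop("ros23: step size underflow at t = %g", t);
  }
}

static void integrate(int method, RhsFn f, JacFn jac, int dim, const double *y0,
                      const NumericVector &times, const Pars &p, double rtol,
                      double atol, double maxsteps, NumericMatrix &out) {
  if (method == 1)
    ros23(f, jac, dim, y0, times, p, rtol, atol, maxsteps, out);
  else
    dopri5(f, dim, y0, times, p, rtol, atol, maxsteps, out);
}

static Pars make_pars(const NumericVector &k, const NumericVector &pools,
                      const NumericVector &gtpase) {
  Pars p;
  for (int i = 0; i < 8; ++i) p.k[i] = k[i];
  p.gdp = pools[0];
  p.gtp = pools[1];
  p.mode = (int)gtpase[0];
  p.kase = gtpase[1];
  p.km = gtpase[2];
  p.f0 = gtpase[3];
  p.e0 = 0.0;
  p.removal = false;
  p.gd_c = p.gt_c = 0.0;
  return p;
}

// [[Rcpp::export]]
NumericMatrix cpp_ode_full(NumericVector y0, NumericVector times,
                           NumericVector k, NumericVector pools,
                           NumericVector gtpase, double rtol, double atol,
                           double maxsteps, int method) {
  Pars p = make_pars(k, pools, gtpase);
  NumericMatrix out(times.size(), 6);
  integrate(method, rhs_full, jac_full, 6, REAL(y0), times, p, rtol, atol,
            maxsteps, out);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_ode_protocol(NumericVector y0, NumericVector times,
                               NumericVector k, NumericVector pools,
                               NumericVector gtpase, double e0, bool removal,
                               double rtol, double atol, double maxsteps,
                               int method) {
  Pars p = make_pars(k, pools, gtpase);
  p.e0 = e0;
  p.removal = removal;
  NumericMatrix out(times.size(), 5);
  integrate(method, rhs_protocol, jac_protocol, 5, REAL(y0), times, p, rtol,
            atol, maxsteps, out);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_ode_clamped(NumericVector y0, NumericVector times,
                              NumericVector k, NumericVector pools,
                              double gd, double gt, double rtol, double atol,
                              double maxsteps, int method) {
  NumericVector noase = NumericVector::create(0.0, 0.0, 0.0, 0.0);
  Pars p = make_pars(k, pools, noase);
  p.gd_c = gd;
  p.gt_c = gt;
  NumericMatrix out(times.size(), 4);
  integrate(method, rhs_clamped, jac_clamped, 4, REAL(y0), times, p, rtol,
            atol, maxsteps, out);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rhs_full(NumericVector y, NumericVector k,
                           NumericVector pools, NumericVector gtpase) {
  Pars p = make_pars(k, pools, gtpase);
  NumericVector dy(6);
  rhs_full(REAL(y), REAL(dy), p);
  return dy;
}
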