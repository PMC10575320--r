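// Core kernels for the helical homopolymer model: potentials, chain
// geometry, the bundling order parameter q, Monte Carlo move proposals and
// Metropolis sweeps. All randomness goes through R's RNG (unif_rand), so
// set.seed() in R makes every kernel deterministic.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Params {
  double r0, R, sigma, rc, vc;
  double s_fene, s_lj, s_theta, s_tau;
  double theta0, tau0;
  bool lj_bonded;     // include |i-j| == 1 pairs in the LJ sum (off by default)
  bool interior_angle; // alternate bending-angle convention
};

static Params parse_params(const List& p) {
  Params q;
  q.r0 = as<double>(p["r0"]);
  q.R = as<double>(p["R"]);
  q.sigma = as<double>(p["sigma"]);
  q.rc = as<double>(p["rc"]);
  q.vc = as<double>(p["vc"]);
  q.s_fene = as<double>(p["s_fene"]);
  q.s_lj = as<double>(p["s_lj"]);
  q.s_theta = as<double>(p["s_theta"]);
  q.s_tau = as<double>(p["s_tau"]);
  q.theta0 = as<double>(p["theta0"]);
  q.tau0 = as<double>(p["tau0"]);
  q.lj_bonded = as<bool>(p["lj_bonded"]);
  q.interior_angle = as<bool>(p["interior_angle"]);
  return q;
}

static inline double dist3(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static inline double v_lj(double r, const Params& p) {
  if (r >= p.rc) return 0.0;
  double sr2 = (p.sigma * p.sigma) / (r * r);
  double sr6 = sr2 * sr2 * sr2;
  return 4.0 * (sr6 * sr6 - sr6) - p.vc;
}

static inline double v_fene(double r, const Params& p) {
  double x = (r - p.r0) / p.R;
  return std::log(1.0 - x * x); // caller guarantees |x| < 1
}

static inline void sub3(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// angle between successive bond vectors (b-a) and (c-b); interior convention
// measures instead the angle at b between (a-b) and (c-b)
static double bend_angle(const double* a, const double* b, const double* c,
                         bool interior) {
  double u[3], v[3];
  sub3(b, a, u);
  sub3(c, b, v);
  if (interior) { u[0] = -u[0]; u[1] = -u[1]; u[2] = -u[2]; }
  double nu = norm3(u), nv = norm3(v);
  if (nu == 0.0 || nv == 0.0) return NA_REAL;
  double ca = dot3(u, v) / (nu * nv);
  if (ca > 1.0) ca = 1.0;
  if (ca < -1.0) ca = -1.0;
  return std::acos(ca);
}

// signed dihedral over bonds b1=b-a, b2=c-b, b3=d-c; IUPAC atan2 convention,
// positive for right-handed twist
static double dihedral(const double* a, const double* b, const double* c,
                       const double* d) {
  double b1[3], b2[3], b3[3], n1[3], n2[3], m[3];
  sub3(b, a, b1);
  sub3(c, b, b2);
  sub3(d, c, b3);
  cross3(b1, b2, n1);
  cross3(b2, b3, n2);
  double nb2 = norm3(b2);
  if (nb2 == 0.0 || norm3(n1) == 0.0 || norm3(n2) == 0.0) return NA_REAL;
  cross3(n1, n2, m);
  double y = dot3(m, b2) / nb2;
  double x = dot3(n1, n2);
  return std::atan2(y, x);
}

// raw (unscaled) sums of each Hamiltonian term: fene, lj, bend, torsion.
// If any bond leaves the FENE domain, fene is -Inf (energy undefined).
static void terms_raw(const double* X, int n, const Params& p, double* out) {
  double fene = 0.0, lj = 0.0, bend = 0.0, tor = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    double r = dist3(X + 3 * i, X + 3 * (i + 1));
    if (std::fabs(r - p.r0) >= p.R) { fene = R_NegInf; break; }
    fene += v_fene(r, p);
  }
  int dmin = p.lj_bonded ? 1 : 2;
  for (int i = 0; i < n; ++i)
    for (int j = i + dmin; j < n; ++j)
      lj += v_lj(dist3(X + 3 * i, X + 3 * j), p);
  for (int k = 1; k + 1 < n; ++k) {
    double th = bend_angle(X + 3 * (k - 1), X + 3 * k, X + 3 * (k + 1),
                           p.interior_angle);
    bend += 1.0 - std::cos(th - p.theta0);
  }
  for (int l = 0; l + 3 < n; ++l) {
    double ta = dihedral(X + 3 * l, X + 3 * (l + 1), X + 3 * (l + 2),
                         X + 3 * (l + 3));
    tor += 1.0 - std::cos(ta - p.tau0);
  }
  out[0] = fene; out[1] = lj; out[2] = bend; out[3] = tor;
}

static inline double scale_terms(const double* t, const Params& p) {
  if (t[0] == R_NegInf) return R_PosInf;
  return p.s_fene * t[0] + p.s_lj * t[1] + p.s_theta * t[2] + p.s_tau * t[3];
}

static double order_q_raw(const double* X, int n, const Params& p,
                          double eps) {
  double num = 0.0, den = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 2; j < n; ++j) {
      double v = v_lj(dist3(X + 3 * i, X + 3 * j), p);
      if (j - i > 6) num += v; else den += v;
    }
  if (std::fabs(den) < eps) return 0.0;
  return num / den;
}

// [[Rcpp::export]]
NumericVector energy_terms_cpp(NumericMatrix X, List params) {
  Params p = parse_params(params);
  int n = X.nrow();
  std::vector<double> C(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) C[3 * i + k] = X(i, k);
  NumericVector out(4);
  terms_raw(C.data(), n, p, &out[0]);
  out.names() = CharacterVector::create("fene", "lj", "bend", "torsion");
  return out;
}

// [[Rcpp::export]]
double order_q_cpp(NumericMatrix X, List params, double eps) {
  Params p = parse_params(params);
  int n = X.nrow();
  std::vector<double> C(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) C[3 * i + k] = X(i, k);
  return order_q_raw(C.data(), n, p, eps);
}

// ---- move proposals -------------------------------------------------------
// Each proposal writes the trial coordinates in place over a working copy.
// Pivot ranges: local 0..n-1; global 0..n-2 (block k+1..n-1 nonempty);
// bend 1..n-2; torsion 1..n-2.

static inline int rand_int(int m) {
  int k = (int)(unif_rand() * m);
  return k >= m ? m - 1 : k;
}
static inline double rand_unif(double lo, double hi) {
  return lo + (hi - lo) * unif_rand();
}

static void rotate_block(double* X, int n, int from, const double* origin,
                         const double* axis, double angle) {
  double c = std::cos(angle), s = std::sin(angle);
  for (int i = from; i < n; ++i) {
    double v[3] = {X[3 * i] - origin[0], X[3 * i + 1] - origin[1],
                   X[3 * i + 2] - origin[2]};
    double kxv[3];
    cross3(axis, v, kxv);
    double kd = dot3(axis, v);
    for (int d = 0; d < 3; ++d)
      X[3 * i + d] = origin[d] + v[d] * c + kxv[d] * s +
                     axis[d] * kd * (1.0 - c);
  }
}

static int propose_local(double* X, int n, double step, double* info) {
  int i = rand_int(n);
  for (int d = 0; d < 3; ++d) {
    double dx = rand_unif(-step, step);
    X[3 * i + d] += dx;
    info[d] = dx;
  }
  return i;
}

static int propose_global(double* X, int n, double step, double* info) {
  int k = rand_int(n - 1); // 0..n-2
  for (int d = 0; d < 3; ++d) info[d] = rand_unif(-step, step);
  for (int i = k + 1; i < n; ++i)
    for (int d = 0; d < 3; ++d) X[3 * i + d] += info[d];
  return k;
}

static int propose_bend(double* X, int n, double max_angle, double* info) {
  int k = 1 + rand_int(n - 2); // 1..n-2
  double b1[3], b2[3], axis[3];
  sub3(X + 3 * k, X + 3 * (k - 1), b1);
  sub3(X + 3 * (k + 1), X + 3 * k, b2);
  cross3(b1, b2, axis);
  double na = norm3(axis);
  if (na < 1e-12) {
    // neighboring bonds parallel: uniform axis in the plane perpendicular to
    // the shared bond direction (measure-symmetric, so reversible)
    double u[3] = {b1[0], b1[1], b1[2]};
    double nu = norm3(u);
    for (int d = 0; d < 3; ++d) u[d] /= nu;
    double ref[3] = {1.0, 0.0, 0.0};
    if (std::fabs(u[0]) > 0.9) { ref[0] = 0.0; ref[1] = 1.0; }
    double m1[3], m2[3];
    cross3(u, ref, m1);
    double nm = norm3(m1);
    for (int d = 0; d < 3; ++d) m1[d] /= nm;
    cross3(u, m1, m2);
    double phi = rand_unif(0.0, 2.0 * M_PI);
    for (int d = 0; d < 3; ++d)
      axis[d] = std::cos(phi) * m1[d] + std::sin(phi) * m2[d];
  } else {
    for (int d = 0; d < 3; ++d) axis[d] /= na;
  }
  double ang = rand_unif(-max_angle, max_angle);
  info[0] = ang;
  rotate_block(X, n, k + 1, X + 3 * k, axis, ang);
  return k;
}

static int propose_torsion(double* X, int n, double max_angle, double* info) {
  int k = 1 + rand_int(n - 2); // 1..n-2, axis = bond (k-1,k)
  double axis[3];
  sub3(X + 3 * k, X + 3 * (k - 1), axis);
  double na = norm3(axis);
  for (int d = 0; d < 3; ++d) axis[d] /= na;
  double ang = rand_unif(-max_angle, max_angle);
  info[0] = ang;
  rotate_block(X, n, k + 1, X + 3 * k, axis, ang);
  return k;
}

static List wrap_proposal(const std::vector<double>& C, int n, int pivot,
                          const double* info, int ninfo) {
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = C[3 * i + d];
  NumericVector iv(info, info + ninfo);
  return List::create(_["coords"] = out, _["pivot"] = pivot + 1,
                      _["draw"] = iv);
}

static std::vector<double> flatten(const NumericMatrix& X) {
  int n = X.nrow();
  std::vector<double> C(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) C[3 * i + d] = X(i, d);
  return C;
}

// [[Rcpp::export]]
List propose_local_cpp(NumericMatrix X, double step) {
  std::vector<double> C = flatten(X);
  double info[3];
  int piv = propose_local(C.data(), X.nrow(), step, info);
  return wrap_proposal(C, X.nrow(), piv, info, 3);
}

// [[Rcpp::export]]
List propose_global_cpp(NumericMatrix X, double step) {
  std::vector<double> C = flatten(X);
  double info[3];
  int piv = propose_global(C.data(), X.nrow(), step, info);
  return wrap_proposal(C, X.nrow(), piv, info, 3);
}

// [[Rcpp::export]]
List propose_bend_cpp(NumericMatrix X, double max_angle) {
  std::vector<double> C = flatten(X);
  double info[1];
  int piv = propose_bend(C.data(), X.nrow(), max_angle, info);
  return wrap_proposal(C, X.nrow(), piv, info, 1);
}

// [[Rcpp::export]]
List propose_torsion_cpp(NumericMatrix X, double max_angle) {
  std::vector<double> C = flatten(X);
  double info[1];
  int piv = propose_torsion(C.data(), X.nrow(), max_angle, info);
  return wrap_proposal(C, X.nrow(), piv, info, 1);
}

// ---- Metropolis sweeps ----------------------------------------------------
// One sweep = n move attempts drawn from the move mix
// (local, global displacement, bend rotation, torsion rotation).
// Energy is fully recomputed for every proposal; proposals that push a bond
// out of the FENE domain are rejected unconditionally. E and q are recorded
// once per sweep.

// [[Rcpp::export]]
List run_sweeps_cpp(NumericMatrix X, List params, double beta, int n_sweeps,
                    NumericVector move_probs, double local_step,
                    double global_step, double bend_max, double torsion_max,
                    double q_eps, bool record) {
  Params p = parse_params(params);
  int n = X.nrow();
  std::vector<double> C = flatten(X), T(C);
  double cum[4];
  double tot = 0.0;
  for (int k = 0; k < 4; ++k) tot += move_probs[k];
  double acc0 = 0.0;
  for (int k = 0; k < 4; ++k) { acc0 += move_probs[k] / tot; cum[k] = acc0; }

  double cur[4], trial[4];
  terms_raw(C.data(), n, p, cur);
  if (cur[0] == R_NegInf)
    stop("initial conformation violates the FENE bond-length domain");
  double E = scale_terms(cur, p);

  NumericVector e_trace(record ? n_sweeps : 0),
      q_trace(record ? n_sweeps : 0);
  IntegerVector att(4), acc(4);
  double min_E = E;
  std::vector<double> min_C(C);
  double info[3];

  for (int s = 0; s < n_sweeps; ++s) {
    for (int m = 0; m < n; ++m) {
      double u = unif_rand();
      int kind = 0;
      while (kind < 3 && u > cum[kind]) ++kind;
      T = C;
      switch (kind) {
        case 0: propose_local(T.data(), n, local_step, info); break;
        case 1: propose_global(T.data(), n, global_step, info); break;
        case 2: propose_bend(T.data(), n, bend_max, info); break;
        default: propose_torsion(T.data(), n, torsion_max, info);
      }
      att[kind]++;
      terms_raw(T.data(), n, p, trial);
      if (trial[0] == R_NegInf) continue; // FENE domain violation: reject
      double Et = scale_terms(trial, p);
      double dE = Et - E;
      if (dE <= 0.0 || unif_rand() < std::exp(-beta * dE)) {
        C = T;
        for (int k = 0; k < 4; ++k) cur[k] = trial[k];
        E = Et;
        acc[kind]++;
        if (E < min_E) { min_E = E; min_C = C; }
      }
    }
    if (record) {
      e_trace[s] = E;
      q_trace[s] = order_q_raw(C.data(), n, p, q_eps);
    }
  }
  if (!R_finite(E)) stop("non-finite energy encountered during sweeps");

  NumericMatrix Xout(n, 3), Xmin(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      Xout(i, d) = C[3 * i + d];
      Xmin(i, d) = min_C[3 * i + d];
    }
  NumericVector terms(cur, cur + 4);
  terms.names() = CharacterVector::create("fene", "lj", "bend", "torsion");
  return List::create(
      _["coords"] = Xout, _["energy"] = E, _["terms"] = terms,
      _["e_trace"] = e_trace, _["q_trace"] = q_trace, _["attempts"] = att,
      _["accepts"] = acc, _["min_energy"] = min_E, _["min_coords"] = Xmin);
}
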