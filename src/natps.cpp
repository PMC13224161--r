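// Core MASH propagation for the coupled-harmonic two-state model.
//
// State layout (length-6 numeric vector):
//   [0] q   nuclear position (bohr)
//   [1] p   nuclear momentum (m_e * bohr / a.t.u.)
//   [2] Re c_minus  (lower-adiabat amplitude)
//   [3] Im c_minus
//   [4] Re c_plus   (upper-adiabat amplitude)
//   [5] Im c_plus
//
// The active surface is sign(S_z) with S_z = |c+|^2 - |c-|^2; the tie
// S_z == 0 is resolved to the lower surface so that the rule is
// deterministic and identical under time reversal.

#include <Rcpp.h>
#include <complex>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

struct Model {
  double eps, x0, Vc, mass;
};

static Model as_model(const List& pars) {
  Model m;
  m.eps  = as<double>(pars["epsilon"]);
  m.x0   = as<double>(pars["x0"]);
  m.Vc   = as<double>(pars["Vc"]);
  m.mass = as<double>(pars["mass"]);
  return m;
}

// diabatic diagonal entries and derived quantities
static inline double h11(const Model& m, double q) {
  double u = (q - m.x0) / m.x0; return m.eps * u * u;
}
static inline double h22(const Model& m, double q) {
  double u = (q + m.x0) / m.x0; return m.eps * u * u;
}
static inline double vbar(const Model& m, double q) {
  return 0.5 * (h11(m, q) + h22(m, q));
}
static inline double delta(const Model& m, double q) {
  return 0.5 * (h11(m, q) - h22(m, q));
}
static inline double vz(const Model& m, double q) {
  double d = delta(m, q);
  return std::sqrt(d * d + m.Vc * m.Vc);
}
static inline double dvbar(const Model& m, double q) {
  return 2.0 * m.eps * q / (m.x0 * m.x0);
}
// d(delta)/dq is constant for this model
static inline double ddelta(const Model& m) { return -2.0 * m.eps / m.x0; }
static inline double dvz(const Model& m, double q) {
  return delta(m, q) * ddelta(m) / vz(m, q);
}
// mixing half-angle: eigenvectors lower = (-sin, cos), upper = (cos, sin)
static inline double theta(const Model& m, double q) {
  return 0.5 * std::atan2(m.Vc, delta(m, q));
}
static inline double force(const Model& m, double q, int sgn) {
  return -dvbar(m, q) - sgn * dvz(m, q);
}
static inline int sgn_sz(double sz) { return (sz > 0.0) ? 1 : -1; }

struct State {
  double q, p;
  cplx clo, chi;
};

static State as_state(const NumericVector& v) {
  State s;
  s.q = v[0]; s.p = v[1];
  s.clo = cplx(v[2], v[3]);
  s.chi = cplx(v[4], v[5]);
  return s;
}
static NumericVector state_vec(const State& s) {
  return NumericVector::create(s.q, s.p,
    s.clo.real(), s.clo.imag(), s.chi.real(), s.chi.imag());
}
static inline double sz_of(const State& s) {
  return std::norm(s.chi) - std::norm(s.clo);
}
static inline double sx_of(const State& s) {
  return 2.0 * (std::conj(s.chi) * s.clo).real();
}
static inline double sy_of(const State& s) {
  return 2.0 * (std::conj(s.chi) * s.clo).imag();
}

// ---------------------------------------------------------------------------
// Electronic propagation in the (global) diabatic frame.
//
// The nuclear path inside a velocity-Verlet segment is the drift
// q(s) = q0 + v * s.  Coefficients are rotated from the adiabatic basis at
// q0 into the diabatic frame with the analytic eigenvector matrix
// U = [[-sin t, cos t], [cos t, sin t]] (symmetric, orthogonal), propagated
// with a 4th-order Magnus integrator (two Gauss-Legendre nodes per substep),
// and rotated back at the segment end.  Each substep propagator is exactly
// unitary; the whole map is exactly time-reversal symmetric because the
// Gauss nodes are placed symmetrically and the diabatic H is real.
// ---------------------------------------------------------------------------
static void el_rotate(const Model& m, double q, cplx& a, cplx& b, bool to_dia) {
  // U is symmetric so the same rotation serves both directions
  double th = theta(m, q), s = std::sin(th), c = std::cos(th);
  cplx na = -s * a + c * b;
  cplx nb =  c * a + s * b;
  (void)to_dia;
  a = na; b = nb;
}

static void el_propagate(const Model& m, cplx& clo, cplx& chi,
                         double q0, double v, double tau, int nsub) {
  if (tau <= 0.0) return;
  el_rotate(m, q0, clo, chi, true);      // adiabatic -> diabatic at q0
  const double r6 = 0.28867513459481287; // sqrt(3)/6
  const double s3 = 1.7320508075688772;  // sqrt(3)
  double h = tau / nsub;
  for (int k = 0; k < nsub; ++k) {
    double t0 = k * h;
    double qa = q0 + v * (t0 + h * (0.5 - r6));
    double qb = q0 + v * (t0 + h * (0.5 + r6));
    double H1a = h11(m, qa), H1b = h22(m, qa);
    double H2a = h11(m, qb), H2b = h22(m, qb);
    double d1 = 0.5 * (H1a - H1b), d2 = 0.5 * (H2a - H2b);
    // Omega = -i * (n0 I + n . sigma)
    double n0 = 0.25 * h * (H1a + H1b + H2a + H2b);
    double nx = h * m.Vc;
    double ny = (s3 * h * h / 6.0) * m.Vc * (d2 - d1);
    double nz = 0.5 * h * (d1 + d2);
    double r = std::sqrt(nx * nx + ny * ny + nz * nz);
    cplx ph = std::exp(cplx(0.0, -n0));
    cplx u = clo, w = chi;          // diabatic components
    if (r > 0.0) {
      double cr = std::cos(r), sr = std::sin(r) / r;
      cplx mi(0.0, -1.0);
      cplx su = nz * u + cplx(nx, -ny) * w;
      cplx sw = cplx(nx, ny) * u - nz * w;
      clo = ph * (cr * u + mi * sr * su);
      chi = ph * (cr * w + mi * sr * sw);
    } else {
      clo = ph * u;
      chi = ph * w;
    }
  }
  el_rotate(m, q0 + v * tau, clo, chi, false); // diabatic -> adiabatic at end
}

// one velocity-Verlet segment of duration tau on the active surface,
// with concurrent electronic propagation along the drift path
static State vv_segment(const Model& m, const State& s0, double tau,
                        int act, int nsub) {
  State s = s0;
  if (tau <= 0.0) return s;
  double ph = s.p + 0.5 * tau * force(m, s.q, act);
  double v = ph / m.mass;
  double qn = s.q + tau * v;
  double pn = ph + 0.5 * tau * force(m, qn, act);
  el_propagate(m, s.clo, s.chi, s.q, v, tau, nsub);
  s.q = qn; s.p = pn;
  return s;
}

static inline int nsub_for(double tau, double dt, int nsub) {
  int n = (int)std::ceil(nsub * tau / dt);
  return n < 1 ? 1 : n;
}

// ---------------------------------------------------------------------------
// One MASH step with in-step hop detection.
//
// A trial full step is taken on the active surface; if sign(S_z) flips, the
// crossing time is bracketed by bisection on sub-propagated segments (each
// evaluation restarts from the step's initial state, so the map is exactly
// deterministic).  The hop (rescale / reflect) is applied at the bracket
// endpoint on the new-sign side for allowed hops, and on the old-sign side
// for frustrated hops so that sign(S_z) remains consistent with the active
// surface throughout.
//
// hop record: t_in_step, q, Sx, Sy, direction (+1 up / -1 down), frustrated
// status: 0 ok, 1 second sign change, 2 root search failure
// ---------------------------------------------------------------------------
struct StepResult {
  State s;
  int nhops;
  double hop[8][6];
  int status;
};

static StepResult mash_step_core(const Model& m, const State& s0, double dt,
                                 int nsub, double root_tol, int hop_mode) {
  StepResult res;
  res.nhops = 0;
  res.status = 0;
  int act = sgn_sz(sz_of(s0));
  State trial = vv_segment(m, s0, dt, act, nsub);
  int send = sgn_sz(sz_of(trial));
  if (send == act) {
    res.s = trial;
    return res;
  }

  if (hop_mode == 0) {
    // naive end-of-step detection (reference variant used to demonstrate
    // that the root search is required for time reversibility)
    State s = trial;
    double Vzq = vz(m, s.q);
    int dir = -act;           // +1 attempted up, -1 down
    bool frustrated = false;
    if (dir > 0) {
      double ke = s.p * s.p / (2.0 * m.mass);
      if (ke >= 2.0 * Vzq) {
        double p2 = s.p * s.p - 4.0 * m.mass * Vzq;
        s.p = (s.p >= 0 ? 1.0 : -1.0) * std::sqrt(p2);
      } else {
        s.p = -s.p;
        frustrated = true;
      }
    } else {
      double p2 = s.p * s.p + 4.0 * m.mass * Vzq;
      s.p = (s.p >= 0 ? 1.0 : -1.0) * std::sqrt(p2);
    }
    res.s = s;
    res.nhops = 1;
    res.hop[0][0] = dt; res.hop[0][1] = s.q;
    res.hop[0][2] = sx_of(s); res.hop[0][3] = sy_of(s);
    res.hop[0][4] = dir; res.hop[0][5] = frustrated ? 1.0 : 0.0;
    return res;
  }

  // Piecewise-continuous in-step hop handling, applied iteratively: locate
  // the crossing by bisection, hop there, and treat the remainder of the
  // step as a fresh segment (a further crossing inside the remainder is
  // handled the same way).  More than `max_hops` events in one step abort
  // with a diagnostic.
  const int max_hops = 8;
  State scur = s0;
  double t_off = 0.0;   // time already consumed within the step
  while (true) {
    double span = dt - t_off;
    // bisection bracket on the crossing time within the current segment
    double lo = 0.0, hi = span;
    int maxit = 200, it = 0;
    while (hi - lo > root_tol && it < maxit) {
      double mid = 0.5 * (lo + hi);
      State sm = vv_segment(m, scur, mid, act, nsub_for(mid, dt, nsub));
      if (sgn_sz(sz_of(sm)) == act) lo = mid; else hi = mid;
      ++it;
    }
    if (it >= maxit) { res.status = 2; res.s = scur; return res; }

    int dir = -act;
    bool frustrated = false;
    double t_used;
    State sh;
    if (dir > 0) { // attempted upward hop
      sh = vv_segment(m, scur, hi, act, nsub_for(hi, dt, nsub));
      double Vzq = vz(m, sh.q);
      double ke = sh.p * sh.p / (2.0 * m.mass);
      if (ke >= 2.0 * Vzq) {
        double p2 = sh.p * sh.p - 4.0 * m.mass * Vzq;
        sh.p = (sh.p >= 0 ? 1.0 : -1.0) * std::sqrt(p2);
        t_used = hi;
      } else {
        // frustrated: reflect momentum at the old-sign side of the bracket
        sh = vv_segment(m, scur, lo, act, nsub_for(lo, dt, nsub));
        sh.p = -sh.p;
        frustrated = true;
        t_used = lo;
      }
    } else {       // downward hop: always allowed
      sh = vv_segment(m, scur, hi, act, nsub_for(hi, dt, nsub));
      double Vzq = vz(m, sh.q);
      double p2 = sh.p * sh.p + 4.0 * m.mass * Vzq;
      sh.p = (sh.p >= 0 ? 1.0 : -1.0) * std::sqrt(p2);
      t_used = hi;
    }

    if (res.nhops >= max_hops) { res.status = 1; res.s = sh; return res; }
    res.hop[res.nhops][0] = t_off + t_used;
    res.hop[res.nhops][1] = sh.q;
    res.hop[res.nhops][2] = sx_of(sh);
    res.hop[res.nhops][3] = sy_of(sh);
    res.hop[res.nhops][4] = dir;
    res.hop[res.nhops][5] = frustrated ? 1.0 : 0.0;
    res.nhops += 1;

    int act_new = frustrated ? act : -act;
    t_off += t_used;
    double rem = dt - t_off;
    State sf = vv_segment(m, sh, rem, act_new, nsub_for(rem, dt, nsub));
    if (sgn_sz(sz_of(sf)) == act_new) {
      res.s = sf;
      return res;
    }
    // another crossing inside the remainder: continue from the hop point
    scur = sh;
    act = act_new;
  }
}

// [[Rcpp::export]]
List cpp_mash_step(NumericVector state, double dt, List pars,
                   int nsub, double root_tol, int hop_mode) {
  Model m = as_model(pars);
  StepResult r = mash_step_core(m, as_state(state), dt, nsub, root_tol,
                                hop_mode);
  List out = List::create(
    _["state"]  = state_vec(r.s),
    _["status"] = r.status,
    _["hop"]    = R_NilValue);
  if (r.nhops > 0) {
    NumericMatrix hm(r.nhops, 6);
    for (int i = 0; i < r.nhops; ++i)
      for (int j = 0; j < 6; ++j) hm(i, j) = r.hop[i][j];
    out["hop"] = hm;
  }
  return out;
}

// basin membership: side -1 => q < bound, +1 => q > bound
static inline bool in_basin(double q, int act, double bound, int side,
                            int req_sign) {
  if (act != req_sign) return false;
  return side < 0 ? (q < bound) : (q > bound);
}

// ---------------------------------------------------------------------------
// Multi-step propagation.
//
// mode 0: fixed number of steps.
// mode 1: stop as soon as a basin is entered (the entering point is kept);
//         status "A"/"B"/"maxsteps".
// Records every point on the uniform grid plus all hop events.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_propagate(NumericVector state, double t0, double dt, int nsteps,
                   List pars, int nsub, double root_tol, int hop_mode,
                   int mode,
                   double boundA, int sideA, double boundB, int sideB,
                   int req_sign) {
  Model m = as_model(pars);
  State s = as_state(state);
  NumericMatrix pts(nsteps + 1, 7);
  std::vector<double> hops;
  hops.reserve(64);

  auto record = [&](int row, double t, const State& st) {
    pts(row, 0) = t;
    pts(row, 1) = st.q;
    pts(row, 2) = st.p;
    pts(row, 3) = sx_of(st);
    pts(row, 4) = sy_of(st);
    pts(row, 5) = sz_of(st);
    pts(row, 6) = sgn_sz(sz_of(st));
  };

  record(0, t0, s);
  std::string status = "maxsteps";
  int done = 0;
  int act0 = sgn_sz(sz_of(s));
  if (mode == 1) {
    if (in_basin(s.q, act0, boundA, sideA, req_sign)) status = "A";
    if (in_basin(s.q, act0, boundB, sideB, req_sign)) status = "B";
    if (status != "maxsteps") {
      List out = List::create(
        _["points"] = pts(Range(0, 0), _),
        _["hops"]   = NumericMatrix(0, 6),
        _["status"] = status,
        _["steps"]  = 0,
        _["state"]  = state_vec(s));
      return out;
    }
  }

  for (int k = 0; k < nsteps; ++k) {
    StepResult r = mash_step_core(m, s, dt, nsub, root_tol, hop_mode);
    if (r.status != 0) {
      stop(r.status == 1
        ? "more than 8 S_z sign changes within one step: reduce the time step dt"
        : "hop root search failed to converge");
    }
    s = r.s;
    double t = t0 + (k + 1) * dt;
    for (int i = 0; i < r.nhops; ++i) {
      hops.push_back(t0 + k * dt + r.hop[i][0]);
      for (int j = 1; j < 6; ++j) hops.push_back(r.hop[i][j]);
    }
    record(k + 1, t, s);
    done = k + 1;
    if (mode == 1) {
      int act = sgn_sz(sz_of(s));
      if (in_basin(s.q, act, boundA, sideA, req_sign)) { status = "A"; break; }
      if (in_basin(s.q, act, boundB, sideB, req_sign)) { status = "B"; break; }
    }
  }
  if (mode == 0) status = "done";

  int nh = hops.size() / 6;
  NumericMatrix hm(nh, 6);
  for (int i = 0; i < nh; ++i)
    for (int j = 0; j < 6; ++j) hm(i, j) = hops[6 * i + j];

  List out = List::create(
    _["points"] = pts(Range(0, done), _),
    _["hops"]   = hm,
    _["status"] = status,
    _["steps"]  = done,
    _["state"]  = state_vec(s));
  return out;
}

// electronic propagation along a linear drift path, exported for tests
// [[Rcpp::export]]
NumericVector cpp_electronic_step(NumericVector c4, double q0, double v,
                                  double tau, int nsub, List pars) {
  Model m = as_model(pars);
  cplx clo(c4[0], c4[1]), chi(c4[2], c4[3]);
  el_propagate(m, clo, chi, q0, v, tau, nsub);
  return NumericVector::create(clo.real(), clo.imag(),
                               chi.real(), chi.imag());
}

// adiabatic quantities, exported so R-level formulas can be cross-checked
// [[Rcpp::export]]
List cpp_adiabatize(NumericVector q, List pars) {
  Model m = as_model(pars);
  int n = q.size();
  NumericVector Vb(n), Vzv(n), dVb(n), dVz(n), nac(n);
  for (int i = 0; i < n; ++i) {
    Vb[i]  = vbar(m, q[i]);
    Vzv[i] = vz(m, q[i]);
    dVb[i] = dvbar(m, q[i]);
    dVz[i] = dvz(m, q[i]);
    nac[i] = -0.5 * m.Vc * ddelta(m) /
             (vz(m, q[i]) * vz(m, q[i]));
  }
  return List::create(_["Vbar"] = Vb, _["Vz"] = Vzv, _["dVbar"] = dVb,
                      _["dVz"] = dVz, _["nac"] = nac);
}
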