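// Position-based-dynamics engine for the bed--human world.
//
// Bodies are point masses linked by equality distance constraints (rigid
// torso cluster + limb segments). Collision geometry: an infinite floor plane
// at z = 0 and one axis-aligned bed box; every point carries a contact radius.
// Integration: semi-implicit Euler prediction, Gauss-Seidel constraint
// projection, velocity update from positions, Coulomb-style positional
// friction on floor / bed-top contacts. Fully deterministic.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Params {
  int n;
  std::vector<double> invmass;
  std::vector<int> ea, eb;       // 0-based edge endpoints
  std::vector<double> rest;
  double xmin, xmax, ymin, ymax, top;  // bed footprint + top height
  double dt, gravity, mu_s, mu_k, damping, radius;
  int iters;
  std::vector<int> hand;         // 1 if the point is a hand (wrist)
};

static Params read_params(const List& par) {
  Params p;
  NumericVector invm = par["invmass"];
  p.n = invm.size();
  p.invmass.assign(invm.begin(), invm.end());
  IntegerVector ea = par["edge_a"], eb = par["edge_b"];
  p.ea.assign(ea.begin(), ea.end());
  p.eb.assign(eb.begin(), eb.end());
  NumericVector rest = par["rest"];
  p.rest.assign(rest.begin(), rest.end());
  NumericVector bb = par["bed"]; // xmin xmax ymin ymax top
  p.xmin = bb[0]; p.xmax = bb[1]; p.ymin = bb[2]; p.ymax = bb[3]; p.top = bb[4];
  p.dt = as<double>(par["dt"]);
  p.gravity = as<double>(par["gravity"]);
  p.mu_s = as<double>(par["mu_static"]);
  p.mu_k = as<double>(par["mu_kinetic"]);
  p.damping = as<double>(par["damping"]);
  p.radius = as<double>(par["radius"]);
  p.iters = as<int>(par["iters"]);
  IntegerVector hand = par["hand"];
  p.hand.assign(hand.begin(), hand.end());
  return p;
}

static const double CTOL = 1e-5;

// contact codes: 0 none, 1 bed, 2 floor, 3 bed+floor
static inline int classify_contact(const Params& p, double x, double y, double z) {
  int code = 0;
  if (z - p.radius <= CTOL) code |= 2;
  double dx = std::min(x - (p.xmin - p.radius), (p.xmax + p.radius) - x);
  double dy = std::min(y - (p.ymin - p.radius), (p.ymax + p.radius) - y);
  double dz = (p.top + p.radius) - z;
  double m3 = std::min(std::min(dx, dy), dz);
  if (m3 >= -CTOL && dx >= -CTOL && dy >= -CTOL && dz >= -CTOL && z > CTOL)
    code |= 1;
  return code;
}

// One PBD step in place. Returns false if the state went non-finite.
static bool do_step(std::vector<double>& P, std::vector<double>& V,
                    const Params& p, std::vector<int>& contact) {
  const int n = p.n;
  std::vector<double> prev(P);
  // integrate
  for (int i = 0; i < n; ++i) {
    if (p.invmass[i] > 0.0) {
      V[3 * i + 2] -= p.gravity * p.dt;
      for (int k = 0; k < 3; ++k) V[3 * i + k] *= (1.0 - p.damping);
      for (int k = 0; k < 3; ++k) P[3 * i + k] += p.dt * V[3 * i + k];
    }
  }
  std::vector<double> ncorr(n, 0.0); // accumulated upward normal correction
  for (int it = 0; it < p.iters; ++it) {
    // distance constraints
    for (size_t e = 0; e < p.ea.size(); ++e) {
      int a = p.ea[e], b = p.eb[e];
      double dx = P[3 * b] - P[3 * a];
      double dy = P[3 * b + 1] - P[3 * a + 1];
      double dz = P[3 * b + 2] - P[3 * a + 2];
      double len = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (len < 1e-12) continue;
      double wsum = p.invmass[a] + p.invmass[b];
      if (wsum <= 0.0) continue;
      double corr = (len - p.rest[e]) / (len * wsum);
      double ca = p.invmass[a] * corr, cb = p.invmass[b] * corr;
      P[3 * a] += ca * dx;     P[3 * a + 1] += ca * dy;     P[3 * a + 2] += ca * dz;
      P[3 * b] -= cb * dx;     P[3 * b + 1] -= cb * dy;     P[3 * b + 2] -= cb * dz;
    }
    // collisions
    for (int i = 0; i < n; ++i) {
      double& x = P[3 * i]; double& y = P[3 * i + 1]; double& z = P[3 * i + 2];
      // floor plane
      if (z < p.radius) { ncorr[i] += p.radius - z; z = p.radius; }
      // bed box (expanded by the point radius)
      double lox = p.xmin - p.radius, hix = p.xmax + p.radius;
      double loy = p.ymin - p.radius, hiy = p.ymax + p.radius;
      double hiz = p.top + p.radius;
      if (x > lox && x < hix && y > loy && y < hiy && z < hiz && z > 0.0) {
        double dxl = x - lox, dxr = hix - x;
        double dyl = y - loy, dyr = hiy - y;
        double dzt = hiz - z;
        double m = std::min(std::min(std::min(dxl, dxr), std::min(dyl, dyr)), dzt);
        if (m == dzt)      { ncorr[i] += dzt; z = hiz; }
        else if (m == dxl) { x = lox; }
        else if (m == dxr) { x = hix; }
        else if (m == dyl) { y = loy; }
        else               { y = hiy; }
      }
    }
  }
  // positional friction against horizontal supports (floor, bed top)
  for (int i = 0; i < n; ++i) {
    if (ncorr[i] <= 0.0) continue;
    double tx = P[3 * i] - prev[3 * i];
    double ty = P[3 * i + 1] - prev[3 * i + 1];
    double tl = std::sqrt(tx * tx + ty * ty);
    if (tl < 1e-12) continue;
    if (tl < p.mu_s * ncorr[i]) {
      P[3 * i] = prev[3 * i]; P[3 * i + 1] = prev[3 * i + 1];
    } else {
      double s = std::min(1.0, p.mu_k * ncorr[i] / tl);
      P[3 * i] -= s * tx; P[3 * i + 1] -= s * ty;
    }
  }
  // velocities from positions
  bool finite = true;
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      V[3 * i + k] = (P[3 * i + k] - prev[3 * i + k]) / p.dt;
      if (!std::isfinite(P[3 * i + k]) || !std::isfinite(V[3 * i + k]))
        finite = false;
      if (std::fabs(V[3 * i + k]) > 50.0) finite = false;
    }
  }
  contact.assign(n, 0);
  if (finite) {
    for (int i = 0; i < n; ++i)
      contact[i] = classify_contact(p, P[3 * i], P[3 * i + 1], P[3 * i + 2]);
  }
  return finite;
}

static std::vector<double> mat_to_vec(const NumericMatrix& M) {
  std::vector<double> out(M.nrow() * 3);
  for (int i = 0; i < M.nrow(); ++i)
    for (int k = 0; k < 3; ++k) out[3 * i + k] = M(i, k);
  return out;
}

static NumericMatrix vec_to_mat(const std::vector<double>& v, int n) {
  NumericMatrix M(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) M(i, k) = v[3 * i + k];
  return M;
}

// [[Rcpp::export]]
List eng_step(NumericMatrix P0, NumericMatrix V0, List par) {
  Params p = read_params(par);
  std::vector<double> P = mat_to_vec(P0), V = mat_to_vec(V0);
  std::vector<int> contact;
  bool ok = do_step(P, V, p, contact);
  return List::create(
    _["P"] = vec_to_mat(P, p.n), _["V"] = vec_to_mat(V, p.n),
    _["contact"] = IntegerVector(contact.begin(), contact.end()),
    _["unstable"] = !ok);
}

// Drop phase: step until first humanoid-bed contact. Result codes:
// 0 = bed contact reached, 1 = floor contact before bed, 2 = timeout,
// 3 = instability.
// [[Rcpp::export]]
List eng_drop(NumericMatrix P0, NumericMatrix V0, List par, int max_steps) {
  Params p = read_params(par);
  std::vector<double> P = mat_to_vec(P0), V = mat_to_vec(V0);
  std::vector<int> contact;
  int result = 2, steps = 0;
  for (int s = 1; s <= max_steps; ++s) {
    if (!do_step(P, V, p, contact)) { result = 3; steps = s; break; }
    bool bed = false, floor_hit = false;
    for (int i = 0; i < p.n; ++i) {
      if (contact[i] & 1) bed = true;
      if (contact[i] & 2) floor_hit = true;
    }
    if (bed) { result = 0; steps = s; break; }
    if (floor_hit) { result = 1; steps = s; break; }
    steps = s;
  }
  return List::create(
    _["P"] = vec_to_mat(P, p.n), _["V"] = vec_to_mat(V, p.n),
    _["steps"] = steps, _["result"] = result);
}

// Rollout with fall detection. frame_steps are 0-based step indices at which
// planar keypoint snapshots (first n_key points) are recorded; index 0 is the
// start state. Stops early at the first non-hand floor contact.
// [[Rcpp::export]]
List eng_rollout(NumericMatrix P0, NumericMatrix V0, List par, int n_steps,
                 IntegerVector frame_steps, int n_key) {
  Params p = read_params(par);
  std::vector<double> P = mat_to_vec(P0), V = mat_to_vec(V0);
  std::vector<int> contact;
  int nf = frame_steps.size();
  NumericMatrix frames(nf, 2 * n_key);
  std::fill(frames.begin(), frames.end(), NA_REAL);
  IntegerMatrix log(n_steps, 2); // col 0: non-hand floor, col 1: hand floor
  std::fill(log.begin(), log.end(), 0);
  auto snap = [&](int step_idx) {
    for (int f = 0; f < nf; ++f) {
      if (frame_steps[f] == step_idx) {
        for (int i = 0; i < n_key; ++i) {
          frames(f, 2 * i) = P[3 * i];
          frames(f, 2 * i + 1) = P[3 * i + 1];
        }
      }
    }
  };
  snap(0);
  int fall_step = -1;
  bool unstable = false;
  int steps_run = 0;
  for (int s = 1; s <= n_steps; ++s) {
    if (!do_step(P, V, p, contact)) { unstable = true; steps_run = s; break; }
    bool nonhand = false, handc = false;
    for (int i = 0; i < p.n; ++i) {
      if (contact[i] & 2) {
        if (p.hand[i]) handc = true; else nonhand = true;
      }
    }
    log(s - 1, 0) = nonhand ? 1 : 0;
    log(s - 1, 1) = handc ? 1 : 0;
    steps_run = s;
    if (nonhand) { fall_step = s; break; }
    snap(s);
  }
  return List::create(
    _["P"] = vec_to_mat(P, p.n), _["V"] = vec_to_mat(V, p.n),
    _["fall_step"] = fall_step, _["unstable"] = unstable,
    _["steps_run"] = steps_run, _["frames"] = frames, _["log"] = log);
}
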