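// Arena physics, ray-cast perception, neural controller forward pass and
// the per-episode simulation loop. Kept in C++ because an evolutionary run
// evaluates hundreds of millions of controller steps; the R-level module
// surface wraps these routines and cross-checks them against independent
// R oracles in the test suite.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

constexpr double INF = 1e30;

// Deterministic 64-bit Mersenne-Twister uniform draws, mapped to [0,1)
// explicitly so results do not depend on library distribution internals.
struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
};

struct Config {
  double arena_w, arena_h, radius, diameter;
  int n_proximity;
  double proximity_range;
  int n_camera;
  double camera_fov;  // radians
  double v_max, w_max;
  int n_hidden, n_outputs;
  int episode_steps, capture_steps;
  double catch_distance;
  int n_hares, n_stags;
  double rew_hare_solo, rew_hare_coop, rew_stag_solo, rew_stag_coop;
  bool cumulative;
};

Config parse_config(const List& cfg) {
  Config c;
  c.arena_w = as<double>(cfg["arena_w"]);
  c.arena_h = as<double>(cfg["arena_h"]);
  c.diameter = as<double>(cfg["diameter"]);
  c.radius = c.diameter / 2.0;
  c.n_proximity = as<int>(cfg["n_proximity"]);
  c.proximity_range = as<double>(cfg["proximity_range"]);
  c.n_camera = as<int>(cfg["n_camera"]);
  c.camera_fov = as<double>(cfg["camera_fov_rad"]);
  c.v_max = as<double>(cfg["v_max"]);
  c.w_max = as<double>(cfg["w_max"]);
  c.n_hidden = as<int>(cfg["n_hidden"]);
  c.n_outputs = as<int>(cfg["n_outputs"]);
  c.episode_steps = as<int>(cfg["episode_steps"]);
  c.capture_steps = as<int>(cfg["capture_steps"]);
  c.catch_distance = as<double>(cfg["catch_distance"]);
  c.n_hares = as<int>(cfg["n_hares"]);
  c.n_stags = as<int>(cfg["n_stags"]);
  NumericVector r = cfg["rewards"];  // hare_solo, hare_coop, stag_solo, stag_coop
  c.rew_hare_solo = r[0];
  c.rew_hare_coop = r[1];
  c.rew_stag_solo = r[2];
  c.rew_stag_coop = r[3];
  c.cumulative = as<bool>(cfg["cumulative_capture"]);
  return c;
}

// World: agents 0 and 1 are the hunters, the rest are prey.
// kind: 0 = hunter, 1 = hare, 2 = stag.
struct World {
  std::vector<double> x, y;
  std::vector<int> kind;
  double heading[2];
};

// Distance from an interior point to the arena boundary along a ray.
double ray_wall_distance(double ox, double oy, double dx, double dy,
                         double w, double h) {
  double t = INF;
  if (dx > 0) t = std::min(t, (w - ox) / dx);
  if (dx < 0) t = std::min(t, (0 - ox) / dx);
  if (dy > 0) t = std::min(t, (h - oy) / dy);
  if (dy < 0) t = std::min(t, (0 - oy) / dy);
  return t;
}

// Smallest non-negative ray parameter hitting the disk, or -1 for a miss.
// An origin inside the disk reports distance 0.
double ray_circle_distance(double ox, double oy, double dx, double dy,
                           double cx, double cy, double r) {
  double mx = cx - ox, my = cy - oy;
  double b = mx * dx + my * dy;
  double c = mx * mx + my * my - r * r;
  if (c <= 0.0) return 0.0;  // origin inside or on the disk
  if (b <= 0.0) return -1.0;  // disk centre behind the origin
  double disc = b * b - c;
  if (disc < 0.0) return -1.0;
  double t = b - std::sqrt(disc);
  if (t < 0.0) return -1.0;
  return t;
}

// First agent disk intersected by the ray, excluding `exclude`.
// Returns the index hit (or -1) and writes the distance.
int cast_ray_agents(const World& w, double ox, double oy, double angle,
                    double radius, int exclude, double* dist_out) {
  double dx = std::cos(angle), dy = std::sin(angle);
  double best = INF;
  int hit = -1;
  for (size_t j = 0; j < w.x.size(); ++j) {
    if ((int)j == exclude) continue;
    double t = ray_circle_distance(ox, oy, dx, dy, w.x[j], w.y[j], radius);
    if (t >= 0.0 && t < best) {
      best = t;
      hit = (int)j;
    }
  }
  *dist_out = best;
  return hit;
}

inline double clamp01(double v) {
  return v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
}

inline double sigmoid(double v) { return 1.0 / (1.0 + std::exp(-v)); }

// Unit direction vectors of the sensor rays relative to the heading,
// precomputed once per episode; per step they are rotated by the current
// heading at the cost of two trig calls per hunter.
struct SensorGeom {
  std::vector<double> px, py;  // proximity sensor offsets
  std::vector<double> cx, cy;  // camera ray offsets
  double diag;
  double prox_reach2;  // squared reach of a proximity ray to a disk centre
};

SensorGeom make_sensor_geom(const Config& c) {
  SensorGeom g;
  g.px.resize(c.n_proximity);
  g.py.resize(c.n_proximity);
  for (int k = 0; k < c.n_proximity; ++k) {
    double off = 2.0 * M_PI * k / c.n_proximity;
    g.px[k] = std::cos(off);
    g.py[k] = std::sin(off);
  }
  g.cx.resize(c.n_camera);
  g.cy.resize(c.n_camera);
  for (int k = 0; k < c.n_camera; ++k) {
    double off = -c.camera_fov / 2.0 + c.camera_fov * (k + 0.5) / c.n_camera;
    g.cx[k] = std::cos(off);
    g.cy[k] = std::sin(off);
  }
  g.diag = std::sqrt(c.arena_w * c.arena_w + c.arena_h * c.arena_h);
  double reach = c.radius + c.proximity_range + c.radius;
  g.prox_reach2 = reach * reach;
  return g;
}

// Sensory input vector of hunter h: n_proximity proximity activations,
// 4 values per camera ray (type bit 1, type bit 2, proximity, presence),
// and a trailing bias input fixed at 1.
void build_inputs(const Config& c, const SensorGeom& g, const World& w,
                  int h, std::vector<double>& inputs) {
  const double ox = w.x[h], oy = w.y[h], heading = w.heading[h];
  const double ch = std::cos(heading), sh = std::sin(heading);
  const int n = (int)w.x.size();
  int pos = 0;

  // Agents within reach of any proximity ray (usually none or one).
  static thread_local std::vector<int> near_idx;
  near_idx.clear();
  for (int j = 0; j < n; ++j) {
    if (j == h) continue;
    double dx = w.x[j] - ox, dy = w.y[j] - oy;
    if (dx * dx + dy * dy <= g.prox_reach2) near_idx.push_back(j);
  }
  for (int k = 0; k < c.n_proximity; ++k) {
    double dx = ch * g.px[k] - sh * g.py[k];
    double dy = sh * g.px[k] + ch * g.py[k];
    double t = ray_wall_distance(ox, oy, dx, dy, c.arena_w, c.arena_h);
    for (int j : near_idx) {
      double ta = ray_circle_distance(ox, oy, dx, dy, w.x[j], w.y[j],
                                      c.radius);
      if (ta >= 0.0 && ta < t) t = ta;
    }
    double d = t - c.radius;  // from body surface to the obstacle
    inputs[pos++] = clamp01(1.0 - d / c.proximity_range);
  }

  for (int k = 0; k < c.n_camera; ++k) {
    double dx = ch * g.cx[k] - sh * g.cy[k];
    double dy = sh * g.cx[k] + ch * g.cy[k];
    double twall = ray_wall_distance(ox, oy, dx, dy, c.arena_w, c.arena_h);
    double best = twall;
    int hit = -1;
    for (int j = 0; j < n; ++j) {
      if (j == h) continue;
      double ta = ray_circle_distance(ox, oy, dx, dy, w.x[j], w.y[j],
                                      c.radius);
      if (ta >= 0.0 && ta < best) {
        best = ta;
        hit = j;
      }
    }
    if (hit >= 0) {
      int kind = w.kind[hit];
      // type code: hunter = (0,1), hare = (1,0), stag = (1,1)
      inputs[pos++] = (kind == 1 || kind == 2) ? 1.0 : 0.0;
      inputs[pos++] = (kind == 0 || kind == 2) ? 1.0 : 0.0;
      inputs[pos++] = clamp01(1.0 - best / g.diag);
      inputs[pos++] = 1.0;
    } else {
      inputs[pos++] = 0.0;
      inputs[pos++] = 0.0;
      inputs[pos++] = clamp01(1.0 - twall / g.diag);
      inputs[pos++] = 0.0;
    }
  }
  inputs[pos++] = 1.0;  // bias
}

// Feed-forward pass. Genes in [0,1] map linearly to weights in
// [-w_max, w_max]. Layout: input->hidden weights row-major over inputs,
// then (hidden + hidden-bias)->output weights row-major over hidden.
// `weights` holds the already-decoded values; zero inputs are skipped
// (most sensor channels are silent in a sparse arena).
void forward_pass_decoded(const Config& c, const std::vector<double>& weights,
                          int n_inputs, const std::vector<double>& inputs,
                          double* out) {
  const int H = c.n_hidden, O = c.n_outputs;
  double hidden[64];
  for (int j = 0; j < H; ++j) hidden[j] = 0.0;
  const double* w = weights.data();
  for (int i = 0; i < n_inputs; ++i) {
    const double xi = inputs[i];
    if (xi == 0.0) continue;
    const double* row = w + (size_t)i * H;
    for (int j = 0; j < H; ++j) hidden[j] += row[j] * xi;
  }
  for (int j = 0; j < H; ++j) hidden[j] = sigmoid(hidden[j]);
  const double* v = w + (size_t)n_inputs * H;
  for (int k = 0; k < O; ++k) {
    double acc = v[(size_t)H * O + k];  // hidden-layer bias weight
    for (int j = 0; j < H; ++j) acc += v[(size_t)j * O + k] * hidden[j];
    out[k] = sigmoid(acc);
  }
}

void decode_genes(const Config& c, const double* genes, size_t n,
                  std::vector<double>& weights) {
  weights.resize(n);
  for (size_t i = 0; i < n; ++i) weights[i] = (2.0 * genes[i] - 1.0) * c.w_max;
}

void forward_pass(const Config& c, const double* genes, int n_inputs,
                  const std::vector<double>& inputs, double* out) {
  std::vector<double> weights;
  decode_genes(c, genes,
               (size_t)n_inputs * c.n_hidden + (c.n_hidden + 1) * c.n_outputs,
               weights);
  forward_pass_decoded(c, weights, n_inputs, inputs, out);
}

// Push the moving agent m out of walls (per-axis clamp) and out of every
// other agent disk (displacement along the centre-to-centre axis to exact
// contact); stationary agents never move. Alternating projections handle
// chained contacts (pushed off one body into a wall and back); iteration
// stops as soon as a pass changes nothing.
void resolve_collisions(const Config& c, World& w, int m) {
  // a hair of slack keeps freshly projected contacts from re-triggering
  const double lim = c.diameter * c.diameter - 1e-9;
  for (int pass = 0; pass < 16; ++pass) {
    bool moved = false;
    for (size_t j = 0; j < w.x.size(); ++j) {
      if ((int)j == m) continue;
      double dx = w.x[m] - w.x[j], dy = w.y[m] - w.y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < lim) {
        double d = std::sqrt(d2);
        if (d < 1e-12) {  // coincident centres: deterministic push along +x
          dx = 1.0;
          dy = 0.0;
          d = 1.0;
        }
        w.x[m] = w.x[j] + dx / d * c.diameter;
        w.y[m] = w.y[j] + dy / d * c.diameter;
        moved = true;
      }
    }
    bool on_x = false, on_y = false;  // clamped against a vertical/horizontal wall
    double nx = std::min(std::max(w.x[m], c.radius), c.arena_w - c.radius);
    double ny = std::min(std::max(w.y[m], c.radius), c.arena_h - c.radius);
    if (nx != w.x[m]) {
      w.x[m] = nx;
      on_x = true;
      moved = true;
    }
    if (ny != w.y[m]) {
      w.y[m] = ny;
      on_y = true;
      moved = true;
    }
    // If the wall clamp re-opened a disk overlap, slide along the wall to
    // the exact tangency point instead of bouncing between projections.
    if (on_x != on_y) {
      for (size_t j = 0; j < w.x.size(); ++j) {
        if ((int)j == m) continue;
        double dx = w.x[m] - w.x[j], dy = w.y[m] - w.y[j];
        if (dx * dx + dy * dy < lim) {
          if (on_x) {
            double disc = c.diameter * c.diameter - dx * dx;
            if (disc > 0) {
              double s = (dy >= 0) ? 1.0 : -1.0;
              w.y[m] = w.y[j] + s * std::sqrt(disc);
            }
          } else {
            double disc = c.diameter * c.diameter - dy * dy;
            if (disc > 0) {
              double s = (dx >= 0) ? 1.0 : -1.0;
              w.x[m] = w.x[j] + s * std::sqrt(disc);
            }
          }
        }
      }
      // the slide may itself cross another wall; the next pass re-checks
    }
    if (!moved) return;
  }
  // Corner squeezes that cannot satisfy every contact: walls win.
  w.x[m] = std::min(std::max(w.x[m], c.radius), c.arena_w - c.radius);
  w.y[m] = std::min(std::max(w.y[m], c.radius), c.arena_h - c.radius);
}

// Rejection-sample a position at least `radius` from every wall and not
// overlapping any existing agent disk (indices [0, upto)).
bool sample_position(const Config& c, const World& w, size_t upto, Rng& rng,
                     double* px, double* py, int skip = -1) {
  for (int tries = 0; tries < 10000; ++tries) {
    double x = c.radius + rng.unif() * (c.arena_w - 2.0 * c.radius);
    double y = c.radius + rng.unif() * (c.arena_h - 2.0 * c.radius);
    bool ok = true;
    for (size_t j = 0; j < upto; ++j) {
      if ((int)j == skip) continue;
      double dx = x - w.x[j], dy = y - w.y[j];
      if (dx * dx + dy * dy < c.diameter * c.diameter) {
        ok = false;
        break;
      }
    }
    if (ok) {
      *px = x;
      *py = y;
      return true;
    }
  }
  return false;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_episode(NumericVector genome_a, NumericVector genome_b,
                     List cfg, double seed, bool record_trajectories,
                     Nullable<List> init = R_NilValue) {
  Config c = parse_config(cfg);
  if (c.n_outputs != 2) stop("the episode loop drives exactly two wheels");
  const int n_inputs = c.n_proximity + 4 * c.n_camera + 1;
  const int expected_len = n_inputs * c.n_hidden + (c.n_hidden + 1) * c.n_outputs;
  if (genome_a.size() != expected_len || genome_b.size() != expected_len) {
    stop("genome length must be %d for this architecture", expected_len);
  }
  Rng rng((uint64_t)seed);
  World w;

  if (init.isNotNull()) {
    List ini(init);
    NumericVector ix = ini["x"], iy = ini["y"], ih = ini["heading"];
    IntegerVector ik = ini["kind"];
    int n = ix.size();
    w.x.assign(ix.begin(), ix.end());
    w.y.assign(iy.begin(), iy.end());
    w.kind.assign(ik.begin(), ik.end());
    if (n < 2 || w.kind[0] != 0 || w.kind[1] != 0) {
      stop("init world must start with the two hunters");
    }
    w.heading[0] = ih[0];
    w.heading[1] = ih[1];
  } else {
    int n = 2 + c.n_hares + c.n_stags;
    w.x.resize(n);
    w.y.resize(n);
    w.kind.resize(n);
    for (int i = 0; i < n; ++i) {
      w.kind[i] = i < 2 ? 0 : (i < 2 + c.n_hares ? 1 : 2);
      if (!sample_position(c, w, i, rng, &w.x[i], &w.y[i])) {
        stop("agent placement failed: arena too crowded");
      }
    }
    w.heading[0] = rng.unif() * 2.0 * M_PI;
    w.heading[1] = rng.unif() * 2.0 * M_PI;
  }

  const int n_agents = (int)w.x.size();
  const int n_prey = n_agents - 2;
  std::vector<int> counter(n_prey, 0);
  std::vector<double> inputs(n_inputs);
  double out[8];
  double payoff[2] = {0.0, 0.0};
  int n_hare_hunts = 0, n_coop_stag = 0, n_solo_stag = 0;

  std::vector<int> ev_time, ev_kind, ev_coop, ev_h1, ev_h2;
  std::vector<double> ev_reward;

  NumericMatrix traj(record_trajectories ? c.episode_steps : 0, 7);

  NumericVector init_x(w.x.begin(), w.x.end());
  NumericVector init_y(w.y.begin(), w.y.end());
  NumericVector init_heading = NumericVector::create(w.heading[0], w.heading[1]);
  IntegerVector init_kind(w.kind.begin(), w.kind.end());

  SensorGeom geom = make_sensor_geom(c);
  std::vector<double> weights[2];
  decode_genes(c, genome_a.begin(), expected_len, weights[0]);
  decode_genes(c, genome_b.begin(), expected_len, weights[1]);

  for (int step = 1; step <= c.episode_steps; ++step) {
    // Hunters perceive, decide and move sequentially in id order; the
    // second hunter sees the first one's updated position.
    for (int h = 0; h < 2; ++h) {
      build_inputs(c, geom, w, h, inputs);
      forward_pass_decoded(c, weights[h], n_inputs, inputs, out);
      double vl = (2.0 * out[0] - 1.0) * c.v_max;
      double vr = (2.0 * out[1] - 1.0) * c.v_max;
      w.heading[h] += (vr - vl) / c.diameter;
      double speed = (vl + vr) / 2.0;
      w.x[h] += speed * std::cos(w.heading[h]);
      w.y[h] += speed * std::sin(w.heading[h]);
      resolve_collisions(c, w, h);
    }

    // Capture bookkeeping: a prey's counter advances while at least one
    // hunter is within catching distance and (by default) resets on any
    // step with no hunter in range. A capture is cooperative iff both
    // hunters are in range at the final (triggering) step.
    for (int p = 0; p < n_prey; ++p) {
      int a = 2 + p;
      bool in0, in1;
      {
        double dx = w.x[0] - w.x[a], dy = w.y[0] - w.y[a];
        in0 = dx * dx + dy * dy <= c.catch_distance * c.catch_distance;
        dx = w.x[1] - w.x[a];
        dy = w.y[1] - w.y[a];
        in1 = dx * dx + dy * dy <= c.catch_distance * c.catch_distance;
      }
      if (in0 || in1) {
        counter[p] += 1;
      } else if (!c.cumulative) {
        counter[p] = 0;
      }
      if (counter[p] >= c.capture_steps) {
        bool coop = in0 && in1;
        int kind = w.kind[a];
        double reward;
        if (kind == 1) {
          reward = coop ? c.rew_hare_coop : c.rew_hare_solo;
          n_hare_hunts += 1;
        } else {
          reward = coop ? c.rew_stag_coop : c.rew_stag_solo;
          if (coop) n_coop_stag += 1; else n_solo_stag += 1;
        }
        if (in0) payoff[0] += reward;
        if (in1) payoff[1] += reward;
        ev_time.push_back(step);
        ev_kind.push_back(kind);
        ev_coop.push_back(coop ? 1 : 0);
        ev_h1.push_back(in0 ? 1 : 0);
        ev_h2.push_back(in1 ? 1 : 0);
        ev_reward.push_back(reward);
        // Same-kind respawn keeps the prey count constant; the captured
        // prey's own (vacated) position does not block the draw.
        double nx, ny;
        if (!sample_position(c, w, w.x.size(), rng, &nx, &ny, a)) {
          stop("prey respawn failed: arena too crowded");
        }
        w.x[a] = nx;
        w.y[a] = ny;
        counter[p] = 0;
      }
    }

    if (record_trajectories) {
      traj(step - 1, 0) = step;
      traj(step - 1, 1) = w.x[0];
      traj(step - 1, 2) = w.y[0];
      traj(step - 1, 3) = w.heading[0];
      traj(step - 1, 4) = w.x[1];
      traj(step - 1, 5) = w.y[1];
      traj(step - 1, 6) = w.heading[1];
    }
  }

  List events = List::create(
      _["time"] = IntegerVector(ev_time.begin(), ev_time.end()),
      _["kind"] = IntegerVector(ev_kind.begin(), ev_kind.end()),
      _["cooperative"] = IntegerVector(ev_coop.begin(), ev_coop.end()),
      _["hunter1"] = IntegerVector(ev_h1.begin(), ev_h1.end()),
      _["hunter2"] = IntegerVector(ev_h2.begin(), ev_h2.end()),
      _["reward"] = NumericVector(ev_reward.begin(), ev_reward.end()));

  List res = List::create(
      _["payoff"] = NumericVector::create(payoff[0], payoff[1]),
      _["counts"] = IntegerVector::create(_["hares"] = n_hare_hunts,
                                          _["coop_stags"] = n_coop_stag,
                                          _["solo_stags"] = n_solo_stag),
      _["events"] = events,
      _["init_x"] = init_x, _["init_y"] = init_y,
      _["init_heading"] = init_heading, _["init_kind"] = init_kind,
      _["final_x"] = NumericVector(w.x.begin(), w.x.end()),
      _["final_y"] = NumericVector(w.y.begin(), w.y.end()),
      _["final_heading"] = NumericVector::create(w.heading[0], w.heading[1]));
  if (record_trajectories) res["trajectories"] = traj;
  return res;
}

// [[Rcpp::export]]
NumericVector cpp_cast_ray(double ox, double oy, double angle,
                           NumericVector x, NumericVector y,
                           IntegerVector kind, double radius, int exclude,
                           double arena_w, double arena_h) {
  World w;
  w.x.assign(x.begin(), x.end());
  w.y.assign(y.begin(), y.end());
  w.kind.assign(kind.begin(), kind.end());
  w.heading[0] = w.heading[1] = 0.0;
  double dx = std::cos(angle), dy = std::sin(angle);
  double twall = ray_wall_distance(ox, oy, dx, dy, arena_w, arena_h);
  double tagent;
  int hit = cast_ray_agents(w, ox, oy, angle, radius, exclude, &tagent);
  if (hit >= 0 && tagent < twall) {
    // code: 0 = none, 1 = hunter, 2 = hare, 3 = stag
    return NumericVector::create(w.kind[hit] + 1.0, tagent, hit + 1.0);
  }
  return NumericVector::create(0.0, twall, 0.0);
}

// [[Rcpp::export]]
NumericVector cpp_input_vector(int hunter, NumericVector x, NumericVector y,
                               NumericVector heading, IntegerVector kind,
                               List cfg) {
  Config c = parse_config(cfg);
  World w;
  w.x.assign(x.begin(), x.end());
  w.y.assign(y.begin(), y.end());
  w.kind.assign(kind.begin(), kind.end());
  w.heading[0] = heading[0];
  w.heading[1] = heading.size() > 1 ? heading[1] : 0.0;
  int n_inputs = c.n_proximity + 4 * c.n_camera + 1;
  std::vector<double> inputs(n_inputs);
  SensorGeom geom = make_sensor_geom(c);
  build_inputs(c, geom, w, hunter, inputs);
  return NumericVector(inputs.begin(), inputs.end());
}

// [[Rcpp::export]]
NumericVector cpp_forward(NumericVector genome, NumericVector input,
                          List cfg) {
  Config c = parse_config(cfg);
  int n_inputs = input.size();
  int expected = n_inputs * c.n_hidden + (c.n_hidden + 1) * c.n_outputs;
  if (genome.size() != expected) {
    stop("genome length must be %d for this architecture", expected);
  }
  std::vector<double> in(input.begin(), input.end());
  std::vector<double> out(c.n_outputs);
  forward_pass(c, genome.begin(), n_inputs, in, out.data());
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
List cpp_resolve_collisions(NumericVector x, NumericVector y, int moving,
                            List cfg) {
  Config c = parse_config(cfg);
  World w;
  w.x.assign(x.begin(), x.end());
  w.y.assign(y.begin(), y.end());
  w.kind.assign(x.size(), 0);
  w.heading[0] = w.heading[1] = 0.0;
  resolve_collisions(c, w, moving);
  return List::create(_["x"] = NumericVector(w.x.begin(), w.x.end()),
                      _["y"] = NumericVector(w.y.begin(), w.y.end()));
}
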