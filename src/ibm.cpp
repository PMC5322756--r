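#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Fast in-trial RNG (xoshiro256+), seeded from R's RNG stream so that
// set.seed() / the recorded per-trial seed fully determines a trial.
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double u01() {  // uniform on [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  // uniform direction by rejection from the unit disc; returns unit vector
  inline void dir(double &cx, double &cy) {
    double u, v, n2;
    do {
      u = 2.0 * u01() - 1.0;
      v = 2.0 * u01() - 1.0;
      n2 = u * u + v * v;
    } while (n2 > 1.0 || n2 == 0.0);
    double inv = 1.0 / std::sqrt(n2);
    cx = u * inv; cy = v * inv;
  }
};

inline uint64_t seed_from_r() {
  // two 32-bit words drawn from R's stream
  uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
  return (hi << 32) | lo;
}

// Random-walk displacement with wall truncation: the move stops at the
// first wall crossed. Positions live in [0, W] x [0, H] (cm); the cell of
// a position is the unit square containing it (right/top edge clamped).
inline void walk(double &x, double &y, double dist,
                 double W, double H, Xoshiro &rng) {
  double cx, cy;
  rng.dir(cx, cy);
  double dx = dist * cx, dy = dist * cy;
  double nx = x + dx, ny = y + dy;
  if (nx < 0.0 || nx > W || ny < 0.0 || ny > H) {
    double t = 1.0;
    if (nx < 0.0) t = std::min(t, (0.0 - x) / dx);
    if (nx > W)   t = std::min(t, (W - x) / dx);
    if (ny < 0.0) t = std::min(t, (0.0 - y) / dy);
    if (ny > H)   t = std::min(t, (H - y) / dy);
    nx = x + t * dx;
    ny = y + t * dy;
    if (nx < 0.0) nx = 0.0; else if (nx > W) nx = W;
    if (ny < 0.0) ny = 0.0; else if (ny > H) ny = H;
  }
  x = nx;
  y = ny;
}

inline int cell_of(double x, double y, int wcells, int hcells) {
  int cx = (int)x; if (cx >= wcells) cx = wcells - 1;
  int cy = (int)y; if (cy >= hcells) cy = hcells - 1;
  return cy * wcells + cx;
}

inline double digest(double gut, double rate, double cap, double dt,
                     int model) {
  gut -= (model == 1) ? rate * (gut / cap) * dt : rate * dt;
  return gut < 0.0 ? 0.0 : gut;
}

}  // namespace

// One-predator feeding trial on a gridded arena with refuge cells.
// Per step: all prey take a random-walk step; then the predator digests,
// and -- unless handling or satiated (gut >= 60% of capacity) -- moves and
// attacks one random prey sharing its cell (never in a refuge cell).
// A captured prey is replaced at a uniform random position so the prey
// density stays exactly constant.
//
// digestion_model: 0 = absolute (gut -= D * dt), 1 = proportional
// (exponential gut evacuation, gut -= D * gut / G * dt).
// [[Rcpp::export]]
List run_trial_cpp(int width_cells, int height_cells, LogicalVector refuge,
                   int n_prey, int n_steps,
                   double v_pred, double v_prey,
                   double gut_capacity, double digestion_rate,
                   int handling_steps, double attack_p,
                   double prey_mass, double step_seconds,
                   int digestion_model) {
  if ((R_xlen_t)width_cells * height_cells != refuge.size())
    stop("refuge mask does not match arena dimensions");
  Xoshiro rng(seed_from_r());
  const double W = (double)width_cells, H = (double)height_cells;
  const double d_prey = v_prey * step_seconds;
  const double d_pred = v_pred * step_seconds;
  const double gut_thresh = 0.6 * gut_capacity;
  const int *ref = LOGICAL(refuge);

  std::vector<double> px(n_prey), py(n_prey);
  for (int i = 0; i < n_prey; ++i) {
    px[i] = rng.u01() * W;
    py[i] = rng.u01() * H;
  }
  double qx = rng.u01() * W, qy = rng.u01() * H;
  double gut = 0.0, max_gut = 0.0;
  int handling = 0, eaten = 0, alive_min = n_prey, alive_max = n_prey;

  for (int step = 0; step < n_steps; ++step) {
    for (int i = 0; i < n_prey; ++i)
      walk(px[i], py[i], d_prey, W, H, rng);

    // digestion first, every step (also while handling or resting)
    gut = digest(gut, digestion_rate, gut_capacity, step_seconds,
                 digestion_model);

    if (handling > 0) { --handling; continue; }
    if (gut >= gut_thresh) continue;  // satiated: rest

    walk(qx, qy, d_pred, W, H, rng);
    int pc = cell_of(qx, qy, width_cells, height_cells);
    if (ref[pc]) continue;  // refuge cells support no feeding

    // uniform choice among prey in the predator's cell (reservoir)
    int target = -1, in_cell = 0;
    for (int i = 0; i < n_prey; ++i) {
      if (cell_of(px[i], py[i], width_cells, height_cells) == pc) {
        ++in_cell;
        if (in_cell == 1 || rng.u01() * in_cell < 1.0) target = i;
      }
    }
    if (target >= 0 && rng.u01() < attack_p) {
      ++eaten;
      gut += prey_mass;
      if (gut > max_gut) max_gut = gut;
      handling = handling_steps;
      // replacement keeps density constant
      px[target] = rng.u01() * W;
      py[target] = rng.u01() * H;
    }
    if (n_prey < alive_min) alive_min = n_prey;
    if (n_prey > alive_max) alive_max = n_prey;
  }

  return List::create(_["eaten"] = eaten,
                      _["final_gut"] = gut,
                      _["max_gut"] = max_gut,
                      _["prey_alive_min"] = alive_min,
                      _["prey_alive_max"] = alive_max);
}

// Non-spatial maximum-feeding trial: a prey is encountered with certainty
// every step the predator is neither handling nor satiated; the same
// digestion/handling/gut rules apply.
// [[Rcpp::export]]
int run_max_trial_cpp(int n_steps, double gut_capacity, double digestion_rate,
                      int handling_steps, double attack_p,
                      double prey_mass, double step_seconds,
                      int digestion_model) {
  Xoshiro rng(seed_from_r());
  const double gut_thresh = 0.6 * gut_capacity;
  double gut = 0.0;
  int handling = 0, eaten = 0;
  for (int step = 0; step < n_steps; ++step) {
    gut = digest(gut, digestion_rate, gut_capacity, step_seconds,
                 digestion_model);
    if (handling > 0) { --handling; continue; }
    if (gut >= gut_thresh) continue;
    if (rng.u01() < attack_p) {
      ++eaten;
      gut += prey_mass;
      handling = handling_steps;
    }
  }
  return eaten;
}
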