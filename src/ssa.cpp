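#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Counter-based per-cell RNG: splitmix64 expands (seed, cell) into the state
// of a xoshiro256++ stream, so cell i's draws never depend on how many events
// earlier cells consumed and n_cells can grow without reshuffling.
namespace {

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1); never exactly 0 so log() is safe
  inline double unif() {
    double u = (next() >> 11) * 0x1.0p-53;
    return (u > 0.0) ? u : 0x1.0p-53;
  }
};

} // namespace

// Exact SSA over a finite rectangular lattice of integer states.
//
// dims:    number of values each coordinate takes (coordinate i lives in
//          0..dims[i]-1; R adds back any lower offsets)
// deltas:  n_reactions x m integer state-change vectors
// prop:    n_states x n_reactions propensities, rows indexed by the
//          flattened state (column-major strides); the tabulation must
//          already be 0 where a jump would leave the lattice
// init:    0-based initial coordinates
//
// Returns an n_cells x m matrix of snapshots at t_end, one independent
// chain per cell.
// [[Rcpp::export]]
IntegerMatrix ssa_lattice_cpp(IntegerVector dims, IntegerMatrix deltas,
                              NumericMatrix prop, IntegerVector init,
                              int n_cells, double t_end, double seed,
                              double event_cap) {
  const int m = dims.size();
  const int n_reactions = deltas.nrow();
  if (deltas.ncol() != m) stop("deltas/dims dimension mismatch");

  std::vector<long long> stride(m);
  long long n_states = 1;
  for (int i = 0; i < m; ++i) {
    stride[i] = n_states;
    n_states *= dims[i];
  }
  if (prop.nrow() != n_states || prop.ncol() != n_reactions)
    stop("propensity table has wrong shape");

  long long init_idx = 0;
  for (int i = 0; i < m; ++i) {
    if (init[i] < 0 || init[i] >= dims[i]) stop("initial state outside lattice");
    init_idx += stride[i] * init[i];
  }

  const uint64_t root = static_cast<uint64_t>(seed);
  IntegerMatrix out(n_cells, m);
  std::vector<int> state(m);

  for (int cell = 0; cell < n_cells; ++cell) {
    uint64_t mix = root * 0x9E3779B97F4A7C15ULL + 0xD1B54A32D192ED03ULL +
                   static_cast<uint64_t>(cell);
    Xoshiro256pp rng(mix);
    for (int i = 0; i < m; ++i) state[i] = init[i];
    long long idx = init_idx;
    double t = 0.0;
    double n_events = 0.0;

    for (;;) {
      double total = 0.0;
      for (int r = 0; r < n_reactions; ++r) total += prop(idx, r);
      if (total <= 0.0) break; // absorbing state: snapshot is current state
      t += -std::log(rng.unif()) / total;
      if (t > t_end) break;
      double target = rng.unif() * total;
      double acc = 0.0;
      int chosen = n_reactions - 1;
      for (int r = 0; r < n_reactions; ++r) {
        acc += prop(idx, r);
        if (target <= acc) { chosen = r; break; }
      }
      for (int i = 0; i < m; ++i) {
        int v = state[i] + deltas(chosen, i);
        if (v < 0 || v >= dims[i]) stop("reaction left the lattice; propensity table inconsistent");
        idx += stride[i] * (v - state[i]);
        state[i] = v;
      }
      if (++n_events > event_cap)
        stop("event count exceeded the safety cap; chain appears to be running away");
    }
    for (int i = 0; i < m; ++i) out(cell, i) = state[i];
    if ((cell & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Dedicated simulator for the k-stage gene-cycle counterexample
// G1 -> G2 -> ... -> Gk -> G1 + M,  M -> 0.
// Stage advances at rate `stage_rate` (each of the k steps), the k -> 1
// transition also produces one mRNA (a deliberate multistep event), and each
// mRNA degrades at per-molecule rate `deg`. O(1) work per event, so the
// ~1e8-event regimes the counterexample needs stay fast.
// [[Rcpp::export]]
IntegerMatrix ssa_cycle_cpp(int k_stages, double stage_rate, double deg,
                            int n_cells, double t_end, double seed,
                            double event_cap) {
  const uint64_t root = static_cast<uint64_t>(seed);
  IntegerMatrix out(n_cells, 2); // columns: stage (1-based), mRNA count

  for (int cell = 0; cell < n_cells; ++cell) {
    uint64_t mix = root * 0x9E3779B97F4A7C15ULL + 0xD1B54A32D192ED03ULL +
                   static_cast<uint64_t>(cell);
    Xoshiro256pp rng(mix);
    int stage = 1;
    long long mrna = 0;
    double t = 0.0;
    double n_events = 0.0;

    for (;;) {
      double a_adv = stage_rate;
      double a_deg = deg * static_cast<double>(mrna);
      double total = a_adv + a_deg;
      t += -std::log(rng.unif()) / total;
      if (t > t_end) break;
      if (rng.unif() * total <= a_adv) {
        if (stage == k_stages) { stage = 1; ++mrna; }
        else ++stage;
      } else {
        --mrna;
      }
      if (++n_events > event_cap)
        stop("event count exceeded the safety cap");
    }
    out(cell, 0) = stage;
    out(cell, 1) = static_cast<int>(mrna);
    if ((cell & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
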