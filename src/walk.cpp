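#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Counter-seeded PCG32 with one substream per particle, so trajectories are
// reproducible regardless of evaluation order.
namespace {
struct pcg32 {
  uint64_t state, inc;
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  void init(uint64_t seed, uint64_t seq) {
    state = 0u; inc = (seq << 1u) | 1u;
    next(); state += seed; next();
  }
  double unif() { return (next() + 0.5) * (1.0 / 4294967296.0); }
};
uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97f4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}
}  // namespace

// Lattice random walk with obstacle bouncing on an accessibility map.
// At each step: pick an axis uniformly, a direction uniformly, then accept
// the move with probability alpha(target) (bounce with 1 - alpha). Toroidal
// wrap at frame borders; unwrapped integer offsets are recorded for MSD.
//
// alpha: (nr, nc) or (nr, nc, nz) grid; start: 0-based (n x dims).
// Returns unwrapped positions (pixels) at steps 0, record_every, ...,
// n_steps as an array (n_records x n_particles x dims) plus wrapped finals.

// [[Rcpp::export]]
List mc_run(NumericVector alpha, IntegerVector adim, IntegerMatrix start,
            int n_steps, int record_every, double seed) {
  const int dims = adim.size();
  const int nr = adim[0], nc = adim[1], nz = (dims == 3) ? adim[2] : 1;
  const size_t np = (size_t)nr * nc;
  const int n = start.nrow();
  const double *A = alpha.begin();

  std::vector<int> rec_steps;
  for (int k = 0; k <= n_steps; k += (record_every > 0 ? record_every : n_steps + 1))
    rec_steps.push_back(k);
  if (rec_steps.empty() || rec_steps.back() != n_steps) rec_steps.push_back(n_steps);
  const int n_rec = rec_steps.size();

  NumericVector out((size_t)n_rec * n * dims);
  IntegerMatrix wrapped(n, dims);
  const uint64_t base = splitmix64((uint64_t)seed);

  for (int p = 0; p < n; ++p) {
    pcg32 rng;
    rng.init(splitmix64(base ^ (uint64_t)(p + 1)), (uint64_t)p);
    int r = start(p, 0), c = start(p, 1), z = (dims == 3) ? start(p, 2) : 0;
    long long ur = r, uc = c, uz = z;  // unwrapped
    int ri = 0;
    for (int k = 0; k <= n_steps; ++k) {
      if (ri < n_rec && rec_steps[ri] == k) {
        out[(size_t)ri + (size_t)p * n_rec] = (double)ur;
        out[(size_t)ri + (size_t)p * n_rec + (size_t)n_rec * n] = (double)uc;
        if (dims == 3)
          out[(size_t)ri + (size_t)p * n_rec + 2 * (size_t)n_rec * n] = (double)uz;
        ++ri;
      }
      if (k == n_steps) break;
      const double u1 = rng.unif();
      const int axis = (dims == 2) ? (u1 < 0.5 ? 0 : 1)
                                   : (u1 < 1.0 / 3 ? 0 : (u1 < 2.0 / 3 ? 1 : 2));
      const int dir = (rng.unif() < 0.5) ? -1 : 1;
      int tr = r, tc = c, tz = z;
      if (axis == 0) tr = (r + dir + nr) % nr;
      else if (axis == 1) tc = (c + dir + nc) % nc;
      else tz = (z + dir + nz) % nz;
      const double a = A[(size_t)tr + (size_t)tc * nr + (size_t)tz * np];
      if (rng.unif() >= 1.0 - a) {  // move accepted
        if (axis == 0) { r = tr; ur += dir; }
        else if (axis == 1) { c = tc; uc += dir; }
        else { z = tz; uz += dir; }
      }
    }
    wrapped(p, 0) = r; wrapped(p, 1) = c;
    if (dims == 3) wrapped(p, 2) = z;
  }

  out.attr("dim") = IntegerVector::create(n_rec, n, dims);
  IntegerVector rs(rec_steps.begin(), rec_steps.end());
  return List::create(_["unwrapped"] = out, _["wrapped"] = wrapped,
                      _["record_steps"] = rs);
}
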