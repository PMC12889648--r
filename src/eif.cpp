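#include <Rcpp.h>
using namespace Rcpp;

// Euler--Maruyama integration of a network of exponential integrate-and-fire
// neurons.  Currents are expressed as I/C_m (mV/ms).  Synapses follow a
// difference-of-exponentials kernel eta(t) with unit integral, implemented
// with two decaying state variables per neuron that receive an impulse
// J[post, pre] on every presynaptic spike.  The exponential spike-initiation
// term is clipped at V_th before the spike test to avoid overflow.
//
// W:    n x n weight matrix, W(j, i) = weight from neuron i to neuron j
// Iext: n_steps x n matrix of external current (I/C_m, mV/ms)
//
// The membrane noise uses an internal xoshiro-style generator with
// Box-Muller normals, seeded from R's RNG at entry, so runs remain fully
// reproducible under set.seed() while keeping the per-step cost low (the
// integrator draws ~1e8 normals per large dataset).

namespace {
struct FastNormal {
  uint64_t s0, s1;
  double spare;
  bool has_spare;
  explicit FastNormal(uint64_t seed) : spare(0), has_spare(false) {
    // splitmix64 initialisation
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    auto mix = [](uint64_t &z) {
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
      x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
      return x ^ (x >> 31);
    };
    s0 = mix(z); s1 = mix(z);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  inline uint64_t next_u64() {  // xorshift128+
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline double unif() {
    return (next_u64() >> 11) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double m = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * m;
    has_spare = true;
    return u * m;
  }
};
}

// [[Rcpp::export]]
List eif_simulate_cpp(NumericMatrix W, NumericMatrix Iext,
                      double noise_sigma, double dt,
                      double tau_m, double E_L, double V_T, double V_th,
                      double Delta_T, double V_re, double tau_ref,
                      double tau_d, double tau_r) {
  const int n = W.nrow();
  const int n_steps = Iext.nrow();
  if (W.ncol() != n) stop("weight matrix must be square");
  if (Iext.ncol() != n) stop("Iext must have one column per neuron");
  if (dt > 0.1) stop("dt must be <= 0.1 ms");

  std::vector<double> V(n, E_L), A(n, 0.0), B(n, 0.0);
  std::vector<int> refrac(n, 0);
  const int ref_steps = (int)std::lround(tau_ref / dt);
  const double decay_d = std::exp(-dt / tau_d);
  const double decay_r = std::exp(-dt / tau_r);
  const double kernel_scale = 1.0 / (tau_d - tau_r);
  const double sqdt = std::sqrt(dt);

  std::vector< std::vector<double> > spikes(n);

  // seed the internal noise stream from R's RNG
  uint64_t seed = (uint64_t)std::floor(unif_rand() * 4294967296.0);
  seed = (seed << 21) ^ (uint64_t)std::floor(unif_rand() * 4294967296.0);
  FastNormal rng(seed);
  const double exp_floor = V_T - 12.0 * Delta_T;  // exp term < 1e-5 below this

  for (int s = 0; s < n_steps; ++s) {
    double t_now = (s + 1) * dt;
    for (int j = 0; j < n; ++j) {
      double Isyn = (A[j] - B[j]) * kernel_scale;
      if (refrac[j] > 0) {
        refrac[j]--;
        if (refrac[j] == 0) V[j] = V_re;
      } else {
        double Vc = std::min(V[j], V_th);
        double expterm = (Vc > exp_floor)
          ? Delta_T * std::exp((Vc - V_T) / Delta_T) : 0.0;
        double dV = dt * ((-(V[j] - E_L) + expterm) / tau_m
                          + Isyn + Iext(s, j))
                    + noise_sigma * sqdt * rng.norm();
        V[j] += dV;
        if (!std::isfinite(V[j]))
          stop("membrane potential diverged (non-finite) at t = %f ms, neuron %d",
               t_now, j + 1);
      }
      A[j] *= decay_d;
      B[j] *= decay_r;
    }
    // spike test after all voltage updates; impulses delivered immediately
    for (int j = 0; j < n; ++j) {
      if (refrac[j] == 0 && V[j] >= V_th) {
        spikes[j].push_back(t_now);
        V[j] = V_th;
        refrac[j] = ref_steps > 0 ? ref_steps : 1;
        for (int k = 0; k < n; ++k) {
          double w = W(k, j);
          if (w != 0.0) { A[k] += w; B[k] += w; }
        }
      }
    }
  }

  List out(n);
  for (int j = 0; j < n; ++j) out[j] = wrap(spikes[j]);
  return out;
}
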