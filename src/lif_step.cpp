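#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Minimal counter-free PRNG kept inside the package so spike trains are
// bit-reproducible across platforms (std::normal_distribution is
// implementation-defined).  xorshift64* + Box-Muller.
namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  double uniform() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    uint64_t x = s * 0x2545F4914F6CDD1DULL;
    return (x >> 11) * (1.0 / 9007199254740992.0); // [0,1)
  }
  double gauss() {
    double u1 = uniform(), u2 = uniform();
    while (u1 <= 1e-300) u1 = uniform();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};

} // namespace

//' @noRd
// [[Rcpp::export(name = ".lif_step_cpp")]]
IntegerVector lif_step_cpp(NumericVector current, double dt,
                           double R, double C, double dvth, double ip,
                           int switch_idx, double Rd, double Cd,
                           bool ip_noise, double ip_sigma,
                           double seed, bool exact_scheme) {
  const int n = current.size();
  std::vector<int> spikes;
  Rng rng(static_cast<uint64_t>(seed));

  double vm = 0.0;
  // refractory: membrane held at rest until this sample (exclusive)
  double refr_until = -1.0; // time in seconds
  for (int i = 1; i < n; ++i) {
    const bool dere = (switch_idx >= 0 && i >= switch_idx);
    const double Ri = dere ? Rd : R;
    const double Ci = dere ? Cd : C;
    const double tau = Ri * Ci;
    const double t = i * dt;
    if (t <= refr_until) { vm = 0.0; continue; }
    const double e = std::exp(-dt / tau);
    const double gain = exact_scheme ? Ri * (1.0 - e) : Ri * dt / tau;
    vm = e * vm + gain * current[i];
    if (vm >= dvth) {
      spikes.push_back(i);
      vm = 0.0;
      double ip_eff = ip;
      if (ip_noise) {
        double o = ip_sigma * rng.gauss();
        if (o < -ip) o = -ip; // no negative inert period
        ip_eff = ip + o;
      }
      refr_until = t + ip_eff;
    }
  }
  return IntegerVector(spikes.begin(), spikes.end()); // 0-based indices
}
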