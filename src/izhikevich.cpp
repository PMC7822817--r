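#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Euler-discretized (dt = 1 ms) power-of-two-rescaled Izhikevich dynamics:
//   v[n+1] = v[n] + ( v[n]^2/32 + 4 v[n] + 109.375 - u[n] + ks * I[n] )
//   u[n+1] = u[n] + a * ( b * v[n] - u[n] )          (pre-update v)
//   if v[n+1] >= 30 mV:  v[n+1] <- c,  u[n+1] <- u[n] + d
// Spike emitted at step n is stamped at time (n+1) ms.

// [[Rcpp::export]]
List cpp_izh_simulate(NumericVector I, double a, double b, double c, double d,
                      double ks, double v0, double u0) {
  const int n = I.size();
  std::vector<int> spikes;
  double v = v0, u = u0;
  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(I[i])) stop("non-finite input current");
    const double vn = v + (v * v / 32.0 + 4.0 * v + 109.375 - u + ks * I[i]);
    double un = u + a * (b * v - u);
    if (vn >= 30.0) {
      spikes.push_back(i + 1);
      un = u + d;
      v = c;
    } else {
      v = vn;
    }
    u = un;
  }
  return List::create(_["times_ms"] = wrap(spikes), _["v"] = v, _["u"] = u,
                      _["overflow"] = false);
}

// ---- Q13.18 fixed-point mode ------------------------------------------------
// 32-bit signed register: 1 sign, 13 integer, 18 fractional bits. Values are
// raw integers x * 2^18 held in int64 so products (<= 2^62) never overflow
// the intermediate; results saturate to the 32-bit register range.

static const int FRAC = 18;
static const int64_t RAW_MAX = 2147483647LL;   //  2^31 - 1
static const int64_t RAW_MIN = -2147483648LL;  // -2^31

static inline int64_t fx_sat(int64_t x, bool *ovf) {
  if (x > RAW_MAX) { *ovf = true; return RAW_MAX; }
  if (x < RAW_MIN) { *ovf = true; return RAW_MIN; }
  return x;
}

// round-to-nearest on conversion from real
static inline int64_t fx_from_real(double x, bool *ovf) {
  return fx_sat((int64_t)std::llround(x * (double)(1LL << FRAC)), ovf);
}

// truncation (arithmetic right shift) after multiplication, FPGA convention
static inline int64_t fx_mul(int64_t a, int64_t b, bool *ovf) {
  return fx_sat((a * b) >> FRAC, ovf);
}

// [[Rcpp::export]]
List cpp_izh_simulate_fixed(NumericVector I, double a, double b, double c,
                            double d, double ks, double v0, double u0) {
  const int n = I.size();
  bool ovf = false;
  std::vector<int> spikes;
  const int64_t a_r = fx_from_real(a, &ovf), b_r = fx_from_real(b, &ovf);
  const int64_t c_r = fx_from_real(c, &ovf), d_r = fx_from_real(d, &ovf);
  const int64_t ks_r = fx_from_real(ks, &ovf);
  const int64_t c109 = fx_from_real(109.375, &ovf);  // dyadic, exact
  const int64_t thr = 30LL << FRAC;
  int64_t v = fx_from_real(v0, &ovf), u = fx_from_real(u0, &ovf);
  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(I[i])) stop("non-finite input current");
    const int64_t I_r = fx_from_real(I[i], &ovf);
    const int64_t v2 = fx_mul(v, v, &ovf) >> 5;            // v^2 / 32
    const int64_t inc = fx_sat(
        v2 + fx_sat(4 * v, &ovf) + c109 - u + fx_mul(ks_r, I_r, &ovf), &ovf);
    const int64_t vn = fx_sat(v + inc, &ovf);
    int64_t un = fx_sat(u + fx_mul(a_r, fx_sat(fx_mul(b_r, v, &ovf) - u, &ovf),
                                   &ovf), &ovf);
    if (vn >= thr) {
      spikes.push_back(i + 1);
      un = fx_sat(u + d_r, &ovf);
      v = c_r;
    } else {
      v = vn;
    }
    u = un;
  }
  return List::create(_["times_ms"] = wrap(spikes),
                      _["v"] = (double)v / (double)(1LL << FRAC),
                      _["u"] = (double)u / (double)(1LL << FRAC),
                      _["overflow"] = ovf);
}
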