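#ifndef DIFFJUDGE_BOUND_H
#define DIFFJUDGE_BOUND_H

#include <cmath>

// Logistic collapsing bound B(t) = u / (1 + exp(a (t - d))).
// Overflow-safe for large a (t - d).
inline double bound_at(double t, double u, double a, double d) {
  double z = a * (t - d);
  if (z > 0.0) {
    double e = std::exp(-z);
    return u * e / (1.0 + e);
  }
  return u / (1.0 + std::exp(z));
}

#endif
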