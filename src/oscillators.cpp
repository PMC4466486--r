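#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of coupled noisy phase oscillators.
// theta_i' = omega_i + sum_j K(i,j) * sin(theta_j - lag(i,j) - theta_i)
// plus white phase noise supplied as a pre-drawn (steps x n) matrix so
// that all randomness stays under R's RNG.
//
// Returns the (steps x n) matrix of unwrapped phases.
// [[Rcpp::export(name = ".kuramoto_phases")]]
NumericMatrix kuramoto_phases(int steps, double dt, NumericVector omega,
                              NumericMatrix K, NumericMatrix lag,
                              NumericVector theta0, NumericMatrix noise) {
  const int n = omega.size();
  NumericMatrix theta(steps, n);
  std::vector<double> cur(n), nxt(n);
  for (int i = 0; i < n; ++i) cur[i] = theta0[i];
  for (int t = 0; t < steps; ++t) {
    for (int i = 0; i < n; ++i) theta(t, i) = cur[i];
    for (int i = 0; i < n; ++i) {
      double drive = omega[i];
      for (int j = 0; j < n; ++j) {
        double k = K(i, j);
        if (k != 0.0)
          drive += k * std::sin(cur[j] - lag(i, j) - cur[i]);
      }
      nxt[i] = cur[i] + dt * drive + noise(t, i);
    }
    cur = nxt;
  }
  return theta;
}
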