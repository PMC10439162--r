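#include <Rcpp.h>
using namespace Rcpp;

// Sigmoid firing-rate function S(v) = 2 e0 / (1 + exp(r (v0 - v)))
static inline double sigm(double v, double e0, double r, double v0) {
  return 2.0 * e0 / (1.0 + std::exp(r * (v0 - v)));
}

// Fixed-step Euler integration of the ten-equation Wendling system.
// State layout: y[0..4] PSP channels, y[5..9] their time derivatives.
// Noise p(t) ~ N(noise_mean, noise_sd) is drawn once per integration step
// from R's RNG, so trajectories are reproducible under set.seed().
// Returns the model output y1 - y2 - y3 at every integration step
// (n_steps values); burn-in removal and decimation happen in R.
// [[Rcpp::export]]
NumericVector wendling_euler(int n_steps, double dt, NumericVector y_init,
                             List params) {
  if (y_init.size() != 10)
    stop("initial state must have 10 elements");
  double A = params["A"], B = params["B"], G = params["G"];
  double a = params["a"], b = params["b"], g = params["g"];
  double C1 = params["C1"], C2 = params["C2"], C3 = params["C3"],
         C4 = params["C4"], C5 = params["C5"], C6 = params["C6"],
         C7 = params["C7"];
  double v0 = params["v0"], e0 = params["e0"], r = params["r"];
  double nmean = params["noise_mean"], nsd = params["noise_std"];

  double y[10];
  for (int i = 0; i < 10; ++i) y[i] = y_init[i];

  NumericVector out(n_steps);
  RNGScope scope;

  for (int t = 0; t < n_steps; ++t) {
    double p = (nsd > 0.0) ? R::rnorm(nmean, nsd) : nmean;
    double vpyr = y[1] - y[2] - y[3];

    double d5 = A * a * sigm(vpyr, e0, r, v0) - 2.0 * a * y[5] - a * a * y[0];
    double d6 = A * a * (p + C2 * sigm(C1 * y[0], e0, r, v0)) -
                2.0 * a * y[6] - a * a * y[1];
    double d7 = B * b * C4 * sigm(C3 * y[0], e0, r, v0) -
                2.0 * b * y[7] - b * b * y[2];
    double d8 = G * g * C7 * sigm(C5 * y[0] - C6 * y[4], e0, r, v0) -
                2.0 * g * y[8] - g * g * y[3];
    double d9 = B * b * sigm(C3 * y[0], e0, r, v0) -
                2.0 * b * y[9] - b * b * y[4];

    y[0] += dt * y[5]; y[1] += dt * y[6]; y[2] += dt * y[7];
    y[3] += dt * y[8]; y[4] += dt * y[9];
    y[5] += dt * d5; y[6] += dt * d6; y[7] += dt * d7;
    y[8] += dt * d8; y[9] += dt * d9;

    for (int i = 0; i < 10; ++i)
      if (!std::isfinite(y[i]))
        stop("numerical divergence at integration step %d", t + 1);

    out[t] = y[1] - y[2] - y[3];
  }
  return out;
}
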