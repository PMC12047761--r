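#include <Rcpp.h>
using namespace Rcpp;

// First-passage simulation of a discrete-time diffusion (unit time step).
// x_{t+1} = x_t + drift + noise_sd * N(0,1), started at `bias`, absorbed at
// +/- boundary. One "cycle" is one Euler step; deadlines are given in cycles.
// choice: +1 upper, -1 lower, 0 none (deadline reached).
// Uses R's RNG so runs are reproducible under set.seed().

// [[Rcpp::export]]
List ddm_kernel(NumericVector drift, NumericVector boundary, NumericVector bias,
                double noise_sd, int max_cycles) {
  int n = drift.size();
  if (boundary.size() != n || bias.size() != n)
    stop("drift, boundary and bias must have equal length");
  IntegerVector choice(n), rt(n);
  LogicalVector timed_out(n);
  for (int i = 0; i < n; ++i) {
    double x = bias[i], a = boundary[i], mu = drift[i];
    if (!R_finite(x) || !R_finite(a) || !R_finite(mu))
      stop("non-finite DDM parameters");
    if (a <= fabs(bias[i]))
      stop("boundary must exceed |bias|");
    int t = 0, ch = 0;
    while (t < max_cycles) {
      x += mu + noise_sd * norm_rand();
      ++t;
      if (x >= a)  { ch =  1; break; }
      if (x <= -a) { ch = -1; break; }
    }
    choice[i] = ch;
    rt[i] = (ch == 0) ? max_cycles : t;
    timed_out[i] = (ch == 0);
  }
  return List::create(_["choice"] = choice, _["rt_cycles"] = rt,
                      _["timed_out"] = timed_out);
}
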