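#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama first-passage sampler for a Wiener diffusion between
// absorbing boundaries 0 and a, starting at z, with per-trial drift drawn
// from N(v, eta) and infinitesimal standard deviation s. Uses R's RNG, so
// set.seed() on the R side makes draws reproducible.
//
// Returns decision time (k * dt, in seconds) and the boundary hit
// (1 = upper, 0 = lower); trials still diffusing at max_t come back NA.
// [[Rcpp::export]]
List ddm_sim_cpp(int n, double a, double v, double z, double eta,
                 double s, double dt, double max_t) {
  NumericVector dec_time(n);
  IntegerVector boundary(n);
  const double sd_step = s * std::sqrt(dt);
  const int max_steps = static_cast<int>(max_t / dt) + 1;
  for (int i = 0; i < n; ++i) {
    const double vi = (eta > 0.0) ? R::rnorm(v, eta) : v;
    const double drift_step = vi * dt;
    double x = z;
    int k = 0;
    bool absorbed = false;
    while (k < max_steps) {
      x += drift_step + sd_step * norm_rand();
      ++k;
      if (x >= a) { boundary[i] = 1; absorbed = true; break; }
      if (x <= 0.0) { boundary[i] = 0; absorbed = true; break; }
    }
    if (absorbed) {
      dec_time[i] = k * dt;
    } else {
      dec_time[i] = NA_REAL;
      boundary[i] = NA_INTEGER;
    }
  }
  return List::create(_["dec_time"] = dec_time, _["boundary"] = boundary);
}
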