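#include <Rcpp.h>
using namespace Rcpp;

// Exact Gillespie simulation of the two-state clone model.
//
// Reactions (per proliferative cell X):
//   division:   X -> 2X      propensity g * x * phi
//   transition: X -> Y       propensity k * x
// phi = max(0, 1 - (x+y)/K) when a carrying capacity K > 0 is set, else 1.
//
// Uses R's RNG stream (exp_rand / unif_rand) so runs are reproducible under
// set.seed() on the R side.

// [[Rcpp::export]]
List cpp_simulate_clone(double g, double k, double K, double t_max,
                        double max_cells) {
  std::vector<double> times, xs, ys;
  double t = 0.0;
  double x = 1.0, y = 0.0;
  times.push_back(0.0);
  xs.push_back(x);
  ys.push_back(y);
  int reason = 0; // 0 = t_max, 1 = absorbed, 2 = cell cap hit

  for (;;) {
    if (x <= 0.0) {
      reason = 1;
      break;
    }
    double phi = 1.0;
    if (K > 0.0) {
      phi = 1.0 - (x + y) / K;
      if (phi < 0.0) phi = 0.0;
    }
    double a_div = g * x * phi;
    double a_tr = k * x;
    double a0 = a_div + a_tr;
    if (a0 <= 0.0) break; // frozen (no reaction can fire): runs out the clock
    double dt = exp_rand() / a0;
    if (t + dt > t_max) break;
    t += dt;
    if (unif_rand() * a0 < a_div) {
      x += 1.0;
    } else {
      x -= 1.0;
      y += 1.0;
    }
    times.push_back(t);
    xs.push_back(x);
    ys.push_back(y);
    if (x + y >= max_cells) {
      reason = 2;
      break;
    }
  }

  return List::create(_["times"] = wrap(times), _["x_counts"] = wrap(xs),
                      _["y_counts"] = wrap(ys), _["reason"] = reason);
}

// Final states only, for ensembles: returns an n x 4 matrix with columns
// (x_final, y_final, absorbed, capped).

// [[Rcpp::export]]
NumericMatrix cpp_simulate_finals(double g, double k, double K, int n_clones,
                                  double t_max, double max_cells) {
  NumericMatrix out(n_clones, 4);
  for (int i = 0; i < n_clones; ++i) {
    double t = 0.0, x = 1.0, y = 0.0;
    int absorbed = 0, capped = 0;
    for (;;) {
      if (x <= 0.0) {
        absorbed = 1;
        break;
      }
      double phi = 1.0;
      if (K > 0.0) {
        phi = 1.0 - (x + y) / K;
        if (phi < 0.0) phi = 0.0;
      }
      double a_div = g * x * phi;
      double a_tr = k * x;
      double a0 = a_div + a_tr;
      if (a0 <= 0.0) break;
      double dt = exp_rand() / a0;
      if (t + dt > t_max) break;
      t += dt;
      if (unif_rand() * a0 < a_div) {
        x += 1.0;
      } else {
        x -= 1.0;
        y += 1.0;
      }
      if (x + y >= max_cells) {
        capped = 1;
        break;
      }
    }
    out(i, 0) = x;
    out(i, 1) = y;
    out(i, 2) = absorbed;
    out(i, 3) = capped;
  }
  return out;
}
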