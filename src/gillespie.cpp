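#include <Rcpp.h>
using namespace Rcpp;

// Exact direct-method SSA for the Lotka-Volterra predator-prey jump process.
// Reactions: prey birth (rate th1*X), predation (rate th2*X*Y, X-1 Y+1),
// predator death (rate th3*Y). Uses R's RNG so runs are governed by set.seed().
// Returns c(prey at obs_times, predator at obs_times); if the event count
// exceeds max_events the (partial) result carries attribute capped = TRUE.
// [[Rcpp::export]]
NumericVector gillespie_lv_cpp(NumericVector theta, NumericVector x0,
                               NumericVector obs_times, double max_events) {
  const double th1 = theta[0], th2 = theta[1], th3 = theta[2];
  const int nt = obs_times.size();
  NumericVector prey(nt), pred(nt);
  double x = x0[0], y = x0[1];
  double t = 0.0;
  int idx = 0;
  double events = 0.0;
  bool capped = false;

  while (idx < nt) {
    const double a1 = th1 * x;
    const double a2 = th2 * x * y;
    const double a3 = th3 * y;
    const double a0 = a1 + a2 + a3;

    double tnext;
    if (a0 <= 0.0) {
      tnext = R_PosInf;  // absorbed: state persists to the horizon
    } else {
      tnext = t + R::exp_rand() / a0;
    }

    while (idx < nt && obs_times[idx] < tnext) {
      prey[idx] = x;
      pred[idx] = y;
      ++idx;
    }
    if (idx >= nt || a0 <= 0.0) break;

    events += 1.0;
    if (events > max_events) { capped = true; break; }

    const double u = R::unif_rand() * a0;
    if (u < a1) {
      x += 1.0;
    } else if (u < a1 + a2) {
      x -= 1.0;
      y += 1.0;
    } else {
      y -= 1.0;
    }
    t = tnext;
  }

  NumericVector out(2 * nt);
  for (int i = 0; i < nt; ++i) {
    out[i] = prey[i];
    out[nt + i] = pred[i];
  }
  if (capped) out.attr("capped") = true;
  return out;
}
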