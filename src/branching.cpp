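#include <Rcpp.h>
using namespace Rcpp;

// Gillespie simulation of the two-stage clonal-expansion process.
// Initiations arrive Poisson(rate nuX); each clone is a linear birth-death
// process with per-cell birth alpha, death beta and malignant conversion mu.
// Returns, per subject, the time of the first malignant conversion (before
// the detection lag), or NA if censored at the horizon.  Uses R's RNG so
// set.seed() controls reproducibility.
//
// A clone simulation is abandoned as soon as its internal time passes the
// current best conversion time (a later conversion cannot be the first one),
// which keeps supercritical clones from being followed forever.

static double simulate_clone(double t0, double alpha, double beta, double mu,
                             double cap) {
  // returns conversion time or R_PosInf
  long n = 1;
  double t = t0;
  const double per = alpha + beta + mu;
  if (per <= 0.0) return R_PosInf;
  while (n > 0) {
    double total = per * (double)n;
    t += R::exp_rand() / total;
    if (t >= cap) return R_PosInf;
    double u = unif_rand() * per;
    if (u < alpha) {
      ++n;
    } else if (u < alpha + beta) {
      --n;
    } else {
      return t;  // malignant conversion
    }
  }
  return R_PosInf;  // clone extinct
}

// [[Rcpp::export]]
NumericVector simulate_tsce_cpp(int n_subjects, double nuX, double alpha,
                                double beta, double mu, double horizon) {
  NumericVector out(n_subjects, NA_REAL);
  if (nuX <= 0.0 || mu < 0.0) return out;  // no initiation -> all censored
  RNGScope scope;
  for (int i = 0; i < n_subjects; ++i) {
    double best = horizon;  // first conversion must beat the horizon
    bool found = false;
    double t_init = 0.0;
    for (;;) {
      t_init += R::exp_rand() / nuX;
      if (t_init >= best) break;  // later clones cannot convert earlier
      double conv = simulate_clone(t_init, alpha, beta, mu, best);
      if (conv < best) {
        best = conv;
        found = true;
      }
      if ((i & 0x3ff) == 0) Rcpp::checkUserInterrupt();
    }
    if (found) out[i] = best;
  }
  return out;
}
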