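#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Closed-form HKY transition probabilities. States 0..3 = A,C,G,T; purines
// {0,2}. The rate matrix is normalised to one expected substitution per unit
// distance. JC is the special case kappa = 1, uniform pi.
static void hky_pmat(double d, const double* pi, double kappa, double* P) {
  const double piR = pi[0] + pi[2];
  const double piY = pi[1] + pi[3];
  const double beta =
      1.0 / (2.0 * kappa * (pi[0] * pi[2] + pi[1] * pi[3]) + 2.0 * piR * piY);
  const double e2 = std::exp(-beta * d);
  for (int i = 0; i < 4; ++i) {
    const bool pur_i = (i == 0 || i == 2);
    const double Pi = pur_i ? piR : piY;
    const double e3 = std::exp(-beta * d * (Pi * kappa + 1.0 - Pi));
    for (int j = 0; j < 4; ++j) {
      const bool pur_j = (j == 0 || j == 2);
      double v;
      if (i == j)
        v = pi[j] + pi[j] * (1.0 / Pi - 1.0) * e2 + ((Pi - pi[j]) / Pi) * e3;
      else if (pur_i == pur_j)
        v = pi[j] + pi[j] * (1.0 / Pi - 1.0) * e2 - (pi[j] / Pi) * e3;
      else
        v = pi[j] * (1.0 - e2);
      P[4 * i + j] = v;
    }
  }
}

// Felsenstein pruning over compressed site patterns.
//
// children:  (ntip-1) x 2 matrix; row k holds the two child node ids of
//            internal node (ntip + k), 1-based ape numbering.
// postorder: internal node ids ordered children-before-parents.
// dist:      per-node expected substitutions on the branch above the node
//            (rate x duration); the root entry is ignored.
// patterns:  ntip x npat integer matrix, states 0..3, negative = missing.
// weights:   pattern multiplicities.
// pi, kappa: substitution model; gamma_rates: discrete-gamma category rates
//            (equal weights; pass {1} for rate homogeneity).
//
// Numerical stability: per-node, per-pattern rescaling whenever the largest
// partial falls below 1e-140 (extreme branch lengths arise under tree
// extension).
// [[Rcpp::export]]
double pruning_loglik_cpp(IntegerMatrix children, IntegerVector postorder,
                          NumericVector dist, IntegerMatrix patterns,
                          NumericVector weights, NumericVector pi,
                          double kappa, NumericVector gamma_rates) {
  const int ntip = patterns.nrow();
  const int npat = patterns.ncol();
  const int nint = ntip - 1;
  const int ncat = gamma_rates.size();
  const double scale_thresh = 1e-140;

  std::vector<double> part(static_cast<size_t>(nint) * npat * 4);
  std::vector<double> cscale(npat);
  std::vector<double> site_logl(static_cast<size_t>(npat) * ncat);
  double P1[16], P2[16];

  for (int c = 0; c < ncat; ++c) {
    const double rate = gamma_rates[c];
    std::fill(cscale.begin(), cscale.end(), 0.0);
    int root = 0;
    for (int k = 0; k < nint; ++k) {
      const int v = postorder[k];             // 1-based internal node id
      root = v;
      const int iv = v - ntip - 1;            // 0-based internal index
      const int c1 = children(v - ntip - 1, 0);
      const int c2 = children(v - ntip - 1, 1);
      hky_pmat(dist[c1 - 1] * rate, REAL(pi), kappa, P1);
      hky_pmat(dist[c2 - 1] * rate, REAL(pi), kappa, P2);
      const bool tip1 = c1 <= ntip, tip2 = c2 <= ntip;
      const double* q1 = tip1 ? nullptr : &part[(static_cast<size_t>(c1 - ntip - 1) * npat) * 4];
      const double* q2 = tip2 ? nullptr : &part[(static_cast<size_t>(c2 - ntip - 1) * npat) * 4];
      double* out = &part[(static_cast<size_t>(iv) * npat) * 4];
      for (int s = 0; s < npat; ++s) {
        double l1[4], l2[4];
        if (tip1) {
          const int x = patterns(c1 - 1, s);
          if (x < 0)
            for (int a = 0; a < 4; ++a) l1[a] = 1.0;
          else
            for (int a = 0; a < 4; ++a) l1[a] = P1[4 * a + x];
        } else {
          const double* u = q1 + static_cast<size_t>(s) * 4;
          for (int a = 0; a < 4; ++a)
            l1[a] = P1[4 * a] * u[0] + P1[4 * a + 1] * u[1] +
                    P1[4 * a + 2] * u[2] + P1[4 * a + 3] * u[3];
        }
        if (tip2) {
          const int x = patterns(c2 - 1, s);
          if (x < 0)
            for (int a = 0; a < 4; ++a) l2[a] = 1.0;
          else
            for (int a = 0; a < 4; ++a) l2[a] = P2[4 * a + x];
        } else {
          const double* u = q2 + static_cast<size_t>(s) * 4;
          for (int a = 0; a < 4; ++a)
            l2[a] = P2[4 * a] * u[0] + P2[4 * a + 1] * u[1] +
                    P2[4 * a + 2] * u[2] + P2[4 * a + 3] * u[3];
        }
        double* o = out + static_cast<size_t>(s) * 4;
        double mx = 0.0;
        for (int a = 0; a < 4; ++a) {
          o[a] = l1[a] * l2[a];
          if (o[a] > mx) mx = o[a];
        }
        if (mx < scale_thresh) {
          if (mx <= 0.0) {
            // all-zero partials: impossible pattern, likelihood is 0
            o[0] = o[1] = o[2] = o[3] = 0.0;
            cscale[s] = R_NegInf;
          } else {
            for (int a = 0; a < 4; ++a) o[a] /= mx;
            cscale[s] += std::log(mx);
          }
        }
      }
    }
    const double* rootpart = &part[(static_cast<size_t>(root - ntip - 1) * npat) * 4];
    for (int s = 0; s < npat; ++s) {
      const double* o = rootpart + static_cast<size_t>(s) * 4;
      const double lik =
          pi[0] * o[0] + pi[1] * o[1] + pi[2] * o[2] + pi[3] * o[3];
      site_logl[static_cast<size_t>(s) * ncat + c] =
          (lik > 0.0 && R_finite(cscale[s])) ? std::log(lik) + cscale[s] : R_NegInf;
    }
  }

  // average site likelihoods over categories (log-sum-exp), weight and sum
  double total = 0.0;
  const double log_ncat = std::log(static_cast<double>(ncat));
  for (int s = 0; s < npat; ++s) {
    const double* ls = &site_logl[static_cast<size_t>(s) * ncat];
    double m = ls[0];
    for (int c = 1; c < ncat; ++c)
      if (ls[c] > m) m = ls[c];
    if (!R_finite(m)) return R_NegInf;
    double acc = 0.0;
    for (int c = 0; c < ncat; ++c) acc += std::exp(ls[c] - m);
    total += weights[s] * (m + std::log(acc) - log_ncat);
  }
  return total;
}
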