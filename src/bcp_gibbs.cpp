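#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Product-partition (Barry-Hartigan) change-point model, Gibbs sampler.
//
// Model: x_i = theta_i + e_i, e ~ N(0, s2); theta constant within blocks,
// block mean ~ N(mu0, s02/n_j); flat prior on mu0, scale prior 1/s2;
// p ~ U(0, p0) on the per-position change probability, w = s2/(s2+s02)
// ~ U(0, w0). Integrating mu0, s2, block means gives the partition
// marginal, with k change points, W within- and B between-block SS:
//   f(rho|x) proportional to
//     [int_0^p0 p^k (1-p)^(n-1-k) dp] * [int_0^w0 w^(k/2)/(W+Bw)^((n-1)/2) dw]
// The w-integral is evaluated by fixed Gauss-Legendre quadrature on
// [0, w0] (nodes/weights supplied by the caller); the p-integral is an
// incomplete beta.

static double log_p_term(int k, int n, double p0) {
  // log int_0^p0 p^k (1-p)^(n-1-k) dp
  return R::lbeta(k + 1.0, n - (double)k) +
         R::pbeta(p0, k + 1.0, n - (double)k, 1, 1);
}

static double log_w_term(int k, double W, double B, double n1half,
                         const NumericVector& nodes,
                         const NumericVector& lognodes,
                         const NumericVector& logwts) {
  // log int_0^w0 w^(k/2) / (W + B w)^((n-1)/2) dw, via log-sum-exp
  const int m = nodes.size();
  double mx = -INFINITY;
  std::vector<double> lv(m);
  for (int j = 0; j < m; ++j) {
    double q = W + B * nodes[j];
    if (q < 1e-300) q = 1e-300;
    lv[j] = logwts[j] + 0.5 * k * lognodes[j] - n1half * std::log(q);
    if (lv[j] > mx) mx = lv[j];
  }
  double s = 0.0;
  for (int j = 0; j < m; ++j) s += std::exp(lv[j] - mx);
  return mx + std::log(s);
}

// [[Rcpp::export(name = ".bcp_gibbs_cpp")]]
List bcp_gibbs_cpp(NumericVector x, int iterations, int burn_in,
                   double p0, double w0,
                   NumericVector nodes, NumericVector wts) {
  const int n = x.size();
  const double n1half = (n - 1.0) / 2.0;
  NumericVector lognodes(nodes.size()), logwts(wts.size());
  for (int j = 0; j < nodes.size(); ++j) {
    lognodes[j] = std::log(nodes[j]);
    logwts[j] = std::log(wts[j]);
  }

  // prefix sums for block statistics
  std::vector<double> cs(n + 1, 0.0);
  double ssx = 0.0, sx = 0.0;
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    ssx += x[i] * x[i];
    sx += x[i];
  }
  const double xbar = sx / n;
  const double nxbar2 = n * xbar * xbar;

  auto block_m = [&](int a, int b) {  // n_j * mean^2 for x[a..b]
    double s = cs[b + 1] - cs[a];
    return s * s / (b - a + 1);
  };

  std::vector<int> U(n, 0);  // U[i]=1: new block starts at i (i>=1)
  int k = 0;                 // number of change points
  double S2b = block_m(0, n - 1);  // sum over blocks of n_j mean_j^2

  std::vector<double> count(n, 0.0), mean_acc(n, 0.0);
  std::vector<double> theta(n);
  int n_kept = 0;

  RNGScope scope;
  for (int it = 0; it < iterations; ++it) {
    for (int i = 1; i < n; ++i) {
      // block containing x[i-1] starts at l; block containing x[i] (when
      // split) ends at r-1
      int l = i - 1;
      while (l > 0 && U[l] == 0) --l;
      int r = i + 1;
      while (r < n && U[r] == 0) ++r;
      double m_split = block_m(l, i - 1) + block_m(i, r - 1);
      double m_merge = block_m(l, r - 1);
      double cur = U[i] ? m_split : m_merge;
      double base = S2b - cur;
      int k_other = k - U[i];

      double S2_1 = base + m_split, S2_0 = base + m_merge;
      double W1 = ssx - S2_1, B1 = S2_1 - nxbar2;
      double W0 = ssx - S2_0, B0 = S2_0 - nxbar2;
      if (W1 < 0) W1 = 0; if (B1 < 0) B1 = 0;
      if (W0 < 0) W0 = 0; if (B0 < 0) B0 = 0;

      double lo = log_p_term(k_other + 1, n, p0) - log_p_term(k_other, n, p0)
        + log_w_term(k_other + 1, W1, B1, n1half, nodes, lognodes, logwts)
        - log_w_term(k_other, W0, B0, n1half, nodes, lognodes, logwts);
      double pr = 1.0 / (1.0 + std::exp(-lo));
      int newU = (unif_rand() < pr) ? 1 : 0;
      if (newU != U[i]) {
        U[i] = newU;
        k += newU ? 1 : -1;
        S2b = newU ? (base + m_split) : (base + m_merge);
      }
    }

    if (it >= burn_in) {
      ++n_kept;
      // E[w | partition] by the same quadrature, then Rao-Blackwellised
      // per-day mean: theta_i = (1-Ew) * blockmean + Ew * grand mean
      double W = ssx - S2b, B = S2b - nxbar2;
      if (W < 0) W = 0; if (B < 0) B = 0;
      double mx = -INFINITY;
      const int m = nodes.size();
      std::vector<double> lv(m);
      for (int j = 0; j < m; ++j) {
        double q = W + B * nodes[j];
        if (q < 1e-300) q = 1e-300;
        lv[j] = logwts[j] + 0.5 * k * lognodes[j] - n1half * std::log(q);
        if (lv[j] > mx) mx = lv[j];
      }
      double den = 0.0, num = 0.0;
      for (int j = 0; j < m; ++j) {
        double e = std::exp(lv[j] - mx);
        den += e;
        num += e * nodes[j];
      }
      double Ew = num / den;
      int start = 0;
      for (int i = 1; i <= n; ++i) {
        if (i == n || U[i]) {
          double bm = (cs[i] - cs[start]) / (i - start);
          double th = (1.0 - Ew) * bm + Ew * xbar;
          for (int j = start; j < i; ++j) theta[j] = th;
          start = i;
        }
      }
      for (int i = 0; i < n; ++i) {
        count[i] += U[i];
        mean_acc[i] += theta[i];
      }
    }
  }

  NumericVector prob(n), pmean(n);
  for (int i = 0; i < n; ++i) {
    prob[i] = count[i] / n_kept;
    pmean[i] = mean_acc[i] / n_kept;
  }
  prob[0] = 0.0;
  return List::create(_["posterior_prob"] = prob,
                      _["posterior_mean"] = pmean);
}
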