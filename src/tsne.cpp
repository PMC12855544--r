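// Exact t-SNE (O(n^2)) for 2-D embeddings of standardized cohort matrices.
// Gaussian input kernel with per-point bandwidth calibrated to the target
// perplexity by bisection; Student-t output kernel; gradient descent with
// momentum and early exaggeration.  RNG comes from R so set.seed() governs
// reproducibility.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// symmetrized input affinities P (row-major n*n), calibrated to perplexity
static void compute_p(const NumericMatrix &X, double perplexity,
                      std::vector<double> &P) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> D(static_cast<size_t>(n) * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = X(i, k) - X(j, k);
        s += diff * diff;
      }
      D[(size_t)i * n + j] = s;
      D[(size_t)j * n + i] = s;
    }
  }
  const double logU = std::log(perplexity);
  std::vector<double> row(n);
  for (int i = 0; i < n; ++i) {
    double beta = 1.0, betamin = -1.0, betamax = -1.0;
    for (int iter = 0; iter < 60; ++iter) {
      double sum = 0.0, dsum = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) { row[j] = 0.0; continue; }
        double v = std::exp(-beta * D[(size_t)i * n + j]);
        row[j] = v;
        sum += v;
        dsum += D[(size_t)i * n + j] * v;
      }
      if (sum <= 0) sum = 1e-300;
      double H = std::log(sum) + beta * dsum / sum;  // Shannon entropy
      double diff = H - logU;
      if (std::fabs(diff) < 1e-5) break;
      if (diff > 0) {               // entropy too high -> increase beta
        betamin = beta;
        beta = (betamax < 0) ? beta * 2.0 : (beta + betamax) / 2.0;
      } else {
        betamax = beta;
        beta = (betamin < 0) ? beta / 2.0 : (beta + betamin) / 2.0;
      }
    }
    double sum = 0.0;
    for (int j = 0; j < n; ++j) sum += row[j];
    if (sum <= 0) sum = 1e-300;
    for (int j = 0; j < n; ++j)
      P[(size_t)i * n + j] = row[j] / sum;
  }
  // symmetrize and normalize to a joint distribution
  double tot = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double v = (P[(size_t)i * n + j] + P[(size_t)j * n + i]) / (2.0 * n);
      if (v < 1e-12) v = 1e-12;
      P[(size_t)i * n + j] = v;
      P[(size_t)j * n + i] = v;
      tot += 2.0 * v;
    }
  (void)tot;
}

// [[Rcpp::export(name = ".tsne_embed_cpp")]]
NumericMatrix tsne_embed_cpp(NumericMatrix X, double perplexity, int n_iter,
                             double eta = 200.0) {
  const int n = X.nrow();
  if (n - 1 < 3 * perplexity)
    stop("perplexity too large for %d rows; lower the perplexity", n);
  std::vector<double> P(static_cast<size_t>(n) * n, 0.0);
  compute_p(X, perplexity, P);

  NumericMatrix Y(n, 2);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 2; ++k) Y(i, k) = 1e-4 * R::norm_rand();

  const size_t n_pairs = (size_t)n * (n - 1) / 2;
  std::vector<double> dY((size_t)n * 2, 0.0), iY((size_t)n * 2, 0.0),
      gains((size_t)n * 2, 1.0), num(n_pairs, 0.0),
      y0(n), y1(n);

  const int stop_lying = std::min(250, n_iter / 4);
  const double exaggeration = 12.0;

  for (int iter = 0; iter < n_iter; ++iter) {
    double mom = (iter < 250) ? 0.5 : 0.8;
    double lie = (iter < stop_lying) ? exaggeration : 1.0;

    for (int i = 0; i < n; ++i) { y0[i] = Y(i, 0); y1[i] = Y(i, 1); }

    // pass 1: Student-t kernel over the upper triangle
    double sumq = 0.0;
    size_t k = 0;
    for (int i = 0; i < n; ++i) {
      const double yi0 = y0[i], yi1 = y1[i];
      for (int j = i + 1; j < n; ++j, ++k) {
        double dx = yi0 - y0[j], dy = yi1 - y1[j];
        double q = 1.0 / (1.0 + dx * dx + dy * dy);
        num[k] = q;
        sumq += q;
      }
    }
    sumq *= 2.0;
    if (sumq < 1e-300) sumq = 1e-300;

    // pass 2: symmetric attraction/repulsion forces
    std::fill(dY.begin(), dY.end(), 0.0);
    k = 0;
    for (int i = 0; i < n; ++i) {
      const double yi0 = y0[i], yi1 = y1[i];
      double gi0 = 0.0, gi1 = 0.0;
      const double *Pi = &P[(size_t)i * n];
      for (int j = i + 1; j < n; ++j, ++k) {
        double q = num[k];
        double mult = (lie * Pi[j] - q / sumq) * q;
        double f0 = mult * (yi0 - y0[j]);
        double f1 = mult * (yi1 - y1[j]);
        gi0 += f0; gi1 += f1;
        dY[(size_t)j * 2] -= 4.0 * f0;
        dY[(size_t)j * 2 + 1] -= 4.0 * f1;
      }
      dY[(size_t)i * 2] += 4.0 * gi0;
      dY[(size_t)i * 2 + 1] += 4.0 * gi1;
    }

    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 2; ++k) {
        size_t idx = (size_t)i * 2 + k;
        gains[idx] = ((dY[idx] > 0) != (iY[idx] > 0)) ? gains[idx] + 0.2
                                                      : gains[idx] * 0.8;
        if (gains[idx] < 0.01) gains[idx] = 0.01;
        iY[idx] = mom * iY[idx] - eta * gains[idx] * dY[idx];
        Y(i, k) += iY[idx];
      }

    // re-center
    double m0 = 0.0, m1 = 0.0;
    for (int i = 0; i < n; ++i) { m0 += Y(i, 0); m1 += Y(i, 1); }
    m0 /= n; m1 /= n;
    for (int i = 0; i < n; ++i) { Y(i, 0) -= m0; Y(i, 1) -= m1; }

    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return Y;
}
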