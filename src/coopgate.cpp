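#include <Rcpp.h>
using namespace Rcpp;

// Forward (alpha) recursion for an (N+1)-state hidden Markov chain with
// Gaussian emissions; log-domain with per-frame rescaling so 10^4-frame
// records stay finite.
// [[Rcpp::export(name = ".cg_forward_loglik")]]
double cg_forward_loglik(NumericVector x, NumericMatrix P,
                         NumericVector pi0, NumericVector means, double sd) {
  const int S = P.nrow();
  const int T = x.size();
  std::vector<double> alpha(S), nxt(S);
  double loglik = 0.0;

  // base case: pi_k * phi(x_1; mu_k, sd)
  double scale = 0.0;
  for (int s = 0; s < S; ++s) {
    alpha[s] = pi0[s] * R::dnorm(x[0], means[s], sd, 0);
    scale += alpha[s];
  }
  if (scale <= 0.0) return R_NegInf;
  for (int s = 0; s < S; ++s) alpha[s] /= scale;
  loglik += std::log(scale);

  for (int t = 1; t < T; ++t) {
    scale = 0.0;
    for (int s = 0; s < S; ++s) {
      double acc = 0.0;
      for (int r = 0; r < S; ++r) acc += alpha[r] * P(r, s);
      nxt[s] = acc * R::dnorm(x[t], means[s], sd, 0);
      scale += nxt[s];
    }
    if (scale <= 0.0) return R_NegInf;
    for (int s = 0; s < S; ++s) alpha[s] = nxt[s] / scale;
    loglik += std::log(scale);
  }
  return loglik;
}

// Log-likelihood of a fully observed state path under transition matrix P.
// [[Rcpp::export(name = ".cg_path_loglik")]]
double cg_path_loglik(IntegerVector k, NumericMatrix P, NumericVector pi0) {
  const int T = k.size();
  double ll = std::log(pi0[k[0]]);
  for (int t = 1; t < T; ++t) {
    double p = P(k[t - 1], k[t]);
    if (p <= 0.0) return R_NegInf;
    ll += std::log(p);
  }
  return ll;
}

// Sample a Markov chain trajectory; draws come from the R RNG so set.seed()
// governs reproducibility.
// [[Rcpp::export(name = ".cg_simulate_chain")]]
IntegerVector cg_simulate_chain(NumericMatrix P, int init, int n) {
  const int S = P.nrow();
  IntegerVector k(n);
  int state = init;
  k[0] = state;
  for (int t = 1; t < n; ++t) {
    double u = R::unif_rand();
    double acc = 0.0;
    int s = S - 1;
    for (int j = 0; j < S; ++j) {
      acc += P(state, j);
      if (u <= acc) { s = j; break; }
    }
    state = s;
    k[t] = state;
  }
  return k;
}

// 8-connected component labeling of a binary mask (flood fill).
// [[Rcpp::export(name = ".cg_label_components")]]
IntegerMatrix cg_label_components(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}

static NumericMatrix disk_morph(NumericMatrix img, int radius, bool erode) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const int r2 = radius * radius;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double ext = img(i, j);
      for (int dj = -radius; dj <= radius; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= nc) continue;
        for (int di = -radius; di <= radius; ++di) {
          if (di * di + dj * dj > r2) continue;
          int ii = i + di;
          if (ii < 0 || ii >= nr) continue;
          double v = img(ii, jj);
          if (erode ? (v < ext) : (v > ext)) ext = v;
        }
      }
      out(i, j) = ext;
    }
  }
  return out;
}

// Grayscale opening with a disk structuring element: the rolling-ball
// style smooth-background estimate used before spot detection.
// [[Rcpp::export(name = ".cg_disk_opening")]]
NumericMatrix cg_disk_opening(NumericMatrix img, int radius) {
  return disk_morph(disk_morph(img, radius, true), radius, false);
}
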