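// Permutation engine for the ensemble association measures.
//
// For every unordered taxon pair it evaluates, on the observed data and on B
// sample-label permutations of the second profile: Spearman and Pearson
// correlation (via pre-standardized rows, so a dot product), symmetrized
// Kullback-Leibler dissimilarity (via log-profile cross products),
// Bray-Curtis dissimilarity and a binned plug-in mutual information.
// Permutation p-values use the add-one estimator; per-replicate empirical
// p-values feed the mean/covariance of the -2*log(p) transforms needed by
// the empirical Brown combination.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int count_geq(const std::vector<double>& sorted, double x) {
  return (int)(sorted.end() -
               std::lower_bound(sorted.begin(), sorted.end(), x));
}
static inline int count_leq(const std::vector<double>& sorted, double x) {
  return (int)(std::upper_bound(sorted.begin(), sorted.end(), x) -
               sorted.begin());
}

// [[Rcpp::export]]
List assoc_engine_cpp(const arma::mat& Zs, const arma::mat& Zp,
                      const arma::mat& Rl, const arma::mat& Pk,
                      const arma::mat& Lk, const arma::vec& h,
                      const arma::imat& bins, int nbins,
                      const arma::imat& perms, const LogicalVector& valid) {
  const int T = Zs.n_rows, n = Zs.n_cols;
  const int B = perms.n_rows;
  const int P = T * (T - 1) / 2;
  const int M = 5;

  if ((double)P * M * (B + 1) > 2.5e8)
    stop("problem too large: reduce taxa or permutations");

  arma::vec rowsumRl = arma::sum(Rl, 1);

  // margins of the equal-frequency bins, fixed under permutation
  arma::imat marg(T, nbins, arma::fill::zeros);
  for (int i = 0; i < T; ++i)
    for (int s = 0; s < n; ++s) marg(i, bins(i, s))++;

  NumericMatrix obs(P, M);
  NumericMatrix pval(P, M);
  NumericMatrix w_mean(P, M), w_cov(P, M * M), stat_cor(P, M * M);
  std::fill(pval.begin(), pval.end(), NA_REAL);
  std::fill(w_mean.begin(), w_mean.end(), NA_REAL);
  std::fill(w_cov.begin(), w_cov.end(), NA_REAL);
  std::fill(stat_cor.begin(), stat_cor.end(), NA_REAL);

  // stats under permutation: [pair][measure][replicate]
  std::vector<double> sp;
  if (B > 0) sp.assign((size_t)P * M * B, 0.0);
  auto SP = [&](int p, int m, int b) -> double& {
    return sp[((size_t)p * M + m) * B + b];
  };

  std::vector<int> cont((size_t)nbins * nbins);
  const double ln = std::log((double)n);

  // one pass computes all five measures for permutation b (b = -1: observed)
  auto fill_stats = [&](int b) {
    arma::uvec idx(n);
    if (b < 0) { for (int s = 0; s < n; ++s) idx(s) = s; }
    else       { for (int s = 0; s < n; ++s) idx(s) = perms(b, s); }

    arma::mat Zsp = Zs.cols(idx), Zpp = Zp.cols(idx);
    arma::mat S1 = Zs * Zsp.t();
    arma::mat S2 = Zp * Zpp.t();
    arma::mat A1 = Pk * (Lk.cols(idx)).t();
    arma::mat A2 = Pk.cols(idx) * Lk.t();

    int p = 0;
    for (int i = 0; i < T - 1; ++i) {
      for (int j = i + 1; j < T; ++j, ++p) {
        double s_sp = (valid[i] && valid[j]) ? S1(i, j) : NA_REAL;
        double s_pe = (valid[i] && valid[j]) ? S2(i, j) : NA_REAL;
        double s_kl = h(i) + h(j) - A1(i, j) - A2(j, i);

        double num = 0.0;
        std::fill(cont.begin(), cont.end(), 0);
        for (int s = 0; s < n; ++s) {
          int ps = (int)idx(s);
          num += std::fabs(Rl(i, s) - Rl(j, ps));
          cont[(size_t)bins(i, s) * nbins + bins(j, ps)]++;
        }
        double s_bc = num / (rowsumRl(i) + rowsumRl(j));

        double mi = 0.0;
        for (int a = 0; a < nbins; ++a) {
          if (marg(i, a) == 0) continue;
          for (int bb = 0; bb < nbins; ++bb) {
            int c = cont[(size_t)a * nbins + bb];
            if (c > 0)
              mi += ((double)c / n) *
                    (std::log((double)c) + ln -
                     std::log((double)marg(i, a)) -
                     std::log((double)marg(j, bb)));
          }
        }

        if (b < 0) {
          obs(p, 0) = s_sp; obs(p, 1) = s_pe; obs(p, 2) = s_kl;
          obs(p, 3) = s_bc; obs(p, 4) = mi;
        } else {
          SP(p, 0, b) = s_sp; SP(p, 1, b) = s_pe; SP(p, 2, b) = s_kl;
          SP(p, 3, b) = s_bc; SP(p, 4, b) = mi;
        }
      }
    }
  };

  fill_stats(-1);
  for (int b = 0; b < B; ++b) {
    fill_stats(b);
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }

  if (B == 0)
    return List::create(_["obs"] = obs, _["pval"] = pval,
                        _["w_mean"] = w_mean, _["w_cov"] = w_cov,
                        _["stat_cor"] = stat_cor, _["B"] = B);

  std::vector<double> vals(B), sorted(B);
  arma::mat W(B, M);
  int p = 0;
  for (int i = 0; i < T - 1; ++i) {
    for (int j = i + 1; j < T; ++j, ++p) {
      std::vector<bool> okm(M, true);
      if (!(valid[i] && valid[j])) { okm[0] = okm[1] = false; }
      for (int m = 0; m < M; ++m) {
        if (!okm[m]) { W.col(m).fill(arma::datum::nan); continue; }
        for (int b = 0; b < B; ++b) vals[b] = SP(p, m, b);
        double o = obs(p, m);
        if (m == 2 || m == 3) {
          // dissimilarity: two-sided by doubling the smaller tail
          sorted = vals;
          std::sort(sorted.begin(), sorted.end());
          int lo = count_leq(sorted, o), hi = count_geq(sorted, o);
          double pv = 2.0 * std::min(lo + 1, hi + 1) / (B + 1.0);
          pval(p, m) = std::min(1.0, pv);
          for (int b = 0; b < B; ++b) {
            int l = count_leq(sorted, vals[b]), hh = count_geq(sorted, vals[b]);
            double pb = std::min(1.0, 2.0 * std::min(l, hh) / (B + 1.0));
            W(b, m) = -2.0 * std::log(pb);
          }
        } else {
          // signed measures two-sided on |T|; MI upper tail
          double oa = (m == 4) ? o : std::fabs(o);
          for (int b = 0; b < B; ++b)
            sorted[b] = (m == 4) ? vals[b] : std::fabs(vals[b]);
          std::vector<double> raw = sorted;
          std::sort(sorted.begin(), sorted.end());
          pval(p, m) = (1.0 + count_geq(sorted, oa)) / (B + 1.0);
          for (int b = 0; b < B; ++b)
            W(b, m) = -2.0 * std::log(count_geq(sorted, raw[b]) / (B + 1.0));
        }
      }
      for (int m = 0; m < M; ++m) {
        if (!okm[m]) continue;
        w_mean(p, m) = arma::mean(W.col(m));
      }
      for (int m1 = 0; m1 < M; ++m1) {
        for (int m2 = 0; m2 < M; ++m2) {
          if (!okm[m1] || !okm[m2]) continue;
          arma::vec a = W.col(m1) - arma::mean(W.col(m1));
          arma::vec bvec = W.col(m2) - arma::mean(W.col(m2));
          w_cov(p, m1 * M + m2) = arma::dot(a, bvec) / (B - 1);
          // correlation of the raw permuted statistics (Kost fallback)
          arma::vec s1(B), s2(B);
          for (int b = 0; b < B; ++b) { s1(b) = SP(p, m1, b); s2(b) = SP(p, m2, b); }
          double sd1 = arma::stddev(s1), sd2 = arma::stddev(s2);
          stat_cor(p, m1 * M + m2) =
            (sd1 > 0 && sd2 > 0)
              ? arma::dot(s1 - arma::mean(s1), s2 - arma::mean(s2)) /
                  ((B - 1) * sd1 * sd2)
              : 0.0;
        }
      }
    }
  }

  return List::create(_["obs"] = obs, _["pval"] = pval,
                      _["w_mean"] = w_mean, _["w_cov"] = w_cov,
                      _["stat_cor"] = stat_cor, _["B"] = B);
}
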