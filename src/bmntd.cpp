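#include <Rcpp.h>
using namespace Rcpp;

// betaMNTD between samples k and m:
//   0.5 * [ sum_{i in Tk} f_ik * min_{j in Tm} d(i,j)
//         + sum_{j in Tm} f_jm * min_{i in Tk} d(i,j) ]
// with f the within-sample relative abundances (weighted) or 1/|T|
// (unweighted). `perm` maps taxon columns onto shuffled identities on the
// distance matrix, implementing the tip-label permutation null.
static double pair_bmntd(const NumericMatrix &rel, const NumericMatrix &D,
                         const std::vector<std::vector<int>> &present,
                         int k, int m, bool weighted, const IntegerVector &perm) {
  const std::vector<int> &tk = present[k];
  const std::vector<int> &tm = present[m];
  double s1 = 0.0, s2 = 0.0;
  const double wk = 1.0 / tk.size(), wm = 1.0 / tm.size();
  for (size_t a = 0; a < tk.size(); ++a) {
    const int i = perm[tk[a]];
    double mn = R_PosInf;
    for (size_t b = 0; b < tm.size(); ++b) {
      const double d = D(i, perm[tm[b]]);
      if (d < mn) mn = d;
    }
    s1 += (weighted ? rel(k, tk[a]) : wk) * mn;
  }
  for (size_t b = 0; b < tm.size(); ++b) {
    const int j = perm[tm[b]];
    double mn = R_PosInf;
    for (size_t a = 0; a < tk.size(); ++a) {
      const double d = D(perm[tk[a]], j);
      if (d < mn) mn = d;
    }
    s2 += (weighted ? rel(m, tm[b]) : wm) * mn;
  }
  return 0.5 * (s1 + s2);
}

static std::vector<std::vector<int>> presence_lists(const NumericMatrix &rel) {
  std::vector<std::vector<int>> present(rel.nrow());
  for (int k = 0; k < rel.nrow(); ++k)
    for (int j = 0; j < rel.ncol(); ++j)
      if (rel(k, j) > 0) present[k].push_back(j);
  return present;
}

// [[Rcpp::export]]
NumericMatrix cpp_bmntd(NumericMatrix rel, NumericMatrix D, bool weighted) {
  const int S = rel.nrow();
  IntegerVector ident(rel.ncol());
  for (int j = 0; j < rel.ncol(); ++j) ident[j] = j;
  std::vector<std::vector<int>> present = presence_lists(rel);
  for (int k = 0; k < S; ++k)
    if (present[k].empty()) stop("sample with no present taxa");
  NumericMatrix out(S, S);
  for (int k = 0; k < S; ++k)
    for (int m = k + 1; m < S; ++m)
      out(k, m) = out(m, k) = pair_bmntd(rel, D, present, k, m, weighted, ident);
  return out;
}

// Tip-shuffle null: `perms` is n_null x n_taxa of 0-based permutations, the
// same permutation applied to every pair within an iteration. Returns the
// observed matrix plus per-pair null mean and (n-1)-denominator SD.
// [[Rcpp::export]]
List cpp_bnti_null(NumericMatrix rel, NumericMatrix D, IntegerMatrix perms,
                   bool weighted) {
  const int S = rel.nrow();
  const int n_null = perms.nrow();
  std::vector<std::vector<int>> present = presence_lists(rel);
  for (int k = 0; k < S; ++k)
    if (present[k].empty()) stop("sample with no present taxa");
  IntegerVector ident(rel.ncol());
  for (int j = 0; j < rel.ncol(); ++j) ident[j] = j;
  NumericMatrix obs(S, S), sum(S, S), sumsq(S, S);
  for (int k = 0; k < S; ++k)
    for (int m = k + 1; m < S; ++m)
      obs(k, m) = obs(m, k) = pair_bmntd(rel, D, present, k, m, weighted, ident);
  IntegerVector perm(rel.ncol());
  for (int it = 0; it < n_null; ++it) {
    for (int j = 0; j < rel.ncol(); ++j) perm[j] = perms(it, j);
    for (int k = 0; k < S; ++k)
      for (int m = k + 1; m < S; ++m) {
        const double v = pair_bmntd(rel, D, present, k, m, weighted, perm);
        sum(k, m) += v;
        sumsq(k, m) += v * v;
      }
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix mean(S, S), sdm(S, S);
  for (int k = 0; k < S; ++k)
    for (int m = k + 1; m < S; ++m) {
      const double mu = sum(k, m) / n_null;
      double v = (sumsq(k, m) - n_null * mu * mu) / (n_null - 1.0);
      if (v < 0) v = 0;
      mean(k, m) = mean(m, k) = mu;
      sdm(k, m) = sdm(m, k) = std::sqrt(v);
    }
  return List::create(_["obs"] = obs, _["mean"] = mean, _["sd"] = sdm);
}
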