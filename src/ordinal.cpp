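#include <Rcpp.h>
using namespace Rcpp;

// Ordinal pattern identifiers (Lehmer-code index, 1-based) for every delay
// vector of a series. Ties rank by temporal order (earlier index ranks
// lower). m is small (<= 10), so the O(m^2) pairwise ranking per vector is
// faster than sorting.
// [[Rcpp::export(name = ".pattern_ids")]]
IntegerVector pattern_ids(NumericVector x, int m, int tau) {
  const int N = x.size();
  const int n = N - (m - 1) * tau;
  if (n < 1) stop("series too short for (m, tau)");
  IntegerVector ids(n);
  std::vector<int> rho(m), kappa(m), fact(m + 1);
  fact[0] = 1;
  for (int j = 1; j <= m; ++j) fact[j] = fact[j - 1] * j;
  for (int i = 0; i < n; ++i) {
    const double *v = &x[i];
    for (int j = 0; j < m; ++j) {
      const double xj = v[j * tau];
      int r = 0;
      for (int l = 0; l < m; ++l) {
        if (l == j) continue;
        const double xl = v[l * tau];
        if (xl < xj || (xl == xj && l < j)) ++r;
      }
      rho[j] = r;
    }
    for (int j = 0; j < m; ++j) kappa[rho[j]] = j;
    int id = 0;
    for (int r = 0; r < m - 1; ++r) {
      int lehmer = 0;
      for (int s = r + 1; s < m; ++s)
        if (kappa[s] < kappa[r]) ++lehmer;
      id += lehmer * fact[m - 1 - r];
    }
    ids[i] = id + 1;
  }
  return ids;
}

// Pattern ids plus the two amplitude summaries of each delay vector: AA, the
// mean absolute sample amplitude, and RA, the mean absolute successive
// difference. One pass shared by the weighted and unweighted distributions.
// [[Rcpp::export(name = ".pattern_ids_amplitudes")]]
List pattern_ids_amplitudes(NumericVector x, int m, int tau) {
  IntegerVector ids = pattern_ids(x, m, tau);
  const int n = ids.size();
  NumericVector aa(n), ra(n);
  for (int i = 0; i < n; ++i) {
    const double *v = &x[i];
    double s_aa = 0.0, s_ra = 0.0;
    for (int j = 0; j < m; ++j) {
      s_aa += std::abs(v[j * tau]);
      if (j > 0) s_ra += std::abs(v[j * tau] - v[(j - 1) * tau]);
    }
    aa[i] = s_aa / m;
    ra[i] = s_ra / (m - 1);
  }
  return List::create(_["ids"] = ids, _["aa"] = aa, _["ra"] = ra);
}

// Inner-CV misclassification of the squared-inverse-distance weighted kNN
// for each candidate feature added to the selected set. X holds the
// (already standardised) training features; `fold` the inner fold of each
// row; `y` the 0/1 class. Distances between rows use the selected columns
// plus the candidate column; the candidate's contribution is accumulated on
// the fly so no per-candidate matrix is materialised. Used to make
// sequential forward selection with kNN tractable.
// [[Rcpp::export(name = ".wknn_cv_errors")]]
NumericVector wknn_cv_errors(NumericMatrix X, IntegerVector sel,
                             IntegerVector cand, IntegerVector y,
                             IntegerVector fold, int k) {
  const int n = X.nrow();
  NumericMatrix Dsel(n, n);
  for (int s = 0; s < sel.size(); ++s) {
    const int c = sel[s];
    for (int i = 0; i < n; ++i) {
      const double xi = X(i, c);
      for (int j = i + 1; j < n; ++j) {
        const double d = xi - X(j, c);
        Dsel(i, j) += d * d;
      }
    }
  }
  NumericVector errs(cand.size());
  std::vector<double> bestd(k);
  std::vector<int> besty(k);
  for (int ci = 0; ci < cand.size(); ++ci) {
    const int c = cand[ci];
    int wrong = 0;
    for (int i = 0; i < n; ++i) {
      int used = 0, worst = 0;
      for (int j = 0; j < n; ++j) {
        if (fold[j] == fold[i]) continue;  // same inner fold (or self)
        const double dc = X(i, c) - X(j, c);
        const double d = (i < j ? Dsel(i, j) : Dsel(j, i)) + dc * dc;
        if (used < k) {
          bestd[used] = d; besty[used] = y[j];
          if (bestd[used] > bestd[worst]) worst = used;
          ++used;
        } else if (d < bestd[worst]) {
          bestd[worst] = d; besty[worst] = y[j];
          for (int t = 0; t < k; ++t) if (bestd[t] > bestd[worst]) worst = t;
        }
      }
      double v0 = 0.0, v1 = 0.0;
      for (int t = 0; t < used; ++t) {
        const double w = 1.0 / std::max(bestd[t], 1e-24);
        if (besty[t] == 1) v1 += w; else v0 += w;
      }
      if ((v1 > v0 ? 1 : 0) != y[i]) ++wrong;
    }
    errs[ci] = static_cast<double>(wrong) / n;
  }
  return errs;
}
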