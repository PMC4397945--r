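#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Gibbs sampler core for one inference unit. Mirrors the R reference engine
// (gibbs_core_r): per iteration sample b_z | c, then z, then e | z,c, then
// t | e. All weight computations for b_z are done in log space. Uses R's RNG
// so a set.seed() at the R level makes runs bit-reproducible.
//
// L: n x m likelihood matrix (all rows have a positive entry).
// t_init: 0-based initial assignments.
// [[Rcpp::export]]
List gibbs_core(NumericMatrix L, double pi, double gamma_, int burn_in,
                int n_samples, IntegerVector t_init, bool keep_trace) {
  const int n = L.nrow();
  const int m = L.ncol();
  if (t_init.size() != n) stop("t_init length mismatch");

  std::vector<int> c_counts(m, 0);
  for (int i = 0; i < n; ++i) {
    int t = t_init[i];
    if (t < 0 || t >= m) stop("t_init out of range");
    c_counts[t]++;
  }

  std::vector<int> cnt(m, 0);
  std::vector<double> sum_e(m, 0.0), sum_c(m, 0.0);
  std::vector<int> z(m), jzero(m), t_cur(t_init.begin(), t_init.end());
  std::vector<double> e(m), lw(m + 1), cum(m);
  LogicalMatrix trace_z(keep_trace ? n_samples : 0, keep_trace ? m : 0);
  NumericMatrix trace_e(keep_trace ? n_samples : 0, keep_trace ? m : 0);
  IntegerMatrix trace_c(keep_trace ? n_samples : 0, keep_trace ? m : 0);

  const double lpi = std::log(pi);
  const bool pi_one = (pi >= 1.0);
  const double l1mp = pi_one ? R_NegInf : std::log1p(-pi);
  const int total = burn_in + n_samples;
  int retained = 0;

  for (int it = 0; it < total; ++it) {
    // --- b_z | c ---
    int jp = 0;
    for (int j = 0; j < m; ++j) if (c_counts[j] > 0) jp++;
    const int j0 = m - jp;
    int nb = m - jp + 1;  // support: b = jp..m
    double mx = R_NegInf;
    for (int k = 0; k < nb; ++k) {
      int b = jp + k;
      double w = Rf_lchoose((double)j0, (double)(b - jp)) +
                 Rf_lgammafn(b * gamma_) - Rf_lgammafn(n + b * gamma_) +
                 b * lpi;
      if (m - b > 0) w += pi_one ? R_NegInf : (m - b) * l1mp;
      lw[k] = w;
      if (w > mx) mx = w;
    }
    if (!R_finite(mx)) stop("all b_z weights vanished");
    double tot = 0.0;
    for (int k = 0; k < nb; ++k) { lw[k] = std::exp(lw[k] - mx); tot += lw[k]; }
    double u = unif_rand() * tot;
    int b_z = m;
    for (int k = 0; k < nb; ++k) {
      u -= lw[k];
      if (u <= 0.0) { b_z = jp + k; break; }
    }

    // --- z | b_z ---
    int nz = 0;
    for (int j = 0; j < m; ++j) {
      z[j] = c_counts[j] > 0 ? 1 : 0;
      if (!z[j]) jzero[nz++] = j;
    }
    int extra = b_z - jp;
    for (int k = 0; k < extra; ++k) {  // partial Fisher-Yates draw from J0
      int pick = k + (int)(unif_rand() * (nz - k));
      if (pick >= nz) pick = nz - 1;
      std::swap(jzero[k], jzero[pick]);
      z[jzero[k]] = 1;
    }

    // --- e | z, c ---
    double esum = 0.0;
    for (int j = 0; j < m; ++j) {
      if (z[j]) {
        e[j] = R::rgamma(c_counts[j] + gamma_, 1.0);
        esum += e[j];
      } else e[j] = 0.0;
    }
    if (esum <= 0.0) stop("degenerate Dirichlet draw");
    for (int j = 0; j < m; ++j) e[j] /= esum;

    // --- t | e ---
    std::fill(c_counts.begin(), c_counts.end(), 0);
    for (int i = 0; i < n; ++i) {
      double wtot = 0.0;
      for (int j = 0; j < m; ++j) {
        wtot += L(i, j) * e[j];
        cum[j] = wtot;
      }
      if (wtot <= 0.0) stop("fragment with zero mass under expressed candidates");
      double v = unif_rand() * wtot;
      int t = m - 1;
      for (int j = 0; j < m; ++j) if (cum[j] >= v) { t = j; break; }
      t_cur[i] = t;
      c_counts[t]++;
    }

    if (it >= burn_in) {
      for (int j = 0; j < m; ++j) {
        if (z[j]) { cnt[j]++; sum_e[j] += e[j]; }
        sum_c[j] += c_counts[j];
        if (keep_trace) {
          trace_z(retained, j) = z[j] != 0;
          trace_e(retained, j) = e[j];
          trace_c(retained, j) = c_counts[j];
        }
      }
      retained++;
    }
  }

  return List::create(
    _["expressed_count"] = IntegerVector(cnt.begin(), cnt.end()),
    _["sum_e"] = NumericVector(sum_e.begin(), sum_e.end()),
    _["sum_c"] = NumericVector(sum_c.begin(), sum_c.end()),
    _["retained"] = retained,
    _["trace_z"] = trace_z,
    _["trace_e"] = trace_e,
    _["trace_c"] = trace_c);
}
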