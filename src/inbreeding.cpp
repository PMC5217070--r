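#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo (1992) algorithm.
//
// dam, sire: 1-based codes of the parents in a topologically ordered
// pedigree (parents precede offspring), 0 = unknown. Phantom parents are
// taken as outbred and unrelated, so F = 0 whenever a parent is unknown.
//
// For individual i with both parents known, A_ii = sum_j L_ij^2 d_j over
// ancestors j of i (including i itself), where L is the Cholesky-like
// gene-flow coefficient and d_j the Mendelian sampling variance; then
// F_i = A_ii - 1. Ancestors are visited from the highest code downward so
// path coefficients accumulate before a code is expanded.
// [[Rcpp::export]]
NumericVector ml_inbreeding(IntegerVector dam, IntegerVector sire) {
  const int n = dam.size();
  NumericVector F(n);
  std::vector<double> d(n), L(n + 1, 0.0);
  std::vector<char> inq(n + 1, 0);

  for (int i = 0; i < n; ++i) {
    const int di = dam[i], si = sire[i];
    if (di > i + 1 || si > i + 1 || di < 0 || si < 0)
      stop("pedigree is not ordered: parents must precede offspring");
    const double Fd = di ? F[di - 1] : 0.0;
    const double Fs = si ? F[si - 1] : 0.0;
    if (di && si)
      d[i] = 0.5 - 0.25 * (Fd + Fs);
    else if (di || si)
      d[i] = 0.75 - 0.25 * (di ? Fd : Fs);
    else
      d[i] = 1.0;

    if (!di || !si) {
      F[i] = 0.0;
      continue;
    }

    double aii = 0.0;
    std::priority_queue<int> pq;
    L[i + 1] = 1.0;
    inq[i + 1] = 1;
    pq.push(i + 1);
    while (!pq.empty()) {
      const int j = pq.top();
      pq.pop();
      inq[j] = 0;
      const double v = L[j];
      L[j] = 0.0;
      aii += v * v * d[j - 1];
      const int jd = dam[j - 1], js = sire[j - 1];
      if (jd) {
        L[jd] += 0.5 * v;
        if (!inq[jd]) { inq[jd] = 1; pq.push(jd); }
      }
      if (js) {
        L[js] += 0.5 * v;
        if (!inq[js]) { inq[js] = 1; pq.push(js); }
      }
    }
    F[i] = aii - 1.0;
  }
  return F;
}
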