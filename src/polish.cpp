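#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of a scratch vector (sorts in place); empty -> 0 so all-missing
// rows/columns contribute no change
static double medOf(std::vector<double> &v) {
  const size_t n = v.size();
  if (n == 0) return 0.0;
  std::sort(v.begin(), v.end());
  if (n % 2 == 1) return v[n / 2];
  return (v[n / 2 - 1] + v[n / 2]) / 2.0;
}

// Alternating row-first median sweeps with missing-cell support. After
// each half-sweep the median of the effect vector (over fitted
// rows/columns only) is folded into the overall term. Effects of
// all-missing rows/columns are pinned to 0 on exit.
// [[Rcpp::export(name = ".polishSweeps")]]
List polishSweeps(NumericMatrix x, int maxIter, double tol, double scale0) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix z = clone(x);
  std::vector<double> rowEff(nr, 0.0), colEff(nc, 0.0), buf;
  std::vector<bool> naRow(nr, true), naCol(nc, true);
  buf.reserve(std::max(nr, nc));
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      if (!NumericMatrix::is_na(z(i, j))) {
        naRow[i] = false;
        naCol[j] = false;
      }

  double overall = 0.0;
  bool converged = false;
  int it = 0;
  while (it < maxIter) {
    ++it;
    double change = 0.0;
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int j = 0; j < nc; ++j)
        if (!NumericMatrix::is_na(z(i, j))) buf.push_back(z(i, j));
      const double m = medOf(buf);
      if (m != 0.0)
        for (int j = 0; j < nc; ++j)
          if (!NumericMatrix::is_na(z(i, j))) z(i, j) -= m;
      rowEff[i] += m;
      change += std::abs(m);
    }
    buf.clear();
    for (int j = 0; j < nc; ++j) if (!naCol[j]) buf.push_back(colEff[j]);
    double d = medOf(buf);
    for (int j = 0; j < nc; ++j) colEff[j] -= d;
    overall += d;

    for (int j = 0; j < nc; ++j) {
      buf.clear();
      for (int i = 0; i < nr; ++i)
        if (!NumericMatrix::is_na(z(i, j))) buf.push_back(z(i, j));
      const double m = medOf(buf);
      if (m != 0.0)
        for (int i = 0; i < nr; ++i)
          if (!NumericMatrix::is_na(z(i, j))) z(i, j) -= m;
      colEff[j] += m;
      change += std::abs(m);
    }
    buf.clear();
    for (int i = 0; i < nr; ++i) if (!naRow[i]) buf.push_back(rowEff[i]);
    d = medOf(buf);
    for (int i = 0; i < nr; ++i) rowEff[i] -= d;
    overall += d;

    if (change < tol * scale0) {
      converged = true;
      break;
    }
  }
  for (int i = 0; i < nr; ++i) if (naRow[i]) rowEff[i] = 0.0;
  for (int j = 0; j < nc; ++j) if (naCol[j]) colEff[j] = 0.0;

  return List::create(_["overall"] = overall,
                      _["rowEffects"] = NumericVector(rowEff.begin(), rowEff.end()),
                      _["colEffects"] = NumericVector(colEff.begin(), colEff.end()),
                      _["residuals"] = z,
                      _["nIter"] = it,
                      _["converged"] = converged);
}
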