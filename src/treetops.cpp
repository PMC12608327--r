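// Variable-window local-maximum search on a canopy height model.
//
// A cell is a tree top when its value is >= every non-NA cell whose center
// lies within a circular window of radius f(value) = slope * value +
// intercept (meters) around the cell center, and no equal-valued cell with a
// smaller (row, col) lexicographic index lies inside the window. The second
// clause is the deterministic tie-break for plateaus and exact height ties;
// it keeps exactly one top per tied cluster whenever the window radius is at
// least one cell (guaranteed above the 7 m mask at resolutions <= 1 m).

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

//' @noRd
// [[Rcpp::export(name = ".cpp_local_maxima")]]
IntegerMatrix cpp_local_maxima(NumericMatrix values, double res,
                               double slope, double intercept) {
  const int nr = values.nrow(), nc = values.ncol();
  std::vector<int> ri, ci;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      const double v = values(i, j);
      if (!R_finite(v)) continue;
      const double radius = slope * v + intercept;
      if (radius < 0) continue;
      const int rc = static_cast<int>(std::floor(radius / res + 1e-9));
      const double r2 = radius * radius + 1e-9;
      bool top = true;
      for (int di = -rc; di <= rc && top; ++di) {
        const int ii = i + di;
        if (ii < 0 || ii >= nr) continue;
        for (int dj = -rc; dj <= rc; ++dj) {
          if (di == 0 && dj == 0) continue;
          const int jj = j + dj;
          if (jj < 0 || jj >= nc) continue;
          if ((di * res) * (di * res) + (dj * res) * (dj * res) > r2) continue;
          const double nv = values(ii, jj);
          if (!R_finite(nv)) continue;
          if (nv > v || (nv == v && (ii < i || (ii == i && jj < j)))) {
            top = false;
            break;
          }
        }
      }
      if (top) { ri.push_back(i + 1); ci.push_back(j + 1); }
    }
  }
  IntegerMatrix out(ri.size(), 2);
  for (size_t k = 0; k < ri.size(); ++k) {
    out(k, 0) = ri[k];
    out(k, 1) = ci[k];
  }
  colnames(out) = CharacterVector::create("row", "col");
  return out;
}
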