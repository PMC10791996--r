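#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Moving-window GLCM Haralick statistics.
//
// For each pixel with a complete (window x window) neighbourhood, the gray
// level co-occurrence matrix is accumulated over all pixel pairs separated
// by (dx, dy) that lie fully inside the window (dx = columns east,
// dy = rows south; symmetric = count both directions), normalised to
// probabilities p(i, j), and reduced to the eight standard statistics
// MEA, VAR, HOM, CON, DIS, ENT, SEC, COR. Pairs touching NA are skipped;
// windows with no valid pair (and incomplete border windows) yield NA.
// A zero-variance window reports COR = 0 so constant regions stay usable.
// [[Rcpp::export]]
List glcm_texture_cpp(IntegerMatrix q, int window, int levels,
                      int dx, int dy, bool symmetric) {
  const int nr = q.nrow(), nc = q.ncol();
  const int h = window / 2;
  const char *stat_names[8] = {"MEA", "VAR", "HOM", "CON",
                               "DIS", "ENT", "SEC", "COR"};
  std::vector<NumericMatrix> out;
  for (int s = 0; s < 8; ++s) {
    NumericMatrix m(nr, nc);
    std::fill(m.begin(), m.end(), NA_REAL);
    out.push_back(m);
  }

  std::vector<double> counts((size_t)levels * levels, 0.0);
  std::vector<int> touched;
  touched.reserve(4 * (size_t)window * window);

  for (int r = h; r < nr - h; ++r) {
    for (int c = h; c < nc - h; ++c) {
      touched.clear();
      double n = 0.0;
      // directed pairs fully inside the window
      for (int wr = r - h; wr <= r + h; ++wr) {
        int pr = wr + dy;
        if (pr < r - h || pr > r + h) continue;
        for (int wc = c - h; wc <= c + h; ++wc) {
          int pc = wc + dx;
          if (pc < c - h || pc > c + h) continue;
          int i = q(wr, wc), j = q(pr, pc);
          if (i == NA_INTEGER || j == NA_INTEGER) continue;
          int k1 = i * levels + j;
          if (counts[k1] == 0.0) touched.push_back(k1);
          counts[k1] += 1.0;
          n += 1.0;
          if (symmetric) {
            int k2 = j * levels + i;
            if (counts[k2] == 0.0) touched.push_back(k2);
            counts[k2] += 1.0;
            n += 1.0;
          }
        }
      }
      if (n > 0.0) {
        double mea = 0, mj = 0, hom = 0, con = 0, dis = 0, ent = 0, sec = 0;
        double eij = 0;
        for (int t : touched) {
          double p = counts[t] / n;
          int i = t / levels, j = t % levels;
          double d = (double)(i - j);
          mea += i * p;
          mj  += j * p;
          hom += p / (1.0 + d * d);
          con += d * d * p;
          dis += std::fabs(d) * p;
          ent -= p * std::log(p);
          sec += p * p;
          eij += (double)i * (double)j * p;
        }
        double var = 0, vj = 0;
        for (int t : touched) {
          double p = counts[t] / n;
          int i = t / levels, j = t % levels;
          var += (i - mea) * (i - mea) * p;
          vj  += (j - mj) * (j - mj) * p;
        }
        double denom = std::sqrt(var * vj);
        double cor = denom > 0.0 ? (eij - mea * mj) / denom : 0.0;
        out[0](r, c) = mea; out[1](r, c) = var; out[2](r, c) = hom;
        out[3](r, c) = con; out[4](r, c) = dis; out[5](r, c) = ent;
        out[6](r, c) = sec; out[7](r, c) = cor;
      }
      for (int t : touched) counts[t] = 0.0;
    }
  }

  List res(8);
  for (int s = 0; s < 8; ++s) res[s] = out[s];
  res.attr("names") = CharacterVector::create("MEA", "VAR", "HOM", "CON",
                                              "DIS", "ENT", "SEC", "COR");
  (void)stat_names;
  return res;
}
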