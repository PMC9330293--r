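#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Pairwise alignment kernels for template matching.
//
// Sequences arrive as 0-based integer codes into the scoring matrix.
// Gap model: the first residue of a gap run costs `gap_open`, every further
// residue `gap_extend` (both positive penalties).
//
// Path alphabet: 'M' aligned pair (match or mismatch), 'D' template residue
// skipped by the read (deletion from the read), 'I' read residue absent from
// the template (insertion in the read).
//
// Traceback ties are broken deterministically: diagonal over delete over
// insert, so identical inputs always yield identical paths.

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".cpp_sw_align")]]
List cpp_sw_align(IntegerVector a, IntegerVector b, NumericMatrix mat,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  // state 0 = M (aligned pair), 1 = D (gap in read, consumes template),
  // 2 = I (gap in template, consumes read)
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, 0.0));
  std::vector<std::vector<double>> D(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> I(n + 1, std::vector<double>(m + 1, NEG_INF));

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = mat(a[i - 1], b[j - 1]);
      double prev = M[i - 1][j - 1];
      if (D[i - 1][j - 1] > prev) prev = D[i - 1][j - 1];
      if (I[i - 1][j - 1] > prev) prev = I[i - 1][j - 1];
      if (prev < 0.0) prev = 0.0;  // local: restart
      M[i][j] = prev + s;
      if (M[i][j] < 0.0) M[i][j] = 0.0;

      double d = M[i][j - 1] - gap_open;
      if (I[i][j - 1] - gap_open > d) d = I[i][j - 1] - gap_open;
      if (D[i][j - 1] - gap_extend > d) d = D[i][j - 1] - gap_extend;
      D[i][j] = d;

      double ins = M[i - 1][j] - gap_open;
      if (D[i - 1][j] - gap_open > ins) ins = D[i - 1][j] - gap_open;
      if (I[i - 1][j] - gap_extend > ins) ins = I[i - 1][j] - gap_extend;
      I[i][j] = ins;

      if (M[i][j] > best) { best = M[i][j]; bi = i; bj = j; }
    }
  }

  std::string path;
  int ri = bi, rj = bj;  // traceback cursor
  int read_end = bi, tmpl_end = bj;
  if (best > 0.0) {
    int state = 0;  // optimum always ends in an aligned pair
    while (true) {
      if (state == 0) {
        double s = mat(a[ri - 1], b[rj - 1]);
        double need = M[ri][rj] - s;  // predecessor contribution
        path.push_back('M');
        --ri; --rj;
        if (need <= 0.0) break;  // local restart: alignment starts here
        if (M[ri][rj] == need) state = 0;
        else if (D[ri][rj] == need) state = 1;
        else state = 2;
      } else if (state == 1) {
        double cur = D[ri][rj];
        path.push_back('D');
        --rj;
        if (M[ri][rj] - gap_open == cur) state = 0;
        else if (D[ri][rj] - gap_extend == cur) state = 1;
        else state = 2;
      } else {
        double cur = I[ri][rj];
        path.push_back('I');
        --ri;
        if (M[ri][rj] - gap_open == cur) state = 0;
        else if (D[ri][rj] - gap_open == cur) state = 1;
        else state = 2;
      }
    }
    std::reverse(path.begin(), path.end());
  } else {
    read_end = 0; tmpl_end = 0; ri = 0; rj = 0;
  }

  int read_start = (best > 0.0) ? ri + 1 : 0;
  int tmpl_start = (best > 0.0) ? rj + 1 : 0;
  return List::create(
      _["score"] = best, _["read_start"] = read_start,
      _["read_end"] = read_end, _["tmpl_start"] = tmpl_start,
      _["tmpl_end"] = tmpl_end, _["path"] = path);
}

// Score-only local alignment (no traceback): used where only the optimum
// matters, e.g. scoring reads against decoy templates.
// [[Rcpp::export(name = ".cpp_sw_score")]]
double cpp_sw_score(IntegerVector a, IntegerVector b, NumericMatrix mat,
                    double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  std::vector<double> M(m + 1, 0.0), D(m + 1, NEG_INF), I(m + 1, NEG_INF);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diagM = M[0], diagD = D[0], diagI = I[0];
    M[0] = 0.0; D[0] = NEG_INF; I[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      double sM = M[j], sD = D[j], sI = I[j];  // row i-1, col j
      double s = mat(a[i - 1], b[j - 1]);
      double prev = diagM;
      if (diagD > prev) prev = diagD;
      if (diagI > prev) prev = diagI;
      if (prev < 0.0) prev = 0.0;
      double mm = prev + s;
      if (mm < 0.0) mm = 0.0;

      double d = M[j - 1] - gap_open;
      if (I[j - 1] - gap_open > d) d = I[j - 1] - gap_open;
      if (D[j - 1] - gap_extend > d) d = D[j - 1] - gap_extend;

      double ins = sM - gap_open;
      if (sD - gap_open > ins) ins = sD - gap_open;
      if (sI - gap_extend > ins) ins = sI - gap_extend;

      M[j] = mm; D[j] = d; I[j] = ins;
      diagM = sM; diagD = sD; diagI = sI;
      if (mm > best) best = mm;
    }
  }
  return best;
}

// Global (Needleman-Wunsch) alignment with affine gaps; reports the aligned
// path plus identity statistics, used for template homology distances.
// [[Rcpp::export(name = ".cpp_nw_align")]]
List cpp_nw_align(IntegerVector a, IntegerVector b, NumericMatrix mat,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> D(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> I(n + 1, std::vector<double>(m + 1, NEG_INF));
  M[0][0] = 0.0;
  for (int j = 1; j <= m; ++j)
    D[0][j] = -(gap_open + (j - 1) * gap_extend);
  for (int i = 1; i <= n; ++i)
    I[i][0] = -(gap_open + (i - 1) * gap_extend);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = mat(a[i - 1], b[j - 1]);
      double prev = M[i - 1][j - 1];
      if (D[i - 1][j - 1] > prev) prev = D[i - 1][j - 1];
      if (I[i - 1][j - 1] > prev) prev = I[i - 1][j - 1];
      M[i][j] = prev + s;

      double d = M[i][j - 1] - gap_open;
      if (I[i][j - 1] - gap_open > d) d = I[i][j - 1] - gap_open;
      if (D[i][j - 1] - gap_extend > d) d = D[i][j - 1] - gap_extend;
      D[i][j] = d;

      double ins = M[i - 1][j] - gap_open;
      if (D[i - 1][j] - gap_open > ins) ins = D[i - 1][j] - gap_open;
      if (I[i - 1][j] - gap_extend > ins) ins = I[i - 1][j] - gap_extend;
      I[i][j] = ins;
    }
  }

  // traceback from best terminal state, preference M > D > I
  int state;
  double score = M[n][m];
  state = 0;
  if (D[n][m] > score) { score = D[n][m]; state = 1; }
  if (I[n][m] > score) { score = I[n][m]; state = 2; }

  std::string path;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      double s = mat(a[i - 1], b[j - 1]);
      double need = M[i][j] - s;
      path.push_back('M');
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[i][j] == need) state = 0;
      else if (D[i][j] == need) state = 1;
      else state = 2;
    } else if (state == 1) {
      double fromM = M[i][j - 1] - gap_open;
      double fromI = I[i][j - 1] - gap_open;
      double fromD = D[i][j - 1] - gap_extend;
      double cur = D[i][j];
      path.push_back('D');
      --j;
      if (cur == fromM) state = 0;
      else if (cur == fromD) state = 1;
      else if (cur == fromI) state = 2;
      else state = 0;
    } else {
      double fromM = M[i - 1][j] - gap_open;
      double fromD = D[i - 1][j] - gap_open;
      double fromI = I[i - 1][j] - gap_extend;
      double cur = I[i][j];
      path.push_back('I');
      --i;
      if (cur == fromM) state = 0;
      else if (cur == fromD) state = 1;
      else if (cur == fromI) state = 2;
      else state = 0;
    }
  }
  std::reverse(path.begin(), path.end());

  int identical = 0, columns = (int)path.size();
  int ai = 0, bj = 0;
  for (char c : path) {
    if (c == 'M') {
      if (a[ai] == b[bj]) ++identical;
      ++ai; ++bj;
    } else if (c == 'D') {
      ++bj;
    } else {
      ++ai;
    }
  }
  return List::create(_["score"] = score, _["identical"] = identical,
                      _["columns"] = columns, _["path"] = path);
}
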