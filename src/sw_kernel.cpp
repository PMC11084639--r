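#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). A gap of length k costs open + k*extend.
// Sequences arrive integer-encoded (1-based row/column indices into submat).
// Tie-breaking contract: the reported optimum is the first maximal cell when
// scanning query-major (smallest query end, then subject end); traceback
// prefers diagonal over up (query residue vs gap) over left.

static inline double cell_score(const IntegerVector &q, const IntegerVector &s,
                                const NumericMatrix &submat, int i, int j) {
  return submat(q[i] - 1, s[j] - 1);
}

// [[Rcpp::export(name = ".sw_score_ints")]]
double sw_score_ints(IntegerVector q, IntegerVector s, NumericMatrix submat,
                     double gap_open, double gap_extend) {
  const int m = q.size(), n = s.size();
  std::vector<double> H(n + 1, 0.0), E(n + 1, R_NegInf);
  double best = 0.0;
  const double gi = gap_open + gap_extend;
  for (int i = 1; i <= m; ++i) {
    double diag = 0.0;        // H[i-1][j-1]
    double F = R_NegInf;      // gap in query (left), row-local
    H[0] = 0.0;
    for (int j = 1; j <= n; ++j) {
      E[j] = std::max(H[j] - gi, E[j] - gap_extend);   // gap in subject (up)
      F = std::max(H[j - 1] - gi, F - gap_extend);
      double h = diag + cell_score(q, s, submat, i - 1, j - 1);
      h = std::max(std::max(h, E[j]), std::max(F, 0.0));
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_align_ints")]]
List sw_align_ints(IntegerVector q, IntegerVector s, NumericMatrix submat,
                   double gap_open, double gap_extend) {
  const int m = q.size(), n = s.size();
  const double gi = gap_open + gap_extend;
  NumericMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
  for (int j = 0; j <= n; ++j) { E(0, j) = R_NegInf; F(0, j) = R_NegInf; }
  for (int i = 0; i <= m; ++i) { E(i, 0) = R_NegInf; F(i, 0) = R_NegInf; }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E(i, j) = std::max(H(i - 1, j) - gi, E(i - 1, j) - gap_extend);
      F(i, j) = std::max(H(i, j - 1) - gi, F(i, j - 1) - gap_extend);
      double h = H(i - 1, j - 1) + cell_score(q, s, submat, i - 1, j - 1);
      h = std::max(std::max(h, E(i, j)), std::max(F(i, j), 0.0));
      H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }  // strict '>': first max wins
    }
  }
  std::vector<int> qcol, scol;
  if (best > 0.0) {
    int i = bi, j = bj, state = 0;  // 0 = H, 1 = E (up), 2 = F (left)
    while (i > 0 && j > 0) {
      if (state == 0) {
        double h = H(i, j);
        if (h == 0.0) break;
        double d = H(i - 1, j - 1) + cell_score(q, s, submat, i - 1, j - 1);
        if (h == d) { qcol.push_back(i); scol.push_back(j); --i; --j; }
        else if (h == E(i, j)) state = 1;
        else state = 2;
      } else if (state == 1) {
        qcol.push_back(i); scol.push_back(NA_INTEGER);
        // prefer closing the gap when both moves reproduce the score
        if (E(i, j) == H(i - 1, j) - gi) { --i; state = 0; }
        else { --i; }
      } else {
        qcol.push_back(NA_INTEGER); scol.push_back(j);
        if (F(i, j) == H(i, j - 1) - gi) { --j; state = 0; }
        else { --j; state = 2; }
      }
    }
    // trailing gap-state steps at the matrix border cannot occur in a local
    // alignment (score would be negative), so the loop always ends in H at 0.
    std::reverse(qcol.begin(), qcol.end());
    std::reverse(scol.begin(), scol.end());
  }
  return List::create(_["score"] = best,
                      _["q_map"] = wrap(qcol),
                      _["s_map"] = wrap(scol));
}

// [[Rcpp::export(name = ".sw_score_mat")]]
double sw_score_mat(NumericMatrix S, double gap_open, double gap_extend) {
  const int m = S.nrow(), n = S.ncol();
  std::vector<double> H(n + 1, 0.0), E(n + 1, R_NegInf);
  double best = 0.0;
  const double gi = gap_open + gap_extend;
  for (int i = 1; i <= m; ++i) {
    double diag = 0.0, F = R_NegInf;
    H[0] = 0.0;
    for (int j = 1; j <= n; ++j) {
      E[j] = std::max(H[j] - gi, E[j] - gap_extend);
      F = std::max(H[j - 1] - gi, F - gap_extend);
      double h = diag + S(i - 1, j - 1);
      h = std::max(std::max(h, E[j]), std::max(F, 0.0));
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_align_mat")]]
List sw_align_mat(NumericMatrix S, double gap_open, double gap_extend) {
  const int m = S.nrow(), n = S.ncol();
  const double gi = gap_open + gap_extend;
  NumericMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
  for (int j = 0; j <= n; ++j) { E(0, j) = R_NegInf; F(0, j) = R_NegInf; }
  for (int i = 0; i <= m; ++i) { E(i, 0) = R_NegInf; F(i, 0) = R_NegInf; }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E(i, j) = std::max(H(i - 1, j) - gi, E(i - 1, j) - gap_extend);
      F(i, j) = std::max(H(i, j - 1) - gi, F(i, j - 1) - gap_extend);
      double h = H(i - 1, j - 1) + S(i - 1, j - 1);
      h = std::max(std::max(h, E(i, j)), std::max(F(i, j), 0.0));
      H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::vector<int> qcol, scol;
  if (best > 0.0) {
    int i = bi, j = bj, state = 0;
    while (i > 0 && j > 0) {
      if (state == 0) {
        double h = H(i, j);
        if (h == 0.0) break;
        double d = H(i - 1, j - 1) + S(i - 1, j - 1);
        if (h == d) { qcol.push_back(i); scol.push_back(j); --i; --j; }
        else if (h == E(i, j)) state = 1;
        else state = 2;
      } else if (state == 1) {
        qcol.push_back(i); scol.push_back(NA_INTEGER);
        if (E(i, j) == H(i - 1, j) - gi) { --i; state = 0; } else { --i; }
      } else {
        qcol.push_back(NA_INTEGER); scol.push_back(j);
        if (F(i, j) == H(i, j - 1) - gi) { --j; state = 0; } else { --j; }
      }
    }
    std::reverse(qcol.begin(), qcol.end());
    std::reverse(scol.begin(), scol.end());
  }
  return List::create(_["score"] = best,
                      _["q_map"] = wrap(qcol),
                      _["s_map"] = wrap(scol));
}
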