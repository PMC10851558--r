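// Global (Needleman-Wunsch) alignment with affine gaps (Gotoh algorithm).
// Scores maximize; a gap of length L costs open + L * extend (the BLAST
// convention for open=11, extend=1). Traceback is deterministic with the
// tie-break preference match/mismatch > gap-in-b > gap-in-a.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

static const double NEG = -std::numeric_limits<double>::infinity();

// Build a 256-entry lookup from residue char to matrix row index.
// Unknown residues fall back to 'X' when present, else -1 (score 0).
static std::vector<int> char_index(const CharacterVector &letters) {
  std::vector<int> idx(256, -2);
  for (int i = 0; i < letters.size(); ++i) {
    std::string s = as<std::string>(letters[i]);
    if (s.size() == 1) idx[(unsigned char)s[0]] = i;
  }
  int xi = idx[(unsigned char)'X'];
  for (int c = 0; c < 256; ++c) if (idx[c] == -2) idx[c] = (xi >= -1 ? xi : -1);
  return idx;
}

// Flatten the substitution matrix for fast unchecked lookup; an extra
// final row/column of zeros serves residues missing from the matrix.
static std::vector<double> flatten(const NumericMatrix &sub, int &nL) {
  nL = sub.nrow();
  std::vector<double> flat((nL + 1) * (nL + 1), 0.0);
  for (int i = 0; i < nL; ++i)
    for (int j = 0; j < nL; ++j) flat[i * (nL + 1) + j] = sub(i, j);
  return flat;
}

// Score-only Gotoh with two rolling rows.
static double gotoh_score(const std::string &a, const std::string &b,
                          const double *flat, int nL,
                          const std::vector<int> &idx,
                          double open, double ext) {
  int n = a.size(), m = b.size();
  std::vector<double> M0(m + 1), X0(m + 1), Y0(m + 1);
  std::vector<double> M1(m + 1), X1(m + 1), Y1(m + 1);
  M0[0] = 0; X0[0] = NEG; Y0[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    M0[j] = NEG; X0[j] = NEG; Y0[j] = -(open + j * ext);
  }
  std::vector<int> ai(n);
  for (int i = 0; i < n; ++i) {
    int k = idx[(unsigned char)a[i]];
    ai[i] = (k < 0 ? nL : k);
  }
  std::vector<int> bi(m);
  for (int j = 0; j < m; ++j) {
    int k = idx[(unsigned char)b[j]];
    bi[j] = (k < 0 ? nL : k);
  }
  for (int i = 1; i <= n; ++i) {
    M1[0] = NEG; Y1[0] = NEG;
    X1[0] = -(open + i * ext);
    const double *srow = flat + (size_t)ai[i - 1] * (nL + 1);
    for (int j = 1; j <= m; ++j) {
      double diag = std::max(M0[j - 1], std::max(X0[j - 1], Y0[j - 1]));
      M1[j] = diag + srow[bi[j - 1]];
      double fromM = std::max(M0[j], Y0[j]) - (open + ext);
      X1[j] = std::max(fromM, X0[j] - ext);
      double fromM2 = std::max(M1[j - 1], X1[j - 1]) - (open + ext);
      Y1[j] = std::max(fromM2, Y1[j - 1] - ext);
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }
  return std::max(M0[m], std::max(X0[m], Y0[m]));
}

// [[Rcpp::export]]
double nw_score_cpp(std::string a, std::string b, NumericMatrix sub,
                    double open, double ext) {
  CharacterVector letters = rownames(sub);
  std::vector<int> idx = char_index(letters);
  int nL;
  std::vector<double> flat = flatten(sub, nL);
  return gotoh_score(a, b, flat.data(), nL, idx, open, ext);
}

// All-vs-all score matrix (queries x refs); global NW score is symmetric
// in its arguments so callers can reuse one matrix for both directions.
// [[Rcpp::export]]
NumericMatrix nw_score_matrix_cpp(CharacterVector queries,
                                  CharacterVector refs,
                                  NumericMatrix sub,
                                  double open, double ext) {
  CharacterVector letters = rownames(sub);
  std::vector<int> idx = char_index(letters);
  int nL;
  std::vector<double> flat = flatten(sub, nL);
  int nq = queries.size(), nr = refs.size();
  std::vector<std::string> qs(nq), rs(nr);
  for (int i = 0; i < nq; ++i) qs[i] = as<std::string>(queries[i]);
  for (int j = 0; j < nr; ++j) rs[j] = as<std::string>(refs[j]);
  NumericMatrix out(nq, nr);
  for (int i = 0; i < nq; ++i) {
    Rcpp::checkUserInterrupt();
    for (int j = 0; j < nr; ++j)
      out(i, j) = gotoh_score(qs[i], rs[j], flat.data(), nL, idx, open, ext);
  }
  return out;
}

// Full alignment with deterministic traceback.
// States: 0 = M (match/mismatch), 1 = X (gap in b, consumes a),
//         2 = Y (gap in a, consumes b). Tie preference 0 > 1 > 2.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, NumericMatrix sub,
                  double open, double ext) {
  CharacterVector letters = rownames(sub);
  std::vector<int> idx = char_index(letters);
  int nL;
  std::vector<double> flat = flatten(sub, nL);
  int n = a.size(), m = b.size();
  std::vector<std::vector<double> > M(n + 1, std::vector<double>(m + 1, NEG)),
      X(n + 1, std::vector<double>(m + 1, NEG)),
      Y(n + 1, std::vector<double>(m + 1, NEG));
  // pointer matrices: previous state feeding each state
  std::vector<std::vector<signed char> >
      PM(n + 1, std::vector<signed char>(m + 1, -1)),
      PX(n + 1, std::vector<signed char>(m + 1, -1)),
      PY(n + 1, std::vector<signed char>(m + 1, -1));
  M[0][0] = 0;
  for (int i = 1; i <= n; ++i) { X[i][0] = -(open + i * ext); PX[i][0] = (i == 1 ? 0 : 1); }
  for (int j = 1; j <= m; ++j) { Y[0][j] = -(open + j * ext); PY[0][j] = (j == 1 ? 0 : 2); }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int ia = idx[(unsigned char)a[i - 1]];
      int ib = idx[(unsigned char)b[j - 1]];
      double s = flat[(size_t)(ia < 0 ? nL : ia) * (nL + 1) +
                      (ib < 0 ? nL : ib)];
      // M: from best of M/X/Y at (i-1, j-1); tie preference M > X > Y
      double cand[3] = {M[i - 1][j - 1], X[i - 1][j - 1], Y[i - 1][j - 1]};
      int best = 0;
      for (int k = 1; k < 3; ++k) if (cand[k] > cand[best]) best = k;
      if (cand[best] > NEG) { M[i][j] = cand[best] + s; PM[i][j] = best; }
      // X (gap in b): open from M/Y, extend from X
      double xo = std::max(M[i - 1][j], Y[i - 1][j]) - (open + ext);
      double xe = X[i - 1][j] - ext;
      if (xo >= xe) { X[i][j] = xo; PX[i][j] = (M[i - 1][j] >= Y[i - 1][j]) ? 0 : 2; }
      else          { X[i][j] = xe; PX[i][j] = 1; }
      // Y (gap in a): open from M/X, extend from Y
      double yo = std::max(M[i][j - 1], X[i][j - 1]) - (open + ext);
      double ye = Y[i][j - 1] - ext;
      if (yo >= ye) { Y[i][j] = yo; PY[i][j] = (M[i][j - 1] >= X[i][j - 1]) ? 0 : 1; }
      else          { Y[i][j] = ye; PY[i][j] = 2; }
    }
  }
  double fin[3] = {M[n][m], X[n][m], Y[n][m]};
  int state = 0;
  for (int k = 1; k < 3; ++k) if (fin[k] > fin[state]) state = k;
  double score = fin[state];
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int prev;
    if (state == 0) {
      prev = PM[i][j];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
    } else if (state == 1) {
      prev = PX[i][j];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i;
    } else {
      prev = PY[i][j];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j;
    }
    state = prev;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a_aln"] = ra, _["b_aln"] = rb, _["score"] = score);
}
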