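#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine gap convention throughout: a gap of length k costs gap_open + k * gap_extend
// (BLAST-style; the first gapped column already pays open + extend).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

// Gotoh alignment with full traceback.
// a, b: 0-based residue indices into the substitution matrix.
// Returns aligned index vectors with -1 marking a gap column.
// local = true: Smith-Waterman (empty alignment with score 0 when nothing positive).
// [[Rcpp::export]]
List cpp_pair_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
                    double gap_open, double gap_extend, bool local) {
  const int n = a.size(), m = b.size();
  const double go = gap_open + gap_extend, ge = gap_extend;

  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF); // gap in b (consumes a)
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF); // gap in a (consumes b)
  // traceback: predecessor state 0=M 1=X 2=Y 3=start
  std::vector<signed char> tM((n + 1) * (m + 1), 3);
  std::vector<signed char> tX((n + 1) * (m + 1), 3);
  std::vector<signed char> tY((n + 1) * (m + 1), 3);
  const int W = m + 1;

  M[0] = 0.0;
  if (!local) {
    for (int i = 1; i <= n; ++i) { X[i * W] = -(gap_open + i * ge); tX[i * W] = 1; }
    X[1 * W] = -go; tX[1 * W] = 0;
    for (int j = 1; j <= m; ++j) { Y[j] = -(gap_open + j * ge); tY[j] = 2; }
    Y[1] = -go; tY[1] = 0;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = i * W + j;
      const double s = sub(a[i - 1], b[j - 1]);
      // M
      double dM = M[(i - 1) * W + (j - 1)], dX = X[(i - 1) * W + (j - 1)],
             dY = Y[(i - 1) * W + (j - 1)];
      double best = dM; signed char tb = 0;
      if (dX > best) { best = dX; tb = 1; }
      if (dY > best) { best = dY; tb = 2; }
      if (local && best < 0) { best = 0; tb = 3; }
      if (best == NEG_INF) { M[ij] = NEG_INF; } else { M[ij] = s + best; tM[ij] = tb; }
      // X: consume a[i-1], gap in b
      double xM = M[(i - 1) * W + j] - go, xX = X[(i - 1) * W + j] - ge,
             xY = Y[(i - 1) * W + j] - go;
      best = xM; tb = 0;
      if (xX > best) { best = xX; tb = 1; }
      if (xY > best) { best = xY; tb = 2; }
      if (best > NEG_INF) { X[ij] = best; tX[ij] = tb; }
      // Y: consume b[j-1], gap in a
      double yM = M[i * W + (j - 1)] - go, yY = Y[i * W + (j - 1)] - ge,
             yX = X[i * W + (j - 1)] - go;
      best = yM; tb = 0;
      if (yY > best) { best = yY; tb = 2; }
      if (yX > best) { best = yX; tb = 1; }
      if (best > NEG_INF) { Y[ij] = best; tY[ij] = tb; }
    }
  }

  double score; int ei, ej; int state;
  if (local) {
    score = 0.0; ei = 0; ej = 0; state = 0;
    for (int i = 1; i <= n; ++i)
      for (int j = 1; j <= m; ++j)
        if (M[i * W + j] > score) { score = M[i * W + j]; ei = i; ej = j; }
    if (score <= 0.0) {
      return List::create(_["score"] = 0.0,
                          _["a_aln"] = IntegerVector(0), _["b_aln"] = IntegerVector(0),
                          _["a_start"] = 0, _["a_end"] = 0,
                          _["b_start"] = 0, _["b_end"] = 0);
    }
  } else {
    ei = n; ej = m;
    const int ij = n * W + m;
    score = M[ij]; state = 0;
    if (X[ij] > score) { score = X[ij]; state = 1; }
    if (Y[ij] > score) { score = Y[ij]; state = 2; }
  }
  if (local) state = 0;

  std::vector<int> ra, rb;
  int i = ei, j = ej;
  while (i > 0 || j > 0) {
    if (local && state == 0 && (i == 0 || j == 0)) break;
    if (!local && i == 0) { ra.push_back(-1); rb.push_back(b[j - 1]); --j; continue; }
    if (!local && j == 0) { ra.push_back(a[i - 1]); rb.push_back(-1); --i; continue; }
    const int ij = i * W + j;
    if (state == 0) {
      signed char tb = tM[ij];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
      if (local && tb == 3) break;
      state = tb;
    } else if (state == 1) {
      signed char tb = tX[ij];
      ra.push_back(a[i - 1]); rb.push_back(-1); --i;
      state = tb;
    } else {
      signed char tb = tY[ij];
      ra.push_back(-1); rb.push_back(b[j - 1]); --j;
      state = tb;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score,
                      _["a_aln"] = wrap(ra), _["b_aln"] = wrap(rb),
                      _["a_start"] = i + 1, _["a_end"] = ei,
                      _["b_start"] = j + 1, _["b_end"] = ej);
}

// Score-only batch alignment (rolling rows); used for searches and decoy calibration.
// [[Rcpp::export]]
NumericVector cpp_score_batch(IntegerVector a, List targets, NumericMatrix sub,
                              double gap_open, double gap_extend, bool local) {
  const int n = a.size();
  const double go = gap_open + gap_extend, ge = gap_extend;
  const int nt = targets.size();
  NumericVector out(nt);
  for (int t = 0; t < nt; ++t) {
    IntegerVector b = targets[t];
    const int m = b.size();
    std::vector<double> M0(m + 1, NEG_INF), X0(m + 1, NEG_INF), Y0(m + 1, NEG_INF);
    std::vector<double> M1(m + 1, NEG_INF), X1(m + 1, NEG_INF), Y1(m + 1, NEG_INF);
    M0[0] = 0.0;
    if (!local) for (int j = 1; j <= m; ++j) Y0[j] = -(gap_open + j * ge);
    double best_local = 0.0;
    for (int i = 1; i <= n; ++i) {
      M1[0] = NEG_INF; Y1[0] = NEG_INF;
      X1[0] = local ? NEG_INF : -(gap_open + i * ge);
      for (int j = 1; j <= m; ++j) {
        const double s = sub(a[i - 1], b[j - 1]);
        double d = max3(M0[j - 1], X0[j - 1], Y0[j - 1]);
        if (local && d < 0) d = 0;
        M1[j] = (d == NEG_INF) ? NEG_INF : s + d;
        X1[j] = max3(M0[j] - go, X0[j] - ge, Y0[j] - go);
        Y1[j] = max3(M1[j - 1] - go, Y1[j - 1] - ge, X1[j - 1] - go);
        if (local && M1[j] > best_local) best_local = M1[j];
      }
      std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
    }
    out[t] = local ? best_local : max3(M0[m], X0[m], Y0[m]);
  }
  return out;
}

// Glocal profile scoring: the whole profile must be consumed (deletions are
// penalised); the target sequence has free flanks; internal insertions are
// penalised. emis: (n match columns) x (alphabet) log-odds matrix.
// [[Rcpp::export]]
double cpp_profile_score(NumericMatrix emis, IntegerVector seq,
                         double ins_open, double ins_extend,
                         double del_open, double del_extend) {
  const int L = emis.nrow(), m = seq.size();
  const double io = ins_open + ins_extend, ie = ins_extend;
  const double dopen = del_open + del_extend, de = del_extend;
  std::vector<double> pM(m + 1, 0.0), pI(m + 1, NEG_INF), pD(m + 1, NEG_INF);
  std::vector<double> cM(m + 1), cI(m + 1), cD(m + 1);
  // row 0 = free start: pM[j] = 0 for every j
  for (int i = 1; i <= L; ++i) {
    cM[0] = NEG_INF;
    cI[0] = NEG_INF;
    cD[0] = max3(pM[0] - dopen, pD[0] - de, pI[0] - dopen);
    for (int j = 1; j <= m; ++j) {
      const double e = emis(i - 1, seq[j - 1]);
      const double d = max3(pM[j - 1], pI[j - 1], pD[j - 1]);
      cM[j] = (d == NEG_INF) ? NEG_INF : e + d;
      cI[j] = std::max(cM[j - 1] - io, cI[j - 1] - ie);
      cD[j] = max3(pM[j] - dopen, pD[j] - de, pI[j] - dopen);
    }
    std::swap(pM, cM); std::swap(pI, cI); std::swap(pD, cD);
  }
  double best = NEG_INF;
  for (int j = 0; j <= m; ++j) {
    if (pM[j] > best) best = pM[j];
    if (pD[j] > best) best = pD[j];
  }
  return best;
}

// [[Rcpp::export]]
NumericVector cpp_profile_score_batch(NumericMatrix emis, List seqs,
                                      double ins_open, double ins_extend,
                                      double del_open, double del_extend) {
  const int nt = seqs.size();
  NumericVector out(nt);
  for (int t = 0; t < nt; ++t)
    out[t] = cpp_profile_score(emis, seqs[t], ins_open, ins_extend,
                               del_open, del_extend);
  return out;
}
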