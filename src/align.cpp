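#include <Rcpp.h>
using namespace Rcpp;

// Affine gap convention throughout: a gap of length k costs open + k * ext
// (BLAST convention). Sequences arrive as 1-based integer codes into the
// substitution matrix; 0 is never a residue.

static inline double submat_at(const NumericMatrix& sub, int a, int b) {
  return sub(a - 1, b - 1);
}

// [[Rcpp::export]]
List cpp_sw_affine(IntegerVector a, IntegerVector b, NumericMatrix sub,
                   double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  // Each cell carries its score and the local-alignment start it extends.
  std::vector<double> M(m + 1, 0.0), E(m + 1, R_NegInf);
  std::vector<int> Msi(m + 1, 0), Msj(m + 1, 0), Esi(m + 1, 0), Esj(m + 1, 0);
  double best = 0.0; int bi = 0, bj = 0, bsi = 0, bsj = 0;
  std::vector<double> Mprev(m + 1, 0.0);
  std::vector<int> Mprev_si(m + 1, 0), Mprev_sj(m + 1, 0);
  // F (gap in b, vertical) kept per column while sweeping rows
  std::vector<double> F(m + 1, R_NegInf);
  std::vector<int> Fsi(m + 1, 0), Fsj(m + 1, 0);

  for (int i = 1; i <= n; ++i) {
    std::swap(M, Mprev); std::swap(Msi, Mprev_si); std::swap(Msj, Mprev_sj);
    M[0] = 0.0; Msi[0] = i; Msj[0] = 0;
    double Erow = R_NegInf; int Erow_si = 0, Erow_sj = 0;
    for (int j = 1; j <= m; ++j) {
      // E: gap in a (horizontal)
      double e_open = M[j - 1] - gap_open - gap_ext;
      double e_ext = Erow - gap_ext;
      if (e_open >= e_ext) { Erow = e_open; Erow_si = Msi[j - 1]; Erow_sj = Msj[j - 1]; }
      else Erow = e_ext;
      // F: gap in b (vertical)
      double f_open = Mprev[j] - gap_open - gap_ext;
      double f_ext = F[j] - gap_ext;
      if (f_open >= f_ext) { F[j] = f_open; Fsi[j] = Mprev_si[j]; Fsj[j] = Mprev_sj[j]; }
      else F[j] = f_ext;
      double diag = Mprev[j - 1] + submat_at(sub, a[i - 1], b[j - 1]);
      int dsi = Mprev_si[j - 1], dsj = Mprev_sj[j - 1];
      if (Mprev[j - 1] == 0.0 && dsi == 0 && dsj == 0) { dsi = i - 1; dsj = j - 1; }
      double sc = diag; int si = dsi, sj = dsj;
      if (Erow > sc) { sc = Erow; si = Erow_si; sj = Erow_sj; }
      if (F[j] > sc) { sc = F[j]; si = Fsi[j]; sj = Fsj[j]; }
      if (sc <= 0.0) { sc = 0.0; si = 0; sj = 0; }
      M[j] = sc; Msi[j] = si; Msj[j] = sj;
      if (sc > best) { best = sc; bi = i; bj = j; bsi = si; bsj = sj; }
    }
  }
  // 0-based half-open coordinates of matched segments
  return List::create(_["score"] = best,
                      _["a_start"] = best > 0 ? bsi : 0,
                      _["a_end"] = best > 0 ? bi : 0,
                      _["b_start"] = best > 0 ? bsj : 0,
                      _["b_end"] = best > 0 ? bj : 0);
}

// [[Rcpp::export]]
List cpp_nw_global(IntegerVector a, IntegerVector b, NumericMatrix sub,
                   double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  NumericMatrix M(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  // trace: 0 diag, 1 from E (gap in a), 2 from F (gap in b); per matrix
  IntegerMatrix tM(n + 1, m + 1), tE(n + 1, m + 1), tF(n + 1, m + 1);
  M(0, 0) = 0; E(0, 0) = NEG; F(0, 0) = NEG;
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; F(0, j) = NEG;
    E(0, j) = -gap_open - gap_ext * j;
    tE(0, j) = 1;
  }
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; E(i, 0) = NEG;
    F(i, 0) = -gap_open - gap_ext * i;
    tF(i, 0) = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double eM = M(i, j - 1) - gap_open - gap_ext, eE = E(i, j - 1) - gap_ext;
      if (eM >= eE) { E(i, j) = eM; tE(i, j) = 0; } else { E(i, j) = eE; tE(i, j) = 1; }
      double fM = M(i - 1, j) - gap_open - gap_ext, fF = F(i - 1, j) - gap_ext;
      if (fM >= fF) { F(i, j) = fM; tF(i, j) = 0; } else { F(i, j) = fF; tF(i, j) = 2; }
      double s = submat_at(sub, a[i - 1], b[j - 1]);
      double dM = M(i - 1, j - 1), dE = E(i - 1, j - 1), dF = F(i - 1, j - 1);
      double dbest = dM; int dt = 0;
      if (dE > dbest) { dbest = dE; dt = 1; }
      if (dF > dbest) { dbest = dF; dt = 2; }
      M(i, j) = dbest + s; tM(i, j) = dt;
    }
  }
  double sM = M(n, m), sE = E(n, m), sF = F(n, m);
  double score = sM; int state = 0;
  if (sE > score) { score = sE; state = 1; }
  if (sF > score) { score = sF; state = 2; }
  std::vector<int> aa, bb; // 1-based residue indices, 0 = gap
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tM(i, j);
      aa.push_back(i); bb.push_back(j);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tE(i, j);
      aa.push_back(0); bb.push_back(j);
      --j; state = prev;
    } else {
      int prev = tF(i, j);
      aa.push_back(i); bb.push_back(0);
      --i; state = prev;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["score"] = score,
                      _["a_aln"] = IntegerVector(aa.begin(), aa.end()),
                      _["b_aln"] = IntegerVector(bb.begin(), bb.end()));
}

// Local profile-to-sequence alignment. pssm is L x K (column scores per
// residue code). Returns the best local score, matched column / sequence
// spans (0-based half-open), and an "anchored" vector of length L: for each
// profile column, the 1-based sequence position aligned to it, 0 if the
// column is outside the alignment or deleted; insertions in the sequence
// relative to the profile are skipped.
// [[Rcpp::export]]
List cpp_profile_local(NumericMatrix pssm, IntegerVector b,
                       double gap_open, double gap_ext) {
  const int L = pssm.nrow(), m = b.size();
  const double NEG = -1e30;
  NumericMatrix M(L + 1, m + 1), E(L + 1, m + 1), F(L + 1, m + 1);
  IntegerMatrix tM(L + 1, m + 1), tE(L + 1, m + 1), tF(L + 1, m + 1);
  for (int j = 0; j <= m; ++j) { M(0, j) = 0; E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= L; ++i) { M(i, 0) = 0; E(i, 0) = NEG; F(i, 0) = NEG; }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= m; ++j) {
      // E: insertion in sequence (consumes seq, not profile)
      double eM = M(i, j - 1) - gap_open - gap_ext, eE = E(i, j - 1) - gap_ext;
      if (eM >= eE) { E(i, j) = eM; tE(i, j) = 0; } else { E(i, j) = eE; tE(i, j) = 1; }
      // F: deletion (consumes profile column, not seq)
      double fM = M(i - 1, j) - gap_open - gap_ext, fF = F(i - 1, j) - gap_ext;
      if (fM >= fF) { F(i, j) = fM; tF(i, j) = 0; } else { F(i, j) = fF; tF(i, j) = 2; }
      double s = pssm(i - 1, b[j - 1] - 1);
      double dM = M(i - 1, j - 1), dE = E(i - 1, j - 1), dF = F(i - 1, j - 1);
      double dbest = dM; int dt = 0;
      if (dE > dbest) { dbest = dE; dt = 1; }
      if (dF > dbest) { dbest = dF; dt = 2; }
      double sc = dbest + s;
      int t = dt + 3; // 3,4,5: diag from M/E/F
      if (sc < 0.0) { sc = 0.0; t = -1; } // local restart
      M(i, j) = sc; tM(i, j) = t;
      if (sc > best) { best = sc; bi = i; bj = j; }
    }
  }
  IntegerVector anchored(L, 0);
  int ci = bi, cj = bj, col_start = bi, b_start = bj;
  if (best > 0) {
    int state = 0; // best always ends in M
    while (true) {
      if (state == 0) {
        int t = tM(ci, cj);
        if (t == -1) break; // shouldn't happen at a positive cell start
        anchored[ci - 1] = cj;
        col_start = ci - 1; b_start = cj - 1;
        --ci; --cj;
        if (t == 3) state = 0; else if (t == 4) state = 1; else state = 2;
        if (state == 0 && (ci == 0 || cj == 0 || M(ci, cj) == 0.0)) break;
      } else if (state == 1) {
        int t = tE(ci, cj);
        --cj; // insertion: sequence position skipped
        state = (t == 0) ? 0 : 1;
        if (state == 0 && M(ci, cj) == 0.0) break;
      } else {
        int t = tF(ci, cj);
        // deletion: profile column ci unmatched (stays 0)
        --ci;
        state = (t == 0) ? 0 : 2;
        if (state == 0 && M(ci, cj) == 0.0) break;
      }
    }
  }
  return List::create(_["score"] = best,
                      _["col_start"] = best > 0 ? col_start : 0,
                      _["col_end"] = best > 0 ? bi : 0,
                      _["b_start"] = best > 0 ? b_start : 0,
                      _["b_end"] = best > 0 ? bj : 0,
                      _["anchored"] = anchored);
}
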