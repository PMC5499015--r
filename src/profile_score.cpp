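#include <Rcpp.h>
using namespace Rcpp;

// Best local-alignment log-odds score of a residue-index sequence against a
// position-specific profile (Gotoh affine-gap DP). Rows of `logodds` are
// match columns, columns are the 20 residues in canonical order. `seq` holds
// 0-based residue indices. Insert states emit at background (log-odds 0);
// adjacent insert/delete transitions are disallowed. The empty alignment
// scores 0, so the result is always >= 0.
// [[Rcpp::export]]
double cpp_score_profile(const NumericMatrix& logodds,
                         const IntegerVector& seq,
                         double gap_open, double gap_extend) {
  const int M = logodds.nrow();
  const int L = seq.size();
  if (M == 0 || L == 0) return 0.0;
  const double NEG = -1e30;
  std::vector<double> Mprev(M + 1, NEG), Mcur(M + 1, NEG);
  std::vector<double> Xprev(M + 1, NEG), Xcur(M + 1, NEG);
  std::vector<double> Yprev(M + 1, NEG), Ycur(M + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= L; ++i) {
    Mcur[0] = NEG; Xcur[0] = NEG; Ycur[0] = NEG;
    const int a = seq[i - 1];
    for (int j = 1; j <= M; ++j) {
      // match: start fresh (0) or extend M/X/Y from (i-1, j-1)
      double prev = 0.0;
      if (Mprev[j - 1] > prev) prev = Mprev[j - 1];
      if (Xprev[j - 1] > prev) prev = Xprev[j - 1];
      if (Yprev[j - 1] > prev) prev = Yprev[j - 1];
      Mcur[j] = prev + logodds(j - 1, a);
      // X: gap in profile (sequence residue unaligned)
      double x = Mprev[j] - gap_open;
      double xe = Xprev[j] - gap_extend;
      Xcur[j] = (x > xe) ? x : xe;
      // Y: gap in sequence (profile column skipped)
      double y = Mcur[j - 1] - gap_open;
      double ye = Ycur[j - 1] - gap_extend;
      Ycur[j] = (y > ye) ? y : ye;
      if (Mcur[j] > best) best = Mcur[j];
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }
  return best;
}

// Score many sequences (list of 0-based residue-index vectors) against one
// profile; used for proteome scans and E-value calibration.
// [[Rcpp::export]]
NumericVector cpp_score_profile_many(const NumericMatrix& logodds,
                                     const List& seqs,
                                     double gap_open, double gap_extend) {
  const int n = seqs.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    IntegerVector s = seqs[k];
    out[k] = cpp_score_profile(logodds, s, gap_open, gap_extend);
  }
  return out;
}
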