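#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps.
// Gap of length k costs gap_open + k * gap_ext (BLAST convention).
// Sequences are 0-based integer codes into `submat`; codes < 0 score 0
// against everything (unknown residues).

static inline double subscore(const NumericMatrix& m, int a, int b) {
  if (a < 0 || b < 0) return 0.0;
  return m(a, b);
}

// [[Rcpp::export(name = ".sw_pair_score")]]
double sw_pair_score(IntegerVector a, IntegerVector b, NumericMatrix submat,
                     double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  std::vector<double> H(m + 1, 0.0), E(m + 1, R_NegInf);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diag = 0.0;       // H[i-1][j-1]
    double F = R_NegInf;     // gap in b (vertical run within row i)
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(E[j] - gap_ext, H[j] - gap_open - gap_ext);
      F = std::max(F - gap_ext, H[j - 1] - gap_open - gap_ext);
      double h = diag + subscore(submat, a[i - 1], b[j - 1]);
      h = std::max(h, std::max(E[j], F));
      if (h < 0.0) h = 0.0;
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Full DP with three-state traceback. Returns score, endpoints (1-based),
// alignment length, identities, and gap counts.
// [[Rcpp::export(name = ".sw_pair_align")]]
List sw_pair_align(IntegerVector a, IntegerVector b, NumericMatrix submat,
                   double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  // TBH: 0 stop, 1 diag, 2 from E, 3 from F; TBE/TBF: 1 extend, 0 open
  IntegerMatrix TBH(n + 1, m + 1), TBE(n + 1, m + 1), TBF(n + 1, m + 1);
  std::fill(E.begin(), E.end(), R_NegInf);
  std::fill(F.begin(), F.end(), R_NegInf);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e_ext = E(i - 1, j) - gap_ext;
      double e_opn = H(i - 1, j) - gap_open - gap_ext;
      if (e_ext > e_opn) { E(i, j) = e_ext; TBE(i, j) = 1; }
      else               { E(i, j) = e_opn; TBE(i, j) = 0; }
      double f_ext = F(i, j - 1) - gap_ext;
      double f_opn = H(i, j - 1) - gap_open - gap_ext;
      if (f_ext > f_opn) { F(i, j) = f_ext; TBF(i, j) = 1; }
      else               { F(i, j) = f_opn; TBF(i, j) = 0; }
      double h = H(i - 1, j - 1) + subscore(submat, a[i - 1], b[j - 1]);
      int tb = 1;
      if (E(i, j) > h) { h = E(i, j); tb = 2; }
      if (F(i, j) > h) { h = F(i, j); tb = 3; }
      if (h <= 0.0) { h = 0.0; tb = 0; }
      H(i, j) = h; TBH(i, j) = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int i = bi, j = bj, aln = 0, ident = 0, gaps = 0;
  int a_end = bi, b_end = bj, a_start = bi + 1, b_start = bj + 1;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    if (state == 0) {
      int tb = TBH(i, j);
      if (tb == 0 || H(i, j) <= 0.0) break;
      if (tb == 1) {
        ++aln;
        if (a[i - 1] >= 0 && a[i - 1] == b[j - 1]) ++ident;
        a_start = i; b_start = j; --i; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {  // E: gap in b, consumes a[i]
      ++aln; ++gaps; a_start = i;
      int ext = TBE(i, j); --i;
      if (!ext) state = 0;
    } else {                  // F: gap in a, consumes b[j]
      ++aln; ++gaps; b_start = j;
      int ext = TBF(i, j); --j;
      if (!ext) state = 0;
    }
  }
  return List::create(_["score"] = best, _["aln_len"] = aln,
                      _["n_ident"] = ident, _["n_gap"] = gaps,
                      _["a_start"] = a_start, _["a_end"] = a_end,
                      _["b_start"] = b_start, _["b_end"] = b_end);
}

// Local alignment of a PSSM (rows = profile columns, cols = alphabet) against
// an integer-coded sequence; unknown residues (< 0) score 0.
// [[Rcpp::export(name = ".sw_profile_score")]]
double sw_profile_score(NumericMatrix pssm, IntegerVector seq,
                        double gap_open, double gap_ext) {
  const int n = pssm.nrow(), m = seq.size();
  const double go = gap_open + gap_ext, ge = gap_ext;
  std::vector<double> H(m + 1, 0.0), E(m + 1, R_NegInf);
  std::vector<double> row(20);
  const int *sq = INTEGER(seq);
  double *h = H.data(), *e = E.data();
  const double *pm = REAL(pssm);
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 20; ++c) row[c] = pm[i + c * n];
    double diag = 0.0, F = R_NegInf;
    for (int j = 1; j <= m; ++j) {
      double ej = e[j] - ge, eo = h[j] - go;
      ej = ej > eo ? ej : eo;
      e[j] = ej;
      double fo = h[j - 1] - go;
      F -= ge; if (fo > F) F = fo;
      int c = sq[j - 1];
      double hh = diag + (c < 0 ? 0.0 : row[c]);
      if (ej > hh) hh = ej;
      if (F > hh) hh = F;
      if (hh < 0.0) hh = 0.0;
      diag = h[j];
      h[j] = hh;
      if (hh > best) best = hh;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_profile_align")]]
List sw_profile_align(NumericMatrix pssm, IntegerVector seq,
                      double gap_open, double gap_ext) {
  const int n = pssm.nrow(), m = seq.size();
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix TBH(n + 1, m + 1), TBE(n + 1, m + 1), TBF(n + 1, m + 1);
  std::fill(E.begin(), E.end(), R_NegInf);
  std::fill(F.begin(), F.end(), R_NegInf);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e_ext = E(i - 1, j) - gap_ext;
      double e_opn = H(i - 1, j) - gap_open - gap_ext;
      if (e_ext > e_opn) { E(i, j) = e_ext; TBE(i, j) = 1; }
      else               { E(i, j) = e_opn; TBE(i, j) = 0; }
      double f_ext = F(i, j - 1) - gap_ext;
      double f_opn = H(i, j - 1) - gap_open - gap_ext;
      if (f_ext > f_opn) { F(i, j) = f_ext; TBF(i, j) = 1; }
      else               { F(i, j) = f_opn; TBF(i, j) = 0; }
      int c = seq[j - 1];
      double s = (c < 0) ? 0.0 : pssm(i - 1, c);
      double h = H(i - 1, j - 1) + s; int tb = 1;
      if (E(i, j) > h) { h = E(i, j); tb = 2; }
      if (F(i, j) > h) { h = F(i, j); tb = 3; }
      if (h <= 0.0) { h = 0.0; tb = 0; }
      H(i, j) = h; TBH(i, j) = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int i = bi, j = bj, state = 0;
  int p_end = bi, s_end = bj, p_start = bi + 1, s_start = bj + 1;
  while (i > 0 && j > 0) {
    if (state == 0) {
      int tb = TBH(i, j);
      if (tb == 0 || H(i, j) <= 0.0) break;
      if (tb == 1) { p_start = i; s_start = j; --i; --j; }
      else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      p_start = i; int ext = TBE(i, j); --i;
      if (!ext) state = 0;
    } else {
      s_start = j; int ext = TBF(i, j); --j;
      if (!ext) state = 0;
    }
  }
  return List::create(_["score"] = best,
                      _["prof_start"] = p_start, _["prof_end"] = p_end,
                      _["seq_start"] = s_start, _["seq_end"] = s_end);
}

// Scores of a PSSM against many integer-coded sequences (list of
// IntegerVectors); used for decoy null distributions.
// [[Rcpp::export(name = ".sw_profile_score_many")]]
NumericVector sw_profile_score_many(NumericMatrix pssm, List seqs,
                                    double gap_open, double gap_ext) {
  const int k = seqs.size();
  NumericVector out(k);
  for (int s = 0; s < k; ++s) {
    IntegerVector sq = seqs[s];
    out[s] = sw_profile_score(pssm, sq, gap_open, gap_ext);
  }
  return out;
}
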