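#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). Sequences arrive integer-encoded
// (0-based indices into the substitution matrix). Gap of length k costs
// gap_open + k * gap_extend. Alignment start positions are propagated
// through the DP so that score ties resolve toward the lexicographically
// smallest (start_a, start_b); among equal starts, the smallest end wins.
//
// Returns: score, start_a, end_a, start_b, end_b (0-based half-open).
// [[Rcpp::export(name = ".sw_align_cpp")]]
NumericVector sw_align_cpp(IntegerVector a, IntegerVector b,
                           NumericMatrix sub, double gap_open,
                           double gap_extend) {
  const int m = a.size(), n = b.size();
  const double NEG = -1e30;
  // per-column state for H, E (gap in a), F (gap in b) and their origins
  std::vector<double> H(n + 1, 0.0), E(n + 1, NEG), F(n + 1, NEG);
  std::vector<long long> oH(n + 1), oE(n + 1), oF(n + 1);
  const long long OB = (long long)(n + 2);
  for (int j = 0; j <= n; ++j) { oH[j] = (long long)0 * OB + j; oE[j] = oF[j] = 0; }

  double best = 0.0; long long best_origin = 0; int bi = 0, bj = 0;
  bool have_best = false;

  for (int i = 1; i <= m; ++i) {
    double Hdiag = H[0]; long long oHdiag = oH[0];
    H[0] = 0.0; oH[0] = (long long)i * OB + 0;
    double Fcur = NEG; long long oFcur = 0;
    for (int j = 1; j <= n; ++j) {
      // E: gap in a (consume b[j])
      double e_open = H[j - 1] - gap_open - gap_extend;
      double e_ext  = E[j - 1] - gap_extend;
      double Ecur; long long oEcur;
      if (e_open > e_ext || (e_open == e_ext && oH[j - 1] <= oE[j - 1])) {
        Ecur = e_open; oEcur = oH[j - 1];
      } else { Ecur = e_ext; oEcur = oE[j - 1]; }
      // F: gap in b (consume a[i])
      double f_open = H[j] - gap_open - gap_extend;
      double f_ext  = F[j] - gap_extend;
      if (f_open > f_ext || (f_open == f_ext && oH[j] <= oF[j])) {
        Fcur = f_open; oFcur = oH[j];
      } else { Fcur = f_ext; oFcur = oF[j]; }
      // H: best of restart, diagonal, E, F
      double diag = Hdiag + sub(a[i - 1], b[j - 1]);
      double h = 0.0; long long oh = (long long)i * OB + j; // fresh start here
      if (diag > h || (diag == h && oHdiag < oh)) { h = diag; oh = oHdiag; }
      if (Ecur > h || (Ecur == h && oEcur < oh)) { h = Ecur; oh = oEcur; }
      if (Fcur > h || (Fcur == h && oFcur < oh)) { h = Fcur; oh = oFcur; }
      if (h < 0) { h = 0.0; oh = (long long)i * OB + j; }
      Hdiag = H[j]; oHdiag = oH[j];
      H[j] = h; oH[j] = oh; E[j] = Ecur; oE[j] = oEcur; F[j] = Fcur; oF[j] = oFcur;
      if (h > 0 &&
          (!have_best || h > best ||
           (h == best && (oh < best_origin ||
                          (oh == best_origin && (i < bi || (i == bi && j < bj))))))) {
        best = h; best_origin = oh; bi = i; bj = j; have_best = true;
      }
    }
  }
  NumericVector out(5);
  if (!have_best) { // empty alignment: score 0, empty span at 0
    out[0] = 0; out[1] = 0; out[2] = 0; out[3] = 0; out[4] = 0;
  } else {
    out[0] = best;
    out[1] = (double)(best_origin / OB); out[2] = (double)bi;
    out[3] = (double)(best_origin % OB); out[4] = (double)bj;
  }
  return out;
}

// Global alignment of a query against a fixed-column profile. prof is a
// (nstates x W) matrix: prof(s, j) = score of residue state s placed in
// column j. Columns are never split: a query residue not placed in a
// column is dropped (affine penalty), and a column can be skipped with a
// gap in the query (affine penalty). Traceback prefers match over gaps,
// then residue-drop ("up") over column-gap ("left").
//
// Returns a list: score, placement (length W, 1-based query index or 0
// for a gapped column), dropped (count of unplaced query residues).
// [[Rcpp::export(name = ".profile_align_cpp")]]
List profile_align_cpp(IntegerVector q, NumericMatrix prof, double gap_open,
                       double gap_extend) {
  const int m = q.size(), W = prof.ncol();
  const double NEG = -1e30;
  // DP over (i = query residues used, j = columns used); three states.
  NumericMatrix H(m + 1, W + 1), E(m + 1, W + 1), F(m + 1, W + 1);
  IntegerMatrix TH(m + 1, W + 1); // 0 diag, 1 from F(up/drop), 2 from E(left/gap)
  IntegerMatrix TE(m + 1, W + 1), TF(m + 1, W + 1); // 0 opened from H, 1 extended
  H(0, 0) = 0; E(0, 0) = F(0, 0) = NEG;
  for (int j = 1; j <= W; ++j) {
    H(0, j) = NEG; F(0, j) = NEG;
    double open = H(0, j - 1) - gap_open - gap_extend;
    double ext = E(0, j - 1) - gap_extend;
    if (j == 1 || open >= ext) { E(0, j) = open; TE(0, j) = 0; }
    else { E(0, j) = ext; TE(0, j) = 1; }
  }
  for (int i = 1; i <= m; ++i) {
    H(i, 0) = NEG; E(i, 0) = NEG;
    double open = H(i - 1, 0) - gap_open - gap_extend;
    double ext = F(i - 1, 0) - gap_extend;
    if (i == 1 || open >= ext) { F(i, 0) = open; TF(i, 0) = 0; }
    else { F(i, 0) = ext; TF(i, 0) = 1; }
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= W; ++j) {
      double eo = std::max(H(i, j - 1), F(i, j - 1)) - gap_open - gap_extend;
      double ee = E(i, j - 1) - gap_extend;
      if (eo >= ee) { E(i, j) = eo; TE(i, j) = 0; } else { E(i, j) = ee; TE(i, j) = 1; }
      double fo = std::max(H(i - 1, j), E(i - 1, j)) - gap_open - gap_extend;
      double fe = F(i - 1, j) - gap_extend;
      if (fo >= fe) { F(i, j) = fo; TF(i, j) = 0; } else { F(i, j) = fe; TF(i, j) = 1; }
      double diag = H(i - 1, j - 1);
      double alt = std::max(E(i - 1, j - 1), F(i - 1, j - 1));
      if (alt > diag) diag = alt;
      diag += prof(q[i - 1], j - 1);
      // state H here means "last move was a match"
      H(i, j) = diag; TH(i, j) = 0;
    }
  }
  // terminal: best of the three states at (m, W)
  double s = H(m, W); int state = 0;
  if (F(m, W) > s) { s = F(m, W); state = 1; }
  if (E(m, W) > s) { s = E(m, W); state = 2; }
  // traceback
  IntegerVector placement(W, 0);
  int dropped = 0, i = m, j = W;
  while (i > 0 || j > 0) {
    if (state == 0) { // match consumed a[i] into column j
      placement[j - 1] = i;
      // predecessor: whichever of H/E/F at (i-1, j-1) was max; prefer H, then F, then E
      double hp = H(i - 1, j - 1), fp = F(i - 1, j - 1), ep = E(i - 1, j - 1);
      i--; j--;
      if (i == 0 && j == 0) break;
      if (hp >= fp && hp >= ep) state = 0;
      else if (fp >= ep) state = 1;
      else state = 2;
    } else if (state == 1) { // drop query residue i
      dropped++;
      int t = TF(i, j);
      i--;
      if (t == 0) {
        double hp = H(i, j), ep = E(i, j);
        state = (hp >= ep) ? 0 : 2;
      } else state = 1;
    } else { // gap the column j
      int t = TE(i, j);
      j--;
      if (t == 0) {
        double hp = H(i, j), fp = F(i, j);
        state = (hp >= fp) ? 0 : 1;
      } else state = 2;
    }
  }
  return List::create(_["score"] = s, _["placement"] = placement,
                      _["dropped"] = dropped);
}

// Mismatch / shared-site counts over masked columns for all row pairs.
// aln: integer matrix (rows = sequences, cols = alignment columns),
// 0 = gap, >0 = residue code. mask: logical per column.
// [[Rcpp::export(name = ".pair_counts_cpp")]]
List pair_counts_cpp(IntegerMatrix aln, LogicalVector mask) {
  const int n = aln.nrow(), W = aln.ncol();
  std::vector<int> cols;
  for (int j = 0; j < W; ++j) if (mask[j]) cols.push_back(j);
  IntegerMatrix shared(n, n), mism(n, n);
  for (int i = 0; i < n; ++i) {
    for (int k = i + 1; k < n; ++k) {
      int s = 0, d = 0;
      for (size_t c = 0; c < cols.size(); ++c) {
        int x = aln(i, cols[c]), y = aln(k, cols[c]);
        if (x > 0 && y > 0) { s++; if (x != y) d++; }
      }
      shared(i, k) = shared(k, i) = s;
      mism(i, k) = mism(k, i) = d;
    }
  }
  return List::create(_["shared"] = shared, _["mismatch"] = mism);
}
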