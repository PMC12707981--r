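#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Local (Smith-Waterman) alignment of two integer-encoded peptide sequences
// with affine gaps: a gap of length L costs gap_open + L * gap_extend.
// Sequences are 0-based indices into the rows/columns of `mat`.
//
// Returns the single best local alignment: score, 1-based inclusive
// coordinates in both sequences, identity/mismatch/gap-open counts and the
// number of alignment columns.
// [[Rcpp::export]]
List cpp_sw_align(IntegerVector a, IntegerVector b, NumericMatrix mat,
                  double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  const double NEG = -1e30;
  // Gotoh with full traceback. States: M = 0, Ix = gap in a (consume b),
  // Iy = gap in b (consume a).
  std::vector<double> M((m + 1) * (n + 1), 0.0), Ix((m + 1) * (n + 1), NEG),
      Iy((m + 1) * (n + 1), NEG);
  std::vector<signed char> fM((m + 1) * (n + 1), 0), fIx((m + 1) * (n + 1), 0),
      fIy((m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const double s = mat(a[i - 1], b[j - 1]);
      // M: diagonal step; entry from M > Ix > Iy > fresh-start, strictly
      // greater score wins so the priority order is deterministic.
      double v = M[at(i - 1, j - 1)];
      signed char f = 1;
      if (Ix[at(i - 1, j - 1)] > v) { v = Ix[at(i - 1, j - 1)]; f = 2; }
      if (Iy[at(i - 1, j - 1)] > v) { v = Iy[at(i - 1, j - 1)]; f = 3; }
      if (0.0 >= v) { v = 0.0; f = 0; }
      M[at(i, j)] = v + s;
      fM[at(i, j)] = f;
      // Ix: consume b[j-1] only.
      v = M[at(i, j - 1)] - gap_open - gap_extend;
      f = 1;
      if (Ix[at(i, j - 1)] - gap_extend > v) {
        v = Ix[at(i, j - 1)] - gap_extend; f = 2;
      }
      if (Iy[at(i, j - 1)] - gap_open - gap_extend > v) {
        v = Iy[at(i, j - 1)] - gap_open - gap_extend; f = 3;
      }
      Ix[at(i, j)] = v; fIx[at(i, j)] = f;
      // Iy: consume a[i-1] only.
      v = M[at(i - 1, j)] - gap_open - gap_extend;
      f = 1;
      if (Ix[at(i - 1, j)] - gap_open - gap_extend > v) {
        v = Ix[at(i - 1, j)] - gap_open - gap_extend; f = 2;
      }
      if (Iy[at(i - 1, j)] - gap_extend > v) {
        v = Iy[at(i - 1, j)] - gap_extend; f = 3;
      }
      Iy[at(i, j)] = v; fIy[at(i, j)] = f;
      if (M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; }
    }
  }

  int n_ident = 0, n_mismatch = 0, n_gapopen = 0, n_cols = 0;
  int ai = bi, aj = bj, a_start = bi, b_start = bj;
  int state = 1;  // 1 = M, 2 = Ix, 3 = Iy; best local always ends in M
  if (best > 0.0) {
    while (true) {
      if (state == 1) {
        ++n_cols;
        if (a[ai - 1] == b[aj - 1]) ++n_ident; else ++n_mismatch;
        int f = fM[at(ai, aj)];
        a_start = ai; b_start = aj;
        --ai; --aj;
        if (f == 0) break;
        state = f;
      } else if (state == 2) {
        ++n_cols;
        int f = fIx[at(ai, aj)];
        if (f != 2) ++n_gapopen;
        --aj;
        state = f;
      } else {
        ++n_cols;
        int f = fIy[at(ai, aj)];
        if (f != 3) ++n_gapopen;
        --ai;
        state = f;
      }
    }
  }
  return List::create(_["score"] = best, _["a_start"] = a_start,
                      _["a_end"] = bi, _["b_start"] = b_start,
                      _["b_end"] = bj, _["n_ident"] = n_ident,
                      _["n_mismatch"] = n_mismatch,
                      _["n_gapopen"] = n_gapopen, _["n_cols"] = n_cols);
}

// Frameshift-aware local protein-to-DNA alignment (codon-level Gotoh with
// extra frameshift "codons" of length 1, 2, 4 or 5 nt).
//
// prot:  0-based indices into the rows of `mat` (one per residue)
// dna:   base codes 0=A 1=C 2=G 3=T, >=4 = ambiguous
// codon_aa: length-64 lookup, codon index 16*b1 + 4*b2 + b3 -> matrix column
//           of the translated residue, or -1 for a stop codon
// x_col: matrix column used for codons containing an ambiguous base
//
// Step set: CODON (1 aa + 3 nt, matrix score, stop_score when the codon is a
// stop), SHIFT (1 aa + k nt, k in {1,2,4,5}, flat -frameshift_penalty),
// DNA_GAP (3 nt, affine), PROT_GAP (1 aa, affine). Local: path may start and
// end anywhere but never starts/ends with a gap. Traceback move priority at
// equal score: CODON > SHIFT > DNA_GAP > PROT_GAP.
// [[Rcpp::export]]
List cpp_fs_align(IntegerVector prot, IntegerVector dna, NumericMatrix mat,
                  IntegerVector codon_aa, int x_col, double gap_open,
                  double gap_extend, double frameshift_penalty,
                  double stop_score) {
  const int m = prot.size(), n = dna.size();
  const double NEG = -1e30;
  const size_t ncell = (size_t)(m + 1) * (n + 1);
  std::vector<double> M(ncell, NEG), Ix(ncell, NEG), Iy(ncell, NEG);
  // from-state 0=fresh 1=M 2=Ix 3=Iy; consumed nt for the step into M
  std::vector<signed char> fM(ncell, 0), fIx(ncell, 0), fIy(ncell, 0);
  std::vector<unsigned char> kM(ncell, 3);
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  // codon score for dna[j-3 .. j-1] against residue row r
  auto codon_score = [&](int j, int r) {
    int b1 = dna[j - 3], b2 = dna[j - 2], b3 = dna[j - 1];
    if (b1 > 3 || b2 > 3 || b3 > 3) return mat(r, x_col);
    int aa = codon_aa[16 * b1 + 4 * b2 + b3];
    if (aa < 0) return stop_score;
    return mat(r, aa);
  };

  const int shifts[4] = {1, 2, 4, 5};
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int r = prot[i - 1];
    for (int j = 1; j <= n; ++j) {
      double v = NEG;
      signed char f = 0;
      unsigned char kk = 3;
      // CODON entries, priority M > Ix > Iy > fresh
      if (j >= 3) {
        const double s = codon_score(j, r);
        double e = M[at(i - 1, j - 3)];
        signed char ef = 1;
        if (Ix[at(i - 1, j - 3)] > e) { e = Ix[at(i - 1, j - 3)]; ef = 2; }
        if (Iy[at(i - 1, j - 3)] > e) { e = Iy[at(i - 1, j - 3)]; ef = 3; }
        if (0.0 >= e) { e = 0.0; ef = 0; }
        v = e + s; f = ef; kk = 3;
      }
      // SHIFT entries (k = 1, 2, 4, 5)
      for (int si = 0; si < 4; ++si) {
        const int k = shifts[si];
        if (j < k) continue;
        double e = M[at(i - 1, j - k)];
        signed char ef = 1;
        if (Ix[at(i - 1, j - k)] > e) { e = Ix[at(i - 1, j - k)]; ef = 2; }
        if (Iy[at(i - 1, j - k)] > e) { e = Iy[at(i - 1, j - k)]; ef = 3; }
        if (0.0 >= e) { e = 0.0; ef = 0; }
        const double cand = e - frameshift_penalty;
        if (cand > v) { v = cand; f = ef; kk = (unsigned char)k; }
      }
      M[at(i, j)] = v; fM[at(i, j)] = f; kM[at(i, j)] = kk;
      // DNA_GAP (Ix): 3 extra nt in the locus
      if (j >= 3) {
        double e = M[at(i, j - 3)] - gap_open - gap_extend;
        signed char ef = 1;
        if (Ix[at(i, j - 3)] - gap_extend > e) {
          e = Ix[at(i, j - 3)] - gap_extend; ef = 2;
        }
        if (Iy[at(i, j - 3)] - gap_open - gap_extend > e) {
          e = Iy[at(i, j - 3)] - gap_open - gap_extend; ef = 3;
        }
        Ix[at(i, j)] = e; fIx[at(i, j)] = ef;
      }
      // PROT_GAP (Iy): protein residue unmatched
      {
        double e = M[at(i - 1, j)] - gap_open - gap_extend;
        signed char ef = 1;
        if (Ix[at(i - 1, j)] - gap_open - gap_extend > e) {
          e = Ix[at(i - 1, j)] - gap_open - gap_extend; ef = 2;
        }
        if (Iy[at(i - 1, j)] - gap_extend > e) {
          e = Iy[at(i - 1, j)] - gap_extend; ef = 3;
        }
        Iy[at(i, j)] = e; fIy[at(i, j)] = ef;
      }
      if (M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; }
    }
  }

  std::vector<std::string> step;
  std::vector<int> aa_pos, nt_pos, nt_len;
  int prot_start = 0, prot_end = bi, nt_start = 0, nt_end = bj;
  if (best > 0.0) {
    int ai = bi, aj = bj, state = 1;
    while (true) {
      if (state == 1) {
        int k = kM[at(ai, aj)];
        int f = fM[at(ai, aj)];
        step.push_back(k == 3 ? "CODON" : "SHIFT");
        aa_pos.push_back(ai);
        nt_pos.push_back(aj - k);
        nt_len.push_back(k);
        prot_start = ai; nt_start = aj - k;
        --ai; aj -= k;
        if (f == 0) break;
        state = f;
      } else if (state == 2) {
        int f = fIx[at(ai, aj)];
        step.push_back("DNA_GAP");
        aa_pos.push_back(0);
        nt_pos.push_back(aj - 3);
        nt_len.push_back(3);
        aj -= 3;
        state = f;
      } else {
        int f = fIy[at(ai, aj)];
        step.push_back("PROT_GAP");
        aa_pos.push_back(ai);
        nt_pos.push_back(aj);
        nt_len.push_back(0);
        --ai;
        state = f;
      }
    }
    std::reverse(step.begin(), step.end());
    std::reverse(aa_pos.begin(), aa_pos.end());
    std::reverse(nt_pos.begin(), nt_pos.end());
    std::reverse(nt_len.begin(), nt_len.end());
  }
  return List::create(
      _["score"] = best, _["prot_start"] = prot_start,
      _["prot_end"] = prot_end, _["nt_start"] = nt_start,
      _["nt_end"] = nt_end, _["step"] = wrap(step),
      _["aa_pos"] = wrap(aa_pos), _["nt_pos"] = wrap(nt_pos),
      _["nt_len"] = wrap(nt_len));
}
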