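#include <Rcpp.h>
using namespace Rcpp;

// Pairwise mismatch bookkeeping over an integer-coded alignment.
// Codes: 0=A, 1=C, 2=G, 3=T, negative = ambiguous (N or gap).
// Sites where either sequence is ambiguous are skipped for that pair
// (pairwise deletion).
//
// Returns, for every ordered pair (i<j):
//   nd   raw number of differing sites
//   nv   number of jointly unambiguous sites
//   p1   A<->G differences (purine transitions)
//   p2   C<->T differences (pyrimidine transitions)
//   q    transversions
//   fA..fT  base frequencies averaged over the two sequences at the
//           jointly unambiguous sites (TN93 per-pair convention)
// [[Rcpp::export(name = ".pair_counts_cpp")]]
List pair_counts_cpp(const IntegerMatrix& seqs) {
  const int n = seqs.nrow(), L = seqs.ncol();
  NumericMatrix nd(n, n), nv(n, n), p1(n, n), p2(n, n), q(n, n);
  NumericMatrix fA(n, n), fC(n, n), fG(n, n), fT(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int d = 0, v = 0, t1 = 0, t2 = 0, tv = 0;
      int cnt[4] = {0, 0, 0, 0};
      for (int s = 0; s < L; ++s) {
        const int a = seqs(i, s), b = seqs(j, s);
        if (a < 0 || b < 0) continue;
        ++v;
        cnt[a]++; cnt[b]++;
        if (a != b) {
          ++d;
          const int lo = a < b ? a : b, hi = a < b ? b : a;
          if (lo == 0 && hi == 2) ++t1;        // A-G
          else if (lo == 1 && hi == 3) ++t2;   // C-T
          else ++tv;
        }
      }
      nd(i, j) = nd(j, i) = d;
      nv(i, j) = nv(j, i) = v;
      p1(i, j) = p1(j, i) = t1;
      p2(i, j) = p2(j, i) = t2;
      q(i, j)  = q(j, i)  = tv;
      const double tot = 2.0 * v;
      if (v > 0) {
        fA(i, j) = fA(j, i) = cnt[0] / tot;
        fC(i, j) = fC(j, i) = cnt[1] / tot;
        fG(i, j) = fG(j, i) = cnt[2] / tot;
        fT(i, j) = fT(j, i) = cnt[3] / tot;
      }
    }
  }
  return List::create(_["nd"] = nd, _["nv"] = nv, _["p1"] = p1,
                      _["p2"] = p2, _["q"] = q, _["fA"] = fA,
                      _["fC"] = fC, _["fG"] = fG, _["fT"] = fT);
}
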