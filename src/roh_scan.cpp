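#include <Rcpp.h>
using namespace Rcpp;

// Consecutive-runs scan over one chromosome for all samples.
//
// calls: samples x snps integer matrix (0/1/2, NA = missing), columns in
// map order on a single chromosome; bp: positions. A SNP is admissible in
// the growing run if it is homozygous, or heterozygous/missing while the
// run's budget (maxHet / maxMissing) is not exceeded, and its gap to the
// previous run SNP is <= maxGap. The SNP whose addition violates a
// constraint closes the run; scanning resumes at that SNP with fresh
// budgets. Candidates are trimmed so both endpoints are homozygous
// non-missing calls. Emission thresholds (minSnps, minLength, density)
// are applied by the R caller.
//
// Returns a matrix with one row per trimmed candidate:
// sample index (1-based), start col, end col, n_snps, n_het, n_missing.
// [[Rcpp::export]]
IntegerMatrix roh_scan_chrom(IntegerMatrix calls, NumericVector bp,
                             int maxHet, int maxMissing, double maxGap) {
  const int ns = calls.nrow(), nm = calls.ncol();
  std::vector<int> out;  // flat rows of 6

  for (int s = 0; s < ns; ++s) {
    int i = 0;
    while (i < nm) {
      int g = calls(s, i);
      bool miss0 = (g == NA_INTEGER);
      bool het0 = (!miss0 && g == 1);
      // a run can only open on an admissible single SNP
      if ((het0 && maxHet < 1) || (miss0 && maxMissing < 1)) { ++i; continue; }
      int het = het0 ? 1 : 0, mis = miss0 ? 1 : 0;
      int j = i, viol = -1;
      while (j + 1 < nm) {
        if (bp[j + 1] - bp[j] > maxGap) { viol = j + 1; break; }
        int gn = calls(s, j + 1);
        int nh = het, nmv = mis;
        if (gn == NA_INTEGER) ++nmv; else if (gn == 1) ++nh;
        if (nh > maxHet || nmv > maxMissing) { viol = j + 1; break; }
        het = nh; mis = nmv; ++j;
      }
      // trim candidate [i..j] to homozygous non-missing endpoints
      int a = i, b = j;
      while (a <= b) {
        int ga = calls(s, a);
        if (ga != NA_INTEGER && (ga == 0 || ga == 2)) break;
        ++a;
      }
      while (b >= a) {
        int gb = calls(s, b);
        if (gb != NA_INTEGER && (gb == 0 || gb == 2)) break;
        --b;
      }
      if (a <= b) {
        int nh = 0, nmv = 0;
        for (int k = a; k <= b; ++k) {
          int gk = calls(s, k);
          if (gk == NA_INTEGER) ++nmv; else if (gk == 1) ++nh;
        }
        out.push_back(s + 1);
        out.push_back(a + 1);
        out.push_back(b + 1);
        out.push_back(b - a + 1);
        out.push_back(nh);
        out.push_back(nmv);
      }
      if (viol < 0) break;
      i = viol;
    }
  }

  const int nr = (int)(out.size() / 6);
  IntegerMatrix res(nr, 6);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < 6; ++c) res(r, c) = out[r * 6 + c];
  colnames(res) = CharacterVector::create("sample", "start_idx", "end_idx",
                                          "n_snps", "n_het", "n_missing");
  return res;
}
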