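#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Null distribution of overlap counts under genome-wide interval shuffling.
//
// Each permutation independently re-places every query interval uniformly
// over all valid genome-wide start positions (chromosome chosen with
// probability proportional to its number of valid starts for that interval's
// length), then counts overlaps with a fixed site set:
//   count_sites = true  -> number of distinct sites overlapped by >= 1
//                          placed interval (TFBS enrichment statistic)
//   count_sites = false -> number of placed intervals overlapping >= 1 site
//                          (interval-set overlap statistic)
// Sites must be supplied per chromosome, sorted by start (0-based
// half-open). Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector perm_null_counts(List site_starts, List site_ends,
                               NumericVector chrom_len, IntegerVector iv_len,
                               int n_perm, bool count_sites) {
  const int n_chrom = chrom_len.size();
  const int n_iv = iv_len.size();

  std::vector<std::vector<double>> ss(n_chrom), se(n_chrom);
  std::vector<double> max_site_len(n_chrom, 0.0);
  std::vector<int> site_offset(n_chrom, 0);
  int n_sites_total = 0;
  for (int c = 0; c < n_chrom; ++c) {
    NumericVector s = site_starts[c], e = site_ends[c];
    ss[c] = std::vector<double>(s.begin(), s.end());
    se[c] = std::vector<double>(e.begin(), e.end());
    for (size_t j = 0; j < ss[c].size(); ++j)
      max_site_len[c] = std::max(max_site_len[c], se[c][j] - ss[c][j]);
    site_offset[c] = n_sites_total;
    n_sites_total += ss[c].size();
  }

  // cumulative valid-start weights per interval across chromosomes
  std::vector<std::vector<double>> cumw(n_iv, std::vector<double>(n_chrom));
  std::vector<double> total(n_iv);
  for (int i = 0; i < n_iv; ++i) {
    double acc = 0.0;
    for (int c = 0; c < n_chrom; ++c) {
      double v = chrom_len[c] - iv_len[i] + 1.0;
      if (v < 0.0) v = 0.0;
      acc += v;
      cumw[i][c] = acc;
    }
    total[i] = acc;
    if (acc <= 0.0)
      stop("interval longer than every chromosome: cannot shuffle");
  }

  IntegerVector out(n_perm);
  std::vector<char> seen(n_sites_total);
  for (int p = 0; p < n_perm; ++p) {
    int stat = 0;
    if (count_sites) std::fill(seen.begin(), seen.end(), 0);
    for (int i = 0; i < n_iv; ++i) {
      double u = std::floor(unif_rand() * total[i]);
      if (u >= total[i]) u = total[i] - 1.0;
      int c = 0;
      while (c < n_chrom - 1 && u >= cumw[i][c]) ++c;
      double before = (c == 0) ? 0.0 : cumw[i][c - 1];
      double x = u - before;             // placed start
      double xe = x + iv_len[i];         // placed end (exclusive)
      const std::vector<double>& s = ss[c];
      const std::vector<double>& e = se[c];
      if (s.empty()) continue;
      // sites with start < xe, walking back while start could still overlap
      int hi = std::upper_bound(s.begin(), s.end(), xe - 1.0) - s.begin();
      bool any_hit = false;
      for (int j = hi - 1; j >= 0; --j) {
        if (s[j] + max_site_len[c] <= x) break;
        if (e[j] > x) {
          any_hit = true;
          if (count_sites) seen[site_offset[c] + j] = 1;
          else break;
        }
      }
      if (!count_sites && any_hit) ++stat;
    }
    if (count_sites) {
      for (int k = 0; k < n_sites_total; ++k) stat += seen[k];
    }
    out[p] = stat;
  }
  return out;
}
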