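#include <Rcpp.h>
using namespace Rcpp;

// Nearest-taxon distances used by betaMNTD.
//
// D        : patristic distance matrix over ALL tips of the supplied tree
//            (the regional pool).
// members  : per sample, 0-based indices (into `tip`) of the OTUs present.
// tip      : 0-based row index of each OTU in D. Tip-shuffling nulls pass a
//            permuted/resampled index vector here; the table stays fixed.
// exclude_self : drop the conspecific match (same OTU in the other sample)
//            from the minimum. If an OTU is the sole candidate, the
//            conspecific zero is kept (nothing else to match against).
//
// Returns M (n_otu x n_sample): M(i, s) = min_{j in members[s]} D(tip[i], tip[j]).
// [[Rcpp::export]]
NumericMatrix min_taxon_dist(const NumericMatrix& D, const List& members,
                             const IntegerVector& tip, const bool exclude_self) {
  const int n_otu = tip.size();
  const int n_s = members.size();
  NumericMatrix M(n_otu, n_s);
  for (int s = 0; s < n_s; ++s) {
    IntegerVector mem = members[s];
    const int m = mem.size();
    for (int i = 0; i < n_otu; ++i) {
      const int ti = tip[i];
      double best = R_PosInf;
      for (int k = 0; k < m; ++k) {
        const int j = mem[k];
        if (exclude_self && j == i) continue;
        const double d = D(ti, tip[j]);
        if (d < best) best = d;
      }
      if (!R_FINITE(best)) best = 0.0;  // lone conspecific: fall back to self
      M(i, s) = best;
    }
  }
  return M;
}
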