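#include <Rcpp.h>
using namespace Rcpp;

//' Greedy duplicate-free assignment for spin permutations
//'
//' Scans (original, rotated) parcel pairs in ascending order of distance and
//' accepts a pair only when both members are still unassigned, so every
//' original parcel receives a distinct rotated parcel.
//'
//' @param ord zero-based linear indices into an n x n column-major distance
//'   matrix (rows = original parcels, columns = rotated parcels), sorted by
//'   ascending distance.
//' @param n number of parcels.
//' @return integer vector perm of length n (1-based): perm[i] is the rotated
//'   parcel matched to original position i.
//' @keywords internal
// [[Rcpp::export]]
IntegerVector greedy_match(IntegerVector ord, int n) {
  IntegerVector perm(n, NA_INTEGER);
  std::vector<bool> row_used(n, false), col_used(n, false);
  int assigned = 0;
  R_xlen_t m = ord.size();
  for (R_xlen_t k = 0; k < m && assigned < n; ++k) {
    int idx = ord[k];
    int i = idx % n;  // row (column-major storage)
    int j = idx / n;  // column
    if (!row_used[i] && !col_used[j]) {
      perm[i] = j + 1;
      row_used[i] = true;
      col_used[j] = true;
      ++assigned;
    }
  }
  return perm;
}
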