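#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Standard persistence column reduction over Z/2.
//
// `cols` holds, for each simplex in filtration order, the sorted 0-based
// indices of its facets (empty for vertices).  Returns, for each column j,
// the index it kills (its final low) or -1 when the column reduces to zero,
// i.e. when the simplex creates a homology class.  Pair (kills[j], j) is a
// finite birth-death pair; creators never appearing as a kill are essential.
// [[Rcpp::export]]
IntegerVector reduce_boundary(List cols) {
  const int m = cols.size();
  std::vector< std::vector<int> > mat(m);
  for (int j = 0; j < m; ++j) {
    IntegerVector c = cols[j];
    mat[j].assign(c.begin(), c.end());
  }
  std::vector<int> lowOwner(m, -1);
  IntegerVector kills(m, -1);
  std::vector<int> tmp;
  for (int j = 0; j < m; ++j) {
    std::vector<int> &col = mat[j];
    while (!col.empty()) {
      const int low = col.back();
      const int owner = lowOwner[low];
      if (owner < 0) break;
      const std::vector<int> &other = mat[owner];
      tmp.clear();
      std::set_symmetric_difference(col.begin(), col.end(),
                                    other.begin(), other.end(),
                                    std::back_inserter(tmp));
      col.swap(tmp);
    }
    if (!col.empty()) {
      lowOwner[col.back()] = j;
      kills[j] = col.back();
    }
  }
  return kills;
}
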