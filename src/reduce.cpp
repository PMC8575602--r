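#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Persistence pairing by column reduction of the boundary matrix over GF(2),
// with the twist/clearing optimization: dimensions are processed from the
// top down, and a column found to be a pivot (a birth) is cleared before its
// own dimension is reduced.
//
// The boundary matrix arrives in compressed column layout: `entries` holds
// the 1-based filtration indices of all facets, column j (0-based) occupying
// entries[colptr[j] .. colptr[j+1]-1] (unsorted); vertices have empty
// columns. `dims` is the simplex dimension per column. Returns (birth,
// death) index pairs and the essential simplex indices, all 1-based.
// [[Rcpp::export]]
List reduce_boundary_z2(IntegerVector entries, IntegerVector colptr,
                        IntegerVector dims) {
  int n = colptr.size() - 1;
  int maxdim = 0;
  for (int j = 0; j < n; ++j) maxdim = std::max(maxdim, dims[j]);

  std::vector< std::vector<int> > R(n);
  std::vector<int> pivot_owner(n, -1);
  std::vector<char> cleared(n, 0), is_death(n, 0);
  std::vector<int> births, deaths;
  std::vector<int> tmp, col;

  for (int d = maxdim; d >= 1; --d) {
    for (int j = 0; j < n; ++j) {
      if (dims[j] != d || cleared[j]) continue;
      col.assign(entries.begin() + colptr[j], entries.begin() + colptr[j + 1]);
      for (auto &v : col) --v;  // to 0-based
      std::sort(col.begin(), col.end());
      while (!col.empty()) {
        int low = col.back();
        int o = pivot_owner[low];
        if (o < 0) break;
        tmp.clear();
        std::set_symmetric_difference(col.begin(), col.end(),
                                      R[o].begin(), R[o].end(),
                                      std::back_inserter(tmp));
        col.swap(tmp);
      }
      if (!col.empty()) {
        int low = col.back();
        pivot_owner[low] = j;
        R[j] = col;
        is_death[j] = 1;
        cleared[low] = 1;
        births.push_back(low + 1);
        deaths.push_back(j + 1);
      }
    }
  }

  std::vector<int> essential;
  for (int j = 0; j < n; ++j)
    if (!cleared[j] && !is_death[j]) essential.push_back(j + 1);

  IntegerMatrix pairs(births.size(), 2);
  for (size_t k = 0; k < births.size(); ++k) {
    pairs(k, 0) = births[k];
    pairs(k, 1) = deaths[k];
  }
  return List::create(_["pairs"] = pairs,
                      _["essential"] = wrap(essential));
}
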