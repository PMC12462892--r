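#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Exact rank of a sparse matrix over GF(p), p an odd prime below 2^16 so
// products fit comfortably in 64-bit intermediates.  Left-to-right column
// reduction with the lowest-one (largest remaining row index) as pivot, the
// standard boundary-matrix reduction; columns are kept as sorted sparse
// vectors and combined by merging.

static inline long long mod_inv(long long a, long long p) {
  // Fermat: a^(p-2) mod p
  long long r = 1, b = a % p, e = p - 2;
  while (e) {
    if (e & 1) r = (r * b) % p;
    b = (b * b) % p;
    e >>= 1;
  }
  return r;
}

typedef std::pair<int, int> Ent; // (row, value mod p)

// [[Rcpp::export(name = ".rank_ff_cpp")]]
int rank_ff_cpp(IntegerVector dims, IntegerVector mi, IntegerVector mp,
                NumericVector mx, int p = 46337) {
  const int ncol = dims[1];
  // pivot row -> index into stored reduced columns
  std::unordered_map<int, int> pivot_of_row;
  std::vector< std::vector<Ent> > reduced;
  std::vector<long long> pivot_val; // value at pivot row of reduced column
  reduced.reserve(1024);
  int rank = 0;
  std::vector<Ent> col, tmp;
  for (int c = 0; c < ncol; ++c) {
    col.clear();
    for (int k = mp[c]; k < mp[c + 1]; ++k) {
      long long v = ((long long)llround(mx[k])) % p;
      if (v < 0) v += p;
      if (v != 0) col.push_back(Ent(mi[k], (int)v));
    }
    // entries of a dgCMatrix are sorted by row already
    while (!col.empty()) {
      int low = col.back().first;
      std::unordered_map<int, int>::iterator it = pivot_of_row.find(low);
      if (it == pivot_of_row.end()) {
        pivot_of_row[low] = (int)reduced.size();
        pivot_val.push_back(col.back().second);
        reduced.push_back(col);
        ++rank;
        break;
      }
      const std::vector<Ent> &piv = reduced[it->second];
      // col <- col - (col_low / piv_low) * piv
      long long alpha = (col.back().second * mod_inv(pivot_val[it->second], p)) % p;
      tmp.clear();
      size_t a = 0, b = 0;
      while (a < col.size() || b < piv.size()) {
        if (b == piv.size() || (a < col.size() && col[a].first < piv[b].first)) {
          tmp.push_back(col[a++]);
        } else if (a == col.size() || piv[b].first < col[a].first) {
          long long v = (p - (alpha * piv[b].second) % p) % p;
          if (v != 0) tmp.push_back(Ent(piv[b].first, (int)v));
          ++b;
        } else {
          long long v = (col[a].second - (alpha * piv[b].second) % p + (long long)p * p) % p;
          if (v != 0) tmp.push_back(Ent(col[a].first, (int)v));
          ++a; ++b;
        }
      }
      col.swap(tmp);
    }
  }
  return rank;
}
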