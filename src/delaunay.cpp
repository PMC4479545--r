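#include <Rcpp.h>
#include <set>
#include <utility>
#include <cmath>
using namespace Rcpp;

// Brute-force Delaunay edge enumeration for point sets of a few hundred
// localities: a triangle belongs to the triangulation iff its circumcircle
// contains no other site (checked with the standard incircle determinant).
// O(n^4) worst case with early exit; intended for n up to a few hundred.
// [[Rcpp::export]]
IntegerMatrix delaunay_edges_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  std::set< std::pair<int,int> > edges;
  if (n == 2) edges.insert(std::make_pair(0, 1));
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      for (int k = j + 1; k < n; ++k) {
        double orient = (x[j]-x[i])*(y[k]-y[i]) - (x[k]-x[i])*(y[j]-y[i]);
        if (std::fabs(orient) < 1e-14) continue;  // collinear triple
        int a = i, b = j, c = k;
        if (orient < 0) std::swap(b, c);          // make a,b,c CCW
        bool empty = true;
        for (int m = 0; m < n && empty; ++m) {
          if (m == i || m == j || m == k) continue;
          double adx = x[a]-x[m], ady = y[a]-y[m];
          double bdx = x[b]-x[m], bdy = y[b]-y[m];
          double cdx = x[c]-x[m], cdy = y[c]-y[m];
          double det = (adx*adx + ady*ady) * (bdx*cdy - cdx*bdy)
                     - (bdx*bdx + bdy*bdy) * (adx*cdy - cdx*ady)
                     + (cdx*cdx + cdy*cdy) * (adx*bdy - bdx*ady);
          if (det > 1e-14) empty = false;         // m strictly inside
        }
        if (empty) {
          edges.insert(std::make_pair(i, j));
          edges.insert(std::make_pair(i, k));
          edges.insert(std::make_pair(j, k));
        }
      }
    }
  }
  IntegerMatrix out(edges.size(), 2);
  int r = 0;
  for (std::set< std::pair<int,int> >::iterator it = edges.begin();
       it != edges.end(); ++it, ++r) {
    out(r, 0) = it->first + 1;   // 1-based for R
    out(r, 1) = it->second + 1;
  }
  return out;
}
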