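#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of an integer-valued 3D volume. Voxels belong
// to the same component iff they carry the same positive value and are
// connected under the given neighbourhood offsets (6/18/26-connectivity
// offsets are built on the R side). Returns an integer array of component
// ids (0 = background), numbered in scan order.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(IntegerVector vol, IntegerMatrix offsets) {
  IntegerVector dims = vol.attr("dim");
  if (dims.size() != 3) stop("expected a 3D array");
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = vol.size();
  const int m = offsets.nrow();
  IntegerVector lab(n);
  lab.attr("dim") = dims;
  const int *v = vol.begin();
  int *L = lab.begin();

  std::vector<int> o1(m), o2(m), o3(m);
  for (int q = 0; q < m; ++q) { o1[q] = offsets(q,0); o2[q] = offsets(q,1); o3[q] = offsets(q,2); }

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (v[s] <= 0 || L[s] != 0) continue;
    const int cls = v[s];
    ++next;
    L[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int i1 = cur % n1;
      const int i2 = (cur / n1) % n2;
      const int i3 = cur / ((R_xlen_t)n1 * n2);
      for (int q = 0; q < m; ++q) {
        const int j1 = i1 + o1[q], j2 = i2 + o2[q], j3 = i3 + o3[q];
        if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3) continue;
        const R_xlen_t t = j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3);
        if (L[t] == 0 && v[t] == cls) {
          L[t] = next;
          stack.push_back(t);
        }
      }
    }
  }
  return lab;
}
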