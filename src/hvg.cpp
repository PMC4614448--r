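#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Horizontal visibility graph of an ordered series, stack-based single pass.
//
// Nodes i < j are linked iff every intermediate value x[k], i < k < j,
// satisfies x[k] < min(x[i], x[j]) (strict: an intermediate equal to the
// smaller endpoint blocks visibility).
//
// The stack holds, left to right, the indices still visible from the
// right end; their values are strictly decreasing. When point j arrives:
// every stacked index with value < x[j] is visible from j and then hidden
// forever (popped); the first index with value >= x[j] is also visible,
// and if its value equals x[j] it too is hidden from everything right of j.
// Each index is pushed and popped at most once, so the pass is O(N) plus
// one entry per emitted edge.
//
// [[Rcpp::export]]
IntegerMatrix hvg_edges_cpp(NumericVector x) {
  const int n = x.size();
  std::vector<int> stack;
  stack.reserve(64);
  std::vector<int> ei, ej;
  ei.reserve(2 * n);
  ej.reserve(2 * n);

  for (int j = 0; j < n; ++j) {
    while (!stack.empty() && x[stack.back()] < x[j]) {
      ei.push_back(stack.back());
      ej.push_back(j);
      stack.pop_back();
    }
    if (!stack.empty()) {
      ei.push_back(stack.back());
      ej.push_back(j);
      if (x[stack.back()] == x[j]) stack.pop_back();
    }
    stack.push_back(j);
  }

  const int m = ei.size();
  IntegerMatrix edges(m, 2);
  for (int e = 0; e < m; ++e) {
    edges(e, 0) = ei[e] + 1;  // 1-based for R
    edges(e, 1) = ej[e] + 1;
  }
  return edges;
}

// Degree sequence straight from the same pass (avoids materialising the
// edge matrix when only degrees are needed, e.g. interlayer MI at scale).
//
// [[Rcpp::export]]
IntegerVector hvg_degrees_cpp(NumericVector x) {
  const int n = x.size();
  std::vector<int> stack;
  stack.reserve(64);
  IntegerVector deg(n);

  for (int j = 0; j < n; ++j) {
    while (!stack.empty() && x[stack.back()] < x[j]) {
      deg[stack.back()] += 1;
      deg[j] += 1;
      stack.pop_back();
    }
    if (!stack.empty()) {
      deg[stack.back()] += 1;
      deg[j] += 1;
      if (x[stack.back()] == x[j]) stack.pop_back();
    }
    stack.push_back(j);
  }
  return deg;
}
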