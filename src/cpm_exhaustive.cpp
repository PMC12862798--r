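#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive maximization of the constant Potts model objective
//   sum_c [ W_c - gamma * n_c (n_c - 1) / 2 ]
// over all set partitions of n elements, by recursive enumeration in
// restricted-growth order. Feasible up to n ~ 13 (Bell(13) ~ 2.8e7);
// intended as a brute-force reference for small instances.

static void recurse(int i, int n, int nblocks,
                    std::vector<int> &memb, std::vector<int> &bsize,
                    double obj, const NumericMatrix &m, double gamma,
                    double &best, std::vector<int> &best_memb) {
  if (i == n) {
    if (obj > best) {
      best = obj;
      best_memb = memb;
    }
    return;
  }
  for (int b = 0; b <= nblocks; ++b) {
    double gain = 0.0;
    for (int j = 0; j < i; ++j) {
      if (memb[j] == b) gain += m(j, i);
    }
    if (b < nblocks) gain -= gamma * bsize[b];
    memb[i] = b;
    if (b < nblocks) {
      bsize[b]++;
      recurse(i + 1, n, nblocks, memb, bsize, obj + gain, m, gamma,
              best, best_memb);
      bsize[b]--;
    } else {
      bsize.push_back(1);
      recurse(i + 1, n, nblocks + 1, memb, bsize, obj + gain, m, gamma,
              best, best_memb);
      bsize.pop_back();
    }
  }
}

// [[Rcpp::export(name = ".cpm_exhaustive_cpp")]]
List cpm_exhaustive_cpp(NumericMatrix m, double gamma) {
  int n = m.nrow();
  if (n != m.ncol()) stop("matrix must be square");
  if (n > 14) stop("exhaustive search is limited to n <= 14 features");
  std::vector<int> memb(n, 0), bsize, best_memb(n, 0);
  double best = -std::numeric_limits<double>::infinity();
  recurse(0, n, 0, memb, bsize, 0.0, m, gamma, best, best_memb);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = best_memb[i] + 1;
  return List::create(_["objective"] = best, _["membership"] = out);
}
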