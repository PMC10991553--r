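#include <Rcpp.h>

// Ma-Sandri-Sarkar recursion for the Luria-Delbruck distribution:
//   p_0 = exp(-m)
//   p_r = (m / r) * sum_{i=0}^{r-1} p_i / (r - i + 1),  r >= 1
// O(r_max^2); kept in C++ because likelihood maximization evaluates it
// repeatedly at r_max up to 1e4.
// [[Rcpp::export(name = ".ld_pmf_cpp")]]
Rcpp::NumericVector ld_pmf_cpp(double m, int r_max) {
  Rcpp::NumericVector p(r_max + 1);
  p[0] = std::exp(-m);
  for (int r = 1; r <= r_max; ++r) {
    double s = 0.0;
    for (int i = 0; i < r; ++i) s += p[i] / (double)(r - i + 1);
    p[r] = m / r * s;
  }
  return p;
}
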