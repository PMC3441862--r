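#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exhaustive maximal-scoring-interval search over one contiguous stretch of
// probes. Score of an interval I is |mean(x over I)| * sqrt(|I|) / sigma,
// i.e. the mean deviation from zero in noise-s.d. units scaled by the square
// root of the probe count. Ties are broken leftmost-then-shortest, which the
// ascending scan order gives for free under a strict improvement test.
//
// Returns c(start, end, score) with 1-based inclusive indices, or
// c(NA, NA, 0) for empty input.
// [[Rcpp::export(name = ".bestIntervalCpp")]]
NumericVector best_interval_cpp(NumericVector x, double sigma) {
    const int n = x.size();
    if (n == 0 || sigma <= 0.0)
        return NumericVector::create(NA_REAL, NA_REAL, 0.0);

    std::vector<double> cs(n + 1, 0.0);
    for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];

    double best = -1.0;
    int bs = -1, be = -1;
    for (int i = 0; i < n; ++i) {
        for (int j = i; j < n; ++j) {
            const int m = j - i + 1;
            const double mean = (cs[j + 1] - cs[i]) / m;
            const double sc = std::fabs(mean) * std::sqrt((double) m) / sigma;
            if (sc > best + 1e-12) {
                best = sc; bs = i; be = j;
            }
        }
    }
    return NumericVector::create(bs + 1.0, be + 1.0, best);
}
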