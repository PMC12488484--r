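#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>

using namespace Rcpp;

// Sliding-window percentile with a window maintained as a sorted buffer.
// For frame i (0-based) the window covers [i + lo_off, i + hi_off],
// truncated at the ends of the trace. A centered 30-s window at 15 Hz uses
// lo_off = -225, hi_off = +225; a trailing window uses lo_off = -(w-1),
// hi_off = 0.
// [[Rcpp::export(name = ".sliding_percentile_cpp")]]
NumericVector sliding_percentile_cpp(NumericVector x, int lo_off, int hi_off,
                                     double prob) {
    const int n = x.size();
    if (n == 0) return NumericVector(0);
    if (lo_off > hi_off) stop("window offsets out of order");
    NumericVector out(n);
    const int wmax = hi_off - lo_off + 1;
    std::vector<double> buf(wmax + 1);
    double* b = buf.data();
    int len = 0;

    int cur_lo = 0, cur_hi = -1;  // current window [cur_lo, cur_hi]
    for (int i = 0; i < n; ++i) {
        int want_lo = std::max(0, i + lo_off);
        int want_hi = std::min(n - 1, i + hi_off);
        while (cur_hi < want_hi) {  // grow right
            double v = x[++cur_hi];
            double* p = std::lower_bound(b, b + len, v);
            std::memmove(p + 1, p, (b + len - p) * sizeof(double));
            *p = v;
            ++len;
        }
        while (cur_lo < want_lo) {  // shrink left
            double v = x[cur_lo++];
            double* p = std::lower_bound(b, b + len, v);
            std::memmove(p, p + 1, (b + len - p - 1) * sizeof(double));
            --len;
        }
        // type-7 quantile on the sorted buffer
        if (len == 1) { out[i] = b[0]; continue; }
        double h = (len - 1) * prob;
        int lo = (int)h;
        out[i] = (lo >= len - 1) ? b[len - 1]
                                 : b[lo] + (h - lo) * (b[lo + 1] - b[lo]);
    }
    return out;
}
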