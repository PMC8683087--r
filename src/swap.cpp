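#include <Rcpp.h>
using namespace Rcpp;

// Independent-swap randomization of a non-negative matrix.
//
// Each attempt samples two distinct rows and two distinct columns uniformly.
// If the 2x2 quartet is an occupancy checkerboard (exactly one diagonal
// nonzero, the other diagonal zero) the two nonzero values are relocated to
// the zero cells along their rows.  This preserves the binarized row and
// column sums, the grand total, and each row's multiset of nonzero values.
//
// Draws come from R's RNG so results are reproducible under set.seed().
// countSuccesses = false: nIter counts attempts (failed quartets consume an
// iteration).  true: nIter counts successful swaps, with a hard cap of
// 1000 * nIter attempts to guarantee termination on swap-free matrices.

// [[Rcpp::export(name = ".independentSwapCpp")]]
NumericMatrix independent_swap_cpp(NumericMatrix m, double nIter,
                                   bool countSuccesses = false) {
    NumericMatrix x = clone(m);
    int nr = x.nrow(), nc = x.ncol();
    if (nr < 2 || nc < 2 || nIter <= 0)
        return x;
    double done = 0;
    double attempts = 0;
    double maxAttempts = countSuccesses ? 1000.0 * nIter : nIter;
    while (attempts < maxAttempts) {
        attempts += 1;
        int i = (int)(unif_rand() * nr); if (i == nr) i = nr - 1;
        int k = (int)(unif_rand() * (nr - 1)); if (k == nr - 1) k = nr - 2;
        if (k >= i) k++;
        int j = (int)(unif_rand() * nc); if (j == nc) j = nc - 1;
        int l = (int)(unif_rand() * (nc - 1)); if (l == nc - 1) l = nc - 2;
        if (l >= j) l++;
        double a = x(i, j), b = x(i, l), c = x(k, j), d = x(k, l);
        bool swapped = false;
        if (a > 0 && d > 0 && b == 0 && c == 0) {
            x(i, l) = a; x(i, j) = 0;
            x(k, j) = d; x(k, l) = 0;
            swapped = true;
        } else if (b > 0 && c > 0 && a == 0 && d == 0) {
            x(i, j) = b; x(i, l) = 0;
            x(k, l) = c; x(k, j) = 0;
            swapped = true;
        }
        if (swapped) done += 1;
        if (countSuccesses) {
            if (done >= nIter) break;
        } else {
            if (attempts >= nIter) break;
        }
    }
    x.attr("swaps") = done;
    return x;
}
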