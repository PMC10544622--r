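#include <Rcpp.h>
using namespace Rcpp;

// Local maxima of a numeric vector with their topographic prominences.
//
// A local maximum is a sample strictly greater than its left neighbour and
// at the left edge of any plateau that is followed by a strict drop.
// Prominence of a peak p: walk outwards on each side, tracking the minimum,
// until a sample strictly higher than x[p] (or the signal edge) is reached;
// the prominence is x[p] minus the higher of the two side minima.  This is
// the standard definition used by signal-processing peak finders.
//
// Returns a list with 0-based peak indices, peak heights and prominences.
// [[Rcpp::export(name = ".findPeaksC")]]
List findPeaksC(NumericVector x) {
    const int n = x.size();
    std::vector<int> idx;
    std::vector<double> height;

    int i = 1;
    while (i < n - 1) {
        if (x[i] > x[i - 1]) {
            // scan over a possible plateau
            int j = i;
            while (j < n - 1 && x[j + 1] == x[i]) ++j;
            if (j < n - 1 && x[j + 1] < x[i]) {
                idx.push_back(i);          // leftmost sample of the plateau
                height.push_back(x[i]);
            }
            i = j + 1;
        } else {
            ++i;
        }
    }

    const int m = (int) idx.size();
    NumericVector prom(m);
    for (int k = 0; k < m; ++k) {
        const int p = idx[k];
        const double h = x[p];
        double lmin = h, rmin = h;
        for (int l = p - 1; l >= 0; --l) {
            if (x[l] > h) break;
            if (x[l] < lmin) lmin = x[l];
        }
        for (int r = p + 1; r < n; ++r) {
            if (x[r] > h) break;
            if (x[r] < rmin) rmin = x[r];
        }
        prom[k] = h - std::max(lmin, rmin);
    }

    return List::create(_["index"] = wrap(idx),
                        _["height"] = wrap(height),
                        _["prominence"] = prom);
}
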