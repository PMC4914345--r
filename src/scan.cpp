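#include <Rcpp.h>
using namespace Rcpp;

// Raw information-weighted score sums for every window of a sequence.
// seq_int codes bases 0..3 = A,C,G,T; 4 = N or other (contributes the
// position minimum). w is the L x 4 weight matrix I(i) * f_i(b); wmin its
// per-position row minimum. Returns n - L + 1 raw sums (empty if n < L).
// [[Rcpp::export]]
NumericVector scan_scores(const IntegerVector& seq_int,
                          const NumericMatrix& w,
                          const NumericVector& wmin) {
    const int L = w.nrow();
    const int n = seq_int.size();
    const int nw = n - L + 1;
    if (nw < 1) return NumericVector(0);
    NumericVector out(nw);
    for (int i = 0; i < nw; ++i) {
        double s = 0.0;
        for (int j = 0; j < L; ++j) {
            const int b = seq_int[i + j];
            s += (b >= 0 && b < 4) ? w(j, b) : wmin[j];
        }
        out[i] = s;
    }
    return out;
}

static bool any_window_hit(const IntegerVector& s, const NumericMatrix& w,
                           const NumericVector& wmin, double cut) {
    const int L = w.nrow();
    const int nw = s.size() - L + 1;
    for (int i = 0; i < nw; ++i) {
        double sum = 0.0;
        for (int j = 0; j < L; ++j) {
            const int b = s[i + j];
            sum += (b >= 0 && b < 4) ? w(j, b) : wmin[j];
        }
        if (sum >= cut) return true;
    }
    return false;
}

// Per-sequence occurrence indicator for one motif over a whole promoter
// set. fwd/rev hold the integer-coded strands; cut is the raw-score cutoff
// corresponding to the normalized threshold. Early-exits on the first hit.
// [[Rcpp::export]]
LogicalVector scan_any_hit(const List& fwd, const List& rev,
                           const NumericMatrix& w, const NumericVector& wmin,
                           double cut, bool both_strands) {
    const int n = fwd.size();
    LogicalVector out(n);
    for (int i = 0; i < n; ++i) {
        const IntegerVector f = fwd[i];
        bool hit = any_window_hit(f, w, wmin, cut);
        if (!hit && both_strands) {
            const IntegerVector r = rev[i];
            hit = any_window_hit(r, w, wmin, cut);
        }
        out[i] = hit;
    }
    return out;
}
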