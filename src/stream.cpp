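#include <Rcpp.h>
using namespace Rcpp;

// Per-sample streaming update over all candidate periods.
//
// For each period w the state holds a ring buffer e of w moving-average
// ensemble means, a running sum of squares P, and a wrap index ind.  One
// input sample advances ind by 1 (mod w), rewrites that single slot with
// c1*old + c2*x, and adjusts P by the difference of squares -- the update
// order (read old, write new, adjust P) matters and is fixed here.
//
// Input state vectors are cloned so the caller's state keeps R value
// semantics.  When emit_every > 0 a spectrum column
// S_w = n(w) * sqrt(max(P_w, 0)) * scale is emitted after every
// emit_every-th sample; negative P from floating-point drift is clamped
// at zero and counted.
// [[Rcpp::export]]
List stream_advance_cpp(NumericVector e_in, NumericVector P_in,
                        IntegerVector ind_in, NumericVector c1,
                        NumericVector c2, NumericVector nseg,
                        IntegerVector w, IntegerVector off,
                        NumericVector x, double k0, double scale,
                        int emit_every) {
  NumericVector e = clone(e_in);
  NumericVector P = clone(P_in);
  IntegerVector ind = clone(ind_in);
  const int nw = w.size();
  const int L = x.size();
  const int nemit = emit_every > 0 ? L / emit_every : 0;
  NumericMatrix S(nw, nemit > 0 ? nemit : 0);
  IntegerVector ek(nemit > 0 ? nemit : 0);
  double *ep = REAL(e);
  double *Pp = REAL(P);
  int *indp = INTEGER(ind);
  const double *c1p = REAL(c1), *c2p = REAL(c2), *np = REAL(nseg);
  const int *wp = INTEGER(w), *offp = INTEGER(off);
  int emi = 0, clamped = 0;
  for (int t = 0; t < L; ++t) {
    const double xt = x[t];
    if (!R_finite(xt)) {
      stop("stream corrupt: non-finite sample at k = %d",
           static_cast<int>(k0) + t + 1);
    }
    for (int j = 0; j < nw; ++j) {
      int id = indp[j] + 1;
      if (id >= wp[j]) id = 0;
      indp[j] = id;
      double *slot = ep + offp[j] + id;
      const double eold = *slot;
      const double enew = c1p[j] * eold + c2p[j] * xt;
      *slot = enew;
      Pp[j] += enew * enew - eold * eold;
    }
    if (nemit > 0 && (t + 1) % emit_every == 0) {
      for (int j = 0; j < nw; ++j) {
        double p = Pp[j];
        if (p < 0) { p = 0; ++clamped; }
        S(j, emi) = np[j] * std::sqrt(p) * scale;
      }
      ek[emi] = static_cast<int>(k0) + t + 1;
      ++emi;
    }
  }
  return List::create(_["e"] = e, _["P"] = P, _["ind"] = ind,
                      _["k"] = k0 + L, _["S"] = S, _["emit_k"] = ek,
                      _["clamped"] = clamped);
}
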