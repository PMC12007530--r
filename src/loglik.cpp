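#include <Rcpp.h>
using namespace Rcpp;

// Per-subject sums of the choice log-likelihood for a full subject-parameter
// matrix. Mirrors the R-level .ll_core() arithmetic (clipped exponents,
// overflow-safe logistic); used by the sampler's hot loop. Columns of th:
// log_k, s_ero_k, beta, s_ero_beta, omega (or logit omega), s_ero_omega.

static inline double clip30(double x) {
  if (x > 30.0) return 30.0;
  if (x < -30.0) return -30.0;
  return x;
}

// [[Rcpp::export(name = ".cohort_loglik_sums")]]
NumericVector cohort_loglik_sums(NumericMatrix th, IntegerVector subj,
                                 IntegerVector iero, NumericVector ll,
                                 NumericVector d, IntegerVector y,
                                 double ss, int S, bool offset,
                                 bool logit_link) {
  int N = ll.size();
  NumericVector out(S);
  for (int i = 0; i < N; i++) {
    int s = subj[i] - 1;
    int ie = iero[i];
    double k = exp(clip30(th(s, 0) + ie * th(s, 1)));
    double sv = ll[i] / (1.0 + k * d[i]);
    if (offset) {
      double om;
      if (logit_link) {
        double lo = th(s, 4) + ie * th(s, 5);
        om = 1.0 / (1.0 + exp(-lo));
      } else {
        om = th(s, 4) + ie * th(s, 5);
        if (om <= 0.0 || om > 1.0) {
          out[s] = R_NegInf;
          continue;
        }
      }
      sv *= om;
    }
    double x = clip30((th(s, 2) + ie * th(s, 3)) * (sv - ss));
    double xs = (y[i] == 1) ? -x : x;
    out[s] += -log1p(exp(xs));
  }
  return out;
}
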