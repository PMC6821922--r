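#include <Rcpp.h>
using namespace Rcpp;

// Reserve update shared by both branches: when S + PS <= LT the costs are
// zero and the expression collapses to pure accumulation.
static inline double rbm_next(double S, double PS, double Cf, double Ca) {
  return S + PS - Cf - Ca;
}

//' @noRd
// [[Rcpp::export(name = ".cppReducedOrbit")]]
NumericVector cpp_reduced_orbit(double S0, int nTransient, int nRecord,
                                double RC, double beta, double P0, double LT) {
  double S = S0;
  const double Pb = std::pow(P0, beta);
  NumericVector out(nRecord);
  for (int t = 0; t < nTransient + nRecord; ++t) {
    double acc = S + P0;
    if (acc <= LT) {
      S = acc;
    } else {
      double Cf = acc - LT;
      S = LT - RC * std::pow(Cf, beta + 1.0) / Pb;
    }
    if (!std::isfinite(S))
      stop("reduced map diverged (non-finite reserve) at iteration %d", t + 1);
    if (t >= nTransient) out[t - nTransient] = S;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cppSimulateGCM")]]
List cpp_simulate_gcm(NumericVector S0, NumericVector sigma,
                      NumericMatrix delta, double RC, double beta,
                      double P0, double LT, double eI, double eC,
                      int nTransient) {
  const int N = S0.size();
  const int Ttot = sigma.size();
  const int nRecord = Ttot - nTransient;
  if (delta.nrow() != Ttot || delta.ncol() != N)
    stop("noise matrix must be (transient + record) years by N trees");
  if (nRecord < 1) stop("no recorded years");

  NumericVector S = clone(S0);
  NumericVector PS(N), Cf(N), Y(N);
  NumericMatrix rS(N, nRecord), rCf(N, nRecord), rCa(N, nRecord),
      rCs(N, nRecord), rY(N, nRecord);

  for (int t = 0; t < Ttot; ++t) {
    double sumCf = 0.0;
    for (int i = 0; i < N; ++i) {
      PS[i] = P0 * (1.0 + eC * sigma[t]) * (1.0 + eI * delta(t, i));
      double ex = S[i] + PS[i] - LT;
      Cf[i] = ex > 0.0 ? ex : 0.0;
      sumCf += Cf[i];
    }
    for (int i = 0; i < N; ++i) {
      // outcross pollen availability: mean flowering effort of the others
      double y;
      if (beta == 0.0) {
        y = 1.0;
      } else {
        double others = (sumCf - Cf[i]) / ((N - 1) * P0);
        y = std::pow(others, beta);
      }
      Y[i] = y;
      double Ca = RC * Cf[i] * y;
      double Snew = rbm_next(S[i], PS[i], Cf[i], Ca);
      if (!std::isfinite(Snew))
        stop("simulation diverged (non-finite reserve) at year %d, tree %d",
             t + 1, i + 1);
      if (t >= nTransient) {
        int k = t - nTransient;
        rS(i, k) = Snew;
        rCf(i, k) = Cf[i];
        rCa(i, k) = Ca;
        rCs(i, k) = Cf[i] * y;
        rY(i, k) = y;
      }
      S[i] = Snew;
    }
  }
  return List::create(_["S"] = rS, _["Cf"] = rCf, _["Ca"] = rCa,
                      _["Cs"] = rCs, _["Y"] = rY);
}
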