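#include <Rcpp.h>
using namespace Rcpp;

// Local-level (random-walk + observation noise) Kalman recursions on an
// irregular time grid. The state innovation variance is scaled by the
// inter-observation interval: x_t = x_{t-dt} + eta, eta ~ N(0, q * dt),
// y_t = x_t + eps, eps ~ N(0, r). NA observations are propagated without
// an update step so the same code serves filtering over gaps.

// [[Rcpp::export]]
double ll_loglik(NumericVector y, NumericVector dt, double q, double r) {
  int n = y.size();
  if (n < 2) return NA_REAL;
  double a = y[0];
  double P = 1e7;  // diffuse initial level
  double ll = 0.0;
  int used = 0;
  for (int i = 1; i < n; ++i) {
    double Ppred = P + q * dt[i];
    double apred = a;
    if (NumericVector::is_na(y[i])) {
      a = apred;
      P = Ppred;
      continue;
    }
    double F = Ppred + r;
    double v = y[i] - apred;
    ll += -0.5 * (std::log(2.0 * M_PI) + std::log(F) + v * v / F);
    double K = Ppred / F;
    a = apred + K * v;
    P = (1.0 - K) * Ppred;
    ++used;
  }
  if (used == 0) return NA_REAL;
  return ll;
}

// Fixed-interval (RTS) smoother. Returns smoothed means and variances at
// every grid position, including NA (missing) ones.
// [[Rcpp::export]]
List ll_smooth(NumericVector y, NumericVector dt, double q, double r) {
  int n = y.size();
  NumericVector apred(n), Ppred(n), afilt(n), Pfilt(n);
  double a = NA_REAL, P = 1e7;
  bool init = false;
  for (int i = 0; i < n; ++i) {
    double Pp, ap;
    if (!init) {
      // before the first observation the level is diffuse
      ap = NumericVector::is_na(y[i]) ? 0.0 : y[i];
      Pp = 1e7;
    } else {
      ap = a;
      Pp = P + q * dt[i];
    }
    apred[i] = ap; Ppred[i] = Pp;
    if (NumericVector::is_na(y[i])) {
      a = ap; P = Pp;
    } else {
      if (!init) {
        a = y[i]; P = r;  // first observation: posterior N(y, r) under diffuse prior
        init = true;
      } else {
        double F = Pp + r;
        double K = Pp / F;
        a = ap + K * (y[i] - ap);
        P = (1.0 - K) * Pp;
      }
    }
    afilt[i] = a; Pfilt[i] = P;
  }
  NumericVector asm_(n), Psm(n);
  asm_[n - 1] = afilt[n - 1];
  Psm[n - 1] = Pfilt[n - 1];
  for (int i = n - 2; i >= 0; --i) {
    double Pp = Pfilt[i] + q * dt[i + 1];  // P_{i+1|i}
    double C = (Pp > 0) ? Pfilt[i] / Pp : 0.0;
    asm_[i] = afilt[i] + C * (asm_[i + 1] - afilt[i]);
    Psm[i] = Pfilt[i] + C * C * (Psm[i + 1] - Pp);
    if (Psm[i] < 0) Psm[i] = 0;
  }
  return List::create(_["mean"] = asm_, _["var"] = Psm);
}
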