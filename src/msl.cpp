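#include <Rcpp.h>
using namespace Rcpp;

// Simulated log-likelihood kernel: per observation, average the count
// probability over H draws of the random-parameter linear predictor and
// accumulate the log. devsum holds the draw-specific additions to the fixed
// linear predictor; lgy = lgamma(y + 1) is precomputed. model: 0 = Poisson,
// 1 = NB2, 2 = generalized Poisson (Famoye restricted form).
// [[Rcpp::export]]
double msl_loglik_cpp(NumericVector eta0, NumericMatrix devsum,
                      NumericVector y, double phi, int model,
                      NumericVector lgy) {
  const int n = eta0.size();
  const int H = devsum.ncol();
  // NB with phi below ~1e-9: lgamma(r + y) - lgamma(r) cancels in double
  // precision; fall back to the Poisson limit
  if (model == 1 && phi < 1e-9) model = 0;
  const double r = (model == 1) ? 1.0 / phi : 0.0;
  const double lgr = (model == 1) ? R::lgammafn(r) : 0.0;
  const double logr = (model == 1) ? log(r) : 0.0;
  std::vector<double> lp(H);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    const double yi = y[i], lgyi = lgy[i], e0 = eta0[i];
    double mx = R_NegInf;
    for (int h = 0; h < H; ++h) {
      double lam = exp(e0 + devsum(i, h));
      if (lam < 1e-10) lam = 1e-10; else if (lam > 1e10) lam = 1e10;
      const double llam = log(lam);
      double v;
      if (model == 0) {
        v = yi * llam - lam - lgyi;
      } else if (model == 1) {
        v = R::lgammafn(r + yi) - lgr - lgyi +
            r * (logr - log(r + lam)) + yi * (llam - log(r + lam));
      } else {
        v = yi * (llam - log1p(phi * lam)) + (yi - 1.0) * log1p(phi * yi) -
            lgyi - lam * (1.0 + phi * yi) / (1.0 + phi * lam);
      }
      lp[h] = v;
      if (v > mx) mx = v;
    }
    if (!R_finite(mx)) { total += mx; continue; }
    double s = 0.0;
    for (int h = 0; h < H; ++h) s += exp(lp[h] - mx);
    total += mx + log(s / H);
  }
  return total;
}

// Simulated log-likelihood with analytic score. For each observation the
// gradient is the posterior-draw-weighted average of per-draw score terms:
//   d lnL_i / d theta = sum_h w_ih d logP_ih / d theta,  w_ih ~ P_ih.
// xb holds, per random dimension, the n x H matrix d eta_ih / d omega_d
// (factor column folded in). Returns the per-observation pieces needed to
// assemble gradients and OPG scores in R: Eg (d/d eta), Egz per dimension
// (d/d omega_d), Ephi (d/d log phi) and the per-observation log-likelihood.
// [[Rcpp::export]]
List msl_score_cpp(NumericVector eta0, NumericMatrix devsum, NumericVector y,
                   double phi, int model, NumericVector lgy, List xb) {
  const int n = eta0.size();
  const int H = devsum.ncol();
  const int D = xb.size();
  if (model == 1 && phi < 1e-9) model = 0;
  const double r = (model == 1) ? 1.0 / phi : 0.0;
  const double lgr = (model == 1) ? R::lgammafn(r) : 0.0;
  const double logr = (model == 1) ? log(r) : 0.0;
  const double dgr = (model == 1) ? R::digamma(r) : 0.0;

  std::vector<NumericMatrix> xbm;
  for (int d = 0; d < D; ++d) xbm.push_back(as<NumericMatrix>(xb[d]));

  NumericVector ll(n), Eg(n), Ephi(n);
  NumericMatrix Egz(n, D);
  std::vector<double> lp(H), gg(H), gp(H);

  for (int i = 0; i < n; ++i) {
    const double yi = y[i], lgyi = lgy[i], e0 = eta0[i];
    double mx = R_NegInf;
    for (int h = 0; h < H; ++h) {
      double lam = exp(e0 + devsum(i, h));
      if (lam < 1e-10) lam = 1e-10; else if (lam > 1e10) lam = 1e10;
      const double llam = log(lam);
      double v, g, p = 0.0;
      if (model == 0) {
        v = yi * llam - lam - lgyi;
        g = yi - lam;
      } else if (model == 1) {
        v = R::lgammafn(r + yi) - lgr - lgyi +
            r * (logr - log(r + lam)) + yi * (llam - log(r + lam));
        g = yi - lam * (r + yi) / (r + lam);
        // d logP / d log(phi) = -(1/phi) d logP / d r
        double dr = R::digamma(r + yi) - dgr + logr + 1.0 - log(r + lam) -
                    (r + yi) / (r + lam);
        p = -dr / phi;  // (-dr/phi^2) times dphi/dlphi = phi
      } else {
        const double a = 1.0 + phi * lam, b = 1.0 + phi * yi;
        v = yi * (llam - log(a)) + (yi - 1.0) * log(b) - lgyi - lam * b / a;
        g = yi - yi * phi * lam / a - lam * b / (a * a);
        double dphi = -yi * lam / a + (yi - 1.0) * yi / b -
                      lam * (yi * a - lam * b) / (a * a);
        p = phi * dphi;
      }
      lp[h] = v; gg[h] = g; gp[h] = p;
      if (v > mx) mx = v;
    }
    if (!R_finite(mx)) {
      ll[i] = mx; Eg[i] = 0; Ephi[i] = 0;
      for (int d = 0; d < D; ++d) Egz(i, d) = 0;
      continue;
    }
    double s = 0.0, sg = 0.0, sp = 0.0;
    std::vector<double> sgz(D, 0.0);
    for (int h = 0; h < H; ++h) {
      const double w = exp(lp[h] - mx);
      s += w; sg += w * gg[h]; sp += w * gp[h];
      for (int d = 0; d < D; ++d) sgz[d] += w * gg[h] * xbm[d](i, h);
    }
    ll[i] = mx + log(s / H);
    Eg[i] = sg / s;
    Ephi[i] = sp / s;
    for (int d = 0; d < D; ++d) Egz(i, d) = sgz[d] / s;
  }
  return List::create(_["ll"] = ll, _["Eg"] = Eg, _["Egz"] = Egz,
                      _["Ephi"] = Ephi);
}
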