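#include <Rcpp.h>
using namespace Rcpp;

// Continuous-time correlated random walk (integrated Ornstein-Uhlenbeck
// velocity) Kalman filter + Rauch-Tung-Striebel smoother, one axis at a time.
// State per axis: (position, velocity). Exact discrete transitions over the
// (possibly irregular) gaps between supplied times. Observations are the
// positions with per-time Gaussian SD; NA observations are prediction-only
// steps. Position prior is diffuse at the first time; velocity prior is the
// stationary OU distribution.
//
// Returns the marginal log-likelihood (over observed steps), smoothed state
// means, smoothed and filtered position variances, and standardised one-step
// innovations at observation times.
// [[Rcpp::export(name = ".ctcrw_kalman_cpp")]]
List ctcrw_kalman(NumericVector t, NumericVector y, NumericVector obs_sd,
                  double beta, double sigma, bool smooth = true) {
  int n = t.size();
  double q = sigma * sigma;
  double vstat = q / (2.0 * beta);

  // storage for smoother
  std::vector<double> xp(2 * n), Pp(4 * n);  // predicted
  std::vector<double> xf(2 * n), Pf(4 * n);  // filtered
  NumericVector innov(n), innov_sd(n);

  int f0 = -1;
  for (int i = 0; i < n && f0 < 0; ++i) if (!ISNAN(y[i])) f0 = i;
  if (f0 < 0) stop("no observations");

  // position prior: conditioned on the first observation (the equivalent of
  // a diffuse prior updated by it, without the 1e12-scale cancellation in
  // the smoother); velocity prior is stationary. The first observation
  // therefore contributes no likelihood term, identically across parameters.
  double mx = y[f0], mv = 0.0;
  double P00 = obs_sd[f0] * obs_sd[f0], P01 = 0.0, P11 = vstat;
  double ll = 0.0;

  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      double dt = t[i] - t[i - 1];
      if (dt < 0) stop("times must be non-decreasing");
      double a = std::exp(-beta * dt);
      double phi01 = (1.0 - a) / beta;
      // Q entries
      double Qvv = q * (1.0 - a * a) / (2.0 * beta);
      double Qxv = q * (1.0 - a) * (1.0 - a) / (2.0 * beta * beta);
      double Qxx = q / (beta * beta) *
        (dt - 2.0 * (1.0 - a) / beta + (1.0 - a * a) / (2.0 * beta));
      // predict mean
      double nmx = mx + phi01 * mv;
      double nmv = a * mv;
      // predict cov: P' = F P F^T + Q, F = [[1, phi01], [0, a]]
      double F00 = 1.0, F01 = phi01, F10 = 0.0, F11 = a;
      double A00 = F00 * P00 + F01 * P01;
      double A01 = F00 * P01 + F01 * P11;
      double A10 = F10 * P00 + F11 * P01;
      double A11 = F10 * P01 + F11 * P11;
      double nP00 = A00 * F00 + A01 * F01 + Qxx;
      double nP01 = A00 * F10 + A01 * F11 + Qxv;
      double nP11 = A10 * F10 + A11 * F11 + Qvv;
      mx = nmx; mv = nmv; P00 = nP00; P01 = nP01; P11 = nP11;
    }
    xp[2 * i] = mx; xp[2 * i + 1] = mv;
    Pp[4 * i] = P00; Pp[4 * i + 1] = P01; Pp[4 * i + 2] = P01; Pp[4 * i + 3] = P11;

    if (!ISNAN(y[i]) && i != f0) {
      double r = obs_sd[i] * obs_sd[i];
      double S = P00 + r;
      double e = y[i] - mx;
      ll += -0.5 * (std::log(2.0 * M_PI * S) + e * e / S);
      innov[i] = e / std::sqrt(S);
      innov_sd[i] = std::sqrt(S);
      double K0 = P00 / S, K1 = P01 / S;
      mx += K0 * e; mv += K1 * e;
      double nP00 = (1.0 - K0) * P00;
      double nP01 = (1.0 - K0) * P01;
      double nP11 = P11 - K1 * P01;
      P00 = nP00; P01 = nP01; P11 = nP11;
    } else {
      innov[i] = NA_REAL; innov_sd[i] = NA_REAL;
    }
    xf[2 * i] = mx; xf[2 * i + 1] = mv;
    Pf[4 * i] = P00; Pf[4 * i + 1] = P01; Pf[4 * i + 2] = P01; Pf[4 * i + 3] = P11;
  }

  NumericVector sm_x(n), sm_v(n), sm_var(n), f_var(n);
  if (smooth) {
    // RTS backward pass
    double sx = xf[2 * (n - 1)], sv = xf[2 * (n - 1) + 1];
    double S00 = Pf[4 * (n - 1)], S01 = Pf[4 * (n - 1) + 1], S11 = Pf[4 * (n - 1) + 3];
    sm_x[n - 1] = sx; sm_v[n - 1] = sv; sm_var[n - 1] = S00;
    for (int i = n - 2; i >= 0; --i) {
      double dt = t[i + 1] - t[i];
      double a = std::exp(-beta * dt);
      double phi01 = (1.0 - a) / beta;
      double F00 = 1.0, F01 = phi01, F10 = 0.0, F11 = a;
      double p00 = Pf[4 * i], p01 = Pf[4 * i + 1], p11 = Pf[4 * i + 3];
      // C = Pf_i F^T
      double C00 = p00 * F00 + p01 * F01;
      double C01 = p00 * F10 + p01 * F11;
      double C10 = p01 * F00 + p11 * F01;
      double C11 = p01 * F10 + p11 * F11;
      // G = C (Pp_{i+1})^{-1}
      double q00 = Pp[4 * (i + 1)], q01 = Pp[4 * (i + 1) + 1], q11 = Pp[4 * (i + 1) + 3];
      double det = q00 * q11 - q01 * q01;
      if (det <= 0) det = 1e-300;
      double i00 = q11 / det, i01 = -q01 / det, i11 = q00 / det;
      double G00 = C00 * i00 + C01 * i01;
      double G01 = C00 * i01 + C01 * i11;
      double G10 = C10 * i00 + C11 * i01;
      double G11 = C10 * i01 + C11 * i11;
      // smoothed mean
      double dx = sx - xp[2 * (i + 1)];
      double dv = sv - xp[2 * (i + 1) + 1];
      double nsx = xf[2 * i] + G00 * dx + G01 * dv;
      double nsv = xf[2 * i + 1] + G10 * dx + G11 * dv;
      // smoothed cov: Pf + G (Ps_{i+1} - Pp_{i+1}) G^T
      double D00 = S00 - q00, D01 = S01 - q01, D11 = S11 - q11;
      double T00 = G00 * D00 + G01 * D01;
      double T01 = G00 * D01 + G01 * D11;
      double T10 = G10 * D00 + G11 * D01;
      double T11 = G10 * D01 + G11 * D11;
      double nS00 = p00 + T00 * G00 + T01 * G01;
      double nS01 = p01 + T00 * G10 + T01 * G11;
      double nS11 = p11 + T10 * G10 + T11 * G11;
      sx = nsx; sv = nsv; S00 = nS00; S01 = nS01; S11 = nS11;
      sm_x[i] = sx; sm_v[i] = sv; sm_var[i] = S00;
    }
    for (int i = 0; i < n; ++i) f_var[i] = Pf[4 * i];
  }

  return List::create(_["loglik"] = ll, _["x"] = sm_x, _["v"] = sm_v,
                      _["var"] = sm_var, _["filter_var"] = f_var,
                      _["innovation"] = innov, _["innovation_sd"] = innov_sd);
}
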