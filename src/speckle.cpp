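#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Assemble the speckle intensity time series from per-photon amplitudes,
// initial phases, static optical paths and Brownian phase-driver standard
// deviations, for a discretized source spectrum.
//
// For photon n the unit-wavevector-scaled path-difference process X_n(t)
// is a Wiener process with per-bin increments N(0, sigma_step[n]^2),
// X_n(0) = 0 (the sum over scattering events of q-hat . displacement is a
// sum of independent Gaussian increments, so it can be generated directly).
// The field of spectral line i is
//   E_i(t) = sum_n  s_lines[i] * amp[n] * exp(i (phi0[n] + k_i (L[n] - X_n(t))))
// and I(t) = sum_i |E_i(t)|^2 (incoherent sum over lines: different optical
// frequencies do not interfere over the measurement time).
//
// [[Rcpp::export]]
NumericVector synth_intensity_cpp(NumericVector amp, NumericVector phi0,
                                  NumericVector L, NumericVector sigma_step,
                                  NumericVector k_lines, NumericVector s_lines,
                                  int n_bins) {
  const int n_ph = amp.size();
  const int n_li = k_lines.size();
  std::vector<double> re((size_t)n_li * n_bins, 0.0);
  std::vector<double> im((size_t)n_li * n_bins, 0.0);

  for (int n = 0; n < n_ph; n++) {
    double X = 0.0;
    const double a = amp[n], p0 = phi0[n], Ln = L[n], ss = sigma_step[n];
    for (int t = 0; t < n_bins; t++) {
      if (t > 0 && ss > 0.0) X += ss * norm_rand();
      const double base = Ln - X;
      for (int i = 0; i < n_li; i++) {
        const double th = p0 + k_lines[i] * base;
        const double w = a * s_lines[i];
        re[(size_t)i * n_bins + t] += w * std::cos(th);
        im[(size_t)i * n_bins + t] += w * std::sin(th);
      }
    }
  }

  NumericVector I(n_bins);
  for (int t = 0; t < n_bins; t++) {
    double s = 0.0;
    for (int i = 0; i < n_li; i++) {
      const double r = re[(size_t)i * n_bins + t], m = im[(size_t)i * n_bins + t];
      s += r * r + m * m;
    }
    I[t] = s;
  }
  return I;
}

// Same field assembly but from a pre-computed phase-driver matrix X
// (n_photons x n_bins, in mm), used for the explicit per-scatterer mode.
// [[Rcpp::export]]
NumericVector synth_intensity_from_X_cpp(NumericVector amp, NumericVector phi0,
                                         NumericVector L, NumericMatrix X,
                                         NumericVector k_lines, NumericVector s_lines) {
  const int n_ph = amp.size();
  const int n_li = k_lines.size();
  const int n_bins = X.ncol();
  NumericVector I(n_bins);
  std::vector<double> re(n_li), im(n_li);
  for (int t = 0; t < n_bins; t++) {
    std::fill(re.begin(), re.end(), 0.0);
    std::fill(im.begin(), im.end(), 0.0);
    for (int n = 0; n < n_ph; n++) {
      const double base = L[n] - X(n, t);
      for (int i = 0; i < n_li; i++) {
        const double th = phi0[n] + k_lines[i] * base;
        re[i] += amp[n] * s_lines[i] * std::cos(th);
        im[i] += amp[n] * s_lines[i] * std::sin(th);
      }
    }
    double s = 0.0;
    for (int i = 0; i < n_li; i++) s += re[i] * re[i] + im[i] * im[i];
    I[t] = s;
  }
  return I;
}

// Lagged-product autocorrelation estimator
// g2(m) = mean(x[t] * x[t+m]) / mean(x)^2 over the available pairs.
// [[Rcpp::export]]
List g2_lagged_cpp(NumericVector x, IntegerVector lags) {
  const int n = x.size();
  const double mu = mean(x);
  NumericVector g2(lags.size());
  IntegerVector npair(lags.size());
  for (int j = 0; j < lags.size(); j++) {
    const int m = lags[j];
    double s = 0.0;
    const int np = n - m;
    for (int t = 0; t < np; t++) s += x[t] * x[t + m];
    g2[j] = (s / np) / (mu * mu);
    npair[j] = np;
  }
  return List::create(_["g2"] = g2, _["npairs"] = npair);
}
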