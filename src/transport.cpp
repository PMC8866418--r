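#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Unpolarized Fresnel reflectance for a photon hitting the z=0 surface from
// inside (index n_in) toward outside (n_out), incidence cosine cti >= 0.
// Returns 1 for total internal reflection.
static inline double fresnel_R(double cti, double n_in, double n_out) {
  const double nr = n_in / n_out;
  const double sti2 = 1.0 - cti * cti;
  const double stt2 = nr * nr * sti2;
  if (stt2 >= 1.0) return 1.0;
  const double ctt = std::sqrt(1.0 - stt2);
  const double rs = (nr * cti - ctt) / (nr * cti + ctt);
  const double rp = (nr * ctt - cti) / (nr * ctt + cti);
  return 0.5 * (rs * rs + rp * rp);
}

// Photon-migration Monte Carlo in a layered semi-infinite medium with
// isotropic scattering (g = 0). Layers are stacked in z; boundaries_cum
// holds the cumulative lower-layer boundaries (length n_layers - 1; the
// last layer is semi-infinite). Absorption is NOT applied here: detected
// photons are later weighted by exp(-sum(mu_a * L)).
//
// boundary_mode: 0 = index-mismatched Fresnel (reflect with probability
// R(theta), escape otherwise), 1 = absorbing (photon escapes at first
// surface contact).
// tally_mode: 0 = direct (record photons escaping inside the detector
// disc, weight 1), 1 = ring (record every escape whose exit radius falls
// within [rho - a, rho + a], weighted by the azimuthal overlap of that
// radius with the disc; exact in expectation by rotational symmetry).
//
// [[Rcpp::export]]
List mc_transport_cpp(NumericVector mu_s, NumericVector boundaries_cum,
                      double rho, double det_radius,
                      double n_in, double n_out, int boundary_mode,
                      double n_launch, double max_path, int tally_mode) {
  const int n_layers = mu_s.size();
  std::vector<std::vector<int> > ns_out(n_layers);
  std::vector<std::vector<double> > l_out(n_layers);
  std::vector<double> exit_x, exit_y, wgt;

  const double two_pi = 2.0 * M_PI;
  const long n_launch_l = (long)(n_launch + 0.5);

  for (long ph = 0; ph < n_launch_l; ph++) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    int layer = 0;
    double Ltot = 0.0;
    std::vector<int> ns(n_layers, 0);
    std::vector<double> lpath(n_layers, 0.0);
    bool alive = true;

    // dimensionless step, consumed across layer boundaries
    double tau_step = -std::log(1.0 - unif_rand());

    while (alive) {
      // distance to the next z-boundary along the current direction
      double d_bound = R_PosInf;
      int bound_kind = -1; // 0 = surface z=0, 1 = interface below, 2 = interface above
      if (uz < 0.0) {
        double zlow = (layer == 0) ? 0.0 : boundaries_cum[layer - 1];
        d_bound = (zlow - z) / uz;
        bound_kind = (layer == 0) ? 0 : 2;
      } else if (uz > 0.0 && layer < n_layers - 1) {
        d_bound = (boundaries_cum[layer] - z) / uz;
        bound_kind = 1;
      }
      const double d_free = tau_step / mu_s[layer];

      if (d_free < d_bound) {
        // scattering event inside the current layer
        x += ux * d_free; y += uy * d_free; z += uz * d_free;
        lpath[layer] += d_free; Ltot += d_free;
        if (Ltot > max_path) break;
        ns[layer] += 1;
        const double ct = 2.0 * unif_rand() - 1.0;
        const double st = std::sqrt(1.0 - ct * ct);
        const double phi = two_pi * unif_rand();
        ux = st * std::cos(phi); uy = st * std::sin(phi); uz = ct;
        tau_step = -std::log(1.0 - unif_rand());
      } else {
        // advance to the boundary
        x += ux * d_bound; y += uy * d_bound; z += uz * d_bound;
        lpath[layer] += d_bound; Ltot += d_bound;
        tau_step -= d_bound * mu_s[layer];
        if (Ltot > max_path) break;
        if (bound_kind == 1) { layer += 1; z = boundaries_cum[layer - 1]; continue; }
        if (bound_kind == 2) { layer -= 1; z = boundaries_cum[layer]; continue; }
        // surface z = 0
        z = 0.0;
        const double cti = -uz;
        double R = (boundary_mode == 0) ? fresnel_R(cti, n_in, n_out) : 0.0;
        if (R > 0.0 && unif_rand() < R) { uz = -uz; continue; }
        // photon escapes at (x, y)
        if (tally_mode == 0) {
          const double dx = x - rho;
          if (dx * dx + y * y < det_radius * det_radius) {
            for (int k = 0; k < n_layers; k++) { ns_out[k].push_back(ns[k]); l_out[k].push_back(lpath[k]); }
            exit_x.push_back(x); exit_y.push_back(y); wgt.push_back(1.0);
          }
        } else {
          const double r = std::sqrt(x * x + y * y);
          double w = 0.0;
          if (r + rho < det_radius) {
            w = 1.0;
          } else if (std::fabs(r - rho) < det_radius && r > 0.0) {
            double arg = (r * r + rho * rho - det_radius * det_radius) / (2.0 * r * rho);
            if (arg > 1.0) arg = 1.0; else if (arg < -1.0) arg = -1.0;
            w = std::acos(arg) / M_PI;
          }
          if (w > 0.0) {
            for (int k = 0; k < n_layers; k++) { ns_out[k].push_back(ns[k]); l_out[k].push_back(lpath[k]); }
            exit_x.push_back(x); exit_y.push_back(y); wgt.push_back(w);
          }
        }
        alive = false;
      }
    }
  }

  List cols;
  CharacterVector nm;
  for (int k = 0; k < n_layers; k++) {
    cols.push_back(IntegerVector(ns_out[k].begin(), ns_out[k].end()));
    nm.push_back("ns_" + std::to_string(k + 1));
  }
  for (int k = 0; k < n_layers; k++) {
    cols.push_back(NumericVector(l_out[k].begin(), l_out[k].end()));
    nm.push_back("path_" + std::to_string(k + 1));
  }
  cols.push_back(NumericVector(exit_x.begin(), exit_x.end())); nm.push_back("exit_x");
  cols.push_back(NumericVector(exit_y.begin(), exit_y.end())); nm.push_back("exit_y");
  cols.push_back(NumericVector(wgt.begin(), wgt.end())); nm.push_back("weight");
  cols.attr("names") = nm;
  return cols;
}
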