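#' Semi-infinite medium parameters for the analytic reference models
#'
#' Collects the optical and dynamic parameters of a homogeneous
#' semi-infinite medium and the derived quantities used by the
#' closed-form models: `z0 = 1/mu_s'`, the photon diffusion length
#' `D = 1/(3 (mu_a + mu_s'))` (mm), the extrapolated-boundary distance
#' `zb = 2 D (1 + Reff) / (1 - Reff)`, the image-source distances
#' `z-^2 = z0^2 + rho^2`, `z+^2 = (z0 + 2 zb)^2 + rho^2`, and the source
#' and mirror distances `r1`, `r2` entering the field autocorrelation.
#'
#' For the field autocorrelation the boundary distance is
#' `(5/3) / mu_s'` (the dimensionally consistent form of the `5/3`
#' extrapolation factor; `zb_convention = "printed"` keeps the literal
#' `(5/3) * mu_s'`, identical when `mu_s' = 1`).
#'
#' @param rho source-detector separation, mm.
#' @param mu_s_prime reduced scattering coefficient, 1/mm.
#' @param mu_a absorption coefficient, 1/mm.
#' @param lambda0 vacuum wavelength, nm (`k0 = 2 pi / lambda0`).
#' @param DB Brownian diffusion coefficient, mm^2/s.
#' @param refractive_index tissue index (sets `v = c / n`).
#' @param Reff effective boundary reflectivity (0.493 for tissue-air at
#'   n = 1.33).
#' @param zb_convention `"dimensional"` or `"printed"` (field model only).
#' @return A `semi_infinite_params` object.
#' @export
semi_infinite_params <- function(rho, mu_s_prime = 1, mu_a = 0.01,
                                 lambda0 = 800, DB = 1e-6,
                                 refractive_index = 1.33, Reff = 0.493,
                                 zb_convention = c("dimensional", "printed")) {
  zb_convention <- match.arg(zb_convention)
  z0 <- 1 / mu_s_prime
  D <- 1 / (3 * (mu_a + mu_s_prime))
  zb <- 2 * D * (1 + Reff) / (1 - Reff)
  zb_g1 <- if (zb_convention == "dimensional") (5 / 3) / mu_s_prime
           else (5 / 3) * mu_s_prime
  structure(list(rho = rho, mu_s_prime = mu_s_prime, mu_a = mu_a,
                 lambda0 = lambda0, k0 = 2 * pi / (lambda0 * 1e-6),
                 DB = DB, refractive_index = refractive_index,
                 v = C_MM_PER_NS / refractive_index * 1e9,  # mm/s
                 Reff = Reff, z0 = z0, D = D, zb = zb, zb_g1 = zb_g1,
                 r1 = sqrt(rho^2 + z0^2),
                 r2 = sqrt(rho^2 + (z0 + 2 * zb_g1)^2),
                 zminus2 = z0^2 + rho^2,
                 zplus2 = (z0 + 2 * zb)^2 + rho^2),
            class = "semi_infinite_params")
}

#' Normalized field autocorrelation of a semi-infinite medium
#'
#' Evaluates the correlation-diffusion Green-function solution
#' `g1(rho, tau) propto exp(-K r1)/r1 - exp(-K r2)/r2` with
#' `K^2 = 3 mu_a mu_s' + 6 mu_s'^2 k0^2 DB tau`, normalized so
#' `g1(rho, 0) = 1`.
#'
#' @param params a [semi_infinite_params()].
#' @param tau lag times, s (>= 0).
#' @return Numeric vector of `g1` values.
#' @export
g1_semi_infinite <- function(params, tau) {
  stopifnot(all(tau >= 0))
  val <- function(tt) {
    K <- sqrt(3 * params$mu_a * params$mu_s_prime +
                6 * params$mu_s_prime^2 * params$k0^2 * params$DB * tt)
    exp(-K * params$r1) / params$r1 - exp(-K * params$r2) / params$r2
  }
  val(tau) / val(0)
}

#' Pathlength-resolved field autocorrelation
#'
#' `g1(L, tau) = exp(-2 mu_s' DB k0^2 L tau)`: a photon of pathlength `L`
#' undergoes on average `mu_s' L` isotropic scattering events, each
#' contributing mean squared momentum transfer `2 k0^2` times the mean
#' squared scatterer displacement `6 DB tau / 3` per transfer direction.
#'
#' @param L pathlength, mm (>= 0).
#' @param tau lag, s (>= 0).
#' @param mu_s_prime reduced scattering coefficient, 1/mm.
#' @param DB Brownian diffusion coefficient, mm^2/s.
#' @param k0 central wavevector, 1/mm.
#' @return Numeric `g1` values.
#' @export
g1_pathlength <- function(L, tau, mu_s_prime, DB, k0) {
  stopifnot(all(L >= 0), all(tau >= 0))
  exp(-2 * mu_s_prime * DB * k0^2 * L * tau)
}

pathlength_kernel <- function(L, params) {
  out <- numeric(length(L))
  pos <- L > 0
  Lp <- L[pos]
  out[pos] <- Lp^(-3 / 2) * exp(-params$mu_a * Lp) *
    (exp(-params$zminus2 / (4 * params$D * Lp)) -
       exp(-params$zplus2 / (4 * params$D * Lp)))
  out
}

pathlength_norm <- function(params) {
  integrate(pathlength_kernel, 0, Inf, params = params,
            rel.tol = 1e-9, subdivisions = 500L)$value
}

#' Pathlength probability density of detected photons
#'
#' Image-source diffusion solution for the distribution of total optical
#' pathlengths of photons detected at separation `rho` on a semi-infinite
#' medium,
#' `P(L) propto L^(-3/2) exp(-mu_a L) [exp(-z-^2/(4 D L)) - exp(-z+^2/(4 D L))]`,
#' normalized to unit integral by adaptive quadrature. `P(0+) = 0`.
#'
#' @param L pathlengths, mm (> 0; 0 allowed, mapped to density 0).
#' @param params a [semi_infinite_params()].
#' @return Density values, 1/mm.
#' @export
pathlength_pdf <- function(L, params) {
  stopifnot(all(L >= 0))
  pathlength_kernel(L, params) / pathlength_norm(params)
}

#' @rdname pathlength_pdf
#' @details `pathlength_cdf` integrates the density from 0 to `L`.
#' @export
pathlength_cdf <- function(L, params) {
  S <- pathlength_norm(params)
  vapply(L, function(l) {
    if (l <= 0) return(0)
    integrate(pathlength_kernel, 0, l, params = params,
              rel.tol = 1e-8, subdivisions = 500L)$value / S
  }, 0)
}

# Quadrature nodes and trapezoid weights for P(L), log-spaced between z0
# and an upper limit set by absorption (or 10x the mean pathlength when
# mu_a = 0).
pathlength_grid <- function(params, n_nodes = 400) {
  lo <- params$z0 / 4
  hi <- if (params$mu_a > 0) 50 / params$mu_a else {
    m1 <- integrate(function(l) l * pathlength_kernel(l, params), 0, Inf,
                    rel.tol = 1e-8)$value / pathlength_norm(params)
    10 * m1
  }
  L <- exp(seq(log(lo), log(hi), length.out = n_nodes))
  w <- pathlength_pdf(L, params) * c(diff(L) / 2, 0) +
    pathlength_pdf(L, params) * c(0, diff(L) / 2)
  list(L = L, w = w)
}

coherence_envelope <- function(dL, lc, envelope = c("spectrum", "printed")) {
  envelope <- match.arg(envelope)
  if (is.infinite(lc)) return(dL * 0 + 1)  # preserves matrix shape
  if (envelope == "spectrum") {
    # pairs of lines drawn from the power spectrum S(k)^2 (variance kc^2/2)
    # have wavevector differences ~ N(0, kc^2), giving this interference
    # envelope for a pathlength difference dL
    kc <- pi / (2 * lc)
    exp(-kc^2 * dL^2 / 2)
  } else {
    exp(-16 * (dL / (pi * lc))^2)
  }
}

#' Coherence factor from a finite coherence length
#'
#' Double quadrature of the two-pathlength interference integral at zero
#' lag, `beta = int int P(L) P(L') env(L - L') dL dL'`: partial waves with
#' pathlength difference beyond the coherence length no longer interfere,
#' reducing the speckle contrast. Two envelope conventions are exposed:
#' `"spectrum"` (default) is `exp(-kc^2 (L-L')^2 / 2)` with
#' `kc = pi/(2 lc)`, the envelope self-consistent with the discretized
#' Gaussian amplitude spectrum of [discretize_spectrum()] (line pairs
#' drawn from the power spectrum have wavevector differences of variance
#' `kc^2`); `"printed"` is `exp(-16 ((L-L')/(pi lc))^2)`,
#' the conventional closed form (the two differ because coherence-length
#' definitions differ between spectral-width and pathlength-envelope
#' conventions).
#'
#' @param params a [semi_infinite_params()].
#' @param lc coherence length, mm (> 0 or `Inf`).
#' @param envelope `"spectrum"` or `"printed"`.
#' @param n_nodes quadrature nodes (doubling changes the result by
#'   < 1e-4 at the default).
#' @return The coherence factor beta in (0, 1].
#' @export
beta_of_coherence <- function(params, lc, envelope = c("spectrum", "printed"),
                              n_nodes = 400) {
  stopifnot(lc > 0)
  if (is.infinite(lc)) return(1)
  g <- pathlength_grid(params, n_nodes)
  env <- coherence_envelope(outer(g$L, g$L, "-"), lc, envelope)
  as.numeric(g$w %*% env %*% g$w) / sum(g$w)^2
}

#' Gated intensity autocorrelation from theory
#'
#' Double quadrature of the gated two-pathlength integral: the effective
#' pathlength weight at gate delay `ts` is `P(L) * G(L)`, where `G` is the
#' instrument response evaluated at `ts - L/v` (point rule), its integral
#' over the gate window when a finite width `tw` is given, or the
#' indicator of `L/v` in the gate window for an ideal (delta) instrument.
#' The returned curve is
#' `g2(ts, tau) = 1 + int int Peff Peff' g1(L,tau) g1(L',tau) env(L-L') / (int Peff)^2`.
#'
#' @param params a [semi_infinite_params()].
#' @param ts gate delay, ns.
#' @param tau lag grid, s.
#' @param tw gate width, ns (`NULL` for the point rule with a measured
#'   IRF).
#' @param irf an `irf_profile`, or `NULL` for an ideal instrument
#'   (requires `tw`).
#' @param lc coherence length, mm.
#' @param envelope see [beta_of_coherence()].
#' @param n_nodes quadrature nodes.
#' @return A `g2_curve` data frame (`lag`, `g2`).
#' @export
gated_g2_theory <- function(params, ts, tau, tw = NULL, irf = NULL,
                            lc = Inf, envelope = c("spectrum", "printed"),
                            n_nodes = 400) {
  g <- pathlength_grid(params, n_nodes)
  v_ns <- C_MM_PER_NS / params$refractive_index  # mm/ns
  tL <- g$L / v_ns
  G <- if (is.null(irf)) {
    if (is.null(tw)) stop("need a gate width tw when no IRF is supplied")
    as.numeric(tL >= ts - tw / 2 & tL < ts + tw / 2)
  } else if (is.null(tw)) {
    dens_at(irf, ts - tL)
  } else {
    irf_cdf_at(irf, ts + tw / 2 - tL) - irf_cdf_at(irf, ts - tw / 2 - tL)
  }
  w <- g$w * G
  if (sum(w) <= 0)
    stop("empty effective support: gate does not overlap the pathlength distribution")
  env <- coherence_envelope(outer(g$L, g$L, "-"), lc, envelope)
  rate <- 2 * params$mu_s_prime * params$DB * params$k0^2 * g$L
  g2 <- vapply(tau, function(tt) {
    f <- w * exp(-rate * tt)
    as.numeric(f %*% env %*% f) / sum(w)^2
  }, 0)
  structure(data.frame(lag = tau, g2 = 1 + g2,
                       npairs = NA_integer_),
            class = c("g2_curve", "data.frame"), source = "theory")
}

dens_at <- function(irf, t) {
  approx(irf$time, irf$density, xout = t, yleft = 0, yright = 0)$y
}

irf_cdf_at <- function(irf, t) {
  approx(irf$time, irf$cdf, xout = t, yleft = 0, yright = 1)$y
}

#' Correlator noise model for continuous-wave operation
#'
#' Standard deviation of `g2(tau) - 1` for a single-exponential
#' correlation `g2 - 1 = beta exp(-2 Gamma tau)` measured with bin time
#' `Tb` over a window `T`, at mean counts per bin `n = mean_counts`
#' (Koppel-type photon-counting noise model):
#' `sigma(tau) = sqrt(Tb/T) * [ beta^2 ((1 + e^(-2 Gamma Tb))(1 + e^(-2 Gamma tau)) +
#'  2 m (1 - e^(-2 Gamma Tb)) e^(-2 Gamma tau)) / (1 - e^(-2 Gamma Tb)) +
#'  2 n^-1 beta (1 + e^(-2 Gamma tau)) + n^-2 (1 + beta e^(-Gamma tau)) ]^(1/2)`
#' with `m = tau / Tb` the bin index.
#'
#' @param Tb bin time, s.
#' @param T_total measurement window, s (> Tb).
#' @param beta coherence factor.
#' @param Gamma decay rate `1/tau_c`, 1/s (> 0).
#' @param mean_counts mean photon counts per bin (> 0).
#' @param tau lag grid, s.
#' @return Numeric vector `sigma(tau)`.
#' @export
sigma_noise_cw <- function(Tb, T_total, beta, Gamma, mean_counts, tau) {
  stopifnot(T_total > Tb, Tb > 0, Gamma > 0, mean_counts > 0)
  m <- tau / Tb
  eb <- exp(-2 * Gamma * Tb)
  et <- exp(-2 * Gamma * tau)
  e1 <- exp(-Gamma * tau)
  sqrt(Tb / T_total) *
    sqrt(beta^2 * ((1 + eb) * (1 + et) + 2 * m * (1 - eb) * et) / (1 - eb) +
           2 * mean_counts^-1 * beta * (1 + et) +
           mean_counts^-2 * (1 + beta * e1))
}

#' Weighted Kolmogorov-Smirnov distance to a reference distribution
#'
#' Supremum distance between the weighted empirical CDF of a sample and a
#' reference CDF, for samples carrying nonnegative importance weights
#' (e.g. detection and absorption weights of photon records).
#'
#' @param x sample values.
#' @param weights nonnegative weights (default 1).
#' @param cdf reference CDF function of one argument.
#' @return The KS statistic.
#' @export
ks_statistic_weighted <- function(x, weights = NULL, cdf) {
  if (is.null(weights)) weights <- rep(1, length(x))
  o <- order(x)
  x <- x[o]; w <- weights[o] / sum(weights)
  ecdf_hi <- cumsum(w)
  ecdf_lo <- c(0, ecdf_hi[-length(ecdf_hi)])
  th <- cdf(x)
  max(abs(ecdf_hi - th), abs(ecdf_lo - th))
}
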