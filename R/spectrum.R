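#' Discretize a Gaussian source spectrum
#'
#' Represents the source as a comb of spectral lines in wavevector space.
#' The Gaussian spectral amplitude is `S(k) = exp(-(k - k0)^2 / (2 kc^2))`
#' with `kc = pi / (2 lc)`, so the coherence length `lc` is the width of
#' the corresponding Gaussian envelope in pathlength-difference space
#' (`S(L) = exp(-L^2 / (2 lc^2))`). An infinite coherence length collapses
#' to a single line of unit weight at `k0 = 2 pi / lambda0`.
#'
#' Lines are spaced uniformly over `k0 +/- span_sigmas * kc` with an odd
#' count so one line sits exactly at `k0`. Weights are the amplitudes
#' `S(k_i)`; they multiply the field, so line powers carry `S^2`.
#'
#' @param lambda0 central vacuum wavelength, nm.
#' @param lc coherence length, mm (`Inf` allowed).
#' @param n_lines odd number of lines (ignored when `lc = Inf`).
#' @param span_sigmas half-span of the comb in units of `kc`.
#' @return A `spectrum_model` with fields `lambda0`, `k0` (1/mm), `lc`,
#'   `kc` (1/mm), `k` (line wavevectors) and `weight` (amplitudes).
#' @export
discretize_spectrum <- function(lambda0 = 800, lc = Inf, n_lines = 21,
                                span_sigmas = 3.5) {
  stopifnot(lambda0 > 0, lc > 0)
  k0 <- 2 * pi / (lambda0 * 1e-6)  # nm -> mm
  if (is.infinite(lc)) {
    return(structure(list(lambda0 = lambda0, k0 = k0, lc = Inf, kc = 0,
                          k = k0, weight = 1), class = "spectrum_model"))
  }
  if (n_lines < 1 || n_lines %% 2 == 0)
    stop("n_lines must be odd so that one line sits at k0")
  kc <- pi / (2 * lc)
  k <- k0 + seq(-span_sigmas, span_sigmas, length.out = n_lines) * kc
  w <- exp(-(k - k0)^2 / (2 * kc^2))
  structure(list(lambda0 = lambda0, k0 = k0, lc = lc, kc = kc,
                 k = k, weight = w), class = "spectrum_model")
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat(sprintf("<spectrum_model> lambda0 = %g nm (k0 = %.6g /mm), lc = %g mm, %d line(s)\n",
              x$lambda0, x$k0, x$lc, length(x$k)))
  invisible(x)
}
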