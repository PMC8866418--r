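#' Convert a speckle intensity series to photon counts
#'
#' Rescales the intensity so its mean equals the expected counts per bin
#' `Nbin = flux * Tb`, then draws each bin independently from a Poisson
#' distribution with that bin's rescaled intensity as mean. This
#' discretizes the series and injects shot noise.
#'
#' @param series a `speckle_series`.
#' @param flux mean detected photon flux, photons/s (> 0).
#' @param seed integer seed (Poisson sub-stream).
#' @return A `count_series`: list with `counts`, `Tb`, `T_total`, `Nbin`.
#' @export
to_counts <- function(series, flux, seed = NULL) {
  stopifnot(inherits(series, "speckle_series"))
  if (!is.numeric(flux) || flux <= 0) stop("flux must be positive")
  Nbin <- flux * series$Tb
  lam <- series$intensity / mean(series$intensity) * Nbin
  counts <- with_seed(seed, rpois(length(lam), lam))
  structure(list(counts = counts, Tb = series$Tb,
                 T_total = series$T_total, Nbin = Nbin),
            class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series> %d bins of %g s, mean %.3g counts/bin (target %.3g)\n",
              length(x$counts), x$Tb, mean(x$counts), x$Nbin))
  invisible(x)
}

#' Estimate the intensity autocorrelation g2
#'
#' Linear (non-circular) lagged-product estimator
#' `g2(tau) = <x(t) x(t + tau)> / <x>^2`, with the full-series mean in the
#' denominator and averaging over the available pairs at each lag. For an
#' intensity source the zero lag is included; for photon counts it is
#' excluded, since the Poisson self-pairing term (shot noise) makes
#' `g2(0)` reflect counting statistics rather than the field.
#'
#' @param series a `speckle_series` or `count_series` (or a bare numeric
#'   vector, treated as intensity with `Tb = 1`).
#' @param max_lag largest lag in bins; the series must be at least twice
#'   as long.
#' @return A `g2_curve` data frame with columns `lag` (s), `g2`, `npairs`;
#'   attribute `source` is `"intensity"` or `"counts"`.
#' @export
g2_estimate <- function(series, max_lag) {
  if (is.numeric(series))
    series <- structure(list(intensity = series, Tb = 1,
                             T_total = length(series)),
                        class = "speckle_series")
  src <- if (inherits(series, "count_series")) "counts" else "intensity"
  x <- if (src == "counts") as.numeric(series$counts) else series$intensity
  n <- length(x)
  if (n < 2 * max_lag)
    stop("series too short: need length >= 2 * max_lag")
  if (mean(x) == 0) stop("zero-mean series: g2 estimator undefined")
  lags <- if (src == "counts") seq_len(max_lag) else 0:max_lag
  res <- g2_lagged_cpp(x, as.integer(lags))
  structure(data.frame(lag = lags * series$Tb, g2 = res$g2,
                       npairs = res$npairs),
            class = c("g2_curve", "data.frame"), source = src,
            Tb = series$Tb, T_total = series$T_total)
}

#' Average g2 curves over replicates
#'
#' @param curves list of `g2_curve` objects on one common lag grid.
#' @return A `g2_curve` with the mean g2 at each lag.
#' @export
average_g2 <- function(curves) {
  stopifnot(length(curves) >= 1)
  out <- curves[[1]]
  out$g2 <- rowMeans(vapply(curves, `[[`, out$g2, "g2"))
  out
}

#' Fit the correlation decay time and coherence factor
#'
#' Fits `g2(tau) = 1 + beta * exp(-2 tau / tau_c)` (the Siegert relation
#' with a single-exponential field correlation `g1 = exp(-tau / tau_c)`)
#' by nonlinear least squares with uniform weights. The fitted lag window
#' runs from the first lag to the first lag where a 5-point moving average
#' of `g2 - 1` drops below `0.05 * beta0`, with `beta0` from a log-linear
#' pre-fit; this bounds the bias from the noise floor. Optionally `beta`
#' can be fixed.
#'
#' The returned `tau_c` parameterizes `g1 = exp(-tau / tau_c)`;
#' `tau_decay = tau_c / 2` is the 1/e decay time of `g2 - 1` itself, the
#' quantity usually quoted from a direct single-exponential fit of the
#' measured correlation.
#'
#' @param curve a `g2_curve`.
#' @param fix_beta optional fixed coherence factor.
#' @param window `"auto"` (noise-floor rule above) or `"all"`.
#' @param min_lags minimum number of lags required with `g2 > 1`.
#' @return A `fit_result`: list with `tau_c` (s), `beta`, `gamma`
#'   (= 1/tau_c, 1/s), `tau_decay` (s), `converged`, `rss`, `window`
#'   (lag range used, s).
#' @export
fit_tau_c <- function(curve, fix_beta = NULL, window = c("auto", "all"),
                      min_lags = 5) {
  window <- match.arg(window)
  d <- curve[curve$lag > 0, , drop = FALSE]
  if (sum(d$g2 > 1) < min_lags)
    stop("non-decaying or all-noise curve: fewer than ", min_lags,
         " lags with g2 > 1")
  y <- d$g2 - 1
  # log-linear pre-fit on the positive early part for starting values
  pos <- which(y > 0)
  head_pos <- pos[seq_len(min(length(pos), max(min_lags, 20)))]
  if (length(head_pos) >= 3) {
    lf <- stats::lm(log(y[head_pos]) ~ d$lag[head_pos])
    beta0 <- min(exp(coef(lf)[1]), 1.5)
    rate0 <- max(-coef(lf)[2], 1 / max(d$lag))
    tau0 <- 2 / rate0
  } else {
    beta0 <- max(y[1], 0.1)
    tau0 <- max(d$lag) / 3
  }
  if (window == "auto") {
    ma <- stats::filter(y, rep(1 / 5, 5), sides = 1)
    cut <- which(!is.na(ma) & ma < 0.05 * beta0)
    if (length(cut) && cut[1] > min_lags) d <- d[seq_len(cut[1]), ]
  }
  fit <- tryCatch({
    if (is.null(fix_beta)) {
      minpack.lm::nlsLM(g2 ~ 1 + beta * exp(-2 * lag / tau_c), data = d,
                        start = list(beta = beta0, tau_c = tau0),
                        lower = c(1e-6, 1e-12), upper = c(2, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(g2 ~ 1 + fix_beta * exp(-2 * lag / tau_c), data = d,
                        start = list(tau_c = tau0),
                        lower = 1e-12,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(tau_c = NA_real_, beta = NA_real_,
                          gamma = NA_real_, tau_decay = NA_real_,
                          converged = FALSE, rss = NA_real_,
                          window = range(d$lag)),
                     class = "fit_result"))
  }
  cf <- coef(fit)
  tau_c <- unname(cf["tau_c"])
  beta <- if (is.null(fix_beta)) unname(cf["beta"]) else fix_beta
  structure(list(tau_c = tau_c, beta = beta, gamma = 1 / tau_c,
                 tau_decay = tau_c / 2, converged = TRUE,
                 rss = sum(stats::residuals(fit)^2),
                 window = range(d$lag)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (!x$converged) { cat("<fit_result> fit failed\n"); return(invisible(x)) }
  cat(sprintf("<fit_result> tau_c = %.4g s (g2-1 decay %.4g s), beta = %.3f\n",
              x$tau_c, x$tau_decay, x$beta))
  invisible(x)
}
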