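#' Scatterer dynamics specification
#'
#' Per-layer Brownian diffusion coefficients of the moving scatterers
#' (red blood cells). Activation in the deep layer is expressed by raising
#' its coefficient, conventionally from 1e-6 to 2.25e-6 mm^2/s.
#'
#' @param DB per-layer Brownian diffusion coefficients, mm^2/s (>= 0).
#' @param state free-text label, e.g. `"baseline"` or `"activated"`.
#' @return A `dynamics_spec` object.
#' @export
dynamics_spec <- function(DB, state = "baseline") {
  stopifnot(all(DB >= 0))
  structure(list(DB = DB, state = state), class = "dynamics_spec")
}

#' Draw per-event squared direction changes
#'
#' For isotropic scattering each event's outgoing direction is uniform on
#' the sphere; in the local frame with the incoming direction along z the
#' squared direction change is `|n_out - n_in|^2 = 2 (1 - cos theta)` with
#' `cos theta` uniform on `[-1, 1]` (mean 2, range `[0, 4]`). Only the
#' per-photon, per-layer sums enter the aggregated phase dynamics; the
#' per-event values (and explicit unit vectors) can be kept for the
#' explicit per-scatterer mode.
#'
#' @param records a `photon_records` object.
#' @param seed integer seed (direction-change sub-stream).
#' @param keep_events if `TRUE`, also return the per-event values and the
#'   3-D direction-change vectors (memory scales with total scattering
#'   events; intended for small record sets).
#' @return A `direction_changes` object: list with `sum_dn2` (matrix,
#'   photons x layers, sums of `|dn|^2`) and optionally `events` (list per
#'   photon: `dn2`, `layer`, and `dn` a 3-column matrix of direction
#'   changes).
#' @export
draw_direction_changes <- function(records, seed = NULL,
                                   keep_events = FALSE) {
  Ns <- ns_matrix(records)
  n_ph <- nrow(Ns); n_lay <- ncol(Ns)
  tot <- rowSums(Ns)
  with_seed(seed, {
    if (!keep_events) {
      # one uniform draw per scattering event, summed per photon and layer
      sum_dn2 <- matrix(0, n_ph, n_lay)
      for (k in seq_len(n_lay)) {
        nk <- Ns[, k]
        u <- runif(sum(nk), -1, 1)
        grp <- rep.int(seq_len(n_ph), nk)
        s <- numeric(n_ph)
        if (length(u)) {
          agg <- rowsum(2 * (1 - u), grp)
          s[as.integer(rownames(agg))] <- agg[, 1]
        }
        sum_dn2[, k] <- s
      }
      structure(list(sum_dn2 = sum_dn2, events = NULL),
                class = "direction_changes")
    } else {
      events <- vector("list", n_ph)
      sum_dn2 <- matrix(0, n_ph, n_lay)
      for (n in seq_len(n_ph)) {
        m <- tot[n]
        ct <- runif(m, -1, 1); phi <- runif(m, 0, 2 * pi)
        st <- sqrt(1 - ct^2)
        # n_out uniform on the sphere, n_in = (0, 0, 1) in the local frame
        dn <- cbind(st * cos(phi), st * sin(phi), ct - 1)
        dn2 <- 2 * (1 - ct)
        layer <- rep.int(seq_len(n_lay), Ns[n, ])
        events[[n]] <- list(dn2 = dn2, layer = layer, dn = dn)
        sum_dn2[n, ] <- vapply(seq_len(n_lay), function(k)
          sum(dn2[layer == k]), 0)
      }
      structure(list(sum_dn2 = sum_dn2, events = events),
                class = "direction_changes")
    }
  })
}

#' Per-photon Brownian phase-driver variance rates
#'
#' For photon n the dynamic phase of spectral line k_i is
#' `k_i * X_n(t)` where `X_n(t)` sums `dn_hat . dr(t)` over its scattering
#' events. Each term is Gaussian, so `X_n` is a Wiener process with
#' variance rate `2 * sum_layers(DB * sum_events |dn|^2)` (mm^2/s).
#'
#' @param dirchanges a `direction_changes` object.
#' @param dynamics a [dynamics_spec()].
#' @return Numeric vector of variance rates, mm^2/s.
#' @export
phase_variance_rates <- function(dirchanges, dynamics) {
  stopifnot(inherits(dynamics, "dynamics_spec"),
            length(dynamics$DB) == ncol(dirchanges$sum_dn2))
  2 * as.vector(dirchanges$sum_dn2 %*% dynamics$DB)
}

#' Simulate the Brownian phase drivers explicitly
#'
#' Builds the per-photon phase-driver trajectories `X_n(t)` on a uniform
#' time grid. In `"aggregated"` mode each `X_n` is generated directly as a
#' Wiener process with the variance rate of [phase_variance_rates()] -
#' exact in distribution, since a sum of independent Gaussian increments
#' is Gaussian. In `"explicit"` mode every scatterer performs its own 3-D
#' random walk (per-axis increments `N(0, 2 DB dt)`) which is dotted with
#' that event's direction-change vector and summed; this is the literal
#' construction and is kept as the oracle for the aggregated mode (cost
#' scales with total scattering events x time bins).
#'
#' @param records a `photon_records` object.
#' @param dirchanges a `direction_changes` object; `"explicit"` mode
#'   requires `keep_events = TRUE` draws.
#' @param dynamics a [dynamics_spec()].
#' @param n_bins number of time bins.
#' @param Tb bin time, s.
#' @param seed integer seed (Brownian sub-stream).
#' @param mode `"aggregated"` or `"explicit"`.
#' @return Matrix `X` (photons x n_bins, mm) with `X[, 1] = 0`.
#' @export
simulate_dynamic_phases <- function(records, dirchanges, dynamics,
                                    n_bins, Tb, seed = NULL,
                                    mode = c("aggregated", "explicit")) {
  mode <- match.arg(mode)
  n_ph <- nrow(records)
  with_seed(seed, {
    if (mode == "aggregated") {
      rates <- phase_variance_rates(dirchanges, dynamics)
      inc <- matrix(rnorm(n_ph * (n_bins - 1)), n_ph) *
        sqrt(rates * Tb)
      cbind(0, t(apply(inc, 1, cumsum)))
    } else {
      if (is.null(dirchanges$events))
        stop("explicit mode needs draw_direction_changes(keep_events = TRUE)")
      X <- matrix(0, n_ph, n_bins)
      for (n in seq_len(n_ph)) {
        ev <- dirchanges$events[[n]]
        m <- length(ev$dn2)
        if (!m) next
        sdv <- sqrt(2 * dynamics$DB[ev$layer] * Tb)
        acc <- numeric(n_bins)
        for (ax in 1:3) {
          # per-scatterer random walk along one axis, projected on dn
          inc <- matrix(rnorm(m * (n_bins - 1)), m) * sdv
          walk <- cbind(0, t(apply(inc, 1, cumsum)))
          acc <- acc + colSums(walk * ev$dn[, ax])
        }
        X[n, ] <- acc
      }
      X
    }
  })
}

#' Synthesize the speckle intensity time series
#'
#' Assembles the detected field from all photon trajectories and spectral
#' lines and returns the binned intensity
#' `I(t) = sum_i | sum_n S(k_i) w_n exp(i (phi_n + k_i (L_n - X_n(t)))) |^2`,
#' where `phi_n` is a uniform initial phase, `L_n` the static optical
#' pathlength, `X_n(t)` the Brownian phase driver and `w_n` the product of
#' the detection weight (square root, since weights are intensity-like)
#' and the absorption weight. The sum over spectral lines is incoherent
#' (distinct optical frequencies do not interfere over the measurement
#' time) and the optical carrier is omitted. Brownian updates occur at the
#' bin resolution: the intensity is only observed per bin, and Wiener
#' self-similarity makes sub-bin resolution statistically redundant.
#'
#' @param records a `photon_records` object (typically gated via
#'   [gate_records()] for time-domain operation).
#' @param spectrum a [discretize_spectrum()] model.
#' @param dynamics a [dynamics_spec()].
#' @param Tb bin time, s.
#' @param T_total measurement window, s; `n_bins = T_total / Tb`.
#' @param seed master integer seed; sub-streams for initial phases,
#'   direction changes and Brownian motion are derived from it.
#' @param dirchanges optional pre-drawn `direction_changes`.
#' @param phases optional explicit phase-driver matrix from
#'   [simulate_dynamic_phases()] (photons x n_bins); when supplied the
#'   Brownian stream is not consumed.
#' @param absorption `"intensity"` (photon intensity attenuates as
#'   `exp(-mu_a L)`, the default) or `"field"` (the field carries the full
#'   `exp(-mu_a L)`).
#' @param mu_a optional per-layer absorption override, 1/mm.
#' @return A `speckle_series` object: list with `intensity`, `Tb`,
#'   `T_total`, `n_photons`, `seed`.
#' @export
synthesize_intensity <- function(records, spectrum, dynamics,
                                 Tb = 1e-6, T_total = 1e-2, seed = NULL,
                                 dirchanges = NULL, phases = NULL,
                                 absorption = c("intensity", "field"),
                                 mu_a = NULL) {
  if (nrow(records) == 0) stop("no photons in gate: cannot synthesize speckle")
  stopifnot(inherits(spectrum, "spectrum_model"))
  absorption <- match.arg(absorption)
  n_bins <- as.integer(round(T_total / Tb))
  if (is.null(dirchanges))
    dirchanges <- draw_direction_changes(
      records, seed = if (is.null(seed)) NULL else derive_seed(seed, "dirchange"))
  amp <- sqrt(records$weight) *
    absorption_weights(records, mu_a = mu_a, mode = absorption)
  phi0 <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, "phases"),
                    runif(nrow(records), 0, 2 * pi))
  L <- total_path(records)
  intensity <- if (is.null(phases)) {
    sigma_step <- sqrt(phase_variance_rates(dirchanges, dynamics) * Tb)
    with_seed(if (is.null(seed)) NULL else derive_seed(seed, "brownian"),
              synth_intensity_cpp(amp, phi0, L, sigma_step,
                                  spectrum$k, spectrum$weight, n_bins))
  } else {
    stopifnot(nrow(phases) == nrow(records))
    synth_intensity_from_X_cpp(amp, phi0, L, phases,
                               spectrum$k, spectrum$weight)
  }
  structure(list(intensity = intensity, Tb = Tb, T_total = T_total,
                 n_photons = nrow(records), seed = seed),
            class = "speckle_series")
}

#' @export
print.speckle_series <- function(x, ...) {
  cat(sprintf("<speckle_series> %d bins of %g s (%g s window), %d photons\n",
              length(x$intensity), x$Tb, x$T_total, x$n_photons))
  invisible(x)
}
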