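#' Run replicate speckle syntheses and fit each decay time
#'
#' Repeats the wave stage of the simulator on one photon-record set:
#' every replicate draws fresh initial phases, direction changes and
#' Brownian paths (and Poisson counts when a flux is given), estimates
#' g2 and fits the decay. Photon records are shared across replicates, so
#' the ensemble spread reflects speckle (and optionally shot) noise, not
#' transport noise.
#'
#' @param records a `photon_records` object (gate first via
#'   [gate_records()] for time-domain conditions).
#' @param spectrum a [discretize_spectrum()] model.
#' @param dynamics a [dynamics_spec()].
#' @param n_reps number of replicates (>= 2 for a spread).
#' @param seed master seed; replicate r uses sub-seed
#'   `derive_seed(seed, "replicate", r)`.
#' @param Tb,T_total bin time and window, s.
#' @param max_lag number of lags used for g2 (default `n_bins / 20`,
#'   at least 50).
#' @param flux optional detected photon flux, photons/s: when given, g2 is
#'   estimated from Poisson counts (shot + speckle noise); otherwise from
#'   the intensity (speckle noise only).
#' @param subset_size optional importance-subsample size applied to
#'   `records` once before the loop (bounds synthesis cost).
#' @param fix_beta optional fixed coherence factor for the fits.
#' @param label condition label stored on the ensemble.
#' @return A `replicate_ensemble` data frame with one row per replicate
#'   (`tau_c`, `tau_decay`, `beta`, `converged`) and attributes `label`,
#'   `failure_rate`, `n_photons`, `flagged_invalid` (failure rate > 20%).
#' @export
run_replicates <- function(records, spectrum, dynamics, n_reps, seed,
                           Tb = 1e-6, T_total = 1e-2, max_lag = NULL,
                           flux = NULL, subset_size = NULL,
                           fix_beta = NULL, label = "condition") {
  stopifnot(n_reps >= 1)
  if (!is.null(subset_size) && nrow(records) > subset_size)
    records <- subsample_records(records, subset_size,
                                 seed = derive_seed(seed, "subsample"))
  n_bins <- round(T_total / Tb)
  if (is.null(max_lag)) max_lag <- max(50, round(n_bins / 20))
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rs <- derive_seed(seed, "replicate", r)
    series <- synthesize_intensity(records, spectrum, dynamics,
                                   Tb = Tb, T_total = T_total, seed = rs)
    src <- if (is.null(flux)) series
           else to_counts(series, flux, seed = derive_seed(rs, "poisson"))
    fit <- tryCatch(
      fit_tau_c(g2_estimate(src, max_lag), fix_beta = fix_beta),
      error = function(e) list(tau_c = NA_real_, tau_decay = NA_real_,
                               beta = NA_real_, converged = FALSE))
    rows[[r]] <- data.frame(rep = r, tau_c = fit$tau_c,
                            tau_decay = fit$tau_decay, beta = fit$beta,
                            converged = isTRUE(fit$converged))
  }
  out <- do.call(rbind, rows)
  fr <- mean(!out$converged)
  if (fr > 0)
    message(sprintf("%s: %d/%d replicate fits failed and are excluded",
                    label, sum(!out$converged), n_reps))
  structure(out, class = c("replicate_ensemble", "data.frame"),
            label = label, failure_rate = fr,
            n_photons = nrow(records), flagged_invalid = fr > 0.2)
}

ensemble_tau <- function(ensemble) ensemble$tau_c[ensemble$converged]

#' Summary metrics of a replicate ensemble
#'
#' `snr = mean(tau_c) / sd(tau_c)` over converged replicates.
#'
#' @param ensemble a `replicate_ensemble`.
#' @return List with `tau_c_mean`, `tau_c_sd`, `snr`, `n_used`.
#' @export
ensemble_metrics <- function(ensemble) {
  tc <- ensemble_tau(ensemble)
  if (length(tc) < 2)
    stop("need at least 2 converged replicates for a spread")
  list(tau_c_mean = mean(tc), tau_c_sd = sd(tc),
       snr = mean(tc) / sd(tc), n_used = length(tc))
}

#' Activation contrast between two matched ensembles
#'
#' `delta_tau_c = mean(tau_c, baseline) - mean(tau_c, activated)`;
#' positive when activation (faster dynamics) speeds the decay.
#'
#' @param baseline,activated `replicate_ensemble`s differing only in the
#'   dynamics state.
#' @return The contrast, s.
#' @export
compute_contrast <- function(baseline, activated) {
  if (attr(baseline, "n_photons") != attr(activated, "n_photons"))
    stop("ensembles are not matched: different photon sets")
  mean(ensemble_tau(baseline)) - mean(ensemble_tau(activated))
}

#' Depth specificity of an activation contrast
#'
#' Ratio of the contrast obtained with activation confined to the deep
#' layer to the contrast with the same activation applied homogeneously.
#'
#' @param layer_contrast deep-layer-only contrast, s.
#' @param homogeneous_contrast whole-medium contrast, s (nonzero).
#' @return The specificity ratio.
#' @export
compute_specificity <- function(layer_contrast, homogeneous_contrast) {
  if (homogeneous_contrast == 0)
    stop("homogeneous contrast is zero: specificity undefined")
  layer_contrast / homogeneous_contrast
}

#' Contrast-to-noise ratio
#'
#' `cnr = delta_tau_c / sd(tau_c baseline)`.
#'
#' @param contrast activation contrast, s.
#' @param baseline a `replicate_ensemble` at baseline.
#' @return The CNR.
#' @export
compute_cnr <- function(contrast, baseline) {
  contrast / ensemble_metrics(baseline)$tau_c_sd
}

#' Shot-noise component of the decay-time spread
#'
#' Separates the photon-counting (shot) contribution to `sd(tau_c)` from
#' the finite-window speckle contribution. For each of `n_outer` fresh
#' speckle series: draw `Navg` independent Poisson count realizations of
#' that one intensity, average their g2 curves, and fit `tau_c_avg` on
#' the average. Across the outer loop, `var(tau_c_avg) = var_speckle +
#' var_shot / Navg`. Two estimates of the shot-only spread are returned:
#' `sd_shot_scaled = Navg * sd(tau_c_avg)` (the conventional linear scaling)
#' and the variance-consistent
#' `sd_shot = sqrt(Navg * max(0, var(tau_c_avg) - var_speckle))`, which
#' uses the intensity-based fits of the same series for `var_speckle`.
#' Both are reported because that linear scaling is dimensionally
#' ambiguous ("proportional to 1/Navg" describes the variance, not the
#' standard deviation).
#'
#' @param records,spectrum,dynamics,Tb,T_total as in [run_replicates()].
#' @param flux detected photon flux, photons/s.
#' @param Navg Poisson draws averaged per outer repeat (>= 2).
#' @param n_outer outer repeats (>= 2).
#' @param seed master seed.
#' @param max_lag lags for g2.
#' @return List with `sd_shot`, `sd_shot_scaled`, `sd_avg`, `sd_speckle`,
#'   `tau_c_avg_mean`, `Navg`, `n_outer`.
#' @export
shot_noise_decomposition <- function(records, spectrum, dynamics, flux,
                                     Navg = 1000, n_outer = 100, seed = 1,
                                     Tb = 1e-6, T_total = 1e-2,
                                     max_lag = NULL) {
  stopifnot(Navg >= 1, n_outer >= 2, flux > 0)
  n_bins <- round(T_total / Tb)
  if (is.null(max_lag)) max_lag <- max(50, round(n_bins / 20))
  tau_avg <- tau_speckle <- rep(NA_real_, n_outer)
  for (o in seq_len(n_outer)) {
    rs <- derive_seed(seed, "replicate", o)
    series <- synthesize_intensity(records, spectrum, dynamics,
                                   Tb = Tb, T_total = T_total, seed = rs)
    curves <- lapply(seq_len(Navg), function(j)
      g2_estimate(to_counts(series, flux,
                            seed = derive_seed(rs, "poisson", j)), max_lag))
    fit_a <- tryCatch(fit_tau_c(average_g2(curves)),
                      error = function(e) list(tau_c = NA_real_))
    fit_s <- tryCatch(fit_tau_c(g2_estimate(series, max_lag)),
                      error = function(e) list(tau_c = NA_real_))
    tau_avg[o] <- fit_a$tau_c
    tau_speckle[o] <- fit_s$tau_c
  }
  sd_avg <- sd(tau_avg, na.rm = TRUE)
  var_speckle <- stats::var(tau_speckle, na.rm = TRUE)
  list(sd_shot = sqrt(Navg * max(0, sd_avg^2 - var_speckle)),
       sd_shot_scaled = Navg * sd_avg,
       sd_avg = sd_avg, sd_speckle = sqrt(var_speckle),
       tau_c_avg_mean = mean(tau_avg, na.rm = TRUE),
       Navg = Navg, n_outer = n_outer)
}

#' Scale the detected photon flux to a measurement condition
#'
#' Fluxes are anchored at a reference condition (conventionally 100,000
#' photons/s for continuous-wave detection at rho = 20 mm) and scaled in
#' proportion to the detected - or gated - photon count of the condition
#' of interest.
#'
#' @param n_detected detected (or gated) photon count, or sum of weights,
#'   of the condition.
#' @param n_reference the same quantity for the reference condition (> 0).
#' @param flux_reference reference flux, photons/s.
#' @return Flux for the condition, photons/s.
#' @export
flux_for_condition <- function(n_detected, n_reference,
                               flux_reference = 1e5) {
  if (n_reference <= 0) stop("reference condition has no detected photons")
  if (n_detected <= 0) stop("condition has no detected photons")
  flux_reference * n_detected / n_reference
}
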