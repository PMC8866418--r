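# Shared transport fixtures, computed once per test run and cached.
# The main fixture is a ring-tally run at the standard two-layer geometry
# (rho = 20 mm); heavy validation tests share it instead of re-running
# transport.

.fixtures <- new.env(parent = emptyenv())

fixture_records <- function(rho = 20, n_launch = 4e6, seed = 5,
                            tally = "ring") {
  key <- sprintf("rec_%g_%g_%d_%s", rho, n_launch, seed, tally)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- simulate_photons(two_layer_medium(),
                                         detection_geometry(rho),
                                         n_launch, seed = seed,
                                         tally = tally)
  }
  .fixtures[[key]]
}

# small CW photon subset for speckle-stage tests
fixture_cw_subset <- function(m = 1200, seed = 6) {
  key <- sprintf("sub_%d_%d", m, seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- subsample_records(fixture_records(), m, seed = seed)
  .fixtures[[key]]
}

# average intensity-based g2 curves over replicate syntheses
replicate_g2 <- function(records, spectrum, dynamics, n_reps, seed,
                         max_lag = 150, Tb = 1e-6, T_total = 1e-2) {
  lapply(seq_len(n_reps), function(r)
    g2_estimate(synthesize_intensity(records, spectrum, dynamics,
                                     Tb = Tb, T_total = T_total,
                                     seed = derive_seed(seed, "replicate", r)),
                max_lag))
}

# weighted mean and its standard error
wmean_se <- function(x, w) {
  m <- sum(w * x) / sum(w)
  se <- sqrt(sum(w^2 * (x - m)^2)) / sum(w)
  c(mean = m, se = se)
}

cw_spectrum <- function() discretize_spectrum(800, Inf)
baseline_dynamics <- function() dynamics_spec(c(1e-6, 1e-6), "baseline")
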