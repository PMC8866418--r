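test_that("squared direction changes have the isotropic-scattering moments", {
  rec <- fixture_records(rho = 20, n_launch = 2e5, seed = 13,
                         tally = "direct")
  dc <- draw_direction_changes(rec, seed = 2, keep_events = TRUE)
  dn2 <- unlist(lapply(dc$events, `[[`, "dn2"))
  expect_true(all(dn2 >= 0 & dn2 <= 4))          # forward 0 ... backscatter 4
  expect_lt(abs(mean(dn2) - 2), 3 * sd(dn2) / sqrt(length(dn2)))
  # |dn|^2 is consistent with the explicit unit-vector difference
  ev <- dc$events[[1]]
  expect_equal(ev$dn2, rowSums(ev$dn^2), tolerance = 1e-12)
  # per-layer sums add up to the total
  expect_equal(rowSums(dc$sum_dn2),
               vapply(dc$events, function(e) sum(e$dn2), 0),
               tolerance = 1e-9)
  # reproducible (same seed, same mode)
  dc2 <- draw_direction_changes(rec, seed = 2, keep_events = TRUE)
  expect_equal(dc$sum_dn2, dc2$sum_dn2, tolerance = 1e-12)
  # the fast path draws the same distribution: per-layer means agree
  dc3 <- draw_direction_changes(rec, seed = 2)
  Ns <- cbind(rec$ns_1, rec$ns_2)
  for (k in 1:2) {
    d <- (dc$sum_dn2[, k] - dc3$sum_dn2[, k])
    expect_lt(abs(sum(d)) / sqrt(sum(4 / 3 * 2 * Ns[, k]) + 1), 4)
  }
})

test_that("frozen dynamics give a constant intensity", {
  sub <- fixture_cw_subset(200)
  s <- synthesize_intensity(sub, cw_spectrum(), dynamics_spec(c(0, 0)),
                            Tb = 1e-6, T_total = 2e-4, seed = 9)
  expect_lt(diff(range(s$intensity)) / mean(s$intensity), 1e-12)
})

test_that("one photon gives a constant intensity equal to its weighted power", {
  sub <- fixture_cw_subset(200)[1, ]
  s <- synthesize_intensity(sub, cw_spectrum(), baseline_dynamics(),
                            Tb = 1e-6, T_total = 1e-4, seed = 10)
  expect_lt(diff(range(s$intensity)) / mean(s$intensity), 1e-12)
  expected <- sub$weight * absorption_weights(sub)^2
  expect_equal(mean(s$intensity), expected, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("two-photon interference stays within the coherent bounds", {
  sub <- fixture_cw_subset(200)[1:2, ]
  sub$weight <- c(1, 1)
  one <- sub[1, ]
  s1 <- synthesize_intensity(one, cw_spectrum(), baseline_dynamics(),
                             Tb = 1e-6, T_total = 1e-4, seed = 11)
  s2 <- synthesize_intensity(sub, cw_spectrum(), baseline_dynamics(),
                             Tb = 1e-6, T_total = 5e-3, seed = 12)
  amax <- (sqrt(absorption_weights(sub)[1]^2) + absorption_weights(sub)[2])^2
  expect_true(all(s2$intensity >= 0))
  expect_true(all(s2$intensity <= amax + 1e-9))
})

test_that("the Brownian phase driver has the Wiener variance", {
  rec <- fixture_cw_subset()
  dc <- draw_direction_changes(rec, seed = 3)
  dyn <- baseline_dynamics()
  rates <- phase_variance_rates(dc, dyn)
  expect_equal(rates, 2 * (dc$sum_dn2 %*% dyn$DB)[, 1], tolerance = 1e-12)
  nb <- 60L
  X <- simulate_dynamic_phases(rec, dc, dyn, nb, 1e-6, seed = 4)
  expect_true(all(X[, 1] == 0))
  z2 <- X[, nb]^2 / (rates * 1e-6 * (nb - 1))   # standardized squared endpoint
  expect_equal(mean(z2), 1, tolerance = 5 * sqrt(2 / length(z2)))
})

test_that("explicit per-scatterer walks and the aggregated Wiener process agree", {
  rec <- subsample_records(fixture_records(), 25, seed = 8)
  dc <- draw_direction_changes(rec, seed = 10, keep_events = TRUE)
  dyn <- baseline_dynamics()
  nb <- 400L
  Xa <- simulate_dynamic_phases(rec, dc, dyn, nb, 1e-6, seed = 11,
                                mode = "aggregated")
  Xe <- simulate_dynamic_phases(rec, dc, dyn, nb, 1e-6, seed = 12,
                                mode = "explicit")
  rates <- phase_variance_rates(dc, dyn)
  # per-photon standardized increments; apply() returns (nb-1) x photons
  inc_a <- sweep(apply(Xa, 1, diff), 2, sqrt(rates * 1e-6), "/")
  inc_e <- sweep(apply(Xe, 1, diff), 2, sqrt(rates * 1e-6), "/")
  ks <- suppressWarnings(stats::ks.test(as.vector(inc_a), as.vector(inc_e)))
  expect_gt(ks$p.value, 0.01)
  # both synthesis paths produce speckle with the same coherence factor
  sp <- cw_spectrum()
  cs_e <- lapply(1:6, function(r) {
    Xr <- simulate_dynamic_phases(rec, dc, dyn, 2000L, 1e-6,
                                  seed = 100 + r, mode = "explicit")
    g2_estimate(synthesize_intensity(rec, sp, dyn, Tb = 1e-6,
                                     T_total = 2e-3,
                                     seed = 200 + r, phases = Xr), 60)
  })
  beta_exp <- average_g2(cs_e)$g2[1] - 1
  cs_a <- replicate_g2(rec, sp, dyn, 6, seed = 300, max_lag = 60,
                       T_total = 2e-3)
  beta_agg <- average_g2(cs_a)$g2[1] - 1
  expect_lt(abs(beta_exp - beta_agg), 0.25)  # few-photon speckle noise band
})

test_that("fully developed speckle intensity is exponentially distributed", {
  sub <- fixture_cw_subset()
  pool <- unlist(lapply(1:10, function(r) {
    s <- synthesize_intensity(sub, cw_spectrum(), baseline_dynamics(),
                              seed = derive_seed(66, "replicate", r))
    s$intensity[seq(1, length(s$intensity), by = 150)]  # decorrelated bins
  }))
  ks <- suppressWarnings(stats::ks.test(pool, "pexp", rate = 1 / mean(pool)))
  expect_gt(ks$p.value, 0.01)
})

test_that("the simulated field correlation follows the semi-infinite theory", {
  sub <- fixture_cw_subset()
  curves <- replicate_g2(sub, cw_spectrum(), baseline_dynamics(), 25,
                         seed = 55, max_lag = 150)
  avg <- average_g2(curves)
  beta <- avg$g2[1] - 1
  g1_sim <- sqrt(pmax(0, (avg$g2 - 1) / beta))
  th <- g1_semi_infinite(semi_infinite_params(20), avg$lag)
  idx <- avg$lag <= 3 * 34e-6
  expect_lt(sqrt(mean((g1_sim[idx] - th[idx])^2)), 0.02)
})

test_that("coherence degradation: beta falls as the coherence length shrinks", {
  sub <- fixture_cw_subset(800, seed = 19)
  dyn <- baseline_dynamics()
  beta_at <- function(lc, seed) {
    sp <- discretize_spectrum(800, lc)
    average_g2(replicate_g2(sub, sp, dyn, 8, seed = seed,
                            max_lag = 30))$g2[1] - 1
  }
  b <- c(beta_at(Inf, 81), beta_at(300, 82), beta_at(90, 83),
         beta_at(30, 84))
  expect_true(all(diff(b) < 0))
  # and each matches the quadrature of the coherence integral to speckle
  # accuracy
  par <- semi_infinite_params(20)
  expect_equal(b[3], beta_of_coherence(par, 90), tolerance = 0.08)
  expect_equal(b[4], beta_of_coherence(par, 30), tolerance = 0.12)
})

test_that("a narrowly gated subset recovers near-unit coherence at finite lc", {
  rec <- fixture_records()
  gated <- subsample_records(gate_records(rec, gate(1.5, 0.05)), 400,
                             seed = 20)
  sp <- discretize_spectrum(800, 90)
  b <- average_g2(replicate_g2(gated, sp, baseline_dynamics(), 8,
                               seed = 85, max_lag = 30))$g2[1] - 1
  expect_gt(b, 0.9)
})
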