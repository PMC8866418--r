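test_that("profiles are normalized and re-centred on their peak", {
  # symmetric triangle: peak moves to t = 0 and half the mass sits left of it
  tt <- seq(0, 2, by = 0.01)
  tri <- irf_profile(tt, pmax(0, 1 - abs(tt - 1)))
  expect_equal(tri$time[which.max(tri$density)], 0)
  expect_equal(approx(tri$time, tri$cdf, 0)$y, 0.5, tolerance = 1e-6)
  dt <- diff(tri$time)
  expect_equal(sum(dt * (tri$density[-1] + tri$density[-length(tri$density)]) / 2),
               1, tolerance = 1e-9)
  # normalization is idempotent for a narrow single-bin spike
  spike <- irf_profile(c(-0.01, 0, 0.01), c(0, 1, 0))
  dt <- diff(spike$time)
  expect_equal(sum(dt * (spike$density[-1] + spike$density[-3]) / 2), 1,
               tolerance = 1e-9)
})

test_that("malformed IRF tables are rejected", {
  expect_error(irf_profile(c(0, 1), c(1, 1)), "3 rows")
  expect_error(irf_profile(c(0, 2, 1), c(1, 1, 1)), "increasing")
  expect_error(irf_profile(0:2, c(1, -1, 1)), "nonnegative")
  expect_error(irf_profile(0:2, c(0, 0, 0)), "zero")
})

test_that("width_at_fraction matches Gaussian level-set algebra", {
  irf <- synth_irf("gaussian", fwhm = 0.31)
  sigma <- 0.31 / (2 * sqrt(2 * log(2)))
  expect_equal(width_at_fraction(irf, 0.5), 0.31, tolerance = 0.31 / 50)
  # closed form: width at fraction f is 2 sigma sqrt(2 log(1/f))
  for (f in c(0.1, 0.01, 0.001))
    expect_equal(width_at_fraction(irf, f), 2 * sigma * sqrt(2 * log(1 / f)),
                 tolerance = 1e-2)
  expect_equal(width_at_fraction(irf, 0.01) / width_at_fraction(irf, 0.5),
               sqrt(log2(100)), tolerance = 1e-3)
  expect_error(width_at_fraction(irf, 1.2), "fraction")
})

test_that("rectangular density has the same width at every fraction", {
  tt <- seq(-1, 1, by = 0.001)
  rect <- irf_profile(tt, as.numeric(abs(tt) <= 0.5))
  for (f in c(0.1, 0.5, 0.9))
    expect_equal(width_at_fraction(rect, f), 1, tolerance = 0.005)
})

test_that("exgaussian tails nest and the long tail shows at low fractions", {
  irf <- synth_irf("exgaussian", fwhm = 0.31, tail_tau = 0.4)
  expect_gt(width_at_fraction(irf, 0.001), width_at_fraction(irf, 0.1))
  # tail is one-sided: the 1% width is asymmetric around the peak
  expect_gt(width_at_fraction(irf, 0.01), width_at_fraction(synth_irf("gaussian", 0.31), 0.01))
})

test_that("inverse-transform sampling reproduces the profile", {
  irf <- synth_irf("gaussian", fwhm = 0.31)
  sigma <- 0.31 / (2 * sqrt(2 * log(2)))
  x <- sample_irf_times(irf, 1e5, seed = 21)
  expect_lt(abs(mean(x)), 3 * sigma / sqrt(1e5))
  expect_equal(sd(x), sigma, tolerance = 0.02)
  ks <- ks_statistic_weighted(x, cdf = function(t)
    approx(irf$time, irf$cdf, t, yleft = 0, yright = 1)$y)
  expect_lt(ks, 0.01)
  # seed reproducibility, and a delta-like instrument returns zeros
  expect_identical(x, sample_irf_times(irf, 1e5, seed = 21))
  expect_true(all(abs(sample_irf_times(synth_irf("gaussian", 1e-4), 100,
                                       seed = 1)) < 1e-3))
  expect_identical(sample_irf_times(NULL, 5), rep(0, 5))
})

test_that("arrival times add transit and instrument delays", {
  expect_equal(arrival_times(c(1, 2), c(0, 0)), c(1, 2))
  expect_equal(arrival_times(1.0, 0.2), 1.2)
  expect_error(arrival_times(1:3, 1:2), "length")
})

test_that("shifting the IRF time origin shifts all arrivals equally", {
  irf <- synth_irf("gaussian", fwhm = 0.31)
  shifted <- irf
  shifted$time <- irf$time + 0.7
  a <- sample_irf_times(irf, 1000, seed = 4)
  b <- sample_irf_times(shifted, 1000, seed = 4)
  expect_equal(b, a + 0.7, tolerance = 1e-10)
})

test_that("gate selection obeys the half-open window", {
  ta <- c(0.9, 1.0, 1.05, 1.1, 1.3)
  g <- gate(1.0, 0.2)
  expect_equal(select_gate(ta, g), c(1, 2, 3))  # [0.9, 1.1): 0.9 in, 1.1 out
  expect_equal(select_gate(ta, gate(1, 10)), seq_along(ta))
  expect_warning(idx <- select_gate(ta, gate(5, 0.2)), "empty gate")
  expect_length(idx, 0)
})

test_that("gated counts match the transit-IRF convolution integral", {
  rec <- fixture_records()
  irf <- synth_irf("gaussian", fwhm = 0.31)
  tl <- transit_times(rec)
  g <- gate(1.5, 0.4)
  # expected gated weight: sum over photons of the IRF mass falling in
  # [ts - tw/2 - tL, ts + tw/2 - tL)
  pgate <- approx(irf$time, irf$cdf, g$ts + g$tw / 2 - tl,
                  yleft = 0, yright = 1)$y -
    approx(irf$time, irf$cdf, g$ts - g$tw / 2 - tl, yleft = 0, yright = 1)$y
  expected <- sum(rec$weight * pgate)
  gated <- gate_records(rec, g, irf = irf, seed = 31)
  observed <- sum(gated$weight)
  se <- sqrt(sum(rec$weight^2 * pgate * (1 - pgate)))
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("without an IRF the gated pathlength support is exactly the window", {
  rec <- fixture_records()
  v <- 300 / 1.33
  g <- gate(1.5, 0.2)
  gated <- gate_records(rec, g)
  L <- total_path(gated)
  expect_true(all(L >= v * (g$ts - g$tw / 2) - 1e-9))
  expect_true(all(L < v * (g$ts + g$tw / 2)))
  expect_gt(nrow(gated), 100)
})

test_that("with an IRF the gated pathlength histogram follows the broadened effective density", {
  rec <- fixture_records()
  irf <- synth_irf("gaussian", fwhm = 0.31)
  ts <- 1.5; tw <- 1.2
  gated <- gate_records(rec, gate(ts, tw), irf = irf, seed = 37)
  w <- gated$weight * absorption_weights(gated)^2
  n_eff <- sum(w)^2 / sum(w^2)
  expect_gt(n_eff, 1e4)
  L <- total_path(gated)
  par <- semi_infinite_params(20)
  v <- 300 / 1.33
  brk <- seq(min(L), max(L), length.out = 16)
  obs <- vapply(seq_len(15), function(i)
    sum(w[L >= brk[i] & L < brk[i + 1]]), 0)
  mids <- (brk[-1] + brk[-16]) / 2
  # effective density: P(L) times the IRF mass the gate catches at that
  # transit time (reduces to P(L) Ip(ts - L/v) as tw -> 0)
  cdf_at <- function(t) approx(irf$time, irf$cdf, t, yleft = 0,
                               yright = 1)$y
  expc <- pathlength_pdf(mids, par) *
    (cdf_at(ts + tw / 2 - mids / v) - cdf_at(ts - tw / 2 - mids / v))
  expc <- expc / sum(expc) * sum(obs)
  # chi-square on effective counts
  scl <- n_eff / sum(obs)
  keep <- expc * scl > 5
  chi2 <- sum(((obs - expc)^2 / expc)[keep] * scl)
  expect_gt(stats::pchisq(chi2, sum(keep) - 1, lower.tail = FALSE), 0.001)
})

test_that("IRF text tables load through the same constructor", {
  path <- withr::local_tempfile(fileext = ".txt")
  tt <- seq(0, 3, by = 0.02)
  writeLines(sprintf("%g %g", tt, exp(-(tt - 1)^2 / 0.02)), path)
  irf <- load_irf(path)
  expect_s3_class(irf, "irf_profile")
  expect_equal(width_at_fraction(irf, 0.5), 2 * sqrt(0.01) * sqrt(2 * log(2)),
               tolerance = 0.02)
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 1", "1 -2", "2 1"), bad)
  expect_error(load_irf(bad), "nonnegative")
})
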