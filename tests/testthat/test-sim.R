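test_that("synthesized series realizes the constructed spectrum exactly", {
  sp <- sim_spec(1.5, duration_s = 4, f_sample = 1000, seed = 3)
  ts <- synthesize(sp)
  expect_length(ts$samples, 4000)
  cs <- constructed_spectrum(sp)
  pg <- Mod(stats::fft(ts$samples))^2
  # inverse-transform round trip: periodogram equals construction per bin
  rel <- abs(pg[seq_along(cs$freq)][-1] - cs$power[-1]) / cs$power[-1]
  expect_lt(max(rel), 1e-9)
  expect_equal(cs$power[1], 0)              # DC excluded
  expect_equal(stats::var(ts$samples) * (3999 / 4000), 1, tolerance = 1e-9)
})

test_that("same recipe and seed give identical samples", {
  sp <- sim_spec(2, duration_s = 2, f_sample = 600,
                 peaks = peak_spec(10, 3, 1), white_noise_scale = 0.1,
                 seed = 7)
  expect_identical(synthesize(sp)$samples, synthesize(sp)$samples)
  sp2 <- sp; sp2$seed <- 8L
  expect_false(identical(synthesize(sp)$samples, synthesize(sp2)$samples))
})

test_that("constructed spectra have the preset log-log slope", {
  slope_of <- function(beta) {
    cs <- constructed_spectrum(sim_spec(beta, 4, 1000, seed = 1))
    k <- cs$freq > 0
    unname(stats::coef(stats::lm(log10(cs$power[k]) ~ log10(cs$freq[k])))[2])
  }
  expect_equal(slope_of(0), 0, tolerance = 1e-12)
  expect_equal(slope_of(1.5), -1.5, tolerance = 1e-9)
})

test_that("a spectral peak only alters power near its center frequency", {
  base <- sim_spec(1, 8, 500, seed = 1)
  peaky <- sim_spec(1, 8, 500, peaks = peak_spec(20, 4, 1.5), seed = 1)
  p0 <- constructed_spectrum(base)
  p1 <- constructed_spectrum(peaky)
  # the unit-variance normalization rescales all bins by one constant;
  # peak locality concerns the spectral shape on top of that constant
  ratio <- p1$power / p0$power
  far <- p0$freq > 0 & abs(p0$freq - 20) > 6 * 1.5
  cc <- stats::median(ratio[far])
  expect_lt(max(abs(ratio[far] / cc - 1)), 4 * 1e-8)
  near <- abs(p0$freq - 20) < 1.5
  expect_gt(min(ratio[near] / cc), 2)
})

test_that("invalid recipes are rejected with explanations", {
  expect_error(sim_spec(2, duration_s = 1.0005, f_sample = 1000),
               "integer sample count")
  expect_error(sim_spec(2, 4, 100, peaks = peak_spec(60, 1, 1)), "Nyquist")
  expect_error(sim_spec(2, 4, 100,
                        transients = transient_spec(3, 1, 2, 6)),
               "duration")
})

test_that("sawtooth transients alter only the requested interval", {
  sp <- sim_spec(1.5, 10, 500, seed = 5)
  ts <- synthesize(sp)
  tr0 <- transient_spec(3, 0, 2, 6)
  expect_equal(inject_transient(ts, tr0)$samples, ts$samples)
  tr <- transient_spec(3, 1.5, 2, 6)
  out <- inject_transient(ts, tr)
  idx_out <- c(1:(2 * 500 - 1), (6 * 500 + 2):5000)
  expect_equal(out$samples[idx_out], ts$samples[idx_out])
  delta <- out$samples - ts$samples
  expect_equal(max(abs(delta)), 1.5, tolerance = 0.01)  # half peak-to-peak
  expect_error(inject_transient(ts, transient_spec(3, 1, 8, 12)),
               "outside the series")
})

test_that("sawtooth harmonics carry power proportional to 1/k^2", {
  # oracle: Fourier coefficients of an ideal sawtooth, |c_k|^2 ~ 1/k^2
  flat <- as_timeseries(rep(0, 60 * 600), 600)
  out <- inject_transient(flat, transient_spec(3, 1, 0, 60))
  psd <- welch_psd(out, segment_s = 4)
  p_at <- function(f) psd$power[which.min(abs(psd$freq - f))]
  expect_equal(p_at(6) / p_at(3), 1 / 4, tolerance = 0.05)
  expect_equal(p_at(9) / p_at(3), 1 / 9, tolerance = 0.05)
  expect_equal(p_at(12) / p_at(3), 1 / 16, tolerance = 0.05)
})

test_that("flat-spectrum series fit as white over a broad band", {
  psd <- welch_psd(synthesize(sim_spec(0, 180, 2400, seed = 2)), 1)
  band <- psd$freq >= 10 & psd$freq <= 1000
  sl <- stats::coef(stats::lm(log10(psd$power[band]) ~
                                log10(psd$freq[band])))[2]
  expect_lt(abs(sl), 0.05)
})

test_that("the highpass filter empties the stopband and keeps the slope", {
  sp <- sim_spec(2, 60, 500, highpass_hz = 1, seed = 9)
  psd <- welch_psd(synthesize(sp), segment_s = 4)
  truth <- ground_truth_psd(sp, c(0.25, 10), "aperiodic_noiseless")
  expect_lt(psd$power[psd$freq == 0.25] / truth[1], 0.05)
  band <- psd$freq >= 3 & psd$freq <= 30
  sl <- -stats::coef(stats::lm(log10(psd$power[band]) ~
                                 log10(psd$freq[band])))[2]
  expect_equal(unname(sl), 2, tolerance = 0.1)
})

test_that("noise calibration reports degenerate brackets", {
  sp <- sim_spec(2, 30, 1200, seed = 1)
  expect_error(
    calibrate_noise_for_plateau(sp, 100, n_seeds = 1, lower = 20),
    "bracket failure")
  expect_error(calibrate_noise_for_plateau(sp, 590), "target onset")
})
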