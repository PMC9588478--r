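test_that("evaluated-range arithmetic follows the resampling factors", {
  ev <- evaluated_range(c(10, 100), 3)
  expect_equal(ev$f_eval_min, 10 / 3)
  expect_equal(ev$f_eval_max, 300)
  ev1 <- evaluated_range(c(10, 100), 1)
  expect_equal(c(ev1$f_eval_min, ev1$f_eval_max), c(10, 100))
  ev2 <- evaluated_range(c(30, 45), 3)
  expect_equal(c(ev2$f_eval_min, ev2$f_eval_max), c(10, 135))
})

test_that("the resampled Nyquist frequency scales with h_max", {
  expect_equal(resampled_nyquist(2400, 10), 120)
  expect_equal(resampled_nyquist(2400, 1), 1200)
  expect_equal(resampled_nyquist(256, 2), 64)
})

test_that("the default resampling set has 17 factors from 1.1 to 1.9", {
  hs <- irasa_hset()
  expect_length(hs$factors, 17)
  expect_equal(hs$factors, seq(1.1, 1.9, by = 0.05))
  expect_equal(hs$h_max, 1.9)
  expect_error(irasa_hset(h_max = 0.9), "h_min")
})

test_that("the identity resampling pair reproduces the plain spectrum", {
  ts <- short_ts()
  pair <- resample_pair_psd(ts, 1, segment_s = 4)
  plain <- welch_psd(ts, segment_s = 4)
  expect_equal(pair$power, plain$power)
})

test_that("geometric means preserve the power-law slope", {
  # oracle: log-log regression on the plain Welch PSD of the same series
  ts <- short_ts()
  plain <- welch_psd(ts, segment_s = 4)
  slope_of <- function(psd) {
    b <- psd$freq >= 1 & psd$freq <= 30
    unname(stats::coef(stats::lm(log10(psd$power[b]) ~
                                   log10(psd$freq[b])))[2])
  }
  for (h in c(1.3, 1.9)) {
    pair <- resample_pair_psd(ts, h, segment_s = 4)
    expect_equal(slope_of(pair), slope_of(plain), tolerance = 0.05)
  }
})

test_that("resampling shifts a narrow peak to cf*h and cf/h", {
  ts <- cached("peak10_ts", synthesize(
    sim_spec(1, 60, 500, peaks = peak_spec(10, 6, 0.8), seed = 2)))
  pair <- resample_pair_psd(ts, 1.3, segment_s = 4)
  loc <- function(p, lo, hi) {
    i <- p$freq > lo & p$freq < hi
    p$freq[i][which.max(p$power[i])]
  }
  expect_lt(abs(loc(pair, 11, 15) - 13), 1)
  expect_lt(abs(loc(pair, 6.5, 9) - 10 / 1.3), 1)
})

test_that("aperiodic and periodic components rebuild the input spectrum", {
  ts <- short_ts()
  dec <- irasa(ts, c(1, 30))
  expect_equal(dec$aperiodic_psd$power + dec$periodic_psd$power,
               dec$original_psd$power)
  expect_true(all(dec$aperiodic_psd$power > 0))
  expect_equal(dec$evaluated$f_eval_min, 1 / 1.9)
  expect_equal(dec$evaluated$f_eval_max, 30 * 1.9)
})

test_that("refitting a decomposition matches a fresh separation fit", {
  ts <- short_ts()
  dec <- irasa(ts, c(1, 30))
  re <- irasa_refit(dec, c(5, 25))
  expect_equal(coef(re), coef(irasa(ts, c(5, 25))))
  expect_error(irasa_refit(dec, c(5, 200)), "resampled Nyquist")
})

test_that("pure power laws separate into aperiodic power and a null residual", {
  for (beta in c(0.5, 1, 2)) {
    ts <- synthesize(sim_spec(beta, 120, 500, seed = 20 + beta * 10))
    dec <- irasa(ts, c(1, 30))
    expect_lt(abs(coef(dec)["exponent"] - beta), 0.05)
    band <- dec$periodic_psd$freq >= dec$evaluated$f_eval_min &
      dec$periodic_psd$freq <= min(dec$evaluated$f_eval_max,
                                   resampled_nyquist(500, 1.9))
    rel <- abs(dec$periodic_psd$power[band]) / dec$aperiodic_psd$power[band]
    expect_lt(mean(rel), 0.05)
  }
})

test_that("range-safety violations are errors naming the violated bound", {
  ts <- short_ts()
  expect_error(irasa(ts, c(1, 200)), "resampled Nyquist")
  hp <- synthesize(sim_spec(2, 30, 500, highpass_hz = 1, seed = 4))
  expect_error(irasa(hp, c(1, 30)), "highpass")
  dec <- irasa(hp, c(1, 30), enforce_range = FALSE)
  expect_s3_class(dec, "irasa")
  dec2 <- irasa(hp, c(4, 30))   # evaluated min 2.1 Hz clears the cutoff
  expect_s3_class(dec2, "irasa")
})

test_that("series too short for the downsampled segments are rejected", {
  ts <- synthesize(sim_spec(1, 6, 500, seed = 1))
  expect_error(resample_pair_psd(ts, 1.9, segment_s = 4), "too short")
})
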