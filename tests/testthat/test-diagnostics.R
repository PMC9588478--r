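test_that("logarithmic peak width is the log ratio of the bounds", {
  expect_equal(log_peak_width(10, 10), 0)
  expect_equal(log_peak_width(10, 100), 1)
  expect_error(log_peak_width(-1, 10), "positive")
  expect_error(log_peak_width(10, 5), "smaller")
  # scale invariance
  set.seed(1)
  for (i in 1:20) {
    f1 <- runif(1, 0.1, 50); f2 <- f1 * runif(1, 1, 20)
    cc <- runif(1, 0.01, 100)
    expect_equal(log_peak_width(cc * f1, cc * f2), log_peak_width(f1, f2))
  }
})

test_that("the straight-line exponent matches endpoint arithmetic", {
  psd <- power_law_psd(1.7, 200)
  expect_equal(straight_line_exponent(psd, 1, 95), 1.7)
  # equals the least-squares slope exactly on an exact power law
  m <- specparam(psd, c(1, 95), max_n_peaks = 0)
  expect_equal(straight_line_exponent(psd, 1, 95),
               unname(coef(m)["exponent"]), tolerance = 1e-9)
  expect_error(straight_line_exponent(psd, 1.5, 95), "not on the PSD grid")
  expect_warning(straight_line_exponent(psd, 1.5, 95, nearest = TRUE),
                 "snapping")
})

test_that("a plateau shortens the straight-line exponent", {
  f <- 1:500
  plat <- analytic_psd(f, f^-2 + 0.0026)   # flattens near 100 Hz
  expect_lt(straight_line_exponent(plat, 1, 200),
            straight_line_exponent(plat, 1, 50))
})

test_that("plateau detection scans windows upward from the start", {
  flat <- analytic_psd(1:300, rep(2, 300))
  rep1 <- detect_plateau_onset(flat, start_hz = 1)
  expect_equal(rep1$onset_hz, 1)
  law <- power_law_psd(2, 500)
  rep2 <- detect_plateau_onset(law, start_hz = 1)
  expect_true(is.na(rep2$onset_hz))
  expect_true(all(rep2$window_slopes$exponent > 1.9))
  plat <- analytic_psd(1:500, (1:500)^-2 + 0.0026)
  rep3 <- detect_plateau_onset(plat, start_hz = 1)
  expect_false(is.na(rep3$onset_hz))
  expect_lt(abs(rep3$onset_hz - 101), 3)   # deterministic shape crossing
  expect_error(detect_plateau_onset(power_law_psd(2, 40), start_hz = 1),
               "narrower")
})

test_that("peak bounds bracket generated peaks on the shared grid", {
  f <- seq(0.25, 500, by = 0.25)
  ap <- analytic_psd(f, f^-2)
  expect_equal(nrow(peak_bounds(ap, ap)), 0)
  one <- analytic_psd(f, f^-2 * (1 + 5 * exp(-(f - 30)^2 / (2 * 2^2))))
  b1 <- peak_bounds(one, ap)
  expect_equal(nrow(b1), 1)
  expect_true(b1$f1 < 30 && b1$f2 > 30)
  # analytic bound: deviation crosses 0.001 at 30 +- sigma*sqrt(2 ln(A/thr))
  half <- 2 * sqrt(2 * log(5 / 0.001))
  expect_lt(abs(b1$f1 - (30 - half)), 0.25)
  expect_lt(abs(b1$f2 - (30 + half)), 0.25)
  expect_equal(log_peak_width(b1$f1, b1$f2),
               log_peak_width(30 - half, 30 + half), tolerance = 0.01)
  expect_error(peak_bounds(one, analytic_psd(f[-1], f[-1]^-2)), "grids")
})

test_that("equal logarithmic widths at 30 and 300 Hz measure equally", {
  f <- seq(0.25, 600, by = 0.25)
  ap <- analytic_psd(f, f^-2)
  sig <- function(cf) cf * 0.02
  two <- analytic_psd(f, f^-2 *
    (1 + 5 * exp(-(f - 30)^2 / (2 * sig(30)^2)) +
       5 * exp(-(f - 300)^2 / (2 * sig(300)^2))))
  b <- peak_bounds(two, ap)
  expect_equal(nrow(b), 2)
  w <- log_peak_width(b$f1, b$f2)
  # agreement up to one grid bin at each bound of the narrower (30 Hz) peak
  expect_lt(abs(w[1] - w[2]), 2 * log10((28 + 0.25) / 28))
})

test_that("border sweeps stay flat when no peaks can cross the border", {
  ts <- cached("long_law_ts",
               synthesize(sim_spec(1.5, 150, 500, seed = 31)))
  sw <- sweep_lower_border(ts, "specparam", upper_hz = 100,
                           borders = c(1, 5, 10, 20, 30, 40))
  expect_true(all(sw$abs_error < 0.05))
  expect_equal(attr(sw, "method"), "specparam")
  # the two-point estimator carries per-bin noise but stays unbiased
  st <- sweep_lower_border(ts, "straight", upper_hz = 100,
                           borders = c(1, 5, 10, 20, 30, 40))
  expect_true(all(!is.na(st$beta_hat)))
  expect_lt(abs(mean(st$beta_hat) - 1.5), 0.05)
  expect_error(sweep_lower_border(as_timeseries(rnorm(1000), 500),
                                  "straight", borders = 1:10),
               "beta_truth")
})
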