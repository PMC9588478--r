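test_that("an exact power law is recovered to machine precision", {
  m <- specparam(power_law_psd(2), c(1, 100))
  expect_equal(unname(coef(m)["exponent"]), 2, tolerance = 1e-6)
  expect_equal(unname(coef(m)["offset"]), 0, tolerance = 1e-6)
  expect_equal(nrow(m$peaks), 0)
  # the aperiodic component then reproduces the input everywhere
  expect_lt(max(abs(aperiodic_component(m) - log10(m$freq^-2))), 1e-6)
  # plain evaluation: offset 0, exponent 2 at 10 Hz
  expect_equal(aperiodic_component(m, 10), -2, tolerance = 1e-6)
  expect_error(aperiodic_component(m, c(-1, 10)), "positive")
})

test_that("noiseless power-law exponents are recovered across beta", {
  for (beta in c(0.5, 1, 1.5, 2, 3)) {
    m <- specparam(power_law_psd(beta, offset = 3), c(1, 100))
    expect_equal(unname(coef(m)["exponent"]), beta, tolerance = 1e-3)
  }
})

test_that("a single generated peak is recovered from a noiseless spectrum", {
  # oracle: the generation parameters. A log-additive Gaussian lies in the
  # model family and must come back exactly as one peak ...
  f <- 1:100
  p_log <- f^-1 * 10^(0.8 * exp(-(f - 10)^2 / (2 * 1.5^2)))
  m <- specparam(analytic_psd(f, p_log), c(1, 100))
  expect_equal(nrow(m$peaks), 1)
  expect_lt(abs(m$peaks$cf - 10), 0.5)
  expect_lt(abs(m$peaks$pw - 0.8), 0.05)
  expect_lt(abs(m$peaks$sigma - 1.5), 0.15)
  expect_lt(abs(coef(m)["exponent"] - 1), 0.05)
  expect_equal(m$peaks$bw, 2 * m$peaks$sigma^2)
  # ... while the simulator's multiplicative peak (whose log shape is not
  # exactly Gaussian) is still dominated by one component at the right cf
  # ... while the simulator's multiplicative peak (whose log shape is
  # broader-shouldered than a Gaussian) resolves into components that all
  # stay local to the generated center frequency
  p_mul <- f^-1 * (1 + 4 * exp(-(f - 10)^2 / (2 * 1.5^2)))
  m2 <- specparam(analytic_psd(f, p_mul), c(1, 100))
  main <- which.max(m2$peaks$pw)
  expect_lt(abs(m2$peaks$cf[main] - 10), 0.5)
  expect_true(all(abs(m2$peaks$cf - 10) < 3 * 1.5))
  expect_lt(abs(coef(m2)["exponent"] - 1), 0.05)
})

test_that("model predictions decompose into the two components", {
  f <- 1:100
  p <- f^-1 * (1 + 4 * exp(-(f - 10)^2 / (2 * 1.5^2)))
  m <- specparam(analytic_psd(f, p), c(1, 100))
  full <- predict(m, f)
  expect_equal(full, predict(m, f, "aperiodic") + predict(m, f, "periodic"))
  expect_equal(predict(m, f, type = "linear"), 10^full)
  expect_equal(fitted(m) + residuals(m), m$power_log10)
  expect_lt(sqrt(mean(residuals(m)^2)), 0.05)
  expect_gt(m$goodness$r_squared, 0.99)
})

test_that("raising the relative threshold never adds peaks", {
  psd <- cached("peaky_psd", {
    sp <- sim_spec(1, 120, 500,
                   peaks = list(peak_spec(10, 4, 1.5), peak_spec(22, 2, 2)),
                   seed = 7)
    welch_psd(synthesize(sp), segment_s = 1)
  })
  n_at <- vapply(c(1, 1.5, 2, 3), function(th)
    nrow(specparam(psd, c(1, 100), peak_threshold = th)$peaks), numeric(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("residual maxima after aperiodic subtraction sit at generated cfs", {
  psd <- cached("peaky_psd", stop("fixture missing"))
  m <- specparam(psd, c(1, 100))
  flat <- m$power_log10 - aperiodic_component(m)
  for (cf in c(10, 22)) {
    win <- which(abs(m$freq - cf) <= 4)
    expect_lte(abs(m$freq[win][which.max(flat[win])] - cf), 1)
  }
})

test_that("degenerate inputs are rejected", {
  f <- 1:100
  expect_error(specparam(analytic_psd(f, c(-1, f[-1]^-2)), c(1, 100)),
               "non-positive")
  expect_error(specparam(power_law_psd(2), c(50, 51)), "fewer than 3")
  expect_error(specparam(analytic_psd(f, rep(2, 100)), c(1, 100)),
               "singular")
})

test_that("the knee mode recovers a bent aperiodic spectrum", {
  f <- 1:200
  p <- 10^(1 - log10(150 + f^2.5))
  m <- specparam(analytic_psd(f, p), c(1, 200), aperiodic_mode = "knee")
  expect_equal(unname(coef(m)["exponent"]), 2.5, tolerance = 0.05)
  expect_equal(unname(coef(m)["knee"]), 150, tolerance = 0.2 * 150)
  # fixed mode never reports a knee
  m2 <- specparam(analytic_psd(f, p), c(1, 200))
  expect_null(m2$aperiodic$knee)
})

test_that("amplitude scaling of a border peak tabulates cleanly", {
  base <- sim_spec(1.5, 60, 500,
                   peaks = list(peak_spec(2, 3, 2), peak_spec(20, 2, 1.5)),
                   seed = 3)
  expect_equal(nrow(delta_sensitivity_experiment(base, numeric(0))), 0)
  tab <- delta_sensitivity_experiment(base, c(0, 1, 2), peak_index = 2,
                                      fit_range = c(5, 95))
  # a peak fully inside the range does not move the exponent
  expect_lt(max(tab$beta_hat) - min(tab$beta_hat), 0.05)
  expect_true(all(tab$beta_truth == 1.5))
})
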