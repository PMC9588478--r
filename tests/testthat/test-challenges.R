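quick_delta_cfg <- list(duration_s = 30, f_sample = 600,
                        other_cf = c(12, 18), other_amp = c(1.5, 1),
                        other_sigma = c(1.5, 2))

test_that("unknown scenarios and config keys are rejected", {
  expect_error(run_challenge("nonsense"), "plateau_bias")
  expect_error(run_challenge("delta_power", config = list(bogus = 1)),
               "invalid config keys")
  expect_setequal(list_challenges(),
                  c("plateau_bias", "border_sweep", "delta_power",
                    "sawtooth", "highpass_hmax", "plateau_hmax",
                    "peak_width_hmax", "overlap_failure"))
})

test_that("identical configuration and seeds give identical reports", {
  r1 <- run_challenge("delta_power", config = quick_delta_cfg, seeds = 0)
  r2 <- run_challenge("delta_power", config = quick_delta_cfg, seeds = 0)
  expect_identical(r1$table, r2$table)
  expect_equal(r1$seeds, 0L)
})

test_that("report aggregation reproduces single reports and pools seeds", {
  expect_equal(nrow(summarize_challenges(list())), 0)
  r1 <- run_challenge("delta_power", config = quick_delta_cfg, seeds = 0)
  agg1 <- summarize_challenges(r1)
  expect_equal(sort(agg1$mean_beta_hat), sort(r1$table$beta_hat))
  expect_true(all(is.na(agg1$sd_beta_hat)))
  r2 <- run_challenge("delta_power", config = quick_delta_cfg, seeds = 0:1)
  agg2 <- summarize_challenges(r2)
  expect_true(all(agg2$n == 2))
  expect_true(all(is.finite(agg2$sd_abs_error)))
  expect_error(summarize_challenges(list(1)), "challenge_report")
})

test_that("the scenario registry exercises the full analysis pipeline", {
  # scaled-down integration pass: one scenario per failure-mode family,
  # touching simulator, Welch, parameterizer, separator and diagnostics
  saw <- run_challenge("sawtooth", seeds = 0)
  expect_setequal(unique(saw$table$method), c("specparam", "irasa"))
  expect_setequal(unique(saw$table$label), c("pre", "transient", "post"))
  ov <- run_challenge("overlap_failure", config = list(duration_s = 30),
                      seeds = 0)
  expect_equal(nrow(ov$table), 2)
  expect_true(all(ov$table$abs_error >= 0))
  hp <- run_challenge("highpass_hmax",
                      config = list(duration_s = 32, h_maxes = c(2, 8),
                                    n_factors = 5),
                      seeds = 0)
  expect_equal(nrow(hp$table), 2)
  # the printed summary carries per-condition means
  expect_output(print(hp), "h_max=2")
})
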