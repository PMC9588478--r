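# Scenario registry. Every scenario function takes (config, seeds) and
# returns list(table, ground_truth). Tables share the core columns
# seed, method, label, beta_truth, beta_hat, abs_error (extras allowed).

challenge_row <- function(seed, method, label, beta_truth, beta_hat, ...) {
  data.frame(seed = seed, method = method, label = label,
             beta_truth = beta_truth, beta_hat = beta_hat,
             abs_error = abs(beta_truth - beta_hat), ...)
}

merge_config <- function(defaults, config) {
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    stop("invalid config keys: ", paste(bad, collapse = ", "),
         " (valid: ", paste(names(defaults), collapse = ", "), ")")
  defaults[names(config)] <- config
  defaults
}

scenario_plateau_bias <- function(config, seeds) {
  cfg <- merge_config(list(
    beta = 2, duration_s = 180, f_sample = 2400, target_onset_hz = 100,
    ranges = list(c(1, 10), c(1, 50), c(1, 100), c(1, 200)),
    calib_seeds = 10), config)
  base <- sim_spec(cfg$beta, cfg$duration_s, cfg$f_sample,
                   seed = seeds[1] + 90000L)
  w <- calibrate_noise_for_plateau(base, cfg$target_onset_hz,
                                   n_seeds = cfg$calib_seeds)
  rows <- lapply(seeds, function(s) {
    sp <- sim_spec(cfg$beta, cfg$duration_s, cfg$f_sample,
                   white_noise_scale = as.numeric(w), seed = s)
    psd <- welch_psd(synthesize(sp), segment_s = 1)
    do.call(rbind, lapply(cfg$ranges, function(r) {
      fit <- specparam(psd, r, max_n_peaks = 0)
      challenge_row(s, "specparam", sprintf("%g-%g Hz", r[1], r[2]),
                    cfg$beta, unname(coef(fit)["exponent"]))
    }))
  })
  list(table = do.call(rbind, rows),
       ground_truth = list(beta = cfg$beta, white_noise_scale = as.numeric(w),
                           plateau_onset_hz = attr(w, "onset_hz")))
}

border_sweep_spec <- function(cfg, seed) {
  peaks <- mapply(peak_spec, cfg$peak_cf, cfg$peak_amp, cfg$peak_sigma,
                  SIMPLIFY = FALSE)
  sim_spec(cfg$beta, cfg$duration_s, cfg$f_sample, peaks = peaks,
           seed = seed)
}

scenario_border_sweep <- function(config, seeds) {
  cfg <- merge_config(list(
    beta = 2, duration_s = 180, f_sample = 2400,
    peak_cf = c(5, 15, 35), peak_amp = c(5, 3, 2),
    peak_sigma = c(0.3, 0.6, 1.2),
    upper_hz = 100, borders = 1:80,
    methods = c("specparam", "irasa")), config)
  rows <- lapply(seeds, function(s) {
    ts <- synthesize(border_sweep_spec(cfg, s))
    do.call(rbind, lapply(cfg$methods, function(m) {
      sw <- sweep_lower_border(ts, m, upper_hz = cfg$upper_hz,
                               borders = cfg$borders)
      challenge_row(s, m, sprintf("%g-%g Hz", sw$lower_hz, cfg$upper_hz),
                    cfg$beta, sw$beta_hat, lower_hz = sw$lower_hz)
    }))
  })
  list(table = do.call(rbind, rows),
       ground_truth = list(beta = cfg$beta, peak_cf = cfg$peak_cf,
                           peak_amp = cfg$peak_amp,
                           peak_sigma = cfg$peak_sigma))
}

scenario_delta_power <- function(config, seeds) {
  cfg <- merge_config(list(
    beta = 1.5, duration_s = 180, f_sample = 2400,
    scales = c(0, 1, 2), delta_cf = 2, delta_amp = 3, delta_sigma = 2,
    other_cf = c(12, 18, 27, 50), other_amp = c(1.5, 1, 0.8, 0.5),
    other_sigma = c(1.5, 2, 2.5, 1), white_noise_scale = 0.02,
    fit_range = c(1, 95)), config)
  peaks <- c(list(peak_spec(cfg$delta_cf, cfg$delta_amp, cfg$delta_sigma)),
             mapply(peak_spec, cfg$other_cf, cfg$other_amp, cfg$other_sigma,
                    SIMPLIFY = FALSE))
  rows <- lapply(seeds, function(s) {
    base <- sim_spec(cfg$beta, cfg$duration_s, cfg$f_sample, peaks = peaks,
                     white_noise_scale = cfg$white_noise_scale, seed = s)
    tab <- delta_sensitivity_experiment(base, cfg$scales, peak_index = 1,
                                        fit_range = cfg$fit_range,
                                        peak_width_limits = c(1, 100))
    challenge_row(s, "specparam", sprintf("delta x%g", tab$scale),
                  cfg$beta, tab$beta_hat, scale = tab$scale)
  })
  list(table = do.call(rbind, rows),
       ground_truth = list(beta = cfg$beta, delta_cf = cfg$delta_cf,
                           scales = cfg$scales))
}

scenario_sawtooth <- function(config, seeds) {
  cfg <- merge_config(list(
    beta = 1.8, duration_s = 40, f_sample = 256,
    saw_hz = 3, saw_amp = 2, interval = c(17, 23),
    fit_range = c(1, 100), irasa_fit_range = c(1, 60),
    irasa_segment_s = 2), config)
  rows <- lapply(seeds, function(s) {
    tr <- transient_spec(cfg$saw_hz, cfg$saw_amp, cfg$interval[1],
                         cfg$interval[2])
    sp <- sim_spec(cfg$beta, cfg$duration_s, cfg$f_sample,
                   transients = list(tr), seed = s)
    ts <- synthesize(sp)
    segs <- list(pre = c(0, cfg$interval[1]),
                 transient = cfg$interval,
                 post = c(cfg$interval[2], cfg$duration_s))
    do.call(rbind, lapply(names(segs), function(nm) {
      iv <- segs[[nm]]
      idx <- (floor(iv[1] * cfg$f_sample) + 1L):(iv[2] * cfg$f_sample)
      sub <- as_timeseries(ts$samples[idx], cfg$f_sample)
      fit <- specparam(welch_psd(sub, segment_s = 1), cfg$fit_range)
      dec <- irasa(sub, cfg$irasa_fit_range,
                   segment_s = cfg$irasa_segment_s)
      rbind(
        challenge_row(s, "specparam", nm, cfg$beta,
                      unname(coef(fit)["exponent"])),
        challenge_row(s, "irasa", nm, cfg$beta,
                      unname(coef(dec)["exponent"])))
    }))
  })
  list(table = do.call(rbind, rows),
       ground_truth = list(beta = cfg$beta, saw_hz = cfg$saw_hz,
                           interval = cfg$interval))
}

scenario_highpass_hmax <- function(config, seeds) {
  cfg <- merge_config(list(
    beta = 2, duration_s = 60, f_sample = 2400, highpass_hz = 1,
    fit_range = c(2, 30), h_maxes = c(2, 8, 15), n_factors = 9), config)
  rows <- lapply(seeds, function(s) {
    sp <- sim_spec(cfg$beta, cfg$duration_s, cfg$f_sample,
                   highpass_hz = cfg$highpass_hz, seed = s)
    ts <- synthesize(sp)
    do.call(rbind, lapply(cfg$h_maxes, function(hm) {
      dec <- irasa(ts, cfg$fit_range,
                   h_set = irasa_hset(hm, n = cfg$n_factors),
                   enforce_range = FALSE)
      challenge_row(s, "irasa", sprintf("h_max=%g", hm), cfg$beta,
                    unname(coef(dec)["exponent"]), h_max = hm)
    }))
  })
  list(table = do.call(rbind, rows),
       ground_truth = list(beta = cfg$beta, highpass_hz = cfg$highpass_hz))
}

scenario_plateau_hmax <- function(config, seeds) {
  cfg <- merge_config(list(
    beta = 2, duration_s = 60, f_sample = 2400, target_onset_hz = 100,
    fit_range = c(2, 30), h_maxes = c(2, 8, 15), n_factors = 9,
    calib_seeds = 10, calib_duration_s = 180), config)
  # calibrate on a long series (the detector needs a smooth PSD); the noise
  # scale carries over because the spectral shape is duration-independent
  base <- sim_spec(cfg$beta, max(cfg$duration_s, cfg$calib_duration_s),
                   cfg$f_sample, seed = seeds[1] + 90000L)
  w <- calibrate_noise_for_plateau(base, cfg$target_onset_hz,
                                   n_seeds = cfg$calib_seeds)
  rows <- lapply(seeds, function(s) {
    sp <- sim_spec(cfg$beta, cfg$duration_s, cfg$f_sample,
                   white_noise_scale = as.numeric(w), seed = s)
    ts <- synthesize(sp)
    do.call(rbind, lapply(cfg$h_maxes, function(hm) {
      dec <- irasa(ts, cfg$fit_range,
                   h_set = irasa_hset(hm, n = cfg$n_factors),
                   enforce_range = FALSE)
      challenge_row(s, "irasa", sprintf("h_max=%g", hm), cfg$beta,
                    unname(coef(dec)["exponent"]), h_max = hm)
    }))
  })
  list(table = do.call(rbind, rows),
       ground_truth = list(beta = cfg$beta, white_noise_scale = as.numeric(w),
                           plateau_onset_hz = attr(w, "onset_hz")))
}

# Gaussian sigma whose half-maximum points span a requested logarithmic
# peak width: (cf + 1.177 sigma)/(cf - 1.177 sigma) = 10^width_log.
sigma_for_log_width <- function(cf, width_log) {
  cf * (10^width_log - 1) / ((10^width_log + 1) * 1.177)
}

scenario_peak_width_hmax <- function(config, seeds) {
  cfg <- merge_config(list(
    beta = 2, duration_s = 120, f_sample = 2400,
    peak_cf = c(8, 80), peak_amp = 100,
    widths_log = c(0.05, 0.2), h_maxes = c(2, 8), n_factors = 9,
    fit_range = c(2, 30)), config)
  rows <- lapply(seeds, function(s) {
    do.call(rbind, lapply(cfg$widths_log, function(wl) {
      peaks <- lapply(cfg$peak_cf, function(cf)
        peak_spec(cf, cfg$peak_amp, sigma_for_log_width(cf, wl)))
      sp <- sim_spec(cfg$beta, cfg$duration_s, cfg$f_sample, peaks = peaks,
                     seed = s)
      ts <- synthesize(sp)
      do.call(rbind, lapply(cfg$h_maxes, function(hm) {
        dec <- irasa(ts, cfg$fit_range,
                     h_set = irasa_hset(hm, n = cfg$n_factors),
                     enforce_range = FALSE)
        ap <- dec$aperiodic_psd
        truth <- ground_truth_psd(sp, ap$freq[ap$freq > 0],
                                  component = "aperiodic_noiseless")
        # residual periodic power left in the aperiodic component, as a
        # fraction of the true peak height, worst case over the peak cores
        resid <- vapply(seq_along(cfg$peak_cf), function(i) {
          cf <- cfg$peak_cf[i]
          half <- 1.177 * sigma_for_log_width(cf, wl)
          nyq_h <- resampled_nyquist(cfg$f_sample, hm)
          band <- ap$freq > 0 & ap$freq >= cf - half &
            ap$freq <= min(cf + half, nyq_h)
          tr_band <- truth[band[ap$freq > 0]]
          height <- cfg$peak_amp *
            ground_truth_psd(sp, cf, component = "aperiodic_noiseless")
          max((ap$power[band] - tr_band) / height)
        }, numeric(1))
        challenge_row(s, "irasa", sprintf("dflog=%g h_max=%g", wl, hm),
                      cfg$beta, unname(coef(dec)["exponent"]),
                      width_log = wl, h_max = hm,
                      residual_frac = max(resid))
      }))
    }))
  })
  list(table = do.call(rbind, rows),
       ground_truth = list(beta = cfg$beta, peak_cf = cfg$peak_cf,
                           widths_log = cfg$widths_log))
}

scenario_overlap_failure <- function(config, seeds) {
  cfg <- merge_config(list(
    beta = 1.8, duration_s = 60, f_sample = 600,
    overlap_cf = c(10, 25), overlap_amp = c(15, 10), overlap_sigma = c(5, 10),
    fit_range = c(1, 45)), config)
  rows <- lapply(seeds, function(s) {
    clean <- sim_spec(cfg$beta, cfg$duration_s, cfg$f_sample, seed = s)
    peaks <- mapply(peak_spec, cfg$overlap_cf, cfg$overlap_amp,
                    cfg$overlap_sigma, SIMPLIFY = FALSE)
    peaky <- sim_spec(cfg$beta, cfg$duration_s, cfg$f_sample, peaks = peaks,
                      seed = s)
    rbind(
      challenge_row(s, "irasa", "no overlapping peaks", cfg$beta,
                    unname(coef(irasa(synthesize(clean),
                                      cfg$fit_range))["exponent"])),
      challenge_row(s, "irasa", "overlapping peaks", cfg$beta,
                    unname(coef(irasa(synthesize(peaky),
                                      cfg$fit_range))["exponent"])))
  })
  list(table = do.call(rbind, rows),
       ground_truth = list(beta = cfg$beta, overlap_cf = cfg$overlap_cf))
}

challenge_registry <- list(
  plateau_bias = list(fn = scenario_plateau_bias, seeds = 0:9),
  border_sweep = list(fn = scenario_border_sweep, seeds = 0L),
  delta_power = list(fn = scenario_delta_power, seeds = 0:9),
  sawtooth = list(fn = scenario_sawtooth, seeds = 0:9),
  highpass_hmax = list(fn = scenario_highpass_hmax, seeds = 0:2),
  plateau_hmax = list(fn = scenario_plateau_hmax, seeds = 0:2),
  peak_width_hmax = list(fn = scenario_peak_width_hmax, seeds = 0:1),
  overlap_failure = list(fn = scenario_overlap_failure, seeds = 0:2)
)

#' List the registered challenge scenarios
#'
#' @return Character vector of scenario names accepted by
#'   \code{\link{run_challenge}}.
#' @export
list_challenges <- function() names(challenge_registry)

#' Run a simulation challenge scenario
#'
#' Each scenario reproduces one known failure mode of periodic/aperiodic
#' separation on synthetic series with known ground truth: the spectral
#' plateau biasing the fitted exponent (\code{plateau_bias},
#' \code{plateau_hmax}), oscillations crossing fitting-range borders
#' (\code{border_sweep}, \code{delta_power}), non-sinusoidal transients
#' (\code{sawtooth}), highpass stopbands inside the evaluated range
#' (\code{highpass_hmax}), broad logarithmic peak widths
#' (\code{peak_width_hmax}) and strongly overlapping peaks
#' (\code{overlap_failure}).
#'
#' @param name Scenario name; see \code{\link{list_challenges}}.
#' @param config Named list overriding scenario defaults; unknown keys are
#'   an error.
#' @param seeds Integer seeds; \code{NULL} uses the scenario default.
#' @return Object of class \code{"challenge_report"}: the scenario name,
#'   ground-truth parameters, a per-seed estimate table with absolute
#'   errors, the seeds and the effective config.
#' @export
run_challenge <- function(name, config = list(), seeds = NULL) {
  if (!name %in% names(challenge_registry))
    stop("unknown scenario '", name, "'; registered scenarios: ",
         paste(names(challenge_registry), collapse = ", "))
  entry <- challenge_registry[[name]]
  if (is.null(seeds)) seeds <- entry$seeds
  seeds <- as.integer(seeds)
  res <- entry$fn(config, seeds)
  tab <- res$table
  rownames(tab) <- NULL
  structure(list(scenario = name, ground_truth = res$ground_truth,
                 table = tab, seeds = seeds, config = config),
            class = "challenge_report")
}

#' @export
print.challenge_report <- function(x, ...) {
  cat("Challenge scenario:", x$scenario, "\n")
  cat("  seeds:", paste(x$seeds, collapse = ", "), "\n")
  agg <- stats::aggregate(cbind(beta_hat, abs_error) ~ method + label,
                          data = x$table, FUN = mean)
  agg$beta_hat <- round(agg$beta_hat, 3)
  agg$abs_error <- round(agg$abs_error, 3)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Aggregate challenge reports across seeds
#'
#' @param reports A list of \code{"challenge_report"} objects (or a single
#'   report).
#' @return Data frame with per-scenario, per-method, per-condition mean and
#'   standard deviation of the estimates and absolute errors.
#' @export
summarize_challenges <- function(reports) {
  if (inherits(reports, "challenge_report")) reports <- list(reports)
  if (length(reports) == 0)
    return(data.frame(scenario = character(0), method = character(0),
                      label = character(0), n = integer(0),
                      beta_truth = numeric(0), mean_beta_hat = numeric(0),
                      sd_beta_hat = numeric(0), mean_abs_error = numeric(0),
                      sd_abs_error = numeric(0)))
  core <- c("seed", "method", "label", "beta_truth", "beta_hat", "abs_error")
  tabs <- lapply(reports, function(r) {
    if (!inherits(r, "challenge_report"))
      stop("summarize_challenges expects challenge_report objects")
    if (!all(core %in% names(r$table)))
      stop("report for scenario '", r$scenario,
           "' lacks the shared table schema")
    cbind(scenario = r$scenario, r$table[core])
  })
  tab <- do.call(rbind, tabs)
  split_keys <- interaction(tab$scenario, tab$method, tab$label, drop = TRUE)
  out <- do.call(rbind, lapply(split(tab, split_keys), function(d) {
    data.frame(scenario = d$scenario[1], method = d$method[1],
               label = d$label[1], n = nrow(d),
               beta_truth = d$beta_truth[1],
               mean_beta_hat = mean(d$beta_hat, na.rm = TRUE),
               sd_beta_hat = stats::sd(d$beta_hat),
               mean_abs_error = mean(d$abs_error, na.rm = TRUE),
               sd_abs_error = stats::sd(d$abs_error))
  }))
  rownames(out) <- NULL
  out[order(out$scenario, out$method, out$label), ]
}
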