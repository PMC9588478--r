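# Aperiodic fits operate on log10 power vs log10 frequency throughout.

# Plain least-squares aperiodic fit: returns c(offset, exponent) for the
# model log10 P = offset - exponent * log10 f.
ols_aperiodic <- function(logf, logp) {
  fit <- stats::lsfit(logf, logp)
  c(offset = unname(fit$coefficients[1]),
    exponent = unname(-fit$coefficients[2]))
}

# Robust initial fit: ordinary least squares, then refit using only bins
# whose positive residual lies at or below the 2.5th percentile of positive
# residuals. This discards the bins most elevated by oscillatory peaks.
robust_aperiodic <- function(logf, logp) {
  ab <- ols_aperiodic(logf, logp)
  res <- logp - (ab[1] - ab[2] * logf)
  pos <- res[res > 0]
  if (length(pos) < 2) return(ab)
  thr <- stats::quantile(pos, 0.025, names = FALSE)
  keep <- res <= thr
  if (sum(keep) < 3) return(ab)
  ols_aperiodic(logf[keep], logp[keep])
}

# Bent aperiodic fit, log10 P = offset - log10(knee + f^exponent); the
# error surface is multimodal in knee, so several magnitudes are tried.
knee_aperiodic <- function(freq, y, start_exp) {
  fit <- NULL
  for (k0 in c(0.1, 1, 10, 100, 1000)) {
    cand <- tryCatch(
      minpack.lm::nls.lm(
        par = c(offset = mean(y) + log10(k0 + mean(freq)^start_exp),
                knee = k0, exponent = max(start_exp, 0.1)),
        fn = function(p)
          y - (p[["offset"]] - log10(p[["knee"]] + freq^p[["exponent"]])),
        lower = c(-Inf, 0, 0), upper = c(Inf, Inf, 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(cand) && (is.null(fit) || cand$deviance < fit$deviance))
      fit <- cand
  }
  fit
}

eval_aperiodic <- function(offset, exponent, knee, logf) {
  if (is.null(knee) || is.na(knee))
    offset - exponent * logf
  else
    offset - log10(knee + (10^logf)^exponent)
}

gauss_log <- function(logx_freq, cf, pw, sigma) {
  pw * exp(-(logx_freq - cf)^2 / (2 * sigma^2))
}

# Numerical floor below which flattened-spectrum maxima are treated as
# machine noise rather than peaks (log10-power units).
.height_floor <- 1e-6

# Fit one bounded Gaussian to the flattened spectrum around index i_max.
# Returns c(cf, pw, sigma); falls back to the seeding guess on failure.
fit_single_gaussian <- function(freq, flat, i_max, sig_lim, f_range) {
  h <- flat[i_max]
  cf <- freq[i_max]
  # initial sigma from the half-maximum crossing distance
  half <- h / 2
  il <- i_max
  while (il > 1 && flat[il] > half) il <- il - 1L
  ir <- i_max
  while (ir < length(flat) && flat[ir] > half) ir <- ir + 1L
  dl <- if (flat[il] <= half) cf - freq[il] else NA
  dr <- if (flat[ir] <= half) freq[ir] - cf else NA
  fwhm <- if (is.na(dl) && is.na(dr)) 2 * sig_lim[1] * 2.355 else
    2 * mean(c(dl, dr), na.rm = TRUE)
  sig <- min(max(fwhm / 2.355, sig_lim[1]), sig_lim[2])
  win <- which(freq >= cf - 3 * sig & freq <= cf + 3 * sig)
  if (length(win) < 4) win <- seq(max(1, i_max - 2), min(length(freq), i_max + 2))
  start <- c(pw = h, cf = cf, sigma = sig)
  lowr <- c(pw = 0, cf = max(f_range[1], cf - 2 * sig), sigma = sig_lim[1])
  uppr <- c(pw = 3 * h, cf = min(f_range[2], cf + 2 * sig), sigma = sig_lim[2])
  start <- pmin(pmax(start, lowr), uppr)
  fw <- freq[win]; yw <- flat[win]
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      fn = function(p) yw - gauss_log(fw, p[["cf"]], p[["pw"]], p[["sigma"]]),
      lower = lowr, upper = uppr,
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(c(start[["cf"]], start[["pw"]], start[["sigma"]]))
  p <- fit$par
  c(p[["cf"]], p[["pw"]], p[["sigma"]])
}

# Joint bounded least squares over all accepted Gaussians, started from the
# iterative estimates. Returns the peak matrix (cols cf, pw, sigma) and a
# convergence flag.
joint_gaussian_refit <- function(freq, flat0, peaks, sig_lim, f_range) {
  k <- nrow(peaks)
  par <- as.numeric(t(peaks))   # cf1, pw1, s1, cf2, ...
  lowr <- as.numeric(t(cbind(pmax(f_range[1], peaks[, 1] - 2 * peaks[, 3]),
                             0, sig_lim[1])))
  uppr <- as.numeric(t(cbind(pmin(f_range[2], peaks[, 1] + 2 * peaks[, 3]),
                             3 * pmax(peaks[, 2], .height_floor),
                             sig_lim[2])))
  model <- function(p) {
    m <- matrix(p, ncol = 3, byrow = TRUE)
    out <- numeric(length(freq))
    for (i in seq_len(k))
      out <- out + gauss_log(freq, m[i, 1], m[i, 2], m[i, 3])
    out
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = pmin(pmax(par, lowr), uppr),
                       fn = function(p) flat0 - model(p),
                       lower = lowr, upper = uppr,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9))
    return(list(peaks = peaks, converged = FALSE))
  list(peaks = matrix(fit$par, ncol = 3, byrow = TRUE,
                      dimnames = list(NULL, c("cf", "pw", "sigma"))),
       converged = TRUE)
}

#' Parameterize a power spectrum into aperiodic and periodic components
#'
#' Iterative Gaussian peak extraction over an aperiodic 1/f fit, in log10
#' power: an initial robust linear fit in double-logarithmic space is
#' subtracted; Gaussians are fitted to the largest remaining peak until no
#' maximum exceeds both the relative threshold (a multiple of the standard
#' deviation of the flattened spectrum, recomputed after each removal) and
#' the absolute threshold; all accepted Gaussians are then refit jointly;
#' finally the peak-free spectrum is refit to give the reported offset and
#' exponent. Negative troughs are never fitted, and partial peaks are not
#' modeled: a Gaussian whose center lies within one standard deviation of a
#' fitting-range border is discarded, so its power stays in the spectrum
#' seen by the final aperiodic fit (the root of the border-crossing failure
#' mode).
#'
#' @param psd A \code{"psd"} object covering \code{fit_range} with strictly
#'   positive power.
#' @param fit_range Length-2 numeric, fitting range in Hz.
#' @param peak_width_limits Limits (Hz) on the full width (2 sigma) of
#'   fitted Gaussians; default 0.5-12 Hz.
#' @param max_n_peaks Maximum number of peak iterations (default unlimited);
#'   0 disables peak fitting entirely.
#' @param min_peak_height Absolute threshold in log10-power units.
#' @param peak_threshold Relative threshold in standard-deviation multiples.
#' @param aperiodic_mode \code{"fixed"} (offset and exponent) or
#'   \code{"knee"} (offset, knee and exponent:
#'   \code{log10 P = offset - log10(knee + f^exponent)}).
#' @return Object of class \code{"specparam"} with the aperiodic fit, a peak
#'   table (columns \code{cf} in Hz, \code{pw} in log10-power units,
#'   \code{bw} = 2 sigma_f^2 and \code{sigma} in Hz), the flattened
#'   residual and goodness of fit.
#' @seealso \code{\link{aperiodic_component}}, \code{\link{irasa}}
#' @export
specparam <- function(psd, fit_range,
                      peak_width_limits = c(0.5, 12),
                      max_n_peaks = Inf,
                      min_peak_height = 0,
                      peak_threshold = 2,
                      aperiodic_mode = c("fixed", "knee")) {
  aperiodic_mode <- match.arg(aperiodic_mode)
  stopifnot(inherits(psd, "psd"), length(fit_range) == 2,
            fit_range[1] < fit_range[2], fit_range[1] > 0,
            peak_width_limits[1] > 0,
            peak_width_limits[1] <= peak_width_limits[2],
            min_peak_height >= 0, peak_threshold >= 0)
  band <- psd_band(psd, fit_range[1], fit_range[2])
  if (length(band$freq) < 3)
    stop("fit_range covers fewer than 3 frequency bins")
  if (any(band$power <= 0))
    stop("non-positive power inside the fitting range; cannot take log10")
  freq <- band$freq
  logf <- log10(freq)
  y <- log10(band$power)
  if (stats::sd(y) < 1e-12 && stats::sd(logf) > 0)
    stop("degenerate (constant) spectrum in log-log space: singular fit")
  sig_lim <- peak_width_limits / 2

  if (aperiodic_mode == "fixed") {
    ab0 <- robust_aperiodic(logf, y)
    init_pred <- ab0[1] - ab0[2] * logf
  } else {
    # the initial flattening must use the knee form, or the spectral bend
    # itself would be fitted as broad peaks
    ab_lin <- ols_aperiodic(logf, y)
    knee_pred <- function(kf)
      kf$par[["offset"]] - log10(kf$par[["knee"]] +
                                   freq^kf$par[["exponent"]])
    kf <- knee_aperiodic(freq, y, ab_lin[[2]])
    init_pred <- if (is.null(kf)) ab_lin[[1]] - ab_lin[[2]] * logf else
      knee_pred(kf)
    res <- y - init_pred
    pos <- res[res > 0]
    if (length(pos) >= 2) {
      thr <- stats::quantile(pos, 0.025, names = FALSE)
      keep <- res <= thr
      if (sum(keep) >= 4) {
        kf2 <- knee_aperiodic(freq[keep], y[keep], ab_lin[[2]])
        if (!is.null(kf2))
          init_pred <- kf2$par[["offset"]] -
            log10(kf2$par[["knee"]] + freq^kf2$par[["exponent"]])
      }
    }
  }
  flat0 <- y - init_pred
  flat <- flat0
  peaks <- matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("cf", "pw", "sigma")))
  n_fit <- 0
  iter_cap <- min(max_n_peaks, 50)   # termination guard for noisy spectra
  while (n_fit < iter_cap) {
    i_max <- which.max(flat)          # ties resolve to the lowest frequency
    h <- flat[i_max]
    rel_thr <- peak_threshold * stats::sd(flat)
    if (h < max(min_peak_height, rel_thr, .height_floor)) break
    g <- fit_single_gaussian(freq, flat, i_max, sig_lim, fit_range)
    removal <- gauss_log(freq, g[1], g[2], g[3])
    if (removal[i_max] < 0.5 * h) {
      # the bounded fit slid off the maximum; fall back to subtracting the
      # seeded guess so the iteration always makes progress
      g <- c(freq[i_max], h, min(max(g[3], sig_lim[1]), sig_lim[2]))
      removal <- gauss_log(freq, g[1], g[2], g[3])
    }
    flat <- flat - removal
    peaks <- rbind(peaks, g)
    n_fit <- n_fit + 1
  }

  converged <- TRUE
  if (nrow(peaks) > 0) {
    # partial Gaussians are never fitted: a peak whose center lies within
    # one standard deviation of a fitting-range border is dropped, and its
    # power remains in the spectrum seen by the final aperiodic fit
    edge <- peaks[, "cf"] - peaks[, "sigma"] < fit_range[1] |
      peaks[, "cf"] + peaks[, "sigma"] > fit_range[2]
    peaks <- peaks[!edge, , drop = FALSE]
  }
  if (nrow(peaks) > 0) {
    jr <- joint_gaussian_refit(freq, flat0, peaks, sig_lim, fit_range)
    peaks <- jr$peaks
    converged <- jr$converged
    keep <- peaks[, "pw"] > max(min_peak_height, .height_floor)
    peaks <- peaks[keep, , drop = FALSE]
  }

  peak_model <- numeric(length(freq))
  for (i in seq_len(nrow(peaks)))
    peak_model <- peak_model +
      gauss_log(freq, peaks[i, 1], peaks[i, 2], peaks[i, 3])
  peak_free <- y - peak_model

  knee <- NULL
  if (aperiodic_mode == "fixed") {
    ab <- ols_aperiodic(logf, peak_free)
  } else {
    ab_init <- ols_aperiodic(logf, peak_free)
    fit <- knee_aperiodic(freq, peak_free, ab_init[[2]])
    if (is.null(fit)) {
      ab <- ab_init
    } else {
      ab <- c(offset = fit$par[["offset"]], exponent = fit$par[["exponent"]])
      knee <- fit$par[["knee"]]
    }
  }
  ap_model <- eval_aperiodic(ab[1], ab[2], knee, logf)
  model <- ap_model + peak_model
  resid <- y - model
  rmse <- sqrt(mean(resid^2))
  r2 <- if (stats::sd(y) > 0) 1 - sum(resid^2) / sum((y - mean(y))^2) else NA

  peaks_df <- data.frame(cf = peaks[, 1], pw = peaks[, 2],
                         bw = 2 * peaks[, 3]^2, sigma = peaks[, 3])
  peaks_df <- peaks_df[order(peaks_df$cf), , drop = FALSE]
  rownames(peaks_df) <- NULL

  structure(list(
    aperiodic = list(offset = unname(ab[1]), exponent = unname(ab[2]),
                     knee = knee, fit_range = fit_range,
                     rmse = sqrt(mean((peak_free - ap_model)^2))),
    peaks = peaks_df,
    freq = freq,
    power_log10 = y,
    model_log10 = model,
    flattened_residual = y - ap_model - peak_model,
    goodness = list(r_squared = r2, rmse = rmse),
    params = list(fit_range = fit_range,
                  peak_width_limits = peak_width_limits,
                  max_n_peaks = max_n_peaks,
                  min_peak_height = min_peak_height,
                  peak_threshold = peak_threshold,
                  aperiodic_mode = aperiodic_mode),
    converged = converged), class = "specparam")
}

#' Evaluate the aperiodic component of a fitted spectral model
#'
#' @param model A \code{"specparam"} fit.
#' @param freqs Frequencies in Hz (> 0); defaults to the fitted grid.
#' @return Per-bin log10 power of the aperiodic component.
#' @export
aperiodic_component <- function(model, freqs = model$freq) {
  stopifnot(inherits(model, "specparam"))
  if (any(freqs <= 0)) stop("frequencies must be positive")
  eval_aperiodic(model$aperiodic$offset, model$aperiodic$exponent,
                 model$aperiodic$knee, log10(freqs))
}

#' @export
print.specparam <- function(x, ...) {
  cat("Spectral parameterization over ", x$aperiodic$fit_range[1], "-",
      x$aperiodic$fit_range[2], " Hz\n", sep = "")
  cat(sprintf("  aperiodic: offset %.3f, exponent %.3f", x$aperiodic$offset,
              x$aperiodic$exponent))
  if (!is.null(x$aperiodic$knee)) cat(sprintf(", knee %.3f", x$aperiodic$knee))
  cat("\n")
  cat("  peaks:", nrow(x$peaks), "\n")
  if (nrow(x$peaks)) {
    df <- x$peaks
    df[] <- lapply(df, round, 3)
    print(df)
  }
  cat(sprintf("  R^2 %.4f, rmse %.4f\n", x$goodness$r_squared,
              x$goodness$rmse))
  invisible(x)
}

#' @export
summary.specparam <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.specparam <- function(object, ...) {
  out <- c(offset = object$aperiodic$offset,
           exponent = object$aperiodic$exponent)
  if (!is.null(object$aperiodic$knee))
    out <- c(out, knee = object$aperiodic$knee)
  out
}

#' Predict from a fitted spectral model
#'
#' @param object A \code{"specparam"} fit.
#' @param freqs Frequencies in Hz.
#' @param component \code{"full"}, \code{"aperiodic"} or \code{"periodic"}.
#' @param type \code{"log10"} (log10 power) or \code{"linear"} (power).
#' @param ... Unused.
#' @export
predict.specparam <- function(object, freqs = object$freq,
                              component = c("full", "aperiodic", "periodic"),
                              type = c("log10", "linear"), ...) {
  component <- match.arg(component)
  type <- match.arg(type)
  ap <- aperiodic_component(object, freqs)
  pk <- numeric(length(freqs))
  for (i in seq_len(nrow(object$peaks)))
    pk <- pk + gauss_log(freqs, object$peaks$cf[i], object$peaks$pw[i],
                         object$peaks$sigma[i])
  out <- switch(component, full = ap + pk, aperiodic = ap, periodic = pk)
  if (type == "linear") 10^out else out
}

#' @export
fitted.specparam <- function(object, ...) object$model_log10

#' @export
residuals.specparam <- function(object, ...)
  object$power_log10 - object$model_log10

#' @export
plot.specparam <- function(x, ...) {
  graphics::plot(x$freq, x$power_log10, type = "l", log = "x",
                 xlab = "Frequency (Hz)", ylab = "log10 PSD", ...)
  graphics::lines(x$freq, x$model_log10, col = "red")
  graphics::lines(x$freq, aperiodic_component(x), col = "blue", lty = 2)
  graphics::legend("bottomleft", c("data", "model", "aperiodic"),
                   col = c("black", "red", "blue"), lty = c(1, 1, 2),
                   bty = "n")
  invisible(x)
}

#' Sensitivity of the fitted exponent to a border-crossing peak
#'
#' Rescales the amplitude of one designated low-frequency peak of a
#' simulation recipe, refits each realization, and tabulates the estimated
#' exponent against the (constant) ground truth. Demonstrates how power in
#' an oscillation that crosses the lower fitting border biases the aperiodic
#' exponent even though the true aperiodic component never changes.
#'
#' @param base A \code{\link{sim_spec}} containing at least one peak.
#' @param scales Numeric amplitude multipliers (may be empty).
#' @param peak_index Which peak of \code{base} to rescale.
#' @param fit_range Fitting range in Hz.
#' @param segment_s Welch segment length in seconds.
#' @param ... Further arguments passed to \code{\link{specparam}}.
#' @return Data frame with columns \code{scale}, \code{beta_truth},
#'   \code{beta_hat} (NA where the fit failed).
#' @export
delta_sensitivity_experiment <- function(base, scales, peak_index = 1,
                                         fit_range = c(1, 95),
                                         segment_s = 1, ...) {
  stopifnot(inherits(base, "sim_spec"))
  if (length(scales) == 0)
    return(data.frame(scale = numeric(0), beta_truth = numeric(0),
                      beta_hat = numeric(0)))
  stopifnot(peak_index >= 1, peak_index <= length(base$peaks))
  a0 <- base$peaks[[peak_index]]$amplitude
  out <- lapply(scales, function(s) {
    sp <- base
    sp$peaks[[peak_index]]$amplitude <- a0 * s
    psd <- welch_psd(synthesize(sp), segment_s = segment_s)
    bh <- tryCatch(
      unname(coef(specparam(psd, fit_range, ...))["exponent"]),
      error = function(e) NA_real_)
    data.frame(scale = s, beta_truth = base$beta, beta_hat = bh)
  })
  do.call(rbind, out)
}
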