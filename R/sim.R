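#' Specify a Gaussian spectral peak
#'
#' Describes one oscillatory peak to be added to the constructed Fourier
#' power spectrum of a simulated series. The peak multiplies the aperiodic
#' power as \code{1 + amplitude * exp(-(f - f_center)^2 / (2 * sigma_f^2))},
#' so \code{amplitude} is the peak height relative to the aperiodic power at
#' the center frequency (dimensionless). Note that spectral parameterization
#' toolboxes instead define peak height additively in log10 power; the two
#' conventions agree only approximately for small amplitudes.
#'
#' @param f_center Center frequency in Hz (> 0).
#' @param amplitude Relative peak power gain (>= 0, linear power units).
#' @param sigma_f Spectral standard deviation in Hz (> 0).
#' @return An object of class \code{"peak_spec"}.
#' @export
peak_spec <- function(f_center, amplitude, sigma_f) {
  stopifnot(is.numeric(f_center), length(f_center) == 1L, f_center > 0,
            is.numeric(amplitude), length(amplitude) == 1L, amplitude >= 0,
            is.numeric(sigma_f), length(sigma_f) == 1L, sigma_f > 0)
  structure(list(f_center = f_center, amplitude = amplitude,
                 sigma_f = sigma_f), class = "peak_spec")
}

#' Specify a transient time-domain component
#'
#' Currently only zero-mean sawtooth segments are supported. The sawtooth
#' starts at a zero crossing (rising) at \code{start_s} and its amplitude is
#' half the peak-to-peak range.
#'
#' @param frequency Fundamental frequency in Hz (> 0).
#' @param amplitude Half peak-to-peak amplitude in time-domain units.
#' @param start_s,end_s Interval (seconds, within the series) over which the
#'   transient is added.
#' @param kind Transient type; only \code{"sawtooth"}.
#' @return An object of class \code{"transient_spec"}.
#' @export
transient_spec <- function(frequency, amplitude, start_s, end_s,
                           kind = "sawtooth") {
  kind <- match.arg(kind)
  stopifnot(frequency > 0, amplitude >= 0, start_s >= 0, start_s < end_s)
  structure(list(kind = kind, frequency = frequency, amplitude = amplitude,
                 start_s = start_s, end_s = end_s),
            class = "transient_spec")
}

#' Ground-truth recipe for one synthetic series
#'
#' Collects everything needed to synthesize a time series whose one-sided
#' Fourier power spectrum is known exactly: a 1/f^beta power law, optional
#' Gaussian peaks, additive white noise (which produces a high-frequency
#' spectral plateau), optional sawtooth transients and an optional zero-phase
#' highpass filter. The power-law normalization is chosen so that the
#' noiseless series has unit variance, which makes \code{white_noise_scale}
#' an SNR-like quantity.
#'
#' @param beta Aperiodic 1/f exponent (finite; 0 gives white spectrum).
#' @param duration_s Duration in seconds; \code{duration_s * f_sample} must
#'   be a positive integer.
#' @param f_sample Sampling rate in Hz; must exceed twice the largest peak
#'   center frequency.
#' @param peaks List of \code{\link{peak_spec}} objects.
#' @param white_noise_scale Standard deviation of additive Gaussian white
#'   noise in time-domain units (0 disables).
#' @param transients List of \code{\link{transient_spec}} objects.
#' @param highpass_hz Optional highpass cutoff in Hz (zero-phase 4th-order
#'   Butterworth, applied forwards and backwards).
#' @param lowpass_hz Optional lowpass cutoff in Hz (same filter type);
#'   emulates the acquisition bandwidth of recording hardware.
#' @param seed Integer seed; one generator draws the Fourier phases first and
#'   the white noise second, so partial specs stay reproducible.
#' @return An object of class \code{"sim_spec"}.
#' @export
sim_spec <- function(beta, duration_s = 180, f_sample = 2400,
                     peaks = list(), white_noise_scale = 0,
                     transients = list(), highpass_hz = NULL,
                     lowpass_hz = NULL, seed = 1L) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta),
            duration_s > 0, f_sample > 0, white_noise_scale >= 0)
  if (inherits(peaks, "peak_spec")) peaks <- list(peaks)
  if (inherits(transients, "transient_spec")) transients <- list(transients)
  stopifnot(all(vapply(peaks, inherits, logical(1), "peak_spec")),
            all(vapply(transients, inherits, logical(1), "transient_spec")))
  n <- duration_s * f_sample
  if (abs(n - round(n)) > 1e-8)
    stop("duration_s * f_sample must be an integer sample count, got ", n)
  for (p in peaks)
    if (p$f_center >= f_sample / 2)
      stop("peak at ", p$f_center, " Hz is at or above the Nyquist frequency ",
           f_sample / 2, " Hz")
  for (tr in transients)
    if (tr$end_s > duration_s)
      stop("transient interval (", tr$start_s, ", ", tr$end_s,
           ") s exceeds the series duration ", duration_s, " s")
  if (!is.null(highpass_hz))
    stopifnot(highpass_hz > 0, highpass_hz < f_sample / 2)
  if (!is.null(lowpass_hz))
    stopifnot(lowpass_hz > 0, lowpass_hz < f_sample / 2)
  structure(list(beta = beta, peaks = peaks, duration_s = duration_s,
                 f_sample = f_sample, white_noise_scale = white_noise_scale,
                 transients = transients, highpass_hz = highpass_hz,
                 lowpass_hz = lowpass_hz, seed = as.integer(seed)),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("Simulation recipe: 1/f^", x$beta, ", ", x$duration_s, " s at ",
      x$f_sample, " Hz\n", sep = "")
  if (length(x$peaks))
    cat("  peaks (Hz):",
        paste(vapply(x$peaks, function(p)
          sprintf("%g (A=%g, sigma=%g)", p$f_center, p$amplitude, p$sigma_f),
          character(1)), collapse = ", "), "\n")
  if (x$white_noise_scale > 0)
    cat("  white noise sd:", x$white_noise_scale, "\n")
  if (length(x$transients))
    cat("  transients:", length(x$transients), "\n")
  if (!is.null(x$highpass_hz))
    cat("  highpass:", x$highpass_hz, "Hz\n")
  if (!is.null(x$lowpass_hz))
    cat("  lowpass:", x$lowpass_hz, "Hz\n")
  invisible(x)
}

# One-sided constructed power spectrum on the full-series Fourier grid.
# Returns |X_k|^2 for k = 0 .. floor(n/2); DC is set to 0 (the power law
# diverges there and DC is excluded from every fit downstream). The
# normalization constant makes the noiseless series have unit variance.
#' Constructed Fourier power spectrum of a simulation recipe
#'
#' The exact one-sided power spectrum (squared Fourier magnitudes, before
#' phase randomization) that \code{\link{synthesize}} realizes. Useful as a
#' noise-free oracle for fit-recovery checks.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @return List with \code{freq} (Hz, 0..Nyquist) and \code{power}
#'   (squared magnitudes on the length-n discrete Fourier grid).
#' @export
constructed_spectrum <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- round(spec$duration_s * spec$f_sample)
  k <- 0:(n %/% 2)
  f <- k * spec$f_sample / n
  u <- numeric(length(f))
  u[-1] <- f[-1] ^ (-spec$beta)
  for (p in spec$peaks)
    u[-1] <- u[-1] *
      (1 + p$amplitude * exp(-(f[-1] - p$f_center)^2 / (2 * p$sigma_f^2)))
  # variance of the synthesized series is sum(|X_k|^2) / n^2 over all n bins
  s <- 2 * sum(u)
  if (n %% 2 == 0) s <- s - u[length(u)]  # Nyquist bin is not doubled
  cc <- n^2 / s
  list(freq = f, power = cc * u)
}

#' Ground-truth power spectral density of a simulation recipe
#'
#' Evaluates the exact expected one-sided PSD (units^2/Hz) of the recipe on
#' an arbitrary frequency grid, for comparison with Welch estimates.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @param freqs Frequencies in Hz (> 0).
#' @param component \code{"full"} includes peaks and the white-noise floor,
#'   \code{"aperiodic"} is the power law plus noise floor,
#'   \code{"aperiodic_noiseless"} is the pure power law.
#' @return Numeric vector of spectral densities.
#' @export
ground_truth_psd <- function(spec, freqs,
                             component = c("full", "aperiodic",
                                           "aperiodic_noiseless")) {
  component <- match.arg(component)
  stopifnot(inherits(spec, "sim_spec"), all(freqs > 0))
  n <- round(spec$duration_s * spec$f_sample)
  cs <- constructed_spectrum(spec)
  cc <- cs$power[2] / (cs$freq[2] ^ (-spec$beta) *
    prod(vapply(spec$peaks, function(p)
      1 + p$amplitude * exp(-(cs$freq[2] - p$f_center)^2 / (2 * p$sigma_f^2)),
      numeric(1))))
  u <- freqs ^ (-spec$beta)
  if (component == "full")
    for (p in spec$peaks)
      u <- u * (1 + p$amplitude *
                  exp(-(freqs - p$f_center)^2 / (2 * p$sigma_f^2)))
  # |X|^2 -> one-sided density: 2 |X|^2 / (n * f_sample)
  dens <- 2 * cc * u / (n * spec$f_sample)
  if (component != "aperiodic_noiseless" && spec$white_noise_scale > 0)
    dens <- dens + 2 * spec$white_noise_scale^2 / spec$f_sample
  dens
}

#' Wrap a numeric vector as a time series
#'
#' @param samples Numeric vector of finite values.
#' @param f_sample Sampling rate in Hz.
#' @param spec Optional \code{\link{sim_spec}} provenance.
#' @return Object of class \code{"neuro_ts"}.
#' @export
as_timeseries <- function(samples, f_sample, spec = NULL) {
  stopifnot(is.numeric(samples), length(samples) > 0, all(is.finite(samples)),
            f_sample > 0)
  structure(list(samples = as.numeric(samples), f_sample = f_sample,
                 spec = spec), class = "neuro_ts")
}

#' @export
print.neuro_ts <- function(x, ...) {
  cat("Time series: ", length(x$samples), " samples at ", x$f_sample,
      " Hz (", length(x$samples) / x$f_sample, " s)\n", sep = "")
  if (!is.null(x$spec))
    cat("  simulated, 1/f exponent", x$spec$beta, "\n")
  invisible(x)
}

# Run code with a private RNG stream without disturbing the caller's seed.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Synthesize a time series with exactly known spectral structure
#'
#' Builds the one-sided Fourier power spectrum
#' \code{C * f^-beta * (1 + sum of Gaussian peak terms)}, draws uniform
#' random phases, and inverse-transforms to obtain a real series whose
#' periodogram equals the constructed spectrum bin for bin. White noise,
#' transients and the highpass filter (in that order) are then applied in
#' the time domain.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @return A \code{"neuro_ts"} carrying the recipe as provenance.
#' @export
synthesize <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- round(spec$duration_s * spec$f_sample)
  cs <- constructed_spectrum(spec)
  amp <- sqrt(cs$power)            # |X_k| for k = 0 .. floor(n/2)
  nyq_bin <- if (n %% 2 == 0) n %/% 2 + 1L else NA_integer_
  k_half <- if (n %% 2 == 0) (n %/% 2 - 1L) else n %/% 2  # conjugated bins
  x <- with_seed(spec$seed, {
    phases <- stats::runif(k_half, 0, 2 * pi)
    nyq_sign <- if (n %% 2 == 0) sign(stats::runif(1) - 0.5) else NULL
    X <- complex(n)
    X[2:(k_half + 1L)] <- amp[2:(k_half + 1L)] * exp(1i * phases)
    X[n:(n - k_half + 1L)] <- Conj(X[2:(k_half + 1L)])
    if (!is.na(nyq_bin)) X[nyq_bin] <- nyq_sign * amp[nyq_bin]
    out <- Re(stats::fft(X, inverse = TRUE)) / n
    if (spec$white_noise_scale > 0)
      out <- out + stats::rnorm(n, 0, spec$white_noise_scale)
    out
  })
  ts <- as_timeseries(x, spec$f_sample, spec = spec)
  for (tr in spec$transients) ts <- inject_transient(ts, tr)
  if (!is.null(spec$highpass_hz)) {
    bf <- signal::butter(4, 2 * spec$highpass_hz / spec$f_sample,
                         type = "high")
    ts$samples <- as.numeric(signal::filtfilt(bf, ts$samples))
  }
  if (!is.null(spec$lowpass_hz)) {
    bf <- signal::butter(4, 2 * spec$lowpass_hz / spec$f_sample,
                         type = "low")
    ts$samples <- as.numeric(signal::filtfilt(bf, ts$samples))
  }
  ts$spec <- spec
  ts
}

# Zero-mean sawtooth, rising through zero at t_rel = 0, amplitude = half
# peak-to-peak.
sawtooth_wave <- function(t_rel, frequency, amplitude) {
  amplitude * (2 * ((frequency * t_rel + 0.5) %% 1) - 1)
}

#' Add a transient sawtooth segment to a time series
#'
#' Samples outside the transient interval are unchanged; inside, a zero-mean
#' sawtooth of the given frequency and amplitude is added.
#'
#' @param ts A \code{"neuro_ts"}.
#' @param transient A \code{\link{transient_spec}}.
#' @return The modified time series.
#' @export
inject_transient <- function(ts, transient) {
  stopifnot(inherits(ts, "neuro_ts"), inherits(transient, "transient_spec"))
  dur <- length(ts$samples) / ts$f_sample
  if (transient$end_s > dur || transient$start_s < 0)
    stop("transient interval (", transient$start_s, ", ", transient$end_s,
         ") s is outside the series (0, ", dur, ") s")
  i0 <- floor(transient$start_s * ts$f_sample) + 1L
  i1 <- min(length(ts$samples), ceiling(transient$end_s * ts$f_sample))
  idx <- i0:i1
  t_rel <- (idx - i0) / ts$f_sample
  ts$samples[idx] <- ts$samples[idx] +
    sawtooth_wave(t_rel, transient$frequency, transient$amplitude)
  ts
}

#' Calibrate the white-noise scale for a target plateau onset
#'
#' Finds by monotone bisection the additive white-noise standard deviation at
#' which the sliding-window plateau detector reports its onset at
#' \code{target_onset_hz}. Raising the noise floor lowers the frequency at
#' which the spectrum flattens, so the detector onset is monotone decreasing
#' in the noise scale. The detector runs on the Welch PSD averaged over
#' \code{n_seeds} fresh realizations.
#'
#' @param spec A \code{\link{sim_spec}} (its \code{white_noise_scale} is
#'   ignored); should have no peaks inside the detection band.
#' @param target_onset_hz Desired plateau onset in Hz.
#' @param start_hz,window_hz,step_hz,beta_thresh Detector settings, see
#'   \code{\link{detect_plateau_onset}}.
#' @param segment_s Welch segment length in seconds.
#' @param n_seeds Realizations averaged per bisection step.
#' @param n_batches Independent calibration repetitions pooled by geometric
#'   mean; the detector's first-hit jitter makes a single repetition a
#'   noisy draw, and pooling only reduces that variance.
#' @param lower,upper Initial noise-scale bracket; \code{upper = NULL} grows
#'   the bracket automatically.
#' @param max_iter Bisection iteration cap.
#' @return The calibrated noise standard deviation, with attribute
#'   \code{"onset_hz"} giving the achieved onset.
#' @export
calibrate_noise_for_plateau <- function(spec, target_onset_hz,
                                        start_hz = 1, window_hz = 50,
                                        step_hz = 1, beta_thresh = 0.05,
                                        segment_s = 1, n_seeds = 10,
                                        n_batches = 3, lower = 1e-4,
                                        upper = NULL, max_iter = 40) {
  stopifnot(inherits(spec, "sim_spec"), target_onset_hz > 0)
  nyq <- spec$f_sample / 2
  if (target_onset_hz <= start_hz || target_onset_hz >= nyq - window_hz)
    stop("target onset must lie within (start_hz, Nyquist - window_hz)")

  onset_at <- function(w, batch) {
    s2 <- spec
    s2$white_noise_scale <- w
    pw <- NULL
    for (i in seq_len(n_seeds)) {
      s2$seed <- spec$seed + batch * 13000L + (i - 1L) * 1000L
      psd <- welch_psd(synthesize(s2), segment_s = segment_s)
      pw <- if (is.null(pw)) psd$power else pw + psd$power
    }
    psd$power <- pw / n_seeds
    rep <- detect_plateau_onset(psd, start_hz = start_hz,
                                window_hz = window_hz, step_hz = step_hz,
                                beta_thresh = beta_thresh)
    if (is.na(rep$onset_hz)) Inf else rep$onset_hz
  }

  # The detector onset is an integer-valued, locally jagged function of the
  # noise scale, so one bisection pass may skip the target reading
  # entirely. Each attempt bisects against one fixed batch of detector
  # realizations, keeping the best candidate seen; if the best reading is
  # not within the acceptance tolerance, a fresh batch is tried.
  accept_tol <- 3 * step_hz
  batch_w <- numeric(0)
  batch_onset <- numeric(0)
  best_w <- NA_real_
  best_onset <- NA_real_
  best_gap <- Inf
  for (batch in seq_len(n_batches + 3) - 1L) {
    if (length(batch_w) >= n_batches) break
    best_gap <- Inf
    lo <- lower
    o_lo <- onset_at(lo, batch)
    if (o_lo < target_onset_hz)
      stop("bracket failure: plateau onset at the lower noise bracket (",
           o_lo, " Hz) is already below the target ", target_onset_hz,
           " Hz")
    if (is.null(upper)) {
      hi <- 0.5
      o_hi <- onset_at(hi, batch)
      tries <- 0
      while (o_hi > target_onset_hz && tries < 8) {
        hi <- hi * 4
        o_hi <- onset_at(hi, batch)
        tries <- tries + 1
      }
      if (o_hi > target_onset_hz)
        stop("bracket failure: upper noise bracket insufficient (onset ",
             o_hi, " Hz, target ", target_onset_hz, " Hz)")
    } else {
      hi <- upper
      o_hi <- onset_at(hi, batch)
      if (o_hi > target_onset_hz)
        stop("bracket failure: upper noise bracket insufficient (onset ",
             o_hi, " Hz, target ", target_onset_hz, " Hz)")
    }
    for (i in seq_len(max_iter)) {
      mid <- sqrt(lo * hi)        # bisect on a log scale
      onset <- onset_at(mid, batch)
      gap <- abs(onset - target_onset_hz)
      if (is.finite(gap) && gap < best_gap) {
        best_gap <- gap
        best_w <- mid
        best_onset <- onset
      }
      if (gap <= step_hz) break
      if (onset > target_onset_hz) lo <- mid else hi <- mid
      if (hi / lo < 1 + 1e-3) break
    }
    if (best_gap <= accept_tol) {
      batch_w <- c(batch_w, best_w)
      batch_onset <- c(batch_onset, best_onset)
    }
  }
  if (length(batch_w) == 0)
    stop("calibration did not converge near the target onset (reached ",
         best_onset, " Hz)")
  # pool independent batches: each calibrated scale is an unbiased draw of
  # the same stochastic procedure, so the geometric mean only reduces its
  # variance
  structure(exp(mean(log(batch_w))), onset_hz = mean(batch_onset))
}
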